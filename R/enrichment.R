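#' Target enrichment per community
#'
#' For each community `i`, `D(i) = i_D / |D|` is the share of all known
#' targets falling in `i` and `PT(i) = i_PT / |PT|` the share of pending
#' proteins. Their ratio `rd(i) = D(i) / PT(i)` measures how target-like the
#' community is: `rd(i) > 1` means targets are over-represented relative to
#' the global target/pending balance. "Pending" here is all non-targets
#' (PT1 and PT2 together).
#'
#' @param partition A `community_partition` or a named community membership
#'   vector.
#' @param labels A `labeled_proteome` with at least one target and one
#'   pending protein among the partitioned nodes.
#' @param pool_small If `TRUE` and `partition` is a `community_partition`,
#'   communities below its `min_report_size` are pooled into one `"other"`
#'   row before computing shares.
#' @return A tibble with one row per community: `community`, `n_target`,
#'   `n_pending`, `target_share`, `pending_share`, `rd`, `target_like`.
#'   `rd` is `Inf` when a community has targets but no pending proteins and
#'   `NA` when it has neither.
#' @export
community_enrichment <- function(partition, labels, pool_small = FALSE) {
  memb <- if (inherits(partition, "community_partition")) partition$membership else partition
  comm <- as.character(memb)
  names(comm) <- names(memb)
  if (pool_small && inherits(partition, "community_partition")) {
    small <- partition$sizes$community[!partition$sizes$main]
    comm[comm %in% as.character(small)] <- "other"
  }
  sets <- label_sets(labels)
  d_ids <- intersect(sets$D, names(comm))
  pt_ids <- intersect(sets$PT, names(comm))
  if (length(d_ids) == 0) abort("Community enrichment requires at least one target in the partition.")
  if (length(pt_ids) == 0) abort("Community enrichment requires at least one pending protein in the partition.")
  lvls <- unique(comm)
  lvls <- lvls[order(suppressWarnings(as.numeric(lvls)), lvls, na.last = TRUE)]
  n_d <- table(factor(comm[d_ids], levels = lvls))
  n_pt <- table(factor(comm[pt_ids], levels = lvls))
  out <- tibble(
    community = lvls,
    n_target = as.integer(n_d),
    n_pending = as.integer(n_pt),
    target_share = as.integer(n_d) / length(d_ids),
    pending_share = as.integer(n_pt) / length(pt_ids)
  ) |>
    mutate(
      rd = dplyr::case_when(
        .data$n_pending > 0 ~ .data$target_share / .data$pending_share,
        .data$n_target > 0 ~ Inf,
        TRUE ~ NA_real_
      ),
      target_like = .data$rd > 1
    )
  out
}

#' Target enrichment per coreness level
#'
#' For each occupied coreness level `k`, `p_k^D` and `p_k^PT` are the
#' proportions of targets and pending proteins whose coreness is exactly `k`
#' (or at least `k` with `cumulative = TRUE`, i.e. membership in the k-core).
#' These are normalized by the global target and pending ratios:
#' `rc_D(k) = p_k^D / DR`, `rc_PT(k) = p_k^PT / PR`. `rc_D(k) > 1` flags a
#' target-dominated shell.
#'
#' @param coreness Named integer vector of coreness values (from
#'   [node_coreness()]).
#' @param labels A `labeled_proteome`.
#' @param cumulative If `TRUE`, proportions count membership in the k-core
#'   (coreness >= k) instead of the coreness-k shell.
#' @return A tibble with one row per occupied level: `k`, `n_target`,
#'   `n_pending`, `p_target`, `p_pending`, `rc_target`, `rc_pending`,
#'   `rc_ratio` (= `p_target / p_pending`, the direct analogue of `rd`:
#'   equal to 1 when targets and pending proteins share the same coreness
#'   distribution), `target_dominated` (`rc_target > 1`).
#' @export
coreness_enrichment <- function(coreness, labels, cumulative = FALSE) {
  sets <- label_sets(labels)
  d_ids <- intersect(sets$D, names(coreness))
  pt_ids <- intersect(sets$PT, names(coreness))
  if (length(d_ids) == 0) abort("Coreness enrichment requires at least one target.")
  if (length(pt_ids) == 0) abort("Coreness enrichment requires at least one pending protein.")
  n <- length(d_ids) + length(pt_ids)
  dr <- length(d_ids) / n
  pr <- length(pt_ids) / n
  ks <- sort(unique(coreness[c(d_ids, pt_ids)]))
  rows <- purrr::map(ks, function(k) {
    in_level <- if (cumulative) coreness >= k else coreness == k
    nd <- sum(in_level[d_ids])
    npt <- sum(in_level[pt_ids])
    if (nd + npt == 0) return(NULL)
    tibble(
      k = as.integer(k), n_target = nd, n_pending = npt,
      p_target = nd / length(d_ids), p_pending = npt / length(pt_ids)
    )
  })
  bind_rows(rows) |>
    mutate(
      rc_target = .data$p_target / dr,
      rc_pending = .data$p_pending / pr,
      rc_ratio = .data$p_target / .data$p_pending,
      target_dominated = .data$rc_target > 1
    )
}
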