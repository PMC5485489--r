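#' Modularity of a partition
#'
#' `Q = (1/2m) * sum_ij [A_ij - k_i k_j / 2m] delta(c_i, c_j)`: the excess of
#' intra-community edge weight over a degree-preserving random null.
#'
#' @param net An igraph network with at least one edge.
#' @param partition A `community_partition`, or a vector of community labels
#'   named by protein identifier covering every node.
#' @return The modularity `Q` as a single number.
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- letters[1:4]
#' modularity_score(g, c(a = 1, b = 1, c = 1, d = 1))  # 0
#' @export
modularity_score <- function(net, partition) {
  if (igraph::gsize(net) == 0) abort("Modularity is undefined on a network with no edges.")
  memb <- if (inherits(partition, "community_partition")) partition$membership else partition
  ids <- igraph::V(net)$name
  if (is.null(names(memb)) || !all(ids %in% names(memb))) {
    abort("`partition` must be named by protein identifier and cover every node.")
  }
  igraph::modularity(net, as.integer(factor(memb[ids])))
}

#' Detect communities by greedy modularity maximization
#'
#' Louvain-style multi-level maximization of modularity. The node visitation
#' order of the underlying routine is driven by R's RNG, so a fixed `seed`
#' makes the result deterministic. Communities are renumbered 1..K by
#' decreasing size; communities smaller than `min_report_size` are flagged as
#' non-main and can be pooled into an "other" bucket by the enrichment
#' reporting, mirroring the reduction of many detected communities to a few
#' main ones.
#'
#' @param net An igraph network with at least one edge.
#' @param seed Integer seed controlling the (otherwise arbitrary) visitation
#'   order.
#' @param min_report_size Minimum size for a community to count as "main".
#' @return A `community_partition` object with elements `membership` (named
#'   integer vector), `modularity`, `sizes` (tibble with `community`, `size`,
#'   `main`), `min_report_size`, `seed`.
#' @export
detect_communities <- function(net, seed = 1L, min_report_size = 50L) {
  if (igraph::gsize(net) == 0) abort("Community detection requires at least one edge.")
  cl <- withr::with_seed(as.integer(seed), igraph::cluster_louvain(net))
  memb <- igraph::membership(cl)
  # renumber by decreasing size, ties by smallest original index
  tab <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(tab), names(tab))
  memb2 <- setNames(as.integer(relabel[as.character(memb)]), igraph::V(net)$name)
  sizes <- tibble(community = seq_along(tab), size = as.integer(tab)) |>
    mutate(main = .data$size >= min_report_size)
  structure(
    list(
      membership = memb2,
      modularity = modularity_score(net, memb2),
      sizes = sizes,
      min_report_size = as.integer(min_report_size),
      seed = as.integer(seed),
      method = "louvain"
    ),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition>\n")
  cat(sprintf("  %d communities (%d main, >= %d nodes), Q = %.4f, seed = %d\n",
              nrow(x$sizes), sum(x$sizes$main), x$min_report_size,
              x$modularity, x$seed))
  invisible(x)
}

#' @describeIn detect_communities Per-protein community assignments.
#' @param x A `community_partition`.
#' @param ... Unused.
#' @export
tidy.community_partition <- function(x, ...) {
  tibble(protein = names(x$membership),
         community = unname(x$membership)) |>
    left_join(x$sizes, by = "community") |>
    select("protein", "community", "main")
}

#' @describeIn detect_communities One-row summary (counts, Q, seed).
#' @export
glance.community_partition <- function(x, ...) {
  tibble(n_communities = nrow(x$sizes), n_main = sum(x$sizes$main),
         modularity = x$modularity, seed = x$seed)
}
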