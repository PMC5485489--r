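#' Specification for a synthetic labeled interaction network
#'
#' Describes a degree-corrected planted-partition network plus planted
#' target labels and a chemical-physical feature table, emulating the
#' statistical structure of a curated drug-target interactome: a power-law
#' degree tail, a small labeled target fraction (about 1.2% of proteins),
#' concentration of targets in a few communities, optional concentration in
#' particular coreness shells, and a feature table of 39 properties
#' available only for a featured subset.
#'
#' @param n Number of proteins.
#' @param n_communities Number of planted communities; sizes are as equal as
#'   possible unless `sizes` is given.
#' @param sizes Optional integer vector of community sizes summing to `n`.
#' @param mixing Mixing parameter in `[0, 1]`: approximate fraction of each
#'   protein's expected degree that ignores community structure. `mixing = 1`
#'   recovers the degree-corrected random null (true-partition modularity
#'   near 0); small values give strong, recoverable communities.
#' @param exponent Exponent of the truncated power law from which expected
#'   degrees are drawn (default 2.5).
#' @param min_degree Lower cutoff of the expected-degree distribution.
#' @param mean_degree Target mean degree after rescaling (default 12,
#'   matching the order of curated interactomes).
#' @param n_targets Number of planted drug targets (default 1.2% of `n`).
#' @param target_rr Named numeric vector of per-community relative risks:
#'   the planted target-like ratio rd of those communities. Names are
#'   community indices. The default enriches communities 1-3 so that they
#'   jointly hold roughly two thirds of all targets.
#' @param coreness_levels Optional integer vector; when given, targets are
#'   drawn only from proteins whose coreness lies in these levels.
#' @param pt1_fraction Fraction of non-target proteins carrying the feature
#'   table (default 0.105, the order of the curated data).
#' @param n_features Number of chemical-physical properties (default 39).
#' @param n_informative Number of features whose class-conditional means
#'   differ (default 10).
#' @param effect_size Mean shift of informative features for targets, in
#'   noise standard deviations.
#' @param noise_sd Feature noise standard deviation (default 1).
#' @return A `synthetic_spec` object (validated list).
#' @export
synthetic_spec <- function(n = 3000, n_communities = 12, sizes = NULL,
                           mixing = 0.15, exponent = 2.5, min_degree = 2,
                           mean_degree = 12,
                           n_targets = max(10L, round(0.012 * n)),
                           target_rr = c("1" = 2.6, "2" = 2.6, "3" = 2.6),
                           coreness_levels = NULL, pt1_fraction = 0.105,
                           n_features = 39, n_informative = 10,
                           effect_size = 1, noise_sd = 1) {
  if (is.null(sizes)) {
    sizes <- rep(n %/% n_communities, n_communities)
    sizes[seq_len(n %% n_communities)] <- sizes[seq_len(n %% n_communities)] + 1L
  }
  if (sum(sizes) != n) abort("`sizes` must sum to `n`.")
  if (mixing < 0 || mixing > 1) abort("`mixing` must be in [0, 1].")
  if (exponent <= 1) abort("`exponent` must exceed 1.")
  if (n_targets < 0 || n_targets > n) abort("`n_targets` must be in [0, n].")
  if (any(target_rr < 0)) abort("Relative risks must be nonnegative.")
  if (n_informative > n_features) abort("`n_informative` cannot exceed `n_features`.")
  if (effect_size < 0) abort("`effect_size` must be nonnegative.")
  structure(
    list(n = as.integer(n), n_communities = length(sizes),
         sizes = as.integer(sizes), mixing = mixing, exponent = exponent,
         min_degree = min_degree, mean_degree = mean_degree,
         n_targets = as.integer(n_targets), target_rr = target_rr,
         coreness_levels = coreness_levels, pt1_fraction = pt1_fraction,
         n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         effect_size = effect_size, noise_sd = noise_sd),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> n = %d, %d communities, mixing = %.2f, exponent = %.2f\n",
              x$n, x$n_communities, x$mixing, x$exponent))
  cat(sprintf("  targets: %d, enriched communities: %s\n", x$n_targets,
              if (length(x$target_rr)) paste0(names(x$target_rr), " (rr ",
                                              x$target_rr, ")", collapse = ", ") else "none"))
  invisible(x)
}

node_names <- function(n) sprintf(paste0("P%0", max(4, nchar(n)), "d"), seq_len(n))

# expected degrees from a truncated power law, rescaled to the target mean
draw_propensities <- function(spec) {
  alpha <- spec$exponent
  xmin <- spec$min_degree
  cap <- sqrt(spec$n * spec$mean_degree)
  u <- runif(spec$n)
  # inverse CDF of the Pareto truncated at cap
  fmax <- 1 - (cap / xmin)^(1 - alpha)
  w <- xmin * (1 - u * fmax)^(1 / (1 - alpha))
  w <- w * spec$mean_degree / mean(w)
  pmin(w, cap)
}

#' Generate a degree-corrected planted-partition network
#'
#' Samples a simple undirected graph whose expected degrees follow a
#' truncated power law and whose edges are biased toward planted community
#' blocks. Edges are drawn by Poisson block sampling with endpoints chosen
#' proportional to degree propensity; multi-edges and self-loops are
#' discarded. Unless `connect = FALSE`, any components detached from the
#' giant component are attached to it by a single edge between the
#' highest-propensity nodes involved, so the result is connected with the
#' planted structure intact.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the generator is fully deterministic given
#'   `spec` and `seed`.
#' @param connect Attach stray components to the giant component
#'   (default `TRUE`).
#' @return A list with `network` (igraph), `membership` (named integer
#'   vector, the planted partition), `propensity` (named numeric vector of
#'   expected degrees), and `spec`.
#' @export
generate_network <- function(spec, seed = 1L, connect = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$mean_degree >= spec$n) abort("Expected degree exceeds network size; infeasible spec.")
  withr::with_seed(as.integer(seed), {
    ids <- node_names(spec$n)
    memb <- rep(seq_len(spec$n_communities), spec$sizes)
    w <- draw_propensities(spec)
    W <- sum(w)
    Wc <- tapply(w, memb, sum)
    mu <- spec$mixing
    K <- spec$n_communities
    from <- to <- vector("list", K * (K + 1) / 2)
    slot <- 0L
    for (a in seq_len(K)) {
      idx_a <- which(memb == a)
      for (b in a:K) {
        slot <- slot + 1L
        omega <- if (a == b) (1 - mu) * W / Wc[a] + mu else mu
        lam <- if (a == b) omega * Wc[a]^2 / (2 * W) else omega * Wc[a] * Wc[b] / W
        m_ab <- rpois(1, lam)
        if (m_ab == 0) next
        idx_b <- which(memb == b)
        from[[slot]] <- sample(idx_a, m_ab, replace = TRUE, prob = w[idx_a])
        to[[slot]] <- sample(idx_b, m_ab, replace = TRUE, prob = w[idx_b])
      }
    }
    edges <- data.frame(from = ids[unlist(from)], to = ids[unlist(to)])
    net <- protein_network(edges, nodes = ids)
    names(memb) <- names(w) <- ids
    if (connect) {
      comp <- igraph::components(net)
      if (comp$no > 1) {
        giant <- which.max(comp$csize)
        anchors <- character(0)
        for (k in setdiff(seq_len(comp$no), giant)) {
          members <- ids[comp$membership == k]
          src <- members[which.max(w[members])]
          cand <- ids[comp$membership == giant & memb == memb[src]]
          if (length(cand) == 0) cand <- ids[comp$membership == giant]
          dst <- cand[which.max(w[cand])]
          anchors <- c(anchors, src, dst)
        }
        net <- igraph::add_edges(net, anchors)
      }
    }
    list(network = net, membership = memb, propensity = w, spec = spec)
  })
}

# target allocation shares across communities so that the planted rd of an
# enriched community equals its stated relative risk in expectation
target_allocation <- function(spec, memb) {
  sizes <- as.numeric(table(memb))
  s <- sizes / sum(sizes)
  n <- length(memb)
  nd <- spec$n_targets
  f <- setNames(rep(NA_real_, length(s)), seq_along(s))
  rr_idx <- as.integer(names(spec$target_rr))
  if (length(rr_idx) && any(rr_idx > length(s))) {
    abort("`target_rr` names a community beyond the planted partition.")
  }
  for (i in seq_along(rr_idx)) {
    c_i <- rr_idx[i]
    rho <- spec$target_rr[i]
    f[c_i] <- rho * s[c_i] * n / (n - nd + rho * nd)
  }
  enriched_mass <- sum(f, na.rm = TRUE)
  if (enriched_mass >= 1) {
    abort("Unsatisfiable target allocation: enriched communities absorb the whole target mass; lower `target_rr` or the enriched community sizes.")
  }
  base <- which(is.na(f))
  f[base] <- (1 - enriched_mass) * s[base] / sum(s[base])
  f
}

#' Plant drug-target labels on a synthetic network
#'
#' Samples the target set so that (a) each enriched community attains its
#' stated target-like ratio rd in expectation, (b) targets may optionally be
#' confined to stated coreness shells, and (c) the target degree
#' distribution matches the non-target distribution by stratified sampling
#' within global degree deciles — so that, by construction, targets are not
#' hubs. Non-target proteins are split into a featured set (PT1) and the
#' remainder (PT2).
#'
#' @param net An igraph network (from [generate_network()]).
#' @param partition Named integer vector: planted community membership.
#' @param spec The [synthetic_spec()] used for generation.
#' @param seed Integer seed.
#' @return A list with `labels` (a `labeled_proteome`) and `truth` (planted
#'   allocation shares, enriched communities, target identifiers).
#' @export
plant_target_labels <- function(net, partition, spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_targets == 0) abort("`n_targets` must be positive to plant labels.")
  ids <- igraph::V(net)$name
  partition <- partition[ids]
  withr::with_seed(as.integer(seed), {
    eligible <- ids
    if (!is.null(spec$coreness_levels)) {
      kc <- node_coreness(net)
      eligible <- ids[kc[ids] %in% spec$coreness_levels]
    }
    deg <- node_degree(net)
    breaks <- unique(quantile(deg, probs = seq(0, 1, 0.1), type = 1))
    decile <- cut(deg, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    names(decile) <- names(deg)
    f <- target_allocation(spec, partition)
    n_per_comm <- as.integer(rmultinom(1, spec$n_targets, f))
    targets <- character(0)
    for (c_i in seq_along(n_per_comm)) {
      need <- n_per_comm[c_i]
      if (need == 0) next
      pool <- eligible[partition[eligible] == c_i]
      if (length(pool) < need) {
        abort(sprintf("Unsatisfiable constraint: community %d offers %d eligible proteins but needs %d targets (binding constraint: %s).",
                      c_i, length(pool), need,
                      if (is.null(spec$coreness_levels)) "community size" else "coreness levels"))
      }
      # allocate across degree deciles proportional to the pool's composition
      dec_tab <- table(decile[pool])
      alloc <- floor(need * as.numeric(dec_tab) / length(pool))
      rem <- need - sum(alloc)
      if (rem > 0) {
        frac <- need * as.numeric(dec_tab) / length(pool) - alloc
        alloc[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
          alloc[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
      }
      for (j in seq_along(dec_tab)) {
        if (alloc[j] == 0) next
        cell <- pool[decile[pool] == as.integer(names(dec_tab)[j])]
        take <- min(alloc[j], length(cell))
        targets <- c(targets, sample(cell, take))
      }
    }
    pending <- setdiff(ids, targets)
    n_pt1 <- round(spec$pt1_fraction * length(pending))
    pt1 <- sample(pending, n_pt1)
    labels <- assign_labels(net, targets, featured = c(targets, pt1))
    truth <- list(
      target_ids = sort(targets),
      allocation = tibble(community = seq_along(f), share = unname(f)),
      enriched = tibble(community = as.integer(names(spec$target_rr)),
                        rr = unname(spec$target_rr))
    )
    list(labels = labels, truth = truth)
  })
}

#' Generate a synthetic chemical-physical feature table
#'
#' Class-conditional Gaussian features for the featured proteins (targets
#' and PT1): non-targets have mean 0 in every property; targets have mean
#' `effect_size` (in noise standard deviations) on the first
#' `n_informative` properties and 0 elsewhere.
#'
#' @param labels A `labeled_proteome`.
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A list with `features` (tibble: `protein` plus `cp01`...) and
#'   `truth` (informative property names and planted effect size).
#' @export
generate_feature_table <- function(labels, spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sets <- label_sets(labels)
  rows <- sort(c(sets$D, sets$PT1))
  p <- spec$n_features
  cols <- sprintf("cp%02d", seq_len(p))
  withr::with_seed(as.integer(seed), {
    x <- matrix(rnorm(length(rows) * p, sd = spec$noise_sd), length(rows), p,
                dimnames = list(rows, cols))
    inform <- cols[seq_len(spec$n_informative)]
    x[rows %in% sets$D, seq_len(spec$n_informative)] <-
      x[rows %in% sets$D, seq_len(spec$n_informative)] +
      spec$effect_size * spec$noise_sd
    features <- dplyr::bind_cols(tibble(protein = rows), as_tibble(x))
    list(features = features,
         truth = list(informative = inform,
                      effect_size = spec$effect_size))
  })
}

#' Generate a complete synthetic study (network, labels, features)
#'
#' Convenience wrapper running [generate_network()],
#' [plant_target_labels()] and [generate_feature_table()] with sub-seeds
#' derived from `seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A list `network`, `membership`, `labels`, `features`, `truth`,
#'   `spec`.
#' @export
generate_study <- function(spec = synthetic_spec(), seed = 1L) {
  seed <- as.integer(seed)
  gen <- generate_network(spec, seed = seed)
  lab <- plant_target_labels(gen$network, gen$membership, spec,
                             seed = seed + 1L)
  feat <- generate_feature_table(lab$labels, spec, seed = seed + 2L)
  list(network = gen$network, membership = gen$membership,
       labels = lab$labels, features = feat$features,
       truth = c(lab$truth, feat$truth), spec = spec)
}

#' Deterministic hand-checkable fixture
#'
#' A 16-protein connected network built from an explicit edge list: two
#' 5-cliques joined by a bridge, a path, and a pendant triangle — small
#' enough that every topological index can be verified by hand or exhaustive
#' enumeration. Ships with labels (three targets in the first clique) and a
#' deterministic 39-property feature table for the featured proteins.
#'
#' @return A list `network`, `labels`, `features`, `membership` (the obvious
#'   two-block partition used in examples).
#' @export
tiny_fixture <- function() {
  edges <- rbind(
    t(utils::combn(c("T1", "T2", "T3", "P01", "P02"), 2)),  # clique 1
    t(utils::combn(c("P03", "P04", "P05", "P06", "P07"), 2)),  # clique 2
    c("P01", "P03"),                                        # bridge
    cbind(c("P07", "P08", "P09"), c("P08", "P09", "P10")),  # path
    cbind(c("P10", "P10", "P11"), c("P11", "P12", "P12")),  # triangle
    c("P12", "P13")                                         # pendant
  )
  net <- protein_network(data.frame(from = edges[, 1], to = edges[, 2]))
  labels <- assign_labels(
    net,
    target_ids = c("T1", "T2", "T3"),
    featured_ids = c("T1", "T2", "T3", "P01", "P02", "P03", "P04", "P05")
  )
  spec <- synthetic_spec(n = 16, n_communities = 2, sizes = c(8L, 8L),
                         n_targets = 3, target_rr = c("1" = 2),
                         n_features = 39, n_informative = 5, effect_size = 2)
  features <- generate_feature_table(labels, spec, seed = 42L)$features
  memb <- setNames(c(rep(1L, 5), rep(2L, 11)),
                   c("T1", "T2", "T3", "P01", "P02", "P03", "P04", "P05",
                     "P06", "P07", "P08", "P09", "P10", "P11", "P12", "P13"))
  list(network = net, labels = labels, features = features, membership = memb)
}
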