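#' Node degree
#'
#' Number of interaction partners of each protein.
#'
#' @param net An igraph network.
#' @return Named integer vector, one entry per node.
#' @export
node_degree <- function(net) {
  d <- igraph::degree(net)
  storage.mode(d) <- "integer"
  d
}

#' Local clustering coefficient
#'
#' `2 * e_v / (k_v * (k_v - 1))` where `e_v` counts edges among the
#' neighbours of `v`. Defined as 0 for nodes of degree below 2 so that group
#' means over all proteins are always computable.
#'
#' @param net An igraph network.
#' @return Named numeric vector in `[0, 1]`.
#' @export
node_clustering <- function(net) {
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  setNames(cc, igraph::V(net)$name)
}

#' Betweenness centrality
#'
#' `Btwn(v) = sum over pairs {s, t} (s != v != t) of sigma_st(v)/sigma_st`,
#' where `sigma_st` counts shortest s-t paths and `sigma_st(v)` those passing
#' through `v`. Unordered pairs, endpoints excluded; computed exactly by
#' Brandes-style accumulation over single-source shortest-path DAGs.
#'
#' @param net An igraph network.
#' @return Named numeric vector.
#' @export
node_betweenness <- function(net) {
  igraph::betweenness(net, directed = FALSE, weights = NA)
}

#' Min-max normalized betweenness
#'
#' `NB(v) = (Btwn(v) - min Btwn) / (max Btwn - min Btwn)`, giving values in
#' `[0, 1]`. When all raw values coincide the normalization is degenerate and
#' every node gets 0.
#'
#' @param raw Named numeric vector of raw betweenness values.
#' @return Named numeric vector of normalized values.
#' @export
normalize_betweenness <- function(raw) {
  if (length(raw) == 0) abort("Cannot normalize an empty betweenness map.")
  rng <- range(raw)
  if (rng[1] == rng[2]) return(setNames(rep(0, length(raw)), names(raw)))
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Eigenvector centrality by power iteration
#'
#' The score of a protein is proportional to the summed scores of its
#' neighbours: `x = A x / lambda` with `lambda` the leading eigenvalue of the
#' adjacency matrix. Computed by power iteration started from the all-ones
#' vector with Euclidean renormalization at every step; iteration runs on
#' `A + I` (same eigenvectors, strictly dominant leading eigenvalue) so that
#' convergence is guaranteed on bipartite-like connected graphs, and `lambda`
#' is reported for `A` via the Rayleigh quotient.
#'
#' @param net A connected igraph network.
#' @param tolerance Max-norm convergence threshold on successive iterates.
#' @param max_iterations Iteration budget; exceeded budget is an error.
#' @return A list with `vector` (named, nonnegative, unit Euclidean norm),
#'   `lambda`, and `iterations`.
#' @export
eigenvector_centrality <- function(net, tolerance = 1e-10, max_iterations = 1000) {
  n <- igraph::vcount(net)
  if (n == 0) abort("Empty network.")
  if (!igraph::is_connected(net)) {
    abort("Eigenvector centrality requires a connected network; extract the largest connected component first.")
  }
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  x <- rep(1 / sqrt(n), n)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iterations)) {
    y <- as.numeric(A %*% x) + x
    y <- y / sqrt(sum(y^2))
    delta <- max(abs(y - x))
    x <- y
    iterations <- it
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf("Power iteration did not converge within %d iterations.", max_iterations))
  }
  lambda <- sum(x * as.numeric(A %*% x))
  list(vector = setNames(x, igraph::V(net)$name), lambda = lambda,
       iterations = iterations)
}

#' Shortest-path lengths from one protein
#'
#' Breadth-first-search hop counts from `source` to every reachable node.
#' Unreachable nodes are absent from the result (the diameter substitution
#' is applied downstream by [average_distance_map()]).
#'
#' @param net An igraph network.
#' @param source A node identifier present in the network.
#' @return Named integer vector of distances over reachable nodes.
#' @export
shortest_path_lengths <- function(net, source) {
  if (!source %in% igraph::V(net)$name) {
    abort(paste0("Unknown source node: ", source))
  }
  d <- igraph::distances(net, v = source, weights = NA)[1, ]
  d <- d[is.finite(d)]
  storage.mode(d) <- "integer"
  d
}

#' Eccentricity profile
#'
#' `ecc(v) = max_u d(v, u)`, the greatest geodesic distance from each
#' protein. Defined on connected networks only; the diameter `D_G = max ecc`
#' and the modal eccentricity (smallest mode on ties) are also reported.
#'
#' @param net A connected igraph network.
#' @return A list with `eccentricity` (named integer vector), `diameter`,
#'   and `modal` (the most frequent eccentricity value).
#' @export
eccentricity_profile <- function(net) {
  if (igraph::vcount(net) == 0) abort("Empty network.")
  if (!igraph::is_connected(net)) {
    abort("Eccentricity requires a connected network; extract the largest connected component first.")
  }
  ecc <- igraph::eccentricity(net)
  storage.mode(ecc) <- "integer"
  tab <- table(ecc)
  modal <- as.integer(names(tab)[which.max(tab)])
  list(eccentricity = ecc, diameter = max(ecc), modal = modal)
}

#' Average distance with diameter substitution
#'
#' `l(v) = mean over u != v of d(v, u)`, where an unreachable pair
#' contributes the network diameter `D_G` instead of infinity: a stimulus
#' that cannot propagate is maximally remote, not absent. On a connected
#' network this equals the ordinary mean shortest distance. For disconnected
#' input `D_G` defaults to the maximum finite eccentricity over all
#' components unless supplied.
#'
#' @param net An igraph network with at least one node.
#' @param diameter Optional numeric `D_G` to substitute for unreachable
#'   pairs (e.g. the diameter of a reference network).
#' @return Named numeric vector; `NA` for a single-node network.
#' @export
average_distance_map <- function(net, diameter = NULL) {
  n <- igraph::vcount(net)
  if (n == 0) abort("Empty network.")
  if (n == 1) return(setNames(NA_real_, igraph::V(net)$name))
  d <- igraph::distances(net, weights = NA)
  if (any(!is.finite(d))) {
    dg <- diameter %||% max(d[is.finite(d)])
    d[!is.finite(d)] <- dg
  }
  rowSums(d) / (n - 1)
}

#' Coreness by iterative pruning
#'
#' The k-core is the maximal subgraph in which every node has degree at
#' least k, obtained by iteratively pruning nodes of degree below k; the
#' coreness of a protein is the largest k whose k-core still contains it.
#'
#' @param net An igraph network.
#' @return Named integer vector of coreness values.
#' @export
node_coreness <- function(net) {
  k <- igraph::coreness(net)
  storage.mode(k) <- "integer"
  k
}

#' Extract the k-core subgraph
#'
#' @param net An igraph network.
#' @param k Minimum degree of the core.
#' @return The induced subgraph on nodes of coreness at least `k`.
#' @export
k_core <- function(net, k) {
  igraph::induced_subgraph(net, which(igraph::coreness(net) >= k))
}

#' Full per-protein topological profile
#'
#' Computes every topological index used in the analysis on a connected
#' network and returns them as one tibble row per protein: degree,
#' betweenness and its min-max normalization, eigenvector centrality,
#' clustering coefficient, eccentricity, average distance and coreness, plus
#' the label class and community assignment when supplied.
#'
#' @param net A connected igraph network (run
#'   [largest_connected_component()] first).
#' @param labels Optional `labeled_proteome` from [assign_labels()].
#' @param partition Optional `community_partition` from
#'   [detect_communities()] or a named membership vector.
#' @param tolerance,max_iterations Passed to [eigenvector_centrality()].
#' @return A tibble with columns `protein`, (`class`,) `degree`,
#'   `betweenness`, `nb`, `eigenvector`, `clustering`, `eccentricity`,
#'   `avg_distance`, `coreness` (, `community`).
#' @export
topology_profile <- function(net, labels = NULL, partition = NULL,
                             tolerance = 1e-10, max_iterations = 1000) {
  if (!igraph::is_connected(net)) {
    abort("topology_profile() runs on a connected network; extract the largest connected component first.")
  }
  ids <- igraph::V(net)$name
  btwn <- node_betweenness(net)
  ecc <- eccentricity_profile(net)
  eig <- eigenvector_centrality(net, tolerance, max_iterations)
  out <- tibble(
    protein = ids,
    degree = as.integer(node_degree(net)[ids]),
    betweenness = unname(btwn[ids]),
    nb = unname(normalize_betweenness(btwn)[ids]),
    eigenvector = unname(eig$vector[ids]),
    clustering = unname(node_clustering(net)[ids]),
    eccentricity = as.integer(ecc$eccentricity[ids]),
    avg_distance = unname(average_distance_map(net)[ids]),
    coreness = as.integer(node_coreness(net)[ids])
  )
  if (!is.null(labels)) {
    out <- left_join(out, tidy(labels), by = "protein") |>
      select("protein", "class", dplyr::everything())
  }
  if (!is.null(partition)) {
    memb <- if (inherits(partition, "community_partition")) partition$membership else partition
    out$community <- as.integer(memb[out$protein])
  }
  attr(out, "lambda") <- eig$lambda
  attr(out, "diameter") <- ecc$diameter
  out
}
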