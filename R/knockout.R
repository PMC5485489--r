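#' Maximum gap between two empirical distributions
#'
#' The largest vertical distance between the empirical cumulative
#' distribution functions of two samples (the Kolmogorov-Smirnov statistic),
#' used as the quantitative summary of how much a metric's distribution
#' shifts after a knockout. Always in `[0, 1]`; 0 iff the two empirical
#' distributions coincide.
#'
#' @param x,y Numeric samples.
#' @return A single number in `[0, 1]`.
#' @export
ecdf_gap <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must contain finite values.")
  }
  grid <- sort(unique(c(x, y)))
  fx <- ecdf(x)(grid)
  fy <- ecdf(y)(grid)
  max(abs(fx - fy))
}

# metric functions available to knockout_experiment (each: connected net -> named numeric)
knockout_metric_fns <- function() {
  list(
    degree = function(net) as.numeric(node_degree(net)),
    betweenness = function(net) unname(node_betweenness(net)),
    clustering = function(net) unname(node_clustering(net)),
    eigenvector = function(net) unname(eigenvector_centrality(net)$vector),
    eccentricity = function(net) as.numeric(eccentricity_profile(net)$eccentricity),
    avg_distance = function(net) unname(average_distance_map(net)),
    coreness = function(net) as.numeric(node_coreness(net))
  )
}

modal_value <- function(x) {
  if (!all(x == round(x))) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Target-knockout experiment
#'
#' Deletes a set of proteins (typically the known drug targets), restricts
#' both the original and the reduced network to their largest connected
#' components, recomputes the requested topological metrics, and quantifies
#' the change per metric: before/after mean and median, the modal value for
#' integer-valued metrics (e.g. the eccentricity mode, which shifts when
#' structurally load-bearing nodes are removed), and the maximum vertical gap
#' between the before/after empirical distribution functions.
#'
#' @param net An igraph network.
#' @param remove A `labeled_proteome` (its target set is removed) or a
#'   character vector of identifiers.
#' @param metrics Character vector drawn from `degree`, `betweenness`,
#'   `clustering`, `eigenvector`, `eccentricity`, `avg_distance`,
#'   `coreness`.
#' @return A tibble with one row per metric: `metric`, `mean_before`,
#'   `mean_after`, `median_before`, `median_after`, `mode_before`,
#'   `mode_after`, `gap_statistic`, `n_before`, `n_after`.
#' @export
knockout_experiment <- function(net, remove,
                                metrics = c("degree", "eccentricity",
                                            "avg_distance", "clustering")) {
  ids <- if (inherits(remove, "labeled_proteome")) label_sets(remove)$D else as.character(remove)
  fns <- knockout_metric_fns()
  unknown <- setdiff(metrics, names(fns))
  if (length(unknown)) abort(paste0("Unknown metric(s): ", paste(unknown, collapse = ", ")))
  before <- largest_connected_component(net)
  reduced <- remove_nodes(net, ids)
  if (igraph::vcount(reduced) == 0) abort("Removal empties the network.")
  after <- largest_connected_component(reduced)
  purrr::map(metrics, function(m) {
    b <- fns[[m]](before)
    a <- fns[[m]](after)
    tibble(
      metric = m,
      mean_before = mean(b), mean_after = mean(a),
      median_before = median(b), median_after = median(a),
      mode_before = modal_value(b), mode_after = modal_value(a),
      gap_statistic = ecdf_gap(b, a),
      n_before = length(b), n_after = length(a)
    )
  }) |> bind_rows()
}
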