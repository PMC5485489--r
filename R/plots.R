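#' Degree distribution on log-log axes
#'
#' Plots the empirical degree distribution of each label class on double
#' logarithmic axes, the standard diagnostic for a power-law tail and for
#' comparing targets with other proteins.
#'
#' @param profile A [topology_profile()] tibble with a `class` column (or
#'   without, for a single series).
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(profile) {
  df <- as_tibble(profile)
  if (!"class" %in% names(df)) df$class <- "all"
  df <- df |>
    mutate(group = ifelse(.data$class == "target", "target", "pending")) |>
    count(.data$group, .data$degree) |>
    group_by(.data$group) |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup() |>
    filter(.data$degree > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$prop,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "proportion of proteins",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Community target-enrichment plot
#'
#' Bar chart of the target-like ratio rd per community, with the rd = 1
#' reference line separating target-like from non-target-like communities.
#'
#' @param enrichment A [community_enrichment()] tibble.
#' @return A ggplot object.
#' @export
plot_community_enrichment <- function(enrichment) {
  df <- filter(enrichment, is.finite(.data$rd))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$community,
                                              levels = .data$community),
                                   y = .data$rd, fill = .data$target_like)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "community", y = "rd(i) = D(i) / PT(i)", fill = "target-like") +
    ggplot2::theme_minimal()
}

#' Coreness-shell enrichment plot
#'
#' Normalized occupancy of each coreness shell by targets and pending
#' proteins.
#'
#' @param enrichment A [coreness_enrichment()] tibble.
#' @return A ggplot object.
#' @export
plot_coreness_enrichment <- function(enrichment) {
  df <- tidyr::pivot_longer(enrichment, c("rc_target", "rc_pending"),
                            names_to = "group", values_to = "rc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$rc,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "coreness k", y = "rc(k)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn cross_validate Bar chart of the cross-validated metrics.
#' @param object A `target_cv`.
#' @export
autoplot.target_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "pooled cross-validation value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
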