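#' Configuration for the end-to-end analysis pipeline
#'
#' @param edge_list Path to the interaction edge list (two-column,
#'   `#` comments).
#' @param targets Path to the drug-target label file (one id per line).
#' @param featured Optional path to a label file of featured proteins
#'   (defaults to the identifiers of the feature table, if given).
#' @param features Optional path to the chemical-physical property TSV;
#'   without it the prediction stage is skipped.
#' @param out_dir Output directory (created if absent).
#' @param delimiter Edge-list field separator.
#' @param min_report_size Main-community size threshold.
#' @param knockout_metrics Metrics for the knockout stage.
#' @param fraction Negative-set selection fraction.
#' @param folds Cross-validation folds.
#' @param seed Integer seed recorded in every output header and driving all
#'   random choices.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(edge_list, targets, featured = NULL,
                            features = NULL, out_dir,
                            delimiter = "\t", min_report_size = 50,
                            knockout_metrics = c("degree", "eccentricity",
                                                 "avg_distance", "clustering"),
                            fraction = 0.5, folds = 10, seed = 1L) {
  for (p in c(edge_list, targets, featured, features)) {
    if (!is.null(p) && !file.exists(p)) abort(paste0("Input path does not exist: ", p))
  }
  structure(
    list(edge_list = edge_list, targets = targets, featured = featured,
         features = features, out_dir = out_dir, delimiter = delimiter,
         min_report_size = min_report_size,
         knockout_metrics = knockout_metrics, fraction = fraction,
         folds = folds, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key=value`; `#` comments and blank lines ignored.
#' List-valued keys (`knockout_metrics`) take comma-separated values.
#'
#' @param path Path to the config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  cfg <- setNames(as.list(vals), keys)
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  pipeline_config(
    edge_list = cfg$edge_list, targets = cfg$targets,
    featured = cfg$featured, features = cfg$features,
    out_dir = cfg$out_dir %||% ".",
    delimiter = cfg$delimiter %||% "\t",
    min_report_size = num(cfg$min_report_size, 50),
    knockout_metrics = if (is.null(cfg$knockout_metrics))
      c("degree", "eccentricity", "avg_distance", "clustering")
    else trimws(strsplit(cfg$knockout_metrics, ",")[[1]]),
    fraction = num(cfg$fraction, 0.5),
    folds = num(cfg$folds, 10),
    seed = as.integer(num(cfg$seed, 1))
  )
}

write_stage_tsv <- function(x, path, seed, config_hash) {
  writeLines(sprintf("# seed=%d config=%s", seed, config_hash), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  path
}

#' Run the full drug-target analysis pipeline
#'
#' Orchestrates, in order: network loading and largest-connected-component
#' extraction, label assignment, per-protein topological profiling,
#' community detection, community and coreness enrichment, the
#' target-knockout experiment, and (when a feature table is supplied) the
#' prediction stage: naive-Bayes negative-set selection, SVM training with
#' cross-validation, and candidate calling. Every output table is TSV with a
#' `#` header naming the seed and a configuration hash; a manifest records
#' inputs and their checksums. A stage failure writes a `FAILED` marker and
#' returns status 1, retaining the artifacts already produced.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `status` (0 on success), `artifacts`
#'   (named paths), and `skipped` (named reasons).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  chash <- substr(rlang::hash(config[setdiff(names(config), "out_dir")]), 1, 12)
  artifacts <- list()
  skipped <- list()
  emit <- function(x, name) {
    artifacts[[name]] <<- write_stage_tsv(
      x, file.path(config$out_dir, paste0(name, ".tsv")), seed, chash)
  }
  status <- 0L
  tryCatch({
    net0 <- read_edge_list(config$edge_list, config$delimiter)
    net <- largest_connected_component(net0)
    feats <- if (!is.null(config$features)) read_feature_table(config$features)
    featured_ids <- if (!is.null(config$featured)) {
      read_labels(config$featured)
    } else if (!is.null(feats)) feats$protein else character()
    labels <- assign_labels(net, read_labels(config$targets),
                            featured_ids = featured_ids)
    emit(tibble(
      nodes_original = igraph::vcount(net0), edges_original = igraph::gsize(net0),
      nodes_lcc = igraph::vcount(net), edges_lcc = igraph::gsize(net)
    ) |> dplyr::bind_cols(glance(labels)), "network_stats")

    partition <- detect_communities(net, seed = seed,
                                    min_report_size = config$min_report_size)
    profile <- topology_profile(net, labels = labels, partition = partition)
    emit(profile, "profile")
    emit(tidy(partition), "communities")
    emit(partition$sizes, "community_sizes")
    emit(community_enrichment(partition, labels, pool_small = TRUE),
         "enrichment_communities")
    coreness <- setNames(profile$coreness, profile$protein)
    emit(coreness_enrichment(coreness, labels), "enrichment_coreness")
    emit(knockout_experiment(net, labels, metrics = config$knockout_metrics),
         "knockout")

    if (is.null(feats)) {
      skipped$prediction <- "no feature table supplied"
    } else {
      sets <- label_sets(labels)
      scores <- naive_bayes_target_score(profile, labels,
                                         score = intersect(sets$PT1, feats$protein))
      negatives <- select_negative_set(scores, config$fraction)
      pos <- feats[feats$protein %in% sets$D, ]
      neg <- feats[feats$protein %in% negatives, ]
      cv <- cross_validate(pos, neg, folds = config$folds, seed = seed)
      model <- train_margin_classifier(pos, neg, seed = seed)
      cand_pool <- feats[feats$protein %in% setdiff(sets$PT1, negatives), ]
      candidates <- predict_candidates(model, cand_pool)
      emit(tibble(protein = scores$protein, posterior = scores$posterior,
                  selected_negative = scores$protein %in% negatives),
           "negative_set")
      emit(glance(cv), "prediction_metrics")
      emit(predict(model, cand_pool), "candidates")
    }
    manifest <- tibble(
      key = c("package", "version", "seed", "config_hash",
              paste0("input_", c("edge_list", "targets", "featured", "features")),
              if (length(skipped)) paste0("skipped_", names(skipped))),
      value = c("dtnet", as.character(utils::packageVersion("dtnet")),
                as.character(seed), chash,
                vapply(list(config$edge_list, config$targets,
                            config$featured, config$features),
                       function(p) if (is.null(p)) "" else
                         paste0(p, ":", substr(rlang::hash(readLines(p, warn = FALSE)), 1, 12)),
                       character(1)),
                if (length(skipped)) unlist(skipped))
    )
    emit(manifest, "manifest")
  }, error = function(e) {
    status <<- 1L
    writeLines(paste0("FAILED: ", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
  })
  invisible(list(status = status, artifacts = artifacts, skipped = skipped))
}
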