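#' Posterior target probability by categorical naive Bayes
#'
#' The negative-set construction: with no curated non-target catalogue, the
#' least target-like pending proteins must be found from topology alone.
#' Community membership and coreness — the two structures in which known
#' targets concentrate — are treated as categorical features; class-
#' conditional level frequencies are estimated from the known targets (D)
#' versus all pending proteins (PT) with add-one smoothing, and combined
#' under a fixed 50% prior probability of being a target.
#'
#' @param topo A data frame with columns `protein`, `community`, `coreness`
#'   covering the labeled nodes (e.g. from [topology_profile()]).
#' @param labels A `labeled_proteome`.
#' @param score Identifiers to score; defaults to PT1 (the pending proteins
#'   that have chemical-physical properties).
#' @param prior Prior probability that a pending protein is a target
#'   (fixed at 0.5).
#' @param smoothing Additive smoothing pseudo-count (default 1), which also
#'   covers feature levels unseen in a class.
#' @return A tibble `protein`, `posterior`, sorted by identifier.
#' @export
naive_bayes_target_score <- function(topo, labels, score = NULL,
                                     prior = 0.5, smoothing = 1) {
  topo <- as_tibble(topo)
  stopifnot(all(c("protein", "community", "coreness") %in% names(topo)))
  sets <- label_sets(labels)
  score <- score %||% sets$PT1
  score <- intersect(as.character(score), topo$protein)
  feats <- c("community", "coreness")
  rownames_idx <- setNames(seq_len(nrow(topo)), topo$protein)
  d_rows <- topo[rownames_idx[intersect(sets$D, topo$protein)], ]
  pt_rows <- topo[rownames_idx[intersect(sets$PT, topo$protein)], ]
  if (nrow(d_rows) == 0) abort("No targets among the profiled proteins.")
  if (nrow(pt_rows) == 0) abort("No pending proteins among the profiled proteins.")
  # smoothed log-likelihood of each scored protein's level under one class
  loglik <- function(class_rows, score_rows) {
    out <- rep(0, nrow(score_rows))
    for (f in feats) {
      lvls <- unique(as.character(topo[[f]]))
      cnt <- table(factor(as.character(class_rows[[f]]), levels = lvls))
      p <- (as.numeric(cnt) + smoothing) /
        (nrow(class_rows) + smoothing * length(lvls))
      names(p) <- lvls
      out <- out + log(p[as.character(score_rows[[f]])])
    }
    out
  }
  score_rows <- topo[rownames_idx[score], ]
  ll_d <- loglik(d_rows, score_rows)
  ll_pt <- loglik(pt_rows, score_rows)
  post <- 1 / (1 + exp(log(1 - prior) - log(prior) + ll_pt - ll_d))
  tibble(protein = score, posterior = unname(post)) |> arrange(.data$protein)
}

#' Select the non-target training set
#'
#' Takes the `floor(fraction * n)` proteins with the lowest posterior target
#' probability as putative non-targets. Ties at the cut are broken by
#' lexicographic identifier order, so the selection is deterministic.
#'
#' @param scores A tibble with `protein` and `posterior` columns (from
#'   [naive_bayes_target_score()]) or a named numeric vector.
#' @param fraction Fraction of scored proteins to select, in (0, 1);
#'   default 0.5.
#' @return Character vector of selected identifiers, sorted.
#' @export
select_negative_set <- function(scores, fraction = 0.5) {
  if (is.data.frame(scores)) {
    ids <- scores$protein
    p <- scores$posterior
  } else {
    ids <- names(scores)
    p <- unname(scores)
  }
  if (length(ids) == 0) abort("Cannot select a negative set from zero scored proteins.")
  if (!(fraction > 0 && fraction < 1)) abort("`fraction` must be in (0, 1).")
  k <- floor(fraction * length(ids))
  ord <- order(p, ids)
  sort(ids[ord][seq_len(k)])
}

# standardization parameters fitted on training rows only
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

feature_matrix <- function(df) {
  df <- as.data.frame(df)
  id <- as.character(df[["protein"]])
  x <- as.matrix(df[setdiff(names(df), "protein")])
  storage.mode(x) <- "double"
  rownames(x) <- id
  x
}

#' Train the maximum-margin target classifier
#'
#' A linear support-vector machine with unit regularization cost, fitted on
#' standardized chemical-physical features (centering and scaling estimated
#' from the training rows only). The decision function is oriented so that
#' positive values mean "target".
#'
#' @param positives,negatives Data frames with a `protein` column and
#'   identical numeric feature columns; both classes must be nonempty.
#' @param seed Integer seed (the linear SVM fit itself is deterministic;
#'   the seed is recorded for provenance).
#' @param cost Soft-margin cost parameter (default 1).
#' @return A `target_classifier` object.
#' @export
train_margin_classifier <- function(positives, negatives, seed = 1L, cost = 1) {
  if (nrow(positives) == 0 || nrow(negatives) == 0) {
    abort("Both classes must be nonempty to train a margin classifier.")
  }
  xp <- feature_matrix(positives)
  xn <- feature_matrix(negatives)
  if (!identical(colnames(xp), colnames(xn))) {
    abort("Positive and negative feature columns must match.")
  }
  x <- rbind(xp, xn)
  y <- factor(rep(c("target", "nontarget"), c(nrow(xp), nrow(xn))),
              levels = c("nontarget", "target"))
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  model <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
  dv <- attr(predict(model, xs, decision.values = TRUE), "decision.values")[, 1]
  flip <- mean(dv[y == "target"]) < mean(dv[y == "nontarget"])
  structure(
    list(model = model, scaler = scaler, features = colnames(x),
         flip = flip, cost = cost, seed = as.integer(seed)),
    class = "target_classifier"
  )
}

#' @export
print.target_classifier <- function(x, ...) {
  cat(sprintf("<target_classifier> linear SVM, cost = %g, %d features\n",
              x$cost, length(x$features)))
  invisible(x)
}

#' Decision values and predicted classes for new proteins
#'
#' @param object A `target_classifier`.
#' @param newdata Data frame with a `protein` column and the training
#'   feature columns.
#' @param ... Unused.
#' @return A tibble `protein`, `decision`, `predicted_target`.
#' @export
predict.target_classifier <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  if (!identical(colnames(x), object$features)) {
    abort("Feature columns of `newdata` do not match the training features.")
  }
  if (nrow(x) == 0) {
    return(tibble(protein = character(), decision = numeric(),
                  predicted_target = logical()))
  }
  xs <- apply_scaler(x, object$scaler)
  dv <- attr(predict(object$model, xs, decision.values = TRUE),
             "decision.values")[, 1]
  if (object$flip) dv <- -dv
  tibble(protein = rownames(x), decision = unname(dv),
         predicted_target = unname(dv) > 0)
}

#' Predict candidate drug targets
#'
#' Scores candidate proteins with a trained classifier and returns those
#' with a positive decision value.
#'
#' @param model A `target_classifier`.
#' @param candidates Data frame with `protein` plus the training feature
#'   columns.
#' @return Sorted character vector of predicted candidate identifiers, with
#'   attribute `n_scored`.
#' @export
predict_candidates <- function(model, candidates) {
  pred <- predict(model, candidates)
  out <- sort(pred$protein[pred$predicted_target])
  attr(out, "n_scored") <- nrow(pred)
  out
}

confusion_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  tibble(
    accuracy = (tp + tn) / n,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

# stratified fold assignment: within each class, shuffle then deal round-robin
stratified_folds <- function(y, folds, seed) {
  withr::with_seed(as.integer(seed), {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

# pluggable classifier backends for cross_validate/feature_benchmark;
# each returns function(train_x, train_y) -> function(test_x) -> factor
classifier_backends <- function(cost = 1) {
  list(
    svm = function(x, y) {
      scaler <- fit_scaler(x)
      m <- e1071::svm(apply_scaler(x, scaler), y, kernel = "linear",
                      cost = cost, scale = FALSE)
      function(xt) predict(m, apply_scaler(xt, scaler))
    },
    naive_bayes = function(x, y) {
      m <- e1071::naiveBayes(as.data.frame(x), y)
      function(xt) predict(m, as.data.frame(xt))
    },
    logistic = function(x, y) {
      df <- as.data.frame(x)
      df$.y <- y
      m <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
      function(xt) {
        p <- predict(m, newdata = as.data.frame(xt), type = "response")
        factor(ifelse(p > 0.5, levels(y)[2], levels(y)[1]), levels = levels(y))
      }
    },
    tree = function(x, y) {
      df <- as.data.frame(x)
      df$.y <- y
      m <- rpart::rpart(.y ~ ., data = df, method = "class")
      function(xt) predict(m, newdata = as.data.frame(xt), type = "class")
    }
  )
}

#' Cross-validated classifier evaluation
#'
#' Stratified k-fold cross-validation of a target/non-target classifier.
#' Fold assignment is drawn once from `seed`; per fold, the classifier
#' (including feature standardization for the SVM) is fitted on the training
#' folds only and evaluated on the held-out fold. Held-out predictions are
#' pooled into one confusion matrix from which accuracy, positive predictive
#' value `TP/(TP+FP)` and negative predictive value `TN/(TN+FN)` are
#' computed.
#'
#' @param positives,negatives Data frames with `protein` plus identical
#'   numeric feature columns.
#' @param folds Number of folds (>= 2; each class must have at least `folds`
#'   members).
#' @param seed Integer seed for the fold assignment.
#' @param classifier One of `"svm"`, `"naive_bayes"`, `"logistic"`,
#'   `"tree"`.
#' @param cost SVM soft-margin cost.
#' @return A `target_cv` object; see [glance.target_cv()].
#' @export
cross_validate <- function(positives, negatives, folds = 10, seed = 1L,
                           classifier = "svm", cost = 1) {
  backends <- classifier_backends(cost)
  if (!classifier %in% names(backends)) {
    abort(paste0("Unknown classifier: ", classifier,
                 " (available: ", paste(names(backends), collapse = ", "), ")"))
  }
  if (folds < 2) abort("`folds` must be at least 2.")
  xp <- feature_matrix(positives)
  xn <- feature_matrix(negatives)
  if (!identical(colnames(xp), colnames(xn))) {
    abort("Positive and negative feature columns must match.")
  }
  if (nrow(xp) < folds || nrow(xn) < folds) {
    abort("Each class must have at least as many members as folds.")
  }
  x <- rbind(xp, xn)
  y <- factor(rep(c("target", "nontarget"), c(nrow(xp), nrow(xn))),
              levels = c("nontarget", "target"))
  fold <- stratified_folds(y, folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- backends[[classifier]](x[tr, , drop = FALSE], y[tr])
    pred[!tr] <- fit(x[!tr, , drop = FALSE])
  }
  tp <- sum(pred == "target" & y == "target")
  fp <- sum(pred == "target" & y == "nontarget")
  tn <- sum(pred == "nontarget" & y == "nontarget")
  fn <- sum(pred == "nontarget" & y == "target")
  structure(
    list(
      metrics = confusion_metrics(tp, fp, tn, fn)[, c("accuracy", "ppv", "npv")],
      confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                         dimnames = list(predicted = c("target", "nontarget"),
                                         truth = c("target", "nontarget"))),
      assignments = tibble(protein = rownames(x), class = y, fold = fold,
                           predicted = pred),
      classifier = classifier, folds = folds, seed = as.integer(seed)
    ),
    class = "target_cv"
  )
}

#' @export
print.target_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<target_cv> %s, %d-fold (seed %d): accuracy %.3f, PPV %.3f, NPV %.3f\n",
              x$classifier, x$folds, x$seed, m$accuracy, m$ppv, m$npv))
  invisible(x)
}

#' @describeIn cross_validate Long tibble of metric name/value pairs.
#' @param x A `target_cv`.
#' @param ... Unused.
#' @export
tidy.target_cv <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @describeIn cross_validate One-row tibble: metrics, confusion counts,
#'   folds, seed.
#' @export
glance.target_cv <- function(x, ...) {
  cm <- x$confusion
  dplyr::bind_cols(
    x$metrics,
    tibble(tp = cm[1, 1], fp = cm[1, 2], fn = cm[2, 1], tn = cm[2, 2],
           folds = x$folds, seed = x$seed, classifier = x$classifier)
  )
}

#' Benchmark classifiers across topological feature sets
#'
#' Cross-validates each requested classifier on each named feature set drawn
#' from a topological profile table, reproducing the layout of the
#' all-features versus particular-features comparison: `all` uses the eight
#' topological features (degree, betweenness, eigenvector centrality,
#' average distance, eccentricity, clustering coefficient, community,
#' coreness) and `particular` the three in which known targets show
#' distinctive structure (eccentricity, community, coreness). Community
#' identifiers enter as an integer covariate.
#'
#' @param profiles A [topology_profile()] tibble including a `community`
#'   column.
#' @param labels A `labeled_proteome`.
#' @param classifiers Character vector of backend names (see
#'   [cross_validate()]).
#' @param feature_sets Named list of character vectors of profile columns.
#' @param folds,seed Cross-validation settings.
#' @param negatives Optional character vector of non-target identifiers to
#'   use as the negative class; defaults to a size-matched random sample of
#'   pending proteins drawn with `seed`.
#' @return A tibble: `classifier`, `feature_set`, `accuracy`, `ppv`, `npv`.
#' @export
feature_benchmark <- function(profiles, labels,
                              classifiers = c("svm", "naive_bayes",
                                              "logistic", "tree"),
                              feature_sets = list(
                                all = c("degree", "betweenness", "eigenvector",
                                        "avg_distance", "eccentricity",
                                        "clustering", "community", "coreness"),
                                particular = c("eccentricity", "community",
                                               "coreness")
                              ),
                              folds = 10, seed = 1L, negatives = NULL) {
  profiles <- as_tibble(profiles)
  sets <- label_sets(labels)
  missing_cols <- setdiff(unique(unlist(feature_sets)), names(profiles))
  if (length(missing_cols)) {
    abort(paste0("Profile table lacks feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  pos_ids <- intersect(sets$D, profiles$protein)
  if (is.null(negatives)) {
    pool <- intersect(sets$PT, profiles$protein)
    negatives <- withr::with_seed(as.integer(seed),
                                  sample(pool, min(length(pos_ids), length(pool))))
  }
  neg_ids <- intersect(as.character(negatives), profiles$protein)
  grid <- tidyr::expand_grid(classifier = classifiers,
                             feature_set = names(feature_sets))
  purrr::pmap(grid, function(classifier, feature_set) {
    cols <- feature_sets[[feature_set]]
    tab <- profiles |>
      select("protein", dplyr::all_of(cols)) |>
      mutate(dplyr::across(-"protein", as.numeric))
    cv <- cross_validate(
      tab[match(pos_ids, tab$protein), ],
      tab[match(neg_ids, tab$protein), ],
      folds = folds, seed = seed, classifier = classifier
    )
    dplyr::bind_cols(tibble(classifier = classifier, feature_set = feature_set),
                     cv$metrics)
  }) |> bind_rows()
}
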