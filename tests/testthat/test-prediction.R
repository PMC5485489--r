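# small labeled topology table for naive-Bayes tests
nb_topo <- function(community, coreness, ids = NULL) {
  ids <- ids %||% sprintf("P%03d", seq_along(community))
  tibble::tibble(protein = ids, community = community, coreness = coreness)
}

nb_labels <- function(ids, d, pt1 = NULL) {
  net <- protein_network(data.frame(a = character(), b = character()),
                         nodes = ids)
  assign_labels(net, target_ids = d, featured_ids = c(d, pt1 %||% setdiff(ids, d)))
}

test_that("identical class feature distributions give posterior one half", {
  ids <- sprintf("P%03d", 1:40)
  topo <- nb_topo(rep(1:2, each = 20), rep(c(1L, 2L), 20), ids)
  # targets and pending split identically over both features
  d <- ids[c(1:4, 21:24)]
  lab <- nb_labels(ids, d)
  sc <- naive_bayes_target_score(topo, lab, score = setdiff(ids, d))
  expect_true(all(abs(sc$posterior - 0.5) < 1e-12))
})

test_that("a perfectly separating community drives posteriors to the extremes", {
  ids <- sprintf("P%03d", 1:200)
  comm <- rep(1:2, each = 100)
  topo <- nb_topo(comm, rep(1L, 200), ids)
  d <- ids[1:100]
  lab <- nb_labels(ids, d)
  sc <- naive_bayes_target_score(topo, lab, score = ids)
  expect_true(all(sc$posterior[match(ids[1:100], sc$protein)] > 0.9))
  expect_true(all(sc$posterior[match(ids[101:200], sc$protein)] < 0.1))
})

test_that("posteriors equal the hand-applied Bayes rule with add-one smoothing", {
  # 6 targets, 6 pending over communities {1,2} and coreness {1,2}
  ids <- sprintf("P%03d", 1:12)
  comm <- c(1, 1, 1, 1, 2, 2, 1, 2, 2, 2, 2, 2)
  core <- c(1, 1, 2, 2, 2, 2, 1, 1, 1, 2, 2, 2)
  topo <- nb_topo(comm, as.integer(core), ids)
  d <- ids[1:6]
  lab <- nb_labels(ids, d)
  sc <- naive_bayes_target_score(topo, lab, score = ids[7])
  # protein 7: community 1, coreness 1
  p_c_d <- (4 + 1) / (6 + 2)   # community=1 | target
  p_c_pt <- (1 + 1) / (6 + 2)
  p_k_d <- (2 + 1) / (6 + 2)   # coreness=1 | target
  p_k_pt <- (3 + 1) / (6 + 2)
  want <- (0.5 * p_c_d * p_k_d) / (0.5 * p_c_d * p_k_d + 0.5 * p_c_pt * p_k_pt)
  expect_equal(sc$posterior, want, tolerance = 1e-12)
})

test_that("negative-set selection takes the floor fraction of lowest posteriors", {
  ids <- sprintf("N%04d", 1:1180)
  sc <- tibble::tibble(protein = ids,
                       posterior = seq(0, 1, length.out = 1180))
  neg <- select_negative_set(sc, 0.5)
  expect_length(neg, 590)
  expect_setequal(neg, ids[1:590])

  sc7 <- tibble::tibble(protein = letters[1:7], posterior = rep(0.5, 7))
  neg7 <- select_negative_set(sc7, 0.5)
  expect_length(neg7, 3)
  expect_identical(neg7, c("a", "b", "c"))  # ties -> lexicographically smallest

  expect_error(select_negative_set(tibble::tibble(protein = character(),
                                                  posterior = numeric())),
               "zero scored")
  expect_error(select_negative_set(sc7, 1), "in \\(0, 1\\)")
})

gaussian_blobs <- function(n_per, delta, p = 5, seed = 1) {
  withr::with_seed(seed, {
    pos <- matrix(rnorm(n_per * p, mean = delta), n_per, p)
    neg <- matrix(rnorm(n_per * p), n_per, p)
    colnames(pos) <- colnames(neg) <- sprintf("f%02d", 1:p)
    list(
      pos = dplyr::bind_cols(tibble::tibble(protein = sprintf("D%03d", 1:n_per)),
                             tibble::as_tibble(pos)),
      neg = dplyr::bind_cols(tibble::tibble(protein = sprintf("N%03d", 1:n_per)),
                             tibble::as_tibble(neg))
    )
  })
}

test_that("the margin classifier separates well-separated blobs", {
  b <- gaussian_blobs(40, delta = 3, seed = 2)
  model <- train_margin_classifier(b$pos, b$neg)
  pred <- predict(model, dplyr::bind_rows(b$pos, b$neg))
  truth <- c(rep(TRUE, 40), rep(FALSE, 40))
  expect_gte(mean(pred$predicted_target == truth), 0.99)
})

test_that("the decision boundary matches a hand-placed separating line", {
  pos <- tibble::tibble(protein = c("p1", "p2", "p3"),
                        x = c(2, 3, 2.5), y = c(2, 2.5, 3))
  neg <- tibble::tibble(protein = c("n1", "n2", "n3"),
                        x = -pos$x, y = -pos$y)
  model <- train_margin_classifier(pos, neg)
  test <- tibble::tibble(protein = c("q1", "q2"),
                         x = c(4, -4), y = c(4, -4))
  pred <- predict(model, test)
  expect_identical(pred$predicted_target, c(TRUE, FALSE))
  expect_error(train_margin_classifier(pos[0, ], neg), "nonempty")
})

test_that("pooled confusion metrics follow their definitions", {
  m <- dtnet:::confusion_metrics(tp = 8, fp = 3, tn = 14, fn = 3)
  expect_equal(m$ppv, 8 / 11)
  expect_equal(m$npv, 14 / 17)
  expect_equal(m$accuracy, 22 / 28)
  # all-positive predictor: NPV undefined
  m2 <- dtnet:::confusion_metrics(tp = 10, fp = 10, tn = 0, fn = 0)
  expect_true(is.na(m2$npv))
})

test_that("cross-validation pools folds into one consistent confusion matrix", {
  b <- gaussian_blobs(30, delta = 3, seed = 3)
  cv <- cross_validate(b$pos, b$neg, folds = 5, seed = 1)
  cm <- cv$confusion
  m <- dtnet:::confusion_metrics(cm[1, 1], cm[1, 2], cm[2, 2], cm[2, 1])
  expect_equal(cv$metrics$accuracy, m$accuracy)
  expect_equal(cv$metrics$ppv, m$ppv)
  expect_equal(cv$metrics$npv, m$npv)
  expect_equal(sum(cm), 60)
  # perfect separation -> perfect pooled metrics
  b2 <- gaussian_blobs(30, delta = 6, seed = 4)
  cv2 <- cross_validate(b2$pos, b2$neg, folds = 5, seed = 1)
  expect_equal(unlist(cv2$metrics), c(accuracy = 1, ppv = 1, npv = 1))
})

test_that("fold assignment is a stratified partition", {
  b <- gaussian_blobs(25, delta = 1, seed = 5)
  cv <- cross_validate(b$pos, b$neg, folds = 5, seed = 9)
  a <- cv$assignments
  expect_equal(nrow(a), 50)
  expect_true(all(table(a$fold) == 10))
  expect_true(all(table(a$fold, a$class) == 5))
  expect_error(cross_validate(b$pos[1:3, ], b$neg, folds = 5),
               "at least as many members")
})

test_that("chance-level data yields chance-level cross-validation", {
  accs <- vapply(1:10, function(seed) {
    b <- gaussian_blobs(50, delta = 0, seed = 100 + seed)
    cross_validate(b$pos, b$neg, folds = 5, seed = seed)$metrics$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("candidate prediction returns positive-decision identifiers", {
  b <- gaussian_blobs(40, delta = 3, seed = 6)
  model <- train_margin_classifier(b$pos, b$neg)
  cands <- predict_candidates(model, b$pos)
  expect_setequal(cands, b$pos$protein)  # training positives all called
  empty <- predict_candidates(model, b$pos[0, ])
  expect_length(empty, 0)
  bad <- dplyr::rename(b$pos, zz = "f01")
  expect_error(predict_candidates(model, bad), "do not match")
})

test_that("planted positives among candidates are recovered with high recall", {
  recalls <- vapply(1:5, function(seed) {
    b <- gaussian_blobs(100, delta = 2, p = 10, seed = 200 + seed)
    model <- train_margin_classifier(b$pos[1:50, ], b$neg[1:50, ])
    pool <- dplyr::bind_rows(b$pos[51:100, ], b$neg[51:100, ])
    cands <- predict_candidates(model, pool)
    mean(b$pos$protein[51:100] %in% cands)
  }, numeric(1))
  expect_gte(mean(recalls), 0.8)
})

test_that("the feature benchmark runs the full classifier-by-set grid", {
  study <- generate_study(synthetic_spec(n = 600, n_communities = 6,
                                         n_targets = 60, mixing = 0.1,
                                         target_rr = c("1" = 2)),
                          seed = 7)
  part <- detect_communities(study$network, seed = 7)
  prof <- topology_profile(study$network, labels = study$labels,
                           partition = part)
  bench <- feature_benchmark(prof, study$labels,
                             classifiers = c("svm", "tree"),
                             folds = 5, seed = 7)
  expect_equal(nrow(bench), 4)
  expect_named(bench, c("classifier", "feature_set", "accuracy", "ppv", "npv"))
  expect_true(all(bench$accuracy >= 0 & bench$accuracy <= 1))

  single <- feature_benchmark(prof, study$labels, classifiers = "logistic",
                              feature_sets = list(deg = "degree"),
                              folds = 5, seed = 7)
  expect_equal(nrow(single), 1)
  expect_error(feature_benchmark(prof, study$labels, classifiers = "mlp"),
               "Unknown classifier")
})

test_that("labels independent of the profile give near-chance benchmark cells", {
  study <- generate_study(synthetic_spec(n = 500, n_communities = 5,
                                         n_targets = 50,
                                         target_rr = numeric(0)), seed = 8)
  # shuffle labels so no feature carries signal
  ids <- igraph::V(study$network)$name
  lab <- withr::with_seed(8, assign_labels(study$network, sample(ids, 50)))
  part <- detect_communities(study$network, seed = 8)
  prof <- topology_profile(study$network, labels = lab, partition = part)
  bench <- feature_benchmark(prof, lab, classifiers = "svm", folds = 5, seed = 8)
  expect_true(all(abs(bench$accuracy - 0.5) < 0.2))
})
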