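test_that("the RBF kernel is bounded, symmetric and PSD", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 0.5), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), 0.38), exp(-0.38))
  expect_error(rbf_kernel(1:2, 1:3, 1), "dimension")
  withr::with_seed(5, {
    for (i in 1:10) {
      x <- rnorm(5); y <- rnorm(5)
      expect_equal(rbf_kernel(x, y, 0.7), rbf_kernel(y, x, 0.7))
    }
    # kernel matrices on random 20-point sets are positive semi-definite
    for (i in 1:5) {
      X <- matrix(rnorm(100), 20, 5)
      K <- focis:::rbf_kernel_matrix(X, X, runif(1, 0.1, 2))
      expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    }
  })
})

test_that("the sigma heuristic stays inside its quantile bracket", {
  # two points: bracket collapses to 1/d^2
  X <- rbind(c(0, 0), c(3, 4))   # distance 5
  expect_equal(estimate_sigma(X, seed = 1), 1 / 25)
  expect_equal(estimate_sigma(X, method = "midpoint"), 1 / 25)
  # seeded determinism
  X <- withr::with_seed(3, matrix(rnorm(100), 20, 5))
  expect_identical(estimate_sigma(X, seed = 7), estimate_sigma(X, seed = 7))
  # contract: the draw lies within the computed bracket
  for (s in 1:20) {
    X <- withr::with_seed(s, matrix(rnorm(60), 12, 5))
    d2 <- as.numeric(dist(X))^2
    q <- quantile(1 / d2, c(0.1, 0.9), names = FALSE)
    sg <- estimate_sigma(X, seed = s)
    expect_gte(sg, q[1]); expect_lte(sg, q[2])
  }
  expect_error(estimate_sigma(matrix(1, 4, 2)), "degenerate")
})

test_that("training separable data gives perfect training accuracy", {
  corp <- sim_labeled_features(n = 60, separation = 6, seed = 21)
  m <- focis_train(corp$features, corp$labels, seed = 1)
  expect_identical(unname(predict(m, corp$features)), corp$labels$label)
  expect_lte(nrow(m$support_vectors), 60)
  expect_gt(m$sigma, 0)
})

test_that("the stored decision function matches the kernlab solver", {
  cc <- classifier_corpus()
  m <- focis_train(cc$features_train, cc$train$labels, seed = 3)
  # agreement is asserted inside focis_train; check held-out predictions too
  pred <- predict(m, cc$features_test)
  expect_true(all(pred %in% c("RFN", "ART")))
  d <- predict(m, cc$features_test, type = "decision")
  expect_identical(unname(pred), ifelse(d > 0, m$sign_positive,
                                        setdiff(m$levels, m$sign_positive)))
})

test_that("the decision function is invariant to training-point order", {
  corp <- sim_labeled_features(n = 40, separation = 5, seed = 12)
  perm <- withr::with_seed(1, sample(40))
  m1 <- focis_train(corp$features, corp$labels, sigma = 0.4)
  m2 <- focis_train(corp$features[perm, ], corp$labels$label[perm], sigma = 0.4)
  probe <- sim_labeled_features(n = 30, separation = 5, seed = 99)$features
  # the exact solution is order-invariant; the SMO solver stops at finite
  # precision, so compare at solver tolerance and require identical labels
  expect_equal(predict(m1, probe, type = "decision"),
               predict(m2, probe, type = "decision"), tolerance = 5e-3)
  expect_identical(predict(m1, probe), predict(m2, probe))
})

test_that("raising the RFN weight never lowers training sensitivity", {
  for (s in 1:20) {
    corp <- sim_labeled_features(n = 40, separation = 1, seed = 400 + s)
    sens <- vapply(c(1, 10), function(w) {
      m <- focis_train(corp$features, corp$labels, sigma = 0.3,
                       class_weights = c(RFN = w, ART = 1))
      classification_metrics(
        tibble::tibble(id = corp$features$id, label = predict(m, corp$features)),
        corp$labels)$sensitivity
    }, numeric(1))
    expect_gte(sens[2], sens[1])
  }
})

test_that("grid search evaluates the full grid and honours the constraint", {
  gs <- corpus_grid_search()
  # (1000 - 10)/10 + 1 = 100 cost values x 10 sigma values
  expect_equal(nrow(gs$cv), 1000)
  expect_equal(sort(unique(gs$cv$cost)), seq(10, 1000, 10))
  expect_equal(sort(unique(gs$cv$sigma)), seq(0.1, 1, 0.1), tolerance = 1e-9)
  expect_true(gs$sensitivity_constrained)
  best_rows <- gs$cv[gs$cv$sensitivity == 1 &
                     gs$cv$accuracy == max(gs$cv$accuracy[gs$cv$sensitivity == 1]), ]
  # tie-break: smallest C, then smallest sigma
  expect_equal(gs$best_cost, min(best_rows$cost))
  expect_equal(gs$best_sigma,
               min(best_rows$sigma[best_rows$cost == gs$best_cost]))
})

test_that("grid search is deterministic under a fixed seed", {
  corp <- sim_labeled_features(n = 40, separation = 5, seed = 77)
  g1 <- suppressWarnings(
    focis_grid_search(corp$features, corp$labels, c_range = c(10, 20),
                      sigma_range = c(0.1, 0.5), folds = 4, seed = 5))
  g2 <- suppressWarnings(
    focis_grid_search(corp$features, corp$labels, c_range = c(10, 20),
                      sigma_range = c(0.1, 0.5), folds = 4, seed = 5))
  expect_identical(g1$cv, g2$cv)
  # tie-break contract: best point is lexicographically smallest (C, sigma)
  # among the feasible accuracy maximizers
  cand <- if (g1$sensitivity_constrained) g1$cv[g1$cv$sensitivity == 1, ] else g1$cv
  cand <- cand[cand$accuracy == max(cand$accuracy), ]
  expect_equal(g1$best_cost, min(cand$cost))
  expect_equal(g1$best_sigma, min(cand$sigma[cand$cost == g1$best_cost]))
})

test_that("classification labels every component and is idempotent", {
  cc <- classifier_corpus()
  m <- focis_train(cc$features_train, cc$train$labels, seed = 3)
  out1 <- classify_components(m, cc$test$set, cc$test$templates$gm)
  out2 <- classify_components(m, cc$test$set, cc$test$templates$gm)
  expect_identical(out1, out2)
  expect_equal(nrow(out1), cc$test$set$nic)
  counts <- count_classes(out1)
  expect_equal(counts$n_rfn + counts$n_art, cc$test$set$nic)
  met <- classification_metrics(out1, cc$test$labels)
  expect_gte(met$accuracy, 0.9)
})

test_that("metric bookkeeping matches hand-derived confusion tables", {
  m <- metrics_from_counts(tp = 15, fp = 1, tn = 14, fn = 0)
  expect_equal(round(m$precision, 2), 0.94)
  expect_equal(m$sensitivity, 1)
  expect_equal(round(m$specificity, 2), 0.93)
  expect_equal(round(m$accuracy, 2), 0.97)

  m <- metrics_from_counts(tp = 17, fp = 0, tn = 13, fn = 0)
  expect_equal(unlist(m[, c("precision", "sensitivity", "specificity", "accuracy")]),
               c(precision = 1, sensitivity = 1, specificity = 1, accuracy = 1))

  # perfect disagreement on a balanced set
  pred <- tibble::tibble(id = 0:3, label = c("RFN", "RFN", "ART", "ART"))
  truth <- tibble::tibble(id = 0:3, label = c("ART", "ART", "RFN", "RFN"))
  m <- classification_metrics(pred, truth)
  expect_equal(m$accuracy, 0)
  expect_equal(m$sensitivity, 0)

  # zero denominators are NA with a flag, never silently zero
  m <- metrics_from_counts(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_true(is.na(m$precision))
  expect_match(m$undefined, "precision")
  expect_error(classification_metrics(pred, truth[1:2, ]), "different component ids")
})

test_that("models serialize to JSON and restore identical predictions", {
  corp <- sim_labeled_features(n = 40, separation = 4, seed = 15)
  m <- focis_train(corp$features, corp$labels, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_focis_model(m, path)
  m2 <- read_focis_model(path)
  probe <- sim_labeled_features(n = 100, separation = 4, seed = 555)$features
  expect_equal(predict(m2, probe, type = "decision"),
               predict(m, probe, type = "decision"), tolerance = 1e-12)
  expect_identical(predict(m2, probe), predict(m, probe))
})

test_that("artifact-identification agreement arithmetic", {
  expect_equal(artifact_agreement_pct(231, 4), 100 * 227 / 231)
  expect_equal(artifact_agreement_pct(100, 0), 100)
  expect_error(artifact_agreement_pct(0, 0), "positive")
})
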