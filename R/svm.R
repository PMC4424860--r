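#' Gaussian radial basis kernel
#'
#' `k(x, y) = exp(-sigma * ||x - y||^2)`, the bounded LIBSVM/kernlab
#' convention, in (0, 1] with `k(x, x) = 1`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param sigma Positive kernel width parameter.
#' @return Scalar kernel value.
#' @export
rbf_kernel <- function(x, y, sigma) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  exp(-sigma * sum((x - y)^2))
}

rbf_kernel_matrix <- function(X, Y, sigma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-sigma * d2)
}

#' Quantile heuristic for the RBF kernel width
#'
#' Good values of sigma lie between the 0.1 and 0.9 quantiles of the inverse
#' squared pairwise-distance statistic of the (conditioned) training data.
#' The bracket is computed on a random subsample of point pairs; the
#' returned sigma is either a seeded uniform draw within the bracket or its
#' midpoint.
#'
#' @param X Numeric matrix (rows = conditioned feature vectors).
#' @param quantile_lo,quantile_hi Quantiles of the inverse squared distance
#'   statistic bounding the bracket.
#' @param seed Integer seed for the subsample and draw; with `method =
#'   "random"` a seed is required for reproducibility.
#' @param method `"random"` (uniform draw in the bracket), `"midpoint"`
#'   (bracket midpoint), or `"median"` (inverse median squared distance, a
#'   robust single-point choice for very small sets).
#' @param n_pairs Maximum number of sampled point pairs.
#' @return Positive scalar sigma, always inside the computed bracket.
#' @export
estimate_sigma <- function(X, quantile_lo = 0.1, quantile_hi = 0.9,
                           seed = NULL, method = c("random", "midpoint", "median"),
                           n_pairs = 2000L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 points", call. = FALSE)
  draw <- function() {
    n <- nrow(X)
    if (n * (n - 1) / 2 <= n_pairs) {
      d2 <- as.numeric(stats::dist(X))^2
    } else {
      i <- sample.int(n, n_pairs, replace = TRUE)
      j <- sample.int(n, n_pairs, replace = TRUE)
      keep <- i != j
      d2 <- rowSums((X[i[keep], , drop = FALSE] - X[j[keep], , drop = FALSE])^2)
    }
    d2 <- d2[d2 > 0]
    if (length(d2) == 0L) stop("degenerate geometry: all points identical", call. = FALSE)
    if (method == "median") return(1 / stats::median(d2))
    q <- stats::quantile(1 / d2, c(quantile_lo, quantile_hi), names = FALSE)
    if (method == "midpoint") mean(q) else stats::runif(1, q[1], q[2])
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Train the RBF-SVM component classifier
#'
#' Soft-margin C-classification with a Gaussian kernel, solved by kernlab's
#' LIBSVM-derived optimizer. Per-class error weights default to penalizing
#' mistakes on true-RFN components 10x more heavily than on true-ART ones,
#' so that genuine networks are not discarded as artifacts. Conditioning
#' (mean/sd) is fitted on the training features and stored in the model; raw
#' features are expected at prediction time.
#'
#' @param features Raw feature tibble of the training components.
#' @param labels Label vector or `(id, label)` tibble (classes RFN/ART).
#' @param cost Soft-margin cost C (default 100).
#' @param sigma Kernel width; `NULL` uses [estimate_sigma()] (seeded draw
#'   when `seed` is given, bracket midpoint otherwise).
#' @param class_weights Named per-class error weights.
#' @param feature_cols Feature columns used by the model.
#' @param seed Seed for the sigma heuristic.
#' @return A `focis_model`: support vectors (conditioned), dual
#'   coefficients, bias, `sigma`, `cost`, class weights, conditioning stats
#'   and feature names. Prediction uses the stored state only, so a
#'   serialized model reproduces its decisions exactly.
#' @export
focis_train <- function(features, labels, cost = 100, sigma = NULL,
                        class_weights = c(RFN = 10, ART = 1),
                        feature_cols = NULL, seed = NULL) {
  feature_cols <- default_feature_cols(features, feature_cols)
  y <- align_labels(features, labels)
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("training data must contain both classes", call. = FALSE)
  conditioning <- fit_conditioning(features, feature_cols)
  Xc <- as.matrix(apply_conditioning(features, conditioning)[, feature_cols, drop = FALSE])
  if (is.null(sigma))
    sigma <- estimate_sigma(Xc, seed = seed,
                            method = if (is.null(seed)) "midpoint" else "random")
  cw <- class_weights[lev]
  if (anyNA(cw)) stop("`class_weights` must name both classes: ",
                      paste(lev, collapse = ", "), call. = FALSE)
  yf <- factor(y, levels = lev)
  fit <- kernlab::ksvm(Xc, yf, type = "C-svc", kernel = "rbfdot",
                       kpar = list(sigma = sigma), C = cost,
                       class.weights = cw, scaled = FALSE)
  sv_index <- unlist(kernlab::alphaindex(fit))
  model <- structure(list(
    support_vectors = Xc[sv_index, , drop = FALSE],
    dual_coef = unlist(kernlab::coef(fit)),
    bias = kernlab::b(fit),
    sigma = sigma, cost = cost,
    class_weights = as.list(cw),
    conditioning = conditioning,
    feature_names = feature_cols,
    levels = lev, sign_positive = lev[1]), class = "focis_model")
  # orient the stored decision function against the solver's own predictions
  d <- decision_values(model, Xc, conditioned = TRUE)
  ref <- as.character(kernlab::predict(fit, Xc))
  pos_lab <- ref[d > 0]
  neg_lab <- ref[d <= 0]
  model$sign_positive <- if (length(pos_lab)) names(which.max(table(pos_lab))) else
    setdiff(lev, names(which.max(table(neg_lab))))
  agree <- mean(ifelse(d > 0, model$sign_positive,
                       setdiff(lev, model$sign_positive)) == ref)
  if (agree < 1)
    stop("internal error: stored decision function disagrees with solver", call. = FALSE)
  model
}

decision_values <- function(model, features, conditioned = FALSE) {
  if (is.matrix(features)) {
    X <- features
  } else {
    df <- if (conditioned) features else apply_conditioning(features, model$conditioning)
    X <- as.matrix(df[, model$feature_names, drop = FALSE])
  }
  K <- rbf_kernel_matrix(X, model$support_vectors, model$sigma)
  as.numeric(K %*% model$dual_coef - model$bias)
}

#' @export
print.focis_model <- function(x, ...) {
  cat("<focis_model> ", nrow(x$support_vectors), " support vectors, sigma = ",
      signif(x$sigma, 3), ", C = ", x$cost, "\n", sep = "")
  invisible(x)
}

#' Predict component classes
#'
#' @param object A `focis_model`.
#' @param newdata Raw feature tibble (conditioning is applied internally).
#' @param type `"class"` for labels, `"decision"` for the signed decision
#'   values.
#' @param ... Unused.
#' @return Character labels or numeric decision values.
#' @export
predict.focis_model <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  d <- decision_values(object, newdata)
  if (type == "decision") return(d)
  neg <- setdiff(object$levels, object$sign_positive)
  ifelse(d > 0, object$sign_positive, neg)
}

#' @rdname focis_train
#' @param x A `focis_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.focis_model <- function(x, ...) {
  sv <- as_tibble(as.data.frame(x$support_vectors))
  sv$dual_coef <- x$dual_coef
  sv
}

#' @rdname focis_train
#' @exportS3Method generics::glance
glance.focis_model <- function(x, ...) {
  tibble(n_support = nrow(x$support_vectors), sigma = x$sigma, cost = x$cost,
         bias = x$bias,
         weight_rfn = x$class_weights[["RFN"]] %||% NA_real_,
         weight_art = x$class_weights[["ART"]] %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exhaustive grid search over (C, sigma)
#'
#' Evaluates every grid point by stratified k-fold cross-validation and
#' returns the point maximizing pooled accuracy among points whose pooled
#' sensitivity (RFN recall) equals 1 — the "maximize accuracy while
#' retaining sensitivity at 1" objective. Ties break toward smaller C, then
#' smaller sigma. If no point reaches sensitivity 1, the search falls back
#' to pure accuracy maximization with a warning.
#'
#' @param features Raw feature tibble.
#' @param labels Label vector or `(id, label)` tibble.
#' @param c_range Cost values (default 10 to 1000 in steps of 10).
#' @param sigma_range Kernel widths (default 0.1 to 1.0 in steps of 0.1).
#' @param folds Number of stratified CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param class_weights,feature_cols As in [focis_train()].
#' @return A `focis_grid_search` object: `best_cost`, `best_sigma`,
#'   `cv` (tibble with one row per grid point: cost, sigma, accuracy,
#'   sensitivity), `sensitivity_constrained` flag.
#' @export
focis_grid_search <- function(features, labels,
                              c_range = seq(10, 1000, by = 10),
                              sigma_range = seq(0.1, 1.0, by = 0.1),
                              folds = 5L, seed = 1L,
                              class_weights = c(RFN = 10, ART = 1),
                              feature_cols = NULL) {
  feature_cols <- default_feature_cols(features, feature_cols)
  y <- align_labels(features, labels)
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("need both classes", call. = FALSE)
  positive <- if ("RFN" %in% lev) "RFN" else lev[2]
  negative <- setdiff(lev, positive)
  n <- length(y)
  if (min(table(y)) < folds) stop("too few samples per class for ", folds, " folds", call. = FALSE)
  conditioning <- fit_conditioning(features, feature_cols)
  X <- as.matrix(apply_conditioning(features, conditioning)[, feature_cols, drop = FALSE])
  cw <- class_weights[lev]
  yf <- factor(y, levels = lev)

  fold_id <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (cl in lev) {
      ix <- sample(which(y == cl))
      fold_id[ix] <- rep_len(seq_len(folds), length(ix))
    }
  })
  D2 <- as.matrix(stats::dist(X))^2
  grid <- expand.grid(sigma = sigma_range, cost = c_range)
  res <- vector("list", nrow(grid))
  for (s in sigma_range) {
    K <- exp(-s * D2)
    for (cc in c_range) {
      tp <- fp <- tn <- fn <- 0L
      for (f in seq_len(folds)) {
        tr <- which(fold_id != f); va <- which(fold_id == f)
        m <- kernlab::ksvm(kernlab::as.kernelMatrix(K[tr, tr, drop = FALSE]),
                           yf[tr], type = "C-svc", C = cc,
                           class.weights = cw, scaled = FALSE)
        sv <- kernlab::SVindex(m)
        pred <- kernlab::predict(
          m, kernlab::as.kernelMatrix(K[va, tr, drop = FALSE][, sv, drop = FALSE]))
        pred <- as.character(pred)
        truth <- y[va]
        tp <- tp + sum(pred == positive & truth == positive)
        fn <- fn + sum(pred == negative & truth == positive)
        tn <- tn + sum(pred == negative & truth == negative)
        fp <- fp + sum(pred == positive & truth == negative)
      }
      res[[match(s, sigma_range) + (match(cc, c_range) - 1L) * length(sigma_range)]] <-
        tibble(cost = cc, sigma = s,
               accuracy = (tp + tn) / n,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
    }
  }
  cv <- dplyr::arrange(dplyr::bind_rows(res), .data$cost, .data$sigma)
  feasible <- !is.na(cv$sensitivity) & cv$sensitivity == 1
  constrained <- any(feasible)
  if (!constrained) {
    warning("no grid point achieved sensitivity 1; maximizing accuracy only")
    feasible <- rep(TRUE, nrow(cv))
  }
  cand <- cv[feasible, ]
  best <- cand[cand$accuracy == max(cand$accuracy), ]
  best <- best[order(best$cost, best$sigma), ][1, ]   # smallest C, then sigma
  structure(list(best_cost = best$cost, best_sigma = best$sigma, cv = cv,
                 sensitivity_constrained = constrained,
                 folds = folds, seed = as.integer(seed)),
            class = "focis_grid_search")
}

#' @export
print.focis_grid_search <- function(x, ...) {
  cat("<focis_grid_search> ", nrow(x$cv), " grid points; best C = ",
      x$best_cost, ", sigma = ", x$best_sigma,
      if (!x$sensitivity_constrained) " (sensitivity constraint infeasible)",
      "\n", sep = "")
  invisible(x)
}

#' @rdname focis_grid_search
#' @param x A `focis_grid_search`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.focis_grid_search <- function(x, ...) x$cv

#' @rdname focis_grid_search
#' @exportS3Method generics::glance
glance.focis_grid_search <- function(x, ...) {
  tibble(best_cost = x$best_cost, best_sigma = x$best_sigma,
         best_accuracy = max(x$cv$accuracy),
         n_points = nrow(x$cv), folds = x$folds,
         sensitivity_constrained = x$sensitivity_constrained)
}

#' Classify every component of an ICA set
#'
#' Extracts features with the same pipeline used at training time and
#' applies the classifier. Degenerate components (no suprathreshold cluster
#' survives filtering) are force-labelled ART: a map with no significant
#' cluster cannot represent a network.
#'
#' @param model A `focis_model`.
#' @param set An [ica_set()].
#' @param gm Gray-matter [binary_mask()].
#' @param spec,band,connectivity Extraction settings (must match training).
#' @return Tibble `(id, label, decision, degenerate)`, one row per
#'   component.
#' @export
classify_components <- function(model, set, gm, spec = threshold_spec(),
                                band = c(0.01, 0.08), connectivity = 6) {
  stopifnot(inherits(model, "focis_model"), inherits(set, "ica_set"))
  feats <- ic_features(set, gm, spec, band, connectivity)
  d <- decision_values(model, feats)
  neg <- setdiff(model$levels, model$sign_positive)
  lab <- ifelse(d > 0, model$sign_positive, neg)
  lab[feats$degenerate] <- "ART"
  tibble(id = feats$id, label = lab, decision = d, degenerate = feats$degenerate)
}

#' Count components per class
#'
#' @param labels Tibble with a `label` column (RFN/ART).
#' @return One-row tibble `(n_rfn, n_art)` with `n_rfn + n_art` equal to the
#'   number of components.
#' @export
count_classes <- function(labels) {
  tibble(n_rfn = sum(labels$label == "RFN"), n_art = sum(labels$label == "ART"))
}

#' Agreement rate in identifying artifact components
#'
#' Percentage of manually labelled artifact components that the automated
#' classification also identified: `100 * (n_art - n_missed) / n_art`.
#'
#' @param n_art Number of manually labelled ART components.
#' @param n_missed Number of those the classifier labelled RFN (false
#'   negatives for artifact detection).
#' @return Percentage in \[0, 100\].
#' @export
artifact_agreement_pct <- function(n_art, n_missed) {
  if (n_art <= 0) stop("`n_art` must be positive", call. = FALSE)
  100 * (n_art - n_missed) / n_art
}

#' Classification metrics against a reference labelling
#'
#' Confusion counts and the four standard metrics with RFN as the positive
#' class: precision `tp/(tp+fp)`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, accuracy `(tp+tn)/n`. Ratios with a zero denominator are
#' reported as `NA` and named in the `undefined` column — never silently 0.
#'
#' @param predicted,truth Tibbles `(id, label)` over the same component ids.
#' @param positive Positive class (default `"RFN"`).
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `precision`,
#'   `sensitivity`, `specificity`, `accuracy`, `undefined`.
#' @export
classification_metrics <- function(predicted, truth, positive = "RFN") {
  stopifnot(all(c("id", "label") %in% names(predicted)),
            all(c("id", "label") %in% names(truth)))
  if (!setequal(predicted$id, truth$id))
    stop("predicted and truth tables cover different component ids", call. = FALSE)
  m <- dplyr::inner_join(predicted[, c("id", "label")], truth[, c("id", "label")],
                         by = "id", suffix = c("_pred", "_true"))
  metrics_from_counts(
    tp = sum(m$label_pred == positive & m$label_true == positive),
    fp = sum(m$label_pred == positive & m$label_true != positive),
    tn = sum(m$label_pred != positive & m$label_true != positive),
    fn = sum(m$label_pred != positive & m$label_true == positive))
}

#' @rdname classification_metrics
#' @param tp,fp,tn,fn Confusion counts (RFN positive).
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                precision = ratio(tp, tp + fp),
                sensitivity = ratio(tp, tp + fn),
                specificity = ratio(tn, tn + fp),
                accuracy = ratio(tp + tn, tp + fp + tn + fn))
  und <- c("precision", "sensitivity", "specificity", "accuracy")[
    vapply(out[, c("precision", "sensitivity", "specificity", "accuracy")],
           is.na, logical(1))]
  out$undefined <- paste(und, collapse = ",")
  out
}

#' Serialize / restore a trained model as JSON
#'
#' The JSON file stores the complete decision state (support vectors, dual
#' coefficients, bias, kernel width, cost, class weights, conditioning and
#' feature names), so a restored model reproduces predictions exactly.
#'
#' @param model A `focis_model` or `focis_tracker`.
#' @param path Output path.
#' @return `path` invisibly; `read_focis_model()` returns the restored
#'   object.
#' @export
write_focis_model <- function(model, path) {
  stopifnot(inherits(model, "focis_model") || inherits(model, "focis_tracker"))
  payload <- list(
    class = class(model)[1],
    package_version = as.character(utils::packageVersion("focis")),
    support_vectors = unclass(model$support_vectors),
    dual_coef = model$dual_coef,
    bias = model$bias, sigma = model$sigma,
    conditioning = model$conditioning,
    feature_names = model$feature_names)
  extra <- setdiff(names(model), names(payload))
  payload <- c(payload, model[intersect(extra, c(
    "cost", "class_weights", "levels", "sign_positive",
    "epsilon", "reference_id", "reference_nic"))])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_focis_model
#' @export
read_focis_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- p$class
  p$class <- NULL
  p$package_version <- NULL
  p$support_vectors <- as.matrix(p$support_vectors)
  colnames(p$support_vectors) <- p$feature_names
  p$conditioning <- as_tibble(p$conditioning)
  if (!is.null(p$class_weights)) p$class_weights <- as.list(p$class_weights)
  structure(p, class = cls)
}
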