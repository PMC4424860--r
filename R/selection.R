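#' Fisher-ratio F-score of one feature against a two-class labelling
#'
#' `F = [(mean+ - mean)^2 + (mean- - mean)^2] / (var+ + var-)` where `mean`
#' is the pooled mean and the variances are within-class sample variances.
#' Large values mean the class means are far apart relative to within-class
#' spread. The score is invariant to affine rescaling of the feature and to
#' swapping the class labels.
#'
#' @param values Numeric feature vector.
#' @param labels Two-level factor/character vector of the same length, both
#'   classes with at least 2 samples.
#' @return Non-negative scalar; `Inf` with a warning when both within-class
#'   variances vanish but the means differ.
#' @export
f_score <- function(values, labels) {
  values <- as.numeric(values)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stop("labels must contain exactly two classes", call. = FALSE)
  a <- values[labels == lev[1]]
  b <- values[labels == lev[2]]
  if (length(a) < 2L || length(b) < 2L)
    stop("each class needs at least 2 samples", call. = FALSE)
  m <- mean(values)
  num <- (mean(a) - m)^2 + (mean(b) - m)^2
  den <- stats::var(a) + stats::var(b)
  if (den == 0) {
    if (num == 0) return(0)
    warning("zero within-class variance in both classes; F-score is infinite")
    return(Inf)
  }
  num / den
}

#' F-score ranking of all features
#'
#' @param features Feature tibble.
#' @param labels Label vector aligned with rows of `features`, or a tibble
#'   `(id, label)` joined on the `id` column.
#' @param feature_cols Feature columns to score (default: the five standard
#'   features present).
#' @return Tibble `(feature, f_score)` sorted descending.
#' @export
f_score_table <- function(features, labels, feature_cols = NULL) {
  feature_cols <- default_feature_cols(features, feature_cols)
  y <- align_labels(features, labels)
  tibble(feature = feature_cols,
         f_score = vapply(feature_cols, function(f) f_score(features[[f]], y), numeric(1))) |>
    dplyr::arrange(dplyr::desc(.data$f_score))
}

align_labels <- function(features, labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("id", "label") %in% names(labels)), "id" %in% names(features))
    y <- labels$label[match(features$id, labels$id)]
    if (anyNA(y)) stop("labels missing for some component ids", call. = FALSE)
    y
  } else {
    if (length(labels) != nrow(features)) stop("label length mismatch", call. = FALSE)
    as.character(labels)
  }
}

#' Iterative F-score feature reduction with SVM validation
#'
#' Implements the threshold-and-validate loop: for each ascending F-score
#' threshold, drop the features scoring below it, then estimate validation
#' accuracy by repeated random stratified splits, training the RBF-SVM on
#' each training subset. The sweep stops early once the mean accuracy falls
#' more than `tolerance` below the best mean seen so far ("decreases
#' significantly"), or when a threshold would drop every feature. The kept
#' set is the smallest feature set whose mean accuracy is within `tolerance`
#' of the best observed mean.
#'
#' @param features Feature tibble (raw; conditioning is fitted within each
#'   training split).
#' @param labels Label vector or `(id, label)` tibble.
#' @param thresholds Ascending numeric F-score thresholds; the default
#'   starts at 0 (keep everything) and rises through the observed scores.
#' @param n_repeats Random splits per threshold (default 50).
#' @param holdout_frac Fraction held out for validation (default 0.3).
#' @param tolerance Accuracy drop treated as significant (default 0.02).
#' @param seed Integer seed; the whole sweep is deterministic given it.
#' @param cost,class_weights Passed to [focis_train()].
#' @param feature_cols Candidate feature columns.
#' @return A `focis_selection` object: `kept_features`, `path` (tibble of
#'   threshold, n_features, mean/sd accuracy, features list-column),
#'   `f_scores`, `n_repeats`, `seed`.
#' @export
select_features <- function(features, labels, thresholds = NULL,
                            n_repeats = 50L, holdout_frac = 0.3,
                            tolerance = 0.02, seed = 1L,
                            cost = 100, class_weights = c(RFN = 10, ART = 1),
                            feature_cols = NULL) {
  feature_cols <- default_feature_cols(features, feature_cols)
  y <- align_labels(features, labels)
  if (nrow(features) < 10L) stop("need at least 10 samples", call. = FALSE)
  fs <- f_score_table(features, y, feature_cols)
  if (is.null(thresholds)) {
    thresholds <- c(0, sort(unique(fs$f_score[is.finite(fs$f_score)])))
  }
  if (is.unsorted(thresholds)) stop("`thresholds` must be ascending", call. = FALSE)

  idx_by_class <- split(seq_along(y), y)
  path <- list()
  best <- -Inf
  withr::with_seed(as.integer(seed), {
    for (th in thresholds) {
      kept <- fs$feature[fs$f_score >= th]
      if (length(kept) == 0L) break
      accs <- vapply(seq_len(n_repeats), function(r) {
        val <- unlist(lapply(idx_by_class, function(ix)
          sample(ix, max(1L, round(length(ix) * holdout_frac)))))
        tr_idx <- setdiff(seq_along(y), val)
        model <- focis_train(features[tr_idx, , drop = FALSE], y[tr_idx],
                             cost = cost, class_weights = class_weights,
                             feature_cols = kept)
        pred <- predict(model, features[val, , drop = FALSE])
        mean(pred == y[val])
      }, numeric(1))
      path[[length(path) + 1L]] <- tibble(
        threshold = th, n_features = length(kept),
        mean_accuracy = mean(accs), sd_accuracy = stats::sd(accs),
        features = list(kept))
      best <- max(best, mean(accs))
      if (mean(accs) < best - tolerance) break
    }
  })
  path <- dplyr::bind_rows(path)
  ok <- path$mean_accuracy >= max(path$mean_accuracy) - tolerance
  kept_row <- path[ok, ][which.min(path$n_features[ok]), ]
  structure(list(kept_features = kept_row$features[[1]],
                 path = path, f_scores = fs,
                 n_repeats = as.integer(n_repeats),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "focis_selection")
}

#' @export
print.focis_selection <- function(x, ...) {
  cat("<focis_selection> kept:", paste(x$kept_features, collapse = ", "), "\n")
  print(dplyr::select(x$path, -"features"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname select_features
#' @param x A `focis_selection` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.focis_selection <- function(x, ...) dplyr::select(x$path, -"features")

#' @rdname select_features
#' @exportS3Method generics::glance
glance.focis_selection <- function(x, ...) {
  tibble(n_kept = length(x$kept_features),
         best_accuracy = max(x$path$mean_accuracy),
         n_thresholds = nrow(x$path),
         n_repeats = x$n_repeats, seed = x$seed)
}

#' Explanatory-power test via a binomial GLM
#'
#' Logistic regression (binomial variance, logit link) of class membership on
#' the conditioned features, with per-coefficient Wald statistics and the
#' model AIC. Perfect separation is reported via the `separation` flag
#' rather than an error: the fit then sits at the optimizer's boundary and
#' the Wald p-values are untrustworthy.
#'
#' @param features Conditioned feature tibble.
#' @param labels Label vector or `(id, label)` tibble; the positive class is
#'   `"RFN"` when present, else the second factor level.
#' @param feature_cols Feature columns to include.
#' @return A `focis_glm` object wrapping the [stats::glm()] fit, with
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
glm_explanatory <- function(features, labels, feature_cols = NULL) {
  feature_cols <- default_feature_cols(features, feature_cols)
  y <- align_labels(features, labels)
  lev <- unique(y)
  if (length(lev) != 2L) stop("need exactly two classes", call. = FALSE)
  positive <- if ("RFN" %in% lev) "RFN" else lev[2]
  df <- features[, feature_cols, drop = FALSE]
  df$.y <- as.integer(y == positive)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  # a boundary fit can also converge quietly; check the fitted probabilities
  if (!separation && all(abs(fit$fitted.values - df$.y) < 1e-6))
    separation <- TRUE
  structure(list(fit = fit, positive = positive, separation = separation),
            class = "focis_glm")
}

#' @export
print.focis_glm <- function(x, ...) {
  cat("<focis_glm> positive class:", x$positive,
      if (x$separation) "(perfect separation detected)" else "", "\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname glm_explanatory
#' @param x A `focis_glm` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.focis_glm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' @rdname glm_explanatory
#' @exportS3Method generics::glance
glance.focis_glm <- function(x, ...) {
  tibble(aic = stats::AIC(x$fit),
         deviance = stats::deviance(x$fit),
         null_deviance = x$fit$null.deviance,
         df_residual = stats::df.residual(x$fit),
         n = stats::nobs(x$fit),
         separation = x$separation)
}

#' Relative AIC of two models
#'
#' `exp((aic_a - aic_b) / 2)` estimates how probable it is that model A
#' minimizes information loss relative to model B; values far below 1 favour
#' model A.
#'
#' @param aic_a,aic_b Finite AIC values.
#' @return Positive scalar.
#' @export
relative_aic <- function(aic_a, aic_b) {
  if (!is.finite(aic_a) || !is.finite(aic_b)) stop("AIC values must be finite", call. = FALSE)
  exp((aic_a - aic_b) / 2)
}
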