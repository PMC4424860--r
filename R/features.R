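#' @name ic_feature_set
#' @title The five component features
#'
#' @description
#' Five features summarize one IC, mirroring the visual criteria raters use
#' to separate resting-state networks from artifacts:
#'
#' * `gm_pos_overlap` — fraction of suprathreshold positive statistic mass
#'   inside the gray-matter mask (value-weighted), in \[0, 1\].
#' * `peak_in_gm` — 1 if the suprathreshold peak voxel lies in gray matter.
#' * `freq_ratio` — periodogram power of the time course within the
#'   low-frequency band (default 0.01–0.08 Hz) over total non-DC power.
#' * `lag1_autocorr` — lag-1 Pearson autocorrelation of the time course.
#' * `bbox_voxel_ratio` — size-weighted mean over clusters of bounding-box
#'   volume / cluster size; 1 for solid blocks, large for sheets and rims.
#'
#' Components whose map retains no cluster after filtering are degenerate:
#' their spatial features take documented defaults (`gm_pos_overlap = 0`,
#' `peak_in_gm = 0`, `bbox_voxel_ratio = 27`, the worst isolated-voxel
#' neighbourhood) and they are flagged so classification can force-label
#' them ART — such maps cannot represent a network under the extent rule.
NULL

focis_feature_names <- function() {
  c("gm_pos_overlap", "peak_in_gm", "freq_ratio", "lag1_autocorr", "bbox_voxel_ratio")
}

#' Fraction of positive suprathreshold mass inside gray matter
#'
#' Sum of positive statistic values over the suprathreshold voxels that fall
#' inside the gray-matter mask, divided by the same sum over all
#' suprathreshold voxels. Value-weighted rather than voxel-counted, so a
#' strong gray-matter peak dominates a faint spill-over.
#'
#' @param map A [stat_map()].
#' @param supra Suprathreshold [binary_mask()] (after extent filtering).
#' @param gm Gray-matter [binary_mask()].
#' @return Scalar in \[0, 1\]; 0 with a warning when no positive mass exists.
#' @export
feat_gm_pos_overlap <- function(map, supra, gm) {
  stopifnot(inherits(map, "stat_map"))
  check_mask_grid(map, supra, gm)
  v <- map$values
  pos <- supra$membership & v > 0
  denom <- sum(v[pos])
  if (denom <= 0) {
    warning("no positive suprathreshold mass; gm_pos_overlap defined as 0")
    return(0)
  }
  sum(v[pos & gm$membership]) / denom
}

#' Is the suprathreshold peak voxel in gray matter?
#'
#' @inheritParams feat_gm_pos_overlap
#' @return 1 or 0. Ties at the maximum resolve to the lowest linear voxel
#'   index; an empty mask gives 0 with a warning.
#' @export
feat_peak_in_gm <- function(map, supra, gm) {
  stopifnot(inherits(map, "stat_map"))
  check_mask_grid(map, supra, gm)
  idx <- which(supra$membership)
  if (length(idx) == 0L) {
    warning("empty suprathreshold mask; peak_in_gm defined as 0")
    return(0)
  }
  vals <- map$values[idx]
  if (max(vals) <= 0) {
    warning("no positive suprathreshold voxel; peak_in_gm defined as 0")
    return(0)
  }
  peak <- idx[which.max(vals)]  # which() is ascending, so first max = lowest index
  as.numeric(gm$membership[peak])
}

check_mask_grid <- function(map, ...) {
  for (m in list(...)) {
    stopifnot(inherits(m, "binary_mask"))
    if (!same_grid(m$grid, map$grid)) stop("mask grid mismatch", call. = FALSE)
  }
  invisible(TRUE)
}

#' Low-frequency power fraction of a time course
#'
#' Plain (untapered) periodogram of the demeaned series; the ratio of power
#' at frequencies within `band` to total power over (0, Nyquist\]. The DC
#' term is excluded. Resting-state fluctuations concentrate below 0.08 Hz,
#' so networks score near 1 and high-frequency artifacts near 0.
#'
#' @param samples Numeric time course (length >= 8).
#' @param tr Sampling interval in seconds.
#' @param band Numeric `(f_lo, f_hi)` in Hz; `f_hi` must not exceed Nyquist.
#' @return Scalar in \[0, 1\]; 0 with a warning for a constant series.
#' @export
feat_freq_ratio <- function(samples, tr, band = c(0.01, 0.08)) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 8L) stop("time course must have length >= 8", call. = FALSE)
  if (!is.finite(tr) || tr <= 0) stop("`tr` must be positive", call. = FALSE)
  nyquist <- 1 / (2 * tr)
  if (band[2] > nyquist + 1e-12)
    stop("band upper edge ", band[2], " Hz exceeds Nyquist ", nyquist, " Hz", call. = FALSE)
  x <- samples - mean(samples)
  if (stats::sd(x) == 0) {
    warning("constant time course; freq_ratio defined as 0")
    return(0)
  }
  pw <- Mod(stats::fft(x))^2
  k <- seq_len(floor(n / 2))          # positive frequencies, DC excluded
  freqs <- k / (n * tr)
  pw <- pw[k + 1L]
  sum(pw[freqs >= band[1] & freqs <= band[2]]) / sum(pw)
}

#' Lag-1 autocorrelation of a time course
#'
#' Pearson correlation between the series and its one-sample shift. Slow
#' hemodynamic fluctuations give values near 1; spiky or alternating
#' artifacts give values near 0 or below.
#'
#' @param samples Numeric time course (length >= 3, non-constant).
#' @return Scalar in \[-1, 1\].
#' @export
feat_lag1_autocorr <- function(samples) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(samples) == 0) stop("zero variance time course", call. = FALSE)
  stats::cor(samples[-n], samples[-1])
}

#' Bounding-box to voxel-count ratio of the retained clusters
#'
#' For each cluster, bounding-box volume divided by cluster size; averaged
#' over clusters with size weights. Solid compact blobs score 1; planes,
#' shells and diagonal streaks score high. With no clusters the feature is
#' capped at 27 (a single voxel against its full 3x3x3 neighbourhood), the
#' documented worst case, with a warning.
#'
#' @param clusters Cluster tibble from [find_clusters()]/[filter_clusters()].
#' @return Scalar >= 1 (or the 27 cap for an empty list).
#' @export
feat_bbox_voxel_ratio <- function(clusters) {
  if (nrow(clusters) == 0L) {
    warning("no clusters; bbox_voxel_ratio capped at 27")
    return(27)
  }
  stats::weighted.mean(clusters$bbox_volume / clusters$size, w = clusters$size)
}

#' Extract the five features for one component
#'
#' Applies the filtering pipeline (voxelwise threshold, contiguous clusters,
#' extent filter) and then the five feature computations.
#'
#' @param component An [ic_component()].
#' @param gm Gray-matter [binary_mask()] on the component's grid.
#' @param spec A [threshold_spec()].
#' @param band Low-frequency band (Hz) for `freq_ratio`.
#' @param connectivity Cluster neighbourhood.
#' @return One-row tibble: `id`, the five features, `n_clusters`,
#'   `n_suprathreshold`, `degenerate`.
#' @export
extract_features <- function(component, gm, spec = threshold_spec(),
                             band = c(0.01, 0.08), connectivity = 6) {
  stopifnot(inherits(component, "ic_component"))
  st <- suprathreshold_mask(component$map, spec, connectivity)
  degenerate <- nrow(st$clusters) == 0L
  if (degenerate) {
    gmov <- 0; pk <- 0; bbr <- 27
  } else {
    gmov <- feat_gm_pos_overlap(component$map, st$mask, gm)
    pk <- feat_peak_in_gm(component$map, st$mask, gm)
    bbr <- feat_bbox_voxel_ratio(st$clusters)
  }
  tibble(
    id = component$id,
    gm_pos_overlap = gmov,
    peak_in_gm = pk,
    freq_ratio = feat_freq_ratio(component$samples, component$tr, band),
    lag1_autocorr = feat_lag1_autocorr(component$samples),
    bbox_voxel_ratio = bbr,
    n_clusters = nrow(st$clusters),
    n_suprathreshold = sum(st$mask$membership),
    degenerate = degenerate
  )
}

#' Feature table for a whole ICA set
#'
#' @param set An [ica_set()].
#' @param gm Gray-matter [binary_mask()].
#' @inheritParams extract_features
#' @return Tibble with one row per component (see [extract_features()]).
#' @export
ic_features <- function(set, gm, spec = threshold_spec(),
                        band = c(0.01, 0.08), connectivity = 6) {
  stopifnot(inherits(set, "ica_set"))
  purrr::map_dfr(set$components, extract_features,
                 gm = gm, spec = spec, band = band, connectivity = connectivity)
}

#' Fit feature conditioning statistics on a training table
#'
#' Conditioning is mean-centering and scaling by the sample standard
#' deviation, fitted on the training set and then applied unchanged to any
#' set being classified.
#'
#' @param features Feature tibble (e.g. from [ic_features()]).
#' @param feature_cols Character vector of columns to condition; defaults to
#'   the five standard features present in `features`.
#' @return Tibble `(feature, mean, sd)`; zero-variance features are an error
#'   naming the offender.
#' @export
fit_conditioning <- function(features, feature_cols = NULL) {
  feature_cols <- default_feature_cols(features, feature_cols)
  if (nrow(features) < 2L) stop("need at least 2 training vectors", call. = FALSE)
  stats_tbl <- purrr::map_dfr(feature_cols, function(f) {
    x <- features[[f]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("feature `", f, "` has zero variance on the training set", call. = FALSE)
    tibble(feature = f, mean = mean(x), sd = s)
  })
  stats_tbl
}

#' Apply conditioning statistics to a feature table
#'
#' @param features Feature tibble.
#' @param conditioning Tibble from [fit_conditioning()].
#' @return `features` with the conditioned columns replaced by
#'   `(x - mean) / sd`; gains attribute `conditioned = TRUE`.
#' @export
apply_conditioning <- function(features, conditioning) {
  stopifnot(all(c("feature", "mean", "sd") %in% names(conditioning)))
  out <- features
  for (i in seq_len(nrow(conditioning))) {
    f <- conditioning$feature[i]
    if (!f %in% names(out)) stop("feature `", f, "` missing from table", call. = FALSE)
    out[[f]] <- (out[[f]] - conditioning$mean[i]) / conditioning$sd[i]
  }
  attr(out, "conditioned") <- TRUE
  out
}

default_feature_cols <- function(features, feature_cols) {
  if (!is.null(feature_cols)) return(feature_cols)
  cols <- intersect(focis_feature_names(), names(features))
  if (length(cols) == 0L) stop("no recognised feature columns", call. = FALSE)
  cols
}

#' Andrews-curve projection of a feature vector
#'
#' Projects a 5-vector x onto `[sin t, cos t, sin 2t, cos 2t, sin 3t]`:
#' `f(x, t) = x1 sin t + x2 cos t + x3 sin 2t + x4 cos 2t + x5 sin 3t`,
#' uniquely defined for t in \[-pi, pi\]. Used to visualize the conditioned
#' feature space with one curve per component.
#'
#' @param x Numeric vector of length 5.
#' @param t Numeric vector of evaluation points.
#' @return Numeric vector, one value per `t`.
#' @export
andrews_projection <- function(x, t) {
  x <- as.numeric(x)
  if (length(x) != 5L) stop("`x` must have exactly 5 components", call. = FALSE)
  x[1] * sin(t) + x[2] * cos(t) + x[3] * sin(2 * t) + x[4] * cos(2 * t) + x[5] * sin(3 * t)
}

#' Andrews curves for a feature table
#'
#' @param features Feature tibble (ideally conditioned) with an `id` column.
#' @param labels Optional label tibble `(id, label)` to colour curves.
#' @param feature_cols Feature columns, in projection order (5 required).
#' @param n_points Number of evaluation points on \[-pi, pi\].
#' @return Long tibble `(id, t, value, label)`.
#' @export
andrews_curves <- function(features, labels = NULL, feature_cols = NULL, n_points = 201L) {
  feature_cols <- default_feature_cols(features, feature_cols)
  if (length(feature_cols) != 5L) stop("Andrews projection needs 5 features", call. = FALSE)
  tt <- seq(-pi, pi, length.out = n_points)
  out <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    x <- as.numeric(features[i, feature_cols])
    tibble(id = features$id[i], t = tt, value = andrews_projection(x, tt))
  })
  if (!is.null(labels)) out <- dplyr::left_join(out, labels, by = "id")
  out
}

#' Plot Andrews curves of the component feature space
#'
#' @inheritParams andrews_curves
#' @return A ggplot object.
#' @export
plot_andrews <- function(features, labels = NULL, feature_cols = NULL, n_points = 201L) {
  df <- andrews_curves(features, labels, feature_cols, n_points)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                        group = .data$id))
  if ("label" %in% names(df)) {
    p <- p + ggplot2::aes(colour = .data$label) +
      ggplot2::scale_colour_manual(values = c(ART = "black", RFN = "red"))
  }
  p + ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "t", y = "f(x, t)", colour = NULL) +
    ggplot2::theme_minimal()
}
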