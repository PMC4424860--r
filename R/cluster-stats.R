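#' Voxelwise-plus-extent thresholding specification
#'
#' Bundles the voxelwise p threshold, the degrees of freedom (or `NULL` for a
#' normal quantile), the minimum cluster extent and sidedness. The defaults
#' are the filtering rule applied to every IC map before feature extraction:
#' p < 0.001 voxelwise with clusters of at least 20 contiguous voxels.
#'
#' @param voxel_p Voxelwise tail probability, in (0, 1).
#' @param df Degrees of freedom for a Student-t cutoff, or `NULL` to use the
#'   standard-normal quantile (z maps).
#' @param min_cluster Minimum cluster extent in voxels (>= 1).
#' @param sided `"one"` (positive tail) or `"two"` (threshold |value|).
#' @return A `threshold_spec` object.
#' @export
threshold_spec <- function(voxel_p = 0.001, df = NULL, min_cluster = 20L,
                           sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!is.finite(voxel_p) || voxel_p <= 0 || voxel_p >= 1)
    stop("`voxel_p` must lie in (0, 1)", call. = FALSE)
  if (!is.null(df) && (!is.finite(df) || df < 1))
    stop("`df` must be >= 1 or NULL for a z cutoff", call. = FALSE)
  min_cluster <- as.integer(min_cluster)
  if (min_cluster < 1L) stop("`min_cluster` must be >= 1", call. = FALSE)
  structure(list(voxel_p = voxel_p, df = df, min_cluster = min_cluster, sided = sided),
            class = "threshold_spec")
}

stat_cutoff <- function(spec) {
  p <- if (spec$sided == "two") spec$voxel_p / 2 else spec$voxel_p
  if (is.null(spec$df)) stats::qnorm(1 - p) else stats::qt(1 - p, df = spec$df)
}

#' Threshold a statistic map voxelwise
#'
#' A voxel survives when its statistic exceeds the upper-tail quantile
#' implied by `spec$voxel_p` (the absolute value is used for two-sided
#' specs). Extent filtering is separate: see [find_clusters()] and
#' [filter_clusters()], or [suprathreshold_mask()] for the combined rule.
#'
#' @param map A [stat_map()].
#' @param spec A [threshold_spec()].
#' @return A [binary_mask()] of suprathreshold voxels.
#' @export
threshold_map <- function(map, spec = threshold_spec()) {
  stopifnot(inherits(map, "stat_map"), inherits(spec, "threshold_spec"))
  cut <- stat_cutoff(spec)
  v <- if (spec$sided == "two") abs(map$values) else map$values
  binary_mask(v > cut, map$grid)
}

neighbour_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dist <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
                 "6" = dist == 1,
                 "18" = dist >= 1 & rowSums(offs != 0) <= 2,
                 "26" = dist >= 1,
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  offs[keep, , drop = FALSE]
}

cluster_members <- function(mem, dims, connectivity) {
  offs <- neighbour_offsets(connectivity)
  # half the offsets suffice: each adjacency is seen from one side
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), , drop = FALSE]
  idx <- which(mem)                       # sorted linear indices of set voxels
  if (length(idx) == 0L) return(list())
  co <- arrayInd(idx, dims)
  # union-find over the set voxels, edges from the neighbour offsets
  parent <- seq_along(idx)
  find_root <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (k in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[k, ], nrow(co), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] + (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    j <- match(lin, idx)                  # NA when the neighbour is unset
    a <- which(ok)[!is.na(j)]
    b <- j[!is.na(j)]
    for (e in seq_along(a)) {
      ra <- find_root(a[e]); rb <- find_root(b[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(idx), find_root, integer(1))
  groups <- split(idx, roots)
  # order clusters by their lowest voxel index
  unname(lapply(groups[order(vapply(groups, min, numeric(1)))], sort))
}

#' Find contiguous suprathreshold clusters
#'
#' Connected-component labelling by union-find over the chosen voxel
#' neighbourhood. Face adjacency (6) is the default — the most
#' conservative notion of contiguity, AFNI's NN=1.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full cube).
#' @param source Optional [stat_map()] used to locate each cluster's peak;
#'   peak ties are broken by lowest linear voxel index.
#' @return A tibble with one row per cluster: `cluster`, `size`, bounding-box
#'   side lengths `bbox_x/y/z`, `bbox_volume`, `peak_voxel` (1-based linear
#'   index), `peak_value`, and a list-column `voxels` of sorted linear
#'   indices. Empty mask gives zero rows.
#' @export
find_clusters <- function(mask, connectivity = 6, source = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.null(source)) {
    stopifnot(inherits(source, "stat_map"))
    if (!same_grid(source$grid, mask$grid)) stop("source map grid mismatch", call. = FALSE)
  }
  dims <- mask$grid$dims
  members <- cluster_members(mask$membership, dims, connectivity)
  if (length(members) == 0L) {
    return(tibble(cluster = integer(), size = integer(),
                  bbox_x = integer(), bbox_y = integer(), bbox_z = integer(),
                  bbox_volume = integer(), peak_voxel = integer(),
                  peak_value = numeric(), voxels = list()))
  }
  rows <- lapply(seq_along(members), function(i) {
    vox <- members[[i]]
    co <- arrayInd(vox, dims)
    bbox <- apply(co, 2, function(z) diff(range(z)) + 1L)
    if (!is.null(source)) {
      vals <- source$values[vox]
      pk <- vox[which.max(vals)]   # first max = lowest linear index on ties
      pv <- max(vals)
    } else {
      pk <- vox[1]
      pv <- NA_real_
    }
    tibble(cluster = i, size = length(vox),
           bbox_x = bbox[1], bbox_y = bbox[2], bbox_z = bbox[3],
           bbox_volume = as.integer(prod(bbox)),
           peak_voxel = pk, peak_value = pv, voxels = list(vox))
  })
  dplyr::bind_rows(rows)
}

#' Drop clusters below the extent threshold
#'
#' @param clusters Cluster tibble from [find_clusters()].
#' @param min_cluster Minimum size in voxels.
#' @return The retained rows, order preserved.
#' @export
filter_clusters <- function(clusters, min_cluster = 20L) {
  min_cluster <- as.integer(min_cluster)
  if (min_cluster < 1L) stop("`min_cluster` must be >= 1", call. = FALSE)
  dplyr::filter(clusters, .data$size >= min_cluster)
}

#' Combined voxelwise + extent filtering of one map
#'
#' The standard filtering rule applied to every IC before feature
#' extraction: threshold voxelwise, find contiguous clusters, keep those of
#' at least `spec$min_cluster` voxels.
#'
#' @inheritParams threshold_map
#' @param connectivity Neighbourhood passed to [find_clusters()].
#' @return List with `clusters` (filtered tibble, peaks computed from `map`)
#'   and `mask` (a [binary_mask()] of the retained voxels).
#' @export
suprathreshold_mask <- function(map, spec = threshold_spec(), connectivity = 6) {
  cl <- filter_clusters(find_clusters(threshold_map(map, spec), connectivity, source = map),
                        spec$min_cluster)
  mem <- array(FALSE, map$grid$dims)
  if (nrow(cl)) mem[unlist(cl$voxels)] <- TRUE
  list(clusters = cl, mask = binary_mask(mem, map$grid))
}

gaussian_axis_matrix <- function(n, voxel_mm, fwhm_mm) {
  if (fwhm_mm <= 0) return(diag(n))
  s <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j) * voxel_mm)
  k <- exp(-d^2 / (2 * s^2))
  sweep(k, 1, rowSums(k), "/")
}

smooth_volume <- function(vol, mats) {
  d <- dim(vol)
  # contract each axis in turn via matrix products on unfolded arrays
  m <- mats[[1]] %*% matrix(vol, d[1], d[2] * d[3])
  vol <- array(m, d)
  vol <- aperm(vol, c(2, 1, 3))
  m <- mats[[2]] %*% matrix(vol, d[2], d[1] * d[3])
  vol <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  vol <- aperm(vol, c(3, 2, 1))
  m <- mats[[3]] %*% matrix(vol, d[3], d[2] * d[1])
  aperm(array(m, c(d[3], d[2], d[1])), c(3, 2, 1))
}

#' Monte-Carlo calibration of the cluster-extent null
#'
#' Estimates, for a given grid, smoothness and voxelwise threshold, the
#' probability that pure noise produces a suprathreshold cluster of at least
#' k voxels anywhere in the mask. Each iteration draws unit Gaussian white
#' noise, smooths it with a Gaussian kernel of the stated FWHM,
#' re-standardizes to zero mean and unit variance within the mask (so the
#' voxelwise cutoff stays calibrated after smoothing), thresholds at
#' `voxel_p` (one-sided z), and records the largest cluster.
#'
#' @param grid A [volume_grid()].
#' @param fwhm_mm Smoothing kernel FWHM in mm (0 = no smoothing).
#' @param voxel_p Voxelwise threshold probability.
#' @param n_iter Number of noise realizations (>= 100).
#' @param seed Integer seed; identical seeds give identical calibrations.
#' @param mask Optional [binary_mask()]; defaults to the full grid.
#' @param connectivity Cluster neighbourhood (default 6).
#' @return A `cluster_calibration` object; its `prob` element is a tibble
#'   `(size, prob)` with `prob[k] = P(max cluster >= k)`, non-increasing in k.
#' @export
calibrate_cluster_null <- function(grid, fwhm_mm, voxel_p = 0.001, n_iter = 2000L,
                                   seed = 1L, mask = NULL, connectivity = 6) {
  stopifnot(inherits(grid, "volume_grid"))
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0", call. = FALSE)
  n_iter <- as.integer(n_iter)
  if (n_iter < 100L) stop("`n_iter` must be >= 100", call. = FALSE)
  if (is.null(mask)) mask <- binary_mask(array(TRUE, grid$dims), grid)
  if (!same_grid(mask$grid, grid)) stop("mask grid mismatch", call. = FALSE)
  if (!any(mask$membership)) stop("degenerate mask: no voxels", call. = FALSE)
  cut <- stats::qnorm(1 - voxel_p)
  mats <- lapply(1:3, function(a) gaussian_axis_matrix(grid$dims[a], grid$voxel_size[a], fwhm_mm))
  in_mask <- which(mask$membership)
  nvox <- prod(grid$dims)
  max_sizes <- integer(n_iter)
  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      vol <- array(stats::rnorm(nvox), grid$dims)
      if (fwhm_mm > 0) vol <- smooth_volume(vol, mats)
      v <- vol[in_mask]
      v <- (v - mean(v)) / stats::sd(v)
      supra <- array(FALSE, grid$dims)
      supra[in_mask[v > cut]] <- TRUE
      if (!any(supra)) next
      members <- cluster_members(supra, grid$dims, connectivity)
      max_sizes[it] <- max(lengths(members))
    }
  })
  kmax <- max(max_sizes, 1L)
  ks <- seq_len(kmax)
  prob <- vapply(ks, function(k) mean(max_sizes >= k), numeric(1))
  structure(list(prob = tibble(size = ks, prob = prob),
                 fwhm_mm = fwhm_mm, voxel_p = voxel_p, n_iter = n_iter,
                 grid = grid, seed = as.integer(seed),
                 connectivity = connectivity, max_sizes = max_sizes),
            class = "cluster_calibration")
}

#' @export
print.cluster_calibration <- function(x, ...) {
  cat("<cluster_calibration> FWHM ", x$fwhm_mm, " mm, p < ", x$voxel_p,
      ", ", x$n_iter, " iterations on ",
      paste(x$grid$dims, collapse = " x "), "\n", sep = "")
  print(utils::head(x$prob, 10))
  invisible(x)
}

#' Null probability of observing a cluster of at least k voxels
#'
#' @param calibration A `cluster_calibration` from [calibrate_cluster_null()].
#' @param k Cluster size(s) in voxels.
#' @return Estimated `P(max cluster >= k)` per `k`; 0 beyond the largest
#'   simulated cluster.
#' @export
cluster_null_prob <- function(calibration, k) {
  stopifnot(inherits(calibration, "cluster_calibration"))
  p <- calibration$prob
  vapply(as.integer(k), function(ki) {
    if (ki <= 0L) 1 else if (ki > max(p$size)) 0 else p$prob[p$size == ki]
  }, numeric(1))
}
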