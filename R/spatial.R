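#' focis: classification and tracking of ICA components from resting-state fMRI
#'
#' Spatial maps live on a shared [volume_grid()]; components pair a
#' [stat_map()] with a time course. All tabular results are tibbles so the
#' pipeline composes with dplyr verbs.
#'
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

#' Define a 3D voxel grid
#'
#' A grid couples array dimensions with voxel size (mm) and a voxel-to-world
#' affine. The affine is carried through I/O but never used for resampling:
#' all inputs are assumed pre-aligned, and any grid mismatch is an error.
#'
#' @param dims Integer vector of length 3 (voxels along x, y, z).
#' @param voxel_size Numeric vector of length 3, voxel edge lengths in mm.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity built from `voxel_size`.
#' @return A `volume_grid` object.
#' @export
#' @examples
#' volume_grid(c(32, 32, 16), c(3, 3, 3))
volume_grid <- function(dims, voxel_size = c(3, 3, 3), affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("`dims` must be three integers >= 1", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive lengths (mm)", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$dims, collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size, 3), collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

#' Test whether two grids coincide
#'
#' Grids match when dimensions agree and voxel sizes agree to numerical
#' tolerance. The affine is deliberately excluded: maps that only differ in
#' world anchoring still share a voxel lattice.
#'
#' @param a,b `volume_grid` objects.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b) {
  stopifnot(inherits(a, "volume_grid"), inherits(b, "volume_grid"))
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-6))
}

#' Voxelwise statistic map for one component
#'
#' @param values 3D numeric array (t or z units) matching `grid$dims`.
#' @param grid A [volume_grid()].
#' @return A `stat_map` object.
#' @export
stat_map <- function(values, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$dims))
    stop("map extent does not match grid dims", call. = FALSE)
  if (!all(is.finite(values)))
    stop("stat map contains non-finite values", call. = FALSE)
  structure(list(values = values, grid = grid), class = "stat_map")
}

#' Binary voxel mask
#'
#' @param membership Logical (or 0/1 numeric) 3D array matching `grid$dims`.
#' @param grid A [volume_grid()].
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(membership, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  membership <- as.array(membership)
  if (length(dim(membership)) != 3L || !all(dim(membership) == grid$dims))
    stop("mask extent does not match grid dims", call. = FALSE)
  if (anyNA(membership)) stop("mask contains NA", call. = FALSE)
  storage.mode(membership) <- "logical"
  structure(list(membership = membership, grid = grid), class = "binary_mask")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", paste(x$grid$dims, collapse = " x "),
      ", range [", signif(min(x$values), 4), ", ", signif(max(x$values), 4), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(x$grid$dims, collapse = " x "),
      ", ", sum(x$membership), " voxels set\n", sep = "")
  invisible(x)
}

#' One IC: a spatial statistic map paired with its time course
#'
#' @param id Integer component id (0-based, unique within a set).
#' @param map A [stat_map()].
#' @param samples Numeric time-course vector (length >= 8).
#' @param tr Repetition time in seconds (> 0).
#' @return An `ic_component` object.
#' @export
ic_component <- function(id, map, samples, tr) {
  stopifnot(inherits(map, "stat_map"))
  id <- as.integer(id)
  samples <- as.numeric(samples)
  if (length(samples) < 8L) stop("time course must have length >= 8", call. = FALSE)
  if (!all(is.finite(samples))) stop("time course contains non-finite values", call. = FALSE)
  if (!is.finite(tr) || tr <= 0) stop("`tr` must be a positive time in seconds", call. = FALSE)
  structure(list(id = id, map = map, samples = samples, tr = as.numeric(tr)),
            class = "ic_component")
}

#' A full ICA decomposition: NIC components on one grid
#'
#' @param components List of [ic_component()] objects sharing one grid,
#'   time-course length and TR, with unique ids.
#' @param source_tag Free-text provenance label.
#' @return An `ica_set` object with element `nic`.
#' @export
ica_set <- function(components, source_tag = "") {
  stopifnot(length(components) >= 1L,
            all(vapply(components, inherits, logical(1), "ic_component")))
  grid <- components[[1]]$map$grid
  n_t <- length(components[[1]]$samples)
  tr <- components[[1]]$tr
  for (comp in components) {
    if (!same_grid(comp$map$grid, grid)) stop("components on mismatched grids", call. = FALSE)
    if (length(comp$samples) != n_t || comp$tr != tr)
      stop("components with mismatched time courses", call. = FALSE)
  }
  ids <- vapply(components, function(c) c$id, integer(1))
  if (anyDuplicated(ids)) stop("component ids must be unique", call. = FALSE)
  structure(list(nic = length(components), components = components,
                 grid = grid, tr = tr, source_tag = source_tag),
            class = "ica_set")
}

#' @export
print.ica_set <- function(x, ...) {
  cat("<ica_set> NIC = ", x$nic, ", grid ",
      paste(x$grid$dims, collapse = " x "),
      ", T = ", length(x$components[[1]]$samples),
      " @ TR ", x$tr, " s", sep = "")
  if (nzchar(x$source_tag)) cat("  [", x$source_tag, "]", sep = "")
  cat("\n")
  invisible(x)
}

ids_of <- function(set) vapply(set$components, function(c) c$id, integer(1))

get_component <- function(set, id) {
  i <- match(as.integer(id), ids_of(set))
  if (is.na(i)) stop("component id ", id, " not present in set", call. = FALSE)
  set$components[[i]]
}
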