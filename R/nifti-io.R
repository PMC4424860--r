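grid_from_nifti <- function(img) {
  d <- dim(img)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  volume_grid(d[1:3], pd[1:3], affine = unclass(RNifti::xform(img)))
}

#' Read a 4D stack of IC statistic maps (melodic_IC layout)
#'
#' Each volume along the 4th dimension becomes one [stat_map()]. Files with
#' NaN voxels are rejected outright: the pipeline has no NaN semantics and a
#' silent fill would bias the spatial features.
#'
#' @param path Path to a 4D NIfTI file (`.nii` or `.nii.gz`).
#' @return List of `stat_map`, one per component, sharing one grid.
#' @export
read_ic_maps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected 4D image (one volume per IC), got ", length(d), "D", call. = FALSE)
  arr <- as.array(img)
  if (anyNA(arr)) stop("IC maps contain NaN voxels; refusing to read", call. = FALSE)
  grid <- grid_from_nifti(img)
  lapply(seq_len(d[4]), function(i) stat_map(arr[, , , i], grid))
}

#' Write IC statistic maps as a 4D NIfTI file
#'
#' @param maps List of [stat_map()] on a common grid.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_ic_maps <- function(maps, path) {
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, logical(1), "stat_map")))
  grid <- maps[[1]]$grid
  for (m in maps) if (!same_grid(m$grid, grid)) stop("maps on mismatched grids", call. = FALSE)
  arr <- array(0, c(grid$dims, length(maps)))
  for (i in seq_along(maps)) arr[, , , i] <- maps[[i]]$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(grid$voxel_size, 1)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a melodic-style mixing matrix as time courses
#'
#' The text file holds T rows by NIC columns; column `j` is the time course
#' of component `j` (the melodic dialect). Ragged rows and non-numeric
#' tokens are hard errors.
#'
#' @param path Path to whitespace-delimited text.
#' @param tr Repetition time in seconds.
#' @return List of time courses, each a list with elements `samples` and `tr`.
#' @export
read_mixing_matrix <- function(path, tr) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!is.finite(tr) || tr <= 0) stop("`tr` must be positive seconds", call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty mixing matrix", call. = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  ncols <- length(toks[[1]])
  if (any(lengths(toks) != ncols))
    stop("ragged mixing matrix: rows have differing column counts", call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) stop("non-numeric token in mixing matrix", call. = FALSE)
  mat <- matrix(vals, nrow = length(toks), ncol = ncols, byrow = TRUE)
  lapply(seq_len(ncols), function(j) list(samples = mat[, j], tr = tr))
}

#' Write time courses as a melodic-style mixing matrix
#'
#' @param timecourses List of numeric vectors (or lists with `samples`), all
#'   of one length; written as columns.
#' @param path Output text path.
#' @return `path`, invisibly.
#' @export
write_mixing_matrix <- function(timecourses, path) {
  cols <- lapply(timecourses, function(tc) if (is.list(tc)) tc$samples else as.numeric(tc))
  n <- unique(lengths(cols))
  if (length(n) != 1L) stop("time courses of differing lengths", call. = FALSE)
  mat <- do.call(cbind, cols)
  utils::write.table(format(mat, digits = 17, scientific = TRUE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a binary mask, checked against a reference grid
#'
#' Voxels are thresholded at 0.5 after reading. If `reference_grid` is given,
#' any dimension or voxel-size mismatch is a hard error — the framework never
#' resamples.
#'
#' @param path Path to a 3D NIfTI file.
#' @param reference_grid Optional [volume_grid()] the mask must match.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, reference_grid = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) dim(img) <- d[1:3]
  if (length(dim(img)) != 3L) stop("expected a 3D mask image", call. = FALSE)
  arr <- as.array(img)
  if (anyNA(arr)) stop("mask contains NaN voxels", call. = FALSE)
  grid <- grid_from_nifti(img)
  if (!is.null(reference_grid) && !same_grid(grid, reference_grid))
    stop("grid mismatch: mask is ", paste(grid$dims, collapse = "x"),
         " but IC maps are ", paste(reference_grid$dims, collapse = "x"),
         call. = FALSE)
  binary_mask(arr > 0.5, grid)
}

#' Write a binary mask as NIfTI
#'
#' @param mask A [binary_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.numeric(mask$membership), mask$grid$dims))
  RNifti::pixdim(img) <- mask$grid$voxel_size
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read and write component label tables
#'
#' Labels are a two-column whitespace/tab-separated file: integer component
#' id, then `RFN` or `ART`. Any other label is rejected.
#'
#' @param path File path.
#' @return `read_labels()`: a tibble with columns `id` (integer) and
#'   `label` (character).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, col.names = c("id", "label"),
                          colClasses = c("integer", "character"))
  bad <- setdiff(unique(df$label), c("RFN", "ART"))
  if (length(bad))
    stop("labels must be RFN or ART; found: ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate component ids in label file", call. = FALSE)
  tibble(id = as.integer(df$id), label = df$label)
}

#' @rdname read_labels
#' @param labels Tibble/data frame with columns `id` and `label`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("id", "label") %in% names(labels)))
  bad <- setdiff(unique(labels$label), c("RFN", "ART"))
  if (length(bad)) stop("labels must be RFN or ART", call. = FALSE)
  utils::write.table(labels[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble an ICA set from melodic-style files
#'
#' Convenience reader wiring [read_ic_maps()] and [read_mixing_matrix()]
#' together, checking that the component counts agree.
#'
#' @param ic_path 4D NIfTI of component maps.
#' @param mix_path Mixing-matrix text file.
#' @param tr Repetition time (s).
#' @param source_tag Provenance label stored on the set.
#' @return An [ica_set()].
#' @export
read_ica_set <- function(ic_path, mix_path, tr, source_tag = ic_path) {
  maps <- read_ic_maps(ic_path)
  tcs <- read_mixing_matrix(mix_path, tr)
  if (length(maps) != length(tcs))
    stop("IC maps (", length(maps), ") and mixing-matrix columns (",
         length(tcs), ") disagree", call. = FALSE)
  comps <- lapply(seq_along(maps), function(i)
    ic_component(i - 1L, maps[[i]], tcs[[i]]$samples, tr))
  ica_set(comps, source_tag = source_tag)
}

#' Write an ICA set as melodic-style files
#'
#' @param set An [ica_set()].
#' @param dir Output directory (created if missing); writes `melodic_IC.nii.gz`
#'   and `melodic_mix`.
#' @return `dir`, invisibly.
#' @export
write_ica_set <- function(set, dir) {
  stopifnot(inherits(set, "ica_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ic_maps(lapply(set$components, function(c) c$map),
                file.path(dir, "melodic_IC.nii.gz"))
  write_mixing_matrix(lapply(set$components, function(c) c$samples),
                      file.path(dir, "melodic_mix"))
  invisible(dir)
}
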