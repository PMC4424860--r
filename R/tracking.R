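#' Train an epsilon-SVR tracker for one reference component
#'
#' One-vs-rest support vector regression on the conditioned five-feature
#' vectors of a reference ICA decomposition: the reference component gets
#' target 1, every other component target 0. Applying the model to another
#' decomposition scores each component's similarity to the reference; the
#' epsilon-insensitive loss ignores training residuals below `epsilon`.
#'
#' @param set Reference [ica_set()] (>= 3 components).
#' @param reference_id Id of the component to track.
#' @param gm Gray-matter [binary_mask()].
#' @param spec,band,connectivity Feature-extraction settings.
#' @param epsilon SVR insensitivity threshold (default 0.1).
#' @param cost SVR cost parameter (default 100, as for classification).
#' @param sigma Kernel width; `NULL` uses the robust inverse-median-squared
#'   distance heuristic ([estimate_sigma()] with `method = "median"`), which
#'   keeps the kernel wide enough to generalize on the few components of one
#'   decomposition.
#' @param seed Seed for the sigma heuristic.
#' @return A `focis_tracker` holding the SVR state, conditioning, and the
#'   reference id / NIC.
#' @export
train_tracker <- function(set, reference_id, gm, spec = threshold_spec(),
                          band = c(0.01, 0.08), connectivity = 6,
                          epsilon = 0.1, cost = 100, sigma = NULL, seed = NULL) {
  stopifnot(inherits(set, "ica_set"))
  if (set$nic < 3L) stop("reference set needs at least 3 components", call. = FALSE)
  if (!as.integer(reference_id) %in% ids_of(set))
    stop("reference id ", reference_id, " not present in set", call. = FALSE)
  feats <- ic_features(set, gm, spec, band, connectivity)
  conditioning <- fit_conditioning(feats)
  Xc <- as.matrix(apply_conditioning(feats, conditioning)[, focis_feature_names()])
  y <- as.numeric(feats$id == as.integer(reference_id))
  if (is.null(sigma)) sigma <- estimate_sigma(Xc, method = "median")
  fit <- kernlab::ksvm(Xc, y, type = "eps-svr", kernel = "rbfdot",
                       kpar = list(sigma = sigma), C = cost,
                       epsilon = epsilon, scaled = FALSE)
  structure(list(
    support_vectors = Xc[kernlab::SVindex(fit), , drop = FALSE],
    dual_coef = as.numeric(unlist(kernlab::coef(fit))),
    bias = kernlab::b(fit),
    sigma = sigma, cost = cost, epsilon = epsilon,
    conditioning = conditioning,
    feature_names = focis_feature_names(),
    reference_id = as.integer(reference_id),
    reference_nic = set$nic), class = "focis_tracker")
}

#' @export
print.focis_tracker <- function(x, ...) {
  cat("<focis_tracker> reference id ", x$reference_id, " of NIC = ",
      x$reference_nic, "; ", nrow(x$support_vectors), " support vectors\n", sep = "")
  invisible(x)
}

tracker_predict <- function(tracker, feats) {
  Xc <- as.matrix(apply_conditioning(feats, tracker$conditioning)[, tracker$feature_names])
  K <- rbf_kernel_matrix(Xc, tracker$support_vectors, tracker$sigma)
  as.numeric(K %*% tracker$dual_coef - tracker$bias)
}

#' Rank a target decomposition against the tracked reference
#'
#' SVR outputs are clipped to \[0, 1\] and reported as class probabilities
#' (no calibration step: near the training NIC the regression
#' near-interpolates its 0/1 targets). Components are ranked by descending
#' probability with ties broken by component id.
#'
#' @param tracker A `focis_tracker`.
#' @param set Target [ica_set()].
#' @param gm Gray-matter [binary_mask()].
#' @param spec,band,connectivity Feature-extraction settings (must match
#'   training).
#' @return Tibble `(rank, id, probability)`; row 1 is the best match.
#' @export
rank_components <- function(tracker, set, gm, spec = threshold_spec(),
                            band = c(0.01, 0.08), connectivity = 6) {
  stopifnot(inherits(tracker, "focis_tracker"), inherits(set, "ica_set"))
  if (set$nic < 1L) stop("empty target set", call. = FALSE)
  feats <- ic_features(set, gm, spec, band, connectivity)
  p <- pmin(pmax(tracker_predict(tracker, feats), 0), 1)
  ord <- order(-p, feats$id)
  tibble(rank = seq_along(ord), id = feats$id[ord], probability = p[ord])
}

#' Fraction of a reference mask covered by a candidate
#'
#' `|reference intersect candidate| / |reference|`: 1 when the candidate
#' covers the reference entirely, 0 when disjoint.
#'
#' @param reference,candidate [binary_mask()] objects on one grid;
#'   `reference` must be non-empty.
#' @return Scalar in \[0, 1\].
#' @export
spatial_overlap <- function(reference, candidate) {
  stopifnot(inherits(reference, "binary_mask"), inherits(candidate, "binary_mask"))
  if (!same_grid(reference$grid, candidate$grid)) stop("grid mismatch", call. = FALSE)
  n_ref <- sum(reference$membership)
  if (n_ref == 0L) stop("empty reference mask", call. = FALSE)
  sum(reference$membership & candidate$membership) / n_ref
}

#' CISOTA: change index of spatial overlap and temporal association
#'
#' `CISOTA = 1 / (spatial overlap x time-course correlation)`. Both maps are
#' binarized with the same threshold-and-extent rule used for
#' classification; the correlation is Pearson's r between the two time
#' courses. An unchanged component scores exactly 1 (the minimum); values
#' grow as the match loses spatial coverage or temporal coherence. When the
#' product is not positive the index is undefined and a flagged `Inf`
#' sentinel is returned ("no association") rather than a signed value.
#'
#' @param reference,candidate [ic_component()] objects on one grid with
#'   equal time-course lengths.
#' @param spec,connectivity Map binarization settings.
#' @param abs_r Use `|r|` to neutralize ICA sign ambiguity (default FALSE).
#' @return One-row tibble `(spatial_overlap, timecourse_r, cisota,
#'   no_association)`.
#' @export
cisota <- function(reference, candidate, spec = threshold_spec(),
                   connectivity = 6, abs_r = FALSE) {
  stopifnot(inherits(reference, "ic_component"), inherits(candidate, "ic_component"))
  if (!same_grid(reference$map$grid, candidate$map$grid)) stop("grid mismatch", call. = FALSE)
  if (length(reference$samples) != length(candidate$samples))
    stop("time-course length mismatch", call. = FALSE)
  if (stats::sd(reference$samples) == 0 || stats::sd(candidate$samples) == 0)
    stop("degenerate (constant) time course", call. = FALSE)
  ref_mask <- suprathreshold_mask(reference$map, spec, connectivity)$mask
  cand_mask <- suprathreshold_mask(candidate$map, spec, connectivity)$mask
  ov <- spatial_overlap(ref_mask, cand_mask)
  r <- stats::cor(reference$samples, candidate$samples)
  if (abs_r) r <- abs(r)
  prod <- ov * r
  tibble(spatial_overlap = ov, timecourse_r = r,
         cisota = if (prod > 0) 1 / prod else Inf,
         no_association = prod <= 0)
}

#' Track a reference component across a series of model orders
#'
#' Trains the epsilon-SVR tracker on the decomposition at `reference_nic`,
#' then for every other decomposition in the series ranks all components
#' and computes CISOTA of the top match against the reference.
#'
#' @param series List of [ica_set()] objects (ascending NIC recommended).
#' @param reference_nic NIC of the decomposition holding the reference.
#' @param reference_id Component id of the reference within that set.
#' @param gm Gray-matter [binary_mask()].
#' @param spec,band,connectivity Feature-extraction settings.
#' @param epsilon,cost,sigma,seed Tracker hyper-parameters (see
#'   [train_tracker()]).
#' @param abs_r Passed to [cisota()].
#' @return Tibble with one row per tracked decomposition: `nic`,
#'   `matched_id`, `probability`, `rank` (always 1 for the match),
#'   `spatial_overlap`, `timecourse_r`, `cisota`, `no_association`.
#' @export
track_across_nic <- function(series, reference_nic, reference_id, gm,
                             spec = threshold_spec(), band = c(0.01, 0.08),
                             connectivity = 6, epsilon = 0.1, cost = 100,
                             sigma = NULL, seed = NULL, abs_r = FALSE) {
  stopifnot(length(series) >= 1L)
  nics <- vapply(series, function(s) s$nic, integer(1))
  i_ref <- match(as.integer(reference_nic), nics)
  if (is.na(i_ref)) stop("no decomposition with NIC = ", reference_nic, call. = FALSE)
  ref_set <- series[[i_ref]]
  ref_comp <- get_component(ref_set, reference_id)
  tracker <- train_tracker(ref_set, reference_id, gm, spec, band, connectivity,
                           epsilon = epsilon, cost = cost, sigma = sigma, seed = seed)
  purrr::map_dfr(series[setdiff(seq_along(series), i_ref)], function(set) {
    rk <- rank_components(tracker, set, gm, spec, band, connectivity)
    match_id <- rk$id[1]
    ci <- cisota(ref_comp, get_component(set, match_id), spec, connectivity, abs_r)
    dplyr::bind_cols(
      tibble(nic = set$nic, matched_id = match_id,
             probability = rk$probability[1], rank = 1L), ci)
  })
}

#' Cross-sectional component change between consecutive model orders
#'
#' For each pair of consecutive decompositions and each component of the
#' lower-order set, finds the candidate in the higher-order set with the
#' smallest CISOTA (largest overlap-correlation product) and reports that
#' index. Components whose best-match CISOTA exceeds `change_threshold`
#' count as changed by the NIC increment.
#'
#' @param series List of [ica_set()] objects, ascending NIC.
#' @param spec,connectivity Map binarization settings.
#' @param change_threshold CISOTA above which a component is called changed
#'   (default 2: the match lost half its overlap-correlation product).
#' @param abs_r Passed to [cisota()].
#' @return Tibble `(nic_from, nic_to, id, matched_id, spatial_overlap,
#'   timecourse_r, cisota, changed)`.
#' @export
track_cross_sections <- function(series, spec = threshold_spec(),
                                 connectivity = 6, change_threshold = 2,
                                 abs_r = FALSE) {
  stopifnot(length(series) >= 2L)
  purrr::map_dfr(seq_len(length(series) - 1L), function(i) {
    lo <- series[[i]]; hi <- series[[i + 1L]]
    purrr::map_dfr(lo$components, function(comp) {
      cis <- purrr::map_dfr(hi$components, function(cand) {
        ci <- cisota(comp, cand, spec, connectivity, abs_r)
        ci$matched_id <- cand$id
        ci
      })
      best <- cis[order(cis$cisota, cis$matched_id), ][1, ]
      tibble(nic_from = lo$nic, nic_to = hi$nic, id = comp$id,
             matched_id = best$matched_id,
             spatial_overlap = best$spatial_overlap,
             timecourse_r = best$timecourse_r,
             cisota = best$cisota,
             changed = best$cisota > change_threshold)
    })
  })
}
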