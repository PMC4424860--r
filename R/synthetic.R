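#' Configuration for the synthetic IC generator
#'
#' The generator emulates melodic-style ICA output: pseudo-t spatial maps on
#' a small brain-shaped grid paired with time courses, for two component
#' families. RFN-like components are compact Gaussian blobs centred in the
#' gray-matter shell with slow, autocorrelated time courses; artifact-like
#' components are rim shells on the brain contour, ventricle blobs, or core
#' blobs with spiky or high-frequency time courses. No BOLD simulation or
#' ICA decomposition is run — the framework consumes ICA outputs, so the
#' generator produces objects at that interface directly.
#'
#' Defaults: a 32 x 32 x 16 grid at 3 mm isotropic, 200 timepoints at TR =
#' 2 s (shaped like typical resting-state acquisitions), blob amplitude 12
#' over unit noise so every planted component safely survives the p < 0.001 /
#' 20-voxel filtering rule.
#'
#' @param dims,voxel_size Grid geometry.
#' @param n_rfn,n_art Component counts per class.
#' @param tr,n_timepoints Time-course sampling.
#' @param rfn_blob_radius Gaussian blob radius in voxels.
#' @param artifact_styles Styles cycled over ART components; subset of
#'   `"rim"`, `"ventricle"`, `"spike"`, `"highfreq"`.
#' @param effect_amplitude Peak signal amplitude (pseudo-t units).
#' @param noise_sd Additive white-noise SD on the maps.
#' @param seed Master seed; every generator output is a pure function of
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(dims = c(32, 32, 16), voxel_size = c(3, 3, 3),
                       n_rfn = 10L, n_art = 20L, tr = 2, n_timepoints = 200L,
                       rfn_blob_radius = 2.2,
                       artifact_styles = c("rim", "ventricle", "spike", "highfreq"),
                       effect_amplitude = 12, noise_sd = 1, seed = 1L) {
  stopifnot(n_rfn + n_art >= 2L, effect_amplitude > 0, noise_sd > 0)
  artifact_styles <- match.arg(artifact_styles, several.ok = TRUE)
  structure(list(dims = as.integer(dims), voxel_size = voxel_size,
                 n_rfn = as.integer(n_rfn), n_art = as.integer(n_art),
                 tr = tr, n_timepoints = as.integer(n_timepoints),
                 rfn_blob_radius = rfn_blob_radius,
                 artifact_styles = artifact_styles,
                 effect_amplitude = effect_amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "sim_config")
}

norm_radius <- function(dims, semi_scale = c(0.85, 0.85, 0.8)) {
  ctr <- (dims + 1) / 2
  semi <- dims / 2 * semi_scale
  x2 <- ((seq_len(dims[1]) - ctr[1]) / semi[1])^2
  y2 <- ((seq_len(dims[2]) - ctr[2]) / semi[2])^2
  z2 <- ((seq_len(dims[3]) - ctr[3]) / semi[3])^2
  sqrt(outer(outer(x2, y2, "+"), z2, "+"))
}

#' Nested tissue templates on a synthetic brain
#'
#' The brain is a central ellipsoid; gray matter is an outer shell of it
#' (normalized radius 0.55-0.85, kept clear of the brain contour so rim
#' artifacts do not touch it); the ventricle/CSF region is a small central
#' core. By construction csf and gm are disjoint and both inside the brain.
#'
#' @param cfg A [sim_config()].
#' @return List of [binary_mask()]: `brain`, `gm`, `csf`, plus `rim` (the
#'   contour shell used by the rim artifact style) and the shared `grid`.
#' @export
sim_templates <- function(cfg = sim_config()) {
  grid <- volume_grid(cfg$dims, cfg$voxel_size)
  rho <- norm_radius(cfg$dims)
  brain <- rho <= 1
  gm <- rho >= 0.55 & rho <= 0.85
  csf <- rho <= 0.3
  rim <- rho > 0.92 & rho <= 1
  if (!any(gm) || !any(csf) || !any(brain))
    stop("grid too small for nested tissue templates", call. = FALSE)
  list(brain = binary_mask(brain, grid), gm = binary_mask(gm, grid),
       csf = binary_mask(csf, grid), rim = binary_mask(rim, grid),
       grid = grid, rho = rho)
}

gaussian_blob <- function(dims, center, radius) {
  radius <- rep_len(radius, 3L)   # scalar = isotropic, vector = per-axis
  x2 <- ((seq_len(dims[1]) - center[1]) / radius[1])^2
  y2 <- ((seq_len(dims[2]) - center[2]) / radius[2])^2
  z2 <- ((seq_len(dims[3]) - center[3]) / radius[3])^2
  exp(-outer(outer(x2, y2, "+"), z2, "+") / 2)
}

pick_voxel <- function(candidates, dims) {
  idx <- which(candidates)
  arrayInd(idx[sample.int(length(idx), 1)], dims)[1, ]
}

tc_slow <- function(n, tr) {
  t <- (seq_len(n) - 1) * tr
  x <- rowSums(vapply(1:3, function(i)
    stats::runif(1, 0.8, 1.2) *
      sin(2 * pi * stats::runif(1, 0.015, 0.06) * t + stats::runif(1, 0, 2 * pi)),
    numeric(n)))
  x / stats::sd(x) + 0.15 * stats::rnorm(n)
}

tc_highfreq <- function(n, tr) {
  t <- (seq_len(n) - 1) * tr
  x <- rowSums(vapply(1:3, function(i)
    stats::runif(1, 0.8, 1.2) *
      sin(2 * pi * stats::runif(1, 0.12, 0.2) * t + stats::runif(1, 0, 2 * pi)),
    numeric(n)))
  x / stats::sd(x) + 0.15 * stats::rnorm(n)
}

tc_spiky <- function(n, tr) {
  x <- 0.3 * stats::rnorm(n)
  k <- max(4L, round(n / 25))
  at <- sample.int(n, k)
  x[at] <- x[at] + sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 4, 8)
  x
}

# Noise-free spatial signal and time course for one planted component.
component_signal <- function(style, templates, cfg) {
  dims <- cfg$dims
  amp <- cfg$effect_amplitude
  rho <- templates$rho
  gm <- templates$gm$membership
  n <- cfg$n_timepoints
  if (style == "rfn") {
    ctr <- pick_voxel(gm & rho >= 0.62 & rho <= 0.78, dims)
    w <- ifelse(gm, 1, 0.08)
    map <- amp * gaussian_blob(dims, ctr, cfg$rfn_blob_radius) * w
    tc <- tc_slow(n, cfg$tr)
  } else if (style == "rim") {
    ctr <- (dims + 1) / 2
    az <- atan2(outer(outer(rep(1, dims[1]), seq_len(dims[2]) - ctr[2]), rep(1, dims[3])),
                outer(outer(seq_len(dims[1]) - ctr[1], rep(1, dims[2])), rep(1, dims[3])))
    mod <- 0.6 + 0.4 * abs(cos(2 * az))
    map <- amp * 0.8 * templates$rim$membership * mod
    tc <- tc_spiky(n, cfg$tr)
  } else if (style == "ventricle") {
    ctr <- pick_voxel(templates$csf$membership, dims)
    w <- ifelse(gm, 0.05, 1)
    map <- amp * gaussian_blob(dims, ctr, 1.8) * w
    tc <- tc_highfreq(n, cfg$tr)
  } else if (style == "spike") {
    ctr <- pick_voxel(rho >= 0.35 & rho <= 0.5 & !templates$csf$membership, dims)
    w <- ifelse(gm, 0.05, 1)
    map <- amp * gaussian_blob(dims, ctr, 2.0) * w
    tc <- tc_spiky(n, cfg$tr)
  } else if (style == "highfreq") {
    ctr <- pick_voxel(rho >= 0.35 & rho <= 0.5 & !templates$csf$membership, dims)
    w <- ifelse(gm, 0.05, 1)
    map <- amp * gaussian_blob(dims, ctr, 2.0) * w
    tc <- tc_highfreq(n, cfg$tr)
  } else stop("unknown style: ", style, call. = FALSE)
  list(map = map, tc = tc, label = if (style == "rfn") "RFN" else "ART",
       style = style)
}

realize_component <- function(signal, id, templates, cfg) {
  vals <- signal$map + stats::rnorm(length(signal$map), sd = cfg$noise_sd)
  ic_component(id, stat_map(array(vals, cfg$dims), templates$grid),
               signal$tc + 0.05 * stats::rnorm(length(signal$tc)), cfg$tr)
}

#' Generate one RFN-like component
#'
#' @param cfg A [sim_config()].
#' @param templates Output of [sim_templates()].
#' @param seed Integer seed.
#' @param id Component id.
#' @return An [ic_component()].
#' @export
sim_rfn_component <- function(cfg = sim_config(), templates = sim_templates(cfg),
                              seed = 1L, id = 0L) {
  withr::with_seed(as.integer(seed),
    realize_component(component_signal("rfn", templates, cfg), id, templates, cfg))
}

#' Generate one artifact-like component
#'
#' @inheritParams sim_rfn_component
#' @param style One of `"rim"`, `"ventricle"`, `"spike"`, `"highfreq"`.
#' @return An [ic_component()].
#' @export
sim_artifact_component <- function(cfg = sim_config(), templates = sim_templates(cfg),
                                   style = "rim", seed = 1L, id = 0L) {
  style <- match.arg(style, c("rim", "ventricle", "spike", "highfreq"))
  withr::with_seed(as.integer(seed),
    realize_component(component_signal(style, templates, cfg), id, templates, cfg))
}

#' Generate a labeled synthetic ICA decomposition
#'
#' Draws `n_rfn` RFN-like and `n_art` artifact-like components (styles
#' cycled), shuffles their order, and returns the set with its ground-truth
#' label table. Two calls with the same config and seed are identical.
#'
#' @param cfg A [sim_config()].
#' @param source_tag Provenance label for the set.
#' @return List: `set` (an [ica_set()]), `labels` (tibble `(id, label)`),
#'   `templates` (from [sim_templates()]).
#' @export
sim_ica_set <- function(cfg = sim_config(), source_tag = "synthetic") {
  templates <- sim_templates(cfg)
  n <- cfg$n_rfn + cfg$n_art
  styles <- c(rep("rfn", cfg$n_rfn),
              rep_len(cfg$artifact_styles, cfg$n_art))
  withr::with_seed(cfg$seed, {
    styles <- sample(styles)
    comps <- lapply(seq_len(n), function(i)
      realize_component(component_signal(styles[i], templates, cfg),
                        i - 1L, templates, cfg))
  })
  labels <- tibble(id = seq_len(n) - 1L,
                   label = ifelse(styles == "rfn", "RFN", "ART"))
  list(set = ica_set(comps, source_tag = source_tag), labels = labels,
       templates = templates)
}

#' Generate an NIC series with an optional planted component split
#'
#' Builds a pool of persistent components and realizes the first `nic` of
#' them (with fresh map and time-course noise) at each requested model
#' order. The reference component occupies id 0 and is an RFN-like blob with
#' an enlarged radius. When `split_nic` is set, at and above that model
#' order the reference's blob is partitioned into two spatially
#' complementary children (a one-voxel overlap band at the cut plane) that
#' share its time course: the left child keeps id 0, the right child is
#' appended as the last component. This mirrors the way a network splits
#' into sub-networks as ICA dimensionality grows.
#'
#' @param cfg A [sim_config()] (`n_rfn`/`n_art` set the pool mix ratio).
#' @param nic_list Ascending model orders to realize.
#' @param split_nic Model order at which the reference splits, or `NULL`.
#' @return List with `sets` (list of `list(set, labels)` per NIC),
#'   `templates`, `reference_id` (always 0), `reference_nic`
#'   (`min(nic_list)`), `split_nic`.
#' @export
sim_nic_series <- function(cfg = sim_config(), nic_list = c(20, 30, 40, 50, 60),
                           split_nic = NULL) {
  nic_list <- sort(as.integer(nic_list))
  templates <- sim_templates(cfg)
  n_pool <- max(nic_list)
  frac_rfn <- cfg$n_rfn / (cfg$n_rfn + cfg$n_art)
  out <- withr::with_seed(cfg$seed, {
    styles <- c("rfn", vapply(seq_len(n_pool - 1L), function(i) {
      if (stats::runif(1) < frac_rfn) "rfn"
      else sample(cfg$artifact_styles, 1)
    }, character(1)))
    # The tracked reference must be identifiable in the 5-feature space:
    # among generic blobs whose features coincide, no tracker could single
    # it out. It therefore carries a distinctive temporal fingerprint (a
    # mixed slow + fast band time course: freq_ratio ~ 0.5, lag-1 ~ 0.4,
    # away from both the pure-slow networks and every artifact style) and an
    # elongated blob; split children inherit the time course verbatim.
    ref_signal <- local({
      gm <- templates$gm$membership
      ctr <- pick_voxel(gm & templates$rho >= 0.62 & templates$rho <= 0.78, cfg$dims)
      w <- ifelse(gm, 1, 0.08)
      t <- (seq_len(cfg$n_timepoints) - 1) * cfg$tr
      tc <- sin(2 * pi * stats::runif(1, 0.02, 0.04) * t + stats::runif(1, 0, 2 * pi)) +
        sin(2 * pi * stats::runif(1, 0.12, 0.16) * t + stats::runif(1, 0, 2 * pi))
      list(map = cfg$effect_amplitude *
             gaussian_blob(cfg$dims, ctr, cfg$rfn_blob_radius * c(1, 2.8, 0.9)) * w,
           tc = tc / stats::sd(tc) + 0.1 * stats::rnorm(cfg$n_timepoints),
           label = "RFN", style = "rfn")
    })
    # realize each pool component once; sets below re-use these base
    # realizations so a component persists across model orders
    base <- lapply(seq_len(n_pool), function(i)
      realize_component(if (i == 1L) ref_signal
                        else component_signal(styles[i], templates, cfg),
                        i - 1L, templates, cfg))
    left <- right <- NULL
    if (!is.null(split_nic)) {
      ref <- base[[1L]]
      cut_x <- arrayInd(which.max(ref$map$values), cfg$dims)[1, 1]
      xs <- slice.index(array(0, cfg$dims), 1)
      lv <- ref$map$values * (xs <= cut_x)
      rv <- ref$map$values * (xs >= cut_x)
      left <- ic_component(0L, stat_map(lv, templates$grid), ref$samples, cfg$tr)
      right <- ic_component(0L, stat_map(rv, templates$grid),
                            ref$samples + 0.05 * stats::rnorm(length(ref$samples)),
                            cfg$tr)
    }
    lapply(nic_list, function(nic) {
      split_now <- !is.null(split_nic) && nic >= split_nic
      sty <- styles[seq_len(nic)]
      comps <- lapply(seq_len(nic), function(i) {
        if (i == 1L) {                          # reference: intact until split
          if (split_now) return(left) else return(base[[1L]])
        }
        if (split_now && i == nic) {            # right child takes the last slot
          c2 <- right; c2$id <- as.integer(nic - 1L); return(c2)
        }
        b <- base[[i]]                           # small per-order perturbation
        vals <- b$map$values + stats::rnorm(length(b$map$values), sd = 0.3 * cfg$noise_sd)
        ic_component(as.integer(i - 1L), stat_map(vals, templates$grid),
                     b$samples + 0.05 * stats::rnorm(length(b$samples)), cfg$tr)
      })
      if (split_now) sty[nic] <- "rfn"
      list(set = ica_set(comps, source_tag = paste0("synthetic nic", nic)),
           labels = tibble(id = seq_len(nic) - 1L,
                           label = ifelse(sty == "rfn", "RFN", "ART")))
    })
  })
  list(sets = out, templates = templates, reference_id = 0L,
       reference_nic = nic_list[1], split_nic = split_nic)
}

#' Tabular corpus with a planted informative feature
#'
#' A purely tabular companion to the image-based generator, for exercising
#' the feature-selection loop: one feature separates the classes by
#' `separation` within-class standard deviations, the remaining four are
#' pure noise. Columns carry the standard five feature names so downstream
#' defaults apply.
#'
#' @param n Number of samples (split evenly RFN/ART).
#' @param separation Class-mean separation of the planted feature, in SD
#'   units.
#' @param planted Name of the informative feature column.
#' @param seed Integer seed.
#' @return List: `features` (tibble with `id` and the five feature columns),
#'   `labels` (tibble `(id, label)`), `planted`.
#' @export
sim_labeled_features <- function(n = 200L, separation = 4, planted = "gm_pos_overlap",
                                 seed = 1L) {
  stopifnot(planted %in% focis_feature_names())
  n <- as.integer(n)
  lab <- rep(c("RFN", "ART"), length.out = n)
  feats <- withr::with_seed(as.integer(seed), {
    out <- tibble(id = seq_len(n) - 1L)
    for (f in focis_feature_names()) {
      out[[f]] <- stats::rnorm(n) +
        if (f == planted) separation * (lab == "RFN") else 0
    }
    out
  })
  list(features = feats, labels = tibble(id = feats$id, label = lab),
       planted = planted)
}
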