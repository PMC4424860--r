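make_masks <- function(dims, supra_idx, gm_idx) {
  supra <- array(FALSE, dims); supra[supra_idx] <- TRUE
  gm <- array(FALSE, dims); gm[gm_idx] <- TRUE
  list(supra = binary_mask(supra, volume_grid(dims)),
       gm = binary_mask(gm, volume_grid(dims)))
}

test_that("gray-matter overlap is the value-weighted positive-mass fraction", {
  dims <- c(6, 6, 6)
  v <- array(0, dims); v[1:4] <- c(2, 2, 3, 3)
  map <- stat_map(v, volume_grid(dims))
  # all suprathreshold voxels inside GM
  m <- make_masks(dims, 1:4, 1:4)
  expect_equal(feat_gm_pos_overlap(map, m$supra, m$gm), 1)
  # all outside GM
  m <- make_masks(dims, 1:4, 10:12)
  expect_equal(feat_gm_pos_overlap(map, m$supra, m$gm), 0)
  # two equal-valued voxels, one in GM -> 0.5
  v2 <- array(0, dims); v2[1:2] <- 4
  m <- make_masks(dims, 1:2, 1)
  expect_equal(feat_gm_pos_overlap(stat_map(v2, volume_grid(dims)), m$supra, m$gm), 0.5)
  # empty suprathreshold mass -> 0 with warning
  m <- make_masks(dims, integer(0), 1:4)
  expect_warning(out <- feat_gm_pos_overlap(map, m$supra, m$gm), "defined as 0")
  expect_equal(out, 0)
})

test_that("peak-in-GM follows the maximum with lowest-index tie-breaking", {
  dims <- c(6, 6, 6)
  v <- array(0, dims); v[5] <- 3
  map <- stat_map(v, volume_grid(dims))
  m <- make_masks(dims, 5, 5)
  expect_equal(feat_peak_in_gm(map, m$supra, m$gm), 1)
  m <- make_masks(dims, 5, 7)   # peak not in GM
  expect_equal(feat_peak_in_gm(map, m$supra, m$gm), 0)

  # exhaustive-scan oracle on random maps, including ties
  for (seed in 1:5) {
    map <- random_map(seed, dims)
    vals <- round(map$values, 1)           # force occasional ties
    map <- stat_map(vals, volume_grid(dims))
    m <- make_masks(dims, which(vals > 0.5), sample(seq_len(prod(dims)), 40))
    if (!any(m$supra$membership)) next
    idx <- which(m$supra$membership)
    peak <- idx[which(vals[idx] == max(vals[idx]))][1]   # lowest index among maxima
    expect_equal(feat_peak_in_gm(map, m$supra, m$gm),
                 as.numeric(m$gm$membership[peak]))
  }
})

test_that("frequency ratio captures band power of sinusoids and noise", {
  t <- (0:255) * 2
  expect_gt(feat_freq_ratio(sin(2 * pi * 0.02 * t), tr = 2), 0.99)
  expect_lt(feat_freq_ratio(sin(2 * pi * 0.20 * t), tr = 2), 0.01)
  # white noise: ratio ~ band fraction of (0, 0.25] = (0.08 - 0.01) / 0.25
  ratios <- vapply(1:100, function(s)
    withr::with_seed(s, feat_freq_ratio(rnorm(4096), tr = 2)), numeric(1))
  expect_equal(mean(ratios), 0.28, tolerance = 0.05 / 0.28)
  # constant series
  expect_warning(out <- feat_freq_ratio(rep(1, 64), tr = 2), "constant")
  expect_equal(out, 0)
  # band above Nyquist rejected
  expect_error(feat_freq_ratio(rnorm(64), tr = 10, band = c(0.01, 0.08)), "Nyquist")
})

test_that("lag-1 autocorrelation matches known series", {
  expect_equal(feat_lag1_autocorr(rep(c(1, -1), 50)), -1, tolerance = 1e-9)
  t <- (0:199) * 2
  expect_gt(feat_lag1_autocorr(sin(2 * pi * 0.01 * t)), 0.9)
  # AR(1) with phi = 0.6: population lag-1 autocorrelation 0.6
  x <- withr::with_seed(10, as.numeric(arima.sim(list(ar = 0.6), 10000)))
  expect_equal(feat_lag1_autocorr(x), 0.6, tolerance = 0.03 / 0.6)
  expect_error(feat_lag1_autocorr(rep(2, 50)), "zero variance")
})

test_that("bounding-box ratio is size-weighted over clusters", {
  dims <- c(8, 8, 8)
  block <- array(FALSE, dims); block[1:2, 1:3, 1:4] <- TRUE
  cl <- find_clusters(binary_mask(block, volume_grid(dims)))
  expect_equal(feat_bbox_voxel_ratio(cl), 1)

  diag3 <- array(FALSE, dims); diag3[cbind(1:3, 1:3, 1:3)] <- TRUE
  cl <- find_clusters(binary_mask(diag3, volume_grid(dims)), connectivity = 26)
  expect_equal(feat_bbox_voxel_ratio(cl), 9)

  # cube of 8 (ratio 1) + 3-voxel diagonal (ratio 9): (8*1 + 3*9) / 11
  both <- array(FALSE, dims)
  both[1:2, 1:2, 1:2] <- TRUE
  both[cbind(5:7, 5:7, 5:7)] <- TRUE
  cl <- find_clusters(binary_mask(both, volume_grid(dims)), connectivity = 26)
  expect_equal(feat_bbox_voxel_ratio(cl), 35 / 11)

  expect_warning(out <- feat_bbox_voxel_ratio(cl[0, ]), "capped")
  expect_equal(out, 27)
})

test_that("extraction separates generator classes with wide margins", {
  cfg <- sim_config(seed = 7)
  tpl <- sim_templates(cfg)
  rfn <- extract_features(sim_rfn_component(cfg, tpl, seed = 1), tpl$gm)
  expect_gt(rfn$gm_pos_overlap, 0.9)
  expect_equal(rfn$peak_in_gm, 1)
  expect_gt(rfn$freq_ratio, 0.8)
  expect_false(rfn$degenerate)

  rim <- extract_features(sim_artifact_component(cfg, tpl, "rim", seed = 2), tpl$gm)
  expect_lt(rim$gm_pos_overlap, 0.3)
  expect_gt(rim$bbox_voxel_ratio, rfn$bbox_voxel_ratio)

  hf <- extract_features(sim_artifact_component(cfg, tpl, "highfreq", seed = 3), tpl$gm)
  expect_lt(hf$freq_ratio, 0.2)

  vent <- extract_features(sim_artifact_component(cfg, tpl, "ventricle", seed = 4), tpl$gm)
  expect_equal(vent$peak_in_gm, 0)
})

test_that("a component with no suprathreshold voxels gets flagged defaults", {
  cfg <- sim_config(dims = c(16, 16, 8), n_timepoints = 40)
  tpl <- sim_templates(cfg)
  flat <- ic_component(0L, stat_map(array(0, cfg$dims), tpl$grid),
                       withr::with_seed(1, rnorm(40)), 2)
  f <- extract_features(flat, tpl$gm)
  expect_true(f$degenerate)
  expect_equal(f$gm_pos_overlap, 0)
  expect_equal(f$peak_in_gm, 0)
  expect_equal(f$bbox_voxel_ratio, 27)
})

test_that("raw features respect their declared ranges and are deterministic", {
  cfg <- sim_config(n_rfn = 4, n_art = 6, seed = 31)
  sim <- sim_ica_set(cfg)
  f1 <- ic_features(sim$set, sim$templates$gm)
  f2 <- ic_features(sim$set, sim$templates$gm)
  expect_identical(f1, f2)
  expect_true(all(f1$gm_pos_overlap >= 0 & f1$gm_pos_overlap <= 1))
  expect_true(all(f1$peak_in_gm %in% c(0, 1)))
  expect_true(all(f1$freq_ratio >= 0 & f1$freq_ratio <= 1))
  expect_true(all(f1$lag1_autocorr >= -1 & f1$lag1_autocorr <= 1))
  expect_true(all(f1$bbox_voxel_ratio >= 1))
})

test_that("conditioning standardizes the training set and is reversible", {
  f <- tibble::tibble(id = 0:1, gm_pos_overlap = c(0, 2), peak_in_gm = c(0, 1),
                      freq_ratio = c(0.1, 0.9), lag1_autocorr = c(-0.5, 0.5),
                      bbox_voxel_ratio = c(1, 3))
  st <- fit_conditioning(f)
  expect_equal(st$mean[st$feature == "gm_pos_overlap"], 1)
  expect_equal(st$sd[st$feature == "gm_pos_overlap"], sqrt(2))
  cond <- apply_conditioning(f, st)
  expect_equal(cond$gm_pos_overlap, c(-1, 1) / sqrt(2))

  # column means 0, sd 1 on a larger table
  sim <- sim_ica_set(sim_config(n_rfn = 4, n_art = 6, seed = 8))
  feats <- ic_features(sim$set, sim$templates$gm)
  cc <- apply_conditioning(feats, fit_conditioning(feats))
  for (col in c("gm_pos_overlap", "freq_ratio", "bbox_voxel_ratio")) {
    expect_equal(mean(cc[[col]]), 0, tolerance = 1e-12)
    expect_equal(sd(cc[[col]]), 1, tolerance = 1e-12)
  }

  expect_error(fit_conditioning(f[1, ]), "at least 2")
  f$peak_in_gm <- 1
  expect_error(fit_conditioning(f), "peak_in_gm")
})

test_that("the Andrews projection evaluates the trigonometric expansion", {
  expect_equal(andrews_projection(rep(0, 5), seq(-pi, pi, 0.5)),
               rep(0, length(seq(-pi, pi, 0.5))))
  expect_equal(andrews_projection(c(1, 0, 0, 0, 0), pi / 2), 1)
  expect_equal(andrews_projection(rep(1, 5), 0), 2)
  expect_error(andrews_projection(1:4, 0), "5 components")

  curves <- andrews_curves(
    tibble::tibble(id = 0:1, gm_pos_overlap = c(1, 0), peak_in_gm = c(0, 1),
                   freq_ratio = 0, lag1_autocorr = 0, bbox_voxel_ratio = 0),
    labels = tibble::tibble(id = 0:1, label = c("RFN", "ART")), n_points = 11)
  expect_equal(nrow(curves), 22)
  expect_equal(curves$value[curves$id == 0], sin(curves$t[curves$id == 0]))
  p <- plot_andrews(tibble::tibble(id = 0, gm_pos_overlap = 1, peak_in_gm = 0,
                                   freq_ratio = 0, lag1_autocorr = 0,
                                   bbox_voxel_ratio = 0))
  expect_s3_class(p, "ggplot")
})
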