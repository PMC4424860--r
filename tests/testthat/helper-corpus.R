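# Shared heavier fixtures, computed once per test run and cached.

.corpus_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .corpus_env)) assign(key, force(expr), .corpus_env)
  get(key, .corpus_env)
}

# training corpus of 50 components and test corpus of 30, with features
classifier_corpus <- function() {
  memo("classifier_corpus", {
    tr <- sim_ica_set(sim_config(n_rfn = 20, n_art = 30, seed = 101))
    te <- sim_ica_set(sim_config(n_rfn = 10, n_art = 20, seed = 202))
    list(train = tr, test = te,
         features_train = ic_features(tr$set, tr$templates$gm),
         features_test = ic_features(te$set, te$templates$gm))
  })
}

# the full 1000-point grid search over the corpus (shared across tests)
corpus_grid_search <- function() {
  memo("grid_search", {
    cc <- classifier_corpus()
    focis_grid_search(cc$features_train, cc$train$labels, seed = 11)
  })
}

# smoothed-vs-unsmoothed cluster-null calibrations on a brain-scale volume
calibration_pair <- function() {
  memo("calibration_pair", {
    grid <- volume_grid(c(48, 48, 48), c(3, 3, 3))
    list(fwhm0 = calibrate_cluster_null(grid, fwhm_mm = 0, voxel_p = 0.001,
                                        n_iter = 2000, seed = 21),
         fwhm6 = calibrate_cluster_null(grid, fwhm_mm = 6, voxel_p = 0.001,
                                        n_iter = 2000, seed = 21))
  })
}
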