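# Shared fixtures. The trained-model experiments are expensive, so they are
# computed once per test run and memoised for every file that needs them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# brute-force dose-quantile oracle: sort the voxel list and linearly
# interpolate the empirical distribution (positions v * n over order
# statistics), independent of the package's quantile-type shortcut
oracle_quantile_curve <- function(voxels, dv) {
  s <- sort(voxels)
  n <- length(s)
  v <- seq_len(round(1 / dv)) * dv
  vapply(v, function(vi) {
    h <- vi * n
    lo <- max(floor(h), 1)
    hi <- min(lo + 1, n)
    if (h <= 1) s[1] else s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

# brute-force hottest-fraction metric on a voxel list
oracle_dose_at_fraction <- function(voxels, f) {
  s <- sort(voxels, decreasing = TRUE)
  min(s[seq_len(round(f * length(s)))])
}

# standard study conditions for the learnability experiment: 100 patients
# (80 train / 20 test) x 8 organs, noiseless fixed-mixing composites on a
# 100-bin grid
noiseless_cohort <- function() {
  cached("noiseless_cohort", generate_cohort(cohort_config(
    n_patients = 100, dv = 0.01, noise_sd_gy = 0, sparing = "fixed", seed = 1
  )))
}

learn_config <- function() {
  gru_config(dv = 0.01, epochs = 150L, learning_rate = 3e-3,
             batch_size = 16L, seed = 1L)
}

# pooled model trained on the noiseless cohort plus held-out EUD errors and
# the mean-training-curve baseline
learnability <- function() {
  cached("learnability", {
    ch <- noiseless_cohort()
    train <- ch$samples[ch$samples$split == "train", ]
    test <- ch$samples[ch$samples$split == "test", ]
    fit <- train_dvh_model(train, learn_config())
    reg <- k_registry()
    k <- purrr::map_dbl(test$structure_id, ~ resolve_k(reg, .x))
    pred <- purrr::map(test$beams, predict_dvh, model = fit)
    eud_pred <- purrr::map2_dbl(pred, k, eud)
    eud_true <- purrr::map2_dbl(test$plan, k, eud)
    n_bins <- round(1 / 0.01)
    baseline <- dvh_curve(
      cummax(rowMeans(vapply(train$plan, function(p) p$doses, numeric(n_bins)))),
      dv = 0.01
    )
    eud_base <- purrr::map_dbl(k, ~ eud(baseline, .x))
    list(
      fit = fit, test = test, pred = pred,
      heldout_mae = mean(abs(eud_pred - eud_true)),
      baseline_mae = mean(abs(eud_base - eud_true)),
      eud_pred = eud_pred, eud_true = eud_true
    )
  })
}

# single patient-organ pair memorized by the model
overfit_fixture <- function() {
  cached("overfit", {
    ch <- generate_cohort(cohort_config(
      n_patients = 2, dv = 0.01, noise_sd_gy = 0, sparing = "fixed", seed = 3
    ))
    sample1 <- ch$samples[1, ]
    cfg <- gru_config(dv = 0.01, epochs = 1500L, learning_rate = 5e-3,
                      batch_size = 1L, seed = 1L)
    fit <- train_dvh_model(sample1, cfg)
    list(sample = sample1, fit = fit,
         pred = predict_dvh(fit, sample1$beams[[1]]))
  })
}

tiny_dvh_set <- function(dv = 0.1) {
  n <- round(1 / dv)
  mk <- function(top) dvh_curve(seq(0, top, length.out = n), dv = dv,
                                total_volume_cc = 10)
  dvh_set(
    patient_id = rep(c("p001", "p002"), each = 2),
    structure_id = rep(c("brainstem", "larynx"), 2),
    source = "plan", field_index = 0L,
    curve = list(mk(50), mk(60), mk(45), mk(66))
  )
}
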