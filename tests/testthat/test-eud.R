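random_curve <- function(n = 100, top = NULL) {
  if (is.null(top)) top <- runif(1, 5, 70)
  dvh_curve(cummax(runif(n, 0, top)), dv = 1 / n)
}

test_that("EUD reduces to the analytic cases", {
  u <- dvh_curve(rep(50, 4), dv = 0.25)
  expect_equal(eud(u, 9.8), 50)
  cv <- dvh_curve(c(20, 20, 60, 60), dv = 0.25)
  expect_equal(eud(cv, 1), 40)  # k = 1 is the mean dose
  # direct-summation oracle at k = 10
  expect_equal(eud(cv, 10), (0.5 * 20^10 + 0.5 * 60^10)^(1 / 10), tolerance = 1e-12)
  expect_lt(abs(eud(cv, 1000) - 60), 0.1)  # large-k limit is the max dose
  expect_error(eud(cv, -5), "positive")
  expect_error(eud(cv, 0), "positive")
  zero <- dvh_curve(rep(0, 4), dv = 0.25)
  expect_equal(eud(zero, 9.8), 0)
})

test_that("EUD is a monotone, scale-equivariant power mean bounded by the curve", {
  set.seed(31)
  ks <- c(0.5, 1, 2, 3.9, 6.8, 9.8, 10, 50, 1000)
  for (rep in 1:20) {
    cv <- random_curve()
    vals <- vapply(ks, function(k) eud(cv, k), numeric(1))
    expect_true(all(diff(vals) >= -1e-9))                   # monotone in k
    expect_gte(min(vals), min(cv$doses) - 1e-9)
    expect_lte(max(vals), max_dose(cv) + 1e-9)
    expect_equal(vals[ks == 1], mean_dose(cv), tolerance = 1e-12)
    expect_lt(abs(vals[ks == 1000] - max_dose(cv)), 0.005 * max(max_dose(cv), 1))
    c0 <- runif(1, 0.1, 3)                                  # scale equivariance
    scaled <- dvh_curve(c0 * cv$doses, dv = cv$dv)
    expect_equal(eud(scaled, 9.8), c0 * eud(cv, 9.8), tolerance = 1e-9)
  }
})

test_that("exponent resolution handles PRVs, laterality and the D50 rule", {
  reg <- k_registry()
  expect_equal(resolve_k(reg, "spinal_cord"), 10.0)
  expect_equal(resolve_k(reg, "spinal_cord_prv"), 10.0)  # PRV shares parent k
  expect_equal(resolve_k(reg, "brainstem"), 9.8)
  expect_equal(resolve_k(reg, "optic_nerve_r"), 9.8)
  expect_equal(resolve_k(reg, "optic_chiasm"), 9.8)
  expect_equal(resolve_k(reg, "larynx"), 6.8)
  expect_equal(resolve_k(reg, "lens_l"), 2.0)
  expect_equal(resolve_k(reg, "parotid_r"), 3.9)
  expect_error(resolve_k(reg, "temporal_lobe_l"), "no exponent available")

  reg2 <- k_registry(c(default_k_entries(),
                       list(temporal_lobe = list(d50_gy = 40))))
  expect_equal(resolve_k(reg2, "temporal_lobe_l"), 6.0)  # 0.15 x D50
  expect_error(k_registry(list(lens = list(k = -1))), "k must be")
})

test_that("registry files load from YAML and JSON", {
  dir <- withr::local_tempdir()
  yaml::write_yaml(list(brainstem = list(k = 9.8),
                        temporal_lobe = list(d50_gy = 40)),
                   file.path(dir, "reg.yaml"))
  r1 <- read_k_registry(file.path(dir, "reg.yaml"))
  expect_equal(resolve_k(r1, "temporal_lobe_r"), 6.0)
  jsonlite::write_json(list(lens = list(k = 2)), file.path(dir, "reg.json"),
                       auto_unbox = TRUE)
  expect_equal(resolve_k(read_k_registry(file.path(dir, "reg.json")), "lens_l"), 2)
})

test_that("correction factor is the mean true/predicted ratio", {
  expect_equal(correction_factor(c(40, 50, 60), c(40, 50, 60)), 1.0)
  expect_equal(correction_factor(c(1.2, 0.8), c(1, 1)), 1.0)
  expect_error(correction_factor(c(1, 2), c(1, 0)), "degenerate prediction")
  expect_error(correction_factor(numeric(0), numeric(0)), "empty")

  # recovery of a known multiplicative bias over 80 training pairs
  set.seed(41)
  for (b in c(0.9, 1.1)) {
    truth <- runif(80, 20, 60)
    pred <- truth / b * exp(rnorm(80, 0, 0.02))
    c_oar <- correction_factor(truth, pred)
    expect_lt(abs(c_oar - b), 0.02)
    # at alpha = 1 the mean ratio of truth to corrected prediction is 1 exactly
    corrected <- corrected_eud_constraint(pred, c_oar, alpha = 1)
    expect_equal(mean(truth / corrected), 1, tolerance = 1e-12)
  }
})

test_that("constraint arithmetic matches the correct-and-tighten rule", {
  expect_equal(corrected_eud_constraint(50, 1.0, 0.97), 48.5)
  expect_equal(corrected_eud_constraint(40, 1.05, 0.97), 40.74)
  expect_equal(corrected_eud_constraint(33, 1.0, 1.0), 33)
  expect_error(corrected_eud_constraint(-1, 1), "positive")
  expect_error(corrected_eud_constraint(50, 1, alpha = 1.5), "alpha")

  expect_equal(corrected_max_dose_constraint(40, c(40, 40), c(40, 40), alpha = 0.97),
               38.8)
  # unbiased max-dose predictions at alpha = 1 leave the prediction unchanged
  expect_equal(corrected_max_dose_constraint(45, c(30, 50), c(30, 50), alpha = 1), 45)
  # constant 10% over-prediction is corrected by 1/1.1
  set.seed(42)
  truth <- runif(80, 30, 50)
  expect_equal(
    correction_factor(truth, truth * 1.1), 1 / 1.1, tolerance = 1e-12
  )
})

test_that("constraint tables carry per-organ corrections and serial max-dose rows", {
  set.seed(43)
  n <- 10
  mk <- function(top, sid, src) dvh_curve(cummax(runif(10, 0, top)), dv = 0.1,
                                          structure_id = sid, source = src)
  ids <- sprintf("p%02d", 1:n)
  train_true <- dvh_set(rep(ids, 2), rep(c("brainstem", "spinal_cord"), each = n),
                        "plan", 0L,
                        purrr::map(rep(c(55, 40), each = n) * runif(2 * n, 0.8, 1),
                                   ~ mk(.x, "brainstem", "plan")))
  train_pred <- train_true
  train_pred$source <- "predicted"
  train_pred$curve <- purrr::map(train_true$curve, function(cv) {
    dvh_curve(cv$doses * 1.05, dv = cv$dv, source = "predicted")
  })
  test_pred <- train_pred[c(1, n + 1), ]
  test_pred$patient_id <- "p_new"
  cs <- constraint_set(test_pred, train_true, train_pred, k_registry(),
                       alpha = 0.97)
  expect_setequal(cs$constraint_type[cs$structure_id == "spinal_cord"],
                  c("eud", "max_dose"))
  expect_equal(cs$constraint_type[cs$structure_id == "brainstem"], "eud")
  # 5% uniform over-prediction: c = 1/1.05 for both EUD and max dose
  expect_equal(unique(round(cs$c_oar, 10)), round(1 / 1.05, 10))
  # the exported value is exactly alpha * c * prediction
  row <- cs[cs$structure_id == "spinal_cord" & cs$constraint_type == "eud", ]
  pred_eud <- eud(test_pred$curve[[2]], 10)
  expect_equal(row$value_gy, 0.97 * row$c_oar * pred_eud, tolerance = 1e-12)
})
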