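mk_set <- function(ids, sid, curves, source = "plan") {
  dvh_set(ids, sid, source, ifelse(source == "beam", 1L, 0L), curves)
}

test_that("EUD errors compose the primitive operations and respect sign mode", {
  set.seed(61)
  reg <- k_registry()
  n <- 6
  truth <- purrr::map(1:n, ~ dvh_curve(cummax(runif(20, 10, 60)), dv = 0.05,
                                       structure_id = "parotid_l", source = "plan"))
  ids <- sprintf("p%02d", 1:n)
  true_set <- mk_set(ids, "parotid_l", truth)
  same <- true_set
  same$source <- "predicted"
  e0 <- eud_errors(same, true_set, reg)
  expect_equal(e0$error, rep(0, n))

  shifted <- mk_set(ids, "parotid_l", purrr::map(truth, function(cv) {
    dvh_curve(cv$doses + 2, dv = cv$dv, structure_id = cv$structure_id,
              source = "predicted")
  }), source = "predicted")
  e2 <- eud_errors(shifted, true_set, k_registry(list(parotid = list(k = 1))))
  expect_equal(e2$error, rep(2, n), tolerance = 1e-9)  # k = 1: pure mean shift

  e_signed <- eud_errors(shifted, true_set, reg, signed = TRUE)
  e_abs <- eud_errors(shifted, true_set, reg, signed = FALSE)
  expect_equal(abs(e_signed$error), e_abs$error)
  # composition oracle: the error column is exactly eud(pred) - eud(true)
  expect_equal(e_signed$error,
               purrr::map_dbl(shifted$curve, ~ eud(.x, 3.9)) -
                 purrr::map_dbl(true_set$curve, ~ eud(.x, 3.9)),
               tolerance = 1e-12)

  expect_error(eud_errors(shifted[-1, ], true_set, reg), "unmatched.*p01")
})

test_that("error summaries implement the mean and n-1 standard deviation", {
  e <- tibble::tibble(structure_id = "larynx", error = c(1, 1, 1))
  s <- summarize_eud_errors(e)
  expect_equal(s$delta_gy, 1)
  expect_equal(s$sigma_gy, 0)

  e2 <- tibble::tibble(structure_id = "larynx", error = c(0, 2))
  s2 <- summarize_eud_errors(e2)
  expect_equal(s2$delta_gy, 1)
  expect_equal(s2$sigma_gy, sqrt(2))

  set.seed(62)
  x <- rnorm(500, 1.3, 2.1)
  s3 <- summarize_eud_errors(tibble::tibble(structure_id = "lens_l", error = x))
  expect_equal(s3$delta_gy, sum(x) / length(x), tolerance = 1e-12)
  expect_equal(s3$sigma_gy, sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
               tolerance = 1e-12)
  # invariance to ordering; constant shifts move delta only
  s4 <- summarize_eud_errors(tibble::tibble(structure_id = "lens_l",
                                            error = rev(x) + 5))
  expect_equal(s4$delta_gy, s3$delta_gy + 5, tolerance = 1e-12)
  expect_equal(s4$sigma_gy, s3$sigma_gy, tolerance = 1e-12)

  expect_error(summarize_eud_errors(tibble::tibble(structure_id = "a", error = 1)),
               "n >= 2")
})

test_that("the metric table reproduces single-metric calls cell by cell", {
  u <- dvh_set("p001", "brainstem", "plan", 0L,
               list(dvh_curve(rep(60, 10), dv = 0.1, total_volume_cc = 20)))
  tab <- plan_metric_table(u)
  expect_equal(unique(tab$value_gy), 60)

  cv <- dvh_curve(c(20, 20, 60, 60), dv = 0.25, total_volume_cc = 4)
  x <- dvh_set("p001", "spinal_cord", "plan", 0L, list(cv))
  tab2 <- plan_metric_table(x)
  expect_equal(tab2$value_gy[tab2$metric == "d1cc"], 60)
  expect_equal(tab2$value_gy[tab2$metric == "dmean"], 40)

  ch <- generate_cohort(cohort_config(n_patients = 3, dv = 0.02, seed = 63))
  sets <- samples_to_dvh_set(ch$samples) |> dplyr::filter(source == "plan")
  tab3 <- plan_metric_table(sets)
  reg <- k_registry()
  for (i in seq_len(nrow(sets))) {
    cv <- sets$curve[[i]]
    sub <- tab3[tab3$patient_id == sets$patient_id[i] &
                  tab3$structure_id == sets$structure_id[i], ]
    expect_equal(sub$value_gy[sub$metric == "d98"], dose_at_relative_volume(cv, 0.98))
    expect_equal(sub$value_gy[sub$metric == "dmax"], max_dose(cv))
    expect_equal(sub$value_gy[sub$metric == "dmean"], mean_dose(cv))
    expect_equal(sub$value_gy[sub$metric == "d1cc"], dose_at_absolute_volume(cv, 1))
    expect_equal(sub$value_gy[sub$metric == "eud"],
                 eud(cv, resolve_k(reg, sets$structure_id[i])))
  }

  # missing organ volume: D1cc cell is NA with a note, other cells intact
  nov <- dvh_set("p001", "larynx", "plan", 0L,
                 list(dvh_curve(rep(30, 4), dv = 0.25)))
  tab4 <- plan_metric_table(nov)
  expect_true(is.na(tab4$value_gy[tab4$metric == "d1cc"]))
  expect_match(tab4$note[tab4$metric == "d1cc"], "requires organ volume")
  expect_equal(tab4$value_gy[tab4$metric == "dmean"], 30)

  summ <- plan_metric_table(sets, summarize = TRUE)
  expect_true(all(c("mean_gy", "sd_gy", "n") %in% names(summ)))
})

test_that("limits of agreement follow the 1.96-SD convention", {
  ident <- limits_of_agreement(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$mean_diff, 0)
  expect_equal(c(ident$lower, ident$upper), c(0, 0))
  expect_equal(ident$frac_within, 1)

  two <- limits_of_agreement(c(0, 2), c(1, 1))  # diffs -1, 1
  expect_equal(two$mean_diff, 0)
  expect_equal(two$upper, 1.96 * sqrt(2))

  # antisymmetry under swapping the arms
  set.seed(64)
  a <- rnorm(50, 10); b <- rnorm(50, 9)
  ab <- limits_of_agreement(a, b); ba <- limits_of_agreement(b, a)
  expect_equal(ab$mean_diff, -ba$mean_diff)
  expect_equal(ab$upper - ab$lower, ba$upper - ba$lower)

  # Monte-Carlo calibration of the 95% convention
  set.seed(65)
  d <- rnorm(1e4)
  mc <- limits_of_agreement(d, rep(0, 1e4))
  expect_lt(abs(mc$frac_within - 0.95), 0.01)

  expect_error(limits_of_agreement(1, 1), "n >= 2")
})

test_that("the signed-rank exact path equals brute-force enumeration", {
  # constant shift, n = 8: the most extreme assignment, p = 2 / 2^8
  b <- c(5.1, 3.2, 8, 1.4, 9.9, 2.2, 7.3, 4.8)
  res <- paired_signed_rank(b + 1, b)
  expect_equal(res$p_value, 2 / 2^8)
  expect_equal(res$statistic, 8 * 9 / 2)
  expect_match(res$method, "exact")

  # antisymmetric differences sit at the null center
  a2 <- c(1, 2, 3, 4, 5, 6) + c(-1, 1, -1, 1, -1, 1) * 0.5
  res2 <- paired_signed_rank(a2, c(1, 2, 3, 4, 5, 6))
  expect_equal(res2$statistic, 6 * 7 / 4)
  expect_gt(res2$p_value, 0.9)

  # property: for every n <= 12 (with ties), enumeration over all sign
  # patterns of the observed ranks reproduces the p-value
  set.seed(66)
  for (n in c(5, 8, 10, 12)) {
    d <- round(rnorm(n, 0.3, 1), 1)  # rounding forces occasional ties
    d[d == 0] <- 0.05
    res <- paired_signed_rank(d, rep(0, n))
    r <- rank(abs(d))
    center <- n * (n + 1) / 4
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- signs %*% r
    p_brute <- mean(abs(vs - center) >= abs(res$statistic - center) - 1e-12)
    expect_equal(res$p_value, p_brute)
  }

  # tie-free cross-check against the reference implementation
  set.seed(67)
  d <- rnorm(10, 0.5)
  res3 <- paired_signed_rank(d, rep(0, 10))
  ref <- stats::wilcox.test(d, exact = TRUE)
  expect_equal(res3$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(res3$statistic, unname(ref$statistic))

  # large-n path: tie-corrected normal approximation
  set.seed(68)
  d2 <- rnorm(40, 0.3)
  res4 <- paired_signed_rank(d2, rep(0, 40))
  ref4 <- stats::wilcox.test(d2, exact = FALSE, correct = FALSE)
  expect_equal(res4$p_value, ref4$p.value, tolerance = 1e-9)
  expect_match(res4$method, "normal")

  expect_error(paired_signed_rank(c(1, 2), c(1, 2)), "no informative pairs")
})
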