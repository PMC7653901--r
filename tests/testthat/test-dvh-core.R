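test_that("curve construction enforces the quantile invariants", {
  expect_error(dvh_curve(c(1, 2, 3), dv = 0.25), "grid points")
  expect_error(dvh_curve(c(1, 2, 3, 2), dv = 0.25), "non-decreasing")
  expect_error(dvh_curve(c(-1, 0, 1, 2), dv = 0.25), "negative")
  expect_error(dvh_curve(c(0, 1, NA, 2), dv = 0.25), "non-finite")
  expect_error(dvh_curve(rep(1, 4), dv = 0.25, structure_id = "femur"), "unknown structure")
  cv <- dvh_curve(rep(50, 1000), dv = 0.001, structure_id = "brainstem")
  expect_s3_class(cv, "dvh_curve")
  expect_equal(volume_grid(cv)[c(1, 1000)], c(0.001, 1))
})

test_that("voxel-dose quantile construction matches order statistics", {
  expect_equal(dvh_from_voxels(rep(50, 4), dv = 0.25)$doses, rep(50, 4))
  expect_equal(dvh_from_voxels(c(0, 10, 20, 30), dv = 0.25)$doses, c(0, 10, 20, 30))
  expect_error(dvh_from_voxels(numeric(0)), "empty structure")
  expect_error(dvh_from_voxels(c(1, -2)), "invalid dose")

  set.seed(101)
  voxels <- rgamma(1000, shape = 2, scale = 10)
  cv <- dvh_from_voxels(voxels, dv = 0.001)
  expect_equal(max(cv$doses), max(voxels))
  expect_equal(cv$doses, oracle_quantile_curve(voxels, 0.001), tolerance = 1e-12)
})

test_that("dose-binned resampling inverts the cumulative curve", {
  # uniform 30 Gy organ expressed as a steep conventional curve
  db <- dose_binned_dvh(c(0, 30, 30 + 1e-9), c(1, 1, 0))
  q <- to_quantile(db, dv = 0.25)
  expect_equal(q$doses, rep(30, 4), tolerance = 1e-6)

  # two-level organ constructed from its voxel representation
  ref <- dvh_from_voxels(c(20, 20, 60, 60), dv = 0.25)
  db2 <- to_dose_binned(ref, c(0, 20, 20 + 1e-9, 40, 60, 60 + 1e-9))
  q2 <- to_quantile(db2, dv = 0.25)
  expect_equal(q2$doses, c(20, 20, 60, 60), tolerance = 1e-6)

  expect_error(dose_binned_dvh(c(0, 10, 20), c(1, 0.5, 0.7)), "not a cumulative DVH")
  expect_error(dose_binned_dvh(c(0, 20, 10), c(1, 0.5, 0.2)), "increasing")
})

test_that("quantile to dose-binned export matches the spec'd fractions", {
  u <- dvh_curve(rep(50, 4), dv = 0.25)
  expect_equal(to_dose_binned(u, c(0, 25, 50, 75))$volume_fractions, c(1, 1, 1, 0))
  cv <- dvh_curve(c(20, 20, 60, 60), dv = 0.25)
  expect_equal(to_dose_binned(cv, c(0, 40, 80))$volume_fractions, c(1, 0.5, 0))
  expect_error(to_dose_binned(u, c(10, 5)), "increasing")
})

test_that("dose-binned export agrees with grid-point counting within one bin", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 50
    doses <- cumsum(runif(n, 0, 2))
    cv <- dvh_curve(doses, dv = 1 / n)
    edges <- seq(0, max(doses) * 1.05, length.out = 37)
    got <- to_dose_binned(cv, edges)$volume_fractions
    counted <- vapply(edges, function(e) mean(doses >= e), numeric(1))
    expect_lt(max(abs(got - counted)), 1 / n + 1e-12)
  }
})

test_that("round trips between the two forms are inverse maps", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 40
    doses <- cumsum(runif(n, 0.05, 2))      # strictly increasing: no flats
    x <- dvh_curve(doses, dv = 1 / n)
    # edges bracketing every dose value resolve all jumps: exact recovery
    edges <- sort(c(doses - 1e-9, doses + 1e-9))
    rt <- to_quantile(to_dose_binned(x, edges), dv = 1 / n)
    expect_equal(rt$doses, x$doses, tolerance = 1e-6)

    # reverse direction: accurate to the edge resolution (one volume bin)
    mids <- c(doses[1] - 0.01, doses[-n] + diff(doses) / 2, doses[n] + 0.01)
    db <- to_dose_binned(x, mids)
    db_rt <- to_dose_binned(to_quantile(db, dv = 1 / n), mids)
    expect_lt(max(abs(db_rt$volume_fractions - db$volume_fractions)), 1 / n + 1e-9)
  }
})

test_that("hottest-fraction metrics follow the order-statistic reading", {
  u70 <- dvh_curve(rep(70, 4), dv = 0.25)
  expect_equal(dose_at_relative_volume(u70, 0.98), 70)
  cv <- dvh_curve(c(20, 20, 60, 60), dv = 0.25, total_volume_cc = 4)
  expect_equal(dose_at_relative_volume(cv, 0.5), 60)
  expect_equal(dose_at_absolute_volume(cv, 1), 60)
  expect_equal(dose_at_absolute_volume(cv, 4), 20)  # whole organ -> min dose
  expect_error(dose_at_relative_volume(cv, 0), "volume fraction")
  expect_error(dose_at_relative_volume(cv, 1.2), "volume fraction")
  expect_error(dose_at_absolute_volume(dvh_curve(rep(40, 4), dv = 0.25), 1),
               "requires organ volume")
  u40 <- dvh_curve(rep(40, 4), dv = 0.25, total_volume_cc = 12)
  expect_equal(dose_at_absolute_volume(u40, 5), 40)

  set.seed(11)
  voxels <- rexp(1000, rate = 1 / 20)
  q <- dvh_from_voxels(voxels, dv = 0.001)
  for (f in c(0.02, 0.1, 0.25, 0.5, 0.9, 0.98)) {
    expect_equal(dose_at_relative_volume(q, f),
                 oracle_dose_at_fraction(voxels, f), tolerance = 1e-9)
  }
})

test_that("Dx is non-increasing in the covered fraction", {
  set.seed(12)
  cv <- dvh_from_voxels(rlnorm(500, 3, 0.5), dv = 0.01)
  fr <- seq(0.02, 1, by = 0.02)
  dx <- vapply(fr, function(f) dose_at_relative_volume(cv, f), numeric(1))
  expect_true(all(diff(dx) <= 1e-12))
})

test_that("mean and max dose bracket the curve and match voxel averages", {
  u <- dvh_curve(rep(50, 4), dv = 0.25)
  expect_equal(mean_dose(u), 50)
  expect_equal(max_dose(u), 50)
  cv <- dvh_curve(c(20, 20, 60, 60), dv = 0.25)
  expect_equal(mean_dose(cv), 40)
  expect_equal(max_dose(cv), 60)

  set.seed(13)
  for (rep in 1:5) {
    voxels <- runif(2000, 0, 70)
    n_bins <- 1000
    q <- dvh_from_voxels(voxels, dv = 1 / n_bins)
    expect_lt(abs(mean_dose(q) - mean(voxels)), max(voxels) / (2 * n_bins))
    expect_lte(min(q$doses), mean_dose(q))
    expect_lte(mean_dose(q), max_dose(q))
  }
})

test_that("DVH sets round trip through CSV and JSON losslessly", {
  dir <- withr::local_tempdir()
  set.seed(21)
  curves <- c(
    purrr::map(1:9, ~ dvh_from_voxels(runif(50, 0, 40), dv = 0.1,
                                      structure_id = "brainstem",
                                      source = "beam", total_volume_cc = 30)),
    list(dvh_from_voxels(runif(50, 0, 55), dv = 0.1, structure_id = "brainstem",
                         source = "plan", total_volume_cc = 30)),
    list(dvh_from_voxels(runif(50, 0, 25), dv = 0.1, structure_id = "larynx",
                         source = "plan"))
  )
  x <- dvh_set(
    patient_id = c(rep("p001", 10), "p002"),
    structure_id = c(rep("brainstem", 10), "larynx"),
    source = c(rep("beam", 9), "plan", "plan"),
    field_index = c(1:9, 0L, 0L),
    curve = curves
  )
  for (fmt in c("csv", "json")) {
    path <- file.path(dir, paste0("set.", fmt))
    write_dvh_set(x, path)
    y <- read_dvh_set(path)
    expect_equal(nrow(y), nrow(x))
    key <- function(t) order(t$patient_id, t$structure_id, t$source, t$field_index)
    xo <- x[key(x), ]; yo <- y[key(y), ]
    expect_equal(purrr::map(yo$curve, "doses"), purrr::map(xo$curve, "doses"),
                 tolerance = 1e-12)
    expect_equal(yo$total_volume_cc, xo$total_volume_cc)
    expect_equal(yo$source, xo$source)
  }
})

test_that("malformed DVH files fail validation with located messages", {
  dir <- withr::local_tempdir()
  good <- tiny_dvh_set()
  path <- file.path(dir, "set.csv")
  write_dvh_set(good, path)

  raw <- readr::read_csv(path, show_col_types = FALSE)
  bad1 <- raw
  bad1$dose_gy[3] <- 0  # break monotonicity inside p001/brainstem
  readr::write_csv(bad1, path)
  expect_error(read_dvh_set(path), "doses decrease")

  bad2 <- raw[-4, ]     # drop a bin: grid length no longer matches dv
  readr::write_csv(bad2, file.path(dir, "short.csv"))
  expect_error(read_dvh_set(file.path(dir, "short.csv")), "bins")

  expect_error(read_dvh_set(file.path(dir, "nope.csv")), "does not exist")
})
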