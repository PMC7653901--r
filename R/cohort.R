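#' Synthetic cohort configuration
#'
#' Parameters of the synthetic dosimetric cohort generator, which stands in
#' for clinical nine-beam conformal plans plus optimized composite plans.
#' Defaults follow the study conditions the package is built around: 100
#' patients split 80/20 into training and test sets, 8 organ-at-risk
#' categories, a 0.1% volume grid, and prescription-scale doses normalized
#' at 70 Gy.
#'
#' Each patient-organ draws a per-beam amplitude and shape; the composite
#' plan is a damped power mean of the nine beam curves (see
#' [generate_patient()]). `sparing = "patient"` draws the mixing weights
#' and the sparing factor per patient — realistic optimizer variability
#' that no pointwise model can fully resolve. `sparing = "fixed"` uses
#' uniform weights and the midpoint sparing factor for every patient, so
#' with `noise_sd_gy = 0` the composite is one exact deterministic function
#' of the nine beam curves: the noiseless mode used for learnability
#' checks, where prediction failures indicate implementation bugs, not
#' data limits.
#'
#' @param n_patients Cohort size (>= 2); default 100.
#' @param organs Structure labels drawn per patient; default 8 categories
#'   with registry-resolvable exponents.
#' @param dv Volume-bin width; default 0.001.
#' @param dose_norm_gy Prescription-scale dose ceiling in Gy; default 70.
#' @param noise_sd_gy Scale of smooth additive noise on the composite, in
#'   Gy; 0 switches noise off. Default 1.
#' @param sparing_range Interval for the sparing (modulation) factor `m`;
#'   default `(0.5, 0.9)` — composite curves sit well below the naive beam
#'   combination, as optimizers achieve.
#' @param sparing `"patient"` (per-patient weights and sparing) or
#'   `"fixed"` (one shared deterministic composite map).
#' @param train_frac Fraction of patients assigned to the training split;
#'   default 0.8.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L,
                          organs = c("brainstem", "brainstem_prv",
                                     "spinal_cord", "optic_chiasm",
                                     "optic_nerve_l", "lens_l",
                                     "parotid_l", "larynx"),
                          dv = 0.001, dose_norm_gy = 70,
                          noise_sd_gy = 1, sparing_range = c(0.5, 0.9),
                          sparing = c("patient", "fixed"),
                          train_frac = 0.8, seed = 1L) {
  sparing <- match.arg(sparing)
  if (n_patients < 2L) abort("n_patients must be at least 2")
  if (noise_sd_gy < 0) abort("noise_sd_gy must be non-negative")
  if (length(sparing_range) != 2L || sparing_range[1] <= 0 ||
      sparing_range[2] > 1 || sparing_range[1] > sparing_range[2]) {
    abort("sparing_range must be an interval within (0, 1]")
  }
  bad <- setdiff(organs, oar_vocabulary())
  if (length(bad) > 0) {
    abort(sprintf("unknown organ label(s): %s", paste(bad, collapse = ", ")))
  }
  if (train_frac <= 0 || train_frac >= 1) abort("train_frac must lie in (0, 1)")
  structure(
    list(n_patients = as.integer(n_patients), organs = organs, dv = dv,
         dose_norm_gy = dose_norm_gy, noise_sd_gy = noise_sd_gy,
         sparing_range = sparing_range, sparing = sparing,
         train_frac = train_frac, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Draw one synthetic patient-organ sample
#'
#' Beam curves follow \eqn{D_v^{(b)} = A g_b v^{\gamma_b}} with a shared
#' patient-organ amplitude \eqn{A \sim U(0.3, 1) \cdot dose\_norm}, beam
#' factors \eqn{g_b \sim U(0.2, 1)} and shape exponents
#' \eqn{\gamma_b \sim U(0.5, 3)} — monotone power-law quantile curves of
#' varying steepness. The composite plan is the damped quadratic power
#' mean \eqn{m (\sum_b u_b (D_v^{(b)})^2)^{1/2}} with simplex weights
#' \eqn{u} and sparing factor \eqn{m}, mimicking an optimizer that spares
#' the organ below the naive beam combination; smooth low-order polynomial
#' noise of scale `noise_sd_gy` is added, then the curve is clipped at 0
#' and monotonized by running maximum. All latent draws are returned for
#' oracle checks.
#'
#' Uses the current RNG state; seed upstream (e.g. via
#' [generate_cohort()]) for reproducibility.
#'
#' @param config A [cohort_config()].
#' @param organ Structure label.
#' @param patient_id Identifier attached to the output.
#' @return A list with elements `beams` ([beam_dvh_set()]), `plan`
#'   ([dvh_curve()]) and `latent` (one-row tibble with `A`, `g1..g9`,
#'   `gamma1..gamma9`, `u1..u9`, `m`).
#' @export
generate_patient <- function(config, organ, patient_id = "p001") {
  stopifnot(inherits(config, "cohort_config"))
  if (!organ %in% oar_vocabulary()) abort(sprintf("unknown organ label '%s'", organ))
  n <- round(1 / config$dv)
  v <- seq_len(n) * config$dv

  A <- stats::runif(1, 0.3, 1.0) * config$dose_norm_gy
  g <- stats::runif(9, 0.2, 1.0)
  gamma <- stats::runif(9, 0.5, 3.0)
  if (config$sparing == "patient") {
    u <- stats::rexp(9); u <- u / sum(u)
    m <- stats::runif(1, config$sparing_range[1], config$sparing_range[2])
  } else {
    u <- rep(1 / 9, 9)
    m <- mean(config$sparing_range)
  }
  total_volume_cc <- stats::runif(1, 5, 60)

  beam_doses <- lapply(seq_len(9), function(b) A * g[b] * v^gamma[b])
  composite <- m * sqrt(Reduce(`+`, purrr::map2(beam_doses, u, ~ .y * .x^2)))
  if (config$noise_sd_gy > 0) {
    coefs <- stats::rnorm(4)
    x <- 2 * v - 1
    p <- coefs[1] + coefs[2] * x + coefs[3] * x^2 + coefs[4] * x^3
    s <- stats::sd(p)
    if (s > 0) composite <- composite + config$noise_sd_gy * p / s
  }
  composite <- cummax(pmax(composite, 0))

  beams <- purrr::map(beam_doses, function(d) {
    dvh_curve(d, dv = config$dv, structure_id = organ, source = "beam",
              total_volume_cc = total_volume_cc)
  })
  plan <- dvh_curve(composite, dv = config$dv, structure_id = organ,
                    source = "plan", total_volume_cc = total_volume_cc)
  latent <- tibble::tibble(
    patient_id = patient_id, structure_id = organ, A = A,
    !!!stats::setNames(as.list(g), paste0("g", 1:9)),
    !!!stats::setNames(as.list(gamma), paste0("gamma", 1:9)),
    !!!stats::setNames(as.list(u), paste0("u", 1:9)),
    m = m, total_volume_cc = total_volume_cc
  )
  list(beams = beam_dvh_set(patient_id, organ, beams), plan = plan,
       latent = latent)
}

#' Generate a full synthetic cohort
#'
#' Draws `n_patients` patients, each with one sample per configured organ,
#' and splits them by patient (never by organ) into training and test sets
#' in the configured proportion. Fully deterministic given the config seed;
#' the caller's RNG state is untouched.
#'
#' @param config A [cohort_config()].
#' @return An object of class `dvh_cohort`: a list with `samples` (tibble
#'   with columns `patient_id, structure_id, split, beams, plan`),
#'   `latents` (latent-parameter table) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- sprintf("p%03d", seq_len(config$n_patients))
  n_train <- round(config$train_frac * config$n_patients)
  split <- rep(c("train", "test"),
               c(n_train, config$n_patients - n_train))
  rows <- withr::with_seed(config$seed, {
    purrr::map(seq_along(ids), function(i) {
      purrr::map(config$organs, function(org) {
        smp <- generate_patient(config, org, patient_id = ids[i])
        tibble::tibble(
          patient_id = ids[i], structure_id = org, split = split[i],
          beams = list(smp$beams), plan = list(smp$plan),
          latent = list(smp$latent)
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  structure(
    list(
      samples = dplyr::select(rows, -"latent"),
      latents = purrr::list_rbind(rows$latent) |>
        dplyr::mutate(split = rows$split, .after = "structure_id"),
      config = config
    ),
    class = "dvh_cohort"
  )
}

#' @export
print.dvh_cohort <- function(x, ...) {
  cat(sprintf(
    "<dvh_cohort> %d patients x %d organs (%d train / %d test samples), dv = %g, noise %g Gy, sparing '%s'\n",
    x$config$n_patients, length(x$config$organs),
    sum(x$samples$split == "train"), sum(x$samples$split == "test"),
    x$config$dv, x$config$noise_sd_gy, x$config$sparing
  ))
  invisible(x)
}

#' Convert cohort samples to a DVH-set tibble
#'
#' @param samples Rows of a cohort `samples` tibble.
#' @return A [dvh_set()] tibble with the 9 beam rows and the plan row of
#'   each sample.
#' @export
samples_to_dvh_set <- function(samples) {
  rows <- purrr::pmap(
    list(samples$patient_id, samples$structure_id, samples$beams, samples$plan),
    function(pid, sid, bs, pl) {
      dvh_set(
        patient_id = pid, structure_id = sid,
        source = c(rep("beam", 9), "plan"),
        field_index = c(1:9, 0L),
        curve = c(bs$beams, list(pl))
      )
    }
  )
  purrr::list_rbind(rows)
}

#' Write a cohort to disk in the DVH-set schema
#'
#' Emits `train.csv`, `test.csv` (the [dvh_set()] CSV schema) and
#' `latents.csv` (the latent-parameter sidecar) into `dir`. Byte-identical
#' across runs with the same config.
#'
#' @param cohort A `dvh_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dvh_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in c("train", "test")) {
    rows <- cohort$samples[cohort$samples$split == sp, ]
    write_dvh_set(samples_to_dvh_set(rows), file.path(dir, paste0(sp, ".csv")))
  }
  readr::write_csv(cohort$latents, file.path(dir, "latents.csv"))
  invisible(dir)
}
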