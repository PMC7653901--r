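#' Per-patient EUD prediction errors
#'
#' Matches predicted and true plan curves by patient and structure and
#' returns the per-pair EUD difference at the registry exponent. Signed
#' errors (predicted minus true) are the default primitive — negative
#' values mean under-prediction; the absolute variant is available behind
#' `signed = FALSE`.
#'
#' @param pred,true [dvh_set()] tibbles of predicted and actual plan
#'   curves; every predicted (patient, structure) pair must have a match.
#' @param registry A [k_registry()].
#' @param signed If `FALSE`, return `|EUD' - EUD|`.
#' @return A tibble with columns `patient_id, structure_id, k, eud_pred,
#'   eud_true, error` (Gy).
#' @export
eud_errors <- function(pred, true, registry, signed = TRUE) {
  stopifnot(inherits(registry, "k_registry"))
  p <- dplyr::select(pred, "patient_id", "structure_id", pred_curve = "curve")
  t_ <- dplyr::select(true, "patient_id", "structure_id", true_curve = "curve")
  joined <- dplyr::full_join(p, t_, by = c("patient_id", "structure_id"))
  missing <- joined[purrr::map_lgl(joined$pred_curve, is.null) |
                      purrr::map_lgl(joined$true_curve, is.null), ]
  if (nrow(missing) > 0) {
    abort(sprintf(
      "unmatched patient/structure pairs: %s",
      paste(sprintf("%s/%s", missing$patient_id, missing$structure_id),
            collapse = ", ")
    ))
  }
  joined |>
    dplyr::mutate(
      k = purrr::map_dbl(.data$structure_id, ~ resolve_k(registry, .x)),
      eud_pred = purrr::map2_dbl(.data$pred_curve, .data$k, eud),
      eud_true = purrr::map2_dbl(.data$true_curve, .data$k, eud),
      error = if (signed) .data$eud_pred - .data$eud_true
              else abs(.data$eud_pred - .data$eud_true)
    ) |>
    dplyr::select("patient_id", "structure_id", "k", "eud_pred", "eud_true",
                  "error")
}

#' Per-organ accuracy and precision of EUD prediction
#'
#' For each structure, the mean error over test patients
#' \eqn{\delta_{OAR} = \sum_P \delta_{P,OAR} / n} and the sample standard
#' deviation \eqn{\sigma_{OAR} = \sqrt{\sum_P (\delta_{P,OAR} -
#' \delta_{OAR})^2 / (n - 1)}}. Bilateral organs contribute one entry per
#' side.
#'
#' @param errors Output of [eud_errors()] (or any tibble with
#'   `structure_id` and `error` columns).
#' @return A tibble with columns `structure_id, delta_gy, sigma_gy, n`.
#' @export
summarize_eud_errors <- function(errors) {
  if (nrow(errors) == 0L) abort("no errors to summarize")
  out <- errors |>
    dplyr::group_by(.data$structure_id) |>
    dplyr::summarise(
      delta_gy = mean(.data$error),
      sigma_gy = stats::sd(.data$error),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n < 2L)) {
    abort(sprintf("sigma requires n >= 2; structure(s) with fewer: %s",
                  paste(out$structure_id[out$n < 2L], collapse = ", ")))
  }
  out
}

#' Dosimetric metric table
#'
#' One row per (patient, structure, metric) covering the usual plan-report
#' quantities: D98 (dose covering 98% of the volume), Dmax, Dmean, D1cc
#' (dose to the hottest cubic centimetre) and EUD at the registry exponent.
#' Cells whose prerequisites are missing (D1cc without an organ volume, EUD
#' without a registry exponent) are emitted as `NA` with the reason in the
#' `note` column; the rest of the table is unaffected.
#'
#' @param x A [dvh_set()] tibble.
#' @param registry A [k_registry()] (needed for the `eud` metric).
#' @param metrics Subset of `c("d98", "dmax", "dmean", "d1cc", "eud")`.
#' @param summarize If `TRUE`, collapse to per-structure mean and SD.
#' @return A tibble; long per-sample layout, or `structure_id, metric,
#'   mean_gy, sd_gy, n` when summarized.
#' @export
plan_metric_table <- function(x, registry = k_registry(),
                              metrics = c("d98", "dmax", "dmean", "d1cc", "eud"),
                              summarize = FALSE) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  one <- function(cv, sid, metric) {
    switch(metric,
      d98 = list(value = dose_at_relative_volume(cv, 0.98), note = NA_character_),
      dmax = list(value = max_dose(cv), note = NA_character_),
      dmean = list(value = mean_dose(cv), note = NA_character_),
      d1cc = {
        tv <- cv$total_volume_cc
        if (is.na(tv) || tv <= 0) {
          list(value = NA_real_, note = "absolute metric requires organ volume")
        } else if (tv < 1) {
          list(value = NA_real_, note = "organ smaller than 1 cc")
        } else {
          list(value = dose_at_absolute_volume(cv, 1), note = NA_character_)
        }
      },
      eud = {
        k <- tryCatch(resolve_k(registry, sid), error = function(e) NA_real_)
        if (is.na(k)) list(value = NA_real_, note = "no exponent available")
        else list(value = eud(cv, k), note = NA_character_)
      }
    )
  }
  long <- tidyr::expand_grid(row = seq_len(nrow(x)), metric = metrics)
  cells <- purrr::map2(long$row, long$metric,
                       ~ one(x$curve[[.x]], x$structure_id[.x], .y))
  out <- tibble::tibble(
    patient_id = x$patient_id[long$row],
    structure_id = x$structure_id[long$row],
    source = x$source[long$row],
    metric = long$metric,
    value_gy = purrr::map_dbl(cells, "value"),
    note = purrr::map_chr(cells, "note")
  )
  if (!summarize) return(out)
  out |>
    dplyr::group_by(.data$structure_id, .data$source, .data$metric) |>
    dplyr::summarise(
      mean_gy = mean(.data$value_gy, na.rm = TRUE),
      sd_gy = stats::sd(.data$value_gy, na.rm = TRUE),
      n = sum(!is.na(.data$value_gy)),
      .groups = "drop"
    )
}

#' Bland-Altman limits of agreement
#'
#' Differences `a - b`; the limits are the mean difference plus/minus 1.96
#' sample standard deviations, and `frac_within` is the fraction of the
#' differences falling inside them.
#'
#' @param a,b Equal-length numeric vectors of paired measurements.
#' @return A one-row tibble: `n, mean_diff, sd_diff, lower, upper,
#'   frac_within`.
#' @export
limits_of_agreement <- function(a, b) {
  if (length(a) != length(b)) abort("paired vectors differ in length")
  if (length(a) < 2L) abort("limits of agreement require n >= 2")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  lower <- m - 1.96 * s
  upper <- m + 1.96 * s
  tibble::tibble(
    n = length(d), mean_diff = m, sd_diff = s, lower = lower, upper = upper,
    frac_within = mean(d >= lower & d <= upper)
  )
}

#' Bland-Altman plot of paired measurements
#'
#' @param a,b Paired numeric vectors (`a - b` is plotted against their
#'   mean).
#' @param label Axis label for the quantity compared.
#' @return A ggplot object with the mean-difference line and the limits of
#'   agreement.
#' @export
plot_agreement <- function(a, b, label = "value (Gy)") {
  loa <- limits_of_agreement(a, b)
  df <- tibble::tibble(avg = (a + b) / 2, diff = a - b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = loa$mean_diff, colour = "red") +
    ggplot2::geom_hline(yintercept = c(loa$lower, loa$upper), colour = "darkgreen") +
    ggplot2::labs(x = paste("Mean", label), y = paste("Difference in", label),
                  title = sprintf("Limits of agreement: %.2f to %.2f",
                                  loa$lower, loa$upper)) +
    ggplot2::theme_minimal()
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of paired differences. Zero differences are dropped;
#' tied absolute differences receive average ranks. With at most
#' `exact_max` informative pairs the null distribution of the positive-rank
#' sum is enumerated exactly over all sign assignments (conditional on the
#' observed ranks, so ties are handled exactly); above that, the
#' tie-corrected normal approximation (without continuity correction) is
#' used.
#'
#' @param a,b Equal-length paired numeric vectors.
#' @param exact_max Largest number of informative pairs for the exact path
#'   (default 12).
#' @return A one-row tibble: `statistic` (positive-rank sum `V`),
#'   `p_value`, `n` (informative pairs), `method`.
#' @export
paired_signed_rank <- function(a, b, exact_max = 12L) {
  if (length(a) != length(b)) abort("paired vectors differ in length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort("no informative pairs: all differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  center <- n * (n + 1) / 4
  if (n <= exact_max) {
    # enumerate the 2^n equally likely sign assignments of the observed ranks
    vnull <- vapply(0:(2^n - 1), function(mask) {
      sum(r[bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L])
    }, numeric(1))
    p <- mean(abs(vnull - center) >= abs(V - center) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - center) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation, tie-corrected"
  }
  tibble::tibble(statistic = V, p_value = p, n = n, method = method)
}
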