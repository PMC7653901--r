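#' Per-organ power-law exponent registry for EUD
#'
#' The generalized equivalent uniform dose uses a single exponent `k` per
#' organ category. The shipped defaults are the values used clinically for
#' nasopharyngeal planning: spinal cord 10.0; brainstem, optic nerves and
#' optic chiasm 9.8; larynx 6.8; lens 2.0; parotid glands 3.9. An organ and
#' its PRV share the same `k`, and bilateral organs (`_l`/`_r`) share one
#' entry. Where `k` is absent but a tolerance dose `D50` is supplied, the
#' Monaco-protocol rule `k = 0.15 * D50` applies.
#'
#' @param entries Named list: `organ -> list(k = , d50_gy = )`. Either
#'   element may be omitted per organ; `k` wins when both are present.
#' @return An object of class `k_registry`.
#' @examples
#' reg <- k_registry()
#' resolve_k(reg, "spinal_cord_prv")  # PRV shares the parent's k = 10
#' @export
k_registry <- function(entries = default_k_entries()) {
  for (org in names(entries)) {
    e <- entries[[org]]
    if (!is.null(e$k) && (!is.finite(e$k) || e$k <= 0)) {
      abort(sprintf("registry entry '%s': k must be > 0", org))
    }
    if (!is.null(e$d50_gy) && (!is.finite(e$d50_gy) || e$d50_gy <= 0)) {
      abort(sprintf("registry entry '%s': d50_gy must be > 0", org))
    }
  }
  structure(list(entries = entries), class = "k_registry")
}

default_k_entries <- function() {
  list(
    spinal_cord  = list(k = 10.0),
    brainstem    = list(k = 9.8),
    optic_nerve  = list(k = 9.8),
    optic_chiasm = list(k = 9.8),
    larynx       = list(k = 6.8),
    lens         = list(k = 2.0),
    parotid      = list(k = 3.9)
  )
}

#' @export
print.k_registry <- function(x, ...) {
  cat("<k_registry>\n")
  for (org in names(x$entries)) {
    e <- x$entries[[org]]
    cat(sprintf("  %-14s k = %s%s\n", org,
                if (is.null(e$k)) sprintf("0.15 x D50 = %.3g", 0.15 * e$d50_gy)
                else format(e$k),
                if (is.null(e$d50_gy)) "" else sprintf("  (D50 = %g Gy)", e$d50_gy)))
  }
  invisible(x)
}

#' Resolve the EUD exponent for a structure label
#'
#' PRV labels resolve to the parent organ; laterality suffixes (`_l`, `_r`)
#' resolve to the shared bilateral entry. Falls back to `0.15 * D50` when
#' only `d50_gy` is registered.
#'
#' @param registry A [k_registry()].
#' @param structure_id Structure label from [oar_vocabulary()] (custom
#'   labels are accepted if the registry has a matching entry).
#' @return The exponent `k` (dimensionless, > 0).
#' @export
resolve_k <- function(registry, structure_id) {
  stopifnot(inherits(registry, "k_registry"))
  base <- sub("_prv$", "", structure_id)
  base <- sub("_[lr]$", "", base)
  e <- registry$entries[[structure_id]] %||% registry$entries[[base]]
  if (is.null(e)) abort(sprintf("no exponent available for '%s'", structure_id))
  if (!is.null(e$k)) return(e$k)
  if (!is.null(e$d50_gy)) return(0.15 * e$d50_gy)
  abort(sprintf("no exponent available for '%s' (neither k nor d50_gy registered)",
                structure_id))
}

#' Read a k registry from YAML or JSON
#'
#' Schema: a map `organ: {k: <float>, d50_gy: <float>}` with either field
#' optional per organ.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [k_registry()].
#' @export
read_k_registry <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  entries <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  k_registry(purrr::map(entries, function(e) {
    list(k = e$k, d50_gy = e$d50_gy)
  }))
}

#' Equivalent uniform dose of a DVH
#'
#' Generalized EUD over the percentage-volume grid,
#' \deqn{EUD = \left(\sum_v \Delta v \, D_v^k\right)^{1/k},}
#' the power mean of the dose quantiles with exponent `k`. `k = 1` gives the
#' mean dose; large `k` approaches the maximum dose, weighting hot spots for
#' serial organs. Computed as `Dmax * (sum(dv * (D/Dmax)^k))^(1/k)` so that
#' clinically large exponents (k near 10, doses near 70 Gy) do not overflow.
#'
#' @param dvh A [dvh_curve()].
#' @param k Power-law exponent, > 0 (target-type negative exponents are
#'   rejected).
#' @return EUD in Gy; an all-zero curve returns 0 for any `k`.
#' @examples
#' cv <- dvh_curve(c(20, 20, 60, 60), dv = 0.25)
#' eud(cv, k = 1)   # mean dose, 40 Gy
#' eud(cv, k = 10)
#' @export
eud <- function(dvh, k) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (length(k) != 1L || !is.finite(k) || k <= 0) {
    abort("k must be a single positive exponent")
  }
  dmax <- max_dose(dvh)
  if (dmax == 0) return(0)
  dmax * (sum(dvh$dv * (dvh$doses / dmax)^k))^(1 / k)
}

#' Mean-ratio prediction correction factor
#'
#' The per-organ multiplicative bias of predicted EUDs, estimated on the
#' training cohort as the arithmetic mean of the true-to-predicted ratios:
#' \deqn{c_{OAR} = \frac{1}{n}\sum_P EUD_P / EUD'_P.}
#' Multiplying predictions by this factor makes the training-set mean ratio
#' of truth to corrected prediction exactly 1.
#'
#' @param eud_true,eud_pred Equal-length numeric vectors in Gy; all
#'   predictions must be positive.
#' @return Dimensionless correction factor.
#' @export
correction_factor <- function(eud_true, eud_pred) {
  if (length(eud_true) == 0L) abort("empty training pairs")
  if (length(eud_true) != length(eud_pred)) abort("pair vectors differ in length")
  if (any(!is.finite(eud_true)) || any(!is.finite(eud_pred))) abort("non-finite EUD")
  if (any(eud_pred <= 0)) abort("degenerate prediction: non-positive predicted EUD")
  mean(eud_true / eud_pred)
}

#' Corrected EUD constraint for inverse planning
#'
#' Tightened, bias-corrected constraint
#' \deqn{cEUD' = \alpha \, c_{OAR} \, EUD',}
#' with `alpha` slightly below 1 (0.97 in practice) so the optimizer is
#' pushed marginally below the predicted achievable dose.
#'
#' @param eud_pred Predicted EUD in Gy (> 0).
#' @param c_oar Correction factor from [correction_factor()] (> 0).
#' @param alpha Tightening factor in (0, 1]; default 0.97.
#' @return Constraint dose in Gy.
#' @export
corrected_eud_constraint <- function(eud_pred, c_oar, alpha = 0.97) {
  if (any(eud_pred <= 0) || any(c_oar <= 0)) abort("inputs must be positive")
  if (length(alpha) != 1L || alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1]")
  alpha * c_oar * eud_pred
}

#' Corrected maximum-dose constraint
#'
#' The same correct-and-tighten process applied to the maximum dose, used
#' for strictly serial structures (spinal cord, lens): the correction factor
#' is the training-set mean ratio of true to predicted maximum dose, and the
#' constraint is `alpha * c_max * dmax_pred`.
#'
#' @param dmax_pred Predicted maximum dose in Gy (> 0).
#' @param dmax_true_train,dmax_pred_train Training-set pairs of true and
#'   predicted maximum doses (Gy).
#' @param alpha Tightening factor in (0, 1]; default 0.97.
#' @return Constraint dose in Gy.
#' @export
corrected_max_dose_constraint <- function(dmax_pred, dmax_true_train,
                                          dmax_pred_train, alpha = 0.97) {
  c_max <- correction_factor(dmax_true_train, dmax_pred_train)
  corrected_eud_constraint(dmax_pred, c_max, alpha = alpha)
}

#' Build a planner-ready constraint table
#'
#' Combines predicted curves with training-set bias correction into one
#' tidy table of EUD constraints (all organs) and maximum-dose constraints
#' (serial organs), ready for [write_constraints()].
#'
#' @param predicted A [dvh_set()] tibble of predicted plan curves
#'   (`source == "predicted"`).
#' @param train_true,train_pred [dvh_set()] tibbles of true and predicted
#'   plan curves for the training cohort, matched by patient and structure.
#' @param registry A [k_registry()].
#' @param alpha Tightening factor; default 0.97.
#' @param max_dose_organs Structure labels that additionally receive a
#'   corrected maximum-dose constraint; defaults to spinal cord and lenses.
#' @return A tibble with columns `patient_id, structure_id, constraint_type,
#'   value_gy, k, c_oar, alpha`.
#' @export
constraint_set <- function(predicted, train_true, train_pred, registry,
                           alpha = 0.97,
                           max_dose_organs = c("spinal_cord", "spinal_cord_prv",
                                               "lens_l", "lens_r")) {
  stopifnot(inherits(registry, "k_registry"))
  train <- dplyr::inner_join(
    dplyr::select(train_true, "patient_id", "structure_id", true_curve = "curve"),
    dplyr::select(train_pred, "patient_id", "structure_id", pred_curve = "curve"),
    by = c("patient_id", "structure_id")
  )
  if (nrow(train) == 0) abort("no matched training pairs")

  per_organ <- train |>
    dplyr::group_by(.data$structure_id) |>
    dplyr::summarise(
      c_oar = correction_factor(
        purrr::map2_dbl(.data$true_curve, .data$structure_id,
                        ~ eud(.x, resolve_k(registry, .y))),
        purrr::map2_dbl(.data$pred_curve, .data$structure_id,
                        ~ eud(.x, resolve_k(registry, .y)))
      ),
      c_max = correction_factor(
        purrr::map_dbl(.data$true_curve, max_dose),
        purrr::map_dbl(.data$pred_curve, max_dose)
      ),
      .groups = "drop"
    )

  out <- predicted |>
    dplyr::left_join(per_organ, by = "structure_id") |>
    dplyr::mutate(
      k = purrr::map_dbl(.data$structure_id, ~ resolve_k(registry, .x)),
      eud_pred = purrr::map2_dbl(.data$curve, .data$k, eud),
      dmax_pred = purrr::map_dbl(.data$curve, max_dose)
    )
  if (anyNA(out$c_oar)) {
    abort(sprintf("no training pairs for structure(s): %s",
                  paste(unique(out$structure_id[is.na(out$c_oar)]), collapse = ", ")))
  }
  eud_rows <- out |>
    dplyr::transmute(
      .data$patient_id, .data$structure_id,
      constraint_type = "eud",
      value_gy = corrected_eud_constraint(.data$eud_pred, .data$c_oar, alpha),
      .data$k, c_oar = .data$c_oar, alpha = alpha
    )
  max_rows <- out |>
    dplyr::filter(.data$structure_id %in% max_dose_organs) |>
    dplyr::transmute(
      .data$patient_id, .data$structure_id,
      constraint_type = "max_dose",
      value_gy = corrected_eud_constraint(.data$dmax_pred, .data$c_max, alpha),
      k = NA_real_, c_oar = .data$c_max, alpha = alpha
    )
  dplyr::bind_rows(eud_rows, max_rows) |>
    dplyr::arrange(.data$patient_id, .data$structure_id, .data$constraint_type)
}

#' @rdname constraint_set
#' @param x Constraint table from [constraint_set()].
#' @param path Output CSV path.
#' @export
write_constraints <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
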