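#' @useDynLib beamdvh, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort .data %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @keywords internal
"_PACKAGE"

#' Controlled organ-at-risk vocabulary
#'
#' Structure labels accepted throughout the package. Bilateral organs carry
#' `_l` / `_r` suffixes; planning organ-at-risk volumes carry `_prv`.
#' Cropped variants (overlap with target volumes removed upstream) use the
#' same label.
#'
#' @export
oar_vocabulary <- function() {
  c(
    "brainstem", "brainstem_prv",
    "spinal_cord", "spinal_cord_prv",
    "optic_chiasm",
    "optic_nerve_l", "optic_nerve_r",
    "lens_l", "lens_r",
    "parotid_l", "parotid_r",
    "larynx",
    "temporal_lobe_l", "temporal_lobe_r"
  )
}

#' Fixed-grid quantile representation of a cumulative DVH
#'
#' A `dvh_curve` stores, for each point of a regular volume grid
#' \eqn{v = \Delta v, 2\Delta v, \ldots, 1}, the dose \eqn{D_v} such that a
#' fraction \eqn{v} of the organ receives at most \eqn{D_v}. This is the
#' dose-quantile function of the dose distribution within the structure,
#' resampled by percentage volume bin so that every curve has the same
#' length regardless of organ size.
#'
#' @param doses Numeric vector of dose quantiles in Gy, one per grid point,
#'   non-decreasing, finite, non-negative. Must have exactly `round(1/dv)`
#'   entries.
#' @param dv Volume-bin width as a fraction (default 0.001, i.e. 0.1%).
#' @param structure_id Organ label from [oar_vocabulary()] (or `NA`).
#' @param source One of `"beam"`, `"plan"`, `"predicted"`.
#' @param total_volume_cc Organ volume in cm^3; only needed for
#'   absolute-volume metrics such as [dose_at_absolute_volume()].
#'
#' @return An object of class `dvh_curve`.
#' @examples
#' cv <- dvh_curve(rep(50, 4), dv = 0.25)
#' mean_dose(cv)
#' @export
dvh_curve <- function(doses, dv = 0.001, structure_id = NA_character_,
                      source = c("plan", "beam", "predicted"),
                      total_volume_cc = NA_real_) {
  source <- match.arg(source)
  doses <- as.numeric(doses)
  if (length(dv) != 1L || !is.finite(dv) || dv <= 0 || dv > 0.5) {
    abort("`dv` must be a single value in (0, 0.5].")
  }
  n <- round(1 / dv)
  if (abs(1 / dv - n) > 1e-8) {
    abort("`dv` must divide 1 into a whole number of volume bins.")
  }
  if (length(doses) != n) {
    abort(sprintf(
      "curve has %d dose values but dv = %g implies %d grid points",
      length(doses), dv, n
    ))
  }
  if (anyNA(doses) || any(!is.finite(doses))) abort("invalid dose: non-finite values")
  if (any(doses < 0)) abort("invalid dose: negative values")
  if (is.unsorted(doses)) abort("doses must be non-decreasing along the volume grid")
  if (!is.na(structure_id) && !structure_id %in% oar_vocabulary()) {
    abort(sprintf("unknown structure label '%s'", structure_id))
  }
  structure(
    list(
      structure_id = structure_id, doses = doses, dv = dv,
      total_volume_cc = total_volume_cc, source = source
    ),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf(
    "<dvh_curve> %s [%s], %d bins (dv = %g), dose %.2f-%.2f Gy\n",
    ifelse(is.na(x$structure_id), "?", x$structure_id), x$source,
    length(x$doses), x$dv, min(x$doses), max(x$doses)
  ))
  invisible(x)
}

#' Volume grid of a quantile DVH
#' @param dvh A [dvh_curve()].
#' @return Numeric vector `dv, 2*dv, ..., 1`.
#' @export
volume_grid <- function(dvh) {
  stopifnot(inherits(dvh, "dvh_curve"))
  dvh$dv * seq_along(dvh$doses)
}

#' Empirical quantile DVH from voxel doses
#'
#' Builds the percentage-volume quantile curve directly from a list of voxel
#' doses, using linear interpolation of the empirical distribution function
#' (quantile type 4), which resolves flat and jump regions to the lowest
#' dose attaining each volume level.
#'
#' @param voxel_doses Non-empty numeric vector of per-voxel doses in Gy.
#' @inheritParams dvh_curve
#' @return A [dvh_curve()].
#' @examples
#' dvh_from_voxels(c(0, 10, 20, 30), dv = 0.25)$doses
#' @export
dvh_from_voxels <- function(voxel_doses, dv = 0.001,
                            structure_id = NA_character_,
                            source = c("plan", "beam", "predicted"),
                            total_volume_cc = NA_real_) {
  if (length(voxel_doses) == 0L) abort("empty structure")
  if (anyNA(voxel_doses) || any(!is.finite(voxel_doses))) abort("invalid dose: non-finite values")
  if (any(voxel_doses < 0)) abort("invalid dose: negative values")
  v <- seq_len(round(1 / dv)) * dv
  q <- stats::quantile(voxel_doses, probs = v, type = 4, names = FALSE)
  dvh_curve(q, dv = dv, structure_id = structure_id, source = source,
            total_volume_cc = total_volume_cc)
}

#' Conventional dose-binned cumulative DVH
#'
#' The familiar clinical form: for each dose edge, the fraction of the
#' structure receiving at least that dose. Complements the quantile form
#' used everywhere else in the package.
#'
#' @param dose_edges Increasing numeric vector of dose values in Gy.
#' @param volume_fractions Fractions in `[0, 1]`, non-increasing, same
#'   length as `dose_edges`; must start at 1 for dose 0.
#' @param structure_id Organ label (or `NA`).
#' @return An object of class `dose_binned_dvh`.
#' @export
dose_binned_dvh <- function(dose_edges, volume_fractions,
                            structure_id = NA_character_) {
  dose_edges <- as.numeric(dose_edges)
  volume_fractions <- as.numeric(volume_fractions)
  if (length(dose_edges) != length(volume_fractions)) {
    abort("dose_edges and volume_fractions must have equal length")
  }
  if (is.unsorted(dose_edges, strictly = TRUE)) abort("dose edges must be strictly increasing")
  if (any(diff(volume_fractions) > 1e-12)) abort("not a cumulative DVH: volume fractions increase with dose")
  if (any(volume_fractions < -1e-12 | volume_fractions > 1 + 1e-12)) {
    abort("volume fractions must lie in [0, 1]")
  }
  if (dose_edges[1] <= 0 && abs(volume_fractions[1] - 1) > 1e-9) {
    abort("not a cumulative DVH: fraction at dose 0 must be 1")
  }
  structure(
    list(structure_id = structure_id, dose_edges = dose_edges,
         volume_fractions = pmin(pmax(volume_fractions, 0), 1)),
    class = "dose_binned_dvh"
  )
}

#' Resample a dose-binned DVH onto the percentage-volume quantile grid
#'
#' Inverts the non-increasing volume-versus-dose curve with linear
#' interpolation; flat segments resolve to the lowest dose attaining the
#' volume level, so the result is the (lower) dose-quantile function on the
#' regular grid.
#'
#' @param dvh A [dose_binned_dvh()].
#' @inheritParams dvh_curve
#' @return A [dvh_curve()].
#' @export
to_quantile <- function(dvh, dv = 0.001, source = c("plan", "beam", "predicted"),
                        total_volume_cc = NA_real_) {
  stopifnot(inherits(dvh, "dose_binned_dvh"))
  source <- match.arg(source)
  v <- seq_len(round(1 / dv)) * dv
  levels <- 1 - v
  y <- dvh$volume_fractions
  x <- dvh$dose_edges
  n <- length(y)
  # D(L) = inf{d : F(d) <= L} for the piecewise-linear F(d) = fraction >= d;
  # the first crossing resolves flat segments to their lowest dose
  q <- vapply(levels, function(L) {
    # tolerance guards exact-level matches against 1-ulp rounding of L
    i <- match(TRUE, y <= L + 1e-9)
    if (is.na(i)) return(x[n])          # curve never drops to L: clamp at max edge
    if (i == 1L) return(x[1])
    x[i - 1] + max(y[i - 1] - L, 0) / (y[i - 1] - y[i]) * (x[i] - x[i - 1])
  }, numeric(1))
  q <- cummax(pmax(q, 0))
  dvh_curve(q, dv = dv, structure_id = dvh$structure_id, source = source,
            total_volume_cc = total_volume_cc)
}

#' Export a quantile DVH in conventional dose-binned form
#'
#' @param dvh A [dvh_curve()].
#' @param dose_edges Increasing dose grid in Gy.
#' @return A [dose_binned_dvh()] giving, at each edge, the fraction of
#'   volume grid points whose dose quantile is at least that edge. The two
#'   forms are mutual inverses to within the edge spacing; choosing edges
#'   that bracket the curve's dose values recovers it exactly under
#'   [to_quantile()].
#' @export
to_dose_binned <- function(dvh, dose_edges) {
  stopifnot(inherits(dvh, "dvh_curve"))
  dose_edges <- as.numeric(dose_edges)
  if (is.unsorted(dose_edges, strictly = TRUE)) abort("dose edges must be strictly increasing")
  d <- dvh$doses
  frac <- vapply(dose_edges, function(edge) mean(d >= edge), numeric(1))
  frac[dose_edges <= 0] <- 1
  dose_binned_dvh(dose_edges, frac, structure_id = dvh$structure_id)
}

#' Dose covering the hottest fraction of a structure (Dx%)
#'
#' `dose_at_relative_volume(dvh, 0.98)` is D98: the minimum dose received by
#' the hottest 98% of the organ, i.e. the dose quantile at volume level
#' `1 - 0.98` (linear interpolation between grid points).
#'
#' @param dvh A [dvh_curve()].
#' @param volume_fraction_at_least Fraction in (0, 1].
#' @return Dose in Gy.
#' @export
dose_at_relative_volume <- function(dvh, volume_fraction_at_least) {
  stopifnot(inherits(dvh, "dvh_curve"))
  f <- volume_fraction_at_least
  if (length(f) != 1L || !is.finite(f) || f <= 0 || f > 1) {
    abort("volume fraction must lie in (0, 1]")
  }
  # bin i holds the voxels in (v_{i-1}, v_i]; the coldest voxel of the
  # hottest fraction f sits at fractional bin position (1 - f)/dv + 1,
  # matching the order-statistic reading (hottest f*n voxels of n)
  d <- dvh$doses
  n <- length(d)
  pos <- min(max((1 - f) / dvh$dv + 1, 1), n)
  lo <- floor(pos)
  hi <- ceiling(pos)
  d[lo] + (pos - lo) * (d[hi] - d[lo])
}

#' Dose to the hottest absolute volume (e.g. D1cc)
#'
#' @param dvh A [dvh_curve()] with `total_volume_cc` set.
#' @param volume_cc Absolute volume in cm^3, in `(0, total_volume_cc]`.
#' @return Dose in Gy.
#' @export
dose_at_absolute_volume <- function(dvh, volume_cc) {
  stopifnot(inherits(dvh, "dvh_curve"))
  tv <- dvh$total_volume_cc
  if (is.na(tv) || !is.finite(tv) || tv <= 0) {
    abort("absolute metric requires organ volume")
  }
  if (volume_cc <= 0 || volume_cc > tv) abort("volume_cc must lie in (0, total_volume_cc]")
  dose_at_relative_volume(dvh, volume_cc / tv)
}

#' Mean and maximum dose of a quantile DVH
#'
#' The mean is the `dv`-weighted Riemann sum over the volume grid; the
#' maximum is the final (largest) grid value.
#'
#' @param dvh A [dvh_curve()].
#' @return Dose in Gy.
#' @export
mean_dose <- function(dvh) {
  stopifnot(inherits(dvh, "dvh_curve"))
  mean(dvh$doses)
}

#' @rdname mean_dose
#' @export
max_dose <- function(dvh) {
  stopifnot(inherits(dvh, "dvh_curve"))
  dvh$doses[length(dvh$doses)]
}

#' Plot a DVH in conventional orientation
#'
#' Dose on the x axis, percent volume receiving at least that dose on the y
#' axis, as treatment planning systems display cumulative DVHs.
#'
#' @param object A [dvh_curve()].
#' @param n_edges Number of dose edges used for display resampling.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dvh_curve <- function(object, n_edges = 200, ...) {
  edges <- seq(0, max(max_dose(object), 1e-9), length.out = n_edges)
  db <- to_dose_binned(object, edges)
  df <- tibble::tibble(dose_gy = db$dose_edges,
                       volume_pct = 100 * db$volume_fractions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_gy, y = .data$volume_pct)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Dose (Gy)", y = "Volume (%)",
      title = ifelse(is.na(object$structure_id), "DVH",
                     paste0("DVH: ", object$structure_id)),
      subtitle = paste0("source: ", object$source)
    ) +
    ggplot2::theme_minimal()
}
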