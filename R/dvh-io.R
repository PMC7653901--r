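#' Assemble a DVH-set tibble
#'
#' The package's tabular container for DVH collections: one row per
#' (patient, structure, source, field) with the curve itself in a list
#' column, so sets flow naturally through dplyr verbs.
#'
#' @param patient_id,structure_id,source Character vectors (recycled).
#' @param field_index Integer vector; 1-9 for beams, 0 for plan/predicted.
#' @param curve List of [dvh_curve()] objects.
#' @return A tibble with columns `patient_id, structure_id, source,
#'   field_index, dv, total_volume_cc, curve`.
#' @export
dvh_set <- function(patient_id, structure_id, source, field_index, curve) {
  tbl <- tibble::tibble(
    patient_id = as.character(patient_id),
    structure_id = as.character(structure_id),
    source = as.character(source),
    field_index = as.integer(field_index),
    dv = vapply(curve, function(cv) cv$dv, numeric(1)),
    total_volume_cc = vapply(curve, function(cv) cv$total_volume_cc, numeric(1)),
    curve = curve
  )
  validate_dvh_set(tbl)
  tbl
}

validate_dvh_set <- function(tbl, file = NULL) {
  where <- if (is.null(file)) "" else sprintf(" in '%s'", file)
  bad_src <- !tbl$source %in% c("beam", "plan", "predicted")
  if (any(bad_src)) {
    abort(sprintf("row %d%s: unknown source '%s'",
                  which(bad_src)[1], where, tbl$source[which(bad_src)[1]]))
  }
  beam_fi <- tbl$source == "beam"
  if (any(tbl$field_index[beam_fi] < 1 | tbl$field_index[beam_fi] > 9)) {
    abort(sprintf("beam rows%s must carry field_index 1-9", where))
  }
  if (any(tbl$field_index[!beam_fi] != 0L)) {
    abort(sprintf("plan/predicted rows%s must carry field_index 0", where))
  }
  invisible(tbl)
}

csv_cols <- c("patient_id", "structure_id", "source", "field_index",
              "dv", "bin_index", "dose_gy", "total_volume_cc")

#' Read and write DVH sets
#'
#' Two plain-text on-disk schemas are supported. CSV: one row per
#' (patient, structure, source, field, volume-bin) with columns
#' `patient_id, structure_id, source, field_index, dv, bin_index, dose_gy,
#' total_volume_cc`. JSON: a nested
#' `{patients: [{patient_id, structures: [...]}]}` document with per-structure
#' `plan`, `beams` (keyed by field index) and optional `predicted` dose
#' arrays. Write-then-read is lossless for valid curves; curves are
#' validated on read and schema violations name the file, row and failed
#' invariant.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `read_dvh_set()` returns a [dvh_set()] tibble;
#'   `write_dvh_set()` returns `path` invisibly.
#' @export
read_dvh_set <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  if (format == "csv") read_dvh_csv(path) else read_dvh_json(path)
}

#' @rdname read_dvh_set
#' @param x A [dvh_set()] tibble.
#' @export
write_dvh_set <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  validate_dvh_set(x)
  if (format == "csv") write_dvh_csv(x, path) else write_dvh_json(x, path)
  invisible(path)
}

read_dvh_csv <- function(path) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           structure_id = readr::col_character(),
                           source = readr::col_character(),
                           field_index = readr::col_integer(),
                           dv = readr::col_double(),
                           bin_index = readr::col_integer(),
                           dose_gy = readr::col_double(),
                           total_volume_cc = readr::col_double()
                         ))
  missing <- setdiff(csv_cols, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("'%s': missing columns: %s", path, paste(missing, collapse = ", ")))
  }
  grp <- raw |>
    dplyr::group_by(.data$patient_id, .data$structure_id, .data$source,
                    .data$field_index) |>
    dplyr::arrange(.data$bin_index, .by_group = TRUE)
  keys <- dplyr::group_keys(grp)
  chunks <- dplyr::group_split(grp)
  curves <- purrr::map2(chunks, seq_along(chunks), function(ch, i) {
    dv <- ch$dv[1]
    n_expected <- round(1 / dv)
    if (nrow(ch) != n_expected) {
      abort(sprintf(
        "'%s': %s/%s/%s field %d has %d bins but dv = %g implies %d",
        path, ch$patient_id[1], ch$structure_id[1], ch$source[1],
        ch$field_index[1], nrow(ch), dv, n_expected
      ))
    }
    if (!identical(ch$bin_index, seq_len(n_expected))) {
      abort(sprintf("'%s': %s/%s: bin_index must run 1..%d",
                    path, ch$patient_id[1], ch$structure_id[1], n_expected))
    }
    if (is.unsorted(ch$dose_gy)) {
      bad <- which(diff(ch$dose_gy) < 0)[1]
      abort(sprintf(
        "'%s': %s/%s/%s field %d: doses decrease at bin %d (not a quantile DVH)",
        path, ch$patient_id[1], ch$structure_id[1], ch$source[1],
        ch$field_index[1], bad + 1L
      ))
    }
    dvh_curve(ch$dose_gy, dv = dv, structure_id = ch$structure_id[1],
              source = ch$source[1], total_volume_cc = ch$total_volume_cc[1])
  })
  out <- dvh_set(keys$patient_id, keys$structure_id, keys$source,
                 keys$field_index, curves)
  validate_dvh_set(out, file = path)
  out
}

write_dvh_csv <- function(x, path) {
  long <- purrr::pmap(
    list(x$patient_id, x$structure_id, x$source, x$field_index,
         x$dv, x$total_volume_cc, x$curve),
    function(pid, sid, src, fi, dv, tv, cv) {
      tibble::tibble(
        patient_id = pid, structure_id = sid, source = src, field_index = fi,
        dv = dv, bin_index = seq_along(cv$doses), dose_gy = cv$doses,
        total_volume_cc = tv
      )
    }
  ) |> purrr::list_rbind()
  readr::write_csv(long[, csv_cols], path)
}

read_dvh_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(doc$patients)) abort(sprintf("'%s': missing top-level 'patients'", path))
  rows <- purrr::map(doc$patients, function(p) {
    purrr::map(p$structures, function(s) {
      dv <- s$dv
      tv <- if (is.null(s$total_volume_cc)) NA_real_ else s$total_volume_cc
      out <- list()
      if (!is.null(s$plan)) {
        out <- c(out, list(list(
          patient_id = p$patient_id, structure_id = s$structure_id,
          source = "plan", field_index = 0L,
          curve = dvh_curve(unlist(s$plan), dv = dv, structure_id = s$structure_id,
                            source = "plan", total_volume_cc = tv)
        )))
      }
      if (!is.null(s$predicted)) {
        out <- c(out, list(list(
          patient_id = p$patient_id, structure_id = s$structure_id,
          source = "predicted", field_index = 0L,
          curve = dvh_curve(unlist(s$predicted), dv = dv,
                            structure_id = s$structure_id,
                            source = "predicted", total_volume_cc = tv)
        )))
      }
      for (fi in names(s$beams)) {
        out <- c(out, list(list(
          patient_id = p$patient_id, structure_id = s$structure_id,
          source = "beam", field_index = as.integer(fi),
          curve = dvh_curve(unlist(s$beams[[fi]]), dv = dv,
                            structure_id = s$structure_id,
                            source = "beam", total_volume_cc = tv)
        )))
      }
      out
    })
  })
  rows <- purrr::flatten(purrr::flatten(rows))
  if (length(rows) == 0) abort(sprintf("'%s': no curves", path))
  out <- dvh_set(
    purrr::map_chr(rows, "patient_id"),
    purrr::map_chr(rows, "structure_id"),
    purrr::map_chr(rows, "source"),
    purrr::map_int(rows, "field_index"),
    purrr::map(rows, "curve")
  )
  validate_dvh_set(out, file = path)
  out
}

write_dvh_json <- function(x, path) {
  patients <- x |> dplyr::group_by(.data$patient_id) |> dplyr::group_split()
  doc <- list(patients = purrr::map(patients, function(p) {
    structs <- p |> dplyr::group_by(.data$structure_id) |> dplyr::group_split()
    list(
      patient_id = p$patient_id[1],
      structures = purrr::map(structs, function(s) {
        entry <- list(structure_id = s$structure_id[1], dv = s$dv[1])
        tv <- s$total_volume_cc[1]
        if (!is.na(tv)) entry$total_volume_cc <- tv
        plan <- s$curve[s$source == "plan"]
        if (length(plan) > 0) entry$plan <- plan[[1]]$doses
        pred <- s$curve[s$source == "predicted"]
        if (length(pred) > 0) entry$predicted <- pred[[1]]$doses
        beams <- s[s$source == "beam", ]
        if (nrow(beams) > 0) {
          entry$beams <- stats::setNames(
            purrr::map(beams$curve, "doses"),
            as.character(beams$field_index)
          )
        }
        entry
      })
    )
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
}
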