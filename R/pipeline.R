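#' Resolved run configuration
#'
#' One YAML (or list) configuration drives the whole pipeline:
#' `simulate -> train -> predict -> constraints -> evaluate`. Recognised
#' top-level keys: `seed`, `out_dir`, `cohort` (fields of
#' [cohort_config()]), `model` (fields of [gru_config()]), `registry`
#' (optional path to a YAML/JSON exponent map for [read_k_registry()]),
#' `alpha`, `log_level`. Unknown keys anywhere are rejected. The top-level
#' `seed` overrides the cohort and model seeds so one integer controls
#' every source of randomness.
#'
#' @param config Path to a YAML file, or a named list.
#' @param seed,out_dir Optional overrides.
#' @return An object of class `run_config`.
#' @export
run_config <- function(config = list(), seed = NULL, out_dir = NULL) {
  if (inherits(config, "run_config")) {
    cfg <- config
    if (!is.null(seed)) cfg <- run_config(cfg$raw, seed = seed, out_dir = out_dir %||% cfg$out_dir)
    if (!is.null(out_dir)) cfg$out_dir <- out_dir
    return(cfg)
  }
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file '%s' does not exist", config),
            class = "beamdvh_validation")
    }
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  allowed <- c("seed", "out_dir", "cohort", "model", "registry", "alpha",
               "log_level")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "beamdvh_validation")
  }
  check_block <- function(block, fn, name) {
    block <- block %||% list()
    unknown <- setdiff(names(block), names(formals(fn)))
    if (length(unknown) > 0) {
      abort(sprintf("unknown %s config key(s): %s", name,
                    paste(unknown, collapse = ", ")),
            class = "beamdvh_validation")
    }
    block
  }
  cohort_block <- check_block(config$cohort, cohort_config, "cohort")
  model_block <- check_block(config$model, gru_config, "model")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  cohort_block$seed <- seed
  model_block$seed <- seed
  out_dir <- out_dir %||% config$out_dir %||% "beamdvh_run"
  registry <- if (!is.null(config$registry)) read_k_registry(config$registry) else k_registry()
  cfg <- list(
    seed = seed, out_dir = out_dir,
    cohort = do.call(cohort_config, cohort_block),
    model = do.call(gru_config, model_block),
    registry = registry,
    registry_path = config$registry,
    alpha = config$alpha %||% 0.97,
    log_level = config$log_level %||% "info",
    raw = config
  )
  if (cfg$alpha <= 0 || cfg$alpha > 1) {
    abort("alpha must lie in (0, 1]", class = "beamdvh_validation")
  }
  structure(cfg, class = "run_config")
}

pipeline_paths <- function(cfg) {
  od <- cfg$out_dir
  list(
    cohort_dir = file.path(od, "cohort"),
    train = file.path(od, "cohort", "train.csv"),
    test = file.path(od, "cohort", "test.csv"),
    model = file.path(od, "model.json"),
    predicted_train = file.path(od, "predicted_train.csv"),
    predicted_test = file.path(od, "predicted_test.csv"),
    constraints = file.path(od, "constraints.csv"),
    eval_summary = file.path(od, "eval_summary.csv"),
    metrics = file.path(od, "metrics.csv"),
    agreement = file.path(od, "agreement.csv")
  )
}

# out_dir is a location, not configuration: kept out of snapshots so two
# runs of one config into different directories are byte-identical
resolved_config_list <- function(cfg) {
  list(
    seed = cfg$seed,
    cohort = unclass(cfg$cohort), model = unclass(cfg$model),
    registry = cfg$registry_path, alpha = cfg$alpha
  )
}

write_snapshot <- function(cfg, step, inputs = character()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  snap <- file.path(cfg$out_dir, sprintf("config_%s.yaml", step))
  yaml::write_yaml(resolved_config_list(cfg), snap)
  prov <- list(
    step = step,
    package = "beamdvh",
    version = as.character(utils::packageVersion("beamdvh")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(snap)),
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(inputs[file.exists(inputs)])),
      basename(inputs[file.exists(inputs)])
    ))
  )
  jsonlite::write_json(prov, file.path(cfg$out_dir, sprintf("provenance_%s.json", step)),
                       auto_unbox = TRUE, digits = NA)
  invisible(snap)
}

write_csv_with_header <- function(df, path, header) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  readr::write_csv(df, con)
  invisible(path)
}

log_step <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message(sprintf(...))
}

#' Pipeline steps
#'
#' Each step reads its inputs from, and writes its outputs under, the
#' configured `out_dir`, alongside a resolved-config snapshot and a
#' provenance record (package version, seed, input file hashes). All steps
#' are deterministic given (config, seed): two runs produce byte-identical
#' outputs.
#'
#' * `run_simulate()`: generate the synthetic cohort (`cohort/train.csv`,
#'   `cohort/test.csv`, `cohort/latents.csv`).
#' * `run_train()`: fit the pooled DVH model on the training split
#'   (`model.json`).
#' * `run_predict()`: predict composite DVHs for the training and test
#'   splits (`predicted_train.csv`, `predicted_test.csv`).
#' * `run_constraints()`: corrected EUD / max-dose constraints for the test
#'   patients, bias-corrected on the training split (`constraints.csv`).
#' * `run_evaluate()`: per-organ accuracy summary, metric table and
#'   agreement analysis (`eval_summary.csv`, `metrics.csv`,
#'   `agreement.csv`).
#' * `run_pipeline()`: all five in order.
#'
#' @param config A [run_config()], a path to a YAML config, or a list.
#' @param seed,out_dir Optional overrides.
#' @return The paths written, invisibly (a list for `run_pipeline()`).
#' @export
run_simulate <- function(config = list(), seed = NULL, out_dir = NULL) {
  cfg <- run_config(config, seed = seed, out_dir = out_dir)
  paths <- pipeline_paths(cfg)
  log_step(cfg, "simulate: %d patients x %d organs -> %s",
           cfg$cohort$n_patients, length(cfg$cohort$organs), paths$cohort_dir)
  cohort <- generate_cohort(cfg$cohort)
  write_cohort(cohort, paths$cohort_dir)
  write_snapshot(cfg, "simulate")
  invisible(paths$cohort_dir)
}

#' @rdname run_simulate
#' @export
run_train <- function(config = list(), seed = NULL, out_dir = NULL) {
  cfg <- run_config(config, seed = seed, out_dir = out_dir)
  paths <- pipeline_paths(cfg)
  if (!file.exists(paths$train)) {
    abort(sprintf("training set '%s' not found; run run_simulate() first",
                  paths$train), class = "beamdvh_validation")
  }
  samples <- collect_samples(read_dvh_set(paths$train))
  log_step(cfg, "train: %d samples, %d epochs", nrow(samples), cfg$model$epochs)
  model <- train_dvh_model(samples, cfg$model)
  save_dvh_model(model, paths$model)
  write_snapshot(cfg, "train", inputs = paths$train)
  invisible(paths$model)
}

#' @rdname run_simulate
#' @export
run_predict <- function(config = list(), seed = NULL, out_dir = NULL) {
  cfg <- run_config(config, seed = seed, out_dir = out_dir)
  paths <- pipeline_paths(cfg)
  for (p in c(paths$model, paths$train, paths$test)) {
    if (!file.exists(p)) {
      abort(sprintf("input '%s' not found; run earlier pipeline steps first", p),
            class = "beamdvh_validation")
    }
  }
  model <- load_dvh_model(paths$model)
  for (split in c("train", "test")) {
    samples <- collect_samples(read_dvh_set(paths[[split]]))
    pred <- purrr::map(samples$beams, predict_dvh, model = model)
    out <- dvh_set(samples$patient_id, samples$structure_id,
                   rep("predicted", nrow(samples)), rep(0L, nrow(samples)),
                   pred)
    write_dvh_set(out, paths[[paste0("predicted_", split)]])
  }
  log_step(cfg, "predict: wrote %s and %s",
           paths$predicted_train, paths$predicted_test)
  write_snapshot(cfg, "predict", inputs = c(paths$model, paths$train, paths$test))
  invisible(c(paths$predicted_train, paths$predicted_test))
}

#' @rdname run_simulate
#' @export
run_constraints <- function(config = list(), seed = NULL, out_dir = NULL) {
  cfg <- run_config(config, seed = seed, out_dir = out_dir)
  paths <- pipeline_paths(cfg)
  needed <- c(paths$train, paths$predicted_train, paths$predicted_test)
  for (p in needed) {
    if (!file.exists(p)) {
      abort(sprintf("input '%s' not found; run earlier pipeline steps first", p),
            class = "beamdvh_validation")
    }
  }
  train_true <- read_dvh_set(paths$train) |> dplyr::filter(.data$source == "plan")
  train_pred <- read_dvh_set(paths$predicted_train)
  test_pred <- read_dvh_set(paths$predicted_test)
  cs <- constraint_set(test_pred, train_true, train_pred, cfg$registry,
                       alpha = cfg$alpha)
  write_constraints(cs, paths$constraints)
  log_step(cfg, "constraints: %d rows -> %s", nrow(cs), paths$constraints)
  write_snapshot(cfg, "constraints", inputs = needed)
  invisible(paths$constraints)
}

#' @rdname run_simulate
#' @export
run_evaluate <- function(config = list(), seed = NULL, out_dir = NULL) {
  cfg <- run_config(config, seed = seed, out_dir = out_dir)
  paths <- pipeline_paths(cfg)
  needed <- c(paths$test, paths$predicted_test, paths$model)
  for (p in needed) {
    if (!file.exists(p)) {
      abort(sprintf("input '%s' not found; run earlier pipeline steps first", p),
            class = "beamdvh_validation")
    }
  }
  test_true <- read_dvh_set(paths$test) |> dplyr::filter(.data$source == "plan")
  test_pred <- read_dvh_set(paths$predicted_test)
  header <- sprintf("beamdvh %s seed=%d model_md5=%s config_md5=%s",
                    utils::packageVersion("beamdvh"), cfg$seed,
                    unname(tools::md5sum(paths$model)),
                    digest_config(cfg))

  errors <- eud_errors(test_pred, test_true, cfg$registry, signed = TRUE)
  write_csv_with_header(summarize_eud_errors(errors), paths$eval_summary, header)

  both <- dplyr::bind_rows(test_true, test_pred)
  write_csv_with_header(
    plan_metric_table(both, cfg$registry, summarize = TRUE),
    paths$metrics, header
  )

  agreement <- errors |>
    dplyr::group_by(.data$structure_id) |>
    dplyr::group_modify(function(g, key) {
      loa <- limits_of_agreement(g$eud_pred, g$eud_true)
      test <- paired_signed_rank(g$eud_pred, g$eud_true)
      dplyr::bind_cols(loa, dplyr::select(test, wilcoxon_v = "statistic",
                                          p_value = "p_value"))
    }) |>
    dplyr::ungroup()
  write_csv_with_header(agreement, paths$agreement, header)
  log_step(cfg, "evaluate: wrote %s, %s, %s",
           paths$eval_summary, paths$metrics, paths$agreement)
  write_snapshot(cfg, "evaluate", inputs = needed)
  invisible(c(paths$eval_summary, paths$metrics, paths$agreement))
}

digest_config <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(resolved_config_list(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' @rdname run_simulate
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = NULL) {
  cfg <- run_config(config, seed = seed, out_dir = out_dir)
  run_simulate(cfg)
  run_train(cfg)
  run_predict(cfg)
  run_constraints(cfg)
  run_evaluate(cfg)
  invisible(pipeline_paths(cfg))
}
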