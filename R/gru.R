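#' Ordered set of nine per-beam DVH curves for one patient-organ
#'
#' The prediction input: the cumulative DVHs an organ receives from each of
#' nine individual conformal beams at equally spaced gantry angles. Curves
#' are ordered by field index FI = 1..9, never by angle value; the fixed
#' angle tuple is (160, 120, 80, 40, 0, 320, 280, 240, 200) degrees.
#'
#' @param patient_id,structure_id Identifiers.
#' @param beams List of exactly 9 [dvh_curve()] objects sharing one `dv`.
#' @return An object of class `beam_dvh_set`.
#' @export
beam_dvh_set <- function(patient_id, structure_id, beams) {
  if (length(beams) != 9L) abort("a beam set requires exactly 9 curves")
  ok <- vapply(beams, inherits, logical(1), what = "dvh_curve")
  if (!all(ok)) abort("all beams must be dvh_curve objects")
  dvs <- vapply(beams, function(b) b$dv, numeric(1))
  if (length(unique(dvs)) != 1L) abort("all 9 beam curves must share the same dv")
  structure(
    list(
      patient_id = patient_id, structure_id = structure_id, beams = beams,
      gantry_angles = gantry_angles()
    ),
    class = "beam_dvh_set"
  )
}

#' Fixed gantry angles of the nine conformal input beams
#' @return Integer vector of degrees, indexed by field index FI = 1..9.
#' @export
gantry_angles <- function() {
  c(160L, 120L, 80L, 40L, 0L, 320L, 280L, 240L, 200L)
}

#' @export
print.beam_dvh_set <- function(x, ...) {
  cat(sprintf("<beam_dvh_set> %s / %s: 9 beams, %d bins (dv = %g)\n",
              x$patient_id, x$structure_id,
              length(x$beams[[1]]$doses), x$beams[[1]]$dv))
  invisible(x)
}

#' Predictor configuration
#'
#' Architecture and training hyper-parameters of the DVH sequence
#' regressor. The model stacks three gated recurrent units with hidden
#' state sizes 18, 9 and 1; the final size-1 state sequence, read along the
#' volume grid, is the predicted curve. Doses are normalized by the highest
#' prescription dose (70 Gy) before entering the network.
#'
#' @param hidden_sizes Recurrent state sizes; the last must be 1.
#' @param dv Volume-bin width of the curves the model consumes.
#' @param dose_norm_gy Dose normalization divisor in Gy.
#' @param learning_rate,epochs,batch_size Adam training hyper-parameters.
#' @param seed Integer seed controlling parameter initialization and batch
#'   shuffling; recorded in checkpoints.
#' @return An object of class `gru_config`.
#' @export
gru_config <- function(hidden_sizes = c(18L, 9L, 1L), dv = 0.001,
                       dose_norm_gy = 70, learning_rate = 1e-3,
                       epochs = 200L, batch_size = 16L, seed = 1L) {
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) < 1L || any(hidden_sizes < 1L)) {
    abort("hidden_sizes must be positive integers")
  }
  if (hidden_sizes[length(hidden_sizes)] != 1L) {
    abort("the last hidden size must be 1 (the per-step predicted dose)")
  }
  if (dose_norm_gy <= 0) abort("dose_norm_gy must be positive")
  if (learning_rate <= 0 || epochs < 1L || batch_size < 1L) {
    abort("invalid training hyper-parameters")
  }
  structure(
    list(hidden_sizes = hidden_sizes, dv = dv, dose_norm_gy = dose_norm_gy,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "gru_config"
  )
}

layer_sizes <- function(config) c(9L, config$hidden_sizes)

#' Arrange a beam set as the model's input sequence
#'
#' One sequence step per volume grid point, ordered from `v = dv` to
#' `v = 1`; step `t` carries the nine beams' dose quantiles at grid point
#' `t`, each divided by `dose_norm_gy`. Column `b` belongs to field index
#' `b`.
#'
#' @param beam_set A [beam_dvh_set()].
#' @param config A [gru_config()].
#' @return Numeric matrix of shape `(n_bins, 9)`.
#' @export
assemble_sequence <- function(beam_set, config) {
  stopifnot(inherits(beam_set, "beam_dvh_set"), inherits(config, "gru_config"))
  n <- round(1 / config$dv)
  lens <- vapply(beam_set$beams, function(b) length(b$doses), integer(1))
  if (any(lens != n)) {
    abort(sprintf("beam grids (%d bins) do not match config dv = %g (%d bins)",
                  lens[1], config$dv, n))
  }
  vapply(beam_set$beams, function(b) b$doses / config$dose_norm_gy, numeric(n))
}

init_params <- function(config) {
  sizes <- layer_sizes(config)
  unlist(lapply(seq_len(length(sizes) - 1L), function(l) {
    I <- sizes[l]; H <- sizes[l + 1L]
    a <- 1 / sqrt(H)
    stats::runif(3L * H * I + 3L * H * H + 3L * H, min = -a, max = a)
  }))
}

#' Train the pooled DVH prediction model
#'
#' Fits one organ-independent model on all supplied patient-organ samples
#' by minimizing the mean squared difference between predicted and actual
#' plan curves over the volume grid, using the Adam optimizer with
#' mini-batches. Per-organ residual bias is handled downstream by the
#' correction factor, not by per-organ specialist models.
#'
#' Training is reproducible bit-for-bit given (`seed`, dataset order,
#' config) on one machine: the seed drives parameter initialization and
#' batch shuffling, and the caller's RNG state is left untouched.
#'
#' @param samples A tibble with list columns `beams` ([beam_dvh_set()]) and
#'   `plan` ([dvh_curve()]), one row per patient-organ pair, e.g. from
#'   [collect_samples()].
#' @param config A [gru_config()].
#' @param verbose Print epoch losses.
#' @return A fitted object of class `dvh_model` with elements `params`,
#'   `sizes`, `config`, `training_log` (per-epoch MSE on normalized doses)
#'   and `fitted`.
#' @export
train_dvh_model <- function(samples, config = gru_config(), verbose = FALSE) {
  stopifnot(inherits(config, "gru_config"))
  if (!is.data.frame(samples) || nrow(samples) == 0L) {
    abort("empty dataset: no training samples")
  }
  if (!all(c("beams", "plan") %in% names(samples))) {
    abort("samples must carry `beams` and `plan` list columns")
  }
  n_bins <- round(1 / config$dv)
  X <- purrr::map(samples$beams, assemble_sequence, config = config)
  Y <- purrr::map(samples$plan, function(p) {
    if (length(p$doses) != n_bins) {
      abort("plan curve grid does not match config dv")
    }
    p$doses / config$dose_norm_gy
  })
  sizes <- layer_sizes(config)
  n <- length(X)

  withr::with_seed(config$seed, {
    theta <- init_params(config)
    m <- v <- numeric(length(theta))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    training_log <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      sse_epoch <- 0; cnt_epoch <- 0
      for (s in starts) {
        batch <- idx[s:min(s + config$batch_size - 1L, n)]
        g <- cpp_gru_grad(theta, sizes, X[batch], Y[batch])
        grad <- as.numeric(g$grad)
        step <- step + 1L
        m <- beta1 * m + (1 - beta1) * grad
        v <- beta2 * v + (1 - beta2) * grad^2
        mhat <- m / (1 - beta1^step)
        vhat <- v / (1 - beta2^step)
        theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + eps)
        nb <- length(batch) * n_bins
        sse_epoch <- sse_epoch + g$loss * nb
        cnt_epoch <- cnt_epoch + nb
      }
      training_log[epoch] <- sse_epoch / cnt_epoch
      if (verbose && (epoch %% 10L == 0L || epoch == 1L)) {
        message(sprintf("epoch %4d  mse %.6g", epoch, training_log[epoch]))
      }
    }
  })

  structure(
    list(params = theta, sizes = sizes, config = config,
         training_log = training_log, fitted = TRUE),
    class = "dvh_model"
  )
}

#' @export
print.dvh_model <- function(x, ...) {
  cat(sprintf(
    "<dvh_model> GRU stack %s, %d parameters, %s\n",
    paste(x$sizes, collapse = "-"), length(x$params),
    if (isTRUE(x$fitted)) {
      sprintf("fitted (%d epochs, final mse %.3g)",
              length(x$training_log), utils::tail(x$training_log, 1))
    } else "unfitted"
  ))
  invisible(x)
}

#' Predict a composite-plan DVH from nine beam DVHs
#'
#' Runs the fitted sequence model over the volume grid, rescales by the
#' normalization dose, clips at zero and projects onto the monotone
#' non-decreasing cone by running maximum, so the output is always a valid
#' quantile DVH.
#'
#' @param model A fitted `dvh_model`.
#' @param beam_set A [beam_dvh_set()] on the model's grid.
#' @return A [dvh_curve()] with `source = "predicted"`.
#' @export
predict_dvh <- function(model, beam_set) {
  stopifnot(inherits(model, "dvh_model"))
  if (!isTRUE(model$fitted)) abort("model is not fitted")
  X <- assemble_sequence(beam_set, model$config)
  y <- cpp_gru_forward(model$params, model$sizes, X)[, 1]
  doses <- cummax(pmax(y * model$config$dose_norm_gy, 0))
  dvh_curve(doses, dv = model$config$dv,
            structure_id = beam_set$structure_id, source = "predicted")
}

#' @export
predict.dvh_model <- function(object, newdata, ...) {
  if (inherits(newdata, "beam_dvh_set")) return(predict_dvh(object, newdata))
  if (is.data.frame(newdata) && "beams" %in% names(newdata)) {
    out <- newdata
    out$predicted <- purrr::map(newdata$beams, predict_dvh, model = object)
    return(out)
  }
  abort("newdata must be a beam_dvh_set or a tibble with a `beams` column")
}

checkpoint_schema <- "beamdvh-gru-1"

#' Save and load model checkpoints
#'
#' Checkpoints are single JSON files carrying a schema version, the full
#' configuration (including the normalization dose, so prediction after
#' reload needs no external config), the flat parameter vector and the
#' training log. Doubles are written at full precision, so a reloaded model
#' reproduces predictions bit-for-bit.
#'
#' @param model A `dvh_model`.
#' @param path Checkpoint path (JSON).
#' @return `load_dvh_model()` returns the restored `dvh_model`.
#' @export
save_dvh_model <- function(model, path) {
  stopifnot(inherits(model, "dvh_model"))
  doc <- list(
    schema = checkpoint_schema,
    sizes = model$sizes,
    config = unclass(model$config),
    n_params = length(model$params),
    # 17 significant digits: decimal round trip is bit-exact for doubles
    params = sprintf("%.17g", model$params),
    training_log = model$training_log,
    fitted = isTRUE(model$fitted)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dvh_model
#' @export
load_dvh_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("checkpoint '%s' does not exist", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, checkpoint_schema)) {
    abort(sprintf("checkpoint schema mismatch: expected '%s', found '%s'",
                  checkpoint_schema, doc$schema %||% "<none>"))
  }
  cfg <- doc$config
  config <- gru_config(
    hidden_sizes = cfg$hidden_sizes, dv = cfg$dv,
    dose_norm_gy = cfg$dose_norm_gy, learning_rate = cfg$learning_rate,
    epochs = cfg$epochs, batch_size = cfg$batch_size, seed = cfg$seed
  )
  sizes <- as.integer(doc$sizes)
  expected <- cpp_gru_n_params(sizes)
  if (length(doc$params) != expected || doc$n_params != expected) {
    abort(sprintf(
      "checkpoint schema mismatch: %d parameters expected for sizes %s, found %d",
      expected, paste(sizes, collapse = "-"), length(doc$params)
    ))
  }
  structure(
    list(params = as.numeric(doc$params), sizes = sizes, config = config,
         training_log = as.numeric(doc$training_log), fitted = isTRUE(doc$fitted)),
    class = "dvh_model"
  )
}

#' Pair beam sets with plan curves for training
#'
#' Reshapes a [dvh_set()] tibble into one row per patient-organ sample with
#' a `beams` column ([beam_dvh_set()], the 9 beam curves) and a `plan`
#' column (the composite-plan [dvh_curve()]).
#'
#' @param x A [dvh_set()] tibble containing 9 beam rows and one plan row
#'   per patient-structure.
#' @return A tibble with columns `patient_id, structure_id, beams, plan`.
#' @export
collect_samples <- function(x) {
  validate_dvh_set(x)
  grp <- x |>
    dplyr::group_by(.data$patient_id, .data$structure_id) |>
    dplyr::group_split()
  rows <- purrr::map(grp, function(g) {
    b <- g[g$source == "beam", ]
    p <- g[g$source == "plan", ]
    if (nrow(b) != 9L || nrow(p) != 1L) {
      abort(sprintf("%s/%s: expected 9 beam curves and 1 plan curve, found %d/%d",
                    g$patient_id[1], g$structure_id[1], nrow(b), nrow(p)))
    }
    b <- b[order(b$field_index), ]
    tibble::tibble(
      patient_id = g$patient_id[1], structure_id = g$structure_id[1],
      beams = list(beam_dvh_set(g$patient_id[1], g$structure_id[1], b$curve)),
      plan = p$curve
    )
  })
  purrr::list_rbind(rows)
}

#' @export
tidy.dvh_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$training_log), mse = x$training_log)
}

#' @export
glance.dvh_model <- function(x, ...) {
  tibble::tibble(
    n_params = length(x$params),
    layers = paste(x$sizes, collapse = "-"),
    epochs = length(x$training_log),
    final_mse = utils::tail(x$training_log, 1),
    dv = x$config$dv,
    dose_norm_gy = x$config$dose_norm_gy,
    seed = x$config$seed
  )
}

#' Training-loss curve of a fitted model
#' @param object A fitted `dvh_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dvh_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "Training MSE (normalized dose)",
                  title = "DVH model training loss") +
    ggplot2::theme_minimal()
}

#' Plot the nine beam DVHs of one patient-organ
#'
#' @param object A [beam_dvh_set()].
#' @param plan Optional composite-plan or predicted [dvh_curve()] overlay.
#' @param n_edges Dose-grid resolution for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beam_dvh_set <- function(object, plan = NULL, n_edges = 150, ...) {
  dmax <- max(vapply(object$beams, max_dose, numeric(1)),
              if (!is.null(plan)) max_dose(plan) else 0, 1e-9)
  edges <- seq(0, dmax, length.out = n_edges)
  df <- purrr::imap(object$beams, function(b, i) {
    db <- to_dose_binned(b, edges)
    tibble::tibble(series = sprintf("FI %d (%d°)", i, object$gantry_angles[i]),
                   kind = "beam", dose_gy = edges, volume_pct = 100 * db$volume_fractions)
  }) |> purrr::list_rbind()
  if (!is.null(plan)) {
    db <- to_dose_binned(plan, edges)
    df <- dplyr::bind_rows(df, tibble::tibble(
      series = plan$source, kind = "plan",
      dose_gy = edges, volume_pct = 100 * db$volume_fractions
    ))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_gy, y = .data$volume_pct,
                                   colour = .data$series,
                                   linewidth = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::scale_linewidth_manual(values = c(beam = 0.4, plan = 1.1), guide = "none") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = NULL,
                  title = sprintf("%s / %s", object$patient_id, object$structure_id)) +
    ggplot2::theme_minimal()
}
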