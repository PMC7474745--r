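# Train/test protocol and accuracy metrics: a random training subset of the
# angle-torque samples trains the network and the remainder tests it;
# accuracy per world-axis component is summarized by the mean absolute
# torque value (MAV), the mean squared prediction error (MSE) and their
# ratio, the relative error RE = MSE / MAV.

#' Random train/test split of passive-torque samples
#'
#' Uniform sampling without replacement of `n_train` row indices; train and
#' test partition the data.  Seeded and reproducible.
#'
#' @param samples `data.frame` of angle-torque samples.
#' @param n_train training-set size; default 500.
#' @param seed integer seed.
#' @return list `train`, `test` (`data.frame`s) and `train_idx`.
#' @export
split_samples <- function(samples, n_train = 500L, seed = 1L) {
  n <- nrow(samples)
  if (n_train >= n || n_train < 1L) {
    stop("n_train must satisfy 0 < n_train < number of samples",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sort(sample.int(n, n_train))
  list(train = samples[idx, , drop = FALSE],
       test = samples[-idx, , drop = FALSE],
       train_idx = idx)
}

#' Per-component accuracy metrics (MAV, MSE, RE)
#'
#' For each world-axis torque component: `MAV = mean(|y_true|)` (the
#' magnitude scale of that component), `MSE = mean((y_pred - y_true)^2)`,
#' and `RE = MSE / MAV`.  MAV is taken over the true torques, against whose
#' magnitude the prediction error is judged.  When MAV is zero RE is
#' undefined and reported as `NaN` with `re_defined = FALSE`.
#'
#' @param y_true,y_pred numeric n x 3 matrices (N m).
#' @return `data.frame` of class `metric_report` with one row per component
#'   (`x`, `y`, `z`): `mav`, `mse`, `re`, `re_defined`.
#' @export
torque_metrics <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred)) || nrow(y_true) < 1L) {
    stop("y_true and y_pred must be nonempty and of equal shape",
         call. = FALSE)
  }
  mav <- colMeans(abs(y_true))
  mse <- colMeans((y_pred - y_true)^2)
  re <- ifelse(mav > 0, mse / mav, NaN)
  structure(data.frame(component = c("x", "y", "z")[seq_along(mav)],
                       mav = as.numeric(mav), mse = as.numeric(mse),
                       re = as.numeric(re), re_defined = mav > 0),
            class = c("metric_report", "data.frame"))
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Per-component prediction accuracy (world axes):\n")
  df <- data.frame(component = x$component,
                   `MAV [N m]` = round(x$mav, 3),
                   `MSE [N m]` = round(x$mse, 3),
                   RE = round(x$re, 4), check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Run the full estimation-and-prediction pipeline on robot logs
#'
#' Chains every stage: per-run posture recovery (sphere fitted on the former
#' part of the first run, reused for all runs so postures share one centre),
#' quasi-static torque extraction with smoothing and orthosis compensation,
#' the repeatability gate when two runs of the same trajectory are supplied,
#' pooling of all angle-torque samples, the random training split, LM
#' training of the network, and held-out evaluation.
#'
#' @param logs a single robot-log `data.frame` or a list of them (one per
#'   run).  With `repeat_pairs = TRUE`, consecutive logs are treated as
#'   repeated runs of the same trajectory and checked for repeatability.
#' @param calib a `calibration_record`.
#' @param orthosis an `orthosis_params`.
#' @param params a `robot_params`.
#' @param n_hidden hidden units; default 9.
#' @param n_train training-subset size; default 500.
#' @param window moving-average window (odd samples); default 25.
#' @param fit_fraction former-part fraction for sphere fitting; default 0.7.
#' @param repeat_tol repeatability tolerance (fraction of torque range).
#' @param repeat_pairs check consecutive log pairs for repeatability.
#' @param cfg a `training_config`.
#' @param seed seed for the split (training init uses `cfg$seed`).
#' @param out_dir optional directory: writes `postures.csv`, `torques.csv`,
#'   `model.json`, `history.csv`, `metrics.json`.
#' @return list: `metrics` (`metric_report`), `model`, `history`, `samples`
#'   (pooled angle-torque data), `split`, `fit` (`sphere_fit`),
#'   `repeatability` (list, possibly empty).
#' @export
run_pipeline <- function(logs, calib, orthosis = orthosis_params(),
                         params = default_robot_params(), n_hidden = 9L,
                         n_train = 500L, window = 25L, fit_fraction = 0.7,
                         repeat_tol = 0.1, repeat_pairs = FALSE,
                         cfg = training_config(), seed = 1L,
                         out_dir = NULL) {
  if (is.data.frame(logs)) logs <- list(logs)
  message("[kinematics] fitting rotation-center sphere on run 1 (fraction ",
          fit_fraction, ")")
  first <- posture_series(logs[[1]], calib, params, fit_fraction)
  postures <- vector("list", length(logs))
  torques <- vector("list", length(logs))
  postures[[1]] <- first
  for (i in seq_along(logs)) {
    if (i > 1L) {
      postures[[i]] <- posture_series(logs[[i]], calib, params,
                                      fit = first$fit)
    }
    torques[[i]] <- torque_series(logs[[i]], postures[[i]], orthosis, params,
                                  window = window)
  }
  repeatability <- list()
  if (repeat_pairs && length(logs) >= 2L) {
    for (i in seq(1L, length(logs) - 1L, by = 2L)) {
      chk <- repeatability_check(torques[[i]], torques[[i + 1L]],
                                 tol = repeat_tol)
      repeatability[[length(repeatability) + 1L]] <- chk
      if (!chk$pass) {
        stop(sprintf(
          "invalid data: runs %d/%d fail the repeatability check (metric %.3f > tol %.3f)",
          i, i + 1L, chk$metric, chk$tol), call. = FALSE)
      }
    }
    message("[statics] repeatability check passed for ",
            length(repeatability), " run pair(s)")
  }
  samples <- do.call(rbind, torques)
  message("[evaluation] pooled ", nrow(samples), " angle-torque samples")
  sp <- split_samples(samples, n_train = n_train, seed = seed)
  xcols <- c("plane_of_elevation", "elevation")
  ycols <- c("mp_x", "mp_y", "mp_z")
  message("[bpann] training H = ", n_hidden, " network on ", n_train,
          " samples")
  fit <- train_lm(init_mlp(n_hidden, seed = cfg$seed),
                  as.matrix(sp$train[, xcols]), as.matrix(sp$train[, ycols]),
                  cfg)
  y_pred <- predict(fit$model, as.matrix(sp$test[, xcols]))
  metrics <- torque_metrics(as.matrix(sp$test[, ycols]), y_pred)
  message(sprintf("[evaluation] goal %s after %d epochs (final MSE %.2e)",
                  if (fit$history$goal_met) "met" else "NOT met",
                  fit$history$epochs_run, fit$history$final_mse))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pdeg <- samples
    pdeg$plane_of_elevation <- pdeg$plane_of_elevation * 180 / pi
    pdeg$elevation <- pdeg$elevation * 180 / pi
    names(pdeg)[names(pdeg) == "plane_of_elevation"] <- "plane_of_elevation_deg"
    names(pdeg)[names(pdeg) == "elevation"] <- "elevation_deg"
    utils::write.csv(pdeg[, c("t", "plane_of_elevation_deg", "elevation_deg")],
                     file.path(out_dir, "postures.csv"), row.names = FALSE)
    utils::write.csv(pdeg, file.path(out_dir, "torques.csv"),
                     row.names = FALSE)
    write_mlp_json(fit$model, file.path(out_dir, "model.json"))
    utils::write.csv(data.frame(epoch = seq_along(fit$history$mse) - 1L,
                                mse = fit$history$mse),
                     file.path(out_dir, "history.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(mav = metrics$mav, mse = metrics$mse, re = metrics$re),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  list(metrics = metrics, model = fit$model, history = fit$history,
       samples = samples, split = sp, fit = first$fit,
       repeatability = repeatability)
}
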