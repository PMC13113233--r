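# Evaluation suite: accuracy metrics, physical-consistency metrics,
# run-to-run stability, and the noise-robustness sweep.

#' Trajectory accuracy metrics
#'
#' `r2 = 1 - SSres/SStot`, root mean square error, NRMSE as a percentage
#' of the ground-truth range, and the Pearson correlation. A constant
#' ground-truth trajectory leaves r2/pcc undefined; they are returned as
#' `NA` with a warning rather than silently zeroed.
#'
#' @param y Ground-truth trajectory.
#' @param yhat Prediction, same length.
#' @return Named numeric vector `r2`, `rmse`, `nrmse_pct`, `pcc`.
#' @export
accuracy_metrics <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop("trajectory lengths disagree")
  if (length(y) < 2L) stop("need at least 2 samples")
  ssres <- sum((y - yhat)^2)
  sstot <- sum((y - mean(y))^2)
  rmse <- sqrt(mean((y - yhat)^2))
  rng <- max(y) - min(y)
  if (sstot == 0 || rng == 0) {
    warning("constant ground-truth trajectory: r2/pcc/nrmse undefined")
    return(c(r2 = NA_real_, rmse = rmse, nrmse_pct = NA_real_,
             pcc = NA_real_))
  }
  pcc <- if (stats::sd(yhat) == 0) NA_real_ else stats::cor(y, yhat)
  c(r2 = 1 - ssres / sstot, rmse = rmse, nrmse_pct = 100 * rmse / rng,
    pcc = pcc)
}

#' Physical-consistency error and peak error
#'
#' `pce` is the root mean (over interior time steps) of the squared
#' Newton-Euler residual norm `||tau_s - NE(kin; I, G)||`: small values
#' mean the prediction is dynamically consistent with the supplied
#' inertia/gravity parameters. `peak_error` is the largest absolute
#' prediction deviation at the torque extrema of a cycle; extrema are
#' located on the ground-truth sagittal trajectory by default (more stable
#' than prediction-anchored extrema; both conventions are available).
#'
#' @param tau_s Predicted torque (T x 3).
#' @param tau_gt Ground-truth torque (T x 3).
#' @param kin [kinematic_cycle].
#' @param inertia SPD inertia ([spd_from_cholesky] result or matrix).
#' @param g [gravity_model].
#' @param sg [sg_config] for the robust differentiator.
#' @param axis Sagittal axis index (default 3).
#' @param peak_anchor `"ground_truth"` or `"prediction"`.
#' @param prefiltered Set when `kin` already carries filtered kinematics.
#' @return Named vector `pce`, `peak_error`.
#' @export
physical_metrics <- function(tau_s, tau_gt, kin, inertia, g,
                             sg = sg_config(), axis = 3L,
                             peak_anchor = c("ground_truth", "prediction"),
                             prefiltered = FALSE) {
  peak_anchor <- match.arg(peak_anchor)
  tau_s <- as.matrix(tau_s); tau_gt <- as.matrix(tau_gt)
  if (!prefiltered) kin <- filter_kinematics(kin, sg)
  tau_m <- newton_euler_torque(inertia, kin, g)
  idx <- kin$interior
  pce <- sqrt(mean(rowSums((tau_s[idx, , drop = FALSE] -
                              tau_m[idx, , drop = FALSE])^2)))
  ref <- if (peak_anchor == "ground_truth") tau_gt[, axis] else tau_s[, axis]
  ext <- c(which.max(ref), which.min(ref))
  peak <- max(abs(tau_s[ext, axis] - tau_gt[ext, axis]))
  c(pce = pce, peak_error = peak)
}

#' Coefficient of variation across repeated runs
#'
#' `100 * sd / mean` with the population standard deviation; quantifies
#' run-to-run stability of a metric across seeds.
#'
#' @param values Metric values from n >= 2 runs, positive mean.
#' @return CV in percent.
#' @export
stability_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 runs")
  m <- mean(values)
  if (m == 0) stop("zero mean: coefficient of variation undefined")
  100 * sqrt(mean((values - m)^2)) / m
}

#' Evaluate a trained student on a dataset split
#'
#' Per-cycle sagittal-axis accuracy metrics and physical-consistency
#' metrics (using the model's own learned inertia/gravity parameters by
#' default), averaged over cycles.
#'
#' @param state Result of [distill] or a loaded checkpoint.
#' @param ds `gait_dataset`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @param axis Sagittal axis index.
#' @param physics Override physics parameters (e.g. known truth for
#'   synthetic audits): list with `inertia`, `gravity`.
#' @return One-row data.frame of averaged metrics.
#' @export
evaluate_student <- function(state, ds, split = "test", axis = 3L,
                             physics = NULL) {
  cy <- split_cycles(ds, split)
  if (length(cy) == 0L) stop("no cycles in split '", split, "'")
  d <- stack_student_inputs(cy, state$joint)
  pred <- student_forward(state$model, d$x)$tau
  ph <- physics %||% state$physics %||%
    stop("no physics parameters available for PCE")
  kins <- cycle_kinematics(cy, state$joint)
  acc <- matrix(0, length(cy), 4L)
  phys <- matrix(0, length(cy), 2L)
  for (i in seq_along(cy)) {
    ts <- matrix(pred[i, , ], ncol = 3L)
    tg <- matrix(d$tau[i, , ], ncol = 3L)
    acc[i, ] <- accuracy_metrics(tg[, axis], ts[, axis])
    phys[i, ] <- physical_metrics(ts, tg, kins[[i]], ph$inertia, ph$gravity,
                                  axis = axis, prefiltered = TRUE)
  }
  data.frame(joint = state$joint, split = split, n_cycles = length(cy),
             r2 = mean(acc[, 1]), rmse = mean(acc[, 2]),
             nrmse_pct = mean(acc[, 3]), pcc = mean(acc[, 4]),
             pce = mean(phys[, 1]), peak_error = mean(phys[, 2]))
}

#' Noise-robustness sweep
#'
#' Perturbs the held-out inputs with seeded additive Gaussian noise at
#' each level in `sigmas` (relative to the per-channel normalization
#' scale of the model) and recomputes all metrics. The `sigma = 0` row is
#' computed without perturbation and therefore equals the clean
#' evaluation exactly.
#'
#' @param state Trained student state.
#' @param ds `gait_dataset`.
#' @param sigmas Nonnegative noise levels.
#' @param seed Sweep seed.
#' @param split Evaluation split.
#' @param axis Sagittal axis index.
#' @return data.frame, one row per sigma.
#' @export
noise_sweep <- function(state, ds, sigmas = c(0, 0.1, 0.2, 0.5, 1.0),
                        seed = 1L, split = "test", axis = 3L) {
  if (any(sigmas < 0)) stop("noise sigma must be >= 0")
  cy <- split_cycles(ds, split)
  d <- stack_student_inputs(cy, state$joint)
  kins <- cycle_kinematics(cy, state$joint)
  ph <- state$physics
  rows <- list()
  for (si in seq_along(sigmas)) {
    s <- sigmas[si]
    x <- d$x
    if (s > 0) {
      set.seed(as.integer((seed + 7919 * si) %% 2147483647))
      for (ci in seq_len(dim(x)[2])) {
        x[, ci, ] <- x[, ci, ] +
          stats::rnorm(length(x[, ci, ]), 0, s * state$model$norm$sd[ci])
      }
    }
    pred <- student_forward(state$model, x)$tau
    acc <- matrix(0, length(cy), 4L); phys <- matrix(0, length(cy), 2L)
    for (i in seq_along(cy)) {
      ts <- matrix(pred[i, , ], ncol = 3L)
      tg <- matrix(d$tau[i, , ], ncol = 3L)
      acc[i, ] <- accuracy_metrics(tg[, axis], ts[, axis])
      phys[i, ] <- physical_metrics(ts, tg, kins[[i]], ph$inertia, ph$gravity,
                                    axis = axis, prefiltered = TRUE)
    }
    rows[[si]] <- data.frame(sigma = s, r2 = mean(acc[, 1]),
                             rmse = mean(acc[, 2]),
                             nrmse_pct = mean(acc[, 3]), pcc = mean(acc[, 4]),
                             pce = mean(phys[, 1]),
                             peak_error = mean(phys[, 2]))
  }
  do.call(rbind, rows)
}

#' Run the ablation ladder
#'
#' Distills one student per preset (M0 supervised, M1 vanilla KD, M2
#' geometry-aware KD, M3 full framework with physics) at a shared seed and
#' reports the evaluation metrics per preset.
#'
#' @param tstate Frozen teacher state.
#' @param ds `gait_dataset`.
#' @param presets Character vector of preset ids.
#' @param cfg [train_config].
#' @param scfg [student_config].
#' @param joint Joint to train.
#' @param split Evaluation split.
#' @return data.frame, one row per preset (metrics x presets).
#' @export
ablation_run <- function(tstate, ds, presets = c("M0", "M1", "M2", "M3"),
                         cfg = train_config(), scfg = student_config(),
                         joint = "hip", split = "test") {
  caches <- NULL
  rows <- lapply(presets, function(pid) {
    w <- ablation_weights(pid)
    if ((w$beta > 0 || w$delta > 0) && is.null(caches)) {
      caches <<- build_teacher_caches(tstate, ds)
    }
    st <- distill(tstate, ds, scfg, cfg, w, joint = joint, caches = caches)
    cbind(data.frame(preset = pid), evaluate_student(st, ds, split = split))
  })
  do.call(rbind, rows)
}
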