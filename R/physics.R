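#' Savitzky-Golay configuration
#'
#' @param window Odd window length >= 5.
#' @param polyorder Polynomial order, `2 <= polyorder < window`.
#' @param deriv_order 0 (smoothing) or 1 (smoothed first derivative).
#' @return List of class `sg_config`.
#' @export
sg_config <- function(window = 11L, polyorder = 3L, deriv_order = 0L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window < 5L || window %% 2L == 0L) {
    stop("SG window must be an odd integer >= 5, got ", window)
  }
  if (polyorder < 2L || polyorder >= window) {
    stop("SG polyorder must satisfy 2 <= polyorder < window")
  }
  if (!deriv_order %in% c(0L, 1L)) stop("deriv_order must be 0 or 1")
  structure(list(window = window, polyorder = polyorder,
                 deriv_order = as.integer(deriv_order)),
            class = "sg_config")
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Applies a local least-squares polynomial filter column-wise to a
#' trajectory. With `deriv_order = 1` the result is the smoothed first
#' derivative scaled by `1/dt`; the filter is exact for polynomials up to
#' `polyorder` at interior points (edges use the one-sided fit rows).
#'
#' @param x Numeric vector or (T x C) matrix.
#' @param cfg An [sg_config].
#' @param dt Sample interval in seconds.
#' @return Same shape as `x`.
#' @export
sg_smooth_derivative <- function(x, cfg = sg_config(), dt = 0.01) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  if (nrow(xm) < cfg$window) {
    stop(sprintf(
      "trajectory length %d is shorter than the SG window %d; need T >= %d",
      nrow(xm), cfg$window, cfg$window))
  }
  out <- apply(xm, 2L, function(col) {
    signal::sgolayfilt(col, p = cfg$polyorder, n = cfg$window,
                       m = cfg$deriv_order, ts = dt)
  })
  out <- matrix(out, nrow = nrow(xm))
  if (is.matrix(x)) out else drop(out)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_grad <- function(x) 1 / (1 + exp(-x))

CHOL_EPS <- 1e-6

#' SPD equivalent inertia from unconstrained parameters
#'
#' Maps 6 unconstrained reals to a lower-triangular factor L (diagonal
#' passed through softplus + eps, strictly positive) and the symmetric
#' positive-definite equivalent inertia tensor `I_eff = L L'`. Every finite
#' parameter value yields a valid SPD tensor, so optimization can run
#' unconstrained. Units are mass-normalized (kg m^2 / kg), matching torque
#' labels in N m / kg. The tensor absorbs the unknown sensor-to-segment
#' rotation; it is an engineering surrogate, not a physiological inertia.
#'
#' @param raw Numeric vector of length 6: diagonal parameters (3) then
#'   below-diagonal entries (l21, l31, l32).
#' @return Object of class `inertia_cholesky` with fields `raw`, `factor`,
#'   `I_eff`.
#' @export
spd_from_cholesky <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) != 6L || any(!is.finite(raw))) {
    stop("inertia parameterization needs 6 finite values")
  }
  L <- matrix(0, 3, 3)
  diag(L) <- softplus(raw[1:3]) + CHOL_EPS
  L[2, 1] <- raw[4]; L[3, 1] <- raw[5]; L[3, 2] <- raw[6]
  ie <- tcrossprod(L)
  structure(list(raw = raw, factor = L, I_eff = (ie + t(ie)) / 2),
            class = "inertia_cholesky")
}

#' @export
print.inertia_cholesky <- function(x, ...) {
  cat("<inertia_cholesky> I_eff (kg m^2/kg):\n")
  print(round(x$I_eff, 5))
  cat("eigenvalues:", format(eigen(x$I_eff, symmetric = TRUE,
                                   only.values = TRUE)$values, digits = 4), "\n")
  invisible(x)
}

#' Raw parameters reproducing a given SPD tensor
#'
#' Inverse of [spd_from_cholesky] (softplus inverted on the diagonal);
#' handy for seeding the simulator and identifiability probes.
#' @param I_mat SPD 3x3 matrix.
#' @return Length-6 raw vector.
#' @export
cholesky_raw_from_spd <- function(I_mat) {
  L <- t(chol(I_mat))
  d <- pmax(diag(L) - CHOL_EPS, 1e-12)
  inv_sp <- function(y) ifelse(y > 30, y, log(expm1(y)))
  c(inv_sp(d), L[2, 1], L[3, 1], L[3, 2])
}

#' Pendulum-style gravity model
#'
#' The gravity compensation torque is modeled per axis as
#' `G(theta) = a_sin * sin(theta) + a_cos * cos(theta)` with learnable
#' 3-vector coefficients: linear in its parameters and shaped like a
#' gravitational moment on a rotating segment. Disabled models return zero.
#'
#' @param a_sin,a_cos Numeric 3-vectors.
#' @param enabled Logical flag.
#' @return Object of class `gravity_model`.
#' @export
gravity_model <- function(a_sin = c(0, 0, 0), a_cos = c(0, 0, 0),
                          enabled = TRUE) {
  stopifnot(length(a_sin) == 3L, length(a_cos) == 3L)
  structure(list(a_sin = as.numeric(a_sin), a_cos = as.numeric(a_cos),
                 enabled = isTRUE(enabled)),
            class = "gravity_model")
}

#' Gravity torque trajectory
#' @param theta Joint-angle trajectory (radians, length T).
#' @param g A [gravity_model].
#' @return (T x 3) matrix.
#' @export
gravity_torque <- function(theta, g) {
  theta <- as.numeric(theta)
  if (any(!is.finite(theta))) stop("theta contains non-finite values")
  if (!g$enabled) return(matrix(0, length(theta), 3L))
  outer(sin(theta), g$a_sin) + outer(cos(theta), g$a_cos)
}

#' Per-cycle kinematics container
#'
#' @param theta Joint angle (radians), length T.
#' @param omega Angular velocity (rad/s), (T x 3).
#' @param omega_dot Angular acceleration (rad/s^2), (T x 3).
#' @param dt Sample interval (s).
#' @param omega_filt,omega_dot_filt Optional filtered counterparts.
#' @return Object of class `kinematic_cycle`.
#' @export
kinematic_cycle <- function(theta, omega, omega_dot, dt,
                            omega_filt = NULL, omega_dot_filt = NULL) {
  omega <- as.matrix(omega); omega_dot <- as.matrix(omega_dot)
  stopifnot(ncol(omega) == 3L, ncol(omega_dot) == 3L,
            nrow(omega) == length(theta), nrow(omega_dot) == length(theta))
  if (!all(is.finite(theta), is.finite(omega), is.finite(omega_dot))) {
    stop("kinematic trajectories contain non-finite values")
  }
  structure(list(theta = as.numeric(theta), omega = omega,
                 omega_dot = omega_dot, dt = dt,
                 omega_filt = omega_filt, omega_dot_filt = omega_dot_filt),
            class = "kinematic_cycle")
}

#' Forward Newton-Euler torque
#'
#' Rigid-body torque `tau(t) = I w_dot(t) + w(t) x (I w(t)) + G(theta(t))`
#' evaluated along a cycle. Filtered kinematics are used when present on
#' the cycle.
#'
#' @param inertia An [spd_from_cholesky] result (or plain SPD 3x3 matrix).
#' @param kin A [kinematic_cycle].
#' @param g A [gravity_model].
#' @return (T x 3) torque trajectory, N m / kg.
#' @export
newton_euler_torque <- function(inertia, kin, g = gravity_model(enabled = FALSE)) {
  I_eff <- if (is.list(inertia) && !is.null(inertia$I_eff)) inertia$I_eff else as.matrix(inertia)
  w <- if (!is.null(kin$omega_filt)) kin$omega_filt else kin$omega
  wd <- if (!is.null(kin$omega_dot_filt)) kin$omega_dot_filt else kin$omega_dot
  if (!identical(dim(w), dim(wd))) {
    stop("omega and omega_dot shapes disagree: ",
         paste(dim(w), collapse = "x"), " vs ", paste(dim(wd), collapse = "x"))
  }
  iw <- w %*% I_eff     # row t is (I w_t)' since I symmetric
  iwd <- wd %*% I_eff
  gyro <- cross_rows(w, iw)
  iwd + gyro + gravity_torque(kin$theta, g)
}

# row-wise cross product of (T x 3) matrices
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# SG-filter a cycle's angular velocity and differentiate it; returns the
# cycle with omega_filt/omega_dot_filt set and the interior index mask.
filter_kinematics <- function(kin, sg = sg_config()) {
  half <- (sg$window - 1L) %/% 2L
  Tn <- nrow(kin$omega)
  if (Tn < sg$window) {
    stop(sprintf("cycle length %d shorter than SG window %d", Tn, sg$window))
  }
  cfg0 <- sg_config(sg$window, sg$polyorder, 0L)
  cfg1 <- sg_config(sg$window, sg$polyorder, 1L)
  kin$omega_filt <- sg_smooth_derivative(kin$omega, cfg0, kin$dt)
  kin$omega_dot_filt <- sg_smooth_derivative(kin$omega, cfg1, kin$dt)
  kin$interior <- (half + 1L):(Tn - half)
  kin
}

#' Newton-Euler physics-consistency loss
#'
#' Measures how far a predicted torque trajectory is from the rigid-body
#' torque implied by the cycle's own kinematics: angular velocity is
#' SG-smoothed, its derivative taken by the SG differentiator, and the
#' mean squared residual norm is computed over interior samples (edge
#' samples within half a window are excluded, avoiding edge-artifact
#' gradients).
#'
#' @param tau_s Predicted torque, (T x 3).
#' @param kin_raw A [kinematic_cycle] with raw (unfiltered) omega.
#' @param inertia [spd_from_cholesky] result.
#' @param g [gravity_model].
#' @param sg [sg_config] (smoothing config; derivative order handled
#'   internally).
#' @return Nonnegative scalar.
#' @export
physics_loss <- function(tau_s, kin_raw, inertia, g = gravity_model(enabled = FALSE),
                         sg = sg_config()) {
  tau_s <- as.matrix(tau_s)
  kin <- filter_kinematics(kin_raw, sg)
  if (nrow(tau_s) != nrow(kin$omega)) {
    stop("torque and kinematic lengths disagree")
  }
  tau_m <- newton_euler_torque(inertia, kin, g)
  idx <- kin$interior
  mean(rowSums((tau_s[idx, , drop = FALSE] - tau_m[idx, , drop = FALSE])^2))
}

# Residual and analytic gradient of the physics loss wrt the 6 raw inertia
# parameters (and gravity coefficients). Kinematics must be pre-filtered.
physics_residual_grad <- function(tau_s, kin, raw, g, param = "cholesky") {
  ic <- if (param == "naive") naive_inertia(raw) else spd_from_cholesky(raw)
  tau_m <- newton_euler_torque(ic, kin, g)
  idx <- kin$interior
  r <- tau_s[idx, , drop = FALSE] - tau_m[idx, , drop = FALSE]
  n <- length(idx)
  w <- kin$omega_filt[idx, , drop = FALSE]
  wd <- kin$omega_dot_filt[idx, , drop = FALSE]
  # dLoss/dI_ab = sum_t -2/n * r_t . (wd_b e_a + w_t x (e_a w_b))
  gI <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    ea <- numeric(3); ea[a] <- 1
    term <- outer(wd[, b], ea) + cross_rows(w, outer(w[, b], ea))
    gI[a, b] <- -2 / n * sum(r * term)
  }
  if (param == "naive") {
    graw <- naive_raw_grad(gI)
  } else {
    # chain through I = L L': dI/dL gives gL = (gI + gI') L
    gL <- (gI + t(gI)) %*% ic$factor
    graw <- c(diag(gL)[1:3] * softplus_grad(raw[1:3]),
              gL[2, 1], gL[3, 1], gL[3, 2])
  }
  gg <- NULL
  if (g$enabled) {
    s <- sin(kin$theta[idx]); cth <- cos(kin$theta[idx])
    gg <- list(a_sin = -2 / n * colSums(r * s),
               a_cos = -2 / n * colSums(r * cth))
  }
  loss <- mean(rowSums(r^2))
  # gradient of loss wrt tau_s on interior rows (for network training)
  gtau <- matrix(0, nrow(tau_s), 3L)
  gtau[idx, ] <- 2 / n * r
  list(loss = loss, graw = graw, ggrav = gg, gtau = gtau)
}

#' Fit the equivalent inertia tensor to observed torque cycles
#'
#' Gradient-based minimization (BFGS with analytic gradients) of the mean
#' physics loss over a set of cycles with respect to the unconstrained
#' Cholesky parameters, and the gravity coefficients when the model is
#' enabled. The SPD parameterization keeps every iterate physically valid.
#' Full identifiability needs persistently exciting 3D rotation; with
#' single-axis excitation the out-of-axis entries are unidentifiable (the
#' loss is flat along those directions).
#'
#' @param cycles List of `list(kin = <kinematic_cycle>, tau = <T x 3 matrix>)`.
#' @param g [gravity_model]; its coefficients are optimized when enabled.
#' @param sg [sg_config] for robust differentiation.
#' @param raw_init Optional starting raw parameters (default: 0.05 * identity
#'   factor).
#' @param maxit BFGS iteration budget.
#' @return List with `inertia` ([spd_from_cholesky] result), `gravity`,
#'   `loss` (final mean physics loss), `convergence`.
#' @export
fit_inertia <- function(cycles, g = gravity_model(enabled = FALSE),
                        sg = sg_config(), raw_init = NULL, maxit = 200L) {
  if (length(cycles) < 1L) stop("need at least one cycle")
  kins <- lapply(cycles, function(cy) filter_kinematics(cy$kin, sg))
  taus <- lapply(cycles, function(cy) as.matrix(cy$tau))
  n_g <- if (g$enabled) 6L else 0L
  if (is.null(raw_init)) {
    raw_init <- cholesky_raw_from_spd(diag(0.05, 3))
  }
  par0 <- c(raw_init, if (g$enabled) c(g$a_sin, g$a_cos))
  unpack <- function(par) {
    gm <- g
    if (g$enabled) {
      gm$a_sin <- par[7:9]; gm$a_cos <- par[10:12]
    }
    list(raw = par[1:6], g = gm)
  }
  fn <- function(par) {
    p <- unpack(par)
    val <- mean(vapply(seq_along(kins), function(i) {
      physics_residual_grad(taus[[i]], kins[[i]], p$raw, p$g)$loss
    }, numeric(1)))
    if (!is.finite(val)) stop("physics loss diverged (non-finite) during fit")
    val
  }
  gr <- function(par) {
    p <- unpack(par)
    acc <- numeric(length(par))
    for (i in seq_along(kins)) {
      res <- physics_residual_grad(taus[[i]], kins[[i]], p$raw, p$g)
      acc[1:6] <- acc[1:6] + res$graw
      if (n_g > 0) acc[7:12] <- acc[7:12] + c(res$ggrav$a_sin, res$ggrav$a_cos)
    }
    acc / length(kins)
  }
  fit <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  p <- unpack(fit$par)
  list(inertia = spd_from_cholesky(p$raw), gravity = p$g,
       loss = fit$value, convergence = fit$convergence)
}

#' Unconstrained ("naive") symmetric inertia parameterization
#'
#' Ablation variant of the physics pathway: the six raw parameters are
#' placed directly into a symmetric 3x3 matrix (diagonal then
#' below-diagonal) with no positive-definiteness guarantee. Same interface
#' as [spd_from_cholesky] so the training loop can swap formulations.
#'
#' @param raw Numeric vector of length 6.
#' @return Object of classes `inertia_naive`, `inertia_cholesky`-compatible
#'   (fields `raw`, `I_eff`).
#' @export
naive_inertia <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) != 6L || any(!is.finite(raw))) {
    stop("inertia parameterization needs 6 finite values")
  }
  I_mat <- matrix(0, 3, 3)
  diag(I_mat) <- raw[1:3]
  I_mat[2, 1] <- I_mat[1, 2] <- raw[4]
  I_mat[3, 1] <- I_mat[1, 3] <- raw[5]
  I_mat[3, 2] <- I_mat[2, 3] <- raw[6]
  structure(list(raw = raw, I_eff = I_mat), class = "inertia_naive")
}

# gradient chain for the naive parameterization: dLoss/draw from dLoss/dI
naive_raw_grad <- function(gI) {
  gs <- gI + t(gI)
  c(diag(gI), gs[2, 1], gs[3, 1], gs[3, 2])
}

#' Text report of a fitted inertia tensor
#'
#' @param inertia [spd_from_cholesky] result.
#' @param path Optional path; when given, the JSON report is written there.
#' @return JSON string (invisibly when written to file).
#' @export
inertia_report <- function(inertia, path = NULL) {
  rep <- list(
    I_eff = unname(apply(inertia$I_eff, 1L, as.numeric, simplify = FALSE)),
    eigenvalues = as.numeric(eigen(inertia$I_eff, symmetric = TRUE,
                                   only.values = TRUE)$values),
    raw = inertia$raw)
  js <- jsonlite::toJSON(rep, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
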