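test_that("SG filter validates its configuration and input length", {
  expect_error(sg_config(window = 10), "odd")
  expect_error(sg_config(window = 3), "odd")
  expect_error(sg_config(polyorder = 11, window = 11), "polyorder")
  expect_error(sg_smooth_derivative(rnorm(8), sg_config(window = 11)),
               "T >= 11")
})

test_that("SG differentiator is exact on polynomials at interior points", {
  dt <- 0.01
  t <- (0:100) * dt
  cfg1 <- sg_config(window = 11L, polyorder = 3L, deriv_order = 1L)
  interior <- 6:96
  # constant -> zero derivative
  expect_equal(sg_smooth_derivative(rep(2.5, 101), cfg1, dt)[interior],
               rep(0, length(interior)), tolerance = 1e-12)
  # linear ramp x = 2 t -> slope 2 everywhere inside
  expect_equal(sg_smooth_derivative(2 * t, cfg1, dt)[interior],
               rep(2, length(interior)), tolerance = 1e-9)
  # cubic polynomial matches the analytic derivative to 1e-8
  x <- 1.2 * t^3 - 0.7 * t^2 + 0.3 * t - 4
  dx <- 3.6 * t^2 - 1.4 * t + 0.3
  expect_equal(sg_smooth_derivative(x, cfg1, dt)[interior], dx[interior],
               tolerance = 1e-8)
  # smoothing mode reproduces the cubic itself
  cfg0 <- sg_config(11L, 3L, 0L)
  expect_equal(sg_smooth_derivative(x, cfg0, dt)[interior], x[interior],
               tolerance = 1e-10)
})

test_that("SG operator is linear", {
  set.seed(8)
  cfg <- sg_config(11L, 3L, 1L)
  a <- rnorm(60); b <- rnorm(60)
  expect_equal(sg_smooth_derivative(2 * a + 3 * b, cfg, 0.01),
               2 * sg_smooth_derivative(a, cfg, 0.01) +
                 3 * sg_smooth_derivative(b, cfg, 0.01),
               tolerance = 1e-10)
})

test_that("Cholesky parameterization always yields an SPD inertia tensor", {
  ic <- spd_from_cholesky(c(10, 10, 10, 0, 0, 0))  # softplus(10) ~ 10
  expect_equal(ic$I_eff, ic$factor %*% t(ic$factor), tolerance = 1e-12)
  # diagonal factor squares onto the diagonal
  raw <- cholesky_raw_from_spd(diag(c(4, 9, 16)))
  expect_equal(spd_from_cholesky(raw)$I_eff, diag(c(4, 9, 16)),
               tolerance = 1e-8)
  set.seed(9)
  for (i in 1:1000) {
    ic <- spd_from_cholesky(rnorm(6, 0, 5))
    # eigenvalues of L L' are the squared singular values of L: computing
    # them through the factor avoids the roundoff a dense eigensolver
    # incurs on badly scaled products
    ev <- svd(ic$factor, nu = 0, nv = 0)$d^2
    expect_gt(min(ev), 0)
  }
  expect_error(spd_from_cholesky(c(1, 2, Inf, 0, 0, 0)), "finite")
})

test_that("naive inertia parameterization is unconstrained and symmetric", {
  ni <- naive_inertia(c(1, -2, 3, 0.5, 0, -1))
  expect_equal(ni$I_eff, t(ni$I_eff))
  expect_equal(diag(ni$I_eff), c(1, -2, 3))
  ev <- eigen(ni$I_eff, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev), 0)  # no SPD guarantee, by design
})

test_that("forward Newton-Euler matches hand-computed cases", {
  Tn <- 20
  quiet <- kinematic_cycle(rep(0, Tn), matrix(0, Tn, 3), matrix(0, Tn, 3),
                           dt = 0.01)
  off <- gravity_model(enabled = FALSE)
  expect_equal(newton_euler_torque(diag(3), quiet, off), matrix(0, Tn, 3))
  # isotropic inertia: gyroscopic term vanishes, tau = c * omega_dot
  set.seed(10)
  om <- matrix(rnorm(Tn * 3), Tn, 3); omd <- matrix(rnorm(Tn * 3), Tn, 3)
  kin <- kinematic_cycle(rnorm(Tn), om, omd, dt = 0.01)
  expect_equal(newton_euler_torque(2.5 * diag(3), kin, off), 2.5 * omd,
               tolerance = 1e-12)
  # anisotropic hand case: (1,1,1) x (1,2,3) = (1, -2, 1)
  kin1 <- kinematic_cycle(0, matrix(c(1, 1, 1), 1), matrix(0, 1, 3), 0.01)
  expect_equal(drop(newton_euler_torque(diag(c(1, 2, 3)), kin1, off)),
               c(1, -2, 1))
})

test_that("gravity torque follows the sin/cos model and disables cleanly", {
  th <- c(0, pi / 2, 0.3)
  expect_equal(gravity_torque(th, gravity_model(enabled = FALSE)),
               matrix(0, 3, 3))
  g1 <- gravity_model(a_sin = c(2, 1, 3), a_cos = c(0, 0, 0))
  expect_equal(gravity_torque(pi / 2, g1), matrix(c(2, 1, 3), 1))
  g2 <- gravity_model(a_sin = c(1, 0, 2), a_cos = c(0, 1, 0))
  expect_equal(drop(gravity_torque(0.3, g2)),
               c(sin(0.3), cos(0.3), 2 * sin(0.3)))
})

test_that("physics loss is zero for self-consistent torques and scales quadratically", {
  # polynomial kinematics: SG is exact, so forward-inverse closes to ~0
  dt <- 0.01; t <- (0:80) * dt
  om <- cbind(2 * t^2 - t, 0.5 * t^3, t)
  omd <- cbind(4 * t - 1, 1.5 * t^2, rep(1, length(t)))
  kin <- kinematic_cycle(0.2 * t, om, omd, dt)
  ic <- spd_from_cholesky(cholesky_raw_from_spd(diag(c(0.12, 0.1, 0.05))))
  g <- gravity_model(c(0.1, 0, 0.4), c(0, 0.2, 0))
  kinf <- gaitkd:::filter_kinematics(kin)
  tau <- newton_euler_torque(ic, kinf, g)
  expect_lt(physics_loss(tau, kin, ic, g), 1e-6)
  # quiescent zero torque
  quiet <- kinematic_cycle(rep(0, 60), matrix(0, 60, 3), matrix(0, 60, 3), dt)
  expect_equal(physics_loss(matrix(0, 60, 3), quiet, ic,
                            gravity_model(enabled = FALSE)), 0)
  # squared-norm homogeneity: doubling the residual quadruples the loss
  tau1 <- matrix(rnorm(180), 60, 3)
  l1 <- physics_loss(tau1, quiet, spd_from_cholesky(rep(-20, 6)),
                     gravity_model(enabled = FALSE))
  l2 <- physics_loss(2 * tau1, quiet, spd_from_cholesky(rep(-20, 6)),
                     gravity_model(enabled = FALSE))
  expect_equal(l2 / l1, 4, tolerance = 1e-6)
})

test_that("physics loss gradient passes a finite-difference check", {
  cfg <- tiny_sim_config()
  kin <- generate_kinematics(cfg, 1, 1, "hip")
  tau <- ground_truth_torque(kin, cfg)
  kinf <- gaitkd:::filter_kinematics(kin)
  set.seed(11)
  raw <- rnorm(6, 0, 0.4)
  g <- gravity_model(c(0.1, 0.2, 0.3), c(0.05, 0, 0.2))
  res <- gaitkd:::physics_residual_grad(tau, kinf, raw, g)
  for (i in 1:6) {
    h <- 1e-6
    rp <- raw; rp[i] <- rp[i] + h
    rm <- raw; rm[i] <- rm[i] - h
    fd <- (gaitkd:::physics_residual_grad(tau, kinf, rp, g)$loss -
             gaitkd:::physics_residual_grad(tau, kinf, rm, g)$loss) / (2 * h)
    expect_equal(res$graw[i], fd, tolerance = 1e-4)
  }
})

test_that("fit_inertia recovers the generating tensor from clean cycles", {
  cfg <- tiny_sim_config(seed = 13)
  cycles <- lapply(1:8, function(i) {
    k <- generate_kinematics(cfg, 1, i, "hip")
    list(kin = k, tau = ground_truth_torque(k, cfg))
  })
  g <- gravity_model(cfg$gravity_coeffs$a_sin, cfg$gravity_coeffs$a_cos)
  fit <- fit_inertia(cycles, g = g)
  rel <- norm(fit$inertia$I_eff - cfg$true_inertia, "F") /
    norm(cfg$true_inertia, "F")
  expect_lt(rel, 0.01)
  expect_lt(fit$loss, 1e-10)
  expect_error(fit_inertia(list()), "at least one")
})

test_that("single-axis excitation leaves out-of-axis inertia unidentifiable", {
  # omega = (0, 0, w): the residual only senses I[3,3] (and gravity), so the
  # loss must be flat along the out-of-axis raw directions
  dt <- 0.011; t <- (0:100) * dt
  w <- 2 * sin(2 * pi * t / 1.1)
  om <- cbind(0, 0, w)
  omd <- cbind(0, 0, 2 * 2 * pi / 1.1 * cos(2 * pi * t / 1.1))
  kin <- kinematic_cycle(w, om, omd, dt)
  kinf <- gaitkd:::filter_kinematics(kin)
  truthI <- diag(c(0.12, 0.1, 0.05))
  tau <- newton_euler_torque(truthI, kinf, gravity_model(enabled = FALSE))
  base <- cholesky_raw_from_spd(truthI)
  g0 <- gravity_model(enabled = FALSE)
  l0 <- gaitkd:::physics_residual_grad(tau, kinf, base, g0)$loss
  for (i in c(1, 2)) {  # raw diag entries for the unexcited x, y axes
    pert <- base; pert[i] <- pert[i] + 0.5
    li <- gaitkd:::physics_residual_grad(tau, kinf, pert, g0)$loss
    expect_equal(li, l0, tolerance = 1e-10)
  }
  # the excited axis IS identifiable
  pert <- base; pert[3] <- pert[3] + 0.5
  expect_gt(gaitkd:::physics_residual_grad(tau, kinf, pert, g0)$loss, l0 + 1e-4)
})

test_that("inertia report serializes the tensor and its spectrum", {
  ic <- spd_from_cholesky(cholesky_raw_from_spd(diag(c(1, 2, 3))))
  tf <- tempfile(fileext = ".json")
  inertia_report(ic, tf)
  rep <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(sort(rep$eigenvalues), c(1, 2, 3), tolerance = 1e-8)
})
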