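# Synthetic rigid-body gait simulator. Emulates the structure of open
# lower-limb biomechanics corpora: periodic per-joint kinematics, 6-axis IMU
# per segment, hip/knee/ankle torque labels in N m/kg, cycles normalized to
# 101 time steps, 7:2:1 cycle-level splits, all randomness from one seed.

GAIT_JOINTS <- c("hip", "knee", "ankle")
GRAVITY_MS2 <- 9.81

#' Noise configuration for the simulator
#'
#' @param sigma Additive Gaussian noise scale, relative to the per-channel
#'   standard deviation of the clean signal.
#' @param gyro_bias Constant gyroscope bias, rad/s.
#' @return List of class `noise_config`.
#' @export
noise_config <- function(sigma = 0, gyro_bias = 0) {
  if (sigma < 0) stop("noise sigma must be >= 0")
  structure(list(sigma = sigma, gyro_bias = gyro_bias),
            class = "noise_config")
}

#' Simulator configuration
#'
#' Defaults describe a plausible shank-scale rigid body walking at a
#' typical cadence: 1.1 s cycles sampled at 100 Hz, fourth-order Fourier
#' kinematics, mass-normalized inertia diag(0.12, 0.10, 0.05) with 0.01
#' off-diagonals, and a pendulum gravity term concentrated on the sagittal
#' axis.
#'
#' @param n_subjects,n_cycles_per_subject Cohort size.
#' @param cycle_duration Seconds per gait cycle.
#' @param sample_rate Native sampling rate, Hz.
#' @param fourier_order Harmonics in the angle trajectories.
#' @param excitation `"full_3d"` (all axes carry power; inertia fully
#'   identifiable) or `"sagittal_dominant"`.
#' @param noise A [noise_config].
#' @param true_inertia SPD 3x3 generating inertia (kg m^2/kg).
#' @param gravity_coeffs List with `a_sin`, `a_cos` 3-vectors.
#' @param seed Integer master seed.
#' @return List of class `gait_sim_config`.
#' @export
gait_sim_config <- function(n_subjects = 2L, n_cycles_per_subject = 30L,
                            cycle_duration = 1.1, sample_rate = 100,
                            fourier_order = 4L,
                            excitation = c("full_3d", "sagittal_dominant"),
                            noise = noise_config(),
                            true_inertia = NULL, gravity_coeffs = NULL,
                            seed = 1L) {
  excitation <- match.arg(excitation)
  if (is.null(true_inertia)) {
    true_inertia <- matrix(0.01, 3, 3)
    diag(true_inertia) <- c(0.12, 0.10, 0.05)
  }
  ev <- eigen(true_inertia, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("true_inertia must be symmetric positive definite")
  if (sample_rate * cycle_duration < 32) {
    stop("sample_rate * cycle_duration must be >= 32")
  }
  if (is.null(gravity_coeffs)) {
    gravity_coeffs <- list(a_sin = c(0.15, 0.10, 0.80),
                           a_cos = c(0.05, 0.05, 0.20))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_cycles_per_subject = as.integer(n_cycles_per_subject),
                 cycle_duration = cycle_duration, sample_rate = sample_rate,
                 fourier_order = as.integer(fourier_order),
                 excitation = excitation, noise = noise,
                 true_inertia = true_inertia, gravity_coeffs = gravity_coeffs,
                 seed = as.integer(seed)),
            class = "gait_sim_config")
}

# deterministic sub-seed below 2^31, derived from the master seed
sim_subseed <- function(seed, subject, cycle, joint_ix, salt = 0L) {
  v <- (as.double(seed) %% 65011) * 33013 +
    subject * 7907 + cycle * 641 + joint_ix * 97 + salt * 13
  as.integer(v %% 2147483647)
}

# subject-level Fourier coefficients per axis: sagittal axis (3) dominant,
# off-sagittal amplitudes set by the excitation mode
sim_fourier_coeffs <- function(cfg, subject, cycle, joint_ix) {
  K <- cfg$fourier_order
  amp_axis <- if (cfg$excitation == "full_3d") c(0.18, 0.15, 0.35)
              else c(0.02, 0.02, 0.35)
  set.seed(sim_subseed(cfg$seed, subject, 0L, joint_ix, salt = 1L))
  base <- lapply(1:3, function(ax) {
    sc <- amp_axis[ax] / (1:K)^1.5
    list(a = stats::rnorm(K, 0, sc), b = stats::rnorm(K, 0, sc),
         c0 = stats::rnorm(1, 0, 0.1))
  })
  # small per-cycle stride-to-stride variation
  set.seed(sim_subseed(cfg$seed, subject, cycle, joint_ix, salt = 2L))
  lapply(base, function(cf) {
    jit <- 1 + stats::rnorm(length(cf$a), 0, 0.03)
    list(a = cf$a * jit, b = cf$b * (2 - jit), c0 = cf$c0)
  })
}

#' Generate one cycle of analytic gait kinematics
#'
#' Per-axis joint angles are truncated Fourier series with seeded
#' subject-specific coefficients (plus small per-cycle jitter); angular
#' velocity and acceleration are the exact analytic derivatives, never
#' numerical ones. The scalar joint angle `theta` is the sagittal-axis
#' trajectory.
#'
#' @param cfg A [gait_sim_config].
#' @param subject,cycle Integer indices.
#' @param joint One of `"hip"`, `"knee"`, `"ankle"`.
#' @param n_points Time steps on the cycle grid (101 by convention).
#' @return A [kinematic_cycle]; the (T x 3) per-axis angles are attached as
#'   attribute `"angles"`.
#' @export
generate_kinematics <- function(cfg, subject = 1L, cycle = 1L,
                                joint = "hip", n_points = 101L) {
  j <- match(joint, GAIT_JOINTS)
  if (is.na(j)) stop("unknown joint: ", joint)
  cf <- sim_fourier_coeffs(cfg, subject, cycle, j)
  Tc <- cfg$cycle_duration
  t <- seq(0, Tc, length.out = n_points)
  w0 <- 2 * pi / Tc
  ang <- matrix(0, n_points, 3)
  om <- matrix(0, n_points, 3)
  omd <- matrix(0, n_points, 3)
  for (ax in 1:3) {
    a <- cf[[ax]]$a; b <- cf[[ax]]$b
    th <- rep(cf[[ax]]$c0, n_points)
    v <- numeric(n_points); acc <- numeric(n_points)
    for (k in seq_along(a)) {
      wk <- k * w0
      th <- th + a[k] * sin(wk * t) + b[k] * cos(wk * t)
      v <- v + wk * (a[k] * cos(wk * t) - b[k] * sin(wk * t))
      acc <- acc - wk^2 * (a[k] * sin(wk * t) + b[k] * cos(wk * t))
    }
    ang[, ax] <- th; om[, ax] <- v; omd[, ax] <- acc
  }
  kin <- kinematic_cycle(theta = ang[, 3], omega = om, omega_dot = omd,
                         dt = Tc / (n_points - 1))
  attr(kin, "angles") <- ang
  kin
}

sim_gravity_model <- function(cfg) {
  gravity_model(cfg$gravity_coeffs$a_sin, cfg$gravity_coeffs$a_cos,
                enabled = TRUE)
}

#' Ground-truth torque for a simulated cycle
#'
#' Forward Newton-Euler with the configured true inertia and gravity model.
#' The kinematics are passed through the same Savitzky-Golay robust
#' operator the physics loss uses before the torque is formed, so labels
#' are dynamically consistent with the physics module by construction
#' (physics_loss with the generating parameters is zero to machine
#' precision on noiseless cycles).
#'
#' @param kin A [kinematic_cycle] from [generate_kinematics].
#' @param cfg The [gait_sim_config].
#' @param sg [sg_config] used by the robust operator.
#' @return (T x 3) torque matrix, N m/kg.
#' @export
ground_truth_torque <- function(kin, cfg, sg = sg_config()) {
  kinf <- filter_kinematics(kin, sg)
  newton_euler_torque(cfg$true_inertia, kinf, sim_gravity_model(cfg))
}

# rotation matrix from per-axis angles (ZYX composition)
rot_zyx <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Synthesize 6-axis IMU signals for a cycle
#'
#' Gyroscope channels are the angular velocity plus bias and seeded noise.
#' Accelerometer channels are the specific force at a fixed sensor offset
#' on the segment: gravity projected through the segment orientation plus
#' tangential and centripetal terms, plus noise. Noise standard deviation
#' is `sigma` times the clean per-channel standard deviation.
#'
#' @param kin A [kinematic_cycle] carrying the `"angles"` attribute.
#' @param cfg [gait_sim_config].
#' @param rng_seed Seed for the noise draws.
#' @return (6 x T) matrix, rows acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z.
#' @export
synthesize_imu <- function(kin, cfg, rng_seed = cfg$seed) {
  Tn <- nrow(kin$omega)
  ang <- attr(kin, "angles")
  if (is.null(ang)) ang <- cbind(0, 0, kin$theta)
  r_off <- c(0.03, 0.0, 0.10)               # sensor offset on the segment, m
  g_world <- c(0, 0, GRAVITY_MS2)
  acc <- matrix(0, Tn, 3)
  for (ti in seq_len(Tn)) {
    R <- rot_zyx(ang[ti, ])
    w <- kin$omega[ti, ]; wd <- kin$omega_dot[ti, ]
    centr <- cross3(w, cross3(w, r_off))
    tang <- cross3(wd, r_off)
    acc[ti, ] <- drop(t(R) %*% g_world) + tang + centr
  }
  clean <- rbind(t(acc), t(kin$omega))      # 6 x T
  clean[4:6, ] <- clean[4:6, ] + cfg$noise$gyro_bias
  if (cfg$noise$sigma > 0) {
    set.seed(rng_seed)
    for (ch in 1:6) {
      s <- stats::sd(clean[ch, ])
      if (s > 0) {
        clean[ch, ] <- clean[ch, ] + stats::rnorm(Tn, 0, cfg$noise$sigma * s)
      }
    }
  }
  clean
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Resample a trajectory to the 101-point cycle grid
#'
#' Linear interpolation onto 101 uniformly spaced points spanning the
#' cycle; endpoints are preserved exactly.
#'
#' @param x (T_raw x C) matrix or vector.
#' @param n_out Output length (101 by convention).
#' @return (n_out x C) matrix (vector in, vector out).
#' @export
resample_cycle <- function(x, n_out = 101L) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  if (nrow(xm) < 2L) stop("need at least 2 samples to resample, got ", nrow(xm))
  s_in <- seq(0, 1, length.out = nrow(xm))
  s_out <- seq(0, 1, length.out = n_out)
  out <- apply(xm, 2L, function(col) stats::approx(s_in, col, xout = s_out)$y)
  out <- matrix(out, nrow = n_out)
  if (is.matrix(x)) out else drop(out)
}

#' Build a complete synthetic dataset
#'
#' Generates every subject/cycle/joint, synthesizes IMU at the native rate,
#' resamples signals to 101 steps, computes dynamically consistent torque
#' labels, and assigns cycle-level train/val/test splits at 7:2:1. When
#' `out_dir` is given, writes one TSV per subject plus a JSON manifest.
#'
#' @param cfg A [gait_sim_config].
#' @param out_dir Optional output directory.
#' @return A `gait_dataset`: list with `cycles`, `manifest`.
#' @export
build_dataset <- function(cfg, out_dir = NULL) {
  n_points <- 101L
  native_n <- round(cfg$sample_rate * cfg$cycle_duration) + 1L
  cycles <- list()
  idx <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    for (cy in seq_len(cfg$n_cycles_per_subject)) {
      idx <- idx + 1L
      joints <- list()
      for (j in seq_along(GAIT_JOINTS)) {
        jn <- GAIT_JOINTS[j]
        kin_native <- generate_kinematics(cfg, s, cy, jn, n_points = native_n)
        imu_native <- synthesize_imu(kin_native, cfg,
                                     rng_seed = sim_subseed(cfg$seed, s, cy, j,
                                                            salt = 3L))
        imu <- t(resample_cycle(t(imu_native), n_points))   # 6 x 101
        kin <- generate_kinematics(cfg, s, cy, jn, n_points = n_points)
        tau <- ground_truth_torque(kin, cfg)
        joints[[jn]] <- list(imu = imu, theta = kin$theta,
                             omega = kin$omega, omega_dot = kin$omega_dot,
                             tau = tau)
      }
      cycles[[idx]] <- list(subject_id = s, cycle_id = cy,
                            activity = cfg$excitation, split = NA_character_,
                            dt = cfg$cycle_duration / (n_points - 1L),
                            joints = joints)
    }
  }
  n <- length(cycles)
  set.seed(sim_subseed(cfg$seed, 0L, 0L, 0L, salt = 4L))
  ord <- sample.int(n)
  n_tr <- round(0.7 * n); n_va <- round(0.2 * n)
  split <- character(n)
  split[ord[seq_len(n_tr)]] <- "train"
  split[ord[n_tr + seq_len(n_va)]] <- "val"
  split[ord[(n_tr + n_va + 1L):n]] <- "test"
  for (i in seq_len(n)) cycles[[i]]$split <- split[i]
  ds <- structure(list(cycles = cycles,
                       manifest = dataset_manifest(cfg)),
                  class = "gait_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

dataset_manifest <- function(cfg) {
  list(format_version = "1.0",
       joints = GAIT_JOINTS,
       n_points = 101L,
       config = list(
         n_subjects = cfg$n_subjects,
         n_cycles_per_subject = cfg$n_cycles_per_subject,
         cycle_duration = cfg$cycle_duration,
         sample_rate = cfg$sample_rate,
         fourier_order = cfg$fourier_order,
         excitation = cfg$excitation,
         noise = list(sigma = cfg$noise$sigma,
                      gyro_bias = cfg$noise$gyro_bias),
         true_inertia = as.numeric(cfg$true_inertia),
         gravity_a_sin = cfg$gravity_coeffs$a_sin,
         gravity_a_cos = cfg$gravity_coeffs$a_cos,
         seed = cfg$seed))
}

manifest_to_config <- function(man) {
  mc <- man$config
  gait_sim_config(
    n_subjects = mc$n_subjects,
    n_cycles_per_subject = mc$n_cycles_per_subject,
    cycle_duration = mc$cycle_duration, sample_rate = mc$sample_rate,
    fourier_order = mc$fourier_order, excitation = mc$excitation,
    noise = noise_config(mc$noise$sigma, mc$noise$gyro_bias),
    true_inertia = matrix(mc$true_inertia, 3, 3),
    gravity_coeffs = list(a_sin = mc$gravity_a_sin, a_cos = mc$gravity_a_cos),
    seed = mc$seed)
}

#' @export
print.gait_dataset <- function(x, ...) {
  sp <- table(vapply(x$cycles, function(cy) cy$split, character(1)))
  cat(sprintf("<gait_dataset %d cycles (%s), %d joints, seed=%d>\n",
              length(x$cycles),
              paste(names(sp), sp, sep = "=", collapse = " "),
              length(GAIT_JOINTS), x$manifest$config$seed))
  invisible(x)
}
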