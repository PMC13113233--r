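# Teacher pretraining and student distillation: composite objective,
# warm-up, gradient clipping, ablation presets, per-epoch history.

#' Composite loss weights
#'
#' Weights of the four auxiliary terms on top of the data-fitting loss:
#' `alpha` (output-response distillation), `beta` (Fisher-weighted anchor
#' alignment), `delta` (principal-subspace alignment), `gamma`
#' (Newton-Euler physics consistency).
#'
#' @param alpha,beta,delta,gamma Nonnegative reals.
#' @return List of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.5, beta = 0.1, delta = 0.1, gamma = 0.05) {
  w <- c(alpha = alpha, beta = beta, delta = delta, gamma = gamma)
  if (any(w < 0)) stop("loss weights must be nonnegative")
  structure(as.list(w), class = "loss_weights")
}

#' Ablation presets for the distillation objective
#'
#' `M0` supervised baseline (all four weights zero), `M1` output-response
#' distillation only, `M2` adds the two parameter-structure terms, `M3` the
#' full framework including the physics term.
#'
#' @param preset One of `"M0"`, `"M1"`, `"M2"`, `"M3"`.
#' @param base Weights used for the active terms.
#' @return A [loss_weights].
#' @export
ablation_weights <- function(preset, base = loss_weights()) {
  switch(match.arg(preset, c("M0", "M1", "M2", "M3")),
         M0 = loss_weights(0, 0, 0, 0),
         M1 = loss_weights(base$alpha, 0, 0, 0),
         M2 = loss_weights(base$alpha, base$beta, base$delta, 0),
         M3 = base)
}

#' Training configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Cycles per minibatch.
#' @param lr Base AdamW learning rate.
#' @param warmup_epochs Linear warm-up length (epochs).
#' @param clip_norm Global gradient-norm clip.
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed Integer seed controlling init and shuffling.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 16L, lr = 1e-3,
                         warmup_epochs = 5L, clip_norm = 1.0,
                         weight_decay = 1e-4, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 warmup_epochs = as.integer(warmup_epochs),
                 clip_norm = clip_norm, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Normalized data-fitting loss
#'
#' Squared error summed over torque axes, averaged over batch and time:
#' `(1 / (B T)) * sum_i sum_t ||tau_gt(i,t) - tau_s(i,t)||^2`. The B*T
#' normalization keeps gradient magnitude independent of batch size and
#' sequence length.
#'
#' @param tau_gt,tau_s Torque arrays of equal shape (B x T x A).
#' @return Nonnegative scalar.
#' @export
data_loss <- function(tau_gt, tau_s) {
  if (!identical(dim(tau_gt), dim(tau_s))) {
    stop("torque shapes disagree: ", paste(dim(tau_gt), collapse = "x"),
         " vs ", paste(dim(tau_s), collapse = "x"))
  }
  d <- dim(tau_gt)
  sum((tau_gt - tau_s)^2) / (d[1] * d[2])
}

#' Output-response distillation loss
#'
#' Same normalized formulation as [data_loss], measured against the
#' teacher's predictions instead of the ground truth.
#'
#' @param tau_t,tau_s Teacher and student torque arrays (B x T x A).
#' @return Nonnegative scalar.
#' @export
kd_loss <- function(tau_t, tau_s) data_loss(tau_t, tau_s)

#' Evaluate the composite distillation objective
#'
#' Computes the five loss components and the weighted total
#' `L = L_data + alpha L_KD + beta L_Fisher + delta L_subspace +
#' gamma L_phy` for one batch. Components whose weight is zero are
#' reported as zero without being evaluated (so an M0 run never touches
#' teacher-side state).
#'
#' @param batch List with `tau` (B x T x A ground truth), optionally
#'   `tau_t` (teacher predictions) and `kin` (list of
#'   [kinematic_cycle]s).
#' @param student_out Result of [student_forward].
#' @param caches Teacher-side caches (`gt`, `fisher`, `projector`) from
#'   [build_teacher_caches]; required when `beta` or `delta` is positive.
#' @param physics List with `raw`, `gravity`, `sg`, `param` when `gamma`
#'   is positive.
#' @param w A [loss_weights].
#' @return List of class `loss_breakdown`: `total`, `data`, `kd`,
#'   `fisher`, `subspace`, `phy`.
#' @export
composite_loss <- function(batch, student_out, caches = NULL, physics = NULL,
                           w = loss_weights()) {
  comp <- list(data = data_loss(batch$tau, student_out$tau),
               kd = 0, fisher = 0, subspace = 0, phy = 0)
  if (w$alpha > 0) {
    if (is.null(batch$tau_t)) stop("alpha > 0 needs teacher predictions")
    comp$kd <- kd_loss(batch$tau_t, student_out$tau)
  }
  if (w$beta > 0 || w$delta > 0) {
    if (is.null(caches)) {
      stop("beta/delta > 0 need teacher caches (Gram, Fisher, projector)")
    }
    gs <- gram(student_out$ws)
    if (w$beta > 0) comp$fisher <- fisher_align_loss(gs, caches$gt, caches$fisher)
    if (w$delta > 0) comp$subspace <- subspace_loss(gs, caches$gt, caches$projector)
  }
  if (w$gamma > 0) {
    if (is.null(physics) || is.null(batch$kin)) {
      stop("gamma > 0 needs physics parameters and batch kinematics")
    }
    inert <- if (physics$param == "naive") naive_inertia(physics$raw)
             else spd_from_cholesky(physics$raw)
    B <- dim(student_out$tau)[1]
    vals <- vapply(seq_len(B), function(b) {
      kin <- batch$kin[[b]]
      tau_m <- newton_euler_torque(inert, kin, physics$gravity)
      idx <- kin$interior
      mean(rowSums((matrix(student_out$tau[b, , ], ncol = 3)[idx, ] -
                      tau_m[idx, ])^2))
    }, numeric(1))
    comp$phy <- mean(vals)
  }
  total <- comp$data + w$alpha * comp$kd + w$beta * comp$fisher +
    w$delta * comp$subspace + w$gamma * comp$phy
  structure(c(list(total = total), comp), class = "loss_breakdown")
}

# --- dataset -> tensors ---------------------------------------------------

stack_student_inputs <- function(cycles, joint) {
  B <- length(cycles)
  Tn <- length(cycles[[1]]$joints[[joint]]$theta)
  x <- array(0, c(B, 6L, Tn))
  tau <- array(0, c(B, Tn, 3L))
  for (b in seq_len(B)) {
    j <- cycles[[b]]$joints[[joint]]
    x[b, , ] <- j$imu
    tau[b, , ] <- j$tau
  }
  list(x = x, tau = tau)
}

cycle_kinematics <- function(cycles, joint, sg = sg_config()) {
  lapply(cycles, function(cy) {
    j <- cy$joints[[joint]]
    filter_kinematics(
      kinematic_cycle(j$theta, j$omega, j$omega_dot, cy$dt), sg)
  })
}

scalogram_stack <- function(x, n_scales, dt) {
  B <- dim(x)[1]; C <- dim(x)[2]; Tn <- dim(x)[3]
  out <- array(0, c(C, n_scales, Tn, B))
  for (b in seq_len(B)) {
    out[, , , b] <- cwt_scalogram(x[b, , ], n_scales, dt)$tensor
  }
  out
}

channel_norm3 <- function(x) {
  C <- dim(x)[2]
  mu <- numeric(C); sd <- numeric(C)
  for (ci in seq_len(C)) {
    v <- as.numeric(x[, ci, ])
    mu[ci] <- mean(v); sd[ci] <- max(stats::sd(v), 1e-8)
  }
  list(mu = mu, sd = sd)
}

scalogram_norm <- function(x4) {
  d <- dim(x4)
  mu <- array(0, d[1:2]); sd <- array(1, d[1:2])
  for (ci in seq_len(d[1])) for (si in seq_len(d[2])) {
    v <- as.numeric(x4[ci, si, , ])
    mu[ci, si] <- mean(v); sd[ci, si] <- max(stats::sd(v), 1e-8)
  }
  list(mu = mu, sd = sd)
}

minibatches <- function(n, batch_size) {
  ix <- sample.int(n)
  split(ix, ceiling(seq_along(ix) / batch_size))
}

# --- teacher pretraining --------------------------------------------------

#' Train the teacher network
#'
#' Supervised training of the CWT/attention teacher on scalograms of the
#' training split, AdamW with linear warm-up and gradient clipping,
#' best-validation-checkpoint selection. Fully deterministic given
#' `cfg$seed`.
#'
#' @param ds A `gait_dataset`.
#' @param tcfg [teacher_config].
#' @param cfg [train_config].
#' @param joint Which joint model to train.
#' @return List with `model`, `history` (one row per epoch), `joint`.
#' @export
train_teacher <- function(ds, tcfg = teacher_config(), cfg = train_config(),
                          joint = "hip") {
  tr <- split_cycles(ds, "train"); va <- split_cycles(ds, "val")
  if (length(tr) == 0L) stop("empty training split")
  dt <- tr[[1]]$dt
  tr_d <- stack_student_inputs(tr, joint)
  va_d <- stack_student_inputs(va, joint)
  tr_x <- scalogram_stack(tr_d$x, tcfg$n_scales, dt)
  va_x <- if (length(va) > 0) scalogram_stack(va_d$x, tcfg$n_scales, dt)
  model <- teacher_model(tcfg, seed = cfg$seed)
  model$norm <- scalogram_norm(tr_x)
  opt <- adamw_init(model$params)
  set.seed(cfg$seed + 17L)
  best <- list(val = Inf, params = model$params)
  hist <- data.frame()
  n <- dim(tr_x)[4]
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(ep, cfg$lr, cfg$warmup_epochs)
    ep_loss <- 0; ep_gnorm <- 0; nb <- 0L
    for (bix in minibatches(n, cfg$batch_size)) {
      xb <- tr_x[, , , bix, drop = FALSE]
      tb <- tr_d$tau[bix, , , drop = FALSE]
      fwd <- teacher_forward(model, xb, want_cache = TRUE)
      d <- dim(tb)
      loss <- data_loss(tb, fwd$tau)
      if (!is.finite(loss)) {
        stop(sprintf("teacher loss non-finite at epoch %d batch %d", ep, nb + 1L))
      }
      dtau <- 2 * (fwd$tau - tb) / (d[1] * d[2])
      grads <- teacher_backward(model, fwd, dtau)
      cl <- clip_gradients(grads, cfg$clip_norm)
      st <- adamw_step(model$params, cl$grads, opt, lr,
                       weight_decay = cfg$weight_decay)
      model$params <- st$params; opt <- st$state
      ep_loss <- ep_loss + loss; ep_gnorm <- max(ep_gnorm, cl$norm); nb <- nb + 1L
    }
    val <- if (length(va) > 0) {
      data_loss(va_d$tau, teacher_forward(model, va_x)$tau)
    } else NA_real_
    if (is.finite(val) && val < best$val) {
      best <- list(val = val, params = model$params)
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr,
                                   train_loss = ep_loss / nb,
                                   val_loss = val, grad_norm = ep_gnorm))
  }
  if (is.finite(best$val)) model$params <- best$params
  list(model = model, history = hist, joint = joint, kind = "teacher",
       config = tcfg, train_config = cfg)
}

#' Predict with a trained teacher
#' @param state Result of [train_teacher] (or loaded checkpoint).
#' @param cycles List of cycles.
#' @return (B x T x A) torque array.
#' @export
teacher_predict <- function(state, cycles) {
  d <- stack_student_inputs(cycles, state$joint)
  x4 <- scalogram_stack(d$x, state$model$config$n_scales, cycles[[1]]$dt)
  teacher_forward(state$model, x4)$tau
}

#' Precompute the teacher-side alignment caches
#'
#' Gram matrix of the teacher's anchor projection, diagonal Fisher
#' information estimated over the training split, and the
#' principal-subspace projector. All three are computed once from the
#' frozen teacher before student training and keyed by a checksum of the
#' teacher weights so stale caches are detected at load time.
#'
#' @param tstate Teacher state from [train_teacher].
#' @param ds Dataset (training split is used for the Fisher expectation).
#' @param batch_size Fisher estimation batch size.
#' @param rank Subspace rank override (`NULL`: 95% eigenvalue mass).
#' @return List with `gt`, `fisher`, `projector`, `teacher_checksum`.
#' @export
build_teacher_caches <- function(tstate, ds, batch_size = 16L, rank = NULL) {
  tr <- split_cycles(ds, "train")
  d <- stack_student_inputs(tr, tstate$joint)
  x4 <- scalogram_stack(d$x, tstate$model$config$n_scales, tr[[1]]$dt)
  n <- dim(x4)[4]
  ixs <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  batches <- lapply(ixs, function(ix) {
    list(x = x4[, , , ix, drop = FALSE], tau = d$tau[ix, , , drop = FALSE])
  })
  gt <- gram(anchor_weights(tstate$model$params$Wt, "teacher"))
  fisher <- estimate_fisher_diag(tstate$model, batches)
  projector <- principal_projector(gt, k = rank)
  list(gt = gt, fisher = fisher, projector = projector,
       teacher_checksum = params_checksum(tstate$model$params))
}

default_physics_state <- function(param = "cholesky") {
  raw <- if (param == "naive") c(0.05, 0.05, 0.05, 0, 0, 0)
         else cholesky_raw_from_spd(diag(0.05, 3))
  list(raw = raw, gravity = gravity_model(enabled = TRUE),
       sg = sg_config(), param = param)
}

#' Distill the student network
#'
#' Full student training loop under the composite objective: per-batch
#' forward, analytic gradients for every component (data, KD against
#' cached teacher predictions, Fisher/subspace alignment on the adapter
#' weights, Newton-Euler physics residual), gradient clipping, linear
#' warm-up, best-validation selection. Physics parameters (Cholesky
#' inertia and gravity coefficients) are updated jointly with the network
#' by the same optimizer. With `teacher_state = NULL` and all auxiliary
#' weights zero this is plain supervised training of the student.
#'
#' @param teacher_state Frozen teacher (from [train_teacher]) or `NULL`.
#' @param ds A `gait_dataset`.
#' @param scfg [student_config].
#' @param cfg [train_config].
#' @param w [loss_weights] (or an [ablation_weights] preset).
#' @param joint Joint to train.
#' @param physics_param `"cholesky"` (SPD-guaranteed) or `"naive"`
#'   (unconstrained symmetric; the ablation variant).
#' @param caches Optional precomputed [build_teacher_caches] result.
#' @return List with `model`, `physics`, `history`, `caches`, `joint`.
#' @export
distill <- function(teacher_state, ds, scfg = student_config(),
                    cfg = train_config(), w = loss_weights(), joint = "hip",
                    physics_param = "cholesky", caches = NULL) {
  tr <- split_cycles(ds, "train"); va <- split_cycles(ds, "val")
  if (length(tr) == 0L) stop("empty training split")
  need_teacher <- w$alpha > 0 || w$beta > 0 || w$delta > 0
  if (need_teacher && is.null(teacher_state)) {
    stop("preset/weight contradiction: auxiliary weights need a teacher")
  }
  tr_d <- stack_student_inputs(tr, joint)
  va_d <- stack_student_inputs(va, joint)
  tau_t <- if (w$alpha > 0) teacher_predict(teacher_state, tr) else NULL
  if ((w$beta > 0 || w$delta > 0) && is.null(caches)) {
    caches <- build_teacher_caches(teacher_state, ds)
  }
  if (!is.null(caches) && !is.null(teacher_state)) {
    verify_teacher_cache(caches, teacher_state$model)
  }
  sg <- sg_config()
  kins <- if (w$gamma > 0) cycle_kinematics(tr, joint, sg) else NULL
  va_kins <- cycle_kinematics(va, joint, sg)
  model <- student_model(scfg, seed = cfg$seed)
  model$norm <- channel_norm3(tr_d$x)
  phys <- default_physics_state(physics_param)
  params <- list(net = model$params)
  if (w$gamma > 0) {
    params$phys <- list(raw = phys$raw, a_sin = phys$gravity$a_sin,
                        a_cos = phys$gravity$a_cos)
  }
  opt <- adamw_init(params)
  set.seed(cfg$seed + 29L)
  best <- list(val = Inf, params = params)
  hist <- data.frame()
  n <- dim(tr_d$x)[1]
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(ep, cfg$lr, cfg$warmup_epochs)
    sums <- c(total = 0, data = 0, kd = 0, fisher = 0, subspace = 0, phy = 0)
    gmax <- 0; nb <- 0L
    for (bix in minibatches(n, cfg$batch_size)) {
      xb <- tr_d$x[bix, , , drop = FALSE]
      tb <- tr_d$tau[bix, , , drop = FALSE]
      model$params <- params$net
      fwd <- student_forward(model, xb, want_cache = TRUE)
      d <- dim(tb); B <- d[1]; Tn <- d[2]
      comp <- c(data = data_loss(tb, fwd$tau), kd = 0, fisher = 0,
                subspace = 0, phy = 0)
      dtau <- 2 * (fwd$tau - tb) / (B * Tn)
      dWs_extra <- NULL
      gphys <- NULL
      if (w$alpha > 0) {
        tt <- tau_t[bix, , , drop = FALSE]
        comp["kd"] <- kd_loss(tt, fwd$tau)
        dtau <- dtau + w$alpha * 2 * (fwd$tau - tt) / (B * Tn)
      }
      if (w$beta > 0 || w$delta > 0) {
        gs <- gram(fwd$ws)
        ag <- align_grads_ws(params$net$Ws, caches$gt,
                             f = if (w$beta > 0) caches$fisher,
                             p = if (w$delta > 0) caches$projector)
        dWs_extra <- 0
        if (w$beta > 0) {
          comp["fisher"] <- fisher_align_loss(gs, caches$gt, caches$fisher)
          dWs_extra <- dWs_extra + w$beta * ag$fisher
        }
        if (w$delta > 0) {
          comp["subspace"] <- subspace_loss(gs, caches$gt, caches$projector)
          dWs_extra <- dWs_extra + w$delta * ag$subspace
        }
      }
      if (w$gamma > 0) {
        gmdl <- gravity_model(params$phys$a_sin, params$phys$a_cos,
                              enabled = TRUE)
        graw <- numeric(6); gsin <- numeric(3); gcos <- numeric(3)
        phl <- 0
        for (bi in seq_along(bix)) {
          res <- physics_residual_grad(matrix(fwd$tau[bi, , ], Tn, 3L),
                                       kins[[bix[bi]]], params$phys$raw,
                                       gmdl, param = physics_param)
          phl <- phl + res$loss / B
          graw <- graw + res$graw / B
          gsin <- gsin + res$ggrav$a_sin / B
          gcos <- gcos + res$ggrav$a_cos / B
          dtau[bi, , ] <- dtau[bi, , ] + w$gamma * res$gtau / B
        }
        comp["phy"] <- phl
        gphys <- list(raw = w$gamma * graw, a_sin = w$gamma * gsin,
                      a_cos = w$gamma * gcos)
      }
      total <- comp["data"] + w$alpha * comp["kd"] + w$beta * comp["fisher"] +
        w$delta * comp["subspace"] + w$gamma * comp["phy"]
      if (!is.finite(total)) {
        stop(sprintf("student loss non-finite at epoch %d batch %d", ep, nb + 1L))
      }
      sgrad <- student_backward(model, fwd, dtau, dWs_extra = dWs_extra)
      gtree <- list(net = sgrad)
      if (!is.null(gphys)) gtree$phys <- gphys
      cl <- clip_gradients(gtree, cfg$clip_norm)
      st <- adamw_step(params, cl$grads, opt, lr,
                       weight_decay = cfg$weight_decay)
      params <- st$params; opt <- st$state
      sums <- sums + c(total = unname(total), comp)
      gmax <- max(gmax, cl$norm); nb <- nb + 1L
    }
    model$params <- params$net
    phys_now <- current_physics(params, phys, physics_param)
    val <- NA_real_; val_pce <- NA_real_
    if (length(va) > 0) {
      vf <- student_forward(model, va_d$x)
      val <- data_loss(va_d$tau, vf$tau)
      val_pce <- mean(vapply(seq_along(va), function(i) {
        physical_metrics(matrix(vf$tau[i, , ], ncol = 3),
                         matrix(va_d$tau[i, , ], ncol = 3),
                         va_kins[[i]], phys_now$inertia, phys_now$gravity,
                         prefiltered = TRUE)["pce"]
      }, numeric(1)))
      if (val < best$val) best <- list(val = val, params = params)
    }
    hist <- rbind(hist, cbind(
      data.frame(epoch = ep, lr = lr), as.data.frame(t(sums / nb)),
      data.frame(val_loss = val, val_pce = val_pce, grad_norm = gmax)))
  }
  if (is.finite(best$val)) params <- best$params
  model$params <- params$net
  phys_final <- current_physics(params, phys, physics_param)
  model$physics <- phys_final
  list(model = model, physics = phys_final, history = hist, caches = caches,
       joint = joint, kind = "student", config = scfg, train_config = cfg,
       weights = w)
}

current_physics <- function(params, phys, physics_param) {
  if (!is.null(params$phys)) {
    raw <- params$phys$raw
    grav <- gravity_model(params$phys$a_sin, params$phys$a_cos, enabled = TRUE)
  } else {
    raw <- phys$raw
    grav <- phys$gravity
  }
  inert <- if (physics_param == "naive") naive_inertia(raw)
           else spd_from_cholesky(raw)
  list(raw = raw, inertia = inert, gravity = grav, param = physics_param,
       sg = phys$sg)
}

#' Predict with a trained student
#' @param state Result of [distill] (or loaded checkpoint).
#' @param cycles List of cycles.
#' @return (B x T x A) torque array.
#' @export
student_predict <- function(state, cycles) {
  d <- stack_student_inputs(cycles, state$joint)
  student_forward(state$model, d$x)$tau
}
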