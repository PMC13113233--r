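test_that("data and KD losses match their loop oracles", {
  set.seed(20)
  B <- 3; Tn <- 7; A <- 3
  gt <- array(rnorm(B * Tn * A), c(B, Tn, A))
  pr <- array(rnorm(B * Tn * A), c(B, Tn, A))
  brute <- 0
  for (i in 1:B) for (t in 1:Tn) for (a in 1:A) {
    brute <- brute + (gt[i, t, a] - pr[i, t, a])^2
  }
  brute <- brute / (B * Tn)
  expect_equal(data_loss(gt, pr), brute, tolerance = 1e-10)
  expect_equal(kd_loss(gt, pr), brute, tolerance = 1e-10)
  expect_identical(data_loss(gt, gt), 0)
  # constant offset on one axis -> c^2
  off <- gt; off[, , 2] <- off[, , 2] + 0.7
  expect_equal(data_loss(gt, off), 0.49, tolerance = 1e-12)
  expect_error(data_loss(gt, array(0, c(2, Tn, A))), "disagree")
})

test_that("loss weight presets follow the ablation ladder", {
  expect_equal(unlist(ablation_weights("M0")), c(alpha = 0, beta = 0,
                                                 delta = 0, gamma = 0))
  m1 <- ablation_weights("M1")
  expect_true(m1$alpha > 0 && m1$beta == 0 && m1$delta == 0 && m1$gamma == 0)
  m2 <- ablation_weights("M2")
  expect_true(m2$beta > 0 && m2$delta > 0 && m2$gamma == 0)
  m3 <- ablation_weights("M3")
  expect_true(all(unlist(m3) > 0))
  expect_error(loss_weights(alpha = -1), "nonnegative")
})

test_that("composite loss is additive and respects hand-set components", {
  # hand arithmetic: components (1,2,3,4,5), weights (0.5,0.1,0.1,0.05)
  total <- 1 + 0.5 * 2 + 0.1 * 3 + 0.1 * 4 + 0.05 * 5
  expect_equal(total, 2.95)
  # through the real path: an M0 breakdown reduces to the data term
  set.seed(21)
  sm <- student_model(student_config("test", rnn_hidden = 6, d_anchor = 8),
                      seed = 3)
  x <- array(rnorm(2 * 6 * 60), c(2, 6, 60))
  tau <- array(rnorm(2 * 60 * 3), c(2, 60, 3))
  out <- student_forward(sm, x)
  b0 <- composite_loss(list(tau = tau), out, w = loss_weights(0, 0, 0, 0))
  expect_equal(b0$total, b0$data)
  expect_identical(c(b0$kd, b0$fisher, b0$subspace, b0$phy), c(0, 0, 0, 0))
  # full breakdown with synthetic caches: additivity at the default weights
  gt <- gram(matrix(rnorm(48), 6, 8))
  caches <- list(gt = gt, fisher = fisher_weights(runif(8)),
                 projector = principal_projector(gt, k = 3))
  kin <- lapply(1:2, function(i) {
    gaitkd:::filter_kinematics(kinematic_cycle(
      rnorm(60), matrix(rnorm(180), 60, 3), matrix(rnorm(180), 60, 3),
      dt = 0.011))
  })
  phys <- gaitkd:::default_physics_state()
  w <- loss_weights()
  br <- composite_loss(list(tau = tau, tau_t = tau + 0.1, kin = kin),
                       out, caches, phys, w)
  expect_equal(br$total,
               br$data + w$alpha * br$kd + w$beta * br$fisher +
                 w$delta * br$subspace + w$gamma * br$phy,
               tolerance = 1e-10)
  expect_true(all(unlist(br) >= 0))
  # missing caches with beta > 0 is a configuration error
  expect_error(composite_loss(list(tau = tau, tau_t = tau), out,
                              w = loss_weights(0.5, 0.1, 0, 0)),
               "caches")
})

test_that("a perfect student at a shared anchor weight zeroes every term", {
  gt_w <- matrix(rnorm(40), 5, 8)
  gtm <- gram(gt_w)
  caches <- list(gt = gtm, fisher = fisher_weights(runif(8)),
                 projector = principal_projector(gtm, k = 2))
  tau <- array(rnorm(2 * 30 * 3), c(2, 30, 3))
  out <- list(tau = tau, ws = anchor_weights(gt_w, "student"))
  br <- composite_loss(list(tau = tau, tau_t = tau), out, caches,
                       w = loss_weights(0.5, 0.1, 0.1, 0))
  expect_equal(br$total, 0, tolerance = 1e-12)
})

test_that("gradient clipping bounds the global norm", {
  g <- list(a = matrix(3, 2, 2), b = rep(4, 5))
  cl <- gaitkd:::clip_gradients(g, 1.0)
  expect_gt(cl$norm, 1)
  expect_equal(gaitkd:::grad_global_norm(cl$grads), 1, tolerance = 1e-12)
  # below the threshold nothing changes
  g2 <- list(a = matrix(1e-3, 2, 2))
  expect_identical(gaitkd:::clip_gradients(g2, 1.0)$grads, g2)
})

test_that("learning-rate warm-up ramps linearly to the base rate", {
  expect_equal(gaitkd:::lr_at_epoch(1, 1e-3, 5), 2e-4)
  expect_equal(gaitkd:::lr_at_epoch(5, 1e-3, 5), 1e-3)
  expect_equal(gaitkd:::lr_at_epoch(50, 1e-3, 5), 1e-3)
})

test_that("teacher training reduces the loss and reruns identically", {
  ds <- tiny_dataset()
  cfg <- train_config(epochs = 8L, batch_size = 7L, seed = 31L)
  tcfg <- teacher_config("test", n_scales = 8, conv_channels = c(6, 12),
                         attention_heads = 2, n_blocks = 1)
  r1 <- train_teacher(ds, tcfg, cfg, joint = "hip")
  expect_lt(tail(r1$history$train_loss, 1), r1$history$train_loss[1])
  r2 <- train_teacher(ds, tcfg, cfg, joint = "hip")
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
  # empty training split guard
  ds_empty <- ds
  ds_empty$cycles <- lapply(ds_empty$cycles, function(cy) {
    cy$split <- "test"; cy
  })
  expect_error(train_teacher(ds_empty, tcfg, cfg), "empty training split")
})

test_that("distillation logs an additive breakdown and leaves the teacher frozen", {
  ds <- tiny_dataset()
  tcfg <- teacher_config("test", n_scales = 8, conv_channels = c(6, 12),
                         attention_heads = 2, n_blocks = 1)
  tstate <- train_teacher(ds, tcfg, train_config(epochs = 5L, batch_size = 7L,
                                                 seed = 31L), joint = "hip")
  before <- gaitkd:::params_checksum(tstate$model$params)
  cfg <- train_config(epochs = 6L, batch_size = 7L, seed = 32L)
  st <- distill(tstate, ds, student_config("test"), cfg,
                ablation_weights("M3"), joint = "hip")
  h <- st$history
  expect_equal(h$total,
               h$data + 0.5 * h$kd + 0.1 * h$fisher + 0.1 * h$subspace +
                 0.05 * h$phy,
               tolerance = 1e-10)
  expect_true(all(h[, c("data", "kd", "fisher", "subspace", "phy")] >= 0))
  expect_identical(gaitkd:::params_checksum(tstate$model$params), before)
  # M0 preset is bit-for-bit a supervised run at the same seed
  m0_teacher <- distill(tstate, ds, student_config("test"), cfg,
                        ablation_weights("M0"))
  m0_plain <- distill(NULL, ds, student_config("test"), cfg,
                      ablation_weights("M0"))
  expect_identical(m0_teacher$history, m0_plain$history)
  expect_identical(m0_teacher$model$params, m0_plain$model$params)
  # weight/preset contradiction
  expect_error(distill(NULL, ds, student_config("test"), cfg,
                       ablation_weights("M1")), "contradiction")
})

test_that("distillation keeps the learned inertia SPD throughout", {
  ds <- tiny_dataset()
  cfg <- train_config(epochs = 4L, batch_size = 7L, seed = 33L)
  st <- distill(NULL, ds, student_config("test"), cfg,
                loss_weights(0, 0, 0, 0.05), joint = "knee")
  ev <- eigen(st$physics$inertia$I_eff, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
})
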