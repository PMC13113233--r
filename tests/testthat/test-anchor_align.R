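test_that("gram computes W'W with the documented small cases", {
  expect_equal(unclass(gram(diag(2))), diag(2), ignore_attr = TRUE)
  w <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] row-wise
  expect_equal(unclass(gram(w)),
               matrix(c(10, 14, 14, 20), 2, 2), ignore_attr = TRUE)
  wz <- matrix(rnorm(6), 3, 2); wz[, 2] <- 0
  g <- unclass(gram(wz))
  expect_equal(g[2, ], c(g[1, 2], 0))
  expect_equal(g[, 2], c(g[2, 1], 0))
})

test_that("gram output is symmetric PSD for random weight matrices", {
  set.seed(42)
  for (i in 1:200) {
    nr <- sample(2:8, 1); nc <- sample(2:6, 1)
    w <- matrix(rnorm(nr * nc), nr, nc)
    g <- unclass(gram(w))
    expect_equal(g, t(g))
    ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(g), 1))
  }
})

test_that("gram rejects non-finite weights naming the origin", {
  w <- matrix(c(1, NA, 0, 2), 2, 2)
  expect_error(gram(anchor_weights(w, "teacher")), "teacher")
})

test_that("align_loss is the squared Frobenius distance", {
  g <- gram(matrix(rnorm(9), 3, 3))
  expect_identical(align_loss(g, g), 0)
  expect_equal(align_loss(gram(diag(2)), matrix(0, 2, 2)), 2)
  set.seed(1)
  a <- random_psd(4); b <- random_psd(4)
  brute <- 0
  for (i in 1:4) for (j in 1:4) brute <- brute + (a[i, j] - b[i, j])^2
  expect_equal(align_loss(a, b), brute, tolerance = 1e-12)
  expect_error(align_loss(a, random_psd(3)), "mismatch")
})

test_that("fisher_align_loss weights row discrepancies and matches hand cases", {
  set.seed(2)
  a <- random_psd(3); b <- random_psd(3)
  # unit weights recover the unweighted loss
  expect_equal(fisher_align_loss(a, b, rep(1, 3)), align_loss(a, b),
               tolerance = 1e-10)
  expect_identical(fisher_align_loss(a, b, rep(0, 3)), 0)
  # one-hot at row 2
  f <- c(0, 3.5, 0)
  expect_equal(fisher_align_loss(a, b, f), 3.5 * sum((a[2, ] - b[2, ])^2),
               tolerance = 1e-12)
  expect_error(fisher_align_loss(a, b, c(1, 1)), "length")
})

test_that("fisher diagonal estimation matches the analytic quadratic-loss case", {
  # probe model: loss L = 0.5 * sum(z^2) at fixed z = c gives dL/dz = c,
  # so the Fisher diagonal must equal c^2 exactly
  cvec <- c(1.5, -2, 0, 0.25)
  probe <- list(anchor_dim = 4L,
                anchor_grad = function(x, tau) matrix(cvec, 1, 4, byrow = TRUE))
  f <- estimate_fisher_diag(probe, batches = list(list(x = NULL, tau = NULL),
                                                  list(x = NULL, tau = NULL)))
  expect_equal(f$diag, cvec^2)
  expect_identical(f$diag[3], 0)  # loss independent of z_3
  expect_true(all(f$diag >= 0))
  expect_error(estimate_fisher_diag(probe, list()), "empty")
  expect_error(estimate_fisher_diag(list(foo = 1), list(1)), "anchor")
})

test_that("principal projector is symmetric, idempotent, with trace k", {
  expect_equal(principal_projector(diag(c(3, 1)), k = 1)$projector,
               diag(c(1, 0)))
  g <- random_psd(6, seed = 3)
  expect_equal(principal_projector(g, k = 6)$projector, diag(6),
               tolerance = 1e-10)
  for (k in c(1, 3, 5)) {
    p <- principal_projector(g, k = k)
    pr <- p$projector
    expect_equal(pr, t(pr))
    expect_lt(norm(pr %*% pr - pr, "F"), 1e-8)
    expect_equal(sum(diag(pr)), k, tolerance = 1e-6)
    expect_lt(max(abs(crossprod(p$basis) - diag(k))), 1e-8)
  }
  expect_error(principal_projector(g, k = 0), "out of range")
  expect_error(principal_projector(g, k = 7), "out of range")
})

test_that("principal projector agrees with a dense eigendecomposition oracle", {
  g <- random_psd(8, seed = 4)
  k <- 3
  p <- principal_projector(g, k = k)
  eg <- eigen(g, symmetric = TRUE)
  u <- eg$vectors[, 1:k]
  expect_equal(p$projector, tcrossprod(u), tolerance = 1e-10)
})

test_that("automatic rank captures 95% eigenvalue mass, capped at d/2", {
  g <- diag(c(100, 1, 0.5, 0.1, 0.05, 0.01))
  expect_equal(principal_projector(g)$rank, 1L)
  g2 <- diag(rep(1, 8))  # flat spectrum: cap at d/2 binds
  expect_equal(principal_projector(g2)$rank, 4L)
})

test_that("subspace loss is a contraction of the alignment loss", {
  set.seed(5)
  for (i in 1:100) {
    d <- sample(3:8, 1)
    a <- random_psd(d); b <- random_psd(d)
    p <- principal_projector(b, k = sample(seq_len(d), 1))
    expect_lte(subspace_loss(a, b, p), align_loss(a, b) + 1e-10)
  }
  a <- random_psd(4, seed = 6); b <- random_psd(4)
  expect_identical(subspace_loss(a, a, principal_projector(a, k = 2)), 0)
  expect_equal(subspace_loss(a, b, diag(4)), align_loss(a, b))
})

test_that("alignment losses are differentiable wrt the student adapter", {
  set.seed(7)
  ws <- matrix(rnorm(5 * 4), 5, 4)
  gt <- random_psd(4)
  f <- fisher_weights(runif(4))
  p <- principal_projector(gt, k = 2)
  g <- gaitkd:::align_grads_ws(ws, gt, f = f, p = p)
  for (nm in c("fisher", "subspace")) {
    lossf <- function(w) {
      gs <- gram(w)
      if (nm == "fisher") fisher_align_loss(gs, gt, f)
      else subspace_loss(gs, gt, p)
    }
    ix <- sample(length(ws), 5)
    for (i in ix) {
      h <- 1e-6
      wp <- ws; wp[i] <- wp[i] + h
      wm <- ws; wm[i] <- wm[i] - h
      fd <- (lossf(wp) - lossf(wm)) / (2 * h)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})
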