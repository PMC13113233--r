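# Teacher (CWT scalogram + CNN/attention) and student (lightweight GRU +
# linear dimensional adapter) architectures. Both expose the projection
# weights that land in the shared anchor space; those weights are live
# references into `model$params`, so alignment losses backpropagate into
# the student adapter.

#' Teacher model configuration
#'
#' The `paper` preset instantiates a ~31 M-parameter network (four
#' convolution blocks and two attention/FFN blocks at width 896); the
#' `test` preset is a <= 0.1 M miniature with the same topology for fast
#' desk-scale experiments.
#'
#' @param scale_preset `"paper"` or `"test"`.
#' @param n_scales Number of CWT scales.
#' @param wavelet Analytic wavelet family (only `"morlet"`).
#' @param conv_channels Integer vector of conv block widths.
#' @param attention_heads Number of self-attention heads.
#' @param n_blocks Number of attention/FFN blocks.
#' @param d_anchor Anchor-space width (must match the student's).
#' @param out_axes Torque components per joint.
#' @param in_channels IMU channels per segment.
#' @return List of class `teacher_config`.
#' @export
teacher_config <- function(scale_preset = c("test", "paper"),
                           n_scales = NULL, wavelet = "morlet",
                           conv_channels = NULL, attention_heads = NULL,
                           n_blocks = NULL, d_anchor = 64L, out_axes = 3L,
                           in_channels = 6L) {
  scale_preset <- match.arg(scale_preset)
  def <- if (scale_preset == "paper") {
    list(n_scales = 32L, conv_channels = c(224L, 448L, 896L, 896L),
         attention_heads = 8L, n_blocks = 2L)
  } else {
    list(n_scales = 12L, conv_channels = c(16L, 32L, 64L),
         attention_heads = 2L, n_blocks = 1L)
  }
  cfg <- list(scale_preset = scale_preset,
              n_scales = as.integer(n_scales %||% def$n_scales),
              wavelet = match.arg(wavelet, "morlet"),
              conv_channels = as.integer(conv_channels %||% def$conv_channels),
              attention_heads = as.integer(attention_heads %||% def$attention_heads),
              n_blocks = as.integer(n_blocks %||% def$n_blocks),
              d_anchor = as.integer(d_anchor), out_axes = as.integer(out_axes),
              in_channels = as.integer(in_channels))
  structure(cfg, class = "teacher_config")
}

#' Student model configuration
#'
#' @param scale_preset `"paper"` (2-layer GRU, hidden 128) or `"test"`.
#' @param rnn_hidden GRU hidden width.
#' @param rnn_layers GRU layer count.
#' @param d_anchor Anchor width, must equal the teacher's.
#' @param out_axes Torque components per joint.
#' @param in_channels IMU channels.
#' @return List of class `student_config`.
#' @export
student_config <- function(scale_preset = c("test", "paper"),
                           rnn_hidden = NULL, rnn_layers = NULL,
                           d_anchor = 64L, out_axes = 3L, in_channels = 6L) {
  scale_preset <- match.arg(scale_preset)
  def <- if (scale_preset == "paper") list(rnn_hidden = 128L, rnn_layers = 2L)
         else list(rnn_hidden = 10L, rnn_layers = 1L)
  structure(list(scale_preset = scale_preset,
                 rnn_hidden = as.integer(rnn_hidden %||% def$rnn_hidden),
                 rnn_layers = as.integer(rnn_layers %||% def$rnn_layers),
                 d_anchor = as.integer(d_anchor),
                 out_axes = as.integer(out_axes),
                 in_channels = as.integer(in_channels)),
            class = "student_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- continuous wavelet transform ----------------------------------------

MORLET_W0 <- 6

#' Morlet CWT scalogram of an IMU cycle
#'
#' Per-channel magnitude of an analytic Morlet continuous wavelet transform
#' on log-spaced scales, computed in the frequency domain. This is the 2D
#' time-frequency representation the teacher consumes.
#'
#' @param x IMU cycle, (C x T) matrix (channels x time).
#' @param n_scales Number of scales.
#' @param dt Sample interval in seconds.
#' @return List of class `scalogram` with `tensor` (C x n_scales x T) and
#'   `scales`.
#' @export
cwt_scalogram <- function(x, n_scales = 12L, dt = 0.011) {
  x <- as.matrix(x)
  C <- nrow(x); Tn <- ncol(x)
  if (Tn < 16L) stop("cycle too short for CWT: T = ", Tn, " < 16")
  s_min <- 2 * dt
  s_max <- Tn * dt / 4
  scales <- exp(seq(log(s_min), log(s_max), length.out = n_scales))
  if (2 * max(scales) > Tn * dt) {
    stop(sprintf("largest CWT scale %.4g s does not fit a %d-sample cycle",
                 max(scales), Tn))
  }
  wk <- 2 * pi * c(0:floor(Tn / 2), -(ceiling(Tn / 2) - 1):-1) / (Tn * dt)
  tens <- array(0, c(C, n_scales, Tn))
  for (ci in seq_len(C)) {
    xh <- stats::fft(x[ci, ])
    for (si in seq_len(n_scales)) {
      s <- scales[si]
      psi <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
        exp(-(s * wk - MORLET_W0)^2 / 2) * (wk > 0)
      w <- stats::fft(xh * psi, inverse = TRUE) / Tn
      tens[ci, si, ] <- Mod(w)
    }
  }
  structure(list(tensor = tens, scales = scales, dt = dt),
            class = "scalogram")
}

# approximate center frequency (Hz) of each Morlet scale
scale_frequencies <- function(scales) {
  (MORLET_W0 + sqrt(2 + MORLET_W0^2)) / (4 * pi * scales)
}

# --- teacher --------------------------------------------------------------

#' Instantiate a teacher model
#'
#' CWT scalogram -> conv blocks (3x3, ReLU, scale pooling) -> scale
#' average -> attention/FFN blocks over time -> per-timestep anchor
#' projection `WT` -> linear torque head. All weight-init randomness is
#' drawn from `seed`.
#'
#' @param cfg A [teacher_config].
#' @param seed Integer seed for weight initialization.
#' @return List of class `gaitkd_teacher`.
#' @export
teacher_model <- function(cfg = teacher_config(), seed = 1L) {
  set.seed(seed)
  ch <- c(cfg$in_channels, cfg$conv_channels)
  convs <- lapply(seq_along(cfg$conv_channels), function(i) {
    list(W = glorot(ch[i] * 9L, ch[i + 1L], shape = c(ch[i + 1L], ch[i] * 9L)),
         b = numeric(ch[i + 1L]))
  })
  d <- utils::tail(cfg$conv_channels, 1L)
  blocks <- lapply(seq_len(cfg$n_blocks), function(i)
    attn_block_init(d, cfg$attention_heads))
  params <- list(convs = convs, blocks = blocks,
                 Wt = glorot(d, cfg$d_anchor),
                 head = list(W = glorot(cfg$d_anchor, cfg$out_axes),
                             b = numeric(cfg$out_axes)))
  structure(list(params = params, config = cfg, seed = seed,
                 anchor_dim = cfg$d_anchor, norm = NULL),
            class = "gaitkd_teacher")
}

#' @export
print.gaitkd_teacher <- function(x, ...) {
  cat(sprintf("<gaitkd_teacher preset=%s params=%s d_anchor=%d>\n",
              x$config$scale_preset,
              format(count_parameters(x), big.mark = ","), x$anchor_dim))
  invisible(x)
}

# number of scale-pooling halvings leaves at least one scale row
teacher_scales_after <- function(n_scales, n_conv) {
  s <- n_scales
  for (i in seq_len(n_conv)) s <- max(1L, s %/% 2L)
  s
}

apply_norm4 <- function(x4, norm) {
  if (is.null(norm)) return(x4)
  (x4 - c(norm$mu)) / c(norm$sd)
}

#' Teacher forward pass
#'
#' @param model A [teacher_model].
#' @param x4 Scalogram batch, array (C x S x T x B).
#' @param want_cache Keep caches for backprop.
#' @return List with `tau` (B x T x out_axes), `z` (B x d_anchor, pooled
#'   anchor activation), `wt` ([anchor_weights]), and `cache` when
#'   requested.
#' @export
teacher_forward <- function(model, x4, want_cache = FALSE) {
  cfg <- model$config
  d <- dim(x4)
  if (d[1] != cfg$in_channels || d[2] != cfg$n_scales) {
    stop(sprintf("scalogram shape (%d ch x %d scales) does not match config (%d x %d)",
                 d[1], d[2], cfg$in_channels, cfg$n_scales))
  }
  x4 <- apply_norm4(x4, model$norm)
  caches <- list()
  h <- x4
  for (i in seq_along(model$params$convs)) {
    cv <- conv2d_fwd(h, model$params$convs[[i]]$W, model$params$convs[[i]]$b)
    rl <- relu_fwd(cv$out)
    if (dim(rl$out)[2] >= 2L) {
      pl <- scalepool_fwd(rl$out)
    } else {
      pl <- list(out = rl$out, cache = NULL)
    }
    caches[[i]] <- list(cv = cv, rl = rl, pl = pl)
    h <- pl$out
  }
  sm <- scalemean_fwd(h)
  H <- sm$out                               # (B, T, d)
  bl_caches <- list()
  for (i in seq_along(model$params$blocks)) {
    bf <- attn_block_fwd(H, model$params$blocks[[i]], cfg$attention_heads)
    bl_caches[[i]] <- bf$cache
    H <- bf$out
  }
  B <- dim(H)[1]; Tn <- dim(H)[2]; dm <- dim(H)[3]
  Hm <- matrix(H, B * Tn, dm)
  Z <- Hm %*% model$params$Wt               # (B*T, d_anchor)
  hd <- lin_fwd(Z, model$params$head$W, model$params$head$b)
  tau <- array(hd$out, c(B, Tn, cfg$out_axes))
  zbar <- matrix(0, B, cfg$d_anchor)
  Za <- array(Z, c(B, Tn, cfg$d_anchor))
  for (b in seq_len(B)) zbar[b, ] <- colMeans(matrix(Za[b, , ], Tn, cfg$d_anchor))
  out <- list(tau = tau, z = zbar,
              wt = anchor_weights(model$params$Wt, "teacher"))
  if (want_cache) {
    out$cache <- list(convs = caches, sm = sm, blocks = bl_caches,
                      Hm = Hm, Z = Z, hd = hd, dims = c(B, Tn, dm))
  }
  out
}

# Backward pass from dtau (B x T x A); returns full parameter gradient tree.
teacher_backward <- function(model, fwd, dtau) {
  cfg <- model$config
  dims <- fwd$cache$dims; B <- dims[1]; Tn <- dims[2]; dm <- dims[3]
  dtau_m <- matrix(dtau, B * Tn, cfg$out_axes)
  hb <- lin_bwd(dtau_m, fwd$cache$hd$cache, model$params$head$W)
  dZ <- hb$dx
  dWt <- crossprod(fwd$cache$Hm, dZ)
  dHm <- dZ %*% t(model$params$Wt)
  dH <- array(dHm, c(B, Tn, dm))
  g_blocks <- vector("list", length(model$params$blocks))
  for (i in rev(seq_along(model$params$blocks))) {
    bb <- attn_block_bwd(dH, fwd$cache$blocks[[i]], model$params$blocks[[i]],
                         cfg$attention_heads)
    g_blocks[[i]] <- bb$grads
    dH <- bb$dx
  }
  dx4 <- scalemean_bwd(dH, fwd$cache$sm$cache)
  g_convs <- vector("list", length(model$params$convs))
  for (i in rev(seq_along(model$params$convs))) {
    cc <- fwd$cache$convs[[i]]
    if (!is.null(cc$pl$cache)) dx4 <- scalepool_bwd(dx4, cc$pl$cache)
    dx4 <- relu_bwd(dx4, cc$rl$cache)
    cb <- conv2d_bwd(dx4, cc$cv$cache, model$params$convs[[i]]$W)
    g_convs[[i]] <- list(W = cb$dW, b = cb$db)
    dx4 <- cb$dx
  }
  list(convs = g_convs, blocks = g_blocks, Wt = dWt,
       head = list(W = hb$dW, b = hb$db))
}

# Per-sample gradient of the data loss wrt the anchor activation, aggregated
# over time (the anchor vector z is the time-pooled activation; perturbing
# dimension k uniformly across time has gradient sum_t dL/dZ[t, k]).
teacher_anchor_grad <- function(model, x, tau) {
  if (is.function(model$anchor_grad)) return(model$anchor_grad(x, tau))
  fwd <- teacher_forward(model, x, want_cache = TRUE)
  B <- dim(tau)[1]; Tn <- dim(tau)[2]; A <- dim(tau)[3]
  dtau <- 2 * (fwd$tau - tau) / (B * Tn)    # gradient of data_loss
  dtau_m <- matrix(dtau, B * Tn, A)
  dZ <- dtau_m %*% t(model$params$head$W)   # (B*T, d_anchor)
  dZa <- array(dZ, c(B, Tn, model$anchor_dim))
  gz <- matrix(0, B, model$anchor_dim)
  for (b in seq_len(B)) {
    gz[b, ] <- colSums(matrix(dZa[b, , ], Tn, model$anchor_dim))
  }
  gz
}

# --- student --------------------------------------------------------------

#' Instantiate a student model
#'
#' Raw 1D IMU cycle -> (stacked) GRU -> per-timestep linear dimensional
#' adapter `WS` into the anchor space -> linear torque head. `WS` has shape
#' (rnn_hidden x d_anchor) and is the alignment target.
#'
#' @param cfg A [student_config].
#' @param seed Integer seed for weight initialization.
#' @return List of class `gaitkd_student`.
#' @export
student_model <- function(cfg = student_config(), seed = 1L) {
  set.seed(seed + 1L)
  dims <- c(cfg$in_channels, rep(cfg$rnn_hidden, cfg$rnn_layers))
  grus <- lapply(seq_len(cfg$rnn_layers), function(i)
    gru_layer_init(dims[i], dims[i + 1L]))
  params <- list(grus = grus,
                 Ws = glorot(cfg$rnn_hidden, cfg$d_anchor),
                 head = list(W = glorot(cfg$d_anchor, cfg$out_axes),
                             b = numeric(cfg$out_axes)))
  structure(list(params = params, config = cfg, seed = seed,
                 anchor_dim = cfg$d_anchor, norm = NULL,
                 physics = NULL),
            class = "gaitkd_student")
}

#' @export
print.gaitkd_student <- function(x, ...) {
  cat(sprintf("<gaitkd_student preset=%s params=%s d_anchor=%d>\n",
              x$config$scale_preset,
              format(count_parameters(x), big.mark = ","), x$anchor_dim))
  invisible(x)
}

apply_norm3 <- function(x, norm) {
  # x: (B, C, T); norm per channel
  if (is.null(norm)) return(x)
  for (ci in seq_len(dim(x)[2])) {
    x[, ci, ] <- (x[, ci, ] - norm$mu[ci]) / norm$sd[ci]
  }
  x
}

#' Student forward pass
#'
#' @param model A [student_model].
#' @param x Raw IMU batch, array (B x C x T).
#' @param want_cache Keep caches for backprop.
#' @return List with `tau` (B x T x out_axes), `z` (B x d_anchor, final
#'   timestep anchor activation), `ws` ([anchor_weights]), and `cache`.
#' @export
student_forward <- function(model, x, want_cache = FALSE) {
  cfg <- model$config
  if (dim(x)[2] != cfg$in_channels) {
    stop(sprintf("input has %d channels; student was configured for %d",
                 dim(x)[2], cfg$in_channels))
  }
  x <- apply_norm3(x, model$norm)
  h <- aperm(x, c(1, 3, 2))                 # (B, T, C)
  gru_caches <- list()
  for (i in seq_along(model$params$grus)) {
    gf <- gru_layer_fwd(h, model$params$grus[[i]])
    gru_caches[[i]] <- list(cache = gf$cache, in_dim = dim(h)[3])
    h <- gf$out
  }
  B <- dim(h)[1]; Tn <- dim(h)[2]
  Hm <- matrix(h, B * Tn, cfg$rnn_hidden)
  Z <- Hm %*% model$params$Ws
  hd <- lin_fwd(Z, model$params$head$W, model$params$head$b)
  tau <- array(hd$out, c(B, Tn, cfg$out_axes))
  Za <- array(Z, c(B, Tn, cfg$d_anchor))
  zT <- matrix(Za[, Tn, ], B, cfg$d_anchor)
  out <- list(tau = tau, z = zT, ws = anchor_weights(model$params$Ws, "student"))
  if (want_cache) {
    out$cache <- list(grus = gru_caches, Hm = Hm, Z = Z, hd = hd,
                      dims = c(B, Tn, cfg$rnn_hidden))
  }
  out
}

# Backward from dtau; optional extra gradient on Ws (alignment losses).
student_backward <- function(model, fwd, dtau, dWs_extra = NULL) {
  cfg <- model$config
  dims <- fwd$cache$dims; B <- dims[1]; Tn <- dims[2]
  dtau_m <- matrix(dtau, B * Tn, cfg$out_axes)
  hb <- lin_bwd(dtau_m, fwd$cache$hd$cache, model$params$head$W)
  dZ <- hb$dx
  dWs <- crossprod(fwd$cache$Hm, dZ)
  if (!is.null(dWs_extra)) dWs <- dWs + dWs_extra
  dHm <- dZ %*% t(model$params$Ws)
  dH <- array(dHm, c(B, Tn, cfg$rnn_hidden))
  g_grus <- vector("list", length(model$params$grus))
  for (i in rev(seq_along(model$params$grus))) {
    gb <- gru_layer_bwd(dH, fwd$cache$grus[[i]]$cache, model$params$grus[[i]],
                        fwd$cache$grus[[i]]$in_dim)
    g_grus[[i]] <- gb$grads
    dH <- gb$dx
  }
  list(grus = g_grus, Ws = dWs, head = list(W = hb$dW, b = hb$db))
}
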