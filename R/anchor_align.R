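#' Anchor-space weight matrix
#'
#' Wraps the projection weights that map a network's backbone features into
#' the shared anchor space: the teacher's projection layer and the student's
#' linear dimensional adapter both land in the same `d_anchor`-dimensional
#' space, which is what makes their otherwise incomparable weight matrices
#' geometrically comparable.
#'
#' @param matrix Numeric matrix of shape (d_in x d_anchor).
#' @param origin Either `"teacher"` or `"student"`.
#' @return An object of class `anchor_weights`.
#' @export
anchor_weights <- function(matrix, origin = c("teacher", "student")) {
  origin <- match.arg(origin)
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix) || !all(is.finite(matrix))) {
    stop("anchor weights for origin '", origin, "' contain non-finite entries")
  }
  structure(
    list(matrix = matrix, origin = origin,
         d_in = nrow(matrix), d_anchor = ncol(matrix)),
    class = "anchor_weights"
  )
}

#' @export
print.anchor_weights <- function(x, ...) {
  cat(sprintf("<anchor_weights origin=%s d_in=%d d_anchor=%d>\n",
              x$origin, x$d_in, x$d_anchor))
  invisible(x)
}

as_anchor_matrix <- function(w, origin = "student") {
  if (inherits(w, "anchor_weights")) return(w$matrix)
  anchor_weights(w, origin)$matrix
}

#' Gram matrix of anchor weights
#'
#' Computes G = W'W, the second-order correlation structure of the columns of
#' an anchor-space weight matrix. Weight matrices of different input
#' dimension map to Gram matrices of identical shape
#' (d_anchor x d_anchor), giving teacher and student a common metric space.
#'
#' @param w An [anchor_weights] object or a plain numeric matrix.
#' @return A symmetric positive semidefinite matrix of class `gram_matrix`.
#' @export
gram <- function(w) {
  origin <- if (inherits(w, "anchor_weights")) w$origin else "student"
  m <- as_anchor_matrix(w, origin)
  g <- crossprod(m)
  g <- (g + t(g)) / 2  # exact symmetry against rounding
  structure(g, class = c("gram_matrix", "matrix"))
}

check_gram_pair <- function(gs, gt) {
  gs <- unclass(gs); gt <- unclass(gt)
  if (!identical(dim(gs), dim(gt))) {
    stop(sprintf("Gram matrix shape mismatch: student %dx%d vs teacher %dx%d",
                 nrow(gs), ncol(gs), nrow(gt), ncol(gt)))
  }
  list(gs = gs, gt = gt)
}

#' Unweighted Gram alignment loss
#'
#' Squared Frobenius distance between the student and teacher Gram matrices.
#' In training this quantity is a diagnostic: the optimized objective uses
#' the Fisher-weighted and subspace-projected variants, which reduce to this
#' loss for unit weights / identity projector.
#'
#' @param gs,gt Gram matrices of equal shape (student, teacher).
#' @return Nonnegative scalar.
#' @export
align_loss <- function(gs, gt) {
  p <- check_gram_pair(gs, gt)
  sum((p$gs - p$gt)^2)
}

#' Fisher-weighted alignment loss
#'
#' Sum over anchor dimensions k of `f[k] * ||gs[k, ] - gt[k, ]||^2`: each
#' row discrepancy is weighted by the teacher's Fisher information for that
#' anchor dimension, so alignment concentrates on directions the task loss
#' is actually sensitive to. Gram matrices are symmetric, so the row/column
#' reading is equivalent; rows are used.
#'
#' @param gs,gt Gram matrices of equal shape.
#' @param f A [fisher_weights] object or nonnegative numeric vector of
#'   length `d_anchor`.
#' @return Nonnegative scalar.
#' @export
fisher_align_loss <- function(gs, gt, f) {
  p <- check_gram_pair(gs, gt)
  fv <- if (inherits(f, "fisher_weights")) f$diag else as.numeric(f)
  if (length(fv) != nrow(p$gs)) {
    stop(sprintf("Fisher weight length %d does not match anchor dimension %d",
                 length(fv), nrow(p$gs)))
  }
  d <- p$gs - p$gt
  sum(fv * rowSums(d^2))
}

#' Diagonal Fisher information of the teacher anchor activation
#'
#' Estimates `F[k] = E[(dL/dz_k)^2]` over a stream of batches, where `z` is
#' the teacher's anchor-space activation and `L` the task loss on its torque
#' prediction. The expectation is empirical: per-sample squared gradients
#' averaged over every sample seen. Computed once from the frozen teacher
#' and held fixed for the whole student run.
#'
#' @param teacher A trained teacher model (see [teacher_model]).
#' @param batches List of batches; each batch is a list with elements `x`
#'   (input array) and `tau` (target torque array).
#' @param loss_kind Currently `"mse"` (the data-fitting loss).
#' @return An object of class `fisher_weights` with fields `diag` and
#'   `n_samples`.
#' @export
estimate_fisher_diag <- function(teacher, batches, loss_kind = "mse") {
  if (is.null(teacher$anchor_dim)) {
    stop("model does not expose an anchor head; cannot estimate Fisher weights")
  }
  if (length(batches) == 0L) stop("empty batch stream for Fisher estimation")
  loss_kind <- match.arg(loss_kind, "mse")
  acc <- numeric(teacher$anchor_dim)
  n <- 0L
  for (b in batches) {
    gz <- teacher_anchor_grad(teacher, b$x, b$tau)  # (B x d_anchor)
    acc <- acc + colSums(gz^2)
    n <- n + nrow(gz)
  }
  fisher_weights(acc / n, n_samples = n)
}

#' Construct fixed Fisher weights
#'
#' @param diag Nonnegative numeric vector, one entry per anchor dimension.
#' @param n_samples Number of samples the expectation was taken over.
#' @param normalize If `TRUE`, rescale to unit mean. Raw values are the
#'   default.
#' @return Object of class `fisher_weights`.
#' @export
fisher_weights <- function(diag, n_samples = NA_integer_, normalize = FALSE) {
  diag <- as.numeric(diag)
  if (any(!is.finite(diag)) || any(diag < 0)) {
    stop("Fisher weights must be finite and nonnegative")
  }
  if (normalize && mean(diag) > 0) diag <- diag / mean(diag)
  structure(list(diag = diag, n_samples = n_samples),
            class = "fisher_weights")
}

#' Principal-subspace projector of the teacher Gram matrix
#'
#' Eigendecomposes the (symmetric PSD) teacher Gram matrix and keeps the
#' top-`k` eigenvectors `U_k`; the returned projector is `P = U_k U_k'`.
#' Determinism: each eigenvector's sign is fixed so its largest-magnitude
#' component is positive; degenerate eigenvalues keep the decomposition's
#' index order.
#'
#' @param gt Teacher Gram matrix.
#' @param k Rank. Either a positive integer, or `NULL` to pick the smallest
#'   k capturing at least `energy` of the eigenvalue mass, capped at
#'   `d_anchor / 2`.
#' @param energy Eigenvalue-mass fraction used when `k` is `NULL`
#'   (default 0.95).
#' @return Object of class `subspace_projector` with fields `basis`, `rank`,
#'   `projector`.
#' @export
principal_projector <- function(gt, k = NULL, energy = 0.95) {
  g <- unclass(as.matrix(gt))
  d <- nrow(g)
  eg <- eigen((g + t(g)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (is.null(k)) {
    tot <- sum(ev)
    k <- if (tot <= 0) 1L else which(cumsum(ev) / tot >= energy)[1L]
    k <- min(k, max(1L, floor(d / 2)))
  }
  k <- as.integer(k)
  if (k < 1L || k > d) {
    stop(sprintf("subspace rank k=%d out of range [1, %d]", k, d))
  }
  u <- eg$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-|.| component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  p <- tcrossprod(u)
  structure(list(basis = u, rank = k, projector = (p + t(p)) / 2,
                 eigenvalues = eg$values),
            class = "subspace_projector")
}

#' @export
print.subspace_projector <- function(x, ...) {
  cat(sprintf("<subspace_projector rank=%d of %d>\n",
              x$rank, nrow(x$projector)))
  invisible(x)
}

#' Principal-subspace alignment loss
#'
#' Squared Frobenius norm of the Gram discrepancy after projection onto the
#' teacher's principal subspace: `||P gs - P gt||_F^2`. Restricting the
#' alignment to dominant directions suppresses noise components of the
#' student's parameter updates.
#'
#' @param gs,gt Gram matrices of equal shape.
#' @param p A [subspace_projector] (or a plain projector matrix).
#' @return Nonnegative scalar, never exceeding [align_loss] for an
#'   orthogonal projector.
#' @export
subspace_loss <- function(gs, gt, p) {
  pr <- if (inherits(p, "subspace_projector")) p$projector else as.matrix(p)
  pair <- check_gram_pair(gs, gt)
  if (nrow(pr) != nrow(pair$gs)) {
    stop(sprintf("projector dimension %d does not match Gram dimension %d",
                 nrow(pr), nrow(pair$gs)))
  }
  sum((pr %*% (pair$gs - pair$gt))^2)
}

# Gradients of the alignment losses with respect to the student adapter WS.
# For L(G) with G = W'W, dL/dW = W (D + D') where D = dL/dG elementwise.
align_grads_ws <- function(ws, gt, f = NULL, p = NULL) {
  gs <- unclass(gram(anchor_weights(ws, "student")))
  gt <- unclass(as.matrix(gt))
  d <- gs - gt
  out <- list()
  if (!is.null(f)) {
    fv <- if (inherits(f, "fisher_weights")) f$diag else as.numeric(f)
    df <- 2 * fv * d            # row-scaled
    out$fisher <- ws %*% (df + t(df))
  }
  if (!is.null(p)) {
    pr <- if (inherits(p, "subspace_projector")) p$projector else as.matrix(p)
    dp <- 2 * (pr %*% pr) %*% d # P idempotent -> equals 2 P d
    out$subspace <- ws %*% (dp + t(dp))
  }
  out
}
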