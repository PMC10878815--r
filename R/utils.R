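`%||%` <- function(a, b) if (is.null(a)) b else a

## interleaved flattening: (x1, y1, z1, x2, y2, z2, ...) so that a block of m
## landmarks occupies 3m contiguous columns
flatten_config <- function(points) {
  as.vector(t(points))
}

unflatten_config <- function(v) {
  matrix(v, ncol = 3L, byrow = TRUE)
}

## n x 3k matrix from a k x 3 x n array
flatten_array <- function(arr) {
  n <- dim(arr)[3L]
  out <- t(apply(arr, 3L, flatten_config))
  rownames(out) <- dimnames(arr)[[3L]]
  out
}

## columns of the flattened matrix belonging to landmark indices `idx`
coord_columns <- function(idx) {
  as.vector(t(outer(3L * (idx - 1L), 1:3, `+`)))
}

## uniform random rotation in SO(3)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9L), 3L, 3L))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 3L] <- -R[, 3L]
  R
}

## one Dirichlet draw via independent gammas
rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

## round a probability vector to multiples of `unit` summing to `total`
## (largest-remainder correction)
largest_remainder_round <- function(p, total = 100L, unit = 10L) {
  slots <- total / unit
  raw <- p / sum(p) * slots
  base <- floor(raw)
  short <- slots - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1L
  }
  as.integer(base * unit)
}

## symmetric inverse square root of a positive-definite matrix
mat_inv_sqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  tol <- max(e$values) * 1e-12
  if (any(e$values < tol)) {
    stop("covariance matrix is not positive definite")
  }
  P <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  dimnames(P) <- dimnames(C)
  P
}

## derive a fresh sub-seed so nested generators do not reuse streams
## (computed in doubles: the product stays well below 2^53)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(offset)) %% 2147483562)
}
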