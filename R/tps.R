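## 3-D thin-plate-spline machinery.
##
## Kernel U(r) = -r (the 3-D biharmonic radial basis, conditionally positive
## definite of order 1), so the bending energy quadratic form is positive
## semi-definite with the affine maps as its kernel.

tps_kernel_matrix <- function(ref) {
  -as.matrix(dist(ref))
}

tps_system <- function(ref) {
  k <- nrow(ref)
  K <- tps_kernel_matrix(ref)
  Q <- cbind(1, ref)
  rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4L, 4L)))
}

#' Bending-energy matrix of a reference configuration
#'
#' The k x k matrix `Be` such that the thin-plate-spline bending energy of a
#' deformation taking the reference to a target is
#' `sum_d t(target[, d]) %*% Be %*% target[, d]`. Affine deformations have
#' zero energy. A singular system is ridge-regularized (1e-8 on the
#' diagonal) with a warning.
#'
#' @param ref k x 3 reference configuration.
#' @return a symmetric positive semi-definite k x k matrix.
#' @export
bending_energy_matrix <- function(ref) {
  L <- tps_system(ref)
  k <- nrow(ref)
  Linv <- tryCatch(solve(L), error = function(e) {
    warning("singular bending-energy system; ridge-regularizing",
      call. = FALSE
    )
    solve(L + diag(1e-8, nrow(L)))
  })
  Be <- Linv[seq_len(k), seq_len(k)]
  (Be + t(Be)) / 2
}

#' Thin-plate-spline bending energy of a deformation
#'
#' @param ref k x 3 reference configuration (or a precomputed
#'   bending-energy matrix via `be`).
#' @param target k x 3 deformed configuration.
#' @param be optional precomputed [bending_energy_matrix()] of `ref`.
#' @return non-negative scalar; zero iff the deformation is affine.
#' @export
tps_bending_energy <- function(ref, target, be = NULL) {
  if (is.null(be)) be <- bending_energy_matrix(ref)
  d <- target - ref
  sum(vapply(1:3, function(j) drop(crossprod(d[, j], be %*% d[, j])), 0))
}

#' Thin-plate-spline interpolation map
#'
#' Builds the 3-D thin-plate-spline deformation carrying `ref` exactly onto
#' `target`, returned as a function applicable to any auxiliary point set
#' (e.g. mesh vertices riding along a landmark warp).
#'
#' @param ref k x 3 reference landmarks.
#' @param target k x 3 target landmarks.
#' @return a function mapping an m x 3 matrix to its deformed m x 3 image.
#' @export
tps_map <- function(ref, target) {
  L <- tps_system(ref)
  rhs <- rbind(target, matrix(0, 4L, 3L))
  coefs <- tryCatch(solve(L, rhs), error = function(e) {
    warning("singular TPS system; ridge-regularizing", call. = FALSE)
    solve(L + diag(1e-8, nrow(L)), rhs)
  })
  k <- nrow(ref)
  W <- coefs[seq_len(k), , drop = FALSE]
  A <- coefs[k + 1:4, , drop = FALSE]
  force(ref)
  function(points) {
    points <- rbind(points)
    d2 <- outer(rowSums(points^2), rowSums(ref^2), `+`) -
      2 * tcrossprod(points, ref)
    U <- -sqrt(pmax(d2, 0))
    cbind(1, points) %*% A + U %*% W
  }
}
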