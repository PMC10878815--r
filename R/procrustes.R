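#' Resample a polyline to evenly spaced points
#'
#' Places `n_out` points on a piecewise-linear 3-D path at equal arc-length
#' spacing, preserving both endpoints. This is how digitized curve
#' semi-landmark runs of arbitrary length are brought to the equal counts a
#' template requires.
#'
#' @param points ordered m x 3 matrix defining the polyline (m >= 2).
#' @param n_out number of output points (>= 2).
#' @return an n_out x 3 matrix of points on the input path.
#' @export
resample_curve <- function(points, n_out) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("polyline needs at least 2 points")
  if (n_out < 2L) stop("n_out must be at least 2")
  seg <- diff(points)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  if (total <= 0) stop("zero-length polyline cannot be resampled")
  cum <- c(0, cumsum(seg_len))
  target <- total * (seq_len(n_out) - 1) / (n_out - 1)
  out <- matrix(0, n_out, 3L)
  out[1L, ] <- points[1L, ]
  out[n_out, ] <- points[nrow(points), ]
  j <- 1L
  for (i in seq(2L, n_out - 1L)) {
    s <- target[i]
    while (cum[j + 1L] < s && j < length(seg_len)) j <- j + 1L
    f <- if (seg_len[j] > 0) (s - cum[j]) / seg_len[j] else 0
    out[i, ] <- points[j, ] + f * seg[j, ]
  }
  out
}

#' Centroid size of a configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of all points from their centroid. Homogeneous
#' of degree one in scale and invariant to translation and rotation.
#'
#' @param points k x 3 matrix.
#' @return a positive scalar.
#' @export
centroid_size <- function(points) {
  if (!all(is.finite(points))) stop("non-finite coordinates")
  centered <- sweep(points, 2L, colMeans(points))
  cs <- sqrt(sum(centered^2))
  if (cs <= 0) stop("degenerate configuration: all points coincident")
  cs
}

## optimal rotation (no reflection) of centered X onto centered ref:
## maximizes tr(R' X' ref) over R in SO(3)
optimal_rotation <- function(X, ref) {
  M <- crossprod(X, ref)
  sv <- svd(M)
  s <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
}

## deterministic orientation: principal axes of the consensus with positive
## largest-magnitude loadings and det +1, so GPA output does not depend on
## the arbitrary orientation of the input configurations
canonical_orientation <- function(consensus) {
  e <- eigen(crossprod(consensus), symmetric = TRUE)
  V <- e$vectors
  ## sign convention from the rotated data (orientation-independent):
  ## along each of the first two axes, the largest-magnitude projected
  ## coordinate is positive; the third axis completes a right-handed frame
  for (j in 1:2) {
    cj <- consensus %*% V[, j]
    if (cj[which.max(abs(cj))] < 0) V[, j] <- -V[, j]
  }
  V[, 3L] <- c(
    V[2L, 1L] * V[3L, 2L] - V[3L, 1L] * V[2L, 2L],
    V[3L, 1L] * V[1L, 2L] - V[1L, 1L] * V[3L, 2L],
    V[1L, 1L] * V[2L, 2L] - V[2L, 1L] * V[1L, 2L]
  )
  V
}

#' Generalized Procrustes analysis
#'
#' Partial-Procrustes superimposition of a set of configurations: each is
#' translated to the origin, scaled to unit centroid size, and rotated onto
#' the running consensus by the optimal orthogonal rotation (determinant +1,
#' reflections disallowed); the consensus is recomputed and the cycle
#' iterated until it moves less than `tol` (or `max_iter` is reached, with a
#' warning and a `converged = FALSE` flag). With `slide = TRUE`, rounds of
#' minimum-bending-energy sliding of curve and surface semi-landmarks
#' ([slide_semilandmarks()]) are interleaved with re-superimposition.
#' The final alignment is rotated to a deterministic principal-axis
#' orientation, so the output is invariant to arbitrary similarity
#' transforms of the inputs. Centroid sizes are recorded before scaling.
#'
#' @param configs named list of k x 3 configurations.
#' @param slide logical; slide semi-landmarks by minimum bending energy.
#' @param template `landmark_template`; required when `slide = TRUE`.
#' @param slide_rounds number of outer sliding rounds (default 5).
#' @param tol convergence tolerance on the superimposition objective.
#' @param max_iter iteration cap for the superimposition loop.
#' @return an object of class `aligned_shapes`: list with `coords`
#'   (k x 3 x n array), `species`, `centroid_size`, `consensus`,
#'   `converged`, and diagnostic histories (`q_history`; with sliding also
#'   `be_history`, mean bending energy to the consensus before and after
#'   each sliding round).
#' @export
gpa <- function(configs, slide = FALSE, template = NULL,
                slide_rounds = 5L, tol = 1e-8, max_iter = 100L) {
  n <- length(configs)
  if (n < 2L) stop("need at least 2 configurations")
  if (slide && is.null(template)) stop("sliding requires a template")
  species <- names(configs) %||% paste0("specimen_", seq_len(n))
  k <- nrow(configs[[1L]])

  sizes <- numeric(n)
  arr <- array(0, dim = c(k, 3L, n), dimnames = list(NULL, NULL, species))
  for (i in seq_len(n)) {
    pts <- as.matrix(configs[[i]])
    if (nrow(pts) != k) stop("configurations differ in point count")
    centered <- sweep(pts, 2L, colMeans(pts))
    sizes[i] <- sqrt(sum(centered^2))
    if (sizes[i] <= 0) stop("degenerate configuration '", species[i], "'")
    arr[, , i] <- centered / sizes[i]
  }

  fit <- superimpose(arr, tol = tol, max_iter = max_iter)
  arr <- fit$arr
  consensus <- fit$consensus
  q_history <- fit$q_history
  be_history <- NULL

  if (slide) {
    be_history <- matrix(
      NA_real_, slide_rounds, 2L,
      dimnames = list(NULL, c("before", "after"))
    )
    for (round in seq_len(slide_rounds)) {
      slid <- slide_round(arr, consensus, template)
      be_history[round, ] <- c(slid$be_before, slid$be_after)
      arr <- slid$arr
      ## sliding perturbs centring/scale slightly; re-normalize and re-fit
      for (i in seq_len(n)) {
        centered <- sweep(arr[, , i], 2L, colMeans(arr[, , i]))
        arr[, , i] <- centered / sqrt(sum(centered^2))
      }
      fit <- superimpose(arr, tol = tol, max_iter = max_iter)
      arr <- fit$arr
      consensus <- fit$consensus
      q_history <- c(q_history, fit$q_history)
    }
  }

  V <- canonical_orientation(consensus)
  consensus <- consensus %*% V
  for (i in seq_len(n)) arr[, , i] <- arr[, , i] %*% V

  structure(
    list(
      coords = arr,
      species = species,
      centroid_size = setNames(sizes, species),
      consensus = consensus,
      converged = fit$converged,
      q_history = q_history,
      be_history = be_history,
      template = if (slide) template else NULL
    ),
    class = "aligned_shapes"
  )
}

## inner superimposition loop on pre-centered unit-size configurations
superimpose <- function(arr, tol = 1e-8, max_iter = 100L) {
  n <- dim(arr)[3L]
  consensus <- arr[, , 1L]
  q_prev <- Inf
  q_history <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      arr[, , i] <- arr[, , i] %*% optimal_rotation(arr[, , i], consensus)
    }
    consensus <- apply(arr, c(1L, 2L), mean)
    consensus <- consensus / sqrt(sum(consensus^2))
    q <- sum(apply(arr, 3L, function(x) sum((x - consensus)^2)))
    q_history <- c(q_history, q)
    if (abs(q_prev - q) < tol) {
      converged <- TRUE
      break
    }
    q_prev <- q
  }
  if (!converged) {
    warning("Procrustes superimposition did not converge within ", max_iter,
      " iterations",
      call. = FALSE
    )
  }
  list(
    arr = arr, consensus = consensus,
    q_history = q_history, converged = converged
  )
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(
    "Aligned shapes:", length(x$species), "specimens,",
    nrow(x$consensus), "landmarks\n"
  )
  cat(
    "Centroid size range:",
    sprintf("%.4g - %.4g", min(x$centroid_size), max(x$centroid_size)), "\n"
  )
  invisible(x)
}

#' Flattened shape matrix of an aligned dataset
#'
#' The n x 3k matrix of Procrustes coordinates (columns x1, y1, z1, x2,
#' ...), rows named by species — the response matrix for
#' [pgls_procrustes_anova()] and the blocks of [phylo_two_block_pls()].
#'
#' @param aligned an `aligned_shapes` object.
#' @return an n x 3k numeric matrix.
#' @export
shape_matrix <- function(aligned) {
  flatten_array(aligned$coords)
}

#' Pairwise Procrustes distance matrix
#'
#' Euclidean distances between aligned configurations in shape space:
#' entry (i, j) is the square root of the summed squared coordinate
#' differences between specimens i and j.
#'
#' @param aligned an `aligned_shapes` object.
#' @return an n x n symmetric matrix with zero diagonal.
#' @export
procrustes_distance_matrix <- function(aligned) {
  flat <- flatten_array(aligned$coords)
  as.matrix(dist(flat))
}
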