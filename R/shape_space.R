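#' Principal component analysis of aligned shapes
#'
#' Eigendecomposition (via SVD) of the covariance of the flattened
#' Procrustes coordinates, with divisor n - 1. Axes are ordered by
#' decreasing eigenvalue; the sign convention makes the largest-magnitude
#' entry of each loading vector positive.
#'
#' @param aligned an `aligned_shapes` object (n >= 3 specimens).
#' @return an object of class `shape_pca`: `eigenvalues`,
#'   `percent_variance`, `scores` (n x n_axes), `loadings` (3k x n_axes),
#'   `mean_shape` (k x 3), `center` (flattened mean).
#' @export
shape_pca <- function(aligned) {
  flat <- flatten_array(aligned$coords)
  n <- nrow(flat)
  if (n < 3L) stop("PCA needs at least 3 specimens")
  center <- colMeans(flat)
  Xc <- sweep(flat, 2L, center)
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  eig <- d^2 / (n - 1)
  scores <- U * rep(d, each = n)
  rownames(scores) <- rownames(flat)
  colnames(scores) <- colnames(V) <- paste0("PC", seq_along(eig))
  structure(
    list(
      eigenvalues = eig,
      percent_variance = 100 * eig / sum(eig),
      scores = scores,
      loadings = V,
      mean_shape = unflatten_config(center),
      center = center
    ),
    class = "shape_pca"
  )
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA:", nrow(x$scores), "specimens,", length(x$eigenvalues),
    "axes\n")
  pv <- head(x$percent_variance, 5L)
  cat(
    "Leading axes (% variance):",
    paste(sprintf("%.2f", pv), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Predict shape at a score quantile of a principal axis
#'
#' Returns the landmark configuration predicted at an empirical quantile
#' (type-7 interpolation) of the observed scores along one PC axis — the
#' mean shape displaced by the quantile score times the axis loading —
#' together with the thin-plate-spline map from the mean shape to the
#' prediction, applicable to any auxiliary point set.
#'
#' @param pca a `shape_pca` object.
#' @param axis axis index.
#' @param quantile_ score quantile in (0, 1).
#' @return list with `shape` (k x 3), `score` (the quantile score) and
#'   `tps` (function mapping m x 3 auxiliary points).
#' @export
warp_along_axis <- function(pca, axis, quantile_) {
  if (axis < 1L || axis > ncol(pca$scores)) stop("no such axis")
  if (quantile_ <= 0 || quantile_ >= 1) {
    stop("quantile must be strictly inside (0, 1)")
  }
  q <- quantile(pca$scores[, axis], probs = quantile_, type = 7, names = FALSE)
  flat <- pca$center + q * pca$loadings[, axis]
  shape <- unflatten_config(flat)
  list(
    shape = shape,
    score = q,
    tps = tps_map(pca$mean_shape, shape)
  )
}

#' Per-landmark Procrustes variance
#'
#' For each landmark, the mean squared deviation (summed over the three
#' coordinates) of its position from the consensus across specimens; used
#' to colour landmark constellations by how much shape variation each point
#' carries. Also reported log10-transformed with a floor so exactly
#' invariant landmarks stay finite.
#'
#' @param aligned an `aligned_shapes` object.
#' @param floor lower bound applied before the log10 transform.
#' @return data frame with columns `variance` and `log10_variance`; the sum
#'   of `variance` equals the total Procrustes variance around the
#'   consensus.
#' @export
per_landmark_variance <- function(aligned, floor = 1e-20) {
  dev2 <- apply(
    aligned$coords, 3L,
    function(x) rowSums((x - aligned$consensus)^2)
  )
  v <- rowMeans(dev2)
  data.frame(variance = v, log10_variance = log10(pmax(v, floor)))
}

#' Ancestral scores for a phylomorphospace
#'
#' Maximum-likelihood ancestral states under Brownian motion (equivalently,
#' weighted squared-change parsimony) for each PC axis, computed in closed
#' form from the among-node phylogenetic covariances. Polytomies are
#' handled directly.
#'
#' @param pca a `shape_pca` object whose score rows are named by species.
#' @param tree an [ape::phylo] tree with the same species as tips.
#' @param axes which axes to reconstruct (default: first three).
#' @return list with `node_scores` (internal-node estimates, rows named by
#'   node number), `tip_scores`, and `edges` (the tree edge matrix, for
#'   plotting branches through the ordination).
#' @export
phylomorphospace_scores <- function(pca, tree,
                                    axes = seq_len(min(
                                      3L, ncol(pca$scores)
                                    ))) {
  scores <- pca$scores
  if (!all(tree$tip.label %in% rownames(scores))) {
    stop("score rows do not cover the tree tips")
  }
  Y <- scores[tree$tip.label, axes, drop = FALSE]
  anc <- ancestral_states_bm(tree, Y)
  list(
    node_scores = anc,
    tip_scores = Y,
    edges = tree$edge
  )
}

## closed-form BM ancestral states: for internal node a,
##   E[x_a | tips] = mu + C_{a,tips} C_tips^{-1} (y - mu),
## with mu the GLS root state and C entries the depth of the MRCA
ancestral_states_bm <- function(tree, Y) {
  Y <- as.matrix(Y)
  n <- length(tree$tip.label)
  n_node <- tree$Nnode
  depths <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  Ct <- matrix(depths[M[seq_len(n), seq_len(n)]], n, n)
  Cinv <- solve(Ct)
  one <- rep(1, n)
  denom <- drop(crossprod(one, Cinv %*% one))
  mu <- drop(crossprod(one, Cinv %*% Y)) / denom
  resid <- sweep(Y, 2L, mu)
  internal <- n + seq_len(n_node)
  Cat <- matrix(depths[M[internal, seq_len(n), drop = FALSE]], n_node, n)
  anc <- Cat %*% (Cinv %*% resid)
  anc <- sweep(anc, 2L, mu, `+`)
  rownames(anc) <- internal
  colnames(anc) <- colnames(Y)
  anc
}
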