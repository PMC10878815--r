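test_that("shape PCA matches an SVD oracle and is rotation-faithful", {
  set.seed(31)
  al <- small_aligned()
  p <- shape_pca(al)

  ## percent variance against a direct SVD of the centred flat matrix
  flat <- quadmorph:::flatten_array(al$coords)
  Xc <- scale(flat, scale = FALSE)
  d2 <- svd(Xc)$d^2
  d2 <- d2[d2 > max(d2) * 1e-10]
  expect_equal(p$percent_variance, 100 * d2 / sum(d2), tolerance = 1e-9)
  expect_equal(sum(p$percent_variance), 100, tolerance = 1e-9)

  ## scores are centred and orthogonal
  expect_lt(max(abs(colMeans(p$scores))), 1e-12)
  g <- crossprod(p$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-9)

  ## reconstruction: mean + scores %*% t(loadings) reproduces the data
  recon <- matrix(p$center, nrow(flat), ncol(flat), byrow = TRUE) +
    p$scores %*% t(p$loadings)
  expect_equal(recon, flat, tolerance = 1e-9, ignore_attr = TRUE)

  ## distances in full score space equal Procrustes distances
  D_scores <- as.matrix(dist(p$scores))
  D_shapes <- procrustes_distance_matrix(al)
  expect_equal(D_scores, D_shapes, tolerance = 1e-9, ignore_attr = TRUE)

  ## sign convention: largest-magnitude loading entry is positive
  for (j in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("one-dimensional variation loads 100% on PC1", {
  base <- toy_curve_config()
  dir <- matrix(rnorm(length(base)), nrow(base), 3L)
  dir <- dir / sqrt(sum(dir^2))
  configs <- lapply(seq(-0.02, 0.02, length.out = 6L), function(s) base + s * dir)
  names(configs) <- paste0("s", 1:6)
  ## bypass superimposition: wrap as aligned shapes directly
  arr <- simplify2array(configs)
  al <- structure(
    list(
      coords = arr, species = names(configs),
      consensus = apply(arr, c(1, 2), mean)
    ),
    class = "aligned_shapes"
  )
  p <- shape_pca(al)
  expect_equal(p$percent_variance[1L], 100, tolerance = 1e-6)
})

test_that("axis warps interpolate through the mean and obey the TPS map", {
  al <- small_aligned()
  p <- shape_pca(al)

  ## warping the mean's own landmarks through the TPS equals the prediction
  w <- warp_along_axis(p, 1L, 0.95)
  expect_equal(w$tps(p$mean_shape), w$shape, tolerance = 1e-9, ignore_attr = TRUE)

  ## a quantile at the median of a symmetrized score set is near the mean
  scores1 <- p$scores[, 1L]
  p_sym <- p
  p_sym$scores[, 1L] <- scores1 - median(scores1)
  w_med <- warp_along_axis(p_sym, 1L, 0.5)
  expect_equal(w_med$shape, p$mean_shape, tolerance = 1e-9)

  expect_error(warp_along_axis(p, 1L, 1.2), "quantile")
  expect_error(warp_along_axis(p, 10000L, 0.5), "axis")
})

test_that("per-landmark variances partition the total Procrustes variance", {
  al <- small_aligned()
  v <- per_landmark_variance(al)
  total <- mean(apply(al$coords, 3L, function(x) sum((x - al$consensus)^2)))
  expect_equal(sum(v$variance), total, tolerance = 1e-12)

  ## doubling deviations quadruples the per-landmark variance
  al2 <- al
  for (i in seq_len(dim(al$coords)[3L])) {
    al2$coords[, , i] <- al$consensus + 2 * (al$coords[, , i] - al$consensus)
  }
  v2 <- per_landmark_variance(al2)
  expect_equal(v2$variance, 4 * v$variance, tolerance = 1e-12)

  ## an invariant landmark has zero variance and a finite log10 value
  al3 <- al
  al3$coords[1L, , ] <- al$consensus[1L, ]
  v3 <- per_landmark_variance(al3)
  expect_equal(v3$variance[1L], 0)
  expect_true(is.finite(v3$log10_variance[1L]))
})

test_that("ancestral scores follow the Brownian-motion closed forms", {
  ## two tips, equal branch lengths: root at the midpoint
  two <- ape::read.tree(text = "(A:1,B:1);")
  pca_stub <- list(scores = matrix(c(1, 3), 2L, 1L,
    dimnames = list(c("A", "B"), "PC1")
  ))
  anc <- phylomorphospace_scores(structure(pca_stub, class = "shape_pca"),
    two,
    axes = 1L
  )
  expect_equal(unname(anc$node_scores[1L, 1L]), 2)

  ## star tree: root equals the closed-form GLS mean 1'C^-1 y / 1'C^-1 1
  star <- ape::read.tree(text = "(A:1,B:2,C:4,D:1);")
  y <- c(A = 2, B = -1, C = 5, D = 0)
  C <- diag(c(1, 2, 4, 1))
  mu <- sum(solve(C) %*% y) / sum(solve(C))
  pca_stub$scores <- matrix(y, 4L, 1L, dimnames = list(names(y), "PC1"))
  anc <- phylomorphospace_scores(structure(pca_stub, class = "shape_pca"),
    star,
    axes = 1L
  )
  expect_equal(unname(anc$node_scores[1L, 1L]), mu, tolerance = 1e-12)

  ## symmetric ultrametric tree with antisymmetric scores: root at zero
  quad <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  pca_stub$scores <- matrix(c(A = -2, B = -1, C = 1, D = 2), 4L, 1L,
    dimnames = list(c("A", "B", "C", "D"), "PC1")
  )
  anc <- phylomorphospace_scores(structure(pca_stub, class = "shape_pca"),
    quad,
    axes = 1L
  )
  expect_equal(unname(anc$node_scores["5", 1L]), 0, tolerance = 1e-12)

  ## general tree: agrees with the phytools ML reconstruction
  set.seed(41)
  tree <- ape::rphylo(12L, 0.3, 0)
  yv <- bm_block(tree_covariance(tree), 1L)[, 1L]
  names(yv) <- tree$tip.label
  pca_stub$scores <- matrix(yv, dimnames = list(names(yv), "PC1"))
  anc <- phylomorphospace_scores(structure(pca_stub, class = "shape_pca"),
    tree,
    axes = 1L
  )
  ref <- phytools::fastAnc(tree, yv)
  expect_equal(anc$node_scores[names(ref), 1L], unclass(ref),
    tolerance = 1e-6, ignore_attr = TRUE
  )
})
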