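test_that("region blocks partition the full coordinate matrix", {
  ds <- small_dataset()
  al <- small_aligned()
  tmpl <- ds$template
  flat <- quadmorph:::flatten_array(al$coords)
  regions <- unique(tmpl$region_map)
  blocks <- lapply(regions, subset_block, aligned = al, template = tmpl)
  expect_equal(sum(vapply(blocks, ncol, 0L)), ncol(flat))
  ## reassembled columns reconstitute the full matrix
  rebuilt <- matrix(NA_real_, nrow(flat), ncol(flat))
  for (i in seq_along(regions)) {
    idx <- which(tmpl$region_map == regions[i])
    rebuilt[, quadmorph:::coord_columns(idx)] <- blocks[[i]]
  }
  expect_equal(rebuilt, unname(flat))
  ## block width is 3 columns per point
  m <- sum(tmpl$region_map == regions[1L])
  expect_equal(ncol(blocks[[1L]]), 3L * m)
  expect_error(subset_block(al, tmpl, "coracoid"), "otic_process")
})

test_that("identical blocks give r_pls of exactly one", {
  set.seed(61)
  tree <- ape::rphylo(30L, 0.1, 0)
  C <- tree_covariance(tree)
  Y <- bm_block(C, 8L)
  res <- phylo_two_block_pls(Y, Y, C, n_perm = 99L, seed = 1L)
  expect_equal(res$r_pls, 1, tolerance = 1e-12)
  expect_equal(res$R2, res$r_pls^2)
  expect_gte(res$p, 1 / 100)
})

test_that("r_pls is invariant to joint rotation of a block's coordinate triples", {
  set.seed(62)
  tree <- ape::rphylo(25L, 0.1, 0)
  C <- tree_covariance(tree)
  k1 <- 5L
  Y1 <- bm_block(C, 3L * k1)
  Y2 <- bm_block(C, 9L) + Y1[, 1:9]
  res <- phylo_two_block_pls(Y1, Y2, C, n_perm = 99L, seed = 2L)
  ## rotate every (x, y, z) triple of block 1 by the same rotation
  R <- quadmorph:::random_rotation()
  Y1_rot <- Y1
  for (j in seq_len(k1)) {
    cols <- (3L * (j - 1L) + 1L):(3L * j)
    Y1_rot[, cols] <- Y1[, cols] %*% R
  }
  res_rot <- phylo_two_block_pls(Y1_rot, Y2, C, n_perm = 99L, seed = 2L)
  expect_equal(res_rot$r_pls, res$r_pls, tolerance = 1e-9)
})

test_that("singular values partition the cross-block covariance", {
  set.seed(63)
  tree <- ape::rphylo(20L, 0.2, 0)
  C <- tree_covariance(tree)
  Y1 <- bm_block(C, 6L)
  Y2 <- bm_block(C, 5L) + 0.5 * Y1[, 1:5]
  res <- phylo_two_block_pls(Y1, Y2, C, n_perm = 99L, seed = 3L)
  ## oracle: SVD of the transformed cross-covariance built independently
  P <- quadmorph:::mat_inv_sqrt(C)
  Ci <- solve(C)
  one <- rep(1, 20L)
  cgls <- function(Y) {
    mu <- drop(crossprod(one, Ci %*% Y)) / drop(crossprod(one, Ci %*% one))
    P %*% sweep(Y, 2L, mu)
  }
  d_ref <- svd(crossprod(cgls(Y1), cgls(Y2)) / 19)$d
  expect_equal(res$singular_values, d_ref, tolerance = 1e-9)
  expect_equal(
    res$singular_values[1L]^2 / sum(res$singular_values^2),
    d_ref[1L]^2 / sum(d_ref^2)
  )
})

test_that("PLS guards degenerate inputs", {
  C <- diag(4)
  expect_error(
    phylo_two_block_pls(matrix(rnorm(6), 3L), matrix(rnorm(6), 3L), diag(3)),
    "at least 4"
  )
  expect_error(
    phylo_two_block_pls(matrix(1, 4L, 2L), matrix(rnorm(8), 4L), C),
    "constant"
  )
})

test_that("effect-size comparison matches the normal-theory hand computation", {
  mk <- function(z, se) structure(list(Z = z, se_z = se), class = "pls_result")
  tab <- compare_pls(list(a = mk(3, 1), b = mk(0, 1)))
  expect_equal(tab$statistic, 3 / sqrt(2), tolerance = 1e-12)
  expect_equal(tab$p, 2 * pnorm(-3 / sqrt(2)), tolerance = 1e-12)
  expect_equal(tab$p, 0.0339, tolerance = 1e-2)

  ## identical results compare as indistinguishable
  tab0 <- compare_pls(list(a = mk(2, 0.5), b = mk(2, 0.5)))
  expect_equal(tab0$statistic, 0)
  expect_equal(tab0$p, 1)

  ## swapping the pair leaves the p-value unchanged
  tab_sw <- compare_pls(list(b = mk(0, 1), a = mk(3, 1)))
  expect_equal(tab_sw$p, tab$p)
  expect_error(compare_pls(list(mk(1, 1))), "at least 2")
  expect_error(
    compare_pls(list(mk(1, 1), structure(list(Z = 1), class = "pls_result"))),
    "standard error"
  )
})

test_that("integration suite enumerates pairings by scope", {
  ds <- small_dataset()
  al <- small_aligned()
  suite <- suppressWarnings(run_integration_suite(
    al, ds$template, ds$tree,
    pairings = "internal", n_perm = 99L, seed = 9L
  ))
  n_regions <- length(unique(ds$template$region_map))
  expect_equal(nrow(suite), choose(n_regions, 2L))
  expect_true(all(suite$R2 >= 0 & suite$R2 <= 1))
  expect_equal(suite$R2, suite$r_pls^2)

  ## with two scopes the row count doubles
  sp <- al$species
  suite2 <- suppressWarnings(run_integration_suite(
    al, ds$template, ds$tree,
    scopes = list(all = sp, subset = sp[1:10]),
    pairings = "internal", n_perm = 49L, seed = 9L
  ))
  expect_equal(nrow(suite2), 2L * choose(n_regions, 2L))
})

test_that("within-structure latent factors raise internal over external integration", {
  set.seed(64)
  tree <- ape::rphylo(40L, 0.1, 0)
  C <- tree_covariance(tree)
  ## two internal regions share a strong latent factor; the external block
  ## evolves independently
  z <- bm_block(C, 1L)
  z <- (z - mean(z)) / sd(z)
  mkblock <- function(p, load) {
    d <- rnorm(p)
    d <- d / sqrt(sum(d^2))
    b <- bm_block(C, p)
    v <- sum(apply(b, 2L, var))
    b + sqrt(load / (1 - load) * v) * (z %*% t(d))
  }
  regA <- mkblock(9L, 0.6)
  regB <- mkblock(9L, 0.6)
  external <- bm_block(C, 9L)
  internal <- phylo_two_block_pls(regA, regB, C, n_perm = 199L, seed = 10L)
  cross <- phylo_two_block_pls(regA, external, C, n_perm = 199L, seed = 11L)
  expect_gt(internal$r_pls, cross$r_pls)
  expect_lt(internal$p, 0.05)
})
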