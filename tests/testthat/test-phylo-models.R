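test_that("tree covariance encodes shared path lengths", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- tree_covariance(tree)
  expect_equal(
    unname(C[c("A", "B", "C"), c("A", "B", "C")]),
    rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2))
  )

  star <- ape::read.tree(text = "(A:1,B:2,C:3);")
  Cs <- tree_covariance(star)
  expect_equal(unname(Cs), diag(c(1, 2, 3)))

  ## ultrametric tree: constant diagonal
  set.seed(51)
  ut <- ape::rphylo(10L, 0.3, 0)
  expect_lt(diff(range(diag(tree_covariance(ut)))), 1e-10)

  bad <- tree
  bad$edge.length[1L] <- -0.5
  expect_error(tree_covariance(bad), "negative")
})

test_that("lambda transform rescales off-diagonals and preserves PSD", {
  set.seed(52)
  tree <- ape::rphylo(8L, 0.3, 0)
  C <- tree_covariance(tree)
  expect_equal(lambda_transform(C, 1), C)
  C0 <- lambda_transform(C, 0)
  expect_equal(unname(C0), diag(diag(C)))
  expect_error(lambda_transform(C, 1.5), "lambda")
  expect_error(lambda_transform(C, -0.1), "lambda")

  for (rep in 1:20) {
    Ci <- tree_covariance(ape::rphylo(10L, runif(1, 0.05, 0.5), 0))
    lam <- runif(1)
    ev <- eigen(lambda_transform(Ci, lam), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("lambda estimation agrees with a univariate grid oracle and phytools", {
  set.seed(53)
  tree <- ape::rphylo(60L, 0.1, 0)
  C <- tree_covariance(tree)
  y <- bm_block(lambda_transform(C, 0.6), 1L)

  ## brute-force grid on the same profile likelihood
  grid <- seq(0, 1, by = 1e-3)
  ll <- vapply(grid, quadmorph:::lambda_profile_loglik, 0, resid = y, C = C)
  expect_equal(estimate_lambda(y, C), grid[which.max(ll)], tolerance = 1e-3)

  ## independent implementation: phytools' univariate lambda ML
  yv <- setNames(y[, 1L], tree$tip.label)
  ref <- phytools::phylosig(tree, yv, method = "lambda")$lambda
  expect_equal(estimate_lambda(y, C), ref, tolerance = 1e-3)

  ## iid residuals ignore the tree
  expect_lt(estimate_lambda(matrix(rnorm(60L * 10L), 60L), C), 0.1)

  ## constant columns are dropped with a warning
  expect_warning(
    lam <- estimate_lambda(cbind(y, 1), C),
    "constant"
  )
  expect_equal(lam, estimate_lambda(y, C))
})

test_that("PGLS with fixed lambda reproduces textbook GLS coefficients", {
  set.seed(54)
  tree <- ape::rphylo(40L, 0.1, 0)
  C <- tree_covariance(tree)
  x <- rnorm(40L)
  y <- 1.5 - 0.8 * x + bm_block(C, 1L, sigma = 0.3)[, 1L]
  fit <- pgls_procrustes_anova(
    shape ~ x, data.frame(x = x), C,
    Y = cbind(y), n_perm = 99L, seed = 1L, lambda = 1
  )
  X <- cbind(1, x)
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  expect_equal(unname(fit$coefficients[, 1L]), unname(drop(beta)),
    tolerance = 1e-9
  )
})

test_that("an exact linear response saturates the fit", {
  set.seed(55)
  tree <- ape::rphylo(20L, 0.2, 0)
  C <- tree_covariance(tree)
  x <- rnorm(20L)
  Y <- cbind(2 * x, -x, 0.5 + x)
  fit <- pgls_procrustes_anova(
    shape ~ x, data.frame(x = x), C,
    Y = Y, n_perm = 199L, seed = 2L, lambda = 1
  )
  expect_equal(fit$table$R2, 1, tolerance = 1e-9)
  expect_equal(fit$table$p, 1 / 200)
})

test_that("PGLS results are invariant to species reordering", {
  set.seed(56)
  tree <- ape::rphylo(30L, 0.1, 0)
  C <- tree_covariance(tree)
  g <- factor(sample(letters[1:3], 30L, replace = TRUE))
  Y <- bm_block(C, 4L)
  fit1 <- pgls_procrustes_anova(
    shape ~ g, data.frame(g = g), C,
    Y = Y, n_perm = 199L, seed = 3L
  )
  ord <- sample(30L)
  fit2 <- pgls_procrustes_anova(
    shape ~ g, data.frame(g = g[ord]), C[ord, ord],
    Y = Y[ord, ], n_perm = 199L, seed = 3L
  )
  expect_equal(fit1$lambda, fit2$lambda, tolerance = 1e-6)
  expect_equal(fit1$table$SS, fit2$table$SS, tolerance = 1e-9)
  expect_equal(fit1$table$F, fit2$table$F, tolerance = 1e-9)
})

test_that("lambda forced to zero reduces PGLS to ordinary Procrustes ANOVA", {
  set.seed(57)
  tree <- ape::rphylo(30L, 0.1, 0)
  C <- tree_covariance(tree)
  x <- rnorm(30L)
  Y <- matrix(rnorm(30L * 5L), 30L) + outer(x, rnorm(5L))
  fit <- pgls_procrustes_anova(
    shape ~ x, data.frame(x = x), C,
    Y = Y, n_perm = 99L, seed = 4L, lambda = 0
  )
  ## direct OLS oracle on an ultrametric tree: lambda = 0 gives c * I, so
  ## transformed sums of squares are the ordinary ones divided by c
  X <- cbind(1, x)
  H <- X %*% solve(crossprod(X), t(X))
  Yc <- scale(Y, scale = FALSE)
  ss_tot <- sum(Yc^2)
  ss_res <- sum(((diag(30L) - H) %*% Y)^2)
  cc <- C[1L, 1L]
  expect_equal(fit$table$SS, (ss_tot - ss_res) / cc, tolerance = 1e-9)
  expect_equal(fit$table$R2, (ss_tot - ss_res) / ss_tot, tolerance = 1e-9)
})

test_that("rank-deficient designs are rejected with the aliased term named", {
  set.seed(58)
  tree <- ape::rphylo(20L, 0.2, 0)
  C <- tree_covariance(tree)
  x <- rnorm(20L)
  d <- data.frame(x = x, x2 = 2 * x)
  expect_error(
    pgls_procrustes_anova(shape ~ x + x2, d, C,
      Y = cbind(rnorm(20L)), n_perm = 99L, seed = 1L, lambda = 1
    ),
    "aliased.*x2"
  )
})

test_that("sequential sums of squares decompose the total", {
  set.seed(59)
  tree <- ape::rphylo(40L, 0.1, 0)
  C <- tree_covariance(tree)
  d <- data.frame(
    x = rnorm(40L),
    g = factor(sample(c("u", "v"), 40L, replace = TRUE))
  )
  Y <- bm_block(C, 6L) + outer(d$x, rnorm(6L), `*`) * 0.5
  fit <- pgls_procrustes_anova(shape ~ x + g, d, C,
    Y = Y,
    n_perm = 199L, seed = 5L
  )
  expect_equal(
    sum(fit$table$SS) + fit$ss_residual, fit$ss_total,
    tolerance = 1e-9
  )
  expect_equal(fit$table$R2, fit$table$SS / fit$ss_total)
  expect_true(all(fit$table$p >= 1 / 200))
})
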