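#' Extract the coordinate block of one anatomical region
#'
#' Flattened Procrustes coordinates (x, y, z per point) of the points
#' assigned to a named region of the template. No re-superimposition is
#' performed: the block stays in the common Procrustes frame of the full
#' dataset, so that blocks partition the full coordinate matrix.
#'
#' @param aligned an `aligned_shapes` object.
#' @param template the `landmark_template` with the region map.
#' @param region region name.
#' @return an n x 3m matrix (m = points in the region).
#' @export
subset_block <- function(aligned, template, region) {
  regions <- unique(template$region_map)
  if (!region %in% regions) {
    stop(
      "unknown region '", region, "'; valid regions: ",
      paste(regions, collapse = ", ")
    )
  }
  idx <- which(template$region_map == region)
  flat <- flatten_array(aligned$coords)
  flat[, coord_columns(idx), drop = FALSE]
}

#' Phylogenetic two-block partial least squares
#'
#' Measures evolutionary integration between two trait blocks under a
#' phylogenetic covariance: both blocks are centred on their GLS means and
#' transformed by the inverse square root of `C` (use the lambda-rescaled
#' covariance from an intercept-only PGLS fit to satisfy the Brownian
#' assumption); the cross-covariance matrix is decomposed by SVD and
#' `r_pls` is the correlation of the first pair of singular-axis scores.
#' Significance comes from permuting rows of the second transformed block;
#' the effect size Z standardizes the observed statistic within the
#' permutation distribution after a Fisher z-transform.
#'
#' @param Y1,Y2 n x p1 and n x p2 blocks, rows in species order.
#' @param C phylogenetic covariance (typically lambda-rescaled).
#' @param n_perm number of permutations (999 plus observed by default).
#' @param seed integer seed for the permutation stream.
#' @return an object of class `pls_result`: `r_pls`, `R2` (= r_pls^2),
#'   `Z`, `p`, `se_z`, `left`/`right` first singular axes, `singular_values`,
#'   `scores1`/`scores2`, `n`, `n_perm`.
#' @export
phylo_two_block_pls <- function(Y1, Y2, C, n_perm = 999L, seed = NULL) {
  Y1 <- as.matrix(Y1)
  Y2 <- as.matrix(Y2)
  n <- nrow(Y1)
  if (n < 4L) stop("need at least 4 species")
  if (nrow(Y2) != n || nrow(C) != n) stop("row mismatch among blocks and C")
  if (all(apply(Y1, 2L, var) == 0) || all(apply(Y2, 2L, var) == 0)) {
    stop("constant block has no covariance structure")
  }
  if (!is.null(seed)) set.seed(seed)

  P <- mat_inv_sqrt(C)
  Cinv <- P %*% P
  one <- rep(1, n)
  denom <- drop(crossprod(one, Cinv %*% one))
  center_gls <- function(Y) {
    mu <- drop(crossprod(one, Cinv %*% Y)) / denom
    P %*% sweep(Y, 2L, mu)
  }
  T1 <- center_gls(Y1)
  T2 <- center_gls(Y2)

  pls_r <- function(A, B) {
    sv <- svd(crossprod(A, B) / (n - 1), nu = 1L, nv = 1L)
    s1 <- A %*% sv$u
    s2 <- B %*% sv$v
    list(r = cor(s1, s2)[1L], sv = sv, s1 = s1, s2 = s2)
  }
  obs <- pls_r(T1, T2)
  r_perm <- vapply(
    seq_len(n_perm),
    function(b) pls_r(T1, T2[sample.int(n), , drop = FALSE])$r,
    0
  )
  dist_r <- c(obs$r, r_perm)
  p <- mean(dist_r >= obs$r)
  zt <- atanh(pmin(dist_r, 1 - 1e-12))
  Z <- (zt[1L] - mean(zt)) / sd(zt)
  stand <- (zt - mean(zt)) / sd(zt)
  se_z <- sd(stand) / sqrt(n_perm)

  d_all <- svd(crossprod(T1, T2) / (n - 1))$d
  structure(
    list(
      r_pls = obs$r,
      R2 = obs$r^2,
      Z = Z,
      p = p,
      se_z = se_z,
      left = obs$sv$u[, 1L],
      right = obs$sv$v[, 1L],
      singular_values = d_all,
      scores1 = drop(obs$s1),
      scores2 = drop(obs$s2),
      n = n,
      n_perm = n_perm
    ),
    class = "pls_result"
  )
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic 2B-PLS: r-PLS = %.4f (R2 = %.4f), Z = %.4f, p = %.4g (n = %d, %d permutations)\n",
    x$r_pls, x$R2, x$Z, x$p, x$n, x$n_perm
  ))
  invisible(x)
}

#' Compare integration strength between analyses
#'
#' Pairwise comparison of two-block PLS effect sizes: for each pair of
#' results the statistic |Z1 - Z2| / sqrt(SE1^2 + SE2^2) is referred to the
#' standard normal (two-sided).
#'
#' @param results named list of `pls_result` objects (>= 2), each carrying
#'   `Z` and `se_z`.
#' @return data frame with one row per pair: `pair`, `delta_z`,
#'   `statistic`, `p`.
#' @export
compare_pls <- function(results) {
  if (length(results) < 2L) stop("need at least 2 PLS results")
  if (any(vapply(results, function(r) is.null(r$se_z), TRUE))) {
    stop("every result must carry a permutation standard error of Z")
  }
  nm <- names(results) %||% paste0("pls", seq_along(results))
  pairs <- combn(length(results), 2L)
  out <- apply(pairs, 2L, function(ij) {
    a <- results[[ij[1L]]]
    b <- results[[ij[2L]]]
    stat <- abs(a$Z - b$Z) / sqrt(a$se_z^2 + b$se_z^2)
    c(delta_z = a$Z - b$Z, statistic = stat, p = 2 * pnorm(-stat))
  })
  data.frame(
    pair = paste(nm[pairs[1L, ]], nm[pairs[2L, ]], sep = " vs "),
    t(out),
    row.names = NULL
  )
}

#' Run a battery of phylogenetic two-block PLS analyses
#'
#' Evaluates integration for every configured block pairing at every
#' phylogenetic scope: (i) whole-element shape against each neighbouring
#' bone block, (ii) all pairs of regions within the element (internal
#' integration), and (iii) each region against each neighbour. Within each
#' scope, lambda is re-estimated from the residuals of the intercept-only
#' model on the full coordinates and the covariance rescaled before the
#' PLS.
#'
#' @param aligned an `aligned_shapes` object for the focal element.
#' @param template its `landmark_template`.
#' @param tree an [ape::phylo] tree covering the species.
#' @param neighbours optional named list of n x q neighbour-bone blocks
#'   (rows named by species, in their own Procrustes frames).
#' @param scopes named list of species subsets (default: a single scope
#'   `all` with every species). Scopes with fewer than 10 species trigger a
#'   warning.
#' @param pairings any of `"element_vs_neighbour"`, `"internal"`,
#'   `"region_vs_neighbour"`.
#' @param n_perm,seed permutation controls passed to each PLS.
#' @return data frame with one row per pairing x scope: `block1`, `block2`,
#'   `scope`, `n`, `lambda`, `r_pls`, `R2`, `Z`, `se_z`, `p`; the
#'   `pls_result` objects are attached as attribute `results`.
#' @export
run_integration_suite <- function(aligned, template, tree,
                                  neighbours = NULL,
                                  scopes = NULL,
                                  pairings = c(
                                    "element_vs_neighbour",
                                    "internal",
                                    "region_vs_neighbour"
                                  ),
                                  n_perm = 999L, seed = 1L) {
  pairings <- match.arg(pairings, several.ok = TRUE)
  species <- aligned$species
  if (is.null(scopes)) scopes <- list(all = species)
  flat <- flatten_array(aligned$coords)
  rownames(flat) <- species
  regions <- unique(template$region_map)
  region_blocks <- lapply(regions, function(r) {
    flat[, coord_columns(which(template$region_map == r)), drop = FALSE]
  })
  names(region_blocks) <- regions

  pair_list <- list()
  if ("element_vs_neighbour" %in% pairings && length(neighbours)) {
    for (nb in names(neighbours)) {
      pair_list[[length(pair_list) + 1L]] <- c("element", nb)
    }
  }
  if ("internal" %in% pairings && length(regions) > 1L) {
    cmb <- combn(regions, 2L)
    for (j in seq_len(ncol(cmb))) {
      pair_list[[length(pair_list) + 1L]] <- cmb[, j]
    }
  }
  if ("region_vs_neighbour" %in% pairings && length(neighbours)) {
    for (r in regions) {
      for (nb in names(neighbours)) {
        pair_list[[length(pair_list) + 1L]] <- c(r, nb)
      }
    }
  }
  if (!length(pair_list)) stop("no pairings to evaluate")

  get_block <- function(name, keep) {
    if (name == "element") {
      flat[keep, , drop = FALSE]
    } else if (name %in% regions) {
      region_blocks[[name]][keep, , drop = FALSE]
    } else {
      as.matrix(neighbours[[name]])[keep, , drop = FALSE]
    }
  }

  rows <- list()
  results <- list()
  run_id <- 0L
  for (sc in names(scopes)) {
    keep <- intersect(species, scopes[[sc]])
    if (length(keep) < 10L) {
      warning("scope '", sc, "' has fewer than 10 species")
    }
    sub_tree <- ape::keep.tip(tree, keep)
    keep <- sub_tree$tip.label
    C <- tree_covariance(sub_tree)
    ## lambda from the intercept-only model on the full coordinates
    Ys <- flat[keep, , drop = FALSE]
    Cinv <- solve(C)
    one <- rep(1, length(keep))
    mu <- drop(crossprod(one, Cinv %*% Ys)) / drop(crossprod(one, Cinv %*% one))
    lam <- estimate_lambda(sweep(Ys, 2L, mu), C)
    Cl <- lambda_transform(C, lam)
    for (pp in pair_list) {
      run_id <- run_id + 1L
      res <- phylo_two_block_pls(
        get_block(pp[1L], keep), get_block(pp[2L], keep), Cl,
        n_perm = n_perm, seed = derive_seed(seed, run_id)
      )
      key <- paste(sc, pp[1L], pp[2L], sep = ":")
      results[[key]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        block1 = pp[1L], block2 = pp[2L], scope = sc,
        n = res$n, lambda = lam, r_pls = res$r_pls, R2 = res$R2,
        Z = res$Z, se_z = res$se_z, p = res$p
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
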