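#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with a one-sided
#' (greater) permutation null built by simultaneously permuting rows and
#' columns of the second matrix. Backed by [vegan::mantel()]; the seed
#' controls the permutation stream.
#'
#' @param D1,D2 symmetric distance matrices over the same species order.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return an object of class `mantel_result`: `r`, `p`, `n_perm`, `tail`.
#' @export
mantel_test <- function(D1, D2, n_perm = 9999L, seed = NULL) {
  D1 <- as.matrix(D1)
  D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("distance matrices differ in dimension")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(
    stats::as.dist(D1), stats::as.dist(D2),
    method = "pearson", permutations = n_perm
  )
  structure(
    list(
      r = unname(fit$statistic),
      p = fit$signif,
      n_perm = n_perm,
      tail = "one-sided-greater"
    ),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "Mantel test: r = %.4f, one-sided p = %.4g (%d permutations)\n",
    x$r, x$p, x$n_perm
  ))
  invisible(x)
}

#' Pairwise differences between two Procrustes distance matrices
#'
#' Elementwise `D_full - D_sub`, the signed change in between-species shape
#' distances when surface semi-landmarks are included; a negative mean
#' indicates the denser scheme yields smaller distances overall.
#'
#' @param D_full,D_sub matched n x n distance matrices.
#' @return the signed difference matrix, with attributes `mean_delta` and
#'   `share_negative` (fraction of negative off-diagonal entries).
#' @export
delta_pd_matrix <- function(D_full, D_sub) {
  D_full <- as.matrix(D_full)
  D_sub <- as.matrix(D_sub)
  if (!all(dim(D_full) == dim(D_sub))) stop("matrices differ in dimension")
  delta <- D_full - D_sub
  off <- delta[lower.tri(delta)]
  attr(delta, "mean_delta") <- mean(off)
  attr(delta, "share_negative") <- mean(off < 0)
  delta
}

#' Validate a dense landmark scheme against its subsampled version
#'
#' Re-superimposes the raw configurations twice — once under the full
#' template and once keeping only fixed landmarks and curve semi-landmarks
#' (superimposition depends on the point set, so the subsampled dataset is
#' aligned from raw coordinates rather than sliced from the full
#' alignment) — then compares the two Procrustes distance matrices with a
#' Mantel test and the signed difference matrix.
#'
#' @param configs named list of raw configurations under the full template.
#' @param template the full `landmark_template`.
#' @param slide logical; slide semi-landmarks in both alignments.
#' @param n_perm Mantel permutations (default 9999).
#' @param seed integer seed.
#' @param ... passed to [gpa()].
#' @return list with `mantel` (a `mantel_result`), `delta_pd`, `D_full`,
#'   `D_sub`.
#' @export
compare_landmark_schemes <- function(configs, template, slide = TRUE,
                                     n_perm = 9999L, seed = NULL, ...) {
  sub_template <- subsample_template(template)
  sub_configs <- lapply(configs, subsample_configuration,
    template = template
  )
  full_fit <- gpa(configs, slide = slide, template = template, ...)
  sub_fit <- gpa(sub_configs, slide = slide, template = sub_template, ...)
  D_full <- procrustes_distance_matrix(full_fit)
  D_sub <- procrustes_distance_matrix(sub_fit)
  list(
    mantel = mantel_test(D_full, D_sub, n_perm = n_perm, seed = seed),
    delta_pd = delta_pd_matrix(D_full, D_sub),
    D_full = D_full,
    D_sub = D_sub
  )
}
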