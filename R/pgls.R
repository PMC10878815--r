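#' Phylogenetic Procrustes ANOVA via generalized least squares and RRPP
#'
#' Fits a linear model to multivariate (shape) data under a phylogenetic
#' covariance, with a two-pass lambda protocol: (1) the model is fitted
#' with the Brownian covariance `C` as given and Pagel's lambda is
#' estimated on the residuals ([estimate_lambda()]); (2) `C` is rescaled by
#' that lambda, both sides are transformed by the inverse square root of
#' the rescaled covariance (the intercept column becomes the GLS mean), and
#' sums of squares are computed sequentially (type I) from nested models.
#' Significance comes from residual randomization (RRPP): for each term,
#' rows of the reduced-model residuals are permuted and added back to the
#' reduced-model fit, and the F statistic is recomputed; the effect size Z
#' is the standardized position of the observed statistic in the
#' permutation distribution of log-transformed F values.
#'
#' @param formula model formula; the left-hand side names the n x p
#'   response matrix in `data` (or is ignored when `Y` is given).
#' @param data data frame (or list) of predictors, rows in species order.
#' @param C phylogenetic covariance matrix (species x species).
#' @param Y optional response matrix overriding the formula left-hand side.
#' @param n_perm number of random permutations (999 plus the observed
#'   arrangement by default); fewer than 99 triggers a warning.
#' @param seed integer seed for the permutation stream.
#' @param lambda fix lambda instead of estimating it (e.g. 1 for pure
#'   Brownian motion, 0 for a non-phylogenetic fit).
#' @param lambda_upper search bound passed to [estimate_lambda()].
#' @return an object of class `pgls_anova`: `table` (one row per term with
#'   lambda, df, SS, MS, R2, F, Z, p), `lambda`, `coefficients` (GLS),
#'   `residuals` (untransformed space), `fitted`, `n_perm`.
#' @export
pgls_procrustes_anova <- function(formula, data, C, Y = NULL,
                                  n_perm = 999L, seed = NULL,
                                  lambda = NULL, lambda_upper = 1) {
  if (n_perm < 99L) warning("fewer than 99 permutations is unreliable")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(Y)) {
    resp <- all.vars(formula[[2L]])
    Y <- data[[resp]]
    if (is.null(Y)) stop("response '", resp, "' not found in data")
  }
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (nrow(C) != n) stop("C and response dimensions disagree")

  mf_terms <- delete.response(terms(formula))
  term_labels <- attr(mf_terms, "term.labels")
  if (!length(term_labels)) stop("model has no terms to test")
  df_pred <- model.frame(mf_terms, as.data.frame(data, optional = TRUE))
  X_full <- model.matrix(mf_terms, df_pred)
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    aliased <- colnames(X_full)[qr_full$pivot[-seq_len(qr_full$rank)]]
    stop(
      "rank-deficient design; aliased terms: ",
      paste(aliased, collapse = ", ")
    )
  }

  ## pass 1: fit under C as given, estimate lambda on the residuals
  if (is.null(lambda)) {
    P1 <- mat_inv_sqrt(C)
    B1 <- qr.coef(qr(P1 %*% X_full), P1 %*% Y)
    lambda <- estimate_lambda(Y - X_full %*% B1, C, upper = lambda_upper)
  }

  ## pass 2: transform by the lambda-rescaled covariance
  Cl <- lambda_transform(C, lambda, upper = max(1, lambda_upper))
  P <- mat_inv_sqrt(Cl)
  Yt <- P %*% Y
  Xt <- P %*% X_full

  ## nested (sequential, type-I) designs: intercept, +term1, +term2, ...
  assign_ <- attr(X_full, "assign")
  designs <- lapply(0:length(term_labels), function(t) {
    qr(Xt[, assign_ <= t, drop = FALSE])
  })
  rss <- function(qr_x, Ym) {
    fitted <- qr.fitted(qr_x, Ym)
    sum((Ym - fitted)^2)
  }
  rss_obs <- vapply(designs, rss, 0, Ym = Yt)
  n_terms <- length(term_labels)
  df_terms <- vapply(designs, function(q) q$rank, 0L)
  df_effect <- diff(df_terms)
  df_res <- n - df_terms[n_terms + 1L]
  ss_total <- rss_obs[1L] # around the GLS mean
  ss_effect <- -diff(rss_obs)
  ss_res <- rss_obs[n_terms + 1L]
  ms_effect <- ss_effect / df_effect
  ms_res <- ss_res / df_res
  f_obs <- ms_effect / ms_res

  ## RRPP: permute reduced-model residuals, same permutations for all terms
  perms <- replicate(n_perm, sample.int(n))
  f_perm <- matrix(NA_real_, n_perm, n_terms)
  for (t in seq_len(n_terms)) {
    q_red <- designs[[t]]
    q_full_t <- designs[[t + 1L]]
    fit_red <- qr.fitted(q_red, Yt)
    res_red <- Yt - fit_red
    for (b in seq_len(n_perm)) {
      Y_star <- fit_red + res_red[perms[, b], , drop = FALSE]
      rss_red <- rss(q_red, Y_star)
      rss_full <- rss(q_full_t, Y_star)
      f_perm[b, t] <- ((rss_red - rss_full) / df_effect[t]) /
        (rss(designs[[n_terms + 1L]], Y_star) / df_res)
    }
  }

  p_val <- z_val <- numeric(n_terms)
  for (t in seq_len(n_terms)) {
    dist_t <- c(f_obs[t], f_perm[, t])
    p_val[t] <- mean(dist_t >= f_obs[t])
    log_dist <- log(dist_t[dist_t > 0 & is.finite(dist_t)])
    z_val[t] <- if (is.finite(f_obs[t]) && length(log_dist) > 2 &&
      sd(log_dist) > 0) {
      (log(f_obs[t]) - mean(log_dist)) / sd(log_dist)
    } else if (!is.finite(f_obs[t])) Inf else NA_real_
  }

  B <- qr.coef(qr(Xt), Yt)
  fitted_raw <- X_full %*% B
  tab <- data.frame(
    term = term_labels,
    lambda = lambda,
    df = df_effect,
    SS = ss_effect,
    MS = ms_effect,
    R2 = ss_effect / ss_total,
    F = f_obs,
    Z = z_val,
    p = p_val,
    row.names = NULL
  )
  structure(
    list(
      table = tab,
      lambda = lambda,
      coefficients = B,
      fitted = fitted_raw,
      residuals = Y - fitted_raw,
      ss_total = ss_total,
      ss_residual = ss_res,
      df_residual = df_res,
      n_perm = n_perm
    ),
    class = "pgls_anova"
  )
}

#' @export
print.pgls_anova <- function(x, ...) {
  cat(sprintf(
    "PGLS Procrustes ANOVA (lambda = %.7g, %d permutations)\n",
    x$lambda, x$n_perm
  ))
  print(x$table, digits = 5)
  invisible(x)
}
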