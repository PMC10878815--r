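## shared desk-scale fixtures, built once per test run

small_scenario <- function(seed = 7L, ...) {
  simulation_scenario(
    n_tips = 15L, n_curve = 30L, n_surface = 30L,
    seed = seed, ...
  )
}

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(simulate_dataset(small_scenario()))
    }
    cache
  }
})

small_aligned <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- small_dataset()
      cache <<- gpa(ds$configs,
        slide = TRUE, template = ds$template,
        slide_rounds = 3L
      )
    }
    cache
  }
})

## tiny template: 4 fixed landmarks and one curve of `n_semi` sliding points
toy_curve_template <- function(n_semi = 6L) {
  landmark_template(
    n_fixed = 4L,
    curves = data.frame(
      curve_id = "c1", anchor_start = 1L, anchor_end = 2L,
      n_semi = as.integer(n_semi)
    ),
    patches = data.frame(patch_id = character(0), n_semi = integer(0)),
    region_map = rep("body", 4L + n_semi)
  )
}

## a configuration fitting toy_curve_template: anchors on a bowed curve
toy_curve_config <- function(n_semi = 6L, bow = 0.3, jitter = 0) {
  t_all <- seq(0, 1, length.out = n_semi + 2L)
  curve <- cbind(t_all, bow * sin(pi * t_all), 0)
  fixed <- rbind(curve[1L, ], curve[n_semi + 2L, ], c(0.5, 1, 0.5), c(0.5, -1, 0.5))
  pts <- rbind(fixed, curve[2:(n_semi + 1L), ])
  if (jitter > 0) pts <- pts + matrix(rnorm(length(pts), sd = jitter), nrow(pts))
  pts
}

## BM-distributed block: p columns with covariance sigma2 * C
bm_block <- function(C, p, sigma = 1) {
  crossprod(chol(C), matrix(rnorm(nrow(C) * p), nrow(C), p)) * sigma
}

## random similarity transform of a configuration
similarity_transform <- function(pts, scale = exp(rnorm(1, 0, 0.5))) {
  scale * pts %*% quadmorph:::random_rotation() +
    matrix(runif(3, -10, 10), nrow(pts), 3L, byrow = TRUE)
}

random_configs <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n), function(i) matrix(rnorm(k * 3), k, 3L))
  names(out) <- paste0("sp", seq_len(n))
  out
}
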