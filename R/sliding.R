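## Minimum-bending-energy sliding of semi-landmarks.
##
## Curve semi-landmarks slide along their local tangent (the normalized
## chord between their two polyline neighbours); surface semi-landmarks
## slide within their local tangent plane (first two principal axes of
## their 8 nearest neighbours in the consensus). Slide magnitudes are the
## closed-form generalized-least-squares minimizer of the thin-plate-spline
## bending energy of the consensus-to-specimen deformation, with the
## bending-energy matrix computed from the consensus. After sliding, curve
## points are re-projected onto the specimen's original curve polyline and
## surface points onto the plane through the centroid of their 8
## neighbours, so points cannot drift off the anatomy. Fixed landmarks
## never move.

## tangent-direction bookkeeping shared by all specimens of a round
slide_structure <- function(template, consensus, n_neighbours = 8L) {
  curve_info <- NULL
  if (nrow(template$curves)) {
    curve_info <- do.call(rbind, lapply(
      seq_len(nrow(template$curves)),
      function(ci) {
        path <- template_curve_path(template, ci)
        interior <- seq(2L, length(path) - 1L)
        data.frame(
          point = path[interior],
          prev = path[interior - 1L],
          nxt = path[interior + 1L],
          curve = ci
        )
      }
    ))
  }
  surface_idx <- which(template$roles == "surface")
  nb <- NULL
  if (length(surface_idx)) {
    dmat <- as.matrix(dist(consensus))
    diag(dmat) <- Inf
    nb <- t(vapply(
      surface_idx,
      function(i) order(dmat[i, ])[seq_len(n_neighbours)],
      integer(n_neighbours)
    ))
    rownames(nb) <- surface_idx
  }
  list(curve_info = curve_info, surface_idx = surface_idx, neighbours = nb)
}

## nearest point on a piecewise-linear path
project_on_polyline <- function(p, path_pts) {
  best <- path_pts[1L, ]
  best_d <- Inf
  for (s in seq_len(nrow(path_pts) - 1L)) {
    a <- path_pts[s, ]
    ab <- path_pts[s + 1L, ] - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) max(0, min(1, sum((p - a) * ab) / len2)) else 0
    q <- a + t * ab
    d <- sum((p - q)^2)
    if (d < best_d) {
      best_d <- d
      best <- q
    }
  }
  best
}

## one full sliding pass of every specimen against the given consensus
slide_round <- function(arr, consensus, template, be = NULL,
                        structure_ = NULL, project = TRUE) {
  if (is.null(be)) be <- bending_energy_matrix(consensus)
  if (is.null(structure_)) structure_ <- slide_structure(template, consensus)
  n <- dim(arr)[3L]
  be_before <- be_after <- numeric(n)
  for (i in seq_len(n)) {
    X <- arr[, , i]
    be_before[i] <- tps_bending_energy(consensus, X, be = be)
    Xs <- slide_one(X, consensus, be, structure_, template, project = project)
    be_after[i] <- tps_bending_energy(consensus, Xs, be = be)
    arr[, , i] <- Xs
  }
  list(arr = arr, be_before = mean(be_before), be_after = mean(be_after))
}

## closed-form minimum-bending-energy slide of one specimen
slide_one <- function(X, consensus, be, structure_, template,
                      project = TRUE) {
  ci <- structure_$curve_info
  si <- structure_$surface_idx
  nb <- structure_$neighbours

  pt_idx <- integer(0)
  dirs <- matrix(0, 0L, 3L)
  if (!is.null(ci)) {
    tang <- X[ci$nxt, , drop = FALSE] - X[ci$prev, , drop = FALSE]
    len <- sqrt(rowSums(tang^2))
    ok <- len > 1e-12 # coincident neighbours leave the point unslid
    tang[!ok, ] <- 0
    tang[ok, ] <- tang[ok, , drop = FALSE] / len[ok]
    pt_idx <- ci$point
    dirs <- tang
  }
  if (length(si)) {
    for (j in seq_along(si)) {
      nbp <- X[nb[j, ], , drop = FALSE]
      e <- eigen(stats::cov(nbp), symmetric = TRUE)
      dirs <- rbind(dirs, t(e$vectors[, 1:2]))
      pt_idx <- c(pt_idx, si[j], si[j])
    }
  }
  keep <- rowSums(dirs^2) > 0
  pt_idx <- pt_idx[keep]
  dirs <- dirs[keep, , drop = FALSE]
  if (!length(pt_idx)) {
    return(X)
  }

  D <- X - consensus
  BeD <- be %*% D
  b <- rowSums(dirs * BeD[pt_idx, , drop = FALSE])
  A <- be[pt_idx, pt_idx] * tcrossprod(dirs)
  w <- tryCatch(
    solve(A, -b),
    error = function(e) {
      warning("singular sliding system; ridge-regularizing", call. = FALSE)
      solve(A + diag(1e-8, nrow(A)), -b)
    }
  )

  upd <- rowsum(w * dirs, group = pt_idx)
  moved <- as.integer(rownames(upd))

  apply_slide <- function(step) {
    Xs <- X
    Xs[moved, ] <- Xs[moved, ] + step * upd
    if (!project) {
      return(Xs)
    }
    if (!is.null(ci)) {
      for (cc in unique(ci$curve)) {
        path <- template_curve_path(template, cc)
        path_pts <- X[path, , drop = FALSE] # original polyline, pre-slide
        for (p in ci$point[ci$curve == cc]) {
          Xs[p, ] <- project_on_polyline(Xs[p, ], path_pts)
        }
      }
    }
    if (length(si)) {
      for (j in seq_along(si)) {
        nbp <- X[nb[j, ], , drop = FALSE]
        centre <- colMeans(nbp)
        e <- eigen(stats::cov(nbp), symmetric = TRUE)
        normal <- e$vectors[, 3L]
        p <- Xs[si[j], ]
        Xs[si[j], ] <- p - sum((p - centre) * normal) * normal
      }
    }
    Xs
  }

  ## re-projection onto the anatomy is not energy-aware, so backtrack: halve
  ## the slide vector until the projected configuration does not raise the
  ## bending energy; a fully backtracked point simply stays put
  be_x <- tps_bending_energy(consensus, X, be = be)
  step <- 1
  for (try in seq_len(9L)) {
    Xs <- apply_slide(step)
    if (tps_bending_energy(consensus, Xs, be = be) <= be_x) {
      return(Xs)
    }
    step <- step / 2
  }
  X
}

#' Slide semi-landmarks by minimum bending energy
#'
#' Performs one sliding pass of every specimen against the current
#' consensus of an aligned dataset and returns the dataset re-superimposed.
#' Usually invoked through `gpa(..., slide = TRUE)`, which interleaves
#' several such rounds; exposed separately for diagnostics.
#'
#' @param aligned an `aligned_shapes` object.
#' @param template the `landmark_template` describing point roles.
#' @return an `aligned_shapes` object with slid, re-superimposed
#'   coordinates; `be_history` records mean bending energy to the consensus
#'   before and after the pass.
#' @export
slide_semilandmarks <- function(aligned, template) {
  slid <- slide_round(aligned$coords, aligned$consensus, template)
  arr <- slid$arr
  n <- dim(arr)[3L]
  for (i in seq_len(n)) {
    centered <- sweep(arr[, , i], 2L, colMeans(arr[, , i]))
    arr[, , i] <- centered / sqrt(sum(centered^2))
  }
  fit <- superimpose(arr)
  V <- canonical_orientation(fit$consensus)
  aligned$coords <- fit$arr
  for (i in seq_len(n)) aligned$coords[, , i] <- fit$arr[, , i] %*% V
  aligned$consensus <- fit$consensus %*% V
  aligned$be_history <- rbind(
    aligned$be_history,
    c(before = slid$be_before, after = slid$be_after)
  )
  aligned
}
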