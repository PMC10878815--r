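#' Landmark template
#'
#' Describes a landmarking scheme for a single skeletal element: how many
#' fixed (discrete) landmarks there are, which ordered runs of curve
#' semi-landmarks connect which fixed anchors, which patches of surface
#' semi-landmarks exist, and which named anatomical region every point
#' belongs to. Point indices are laid out as fixed landmarks first, then the
#' curves in order, then the patches, so a template with `n_fixed` fixed
#' points, curves totalling `nc` semi-landmarks and patches totalling `ns`
#' semi-landmarks describes configurations with `n_fixed + nc + ns` points.
#'
#' @param n_fixed number of fixed landmarks.
#' @param curves data frame with columns `curve_id`, `anchor_start`,
#'   `anchor_end` (indices of fixed landmarks) and `n_semi` (number of
#'   sliding points strictly between the anchors).
#' @param patches data frame with columns `patch_id` and `n_semi`.
#' @param region_map character vector, one region name per point index.
#' @return an object of class `landmark_template`.
#' @export
landmark_template <- function(n_fixed, curves, patches, region_map) {
  curves <- as.data.frame(curves)
  patches <- as.data.frame(patches)
  n_curve <- if (nrow(curves)) sum(curves$n_semi) else 0L
  n_surface <- if (nrow(patches)) sum(patches$n_semi) else 0L
  k <- n_fixed + n_curve + n_surface
  if (length(region_map) != k) {
    stop("region_map must name a region for every one of the ", k, " points")
  }
  if (nrow(curves)) {
    anchors <- c(curves$anchor_start, curves$anchor_end)
    if (any(anchors < 1L | anchors > n_fixed)) {
      stop("curve anchors must index fixed landmarks (1..n_fixed)")
    }
  }
  roles <- c(
    rep("fixed", n_fixed),
    rep("curve", n_curve),
    rep("surface", n_surface)
  )
  structure(
    list(
      n_fixed = as.integer(n_fixed),
      curves = curves,
      patches = patches,
      region_map = as.character(region_map),
      roles = roles,
      k = as.integer(k)
    ),
    class = "landmark_template"
  )
}

#' @export
print.landmark_template <- function(x, ...) {
  cat(
    "Landmark template:", x$n_fixed, "fixed +",
    sum(x$roles == "curve"), "curve +",
    sum(x$roles == "surface"), "surface =", x$k, "points\n"
  )
  cat("Regions:", paste(unique(x$region_map), collapse = ", "), "\n")
  invisible(x)
}

#' Point indices of one curve (anchors excluded)
#' @keywords internal
template_curve_indices <- function(template, which_curve) {
  offset <- template$n_fixed
  if (which_curve > 1L) {
    offset <- offset + sum(template$curves$n_semi[seq_len(which_curve - 1L)])
  }
  offset + seq_len(template$curves$n_semi[which_curve])
}

#' Point indices of the full polyline of one curve (anchor, semis, anchor)
#' @keywords internal
template_curve_path <- function(template, which_curve) {
  c(
    template$curves$anchor_start[which_curve],
    template_curve_indices(template, which_curve),
    template$curves$anchor_end[which_curve]
  )
}

## standard region names for the quadrate (Fig.-style partition)
quadrate_regions <- c(
  "otic_process", "orbital_process", "quadrate_body",
  "quadratojugal_cotyle", "mandibular_process", "pterygoid_condyle"
)

## fixed landmarks of the parametric quadrate-like base shape; tips of the
## three processes, articular points, and a body apex
quadrate_fixed_points <- function() {
  pts <- rbind(
    c(0.00, 0.35, 1.20),   # squamosal capitulum (otic process)
    c(0.00, -0.35, 1.20),  # otic capitulum (otic process)
    c(1.50, 0.00, 0.30),   # orbital process tip
    c(0.00, 0.95, -0.20),  # quadratojugal cotyle
    c(0.30, -0.40, -1.10), # medial mandibular condyle
    c(0.30, 0.40, -1.10),  # lateral mandibular condyle
    c(0.85, -0.60, -0.60), # pterygoid condyle
    c(-0.85, 0.00, 0.10)   # caudal apex of the quadrate body
  )
  rownames(pts) <- c(
    "squamosal_capitulum", "otic_capitulum", "orbital_tip",
    "quadratojugal_cotyle", "condyle_medial", "condyle_lateral",
    "pterygoid_condyle", "body_apex"
  )
  pts
}

quadrate_fixed_regions <- c(
  "otic_process", "otic_process", "orbital_process", "quadratojugal_cotyle",
  "mandibular_process", "mandibular_process", "pterygoid_condyle",
  "quadrate_body"
)

## curve definitions: anchors (fixed indices), bowing direction and height,
## and region. Interior points follow the parametric bowed chord
##   p(t) = A + t (B - A) + h sin(pi t) d,  t in (0, 1).
quadrate_curve_specs <- function() {
  data.frame(
    curve_id = c(
      "otic_margin", "orbital_margin", "mandibular_margin",
      "quadratojugal_rim", "pterygoid_margin"
    ),
    anchor_start = c(1L, 3L, 5L, 4L, 7L),
    anchor_end = c(2L, 8L, 6L, 6L, 5L),
    dx = c(0, 0.0, 0.8, 0.9, 0.2),
    dy = c(0, 0.8, 0.0, 0.0, -0.9),
    dz = c(1, 0.6, -0.6, 0.4, 0.3),
    h = c(0.35, 0.30, 0.28, 0.25, 0.22),
    region = c(
      "otic_process", "orbital_process", "mandibular_process",
      "quadratojugal_cotyle", "pterygoid_condyle"
    ),
    stringsAsFactors = FALSE
  )
}

## evaluate the parametric bowed chord of curve `i` at parameters t
quadrate_curve_eval <- function(spec, fixed, i, t) {
  A <- fixed[spec$anchor_start[i], ]
  B <- fixed[spec$anchor_end[i], ]
  d <- c(spec$dx[i], spec$dy[i], spec$dz[i])
  d <- d / sqrt(sum(d^2))
  outer(1 - t, A) + outer(t, B) + spec$h[i] * outer(sin(pi * t), d)
}

## body patch: parametric grid on an ellipsoid centred at the origin
quadrate_patch_points <- function(n_surface) {
  axes <- c(0.75, 0.65, 0.95)
  nu <- max(2L, floor(sqrt(n_surface)))
  nv <- ceiling(n_surface / nu)
  u <- pi * (seq_len(nu) - 0.5) / nu
  v <- 2 * pi * (seq_len(nv) - 0.5) / nv
  grid <- expand.grid(u = u, v = v)
  grid <- grid[seq_len(n_surface), , drop = FALSE]
  cbind(
    axes[1] * sin(grid$u) * cos(grid$v),
    axes[2] * sin(grid$u) * sin(grid$v),
    axes[3] * cos(grid$u)
  )
}

#' Build a quadrate-like landmark template and its base configuration
#'
#' Constructs a parametric base shape emulating the gross geometry of an
#' avian quadrate — an ellipsoidal body bearing three protruding processes —
#' together with the landmarking scheme applied to it: eight fixed landmarks
#' at process tips and articular points, ordered curve semi-landmarks bowed
#' along the process margins, and a surface semi-landmark grid over the
#' body. Every point is assigned to one of the six standard quadrate
#' regions. Default counts follow a dense scheme of 8 fixed, 509 curve and
#' 797 surface semi-landmarks; both counts are configurable (desk-scale
#' analyses typically use far fewer).
#'
#' @param n_curve total number of curve semi-landmarks across the five
#'   margin curves (distributed by largest remainder).
#' @param n_surface number of surface semi-landmarks on the body patch.
#' @return a `landmark_template` with an extra element `base`, the k x 3
#'   base configuration the curves and patch are evaluated on.
#' @export
make_template <- function(n_curve = 509L, n_surface = 797L) {
  if (n_curve < 5L) stop("need at least one semi-landmark per curve")
  if (n_surface < 4L) stop("need at least 4 surface semi-landmarks")
  fixed <- quadrate_fixed_points()
  spec <- quadrate_curve_specs()
  n_curves <- nrow(spec)
  per <- largest_remainder_round(
    rep(1, n_curves),
    total = n_curve, unit = 1L
  )
  spec$n_semi <- as.integer(per)

  curve_pts <- vector("list", n_curves)
  for (i in seq_len(n_curves)) {
    t <- seq_len(spec$n_semi[i]) / (spec$n_semi[i] + 1)
    curve_pts[[i]] <- quadrate_curve_eval(spec, fixed, i, t)
  }
  patch <- quadrate_patch_points(n_surface)

  region_map <- c(
    quadrate_fixed_regions,
    rep(spec$region, spec$n_semi),
    rep("quadrate_body", n_surface)
  )
  template <- landmark_template(
    n_fixed = 8L,
    curves = spec[, c("curve_id", "anchor_start", "anchor_end", "n_semi")],
    patches = data.frame(patch_id = "body", n_semi = as.integer(n_surface)),
    region_map = region_map
  )
  template$curve_specs <- spec
  template$base <- rbind(fixed, do.call(rbind, curve_pts), patch)
  rownames(template$base) <- NULL
  template
}

#' Drop surface semi-landmarks from a template
#'
#' Returns the subsampled scheme containing only the fixed landmarks and
#' curve semi-landmarks, used to validate that dense surface patches do not
#' bias shape estimates. Because surface points occupy the trailing indices,
#' configurations digitized under the full template can be subsampled by
#' keeping their first `n_fixed + n_curve` rows (see
#' [subsample_configuration()]).
#'
#' @param template a `landmark_template`.
#' @return a `landmark_template` without surface points.
#' @export
subsample_template <- function(template) {
  keep <- template$roles != "surface"
  if (all(keep)) {
    return(template)
  }
  out <- landmark_template(
    n_fixed = template$n_fixed,
    curves = template$curves,
    patches = data.frame(
      patch_id = character(0),
      n_semi = integer(0)
    ),
    region_map = template$region_map[keep]
  )
  if (!is.null(template$base)) out$base <- template$base[keep, , drop = FALSE]
  if (!is.null(template$curve_specs)) out$curve_specs <- template$curve_specs
  out
}

#' Restrict a configuration to a subsampled template
#' @param points a k x 3 configuration digitized under the full template.
#' @param template the full `landmark_template`.
#' @return the rows corresponding to fixed and curve points.
#' @export
subsample_configuration <- function(points, template) {
  points[template$roles != "surface", , drop = FALSE]
}
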