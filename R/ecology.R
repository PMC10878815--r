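## standard 10 semi-quantitative diet items (EltonTraits-style bins)
diet_items <- c(
  "fruit", "nect", "seed", "plantseed", "planto",
  "invertebrate", "vert_ect", "vert_end", "vert_fish", "scav"
)

## pull the diet profile matrix out of a trait table (columns diet_<item>)
diet_profile_matrix <- function(traits, required = TRUE) {
  cols <- paste0("diet_", diet_items)
  if (!all(cols %in% names(traits))) {
    if (required) {
      stop(
        "trait table lacks diet profile columns (",
        paste(cols[!cols %in% names(traits)], collapse = ", "), ")"
      )
    }
    return(NULL)
  }
  m <- as.matrix(traits[, cols])
  rownames(m) <- traits$species_id
  colnames(m) <- diet_items
  m
}

check_diet_profiles <- function(profiles) {
  sums <- rowSums(profiles)
  if (any(sums != 100)) {
    stop(
      "diet profiles must sum to 100; offending species: ",
      paste(rownames(profiles)[sums != 100], collapse = ", ")
    )
  }
  if (any(profiles %% 10 != 0)) {
    stop("diet profile entries must be multiples of 10")
  }
  invisible(profiles)
}

#' Euclidean distance matrix of diet profiles
#'
#' Pairwise Euclidean distances between the species' 10-bin
#' semi-quantitative diet profiles (each profile a vector of multiples of
#' 10 summing to 100).
#'
#' @param traits trait table with `diet_<item>` columns, or an n x 10
#'   profile matrix directly.
#' @return n x n symmetric distance matrix.
#' @export
diet_distance <- function(traits) {
  profiles <- if (is.matrix(traits)) traits else diet_profile_matrix(traits)
  check_diet_profiles(profiles)
  as.matrix(dist(profiles))
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical scaling: the doubly centred Gower matrix -1/2 J D^2 J is
#' eigendecomposed and coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Axes with negative eigenvalues are
#' reported but carry no coordinates. For a Euclidean input distance, the
#' full-dimensional coordinates reproduce the distances exactly.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return an object of class `pcoa_result`: `coordinates` (n x n_axes),
#'   `eigenvalues` (all), `percent_variance` (share of the positive
#'   eigenvalue total per retained axis), `negative_eigenvalues`.
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(D)
  G <- -0.5 * D^2
  G <- sweep(G, 1L, rowMeans(G))
  G <- sweep(G, 2L, colMeans(G))
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] *
    rep(sqrt(e$values[pos]), each = n)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(
    list(
      coordinates = coords,
      eigenvalues = e$values,
      percent_variance = 100 * e$values[pos] / sum(e$values[pos]),
      negative_eigenvalues = e$values[e$values < -tol]
    ),
    class = "pcoa_result"
  )
}

#' Derive the main-diet (diet.50) category from a profile
#'
#' The main diet is the single item whose share exceeds 50% of the profile;
#' when no item exceeds 50% (a strict inequality: 50/50 splits are
#' compound), the two largest items form a compound category, ordered
#' alphabetically. Ties at the second rank are broken alphabetically with a
#' warning.
#'
#' @param traits trait table with `diet_<item>` columns, or a profile
#'   matrix.
#' @return character vector of categories, one per species.
#' @export
derive_diet50 <- function(traits) {
  profiles <- if (is.matrix(traits)) traits else diet_profile_matrix(traits)
  items <- colnames(profiles)
  apply(profiles, 1L, function(p) {
    if (max(p) > 50) {
      return(items[which.max(p)])
    }
    ord <- order(-p, items)
    top2 <- ord[1:2]
    if (sum(p == p[ord[2L]]) > sum(p[top2] == p[ord[2L]])) {
      warning("tie at the second diet rank broken alphabetically",
        call. = FALSE
      )
    }
    paste(sort(items[top2]), collapse = "/")
  })
}
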