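#' Read landmark configurations
#'
#' Reads 3-D landmark constellations for one or more species, either from a
#' TPS file (`LM3=` blocks, one per specimen, coordinates taken as-is in mm;
#' any `SCALE=` line is ignored) or from the canonical long-format delimited
#' text with columns `species`, `point`, `x`, `y`, `z`. Every configuration
#' is validated against the template: the point count must match and all
#' coordinates must be finite numbers.
#'
#' @param path file to read.
#' @param template a `landmark_template` the configurations must conform to.
#' @return a named list of k x 3 coordinate matrices, one per species.
#' @export
read_landmarks <- function(path, template) {
  lines <- readLines(path, warn = FALSE)
  is_tps <- any(grepl("^\\s*LM3?\\s*=", lines[nzchar(lines)][1]))
  configs <- if (is_tps) {
    parse_tps(lines)
  } else {
    parse_long_landmarks(path)
  }
  for (sp in names(configs)) {
    pts <- configs[[sp]]
    if (nrow(pts) != template$k) {
      stop(
        "specimen '", sp, "' has ", nrow(pts),
        " points; template expects ", template$k
      )
    }
    if (!all(is.finite(pts))) {
      stop("specimen '", sp, "' has non-numeric or non-finite coordinates")
    }
    validate_configuration(pts, template, species = sp)
  }
  configs
}

## a configuration's own invariants: finite, count, distinct fixed landmarks
validate_configuration <- function(points, template, species = "specimen") {
  fixed <- points[seq_len(template$n_fixed), , drop = FALSE]
  d <- as.matrix(dist(fixed))
  diag(d) <- Inf
  if (any(d < 1e-12)) {
    stop("coincident fixed landmarks in '", species, "'")
  }
  invisible(points)
}

parse_tps <- function(lines) {
  lines <- trimws(lines)
  starts <- grep("^LM3?=", lines)
  if (!length(starts)) stop("no LM3= blocks found in TPS file")
  ends <- c(starts[-1] - 1L, length(lines))
  configs <- list()
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    k <- as.integer(sub("^LM3?=", "", block[1]))
    coord_lines <- block[1L + seq_len(k)]
    vals <- suppressWarnings(
      lapply(strsplit(coord_lines, "\\s+"), as.numeric)
    )
    if (any(vapply(vals, length, 1L) != 3L) ||
      any(!is.finite(unlist(vals)))) {
      stop("non-numeric coordinate in TPS block ", b)
    }
    pts <- do.call(rbind, vals)
    id_line <- grep("^ID=", block, value = TRUE)
    id <- if (length(id_line)) {
      sub("^ID=", "", id_line[1])
    } else {
      paste0("specimen_", b)
    }
    configs[[id]] <- pts
  }
  configs
}

parse_long_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "point", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop(
      "long-format landmark file needs columns: ",
      paste(need, collapse = ", ")
    )
  }
  if (!all(vapply(df[c("x", "y", "z")], is.numeric, TRUE))) {
    stop("non-numeric coordinate in landmark file")
  }
  split_df <- split(df, df$species)
  lapply(split_df, function(d) {
    d <- d[order(d$point), ]
    as.matrix(d[, c("x", "y", "z")])
  })
}

#' Write landmark configurations to the canonical long format
#'
#' Writes full-precision (17 significant digits) comma-separated text with
#' columns `species`, `point`, `x`, `y`, `z`, so that a read/write
#' round-trip reproduces coordinates bit-identically.
#'
#' @param configs named list of k x 3 matrices.
#' @param path output file.
#' @export
write_landmarks <- function(configs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("species,point,x,y,z", con)
  for (sp in names(configs)) {
    pts <- configs[[sp]]
    writeLines(
      sprintf(
        "%s,%d,%.17g,%.17g,%.17g",
        sp, seq_len(nrow(pts)), pts[, 1], pts[, 2], pts[, 3]
      ),
      con
    )
  }
  invisible(path)
}

#' Read a time-calibrated phylogeny
#'
#' Reads a Newick tree, requiring branch lengths on every edge and unique
#' tip labels. Polytomies are retained. If a species list is supplied, every
#' listed species must be a tip.
#'
#' @param path Newick file.
#' @param species optional character vector of species that must be present.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path, species = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree from ", path)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
    length(tree$edge.length) != nrow(tree$edge)) {
    stop("tree has missing branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    stop(
      "duplicated tip labels: ",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
        collapse = ", "
      )
    )
  }
  if (!is.null(species)) {
    absent <- setdiff(species, tree$tip.label)
    if (length(absent)) {
      stop(
        "species missing from tree: ",
        paste(absent, collapse = ", ")
      )
    }
  }
  tree
}

#' Write a phylogeny as Newick
#' @param tree an [ape::phylo] tree.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Restrict shapes, tree and traits to their common species
#'
#' Prunes all three objects to the intersection of their species sets and
#' puts them in the identical (tree tip) order. Species matching is exact on
#' the underscored binomial strings; no fuzzy matching is attempted.
#'
#' @param shapes named list of configurations (or any named-by-species list).
#' @param tree an [ape::phylo] tree.
#' @param traits data frame with a `species_id` column.
#' @return list with elements `shapes`, `tree`, `traits` and `dropped` (the
#'   species removed from each input).
#' @export
match_datasets <- function(shapes, tree, traits) {
  sets <- list(
    shapes = names(shapes),
    tree = tree$tip.label,
    traits = traits$species_id
  )
  common <- Reduce(intersect, sets)
  if (!length(common)) stop("no species shared by shapes, tree and traits")
  tree2 <- ape::keep.tip(tree, common)
  ord <- tree2$tip.label
  list(
    shapes = shapes[ord],
    tree = tree2,
    traits = traits[match(ord, traits$species_id), , drop = FALSE],
    dropped = lapply(sets, setdiff, y = common)
  )
}

#' Check a shapes/tree/traits triple for consistency
#'
#' Validates that the three inputs cover the same species, that every
#' configuration matches the template, and that the diet profile columns are
#' well formed. Errors describe the first inconsistency found.
#'
#' @inheritParams match_datasets
#' @param template a `landmark_template`.
#' @return invisibly `TRUE` when consistent.
#' @export
validate_triple <- function(shapes, tree, traits, template) {
  if (!setequal(names(shapes), tree$tip.label) ||
    !setequal(names(shapes), traits$species_id)) {
    stop("shapes, tree and traits do not cover the same species")
  }
  for (sp in names(shapes)) {
    if (nrow(shapes[[sp]]) != template$k) {
      stop("configuration '", sp, "' does not match the template")
    }
  }
  prof <- diet_profile_matrix(traits, required = FALSE)
  if (!is.null(prof)) check_diet_profiles(prof)
  invisible(TRUE)
}
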