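#' Define a shape-evolution simulation scenario
#'
#' Collects every knob of the synthetic generator into one validated
#' object. Defaults emulate the statistical structure of a 200-species
#' densely landmarked comparative dataset: shapes evolving by Brownian
#' motion on an ultrametric pure-birth tree with phylogenetic signal
#' lambda_true, log-normal centroid sizes with a common allometric shape
#' direction, clade mean shifts, optional latent-factor integration between
#' region blocks, and diet profiles either independent of shape or coupled
#' to it.
#'
#' @param n_tips number of species (default 200).
#' @param birth_rate pure-birth speciation rate per Myr (default 0.1).
#' @param n_curve,n_surface semi-landmark counts for [make_template()].
#' @param sigma2 Brownian rate per coordinate per Myr; shapes are rescaled
#'   if needed so the mean Procrustes-scale displacement from the base
#'   shape stays below `displacement_cap`.
#' @param lambda_true Pagel's lambda of the generating process, in [0, 1].
#' @param beta allometric magnitude: shape displacement per unit log10
#'   centroid size along a fixed unit direction.
#' @param size_meanlog,size_sdlog log-normal centroid-size parameters (mm).
#' @param clade_shift magnitude of a mean-shape shift applied to one basal
#'   clade (0 disables).
#' @param integration `NULL`, or a list with `pair` (two region names) and
#'   `strength` (share of each block's variance explained by a shared
#'   latent Brownian factor, in [0, 1)).
#' @param diet_model `"independent"` or `"coupled"`; under coupling, diet
#'   profile locations shift along the leading shape direction.
#' @param diet_coupling coupling strength (log-weight scale) when coupled.
#' @param n_groups number of clade (phy_group) labels carved from the tree.
#' @param displacement_cap cap on mean Procrustes displacement from base.
#' @param seed mandatory integer seed; every stochastic call derives from
#'   it.
#' @return an object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_tips = 200L, birth_rate = 0.1,
                                n_curve = 509L, n_surface = 797L,
                                sigma2 = 1e-4, lambda_true = 0.8,
                                beta = 0.05,
                                size_meanlog = log(10), size_sdlog = 0.5,
                                clade_shift = 0.05,
                                integration = NULL,
                                diet_model = c("independent", "coupled"),
                                diet_coupling = 0,
                                n_groups = 6L,
                                displacement_cap = 0.2,
                                seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  diet_model <- match.arg(diet_model)
  stopifnot(
    n_tips >= 2L, birth_rate > 0, sigma2 >= 0,
    lambda_true >= 0, lambda_true <= 1, beta >= 0,
    clade_shift >= 0, diet_coupling >= 0
  )
  if (!is.null(integration)) {
    stopifnot(
      length(integration$pair) == 2L,
      integration$strength >= 0, integration$strength < 1
    )
  }
  structure(
    list(
      n_tips = as.integer(n_tips), birth_rate = birth_rate,
      n_curve = as.integer(n_curve), n_surface = as.integer(n_surface),
      sigma2 = sigma2, lambda_true = lambda_true, beta = beta,
      size_meanlog = size_meanlog, size_sdlog = size_sdlog,
      clade_shift = clade_shift, integration = integration,
      diet_model = diet_model, diet_coupling = diet_coupling,
      n_groups = as.integer(n_groups),
      displacement_cap = displacement_cap,
      seed = as.integer(seed)
    ),
    class = "simulation_scenario"
  )
}

#' Simulate an ultrametric pure-birth tree
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed integer seed.
#' @return an ultrametric [ape::phylo] tree with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 0.1, seed) {
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- paste0("sp", seq_len(n_tips))
  tree
}

## carve `g` clade labels by repeatedly splitting the largest group at its
## root-most internal node
clade_groups <- function(tree, g) {
  n <- length(tree$tip.label)
  groups <- rep(1L, n)
  names(groups) <- tree$tip.label
  while (length(unique(groups)) < g) {
    tab <- table(groups)
    big <- names(tab)[which.max(tab)]
    members <- names(groups)[groups == big]
    if (length(members) < 2L) break
    sub_mrca <- ape::getMRCA(tree, members)
    children <- tree$edge[tree$edge[, 1L] == sub_mrca, 2L]
    split_done <- FALSE
    for (ch in children) {
      desc <- if (ch <= n) {
        tree$tip.label[ch]
      } else {
        ape::extract.clade(tree, ch)$tip.label
      }
      desc <- intersect(desc, members)
      if (length(desc) && length(desc) < length(members)) {
        groups[desc] <- max(groups) + 1L
        split_done <- TRUE
        break
      }
    }
    if (!split_done) break
  }
  factor(paste0("clade_", groups))
}

#' Evolve a landmark dataset along a tree
#'
#' Tip shapes are the template base plus a Brownian displacement field
#' accumulated along the branches (per-coordinate rate `sigma2`, tree
#' covariance lambda-transformed by `lambda_true`), an allometric component
#' `beta * log10(size)` along a fixed radial direction, an optional clade
#' mean shift, and an optional shared latent Brownian factor injected into
#' a pair of region blocks. Centroid sizes are drawn log-normal.
#' Configurations are exported pre-superimposition: each receives a random
#' rotation and translation and is scaled so its centroid size equals the
#' drawn size, so that downstream GPA is genuinely exercised.
#'
#' @param tree an [ape::phylo] tree.
#' @param template a template from [make_template()] (with `$base`).
#' @param scenario a `simulation_scenario`.
#' @return list with `configs` (named list of raw k x 3 configurations),
#'   `sizes`, `groups` (clade labels), `tree`, `template`, `latent` (the
#'   latent factor scores, if any), and `shape_signal` (the flattened
#'   pre-transform shapes, for diagnostics).
#' @export
evolve_shapes <- function(tree, template, scenario) {
  set.seed(derive_seed(scenario$seed, 1L))
  n <- length(tree$tip.label)
  base_flat <- flatten_config(template$base)
  p <- length(base_flat)

  C <- tree_covariance(tree)
  Cl <- lambda_transform(C, scenario$lambda_true)
  L <- chol(Cl + diag(1e-10 * mean(diag(Cl)), n))
  disp <- sqrt(scenario$sigma2) * crossprod(L, matrix(rnorm(n * p), n, p))

  ## cap mean Procrustes-scale displacement from the base shape
  base_cs <- centroid_size(template$base)
  rel <- mean(sqrt(rowSums(disp^2))) / base_cs
  if (rel > scenario$displacement_cap) {
    disp <- disp * (scenario$displacement_cap / rel)
  }

  shapes <- sweep(disp, 2L, base_flat, `+`)
  rownames(shapes) <- tree$tip.label

  sizes <- rlnorm(n, scenario$size_meanlog, scenario$size_sdlog)
  names(sizes) <- tree$tip.label
  if (scenario$beta > 0) {
    dir_allo <- allometric_direction(template$base)
    lsize <- log10(sizes) - mean(log10(sizes))
    shapes <- shapes + scenario$beta * base_cs * outer(lsize, dir_allo)
  }

  groups <- clade_groups(tree, scenario$n_groups)
  if (scenario$clade_shift > 0) {
    shift_dir <- rnorm(p)
    shift_dir <- shift_dir / sqrt(sum(shift_dir^2))
    target <- levels(groups)[1L]
    hit <- groups == target
    shapes[hit, ] <- shapes[hit, ] +
      scenario$clade_shift * base_cs * matrix(shift_dir, sum(hit), p,
        byrow = TRUE
      )
  }

  latent <- NULL
  if (!is.null(scenario$integration)) {
    s <- scenario$integration$strength
    if (s > 0) {
      z <- drop(crossprod(chol(C), rnorm(n)))
      z <- (z - mean(z)) / sd(z)
      latent <- setNames(z, tree$tip.label)
      for (region in scenario$integration$pair) {
        cols <- coord_columns(which(template$region_map == region))
        d <- rnorm(length(cols))
        d <- d / sqrt(sum(d^2))
        v_block <- sum(apply(shapes[, cols, drop = FALSE], 2L, var))
        a <- sqrt(s / (1 - s) * v_block)
        shapes[, cols] <- shapes[, cols] + a * outer(z, d)
      }
    }
  }

  configs <- lapply(tree$tip.label, function(sp) {
    pts <- unflatten_config(shapes[sp, ])
    pts <- sweep(pts, 2L, colMeans(pts))
    pts <- pts * (sizes[sp] / sqrt(sum(pts^2)))
    pts <- pts %*% random_rotation()
    sweep(pts, 2L, runif(3L, -5, 5), `+`)
  })
  names(configs) <- tree$tip.label

  list(
    configs = configs, sizes = sizes, groups = groups,
    tree = tree, template = template, latent = latent,
    shape_signal = shapes
  )
}

## a fixed, smooth, genuinely non-affine allometric deformation field:
## quadratic bending of the base shape with the tangent space of similarity
## transforms (translations, rotations, scaling) projected out, so the
## signal survives Procrustes superimposition
allometric_direction <- function(base) {
  k <- nrow(base)
  Xc <- sweep(base, 2L, colMeans(base))
  field <- cbind(Xc[, 3L]^2 - Xc[, 2L]^2, Xc[, 1L] * Xc[, 3L], Xc[, 1L]^2)
  sim_basis <- cbind(
    flatten_config(matrix(rep(c(1, 0, 0), k), k, 3L, byrow = TRUE)),
    flatten_config(matrix(rep(c(0, 1, 0), k), k, 3L, byrow = TRUE)),
    flatten_config(matrix(rep(c(0, 0, 1), k), k, 3L, byrow = TRUE)),
    flatten_config(Xc), # uniform scaling
    flatten_config(Xc %*% rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0))),
    flatten_config(Xc %*% rbind(c(0, 0, -1), c(0, 0, 0), c(1, 0, 0))),
    flatten_config(Xc %*% rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)))
  )
  v <- flatten_config(field)
  q <- qr.Q(qr(sim_basis))
  v <- v - q %*% crossprod(q, v)
  drop(v / sqrt(sum(v^2)))
}

## enumerations of the discrete ecological variables
ecology_levels <- list(
  trophic_level = c("herbivore", "carnivore", "scavenger"),
  trophic_niche = c(
    "frugivore", "granivore", "nectarivore", "terrestrial_herbivore",
    "aquatic_herbivore", "invertivore", "vertivore", "aquatic_predator",
    "scavenger"
  ),
  habitat = c(
    "forest", "woodland", "riverine", "grassland", "wetland",
    "shrubland", "human_modified", "marine", "coastal", "rock"
  ),
  primary_lifestyle = c(
    "aerial", "insessorial", "terrestrial", "aquatic", "generalist"
  ),
  beak_use = c(
    "cracking_ripping", "tearing", "pecking_grazing",
    "grabbing_gleaning", "probing", "filtering"
  )
)

## collapse a 10-bin profile into the 5 coarse diet categories
coarse_diet <- function(profile) {
  groups <- c(
    fruit = "fruinect", nect = "fruinect", seed = "plantseed",
    plantseed = "plantseed", planto = "plantseed",
    invertebrate = "invertebrate", vert_ect = "vertfishscav",
    vert_end = "vertfishscav", vert_fish = "vertfishscav",
    scav = "vertfishscav"
  )
  s <- tapply(profile, groups[names(profile)], sum)
  if (max(s) <= 50) "omnivore" else names(s)[which.max(s)]
}

#' Simulate a species trait table
#'
#' Diet profiles are Dirichlet draws binned to multiples of 10 summing to
#' 100 (largest-remainder correction); discrete ecological variables are
#' drawn with a clade-preferred category (70% adherence); `diet` and
#' `diet_50` are derived from the profiles. Under the shape-coupled model,
#' the Dirichlet concentration tilts along the species' leading shape
#' deviation, so diet carries true signal about shape.
#'
#' @param tree the tree the dataset was evolved on.
#' @param dataset output of [evolve_shapes()].
#' @param scenario the `simulation_scenario`.
#' @return a trait table (data frame) with `species_id`, the discrete
#'   ecological variables, `phy_group`, `diet`, `diet_50` and the 10
#'   `diet_<item>` profile columns.
#' @export
simulate_traits <- function(tree, dataset, scenario) {
  set.seed(derive_seed(scenario$seed, 2L))
  species <- tree$tip.label
  n <- length(species)

  shape_dev <- dataset$shape_signal -
    matrix(colMeans(dataset$shape_signal), n,
      ncol(dataset$shape_signal),
      byrow = TRUE
    )
  lead <- svd(shape_dev, nu = 1L, nv = 0L)$u[, 1L]
  lead <- (lead - mean(lead)) / sd(lead)

  tilt <- c(1, 1, 1, 1, 1, -1, -1, -1, -1, -1) / 2
  profiles <- t(vapply(seq_len(n), function(i) {
    alpha <- rep(0.4, 10L)
    if (scenario$diet_model == "coupled" && scenario$diet_coupling > 0) {
      alpha <- alpha * exp(scenario$diet_coupling * lead[i] * tilt)
    }
    largest_remainder_round(rdirichlet_one(alpha))
  }, integer(10L)))
  colnames(profiles) <- diet_items
  rownames(profiles) <- species

  groups <- dataset$groups
  draw_discrete <- function(levels_) {
    pref <- sample(levels_, nlevels(groups), replace = TRUE)
    vapply(seq_len(n), function(i) {
      if (runif(1) < 0.7) {
        pref[as.integer(groups[i])]
      } else {
        sample(levels_, 1L)
      }
    }, "")
  }

  traits <- data.frame(
    species_id = species,
    trophic_level = draw_discrete(ecology_levels$trophic_level),
    trophic_niche = draw_discrete(ecology_levels$trophic_niche),
    habitat = draw_discrete(ecology_levels$habitat),
    primary_lifestyle = draw_discrete(ecology_levels$primary_lifestyle),
    beak_use = draw_discrete(ecology_levels$beak_use),
    phy_group = as.character(groups),
    stringsAsFactors = FALSE
  )
  traits$diet <- apply(profiles, 1L, coarse_diet)
  traits$diet_50 <- unname(derive_diet50(profiles))
  prof_df <- as.data.frame(profiles)
  names(prof_df) <- paste0("diet_", diet_items)
  cbind(traits, prof_df)
}

#' Simulate a full synthetic comparative dataset
#'
#' Convenience wrapper running [simulate_tree()], [make_template()],
#' [evolve_shapes()] and [simulate_traits()] from one scenario.
#'
#' @param scenario a `simulation_scenario`.
#' @return list with `tree`, `template`, `configs`, `sizes`, `groups`,
#'   `traits`, `latent`, `shape_signal`, `scenario`.
#' @export
simulate_dataset <- function(scenario) {
  tree <- simulate_tree(
    scenario$n_tips, scenario$birth_rate,
    seed = derive_seed(scenario$seed, 0L)
  )
  template <- make_template(scenario$n_curve, scenario$n_surface)
  shapes <- evolve_shapes(tree, template, scenario)
  traits <- simulate_traits(tree, shapes, scenario)
  c(shapes[c(
    "configs", "sizes", "groups", "tree", "template",
    "latent", "shape_signal"
  )], list(traits = traits, scenario = scenario))
}
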