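#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end inference chain on one dataset: GPA with
#' semi-landmark sliding, shape PCA, diet distance/PCoA and derived diet
#' categories, a battery of lambda-rescaled PGLS models, the internal
#' integration suite, and the landmark-scheme Mantel validation. The run is
#' a pure function of (inputs, config, seeds): rerunning with the same
#' configuration yields bit-identical statistic tables.
#'
#' @param config a list (or path to a YAML file) with components:
#'   \describe{
#'     \item{simulate}{scenario arguments passed to
#'       [simulation_scenario()] (synthetic mode), or}
#'     \item{landmarks, tree, traits}{paths to a long-format landmark file,
#'       Newick tree and trait table CSV, plus `template` arguments for
#'       [make_template()] (data mode);}
#'     \item{formulas}{character vector of PGLS model formulas over the
#'       trait columns, `csize` (centroid size) and `diet_matrix`;}
#'     \item{scopes}{optional named list of species subsets;}
#'     \item{n_perm_pgls, n_perm_pls, n_perm_mantel}{permutation counts
#'       (defaults 999, 999, 9999);}
#'     \item{slide, slide_rounds}{sliding controls (defaults TRUE, 5);}
#'     \item{validate_scheme, integration}{logical switches;}
#'     \item{seed}{mandatory integer seed;}
#'     \item{out_dir}{optional output directory for delimited tables and a
#'       YAML manifest.}
#'   }
#' @return list with `aligned`, `pca`, `pca_table`, `diet`, `pgls_table`,
#'   `pgls_fits`, `integration`, `scheme`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must carry a seed")
  seed <- as.integer(config$seed)

  ## ---- inputs -------------------------------------------------------
  if (!is.null(config$simulate)) {
    scen <- do.call(
      simulation_scenario,
      c(config$simulate, list(seed = seed))
    )
    dataset <- simulate_dataset(scen)
    configs <- dataset$configs
    tree <- dataset$tree
    traits <- dataset$traits
    template <- dataset$template
  } else {
    template <- do.call(make_template, config$template %||% list())
    configs <- read_landmarks(config$landmarks, template)
    traits <- read.csv(config$traits, stringsAsFactors = FALSE)
    tree <- read_tree(config$tree)
  }
  matched <- match_datasets(configs, tree, traits)
  configs <- matched$shapes
  tree <- matched$tree
  traits <- matched$traits

  ## ---- superimposition and shape space ------------------------------
  slide <- config$slide %||% TRUE
  aligned <- gpa(configs,
    slide = slide, template = template,
    slide_rounds = config$slide_rounds %||% 5L
  )
  pca <- shape_pca(aligned)
  pca_table <- data.frame(
    axis = seq_along(pca$eigenvalues),
    eigenvalue = pca$eigenvalues,
    percent_variance = pca$percent_variance,
    cumulative_percent = cumsum(pca$percent_variance)
  )

  ## ---- ecology space ------------------------------------------------
  D_diet <- diet_distance(traits)
  diet_pcoa <- pcoa(D_diet)
  traits$diet_50 <- unname(derive_diet50(traits))

  ## ---- PGLS battery -------------------------------------------------
  C <- tree_covariance(tree)
  Y <- flatten_array(aligned$coords)
  model_data <- traits
  model_data$csize <- as.numeric(aligned$centroid_size[traits$species_id])
  n_axes_dm <- min(5L, ncol(diet_pcoa$coordinates))
  model_data$diet_matrix <-
    diet_pcoa$coordinates[traits$species_id, seq_len(n_axes_dm)]
  formulas <- config$formulas %||% c(
    "shape ~ log10(csize)", "shape ~ phy_group", "shape ~ diet",
    "shape ~ diet_50", "shape ~ diet_matrix", "shape ~ habitat",
    "shape ~ beak_use", "shape ~ trophic_level", "shape ~ trophic_niche",
    "shape ~ primary_lifestyle"
  )
  n_perm_pgls <- config$n_perm_pgls %||% 999L
  pgls_fits <- list()
  pgls_rows <- list()
  for (i in seq_along(formulas)) {
    f <- stats::as.formula(formulas[i])
    fit <- pgls_procrustes_anova(
      f, model_data, C,
      Y = Y,
      n_perm = n_perm_pgls, seed = derive_seed(seed, 100L + i)
    )
    pgls_fits[[formulas[i]]] <- fit
    tab <- fit$table
    tab$formula <- formulas[i]
    pgls_rows[[i]] <- tab
  }
  pgls_table <- do.call(rbind, pgls_rows)

  ## ---- integration suite -------------------------------------------
  integration <- NULL
  if (isTRUE(config$integration %||% TRUE)) {
    integration <- run_integration_suite(
      aligned, template, tree,
      neighbours = config$neighbours,
      scopes = config$scopes,
      pairings = "internal",
      n_perm = config$n_perm_pls %||% 999L,
      seed = derive_seed(seed, 200L)
    )
  }

  ## ---- landmark-scheme validation ----------------------------------
  scheme <- NULL
  if (isTRUE(config$validate_scheme %||% TRUE)) {
    scheme <- compare_landmark_schemes(
      configs, template,
      slide = slide,
      n_perm = config$n_perm_mantel %||% 9999L,
      seed = derive_seed(seed, 300L)
    )
  }

  manifest <- list(
    package_version = as.character(packageVersion("quadmorph")),
    seed = seed,
    n_species = length(configs),
    n_landmarks = template$k,
    slide = slide,
    formulas = formulas,
    n_perm = list(
      pgls = n_perm_pgls,
      pls = config$n_perm_pls %||% 999L,
      mantel = config$n_perm_mantel %||% 9999L
    ),
    dropped_species = matched$dropped,
    checksum = list(
      coordinates = signif(sum(abs(Y)), 12),
      tree = signif(sum(tree$edge.length), 12)
    )
  )

  out <- list(
    aligned = aligned, pca = pca, pca_table = pca_table,
    diet = list(
      distance = D_diet, pcoa = diet_pcoa,
      diet_50 = traits$diet_50
    ),
    pgls_table = pgls_table, pgls_fits = pgls_fits,
    integration = integration, scheme = scheme,
    manifest = manifest
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(pgls_table,
      file.path(config$out_dir, "pgls_table.csv"),
      row.names = FALSE
    )
    write.csv(pca_table,
      file.path(config$out_dir, "pca_variance.csv"),
      row.names = FALSE
    )
    if (!is.null(integration)) {
      write.csv(integration,
        file.path(config$out_dir, "integration.csv"),
        row.names = FALSE
      )
    }
    if (!is.null(scheme)) {
      write.csv(scheme$delta_pd,
        file.path(config$out_dir, "delta_pd.csv")
      )
    }
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  out
}
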