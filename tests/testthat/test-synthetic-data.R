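test_that("pure-birth trees are ultrametric and seed-reproducible", {
  two <- simulate_tree(2L, 0.1, seed = 1L)
  expect_equal(length(two$tip.label), 2L)
  expect_true(ape::is.ultrametric(two))

  t1 <- simulate_tree(40L, 0.1, seed = 5L)
  t2 <- simulate_tree(40L, 0.1, seed = 5L)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- simulate_tree(40L, 0.1, seed = 6L)
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
  expect_true(ape::is.ultrametric(t1))
})

test_that("templates have valid structure at default and reduced sizes", {
  tmpl <- make_template(60L, 60L)
  expect_equal(tmpl$k, 128L)
  expect_equal(tmpl$n_fixed, 8L)
  expect_setequal(unique(tmpl$region_map), quadmorph:::quadrate_regions)
  expect_true(all(table(tmpl$region_map) > 0))

  ## roles and regions each cover every point exactly once
  expect_length(tmpl$roles, tmpl$k)
  expect_length(tmpl$region_map, tmpl$k)

  ## no coincident fixed landmarks
  dfix <- dist(tmpl$base[1:8, ])
  expect_gt(min(dfix), 0.1)

  ## curve points lie on their defining parametric arcs
  spec <- tmpl$curve_specs
  fixed <- tmpl$base[1:8, ]
  for (i in seq_len(nrow(spec))) {
    idx <- quadmorph:::template_curve_indices(tmpl, i)
    t <- seq_along(idx) / (length(idx) + 1)
    expected <- quadmorph:::quadrate_curve_eval(spec, fixed, i, t)
    expect_equal(unname(tmpl$base[idx, ]), unname(expected), tolerance = 1e-9)
  }
})

test_that("a signal-free scenario collapses to the base shape after GPA", {
  scen <- suppressWarnings(simulation_scenario(
    n_tips = 8L, n_curve = 20L, n_surface = 20L,
    sigma2 = 0, beta = 0, clade_shift = 0, seed = 3L
  ))
  ds <- suppressWarnings(simulate_dataset(scen))
  al <- gpa(ds$configs)
  D <- procrustes_distance_matrix(al)
  expect_lt(max(D), 1e-8)
})

test_that("diet profiles are valid 10-bin compositions", {
  ds <- small_dataset()
  prof <- quadmorph:::diet_profile_matrix(ds$traits)
  expect_true(all(rowSums(prof) == 100))
  expect_true(all(prof %% 10 == 0))
  expect_true(all(prof >= 0))
  ## discrete variables take values from the documented enumerations
  for (v in names(quadmorph:::ecology_levels)) {
    expect_true(all(ds$traits[[v]] %in% quadmorph:::ecology_levels[[v]]))
  }
})

test_that("the generator is deterministic under its seed", {
  ds1 <- suppressWarnings(simulate_dataset(small_scenario(seed = 12L)))
  ds2 <- suppressWarnings(simulate_dataset(small_scenario(seed = 12L)))
  expect_identical(ds1$configs, ds2$configs)
  expect_identical(ds1$traits, ds2$traits)
  ds3 <- suppressWarnings(simulate_dataset(small_scenario(seed = 13L)))
  expect_false(identical(ds1$configs, ds3$configs))
})

test_that("latent integration factors inject the requested covariance", {
  scen <- simulation_scenario(
    n_tips = 40L, n_curve = 30L, n_surface = 30L,
    integration = list(
      pair = c("otic_process", "mandibular_process"),
      strength = 0.5
    ),
    seed = 21L
  )
  ds <- suppressWarnings(simulate_dataset(scen))
  expect_length(ds$latent, 40L)
  ## the latent factor should explain about half of each block's variance
  tmpl <- ds$template
  for (region in scen$integration$pair) {
    cols <- quadmorph:::coord_columns(which(tmpl$region_map == region))
    block <- ds$shape_signal[, cols]
    r2 <- summary(lm(block %*% rnorm(ncol(block)) ~ ds$latent))$r.squared
    expect_gt(r2, 0.1)
  }
})

test_that("mean displacement from the base shape respects the cap", {
  scen <- simulation_scenario(
    n_tips = 20L, n_curve = 30L, n_surface = 30L,
    sigma2 = 10, seed = 31L # absurdly fast evolution, must be capped
  )
  ds <- suppressWarnings(simulate_dataset(scen))
  base_flat <- quadmorph:::flatten_config(ds$template$base)
  base_cs <- centroid_size(ds$template$base)
  disp <- sweep(ds$shape_signal, 2L, base_flat)
  ## allometry and clade shifts add on top of the capped Brownian field
  rel <- mean(sqrt(rowSums(disp^2))) / base_cs
  expect_lt(rel, 0.35)
})

test_that("default allometry is recoverable by the PGLS chain", {
  rej <- vapply(1:5, function(r) {
    scen <- simulation_scenario(
      n_tips = 100L, n_curve = 30L, n_surface = 30L,
      seed = 1000L + r
    )
    ds <- suppressWarnings(simulate_dataset(scen))
    al <- gpa(ds$configs, slide = FALSE, template = ds$template)
    C <- tree_covariance(ds$tree)
    Y <- quadmorph:::flatten_array(al$coords)
    d <- data.frame(csize = as.numeric(al$centroid_size))
    f <- pgls_procrustes_anova(shape ~ log10(csize), d, C,
      Y = Y,
      n_perm = 199L, seed = r
    )
    f$table$p[1L] < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.8)
})

test_that("shape-coupled diet profiles carry signal; independent ones do not", {
  run_diet <- function(model, strength, seed, n) {
    scen <- simulation_scenario(
      n_tips = n, n_curve = 30L, n_surface = 30L,
      diet_model = model, diet_coupling = strength, seed = seed
    )
    ds <- suppressWarnings(simulate_dataset(scen))
    al <- gpa(ds$configs, slide = FALSE, template = ds$template)
    C <- tree_covariance(ds$tree)
    Y <- quadmorph:::flatten_array(al$coords)
    dm <- pcoa(diet_distance(ds$traits))$coordinates[, 1:2]
    d <- data.frame(row.names = ds$traits$species_id)
    d$diet_matrix <- dm
    f <- pgls_procrustes_anova(shape ~ diet_matrix, d, C,
      Y = Y,
      n_perm = 199L, seed = seed
    )
    f$table$p[1L]
  }
  p_coupled <- vapply(
    1:5, function(s) run_diet("coupled", 4, 2000L + s, 200L), 0
  )
  expect_gte(mean(p_coupled < 0.05), 0.8)
  p_indep <- vapply(
    1:5, function(s) run_diet("independent", 0, 3000L + s, 100L), 0
  )
  expect_lte(sum(p_indep < 0.05), 1L)
})
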