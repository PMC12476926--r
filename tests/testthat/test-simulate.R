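# The synthetic-data generators: determinism, moments, recovery hooks.

test_that("every generator is reproducible from its seed", {
  a <- simulate_traits(n_species = 5, n_sites = 4, seed = 42)
  b <- simulate_traits(n_species = 5, n_sites = 4, seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a$observations,
    simulate_traits(n_species = 5, n_sites = 4, seed = 43)$observations))

  expect_identical(simulate_dem("gaussian_noise", 10, 10, seed = 7),
                   simulate_dem("gaussian_noise", 10, 10, seed = 7))
  expect_identical(simulate_monthly_precip(150, 40, seed = 7),
                   simulate_monthly_precip(150, 40, seed = 7))
  expect_identical(simulate_occurrences(n_species = 3, seed = 7),
                   simulate_occurrences(n_species = 3, seed = 7))
  expect_identical(simulate_coupled_itv_range(n_species = 20, seed = 7),
                   simulate_coupled_itv_range(n_species = 20, seed = 7))
})

test_that("simulated observations have the promised structure", {
  sim <- simulate_traits(n_species = 12, n_sites = 8, seed = 42)
  obs <- sim$observations
  expect_true(all(obs$value > 0))
  # every cell respects the truncation minimum, species occupy >= 4 sites
  cells <- table(obs$species, obs$site)
  expect_true(all(cells[cells > 0] >= 6))
  expect_true(all(rowSums(cells > 0) >= 4))
  # truth records one row per occupied cell
  expect_equal(nrow(sim$truth$cells), sum(cells > 0))
  # fixed_n overrides the Poisson law
  sim2 <- simulate_traits(n_species = 4, n_sites = 4, fixed_n = 9, seed = 42,
                          min_sites_per_species = 4)
  expect_true(all(table(sim2$observations$species,
                        sim2$observations$site) == 9))
})

test_that("hyperdistribution moments are matched across many species", {
  sim <- simulate_traits(n_species = 400, n_sites = 4, mu2 = 0.3,
                         sigma2 = 0.2, seed = 42)
  b2 <- sim$truth$b2
  se_mean <- 0.2 / sqrt(400)
  expect_lt(abs(mean(b2) - 0.3), 4 * se_mean)
  expect_lt(abs(sd(b2) - 0.2), 0.04)
  b1 <- sim$truth$b1
  expect_lt(abs(mean(b1) - (-3)), 4 * 0.3 / sqrt(400))
})

test_that("with no noise and huge cells the measured log ITV* hits the model line", {
  sim <- simulate_traits(n_species = 3, n_sites = 3, mu1 = -3, mu2 = 0.8,
                         sigma1 = 0, sigma2 = 0, tau = 0, fixed_n = 10000,
                         min_sites_per_species = 3, seed = 42)
  tab <- itv_table(sim$observations)
  env_z <- sim$truth$env_z[tab$within$site]
  expect_true(all(abs(tab$within$log_itv_star - (-3 + 0.8 * env_z)) < 0.05))
})

test_that("simulated terrain matches its closed-form roughness", {
  expect_equal(site_roughness(simulate_dem("constant", 20, 20)), 0)
  ramp <- simulate_dem("ramp", 10, 10, slope = 2)
  expect_equal(terrain_roughness(ramp)[5, 5], 1.5)
  # iid noise: E[TRI] = sd * E|Z1 - Z2| = 2 sd / sqrt(pi) in the interior
  noise <- simulate_dem("gaussian_noise", 120, 120, sd = 1, seed = 42)
  tri <- terrain_roughness(noise)
  interior <- tri[2:119, 2:119]
  expect_equal(mean(interior), 2 / sqrt(pi), tolerance = 0.05)
  # linear scaling in sd
  noise3 <- simulate_dem("gaussian_noise", 120, 120, sd = 3, seed = 42)
  expect_equal(site_roughness(noise3), 3 * site_roughness(noise),
               tolerance = 1e-10)
})

test_that("monthly precipitation hits the target CV and mean", {
  expect_equal(simulate_monthly_precip(200, 0, seed = 1), rep(200, 12))
  for (target in c(20, 50, 80)) {
    x <- simulate_monthly_precip(150, target, seed = 42)
    expect_length(x, 12)
    expect_true(all(x >= 0))
    expect_lt(abs(rainfall_cv(x) - target) / target, 0.10)
    expect_equal(mean(x), 150, tolerance = 1)
  }
})

test_that("occurrence niches reproduce their true 95% widths", {
  occ <- simulate_occurrences(n_species = 2, records_per_species = 10000,
                              attributes = list(elevation = c(500, 600, 100)),
                              fixed_widths = c(elevation = 100),
                              geology_classes = c("volcanic", "limestone"),
                              seed = 42)
  r <- species_ranges(occ$occurrences, attributes = "elevation",
                      geology_classes = c("volcanic", "limestone"))
  expect_equal(r$elevation_range, rep(95, 2), tolerance = 0.02 * 95)
  expect_equal(occ$truth$elevation_range, rep(95, 2))
  # width 0 collapses the range to a point
  occ0 <- simulate_occurrences(n_species = 1, records_per_species = 50,
                               attributes = list(pet = c(1500, 1500, 0)),
                               seed = 42)
  expect_equal(species_ranges(occ0$occurrences,
                              attributes = "pet")$pet_range, 0)
  # with enough records every class in the species' set is seen
  expect_true(all(occ$truth$geology_count ==
                    tapply(occ$occurrences$geology, occ$occurrences$species,
                           function(g) length(unique(g)))[occ$truth$species]))
})

test_that("the coupled generator ties across-site ITV to the range predictors", {
  sim <- simulate_coupled_itv_range(n_species = 60, resid_sd = 0.2, seed = 42)
  tab <- itv_table(sim$observations)
  # measured across-site log ITV* tracks the generative target (chi-square
  # sampling noise at n = 100 obs/species has sd ~ sqrt(2/99) ~ 0.14)
  target <- sim$truth$species$target_log_itv[
    match(tab$across$species, sim$truth$species$species)]
  expect_gt(cor(tab$across$log_itv_star, target), 0.8)
  expect_lt(mean(abs(tab$across$log_itv_star - target)), 0.3)
  # truth exposes the standardized predictors used
  expect_equal(dim(sim$truth$X_std), c(60L, 6L))
})

test_that("simulated datasets round-trip through the package readers", {
  sim <- simulate_traits(n_species = 4, n_sites = 4, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(sim$observations, path)
  expect_equal(read_trait_table(path, quiet = TRUE), sim$observations)

  dem <- simulate_dem("gaussian_noise", 8, 9, seed = 3)
  dem$z <- round(dem$z, 6)
  pasc <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(dem, pasc)
  expect_equal(read_esri_ascii(pasc)$z, dem$z)
})
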