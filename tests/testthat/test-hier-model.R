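# The hierarchical within-site model: design assembly, likelihood, MCMC.

make_design_direct <- function(n_species = 20, n_sites = 8, a = -3, b = 0.8,
                               tau = 0.5, seed = 42,
                               n_range = c(6L, 30L)) {
  set.seed(seed)
  env <- scale(seq_len(n_sites))[, 1]
  d <- expand.grid(species = sprintf("sp%02d", seq_len(n_species)),
                   site = sprintf("S%d", seq_len(n_sites)),
                   stringsAsFactors = FALSE)
  d$env <- env[match(d$site, sprintf("S%d", seq_len(n_sites)))]
  d$n <- sample(n_range[1]:n_range[2], nrow(d), replace = TRUE)
  d$log_itv_star <- a + b * d$env + (tau / d$n) * rnorm(nrow(d))
  d
}

test_that("hier_design joins, standardizes and validates", {
  obs <- make_obs(list(sp1 = c(S1 = 6, S2 = 6), sp2 = c(S1 = 6, S2 = 6)))
  tab <- itv_table(obs)
  sites <- data.frame(site = c("S1", "S2"), rainfall_cv = c(30, 50))
  d <- hier_design(tab$within, sites, "rainfall_cv")
  expect_equal(nrow(d), 4L)
  env_site <- unique(d[c("site", "env")])$env
  expect_equal(mean(env_site), 0)
  expect_equal(sd(env_site), 1)
  expect_equal(attr(d, "env_variable"), "rainfall_cv")

  expect_error(hier_design(tab$within, sites[1, ], "rainfall_cv"), "S2")
  expect_error(hier_design(tab$within, sites, "nonexistent"), "not found")
  sites$flat <- 5
  expect_error(hier_design(tab$within, sites, "flat"), "constant")

  # zero-variance cells are excluded with a warning
  w2 <- tab$within
  w2$log_itv_star[1] <- NA
  expect_warning(d2 <- hier_design(w2, sites, "rainfall_cv"), "undefined")
  expect_equal(nrow(d2), 3L)
})

test_that("row log-likelihood matches the scaled-normal density", {
  # at zero residual the density is the normal mode
  row <- data.frame(log_itv_star = -3, env = 0.5, n = 10L, sp = 1L)
  pars <- list(b1 = -3.25, b2 = 0.5, tau = 2)
  expect_equal(hier_loglik(row, pars),
               -log(2 / 10) - 0.5 * log(2 * pi))
  # larger n shrinks the residual sd: identical nonzero residuals cost more
  row_hi <- row; row_hi$log_itv_star <- -2.5
  ll_n10 <- hier_loglik(row_hi, pars)
  row_hi$n <- 20L
  expect_lt(hier_loglik(row_hi, pars), ll_n10)
  # the sqrt convention penalizes the same residual less severely
  expect_gt(hier_loglik(row_hi, pars, "sd_over_sqrt_n"),
            hier_loglik(row_hi, pars, "sd_over_n"))

  # independent oracle on random rows
  set.seed(42)
  for (rep in 1:100) {
    r <- data.frame(log_itv_star = rnorm(1, -3, 1), env = rnorm(1),
                    n = sample(2:40, 1), sp = 1L)
    p <- list(beta0 = rnorm(1, 0, 0.1), b1 = rnorm(1, -3, 0.5),
              b2 = rnorm(1, 0, 0.5), tau = runif(1, 0.1, 5))
    mu <- p$beta0 + p$b1 + p$b2 * r$env
    sdv <- p$tau / r$n
    expect_equal(hier_loglik(r, p),
                 -log(sdv) - 0.5 * log(2 * pi) -
                   0.5 * ((r$log_itv_star - mu) / sdv)^2,
                 tolerance = 1e-12)
  }
  expect_error(hier_loglik(row, list(b1 = 0, b2 = 0, tau = 0)), "tau")
  expect_error(hier_loglik(data.frame(log_itv_star = 0, env = 0, n = 1,
                                      sp = 1L), pars), ">= 2")
})

test_that("MCMC fit recovers a strong community slope and respects priors", {
  sim <- simulate_traits(n_species = 25, n_sites = 8, mu1 = -3, mu2 = 0.8,
                         sigma1 = 0.3, sigma2 = 0.2, tau = 0.5, seed = 42)
  tab <- itv_table(sim$observations)
  sites <- sim$sites
  names(sites)[2] <- "envvar"
  d <- hier_design(tab$within, sites, "envvar")
  fit <- fit_itv_hier(d, chains = 2, iter = 1500, warmup = 750, seed = 42)
  s <- summary(fit)
  expect_equal(s["mu2", "mean"], 0.8, tolerance = 0.25)
  # prior support: sd parameters stay inside (0, 10)
  m <- as.matrix(fit$draws)
  for (p in c("sigma1", "sigma2", "tau")) {
    expect_true(all(m[, p] > 0 & m[, p] < 10))
  }
  # equal draw counts across parameters, chains x iter total
  expect_equal(nrow(m), 2 * 1500)
  expect_true(all(c("mu1", "mu2", "tau") %in% rownames(s)))
  expect_true(all(is.finite(s$rhat[match(c("mu1", "mu2"), rownames(s))])))

  # the community slope is classified positive here
  cl <- classify_slopes(fit)
  expect_equal(cl$label[cl$parameter == "mu2"], "positive")
  # species effects table lines up with the species set
  eff <- species_effects(fit, "b2")
  expect_setequal(eff$species, unique(d$species))

  # same seed reproduces the posterior exactly
  fit2 <- fit_itv_hier(d, chains = 2, iter = 1500, warmup = 750, seed = 42)
  expect_identical(summary(fit2), s)
})

test_that("row order does not change the posterior beyond Monte-Carlo error", {
  d <- make_design_direct(n_species = 10, n_sites = 6, seed = 42)
  fit_a <- fit_itv_hier(d, chains = 2, iter = 1000, warmup = 500, seed = 42)
  set.seed(1)
  fit_b <- fit_itv_hier(d[sample(nrow(d)), ], chains = 2, iter = 1000,
                        warmup = 500, seed = 42)
  expect_equal(coef(fit_a)[["mu2"]], coef(fit_b)[["mu2"]], tolerance = 0.05)
})

test_that("with no species-level spread the fit reduces to n^2-weighted least squares", {
  d <- make_design_direct(n_species = 15, n_sites = 8, a = -3, b = 0.8,
                          tau = 0.5, seed = 42)
  fit <- fit_itv_hier(d, chains = 2, iter = 1500, warmup = 750, seed = 42)
  wls <- lm(log_itv_star ~ env, data = d, weights = n^2)
  expect_equal(coef(fit)[["mu1"]], unname(coef(wls)[1]), tolerance = 0.02)
  expect_equal(coef(fit)[["mu2"]], unname(coef(wls)[2]), tolerance = 0.02)
})

test_that("slope classification follows the CI-versus-zero rule", {
  # handcrafted draws with known quantiles
  n <- 4000
  set.seed(42)
  draws <- coda::mcmc.list(coda::mcmc(cbind(
    mu2 = rnorm(n, 0.5, 0.1),          # CI well above zero
    `b2[1]` = rnorm(n, -0.5, 0.1),     # CI well below zero
    `b2[2]` = rnorm(n, 0, 1))))        # straddles zero
  obj <- structure(list(draws = draws, species = c("spX", "spY")),
                   class = "itv_hier")
  cl <- classify_slopes(obj, level = 0.95)
  expect_equal(cl$label, c("positive", "negative", "nonsignificant"))
  # a wider interval can only lose significance
  cl99 <- classify_slopes(obj, level = 0.999)
  expect_true(all(cl99$lower <= cl$lower + 1e-9))
})

test_that("the caterpillar plot renders without error", {
  d <- make_design_direct(n_species = 6, n_sites = 5, seed = 42)
  fit <- suppressWarnings(fit_itv_hier(d, chains = 2, iter = 300,
                                       warmup = 200, seed = 1))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("the literal double-intercept parameterization keeps beta0 + mu1 identified", {
  d <- make_design_direct(n_species = 10, n_sites = 6, a = -3, b = 0.5,
                          seed = 42)
  fit <- fit_itv_hier(d, chains = 2, iter = 1500, warmup = 750, seed = 42,
                      literal_intercept = TRUE)
  s <- summary(fit)
  expect_true("beta0" %in% rownames(s))
  # beta0 and mu1 are individually pulled by their priors, but their sum is
  # the identified intercept
  expect_equal(s["beta0", "mean"] + s["mu1", "mean"], -3, tolerance = 0.15)
})
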