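# The range regression: design, VIF, Bayesian fit, AIC selection, correlation.

make_range_data <- function(n = 50, p = 4, beta = NULL, sd = 1, seed = 42) {
  set.seed(seed)
  # standardized predictors, so the generating coefficients are on the same
  # scale the fitted design uses
  X <- standardize_columns(matrix(rnorm(n * p), n, p,
                                  dimnames = list(NULL, paste0("x", seq_len(p)))))
  if (is.null(beta)) beta <- rep(0, p)
  y <- drop(X %*% beta) + rnorm(n, 0, sd)
  ranges <- cbind(data.frame(species = sprintf("sp%03d", seq_len(n))),
                  as.data.frame(X))
  resp <- data.frame(species = ranges$species, log_itv_star = y)
  range_design(resp, ranges)
}

test_that("range design joins on species and standardizes predictors", {
  set.seed(42)
  ranges <- data.frame(species = sprintf("sp%02d", 1:33),
                       pet_range = runif(33, 100, 700),
                       cwd_range = runif(33, 50, 600),
                       elevation_range = runif(33, 50, 900),
                       irradiance_range = runif(33, 10, 300),
                       geology_count = sample(1:4, 33, replace = TRUE))
  resp <- data.frame(species = ranges$species,
                     log_itv_star = rnorm(33, -3, 0.5))
  d <- range_design(resp, ranges)
  expect_equal(dim(d$X), c(33L, 5L))
  expect_equal(unname(colMeans(d$X)), rep(0, 5))
  expect_equal(unname(apply(d$X, 2, sd)), rep(1, 5))

  # a species without ranges is excluded with a warning
  expect_warning(d2 <- range_design(rbind(resp,
    data.frame(species = "spXX", log_itv_star = -3)), ranges), "spXX")
  expect_equal(length(d2$y), 33L)

  expect_error(range_design(resp[1:5, ], ranges), "under-determined")
  expect_error(range_design(resp, ranges, predictors = "nope"), "not in ranges")
})

test_that("VIF matches the closed form and the leave-one-out oracle", {
  # exactly orthogonal, mean-zero predictors -> VIF 1
  set.seed(42)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(60), 20, 3))))[, 2:4]
  colnames(X) <- c("a", "b", "c")
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-10)

  # two columns with sample correlation exactly 0.9 -> 1/(1-0.81)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(40), 20, 2))))[, 2:3]
  X2 <- cbind(p = Q[, 1], q = 0.9 * Q[, 1] + sqrt(1 - 0.81) * Q[, 2])
  expect_equal(unname(vif(X2)), rep(1 / (1 - 0.81), 2), tolerance = 1e-10)

  # random matrices against regressing each column on the rest
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(20:60, 1); p <- sample(2:6, 1)
    Xr <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    v <- vif(Xr)
    for (j in seq_len(p)) {
      r2 <- summary(lm(Xr[, j] ~ Xr[, -j]))$r.squared
      expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-10)
    }
  }

  expect_warning(vcol <- vif(cbind(u = 1:10, w = 2 * (1:10))), "collinear")
  expect_true(all(is.infinite(vcol)))
  expect_error(vif(matrix(1:10)), "at least 2")
})

test_that("a noiseless linear response is recovered exactly", {
  d <- make_range_data(n = 40, p = 2, beta = c(2, -1), sd = 0)
  fit <- fit_range_model(d, seed = 42)
  co <- coef(fit)
  expect_equal(unname(co["x1"]), 2, tolerance = 1e-8)
  expect_equal(unname(co["x2"]), -1, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("with weak priors the point estimates approach OLS", {
  set.seed(42)
  for (rep in 1:5) {
    d <- make_range_data(n = 60, p = 3, beta = rnorm(3), sd = 1,
                         seed = 42 + rep)
    fit <- fit_range_model(d, prior_scale = 1e4, seed = 1)
    ols <- coef(lm(d$y ~ d$X))
    expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-5)
  }
})

test_that("duplicated predictors raise a collinearity error naming the column", {
  d <- make_range_data(n = 30, p = 2)
  d$X <- cbind(d$X, dup = d$X[, 1])
  expect_error(fit_range_model(d), "singular.*dup")
})

test_that("AIC identity and interval nesting hold on every fit", {
  set.seed(42)
  for (rep in 1:5) {
    d <- make_range_data(n = 40, p = 3, beta = c(0.5, 0, -0.3), sd = 1,
                         seed = 100 + rep)
    fit <- fit_range_model(d, seed = rep)
    # AIC = 2k - 2 logLik with logLik recomputed from scratch
    co <- coef(fit)
    fitted <- drop(cbind(1, d$X) %*% co)
    rss <- sum((d$y - fitted)^2)
    n <- length(d$y)
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    expect_equal(fit$logLik, ll, tolerance = 1e-10)
    expect_equal(fit$AIC, 2 * fit$k - 2 * ll, tolerance = 1e-10)
    expect_equal(fit$k, ncol(d$X) + 2)  # slopes + intercept + residual sd
    # 95% intervals contain the 90% intervals
    cf <- fit$coefficients
    expect_true(all(cf$lo95 <= cf$lo90 & cf$hi95 >= cf$hi90))
    # R^2 within [0, 1]; VIF >= 1
    expect_gte(fit$r_squared, 0); expect_lte(fit$r_squared, 1)
    expect_true(all(fit$vif >= 1))
  }
})

test_that("90% intervals cover zero at the nominal rate under a null response", {
  set.seed(42)
  cover <- 0L
  for (rep in 1:60) {
    d <- make_range_data(n = 200, p = 1, beta = 0, sd = 1, seed = 500 + rep)
    fit <- fit_range_model(d, seed = rep, draws = 1200, warmup = 300)
    cf <- fit$coefficients[2, ]
    cover <- cover + (cf$lo90 <= 0 && cf$hi90 >= 0)
  }
  expect_gte(cover / 60, 0.8)  # ~90% nominal, binomial noise at 60 reps
})

test_that("backward selection traces are monotone and match the exhaustive search", {
  set.seed(42)
  for (rep in 1:5) {
    d <- make_range_data(n = 200, p = 5, beta = c(1, 0.5, 0, 0, 0), sd = 1,
                         seed = 900 + rep)
    sel <- backward_select(d, draws = 500, warmup = 200, seed = rep)
    acc <- sel$trace$aic[sel$trace$accepted]
    expect_true(all(diff(acc) <= 0))
    expect_lte(sel$aic_final, sel$aic_full)
    ex <- exhaustive_select(d)
    expect_setequal(sel$final_predictors, ex$best_predictors)
    # strong predictors are always retained
    expect_true(all(c("x1", "x2") %in% sel$final_predictors))
  }
})

test_that("selection agrees with an independent OLS-based greedy oracle", {
  d <- make_range_data(n = 300, p = 4, beta = c(0.8, 0, 0, -0.6), sd = 1,
                       seed = 42)
  sel <- backward_select(d, draws = 500, warmup = 200, seed = 1)
  # oracle: greedy backward elimination with exact OLS AIC
  keep <- colnames(d$X)
  cur <- oracle_aic_ols(d$X, d$y, keep)
  repeat {
    if (!length(keep)) break
    cand <- sapply(seq_along(keep),
                   function(j) oracle_aic_ols(d$X, d$y, keep[-j]))
    j <- which.min(cand)
    if (cand[j] < cur) { cur <- cand[j]; keep <- keep[-j] } else break
  }
  expect_setequal(sel$final_predictors, keep)
})

test_that("strong signals everywhere mean nothing is dropped", {
  d <- make_range_data(n = 200, p = 4, beta = c(2, -2, 1.5, 1), sd = 1,
                       seed = 42)
  sel <- backward_select(d, draws = 500, warmup = 200, seed = 1)
  expect_setequal(sel$final_predictors, colnames(d$X))
  expect_equal(sel$aic_final, sel$aic_full)
  # the leave-one-out diagnostics all exceed the final AIC
  expect_true(all(sel$aic_without > sel$aic_final))
})

test_that("coefficients are invariant to affine changes of raw predictor units", {
  set.seed(42)
  ranges <- data.frame(species = sprintf("sp%02d", 1:30),
                       pet_range = runif(30, 100, 700),
                       elevation_range = runif(30, 50, 900))
  resp <- data.frame(species = ranges$species,
                     log_itv_star = rnorm(30, -3, 0.5))
  f1 <- fit_range_model(range_design(resp, ranges), seed = 3)
  ranges$pet_range <- ranges$pet_range * 1000 + 5   # change of units
  f2 <- fit_range_model(range_design(resp, ranges), seed = 3)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
})

test_that("the coefficient interval plot renders without error", {
  d <- make_range_data(n = 40, p = 3, beta = c(1, 0, -1), sd = 1, seed = 42)
  fit <- fit_range_model(d, seed = 1)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("Pearson correlation matches the brute-force formula", {
  means <- data.frame(species = c("a", "b", "c", "d"),
                      mean_log = c(1, 2, 3, 4))
  itv <- data.frame(species = c("a", "b", "c", "d"),
                    log_itv_star = c(2, 1, 3, 4))
  out <- mean_itv_correlation(means, itv)
  x <- means$mean_log; y <- itv$log_itv_star
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_manual, tolerance = 1e-12)
  t_manual <- r_manual * sqrt(2 / (1 - r_manual^2))
  expect_equal(out$p, 2 * pt(-abs(t_manual), df = 2), tolerance = 1e-12)

  # perfect linear association and affine invariance
  itv$log_itv_star <- 2 * means$mean_log + 1
  expect_equal(mean_itv_correlation(means, itv)$r, 1)
  means2 <- means; means2$mean_log <- -3 * means$mean_log + 7
  expect_equal(abs(mean_itv_correlation(means2, itv)$r), 1)

  itv$log_itv_star <- rep(1, 4)
  expect_error(mean_itv_correlation(means, itv), "zero-variance")
  expect_error(mean_itv_correlation(means[1:2, ], itv[1:2, ]), "at least 3")
})
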