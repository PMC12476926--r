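## Hierarchical Bayesian random-slopes model: log within-site ITV* against a
## site-level environmental-variability metric, species random intercepts and
## slopes, residual error scaled by the cell sample size.

#' Assemble the design table for the within-site ITV model
#'
#' Joins the within-site ITV* records for a single trait to the site table,
#' picking one environmental-variability column as the predictor. The
#' predictor is standardized across the distinct site values by default (so
#' the N(0,1) priors on the slope hypermean are weakly informative); rows
#' with undefined log ITV* (zero-variance cells) are excluded with a warning.
#'
#' @param itv_within within-site records from [itv_table()] (one trait).
#' @param sites site table (see [read_sites_table()]).
#' @param env_variable name of the predictor column in `sites`, e.g.
#'   `"rainfall_cv"` or `"terrain_roughness"`.
#' @param standardize z-score the predictor across sites (default `TRUE`).
#' @return data.frame with columns `log_itv_star`, `species`, `site`, `env`,
#'   `n`; attributes `env_variable`, `env_center`, `env_scale`, `trait`.
#' @export
hier_design <- function(itv_within, sites, env_variable, standardize = TRUE) {
  stopifnot(is.data.frame(itv_within), is.data.frame(sites))
  if (!env_variable %in% names(sites)) {
    stop("environment variable '", env_variable, "' not found in site table",
         call. = FALSE)
  }
  if ("trait" %in% names(itv_within) && length(unique(itv_within$trait)) > 1L) {
    stop("design must be built for a single trait; got: ",
         paste(unique(itv_within$trait), collapse = ", "), call. = FALSE)
  }
  missing_sites <- setdiff(unique(itv_within$site), sites$site)
  if (length(missing_sites)) {
    stop("site(s) absent from the site table: ",
         paste(missing_sites, collapse = ", "), call. = FALSE)
  }
  env_by_site <- sites[[env_variable]][match(itv_within$site, sites$site)]
  keep <- is.finite(itv_within$log_itv_star)
  if (any(!keep)) {
    warning(sum(!keep), " record(s) with undefined log ITV* excluded",
            call. = FALSE)
  }
  d <- data.frame(log_itv_star = itv_within$log_itv_star[keep],
                  species = itv_within$species[keep],
                  site = itv_within$site[keep],
                  env = env_by_site[keep],
                  n = itv_within$n[keep],
                  stringsAsFactors = FALSE)
  if (length(unique(d$species)) < 2L) {
    stop("need at least 2 species to fit species-level random effects",
         call. = FALSE)
  }
  site_env <- unique(d[c("site", "env")])
  if (length(unique(site_env$env)) < 2L) {
    stop("environmental predictor is constant across sites: degenerate design",
         call. = FALSE)
  }
  ctr <- 0; scl <- 1
  if (standardize) {
    ctr <- mean(site_env$env)
    scl <- stats::sd(site_env$env)
    d$env <- (d$env - ctr) / scl
  }
  attr(d, "env_variable") <- env_variable
  attr(d, "env_center") <- ctr
  attr(d, "env_scale") <- scl
  attr(d, "trait") <- if ("trait" %in% names(itv_within))
    unique(itv_within$trait)[1] else NA_character_
  d
}

#' Row log-likelihood of the within-site ITV model
#'
#' Normal log-density of `log_itv_star` with mean
#' `beta0 + b1[species] + b2[species] * env` and standard deviation `tau / n`
#' (the residual draw is divided by the cell sample size, so its sd shrinks
#' linearly in n) or `tau / sqrt(n)` under the alternative convention.
#'
#' @param row data.frame with columns `log_itv_star`, `env`, `n`, and a
#'   species index column `sp` (integer) or `species` matched against
#'   `names(pars$b1)`.
#' @param pars list with `beta0` (default 0), vectors `b1`, `b2`, and `tau`.
#' @param error_scaling `"sd_over_n"` (default) or `"sd_over_sqrt_n"`.
#' @return Numeric vector of per-row log-densities.
#' @export
hier_loglik <- function(row, pars,
                        error_scaling = c("sd_over_n", "sd_over_sqrt_n")) {
  error_scaling <- match.arg(error_scaling)
  if (is.null(pars$tau) || pars$tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (any(row$n < 2)) stop("cell sample sizes must be >= 2", call. = FALSE)
  idx <- if (!is.null(row$sp)) row$sp else match(row$species, names(pars$b1))
  beta0 <- if (is.null(pars$beta0)) 0 else pars$beta0
  mu <- beta0 + pars$b1[idx] + pars$b2[idx] * row$env
  sdv <- if (error_scaling == "sd_over_n") pars$tau / row$n
         else pars$tau / sqrt(row$n)
  stats::dnorm(row$log_itv_star, mean = mu, sd = sdv, log = TRUE)
}

# JAGS model code for the random-slopes model; priors follow the analysis
# convention: sd hyperparameters uniform(0, su), means/intercept N(0, pm_sd^2)
hier_jags_code <- function(error_scaling, literal_intercept) {
  sd_expr <- if (error_scaling == "sd_over_n") "tau / n[i]" else "tau / sqrt(n[i])"
  b0_line <- if (literal_intercept) "beta0 ~ dnorm(0, pm_prec)" else "beta0 <- 0"
  paste0("model {
  for (i in 1:N) {
    mu_row[i] <- beta0 + b1[sp[i]] + b2[sp[i]] * env[i]
    y[i] ~ dnorm(mu_row[i], pow(", sd_expr, ", -2))
  }
  for (s in 1:S) {
    b1[s] ~ dnorm(mu1, pow(sigma1, -2))
    b2[s] ~ dnorm(mu2, pow(sigma2, -2))
  }
  ", b0_line, "
  mu1 ~ dnorm(0, pm_prec)
  mu2 ~ dnorm(0, pm_prec)
  sigma1 ~ dunif(0, su)
  sigma2 ~ dunif(0, su)
  tau ~ dunif(0, su)
}\n")
}

# derive a reproducible 31-bit seed for a named substream of `seed`
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 8191 + 1) %% 2147483629) + 1L
}

#' Fit the hierarchical within-site ITV model
#'
#' MCMC fit (JAGS) of the random-slopes model
#' \deqn{\log ITV^*_{si,sp} = \beta_0 + \beta_{1,sp} + \beta_{2,sp}
#'   \cdot env_{si} + \epsilon / n_{si,sp}}
#' with \eqn{\beta_{1,sp} \sim N(\mu_1, \sigma_1)},
#' \eqn{\beta_{2,sp} \sim N(\mu_2, \sigma_2)},
#' \eqn{\epsilon \sim N(0, \tau)}. Standard deviations
#' (\eqn{\sigma_1, \sigma_2, \tau}) get uniform(0, 10) priors; means and
#' intercept get N(0, 1) priors. Dividing the residual draw by the cell
#' sample size makes the row residual sd \eqn{\tau / n} — better-sampled
#' cells are held closer to the regression plane. \eqn{\mu_2} is the
#' community-level effect of environmental variability on ITV; the
#' species-specific slopes \eqn{\beta_{2,sp}} are its random deviations.
#'
#' As written the global intercept \eqn{\beta_0} and the intercept hypermean
#' \eqn{\mu_1} are jointly unidentified; by default \eqn{\beta_0} is fixed at
#' 0 and \eqn{\mu_1} is the reported intercept. Set
#' `literal_intercept = TRUE` to restore the redundant double-intercept
#' parameterization for sensitivity checks (then only \eqn{\beta_0 + \mu_1}
#' is interpretable).
#'
#' @param design output of [hier_design()].
#' @param chains,iter,warmup MCMC settings: `iter` sampled iterations per
#'   chain after `warmup` adaptation+burn-in iterations.
#' @param seed master seed; per-chain RNG seeds are derived from it.
#' @param error_scaling residual convention: sd `tau/n` (default, the literal
#'   reading) or `tau/sqrt(n)` (variance scaled by n).
#' @param prior_sd_upper upper bound of the uniform priors on
#'   \eqn{\sigma_1, \sigma_2, \tau}.
#' @param prior_mean_sd sd of the normal priors on the means/intercept.
#' @param literal_intercept keep the redundant free \eqn{\beta_0}.
#' @param quiet suppress JAGS progress output.
#' @return An object of class `itv_hier`: list with `summary` (per-parameter
#'   posterior mean, sd, quantiles, R-hat), `draws` (a `coda::mcmc.list`),
#'   `species` (level order of the random effects), `design`, and the call
#'   settings. Warns (does not fail) when any R-hat exceeds 1.01.
#' @export
fit_itv_hier <- function(design, chains = 4L, iter = 2000L,
                         warmup = ceiling(iter / 2), seed = 1L,
                         error_scaling = c("sd_over_n", "sd_over_sqrt_n"),
                         prior_sd_upper = 10, prior_mean_sd = 1,
                         literal_intercept = FALSE, quiet = TRUE) {
  error_scaling <- match.arg(error_scaling)
  stopifnot(is.data.frame(design), nrow(design) >= 4L,
            prior_sd_upper > 0, prior_mean_sd > 0, iter >= 2L, chains >= 1L)
  species <- sort(unique(design$species))
  sp <- match(design$species, species)
  data <- list(y = design$log_itv_star, env = design$env, n = design$n,
               sp = sp, N = nrow(design), S = length(species),
               pm_prec = 1 / prior_mean_sd^2, su = prior_sd_upper)
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(mu1 = mean(design$log_itv_star), mu2 = 0,
                sigma1 = min(1, prior_sd_upper / 2),
                sigma2 = min(0.5, prior_sd_upper / 2),
                tau = min(1, prior_sd_upper / 2),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = derive_seed(seed, paste0("chain", ch)))
    if (literal_intercept) ini$beta0 <- 0
    ini
  })
  monitors <- c("mu1", "mu2", "sigma1", "sigma2", "tau", "b1", "b2")
  if (literal_intercept) monitors <- c("beta0", monitors)
  code <- hier_jags_code(error_scaling, literal_intercept)
  run <- function() {
    model <- rjags::jags.model(textConnection(code), data = data,
                               inits = inits, n.chains = chains,
                               n.adapt = warmup, quiet = quiet)
    rjags::coda.samples(model, variable.names = monitors, n.iter = iter)
  }
  draws <- if (quiet) {
    utils::capture.output(s <- suppressWarnings(run())); s
  } else run()

  summ <- summarize_draws(draws)
  # label the species random effects
  rn <- rownames(summ)
  for (k in seq_along(species)) {
    rn[rn == paste0("b1[", k, "]")] <- paste0("b1[", species[k], "]")
    rn[rn == paste0("b2[", k, "]")] <- paste0("b2[", species[k], "]")
  }
  rownames(summ) <- rn
  high <- rn[is.finite(summ$rhat) & summ$rhat > 1.01]
  if (length(high)) {
    warning("R-hat > 1.01 for: ", paste(high, collapse = ", "),
            " — consider more iterations", call. = FALSE)
  }
  structure(list(summary = summ, draws = draws, species = species,
                 design = design,
                 settings = list(chains = chains, iter = iter, warmup = warmup,
                                 seed = seed, error_scaling = error_scaling,
                                 prior_sd_upper = prior_sd_upper,
                                 prior_mean_sd = prior_mean_sd,
                                 literal_intercept = literal_intercept)),
            class = "itv_hier")
}

# posterior mean/sd/quantiles/R-hat table from a coda::mcmc.list
summarize_draws <- function(draws) {
  m <- as.matrix(draws)
  qs <- t(apply(m, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE))
  rhat <- rep(NA_real_, ncol(m))
  if (coda::nchain(draws) >= 2L) {
    g <- try(coda::gelman.diag(draws, multivariate = FALSE,
                               autoburnin = FALSE), silent = TRUE)
    if (!inherits(g, "try-error")) rhat <- g$psrf[colnames(m), 1L]
  }
  out <- data.frame(mean = colMeans(m), sd = apply(m, 2L, stats::sd),
                    q2.5 = qs[, 1L], q50 = qs[, 2L], q97.5 = qs[, 3L],
                    rhat = rhat)
  rownames(out) <- colnames(m)
  out
}

#' @export
print.itv_hier <- function(x, digits = 3, ...) {
  s <- x$settings
  cat("Hierarchical within-site ITV model (",
      attr(x$design, "env_variable"), ", ", length(x$species), " species, ",
      nrow(x$design), " cells)\n", sep = "")
  cat("MCMC: ", s$chains, " chains x ", s$iter, " iterations (warmup ",
      s$warmup, "), residual sd = tau/",
      if (s$error_scaling == "sd_over_n") "n" else "sqrt(n)", "\n", sep = "")
  top <- x$summary[intersect(c("beta0", "mu1", "mu2", "sigma1", "sigma2", "tau"),
                             rownames(x$summary)), ]
  print(round(top, digits))
  invisible(x)
}

#' @export
summary.itv_hier <- function(object, ...) {
  object$summary
}

#' @export
coef.itv_hier <- function(object, ...) {
  hyper <- intersect(c("beta0", "mu1", "mu2", "sigma1", "sigma2", "tau"),
                     rownames(object$summary))
  stats::setNames(object$summary[hyper, "mean"], hyper)
}

#' Extract species random effects
#'
#' Posterior summaries of the species-specific intercepts (`b1`) or slopes
#' (`b2`).
#'
#' @param object an `itv_hier` fit.
#' @param which `"b1"` or `"b2"`.
#' @return data.frame with one row per species.
#' @export
species_effects <- function(object, which = c("b2", "b1")) {
  stopifnot(inherits(object, "itv_hier"))
  which <- match.arg(which)
  rows <- paste0(which, "[", object$species, "]")
  out <- object$summary[rows, ]
  out <- cbind(species = object$species, out)
  rownames(out) <- NULL
  out
}

#' Classify slopes by whether their credible interval crosses zero
#'
#' Labels the community slope hypermean (`mu2`) and every species-specific
#' slope (`b2`) as `positive` (CI lower bound > 0), `negative` (upper bound
#' < 0) or `nonsignificant`.
#'
#' @param object an `itv_hier` fit.
#' @param level credible-interval coverage (default 0.95).
#' @return data.frame with columns `parameter`, `species` (`NA` for `mu2`),
#'   `mean`, `lower`, `upper`, `label`.
#' @export
classify_slopes <- function(object, level = 0.95) {
  stopifnot(inherits(object, "itv_hier"), level > 0, level < 1)
  m <- as.matrix(object$draws)
  a <- (1 - level) / 2
  targets <- c("mu2", paste0("b2[", seq_along(object$species), "]"))
  idx <- match(targets, colnames(m))
  lo <- apply(m[, idx, drop = FALSE], 2L, stats::quantile, probs = a,
              names = FALSE)
  hi <- apply(m[, idx, drop = FALSE], 2L, stats::quantile, probs = 1 - a,
              names = FALSE)
  mean_ <- colMeans(m[, idx, drop = FALSE])
  data.frame(parameter = c("mu2", rep("b2", length(object$species))),
             species = c(NA_character_, object$species),
             mean = unname(mean_), lower = unname(lo), upper = unname(hi),
             label = ifelse(lo > 0, "positive",
                     ifelse(hi < 0, "negative", "nonsignificant")),
             stringsAsFactors = FALSE)
}

#' Caterpillar plot of species slopes
#'
#' Posterior means and credible intervals of the species-specific slopes,
#' colored by the CI-versus-zero classification.
#'
#' @param x an `itv_hier` fit.
#' @param level interval coverage.
#' @param ... passed to `plot()`.
#' @export
plot.itv_hier <- function(x, level = 0.95, ...) {
  cl <- classify_slopes(x, level)
  sp <- cl[cl$parameter == "b2", ]
  sp <- sp[order(sp$mean), ]
  k <- nrow(sp)
  col <- ifelse(sp$label == "nonsignificant", "grey40",
                ifelse(sp$label == "positive", "blue", "red"))
  graphics::plot(sp$mean, seq_len(k), xlim = range(sp$lower, sp$upper, 0),
                 pch = 19, col = col, yaxt = "n",
                 xlab = "species slope (b2)", ylab = "", ...)
  graphics::segments(sp$lower, seq_len(k), sp$upper, seq_len(k), col = col)
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(k), labels = sp$species, las = 1,
                 cex.axis = 0.6)
  invisible(x)
}
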