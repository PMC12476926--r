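## Bayesian regression of across-site log ITV* (or species mean log traits)
## on standardized environmental range breadths, with AIC backward selection,
## VIF diagnostics and credible intervals at 90% and 95%.

#' Assemble the design for the range regression
#'
#' Inner-joins the per-species response (across-site log ITV* or mean log
#' trait) to the per-species environmental range breadths and standardizes
#' the predictor columns (mean 0, sd 1). Species missing from either table
#' are excluded with a warning.
#'
#' @param response data.frame with columns `species` and either
#'   `log_itv_star` (from [itv_table()]`$across`) or `mean_log` (from
#'   [species_mean_log()]); a single trait.
#' @param ranges output of [species_ranges()] (or any data.frame with
#'   `species` plus numeric predictor columns).
#' @param predictors names of the predictor columns in `ranges`. Defaults to
#'   every column except `species`.
#' @return An object of class `range_design`: list with response vector `y`,
#'   standardized predictor matrix `X` (with `center`/`scale` attributes),
#'   `species`, `response_name`, `trait`.
#' @export
range_design <- function(response, ranges, predictors = NULL) {
  stopifnot(is.data.frame(response), is.data.frame(ranges),
            "species" %in% names(response), "species" %in% names(ranges))
  resp_col <- intersect(c("log_itv_star", "mean_log"), names(response))[1]
  if (is.na(resp_col)) {
    stop("response table needs a 'log_itv_star' or 'mean_log' column",
         call. = FALSE)
  }
  if ("trait" %in% names(response) && length(unique(response$trait)) > 1L) {
    stop("range design must be built for a single trait", call. = FALSE)
  }
  if (is.null(predictors)) predictors <- setdiff(names(ranges), "species")
  if (length(predictors) == 0L) stop("empty predictor set", call. = FALSE)
  missing_p <- setdiff(predictors, names(ranges))
  if (length(missing_p)) {
    stop("predictor column(s) not in ranges table: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  keep <- is.finite(response[[resp_col]])
  response <- response[keep, , drop = FALSE]
  common <- intersect(response$species, ranges$species)
  lost <- setdiff(response$species, common)
  if (length(lost)) {
    warning("species without range data excluded: ",
            paste(lost, collapse = ", "), call. = FALSE)
  }
  if (length(common) < length(predictors) + 2L) {
    stop("under-determined design: ", length(common), " species for ",
         length(predictors), " predictors", call. = FALSE)
  }
  common <- sort(common)
  y <- response[[resp_col]][match(common, response$species)]
  X <- as.matrix(ranges[match(common, ranges$species), predictors, drop = FALSE])
  storage.mode(X) <- "double"
  X <- standardize_columns(X)
  structure(list(y = y, X = X, species = common,
                 response_name = resp_col,
                 trait = if ("trait" %in% names(response))
                   response$trait[1] else NA_character_),
            class = "range_design")
}

#' @export
print.range_design <- function(x, ...) {
  cat("range_design: ", length(x$y), " species, ", ncol(x$X),
      " standardized predictors (response: ", x$response_name, ")\n", sep = "")
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor j
#' on all the others; computed here as the diagonal of the inverse
#' correlation matrix. Values near 1 indicate orthogonal predictors; large
#' values flag collinearity. Perfectly collinear columns yield `Inf`.
#'
#' @param x a `range_design` or a numeric matrix of predictors (>= 2
#'   columns).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  X <- if (inherits(x, "range_design")) x$X else as.matrix(x)
  if (ncol(X) < 2L) stop("VIF needs at least 2 predictors", call. = FALSE)
  R <- stats::cor(X)
  inv <- try(solve(R), silent = TRUE)
  if (inherits(inv, "try-error")) {
    # singular correlation matrix: some column is an exact combination of others
    out <- rep(Inf, ncol(X))
    names(out) <- colnames(X)
    warning("perfect collinearity: infinite VIF", call. = FALSE)
    return(out)
  }
  v <- diag(inv)
  names(v) <- colnames(X)
  v
}

# Gaussian log-likelihood of y given fitted values and ML residual variance
gauss_loglik <- function(y, fitted) {
  n <- length(y)
  rss <- sum((y - fitted)^2)
  s2 <- rss / n
  if (s2 <= 0) return(Inf)
  -n / 2 * (log(2 * pi * s2) + 1)
}

#' Fit the Bayesian range regression
#'
#' Gaussian linear model of the per-species response on the standardized
#' range-breadth predictors. Priors are weakly informative on the
#' standardized scale: each slope gets an independent normal(0,
#' `prior_scale` * sd(y) / sd(x_j)) prior and the intercept is flat, so with
#' the default `prior_scale = 2.5` the fit approaches ordinary least squares
#' as information grows. Point estimates are the (analytic) conditional
#' posterior mean given the OLS residual variance — deterministic — while
#' credible intervals come from a Gibbs sampler over (coefficients,
#' residual variance).
#'
#' Reported fit statistics: R^2, the Gaussian log-likelihood at the point
#' estimates with ML residual variance, and AIC = 2k - 2 logLik with k =
#' number of coefficients (including intercept) + 1 for the residual sd.
#'
#' @param design a [range_design()]; or pass `y`/`X` directly.
#' @param ci_levels credible-interval coverages to report (default 0.90 and
#'   0.95; the narrower level is the headline significance level).
#' @param draws,warmup Gibbs sampler length.
#' @param prior_scale slope prior scale multiplier.
#' @param seed RNG seed for the Gibbs sampler.
#' @return An object of class `itv_range`: list with `coefficients` table
#'   (term, estimate, and `lo`/`hi` columns per CI level), `sigma`, `logLik`,
#'   `AIC`, `r_squared`, `vif` (when >= 2 predictors), `n`, `k`, `draws`.
#' @export
fit_range_model <- function(design, ci_levels = c(0.90, 0.95), draws = 2000L,
                            warmup = 500L, prior_scale = 2.5, seed = 1L) {
  stopifnot(inherits(design, "range_design"))
  y <- design$y
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  Xa <- cbind(`(intercept)` = 1, X)
  qrX <- qr(Xa)
  if (qrX$rank < ncol(Xa)) {
    dep <- colnames(Xa)[qrX$pivot[(qrX$rank + 1):ncol(Xa)]]
    stop("singular design: column(s) ", paste(dep, collapse = ", "),
         " linearly dependent on the others", call. = FALSE)
  }
  ols <- qr.coef(qrX, y)
  rss_ols <- sum((y - Xa %*% ols)^2)
  s2_ols <- rss_ols / n
  sd_y <- stats::sd(y)
  prior_sd <- c(Inf, rep(prior_scale * sd_y, p))  # X standardized: sd(x_j)=1
  prior_prec <- ifelse(is.finite(prior_sd), 1 / prior_sd^2, 0)
  XtX <- crossprod(Xa)
  Xty <- crossprod(Xa, y)

  # deterministic point estimate: conditional posterior mean at sigma^2_OLS
  A <- XtX / max(s2_ols, .Machine$double.xmin) + diag(prior_prec, ncol(Xa))
  beta_hat <- drop(solve(A, Xty / max(s2_ols, .Machine$double.xmin)))
  if (s2_ols == 0) beta_hat <- drop(ols)  # noiseless limit: exact OLS
  names(beta_hat) <- colnames(Xa)
  fitted <- drop(Xa %*% beta_hat)
  rss <- sum((y - fitted)^2)
  ll <- gauss_loglik(y, fitted)
  k <- ncol(Xa) + 1L  # coefficients + residual sd
  aic <- 2 * k - 2 * ll
  r2 <- 1 - rss / sum((y - mean(y))^2)

  # Gibbs over (beta | sigma2) and (sigma2 | beta) for credible intervals
  set.seed(derive_seed(seed, "range_gibbs"))
  total <- draws + warmup
  bdraws <- matrix(NA_real_, draws, ncol(Xa),
                   dimnames = list(NULL, colnames(Xa)))
  s2draws <- numeric(draws)
  beta <- drop(ols)
  s2 <- max(s2_ols, 1e-12)
  for (it in seq_len(total)) {
    A <- XtX / s2 + diag(prior_prec, ncol(Xa))
    ch <- chol(A)
    mu <- backsolve(ch, forwardsolve(t(ch), drop(Xty) / s2))
    beta <- mu + backsolve(ch, stats::rnorm(ncol(Xa)))
    rss_b <- sum((y - Xa %*% beta)^2)
    # floor keeps the precision matrix finite for (near-)noiseless responses
    s2 <- max(1 / stats::rgamma(1L, shape = n / 2, rate = rss_b / 2), 1e-30)
    if (it > warmup) {
      bdraws[it - warmup, ] <- beta
      s2draws[it - warmup] <- s2
    }
  }
  ci_levels <- sort(ci_levels)
  coefs <- data.frame(term = colnames(Xa), estimate = unname(beta_hat),
                      stringsAsFactors = FALSE)
  for (lev in ci_levels) {
    a <- (1 - lev) / 2
    lo <- apply(bdraws, 2L, stats::quantile, probs = a, names = FALSE)
    hi <- apply(bdraws, 2L, stats::quantile, probs = 1 - a, names = FALSE)
    coefs[[sprintf("lo%g", lev * 100)]] <- unname(lo)
    coefs[[sprintf("hi%g", lev * 100)]] <- unname(hi)
  }
  structure(list(coefficients = coefs, sigma = sqrt(rss / max(n - ncol(Xa), 1L)),
                 logLik = ll, AIC = aic, r_squared = r2,
                 vif = if (p >= 2L) vif(X) else NULL,
                 n = n, k = k, predictors = colnames(X),
                 ci_levels = ci_levels, response_name = design$response_name,
                 trait = design$trait,
                 draws = list(beta = bdraws, sigma2 = s2draws)),
            class = "itv_range")
}

#' @export
print.itv_range <- function(x, digits = 3, ...) {
  cat("Bayesian range regression (", x$response_name, ", n = ", x$n,
      " species, ", length(x$predictors), " predictors)\n", sep = "")
  cat(sprintf("R^2 = %.3f, AIC = %.2f, logLik = %.2f\n",
              x$r_squared, x$AIC, x$logLik))
  cf <- x$coefficients
  cf[-1L] <- lapply(cf[-1L], round, digits)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' @export
summary.itv_range <- function(object, ...) {
  list(coefficients = object$coefficients, r_squared = object$r_squared,
       AIC = object$AIC, logLik = object$logLik, sigma = object$sigma,
       vif = object$vif, n = object$n)
}

#' @export
coef.itv_range <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Coefficient interval plot
#'
#' Posterior means and credible intervals for each retained predictor,
#' negative slopes in red and positive in blue, filled points where the
#' narrower reported interval excludes zero.
#'
#' @param x an `itv_range` fit.
#' @param ... passed to `plot()`.
#' @export
plot.itv_range <- function(x, ...) {
  cf <- x$coefficients[x$coefficients$term != "(intercept)", ]
  lev <- min(x$ci_levels)
  lo <- cf[[sprintf("lo%g", lev * 100)]]
  hi <- cf[[sprintf("hi%g", lev * 100)]]
  k <- nrow(cf)
  col <- ifelse(cf$estimate < 0, "red", "blue")
  pch <- ifelse(lo > 0 | hi < 0, 19, 1)
  graphics::plot(cf$estimate, seq_len(k), xlim = range(lo, hi, 0), pch = pch,
                 col = col, yaxt = "n", xlab = "standardized coefficient",
                 ylab = "", ...)
  graphics::segments(lo, seq_len(k), hi, seq_len(k), col = col)
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(k), labels = cf$term, las = 1, cex.axis = 0.7)
  invisible(x)
}

# refit a design restricted to a predictor subset (possibly empty)
subset_design <- function(design, predictors) {
  d <- design
  d$X <- design$X[, predictors, drop = FALSE]
  attr(d$X, "center") <- attr(design$X, "center")[predictors]
  attr(d$X, "scale") <- attr(design$X, "scale")[predictors]
  d
}

# deterministic AIC of a predictor subset (point-estimate fit only, no Gibbs)
aic_of_subset <- function(design, predictors, prior_scale = 2.5) {
  y <- design$y
  n <- length(y)
  if (length(predictors) == 0L) {
    ll <- gauss_loglik(y, rep(mean(y), n))
    return(2 * 3 - 2 * ll)  # intercept + residual sd
  }
  Xa <- cbind(1, design$X[, predictors, drop = FALSE])
  ols <- qr.coef(qr(Xa), y)
  s2_ols <- sum((y - Xa %*% ols)^2) / n
  prior_prec <- c(0, rep(1 / (prior_scale * stats::sd(y))^2, length(predictors)))
  A <- crossprod(Xa) / max(s2_ols, .Machine$double.xmin) +
    diag(prior_prec, ncol(Xa))
  beta <- drop(solve(A, crossprod(Xa, y) / max(s2_ols, .Machine$double.xmin)))
  if (s2_ols == 0) beta <- drop(ols)
  ll <- gauss_loglik(y, drop(Xa %*% beta))
  k <- ncol(Xa) + 1L
  2 * k - 2 * ll
}

#' Backward model selection by AIC
#'
#' Greedy backward elimination: starting from the full predictor set,
#' repeatedly drop the predictor whose removal lowers AIC most; stop when no
#' removal lowers AIC. The trace records every candidate AIC at every step,
#' and the leave-one-out AIC values for the final model (the "AIC without X"
#' diagnostics) are attached.
#'
#' @param design a [range_design()] with the full predictor set.
#' @param ci_levels,draws,warmup,prior_scale,seed passed to
#'   [fit_range_model()] for the full and final fits.
#' @return An object of class `range_selection`: list with `trace`
#'   (data.frame of step, candidate dropped, AIC, accepted), `final_predictors`,
#'   `full_fit`, `final_fit`, `aic_without` (leave-one-out AICs around the
#'   final model), `aic_full`, `aic_final`.
#' @export
backward_select <- function(design, ci_levels = c(0.90, 0.95), draws = 2000L,
                            warmup = 500L, prior_scale = 2.5, seed = 1L) {
  stopifnot(inherits(design, "range_design"))
  preds <- colnames(design$X)
  aic_full <- aic_of_subset(design, preds, prior_scale)
  trace <- data.frame(step = 0L, dropped = NA_character_, aic = aic_full,
                      accepted = TRUE, n_predictors = length(preds),
                      stringsAsFactors = FALSE)
  keep <- preds
  cur <- aic_full
  step <- 0L
  while (length(keep) > 0L) {
    step <- step + 1L
    cand_aic <- vapply(seq_along(keep), function(j)
      aic_of_subset(design, keep[-j], prior_scale), 1.0)
    trace <- rbind(trace,
                   data.frame(step = step, dropped = keep, aic = cand_aic,
                              accepted = FALSE,
                              n_predictors = length(keep) - 1L,
                              stringsAsFactors = FALSE))
    j <- which.min(cand_aic)
    if (cand_aic[j] < cur) {
      cur <- cand_aic[j]
      trace$accepted[nrow(trace) - length(keep) + j] <- TRUE
      keep <- keep[-j]
    } else break
  }
  final_fit <- if (length(keep) > 0L) {
    fit_range_model(subset_design(design, keep), ci_levels = ci_levels,
                    draws = draws, warmup = warmup,
                    prior_scale = prior_scale, seed = seed)
  } else NULL
  full_fit <- fit_range_model(design, ci_levels = ci_levels, draws = draws,
                              warmup = warmup, prior_scale = prior_scale,
                              seed = seed)
  aic_without <- if (length(keep) > 0L) {
    stats::setNames(vapply(seq_along(keep), function(j)
      aic_of_subset(design, keep[-j], prior_scale), 1.0), keep)
  } else NULL
  structure(list(trace = trace, final_predictors = keep,
                 full_fit = full_fit, final_fit = final_fit,
                 aic_without = aic_without,
                 aic_full = aic_full, aic_final = cur),
            class = "range_selection")
}

#' @export
print.range_selection <- function(x, digits = 2, ...) {
  cat("Backward AIC selection: ", length(x$final_predictors), " of ",
      length(x$full_fit$predictors), " predictors retained\n", sep = "")
  cat(sprintf("AIC full %.2f -> final %.2f\n", x$aic_full, x$aic_final))
  if (length(x$final_predictors)) {
    cat("final set:", paste(x$final_predictors, collapse = ", "), "\n")
    cat("AIC without each retained predictor:\n")
    print(round(x$aic_without, digits))
  } else cat("final model: intercept only\n")
  invisible(x)
}

#' Exhaustive best-AIC subset search
#'
#' All-subsets search over the predictor set (feasible for <= 8 predictors);
#' an independent cross-check on [backward_select()].
#'
#' @param design a [range_design()].
#' @param prior_scale slope prior scale (as in [fit_range_model()]).
#' @return list with `best_predictors`, `best_aic`, and the full `aic` table.
#' @export
exhaustive_select <- function(design, prior_scale = 2.5) {
  stopifnot(inherits(design, "range_design"))
  preds <- colnames(design$X)
  p <- length(preds)
  if (p > 8L) stop("exhaustive search limited to 8 predictors", call. = FALSE)
  subsets <- lapply(0:(2^p - 1L), function(m) preds[bitwAnd(m, 2^(0:(p - 1L))) > 0])
  aics <- vapply(subsets, function(s) aic_of_subset(design, s, prior_scale), 1.0)
  best <- which.min(aics)
  list(best_predictors = subsets[[best]], best_aic = aics[best],
       aic = data.frame(subset = vapply(subsets, paste, "", collapse = "+"),
                        aic = aics, stringsAsFactors = FALSE))
}

#' Pearson correlation between species mean traits and across-site ITV
#'
#' Tests the expectation that species with more conservative mean trait
#' values are less variable: Pearson's r between the per-species mean log
#' trait and the per-species log across-site ITV*, with the two-sided
#' p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param means data.frame from [species_mean_log()] (single trait).
#' @param itv_across data.frame from [itv_table()]`$across` (same trait).
#' @return list with `r`, `p`, `n`, and the underlying `cor.test` object.
#' @export
mean_itv_correlation <- function(means, itv_across) {
  stopifnot(is.data.frame(means), is.data.frame(itv_across))
  common <- intersect(means$species, itv_across$species)
  x <- means$mean_log[match(common, means$species)]
  y <- itv_across$log_itv_star[match(common, itv_across$species)]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 species", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), test = ct)
}
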