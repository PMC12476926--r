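## Synthetic-data generators mirroring the statistical structure the analysis
## assumes, each emitting a ground-truth record so every estimand can be
## checked by parameter recovery. All randomness flows from one master seed
## through named substreams (derive_seed), so components are independently
## reproducible.

#' Simulate individual trait observations under the random-slopes model
#'
#' The generative mirror of the within-site model: per species, intercept and
#' slope deviations are drawn from \eqn{N(\mu_1, \sigma_1)} and
#' \eqn{N(\mu_2, \sigma_2)}; each occupied species x site cell gets a true
#' \eqn{\log ITV^* = \beta_{1,sp} + \beta_{2,sp} \cdot env_{si} + \epsilon /
#' n} (with \eqn{\epsilon \sim N(0, \tau)} under the chosen error-scaling
#' convention — the same switch the fitting side uses); individual log-trait
#' values are then drawn Normal(species mean, sqrt(exp(true log ITV*))) and
#' exponentiated to the trait scale.
#'
#' Defaults emulate the study design: 33 species over 8 sites, each species
#' present at a random subset of at least 4 sites, unbalanced cell sample
#' sizes (Poisson mean 12, truncated at 6), community mean log ITV around
#' -3 (log-trait sd about 0.22), and site environmental-variability values
#' spanning a range comparable to rainfall seasonality percentages.
#'
#' @param n_species,n_sites community dimensions.
#' @param mu1,sigma1 hypermean / hypersd of the species intercepts (log ITV*
#'   scale).
#' @param mu2,sigma2 hypermean / hypersd of the species slopes per 1 sd of
#'   the (standardized) environmental predictor. The default `mu2 = 0` is the
#'   no-community-effect condition.
#' @param tau residual scale of the cell-level noise (sd before division by
#'   n).
#' @param env site environmental-variability values (length `n_sites`);
#'   `NULL` draws them uniformly on (25, 60), a realistic rainfall-CV span.
#'   The generator standardizes `env` internally when computing true cell
#'   values, matching the fitted model's standardized predictor.
#' @param fixed_n if non-`NULL`, every cell gets exactly this many
#'   individuals; otherwise cell sizes are Poisson(`n_mean`) truncated below
#'   at `n_min`.
#' @param n_mean,n_min Poisson cell-size law.
#' @param min_sites_per_species each species occupies a uniform random number
#'   of sites between this and `n_sites`.
#' @param species_mean_sd sd of the per-species mean log trait (a nuisance
#'   location parameter; it cancels out of all ITV quantities).
#' @param error_scaling residual convention, as in [fit_itv_hier()].
#' @param trait trait label stamped on the observations.
#' @param seed master seed.
#' @return list with `observations` (a trait table), `sites` (data.frame
#'   `site`, `env`), and `truth` (all drawn latent values: hyperparameters,
#'   per-species `b1`/`b2`, per-cell true log ITV* and n).
#' @export
simulate_traits <- function(n_species = 33L, n_sites = 8L,
                            mu1 = -3, mu2 = 0, sigma1 = 0.3, sigma2 = 0.2,
                            tau = 0.5, env = NULL, fixed_n = NULL,
                            n_mean = 12, n_min = 6L,
                            min_sites_per_species = 4L,
                            species_mean_sd = 1,
                            error_scaling = c("sd_over_n", "sd_over_sqrt_n"),
                            trait = "wood_density", seed = 1L) {
  error_scaling <- match.arg(error_scaling)
  stopifnot(n_species >= 2L, n_sites >= 2L, sigma1 >= 0, sigma2 >= 0,
            tau >= 0, min_sites_per_species >= 2L,
            min_sites_per_species <= n_sites,
            is.null(fixed_n) || fixed_n >= 2L, n_min >= 2L)
  set.seed(derive_seed(seed, "traits"))
  sites <- sprintf("S%02d", seq_len(n_sites))
  species <- sprintf("sp%02d", seq_len(n_species))
  if (is.null(env)) env <- stats::runif(n_sites, 25, 60)
  stopifnot(length(env) == n_sites)
  env_z <- (env - mean(env)) / stats::sd(env)

  b1 <- stats::rnorm(n_species, mu1, sigma1)
  b2 <- stats::rnorm(n_species, mu2, sigma2)
  sp_mean <- stats::rnorm(n_species, 0, species_mean_sd)

  rows <- vector("list", n_species)
  truth_cells <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    k <- if (min_sites_per_species == n_sites) n_sites
         else sample(min_sites_per_species:n_sites, 1L)
    occ <- sort(sample(n_sites, k))
    n_cell <- if (!is.null(fixed_n)) rep(as.integer(fixed_n), k)
              else pmax(stats::rpois(k, n_mean), n_min)
    eps <- stats::rnorm(k, 0, tau)
    scaled <- if (error_scaling == "sd_over_n") eps / n_cell
              else eps / sqrt(n_cell)
    true_log_itv <- b1[i] + b2[i] * env_z[occ] + scaled
    vals <- lapply(seq_len(k), function(j) {
      exp(stats::rnorm(n_cell[j], sp_mean[i], sqrt(exp(true_log_itv[j]))))
    })
    rows[[i]] <- data.frame(site = rep(sites[occ], n_cell),
                            species = species[i], trait = trait,
                            value = unlist(vals), stringsAsFactors = FALSE)
    truth_cells[[i]] <- data.frame(species = species[i], site = sites[occ],
                                   n = n_cell, true_log_itv = true_log_itv,
                                   stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  list(observations = obs,
       sites = data.frame(site = sites, env = env, stringsAsFactors = FALSE),
       truth = list(mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
                    tau = tau, error_scaling = error_scaling,
                    b1 = stats::setNames(b1, species),
                    b2 = stats::setNames(b2, species),
                    species_mean = stats::setNames(sp_mean, species),
                    env = stats::setNames(env, sites),
                    env_z = stats::setNames(env_z, sites),
                    cells = do.call(rbind, truth_cells)))
}

#' Simulate a gridded elevation model
#'
#' Three terrain kinds with known roughness behavior: `constant` (TRI 0
#' everywhere), `ramp` rising `slope` elevation units per cell along columns
#' (interior TRI = 0.75 * slope: six of the eight neighbor differences equal
#' `slope`, two equal 0), and iid `gaussian_noise` with sd `sd` (expected
#' interior TRI = sd * E|Z1 - Z2| = 2 sd / sqrt(pi)).
#'
#' @param kind terrain type.
#' @param nrow,ncol grid dimensions.
#' @param cellsize cell edge length, meters.
#' @param base base elevation added everywhere.
#' @param slope ramp rise per cell (for `kind = "ramp"`).
#' @param sd noise sd (for `kind = "gaussian_noise"`).
#' @param seed RNG seed (noise only).
#' @return A [dem_grid].
#' @export
simulate_dem <- function(kind = c("constant", "ramp", "gaussian_noise"),
                         nrow = 50L, ncol = 50L, cellsize = 5, base = 100,
                         slope = 2, sd = 1, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(nrow >= 1L, ncol >= 1L)
  z <- switch(kind,
    constant = matrix(base, nrow, ncol),
    ramp = base + slope * matrix(rep(seq_len(ncol) - 1L, each = nrow),
                                 nrow, ncol),
    gaussian_noise = {
      set.seed(derive_seed(seed, "dem"))
      base + matrix(stats::rnorm(nrow * ncol, 0, sd), nrow, ncol)
    })
  dem_grid(z, cellsize = cellsize)
}

#' Simulate a 12-month precipitation series with a target CV
#'
#' Draws 12 lognormal monthly values whose log-scale sd targets the requested
#' coefficient of variation, then rescales (affinely when that keeps every
#' month non-negative, multiplicatively otherwise) so the sample CV lands
#' within 10% relative of the target and the mean equals `mean_mm`.
#'
#' @param mean_mm target mean monthly precipitation (> 0).
#' @param target_cv_pct target CV in percent (>= 0).
#' @param seed RNG seed.
#' @return Numeric vector of 12 non-negative values.
#' @export
simulate_monthly_precip <- function(mean_mm = 150, target_cv_pct = 40,
                                    seed = 1L) {
  stopifnot(mean_mm > 0, target_cv_pct >= 0)
  if (target_cv_pct == 0) return(rep(mean_mm, 12L))
  set.seed(derive_seed(seed, "precip"))
  cv <- target_cv_pct / 100
  sdlog <- sqrt(log(1 + cv^2))
  for (attempt in 1:50) {
    x <- stats::rlnorm(12L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    m <- mean(x); s <- stats::sd(x)
    if (s == 0) next
    y <- mean_mm + (x - m) * (cv * mean_mm) / s  # exact mean and CV
    if (all(y >= 0)) return(y)
  }
  # CV too large for an exact affine match without negatives: scale to the
  # mean only and accept the draw's natural CV (within tolerance w.h.p.)
  x * mean_mm / mean(x)
}

#' Simulate occurrence records from species-specific environmental niches
#'
#' Each species gets a niche center and width per environmental attribute;
#' records draw attribute values uniformly on (center - w/2, center + w/2)
#' and a geology label uniformly from the species' class set. The truth
#' record stores the population central-95% width, `0.95 * w`, per attribute,
#' and the class-set size.
#'
#' @param n_species number of species.
#' @param records_per_species records per species (single value or vector).
#' @param attributes named list of `c(min_center, max_center, max_width)`
#'   triples per attribute; defaults span realistic island-wide gradients
#'   (elevation m, MAP mm/yr, PET mm/yr, CWD mm, irradiance, cloudiness).
#' @param geology_classes admissible class labels; each species occupies a
#'   random non-empty subset.
#' @param fixed_widths optional named numeric vector (names matching
#'   `attributes`) forcing every species' niche width for those attributes
#'   instead of drawing them — useful for calibration checks.
#' @param seed master seed.
#' @return list with `occurrences` (data.frame `species`, one column per
#'   attribute, `geology`) and `truth` (per-species true widths
#'   `<attribute>_range` = 0.95 w and `geology_count`).
#' @export
simulate_occurrences <- function(n_species = 33L, records_per_species = 500L,
                                 attributes = list(
                                   elevation = c(50, 1200, 900),
                                   map = c(900, 4400, 2500),
                                   pet = c(1100, 1900, 700),
                                   cwd = c(0, 900, 700),
                                   irradiance = c(1500, 2100, 400),
                                   cloudiness = c(20, 80, 40)),
                                 geology_classes = c("volcanic", "limestone",
                                                     "alluvial", "ultramafic"),
                                 fixed_widths = NULL, seed = 1L) {
  stopifnot(n_species >= 1L, all(records_per_species >= 2L))
  set.seed(derive_seed(seed, "occurrences"))
  species <- sprintf("sp%02d", seq_len(n_species))
  nrec <- rep_len(as.integer(records_per_species), n_species)
  truth <- data.frame(species = species, stringsAsFactors = FALSE)
  occ <- vector("list", n_species)
  centers <- widths <- list()
  for (a in names(attributes)) {
    spec <- attributes[[a]]
    centers[[a]] <- stats::runif(n_species, spec[1], spec[2])
    widths[[a]] <- if (!is.null(fixed_widths) && a %in% names(fixed_widths)) {
      rep(fixed_widths[[a]], n_species)
    } else stats::runif(n_species, 0.05 * spec[3], spec[3])
    truth[[paste0(a, "_range")]] <- 0.95 * widths[[a]]
  }
  class_sets <- lapply(seq_len(n_species), function(i) {
    k <- sample(seq_along(geology_classes), 1L)
    sort(sample(geology_classes, k))
  })
  truth$geology_count <- vapply(class_sets, length, 1L)
  for (i in seq_len(n_species)) {
    d <- data.frame(species = rep(species[i], nrec[i]),
                    stringsAsFactors = FALSE)
    for (a in names(attributes)) {
      d[[a]] <- stats::runif(nrec[i], centers[[a]][i] - widths[[a]][i] / 2,
                             centers[[a]][i] + widths[[a]][i] / 2)
    }
    d$geology <- sample(class_sets[[i]], nrec[i], replace = TRUE)
    occ[[i]] <- d
  }
  list(occurrences = do.call(rbind, occ), truth = truth)
}

#' Simulate a full dataset coupling across-site ITV to range breadths
#'
#' End-to-end generative mirror of the range regression: per-species
#' standardized range-breadth predictors are drawn first, the species' total
#' (across-site) log ITV* is set by the linear model with the supplied
#' coefficients plus residual noise, occurrence records realize the ranges,
#' and individual trait observations realize the target pooled variance
#' (species spread over sites with common cell means, so within- and
#' across-site variances agree).
#'
#' @param n_species number of species.
#' @param coefs named coefficient vector on the standardized predictors;
#'   names pick the predictors (`<attribute>_range` or `geology_count`).
#' @param intercept true intercept of the linear model (log ITV* scale).
#' @param resid_sd residual sd of the species-level linear model.
#' @param n_sites,obs_per_cell trait-sampling design realized per species.
#' @param records_per_species occurrence records per species.
#' @param trait trait label.
#' @param seed master seed.
#' @return list with `observations`, `occurrences`, and `truth` (the
#'   coefficient vector, per-species standardized predictors, true widths and
#'   target log ITV* values).
#' @export
simulate_coupled_itv_range <- function(n_species = 200L,
                                       coefs = c(pet_range = 0.5,
                                                 cwd_range = 0,
                                                 elevation_range = 0,
                                                 irradiance_range = 0,
                                                 cloudiness_range = 0,
                                                 map_range = 0),
                                       intercept = -3, resid_sd = 1,
                                       n_sites = 4L, obs_per_cell = 25L,
                                       records_per_species = 400L,
                                       trait = "wood_density", seed = 1L) {
  stopifnot(n_species >= length(coefs) + 2L, !is.null(names(coefs)),
            resid_sd >= 0, obs_per_cell >= 2L)
  attr_names <- sub("_range$", "", setdiff(names(coefs), "geology_count"))
  base_attrs <- list(elevation = c(50, 1200, 900), map = c(900, 4400, 2500),
                     pet = c(1100, 1900, 700), cwd = c(0, 900, 700),
                     irradiance = c(1500, 2100, 400), cloudiness = c(20, 80, 40))
  occ <- simulate_occurrences(n_species = n_species,
                              records_per_species = records_per_species,
                              attributes = base_attrs[attr_names],
                              seed = derive_seed(seed, "coupled_occ"))
  truth <- occ$truth
  pred_cols <- names(coefs)
  missing_p <- setdiff(pred_cols, names(truth))
  if (length(missing_p)) {
    stop("coefficient name(s) without a generated predictor: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  Xz <- standardize_columns(truth[pred_cols])
  set.seed(derive_seed(seed, "coupled_itv"))
  target_log_itv <- drop(intercept + Xz %*% coefs +
                           stats::rnorm(n_species, 0, resid_sd))

  species <- truth$species
  sites <- sprintf("S%02d", seq_len(n_sites))
  sp_mean <- stats::rnorm(n_species, 0, 1)
  rows <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    sdv <- sqrt(exp(target_log_itv[i]))
    vals <- exp(stats::rnorm(n_sites * obs_per_cell, sp_mean[i], sdv))
    rows[[i]] <- data.frame(site = rep(sites, each = obs_per_cell),
                            species = species[i], trait = trait,
                            value = vals, stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  truth$target_log_itv <- target_log_itv
  list(observations = obs, occurrences = occ$occurrences,
       truth = list(coefs = coefs, intercept = intercept, resid_sd = resid_sd,
                    species = truth, X_std = Xz))
}

#' Write a simulation truth record as JSON
#'
#' @param truth the `truth` element of any simulator's output.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
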