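#' itvar: intraspecific trait variation and environmental heterogeneity
#'
#' Tools to quantify intraspecific trait variation (ITV) of log-transformed
#' functional traits with a sample-size (Bessel) correction, and to relate it
#' to environmental heterogeneity at two scales: within sites (hierarchical
#' Bayesian random-slopes model, [fit_itv_hier()]) and across a species'
#' range (Bayesian regression on environmental range breadths with AIC
#' backward selection, [fit_range_model()], [backward_select()]).
#'
#' A typical analysis runs: [read_trait_table()] \eqn{\rightarrow}
#' [filter_included()] \eqn{\rightarrow} [itv_table()] \eqn{\rightarrow}
#' [hier_design()] + [fit_itv_hier()] for the within-site question, and
#' [species_ranges()] \eqn{\rightarrow} [range_design()] +
#' [backward_select()] for the across-site question. [run_pipeline()]
#' orchestrates the whole analysis, including fully synthetic inputs with
#' known ground truth ([simulate_traits()], [simulate_coupled_itv_range()]).
#'
#' @name itvar-package
#' @keywords internal
"_PACKAGE"

#' Recognised trait labels
#'
#' Wood density (g/cm^3) and leaf mass per area (LMA, g/cm^2), the two
#' functional traits the analysis targets. Trait values must be strictly
#' positive because all ITV statistics operate on natural-log values.
#'
#' @export
trait_levels <- c("wood_density", "lma")

## ---- data model ------------------------------------------------------------

#' Construct a table of individual trait observations
#'
#' One row per measured individual: the site it was sampled at, its species,
#' the trait measured and the (strictly positive) value in trait units.
#'
#' @param site,species character vectors of site and species labels.
#' @param trait character vector; each element one of [trait_levels].
#' @param value numeric vector of positive trait values.
#' @return A `data.frame` with columns `site`, `species`, `trait`, `value`.
#' @export
trait_observations <- function(site, species, trait, value) {
  x <- data.frame(site = as.character(site), species = as.character(species),
                  trait = as.character(trait), value = as.numeric(value),
                  stringsAsFactors = FALSE)
  validate_trait_observations(x)
}

validate_trait_observations <- function(x, file = NULL) {
  req <- c("site", "species", "trait", "value")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "),
         if (!is.null(file)) paste0(" [", file, "]"), call. = FALSE)
  }
  bad_trait <- which(!x$trait %in% trait_levels)
  if (length(bad_trait)) {
    stop("unknown trait label(s) ", paste(unique(x$trait[bad_trait]), collapse = ", "),
         " at row(s) ", paste(utils::head(bad_trait, 5L), collapse = ", "),
         "; expected one of: ", paste(trait_levels, collapse = ", "), call. = FALSE)
  }
  bad_val <- which(!is.finite(x$value) | x$value <= 0)
  if (length(bad_val)) {
    stop("trait values must be positive finite numbers (log transform must be ",
         "defined); offending row(s): ", paste(utils::head(bad_val, 5L), collapse = ", "),
         call. = FALSE)
  }
  x[req]
}

#' Read / write a trait observation table
#'
#' CSV with header columns `site,species,trait,value`. Rows are validated on
#' read (schema, closed trait vocabulary, strictly positive values); row
#' order is preserved.
#'
#' @param path path to a CSV file.
#' @param quiet suppress the row-count message.
#' @return `read_trait_table()`: a validated `data.frame` of observations.
#' @export
read_trait_table <- function(path, quiet = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("value" %in% names(raw) && !is.numeric(raw$value)) {
    suppressWarnings(v <- as.numeric(raw$value))
    if (anyNA(v)) {
      stop("non-numeric trait value at row(s) ",
           paste(utils::head(which(is.na(v)), 5L), collapse = ", "),
           " of ", path, call. = FALSE)
    }
    raw$value <- v
  }
  x <- validate_trait_observations(raw, file = path)
  if (!quiet) message("read ", nrow(x), " trait observations from ", path)
  x
}

#' @rdname read_trait_table
#' @param x a trait observation table.
#' @export
write_trait_table <- function(x, path) {
  x <- validate_trait_observations(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- inclusion filter ------------------------------------------------------

# split "a\rb\rc" composite keys back into a data.frame of id columns
split_keys <- function(keys, cols) {
  parts <- strsplit(keys, "\r", fixed = TRUE)
  m <- matrix(unlist(parts), ncol = length(cols), byrow = TRUE)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  out
}

#' Restrict observations to adequately sampled species and sites
#'
#' A species x site cell (within one trait) qualifies when it holds at least
#' `min_per_site` individuals; a species is retained when it has at least
#' `min_sites` qualifying cells. The defaults encode occurrence at more than
#' 3 sites with more than 5 individuals per site, i.e. >= 4 sites and >= 6
#' individuals. Both thresholds are configurable so the inclusive reading
#' (>= 3 / >= 5) is also available.
#'
#' @param observations a trait observation table (see [trait_observations()]).
#' @param min_sites minimum number of qualifying sites per species (>= 1).
#' @param min_per_site minimum individuals per species x site cell (>= 1).
#' @return An object of class `itv_filter`: a list with `observations` (the
#'   retained rows, original order) and `report` (thresholds, dropped species,
#'   dropped cells with reasons, and counts).
#' @export
filter_included <- function(observations, min_sites = 4L, min_per_site = 6L) {
  observations <- validate_trait_observations(observations)
  stopifnot(min_sites >= 1L, min_per_site >= 1L)
  if (nrow(observations) == 0L) {
    warning("empty observation table: nothing to filter", call. = FALSE)
    return(structure(list(observations = observations,
                          report = list(min_sites = min_sites,
                                        min_per_site = min_per_site,
                                        dropped_species = character(0),
                                        dropped_cells = data.frame(),
                                        n_in = 0L, n_out = 0L)),
                     class = "itv_filter"))
  }
  key <- paste(observations$trait, observations$species, observations$site,
               sep = "\r")
  cell_n <- tapply(observations$value, key, length)
  cells <- split_keys(names(cell_n), c("trait", "species", "site"))
  cells$n <- as.integer(cell_n)
  cells$qualifies <- cells$n >= min_per_site

  sp_key <- paste(cells$trait, cells$species, sep = "\r")
  q_sites <- tapply(cells$qualifies, sp_key, sum)
  sp_ok <- names(q_sites)[q_sites >= min_sites]

  cells$species_ok <- sp_key %in% sp_ok
  cells$keep <- cells$qualifies & cells$species_ok
  cells$reason <- ifelse(cells$keep, "",
                  ifelse(!cells$qualifies & !cells$species_ok,
                         "cell below min_per_site; species below min_sites",
                  ifelse(!cells$qualifies, "cell below min_per_site",
                         "species below min_sites")))

  obs_key <- paste(observations$trait, observations$species, observations$site,
                   sep = "\r")
  keep_keys <- paste(cells$trait, cells$species, cells$site, sep = "\r")[cells$keep]
  kept <- observations[obs_key %in% keep_keys, , drop = FALSE]
  rownames(kept) <- NULL

  dropped_cells <- cells[!cells$keep, c("trait", "species", "site", "n", "reason")]
  rownames(dropped_cells) <- NULL
  dropped_species <- sort(sub("\r", ":", unique(sp_key[!cells$species_ok]),
                              fixed = TRUE))
  structure(list(observations = kept,
                 report = list(min_sites = as.integer(min_sites),
                               min_per_site = as.integer(min_per_site),
                               dropped_species = dropped_species,
                               dropped_cells = dropped_cells,
                               n_in = nrow(observations), n_out = nrow(kept))),
            class = "itv_filter")
}

#' @export
print.itv_filter <- function(x, ...) {
  r <- x$report
  cat("Inclusion filter (min_sites = ", r$min_sites,
      ", min_per_site = ", r$min_per_site, ")\n", sep = "")
  cat("  observations: ", r$n_in, " in, ", r$n_out, " retained\n", sep = "")
  cat("  species x trait combinations dropped entirely: ",
      length(r$dropped_species), "\n", sep = "")
  cat("  cells dropped: ", nrow(r$dropped_cells), "\n", sep = "")
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param x an `itv_filter` object.
#' @param path output path.
#' @export
write_filter_report <- function(x, path) {
  stopifnot(inherits(x, "itv_filter"))
  jsonlite::write_json(x$report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

## ---- the ITV* statistic ----------------------------------------------------

#' Sample-size-corrected intraspecific trait variation
#'
#' ITV is the population (denominator-n) variance of the natural-log trait
#' values; ITV* applies Bessel's correction n/(n-1), making it the ordinary
#' unbiased sample variance of the log values. Because the statistic is
#' computed on the log scale it is identical for a trait and its inverse
#' (e.g. LMA and specific leaf area) and invariant to rescaling the trait's
#' units.
#'
#' @param values numeric vector of at least two strictly positive trait
#'   values.
#' @param scope label recording whether the values pool individuals within
#'   one site or across all of a species' sites; does not affect the
#'   computation.
#' @return A one-row `data.frame` with columns `scope`, `n`, `itv_raw`
#'   (denominator-n variance of logs), `itv_star` (Bessel-corrected), and
#'   `log_itv_star` (`NA` when `itv_star` is 0, where the log is undefined).
#' @examples
#' compute_itv_star(c(exp(1), exp(3)))  # itv_raw 1, itv_star 2
#' @export
compute_itv_star <- function(values, scope = c("within_site", "across_site")) {
  scope <- match.arg(scope)
  if (length(values) < 2L) {
    stop("ITV is undefined for fewer than 2 values (n = ", length(values), ")",
         call. = FALSE)
  }
  if (any(!is.finite(values) | values <= 0)) {
    stop("all trait values must be positive and finite", call. = FALSE)
  }
  lv <- log(values)
  n <- length(lv)
  itv_raw <- sum((lv - mean(lv))^2) / n
  itv_star <- itv_raw * n / (n - 1)
  data.frame(scope = scope, n = n, itv_raw = itv_raw, itv_star = itv_star,
             log_itv_star = if (itv_star > 0) log(itv_star) else NA_real_,
             stringsAsFactors = FALSE)
}

#' ITV* records at both scopes
#'
#' Computes one within-site record per species x site cell and one
#' across-site record per species, pooling all of the species' retained
#' observations (so the across-site n is the sum of the cell n's). Traits are
#' processed independently. Input should already have passed
#' [filter_included()], which guarantees every cell has at least two values.
#'
#' @param observations a (filtered) trait observation table.
#' @return An object of class `itv_table`: list with data frames `within`
#'   (`trait`, `species`, `site`, `n`, `itv_raw`, `itv_star`, `log_itv_star`)
#'   and `across` (same without `site`).
#' @export
itv_table <- function(observations) {
  observations <- validate_trait_observations(observations)
  empty_w <- data.frame(trait = character(0), species = character(0),
                        site = character(0), n = integer(0),
                        itv_raw = numeric(0), itv_star = numeric(0),
                        log_itv_star = numeric(0), stringsAsFactors = FALSE)
  if (nrow(observations) == 0L) {
    return(structure(list(within = empty_w, across = empty_w[-3L]),
                     class = "itv_table"))
  }
  one_scope <- function(keys, scope) {
    grp <- split(observations$value, keys, drop = TRUE)
    ids <- split_keys(names(grp),
                      if (scope == "within_site") c("trait", "species", "site")
                      else c("trait", "species"))
    stats <- do.call(rbind, lapply(grp, compute_itv_star, scope = scope))
    out <- cbind(ids, stats[c("n", "itv_raw", "itv_star", "log_itv_star")])
    ord <- if (scope == "within_site") order(out$trait, out$species, out$site)
           else order(out$trait, out$species)
    out <- out[ord, ]
    rownames(out) <- NULL
    out
  }
  within <- one_scope(paste(observations$trait, observations$species,
                            observations$site, sep = "\r"), "within_site")
  across <- one_scope(paste(observations$trait, observations$species, sep = "\r"),
                      "across_site")
  n_zero <- sum(within$itv_star == 0) + sum(across$itv_star == 0)
  if (n_zero > 0) {
    warning(n_zero, " zero-variance record(s): log ITV* undefined, ",
            "excluded downstream", call. = FALSE)
  }
  structure(list(within = within, across = across), class = "itv_table")
}

#' @export
print.itv_table <- function(x, ...) {
  cat("ITV* table: ", nrow(x$within), " within-site records, ",
      nrow(x$across), " across-site records (",
      length(unique(x$across$species)), " species, ",
      length(unique(x$within$site)), " sites)\n", sep = "")
  invisible(x)
}

#' Write the within- and across-site ITV* tables as CSV
#'
#' @param x an `itv_table`.
#' @param dir output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_itv_tables <- function(x, dir) {
  stopifnot(inherits(x, "itv_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pw <- file.path(dir, "itv_within.csv")
  pa <- file.path(dir, "itv_across.csv")
  utils::write.csv(x$within, pw, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$across, pa, row.names = FALSE, quote = FALSE)
  invisible(c(pw, pa))
}

#' Per-species mean of log trait values
#'
#' The response for the mean-trait variant of the range regression: the
#' arithmetic mean of the natural-log trait values over all of a species'
#' retained observations (equivalently the sample-size-weighted mean of its
#' per-site means).
#'
#' @param observations a (filtered) trait observation table.
#' @return data.frame with columns `trait`, `species`, `n`, `mean_log`.
#' @export
species_mean_log <- function(observations) {
  observations <- validate_trait_observations(observations)
  key <- paste(observations$trait, observations$species, sep = "\r")
  grp <- split(log(observations$value), key)
  ids <- split_keys(names(grp), c("trait", "species"))
  out <- cbind(ids, n = vapply(grp, length, 1L),
               mean_log = vapply(grp, mean, 1.0))
  out <- out[order(out$trait, out$species), ]
  rownames(out) <- NULL
  out
}
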