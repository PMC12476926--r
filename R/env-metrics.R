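## Site-level environmental variability metrics and species-level range
## breadths from occurrence records.

#' Construct a gridded elevation model
#'
#' A minimal in-memory digital elevation model: a numeric matrix of
#' elevations (row 1 = northernmost row, as in the ESRI ASCII convention)
#' plus cell size and the coordinates of the lower-left corner. `NA` marks
#' nodata cells, which are excluded from every statistic.
#'
#' @param z numeric matrix of elevations (`NA` = nodata).
#' @param cellsize cell edge length, meters.
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @return An object of class `dem_grid`.
#' @export
dem_grid <- function(z, cellsize = 5, xllcorner = 0, yllcorner = 0) {
  stopifnot(is.matrix(z), nrow(z) >= 1L, ncol(z) >= 1L, cellsize > 0)
  structure(list(z = z, cellsize = cellsize,
                 xllcorner = xllcorner, yllcorner = yllcorner),
            class = "dem_grid")
}

#' @export
print.dem_grid <- function(x, ...) {
  cat("dem_grid: ", nrow(x$z), " x ", ncol(x$z), " cells at ", x$cellsize,
      " m (", sum(is.na(x$z)), " nodata)\n", sep = "")
  invisible(x)
}

#' Read / write an ESRI ASCII grid
#'
#' The plain-text raster interchange format: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' `nrows` whitespace-separated rows of elevations, northernmost row first.
#'
#' @param path file path.
#' @return `read_esri_ascii()`: a [dem_grid] with nodata cells set to `NA`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ESRI ASCII header in ", path, ": missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    stop("ESRI ASCII body has ", length(vals), " values; header promises ",
         hdr$nrows * hdr$ncols, call. = FALSE)
  }
  z <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) z[z == hdr$nodata_value] <- NA
  dem_grid(z, cellsize = hdr$cellsize,
           xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner)
}

#' @rdname read_esri_ascii
#' @param dem a [dem_grid].
#' @param nodata numeric value written for `NA` cells.
#' @export
write_esri_ascii <- function(dem, path, nodata = -9999) {
  stopifnot(inherits(dem, "dem_grid"))
  z <- dem$z
  z[is.na(z)] <- nodata
  hdr <- c(paste("ncols", ncol(z)), paste("nrows", nrow(z)),
           paste("xllcorner", format(dem$xllcorner, scientific = FALSE)),
           paste("yllcorner", format(dem$yllcorner, scientific = FALSE)),
           paste("cellsize", format(dem$cellsize, scientific = FALSE)),
           paste("NODATA_value", format(nodata, scientific = FALSE)))
  body <- apply(z, 1L, function(r) paste(format(r, trim = TRUE, digits = 15),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Terrain roughness index
#'
#' Per-cell TRI: the mean absolute elevation difference between a cell and
#' its valid 8-neighborhood. Edge cells use only their existing neighbors (no
#' padding); cells that are nodata, or whose neighbors are all nodata, get
#' `NA`. A cell surrounded by much lower (or higher) terrain scores high; a
#' grid with many high-TRI cells is uneven.
#'
#' @param dem a [dem_grid].
#' @return Matrix of TRI values, same shape as `dem$z`.
#' @seealso [site_roughness()] for the site-level summary.
#' @export
terrain_roughness <- function(dem) {
  stopifnot(inherits(dem, "dem_grid"))
  z <- dem$z
  if (all(is.na(z))) stop("all cells are nodata: TRI undefined", call. = FALSE)
  nr <- nrow(z); nc <- ncol(z)
  zp <- matrix(NA_real_, nr + 2L, nc + 2L)
  zp[2:(nr + 1L), 2:(nc + 1L)] <- z
  acc <- matrix(0, nr, nc)     # sum |dz| over valid neighbors
  cnt <- matrix(0L, nr, nc)    # number of valid neighbors
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- zp[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
    ok <- !is.na(nb)
    d <- abs(z - nb)
    acc[ok] <- acc[ok] + d[ok]
    cnt <- cnt + ok
  }
  tri <- acc / cnt
  tri[cnt == 0L | is.na(z)] <- NA
  tri
}

#' Site-level terrain roughness
#'
#' Mean of the valid per-cell [terrain_roughness()] values — the site's
#' spatial (topographic) heterogeneity metric.
#'
#' @param dem a [dem_grid].
#' @return A single number.
#' @export
site_roughness <- function(dem) {
  tri <- terrain_roughness(dem)
  mean(tri, na.rm = TRUE)
}

#' Rainfall variability: CV of monthly precipitation
#'
#' Temporal (seasonality) heterogeneity metric: 100 x sample standard
#' deviation / mean of the 12 long-term mean monthly precipitation values.
#' Scale-invariant, so the units of the monthly series do not matter.
#'
#' @param monthly numeric vector of 12 non-negative monthly values (mm).
#' @return CV in percent.
#' @export
rainfall_cv <- function(monthly) {
  if (length(monthly) != 12L) {
    stop("expected 12 monthly values, got ", length(monthly), call. = FALSE)
  }
  if (any(!is.finite(monthly) | monthly < 0)) {
    stop("monthly precipitation must be non-negative and finite", call. = FALSE)
  }
  m <- mean(monthly)
  if (m <= 0) stop("mean monthly precipitation is 0: CV undefined", call. = FALSE)
  100 * stats::sd(monthly) / m
}

#' Central 95% range of an environmental attribute
#'
#' The width of the central 95% interval (97.5th minus 2.5th percentile,
#' linear-interpolation quantiles, `stats::quantile` type 7) across a
#' species' occurrence records — its environmental range breadth for that
#' attribute.
#'
#' @param values numeric vector with at least 2 finite values.
#' @param coverage central coverage of the interval (default 0.95).
#' @return The interval width (>= 0).
#' @export
env_range_95 <- function(values, coverage = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("need at least 2 finite values to estimate a range", call. = FALSE)
  }
  stopifnot(coverage > 0, coverage < 1)
  a <- (1 - coverage) / 2
  q <- stats::quantile(values, probs = c(a, 1 - a), names = FALSE, type = 7)
  unname(q[2] - q[1])
}

#' Number of geological classes a species occupies
#'
#' @param geology character vector of geology class labels for one species'
#'   occurrence records.
#' @param classes the closed vocabulary of admissible classes.
#' @return Integer count of distinct classes.
#' @export
geology_class_count <- function(geology,
                                classes = c("volcanic", "limestone",
                                            "alluvial", "ultramafic")) {
  if (length(geology) < 1L) stop("no records", call. = FALSE)
  bad <- setdiff(unique(geology), classes)
  if (length(bad)) {
    stop("unknown geology class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  length(unique(geology))
}

#' Read occurrence records
#'
#' CSV with columns `species,elevation,map,pet,cwd,irradiance,cloudiness,geology`.
#'
#' @param path CSV path.
#' @return data.frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "geology")
  if (!all(need %in% names(x))) {
    stop("occurrences file must have at least columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  x
}

#' Per-species environmental range breadths
#'
#' Applies [env_range_95()] to each numeric environmental attribute of each
#' species' occurrence records and [geology_class_count()] to its geology
#' labels. Species with fewer than 2 finite values for any requested
#' attribute are excluded with a warning.
#'
#' @param occurrences data.frame as returned by [read_occurrences()].
#' @param attributes names of the numeric attribute columns to use.
#' @param coverage central coverage passed to [env_range_95()].
#' @param geology_classes admissible geology labels.
#' @return data.frame with `species`, one `<attribute>_range` column per
#'   attribute, and `geology_count`.
#' @export
species_ranges <- function(occurrences,
                           attributes = c("elevation", "map", "pet", "cwd",
                                          "irradiance", "cloudiness"),
                           coverage = 0.95,
                           geology_classes = c("volcanic", "limestone",
                                               "alluvial", "ultramafic")) {
  stopifnot(is.data.frame(occurrences), "species" %in% names(occurrences))
  attributes <- intersect(attributes, names(occurrences))
  if (length(attributes) == 0L) stop("no requested attribute columns present",
                                     call. = FALSE)
  sp_list <- split(occurrences, occurrences$species)
  rows <- lapply(names(sp_list), function(sp) {
    d <- sp_list[[sp]]
    ok <- vapply(attributes, function(a) sum(is.finite(d[[a]])) >= 2L, TRUE)
    if (!all(ok)) return(NULL)
    widths <- vapply(attributes, function(a) env_range_95(d[[a]], coverage), 1.0)
    out <- as.data.frame(as.list(widths))
    names(out) <- paste0(attributes, "_range")
    cbind(data.frame(species = sp, stringsAsFactors = FALSE), out,
          geology_count = geology_class_count(d$geology, geology_classes))
  })
  dropped <- names(sp_list)[vapply(rows, is.null, TRUE)]
  if (length(dropped)) {
    warning("excluded species with < 2 finite values for some attribute: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Column standardization with recoverable parameters
#'
#' Centers each column to mean 0 and scales to (n-1 denominator) standard
#' deviation 1, recording the transform so it can be undone. Errors on
#' zero-variance columns, naming them.
#'
#' @param x numeric matrix or data.frame of numeric columns.
#' @return Matrix with attributes `center` and `scale`.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  degenerate <- which(scl == 0 | !is.finite(scl))
  if (length(degenerate)) {
    nm <- colnames(x)[degenerate]
    if (is.null(nm)) nm <- degenerate
    stop("degenerate (zero-sd) predictor column(s): ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' @rdname standardize_columns
#' @param z a matrix produced by `standardize_columns()`.
#' @return `unstandardize_columns()`: the original-scale matrix.
#' @export
unstandardize_columns <- function(z) {
  ctr <- attr(z, "center"); scl <- attr(z, "scale")
  stopifnot(!is.null(ctr), !is.null(scl))
  out <- sweep(sweep(unclass(z), 2L, scl, "*"), 2L, ctr, "+")
  attr(out, "center") <- NULL; attr(out, "scale") <- NULL
  out
}

#' Read a site table
#'
#' CSV mirroring the study's site summary: columns `site`, `map_mm`,
#' `geology`, `elevation_m`, `rainfall_cv`, `terrain_roughness` (additional
#' columns are kept). The packaged fixture
#' `system.file("extdata", "sites_puerto_rico.csv", package = "itvar")`
#' holds the eight Puerto Rico study sites.
#'
#' @param path CSV path.
#' @return data.frame of site records.
#' @export
read_sites_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"site" %in% names(x)) stop("site table needs a 'site' column", call. = FALSE)
  num <- intersect(c("rainfall_cv", "terrain_roughness"), names(x))
  for (cn in num) {
    if (any(is.finite(x[[cn]]) & x[[cn]] < 0)) {
      stop("negative values in ", cn, call. = FALSE)
    }
  }
  x
}

#' Read a monthly precipitation table
#'
#' CSV with columns `site,month,precip_mm` (month 1-12), one row per
#' site x month.
#'
#' @param path CSV path.
#' @return data.frame; use [rainfall_cv()] per site on `precip_mm`.
#' @export
read_monthly_precip <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "month", "precip_mm")
  if (!all(need %in% names(x))) {
    stop("monthly precipitation file needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  x
}
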