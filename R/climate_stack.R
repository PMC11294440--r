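#' Climate raster stack
#'
#' A `climate_stack` holds co-registered climate layers (e.g. the bioclim
#' temperature and precipitation surfaces) on a regular WGS84 lon/lat grid
#' with square cells, together with a single nodata mask shared by every
#' layer. Grids are stored south-up: row 1 is the southernmost row, so
#' `lat = origin_lat + (row - 0.5) * cell_size` at cell centres. ESRI
#' ASCII files (which are written north-up) are flipped on read and write.
#'
#' @param layers named list of numeric matrices, all of identical
#'   dimension. `NA`/non-finite cells are added to the nodata mask.
#' @param origin_lon,origin_lat decimal degrees of the lower-left corner
#'   of the grid (the outer corner of cell `[1, 1]`).
#' @param cell_size cell edge length in decimal degrees (square cells).
#' @param nodata_mask optional logical matrix, `TRUE` where a cell holds
#'   no data; it is unioned with per-layer missingness and applied to all
#'   layers.
#' @return An object of class `climate_stack` with fields `origin_lon`,
#'   `origin_lat`, `cell_size`, `n_rows`, `n_cols`, `layers`, `mask`.
#' @export
climate_stack <- function(layers, origin_lon, origin_lat, cell_size,
                          nodata_mask = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must be uniquely named")
  if (!all(vapply(layers, is.matrix, TRUE)))
    stop("each layer must be a matrix")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("alignment error: layers differ in dimension")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  nr <- dims[1, 1]; nc <- dims[2, 1]
  mask <- if (is.null(nodata_mask)) matrix(FALSE, nr, nc) else nodata_mask
  stopifnot(is.logical(mask), all(dim(mask) == c(nr, nc)))
  for (L in layers) mask <- mask | !is.finite(L)
  layers <- lapply(layers, function(L) { L[mask] <- NA_real_; L })
  structure(
    list(origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         cell_size = as.numeric(cell_size),
         n_rows = nr, n_cols = nc,
         layers = layers, mask = mask),
    class = "climate_stack")
}

#' @export
#' @method print climate_stack
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack: %d x %d cells of %g deg, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat))
  cat(sprintf("  layers: %s\n", paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  nodata cells: %d\n", sum(x$mask)))
  invisible(x)
}

#' Habitat suitability surface
#'
#' Per-cell suitability in `[0, 1]` on the grid of a [climate_stack];
#' produced by [predict_suitability()], [ensemble_predict()] or
#' [true_suitability()].
#'
#' @param values numeric matrix of suitabilities.
#' @param geometry a `climate_stack` (or another `suitability_map`)
#'   supplying the grid geometry and the nodata mask.
#' @return An object of class `suitability_map`.
#' @export
suitability_map <- function(values, geometry) {
  stopifnot(is.matrix(values),
            nrow(values) == geometry$n_rows, ncol(values) == geometry$n_cols)
  mask <- geometry$mask | !is.finite(values)
  v <- values[!mask]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    stop("suitability values must lie in [0, 1]")
  values[mask] <- NA_real_
  structure(
    list(origin_lon = geometry$origin_lon, origin_lat = geometry$origin_lat,
         cell_size = geometry$cell_size, n_rows = geometry$n_rows,
         n_cols = geometry$n_cols, values = values, mask = mask),
    class = "suitability_map")
}

.same_geometry <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    .near(a$origin_lon, b$origin_lon) && .near(a$origin_lat, b$origin_lat) &&
    .near(a$cell_size, b$cell_size)
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------

.read_ascii_header <- function(lines) {
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    if (!grepl("^\\s*[A-Za-z]", ln)) break
    i <- i + 1L
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  list(header = hdr, n_header = i)
}

#' Read one ESRI ASCII grid
#'
#' @param path path to an `.asc` file.
#' @return list with `values` (south-up matrix), `origin_lon`,
#'   `origin_lat`, `cell_size`.
#' @export
read_esri_ascii <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read ", path)
  lines <- readLines(path, warn = FALSE)
  h <- .read_ascii_header(lines)
  hdr <- h$header
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("I/O error: malformed ESRI ASCII header in ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if ("xllcorner" %in% names(hdr)) {
    x0 <- hdr$xllcorner; y0 <- hdr$yllcorner
  } else if ("xllcenter" %in% names(hdr)) {
    x0 <- hdr$xllcenter - cs / 2; y0 <- hdr$yllcenter - cs / 2
  } else stop("I/O error: no lower-left reference in ", path)
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[-seq_len(h$n_header)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("I/O error: expected ", nr * nc, " values, found ", length(vals),
         " in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # north-up on file
  m[m == nodata] <- NA_real_
  m <- m[rev(seq_len(nr)), , drop = FALSE]               # store south-up
  list(values = m, origin_lon = x0, origin_lat = y0, cell_size = cs)
}

#' Write one layer of a stack (or a suitability map) as ESRI ASCII
#'
#' @param x a `climate_stack` or `suitability_map`.
#' @param path output path.
#' @param variable layer name when `x` is a stack; ignored for maps.
#' @param nodata value written for masked cells.
#' @export
write_esri_ascii <- function(x, path, variable = NULL, nodata = -9999) {
  m <- if (inherits(x, "suitability_map")) x$values else {
    if (is.null(variable) || !variable %in% names(x$layers))
      stop("unknown layer: ", variable)
    x$layers[[variable]]
  }
  m[is.na(m)] <- nodata
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to north-up
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(x$origin_lon, digits = 15)),
    paste("yllcorner", format(x$origin_lat, digits = 15)),
    paste("cellsize", format(x$cell_size, digits = 15)),
    paste("NODATA_value", nodata)), con)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.10g", r), collapse = " ")), con)
  invisible(path)
}

#' Read a stack of co-registered climate rasters
#'
#' All rasters must share grid geometry (same origin, cell size and
#' dimensions, WGS84 lon/lat). The nodata mask of the stack is the union
#' of the per-layer nodata cells: a cell missing in any layer is masked
#' in all layers.
#'
#' @param paths character vector of ESRI ASCII grid paths.
#' @param names variable names, one per path (default: file base names).
#' @return A [climate_stack].
#' @export
read_climate_stack <- function(paths, names = NULL) {
  stopifnot(length(paths) >= 1L)
  if (is.null(names)) names <- sub("\\.[^.]*$", "", basename(paths))
  rs <- lapply(paths, read_esri_ascii)
  g <- rs[[1]]
  for (r in rs[-1]) {
    if (!(.near(r$origin_lon, g$origin_lon) && .near(r$origin_lat, g$origin_lat) &&
          .near(r$cell_size, g$cell_size) &&
          identical(dim(r$values), dim(g$values))))
      stop("alignment error: rasters do not share grid geometry")
  }
  layers <- stats::setNames(lapply(rs, `[[`, "values"), names)
  climate_stack(layers, g$origin_lon, g$origin_lat, g$cell_size)
}

# ---- cell indexing ----------------------------------------------------------

# Half-open cell intervals anchored at the lower-left origin: a point on a
# shared interior edge belongs to the higher-index cell. Returns a 2-column
# (row, col) matrix with NA rows for points outside the extent.
.cell_index <- function(stack, lon, lat) {
  col <- floor((lon - stack$origin_lon) / stack$cell_size) + 1
  row <- floor((lat - stack$origin_lat) / stack$cell_size) + 1
  bad <- col < 1 | col > stack$n_cols | row < 1 | row > stack$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

.cell_center <- function(stack, row, col) {
  cbind(lon = stack$origin_lon + (col - 0.5) * stack$cell_size,
        lat = stack$origin_lat + (row - 0.5) * stack$cell_size)
}

#' Attach climate covariates to labelled points
#'
#' Each point is assigned to the grid cell containing it (half-open cell
#' intervals: a point exactly on an interior edge belongs to the
#' higher-index cell) and receives that cell's layer values. Points on
#' nodata cells are dropped with a warning; points outside the raster
#' extent are an error.
#'
#' @param points data frame with `lon` and `lat` columns.
#' @param stack a [climate_stack].
#' @param labels numeric vector of labels (1 = presence, 0 = absence),
#'   recycled to `nrow(points)`.
#' @return data frame with `lon`, `lat`, `label` and one column per layer.
#' @export
extract_covariates <- function(points, stack, labels) {
  stopifnot(all(c("lon", "lat") %in% names(points)))
  labels <- rep_len(labels, nrow(points))
  idx <- .cell_index(stack, points$lon, points$lat)
  out_rows <- which(is.na(idx[, 1]))
  if (length(out_rows))
    stop("out-of-extent error: rows ",
         paste(out_rows, collapse = ", "), " fall outside the raster extent")
  lin <- cbind(idx[, 1], idx[, 2])
  on_nodata <- stack$mask[lin]
  if (any(on_nodata)) {
    warning(sum(on_nodata), " point(s) on nodata cells dropped")
    points <- points[!on_nodata, , drop = FALSE]
    labels <- labels[!on_nodata]
    lin <- lin[!on_nodata, , drop = FALSE]
  }
  covs <- lapply(stack$layers, function(L) L[lin])
  out <- data.frame(lon = points$lon, lat = points$lat, label = labels)
  for (v in names(covs)) out[[v]] <- covs[[v]]
  out
}

#' Drop highly correlated climate variables
#'
#' Pearson correlations are computed between every pair of layers over
#' all non-masked cells of the study extent. While any pair exceeds the
#' threshold in absolute value, the variable with the largest mean
#' absolute correlation to the remaining variables is dropped (ties drop
#' the later variable in stack order). A constant layer has undefined
#' correlations; it is treated as uncorrelated with a warning.
#'
#' @param stack a [climate_stack] with at least 3 non-masked cells.
#' @param threshold absolute Pearson r above which a pair is considered
#'   collinear (default 0.75).
#' @return Character vector of retained variable names, in stack order.
#' @export
prune_correlated_variables <- function(stack, threshold = 0.75) {
  vars <- names(stack$layers)
  if (length(vars) == 1L) return(vars)
  ok <- !stack$mask
  if (sum(ok) < 3L) stop("need at least 3 non-masked cells")
  X <- vapply(stack$layers, function(L) L[ok], numeric(sum(ok)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warning("constant layer(s) treated as uncorrelated: ",
            paste(vars[sds == 0], collapse = ", "))
  C <- suppressWarnings(abs(stats::cor(X)))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  keep <- seq_along(vars)
  while (length(keep) > 1L && max(C[keep, keep]) > threshold) {
    sub <- C[keep, keep, drop = FALSE]
    score <- rowSums(sub) / (length(keep) - 1L)
    worst <- max(score)
    drop_i <- max(which(score >= worst - 1e-12))  # tie: later in stack order
    keep <- keep[-drop_i]
  }
  vars[keep]
}
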