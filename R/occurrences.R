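#' Read species occurrence records
#'
#' Reads a CSV with columns `species,lon,lat` (decimal degrees, WGS84).
#' Coordinates outside valid ranges are an error; exact duplicate
#' coordinates within a species are removed.
#'
#' @param path CSV path.
#' @return data frame with columns `species`, `lon`, `lat`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read ", path)
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "lon", "lat") %in% names(occ)))
    stop("occurrence CSV must have columns species,lon,lat")
  occ <- occ[, c("species", "lon", "lat")]
  occ$lon <- as.numeric(occ$lon); occ$lat <- as.numeric(occ$lat)
  .validate_coords(occ$lon, occ$lat)
  dup <- duplicated(occ)
  if (any(dup)) occ <- occ[!dup, , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

.validate_coords <- function(lon, lat) {
  if (anyNA(lon) || anyNA(lat) ||
      any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90))
    stop("invalid coordinates: lon must be in [-180, 180], lat in [-90, 90]")
  invisible(TRUE)
}

#' Great-circle distance between lon/lat points
#'
#' Haversine formula on a sphere of radius `earth_radius_km`.
#'
#' @param p,q points as `c(lon, lat)` vectors or 2-column (lon, lat)
#'   matrices (recycled to a common length).
#' @param earth_radius_km sphere radius, default 6371 km.
#' @return Distances in km.
#' @export
#' @examples
#' haversine_km(c(0, 0), c(0, 1))  # one degree of latitude: ~111.19 km
haversine_km <- function(p, q, earth_radius_km = 6371) {
  p <- matrix(as.numeric(p), ncol = 2)
  q <- matrix(as.numeric(q), ncol = 2)
  .validate_coords(c(p[, 1], q[, 1]), c(p[, 2], q[, 2]))
  n <- max(nrow(p), nrow(q))
  p <- p[rep_len(seq_len(nrow(p)), n), , drop = FALSE]
  q <- q[rep_len(seq_len(nrow(q)), n), , drop = FALSE]
  to_rad <- pi / 180
  lam1 <- p[, 1] * to_rad; phi1 <- p[, 2] * to_rad
  lam2 <- q[, 1] * to_rad; phi2 <- q[, 2] * to_rad
  a <- sin((phi2 - phi1) / 2)^2 +
    cos(phi1) * cos(phi2) * sin((lam2 - lam1) / 2)^2
  2 * earth_radius_km * asin(pmin(1, sqrt(a)))
}

# full pairwise distance matrix for a (lon, lat) matrix
.haversine_matrix <- function(pts, earth_radius_km = 6371) {
  n <- nrow(pts)
  D <- matrix(0, n, n)
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d <- haversine_km(pts[rep(i, length(j)), , drop = FALSE],
                      pts[j, , drop = FALSE], earth_radius_km)
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

# one thinning replicate: greedy max-neighbour deletion with random
# tie-breaks, followed by a maximality repair pass (re-insert removed
# points that end up with no retained neighbour, in input order).
.thin_once <- function(adj) {
  n <- nrow(adj)
  alive <- rep(TRUE, n)
  repeat {
    idx <- which(alive)
    if (length(idx) <= 1L) break
    deg <- rowSums(adj[idx, idx, drop = FALSE])
    mx <- max(deg)
    if (mx == 0) break
    cand <- idx[deg == mx]
    alive[cand[sample.int(length(cand), 1L)]] <- FALSE
  }
  for (i in which(!alive))
    if (!any(adj[i, alive])) alive[i] <- TRUE
  which(alive)
}

#' Spatially thin occurrence records
#'
#' Removes clustered presence points so that all retained pairs are at
#' least `radius_km` apart (two points are neighbours iff their haversine
#' distance is strictly below the radius, so exactly-radius pairs
#' co-exist). Each replicate repeatedly deletes a point with the maximum
#' neighbour count, breaking ties uniformly at random, until no
#' neighbours remain, then restores any removed point that is not within
#' the radius of a retained one, so the result is always a maximal
#' independent set. The replicate retaining the most points wins (ties:
#' first found).
#'
#' @param occ data frame with `lon`, `lat` and optionally `species`.
#' @param radius_km minimum retained pairwise distance (default 1 km).
#' @param n_restarts independent replicates (default 10).
#' @param seed base RNG seed.
#' @param pool if `FALSE` (default) thinning is applied within each
#'   species separately; if `TRUE` all points are thinned together.
#' @param earth_radius_km sphere radius for distances.
#' @return The thinned subset of `occ` (row order preserved).
#' @export
thin_occurrences <- function(occ, radius_km = 1, n_restarts = 10, seed = 1,
                             pool = FALSE, earth_radius_km = 6371) {
  stopifnot(radius_km > 0)
  if (nrow(occ) == 0L) return(occ)
  if (!pool && "species" %in% names(occ) &&
      length(unique(occ$species)) > 1L) {
    parts <- lapply(unique(occ$species), function(sp) {
      thin_occurrences(occ[occ$species == sp, , drop = FALSE], radius_km,
                       n_restarts, derive_seed(seed, paste0("thin_", sp)),
                       pool = TRUE, earth_radius_km = earth_radius_km)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    return(out)
  }
  pts <- cbind(occ$lon, occ$lat)
  D <- .haversine_matrix(pts, earth_radius_km)
  adj <- D < radius_km
  diag(adj) <- FALSE
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    set.seed(derive_seed(seed, paste0("restart_", r)))
    kept <- .thin_once(adj)
    if (is.null(best) || length(kept) > length(best)) best <- kept
  }
  out <- occ[sort(best), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample pseudo-absence points
#'
#' Draws `n` distinct cells uniformly without replacement from the
#' non-nodata cells of the stack that contain no presence point, and
#' returns their centres. The default `n` equals the number of presences,
#' following the equal-count design commonly used when fitting
#' presence/pseudo-absence niche models.
#'
#' @param stack a [climate_stack].
#' @param presences data frame with `lon`, `lat` of presence points.
#' @param n number of pseudo-absences (default: `nrow(presences)`).
#' @param seed RNG seed.
#' @return data frame with `lon`, `lat` of cell centres.
#' @export
sample_pseudo_absences <- function(stack, presences, n = NULL, seed = 1) {
  n <- n %||% nrow(presences)
  stopifnot(n >= 1L)
  occupied <- matrix(FALSE, stack$n_rows, stack$n_cols)
  idx <- .cell_index(stack, presences$lon, presences$lat)
  idx <- idx[!is.na(idx[, 1]), , drop = FALSE]
  occupied[idx] <- TRUE
  eligible <- which(!stack$mask & !occupied)
  if (n > length(eligible))
    stop("capacity error: requested ", n, " pseudo-absences but only ",
         length(eligible), " eligible cells")
  set.seed(seed)
  cells <- eligible[sample.int(length(eligible), n)]
  rc <- arrayInd(cells, c(stack$n_rows, stack$n_cols))
  ctr <- .cell_center(stack, rc[, 1], rc[, 2])
  data.frame(lon = ctr[, "lon"], lat = ctr[, "lat"])
}
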