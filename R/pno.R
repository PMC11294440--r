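#' Predicted niche occupancy (PNO) profile
#'
#' A PNO links habitat suitability to one climate variable: the
#' variable's range over the study extent is cut into equal-interval
#' bins and each bin receives the summed suitability of the cells whose
#' climate value falls in it, normalised to a probability vector.
#'
#' @param edges strictly increasing numeric vector of `n_bins + 1` bin
#'   edges.
#' @param probabilities nonnegative vector of length `n_bins`; must sum
#'   to 1 (renormalised exactly on construction).
#' @param variable climate variable name.
#' @param units optional unit label (treated as opaque).
#' @return An object of class `pno_profile`.
#' @export
pno_profile <- function(edges, probabilities, variable, units = NULL) {
  stopifnot(is.numeric(edges), is.numeric(probabilities),
            length(edges) == length(probabilities) + 1L,
            length(probabilities) >= 1L)
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (any(probabilities < -1e-12)) stop("probabilities must be nonnegative")
  s <- sum(probabilities)
  if (abs(s - 1) > 1e-6) stop("probabilities must sum to 1")
  structure(list(edges = edges, probabilities = probabilities / s,
                 variable = variable, units = units),
            class = "pno_profile")
}

#' @export
#' @method print pno_profile
print.pno_profile <- function(x, ...) {
  cat(sprintf("pno_profile: %s, %d bins over [%g, %g], mean %.4g\n",
              x$variable, length(x$probabilities),
              x$edges[1], x$edges[length(x$edges)], pno_weighted_mean(x)))
  invisible(x)
}

.pno_midpoints <- function(p) {
  (p$edges[-1] + p$edges[-length(p$edges)]) / 2
}

.check_same_edges <- function(p, q) {
  if (length(p$edges) != length(q$edges) ||
      max(abs(p$edges - q$edges)) > 1e-9)
    stop("binning error: profiles have different bin edges")
  invisible(TRUE)
}

#' Build a PNO profile from a suitability map and one climate layer
#'
#' Bin edges are equally spaced over the min/max of the variable across
#' valid (non-masked) cells of the whole study extent, so profiles of
#' different species share edges and are directly comparable. The last
#' bin is right-closed, the others right-open. Bin `k`'s probability is
#' the summed suitability of cells whose climate value falls in bin `k`,
#' divided by the total suitability.
#'
#' @param suit a [suitability_map].
#' @param stack the [climate_stack] the map was predicted on (geometry
#'   must match).
#' @param variable layer name.
#' @param n_bins number of equal-interval bins (default 100).
#' @return A [pno_profile].
#' @export
compute_pno <- function(suit, stack, variable, n_bins = 100) {
  stopifnot(n_bins >= 2)
  if (!.same_geometry(suit, stack))
    stop("alignment error: map and stack geometry differ")
  if (!variable %in% names(stack$layers))
    stop("unknown layer: ", variable)
  ok <- !stack$mask & !suit$mask
  w <- suit$values[ok]
  v <- stack$layers[[variable]][ok]
  total <- sum(w)
  if (!length(w) || total <= 0)
    stop("undefined-profile error: total suitability is zero")
  vmin <- min(v); vmax <- max(v)
  if (vmin == vmax)
    stop("degenerate bin error: climate layer '", variable,
         "' is constant over valid cells; PNO needs a spread of values")
  edges <- seq(vmin, vmax, length.out = n_bins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  prob <- vapply(split(w, factor(bin, levels = seq_len(n_bins))),
                 sum, numeric(1))
  pno_profile(edges, unname(prob) / total, variable)
}

#' Suitability-weighted mean of a PNO profile
#'
#' The dot product of bin probabilities with bin midpoints, in the
#' variable's units (the point marks of a tolerance-evolution plot).
#'
#' @param p a [pno_profile].
#' @return Numeric scalar.
#' @export
pno_weighted_mean <- function(p) {
  sum(p$probabilities * .pno_midpoints(p))
}

# quantile of the binned distribution, mass uniform within bins
.pno_quantile <- function(p, q) {
  cum <- cumsum(p$probabilities)
  c0 <- c(0, cum)
  vapply(q, function(qi) {
    k <- which(cum >= qi - 1e-15)[1]
    if (is.na(k)) return(p$edges[length(p$edges)])
    w <- p$edges[k + 1] - p$edges[k]
    if (p$probabilities[k] <= 0) p$edges[k]
    else p$edges[k] + (qi - c0[k]) / p$probabilities[k] * w
  }, numeric(1))
}

#' Central density interval of a PNO profile
#'
#' Default is the equal-tail interval: the `(1 - mass)/2` and
#' `(1 + mass)/2` quantiles of the binned distribution, linearly
#' interpolated within bins (mass treated as uniform inside each bin).
#' `method = "shortest"` instead returns the narrowest interval holding
#' the requested mass.
#'
#' @param p a [pno_profile].
#' @param mass central probability mass, in (0, 1); default 0.80.
#' @param method `"equal_tail"` (default) or `"shortest"`.
#' @return `c(lower, upper)` in variable units.
#' @export
pno_central_density <- function(p, mass = 0.8,
                                method = c("equal_tail", "shortest")) {
  stopifnot(mass > 0, mass < 1)
  method <- match.arg(method)
  if (method == "equal_tail") {
    q <- .pno_quantile(p, c((1 - mass) / 2, (1 + mass) / 2))
    return(c(lower = q[1], upper = q[2]))
  }
  a <- seq(0, 1 - mass, length.out = 2001L)
  lo <- .pno_quantile(p, a)
  hi <- .pno_quantile(p, a + mass)
  i <- which.min(hi - lo)
  c(lower = lo[i], upper = hi[i])
}

#' Sample climate values from a PNO profile
#'
#' Bins are drawn with their profile probabilities; by default the bin
#' midpoint is returned (exactly reproducing point-mass profiles), or
#' uniform draws within the bin with `within_bin = "uniform"`.
#'
#' @param p a [pno_profile].
#' @param n number of draws.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param within_bin `"midpoint"` (default) or `"uniform"`.
#' @return Numeric vector of length `n`.
#' @export
sample_from_pno <- function(p, n, seed = NULL,
                            within_bin = c("midpoint", "uniform")) {
  stopifnot(n >= 1)
  within_bin <- match.arg(within_bin)
  if (!is.null(seed)) set.seed(seed)
  nb <- length(p$probabilities)
  bins <- sample.int(nb, n, replace = TRUE, prob = p$probabilities)
  if (within_bin == "midpoint") .pno_midpoints(p)[bins]
  else stats::runif(n, p$edges[bins], p$edges[bins + 1L])
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|p_k - q_k|)`, bounded in `[0, 1]`; 1 iff the
#' profiles are identical, 0 iff their supports are disjoint.
#'
#' @param p,q [pno_profile]s on identical bin edges.
#' @return Numeric scalar in `[0, 1]`.
#' @export
schoener_d <- function(p, q) {
  .check_same_edges(p, q)
  max(0, min(1, 1 - 0.5 * sum(abs(p$probabilities - q$probabilities))))
}

#' Hellinger-based I niche overlap
#'
#' `I = 1 - H^2 / 2` with `H^2 = sum((sqrt(p_k) - sqrt(q_k))^2)`;
#' bounded in `[0, 1]` like Schoener's D.
#'
#' @inheritParams schoener_d
#' @return Numeric scalar in `[0, 1]`.
#' @export
hellinger_i <- function(p, q) {
  .check_same_edges(p, q)
  h2 <- sum((sqrt(p$probabilities) - sqrt(q$probabilities))^2)
  max(0, min(1, 1 - h2 / 2))
}

#' Pairwise niche-overlap matrices
#'
#' @param pnos named list of [pno_profile]s (one per species, shared
#'   variable and edges).
#' @return list with symmetric matrices `D` and `I` (diagonal 1).
#' @export
niche_overlap <- function(pnos) {
  sp <- names(pnos)
  stopifnot(!is.null(sp), length(sp) >= 1L)
  n <- length(sp)
  D <- I <- matrix(1, n, n, dimnames = list(sp, sp))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- schoener_d(pnos[[i]], pnos[[j]])
    I[i, j] <- I[j, i] <- hellinger_i(pnos[[i]], pnos[[j]])
  }
  list(D = D, I = I)
}

#' Write a PNO profile as TSV
#'
#' Columns `bin_lower`, `bin_upper`, `probability`.
#'
#' @param p a [pno_profile].
#' @param path output path.
#' @export
write_pno <- function(p, path) {
  df <- data.frame(bin_lower = p$edges[-length(p$edges)],
                   bin_upper = p$edges[-1],
                   probability = p$probabilities)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
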