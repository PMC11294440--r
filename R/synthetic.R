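#' Species niche with Gaussian response
#'
#' Ground-truth niche used by the synthetic-data generator: occurrence
#' probability is a product of Gaussian responses,
#' `exp(-sum_v (x_v - optimum_v)^2 / (2 * breadth_v^2))`.
#'
#' @param species_id species name.
#' @param optimum named numeric vector of niche optima (variable units).
#' @param breadth named numeric vector of strictly positive niche
#'   breadths, same names as `optimum`.
#' @return An object of class `species_niche`.
#' @export
species_niche <- function(species_id, optimum, breadth) {
  stopifnot(is.character(species_id), length(optimum) == length(breadth),
            identical(sort(names(optimum)), sort(names(breadth))))
  if (any(breadth <= 0)) stop("breadths must be strictly positive")
  structure(list(species_id = species_id, optimum = optimum,
                 breadth = breadth[names(optimum)]),
            class = "species_niche")
}

# white noise smoothed by repeated 3x3 box filtering (clamped edges)
.smooth_noise <- function(nr, nc, passes = 4) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  up <- pmax(seq_len(nr) - 1L, 1L); dn <- pmin(seq_len(nr) + 1L, nr)
  lf <- pmax(seq_len(nc) - 1L, 1L); rt <- pmin(seq_len(nc) + 1L, nc)
  for (p in seq_len(passes)) {
    m <- (m[up, lf] + m[up, ] + m[up, rt] +
          m[, lf]  + m      + m[, rt] +
          m[dn, lf] + m[dn, ] + m[dn, rt]) / 9
  }
  m
}

.zscore <- function(m) (m - mean(m)) / stats::sd(as.numeric(m))

#' Generate a synthetic climate stack
#'
#' Each layer is a planar gradient (gradient directions spread evenly
#' across variables so chance correlations stay modest) plus three
#' low-frequency sinusoids plus smoothed noise, rescaled linearly to the
#' requested `(min, max)`. A spec may declare `correlate_with` and
#' `target_r` to construct a layer correlated with an earlier one via a
#' shared latent field - used to exercise
#' [prune_correlated_variables()].
#'
#' @param n_rows,n_cols grid dimensions (at least 8 x 8).
#' @param variable_specs list of specs, each a list with `name`, `min`,
#'   `max` and optionally `units`, `correlate_with`, `target_r`.
#' @param seed RNG seed (generation is a pure function of spec + seed).
#' @param origin_lon,origin_lat,cell_size grid geometry.
#' @return A [climate_stack].
#' @export
make_climate_stack <- function(n_rows = 100, n_cols = 100, variable_specs,
                               seed = 1, origin_lon = 40, origin_lat = 30,
                               cell_size = 0.01) {
  stopifnot(n_rows >= 8, n_cols >= 8, length(variable_specs) >= 1L)
  set.seed(seed)
  nv <- length(variable_specs)
  X <- matrix(rep(seq_len(n_cols) / n_cols, each = n_rows), n_rows, n_cols)
  Y <- matrix(rep(seq_len(n_rows) / n_rows, n_cols), n_rows, n_cols)
  fields <- list()
  layers <- list()
  for (i in seq_len(nv)) {
    spec <- variable_specs[[i]]
    if (is.null(spec$name) || is.null(spec$min) || is.null(spec$max) ||
        spec$min >= spec$max)
      stop("spec error: each variable needs name and min < max")
    angle <- 2 * pi * (i - 1) / nv + stats::runif(1, -0.2, 0.2)
    f <- cos(angle) * X + sin(angle) * Y
    for (h in 1:3) {
      fx <- stats::runif(1, 0.5, 3); fy <- stats::runif(1, 0.5, 3)
      ph <- stats::runif(1, 0, 2 * pi)
      amp <- stats::runif(1, 0.3, 1)
      f <- f + amp * sin(2 * pi * (fx * X + fy * Y) + ph)
    }
    f <- .zscore(f + 0.3 * .zscore(.smooth_noise(n_rows, n_cols)))
    if (!is.null(spec$correlate_with)) {
      base <- fields[[spec$correlate_with]]
      if (is.null(base))
        stop("spec error: correlate_with must name an earlier variable")
      r <- spec$target_r %||% 0.95
      f <- r * base + sqrt(1 - r^2) * f
    }
    fields[[spec$name]] <- f
    layers[[spec$name]] <-
      (f - min(f)) / (max(f) - min(f)) * (spec$max - spec$min) + spec$min
  }
  climate_stack(layers, origin_lon, origin_lat, cell_size)
}

#' Ground-truth suitability of a Gaussian-niche species
#'
#' @param stack a [climate_stack] containing the niche's variables.
#' @param niche a [species_niche].
#' @return A [suitability_map] with values in `(0, 1]` (1 exactly at the
#'   optimum), masked where the stack is masked.
#' @export
true_suitability <- function(stack, niche) {
  vars <- names(niche$optimum)
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss))
    stop("niche variable(s) not in stack: ", paste(miss, collapse = ", "))
  expo <- matrix(0, stack$n_rows, stack$n_cols)
  for (v in vars) {
    expo <- expo + (stack$layers[[v]] - niche$optimum[[v]])^2 /
      (2 * niche$breadth[[v]]^2)
  }
  suitability_map(exp(-expo), stack)
}

#' Sample clustered occurrence records from a suitability surface
#'
#' Cells are drawn with probability proportional to suitability, with
#' replacement (deliberately producing the clustered, duplicated points
#' that spatial thinning addresses); coordinates are jittered uniformly
#' within the cell.
#'
#' @param truth a [suitability_map] with positive total suitability.
#' @param n number of records (> 0).
#' @param jitter if `TRUE` (default) jitter uniformly within the cell;
#'   otherwise return cell centres.
#' @param seed RNG seed.
#' @param species_id species name for the output.
#' @return data frame with columns `species`, `lon`, `lat`.
#' @export
sample_occurrences <- function(truth, n, jitter = TRUE, seed = 1,
                               species_id = "sp") {
  if (!is.numeric(n) || n <= 0) stop("spec error: n must be positive")
  ok <- which(!truth$mask)
  w <- truth$values[ok]
  if (sum(w) <= 0) stop("total suitability must be positive")
  set.seed(seed)
  cells <- ok[sample.int(length(ok), n, replace = TRUE, prob = w)]
  rc <- arrayInd(cells, c(truth$n_rows, truth$n_cols))
  u <- if (jitter) stats::runif(n, -0.5, 0.5) else rep(0, n)
  v <- if (jitter) stats::runif(n, -0.5, 0.5) else rep(0, n)
  data.frame(
    species = species_id,
    lon = truth$origin_lon + (rc[, 2] - 0.5 + u) * truth$cell_size,
    lat = truth$origin_lat + (rc[, 1] - 0.5 + v) * truth$cell_size)
}

#' Simulate a pure-birth ultrametric chronogram
#'
#' A Yule tree rescaled so the root age equals `root_age_ma`.
#'
#' @param n_tips number of tips (>= 2).
#' @param root_age_ma root age in millions of years.
#' @param seed RNG seed.
#' @return An ultrametric `ape::phylo` tree with tips `t1..tn`.
#' @export
simulate_chronogram <- function(n_tips, root_age_ma, seed = 1) {
  stopifnot(n_tips >= 2, root_age_ma > 0)
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(.node_depths(tr))
  tr$edge.length <- tr$edge.length * root_age_ma / depth
  tr
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Recursive simulation from the root: each child state is the parent
#' state plus a normal increment with variance `sigma_sq * branch
#' length`.
#'
#' @param tree an `ape::phylo` tree.
#' @param root_state trait value at the root.
#' @param sigma_sq BM rate (variance per Ma), >= 0.
#' @param seed RNG seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, root_state, sigma_sq, seed = 1) {
  stopifnot(sigma_sq >= 0)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  x <- rep(NA_real_, nnode)
  x[ntip + 1L] <- root_state
  for (e in rev(seq_len(nrow(po$edge)))) {  # preorder traversal
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    x[ch] <- x[par] + stats::rnorm(1, 0, sqrt(sigma_sq * po$edge.length[e]))
  }
  stats::setNames(x[seq_len(ntip)], tree$tip.label)
}

#' Default synthetic study conditions
#'
#' The reference scenario used throughout the tests: a 100 x 100 grid of
#' six bioclim-style variables (annual mean temperature `bio1`, warmest-
#' month maximum `bio5`, coldest-month minimum `bio6`, wettest-month
#' precipitation `bio13`, driest-month precipitation `bio14`, and
#' precipitation seasonality `bio15` constructed to correlate with
#' `bio14` at r = 0.95, exercising variable pruning), four species with
#' well-separated Gaussian niches defined on `bio1` and `bio13` (the
#' truly informative variables), 40 clustered presence records per
#' species, and a four-tip pure-birth chronogram with root age 11.3 Ma.
#'
#' @param seed RNG seed.
#' @param n_rows,n_cols grid dimensions.
#' @param n_presences presence records per species.
#' @param root_age_ma chronogram root age.
#' @return list with `stack`, `niches`, `occurrences`, `tree`,
#'   `informative_variables`, `species`.
#' @export
default_scenario <- function(seed = 1, n_rows = 100, n_cols = 100,
                             n_presences = 40, root_age_ma = 11.3) {
  specs <- list(
    list(name = "bio1",  min = 0,   max = 30,  units = "degC"),
    list(name = "bio5",  min = 10,  max = 45,  units = "degC"),
    list(name = "bio6",  min = -30, max = 10,  units = "degC"),
    list(name = "bio13", min = 50,  max = 400, units = "mm"),
    list(name = "bio14", min = 0,   max = 60,  units = "mm"),
    list(name = "bio15", min = 20,  max = 120, units = "mm",
         correlate_with = "bio14", target_r = 0.95))
  stack <- make_climate_stack(n_rows, n_cols, specs,
                              seed = derive_seed(seed, "stack"))
  species <- paste0("sp", 1:4)
  # optima sit in distinct corners of the joint (bio1, bio13) climate
  # space: peripheral combinations are rare in the background, which is
  # what makes the four niches well separated
  opt1 <- c(6, 10, 21, 25)       # bio1 optima, degC
  opt13 <- c(120, 330, 90, 320)  # bio13 optima, mm
  niches <- lapply(1:4, function(i) {
    species_niche(species[i],
                  optimum = c(bio1 = opt1[i], bio13 = opt13[i]),
                  breadth = c(bio1 = 1.5, bio13 = 18))
  })
  names(niches) <- species
  occ <- do.call(rbind, lapply(1:4, function(i) {
    sample_occurrences(true_suitability(stack, niches[[i]]), n_presences,
                       seed = derive_seed(seed, paste0("occ_", species[i])),
                       species_id = species[i])
  }))
  rownames(occ) <- NULL
  tree <- simulate_chronogram(4, root_age_ma,
                              seed = derive_seed(seed, "tree"))
  tree$tip.label <- species
  list(stack = stack, niches = niches, occurrences = occ, tree = tree,
       informative_variables = c("bio1", "bio13"), species = species)
}

#' Write a complete synthetic input bundle to a directory
#'
#' Writes the [default_scenario()] as pipeline-ready files: one ESRI
#' ASCII raster per variable, `occurrences.csv`, `tree.nwk`, a
#' ground-truth `truth.json` (niche optima/breadths and the informative
#' variables) and a `config.yaml` ready for [run_pipeline()].
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed, also recorded in the config.
#' @param ... passed to [default_scenario()].
#' @return (Invisibly) the path to the written `config.yaml`.
#' @export
make_synthetic_bundle <- function(dir, seed = 1, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scen <- default_scenario(seed = seed, ...)
  vars <- names(scen$stack$layers)
  raster_paths <- file.path(dir, paste0(vars, ".asc"))
  for (i in seq_along(vars))
    write_esri_ascii(scen$stack, raster_paths[i], vars[i])
  occ_path <- file.path(dir, "occurrences.csv")
  utils::write.csv(scen$occurrences, occ_path, row.names = FALSE,
                   quote = FALSE)
  tree_path <- file.path(dir, "tree.nwk")
  write_newick(scen$tree, tree_path)
  truth <- list(
    informative_variables = scen$informative_variables,
    niches = lapply(scen$niches, function(n)
      list(species = n$species_id, optimum = as.list(n$optimum),
           breadth = as.list(n$breadth))))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- list(
    occurrences = occ_path,
    rasters = list(paths = as.list(raster_paths), names = as.list(vars)),
    tree = tree_path,
    outdir = file.path(dir, "out"),
    seed = seed)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
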