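test_that("ESRI ASCII grids round-trip through the stack reader", {
  dir <- withr::local_tempdir()
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  st <- tiny_stack(bio1 = m)
  p <- file.path(dir, "bio1.asc")
  write_esri_ascii(st, p, "bio1")
  st2 <- read_climate_stack(p, "bio1")
  expect_equal(st2$layers$bio1, m)
  expect_identical(dim(st2$mask), c(2L, 2L))
  expect_equal(st2$cell_size, 1)
})

test_that("stack construction unions nodata masks across layers", {
  a <- matrix(c(1, NA, 3, 4), 2, 2)
  b <- matrix(5:8, 2, 2)
  st <- tiny_stack(a = a, b = b)
  expect_true(st$mask[2, 1])
  expect_true(is.na(st$layers$b[2, 1]))  # masked in every layer
  expect_equal(sum(st$mask), 1L)
})

test_that("mismatched grid geometry is an alignment error", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.asc"); p2 <- file.path(dir, "b.asc")
  write_esri_ascii(tiny_stack(a = matrix(1:4, 2, 2)), p1, "a")
  write_esri_ascii(tiny_stack(a = matrix(1:4, 2, 2), cell_size = 2),
                   p2, "a")
  expect_error(read_climate_stack(c(p1, p2)), "alignment")
})

test_that("haversine distance matches closed forms and geosphere", {
  expect_equal(haversine_km(c(12, 34), c(12, 34)), 0)
  expect_equal(haversine_km(c(0, 0), c(0, 1)), 2 * pi * 6371 / 360,
               tolerance = 1e-9)
  expect_equal(haversine_km(c(0, 0), c(180, 0)), pi * 6371,
               tolerance = 1e-9)
  set.seed(42)
  for (i in 1:20) {
    p <- c(runif(1, -180, 180), runif(1, -89, 89))
    q <- c(runif(1, -180, 180), runif(1, -89, 89))
    expect_equal(haversine_km(p, q),
                 geosphere::distHaversine(p, q, r = 6371),
                 tolerance = 1e-9)
  }
})

test_that("haversine is symmetric and satisfies the triangle inequality", {
  set.seed(7)
  for (i in 1:50) {
    pts <- cbind(runif(3, -180, 180), runif(3, -90, 90))
    d12 <- haversine_km(pts[1, ], pts[2, ])
    d21 <- haversine_km(pts[2, ], pts[1, ])
    d13 <- haversine_km(pts[1, ], pts[3, ])
    d23 <- haversine_km(pts[2, ], pts[3, ])
    expect_equal(d12, d21, tolerance = 1e-12)
    expect_lte(d13, d12 + d23 + 1e-9)
  }
})

test_that("thinning keeps far-apart points and collapses coincident ones", {
  deg_per_km <- 1 / haversine_km(c(0, 0), c(0, 1))
  far <- data.frame(lon = 0, lat = c(0, 5, 10) * deg_per_km)
  expect_equal(nrow(thin_occurrences(far, radius_km = 1, seed = 1)), 3L)
  twin <- data.frame(lon = c(3, 3), lat = c(9, 9))
  expect_equal(nrow(thin_occurrences(twin, radius_km = 1, seed = 1)), 1L)
})

test_that("collinear triple keeps the endpoints", {
  # points at 0, 0.5 and ~1.0001 km along a meridian: the middle point
  # has two neighbours and is deleted; the remaining pair sits at the
  # radius and co-exists (neighbourhood is strict "< radius")
  deg_per_km <- 1 / haversine_km(c(0, 0), c(0, 1))
  occ <- data.frame(lon = 0, lat = c(0, 0.5, 1.0001) * deg_per_km)
  out <- thin_occurrences(occ, radius_km = 1, seed = 3)
  expect_equal(out$lat, occ$lat[c(1, 3)])
})

test_that("thinned sets are independent and maximal on random instances", {
  set.seed(11)
  deg <- 1 / haversine_km(c(0, 0), c(0, 1))  # degrees per km
  for (i in 1:100) {
    n <- sample(4:12, 1)
    occ <- data.frame(lon = runif(n, 0, 3 * deg), lat = runif(n, 0, 3 * deg))
    out <- thin_occurrences(occ, radius_km = 1, n_restarts = 3, seed = i)
    pts <- as.matrix(out[, c("lon", "lat")])
    if (nrow(pts) > 1) {
      D <- outer(seq_len(nrow(pts)), seq_len(nrow(pts)), function(a, b)
        haversine_km(pts[a, , drop = FALSE], pts[b, , drop = FALSE]))
      expect_gte(min(D[upper.tri(D)]), 1)
    }
    # maximality: every removed point is within radius of a retained one
    removed <- occ[!(paste(occ$lon, occ$lat) %in%
                       paste(out$lon, out$lat)), , drop = FALSE]
    if (nrow(removed)) {
      for (j in seq_len(nrow(removed))) {
        d <- haversine_km(
          matrix(rep(as.numeric(removed[j, ]), nrow(out)),
                 ncol = 2, byrow = TRUE),
          as.matrix(out[, c("lon", "lat")]))
        expect_lt(min(d), 1)
      }
    }
  }
})

test_that("restarts never beat the exact optimum and dominate one run", {
  set.seed(23)
  deg <- 1 / haversine_km(c(0, 0), c(0, 1))
  for (i in 1:30) {
    n <- sample(6:10, 1)
    occ <- data.frame(lon = runif(n, 0, 2.5 * deg),
                      lat = runif(n, 0, 2.5 * deg))
    D <- outer(seq_len(n), seq_len(n), function(a, b)
      haversine_km(as.matrix(occ)[a, , drop = FALSE],
                   as.matrix(occ)[b, , drop = FALSE]))
    adj <- D < 1; diag(adj) <- FALSE
    opt <- brute_mis(adj)
    many <- nrow(thin_occurrences(occ, 1, n_restarts = 10, seed = i))
    one <- nrow(thin_occurrences(occ, 1, n_restarts = 1, seed = i))
    expect_lte(many, opt)
    expect_gte(many, one)
  }
})

test_that("per-species thinning is the default, pooling is optional", {
  occ <- data.frame(species = c("a", "b"), lon = c(0, 0), lat = c(0, 1e-4))
  expect_equal(nrow(thin_occurrences(occ, radius_km = 1, seed = 1)), 2L)
  expect_equal(nrow(thin_occurrences(occ, radius_km = 1, seed = 1,
                                     pool = TRUE)), 1L)
})

test_that("pseudo-absences avoid presence cells and respect capacity", {
  st <- tiny_stack(a = matrix(runif(16), 4, 4))
  pres <- data.frame(lon = c(0.5, 1.5), lat = c(0.5, 0.5))
  ab <- sample_pseudo_absences(st, pres, seed = 5)
  expect_equal(nrow(ab), 2L)  # equal-count default
  expect_false(any(paste(ab$lon, ab$lat) %in% paste(0.5 + 0:1, 0.5)))
  ab2 <- sample_pseudo_absences(st, pres, seed = 5)
  expect_identical(ab, ab2)   # reproducible given seed
  # every cell occupied -> capacity error
  full <- expand.grid(lon = 0.5 + 0:3, lat = 0.5 + 0:3)
  expect_error(sample_pseudo_absences(st, full, n = 1), "capacity")
})

test_that("covariate extraction follows the half-open cell convention", {
  st <- tiny_stack(a = matrix(c(1, 2, 3, 4), 2, 2))
  # cell centres
  tab <- extract_covariates(data.frame(lon = 0.5, lat = 0.5), st, 1)
  expect_equal(tab$a, 1)
  # interior shared edge belongs to the higher-index cell
  tab2 <- extract_covariates(data.frame(lon = 1, lat = 0.5), st, 1)
  expect_equal(tab2$a, 3)
  # out of extent errors with offending rows
  expect_error(extract_covariates(data.frame(lon = 3.5, lat = 0.5), st, 1),
               "out-of-extent")
  # nodata cells drop with a warning
  stm <- tiny_stack(a = matrix(c(NA, 2, 3, 4), 2, 2))
  expect_warning(
    out <- extract_covariates(data.frame(lon = c(0.5, 1.5),
                                         lat = c(0.5, 0.5)), stm, 1),
    "nodata")
  expect_equal(nrow(out), 1L)
})

test_that("correlation pruning drops the later of two identical layers", {
  set.seed(9)
  x <- matrix(rnorm(100), 10, 10)
  z <- matrix(rnorm(100), 10, 10)
  st <- tiny_stack(X = x, Y = x, Z = z)
  expect_identical(prune_correlated_variables(st, 0.75), c("X", "Z"))
})

test_that("correlation pruning is idempotent and respects its bound", {
  set.seed(31)
  base <- matrix(rnorm(400), 20, 20)
  st <- tiny_stack(a = base,
                   b = 0.9 * base + 0.1 * matrix(rnorm(400), 20, 20),
                   c = matrix(rnorm(400), 20, 20),
                   d = matrix(rnorm(400), 20, 20))
  kept <- prune_correlated_variables(st, 0.75)
  vals <- vapply(st$layers[kept], as.numeric, numeric(400))
  C <- abs(cor(vals)); diag(C) <- 0
  expect_lte(max(C), 0.75)
  st2 <- climate_stack(st$layers[kept], 0, 0, 1)
  expect_identical(prune_correlated_variables(st2, 0.75), kept)
})

test_that("single and constant layers are handled", {
  st1 <- tiny_stack(only = matrix(rnorm(16), 4, 4))
  expect_identical(prune_correlated_variables(st1), "only")
  st2 <- tiny_stack(flat = matrix(1, 4, 4), v = matrix(rnorm(16), 4, 4))
  expect_warning(kept <- prune_correlated_variables(st2), "constant")
  expect_identical(kept, c("flat", "v"))
})

test_that("occurrence reading validates and de-duplicates", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "occ.csv")
  writeLines(c("species,lon,lat", "a,10,20", "a,10,20", "b,30,40"), p)
  occ <- read_occurrences(p)
  expect_equal(nrow(occ), 2L)
  writeLines(c("species,lon,lat", "a,200,20"), p)
  expect_error(read_occurrences(p), "invalid coordinates")
})
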