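test_that("Newick reading validates and round-trips", {
  tr <- read_newick("(A:1,B:1);")
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(tr$edge.length, c(1, 1))
  expect_error(read_newick("(A:1,B;"), "parse error")
  expect_error(read_newick("(A:1,B:1));"), "parse error")
  big <- simulate_chronogram(20, 7.5, seed = 3)
  back <- read_newick(write_newick(big))
  expect_true(ape::all.equal.phylo(big, back, tolerance = 1e-9))
})

test_that("pruning to one tip per species preserves depths", {
  tr <- read_newick("((A1:1,A2:1):2,B:3);")
  out <- prune_to_one_tip_per_species(tr, c(A = "A1", B = "B"))
  expect_setequal(out$tip.label, c("A1", "B"))
  d <- ape::node.depth.edgelength(out)[1:2]
  expect_equal(d, c(3, 3))
  # relabelled variant maps tips to species names
  out2 <- prune_to_one_tip_per_species(tr, c(A = "A1", B = "B"),
                                       relabel = TRUE)
  expect_setequal(out2$tip.label, c("A", "B"))
  expect_error(prune_to_one_tip_per_species(tr, c(A = "nope")), "lookup")
  # keep everything: unchanged
  all_keep <- setNames(tr$tip.label, tr$tip.label)
  expect_true(ape::all.equal.phylo(
    tr, prune_to_one_tip_per_species(tr, all_keep)))
  # random trees: kept-tip depths (root edge included) unchanged to 1e-9
  set.seed(6)
  for (i in 1:10) {
    big <- simulate_chronogram(12, 9, seed = i)
    keep <- sample(big$tip.label, 5)
    pr <- prune_to_one_tip_per_species(big, setNames(keep, keep))
    d0 <- setNames(ape::node.depth.edgelength(big)[1:12], big$tip.label)
    d1 <- setNames(ape::node.depth.edgelength(pr)[1:5], pr$tip.label) +
      (if (is.null(pr$root.edge)) 0 else pr$root.edge)
    expect_equal(d1, d0[names(d1)], tolerance = 1e-9)
  }
})

test_that("node ages come from depth arithmetic on ultrametric trees", {
  a <- node_ages(read_newick("(A:2,B:2);"))
  expect_equal(unname(a[c("A", "B", "3")]), c(0, 0, 2))
  b <- node_ages(read_newick("((A:2,B:2):3,(C:4,D:4):1);"))
  expect_equal(unname(b[c("5", "6", "7")]), c(5, 2, 4))
  expect_error(node_ages(read_newick("(A:1,B:2);")), "ultrametricity")
})

test_that("BM fit agrees with the explicit C-matrix GLS oracle", {
  set.seed(41)
  for (i in 1:50) {
    tr <- simulate_chronogram(sample(3:12, 1), runif(1, 0.5, 15),
                              seed = 1000 + i)
    x <- simulate_bm(tr, rnorm(1, 0, 3), runif(1, 0.1, 4), seed = 2000 + i)
    fit <- bm_mle(tr, x)
    orc <- gls_oracle(tr, x)
    expect_equal(fit$root_state, orc$root_state, tolerance = 1e-8)
    expect_equal(fit$sigma_sq, orc$sigma_sq, tolerance = 1e-8)
  }
})

test_that("BM fit handles the textbook special cases", {
  # two tips, equal branches: root is the tip mean for any values
  tr <- read_newick("(A:2,B:2);")
  expect_equal(bm_mle(tr, c(A = -3, B = 10))$root_state, 3.5)
  # star tree, branches 1 and 3, values 0 and 3: GLS weights 1/t
  star <- read_newick("(A:1,B:3);")
  expect_equal(bm_mle(star, c(A = 0, B = 3))$root_state, 0.75)
  # identical tip values: zero rate
  tr4 <- simulate_chronogram(4, 5, seed = 2)
  fit <- bm_mle(tr4, setNames(rep(7, 4), tr4$tip.label))
  expect_equal(fit$root_state, 7)
  expect_equal(fit$sigma_sq, 0)
  # zero total depth cannot support the model
  flat <- read_newick("(A:0,B:0);")
  expect_error(bm_mle(flat, c(A = 1, B = 2)), "degenerate-covariance")
})

test_that("BM log-likelihood equals the dense multivariate normal", {
  tr <- simulate_chronogram(7, 6, seed = 11)
  x <- simulate_bm(tr, 1, 2, seed = 12)
  fit <- bm_mle(tr, x)
  C <- ape::vcv(tr)
  z <- x[rownames(C)]
  q <- as.numeric(t(z - fit$root_state) %*% solve(C) %*%
                    (z - fit$root_state))
  ll <- -length(z) / 2 * log(2 * pi * fit$sigma_sq) -
    as.numeric(determinant(C)$modulus) / 2 - q / (2 * fit$sigma_sq)
  expect_equal(fit$log_likelihood, ll, tolerance = 1e-8)
})

test_that("ancestral states match the re-rooting oracle", {
  set.seed(43)
  for (i in 1:12) {
    tr <- simulate_chronogram(8, runif(1, 2, 12), seed = 3000 + i)
    x <- simulate_bm(tr, 0, 1, seed = 4000 + i)
    st <- ancestral_states(tr, x)
    fa <- phytools::fastAnc(tr, x)
    orc <- setNames(as.numeric(fa), names(fa))
    expect_equal(st, orc[names(st)], tolerance = 1e-8)
    expect_equal(unname(st[1]), bm_mle(tr, x)$root_state,
                 tolerance = 1e-12)
  }
})

test_that("ancestral states are affine-equivariant and pin zero branches", {
  tr <- simulate_chronogram(6, 4, seed = 21)
  x <- simulate_bm(tr, 2, 1, seed = 22)
  st <- ancestral_states(tr, x)
  st2 <- ancestral_states(tr, 3 * x + 5)
  expect_equal(st2, 3 * st + 5, tolerance = 1e-9)
  # two-tip equal branches: single state is the tip mean
  expect_equal(unname(ancestral_states(read_newick("(A:1,B:1);"),
                                       c(A = 0, B = 8))), 4)
  # a zero-length terminal branch pins its node to the tip value
  pin <- read_newick("((A:0,B:2):1,C:3);")
  expect_equal(unname(ancestral_states(pin, c(A = 5, B = 0, C = 9))["5"]),
               5)
})

test_that("tolerance reconstruction is exact for point-mass profiles", {
  tr <- simulate_chronogram(4, 11.3, seed = 8)
  edges <- seq(0, 30, length.out = 101)
  vals <- c(4, 11, 19, 26)
  pnos <- lapply(vals, function(v) point_mass_pno(edges, v))
  names(pnos) <- tr$tip.label
  out <- reconstruct_tolerance_evolution(tr, pnos, n_samples = 5, seed = 3)
  mids <- (edges[-1] + edges[-101]) / 2
  snap <- vapply(vals, function(v) mids[which.min(abs(mids - v))],
                 numeric(1))
  st <- ancestral_states(tr, setNames(snap, tr$tip.label))
  internal <- out[out$node_type == "internal", ]
  expect_equal(internal$mean, unname(st[internal$node_id]),
               tolerance = 1e-12)
  expect_equal(internal$sd, rep(0, nrow(internal)))
  # tips: age 0, PNO mean, interval containing the mean
  tips <- out[out$node_type == "tip", ]
  expect_equal(tips$age_ma, rep(0, 4))
  expect_equal(tips$mean, vapply(pnos[tips$node_id], pno_weighted_mean,
                                 numeric(1)), ignore_attr = TRUE)
  expect_true(all(tips$lower <= tips$mean & tips$mean <= tips$upper))
  # internal node ages strictly positive, decreasing from the root
  expect_true(all(internal$age_ma > 0))
  expect_equal(max(internal$age_ma), 11.3, tolerance = 1e-9)
})

test_that("a shared point-mass niche propagates unchanged to every node", {
  tr <- simulate_chronogram(5, 3, seed = 9)
  edges <- seq(0, 10, 1)
  pnos <- setNames(replicate(5, point_mass_pno(edges, 6.2),
                             simplify = FALSE), tr$tip.label)
  out <- reconstruct_tolerance_evolution(tr, pnos, n_samples = 3, seed = 1)
  expect_equal(out$mean[out$node_type == "internal"], rep(6.5, 4))
})

test_that("reconstruction rejects mismatched PNO edges", {
  tr <- simulate_chronogram(3, 2, seed = 10)
  pnos <- list(point_mass_pno(seq(0, 10, 1), 2),
               point_mass_pno(seq(0, 10, 1), 5),
               point_mass_pno(seq(0, 12, 1.2), 5))
  names(pnos) <- tr$tip.label
  expect_error(reconstruct_tolerance_evolution(tr, pnos, n_samples = 2),
               "binning")
})
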