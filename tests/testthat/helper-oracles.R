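# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (enumeration / explicit matrices) and
# never share code with the implementation paths they check.

# concordant-pair AUC by full enumeration (ties count one half)
brute_auc <- function(scores, labels) {
  p <- scores[labels == 1]
  a <- scores[labels == 0]
  s <- 0
  for (x in p) for (y in a) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(p) * length(a))
}

# exact maximum independent set size by subset enumeration
brute_mis <- function(adj) {
  n <- nrow(adj)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(members) <= best) next
    if (length(members) < 2L || !any(adj[members, members])) {
      best <- length(members)
    }
  }
  best
}

# explicit C-matrix GLS fit of the BM model
gls_oracle <- function(tree, x) {
  C <- ape::vcv(tree)
  z <- x[rownames(C)]
  one <- rep(1, length(z))
  Ci <- solve(C)
  root <- as.numeric((one %*% Ci %*% z) / (one %*% Ci %*% one))
  ss <- as.numeric(t(z - root) %*% Ci %*% (z - root)) / length(z)
  list(root_state = root, sigma_sq = ss)
}

# small single- or multi-layer stack on a unit grid
tiny_stack <- function(..., origin_lon = 0, origin_lat = 0, cell_size = 1) {
  climate_stack(list(...), origin_lon, origin_lat, cell_size)
}

# PNO that is a point mass at the bin containing `value`
point_mass_pno <- function(edges, value, variable = "v") {
  nb <- length(edges) - 1L
  k <- min(max(findInterval(value, edges, rightmost.closed = TRUE), 1L), nb)
  prob <- rep(0, nb)
  prob[k] <- 1
  pno_profile(edges, prob, variable)
}

# random valid probability profile on given edges
random_pno <- function(edges, variable = "v") {
  nb <- length(edges) - 1L
  p <- stats::runif(nb)
  pno_profile(edges, p / sum(p), variable)
}

# linearly separable presence/absence table driven by one variable
separable_table <- function(n = 30, seed = 1) {
  set.seed(seed)
  data.frame(
    label = rep(c(1, 0), each = n / 2),
    v1 = c(stats::rnorm(n / 2, 4, 0.5), stats::rnorm(n / 2, -4, 0.5)),
    v2 = stats::rnorm(n))
}
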