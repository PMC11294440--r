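#' Read a Newick chronogram
#'
#' Thin validating wrapper over ape's Newick parser. The tree must carry
#' branch lengths (here in millions of years). A basic syntax scan
#' reports the character position of unbalanced parentheses or a missing
#' terminating semicolon before handing the string to ape.
#'
#' @param text Newick string (ignored if `file` is given).
#' @param file optional path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (!is.null(file)) {
    if (!file.exists(file)) stop("I/O error: cannot read ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  for (i in seq_len(nchar(text))) {
    ch <- substr(text, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("parse error at position ", i,
                           ": unmatched ')'")
    }
  }
  if (depth != 0L)
    stop("parse error at position ", nchar(text), ": ", depth,
         " unclosed '('")
  if (!grepl(";", text))
    stop("parse error at position ", nchar(text), ": missing ';'")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || is.null(tr$tip.label))
    stop("parse error: malformed Newick string")
  if (is.null(tr$edge.length))
    stop("parse error: tree has no branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("tip labels must be unique")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  tr
}

#' Write a tree as Newick
#'
#' @param tree an `ape::phylo` tree.
#' @param file optional path; if `NULL` the string is returned.
#' @param digits significant digits for branch lengths (default 12,
#'   enough to round-trip to 1e-9 on chronogram scales).
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Prune a chronogram to one terminal per species
#'
#' Keeps exactly the listed tips and drops everything else; resulting
#' degree-2 nodes are suppressed with branch lengths summed (ape's
#' drop-tip semantics). When the kept tips' most recent common ancestor
#' lies below the original root, the stem back to that root is kept as
#' the tree's `root.edge`, so root-to-tip depths (root edge included)
#' are unchanged.
#'
#' @param tree an `ape::phylo` tree.
#' @param keep named character vector: `species -> tip label`.
#' @param relabel if `TRUE`, kept tips are renamed to their species
#'   names (useful before matching tips to per-species PNO profiles).
#' @return The pruned tree.
#' @export
prune_to_one_tip_per_species <- function(tree, keep, relabel = FALSE) {
  keep <- unlist(keep)
  miss <- setdiff(keep, tree$tip.label)
  if (length(miss))
    stop("lookup error: tip label(s) not in tree: ",
         paste(miss, collapse = ", "))
  out <- ape::keep.tip(tree, unname(keep))
  # the stem from the original root down to the kept tips' MRCA: its
  # length is the drop in root-to-tip depth, identical for every kept
  # tip, and is recorded as the pruned tree's root edge
  d_old <- .node_depths(tree)[match(out$tip.label, tree$tip.label)]
  d_new <- .node_depths(out)[seq_along(out$tip.label)]
  stem <- mean(d_old - d_new) + (tree$root.edge %||% 0)
  if (stem > 1e-12) out$root.edge <- stem
  if (relabel && !is.null(names(keep)))
    out$tip.label <- names(keep)[match(out$tip.label, unname(keep))]
  out
}

# root-to-node depths (path length from root) for all nodes
.node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

.internal_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  ids <- as.character((ntip + 1L):(ntip + tree$Nnode))
  if (!is.null(tree$node.label) && !anyDuplicated(tree$node.label) &&
      all(nzchar(tree$node.label)))
    ids <- tree$node.label
  ids
}

#' Node ages of an ultrametric chronogram
#'
#' `age(node) = root age - depth(node)` with the root age equal to the
#' maximum root-to-tip depth; tips sit at age 0. Trees that are not
#' ultrametric within the tolerance are rejected.
#'
#' @param tree an `ape::phylo` tree with branch lengths in Ma.
#' @param tol relative ultrametricity tolerance (default 1e-6).
#' @return Named numeric vector of ages (tips first, then internal
#'   nodes in ape numbering order).
#' @export
node_ages <- function(tree, tol = 1e-6) {
  ntip <- length(tree$tip.label)
  d <- .node_depths(tree)
  root_age <- max(d[seq_len(ntip)])
  dev <- root_age - d[seq_len(ntip)]
  if (root_age > 0 && max(dev) / root_age > tol) {
    worst <- tree$tip.label[which.max(dev)]
    stop("ultrametricity error: tip '", worst, "' deviates by ",
         format(max(dev)), " Ma from the root age")
  }
  ages <- root_age - d
  ages[seq_len(ntip)][abs(ages[seq_len(ntip)]) <= tol * max(root_age, 1)] <- 0
  names(ages) <- c(tree$tip.label, .internal_ids(tree))
  ages
}

# ---- Brownian-motion machinery ---------------------------------------------

# Postorder pruning pass. For every node, combines the messages arriving
# from its children by pairwise folding; each fold of (m1, w1), (m2, w2)
# contributes (m1 - m2)^2 / (w1 + w2) to the GLS quadratic form and
# log(w1 + w2) to log det C. Returns per-node conditional means and
# variances plus the per-edge upward messages, so the same pass serves
# both the ML fit and the ancestral-state message passing.
.bm_upward <- function(tree, x) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  comb_m <- comb_w <- rep(NA_real_, nnode)
  has <- rep(FALSE, nnode)
  msg_m <- msg_w <- rep(NA_real_, nnode)  # message from node to its parent
  comb_m[seq_len(ntip)] <- x
  comb_w[seq_len(ntip)] <- 0
  Q <- 0; logdet <- 0
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    msg_m[ch] <- comb_m[ch]
    msg_w[ch] <- comb_w[ch] + po$edge.length[e]
    if (!has[par]) {
      comb_m[par] <- msg_m[ch]; comb_w[par] <- msg_w[ch]; has[par] <- TRUE
    } else {
      w1 <- comb_w[par]; w2 <- msg_w[ch]
      m1 <- comb_m[par]; m2 <- msg_m[ch]
      tot <- w1 + w2
      if (tot <= 0)
        stop("degenerate-covariance error: zero-length sibling branches")
      Q <- Q + (m1 - m2)^2 / tot
      logdet <- logdet + log(tot)
      comb_m[par] <- (m1 * w2 + m2 * w1) / tot
      comb_w[par] <- w1 * w2 / tot
    }
  }
  root <- ntip + 1L
  list(comb_m = comb_m, comb_w = comb_w, msg_m = msg_m, msg_w = msg_w,
       root = root, Q = Q, logdet = logdet + log(comb_w[root]),
       po = po)
}

#' Maximum-likelihood Brownian-motion fit
#'
#' Fits tip values as multivariate normal with mean `root * 1` and
#' covariance `sigma_sq * C`, where `C[i, j]` is the shared path length
#' from the root to tips i and j. Estimates are the GLS root state
#' `(1' C^-1 z) / (1' C^-1 1)` and the ML rate
#' `sigma_sq = (z - root)' C^-1 (z - root) / n`, computed by the
#' linear-time pruning recursion rather than by forming `C`.
#'
#' @param tree an `ape::phylo` tree (>= 2 tips; need not be
#'   ultrametric).
#' @param tip_values named numeric vector with a value for every tip.
#' @return An object of class `bm_fit`: list with `root_state`,
#'   `sigma_sq`, `log_likelihood`, `n_tips`.
#' @export
bm_mle <- function(tree, tip_values) {
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("need at least 2 tips")
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss))
    stop("missing tip value(s): ", paste(miss, collapse = ", "))
  x <- as.numeric(tip_values[tree$tip.label])
  if (anyNA(x)) stop("tip values must be finite")
  up <- .bm_upward(tree, x)
  n <- ntip
  sigma_sq <- up$Q / n
  ll <- if (sigma_sq > 0)
    -n / 2 * log(2 * pi * sigma_sq) - up$logdet / 2 - n / 2
  else Inf
  structure(list(root_state = up$comb_m[up$root], sigma_sq = sigma_sq,
                 log_likelihood = ll, n_tips = n),
            class = "bm_fit")
}

#' @export
#' @method print bm_fit
print.bm_fit <- function(x, ...) {
  cat(sprintf("BM fit (%d tips): root %.6g, sigma^2 %.6g, logLik %.6g\n",
              x$n_tips, x$root_state, x$sigma_sq, x$log_likelihood))
  invisible(x)
}

# precision-weighted combination of normal messages (m_i, w_i);
# a zero-variance message pins the estimate, infinite-variance messages
# carry no information.
.combine_msgs <- function(ms, ws) {
  pin <- which(ws <= 0)
  if (length(pin)) return(c(ms[pin[1]], 0))
  fin <- which(is.finite(ws))
  if (!length(fin)) return(c(NA_real_, Inf))
  wt <- 1 / ws[fin]
  s <- sum(wt)
  c(sum(ms[fin] * wt) / s, 1 / s)
}

#' ML ancestral states under Brownian motion
#'
#' Each internal node's state is the GLS estimate conditional on all tip
#' values under the fitted BM model - equivalently the root estimate of
#' the tree re-rooted at that node. Implemented as a two-pass
#' message-passing scheme (one postorder pass collecting subtree
#' information, one preorder pass propagating the information from the
#' rest of the tree), so the whole set of states costs linear time.
#'
#' @inheritParams bm_mle
#' @return Named numeric vector of states for internal nodes (names are
#'   ape node numbers, root first).
#' @export
ancestral_states <- function(tree, tip_values) {
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("need at least 2 tips")
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss))
    stop("missing tip value(s): ", paste(miss, collapse = ", "))
  x <- as.numeric(tip_values[tree$tip.label])
  up <- .bm_upward(tree, x)
  po <- up$po
  nnode <- ntip + tree$Nnode
  kids <- split(po$edge[, 2], po$edge[, 1])
  elen <- stats::setNames(po$edge.length, po$edge[, 2])
  down_m <- rep(NA_real_, nnode)
  down_w <- rep(Inf, nnode)
  # preorder: edges of the postorder ordering, reversed
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sibs <- setdiff(kids[[as.character(par)]], ch)
    cm <- .combine_msgs(c(up$msg_m[sibs], down_m[par]),
                        c(up$msg_w[sibs], down_w[par]))
    down_m[ch] <- cm[1]
    down_w[ch] <- cm[2] + po$edge.length[e]
  }
  internal <- (ntip + 1L):nnode
  states <- vapply(internal, function(k) {
    .combine_msgs(c(up$comb_m[k], down_m[k]),
                  c(up$comb_w[k], down_w[k]))[1]
  }, numeric(1))
  names(states) <- as.character(internal)
  states
}

#' Reconstruct the evolution of climatic tolerance along a chronogram
#'
#' The ancestral niche-occupancy procedure: each tip's PNO profile is
#' resampled (`n_samples` draws of one climate value per tip), ML
#' ancestral states are computed for every draw, and each internal
#' node's tolerance is reported as the across-sample mean, with the
#' across-sample SD and equal-tail interval as spread. The BM rate is
#' re-estimated within every replicate. Tips are summarised from the
#' PNO itself: the suitability-weighted mean and the `central_mass`
#' central density interval. Node ages come from [node_ages()], so the
#' tree must be ultrametric.
#'
#' @param tree pruned ultrametric `ape::phylo` tree (one tip per
#'   species).
#' @param tip_pnos named list of [pno_profile]s, one per tip, sharing
#'   variable and bin edges.
#' @param n_samples PNO resampling replicates (default 100).
#' @param central_mass central density mass for tip intervals (default
#'   0.80).
#' @param seed RNG seed.
#' @return An object of class `ancestral_tolerance`: data frame with
#'   columns `node_id`, `node_type`, `age_ma`, `variable`, `mean`, `sd`,
#'   `lower`, `upper`; attributes `variable` and `n_samples`.
#' @export
reconstruct_tolerance_evolution <- function(tree, tip_pnos,
                                            n_samples = 100,
                                            central_mass = 0.8, seed = 1) {
  tips <- tree$tip.label
  miss <- setdiff(tips, names(tip_pnos))
  if (length(miss))
    stop("missing PNO for tip(s): ", paste(miss, collapse = ", "))
  tip_pnos <- tip_pnos[tips]
  ref <- tip_pnos[[1]]
  for (p in tip_pnos) .check_same_edges(ref, p)
  ages <- node_ages(tree)
  ntip <- length(tips)
  internal_ids <- .internal_ids(tree)
  set.seed(seed)
  draws <- matrix(NA_real_, n_samples, tree$Nnode)
  for (s in seq_len(n_samples)) {
    tv <- vapply(tip_pnos, function(p) sample_from_pno(p, 1), numeric(1))
    names(tv) <- tips
    draws[s, ] <- ancestral_states(tree, tv)
  }
  half <- (1 - central_mass) / 2
  node_mean <- colMeans(draws)
  node_sd <- apply(draws, 2, stats::sd)
  node_lo <- apply(draws, 2, stats::quantile, probs = half)
  node_hi <- apply(draws, 2, stats::quantile, probs = 1 - half)
  tip_mean <- vapply(tip_pnos, pno_weighted_mean, numeric(1))
  tip_ci <- vapply(tip_pnos, pno_central_density, numeric(2),
                   mass = central_mass)
  out <- rbind(
    data.frame(node_id = tips, node_type = "tip",
               age_ma = unname(ages[tips]), variable = ref$variable,
               mean = unname(tip_mean), sd = NA_real_,
               lower = unname(tip_ci[1, ]), upper = unname(tip_ci[2, ])),
    data.frame(node_id = internal_ids, node_type = "internal",
               age_ma = unname(ages[ntip + seq_len(tree$Nnode)]),
               variable = ref$variable, mean = node_mean, sd = node_sd,
               lower = unname(node_lo), upper = unname(node_hi)))
  rownames(out) <- NULL
  structure(out, variable = ref$variable, n_samples = n_samples,
            class = c("ancestral_tolerance", "data.frame"))
}
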