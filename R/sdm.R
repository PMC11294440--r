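#' @title Species distribution models: fitting
#' @description
#' Four model families are supported, mirroring the common consensus
#' (ensemble) modelling setup for presence/pseudo-absence data:
#' \describe{
#'   \item{GLM}{logistic regression on linear + quadratic terms;}
#'   \item{GAM}{binomial additive model with per-variable cubic
#'     regression spline bases (about 4 effective df each);}
#'   \item{GBM}{gradient-boosted classification trees (100 trees,
#'     depth 3, learning rate 0.1);}
#'   \item{MAXENT_S}{an L1-regularised logistic surrogate of MaxEnt on
#'     linear + quadratic + pairwise-product features (the exact
#'     Phillips-style feature classes and regularisation path are out of
#'     scope).}
#' }
#' Covariates are standardised internally; centre and scale are stored
#' in the model and re-applied at prediction time, so predictions bind
#' to variables by name and are invariant to column order.
#'
#' @param kind one of `"GLM"`, `"GAM"`, `"GBM"`, `"MAXENT_S"`.
#' @param table data frame with a 0/1 `label` column and one numeric
#'   column per covariate (columns `lon`, `lat`, `species` are ignored).
#' @param config a [pipeline_config()] (reserved for future knobs).
#' @param seed RNG seed (boosting and regularisation-path folds).
#' @return An object of class `sdm_model`.
#' @export
fit_sdm <- function(kind, table, config = pipeline_config(), seed = 1) {
  kind <- match.arg(kind, c("GLM", "GAM", "GBM", "MAXENT_S"))
  vars <- .sdm_vars(table)
  if (length(vars) == 0L) stop("no covariate columns in table")
  y <- table$label
  if (length(unique(y)) < 2L)
    stop("degenerate-label error: both classes must be present")
  X <- as.matrix(table[, vars, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- scale(X, ctr, scl)
  set.seed(derive_seed(seed, paste0("fit_", kind)))
  fallback <- NULL
  fit <- switch(kind,
    GLM = {
      if (nrow(Z) < 2L * length(vars) + 1L) {
        fallback <- "ridge_poly"
        warning("rank-deficiency: fewer rows than features; ridge fallback")
        .fit_ridge(.poly_features(Z), y)
      } else {
        df <- as.data.frame(Z); df$label <- y
        form <- stats::as.formula(paste(
          "label ~", paste(sprintf("%s + I(%s^2)", vars, vars),
                           collapse = " + ")))
        f <- .quiet_glm(stats::glm(form, family = stats::binomial(),
                                   data = df))
        co <- stats::coef(f)[-1]
        if (!f$converged || any(abs(co[is.finite(co)]) > 15)) {
          # complete/quasi-separation: the ML logistic estimate diverges
          # and saturates held-out scores at 0/1, so refit with a light
          # ridge penalty on the same quadratic features
          fallback <- "ridge_poly"
          .fit_ridge(.poly_features(Z), y)
        } else f
      }
    },
    GAM = {
      ks <- vapply(vars, function(v) {
        min(5L, length(unique(Z[, v])))
      }, integer(1))
      p <- sum(pmax(ks - 1L, 1L)) + 1L
      if (nrow(Z) < p + 1L) {
        fallback <- "ridge_spline"
        warning("rank-deficiency: fewer rows than features; ridge fallback")
        .fit_ridge_spline(Z, y)
      } else {
        df <- as.data.frame(Z); df$label <- y
        terms <- ifelse(ks >= 3L,
                        sprintf("s(%s, k = %d, bs = \"cr\")", vars, ks),
                        vars)
        form <- stats::as.formula(
          paste("label ~", paste(terms, collapse = " + ")))
        f <- .quiet_glm(mgcv::gam(form, family = stats::binomial(),
                                  data = df, method = "REML"))
        eta <- as.numeric(mgcv::predict.gam(f, type = "link"))
        if (max(abs(eta)) > 30) {
          # separation again: REML leaves the spline null space
          # unpenalised, so shrink an additive natural-spline basis
          fallback <- "ridge_spline"
          .fit_ridge_spline(Z, y)
        } else f
      }
    },
    GBM = {
      dtrain <- xgboost::xgb.DMatrix(Z, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.1, nthread = 1,
                      seed = derive_seed(seed, "xgb")),
        data = dtrain, nrounds = 100, verbose = 0)
    },
    MAXENT_S = {
      Fe <- .maxent_features(Z)
      if (nrow(Fe) >= 10L) {
        foldid <- sample(rep_len(1:5, nrow(Fe)))
        cv <- glmnet::cv.glmnet(Fe, y, family = "binomial", alpha = 1,
                                foldid = foldid, standardize = FALSE)
        list(fit = cv, s = "lambda.min")
      } else {
        list(fit = glmnet::glmnet(Fe, y, family = "binomial", alpha = 1,
                                  standardize = FALSE),
             s = 0.01)
      }
    })
  structure(
    list(kind = kind, variables = vars, center = ctr, scale = scl,
         fit = fit, fallback = fallback,
         meta = list(n_presence = sum(y == 1), n_absence = sum(y == 0),
                     seed = seed)),
    class = "sdm_model")
}

.sdm_vars <- function(table) {
  setdiff(names(table), c("lon", "lat", "label", "species"))
}

# expanded feature matrices on the standardised scale
.poly_features <- function(Z) {
  cbind(Z, `colnames<-`(Z^2, paste0(colnames(Z), "_sq")))
}

.maxent_features <- function(Z) {
  out <- .poly_features(Z)
  v <- colnames(Z)
  if (length(v) >= 2L) {
    for (i in seq_len(length(v) - 1L)) for (j in (i + 1L):length(v)) {
      out <- cbind(out, Z[, i] * Z[, j])
      colnames(out)[ncol(out)] <- paste0(v[i], "_x_", v[j])
    }
  }
  out
}

.fit_ridge <- function(Fe, y, basis = NULL) {
  list(ridge = glmnet::glmnet(Fe, y, family = "binomial", alpha = 0,
                              standardize = FALSE),
       s = 0.01, basis = basis)
}

# additive natural-cubic-spline basis (4 df per variable) with stored
# knots, so the ridge fallback keeps the GAM's additive character
.spline_basis <- function(Z) {
  lapply(stats::setNames(colnames(Z), colnames(Z)), function(v) {
    df <- min(4L, max(1L, length(unique(Z[, v])) - 1L))
    splines::ns(Z[, v], df = df)
  })
}

.spline_features <- function(basis, Z) {
  do.call(cbind, lapply(names(basis), function(v)
    stats::predict(basis[[v]], Z[, v])))
}

.fit_ridge_spline <- function(Z, y) {
  basis <- .spline_basis(Z)
  .fit_ridge(.spline_features(basis, Z), y, basis = basis)
}

# muffle the benign separation warnings glm emits on cleanly separable
# synthetic data
.quiet_glm <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl(paste0("fitted probabilities numerically 0 or 1|",
                     "algorithm did not converge|",
                     "Fitting terminated with step failure|",
                     "Iteration limit reached without full convergence|",
                     "prediction from rank-deficient fit"),
              conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Predict suitability scores for new points
#'
#' @param object an `sdm_model`.
#' @param newdata data frame or matrix containing the model's covariate
#'   columns (matched by name).
#' @param ... unused.
#' @return Numeric vector of suitabilities in `[0, 1]`.
#' @export
predict.sdm_model <- function(object, newdata, ...) {
  miss <- setdiff(object$variables, colnames(newdata))
  if (length(miss))
    stop("schema error: missing variable(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[, object$variables, drop = FALSE])
  Z <- scale(X, object$center, object$scale)
  p <- if (!is.null(object$fallback)) {
    fe <- switch(object$fallback,
                 ridge_spline = .spline_features(object$fit$basis, Z),
                 ridge_poly = .poly_features(Z),
                 .maxent_features(Z))
    as.numeric(stats::predict(object$fit$ridge, newx = fe,
                              s = object$fit$s, type = "response"))
  } else switch(object$kind,
    GLM = {
      df <- as.data.frame(Z)
      .quiet_glm(as.numeric(stats::predict(object$fit, newdata = df,
                                           type = "response")))
    },
    GAM = {
      df <- as.data.frame(Z)
      as.numeric(mgcv::predict.gam(object$fit, newdata = df,
                                   type = "response"))
    },
    GBM = {
      dm <- xgboost::xgb.DMatrix(Z, nthread = 1)
      as.numeric(stats::predict(object$fit, dm))
    },
    MAXENT_S = {
      as.numeric(stats::predict(object$fit$fit, newx = .maxent_features(Z),
                                s = object$fit$s, type = "response"))
    })
  pmin(1, pmax(0, p))
}

#' Predict a suitability map over a climate stack
#'
#' @param model an `sdm_model`.
#' @param stack a [climate_stack] containing the model's variables.
#' @return A [suitability_map] masked where the stack is masked.
#' @export
predict_suitability <- function(model, stack) {
  miss <- setdiff(model$variables, names(stack$layers))
  if (length(miss))
    stop("schema error: stack lacks variable(s): ",
         paste(miss, collapse = ", "))
  ok <- !stack$mask
  newdata <- vapply(stack$layers[model$variables], function(L) L[ok],
                    numeric(sum(ok)))
  newdata <- matrix(newdata, ncol = length(model$variables),
                    dimnames = list(NULL, model$variables))
  vals <- matrix(NA_real_, stack$n_rows, stack$n_cols)
  vals[ok] <- predict(model, newdata)
  suitability_map(vals, stack)
}

# ---- evaluation metrics -----------------------------------------------------

#' Rank-based AUC (Mann-Whitney, midrank ties)
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`: the probability that a random presence
#'   outscores a random absence (ties count one half).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("undefined-AUC error: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a threshold
#'
#' Points with `score >= threshold` are predicted present. TSS is
#' sensitivity + specificity - 1; kappa is the chance-corrected
#' agreement with the standard marginal expectation.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @param threshold decision threshold.
#' @return list with `sensitivity`, `specificity`, `tss`, `kappa`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fn <- n1 - tp
  fp <- sum(pred & labels == 0); tn <- n0 - fp
  n <- n1 + n0
  sens <- tp / n1
  spec <- tn / n0
  po <- (tp + tn) / n
  pe <- ((tp + fp) * n1 + (fn + tn) * n0) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  list(sensitivity = sens, specificity = spec,
       tss = sens + spec - 1, kappa = kappa)
}

#' Threshold maximising the true skill statistic
#'
#' Candidate thresholds are the midpoints between consecutive sorted
#' unique scores, plus 0 and 1. Ties in TSS return the smallest
#' candidate threshold.
#'
#' @inheritParams confusion_metrics
#' @return list with `threshold` and `metrics` (see
#'   [confusion_metrics()]).
#' @export
max_tss_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, if (length(u) > 1L)
    (u[-1] + u[-length(u)]) / 2, 1)))
  tss <- vapply(cand, function(th)
    confusion_metrics(scores, labels, th)$tss, numeric(1))
  best <- max(tss)
  th <- cand[which(tss >= best - 1e-12)[1]]
  list(threshold = th, metrics = confusion_metrics(scores, labels, th))
}

#' Cross-validated evaluation of one model family
#'
#' Repeats stratified random splits (`eval_split_fraction` of each class
#' to training), fits on the training side, scores the held-out side,
#' and reports AUC plus kappa and TSS at the max-TSS threshold of the
#' held-out scores. Top-level values are means across repeats.
#'
#' @inheritParams fit_sdm
#' @return An object of class `sdm_evaluation`: list with `auc`, `kappa`,
#'   `tss`, `threshold` and a `per_repeat` data frame.
#' @export
evaluate_sdm <- function(kind, table, config = pipeline_config(), seed = 1) {
  y <- table$label
  i1 <- which(y == 1); i0 <- which(y == 0)
  if (length(i1) < 2L || length(i0) < 2L)
    stop("table cannot be split with both classes on each side")
  frac <- config$eval_split_fraction
  reps <- config$eval_repeats
  per <- vector("list", reps)
  for (r in seq_len(reps)) {
    rseed <- derive_seed(seed, paste0("eval_", kind, "_", r))
    for (attempt in 1:10) {
      set.seed(rseed + attempt - 1L)
      n1t <- min(max(1L, round(frac * length(i1))), length(i1) - 1L)
      n0t <- min(max(1L, round(frac * length(i0))), length(i0) - 1L)
      tr <- c(sample(i1, n1t), sample(i0, n0t))
      te <- setdiff(seq_along(y), tr)
      if (length(unique(y[tr])) == 2L && length(unique(y[te])) == 2L) break
      if (attempt == 10) stop("could not split with both classes each side")
    }
    model <- fit_sdm(kind, table[tr, , drop = FALSE], config, rseed)
    sc <- predict(model, table[te, , drop = FALSE])
    auc <- roc_auc(sc, y[te])
    mt <- max_tss_threshold(sc, y[te])
    per[[r]] <- data.frame(repeat_id = r, auc = auc,
                           kappa = mt$metrics$kappa, tss = mt$metrics$tss,
                           threshold = mt$threshold)
  }
  per <- do.call(rbind, per)
  structure(list(auc = mean(per$auc), kappa = mean(per$kappa),
                 tss = mean(per$tss), threshold = mean(per$threshold),
                 per_repeat = per, kind = kind),
            class = "sdm_evaluation")
}

#' @export
#' @method print sdm_evaluation
print.sdm_evaluation <- function(x, ...) {
  cat(sprintf("%s evaluation over %d repeats: AUC %.3f, KAPPA %.3f, TSS %.3f\n",
              x$kind, nrow(x$per_repeat), x$auc, x$kappa, x$tss))
  invisible(x)
}

#' Permutation-based variable contributions
#'
#' Fits the model on the full table, then for each variable permutes
#' that column `n_perm` times and records the mean drop in training AUC.
#' Negative importances are clipped to zero and the vector is rescaled
#' to sum to 100 (%). If every importance is zero a uniform vector is
#' returned with a warning.
#'
#' @inheritParams fit_sdm
#' @param n_perm permutations per variable (default 10).
#' @return Named numeric vector of percentages summing to 100.
#' @export
variable_contributions <- function(kind, table, config = pipeline_config(),
                                   seed = 1, n_perm = 10) {
  model <- fit_sdm(kind, table, config, seed)
  vars <- model$variables
  base <- roc_auc(predict(model, table), table$label)
  imp <- vapply(vars, function(v) {
    drops <- vapply(seq_len(n_perm), function(j) {
      set.seed(derive_seed(seed, paste("perm", kind, v, j, sep = "_")))
      tab <- table
      tab[[v]] <- sample(tab[[v]])
      base - roc_auc(predict(model, tab), tab$label)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  imp[imp < 0] <- 0
  if (sum(imp) == 0) {
    warning("all permutation importances are zero; uniform contributions")
    imp[] <- 1
  }
  100 * imp / sum(imp)
}

#' Consensus (ensemble) suitability map
#'
#' Cell-wise weighted mean of member suitability maps, weights
#' proportional to member TSS, restricted to members with
#' `TSS >= tss_cutoff`.
#'
#' @param members list of members; each member is a list with `tss` and
#'   either `model` (an `sdm_model`) or `map` (a precomputed
#'   [suitability_map]).
#' @param stack the [climate_stack] to predict over.
#' @param tss_cutoff minimum TSS for inclusion (default 0.7).
#' @return A [suitability_map].
#' @export
ensemble_predict <- function(members, stack, tss_cutoff = 0.7) {
  tss <- vapply(members, function(m) m$tss, numeric(1))
  keep <- which(tss >= tss_cutoff)
  if (length(keep) == 0L)
    stop("ensemble-empty error: no member passes TSS cutoff ", tss_cutoff,
         " (member TSS: ", paste(sprintf("%.3f", tss), collapse = ", "), ")")
  maps <- lapply(members[keep], function(m) {
    if (!is.null(m$map)) m$map else predict_suitability(m$model, stack)
  })
  w <- tss[keep] / sum(tss[keep])
  vals <- Reduce(`+`, Map(function(m, wi) m$values * wi, maps, w))
  suitability_map(vals, stack)
}
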