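#' Pipeline configuration
#'
#' Collects every fixed scalar of the analysis in one validated object:
#' the 1-km thinning radius, the 0.75 correlation threshold, the 100
#' PNO bins and the 80% central density mass, plus the scalars the
#' protocol leaves open (split design, ensemble TSS cutoff, resampling
#' counts), all overridable.
#'
#' @param thin_radius_km spatial thinning radius, km (default 1).
#' @param corr_threshold absolute Pearson r above which predictors are
#'   pruned (default 0.75).
#' @param n_bins PNO bins (default 100).
#' @param central_mass tip central-density mass (default 0.80).
#' @param n_pno_samples PNO resampling replicates for ancestral
#'   reconstruction (default 100).
#' @param tss_cutoff minimum member TSS for the ensemble (default 0.7).
#' @param eval_split_fraction training share of evaluation splits
#'   (default 0.7).
#' @param eval_repeats evaluation split repeats (default 5).
#' @param n_restarts thinning restarts (default 10).
#' @param random_seed base seed; every stage derives its own stream.
#' @param earth_radius_km sphere radius for distances (default 6371).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(thin_radius_km = 1, corr_threshold = 0.75,
                            n_bins = 100, central_mass = 0.8,
                            n_pno_samples = 100, tss_cutoff = 0.7,
                            eval_split_fraction = 0.7, eval_repeats = 5,
                            n_restarts = 10, random_seed = 1,
                            earth_radius_km = 6371) {
  stopifnot(thin_radius_km > 0, corr_threshold > 0, corr_threshold <= 1,
            n_bins >= 2, central_mass > 0, central_mass < 1,
            n_pno_samples >= 1, tss_cutoff >= -1, tss_cutoff <= 1,
            eval_split_fraction > 0, eval_split_fraction < 1,
            eval_repeats >= 1, n_restarts >= 1, earth_radius_km > 0)
  structure(list(thin_radius_km = thin_radius_km,
                 corr_threshold = corr_threshold, n_bins = n_bins,
                 central_mass = central_mass,
                 n_pno_samples = n_pno_samples, tss_cutoff = tss_cutoff,
                 eval_split_fraction = eval_split_fraction,
                 eval_repeats = eval_repeats, n_restarts = n_restarts,
                 random_seed = random_seed,
                 earth_radius_km = earth_radius_km),
            class = "pipeline_config")
}

.pipeline_stages <- c("thin", "pseudo_absence", "extract",
                      "prune_variables", "fit_evaluate", "ensemble", "pno",
                      "overlap", "prune_tree", "ancestral_reconstruction")

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full niche-evolution pipeline
#'
#' Executes, in fixed order: spatial thinning, pseudo-absence sampling,
#' covariate extraction, correlation pruning, fitting and evaluation of
#' the four model families per species, the TSS-weighted consensus map,
#' PNO profiles per retained variable, niche-overlap matrices, tree
#' pruning to one tip per species, and PNO-resampled ancestral
#' tolerance reconstruction. All tabular outputs are TSV; maps are ESRI
#' ASCII; the run manifest is JSON. Given the same config and seed the
#' numeric outputs are reproduced exactly.
#'
#' @param config path to a YAML/JSON config file, or an equivalent
#'   list. Required fields: `occurrences` (CSV path), `rasters` (list
#'   with `paths` and `names`), `tree` (Newick path), `outdir`.
#'   Optional: `seed`, `keep` (named list species -> tip label; default
#'   maps each species to the identically named tip), plus any
#'   [pipeline_config()] scalar under `params`.
#' @return (Invisibly) an object of class `ancniche_run`: list with
#'   `manifest` and the in-memory stage `results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config)
              else yaml::read_yaml(config)
  }
  need <- c("occurrences", "rasters", "tree", "outdir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config validation error: missing field(s): ",
         paste(miss, collapse = ", "))
  raster_paths <- unlist(config$rasters$paths)
  for (f in c(config$occurrences, raster_paths, config$tree))
    if (!file.exists(f))
      stop("config validation error: input file not found: ", f)
  params <- do.call(pipeline_config,
                    c(config$params %||% list(),
                      list(random_seed = config$seed %||% 1)))
  seed <- params$random_seed
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  occ <- read_occurrences(config$occurrences)
  stack <- read_climate_stack(raster_paths, unlist(config$rasters$names))
  tree <- read_newick(file = config$tree)
  species <- sort(unique(occ$species))

  manifest <- list(package = "ancniche",
                   version = as.character(utils::packageVersion("ancniche")),
                   seed = seed,
                   config = list(occurrences = config$occurrences,
                                 rasters = as.list(raster_paths),
                                 tree = config$tree, outdir = outdir,
                                 params = unclass(params)),
                   stages = list())
  results <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e) {
      manifest$stages[[name]] <<- list(name = name, status = "failed",
                                       error = conditionMessage(e))
      .write_manifest(manifest, outdir)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(
      list(name = name, status = "complete",
           elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)),
      attr(val, "stage_meta") %||% list())
    attr(val, "stage_meta") <- NULL
    val
  }
  meta <- function(val, ...) { attr(val, "stage_meta") <- list(...); val }

  results$thinned <- stage("thin", {
    thinned <- thin_occurrences(occ, params$thin_radius_km,
                                params$n_restarts,
                                derive_seed(seed, "thin"),
                                earth_radius_km = params$earth_radius_km)
    rep_df <- data.frame(
      species = species,
      n_input = vapply(species, function(s) sum(occ$species == s), 0L),
      n_retained = vapply(species, function(s) sum(thinned$species == s), 0L))
    p1 <- .write_tsv(rep_df, file.path(outdir, "thinning_report.tsv"))
    p2 <- file.path(outdir, "thinned_occurrences.csv")
    utils::write.csv(thinned, p2, row.names = FALSE, quote = FALSE)
    meta(thinned, outputs = c(p1, p2), n_retained = nrow(thinned))
  })

  results$absences <- stage("pseudo_absence", {
    ab <- lapply(species, function(sp) {
      pres <- results$thinned[results$thinned$species == sp, , drop = FALSE]
      sample_pseudo_absences(stack, pres,
                             seed = derive_seed(seed, paste0("pa_", sp)))
    })
    names(ab) <- species
    meta(ab, n_per_species = vapply(ab, nrow, 0L))
  })

  results$tables <- stage("extract", {
    tabs <- lapply(species, function(sp) {
      pres <- results$thinned[results$thinned$species == sp,
                              c("lon", "lat"), drop = FALSE]
      abs <- results$absences[[sp]]
      pts <- rbind(pres, abs)
      extract_covariates(pts, stack, c(rep(1, nrow(pres)),
                                       rep(0, nrow(abs))))
    })
    names(tabs) <- species
    meta(tabs, n_rows = vapply(tabs, nrow, 0L))
  })

  results$retained_vars <- stage("prune_variables", {
    keep <- prune_correlated_variables(stack, params$corr_threshold)
    p <- file.path(outdir, "retained_variables.txt")
    writeLines(keep, p)
    meta(keep, outputs = p, n_retained = length(keep))
  })
  vars <- results$retained_vars
  tables <- lapply(results$tables, function(tb)
    tb[, c("lon", "lat", "label", vars), drop = FALSE])

  results$models <- stage("fit_evaluate", {
    kinds <- c("GLM", "GAM", "GBM", "MAXENT_S")
    per_sp <- lapply(species, function(sp) {
      lapply(stats::setNames(kinds, kinds), function(k) {
        s <- derive_seed(seed, paste("sdm", sp, k, sep = "_"))
        list(model = fit_sdm(k, tables[[sp]], params, s),
             evaluation = evaluate_sdm(k, tables[[sp]], params, s),
             contributions = variable_contributions(k, tables[[sp]],
                                                    params, s))
      })
    })
    names(per_sp) <- species
    eval_df <- do.call(rbind, lapply(species, function(sp)
      do.call(rbind, lapply(kinds, function(k) {
        e <- per_sp[[sp]][[k]]$evaluation
        data.frame(species = sp, model = k, AUC = e$auc, KAPPA = e$kappa,
                   TSS = e$tss)
      }))))
    contrib_df <- do.call(rbind, lapply(species, function(sp) {
      cm <- rowMeans(vapply(kinds, function(k)
        per_sp[[sp]][[k]]$contributions, numeric(length(vars))))
      cm <- 100 * cm / sum(cm)
      out <- data.frame(species = sp)
      for (v in vars) out[[v]] <- cm[[v]]
      out
    }))
    p1 <- .write_tsv(eval_df, file.path(outdir, "evaluation.tsv"))
    p2 <- .write_tsv(contrib_df, file.path(outdir, "contributions.tsv"))
    meta(list(per_species = per_sp, evaluation = eval_df,
              contributions = contrib_df),
         outputs = c(p1, p2), n_models = length(species) * length(kinds))
  })

  results$ensembles <- stage("ensemble", {
    ens <- lapply(species, function(sp) {
      members <- lapply(results$models$per_species[[sp]], function(m)
        list(model = m$model, tss = m$evaluation$tss))
      ensemble_predict(members, stack, params$tss_cutoff)
    })
    names(ens) <- species
    paths <- vapply(species, function(sp) {
      p <- file.path(outdir, paste0("ensemble_", sp, ".asc"))
      write_esri_ascii(ens[[sp]], p)
    }, character(1))
    meta(ens, outputs = unname(paths))
  })

  results$pnos <- stage("pno", {
    pn <- lapply(species, function(sp) {
      lapply(stats::setNames(vars, vars), function(v)
        compute_pno(results$ensembles[[sp]], stack, v, params$n_bins))
    })
    names(pn) <- species
    paths <- character(0)
    for (sp in species) for (v in vars) {
      p <- file.path(outdir, paste0("pno_", sp, "_", v, ".tsv"))
      write_pno(pn[[sp]][[v]], p)
      paths <- c(paths, p)
    }
    meta(pn, outputs = paths, n_profiles = length(species) * length(vars))
  })

  results$overlap <- stage("overlap", {
    ov <- lapply(stats::setNames(vars, vars), function(v)
      niche_overlap(lapply(results$pnos, `[[`, v)))
    paths <- character(0)
    for (v in vars) {
      pD <- file.path(outdir, paste0("overlap_D_", v, ".tsv"))
      pI <- file.path(outdir, paste0("overlap_I_", v, ".tsv"))
      utils::write.table(ov[[v]]$D, pD, sep = "\t", quote = FALSE)
      utils::write.table(ov[[v]]$I, pI, sep = "\t", quote = FALSE)
      paths <- c(paths, pD, pI)
    }
    meta(ov, outputs = paths)
  })

  results$pruned_tree <- stage("prune_tree", {
    keep <- if (!is.null(config$keep)) unlist(config$keep)
            else stats::setNames(intersect(tree$tip.label, species),
                                 intersect(tree$tip.label, species))
    if (length(keep) < 2L)
      stop("fewer than 2 species match tree tips")
    ptree <- prune_to_one_tip_per_species(tree, keep, relabel = TRUE)
    p1 <- file.path(outdir, "pruned_tree.nwk")
    write_newick(ptree, p1)
    ages <- node_ages(ptree)
    ages_df <- data.frame(node_id = names(ages),
                          node_type = rep(c("tip", "internal"),
                                          c(length(ptree$tip.label),
                                            ptree$Nnode)),
                          age_ma = unname(ages))
    p2 <- .write_tsv(ages_df, file.path(outdir, "node_ages.tsv"))
    meta(list(tree = ptree, ages = ages_df), outputs = c(p1, p2))
  })

  results$tolerance <- stage("ancestral_reconstruction", {
    ptree <- results$pruned_tree$tree
    tol <- do.call(rbind, lapply(vars, function(v) {
      pnos <- lapply(results$pnos[ptree$tip.label], `[[`, v)
      as.data.frame(reconstruct_tolerance_evolution(
        ptree, pnos, params$n_pno_samples, params$central_mass,
        derive_seed(seed, paste0("anc_", v))))
    }))
    p <- .write_tsv(tol, file.path(outdir, "tolerance.tsv"))
    meta(tol, outputs = p, n_rows = nrow(tol))
  })

  .write_manifest(manifest, outdir)
  invisible(structure(list(manifest = manifest, results = results,
                           outdir = outdir, species = species,
                           variables = vars, params = params),
                      class = "ancniche_run"))
}

.write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @export
#' @method print ancniche_run
print.ancniche_run <- function(x, ...) {
  done <- vapply(x$manifest$stages, function(s) s$status, character(1))
  cat(sprintf("ancniche run: %d/%d stages complete, outputs in %s\n",
              sum(done == "complete"), length(.pipeline_stages), x$outdir))
  invisible(x)
}

#' Write the summary report tables of a pipeline run
#'
#' Produces the familiar report shapes: the per-species-by-model
#' evaluation table (AUC/KAPPA/TSS), the variable-contribution table
#' (one % column per retained predictor), the node-age table of the
#' pruned chronogram, the tolerance-evolution table (one row per node
#' and variable), and optionally one tolerance-through-time line plot
#' per variable (PDF).
#'
#' @param run an `ancniche_run` from [run_pipeline()].
#' @param outdir output directory (default: the run's own).
#' @param plot if `TRUE`, write `tolerance_<variable>.pdf` plots.
#' @return (Invisibly) character vector of written paths.
#' @export
make_reports <- function(run, outdir = NULL, plot = FALSE) {
  stopifnot(inherits(run, "ancniche_run"))
  done <- names(run$manifest$stages)[
    vapply(run$manifest$stages, function(s)
      identical(s$status, "complete"), TRUE)]
  missing_stages <- setdiff(.pipeline_stages, done)
  if (length(missing_stages))
    stop("report error: incomplete run, missing stage(s): ",
         paste(missing_stages, collapse = ", "))
  outdir <- outdir %||% run$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    .write_tsv(run$results$models$evaluation,
               file.path(outdir, "report_evaluation.tsv")),
    .write_tsv(run$results$models$contributions,
               file.path(outdir, "report_contributions.tsv")),
    .write_tsv(run$results$pruned_tree$ages,
               file.path(outdir, "report_node_ages.tsv")),
    .write_tsv(run$results$tolerance,
               file.path(outdir, "report_tolerance.tsv")))
  if (plot) {
    for (v in run$variables) {
      p <- file.path(outdir, paste0("tolerance_", v, ".pdf"))
      grDevices::pdf(p, width = 7, height = 5)
      tol <- run$results$tolerance
      tol <- tol[tol$variable == v, , drop = FALSE]
      plot(-tol$age_ma, tol$mean, pch = ifelse(tol$node_type == "tip",
                                               19, 1),
           xlab = "age (Ma, past to present)", ylab = v,
           main = paste("Climatic tolerance through time:", v))
      tips <- tol[tol$node_type == "tip", , drop = FALSE]
      graphics::segments(-tips$age_ma, tips$lower, -tips$age_ma,
                         tips$upper)
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
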