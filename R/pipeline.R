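# One-command orchestration: graphical-model fitting, imputation,
# synthetic-data simulation, IBS subset selection, and the Bayesian
# relative-survival fit, with per-stage seeds derived from one master
# seed so every stage is independently rerunnable.

GM_VARS_DEFAULT <- c("age_group", "stage", "her2", "adherence",
                     "followup", "exitus")

#' Serialize a fitted graphical model to JSON
#'
#' Stores edges, cliques, separators, levels, fitted joint
#' probabilities, log-likelihood, dimension and criterion, sufficient to
#' reconstruct the model with [read_graph_model()].
#'
#' @param model a `graph_model`.
#' @param path output path.
#' @export
write_graph_model <- function(model, path) {
  stopifnot(inherits(model, "graph_model"))
  obj <- list(vars = model$vars, levels = model$levels,
              edges = apply(model$edges, 1L, paste, collapse = "~"),
              cliques = model$cliques,
              loglik = model$loglik, z = model$z, n = model$n,
              k = model$k, criterion = model$criterion,
              p = as.numeric(model$p))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a graphical model written by [write_graph_model()]
#'
#' @param path path to the JSON file.
#' @return a `graph_model`.
#' @export
read_graph_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(obj$edges) == 0L) NULL else
    do.call(rbind, strsplit(unlist(obj$edges), "~", fixed = TRUE))
  levels <- lapply(obj$levels, as.character)
  jt <- junction_tree(obj$vars, normalize_edges(edges))
  p <- array(obj$p, dim = lengths(levels), dimnames = levels)
  structure(list(vars = obj$vars, levels = levels,
                 edges = normalize_edges(edges), cliques = jt$cliques,
                 separators = jt$separators, parents = jt$parents,
                 order = jt$order, p = p, loglik = obj$loglik,
                 z = obj$z, n = obj$n, k = obj$k %||% NA_real_,
                 criterion = obj$criterion %||% NA_character_),
            class = "graph_model")
}

#' Pipeline configuration
#'
#' Assembles and validates the settings for [run_pipeline()]. `cohort`
#' and `lifetable` may be file paths (canonical CSVs) or in-memory
#' objects.
#'
#' @param cohort cohort CSV path or data.frame.
#' @param lifetable life-table CSV path or `life_table`.
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing artifacts.
#' @param gm_vars variables of the graphical model.
#' @param synd_n synthetic records per model (default 1e6 at full scale;
#'   choose smaller for test runs).
#' @param t_star Brier integration horizon (default 10).
#' @param by stratification variables for subset selection.
#' @param n_draws,n_warmup,chains MCMC settings (see
#'   [fit_ar1_poisson()]).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, lifetable, out_dir = NULL,
                            gm_vars = GM_VARS_DEFAULT,
                            synd_n = 1000000L, t_star = 10L,
                            by = c("age_group", "stage"),
                            n_draws = 5000L, n_warmup = 5000L,
                            chains = 4L, seed = 1L) {
  if (is.character(cohort) && !file.exists(cohort))
    stop("cohort file not found: ", cohort)
  if (is.character(lifetable) && !file.exists(lifetable))
    stop("life-table file not found: ", lifetable)
  structure(list(cohort = cohort, lifetable = lifetable,
                 out_dir = out_dir, gm_vars = gm_vars,
                 synd_n = as.integer(synd_n), t_star = as.integer(t_star),
                 by = by, n_draws = as.integer(n_draws),
                 n_warmup = as.integer(n_warmup),
                 chains = as.integer(chains), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort/life-table intake; contingency table on
#' complete cases; backward stepwise fit of the four model-selection
#' criteria; per-model imputation of missing adherence and refit on the
#' completed data; junction-tree simulation of one synthetic dataset per
#' model; stratum-wise integrated-Brier-score selection and merge into
#' the combined synthetic cohort; hazard series and AR(1) Poisson fit on
#' the combined cohort; posterior survival indicators. Artifacts
#' (model JSONs, scores.csv, combined.csv, indicators.csv, manifest)
#' are written under `out_dir` when given. Reruns with the same config
#' are identical.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `models`, `synds`, `scores`,
#'   `combined`, `series`, `fit`, `indicators`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_fail <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage_fail("cohort_io",
    if (is.character(config$cohort)) read_cohort(config$cohort)
    else validate_cohort(config$cohort))
  lifetable <- stage_fail("cohort_io",
    if (is.character(config$lifetable)) read_lifetable(config$lifetable)
    else config$lifetable)

  complete <- cohort[!is.na(cohort$adherence), , drop = FALSE]
  message("pipeline: ", nrow(cohort), " records in, ",
          nrow(complete), " complete cases for model fitting")
  tab <- stage_fail("gm_fit", build_table(complete, config$gm_vars))
  models <- stage_fail("gm_fit", fit_four_models(tab))

  seeds <- list(impute = derive_seed(config$seed, 1L),
                simulate = derive_seed(config$seed, 2L),
                mcmc = derive_seed(config$seed, 3L))
  synds <- vector("list", length(models)); names(synds) <- names(models)
  refits <- synds
  for (i in seq_along(models)) {
    lbl <- names(models)[i]
    completed <- stage_fail("impute",
      impute_missing(cohort, models[[i]], target = "adherence",
                     seed = seeds$impute + i))
    refit_tab <- build_table(completed, config$gm_vars)
    refits[[lbl]] <- stage_fail("refit", {
      m <- fit_decomposable(refit_tab, models[[i]]$edges)
      m$criterion <- lbl; m$k <- models[[i]]$k; m
    })
    synds[[lbl]] <- stage_fail("simulate",
      simulate_syn(refits[[lbl]], config$synd_n,
                   seed = seeds$simulate + i, cohort = completed))
  }

  scores <- stage_fail("score",
    score_matrix(cohort, synds, t_star = config$t_star, by = config$by))
  combined <- stage_fail("merge",
    select_and_merge(scores, synds, by = config$by))
  series <- stage_fail("hazard_series",
    hazard_series(combined, lifetable, horizon = config$t_star))
  fit <- stage_fail("mcmc",
    fit_ar1_poisson(series, n_draws = config$n_draws,
                    n_warmup = config$n_warmup, chains = config$chains,
                    seed = seeds$mcmc))
  indicators <- stage_fail("indicators", survival_indicators(fit))

  manifest <- list(seed = config$seed, stage_seeds = seeds,
                   n_in = nrow(cohort), n_complete = nrow(complete),
                   synd_n = config$synd_n,
                   selection = as.list(scores$selection),
                   mcmc = list(chains = config$chains,
                               n_draws = config$n_draws,
                               n_warmup = config$n_warmup,
                               converged = fit$converged),
                   package_version =
                     as.character(utils::packageVersion("synsurv")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(config$out_dir, f)
    for (lbl in names(refits))
      write_graph_model(refits[[lbl]],
                        fp(paste0("model_", tolower(lbl), ".json")))
    utils::write.csv(cbind(stratum = rownames(scores$scores),
                           as.data.frame(scores$scores),
                           selected = colnames(scores$scores)[
                             scores$selection]),
                     fp("scores.csv"), row.names = FALSE)
    utils::write.csv(combined, fp("combined.csv"), row.names = FALSE)
    utils::write.csv(indicators$summary, fp("indicators.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, fp("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(models = models, refits = refits, synds = synds,
                 scores = scores, combined = combined, series = series,
                 fit = fit, indicators = indicators,
                 manifest = manifest))
}
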