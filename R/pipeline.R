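#' Declarative run configuration for the full pipeline
#'
#' @param seed master seed; stage seeds derive deterministically from it.
#' @param outdir output directory for artifacts, manifest and logs.
#' @param stages character vector of stages to run, in dependency order
#'   from `simulate`, `cohort`, `standardize`, `covariates`, `moran`,
#'   `fit_spatial`, `fit_st_main`, `fit_st_interaction`, `diagnose`.
#' @param years study calendar years.
#' @param n_rows,n_cols,irregularity lattice settings.
#' @param spatial_window number of final years pooled for the spatial
#'   model (default 5, mirroring a five-calendar-year analysis window).
#' @param truth_sigma2 named list of true generative variances.
#' @param truth_beta named true covariate coefficients (design scale).
#' @param model_form generative model form for the synthetic cube.
#' @param n_iterations,n_burnin,n_chains,thinning sampler settings for all
#'   fits.
#' @param hyperprior `"gamma"` or `"uniform"`.
#' @param interaction_type Knorr-Held type for the interaction fit.
#' @param n_permutations Moran pre-test permutations.
#' @param n_persons persons for the `cohort` stage record simulation.
#' @param mean_stratum_pop synthetic population scale.
#' @param log_level `"info"` or `"quiet"`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(seed, outdir,
                       stages = c("simulate", "standardize", "covariates",
                                  "moran", "fit_spatial", "fit_st_main",
                                  "fit_st_interaction", "diagnose"),
                       years = 2001:2018, n_rows = 12, n_cols = 8,
                       irregularity = 0.2, spatial_window = 5,
                       truth_sigma2 = list(u = 0.1, v = 0.01, gamma = 0.001,
                                           phi = 0.01, delta = 0.02),
                       truth_beta = c(indigenous = 0.07),
                       model_form = "st_interaction",
                       n_iterations = 2000, n_burnin = 1000, n_chains = 2,
                       thinning = 1, hyperprior = "gamma",
                       interaction_type = "IV",
                       n_permutations = 999, n_persons = 2000,
                       mean_stratum_pop = 300,
                       log_level = c("info", "quiet")) {
  if (missing(seed)) stop("run_config requires an explicit seed")
  if (missing(outdir)) stop("run_config requires an output directory")
  known <- c("simulate", "cohort", "standardize", "covariates", "moran",
             "fit_spatial", "fit_st_main", "fit_st_interaction", "diagnose")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stopifnot(n_iterations > n_burnin, spatial_window >= 1,
            spatial_window <= length(years))
  structure(list(seed = as.integer(seed), outdir = outdir,
                 stages = known[known %in% stages], years = years,
                 n_rows = n_rows, n_cols = n_cols,
                 irregularity = irregularity,
                 spatial_window = spatial_window,
                 truth_sigma2 = truth_sigma2, truth_beta = truth_beta,
                 model_form = model_form,
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains),
                 thinning = as.integer(thinning),
                 hyperprior = hyperprior,
                 interaction_type = interaction_type,
                 n_permutations = as.integer(n_permutations),
                 n_persons = as.integer(n_persons),
                 mean_stratum_pop = mean_stratum_pop,
                 log_level = match.arg(log_level)),
            class = "run_config")
}

#' Read and validate a run configuration from JSON
#' @param path JSON file whose keys are [run_config()] arguments; `seed`
#'   and `outdir` are required.
#' @param overrides named list of values overriding the file (flags beat
#'   config).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(overrides)) raw[[nm]] <- overrides[[nm]]
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$truth_sigma2)) raw$truth_sigma2 <- as.list(raw$truth_sigma2)
  if (!is.null(raw$truth_beta)) raw$truth_beta <- unlist(raw$truth_beta)
  do.call(run_config, raw)
}

#' Execute the configured analysis pipeline
#'
#' Runs the enabled stages in dependency order: synthetic-data generation,
#' optional person-level cohort construction, indirect standardization,
#' covariate assembly, the Moran's I pre-test on log standardized ratios,
#' the three model fits, and per-fit diagnostics. Every artifact is
#' written under `config$outdir` and recorded in an append-only manifest
#' with an md5 content hash; the configuration is echoed verbatim.
#' Re-running the same configuration reproduces identical hashes for all
#' deterministic artifacts.
#'
#' @param config a [run_config()].
#' @return data.frame manifest `(stage, artifact, md5, seconds, status)`,
#'   invisibly also written to `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (length(setdiff(config$stages, "simulate")) &&
      !"simulate" %in% config$stages) {
    stop("downstream stages require the 'simulate' stage in this run")
  }
  needs_std <- intersect(c("moran", "fit_spatial", "fit_st_main",
                           "fit_st_interaction"), config$stages)
  if (length(needs_std) && !"standardize" %in% config$stages) {
    stop("stage(s) ", paste(needs_std, collapse = ", "),
         " require the 'standardize' stage")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$log_level == "info") {
    message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), ...)
  }
  cfg_echo <- unclass(config)
  jsonlite::write_json(cfg_echo, file.path(config$outdir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest_path <- file.path(config$outdir, "manifest.tsv")
  manifest <- data.frame(stage = character(0), artifact = character(0),
                         md5 = character(0), seconds = numeric(0),
                         status = character(0))
  add <- function(stage, paths, secs, status = "ok") {
    rows <- data.frame(stage = stage, artifact = basename(paths),
                       md5 = unname(tools::md5sum(paths)),
                       seconds = round(secs, 2), status = status)
    manifest <<- rbind(manifest, rows)
    utils::write.table(rows, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !file.exists(manifest_path),
                       append = file.exists(manifest_path))
  }
  out <- function(...) file.path(config$outdir, ...)
  st <- function(stage) stage %in% config$stages

  env <- new.env(parent = emptyenv())
  run_stage <- function(stage, fn) {
    if (!st(stage)) return(invisible())
    say("stage ", stage)
    t0 <- proc.time()[["elapsed"]]
    paths <- tryCatch(fn(), error = function(e) {
      add(stage, character(0), proc.time()[["elapsed"]] - t0, "failed")
      stop("stage '", stage, "' failed: ", conditionMessage(e))
    })
    add(stage, paths, proc.time()[["elapsed"]] - t0)
  }

  run_stage("simulate", function() {
    env$bundle <- generate_bundle(
      seed = config$seed, n_rows = config$n_rows, n_cols = config$n_cols,
      irregularity = config$irregularity, years = config$years,
      truth = true_params(beta = config$truth_beta,
                          sigma2 = config$truth_sigma2,
                          seed = config$seed + 4L),
      model_form = config$model_form,
      mean_stratum_pop = config$mean_stratum_pop)
    p1 <- out("edges.tsv"); write_edge_list(env$bundle$graph, p1)
    p2 <- out("census.tsv")
    utils::write.table(env$bundle$census, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p3 <- out("cube.tsv"); write_prevalence_cube(env$bundle$cube, p3)
    tr <- env$bundle$truth
    p4 <- out("truth.tsv")
    tdf <- data.frame(
      parameter = c("beta0", paste0("beta_", names(tr$beta)),
                    paste0("sigma2_", names(tr$sigma2)), "seed"),
      value = c(tr$beta0, unname(tr$beta), unlist(tr$sigma2), tr$seed))
    utils::write.table(tdf, p4, sep = "\t", quote = FALSE, row.names = FALSE)
    c(p1, p2, p3, p4)
  })

  run_stage("cohort", function() {
    recs <- simulate_person_records(env$bundle$graph,
                                    n_persons = config$n_persons,
                                    years = config$years,
                                    seed = config$seed + 3L)
    statuses <- lapply(recs, apply_case_definition)
    env$cohort_cube <- build_prevalence_cube(
      statuses, recs, years = config$years,
      regions = env$bundle$graph$region_ids)
    p1 <- out("cohort_cube.tsv")
    write_prevalence_cube(env$cohort_cube, p1)
    p2 <- out("crude_prevalence.tsv")
    utils::write.table(crude_prevalence(env$cohort_cube), p2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    c(p1, p2)
  })

  run_stage("standardize", function() {
    cube <- env$bundle$cube
    yrs <- utils::tail(cube$years, config$spatial_window)
    env$cube_window <- .subset_cube_years(cube, yrs)
    env$E_spatial <- expected_counts(env$cube_window, pool_time = TRUE)
    env$E_st <- expected_counts(cube, pool_time = FALSE)
    p1 <- out("expected_spatial.tsv")
    write_expected_counts(env$cube_window, env$E_spatial, p1)
    p2 <- out("expected_st.tsv")
    write_expected_counts(cube, env$E_st, p2)
    c(p1, p2)
  })

  run_stage("covariates", function() {
    p1 <- out("covariates.tsv")
    write_covariate_table(env$bundle$covariates, p1)
    c(p1, paste0(p1, ".config.json"))
  })

  run_stage("moran", function() {
    sr <- standardized_ratio(env$cube_window, env$E_spatial)
    vals <- log((sr$observed + 0.5) / sr$expected)
    names(vals) <- sr$region
    mi <- morans_i_test(vals, env$bundle$graph,
                        n_permutations = config$n_permutations,
                        seed = config$seed + 7L)
    p <- out("moran.json")
    jsonlite::write_json(unclass(mi), p, auto_unbox = TRUE, digits = NA)
    p
  })

  fits <- list()
  run_stage("fit_spatial", function() {
    Yi <- apply(env$cube_window$Y, 1L, sum)
    cfg <- model_config(model_form = "spatial",
                        hyperprior = config$hyperprior,
                        n_iterations = config$n_iterations,
                        n_burnin = config$n_burnin,
                        n_chains = config$n_chains,
                        thinning = config$thinning,
                        seed = config$seed + 11L)
    env$fit_spatial <- fit_model(Yi, env$E_spatial,
                                 X = env$bundle$covariates[
                                   c("region_id", "sefi2", "indigenous")],
                                 graph = env$bundle$graph, config = cfg)
    p1 <- out("fit_spatial_draws.tsv")
    write_fit_draws(env$fit_spatial, p1)
    p2 <- out("fit_spatial_effects.tsv")
    utils::write.table(covariate_effects(env$fit_spatial), p2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    c(p1, paste0(p1, ".meta.json"), p2)
  })

  for (spec in list(list(stage = "fit_st_main", form = "st_main"),
                    list(stage = "fit_st_interaction",
                         form = "st_interaction"))) {
    local({
      stage <- spec$stage; form <- spec$form
      run_stage(stage, function() {
        Yit <- apply(env$bundle$cube$Y, c(1L, 2L), sum)
        cfg <- model_config(model_form = form,
                            hyperprior = config$hyperprior,
                            n_iterations = config$n_iterations,
                            n_burnin = config$n_burnin,
                            n_chains = config$n_chains,
                            thinning = config$thinning,
                            interaction_type = config$interaction_type,
                            seed = config$seed + 13L +
                              2L * (form == "st_interaction"))
        env[[stage]] <- fit_model(Yit, env$E_st, X = NULL,
                                  graph = env$bundle$graph, config = cfg)
        p1 <- out(paste0(stage, "_draws.tsv"))
        write_fit_draws(env[[stage]], p1)
        c(p1, paste0(p1, ".meta.json"))
      })
    })
  }

  run_stage("diagnose", function() {
    paths <- character(0)
    for (nm in c("fit_spatial", "fit_st_main", "fit_st_interaction")) {
      fit <- env[[nm]]
      if (is.null(fit)) next
      rep <- diagnostics_report(fit, seed = config$seed + 17L)
      stem <- out(paste0("diagnostics_", nm))
      write_diagnostics_report(rep, stem)
      paths <- c(paths, paste0(stem, "_summary.tsv"),
                 paste0(stem, "_units.tsv"))
    }
    if (!length(paths)) stop("no fits available to diagnose")
    paths
  })

  say("pipeline complete: ", nrow(manifest), " artifact(s)")
  invisible(manifest)
}

.subset_cube_years <- function(cube, years) {
  keep <- cube$years %in% as.character(years)
  prevalence_cube(cube$Y[, keep, , drop = FALSE],
                  cube$n[, keep, , drop = FALSE])
}
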