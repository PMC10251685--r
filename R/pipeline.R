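#' Pooled net-benefit regressions across a WTP grid
#'
#' @param imps An `nbr_imputations` object.
#' @param grid WTP grid.
#' @param ... Passed to [nb_regression_mi()] (perspective, covariates,
#'   moderator, ...).
#' @return Named list (by threshold) of `nb_pooled` fits, suitable for
#'   [ceac()] and [coefficient_table()].
#' @export
nb_regression_grid <- function(imps, grid = wtp_grid_coarse(), ...) {
  check_wtp_grid(grid)
  fits <- lapply(grid, function(l) nb_regression_mi(imps, l, ...))
  stats::setNames(fits, as.character(grid))
}

#' Coefficient-by-threshold table of pooled net-benefit regressions
#'
#' One row per model term, one estimate and one two-sided p-value column per
#' WTP threshold (the usual presentation of net-benefit regression results).
#'
#' @param fits Named list of `nb_pooled` objects from
#'   [nb_regression_grid()].
#' @return data.frame with `term` and `beta_<wtp>` / `p_<wtp>` columns.
#' @export
coefficient_table <- function(fits) {
  if (!length(fits) || is.null(names(fits))) {
    stop("`fits` must be a list named by WTP threshold")
  }
  terms <- fits[[1]]$pooled$term
  out <- data.frame(term = terms)
  for (nm in names(fits)) {
    pooled <- fits[[nm]]$pooled
    if (!identical(pooled$term, terms)) {
      stop("fits do not share the same model terms")
    }
    out[[paste0("beta_", nm)]] <- pooled$estimate
    out[[paste0("p_", nm)]] <- pooled$p.value
  }
  out
}

#' Configuration of a full analysis run
#'
#' @param trial An `nbr_trial` data.frame to analyse, or `NULL` to simulate.
#' @param sim_config A [trial_config()] used when `trial` is `NULL` (the
#'   simulated trial is degraded by [impose_missingness()] before analysis).
#' @param perspectives Costing perspectives to run end-to-end.
#' @param table_grid Coarse WTP grid for inference tables and screening.
#' @param ceac_grid Fine WTP grid for acceptability curves.
#' @param confounder_candidates,moderator_candidates Baseline column names
#'   to screen.
#' @param m Number of imputations.
#' @param seed Imputation seed (simulation uses the `sim_config` seed).
#' @param outdir Output directory for run artifacts.
#' @param threshold Acceptability probability threshold (default 0.95).
#' @return A list of class `run_config`.
#' @export
run_config <- function(trial = NULL, sim_config = NULL,
                       perspectives = c("health_system", "limited_societal"),
                       table_grid = wtp_grid_coarse(),
                       ceac_grid = wtp_grid_fine(),
                       confounder_candidates = character(),
                       moderator_candidates = character(),
                       m = 20, seed = 1, outdir = "nbreg-run",
                       threshold = 0.95) {
  if (is.null(trial) && is.null(sim_config)) {
    stop("supply `trial` data or a `sim_config` to simulate from")
  }
  if (!length(perspectives) ||
      !all(perspectives %in% c("health_system", "limited_societal"))) {
    stop("`perspectives` must name at least one known perspective")
  }
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  check_wtp_grid(table_grid)
  check_wtp_grid(ceac_grid)
  structure(list(trial = trial, sim_config = sim_config,
                 perspectives = perspectives, table_grid = table_grid,
                 ceac_grid = ceac_grid,
                 confounder_candidates = confounder_candidates,
                 moderator_candidates = moderator_candidates,
                 m = m, seed = seed, outdir = outdir, threshold = threshold),
            class = "run_config")
}

write_run_csv <- function(x, outdir, name) {
  path <- file.path(outdir, name)
  utils::write.csv(x, path, row.names = FALSE, na = "")
  path
}

#' Run the full net-benefit moderation pipeline
#'
#' Orchestrates: simulate or load the trial, impute (bootstrap-EM, with a
#' negative-cost audit), screen candidate confounders and moderators, fit
#' the final adjusted (and, per flagged moderator, interaction) models over
#' the WTP grid, build overall and stratified acceptability curves, run the
#' diagnostics battery on every completion at the grid endpoints, and write
#' all artifacts plus a machine-readable manifest. Every stage is seeded, so
#' a rerun with the same configuration reproduces the CSV outputs
#' byte-for-byte. All randomized participants stay in the analysis at every
#' stage (intention-to-treat).
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the dataset, imputations, per-perspective
#'   screening objects, fitted grids, CEACs, diagnostics and the manifest.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  t_start <- proc.time()[["elapsed"]]
  say <- function(...) {
    msg <- paste0(sprintf("[%8.2fs] ", proc.time()[["elapsed"]] - t_start),
                  ...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }

  # stage: data
  trial <- config$trial
  if (is.null(trial)) {
    say("simulate: generating trial (seed ", config$sim_config$seed, ")")
    trial <- generate_trial(config$sim_config)
    trial <- impose_missingness(trial, config$sim_config)
  }
  n_all <- nrow(trial)
  say("data: ", n_all, " participants")

  # stage: imputation
  say("impute: m = ", config$m, " (seed ", config$seed, ")")
  imps <- tryCatch(
    em_bootstrap_impute(trial, m = config$m, seed = config$seed),
    error = function(e) stop("stage imputation failed: ",
                             conditionMessage(e), call. = FALSE))
  audit <- data.frame(
    perspective = c("health_system", "limited_societal"),
    negative_total_cost_fraction = c(
      audit_negative_costs(imps, "health_system"),
      audit_negative_costs(imps, "limited_societal")))
  files <- c(audit = write_run_csv(audit, config$outdir,
                                   "imputation_audit.csv"))

  results <- list()
  for (persp in config$perspectives) {
    tag <- if (persp == "health_system") "hs" else "soc"
    say("screen: ", persp)
    screening <- tryCatch(
      screen_candidates(imps, config$confounder_candidates,
                        config$moderator_candidates, perspective = persp,
                        grid = config$table_grid),
      error = function(e) stop("stage screening (", persp, ") failed: ",
                               conditionMessage(e), call. = FALSE))
    files[paste0("screening_", tag)] <-
      write_run_csv(screening$table, config$outdir,
                    paste0("screening_", tag, ".csv"))
    confounders <- names(Filter(function(d) isTRUE(d$is_confounder),
                                screening$confounders))
    moderators <- names(Filter(function(d) isTRUE(d$is_moderator),
                               screening$moderators))
    covs <- if (length(confounders)) confounders else NULL

    # overall adjusted model: table + CEAC
    say("fit: ", persp, " adjusted model over ",
        length(config$table_grid), "-point grid")
    fit_fun <- function(grid, moderator = NULL) {
      tryCatch(
        nb_regression_grid(imps, grid, perspective = persp,
                           covariates = covs, moderator = moderator),
        error = function(e) stop("stage model (", persp,
                                 if (!is.null(moderator))
                                   paste0(", moderator ", moderator),
                                 ") failed: ", conditionMessage(e),
                                 call. = FALSE))
    }
    table_fits <- fit_fun(config$table_grid)
    files[paste0("table_", tag)] <-
      write_run_csv(coefficient_table(table_fits), config$outdir,
                    paste0("coefficients_", tag, ".csv"))
    ceac_fits <- fit_fun(config$ceac_grid)
    overall_ceac <- ceac(ceac_fits)
    ceac_rows <- list(overall_ceac)

    mod_results <- list()
    for (mod in moderators) {
      say("fit: ", persp, " interaction model for ", mod)
      mod_table_fits <- fit_fun(config$table_grid, moderator = mod)
      files[paste0("table_", tag, "_", mod)] <-
        write_run_csv(coefficient_table(mod_table_fits), config$outdir,
                      paste0("coefficients_", tag, "_", mod, ".csv"))
      mod_ceac_fits <- fit_fun(config$ceac_grid, moderator = mod)
      levels_k <- mod_ceac_fits[[1]]$moderator_levels
      strata <- lapply(levels_k, function(k) {
        cc <- ceac(mod_ceac_fits, moderator_level = k,
                   stratum_label = paste0(mod, "=", k))
        files[paste0("ceac_", tag, "_", mod, "_", k)] <<-
          write_run_csv(as.data.frame(cc), config$outdir,
                        paste0("ceac_", tag, "_", mod, "_level", k, ".csv"))
        cc
      })
      ceac_rows <- c(ceac_rows, strata)
      mod_results[[mod]] <- list(table_fits = mod_table_fits,
                                 ceac_fits = mod_ceac_fits,
                                 strata = strata)
    }
    files[paste0("ceac_", tag)] <-
      write_run_csv(as.data.frame(overall_ceac), config$outdir,
                    paste0("ceac_", tag, ".csv"))

    # diagnostics on the final adjusted model at the grid endpoints
    say("diagnostics: ", persp)
    diag_summaries <- list()
    for (l in range(config$table_grid)) {
      fit_l <- table_fits[[as.character(l)]]
      reps <- lapply(fit_l$fits, influence_measures, ids = trial$id)
      flags <- flag_across_imputations(reps,
                                       min_count = min(5, config$m))
      checks <- lapply(fit_l$fits, model_checks)
      diag_summaries[[as.character(l)]] <-
        list(flags = flags, checks = checks)
      files[paste0("diag_flags_", tag, "_", l)] <-
        write_run_csv(flags, config$outdir,
                      paste0("diagnostics_flags_", tag, "_wtp", l, ".csv"))
      checks_tab <- do.call(rbind, lapply(seq_along(checks), function(j) {
        ck <- checks[[j]]
        data.frame(imputation = j, skew_z = ck$skew_z, kurt_z = ck$kurt_z,
                   normality_flagged = ck$normality_flagged,
                   max_vif = if (is.null(ck$vif)) NA else max(ck$vif$vif),
                   levene_p = ck$levene_p)
      }))
      files[paste0("diag_checks_", tag, "_", l)] <-
        write_run_csv(checks_tab, config$outdir,
                      paste0("diagnostics_checks_", tag, "_wtp", l, ".csv"))
    }

    results[[persp]] <- list(
      screening = screening, confounders = confounders,
      moderators = moderators, table_fits = table_fits,
      ceac = overall_ceac,
      ceac_threshold = ceac_threshold(overall_ceac, config$threshold),
      moderator_results = mod_results, ceacs = ceac_rows,
      diagnostics = diag_summaries)
  }

  # ITT guard: no stage may drop participants
  stopifnot(all(vapply(imps$completed, nrow, integer(1)) == n_all))

  manifest <- list(
    package = "nbreg",
    package_version = as.character(utils::packageVersion("nbreg")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_participants = n_all,
    m = config$m,
    seed = config$seed,
    sim_seed = if (!is.null(config$sim_config)) config$sim_config$seed,
    perspectives = config$perspectives,
    table_grid = config$table_grid,
    ceac_grid = range(config$ceac_grid),
    threshold = config$threshold,
    files = as.list(files))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  say("done")
  writeLines(log_lines, file.path(config$outdir, "log.txt"))

  invisible(list(trial = trial, imputations = imps, audit = audit,
                 perspectives = results, manifest = manifest,
                 files = files))
}
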