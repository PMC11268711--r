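#' Pipeline configuration
#'
#' A serializable description of a full synthetic-study analysis run:
#' simulate (or ingest) trial data, compare discounting forms, fit the
#' winning form with drug shifts, validate by posterior-predictive
#' refitting, run the choice GLMM, and correlate discounting across
#' tasks. A persisted config reruns to identical seeded outputs.
#'
#' @param seed Master seed for every stage.
#' @param n_subjects Cohort size per task.
#' @param preset Sampler preset for every MCMC stage.
#' @param out_dir Output directory.
#' @param tasks Character subset of `c("effort", "delay")`.
#' @param compare_forms Run the four-form LOOIC comparison stage.
#' @param n_pp_total,n_pp_selected Posterior-predictive dataset counts
#'   for the validation stage.
#' @param trials_files Optional named list (`effort`, `delay`) of CSV
#'   paths; when given, those tables are ingested instead of simulating.
#' @return A list of class `cbdm_run_config`.
#' @export
run_config <- function(seed = 1L, n_subjects = 62L, preset = "fast",
                       out_dir = "cbdm-run", tasks = c("effort", "delay"),
                       compare_forms = TRUE,
                       n_pp_total = 500L, n_pp_selected = 10L,
                       trials_files = NULL) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  structure(
    list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
         preset = preset, out_dir = out_dir, tasks = tasks,
         compare_forms = isTRUE(compare_forms),
         n_pp_total = as.integer(n_pp_total),
         n_pp_selected = as.integer(n_pp_selected),
         trials_files = trials_files),
    class = "cbdm_run_config"
  )
}

#' Render group-level summary tables
#'
#' Formats one 6-row parameter table per fitted task in the standard
#' reporting layout: `kappa`, `beta`, then the four drug shifts, with
#' posterior mean, SD and 95% HDI bounds.
#'
#' @param fits Named list of `cbdm_fit` objects (e.g. `effort`, `delay`).
#' @return Named list of data frames (also printable via `print`).
#' @export
render_summary_tables <- function(fits) {
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  lapply(fits, function(fit) {
    stopifnot(inherits(fit, "cbdm_fit"))
    s <- summarize_fit(fit)
    s[, c("parameter", "mean", "sd", "lower", "upper")]
  })
}

pipeline_stage <- function(manifest, name, expr) {
  t0 <- Sys.time()
  value <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$stages[[name]] <- list(
    status = "complete",
    seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  )
  list(manifest = manifest, value = value)
}

#' Run the full analysis pipeline
#'
#' Executes, per task: simulate (or ingest) -> compare forms -> fit the
#' winning form -> posterior-predictive validation and recovery ->
#' choice GLMM; then correlates placebo-condition discounting across
#' tasks. All outputs (trial tables, comparison table, parameter
#' summaries, recovery reports, effect tables) are written under
#' `config$out_dir` together with a machine-readable `manifest.json`
#' recording seeds, versions, stage status and durations.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "cbdm_run_config"))
  settings <- fit_settings(config$preset, seed = config$seed)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cbdm")),
    seed = config$seed, preset = config$preset, stages = list()
  )
  fits <- list()
  kappa_means <- list()

  for (task in config$tasks) {
    st <- pipeline_stage(manifest, paste0("simulate_", task), {
      if (!is.null(config$trials_files[[task]])) {
        read_trials(config$trials_files[[task]])
      } else {
        truth <- group_truth(task, n_subjects = config$n_subjects)
        co <- simulate_cohort(truth,
                              seed = combine_seed(config$seed,
                                                  match(task,
                                                        c("effort",
                                                          "delay"))))
        write_cohort(co, file.path(out, paste0("cohort_", task)))
        co$trials
      }
    })
    manifest <- st$manifest
    trials <- st$value

    winning <- if (task == "effort") "parabolic" else "hyperbolic"
    if (config$compare_forms) {
      st <- pipeline_stage(manifest, paste0("compare_", task), {
        cmp <- compare_forms(trials, task_kind = task,
                             settings = settings)
        utils::write.csv(cmp, file.path(out,
                                        paste0("comparison_", task,
                                               ".csv")),
                         row.names = FALSE)
        cmp
      })
      manifest <- st$manifest
      winning <- st$value$form[1]
    }

    st <- pipeline_stage(manifest, paste0("fit_", task), {
      fit <- fit_hierarchical(trials, form = winning, task_kind = task,
                              settings = settings)
      utils::write.csv(summarize_fit(fit, include_sd = TRUE),
                       file.path(out, paste0("summary_", task, ".csv")),
                       row.names = FALSE)
      fit
    })
    manifest <- st$manifest
    fits[[task]] <- st$value

    st <- pipeline_stage(manifest, paste0("validate_", task), {
      pp <- posterior_predictive_datasets(
        fits[[task]], trials, n_total = config$n_pp_total,
        n_selected = config$n_pp_selected,
        seed = combine_seed(config$seed, 77L))
      refits <- lapply(pp, fit_hierarchical, form = winning,
                       task_kind = task, settings = settings)
      grp <- recover_group(refits, fits[[task]])
      sub <- recover_subjects(refits, fits[[task]])
      utils::write.csv(grp, file.path(out,
                                      paste0("recovery_group_", task,
                                             ".csv")),
                       row.names = FALSE)
      utils::write.csv(sub, file.path(out,
                                      paste0("recovery_subjects_", task,
                                             ".csv")),
                       row.names = FALSE)
      list(group = grp, subjects = sub)
    })
    manifest <- st$manifest

    st <- pipeline_stage(manifest, paste0("regress_", task), {
      des <- build_design(trials, regression_spec(task))
      gl <- fit_glmm(des, settings = settings)
      eff <- credible_effects(gl)
      utils::write.csv(eff, file.path(out,
                                      paste0("effects_", task, ".csv")),
                       row.names = FALSE)
      eff
    })
    manifest <- st$manifest

    km <- subject_means(fits[[task]])
    kappa_means[[task]] <- stats::setNames(km$kappa_plc, km$subject_id)
  }

  if (length(config$tasks) == 2) {
    st <- pipeline_stage(manifest, "correlate_tasks", {
      common <- intersect(names(kappa_means$effort),
                          names(kappa_means$delay))
      bc <- bayesian_correlation(kappa_means$effort[common],
                                 kappa_means$delay[common],
                                 settings = settings)
      res <- data.frame(r_mean = bc$mean, lower = bc$lower,
                        upper = bc$upper, credible = bc$credible)
      utils::write.csv(res, file.path(out, "across_task_correlation.csv"),
                       row.names = FALSE)
      res
    })
    manifest <- st$manifest
  }

  tables <- render_summary_tables(fits)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]],
                     file.path(out, paste0("table_", nm, ".csv")),
                     row.names = FALSE)
  }
  csvs <- sort(list.files(out, pattern = "\\.csv$", recursive = TRUE))
  sums <- tools::md5sum(file.path(out, csvs))
  manifest$checksums <- as.list(stats::setNames(unname(sums), csvs))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
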