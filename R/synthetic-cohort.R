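#' Population-level ground truth for cohort simulation
#'
#' Defines the generative population for a synthetic study: for each of
#' the six subject-level parameters, a population mean and a
#' between-subject SD, plus the cohort size. Default means are the
#' published group-level posterior means of the winning models (parabolic
#' effort, hyperbolic delay); those are estimates from one study, used
#' here as a realistic operating point, not as ground truth about any
#' population. Between-subject SDs are not published at all and are the
#' package's own choices: for the baseline parameters they are set to
#' plausible cohort spreads (effort `kappa` 0.05, `beta` 0.25; delay
#' log-`kappa` 1.0, `beta` 0.15), and each shift SD defaults to half the
#' magnitude of its population mean.
#'
#' @param task_kind `"effort"` or `"delay"`.
#' @param means Named numeric vector over
#'   `c("kappa_plc","beta_plc","s_kappa_hal","s_kappa_bip","s_beta_hal",
#'   "s_beta_bip")`; defaults as described above.
#' @param sds Same names; between-subject SDs (>= 0).
#' @param n_subjects Cohort size (default 62, the study sample).
#' @return A list of class `cbdm_group_truth`.
#' @examples
#' group_truth("effort")
#' @export
group_truth <- function(task_kind = c("effort", "delay"),
                        means = NULL, sds = NULL, n_subjects = 62L) {
  task_kind <- match.arg(task_kind)
  default_means <- if (task_kind == "effort") {
    c(kappa_plc = 0.102, beta_plc = 0.667,
      s_kappa_hal = 0.013, s_kappa_bip = -0.012,
      s_beta_hal = -0.089, s_beta_bip = 0.127)
  } else {
    c(kappa_plc = -4.621, beta_plc = 0.356,
      s_kappa_hal = -0.630, s_kappa_bip = -0.125,
      s_beta_hal = -0.055, s_beta_bip = -0.043)
  }
  m <- default_means
  if (!is.null(means)) m[names(means)] <- means
  base_sds <- if (task_kind == "effort") {
    c(kappa_plc = 0.05, beta_plc = 0.25)
  } else {
    c(kappa_plc = 1.0, beta_plc = 0.15)
  }
  s <- c(base_sds, abs(m[grep("^s_", names(m))]) / 2)
  if (!is.null(sds)) s[names(sds)] <- sds
  s <- s[names(m)]
  if (any(s < 0)) stop("between-subject SDs must be >= 0", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  structure(
    list(task_kind = task_kind, means = m, sds = s,
         n_subjects = as.integer(n_subjects)),
    class = "cbdm_group_truth"
  )
}

#' Draw subject-level parameters from a population
#'
#' Each parameter is drawn independently from a normal with the
#' population mean and between-subject SD (no parameter correlations are
#' modelled). Deterministic given `seed`.
#'
#' @param truth A [group_truth()] object.
#' @param seed Integer seed.
#' @return Data frame with `subject_id` and one column per parameter.
#' @export
draw_subjects <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "cbdm_group_truth"))
  n <- truth$n_subjects
  rng <- local_rng(combine_seed(seed, 1L))
  draws <- vapply(param_names, function(p) {
    stats::rnorm(n, truth$means[[p]], truth$sds[[p]])
  }, numeric(n))
  restore_rng(rng)
  draws <- matrix(draws, nrow = n,
                  dimnames = list(NULL, param_names))
  out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), draws,
                    stringsAsFactors = FALSE)
  out
}

#' Simulate choices on a trial list
#'
#' Fills the `choice` column of a design table with Bernoulli draws from
#' the softmax choice rule after resolving the drug condition. Each row's
#' probability comes from [p_choose_hc()] applied to the subjective values
#' of the two options under `form`.
#'
#' @param params A [subject_params()] object (one subject).
#' @param condition Drug condition label applied to all rows.
#' @param design Trial table without choices.
#' @param form Discounting form.
#' @param seed Integer seed.
#' @param effort_coding See [effort_code()].
#' @return The design table with `choice` and `condition` filled in.
#' @export
simulate_choices <- function(params, condition, design, form,
                             seed = 1L, effort_coding = "decile") {
  check_form(form)
  task_kind <- design$task_kind[1]
  res <- resolve_condition(params, rep(condition, nrow(design)))
  sv <- sv_both(form, task_kind, res$kappa, design, effort_coding)
  p <- p_choose_hc(sv$hc, sv$lc, res$beta)
  rng <- local_rng(combine_seed(seed, 2L))
  choice <- stats::rbinom(nrow(design), 1L, p)
  restore_rng(rng)
  design$choice <- as.integer(choice)
  design$condition <- condition
  design
}

simulate_subject_session <- function(params, condition, spec, form, seed,
                                     session_index, effort_coding) {
  design <- if (spec$task_kind == "effort") {
    build_effort_design(spec, seed = combine_seed(seed, 11L))
  } else {
    build_delay_design(spec, session_index = session_index,
                       seed = combine_seed(seed, 13L))
  }
  simulate_choices(params, condition, design, form,
                   seed = combine_seed(seed, 17L),
                   effort_coding = effort_coding)
}

#' Simulate one task's full cohort
#'
#' For every subject and every drug condition (PLC, HAL, BIP), builds a
#' fresh seeded session design and simulates choices from that subject's
#' parameters. Session order follows the condition index, so the delay
#' task's trial order is counterbalanced across conditions.
#'
#' @param truth A [group_truth()] object.
#' @param spec Task spec; defaults to the task's standard design.
#' @param form Generating discounting form; defaults to the winning form
#'   for the task (parabolic effort, hyperbolic delay).
#' @param seed Integer seed.
#' @param effort_coding See [effort_code()].
#' @return A list of class `cbdm_cohort` with elements `subjects` (true
#'   parameters), `trials` (all simulated rows), `truth`, `form`, `seed`.
#' @examples
#' co <- simulate_cohort(group_truth("effort", n_subjects = 2), seed = 1)
#' nrow(co$trials) # 2 subjects x 3 conditions x 125 trials
#' @export
simulate_cohort <- function(truth, spec = NULL, form = NULL, seed = 1L,
                            effort_coding = "decile") {
  stopifnot(inherits(truth, "cbdm_group_truth"))
  if (is.null(spec)) spec <- task_spec(truth$task_kind)
  if (is.null(form)) {
    form <- if (truth$task_kind == "effort") "parabolic" else "hyperbolic"
  }
  subjects <- draw_subjects(truth, seed = seed)
  conditions <- c("PLC", "HAL", "BIP")
  pieces <- vector("list", nrow(subjects) * length(conditions))
  idx <- 1L
  for (i in seq_len(nrow(subjects))) {
    params <- as.list(subjects[i, param_names])
    for (ci in seq_along(conditions)) {
      tab <- simulate_subject_session(
        params, conditions[ci], spec, form,
        seed = combine_seed(seed, i * 8L + ci),
        session_index = ci, effort_coding = effort_coding
      )
      tab$subject_id <- subjects$subject_id[i]
      pieces[[idx]] <- tab
      idx <- idx + 1L
    }
  }
  trials <- do.call(rbind, pieces)
  rownames(trials) <- NULL
  structure(
    list(subjects = subjects, trials = trials, truth = truth,
         form = form, seed = as.integer(seed),
         effort_coding = effort_coding),
    class = "cbdm_cohort"
  )
}

#' Simulate a full two-task study
#'
#' The synthetic stand-in for a within-subject pharmacological crossover
#' study: every subject completes an effort session (125 trials) and a
#' delay session (210 trials) under each of the three drug conditions.
#' The two tasks draw separate subject parameters from their own
#' populations, mirroring the empirical finding that effort and delay
#' discounting are uncorrelated across subjects.
#'
#' @param truth_effort,truth_delay [group_truth()] objects (defaults:
#'   published group means, 62 subjects).
#' @param seed Integer seed.
#' @param ... Passed to [simulate_cohort()].
#' @return List with elements `effort` and `delay`, each a `cbdm_cohort`.
#' @export
simulate_study <- function(truth_effort = group_truth("effort"),
                           truth_delay = group_truth("delay"),
                           seed = 1L, ...) {
  list(
    effort = simulate_cohort(truth_effort, seed = combine_seed(seed, 101L),
                             ...),
    delay = simulate_cohort(truth_delay, seed = combine_seed(seed, 202L),
                            ...)
  )
}

#' Write / read a simulated cohort
#'
#' A cohort serializes to three plain-text files in `dir`: `trials.csv`
#' (the trial table), `subjects.csv` (true subject-level parameters) and
#' `truth.json` (population truth and metadata).
#'
#' @param cohort A `cbdm_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cbdm_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(cohort$trials, file.path(dir, "trials.csv"))
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- list(task_kind = cohort$truth$task_kind,
               means = as.list(cohort$truth$means),
               sds = as.list(cohort$truth$sds),
               n_subjects = cohort$truth$n_subjects,
               form = cohort$form, seed = cohort$seed,
               effort_coding = cohort$effort_coding)
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  truth <- group_truth(meta$task_kind,
                       means = unlist(meta$means),
                       sds = unlist(meta$sds),
                       n_subjects = meta$n_subjects)
  structure(
    list(subjects = utils::read.csv(file.path(dir, "subjects.csv"),
                                    stringsAsFactors = FALSE),
         trials = read_trials(file.path(dir, "trials.csv")),
         truth = truth, form = meta$form, seed = meta$seed,
         effort_coding = meta$effort_coding),
    class = "cbdm_cohort"
  )
}
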