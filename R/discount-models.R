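#' @title Subjective-value discounting models
#' @description
#' Four single-parameter discounting forms describe how a reward loses
#' subjective value (SV) with its cost. For the delay task the discount
#' rate is parameterized in log space (the rate is `exp(kappa)`), because
#' raw delay-discounting rates are heavily skewed towards zero; for the
#' effort task `kappa` enters on its natural scale. The selected forms are
#' parabolic for effort and hyperbolic for delay; the other forms use the
#' standard textbook definitions.
#' @name discount-forms
NULL

discount_forms <- c("linear", "parabolic", "hyperbolic", "exponential")

check_form <- function(form) {
  if (!is.character(form) || length(form) != 1 ||
      !form %in% discount_forms) {
    stop("form must be one of: ", paste(discount_forms, collapse = ", "),
         call. = FALSE)
  }
  form
}

#' Subjective value of a delayed reward
#'
#' All four forms use `exp(kappa)` as the discount rate so that the
#' log-space convention (and additive drug shifts on `kappa`) applies
#' uniformly: hyperbolic `R / (1 + exp(kappa) * D)`, linear
#' `R - exp(kappa) * D`, exponential `R * exp(-exp(kappa) * D)`, parabolic
#' `R - exp(kappa) * D^2`.
#'
#' @param form Discounting form.
#' @param kappa Log-space discount parameter (recycled).
#' @param reward Reward magnitude in euro (> 0).
#' @param delay Delay in days (>= 0).
#' @return Subjective value in euro; equals `reward` at `delay = 0`.
#' @examples
#' sv_delay("hyperbolic", -4.621, 260, 60)
#' @export
sv_delay <- function(form, kappa, reward, delay) {
  check_form(form)
  if (any(delay < 0)) stop("delay must be non-negative", call. = FALSE)
  if (any(reward <= 0)) stop("reward must be positive", call. = FALSE)
  rate <- exp(kappa)
  switch(form,
    hyperbolic  = reward / (1 + rate * delay),
    linear      = reward - rate * delay,
    exponential = reward * exp(-rate * delay),
    parabolic   = reward - rate * delay^2
  )
}

#' Subjective value of an effortful reward
#'
#' `kappa` enters on its natural scale; effort is expressed in coded units
#' (see [effort_code()]; the default decile coding maps 0--80% MVC to
#' 0--8). Forms: parabolic `R - kappa * E^2`, linear `R - kappa * E`,
#' hyperbolic `R / (1 + kappa * E)`, exponential `R * exp(-kappa * E)`.
#' The hyperbolic denominator is floored at 1e-3 so that negative `kappa`
#' values explored during sampling cannot produce a sign flip.
#'
#' @param form Discounting form.
#' @param kappa Discount parameter (recycled).
#' @param reward Reward magnitude in apples (> 0).
#' @param effort Effort in coded units (>= 0).
#' @return Subjective value in apples; equals `reward` at `effort = 0`.
#' @examples
#' sv_effort("parabolic", 0.102, 16, 8) # 16 - 0.102 * 64 = 9.472
#' @export
sv_effort <- function(form, kappa, reward, effort) {
  check_form(form)
  if (any(effort < 0)) stop("effort must be non-negative", call. = FALSE)
  if (any(reward <= 0)) stop("reward must be positive", call. = FALSE)
  switch(form,
    parabolic   = reward - kappa * effort^2,
    linear      = reward - kappa * effort,
    hyperbolic  = reward / pmax(1 + kappa * effort, 1e-3),
    exponential = reward * exp(-kappa * effort)
  )
}

#' Effort coding
#'
#' Converts effort stored as a fraction of maximum voluntary contraction
#' (MVC, 0--0.8 under the default design) into the units used by the
#' discounting model. The default `"decile"` coding (0, 2, 4, 6, 8 for
#' 0--80% MVC) makes a discount parameter of about 0.1 produce parabolic
#' devaluations commensurate with the 2--16 apple reward range; `"percent"`
#' (0--80), `"fraction"` (0--0.8) and `"level"` (rank within the design
#' levels, 0-based) are available for sensitivity analyses. Simulation and
#' fitting must share one coding; parameter recovery is then
#' coding-invariant.
#'
#' @param effort_frac Effort as a fraction of MVC.
#' @param coding One of `"decile"`, `"percent"`, `"fraction"`, `"level"`.
#' @param levels Design cost levels (fractions), used by `"level"` coding.
#' @return Numeric coded effort.
#' @export
effort_code <- function(effort_frac,
                        coding = c("decile", "percent", "fraction", "level"),
                        levels = c(0, 0.2, 0.4, 0.6, 0.8)) {
  coding <- match.arg(coding)
  switch(coding,
    decile   = effort_frac * 10,
    percent  = effort_frac * 100,
    fraction = effort_frac,
    level    = match(effort_frac, sort(levels)) - 1
  )
}

#' Subject-level parameter set
#'
#' The six free parameters of the drug-shift discounting model for one
#' subject: placebo-condition discounting `kappa_plc` (log-space for the
#' delay task) and inverse temperature `beta_plc`, plus additive shifts on
#' each under haloperidol (`s_kappa_hal`, `s_beta_hal`) and biperiden
#' (`s_kappa_bip`, `s_beta_bip`). Positive `s_kappa` means the drug
#' increases discounting; positive `s_beta` means more deterministic
#' choices.
#'
#' @param kappa_plc,beta_plc Placebo-condition parameters.
#' @param s_kappa_hal,s_kappa_bip Shifts on kappa.
#' @param s_beta_hal,s_beta_bip Shifts on beta.
#' @return A list of class `cbdm_subject_params`.
#' @export
subject_params <- function(kappa_plc, beta_plc,
                           s_kappa_hal = 0, s_kappa_bip = 0,
                           s_beta_hal = 0, s_beta_bip = 0) {
  structure(
    list(kappa_plc = kappa_plc, beta_plc = beta_plc,
         s_kappa_hal = s_kappa_hal, s_kappa_bip = s_kappa_bip,
         s_beta_hal = s_beta_hal, s_beta_bip = s_beta_bip),
    class = "cbdm_subject_params"
  )
}

param_names <- c("kappa_plc", "beta_plc", "s_kappa_hal", "s_kappa_bip",
                 "s_beta_hal", "s_beta_bip")

#' Resolve condition-specific parameters
#'
#' Applies the additive drug-shift rule: under placebo the baseline
#' parameters are returned unchanged; under haloperidol or biperiden the
#' corresponding shift is added to `kappa` and `beta`. For the delay task
#' the shifted `kappa` remains in log space (exponentiation happens inside
#' [sv_delay()]). The resolved `beta` is softly bounded below at 1e-6; the
#' returned `beta_valid` flag records whether the bound was active.
#'
#' @param params A [subject_params()] object (or list with the same
#'   fields).
#' @param condition `"PLC"`, `"HAL"` or `"BIP"` (vectorized).
#' @return A list with elements `kappa`, `beta`, `beta_valid`.
#' @examples
#' p <- subject_params(0.102, 0.667, s_kappa_hal = 0.013)
#' resolve_condition(p, "HAL")$kappa # 0.115
#' @export
resolve_condition <- function(params, condition) {
  if (!all(condition %in% c("PLC", "HAL", "BIP"))) {
    stop("condition must be PLC, HAL or BIP", call. = FALSE)
  }
  hal <- as.numeric(condition == "HAL")
  bip <- as.numeric(condition == "BIP")
  kappa <- params$kappa_plc + hal * params$s_kappa_hal +
    bip * params$s_kappa_bip
  beta_raw <- params$beta_plc + hal * params$s_beta_hal +
    bip * params$s_beta_bip
  list(kappa = kappa,
       beta = pmax(beta_raw, 1e-6),
       beta_valid = beta_raw > 0)
}

#' Softmax probability of choosing the high-cost option
#'
#' The two-option softmax `exp(sv_hc * beta) / (exp(sv_hc * beta) +
#' exp(sv_lc * beta))`, computed in the overflow-safe logistic form
#' `plogis(beta * (sv_hc - sv_lc))`. The returned probability is clipped
#' to `[1e-12, 1 - 1e-12]` so downstream log-likelihoods stay finite.
#'
#' @param sv_hc,sv_lc Subjective values of the two options.
#' @param beta Inverse temperature (>= 0 after resolution; `beta = 0`
#'   yields 0.5 everywhere).
#' @return Probability in (0, 1), vectorized.
#' @export
p_choose_hc <- function(sv_hc, sv_lc, beta) {
  if (any(!is.finite(sv_hc)) || any(!is.finite(sv_lc))) {
    stop("subjective values must be finite", call. = FALSE)
  }
  if (any(!is.finite(beta))) {
    stop("beta must be finite", call. = FALSE)
  }
  p <- stats::plogis(beta * (sv_hc - sv_lc))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

sv_both <- function(form, task_kind, kappa, trials, effort_coding) {
  if (task_kind == "delay") {
    list(hc = sv_delay(form, kappa, trials$r_hc, trials$c_hc),
         lc = trials$r_lc)  # immediate option: SV equals its face value
  } else {
    eh <- effort_code(trials$c_hc, effort_coding)
    el <- effort_code(trials$c_lc, effort_coding)
    list(hc = sv_effort(form, kappa, trials$r_hc, eh),
         lc = sv_effort(form, kappa, trials$r_lc, el))
  }
}

#' Trial-level log-likelihood
#'
#' Bernoulli log-probability of the observed choices under the discounting
#' model, vectorized over the rows of a trial table. Conditions are
#' resolved per row via [resolve_condition()]; probabilities are clipped
#' away from 0/1, so the result is always finite. Summing the returned
#' vector gives the dataset log-likelihood used by the sampler.
#'
#' @param form Discounting form.
#' @param params A [subject_params()] object.
#' @param trials Trial table with observed `choice` and `condition`.
#' @param task_kind `"effort"` or `"delay"` (defaults to the table's own
#'   `task_kind`).
#' @param effort_coding Effort coding, see [effort_code()].
#' @return Numeric vector of per-trial log-probabilities.
#' @export
trial_loglik <- function(form, params, trials, task_kind = NULL,
                         effort_coding = "decile") {
  check_form(form)
  if (is.null(task_kind)) task_kind <- trials$task_kind[1]
  if (any(is.na(trials$choice))) {
    stop("trial_loglik requires observed choices on every row",
         call. = FALSE)
  }
  res <- resolve_condition(params, trials$condition)
  sv <- sv_both(form, task_kind, res$kappa, trials, effort_coding)
  p <- p_choose_hc(sv$hc, sv$lc, res$beta)
  ifelse(trials$choice == 1L, log(p), log1p(-p))
}
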