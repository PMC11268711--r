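#' Prior specification for the hierarchical discounting model
#'
#' Group-level means get normal priors, group-level SDs half-normal
#' priors. Defaults are weakly informative and anchored to the scale each
#' parameter lives on: effort `kappa` mean ~ N(0.05, 0.1), delay
#' log-`kappa` mean ~ N(-4, 2), `beta` mean ~ N(0.5, 0.5), all shift
#' means ~ N(0, 0.5); every SD prior is half-normal with scale equal to
#' half the corresponding mean-prior scale. All hyperparameters are
#' overridable.
#'
#' @param task_kind `"effort"` or `"delay"`.
#' @param mu_mean,mu_scale Named numeric vectors (names among
#'   `kappa_plc`, `beta_plc`, `s_kappa_hal`, `s_kappa_bip`, `s_beta_hal`,
#'   `s_beta_bip`) overriding the normal prior on the group means.
#' @param sd_scale Named numeric vector overriding the half-normal scale
#'   of the group SDs.
#' @return A list of class `cbdm_prior_spec`.
#' @export
prior_spec <- function(task_kind = c("effort", "delay"),
                       mu_mean = NULL, mu_scale = NULL, sd_scale = NULL) {
  task_kind <- match.arg(task_kind)
  mm <- c(kappa_plc = if (task_kind == "effort") 0.05 else -4,
          beta_plc = 0.5,
          s_kappa_hal = 0, s_kappa_bip = 0,
          s_beta_hal = 0, s_beta_bip = 0)
  ms <- c(kappa_plc = if (task_kind == "effort") 0.1 else 2,
          beta_plc = 0.5,
          s_kappa_hal = 0.5, s_kappa_bip = 0.5,
          s_beta_hal = 0.5, s_beta_bip = 0.5)
  ss <- ms / 2
  if (!is.null(mu_mean)) mm[names(mu_mean)] <- mu_mean
  if (!is.null(mu_scale)) ms[names(mu_scale)] <- mu_scale
  if (!is.null(sd_scale)) ss[names(sd_scale)] <- sd_scale
  if (any(ms <= 0) || any(ss <= 0)) {
    stop("prior scales must be positive", call. = FALSE)
  }
  structure(list(task_kind = task_kind, mu_mean = mm, mu_scale = ms,
                 sd_scale = ss),
            class = "cbdm_prior_spec")
}

#' Sampler settings
#'
#' Three presets: `"full"` mirrors the published estimation procedure
#' (4 chains, 3,000 warmup iterations, 4,000 retained iterations per
#' chain); `"standard"` is a mid-size profile used for convergence
#' reporting on synthetic cohorts; `"fast"` is the documented reduced
#' profile for tests and recovery experiments. Warmup is split between
#' JAGS adaptation and burn-in. Any field can be overridden.
#'
#' @param preset `"fast"`, `"standard"` or `"full"`.
#' @param chains,adapt,warmup,draws,thin,seed Overrides.
#' @return A list of class `cbdm_fit_settings`.
#' @export
fit_settings <- function(preset = c("fast", "standard", "full"),
                         chains = NULL, adapt = NULL, warmup = NULL,
                         draws = NULL, thin = NULL, seed = NULL) {
  preset <- match.arg(preset)
  s <- switch(preset,
    fast     = list(chains = 2L, adapt = 150L, warmup = 200L,
                    draws = 300L, thin = 1L),
    standard = list(chains = 4L, adapt = 300L, warmup = 500L,
                    draws = 1600L, thin = 1L),
    full     = list(chains = 4L, adapt = 1000L, warmup = 2000L,
                    draws = 4000L, thin = 1L)
  )
  if (!is.null(chains)) s$chains <- as.integer(chains)
  if (!is.null(adapt)) s$adapt <- as.integer(adapt)
  if (!is.null(warmup)) s$warmup <- as.integer(warmup)
  if (!is.null(draws)) s$draws <- as.integer(draws)
  if (!is.null(thin)) s$thin <- as.integer(thin)
  s$seed <- if (is.null(seed)) 1L else as.integer(seed)
  s$preset <- preset
  structure(s, class = "cbdm_fit_settings")
}

# --- JAGS model assembly ----------------------------------------------------

jags_dsv_expr <- function(task_kind, form) {
  if (task_kind == "delay") {
    switch(form,
      hyperbolic  = "rh[t] / (1 + exp(k[t]) * d[t]) - rl[t]",
      linear      = "rh[t] - exp(k[t]) * d[t] - rl[t]",
      exponential = "rh[t] * exp(-exp(k[t]) * d[t]) - rl[t]",
      parabolic   = "rh[t] - exp(k[t]) * d[t] * d[t] - rl[t]"
    )
  } else {
    # parabolic/linear effort differences collapse to dr - k * de,
    # with dr and de precomputed in the data: fewer graph nodes per cell
    switch(form,
      parabolic   = "dr[t] - k[t] * de2[t]",
      linear      = "dr[t] - k[t] * de1[t]",
      hyperbolic  = paste0("rh[t] / max(1 + k[t] * eh[t], 0.001)",
                           " - rl[t] / max(1 + k[t] * el[t], 0.001)"),
      exponential = paste0("rh[t] * exp(-k[t] * eh[t])",
                           " - rl[t] * exp(-k[t] * el[t])")
    )
  }
}

# Subject-level kappa/beta are centered on the group distribution (well
# identified by the placebo data; conjugate hyperparameter updates).
# Drug shifts use the non-centered parameterization, which avoids the
# funnel that otherwise stalls Gibbs updates of the shift-group means
# when the shift heterogeneity is small.
jags_model_string <- function(task_kind, form, priors, with_shifts) {
  dsv <- jags_dsv_expr(task_kind, form)
  prec <- function(x) sprintf("%.10g", 1 / x^2)
  mm <- priors$mu_mean; ms <- priors$mu_scale; ss <- priors$sd_scale
  k_line <- if (with_shifts) {
    "k[t] <- kap[subj[t]] + hal[t] * skh[subj[t]] + bip[t] * skb[subj[t]]"
  } else "k[t] <- kap[subj[t]]"
  b_line <- if (with_shifts) {
    paste0("b[t] <- max(bet[subj[t]] + hal[t] * sbh[subj[t]]",
           " + bip[t] * sbb[subj[t]], 1e-6)")
  } else "b[t] <- max(bet[subj[t]], 1e-6)"
  shift_subj <- if (with_shifts) "
    z_skh[i] ~ dnorm(0, 1); skh[i] <- mu_skh + sd_skh * z_skh[i]
    z_skb[i] ~ dnorm(0, 1); skb[i] <- mu_skb + sd_skb * z_skb[i]
    z_sbh[i] ~ dnorm(0, 1); sbh[i] <- mu_sbh + sd_sbh * z_sbh[i]
    z_sbb[i] ~ dnorm(0, 1); sbb[i] <- mu_sbb + sd_sbb * z_sbb[i]" else ""
  shift_hyper <- if (with_shifts) sprintf("
  mu_skh ~ dnorm(%g, %s); sd_skh ~ dnorm(0, %s) T(0,)
  mu_skb ~ dnorm(%g, %s); sd_skb ~ dnorm(0, %s) T(0,)
  mu_sbh ~ dnorm(%g, %s); sd_sbh ~ dnorm(0, %s) T(0,)
  mu_sbb ~ dnorm(%g, %s); sd_sbb ~ dnorm(0, %s) T(0,)",
    mm[["s_kappa_hal"]], prec(ms[["s_kappa_hal"]]),
    prec(ss[["s_kappa_hal"]]),
    mm[["s_kappa_bip"]], prec(ms[["s_kappa_bip"]]),
    prec(ss[["s_kappa_bip"]]),
    mm[["s_beta_hal"]], prec(ms[["s_beta_hal"]]),
    prec(ss[["s_beta_hal"]]),
    mm[["s_beta_bip"]], prec(ms[["s_beta_bip"]]),
    prec(ss[["s_beta_bip"]])) else ""
  sprintf("
model {
  for (t in 1:N) {
    %s
    %s
    p[t] <- max(min(ilogit(b[t] * (%s)), 1 - 1e-9), 1e-9)
    y[t] ~ dbin(p[t], n[t])
  }
  for (i in 1:S) {
    kap[i] ~ dnorm(mu_k, 1 / sd_k^2)
    bet[i] ~ dnorm(mu_b, 1 / sd_b^2)%s
  }
  mu_k ~ dnorm(%g, %s); sd_k ~ dnorm(0, %s) T(0,)
  mu_b ~ dnorm(%g, %s); sd_b ~ dnorm(0, %s) T(0,)%s
}",
    k_line, b_line, dsv, shift_subj,
    mm[["kappa_plc"]], prec(ms[["kappa_plc"]]), prec(ss[["kappa_plc"]]),
    mm[["beta_plc"]], prec(ms[["beta_plc"]]), prec(ss[["beta_plc"]]),
    shift_hyper)
}

# Collapse a trial table to binomial cells (identical option pair within
# subject x condition). The Bernoulli likelihood factorizes over trials,
# so this is an exact reformulation that cuts the JAGS graph size.
aggregate_trials <- function(trials, task_kind, effort_coding) {
  if (any(is.na(trials$choice))) {
    stop("fitting requires observed choices on every row", call. = FALSE)
  }
  subj_ids <- sort(unique(trials$subject_id))
  subj <- match(trials$subject_id, subj_ids)
  hal <- as.integer(trials$condition == "HAL")
  bip <- as.integer(trials$condition == "BIP")
  if (task_kind == "delay") {
    key <- paste(subj, hal, bip, trials$r_hc, trials$c_hc)
  } else {
    key <- paste(subj, hal, bip, trials$r_hc, trials$r_lc,
                 trials$c_hc, trials$c_lc)
  }
  idx <- match(key, unique(key))
  first <- !duplicated(key)
  dat <- list(
    N = sum(first),
    S = length(subj_ids),
    subj = subj[first],
    hal = hal[first],
    bip = bip[first],
    rh = trials$r_hc[first],
    rl = trials$r_lc[first],
    y = as.vector(tapply(trials$choice, idx, sum)),
    n = as.vector(tapply(rep(1L, nrow(trials)), idx, sum))
  )
  if (task_kind == "delay") {
    dat$d <- trials$c_hc[first]
  } else {
    dat$eh <- effort_code(trials$c_hc, effort_coding)[first]
    dat$el <- effort_code(trials$c_lc, effort_coding)[first]
    dat$dr <- dat$rh - dat$rl
    dat$de1 <- dat$eh - dat$el
    dat$de2 <- dat$eh^2 - dat$el^2
  }
  list(data = dat, subject_ids = subj_ids)
}

group_par_map <- function(with_shifts) {
  means <- c(kappa = "mu_k", beta = "mu_b")
  sds <- c(sd_kappa = "sd_k", sd_beta = "sd_b")
  if (with_shifts) {
    means <- c(means,
               s_kappa_hal = "mu_skh", s_kappa_bip = "mu_skb",
               s_beta_hal = "mu_sbh", s_beta_bip = "mu_sbb")
    sds <- c(sds,
             sd_s_kappa_hal = "sd_skh", sd_s_kappa_bip = "sd_skb",
             sd_s_beta_hal = "sd_sbh", sd_s_beta_bip = "sd_sbb")
  }
  ord <- c("kappa", "beta",
           if (with_shifts) c("s_kappa_hal", "s_kappa_bip",
                              "s_beta_hal", "s_beta_bip"))
  c(means, sds)[c(ord, paste0("sd_", ord[seq_len(2)]),
                  if (with_shifts) paste0("sd_", ord[3:6]))]
}

subject_par_map <- function(with_shifts) {
  m <- c(kappa_plc = "kap", beta_plc = "bet")
  if (with_shifts) {
    m <- c(m, s_kappa_hal = "skh", s_kappa_bip = "skb",
           s_beta_hal = "sbh", s_beta_bip = "sbb")
  }
  m
}

#' Fit the hierarchical Bayesian discounting model
#'
#' Estimates subject-level discounting (`kappa`), inverse temperature
#' (`beta`) and, when the data contain more than the placebo condition,
#' the four drug-shift parameters, with separate group-level mean/SD
#' distributions for every parameter. Sampling is MCMC via JAGS with a
#' per-chain seeded RNG fanned out from `settings$seed`. When only the
#' placebo condition is present (the form-comparison setting) the shift
#' parameters are dropped from the model.
#'
#' @param trials Trial table with observed choices; every subject must
#'   contribute every condition present in the data.
#' @param form Discounting form.
#' @param task_kind `"effort"` or `"delay"` (default: from the table).
#' @param priors A [prior_spec()]; defaults to the task's standard priors.
#' @param settings A [fit_settings()] object.
#' @param effort_coding See [effort_code()].
#' @return A `cbdm_fit` object: `draws$group` (iterations x chains x
#'   parameter array over group means and SDs), `draws$subject`
#'   (iterations x chains x subject x parameter), `subject_ids`,
#'   `diagnostics` (split-chain r-hat per group parameter, with a
#'   `converged` flag at the 1.01 threshold) and `meta`.
#' @export
fit_hierarchical <- function(trials, form, task_kind = NULL,
                             priors = NULL,
                             settings = fit_settings("fast"),
                             effort_coding = "decile") {
  check_form(form)
  if (is.null(task_kind)) task_kind <- trials$task_kind[1]
  if (!"condition" %in% names(trials) || all(is.na(trials$condition))) {
    stop("trial table must have a condition column with PLC/HAL/BIP",
         call. = FALSE)
  }
  conds <- unique(trials$condition)
  with_shifts <- any(conds != "PLC")
  agg <- aggregate_trials(trials, task_kind, effort_coding)
  sv_vars <- if (task_kind == "delay") c("rh", "rl", "d") else
    switch(form,
           parabolic = c("dr", "de2"),
           linear = c("dr", "de1"),
           c("rh", "rl", "eh", "el"))
  keep_vars <- c("N", "S", "subj", "y", "n", sv_vars,
                 if (with_shifts) c("hal", "bip"))
  agg$data <- agg$data[keep_vars]
  if (is.null(priors)) priors <- prior_spec(task_kind)
  model <- jags_model_string(task_kind, form, priors, with_shifts)

  inits <- lapply(seq_len(settings$chains), function(ch) {
    list(mu_k = unname(priors$mu_mean[["kappa_plc"]]),
         mu_b = max(unname(priors$mu_mean[["beta_plc"]]), 0.1),
         sd_k = unname(priors$sd_scale[["kappa_plc"]]) / 2,
         sd_b = unname(priors$sd_scale[["beta_plc"]]) / 2,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = combine_seed(settings$seed, 7000L + ch))
  })
  t0 <- Sys.time()
  jm <- rjags::jags.model(textConnection(model), data = agg$data,
                          inits = inits, n.chains = settings$chains,
                          n.adapt = settings$adapt, quiet = TRUE)
  update(jm, settings$warmup, progress.bar = "none")
  monitors <- c(unname(group_par_map(with_shifts)),
                unname(subject_par_map(with_shifts)))
  samp <- rjags::coda.samples(jm, monitors, n.iter = settings$draws,
                              thin = settings$thin,
                              progress.bar = "none")
  runtime <- as.numeric(Sys.time() - t0, units = "secs")

  n_iter <- nrow(samp[[1]])
  n_chain <- length(samp)
  vn <- colnames(samp[[1]])
  gmap <- group_par_map(with_shifts)
  group <- array(NA_real_, c(n_iter, n_chain, length(gmap)),
                 dimnames = list(NULL, NULL, names(gmap)))
  for (j in seq_along(gmap)) {
    for (ch in seq_len(n_chain)) {
      group[, ch, j] <- samp[[ch]][, gmap[[j]]]
    }
  }
  smap <- subject_par_map(with_shifts)
  S <- length(agg$subject_ids)
  subject <- array(NA_real_, c(n_iter, n_chain, S, length(smap)),
                   dimnames = list(NULL, NULL, agg$subject_ids,
                                   names(smap)))
  for (j in seq_along(smap)) {
    # JAGS drops the index on length-1 vector nodes
    cols <- if (S == 1) smap[[j]] else
      paste0(smap[[j]], "[", seq_len(S), "]")
    stopifnot(all(cols %in% vn))
    for (ch in seq_len(n_chain)) {
      subject[, ch, , j] <- samp[[ch]][, cols]
    }
  }
  diag_rhat <- if (n_chain >= 2) {
    vapply(names(gmap), function(p) rhat(group[, , p]), numeric(1))
  } else {
    stats::setNames(rep(NA_real_, length(gmap)), names(gmap))
  }
  structure(
    list(draws = list(group = group, subject = subject),
         subject_ids = agg$subject_ids,
         diagnostics = list(
           rhat = diag_rhat,
           max_rhat = if (all(is.na(diag_rhat))) NA_real_
                      else max(diag_rhat, na.rm = TRUE),
           converged = if (all(is.na(diag_rhat))) NA
                       else max(diag_rhat, na.rm = TRUE) <= 1.01),
         meta = list(form = form, task_kind = task_kind,
                     with_shifts = with_shifts, settings = settings,
                     priors = priors, effort_coding = effort_coding,
                     runtime_s = runtime)),
    class = "cbdm_fit"
  )
}

#' @export
print.cbdm_fit <- function(x, ...) {
  cat("Hierarchical discounting fit (", x$meta$task_kind, ", ",
      x$meta$form, " form)\n", sep = "")
  cat(length(x$subject_ids), "subjects;",
      dim(x$draws$group)[1], "draws x", dim(x$draws$group)[2],
      "chains\n")
  if (!is.na(x$diagnostics$max_rhat)) {
    cat("max split r-hat:", round(x$diagnostics$max_rhat, 4),
        if (isTRUE(x$diagnostics$converged)) "(converged)"
        else "(NOT converged at 1.01)", "\n")
  }
  invisible(x)
}

#' Highest density interval
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of
#' the sorted samples, found by an exhaustive window scan. Constant
#' samples give a zero-width interval.
#'
#' @param samples Numeric vector (>= 2 finite values).
#' @param mass Probability mass (default 0.95).
#' @return List with `lower`, `upper`, `mass`, `mean`.
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2) stop("hdi requires at least 2 finite samples", call. = FALSE)
  if (mass <= 0 || mass > 1) stop("mass must be in (0, 1]", call. = FALSE)
  x <- sort(samples)
  m <- min(ceiling(mass * n), n)
  if (m < 2) m <- 2L
  k <- n - m + 1L
  widths <- x[m:n] - x[1:k]
  i <- which.min(widths)
  list(lower = x[i], upper = x[i + m - 1L], mass = mass,
       mean = mean(samples))
}

#' Split-chain potential scale reduction factor (r-hat)
#'
#' Gelman-Rubin convergence diagnostic computed on split chains: each
#' chain is halved, and the between/within-variance ratio is computed
#' over the resulting 2C sequences, which also detects trending single
#' chains. Values at or below 1.01 are conventionally acceptable.
#'
#' @param draws Iterations x chains matrix (>= 2 chains, >= 4
#'   iterations), or a `coda::mcmc.list`.
#' @return The r-hat value (>= 1 up to floating error; 1 for constant
#'   draws).
#' @export
rhat <- function(draws) {
  if (inherits(draws, "mcmc.list")) {
    draws <- sapply(draws, function(ch) as.numeric(ch[, 1]))
  }
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) {
    stop("rhat requires at least 2 chains", call. = FALSE)
  }
  n <- nrow(draws)
  if (n < 4) stop("rhat requires at least 4 iterations per chain",
                  call. = FALSE)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Summarize group-level posteriors
#'
#' One row per group-level parameter with the posterior mean, SD, 95%
#' HDI bounds, split-chain r-hat and the posterior sign probability
#' `P(parameter > 0)`. The primary rows follow the standard reporting
#' order: `kappa`, `beta`, then the four drug shifts; group-level SDs are
#' appended when `include_sd = TRUE`.
#'
#' @param fit A `cbdm_fit`.
#' @param mass HDI mass.
#' @param include_sd Also report the group-level SD parameters.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`, `rhat`, `p_gt_0`.
#' @export
summarize_fit <- function(fit, mass = 0.95, include_sd = FALSE) {
  stopifnot(inherits(fit, "cbdm_fit"))
  pars <- dimnames(fit$draws$group)[[3]]
  if (!include_sd) pars <- pars[!startsWith(pars, "sd_")]
  rows <- lapply(pars, function(p) {
    x <- as.numeric(fit$draws$group[, , p])
    h <- hdi(x, mass)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               lower = h$lower, upper = h$upper,
               rhat = unname(fit$diagnostics$rhat[p]),
               p_gt_0 = mean(x > 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
summary.cbdm_fit <- function(object, ...) summarize_fit(object, ...)

#' Subject-level posterior means
#'
#' @param fit A `cbdm_fit`.
#' @return Data frame: `subject_id` plus one column per subject-level
#'   parameter, each the posterior mean over all chains.
#' @export
subject_means <- function(fit) {
  stopifnot(inherits(fit, "cbdm_fit"))
  arr <- fit$draws$subject
  m <- apply(arr, c(3, 4), mean)
  data.frame(subject_id = fit$subject_ids, m, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Pointwise log-likelihood matrix
#'
#' Evaluates the trial-level Bernoulli log-likelihood of `trials` for
#' every retained posterior draw, using the subject-level parameter
#' draws. This is the draws x trials matrix consumed by [looic()].
#'
#' @param fit A `cbdm_fit`.
#' @param trials The trial table the fit was estimated on.
#' @param max_draws Optional cap on the number of draws used (evenly
#'   thinned) to bound memory and time.
#' @return Matrix of dimension draws x trials.
#' @export
pointwise_loglik <- function(fit, trials, max_draws = NULL) {
  stopifnot(inherits(fit, "cbdm_fit"))
  task_kind <- fit$meta$task_kind
  form <- fit$meta$form
  coding <- fit$meta$effort_coding
  subj <- match(trials$subject_id, fit$subject_ids)
  if (any(is.na(subj))) {
    stop("trials contain subjects absent from the fit", call. = FALSE)
  }
  hal <- as.numeric(trials$condition == "HAL")
  bip <- as.numeric(trials$condition == "BIP")
  arr <- fit$draws$subject
  d <- dim(arr)
  flat <- matrix(arr, d[1] * d[2], d[3] * d[4])
  n_draws <- d[1] * d[2]
  keep <- seq_len(n_draws)
  if (!is.null(max_draws) && max_draws < n_draws) {
    keep <- unique(round(seq(1, n_draws, length.out = max_draws)))
  }
  pars <- dimnames(arr)[[4]]
  col_of <- function(p, s) (match(p, pars) - 1L) * d[3] + s
  ws <- fit$meta$with_shifts
  out <- matrix(NA_real_, length(keep), nrow(trials))
  for (ii in seq_along(keep)) {
    s <- keep[ii]
    kap <- flat[s, col_of("kappa_plc", subj)]
    bet <- flat[s, col_of("beta_plc", subj)]
    if (ws) {
      kap <- kap + hal * flat[s, col_of("s_kappa_hal", subj)] +
        bip * flat[s, col_of("s_kappa_bip", subj)]
      bet <- bet + hal * flat[s, col_of("s_beta_hal", subj)] +
        bip * flat[s, col_of("s_beta_bip", subj)]
    }
    bet <- pmax(bet, 1e-6)
    sv <- sv_both(form, task_kind, kap, trials, coding)
    p <- p_choose_hc(sv$hc, sv$lc, bet)
    out[ii, ] <- ifelse(trials$choice == 1L, log(p), log1p(-p))
  }
  out
}

#' Persist / restore a fit
#'
#' Writes the group-level draws (long CSV), subject-level posterior draws
#' (wide CSV), the summary table and metadata (JSON) into `dir`.
#'
#' @param fit A `cbdm_fit`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "cbdm_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- fit$draws$group
  dg <- dim(g)
  long <- data.frame(
    iter = rep(seq_len(dg[1]), dg[2] * dg[3]),
    chain = rep(rep(seq_len(dg[2]), each = dg[1]), dg[3]),
    parameter = rep(dimnames(g)[[3]], each = dg[1] * dg[2]),
    value = as.numeric(g)
  )
  utils::write.csv(long, file.path(dir, "group_draws.csv"),
                   row.names = FALSE, quote = FALSE)
  sm <- subject_means(fit)
  utils::write.csv(sm, file.path(dir, "subject_means.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(summarize_fit(fit, include_sd = TRUE),
                   file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- fit$meta
  meta$settings <- unclass(meta$settings)
  meta$priors <- list(task_kind = meta$priors$task_kind,
                      mu_mean = as.list(meta$priors$mu_mean),
                      mu_scale = as.list(meta$priors$mu_scale),
                      sd_scale = as.list(meta$priors$sd_scale))
  meta$diagnostics <- list(rhat = as.list(fit$diagnostics$rhat),
                           max_rhat = fit$diagnostics$max_rhat,
                           converged = fit$diagnostics$converged)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
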