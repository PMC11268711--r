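#' Posterior-predictive choice datasets
#'
#' Simulates synthetic choice datasets from the subject-level posterior:
#' for each subject, `n_total` datasets are generated, each using one
#' randomly selected posterior draw of that subject's parameters to
#' produce choices on `design`; a seeded random subset of `n_selected`
#' datasets per subject is assembled into full-cohort trial tables for
#' refitting.
#'
#' @param fit A `cbdm_fit`.
#' @param design Trial table covering every subject and condition (its
#'   choices, if any, are ignored).
#' @param n_total Number of datasets simulated per subject.
#' @param n_selected Number of datasets returned (per subject; the d-th
#'   returned table combines every subject's d-th selected dataset).
#' @param seed Integer seed.
#' @return List of `n_selected` trial tables.
#' @export
posterior_predictive_datasets <- function(fit, design, n_total = 500,
                                          n_selected = 10, seed = 1L) {
  stopifnot(inherits(fit, "cbdm_fit"))
  if (n_selected > n_total) {
    stop("n_selected must not exceed n_total", call. = FALSE)
  }
  if (design$task_kind[1] != fit$meta$task_kind) {
    stop("fit and design disagree on task_kind", call. = FALSE)
  }
  arr <- fit$draws$subject
  d <- dim(arr)
  n_draws <- d[1] * d[2]
  flat <- matrix(arr, n_draws, d[3] * d[4])
  pars <- dimnames(arr)[[4]]
  ws <- fit$meta$with_shifts
  subj_ids <- fit$subject_ids

  rng <- local_rng(combine_seed(seed, 31L))
  draw_idx <- matrix(sample(n_draws, length(subj_ids) * n_total,
                            replace = TRUE),
                     nrow = length(subj_ids))
  sel <- t(vapply(seq_along(subj_ids),
                  function(i) sample(n_total, n_selected),
                  integer(n_selected)))
  sel <- matrix(sel, nrow = length(subj_ids))

  out <- vector("list", n_selected)
  for (dd in seq_len(n_selected)) {
    pieces <- lapply(seq_along(subj_ids), function(i) {
      rows <- design[design$subject_id == subj_ids[i], , drop = FALSE]
      s <- draw_idx[i, sel[i, dd]]
      prm <- lapply(param_names, function(p) {
        j <- match(p, pars)
        if (is.na(j)) 0 else flat[s, (j - 1L) * d[3] + i]
      })
      names(prm) <- param_names
      res <- resolve_condition(prm, rows$condition)
      sv <- sv_both(fit$meta$form, fit$meta$task_kind, res$kappa, rows,
                    fit$meta$effort_coding)
      p <- p_choose_hc(sv$hc, sv$lc, res$beta)
      rows$choice <- as.integer(stats::rbinom(nrow(rows), 1L, p))
      rows
    })
    tab <- do.call(rbind, pieces)
    rownames(tab) <- NULL
    out[[dd]] <- tab
  }
  restore_rng(rng)
  out
}

#' Group-level recovery report
#'
#' For each group-level parameter, the fraction of refit posterior means
#' that fall inside the reference fit's 95% HDI — the group-level
#' parameter-recovery check for posterior-predictive refits.
#'
#' @param refits List of `cbdm_fit` objects (refits of simulated data).
#' @param reference The reference `cbdm_fit`.
#' @param mass HDI mass.
#' @return Data frame: `parameter`, `ref_mean`, `ref_lower`, `ref_upper`,
#'   `frac_within`, `n_refits`.
#' @export
recover_group <- function(refits, reference, mass = 0.95) {
  stopifnot(inherits(reference, "cbdm_fit"))
  pars <- dimnames(reference$draws$group)[[3]]
  pars <- pars[!startsWith(pars, "sd_")]
  rows <- lapply(pars, function(p) {
    ref <- as.numeric(reference$draws$group[, , p])
    h <- hdi(ref, mass)
    means <- vapply(refits, function(f) {
      mean(as.numeric(f$draws$group[, , p]))
    }, numeric(1))
    data.frame(parameter = p, ref_mean = mean(ref),
               ref_lower = h$lower, ref_upper = h$upper,
               frac_within = mean(means >= h$lower & means <= h$upper),
               n_refits = length(refits), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subject-level recovery correlations
#'
#' Pearson correlation, per parameter, between the reference fit's
#' subject-level posterior means and the refit subject-level means
#' averaged across all refit datasets.
#'
#' @param refits List of `cbdm_fit` objects.
#' @param reference The reference `cbdm_fit`.
#' @return Data frame: `parameter`, `r` (averaged-refit correlation),
#'   `r_per_dataset` kept as an attribute `"per_dataset"` (matrix
#'   parameter x dataset).
#' @export
recover_subjects <- function(refits, reference) {
  stopifnot(inherits(reference, "cbdm_fit"))
  ref <- subject_means(reference)
  pars <- intersect(param_names, names(ref))
  per <- vapply(refits, function(f) {
    m <- subject_means(f)
    m <- m[match(ref$subject_id, m$subject_id), ]
    vapply(pars, function(p) stats::cor(ref[[p]], m[[p]]), numeric(1))
  }, numeric(length(pars)))
  per <- matrix(per, nrow = length(pars),
                dimnames = list(pars, NULL))
  avg <- Reduce(`+`, lapply(refits, function(f) {
    m <- subject_means(f)
    as.matrix(m[match(ref$subject_id, m$subject_id), pars])
  })) / length(refits)
  r <- vapply(pars, function(p) stats::cor(ref[[p]], avg[, p]),
              numeric(1))
  out <- data.frame(parameter = pars, r = unname(r),
                    stringsAsFactors = FALSE)
  attr(out, "per_dataset") <- per
  out
}

#' Bayesian correlation of two subject-level measures
#'
#' Posterior over the correlation coefficient of a bivariate normal
#' model, estimated by MCMC (JAGS) on standardized inputs with a uniform
#' prior on r and half-normal priors on the scales. The correlation is
#' "credible" when its 95% HDI excludes zero.
#'
#' @param x,y Numeric vectors of equal length (>= 3, non-constant).
#' @param settings A [fit_settings()] object (chains/draws reused).
#' @param mass HDI mass.
#' @return List: `mean`, `lower`, `upper`, `credible`, `draws`.
#' @export
bayesian_correlation <- function(x, y, settings = fit_settings("fast"),
                                 mass = 0.95) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("inputs must not be constant", call. = FALSE)
  }
  z <- cbind(scale(x)[, 1], scale(y)[, 1])
  model <- "
model {
  for (i in 1:n) {
    z[i, 1:2] ~ dmnorm(mu[1:2], omega[1:2, 1:2])
  }
  sigma[1, 1] <- s1 * s1
  sigma[2, 2] <- s2 * s2
  sigma[1, 2] <- r * s1 * s2
  sigma[2, 1] <- r * s1 * s2
  omega[1:2, 1:2] <- inverse(sigma[1:2, 1:2])
  r ~ dunif(-0.999, 0.999)
  mu[1] ~ dnorm(0, 0.25)
  mu[2] ~ dnorm(0, 0.25)
  s1 ~ dnorm(0, 1) T(0,)
  s2 ~ dnorm(0, 1) T(0,)
}"
  inits <- lapply(seq_len(settings$chains), function(ch) {
    list(r = 0, s1 = 1, s2 = 1,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = combine_seed(settings$seed, 9000L + ch))
  })
  jm <- rjags::jags.model(textConnection(model),
                          data = list(z = z, n = nrow(z)),
                          inits = inits, n.chains = settings$chains,
                          n.adapt = max(settings$adapt, 200L),
                          quiet = TRUE)
  update(jm, max(settings$warmup, 200L), progress.bar = "none")
  samp <- rjags::coda.samples(jm, "r",
                              n.iter = max(settings$draws, 1000L),
                              progress.bar = "none")
  draws <- as.numeric(unlist(lapply(samp, function(ch) ch[, "r"])))
  h <- hdi(draws, mass)
  list(mean = mean(draws), lower = h$lower, upper = h$upper,
       credible = h$lower > 0 || h$upper < 0, draws = draws)
}

#' Choice-curve summaries
#'
#' Mean high-cost choice rates per drug condition, per reward level and
#' per cost level, with standard errors — the summary surface for
#' visualising how choice behaviour varies with rewards and costs. For
#' the effort task the reward/cost dimension is the high-minus-low
#' difference (both options vary); for the delay task it is the absolute
#' level of the varying high-cost option.
#'
#' @param trials Trial table with choices.
#' @return Data frame: `condition`, `dimension` (`"reward"`/`"cost"`),
#'   `level`, `rate`, `se`, `n`.
#' @export
choice_curve_summaries <- function(trials) {
  if (any(is.na(trials$choice))) {
    stop("choice_curve_summaries requires observed choices",
         call. = FALSE)
  }
  task_kind <- trials$task_kind[1]
  if (task_kind == "effort") {
    rew <- trials$r_hc - trials$r_lc
    cost <- trials$c_hc - trials$c_lc
  } else {
    rew <- trials$r_hc
    cost <- trials$c_hc
  }
  cell <- function(dimension, value) {
    agg <- stats::aggregate(trials$choice,
                     by = list(condition = trials$condition,
                               level = value), FUN = mean)
    nn <- stats::aggregate(trials$choice,
                    by = list(condition = trials$condition,
                              level = value), FUN = length)
    data.frame(condition = agg$condition, dimension = dimension,
               level = agg$level, rate = agg$x,
               se = sqrt(pmax(agg$x * (1 - agg$x), 0) / nn$x),
               n = nn$x, stringsAsFactors = FALSE)
  }
  out <- rbind(cell("reward", rew), cell("cost", cost))
  out[order(out$dimension, out$condition, out$level), ]
}
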