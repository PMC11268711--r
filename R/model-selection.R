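#' @title PSIS-LOO model comparison
#' @description
#' Trial-based approximate leave-one-out cross-validation from the
#' pointwise log-likelihood matrix, using Pareto-smoothed importance
#' sampling (PSIS): for each trial the importance ratios 1/p(y_t | theta)
#' are tail-smoothed by expected order statistics of a fitted generalized
#' Pareto distribution before forming the LOO predictive density.
#' Reported on the deviance scale (LOOIC = -2 * elpd), lower is better.
#' @name psis-loo
NULL

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalized Pareto fit by the Zhang & Stephens (2009) profile-posterior
# method. Parameterized here by the tail index xi (positive = heavy
# tail) and scale sigma; the profile parameter is theta = -xi / sigma.
# The returned xi carries the weakly informative shrinkage towards 0.5
# used by standard PSIS implementations.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- max(x[max(floor(n / 4 + 0.5), 1)], x[n] * 1e-3)
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  # Zhang-Stephens k(theta) = -mean log(1 - theta x); same sign as theta
  k_of <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  l_theta <- n * (log(theta / k_of) + k_of - 1)
  w <- exp(l_theta - log_sum_exp(l_theta))
  theta_hat <- sum(theta * w)
  xi <- mean(log1p(-theta_hat * x))
  sigma <- -xi / theta_hat
  xi <- (xi * n + 0.5 * 10) / (n + 10)   # shrink xi towards 0.5
  list(k = xi, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance weights. Returns the
# smoothed (unnormalized) log weights and the tail-shape estimate khat.
psis_smooth <- function(lw) {
  s <- length(lw)
  tail_len <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  lw_max <- max(lw)
  if (tail_len < 5) {
    return(list(lw = pmin(lw, lw_max), k = NA_real_))
  }
  ord <- order(lw)
  tail_ids <- ord[(s - tail_len + 1):s]
  cutoff <- lw[ord[s - tail_len]]
  exceed <- exp(lw[tail_ids] - lw_max) - exp(cutoff - lw_max)
  if (all(exceed <= 0) || stats::sd(exceed) == 0) {
    return(list(lw = pmin(lw, lw_max), k = NA_real_))
  }
  fit <- gpd_fit(exceed)
  qq <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- vapply(qq, gpd_quantile, numeric(1),
                     k = fit$k, sigma = fit$sigma) +
    exp(cutoff - lw_max)
  lw_new <- lw
  lw_new[tail_ids[order(lw[tail_ids])]] <- log(smoothed) + lw_max
  lw_new <- pmin(lw_new, lw_max)   # never upweight beyond the raw max
  list(lw = lw_new, k = fit$k)
}

#' LOOIC from a pointwise log-likelihood matrix
#'
#' @param pointwise Draws x trials matrix of log-likelihood values (all
#'   finite), e.g. from [pointwise_loglik()].
#' @return A list of class `cbdm_loo`: `looic`, `se` (standard error of
#'   LOOIC), `elpd`, `elpd_se`, `pointwise` (per-trial elpd),
#'   `pareto_k` (per-trial tail-shape diagnostics), and
#'   `frac_high_k` (share of trials with khat > 0.7).
#' @export
looic <- function(pointwise) {
  pointwise <- as.matrix(pointwise)
  if (any(!is.finite(pointwise))) {
    stop("pointwise log-likelihood must be finite", call. = FALSE)
  }
  s <- nrow(pointwise)
  n <- ncol(pointwise)
  if (s == 1) {
    elpd_i <- as.numeric(pointwise)
    khat <- rep(NA_real_, n)
  } else {
    elpd_i <- numeric(n)
    khat <- numeric(n)
    for (t in seq_len(n)) {
      ll <- pointwise[, t]
      sm <- psis_smooth(-ll)          # log ratios: 1 / p(y_t | theta)
      lw <- sm$lw - log_sum_exp(sm$lw)
      elpd_i[t] <- log_sum_exp(lw + ll)
      khat[t] <- sm$k
    }
  }
  elpd <- sum(elpd_i)
  elpd_se <- sqrt(n * stats::var(elpd_i))
  structure(
    list(looic = -2 * elpd, se = 2 * elpd_se,
         elpd = elpd, elpd_se = elpd_se,
         pointwise = elpd_i, pareto_k = khat,
         frac_high_k = mean(khat > 0.7, na.rm = TRUE)),
    class = "cbdm_loo"
  )
}

#' @export
print.cbdm_loo <- function(x, ...) {
  cat("LOOIC:", round(x$looic, 1), "(SE", paste0(round(x$se, 1), ")"),
      "over", length(x$pointwise), "trials;",
      sprintf("%.1f%%", 100 * x$frac_high_k), "of khat > 0.7\n")
  invisible(x)
}

#' Compare discounting forms by LOOIC
#'
#' Fits each candidate form to the placebo-condition subset (the
#' convention for establishing the task's discounting form before adding
#' drug shifts) and ranks the forms by trial-based PSIS-LOO information
#' criterion.
#'
#' @param trials Trial table with choices.
#' @param task_kind `"effort"` or `"delay"` (default from table).
#' @param forms Character vector of candidate forms.
#' @param priors Optional [prior_spec()] shared by every form.
#' @param settings [fit_settings()] used for every fit.
#' @param condition Condition subset to fit (default `"PLC"`; `NULL`
#'   fits all rows).
#' @param effort_coding See [effort_code()].
#' @param max_draws Cap on draws used for the pointwise log-likelihood.
#' @return Data frame of class `cbdm_comparison`: `form`, `looic`,
#'   `looic_se`, `frac_high_k`, `rank` (1 = best), ordered by rank.
#' @export
compare_forms <- function(trials, task_kind = NULL,
                          forms = c("linear", "parabolic", "hyperbolic",
                                    "exponential"),
                          priors = NULL,
                          settings = fit_settings("fast"),
                          condition = "PLC",
                          effort_coding = "decile",
                          max_draws = 400) {
  if (is.null(task_kind)) task_kind <- trials$task_kind[1]
  sub <- if (is.null(condition)) trials else
    trials[trials$condition %in% condition, , drop = FALSE]
  if (!nrow(sub)) stop("no trials left after condition subset",
                       call. = FALSE)
  rows <- lapply(forms, function(f) {
    fit <- fit_hierarchical(sub, form = f, task_kind = task_kind,
                            priors = priors, settings = settings,
                            effort_coding = effort_coding)
    ll <- pointwise_loglik(fit, sub, max_draws = max_draws)
    lo <- looic(ll)
    data.frame(form = f, looic = lo$looic, looic_se = lo$se,
               frac_high_k = lo$frac_high_k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(out$looic, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("cbdm_comparison", "data.frame")
  out
}
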