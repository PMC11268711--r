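test_that("hdi matches brute-force window minimization and normal theory", {
  expect_equal(hdi(rep(3.2, 10))[c("lower", "upper")],
               list(lower = 3.2, upper = 3.2))
  set.seed(21)
  x <- rnorm(1e6)
  h <- hdi(x)
  expect_lt(abs(h$lower - qnorm(0.025)), 0.02)
  expect_lt(abs(h$upper - qnorm(0.975)), 0.02)
  # oracle: exhaustive scan over all sorted windows
  brute_hdi <- function(x, mass) {
    x <- sort(x)
    n <- length(x)
    m <- ceiling(mass * n)
    best <- c(Inf, NA, NA)
    for (i in 1:(n - m + 1)) {
      w <- x[i + m - 1] - x[i]
      if (w < best[1]) best <- c(w, x[i], x[i + m - 1])
    }
    best[2:3]
  }
  for (rep in 1:10) {
    y <- switch(rep %% 3 + 1, rnorm(200), rexp(150), rt(100, df = 3))
    for (mass in c(0.5, 0.8, 0.95)) {
      h <- hdi(y, mass)
      expect_equal(c(h$lower, h$upper), brute_hdi(y, mass))
    }
  }
  expect_error(hdi(3), "2 finite")
})

test_that("split r-hat separates converged from divergent chains", {
  set.seed(31)
  same <- cbind(rnorm(2000), rnorm(2000), rnorm(2000))
  expect_lt(rhat(same), 1.01)
  apart <- cbind(rnorm(500), rnorm(500) + 100)
  expect_gt(rhat(apart), 10)
  # a single trending chain is caught by splitting
  trend <- cbind(seq(0, 5, length.out = 1000) + rnorm(1000, 0, 0.1),
                 seq(0, 5, length.out = 1000) + rnorm(1000, 0, 0.1))
  expect_gt(rhat(trend), 1.1)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_equal(rhat(matrix(5, 100, 2)), 1)
})

test_that("r-hat agrees with the textbook between/within formula", {
  set.seed(32)
  draws <- matrix(rnorm(200, c(0, 0.3)), 100, 2)
  # independent hand computation on the 4 split half-chains
  halves <- cbind(draws[1:50, 1], draws[51:100, 1],
                  draws[1:50, 2], draws[51:100, 2])
  n <- 50; m <- 4
  W <- mean(apply(halves, 2, var))
  B <- n * var(colMeans(halves))
  expected <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(rhat(draws), expected, tolerance = 1e-12)
})

test_that("summary table reports sign probabilities and hdi bounds", {
  gm <- c(kappa = 0.1, beta = 0.7, s_kappa_hal = 0.01,
          s_kappa_bip = -0.01, s_beta_hal = -0.09, s_beta_bip = 0.13,
          sd_kappa = 0.05, sd_beta = 0.2, sd_s_kappa_hal = 0.01,
          sd_s_kappa_bip = 0.01, sd_s_beta_hal = 0.04,
          sd_s_beta_bip = 0.06)
  sm <- matrix(rnorm(6 * 6, 0.1, 0.01), 6, 6,
               dimnames = list(NULL, c("kappa_plc", "beta_plc",
                                       "s_kappa_hal", "s_kappa_bip",
                                       "s_beta_hal", "s_beta_bip")))
  set.seed(41)
  fit <- fake_fit(gm, sm, jitter = 0.001)
  tab <- summarize_fit(fit)
  expect_equal(tab$parameter,
               c("kappa", "beta", "s_kappa_hal", "s_kappa_bip",
                 "s_beta_hal", "s_beta_bip"))
  expect_true(all(tab$lower <= tab$mean & tab$mean <= tab$upper))
  full <- summarize_fit(fit, include_sd = TRUE)
  expect_equal(nrow(full), 12)
  # sign probability equals the direct count
  x <- as.numeric(fit$draws$group[, , "s_kappa_bip"])
  expect_equal(tab$p_gt_0[tab$parameter == "s_kappa_bip"],
               sum(x > 0) / length(x))
  # symmetric zero-centered draws give p close to one half
  fit0 <- fake_fit(c(gm[1:5], s_beta_bip = 0,
                     gm[7:12]), sm, jitter = 0.05)
  p0 <- summarize_fit(fit0)$p_gt_0[6]
  expect_lt(abs(p0 - 0.5), 0.1)
})

test_that("hierarchical fit recovers a small synthetic cohort", {
  co <- simulate_cohort(group_truth("effort", n_subjects = 6), seed = 2)
  fit <- fit_hierarchical(co$trials, "parabolic",
                          settings = tiny_settings(seed = 2))
  expect_s3_class(fit, "cbdm_fit")
  expect_equal(dim(fit$draws$group), c(150, 2, 12))
  expect_equal(dim(fit$draws$subject), c(150, 2, 6, 6))
  expect_equal(length(fit$diagnostics$rhat), 12)
  tab <- summarize_fit(fit)
  # truth within a generous window of the posterior for baselines
  expect_lt(abs(tab$mean[tab$parameter == "kappa"] - 0.102), 0.06)
  expect_lt(abs(tab$mean[tab$parameter == "beta"] - 0.667), 0.35)
  # subject-level means track the generating parameters
  sm <- subject_means(fit)
  expect_gt(cor(sm$kappa_plc, co$subjects$kappa_plc), 0.85)
  expect_gt(cor(sm$beta_plc, co$subjects$beta_plc), 0.85)
  # persistence writes the documented layout
  dir <- withr::local_tempdir()
  write_fit(fit, dir)
  expect_true(all(file.exists(file.path(dir,
    c("group_draws.csv", "subject_means.csv", "summary.csv",
      "meta.json")))))
  # identical settings and seed reproduce the draws
  fit2 <- fit_hierarchical(co$trials, "parabolic",
                           settings = tiny_settings(seed = 2))
  expect_equal(fit$draws$group, fit2$draws$group)
})

test_that("placebo-only data fit the shift-free model", {
  co <- simulate_cohort(group_truth("effort", n_subjects = 5),
                        spec = small_effort_spec(), seed = 3)
  plc <- co$trials[co$trials$condition == "PLC", ]
  fit <- fit_hierarchical(plc, "parabolic",
                          settings = tiny_settings(seed = 3))
  expect_false(fit$meta$with_shifts)
  expect_equal(dimnames(fit$draws$group)[[3]],
               c("kappa", "beta", "sd_kappa", "sd_beta"))
  expect_equal(nrow(summarize_fit(fit)), 2)
})

test_that("pointwise log-likelihood matches the model's own evaluator", {
  co <- simulate_cohort(group_truth("effort", n_subjects = 3),
                        spec = small_effort_spec(), seed = 4)
  fit <- fit_hierarchical(co$trials, "parabolic",
                          settings = tiny_settings(seed = 4))
  ll <- pointwise_loglik(fit, co$trials, max_draws = 25)
  expect_equal(dim(ll), c(25, nrow(co$trials)))
  expect_true(all(is.finite(ll)))
  # oracle: rebuild one draw's parameter set and call trial_loglik
  arr <- fit$draws$subject
  d <- dim(arr)
  flat <- matrix(arr, d[1] * d[2], d[3] * d[4])
  pars <- dimnames(arr)[[4]]
  keep <- unique(round(seq(1, d[1] * d[2], length.out = 25)))
  for (probe in c(1, 13, 25)) {
    s <- keep[probe]
    rows <- lapply(seq_len(d[3]), function(i) {
      prm <- lapply(pars, function(p) {
        flat[s, (match(p, pars) - 1) * d[3] + i]
      })
      names(prm) <- pars
      sub <- co$trials[co$trials$subject_id == fit$subject_ids[i], ]
      trial_loglik("parabolic", prm, sub)
    })
    ref <- numeric(nrow(co$trials))
    for (i in seq_len(d[3])) {
      ref[co$trials$subject_id == fit$subject_ids[i]] <- rows[[i]]
    }
    expect_lt(max(abs(ll[probe, ] - ref)), 1e-10)
  }
})

test_that("subject-level estimates shrink towards the group mean", {
  co <- simulate_cohort(group_truth("effort", n_subjects = 12), seed = 6)
  plc <- co$trials[co$trials$condition == "PLC", ]
  fit <- fit_hierarchical(plc, "parabolic",
                          settings = fit_settings("fast", draws = 500,
                                                  seed = 6))
  sm <- subject_means(fit)
  gmean <- mean(as.numeric(fit$draws$group[, , "kappa"]))
  # no-pooling maximum likelihood per subject
  mle <- vapply(fit$subject_ids, function(sid) {
    sub <- plc[plc$subject_id == sid, ]
    nll <- function(th) -sum(trial_loglik("parabolic",
      subject_params(th[1], exp(th[2])), sub))
    exp_fit <- stats::optim(c(0.1, log(0.7)), nll,
                            control = list(reltol = 1e-10))
    exp_fit$par[1]
  }, numeric(1))
  # tolerance covers Monte-Carlo error in the posterior means
  eps <- 0.1 * abs(mle - gmean) + 0.003
  between <- (sm$kappa_plc >= pmin(mle, gmean) - eps) &
    (sm$kappa_plc <= pmax(mle, gmean) + eps)
  expect_gte(mean(between), 0.9)
})

test_that("a single data-rich subject is estimated consistently", {
  # large-data consistency: one placebo subject, many trials; the
  # posterior mean must approach the grid-search maximum likelihood
  spec <- task_spec("effort", n_blocks = 80, trials_per_block = 25)
  d <- build_effort_design(spec, seed = 12)
  d$subject_id <- "S001"
  truth <- subject_params(0.11, 0.7)
  d <- simulate_choices(truth, "PLC", d, "parabolic", seed = 12)
  fit <- fit_hierarchical(d, "parabolic",
                          settings = fit_settings("fast", seed = 12))
  post_kappa <- subject_means(fit)$kappa_plc
  # oracle: profile grid search over (kappa, beta)
  grid_k <- seq(0.05, 0.17, by = 0.001)
  grid_b <- seq(0.3, 1.2, by = 0.02)
  ll <- outer(grid_k, grid_b, Vectorize(function(k, b) {
    sum(trial_loglik("parabolic", subject_params(k, b), d))
  }))
  mle_kappa <- grid_k[which(ll == max(ll), arr.ind = TRUE)[1]]
  expect_lt(abs(post_kappa - mle_kappa) / mle_kappa, 0.05)
  expect_lt(abs(post_kappa - 0.11) / 0.11, 0.05)
})
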