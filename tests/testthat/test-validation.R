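make_small_fit <- function(seed = 9, n_subjects = 4) {
  co <- simulate_cohort(group_truth("effort", n_subjects = n_subjects),
                        spec = small_effort_spec(), seed = seed)
  fit <- fit_hierarchical(co$trials, "parabolic",
                          settings = tiny_settings(seed = seed))
  list(cohort = co, fit = fit)
}

test_that("posterior-predictive datasets have the requested shape", {
  sf <- make_small_fit()
  pp <- posterior_predictive_datasets(sf$fit, sf$cohort$trials,
                                      n_total = 20, n_selected = 3,
                                      seed = 1)
  expect_length(pp, 3)
  for (tab in pp) {
    expect_equal(nrow(tab), nrow(sf$cohort$trials))
    expect_true(all(tab$choice %in% 0:1))
    expect_equal(sort(unique(tab$subject_id)), sf$fit$subject_ids)
  }
  expect_error(
    posterior_predictive_datasets(sf$fit, sf$cohort$trials,
                                  n_total = 5, n_selected = 6),
    "n_selected")
  # single-dataset degenerate call passes through
  one <- posterior_predictive_datasets(sf$fit, sf$cohort$trials,
                                       n_total = 1, n_selected = 1,
                                       seed = 2)
  expect_length(one, 1)
  # reproducible under the seed
  pp2 <- posterior_predictive_datasets(sf$fit, sf$cohort$trials,
                                       n_total = 20, n_selected = 3,
                                       seed = 1)
  expect_identical(pp, pp2)
})

test_that("a degenerate posterior leaves only choice noise", {
  gm <- c(kappa = 0.1, beta = 0.7, s_kappa_hal = 0, s_kappa_bip = 0,
          s_beta_hal = 0, s_beta_bip = 0,
          sd_kappa = 0.01, sd_beta = 0.01, sd_s_kappa_hal = 0.01,
          sd_s_kappa_bip = 0.01, sd_s_beta_hal = 0.01,
          sd_s_beta_bip = 0.01)
  sm <- matrix(rep(c(0.1, 0.7, 0, 0, 0, 0), each = 2), 2, 6,
               dimnames = list(NULL, c("kappa_plc", "beta_plc",
                                       "s_kappa_hal", "s_kappa_bip",
                                       "s_beta_hal", "s_beta_bip")))
  fit <- fake_fit(gm, sm)
  d <- build_effort_design(small_effort_spec(), seed = 1)
  design <- do.call(rbind, lapply(c("S001", "S002"), function(sid) {
    dd <- d; dd$subject_id <- sid; dd$condition <- "PLC"; dd
  }))
  pp <- posterior_predictive_datasets(fit, design, n_total = 4,
                                      n_selected = 2, seed = 3)
  # identical parameters -> same per-trial probabilities; datasets
  # differ only by Bernoulli noise, so rates agree within binomial CI
  r1 <- mean(pp[[1]]$choice); r2 <- mean(pp[[2]]$choice)
  expect_lt(abs(r1 - r2), 4 * sqrt(0.5 / nrow(pp[[1]])))
})

test_that("group recovery fractions hit the trivial bounds", {
  gm <- c(kappa = 0.1, beta = 0.7, s_kappa_hal = 0.01,
          s_kappa_bip = -0.01, s_beta_hal = -0.09, s_beta_bip = 0.13,
          sd_kappa = 0.05, sd_beta = 0.2, sd_s_kappa_hal = 0.01,
          sd_s_kappa_bip = 0.01, sd_s_beta_hal = 0.04,
          sd_s_beta_bip = 0.06)
  sm <- matrix(0.1, 3, 6,
               dimnames = list(NULL, c("kappa_plc", "beta_plc",
                                       "s_kappa_hal", "s_kappa_bip",
                                       "s_beta_hal", "s_beta_bip")))
  set.seed(61)
  reference <- fake_fit(gm, sm, jitter = 0.5)   # very wide HDIs
  refits <- list(fake_fit(gm, sm, jitter = 0.01),
                 fake_fit(gm, sm, jitter = 0.01))
  rep1 <- recover_group(refits, reference)
  expect_equal(rep1$frac_within, rep(1, 6))
  # refits displaced by many reference SDs fall outside
  shifted <- lapply(refits, function(f) {
    f$draws$group <- f$draws$group + 50
    f
  })
  rep0 <- recover_group(shifted, reference)
  expect_equal(rep0$frac_within, rep(0, 6))
})

test_that("subject recovery correlation hits the trivial bounds", {
  gm <- c(kappa = 0.1, beta = 0.7, s_kappa_hal = 0, s_kappa_bip = 0,
          s_beta_hal = 0, s_beta_bip = 0,
          sd_kappa = 0.05, sd_beta = 0.2, sd_s_kappa_hal = 0.01,
          sd_s_kappa_bip = 0.01, sd_s_beta_hal = 0.01,
          sd_s_beta_bip = 0.01)
  set.seed(62)
  sm <- matrix(rnorm(60), 10, 6,
               dimnames = list(NULL, c("kappa_plc", "beta_plc",
                                       "s_kappa_hal", "s_kappa_bip",
                                       "s_beta_hal", "s_beta_bip")))
  reference <- fake_fit(gm, sm)
  identical_refit <- fake_fit(gm, sm)
  r1 <- recover_subjects(list(identical_refit), reference)
  expect_true(all(r1$r > 0.999))
  noise <- fake_fit(gm, matrix(rnorm(60), 10, 6,
                               dimnames = dimnames(sm)))
  r0 <- recover_subjects(replicate(4, noise, simplify = FALSE),
                         reference)
  expect_true(all(abs(r0$r) < 0.8))
  expect_equal(dim(attr(r0, "per_dataset")), c(6, 4))
})

test_that("bayesian correlation concentrates correctly", {
  set.seed(63)
  x <- rnorm(50)
  bc <- bayesian_correlation(x, x + rnorm(50, 0, 1e-3),
                             settings = fit_settings("fast", seed = 1))
  expect_gt(bc$mean, 0.95)
  expect_true(bc$credible)
  # posterior mean tracks the sample correlation closely at large n
  x2 <- rnorm(500); y2 <- 0.4 * x2 + rnorm(500, 0, sqrt(1 - 0.16))
  bc2 <- bayesian_correlation(x2, y2,
                              settings = fit_settings("fast", seed = 2))
  expect_lt(abs(bc2$mean - cor(x2, y2)), 0.05)
  expect_error(bayesian_correlation(rep(1, 10), rnorm(10)), "constant")
  expect_error(bayesian_correlation(1:2, 1:2), "length")
})

test_that("independent inputs rarely yield a credible correlation", {
  set.seed(64)
  flags <- vapply(1:10, function(i) {
    x <- rnorm(62); y <- rnorm(62)
    bayesian_correlation(x, y,
                         settings = fit_settings("fast",
                                                 seed = i))$credible
  }, logical(1))
  expect_gte(mean(!flags), 0.9)
})

test_that("choice curves match a hand-grouped oracle", {
  d <- build_effort_design(task_spec("effort", n_blocks = 1,
                                     trials_per_block = 30), seed = 5)
  d$subject_id <- "S001"
  d$condition <- rep(c("PLC", "HAL", "BIP"), each = 10)
  set.seed(65)
  d$choice <- rbinom(30, 1, 0.5)
  cc <- choice_curve_summaries(d)
  # manual check of one reward-difference cell
  rew <- d$r_hc - d$r_lc
  for (cond in c("PLC", "HAL", "BIP")) {
    lv <- rew[d$condition == cond][1]
    manual <- mean(d$choice[d$condition == cond & rew == lv])
    got <- cc$rate[cc$condition == cond & cc$dimension == "reward" &
                     cc$level == lv]
    expect_equal(got, manual)
  }
  # all-ones input gives unit rates everywhere
  d$choice <- 1L
  cc1 <- choice_curve_summaries(d)
  expect_true(all(cc1$rate == 1))
  expect_true(all(cc1$se == 0))
})

test_that("posterior-predictive choice rates cover the observed rate", {
  sf <- make_small_fit(seed = 10, n_subjects = 4)
  observed <- mean(sf$cohort$trials$choice)
  pp <- posterior_predictive_datasets(sf$fit, sf$cohort$trials,
                                      n_total = 200, n_selected = 200,
                                      seed = 4)
  rates <- vapply(pp, function(tab) mean(tab$choice), numeric(1))
  rank <- mean(rates <= observed)
  expect_gte(rank, 0.025)
  expect_lte(rank, 0.975)
})
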