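forms <- c("linear", "parabolic", "hyperbolic", "exponential")

test_that("subjective values match direct evaluation of the formulas", {
  # parabolic effort: 16 - 0.102 * 8^2
  expect_equal(sv_effort("parabolic", 0.102, 16, 8), 9.472)
  # hyperbolic delay at the design extremes, log-space kappa
  expect_equal(sv_delay("hyperbolic", -4.621, 260, 60),
               260 / (1 + exp(-4.621) * 60), tolerance = 1e-12)
  expect_equal(sv_delay("linear", log(0.5), 100, 10), 95)
  expect_equal(sv_delay("exponential", log(0.1), 100, 10),
               100 * exp(-1), tolerance = 1e-12)
  expect_equal(sv_effort("hyperbolic", 0.25, 12, 4), 12 / 2)
})

test_that("zero cost returns the full reward for every form", {
  for (f in forms) {
    expect_equal(sv_delay(f, -2, 37.5, 0), 37.5)
    expect_equal(sv_effort(f, 0.3, 11, 0), 11)
  }
  # no-discounting limits
  expect_equal(sv_delay("hyperbolic", -50, 260, 60), 260,
               tolerance = 1e-6)
  expect_true(all(sv_effort("parabolic", 0, 7, c(0, 2, 8)) == 7))
})

test_that("subjective value is monotone in cost and reward", {
  efforts <- seq(0, 8, by = 2)
  delays <- c(0, 1, 5, 30, 60)
  for (f in forms) {
    sv_e <- sv_effort(f, 0.1, 10, efforts)
    expect_true(all(diff(sv_e) < 0))
    sv_d <- sv_delay(f, -3, 100, delays)
    expect_true(all(diff(sv_d) < 0))
    expect_true(all(diff(sv_delay(f, -3, c(30, 60, 100), 10)) > 0))
  }
  expect_error(sv_delay("hyperbolic", -3, 100, -1), "non-negative")
  expect_error(sv_effort("parabolic", 0.1, 10, -2), "non-negative")
})

test_that("condition resolution applies additive shifts", {
  p <- subject_params(0.102, 0.667, s_kappa_hal = 0.013,
                      s_kappa_bip = -0.012, s_beta_hal = -0.089,
                      s_beta_bip = 0.127)
  plc <- resolve_condition(p, "PLC")
  expect_equal(plc$kappa, 0.102)
  expect_equal(plc$beta, 0.667)
  expect_equal(resolve_condition(p, "HAL")$kappa, 0.115)
  expect_equal(resolve_condition(p, "BIP")$kappa, 0.090)
  expect_equal(resolve_condition(p, "HAL")$beta, 0.667 - 0.089)
  # vectorized over rows
  res <- resolve_condition(p, c("PLC", "HAL", "BIP"))
  expect_equal(res$kappa, c(0.102, 0.115, 0.090))
  expect_error(resolve_condition(p, "XXX"), "condition")
})

test_that("resolved beta is floored and flagged when shifts overwhelm it", {
  p <- subject_params(0.1, 0.05, s_beta_hal = -0.2)
  res <- resolve_condition(p, "HAL")
  expect_equal(res$beta, 1e-6)
  expect_false(res$beta_valid)
  expect_true(resolve_condition(p, "PLC")$beta_valid)
})

test_that("softmax choice rule is symmetric, bounded and overflow-safe", {
  expect_equal(p_choose_hc(5, 5, 0.7), 0.5)
  expect_equal(p_choose_hc(1, 0, 0.667), stats::plogis(0.667))
  # complement identity over random pairs
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(1, 0, 10); b <- rnorm(1, 0, 10); bet <- runif(1, 0, 2)
    expect_equal(p_choose_hc(a, b, bet) + p_choose_hc(b, a, bet), 1,
                 tolerance = 1e-12)
  }
  # beta = 0 ignores the values entirely
  expect_equal(p_choose_hc(1000, -1000, 0), 0.5)
  # extreme value differences stay strictly inside (0, 1)
  p_hi <- p_choose_hc(1000, 0, 1)
  p_lo <- p_choose_hc(0, 1000, 1)
  expect_lt(p_hi, 1)
  expect_gt(p_lo, 0)
  expect_error(p_choose_hc(Inf, 0, 1), "finite")
})

test_that("effort coding maps MVC fractions onto model units", {
  fr <- c(0, 0.2, 0.4, 0.6, 0.8)
  expect_equal(effort_code(fr, "decile"), c(0, 2, 4, 6, 8))
  expect_equal(effort_code(fr, "percent"), c(0, 20, 40, 60, 80))
  expect_equal(effort_code(fr, "fraction"), fr)
  expect_equal(effort_code(fr, "level"), 0:4)
})

test_that("vectorized log-likelihood equals a naive per-trial loop", {
  set.seed(42)
  p <- subject_params(0.09, 0.7, 0.02, -0.01, -0.1, 0.1)
  d <- build_effort_design(seed = 9)
  d$condition <- sample(c("PLC", "HAL", "BIP"), nrow(d), replace = TRUE)
  d$choice <- rbinom(nrow(d), 1, 0.5)
  ll <- trial_loglik("parabolic", p, d)
  # independent brute-force loop over rows
  loop <- vapply(seq_len(nrow(d)), function(i) {
    k <- p$kappa_plc +
      (d$condition[i] == "HAL") * p$s_kappa_hal +
      (d$condition[i] == "BIP") * p$s_kappa_bip
    b <- p$beta_plc +
      (d$condition[i] == "HAL") * p$s_beta_hal +
      (d$condition[i] == "BIP") * p$s_beta_bip
    svh <- d$r_hc[i] - k * (d$c_hc[i] * 10)^2
    svl <- d$r_lc[i] - k * (d$c_lc[i] * 10)^2
    pr <- 1 / (1 + exp(-b * (svh - svl)))
    if (d$choice[i] == 1) log(pr) else log(1 - pr)
  }, numeric(1))
  expect_lt(max(abs(ll - loop)), 1e-10)
  expect_true(all(is.finite(ll)))
  # delay task variant with the immediate option fixed at face value
  dd <- build_delay_design(seed = 9)
  dd$condition <- "PLC"
  dd$choice <- rbinom(nrow(dd), 1, 0.5)
  lld <- trial_loglik("hyperbolic", subject_params(-4.6, 0.05), dd)
  svh <- dd$r_hc / (1 + exp(-4.6) * dd$c_hc)
  pr <- stats::plogis(0.05 * (svh - 20))
  expect_lt(max(abs(lld - ifelse(dd$choice == 1, log(pr), log1p(-pr)))),
            1e-10)
  expect_error(trial_loglik("parabolic", p, build_effort_design(seed = 1)),
               "choice")
})

test_that("log-likelihood stays finite under degenerate probabilities", {
  p <- subject_params(0, 50)  # near-deterministic chooser
  d <- build_effort_design(seed = 2)
  d$condition <- "PLC"
  d$choice <- 0L  # always the low-cost option despite higher HC value
  ll <- trial_loglik("parabolic", p, d)
  expect_true(all(is.finite(ll)))
})
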