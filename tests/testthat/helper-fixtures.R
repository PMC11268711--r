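# Shared fixtures, built in code at test time.

# Small effort design spec: 2 blocks of 25 keeps unit-test fits cheap
# while preserving the 5 x 5 level structure.
small_effort_spec <- function() {
  task_spec("effort", n_blocks = 2, trials_per_block = 25)
}

# Reduced delay spec: 5 rewards x 3 delays, one block.
small_delay_spec <- function() {
  task_spec("delay",
            reward_levels = c(22, 30, 50, 100, 260),
            cost_levels = c(1, 8, 60),
            n_blocks = 1)
}

tiny_settings <- function(seed = 1) {
  fit_settings("fast", adapt = 100, warmup = 100, draws = 150,
               seed = seed)
}

# Hand-built fit skeleton with specified constant group/subject draws;
# used to test reporting code paths without MCMC.
fake_fit <- function(group_means, subject_matrix, n_iter = 50,
                     n_chain = 2, jitter = 0) {
  gp <- names(group_means)
  group <- array(rep(group_means, each = n_iter * n_chain),
                 c(n_iter, n_chain, length(gp)),
                 dimnames = list(NULL, NULL, gp))
  if (jitter > 0) {
    group <- group + array(stats::rnorm(length(group), 0, jitter),
                           dim(group))
  }
  sp <- colnames(subject_matrix)
  S <- nrow(subject_matrix)
  subject <- array(NA_real_, c(n_iter, n_chain, S, length(sp)),
                   dimnames = list(NULL, NULL,
                                   sprintf("S%03d", seq_len(S)), sp))
  for (i in seq_len(S)) {
    for (j in seq_along(sp)) {
      subject[, , i, j] <- subject_matrix[i, j] +
        stats::rnorm(n_iter * n_chain, 0, jitter)
    }
  }
  structure(
    list(draws = list(group = group, subject = subject),
         subject_ids = sprintf("S%03d", seq_len(S)),
         diagnostics = list(rhat = stats::setNames(rep(1, length(gp)),
                                                   gp),
                            max_rhat = 1, converged = TRUE),
         meta = list(form = "parabolic", task_kind = "effort",
                     with_shifts = TRUE,
                     settings = fit_settings("fast"),
                     priors = prior_spec("effort"),
                     effort_coding = "decile", runtime_s = 0)),
    class = "cbdm_fit"
  )
}

fake_glmm <- function(term_means, term_sds, n_iter = 400, n_chain = 2) {
  terms <- names(term_means)
  arr <- array(NA_real_, c(n_iter, n_chain, length(terms)),
               dimnames = list(NULL, NULL, terms))
  for (j in seq_along(terms)) {
    arr[, , j] <- stats::rnorm(n_iter * n_chain, term_means[j],
                               term_sds[j])
  }
  structure(
    list(draws = arr, sd_draws = arr, terms = terms,
         diagnostics = list(rhat = stats::setNames(rep(1, length(terms)),
                                                   terms),
                            separation = FALSE),
         meta = list(settings = fit_settings("fast"), runtime_s = 0,
                     spec = regression_spec("effort"),
                     scaling = list())),
    class = "cbdm_glmm"
  )
}
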