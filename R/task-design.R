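#' Task specification for a cost-benefit discounting task
#'
#' Describes one of the two binary-choice tasks: the grip-force effort task
#' (rewards in "apples", costs as fractions of the subject's maximum
#' voluntary contraction, MVC) or the monetary delay task (rewards in euro,
#' costs in days, with a constant immediate low-cost option).
#'
#' Defaults reproduce the standard designs: the effort task crosses 5 reward
#' levels (2--16 apples) with 5 effort levels (0--80% MVC) over 5 blocks of
#' 25 trials (125 trials); the delay task crosses 15 reward levels
#' (20.20--260 euro) with 7 delays (1--60 days), each of the 105 unique
#' high-cost combinations appearing once per block, over 2 blocks
#' (210 trials), against a fixed immediate 20 euro option.
#'
#' @param task_kind `"effort"` or `"delay"`.
#' @param reward_levels Ordered numeric vector of reward levels for the
#'   varying (high-cost) option.
#' @param cost_levels Ordered numeric vector of cost levels (fraction of MVC
#'   for effort; days for delay).
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block.
#' @param low_cost_fixed For the delay task, `c(reward, cost)` of the
#'   constant low-cost option. Ignored for the effort task.
#' @return A list of class `cbdm_task_spec`.
#' @examples
#' task_spec("effort")
#' task_spec("delay")
#' @export
task_spec <- function(task_kind = c("effort", "delay"),
                      reward_levels = NULL,
                      cost_levels = NULL,
                      n_blocks = NULL,
                      trials_per_block = NULL,
                      low_cost_fixed = NULL) {
  task_kind <- match.arg(task_kind)
  if (task_kind == "effort") {
    if (is.null(reward_levels)) reward_levels <- c(2, 4, 8, 12, 16)
    if (is.null(cost_levels)) cost_levels <- c(0, 0.2, 0.4, 0.6, 0.8)
    if (is.null(n_blocks)) n_blocks <- 5L
    if (is.null(trials_per_block)) trials_per_block <- 25L
    low_cost_fixed <- NULL
  } else {
    if (is.null(reward_levels)) {
      reward_levels <- c(20.20, 20.40, 21, 22, 24, 30, 36, 40,
                         50, 60, 80, 100, 140, 200, 260)
    }
    if (is.null(cost_levels)) cost_levels <- c(1, 2, 3, 5, 8, 30, 60)
    if (is.null(n_blocks)) n_blocks <- 2L
    if (is.null(trials_per_block)) {
      trials_per_block <- length(reward_levels) * length(cost_levels)
    }
    if (is.null(low_cost_fixed)) low_cost_fixed <- c(20, 0)
  }
  if (anyDuplicated(reward_levels) || anyDuplicated(cost_levels)) {
    stop("invalid task spec: duplicate reward or cost levels", call. = FALSE)
  }
  if (is.unsorted(reward_levels, strictly = TRUE) ||
      is.unsorted(cost_levels, strictly = TRUE)) {
    stop("invalid task spec: levels must be strictly increasing",
         call. = FALSE)
  }
  if (n_blocks < 1 || trials_per_block < 1) {
    stop("invalid task spec: n_blocks and trials_per_block must be >= 1",
         call. = FALSE)
  }
  structure(
    list(task_kind = task_kind,
         reward_levels = reward_levels,
         cost_levels = cost_levels,
         n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         low_cost_fixed = low_cost_fixed),
    class = "cbdm_task_spec"
  )
}

trial_table_cols <- c("subject_id", "condition", "task_kind", "block",
                      "trial_index", "r_hc", "c_hc", "r_lc", "c_lc",
                      "choice")

new_trial_table <- function(task_kind, block, r_hc, c_hc, r_lc, c_lc,
                            subject_id = NA_character_,
                            condition = NA_character_) {
  n <- length(r_hc)
  data.frame(
    subject_id = rep_len(subject_id, n),
    condition = rep_len(condition, n),
    task_kind = rep_len(task_kind, n),
    block = as.integer(block),
    trial_index = seq_len(n),
    r_hc = r_hc, c_hc = c_hc, r_lc = r_lc, c_lc = c_lc,
    choice = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
}

#' Build an effort-task trial list
#'
#' Each trial pairs a high-reward/high-effort option with a
#' low-reward/low-effort option. Reward and effort pairs are drawn
#' independently; with `balanced = FALSE` (the default), every trial samples
#' uniformly with replacement from the 10 x 10 ordered (reward pair, effort
#' pair) combinations. With `balanced = TRUE`, all 100 combinations appear
#' once and the remaining trials are uniform resamples, giving exact
#' coverage of the difference grid.
#'
#' @param spec An effort [task_spec()].
#' @param seed Integer seed; identical `(spec, seed)` give identical tables.
#' @param balanced Use the balanced 100-unique + resample layout.
#' @return A trial table (one row per trial) with `r_hc > r_lc` and
#'   `c_hc > c_lc` on every row and no choices filled in.
#' @examples
#' d <- build_effort_design(task_spec("effort"), seed = 1)
#' nrow(d) # 125
#' @export
build_effort_design <- function(spec = task_spec("effort"), seed = 1L,
                                balanced = FALSE) {
  stopifnot(inherits(spec, "cbdm_task_spec"))
  if (spec$task_kind != "effort") {
    stop("spec must describe the effort task", call. = FALSE)
  }
  if (length(spec$reward_levels) < 2 || length(spec$cost_levels) < 2) {
    stop("invalid task spec: need at least 2 levels per dimension",
         call. = FALSE)
  }
  n_trials <- spec$n_blocks * spec$trials_per_block
  r_pairs <- t(utils::combn(spec$reward_levels, 2))   # (low, high)
  c_pairs <- t(utils::combn(spec$cost_levels, 2))
  n_combo <- nrow(r_pairs) * nrow(c_pairs)
  rng <- local_rng(seed)
  if (balanced) {
    base <- seq_len(n_combo)
    extra <- if (n_trials > n_combo) {
      sample(n_combo, n_trials - n_combo, replace = TRUE)
    } else integer(0)
    combo <- sample(c(base, extra))[seq_len(n_trials)]
  } else {
    combo <- sample(n_combo, n_trials, replace = TRUE)
  }
  ri <- (combo - 1L) %/% nrow(c_pairs) + 1L
  ci <- (combo - 1L) %% nrow(c_pairs) + 1L
  restore_rng(rng)
  tab <- new_trial_table(
    task_kind = "effort",
    block = rep(seq_len(spec$n_blocks), each = spec$trials_per_block),
    r_hc = r_pairs[ri, 2], c_hc = c_pairs[ci, 2],
    r_lc = r_pairs[ri, 1], c_lc = c_pairs[ci, 1]
  )
  tab
}

#' Build a delay-task trial list
#'
#' Every block contains each reward x delay combination of the high-cost
#' option exactly once (105 combinations under the default levels); the
#' low-cost option is constant (20 euro, immediately). Trial order is a
#' seeded pseudorandom permutation keyed by `(seed, session_index)`, so the
#' same seed yields a different order in each session (counterbalancing)
#' while remaining reproducible.
#'
#' @param spec A delay [task_spec()].
#' @param session_index 1-based session number (order key).
#' @param seed Integer seed.
#' @return A trial table with `nrow = n_blocks * length(reward_levels) *
#'   length(cost_levels)` and no choices filled in.
#' @examples
#' d <- build_delay_design(task_spec("delay"), session_index = 1, seed = 1)
#' nrow(d) # 210
#' @export
build_delay_design <- function(spec = task_spec("delay"), session_index = 1L,
                               seed = 1L) {
  stopifnot(inherits(spec, "cbdm_task_spec"))
  if (spec$task_kind != "delay") {
    stop("spec must describe the delay task", call. = FALSE)
  }
  if (is.null(spec$low_cost_fixed) || length(spec$low_cost_fixed) != 2) {
    stop("delay spec requires low_cost_fixed = c(reward, cost)",
         call. = FALSE)
  }
  grid <- expand.grid(r_hc = spec$reward_levels, c_hc = spec$cost_levels,
                      KEEP.OUT.ATTRS = FALSE)
  rng <- local_rng(combine_seed(seed, session_index))
  blocks <- lapply(seq_len(spec$n_blocks), function(b) {
    g <- grid[sample(nrow(grid)), , drop = FALSE]
    g$block <- b
    g
  })
  restore_rng(rng)
  all <- do.call(rbind, blocks)
  tab <- new_trial_table(
    task_kind = "delay",
    block = all$block,
    r_hc = all$r_hc, c_hc = all$c_hc,
    r_lc = spec$low_cost_fixed[1], c_lc = spec$low_cost_fixed[2]
  )
  if (any(tab$r_hc <= tab$r_lc) || any(tab$c_hc <= tab$c_lc)) {
    stop("delay spec violates high-cost dominance: every varying option ",
         "must exceed the fixed option in both reward and cost",
         call. = FALSE)
  }
  tab
}

#' Validate a trial table
#'
#' Checks the trial-table schema: all required columns present, the
#' high-cost option dominating on both reward and cost on every row
#' (`r_hc > r_lc`, `c_hc > c_lc`), and choices binary or missing. Errors
#' name the offending column or row.
#'
#' @param tab A data frame.
#' @return `tab`, invisibly, if valid.
#' @export
validate_trials <- function(tab) {
  missing_cols <- setdiff(trial_table_cols, names(tab))
  if (length(missing_cols)) {
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!(tab$r_hc > tab$r_lc))
  if (length(bad)) {
    stop("trial table row ", bad[1], ": r_hc must exceed r_lc",
         call. = FALSE)
  }
  bad <- which(!(tab$c_hc > tab$c_lc))
  if (length(bad)) {
    stop("trial table row ", bad[1], ": c_hc must exceed c_lc",
         call. = FALSE)
  }
  ch <- tab$choice
  bad <- which(!(is.na(ch) | ch %in% c(0L, 1L)))
  if (length(bad)) {
    stop("trial table row ", bad[1], ": choice must be 0, 1 or missing",
         call. = FALSE)
  }
  bad <- which(!(tab$condition %in% c("PLC", "HAL", "BIP") |
                   is.na(tab$condition)))
  if (length(bad)) {
    stop("trial table row ", bad[1],
         ": condition must be PLC, HAL or BIP", call. = FALSE)
  }
  invisible(tab)
}

#' Write a trial table to CSV
#'
#' @param tab A trial table (validated before writing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(tab, path) {
  validate_trials(tab)
  utils::write.csv(tab[, trial_table_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Inverse of [write_trials()]: `read_trials(write_trials(t, f))` equals
#' `t` field for field. The file must contain all trial-table columns; the
#' schema is validated on read.
#'
#' @param path CSV file path.
#' @return A trial table data frame.
#' @export
read_trials <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_table_cols, names(tab))
  if (length(missing_cols)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab$subject_id <- as.character(tab$subject_id)
  tab$condition <- as.character(tab$condition)
  tab$block <- as.integer(tab$block)
  tab$trial_index <- as.integer(tab$trial_index)
  tab$choice <- as.integer(tab$choice)
  validate_trials(tab)
  tab[, trial_table_cols]
}

# Deterministic sub-seed from a master seed and a stream index; stays
# inside the 32-bit integer range R requires of set.seed().
combine_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %%
               2147483629)
}

# Seeded RNG scoping: run a block under a private seed and restore the
# caller's RNG state afterwards, so library code never disturbs user
# simulations.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
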