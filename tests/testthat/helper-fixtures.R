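# Shared fixtures, built in code at test time.

# A tiny, fully valid hand-written dataset: 2 rats x 1 session.
tiny_trials <- function() {
  data.frame(
    rat_id = rep(c("r1", "r2"), each = 4L),
    phase = "choice_learning",
    session_index = 1L,
    trial_index = rep(1:4, 2L),
    trial_type = rep(c("single", "single", "dual", "single"), 2L),
    offered_high = rep(c(TRUE, FALSE, TRUE, TRUE), 2L),
    offered_low = rep(c(FALSE, TRUE, TRUE, FALSE), 2L),
    high_side = rep(c("left", "right", "left", "right"), 2L),
    chosen = rep(c("high", "low", "high", "none"), 2L),
    is_error = rep(c(FALSE, FALSE, FALSE, TRUE), 2L),
    latency_s = rep(c(0.5, 0.62, 0.71, 0.4), 2L) + rep(c(0, 0.01), each = 4L),
    trial_start_s = rep(c(0, 5.1, 10.4, 16.2), 2L),
    stringsAsFactors = FALSE
  )
}

tiny_dataset <- function() trial_dataset(tiny_trials())

# Small synthetic cohort shared across test files (cached per session).
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small_cohort)) {
    .fixture_env$small_cohort <- generate_cohort(
      cohort_config(n_rats = 4L, n_sessions = 2L, trials_per_session = 120L,
                    seed = 99L))
  }
  .fixture_env$small_cohort
}
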