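test_that("transition counting matches hand-enumerated cases", {
  h <- hypnogram(c("W", "N1", "N2", "R", "W"), 30)
  expect_equal(count_transitions(h, "all_stages"), 4L)
  expect_equal(count_transitions(h, "sleep_wake"), 2L)
  expect_equal(count_transitions(h, "nrem_rem"), 1L)
  expect_equal(count_transitions(h, "within_nrem"), 1L)

  const <- hypnogram(rep("N2", 20), 30)
  for (k in c("all_stages", "nrem_rem", "sleep_wake", "within_nrem"))
    expect_equal(count_transitions(const, k), 0L)

  expect_error(count_transitions(h, "weird"), "arg")
})

test_that("counts match the pair-scan oracle and are reversal-invariant", {
  set.seed(31)
  cats <- c("all_stages", "nrem_rem", "sleep_wake", "within_nrem")
  for (i in 1:200) {
    h <- random_hypnogram(sample(2:100, 1), p_unscored = 0.15)
    rev_h <- hypnogram(rev(h$stages), h$epoch_seconds)
    for (k in cats) {
      expect_equal(count_transitions(h, k), oracle_count(h$stages, k))
      expect_equal(count_transitions(h, k), count_transitions(rev_h, k))
    }
  }
})

test_that("category counts partition the all-stages count", {
  set.seed(32)
  for (i in 1:200) {
    h <- random_hypnogram(sample(2:120, 1), p_unscored = 0.1)
    expect_equal(count_transitions(h, "all_stages"),
                 count_transitions(h, "within_nrem") +
                 count_transitions(h, "nrem_rem") +
                 count_transitions(h, "sleep_wake"))
  }
})

test_that("indices are counts per hour of TST", {
  ## exactly 1 h of sleep: 120 x 30 s, alternating N1/N2 -> 119 changes
  h <- hypnogram(rep(c("N1", "N2"), 60), 30)
  ti <- transition_indices(h)
  expect_equal(ti$tst_hours, 1)
  expect_equal(ti$indices_per_hour[["all_stages"]], 119)
  expect_equal(ti$indices_per_hour[["within_nrem"]], 119)
  expect_equal(ti$indices_per_hour[["sleep_wake"]], 0)

  expect_equal(transition_indices(hypnogram(rep("N2", 120), 30))$
                 indices_per_hour[["all_stages"]], 0)

  expect_error(transition_indices(hypnogram(rep("W", 10), 30,
                                            subject_id = "AWAKE")),
               "AWAKE")
})

test_that("wake-period taxonomy classifies run lengths 1 / 2-3 / >=4", {
  mk <- function(runs) {
    parts <- c("N2")
    for (r in runs) parts <- c(parts, rep("W", r), rep("N2", 3))
    hypnogram(parts, 5)
  }
  wp <- wake_period_counts(mk(c(1, 3, 4)))
  expect_equal(c(wp$n_short, wp$n_intermediate, wp$n_long), c(1, 1, 1))

  wp2 <- wake_period_counts(mk(2))
  expect_equal(c(wp2$n_short, wp2$n_intermediate, wp2$n_long), c(0, 1, 0))

  wp0 <- wake_period_counts(hypnogram(rep("N2", 50), 5))
  expect_equal(c(wp0$n_short, wp0$n_intermediate, wp0$n_long), c(0, 0, 0))

  expect_error(wake_period_counts(hypnogram(rep("W", 10), 5)), "no sleep")
  expect_error(wake_period_counts(hypnogram(rep("N2", 10), 30)), "5-s")
})

test_that("wake runs before onset and after the last sleep are not counted", {
  h <- hypnogram(c(rep("W", 7), "N2", "W", "W", "N2", rep("W", 9)), 5)
  wp <- wake_period_counts(h)                      # post-onset region
  expect_equal(c(wp$n_short, wp$n_intermediate, wp$n_long), c(0, 1, 0))
  wpw <- wake_period_counts(h, counting_region = "window")
  expect_equal(c(wpw$n_short, wpw$n_intermediate, wpw$n_long), c(0, 1, 2))
})

test_that("wake-period counts match the run-length oracle", {
  set.seed(33)
  for (i in 1:100) {
    h <- random_night(sample(50:400, 1), stay = 0.7)
    ok <- try(wake_period_counts(h), silent = TRUE)
    if (inherits(ok, "try-error")) next   # all-wake night
    w <- h$stages
    sleep_idx <- which(w %in% ORACLE_SLEEP)
    region <- w[sleep_idx[1]:sleep_idx[length(sleep_idx)]]
    o <- oracle_wake_runs(region)
    expect_equal(c(ok$n_short, ok$n_intermediate, ok$n_long), unname(o))
    expect_equal(ok$n_short + ok$n_intermediate + ok$n_long,
                 sum(rle(region)$values == "W"))
  }
})

test_that("mini-epoch transition counts dominate their 30-s twins", {
  set.seed(34)
  wins <- 0L
  n <- 40L
  for (i in seq_len(n)) {
    h5 <- random_night(1200, stay = 0.9)
    h30 <- downsample_majority(h5, 6)
    if (count_transitions(h5, "all_stages") >=
        count_transitions(h30, "all_stages")) wins <- wins + 1L
  }
  expect_gte(wins / n, 0.95)
})
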