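test_that("architecture summary matches hand-counted worked example", {
  h <- hypnogram(c("W", "W", "N1", "N2", "N2", "N3", "N3", "R", "R",
                   "N2", "W", "N2"), 30)
  a <- compute_architecture(h)
  ## 12 epochs = 6 min TIB; 9 sleep epochs (1 N1, 4 N2, 2 N3, 2 R) = 4.5
  ## min TST; values cross-checked against the per-epoch tally oracle
  o <- oracle_architecture(h$stages, 30)
  expect_equal(a$tib_hours * 60, 6)
  expect_equal(a$tst_hours * 60, 4.5)
  expect_equal(a$tst_hours, o$tst_hours)
  expect_equal(a$sleep_efficiency_pct, o$se)
  expect_equal(a$sleep_latency_min, 1.0)
  expect_equal(a$rem_latency_min, 2.5)
})

test_that("degenerate windows are handled without raising", {
  all_sleep <- compute_architecture(hypnogram(rep("N2", 8), 30))
  expect_equal(all_sleep$sleep_efficiency_pct, 100)
  expect_equal(all_sleep$sleep_latency_min, 0)
  expect_equal(all_sleep$stage_pct[["W"]], 0)

  all_wake <- compute_architecture(hypnogram(rep("W", 8), 30))
  expect_equal(all_wake$tst_hours, 0)
  expect_equal(all_wake$sleep_efficiency_pct, 0)
  expect_true(is.na(all_wake$sleep_latency_min))
  expect_true(is.na(all_wake$rem_latency_min))
  expect_false(all_wake$early_rem_flag)
})

test_that("stage percentages partition scored time and SE identity holds", {
  set.seed(21)
  for (i in 1:200) {
    h <- random_hypnogram(sample(10:200, 1),
                          epoch_seconds = sample(c(5, 30), 1))
    a <- compute_architecture(h)
    expect_equal(sum(a$stage_pct), 100, tolerance = 1e-9)
    expect_equal(a$sleep_efficiency_pct, 100 * a$tst_hours / a$tib_hours)
    expect_true(a$sleep_latency_min >= 0 &&
                a$sleep_latency_min <= a$tib_hours * 60)
  }
})

test_that("architecture agrees with the per-epoch tally oracle", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    es <- sample(c(5, 30), 1)
    h <- random_hypnogram(n, epoch_seconds = es, p_unscored = 0.1)
    a <- compute_architecture(h)
    o <- oracle_architecture(h$stages, es)
    expect_equal(a$tib_hours, o$tib_hours)
    expect_equal(a$tst_hours, o$tst_hours)
    expect_equal(a$sleep_efficiency_pct, o$se)
    expect_equal(unname(a$stage_pct), unname(o$stage_pct))
    expect_equal(a$sleep_latency_min, o$sleep_latency_min)
    expect_equal(a$rem_latency_min, o$rem_latency_min)
  }
})

test_that("early REM uses a strict 15-minute cutoff from sleep onset", {
  ## 30-s epochs: onset at epoch 0; REM beginning at epoch 20 = 10 min
  h10 <- hypnogram(c(rep("N1", 20), "R", rep("N2", 5)), 30)
  expect_true(detect_early_rem(h10)$flag)
  expect_equal(detect_early_rem(h10)$rem_latency_min, 10)

  ## REM beginning exactly at 15.0 min is NOT early
  h15 <- hypnogram(c(rep("N1", 30), "R", rep("N2", 5)), 30)
  expect_equal(detect_early_rem(h15)$rem_latency_min, 15)
  expect_false(detect_early_rem(h15)$flag)
  ## one epoch earlier is
  h145 <- hypnogram(c(rep("N1", 29), "R", rep("N2", 5)), 30)
  expect_true(detect_early_rem(h145)$flag)

  expect_false(detect_early_rem(hypnogram(rep("N2", 10), 30))$flag)
  ## the same rule applies at 5-s resolution: one mini-epoch suffices
  m <- hypnogram(c(rep("N1", 100), "R", rep("N2", 100)), 5)
  expect_true(detect_early_rem(m)$flag)
  expect_equal(detect_early_rem(m)$rem_latency_min, 100 * 5 / 60)
})

test_that("5-s nights and their 30-s majority twins agree on TIB", {
  set.seed(23)
  for (i in 1:10) {
    h5 <- random_night(sample(600:1200, 1))
    h30 <- downsample_majority(h5, 6)
    a5 <- compute_architecture(h5)
    a30 <- compute_architecture(h30)
    expect_lte(abs(a5$tib_hours - a30$tib_hours), 30 / 3600)
  }
})
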