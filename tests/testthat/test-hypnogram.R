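test_that("validation reports each violated invariant without raising", {
  good <- hypnogram(c("W", "N1", "N2"), 30)
  expect_length(validate_hypnogram(good), 0)

  bad_lights <- sleepfrag:::new_hypnogram(c("W", "N1"), 30, 0L, 5L)
  issues <- validate_hypnogram(bad_lights)
  expect_length(issues, 1)
  expect_match(issues, "lights")

  bad_epoch <- sleepfrag:::new_hypnogram(c("W", "N1"), 0, 0L, 2L)
  expect_match(validate_hypnogram(bad_epoch), "epoch_seconds")

  bad_token <- sleepfrag:::new_hypnogram(c("W", "XX"), 30, 0L, 2L)
  expect_match(validate_hypnogram(bad_token), "unknown token 'XX'")

  expect_error(hypnogram(c("W", "XX"), 30), "unknown token")
})

test_that("lights-window cropping is idempotent and rebases indices", {
  h <- hypnogram(rep(c("W", "N2"), 5), 30)
  expect_identical(crop_to_lights(h)$stages, h$stages)

  h2 <- hypnogram(random_stages(10), 30, lights_off = 2, lights_on = 8)
  c1 <- crop_to_lights(h2)
  expect_length(c1$stages, 6)
  expect_identical(c1$stages, h2$stages[3:8])
  expect_identical(c1$lights_off, 0L)
  expect_identical(c1$lights_on, 6L)
  expect_identical(crop_to_lights(c1), c1)
})

test_that("canonical CSV writing and reading round-trips", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    off <- sample(0:(n - 2), 1)
    h <- hypnogram(random_stages(n, p_unscored = 0.1),
                   sample(c(5, 30), 1), lights_off = off,
                   lights_on = sample((off + 1):n, 1),
                   subject_id = sprintf("S%02d", i))
    p <- withr::local_tempfile(fileext = ".csv")
    write_hypnogram(h, p)
    expect_equal(read_hypnogram(p), h)
  }
})

test_that("numeric-coded files equal their letter-coded twins", {
  set.seed(12)
  for (i in 1:100) {
    h <- hypnogram(random_stages(sample(3:40, 1), p_unscored = 0.1), 5)
    p1 <- withr::local_tempfile(fileext = ".csv")
    p2 <- withr::local_tempfile(fileext = ".csv")
    write_hypnogram(h, p1, tokens = "letter")
    write_hypnogram(h, p2, tokens = "numeric")
    expect_false(identical(readLines(p1), readLines(p2)))
    expect_equal(read_hypnogram(p1), read_hypnogram(p2))
  }
})

test_that("malformed hypnogram files are rejected with location", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,a", "epoch_seconds,30", "lights,0,3",
               "0,W", "1,Q7", "2,N2"), p)
  expect_error(read_hypnogram(p), "unknown stage token 'Q7' at data row 2")

  writeLines(c("subject_id,a", "epoch_seconds,30",
               "0,W", "1,N1", "2,N2"), p)
  expect_error(read_hypnogram(p), "lights")

  writeLines(c("subject_id,a", "epoch_seconds,30", "lights,0,3",
               "0,W", "2,N1", "1,N2"), p)
  expect_error(read_hypnogram(p), "non-monotone")
})

test_that("majority downsampling follows the last-in-window tie rule", {
  h <- function(x) hypnogram(x, 5)
  expect_identical(downsample_majority(h(c("N2", "N2", "N2", "N2", "W", "W")))$stages, "N2")
  expect_identical(downsample_majority(h(rep("R", 6)))$stages, "R")
  ## tie: W and N2 both 3; N2 occupies the last mini-epoch
  expect_identical(downsample_majority(h(c("W", "W", "W", "N2", "N2", "N2")))$stages, "N2")
  expect_error(downsample_majority(h(rep("W", 6)), factor = 0), "positive")
})

test_that("downsampling agrees with exhaustive enumeration over 2-stage windows", {
  ## every 6-window over {W, N2}: brute-force the majority + tie rule
  grids <- expand.grid(rep(list(c("W", "N2")), 6), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grids))) {
    win <- unlist(grids[i, ], use.names = FALSE)
    nw <- sum(win == "W")
    ## tie (3 vs 3): whichever of the two stages holds the last
    ## mini-epoch has the later final occurrence, so it wins
    expected <- if (nw > 3) "W" else if (nw < 3) "N2" else win[6]
    got <- downsample_majority(hypnogram(win, 5))$stages
    expect_identical(got, expected, label = paste(win, collapse = ""))
  }
})

test_that("downsampling drops partial windows and outputs only source stages", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(10:100, 1)
    h <- random_hypnogram(n)
    d <- downsample_majority(h, 6)
    expect_length(d$stages, n %/% 6)
    expect_equal(d$epoch_seconds, 30)
    for (j in seq_along(d$stages)) {
      win <- h$stages[((j - 1) * 6 + 1):(j * 6)]
      expect_true(d$stages[j] %in% win)
    }
  }
})
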