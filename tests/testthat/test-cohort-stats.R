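test_that("BH step-up matches forced examples", {
  expect_false(any(benjamini_hochberg(rep(1, 8))$rejected))
  expect_true(benjamini_hochberg(0.04, q = 0.05)$rejected)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  got <- benjamini_hochberg(p, q = 0.05)
  expect_identical(got$rejected, oracle_bh_reject(p, 0.05))
  ## adjusted p monotone nondecreasing in rank
  expect_true(all(diff(got$adjusted_p[order(p)]) >= -1e-15))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH rejection sets equal the exhaustive oracle on random lists", {
  set.seed(61)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_identical(benjamini_hochberg(p, q)$rejected,
                     oracle_bh_reject(p, q),
                     label = paste("m =", m, "q =", q))
  }
})

test_that("log-transform policy fires on skewed positive data only", {
  x <- c(1, 2, 3)
  expect_identical(maybe_log_transform(x, "never"),
                   list(values = x, transformed = FALSE))
  expect_error(maybe_log_transform(c(1, -1), "always"), "positive")
  expect_message(out <- maybe_log_transform(c(1, 0, 2), "auto"), "skipped")
  expect_false(out$transformed)

  set.seed(62)
  ln <- rlnorm(500, 0, 1)
  expect_true(maybe_log_transform(ln, "auto")$transformed)
  nm <- rnorm(500, 10, 1)
  expect_false(maybe_log_transform(nm, "auto")$transformed)
  ## the internal moment skewness agrees with an established oracle
  skip_if_not_installed("e1071")
  expect_equal(sleepfrag:::sample_skewness(ln),
               e1071::skewness(ln, type = 1), tolerance = 1e-10)
  expect_gt(abs(sleepfrag:::sample_skewness(ln)), 1)
  expect_lt(abs(sleepfrag:::sample_skewness(nm)), 1)
})

sim_table <- function(n_per_group, effect_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2 * n_per_group
  fam <- rep(sprintf("F%03d", seq_len(n_per_group)), 2)
  grp <- rep(c("patient", "sibling"), each = n_per_group)
  fam_eff <- rnorm(n_per_group, 0, 0.5)[match(fam, unique(fam))]
  data.frame(
    subject_id = sprintf("X%03d", seq_len(n)),
    family_id = fam,
    group = grp,
    age_years = runif(n, 18, 60),
    sex = sample(c("F", "M"), n, replace = TRUE),
    y = 10 + fam_eff + (grp == "patient") * effect_sd + rnorm(n),
    stringsAsFactors = FALSE)
}

test_that("group comparison reports Cohen's d as beta over residual SD", {
  d <- sim_table(60, effect_sd = 1.5, seed = 63)
  mr <- fit_group_comparison(d, "y", "group", transform = "never")
  expect_equal(mr$cohens_d, mr$coefficient / mr$residual_sd)
  expect_true(mr$ci95_low <= mr$coefficient &&
              mr$coefficient <= mr$ci95_high)
  ## sibling vs patient: the injected patient excess shows as negative
  expect_lt(mr$coefficient, 0)
  expect_lt(mr$p_value, 0.01)
  expect_equal(mr$n_observations, 120)
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- sim_table(20, seed = 64)
  d$y <- 1
  expect_error(fit_group_comparison(d, "y", "group"), "constant outcome")

  d2 <- sim_table(20, seed = 65)
  d2$age_copy <- d2$age_years
  expect_error(
    fit_group_comparison(d2, "y", "group",
                         covariates = c("age_years", "age_copy", "sex")),
    "age_copy")
})

test_that("subjects missing a predictor are excluded from that model only", {
  d <- sim_table(30, effect_sd = 1, seed = 66)
  d$flag <- rbinom(nrow(d), 1, 0.5) == 1
  d$flag[1:5] <- NA
  mr <- fit_group_comparison(d, "y", "flag", transform = "never")
  expect_equal(mr$n_observations, nrow(d) - 5)
  mr_full <- fit_group_comparison(d, "y", "group", transform = "never")
  expect_equal(mr_full$n_observations, nrow(d))
})

test_that("transition grid excludes undefined-row subjects per cell only", {
  set.seed(67)
  cfg <- generator_config(n_patients = 12, n_siblings = 12,
                          night_length_miniepochs = 720, seed = 67)
  co <- generate_cohort(cfg)
  ml <- matrices_long(co$hypnograms_5s)
  g0 <- suppressMessages(compare_transition_probabilities(
    ml, co$cohort_table, min_subjects = 5))
  ## erase one subject's N3 row: as if they never reached N3
  victim <- ml$subject_id[1]
  ml$prob[ml$subject_id == victim & ml$from == "N3"] <- NA
  g <- suppressMessages(compare_transition_probabilities(
    ml, co$cohort_table, min_subjects = 5))
  expect_equal(attr(g, "n_models"), 25)   # one resolution
  expect_equal(g$n[g$from == "N3"], g0$n[g0$from == "N3"] - 1L)
  expect_equal(g$n[g$from != "N3"], g0$n[g0$from != "N3"])
})

test_that("split-night models demand exactly two halves per subject", {
  set.seed(68)
  cfg <- generator_config(n_patients = 15, n_siblings = 15,
                          night_length_miniepochs = 720, seed = 68)
  co <- generate_cohort(cfg)
  sn <- merge(splitnight_table(co$hypnograms_5s), co$cohort_table,
              by = "subject_id")
  expect_error(split_night_model(rbind(sn, sn[1, ]), "index_sleep_wake"),
               "duplicated")
  dropped <- sn[-1, ]
  expect_message(
    m <- split_night_model(dropped, "index_sleep_wake", transform = "never"),
    "excluded")
  expect_s3_class(m$interaction, "model_result")
  expect_named(m$contrasts,
               c("half_effect_in_patient", "half_effect_in_sibling",
                 "group_diff_in_first_half", "group_diff_in_second_half"))
  df <- as.data.frame(m)
  expect_equal(nrow(df), 5)
  expect_equal(df$cohens_d, df$coefficient / df$residual_sd)
})
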