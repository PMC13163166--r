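## ---- generating-matrix presets ------------------------------------------
## Row-stochastic 5x5 matrices over (W, N1, N2, N3, R) at 5-s step scale.
## The presets are synthetic: the source cohort's matrices are not public,
## so these are plausibility-tuned to sit near reported magnitudes (wake
## occupancy, sleep-wake transition indices, roughly equal thirds of
## short/intermediate/long wake runs) rather than calibrated to any
## published matrix. Patients have elevated wake-entry probabilities that
## rise further in the second night-half; siblings use one matrix for
## both halves.

stage_matrix <- function(...) {
  m <- matrix(c(...), nrow = 5L, byrow = TRUE,
              dimnames = list(from = STAGE_ORDER, to = STAGE_ORDER))
  stopifnot(all(abs(rowSums(m) - 1) < 1e-9))
  m
}

SIBLING_MATRIX <- stage_matrix(
  # W      N1     N2     N3     R
  0.750, 0.170, 0.060, 0.005, 0.015,   # W
  0.015, 0.820, 0.130, 0.004, 0.031,   # N1
  0.010, 0.020, 0.925, 0.030, 0.015,   # N2
  0.008, 0.004, 0.048, 0.940, 0.000,   # N3
  0.018, 0.022, 0.015, 0.000, 0.945)   # R

PATIENT_MATRIX_FIRST <- stage_matrix(
  0.750, 0.170, 0.050, 0.004, 0.026,
  0.030, 0.800, 0.115, 0.004, 0.051,
  0.022, 0.030, 0.906, 0.025, 0.017,
  0.012, 0.006, 0.052, 0.930, 0.000,
  0.035, 0.030, 0.012, 0.000, 0.923)

PATIENT_MATRIX_SECOND <- stage_matrix(
  0.750, 0.170, 0.050, 0.004, 0.026,
  0.045, 0.785, 0.115, 0.004, 0.051,
  0.034, 0.030, 0.894, 0.025, 0.017,
  0.018, 0.006, 0.052, 0.924, 0.000,
  0.052, 0.030, 0.012, 0.000, 0.906)

#' Preset generating matrices
#'
#' Synthetic per-group, per-night-half transition matrices used by the
#' cohort generator. `"nt1-vs-sibling"` gives patients elevated
#' wake-entry probabilities, rising in the second night-half, with a
#' half-stationary sibling matrix; `"null"` gives both groups the
#' sibling matrix in both halves (no group or half effect).
#'
#' @param preset `"nt1-vs-sibling"` or `"null"`.
#' @return Nested list `matrices[[group]][[half]]` with groups
#'   `patient`, `sibling` and halves `first`, `second`.
#' @export
preset_matrices <- function(preset = c("nt1-vs-sibling", "null")) {
  preset <- match.arg(preset)
  sib <- list(first = SIBLING_MATRIX, second = SIBLING_MATRIX)
  if (preset == "null") return(list(patient = sib, sibling = sib))
  list(patient = list(first = PATIENT_MATRIX_FIRST,
                      second = PATIENT_MATRIX_SECOND),
       sibling = sib)
}

default_covariate_model <- function() {
  list(age_mean = 32, age_sd = 12, age_range = c(16, 65),
       p_female = 0.5,
       p_h1n1 = c(patient = 0.86, sibling = 0.73),
       p_hcrt1_undetectable = 0.59,     # patients only
       p_all_core_symptoms = 0.58,      # patients only
       p_any_core_symptom = 0.33,       # siblings only
       p_hla = c(patient = 0.97, sibling = 0.61),
       disease_duration_meanlog = log(12),
       disease_duration_sdlog = 0.5)
}

#' Synthetic cohort generator configuration
#'
#' Bundles and validates every knob of the cohort generator. Defaults
#' emulate a two-group sibling-paired cohort: 125 patients and 100
#' non-narcoleptic siblings, every sibling sharing a family with one
#' patient, ~8 h nights of 5-s mini-epochs (5760 units) flanked by
#' fixed wake padding inside the lights window, per-subject Dirichlet
#' personalization of the group matrices, a family-shared lognormal
#' multiplier on wake-entry probabilities, and group-specific rates of
#' early-appearing REM.
#'
#' @param preset matrix preset passed to [preset_matrices()].
#' @param n_patients,n_siblings group sizes.
#' @param family_pairing fraction of patient-sibling pairs sharing a
#'   `family_id` (in `[0, 1]`).
#' @param matrices nested list `[[group]][[half]]` of row-stochastic
#'   5x5 matrices; overrides `preset`.
#' @param subject_heterogeneity Dirichlet concentration for row-wise
#'   personalization (larger = less between-subject spread).
#' @param family_effect_sd SD (log scale) of the family multiplier on
#'   wake-entry probabilities.
#' @param night_length_miniepochs chain length in 5-s units (default
#'   5760, about 8 h).
#' @param lights_padding named vector `c(pre=, post=)` of wake units
#'   inserted before/after the chain, inside the lights window.
#' @param init_distribution start-stage distribution over
#'   (W, N1, N2, N3, R).
#' @param early_rem_prob named per-group probability of forcing one REM
#'   mini-epoch strictly within 15 min of sleep onset.
#' @param covariate_model list of covariate distribution parameters
#'   (see `sleepfrag:::default_covariate_model`).
#' @param seed integer seed, or `NULL` to leave the RNG state alone.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(preset = "nt1-vs-sibling",
                             n_patients = 125L, n_siblings = 100L,
                             family_pairing = 1.0,
                             matrices = NULL,
                             subject_heterogeneity = 400,
                             family_effect_sd = 0.2,
                             night_length_miniepochs = 5760L,
                             lights_padding = c(pre = 60L, post = 24L),
                             init_distribution = c(W = 0.2, N1 = 0.6,
                                                   N2 = 0.2, N3 = 0, R = 0),
                             early_rem_prob = c(patient = 0.60,
                                                sibling = 0.14),
                             covariate_model = default_covariate_model(),
                             seed = NULL) {
  if (is.null(matrices)) matrices <- preset_matrices(preset)
  cfg <- list(n_patients = as.integer(n_patients),
              n_siblings = as.integer(n_siblings),
              family_pairing = family_pairing,
              matrices = matrices,
              subject_heterogeneity = subject_heterogeneity,
              family_effect_sd = family_effect_sd,
              night_length_miniepochs = as.integer(night_length_miniepochs),
              lights_padding = lights_padding,
              init_distribution = init_distribution,
              early_rem_prob = early_rem_prob,
              covariate_model = covariate_model,
              seed = seed)
  for (g in c("patient", "sibling"))
    for (hf in c("first", "second")) {
      m <- cfg$matrices[[g]][[hf]]
      if (is.null(m) || !is.matrix(m) || any(dim(m) != 5L) ||
          any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8))
        stop("matrices$", g, "$", hf, " must be a 5x5 row-stochastic matrix")
    }
  if (cfg$n_patients < 1L || cfg$n_siblings < 1L)
    stop("group sizes must be positive")
  if (family_pairing < 0 || family_pairing > 1)
    stop("family_pairing must lie in [0, 1]")
  if (cfg$night_length_miniepochs < 2L)
    stop("night_length_miniepochs must be at least 2")
  if (any(init_distribution < 0) || sum(init_distribution) <= 0)
    stop("init_distribution must be a nonnegative, nonzero vector")
  structure(cfg, class = "generator_config")
}

row_cumsum <- function(m) t(apply(m, 1L, cumsum))

#' Sample one hypnogram from a pair of transition matrices
#'
#' Draws a stage sequence stepwise from `matrix_first` up to the night
#' midpoint and from `matrix_second` after it. Uniform variates are
#' drawn from R's RNG, so results are reproducible under `set.seed()`
#' (or the `seed` argument).
#'
#' @param matrix_first,matrix_second 5x5 row-stochastic matrices over
#'   (W, N1, N2, N3, R).
#' @param length number of units to sample (>= 2).
#' @param init_distribution start-stage distribution.
#' @param epoch_seconds unit duration (default 5).
#' @param subject_id subject identifier for the result.
#' @param seed optional integer seed.
#' @return A `hypnogram` whose lights window spans the whole sequence.
#' @export
generate_hypnogram <- function(matrix_first, matrix_second = matrix_first,
                               length = 5760L,
                               init_distribution = c(0.2, 0.6, 0.2, 0, 0),
                               epoch_seconds = 5, subject_id = "sim",
                               seed = NULL) {
  for (m in list(matrix_first, matrix_second))
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8))
      stop("generating matrix rows must be nonnegative and sum to 1")
  length <- as.integer(length)
  if (length < 2L) stop("length must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  init <- sample.int(5L, 1L, prob = init_distribution)
  states <- sample_chain_cpp(row_cumsum(matrix_first),
                             row_cumsum(matrix_second),
                             boundary = length %/% 2L,
                             init_state = init,
                             u = stats::runif(length - 1L))
  hypnogram(STAGE_ORDER[states], epoch_seconds, 0L, length, subject_id)
}

## Dirichlet perturbation of each row around the base matrix; zero
## entries are structural and stay zero.
personalize_matrix <- function(m, kappa) {
  out <- m
  for (i in seq_len(nrow(m))) {
    pos <- which(m[i, ] > 0)
    g <- stats::rgamma(length(pos), shape = kappa * m[i, pos])
    out[i, pos] <- g / sum(g)
  }
  out
}

## Multiply wake-entry probabilities (column W of the sleep-origin rows)
## by a family-shared factor, then renormalize each touched row.
apply_wake_multiplier <- function(m, f) {
  for (i in which(rownames(m) %in% SLEEP_STAGES)) {
    m[i, "W"] <- min(m[i, "W"] * f, 0.5)
    m[i, ] <- m[i, ] / sum(m[i, ])
  }
  m
}

truncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

sample_covariates <- function(subject_id, family_id, group, cm) {
  patient <- group == "patient"
  data.frame(
    subject_id = subject_id,
    family_id = family_id,
    group = group,
    age_years = truncnorm1(cm$age_mean, cm$age_sd,
                           cm$age_range[1], cm$age_range[2]),
    sex = if (stats::runif(1) < cm$p_female) "F" else "M",
    h1n1_vaccinated = stats::runif(1) < cm$p_h1n1[[group]],
    hcrt1_undetectable = if (patient)
      stats::runif(1) < cm$p_hcrt1_undetectable else NA,
    all_core_symptoms = if (patient)
      stats::runif(1) < cm$p_all_core_symptoms else NA,
    any_core_symptom = if (patient) TRUE else
      stats::runif(1) < cm$p_any_core_symptom,
    hla_dqb1_0602 = stats::runif(1) < cm$p_hla[[group]],
    disease_duration_years = if (patient)
      stats::rlnorm(1, cm$disease_duration_meanlog,
                    cm$disease_duration_sdlog) else NA_real_,
    stringsAsFactors = FALSE)
}

## Force one REM mini-epoch strictly within `window_min` minutes of
## sleep onset (used to emulate early-appearing REM periods).
inject_early_rem <- function(stages, epoch_seconds, window_min = 15) {
  sleep_pos <- which(stages %in% SLEEP_STAGES)
  if (!length(sleep_pos)) return(stages)
  onset <- sleep_pos[1L]
  max_offset <- as.integer(window_min * 60 / epoch_seconds) - 1L
  pos <- onset + sample.int(max_offset, 1L)
  if (pos <= length(stages)) stages[pos] <- "R"
  stages
}

#' Generate a synthetic two-group cohort of paired hypnograms
#'
#' For each subject the group's half-specific matrices are personalized
#' by Dirichlet row perturbation, wake-entry probabilities are scaled by
#' a family-shared lognormal multiplier, a 5-s night is sampled (first
#' matrix up to the midpoint, second after), wake padding is added
#' inside the lights window, early REM is optionally injected, and a
#' 30-s twin is derived by majority downsampling. Covariates are drawn
#' from the configured distributions; realized per-subject matrices are
#' retained as ground truth.
#'
#' @param config a [generator_config()].
#' @return A `synthetic_cohort`: `hypnograms_5s`, `hypnograms_30s`,
#'   `cohort_table`, `ground_truth`, `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_p <- config$n_patients
  n_s <- config$n_siblings
  n_pairs <- as.integer(round(config$family_pairing * min(n_p, n_s)))

  ids <- c(sprintf("P%03d", seq_len(n_p)), sprintf("S%03d", seq_len(n_s)))
  groups <- rep(c("patient", "sibling"), c(n_p, n_s))
  ## sibling i < n_pairs shares family with patient i
  fam_of <- function(i, grp) {
    k <- if (grp == "patient") i else i - n_p
    if (grp == "sibling" && k <= n_pairs) sprintf("F%03d", k)
    else if (grp == "patient" && k <= n_pairs) sprintf("F%03d", k)
    else sprintf("F%03d", n_pairs + (if (grp == "patient") k else
      n_p - n_pairs + k))
  }
  families <- vapply(seq_along(ids),
                     function(i) fam_of(i, groups[i]), "")
  fam_mult <- stats::setNames(
    stats::rlnorm(length(unique(families)), 0, config$family_effect_sd),
    unique(families))

  h5 <- vector("list", length(ids))
  h30 <- vector("list", length(ids))
  covs <- vector("list", length(ids))
  truth <- vector("list", length(ids))
  pre <- as.integer(config$lights_padding[["pre"]])
  post <- as.integer(config$lights_padding[["post"]])
  L <- config$night_length_miniepochs

  for (i in seq_along(ids)) {
    grp <- groups[i]
    f <- fam_mult[[families[i]]]
    m1 <- apply_wake_multiplier(
      personalize_matrix(config$matrices[[grp]]$first,
                         config$subject_heterogeneity), f)
    m2 <- apply_wake_multiplier(
      personalize_matrix(config$matrices[[grp]]$second,
                         config$subject_heterogeneity), f)
    init <- sample.int(5L, 1L, prob = config$init_distribution)
    states <- sample_chain_cpp(row_cumsum(m1), row_cumsum(m2),
                               boundary = L %/% 2L, init_state = init,
                               u = stats::runif(L - 1L))
    stages <- c(rep("W", pre), STAGE_ORDER[states], rep("W", post))
    if (stats::runif(1) < config$early_rem_prob[[grp]])
      stages <- inject_early_rem(stages, 5)
    h5[[i]] <- hypnogram(stages, 5, 0L, length(stages), ids[i])
    h30[[i]] <- downsample_majority(h5[[i]], 6L)
    covs[[i]] <- sample_covariates(ids[i], families[i], grp,
                                   config$covariate_model)
    truth[[i]] <- list(subject_id = ids[i], group = grp,
                       matrix_first = m1, matrix_second = m2,
                       family_multiplier = f)
  }
  structure(
    list(hypnograms_5s = h5,
         hypnograms_30s = h30,
         cohort_table = do.call(rbind, covs),
         ground_truth = truth,
         config = config),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$cohort_table$group)
  cat(sprintf(
    "<synthetic cohort> %d patients + %d siblings, %d x 5-s units per night (paired 30-s twins)\n",
    tab[["patient"]], tab[["sibling"]], x$config$night_length_miniepochs))
  invisible(x)
}

## First/second chain halves of a generated night, with the padding
## stripped, matching the sampler's matrix-switch boundary.
chain_halves <- function(h5, config) {
  pre <- as.integer(config$lights_padding[["pre"]])
  L <- config$night_length_miniepochs
  chain <- h5$stages[(pre + 1L):(pre + L)]
  b <- L %/% 2L
  list(first = hypnogram(chain[seq_len(b + 1L)], 5, subject_id = h5$subject_id),
       second = hypnogram(chain[(b + 1L):L], 5, subject_id = h5$subject_id))
}

#' Parameter recovery report for a synthetic cohort
#'
#' Compares per-subject estimated transition matrices (per chain half,
#' padding stripped) against the realized generating matrices, and the
#' group-pooled estimated matrices against the preset group matrices.
#' Also summarizes the group-wise transition indices with Monte-Carlo
#' 95% intervals for the mean.
#'
#' @param cohort a `synthetic_cohort` with ground truth.
#' @return A `recovery_report`: `per_subject` (max-abs and mean-abs
#'   error per subject and half), `pooled` (per group and half), and
#'   `index_summary`.
#' @export
parameter_recovery_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!length(cohort$ground_truth)) stop("empty ground truth")
  config <- cohort$config
  per_subject <- list()
  est_sum <- list()   # running per-group/half sums of estimated probs
  est_n <- list()
  for (i in seq_along(cohort$hypnograms_5s)) {
    gt <- cohort$ground_truth[[i]]
    halves <- chain_halves(cohort$hypnograms_5s[[i]], config)
    for (hf in c("first", "second")) {
      est <- estimate_transition_matrix(halves[[hf]])$probs
      tru <- gt[[paste0("matrix_", hf)]]
      err <- abs(est - tru)
      per_subject[[length(per_subject) + 1L]] <- data.frame(
        subject_id = gt$subject_id, group = gt$group, half = hf,
        max_abs_err = max(err, na.rm = TRUE),
        mean_abs_err = mean(err, na.rm = TRUE),
        stringsAsFactors = FALSE)
      key <- paste(gt$group, hf)
      if (is.null(est_sum[[key]])) {
        est_sum[[key]] <- ifelse(is.na(est), 0, est)
        est_n[[key]] <- (!is.na(est)) + 0
      } else {
        est_sum[[key]] <- est_sum[[key]] + ifelse(is.na(est), 0, est)
        est_n[[key]] <- est_n[[key]] + !is.na(est)
      }
    }
  }
  pooled <- do.call(rbind, lapply(names(est_sum), function(key) {
    parts <- strsplit(key, " ")[[1L]]
    pooled_est <- est_sum[[key]] / pmax(est_n[[key]], 1)
    base <- config$matrices[[parts[1L]]][[parts[2L]]]
    err <- abs(pooled_est - base)[est_n[[key]] > 0]
    data.frame(group = parts[1L], half = parts[2L],
               max_abs_err = max(err), mean_abs_err = mean(err),
               stringsAsFactors = FALSE)
  }))
  frag <- fragmentation_table(cohort$hypnograms_5s)
  frag$group <- cohort$cohort_table$group[
    match(frag$subject_id, cohort$cohort_table$subject_id)]
  index_summary <- do.call(rbind, lapply(split(frag, frag$group), function(d) {
    do.call(rbind, lapply(c("index_all_stages", "index_sleep_wake",
                            "index_nrem_rem"), function(k) {
      m <- mean(d[[k]]); s <- stats::sd(d[[k]]) / sqrt(nrow(d))
      data.frame(group = d$group[1L], metric = k, mean = m,
                 ci_low = m - 1.96 * s, ci_high = m + 1.96 * s,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(index_summary) <- NULL
  structure(list(per_subject = do.call(rbind, per_subject),
                 pooled = pooled,
                 index_summary = index_summary),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery report>\n  pooled matrix errors:\n")
  print(x$pooled, row.names = FALSE)
  cat("  group index means (MC 95% CI):\n")
  print(x$index_summary, row.names = FALSE)
  invisible(x)
}
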