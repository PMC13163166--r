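## Independent brute-force oracles. These deliberately share no code
## with the package internals: plain loops and closed forms only.

ORACLE_STAGES <- c("W", "N1", "N2", "N3", "R")
ORACLE_SLEEP <- c("N1", "N2", "N3", "R")
ORACLE_NREM <- c("N1", "N2", "N3")

## pair-by-pair transition count, skipping pairs that touch "U"
oracle_count <- function(stages, category) {
  n <- 0L
  for (i in seq_len(length(stages) - 1L)) {
    a <- stages[i]; b <- stages[i + 1L]
    if (a == "U" || b == "U" || a == b) next
    hit <- switch(category,
      all_stages = TRUE,
      nrem_rem = (a %in% ORACLE_NREM && b == "R") ||
                 (a == "R" && b %in% ORACLE_NREM),
      sleep_wake = (a == "W" && b %in% ORACLE_SLEEP) ||
                   (a %in% ORACLE_SLEEP && b == "W"),
      within_nrem = a %in% ORACLE_NREM && b %in% ORACLE_NREM)
    if (hit) n <- n + 1L
  }
  n
}

## full 5x5 pair tally (self-pairs included), skipping "U"
oracle_pair_counts <- function(stages) {
  m <- matrix(0L, 5, 5, dimnames = list(ORACLE_STAGES, ORACLE_STAGES))
  for (i in seq_len(length(stages) - 1L)) {
    a <- stages[i]; b <- stages[i + 1L]
    if (a == "U" || b == "U") next
    m[a, b] <- m[a, b] + 1L
  }
  m
}

## wake-run taxonomy by explicit scan over a region
oracle_wake_runs <- function(region) {
  counts <- c(short = 0L, intermediate = 0L, long = 0L)
  run <- 0L
  for (s in c(region, "sentinel")) {
    if (s == "W") {
      run <- run + 1L
    } else if (run > 0L) {
      if (run == 1L) counts["short"] <- counts["short"] + 1L
      else if (run <= 3L) counts["intermediate"] <- counts["intermediate"] + 1L
      else counts["long"] <- counts["long"] + 1L
      run <- 0L
    }
  }
  counts
}

## exhaustive BH step-up: largest k with p_(k) <= k*q/m
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  rejected <- rep(FALSE, m)
  if (length(ks)) rejected[o[seq_len(max(ks))]] <- TRUE
  rejected
}

## stationary distribution by eigen-decomposition of the transpose
oracle_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

## per-epoch tally architecture oracle
oracle_architecture <- function(stages, epoch_seconds) {
  n_sleep <- 0L; onset <- NA_integer_; first_rem <- NA_integer_
  n_scored <- 0L
  per <- setNames(integer(5), ORACLE_STAGES)
  for (i in seq_along(stages)) {
    s <- stages[i]
    if (s != "U") {
      n_scored <- n_scored + 1L
      per[s] <- per[s] + 1L
    }
    if (s %in% ORACLE_SLEEP) {
      n_sleep <- n_sleep + 1L
      if (is.na(onset)) onset <- i
    }
    if (s == "R" && is.na(first_rem)) first_rem <- i
  }
  list(tib_hours = length(stages) * epoch_seconds / 3600,
       tst_hours = n_sleep * epoch_seconds / 3600,
       se = 100 * n_sleep / length(stages),
       stage_pct = if (n_scored) 100 * per / n_scored else per * NA,
       sleep_latency_min = if (is.na(onset)) NA_real_ else
         (onset - 1L) * epoch_seconds / 60,
       rem_latency_min = if (is.na(first_rem) || is.na(onset)) NA_real_ else
         (first_rem - onset) * epoch_seconds / 60)
}

random_stages <- function(n, p_unscored = 0,
                          stages = ORACLE_STAGES) {
  tokens <- c(stages, if (p_unscored > 0) "U")
  probs <- c(rep((1 - p_unscored) / length(stages), length(stages)),
             if (p_unscored > 0) p_unscored)
  sample(tokens, n, replace = TRUE, prob = probs)
}

random_hypnogram <- function(n, epoch_seconds = 5, p_unscored = 0) {
  hypnogram(random_stages(n, p_unscored), epoch_seconds,
            subject_id = "rand")
}

## sticky random night: diagonal-dominant chain so runs are realistic
random_night <- function(n, epoch_seconds = 5, stay = 0.85) {
  s <- integer(n)
  s[1] <- sample.int(5L, 1L)
  for (i in 2:n) {
    s[i] <- if (runif(1) < stay) s[i - 1L] else sample.int(5L, 1L)
  }
  hypnogram(ORACLE_STAGES[s], epoch_seconds, subject_id = "night")
}
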