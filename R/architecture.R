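## Sleep onset: first unit scored as any sleep stage after lights off.
## Returns the 0-based offset within the lights window, or NA if the
## subject never sleeps.
sleep_onset_index <- function(w) {
  i <- which(w %in% SLEEP_STAGES)
  if (!length(i)) NA_integer_ else i[1L] - 1L
}

#' Conventional sleep architecture summary
#'
#' Computes the standard polysomnography summary over the lights window:
#' time in bed (TIB, lights-off to lights-on), total sleep time (TST,
#' time in N1/N2/N3/REM), sleep efficiency `100 * TST / TIB`, stage
#' percentages, sleep latency (lights off to first sleep unit), REM
#' latency (sleep onset to first REM unit), and the early-REM flag
#' (at least one REM unit beginning strictly less than 15 min after
#' sleep onset). Identical definitions apply at 30-s and 5-s resolution.
#'
#' Stage percentages are relative to scored time in bed; unscored units
#' are excluded from the denominator so that wake% plus the four sleep
#' stage percentages always total 100.
#'
#' @param h a `hypnogram` with a nonempty lights window.
#' @return An object of class `sleep_architecture`: a list with fields
#'   `tib_hours`, `tst_hours`, `sleep_efficiency_pct`, `stage_pct`,
#'   `sleep_latency_min`, `rem_latency_min`, `early_rem_flag`,
#'   `epochs_per_stage`, `n_unscored`.
#' @examples
#' h <- hypnogram(rep(c("W", "N2"), c(4, 8)), epoch_seconds = 30)
#' compute_architecture(h)
#' @export
compute_architecture <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  w <- lights_window(h)
  es <- h$epoch_seconds
  tib_hours <- length(w) * es / 3600
  counts <- table(factor(w, levels = STAGE_TOKENS))
  per_stage <- as.integer(counts[STAGE_ORDER])
  names(per_stage) <- STAGE_ORDER
  n_scored <- sum(per_stage)
  n_sleep <- sum(per_stage[SLEEP_STAGES])
  tst_hours <- n_sleep * es / 3600
  se <- 100 * tst_hours / tib_hours
  stage_pct <- if (n_scored > 0) 100 * per_stage / n_scored else
    setNames(rep(NA_real_, 5L), STAGE_ORDER)

  onset <- sleep_onset_index(w)
  sleep_latency_min <- if (is.na(onset)) NA_real_ else onset * es / 60
  rem <- detect_early_rem(h)
  structure(
    list(subject_id = h$subject_id,
         resolution_tag = h$resolution_tag,
         tib_hours = tib_hours,
         tst_hours = tst_hours,
         sleep_efficiency_pct = se,
         stage_pct = stage_pct,
         sleep_latency_min = sleep_latency_min,
         rem_latency_min = rem$rem_latency_min,
         early_rem_flag = rem$flag,
         epochs_per_stage = per_stage,
         n_unscored = length(w) - n_scored),
    class = "sleep_architecture")
}

#' @export
print.sleep_architecture <- function(x, ...) {
  cat(sprintf("<sleep architecture> %s (%s)\n", x$subject_id, x$resolution_tag))
  cat(sprintf("  TIB %.2f h, TST %.2f h, SE %.1f%%\n",
              x$tib_hours, x$tst_hours, x$sleep_efficiency_pct))
  cat("  stage %:", paste(sprintf("%s %.1f", names(x$stage_pct), x$stage_pct),
                          collapse = ", "), "\n")
  cat(sprintf("  sleep latency %s min, REM latency %s min, early REM: %s\n",
              format(round(x$sleep_latency_min, 2)),
              format(round(x$rem_latency_min, 2)),
              x$early_rem_flag))
  invisible(x)
}

#' Detect early-appearing REM sleep (SOREMP analogue)
#'
#' Flags whether at least one REM unit begins strictly less than
#' `window_minutes` after sleep onset, and returns the REM latency
#' (sleep onset to first REM unit) in minutes. The strict inequality and
#' the anchoring at sleep onset follow the standard sleep-onset REM
#' period definition; with 5-s mini-epochs a single REM mini-epoch
#' suffices.
#'
#' @param h a `hypnogram`.
#' @param window_minutes latency threshold in minutes (default 15).
#' @return List with `flag` (logical) and `rem_latency_min` (numeric,
#'   `NA` when the subject never sleeps or never reaches REM).
#' @export
detect_early_rem <- function(h, window_minutes = 15) {
  stopifnot(inherits(h, "hypnogram"), window_minutes > 0)
  w <- lights_window(h)
  onset <- sleep_onset_index(w)
  if (is.na(onset)) return(list(flag = FALSE, rem_latency_min = NA_real_))
  first_rem <- which(w == "R")
  if (!length(first_rem)) return(list(flag = FALSE, rem_latency_min = NA_real_))
  rem_latency_min <- (first_rem[1L] - 1L - onset) * h$epoch_seconds / 60
  list(flag = rem_latency_min < window_minutes,
       rem_latency_min = rem_latency_min)
}
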