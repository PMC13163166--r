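TRANSITION_CATEGORIES <- c("all_stages", "nrem_rem", "sleep_wake",
                           "within_nrem")

NREM_STAGES <- c("N1", "N2", "N3")

#' Count stage transitions of a given category
#'
#' Scans adjacent ordered unit pairs inside the lights window and counts
#' stage changes, filtered by category. Pairs containing an unscored
#' unit are skipped. Categories (each direction-symmetric):
#' \describe{
#'   \item{all_stages}{any stage change}
#'   \item{nrem_rem}{N1/N2/N3 to REM or REM to N1/N2/N3}
#'   \item{sleep_wake}{wake to any sleep stage or any sleep stage to wake}
#'   \item{within_nrem}{changes among N1, N2, N3}
#' }
#' The three specific categories partition `all_stages`.
#'
#' @param h a `hypnogram` (the lights window is used).
#' @param category one of the category names above.
#' @return Nonnegative integer count.
#' @export
count_transitions <- function(h, category = "all_stages") {
  stopifnot(inherits(h, "hypnogram"))
  category <- match.arg(category, TRANSITION_CATEGORIES)
  w <- lights_window(h)
  if (length(w) < 2L) return(0L)
  from <- w[-length(w)]
  to <- w[-1L]
  keep <- from != "U" & to != "U" & from != to
  from <- from[keep]; to <- to[keep]
  n <- switch(category,
    all_stages = length(from),
    nrem_rem = sum((from %in% NREM_STAGES & to == "R") |
                   (from == "R" & to %in% NREM_STAGES)),
    sleep_wake = sum((from == "W" & to %in% SLEEP_STAGES) |
                     (from %in% SLEEP_STAGES & to == "W")),
    within_nrem = sum(from %in% NREM_STAGES & to %in% NREM_STAGES))
  as.integer(n)
}

#' Stage transition indices per hour of total sleep time
#'
#' The fragmentation indices: number of stage transitions of each
#' category (see [count_transitions()]) divided by total sleep time in
#' hours, so an all-stages index of 12 means 12 stage changes per hour
#' of sleep. Computed identically for 30-s epochs and 5-s mini-epochs.
#'
#' @param h a `hypnogram` with nonzero total sleep time in its lights
#'   window.
#' @return Object of class `transition_index_set`: list with `counts`
#'   and `indices_per_hour` (named over the four categories) and
#'   `tst_hours`.
#' @export
transition_indices <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  w <- lights_window(h)
  tst_hours <- sum(w %in% SLEEP_STAGES) * h$epoch_seconds / 3600
  if (tst_hours <= 0)
    stop("transition indices undefined: zero total sleep time for subject '",
         h$subject_id, "'")
  counts <- vapply(TRANSITION_CATEGORIES, function(k)
    count_transitions(h, k), 0L)
  structure(
    list(subject_id = h$subject_id,
         resolution_tag = h$resolution_tag,
         counts = counts,
         indices_per_hour = counts / tst_hours,
         tst_hours = tst_hours),
    class = "transition_index_set")
}

#' @export
print.transition_index_set <- function(x, ...) {
  cat(sprintf("<transition indices> %s (%s), TST %.2f h\n",
              x$subject_id, x$resolution_tag, x$tst_hours))
  for (k in names(x$counts))
    cat(sprintf("  %-12s %4d transitions  %7.2f /h\n",
                k, x$counts[[k]], x$indices_per_hour[[k]]))
  invisible(x)
}

#' Wake-period run-length taxonomy for 5-s mini-epoch hypnograms
#'
#' Classifies maximal runs of consecutive wake mini-epochs by duration:
#' short (one mini-epoch, <= 5 s), intermediate (two to three
#' mini-epochs), long (more than three mini-epochs, > 15 s), and reports
#' counts plus rates per hour of total sleep time. By default runs are
#' counted from sleep onset through the last sleep unit, so that sleep
#' latency and the final awakening are not counted as fragmentation;
#' `counting_region = "window"` counts over the whole lights window
#' instead (used for night halves, where the sleep period bounds are
#' already enforced by the split).
#'
#' @param h5 a `hypnogram` at 5-s resolution.
#' @param counting_region `"post-onset"` (default) or `"window"`.
#' @return Object of class `wake_period_counts`: `n_short`,
#'   `n_intermediate`, `n_long`, `rates_per_hour`, `tst_hours`.
#' @export
wake_period_counts <- function(h5, counting_region = c("post-onset", "window")) {
  stopifnot(inherits(h5, "hypnogram"))
  counting_region <- match.arg(counting_region)
  if (!isTRUE(all.equal(h5$epoch_seconds, 5)))
    stop("wake-period taxonomy is defined for 5-s mini-epoch hypnograms")
  w <- lights_window(h5)
  tst_hours <- sum(w %in% SLEEP_STAGES) * h5$epoch_seconds / 3600
  sleep_idx <- which(w %in% SLEEP_STAGES)
  if (!length(sleep_idx))
    stop("no sleep in window: wake-period counting region undefined for '",
         h5$subject_id, "'")
  region <- if (counting_region == "post-onset")
    w[sleep_idx[1L]:sleep_idx[length(sleep_idx)]] else w
  r <- rle(region)
  wake_runs <- r$lengths[r$values == "W"]
  n_short <- sum(wake_runs == 1L)
  n_intermediate <- sum(wake_runs >= 2L & wake_runs <= 3L)
  n_long <- sum(wake_runs >= 4L)
  counts <- c(short = n_short, intermediate = n_intermediate, long = n_long)
  structure(
    list(subject_id = h5$subject_id,
         n_short = n_short,
         n_intermediate = n_intermediate,
         n_long = n_long,
         rates_per_hour = if (tst_hours > 0) counts / tst_hours else
           counts * NA_real_,
         tst_hours = tst_hours,
         counting_region = counting_region),
    class = "wake_period_counts")
}

#' @export
print.wake_period_counts <- function(x, ...) {
  cat(sprintf(
    "<wake periods> %s (%s region): short %d, intermediate %d, long %d\n",
    x$subject_id, x$counting_region, x$n_short, x$n_intermediate, x$n_long))
  cat("  per hour TST:",
      paste(sprintf("%s %.2f", names(x$rates_per_hour), x$rates_per_hour),
            collapse = ", "), "\n")
  invisible(x)
}
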