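#' Split the total sleep period into two equal halves
#'
#' The total sleep period (SPT) runs from the first sleep unit after
#' lights off through the last sleep unit, inclusive; sleep latency and
#' terminal wake are excluded. The SPT is divided at
#' `floor(length / 2)`: when its length is odd the second half receives
#' the extra unit. Both halves are returned as hypnograms with rebased
#' lights windows covering the whole half.
#'
#' @param h a `hypnogram` with at least one sleep unit.
#' @return List with `first` and `second` (hypnograms) and
#'   `half_boundary_index`, the 0-based SPT offset at which the second
#'   half begins.
#' @export
split_total_sleep_period <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  w <- lights_window(h)
  sleep_idx <- which(w %in% SLEEP_STAGES)
  if (!length(sleep_idx))
    stop("no sleep in window: cannot split for subject '", h$subject_id, "'")
  spt <- w[sleep_idx[1L]:sleep_idx[length(sleep_idx)]]
  n <- length(spt)
  if (n < 2L)
    stop("total sleep period shorter than two units for subject '",
         h$subject_id, "'")
  b <- n %/% 2L                    # first half gets the smaller share
  list(first = hypnogram(spt[seq_len(b)], h$epoch_seconds,
                         subject_id = h$subject_id),
       second = hypnogram(spt[(b + 1L):n], h$epoch_seconds,
                          subject_id = h$subject_id),
       half_boundary_index = b)
}

half_metrics <- function(hh, include_matrix, wake_periods) {
  w <- lights_window(hh)
  tst_hours <- sum(w %in% SLEEP_STAGES) * hh$epoch_seconds / 3600
  idx <- if (tst_hours > 0) transition_indices(hh) else NULL
  wp <- if (wake_periods && tst_hours > 0 &&
            isTRUE(all.equal(hh$epoch_seconds, 5)))
    wake_period_counts(hh, counting_region = "window") else NULL
  list(tst_hours = tst_hours,
       indices = idx,
       wake_periods = wp,
       matrix = if (include_matrix) estimate_transition_matrix(hh) else NULL,
       undefined = tst_hours <= 0)
}

#' Per-half fragmentation metrics (split-night analysis)
#'
#' Splits the total sleep period with [split_total_sleep_period()] and
#' recomputes the transition indices, wake-period taxonomy (5-s inputs
#' only; counted over the whole half window, since the split already
#' bounds the sleep period) and optionally the transition matrix on each
#' half, exactly as on full nights. A half with zero total sleep time is
#' flagged undefined rather than raising.
#'
#' @param h a `hypnogram`.
#' @param include_matrix also estimate per-half transition matrices.
#' @return Object of class `split_night_result`: `first`, `second`
#'   (each with `tst_hours`, `indices`, `wake_periods`, `matrix`,
#'   `undefined`), and `half_boundary_index`.
#' @export
per_half_metrics <- function(h, include_matrix = FALSE) {
  halves <- split_total_sleep_period(h)
  is5 <- isTRUE(all.equal(h$epoch_seconds, 5))
  structure(
    list(subject_id = h$subject_id,
         resolution_tag = h$resolution_tag,
         first = half_metrics(halves$first, include_matrix, is5),
         second = half_metrics(halves$second, include_matrix, is5),
         half_boundary_index = halves$half_boundary_index),
    class = "split_night_result")
}

#' @export
print.split_night_result <- function(x, ...) {
  cat(sprintf("<split night> %s (%s), boundary at SPT unit %d\n",
              x$subject_id, x$resolution_tag, x$half_boundary_index))
  for (hf in c("first", "second")) {
    m <- x[[hf]]
    if (m$undefined) {
      cat(sprintf("  %s half: undefined (no sleep)\n", hf))
    } else {
      cat(sprintf("  %s half: TST %.2f h, sleep-wake %.2f /h, all-stages %.2f /h\n",
                  hf, m$tst_hours,
                  m$indices$indices_per_hour[["sleep_wake"]],
                  m$indices$indices_per_hour[["all_stages"]]))
    }
  }
  invisible(x)
}
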