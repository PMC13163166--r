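#' Sleep stage vocabulary
#'
#' The five scoreable sleep stages in the fixed order used throughout the
#' package (and in every matrix output): wake, N1, N2, N3, REM. `"U"`
#' marks unscored units; it is carried in sequences but never enters any
#' metric numerator or denominator.
#'
#' @format Character vectors.
#' @name stage-vocabulary
NULL

#' @rdname stage-vocabulary
#' @export
STAGE_ORDER <- c("W", "N1", "N2", "N3", "R")

#' @rdname stage-vocabulary
#' @export
SLEEP_STAGES <- c("N1", "N2", "N3", "R")

STAGE_TOKENS <- c(STAGE_ORDER, "U")

## AASM-style numeric codes: 0 wake, 1-3 NREM, 5 REM, 9 unscored
NUMERIC_CODE <- c(`0` = "W", `1` = "N1", `2` = "N2", `3` = "N3",
                  `5` = "R", `9` = "U")

resolution_tag_for <- function(epoch_seconds) {
  if (isTRUE(all.equal(epoch_seconds, 30))) "epoch30"
  else if (isTRUE(all.equal(epoch_seconds, 5))) "miniepoch5"
  else "other"
}

#' Construct a hypnogram
#'
#' A hypnogram is an ordered sequence of sleep stage labels at a fixed
#' scoring resolution, together with a lights-off/lights-on window.
#' Epoch indices are 0-based and the lights window is half-open:
#' `[lights_off, lights_on)`, so a window covering the whole recording is
#' `lights_off = 0`, `lights_on = length(stages)`.
#'
#' @param stages character vector of stage tokens (`W`, `N1`, `N2`, `N3`,
#'   `R`, `U`).
#' @param epoch_seconds duration of one unit in seconds (canonically 30
#'   or 5).
#' @param lights_off,lights_on 0-based unit offsets delimiting the
#'   analysis window; defaults cover the full sequence.
#' @param subject_id subject identifier.
#' @return An object of class `hypnogram`.
#' @examples
#' h <- hypnogram(c("W", "N1", "N2", "N2", "R"), epoch_seconds = 30)
#' h
#' @export
hypnogram <- function(stages, epoch_seconds,
                      lights_off = 0L, lights_on = length(stages),
                      subject_id = "anon") {
  h <- new_hypnogram(as.character(stages), epoch_seconds,
                     as.integer(lights_off), as.integer(lights_on),
                     subject_id)
  issues <- validate_hypnogram(h)
  if (length(issues))
    stop("invalid hypnogram '", subject_id, "': ",
         paste(issues, collapse = "; "), call. = FALSE)
  h
}

## low-level constructor, no checks (validate_hypnogram reports on these)
new_hypnogram <- function(stages, epoch_seconds, lights_off, lights_on,
                          subject_id = "anon") {
  structure(
    list(subject_id = subject_id,
         stages = stages,
         epoch_seconds = epoch_seconds,
         lights_off = lights_off,
         lights_on = lights_on,
         resolution_tag = resolution_tag_for(epoch_seconds)),
    class = "hypnogram")
}

#' Validate a hypnogram, reporting issues rather than raising
#'
#' @param h a `hypnogram` (possibly malformed).
#' @return Character vector of issue descriptions; empty when all
#'   invariants hold.
#' @export
validate_hypnogram <- function(h) {
  issues <- character(0)
  if (!length(h$stages))
    issues <- c(issues, "stages: sequence is empty")
  bad <- which(!(h$stages %in% STAGE_TOKENS))
  if (length(bad))
    issues <- c(issues, sprintf(
      "stages: unknown token '%s' at position %d (0-based)",
      h$stages[bad[1]], bad[1] - 1L))
  if (!is.numeric(h$epoch_seconds) || length(h$epoch_seconds) != 1 ||
      is.na(h$epoch_seconds) || h$epoch_seconds <= 0)
    issues <- c(issues, "epoch_seconds: must be a single positive number")
  off <- h$lights_off; on <- h$lights_on
  if (!is.numeric(off) || !is.numeric(on) || is.na(off) || is.na(on) ||
      off < 0 || on > length(h$stages) || off >= on)
    issues <- c(issues, sprintf(
      "lights window: require 0 <= lights_off < lights_on <= length; got [%s, %s) with length %d",
      format(off), format(on), length(h$stages)))
  issues
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x$stages)
  cat(sprintf("<hypnogram> subject %s: %d units x %gs (%s), lights [%d, %d)\n",
              x$subject_id, n, x$epoch_seconds, x$resolution_tag,
              x$lights_off, x$lights_on))
  occ <- table(factor(x$stages, levels = STAGE_TOKENS))
  cat("  units per stage:",
      paste(sprintf("%s=%d", names(occ), occ), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.hypnogram <- function(object, ...) {
  print(object)
  print(compute_architecture(object))
  invisible(object)
}

## stages inside the lights window (1-based view of [off, on))
lights_window <- function(h) {
  h$stages[(h$lights_off + 1L):h$lights_on]
}

#' Crop a hypnogram to its lights window
#'
#' All analyses operate between lights off and lights on; cropping drops
#' units outside the window and rebases the lights indices to
#' `[0, length)`. Idempotent.
#'
#' @param h a `hypnogram`.
#' @return A `hypnogram` containing only the lights window.
#' @export
crop_to_lights <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  w <- lights_window(h)
  hypnogram(w, h$epoch_seconds, 0L, length(w), h$subject_id)
}

#' Downsample a mini-epoch hypnogram by within-window majority vote
#'
#' Collapses each run of `factor` consecutive units (aligned at lights
#' off) to the modal stage of the window. Ties are broken
#' deterministically in favour of the tied stage whose last occurrence in
#' the window is latest ("last-in-window"), biasing towards forward
#' continuity. A trailing partial window is dropped. Used to derive 30-s
#' twins of synthetic 5-s hypnograms.
#'
#' @param h5 a `hypnogram`, typically at 5-s resolution.
#' @param factor positive integer number of units per output window
#'   (default 6: 5 s x 6 = 30 s).
#' @param tie_rule tie-breaking rule; only `"last-in-window"` is defined.
#' @return A `hypnogram` with `epoch_seconds * factor` resolution.
#' @export
downsample_majority <- function(h5, factor = 6L,
                                tie_rule = "last-in-window") {
  stopifnot(inherits(h5, "hypnogram"))
  tie_rule <- match.arg(tie_rule)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  w <- lights_window(h5)
  n_win <- length(w) %/% factor
  if (n_win < 1L) stop("window shorter than one downsampling factor")
  idx <- matrix(match(w[seq_len(n_win * factor)], STAGE_TOKENS),
                nrow = factor)
  out <- apply(idx, 2L, function(col) {
    tab <- tabulate(col, nbins = length(STAGE_TOKENS))
    cand <- which(tab == max(tab))
    if (length(cand) > 1L) {
      ## last-in-window: latest final occurrence among tied stages wins
      last_pos <- vapply(cand, function(s) max(which(col == s)), 0L)
      cand <- cand[which.max(last_pos)]
    }
    cand
  })
  hypnogram(STAGE_TOKENS[out], h5$epoch_seconds * factor,
            0L, n_win, h5$subject_id)
}
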