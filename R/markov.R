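#' Estimate the per-subject discrete-time Markov transition matrix
#'
#' Counts all ordered adjacent stage-to-stage steps in the lights window
#' (including self-transitions) into a 5x5 count matrix over the fixed
#' stage order (W, N1, N2, N3, R), then row-normalizes by the total
#' number of steps originating from each stage. Diagonal elements are
#' the probabilities of remaining in a stage. The final unit of the
#' window originates no step; steps touching an unscored unit are
#' skipped. Rows whose stage never originates a step are left `NA`
#' (explicitly undefined), never silently zero.
#'
#' @param h a `hypnogram` with at least two scored units in its lights
#'   window.
#' @return Object of class `transition_matrix`: `stage_order`, `counts`,
#'   `probs`, `origin_totals`, `n_steps`.
#' @examples
#' h <- hypnogram(c("N2", "N2", "N2", "W", "N2"), epoch_seconds = 30)
#' estimate_transition_matrix(h)
#' @export
estimate_transition_matrix <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  w <- lights_window(h)
  if (sum(w != "U") < 2L)
    stop("need at least two scored units to estimate a transition matrix")
  from <- w[-length(w)]
  to <- w[-1L]
  keep <- from != "U" & to != "U"
  counts <- table(factor(from[keep], levels = STAGE_ORDER),
                  factor(to[keep], levels = STAGE_ORDER))
  counts <- matrix(as.integer(counts), 5L, 5L,
                   dimnames = list(from = STAGE_ORDER, to = STAGE_ORDER))
  origin_totals <- rowSums(counts)
  probs <- counts / ifelse(origin_totals > 0, origin_totals, NA_real_)
  structure(
    list(subject_id = h$subject_id,
         resolution_tag = h$resolution_tag,
         stage_order = STAGE_ORDER,
         counts = counts,
         probs = probs,
         origin_totals = origin_totals,
         n_steps = sum(keep)),
    class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<transition matrix> %s (%s), %d counted steps\n",
              x$subject_id, x$resolution_tag, x$n_steps))
  print(round(x$probs, digits))
  und <- x$stage_order[x$origin_totals == 0]
  if (length(und))
    cat("  undefined rows (no originating steps):",
        paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' Stage occupancy distribution
#'
#' Fraction of scored units per stage over the lights window; sums to 1.
#'
#' @param h a `hypnogram` with at least one scored unit.
#' @return Named numeric vector over (W, N1, N2, N3, R).
#' @export
stage_occupancy <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  w <- lights_window(h)
  w <- w[w != "U"]
  if (!length(w)) stop("all units unscored: occupancy undefined")
  tab <- table(factor(w, levels = STAGE_ORDER))
  as.numeric(tab) / length(w) -> occ
  names(occ) <- STAGE_ORDER
  occ
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Power iteration on the transpose; converges for the irreducible
#' aperiodic matrices used as generator presets.
#'
#' @param P 5x5 (or k x k) row-stochastic matrix.
#' @param tol convergence tolerance on the max-abs update (default 1e-12).
#' @param max_iter iteration cap.
#' @return Probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P, tol = 1e-12, max_iter = 100000L) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (any(abs(rowSums(P) - 1) > 1e-8)) stop("matrix rows must sum to 1")
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(max_iter)) {
    v_new <- as.numeric(v %*% P)
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  names(v) <- rownames(P)
  v / sum(v)
}
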