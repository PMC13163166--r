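## Tidy per-subject table builders: one row per hypnogram, consumed by
## the cohort statistics layer and written out by run_pipeline().

#' Per-subject sleep architecture table
#'
#' @param hypnograms list of `hypnogram` objects.
#' @return Data frame, one row per hypnogram, with the
#'   [compute_architecture()] fields.
#' @export
architecture_table <- function(hypnograms) {
  do.call(rbind, lapply(hypnograms, function(h) {
    a <- compute_architecture(h)
    data.frame(subject_id = a$subject_id,
               resolution_tag = a$resolution_tag,
               tib_hours = a$tib_hours,
               tst_hours = a$tst_hours,
               sleep_efficiency_pct = a$sleep_efficiency_pct,
               pct_wake = a$stage_pct[["W"]],
               pct_n1 = a$stage_pct[["N1"]],
               pct_n2 = a$stage_pct[["N2"]],
               pct_n3 = a$stage_pct[["N3"]],
               pct_rem = a$stage_pct[["R"]],
               sleep_latency_min = a$sleep_latency_min,
               rem_latency_min = a$rem_latency_min,
               early_rem_flag = a$early_rem_flag,
               n_unscored = a$n_unscored,
               stringsAsFactors = FALSE)
  }))
}

#' Per-subject fragmentation table (full night)
#'
#' Transition counts and per-hour indices for the four categories, and
#' for 5-s inputs the wake-period taxonomy.
#'
#' @param hypnograms list of `hypnogram` objects.
#' @param wake_region counting region for [wake_period_counts()].
#' @return Data frame, one row per hypnogram.
#' @export
fragmentation_table <- function(hypnograms,
                                wake_region = "post-onset") {
  do.call(rbind, lapply(hypnograms, function(h) {
    ti <- transition_indices(h)
    row <- data.frame(subject_id = ti$subject_id,
                      resolution_tag = ti$resolution_tag,
                      tst_hours = ti$tst_hours,
                      stringsAsFactors = FALSE)
    for (k in TRANSITION_CATEGORIES) {
      row[[paste0("n_", k)]] <- ti$counts[[k]]
      row[[paste0("index_", k)]] <- ti$indices_per_hour[[k]]
    }
    if (isTRUE(all.equal(h$epoch_seconds, 5))) {
      wp <- wake_period_counts(h, counting_region = wake_region)
      row$wp_short <- wp$n_short
      row$wp_intermediate <- wp$n_intermediate
      row$wp_long <- wp$n_long
      row$wp_short_rate <- wp$rates_per_hour[["short"]]
      row$wp_intermediate_rate <- wp$rates_per_hour[["intermediate"]]
      row$wp_long_rate <- wp$rates_per_hour[["long"]]
    } else {
      row[c("wp_short", "wp_intermediate", "wp_long", "wp_short_rate",
            "wp_intermediate_rate", "wp_long_rate")] <- NA_real_
    }
    row
  }))
}

#' Long-format per-subject transition matrices
#'
#' One row per subject, resolution and ordered stage pair, with the
#' step count and the row-normalized probability (`NA` on undefined
#' rows). The direct input to [compare_transition_probabilities()].
#'
#' @param hypnograms list of `hypnogram` objects.
#' @return Data frame with columns `subject_id`, `resolution_tag`,
#'   `from`, `to`, `count`, `prob`.
#' @export
matrices_long <- function(hypnograms) {
  do.call(rbind, lapply(hypnograms, function(h) {
    tm <- estimate_transition_matrix(h)
    grid <- expand.grid(to = STAGE_ORDER, from = STAGE_ORDER,
                        stringsAsFactors = FALSE)[, c("from", "to")]
    data.frame(subject_id = tm$subject_id,
               resolution_tag = tm$resolution_tag,
               grid,
               count = tm$counts[cbind(grid$from, grid$to)],
               prob = tm$probs[cbind(grid$from, grid$to)],
               stringsAsFactors = FALSE)
  }))
}

#' Per-subject split-night metric table
#'
#' One row per subject, resolution and night-half with the per-half
#' transition indices and (5-s inputs) wake-period counts and rates —
#' the repeated-measures input to [split_night_model()].
#'
#' @param hypnograms list of `hypnogram` objects.
#' @return Data frame in long (half-wise) format.
#' @export
splitnight_table <- function(hypnograms) {
  do.call(rbind, lapply(hypnograms, function(h) {
    sn <- per_half_metrics(h)
    do.call(rbind, lapply(c("first", "second"), function(hf) {
      m <- sn[[hf]]
      row <- data.frame(subject_id = sn$subject_id,
                        resolution_tag = sn$resolution_tag,
                        half = hf,
                        tst_hours = m$tst_hours,
                        stringsAsFactors = FALSE)
      for (k in TRANSITION_CATEGORIES)
        row[[paste0("index_", k)]] <-
          if (m$undefined) NA_real_ else m$indices$indices_per_hour[[k]]
      if (!is.null(m$wake_periods)) {
        wp <- m$wake_periods
        row$wp_short <- wp$n_short
        row$wp_intermediate <- wp$n_intermediate
        row$wp_long <- wp$n_long
        row$wp_short_rate <- wp$rates_per_hour[["short"]]
        row$wp_intermediate_rate <- wp$rates_per_hour[["intermediate"]]
        row$wp_long_rate <- wp$rates_per_hour[["long"]]
      } else {
        row[c("wp_short", "wp_intermediate", "wp_long", "wp_short_rate",
              "wp_intermediate_rate", "wp_long_rate")] <- NA_real_
      }
      row
    }))
  }))
}
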