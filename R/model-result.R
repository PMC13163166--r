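## Container for one fitted comparison: the coefficient of interest with
## Wald CI, p-value, and the standardized effect size defined as the
## coefficient divided by the model's residual standard deviation.
model_result <- function(outcome_name, term, coefficient, se, p_value,
                         residual_sd, n_subjects, n_observations,
                         transformed_flag, model_descriptor, notes = "") {
  z <- stats::qnorm(0.975)
  structure(
    list(outcome_name = outcome_name,
         term = term,
         coefficient = coefficient,
         ci95_low = coefficient - z * se,
         ci95_high = coefficient + z * se,
         se = se,
         p_value = p_value,
         cohens_d = coefficient / residual_sd,
         residual_sd = residual_sd,
         n_subjects = n_subjects,
         n_observations = n_observations,
         transformed_flag = transformed_flag,
         model_descriptor = model_descriptor,
         notes = notes),
    class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model result> %s ~ %s\n", x$outcome_name, x$term))
  cat(sprintf("  beta %.4f [%.4f, %.4f], p = %.4g, d = %.3f%s\n",
              x$coefficient, x$ci95_low, x$ci95_high, x$p_value,
              x$cohens_d,
              if (x$transformed_flag) " (log-transformed outcome)" else ""))
  cat(sprintf("  %s; n = %d subjects, %d observations\n",
              x$model_descriptor, x$n_subjects, x$n_observations))
  if (nzchar(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

#' @export
as.data.frame.model_result <- function(x, ...) {
  data.frame(outcome_name = x$outcome_name, term = x$term,
             coefficient = x$coefficient, ci95_low = x$ci95_low,
             ci95_high = x$ci95_high, se = x$se, p_value = x$p_value,
             cohens_d = x$cohens_d, residual_sd = x$residual_sd,
             n_subjects = x$n_subjects,
             n_observations = x$n_observations,
             transformed_flag = x$transformed_flag,
             model_descriptor = x$model_descriptor, notes = x$notes,
             stringsAsFactors = FALSE)
}
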