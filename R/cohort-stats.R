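#' Optionally log-transform an outcome column
#'
#' Mechanizes the usual "log-transform when residuals look non-normal"
#' rule as a reproducible skewness threshold: under `policy = "auto"`
#' the natural log is applied when the moment skewness of the values
#' exceeds `skew_threshold` in absolute value and all values are
#' strictly positive (otherwise the transform is skipped with a notice).
#' `"always"` demands strictly positive values; `"never"` is the
#' identity.
#'
#' @param values numeric vector.
#' @param policy `"auto"`, `"always"` or `"never"`.
#' @param skew_threshold absolute moment-skewness above which `"auto"`
#'   transforms (default 1).
#' @return List with `values` and `transformed` flag.
#' @export
maybe_log_transform <- function(values, policy = c("auto", "always", "never"),
                                skew_threshold = 1) {
  policy <- match.arg(policy)
  values <- as.numeric(values)
  if (policy == "never")
    return(list(values = values, transformed = FALSE))
  positive <- all(values > 0, na.rm = TRUE)
  if (policy == "always") {
    if (!positive) stop("log transform requires strictly positive values")
    return(list(values = log(values), transformed = TRUE))
  }
  if (!positive) {
    message("auto log-transform skipped: nonpositive values present")
    return(list(values = values, transformed = FALSE))
  }
  if (abs(sample_skewness(values)) > skew_threshold)
    list(values = log(values), transformed = TRUE)
  else
    list(values = values, transformed = FALSE)
}

## moment skewness m3 / m2^(3/2)
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up procedure at false discovery rate `q`: adjusted
#' p-values via [stats::p.adjust()] (method `"BH"`), a hypothesis is
#' rejected when its adjusted p-value is at most `q`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return List with logical `rejected` and numeric `adjusted_p`.
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(rejected = adjusted <= q, adjusted_p = adjusted)
}

## rank-deficiency check on the fixed-effects design, naming the
## columns dropped by the QR decomposition
check_design <- function(data, fixed_terms, outcome) {
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(fixed_terms, collapse = " + "))),
    data = data)
  qr_d <- qr(mm)
  if (qr_d$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_d$pivot[(qr_d$rank + 1L):ncol(mm)]]
    stop("singular design for outcome '", outcome,
         "': collinear columns ", paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit a mixed-effects group (or predictor) comparison for one outcome
#'
#' Fits a linear mixed-effects model
#' `outcome ~ predictor + covariates + (1 | random term)` (random
#' intercept per family and/or participant) and reports the predictor
#' coefficient with Wald 95% CI, its p-value, and Cohen's d defined as
#' the coefficient divided by the model's residual standard deviation.
#' The numerical fit is delegated to \pkg{lmerTest}/\pkg{lme4}
#' (Satterthwaite p-values); when the random-effect variance is
#' estimated at zero (singular fit) or no random terms are given, the
#' model degrades to ordinary least squares with a notice. Rows missing
#' any used column are excluded, so subjects missing an optional
#' predictor drop out only of models that use it.
#'
#' @param data subject-level data frame.
#' @param outcome name of the numeric outcome column.
#' @param predictor name of the focal predictor column (factor, logical
#'   or numeric); for multi-level factors the first non-reference level
#'   is reported.
#' @param covariates adjustment covariate column names.
#' @param random random-intercept grouping column names (possibly
#'   empty for plain multiple regression).
#' @param transform log-transform policy passed to
#'   [maybe_log_transform()].
#' @param subject_col column identifying subjects (for the reported n).
#' @return A `model_result`.
#' @export
fit_group_comparison <- function(data, outcome, predictor,
                                 covariates = c("age_years", "sex"),
                                 random = "family_id",
                                 transform = "auto",
                                 subject_col = "subject_id") {
  used <- c(outcome, predictor, covariates, random)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[used])
  data <- data[keep, , drop = FALSE]
  if (is.character(data[[predictor]]) || is.logical(data[[predictor]]))
    data[[predictor]] <- factor(data[[predictor]])
  if (is.factor(data[[predictor]]) && nlevels(droplevels(data[[predictor]])) < 2L)
    stop("predictor '", predictor, "' has fewer than 2 levels after exclusions")
  y <- data[[outcome]]
  if (length(unique(y)) < 2L)
    stop("constant outcome '", outcome, "'")
  tr <- maybe_log_transform(y, transform)
  data[[".y"]] <- tr$values
  fixed_terms <- c(predictor, covariates)
  check_design(data, fixed_terms, outcome)

  fixed_rhs <- paste(fixed_terms, collapse = " + ")
  notes <- character(0)
  engine <- "OLS"
  fit <- NULL
  if (length(random)) {
    rand_rhs <- paste(sprintf("(1 | %s)", random), collapse = " + ")
    fml <- stats::as.formula(paste(".y ~", fixed_rhs, "+", rand_rhs))
    fit <- tryCatch(
      lmerTest::lmer(fml, data = data,
                     control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) {
      message("random-effect variance estimated at zero for '", outcome,
              "': falling back to fixed-effects model")
      notes <- c(notes, "singular random effect; fixed-effects fallback")
      fit <- NULL
    } else if (is.null(fit)) {
      notes <- c(notes, "mixed fit failed; fixed-effects fallback")
    } else {
      engine <- "LME (lmerTest, Satterthwaite)"
    }
  }
  if (is.null(fit)) {
    fit <- stats::lm(stats::as.formula(paste(".y ~", fixed_rhs)), data = data)
  }
  ct <- stats::coef(summary(fit))
  row <- if (is.factor(data[[predictor]]))
    grep(paste0("^", predictor), rownames(ct))[1L] else
    match(predictor, rownames(ct))
  if (is.na(row)) stop("predictor coefficient not found for '", predictor, "'")
  model_result(
    outcome_name = outcome,
    term = rownames(ct)[row],
    coefficient = ct[row, "Estimate"],
    se = ct[row, "Std. Error"],
    p_value = ct[row, "Pr(>|t|)"],
    residual_sd = stats::sigma(fit),
    n_subjects = if (subject_col %in% names(data))
      length(unique(data[[subject_col]])) else nrow(data),
    n_observations = nrow(data),
    transformed_flag = tr$transformed,
    model_descriptor = sprintf("%s: .y ~ %s%s; Wald 95%% CI", engine,
                               fixed_rhs,
                               if (length(random) && engine != "OLS")
                                 paste0(" + ", rand_rhs) else ""),
    notes = paste(notes, collapse = "; "))
}

#' Per-cell mixed-model comparison of transition probabilities
#'
#' Fits one mixed-effects group comparison per transition-matrix cell
#' and resolution (5 x 5 cells x number of resolutions; 50 models for
#' the canonical two-resolution analysis), adjusting for the given
#' covariates with a family random intercept, then applies
#' Benjamini-Hochberg control jointly across every fitted cell of the
#' grid. Subjects whose originating-stage row is undefined (stage never
#' originates a step) carry `NA` in those cells and are excluded from
#' those cells only. Cells with fewer than `min_subjects` complete
#' observations, or a constant outcome, are marked unfit and excluded
#' from the BH family.
#'
#' @param prob_table long-format per-subject probabilities as produced
#'   by [matrices_long()]: columns `subject_id`, `resolution_tag`,
#'   `from`, `to`, `prob`.
#' @param cohort_table cohort covariate table (merged on `subject_id`);
#'   `NULL` if `prob_table` already carries the covariates.
#' @param predictor,covariates,random,transform passed to
#'   [fit_group_comparison()].
#' @param q false discovery rate for the grid (default 0.05).
#' @param min_subjects minimum complete observations per cell
#'   (default 10).
#' @return A `transition_grid`: data frame with one row per cell
#'   (`resolution_tag`, `from`, `to`, `n`, fit results, `bh_rejected`,
#'   `adjusted_p`, `status`), with attributes `n_models` (cells
#'   attempted), `n_fitted` and `fdr_q`.
#' @export
compare_transition_probabilities <- function(prob_table, cohort_table = NULL,
                                             predictor = "group",
                                             covariates = c("age_years", "sex"),
                                             random = "family_id",
                                             transform = "auto",
                                             q = 0.05, min_subjects = 10) {
  need <- c("subject_id", "resolution_tag", "from", "to", "prob")
  if (!all(need %in% names(prob_table)))
    stop("prob_table must have columns: ", paste(need, collapse = ", "))
  if (!is.null(cohort_table))
    prob_table <- merge(prob_table, cohort_table, by = "subject_id")
  resolutions <- sort(unique(prob_table$resolution_tag))
  cells <- expand.grid(resolution_tag = resolutions,
                       from = STAGE_ORDER, to = STAGE_ORDER,
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$resolution_tag,
                       match(cells$from, STAGE_ORDER),
                       match(cells$to, STAGE_ORDER)), ]
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    d <- prob_table[prob_table$resolution_tag == cell$resolution_tag &
                    prob_table$from == cell$from &
                    prob_table$to == cell$to &
                    !is.na(prob_table$prob), , drop = FALSE]
    base <- data.frame(cell, n = nrow(d), stringsAsFactors = FALSE)
    res <- NULL
    status <- "fitted"
    if (nrow(d) < min_subjects) {
      status <- "too_few_subjects"
    } else if (length(unique(d$prob)) < 2L) {
      status <- "constant_outcome"
    } else {
      res <- tryCatch(
        suppressMessages(fit_group_comparison(
          d, outcome = "prob", predictor = predictor,
          covariates = covariates, random = random,
          transform = transform)),
        error = function(e) {
          status <<- paste0("fit_error: ", conditionMessage(e))
          NULL
        })
    }
    if (is.null(res)) {
      rows[[i]] <- cbind(base, coefficient = NA_real_, ci95_low = NA_real_,
                         ci95_high = NA_real_, se = NA_real_,
                         p_value = NA_real_, cohens_d = NA_real_,
                         residual_sd = NA_real_,
                         transformed_flag = NA, status = status)
    } else {
      rows[[i]] <- cbind(base,
                         coefficient = res$coefficient,
                         ci95_low = res$ci95_low, ci95_high = res$ci95_high,
                         se = res$se, p_value = res$p_value,
                         cohens_d = res$cohens_d,
                         residual_sd = res$residual_sd,
                         transformed_flag = res$transformed_flag,
                         status = status)
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  fitted <- grid$status == "fitted"
  grid$adjusted_p <- NA_real_
  grid$bh_rejected <- NA
  if (any(fitted)) {
    bh <- benjamini_hochberg(grid$p_value[fitted], q = q)
    grid$adjusted_p[fitted] <- bh$adjusted_p
    grid$bh_rejected[fitted] <- bh$rejected
  }
  n_unfit <- sum(!fitted)
  if (n_unfit)
    message(n_unfit, " grid cell(s) unfit (excluded from the BH family)")
  structure(grid,
            n_models = nrow(cells),
            n_fitted = sum(fitted),
            fdr_q = q,
            class = c("transition_grid", "data.frame"))
}

#' @export
print.transition_grid <- function(x, ...) {
  cat(sprintf(
    "<transition probability grid> %d models attempted, %d fitted, FDR q = %g\n",
    attr(x, "n_models"), attr(x, "n_fitted"), attr(x, "fdr_q")))
  rej <- which(x$bh_rejected %in% TRUE)
  if (length(rej)) {
    cat("  BH-significant cells:\n")
    for (i in rej)
      cat(sprintf("    [%s] %s -> %s: beta %.4f, d %.2f, adj. p %.4g\n",
                  x$resolution_tag[i], x$from[i], x$to[i],
                  x$coefficient[i], x$cohens_d[i], x$adjusted_p[i]))
  } else {
    cat("  no BH-significant cells\n")
  }
  invisible(x)
}

#' Split-night interaction model with post-hoc contrasts
#'
#' Repeated-measures comparison of a per-half outcome: fits the
#' `predictor x night-half` interaction model with participant (and
#' family) random intercepts, then the four post-hoc contrasts: the
#' night-half effect within each predictor level (participant random
#' intercept) and the predictor effect within each half (family random
#' intercept).
#'
#' @param data long table with one row per subject and half: columns
#'   `subject_id`, `half` (`"first"`/`"second"`), the outcome, the
#'   predictor, covariates and `family_id`.
#' @param outcome outcome column name.
#' @param predictor focal predictor column (default `"group"`).
#' @param covariates adjustment covariates.
#' @param transform log-transform policy.
#' @return A `split_night_models` object: `interaction` (a
#'   `model_result`) and `contrasts` (named list of four
#'   `model_result`s).
#' @export
split_night_model <- function(data, outcome, predictor = "group",
                              covariates = c("age_years", "sex"),
                              transform = "auto") {
  need <- c("subject_id", "half", outcome, predictor, covariates, "family_id")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(data[c("subject_id", "half")]))
    stop("duplicated subject x half rows")
  n_halves <- table(data$subject_id)
  incomplete <- names(n_halves)[n_halves != 2L]
  if (length(incomplete)) {
    message(length(incomplete),
            " subject(s) lacking both night-halves excluded")
    data <- data[!(data$subject_id %in% incomplete), , drop = FALSE]
  }
  if (is.character(data[[predictor]]) || is.logical(data[[predictor]]))
    data[[predictor]] <- factor(data[[predictor]])
  data$half <- factor(data$half, levels = c("first", "second"))

  tr <- maybe_log_transform(data[[outcome]], transform)
  data[[".y"]] <- tr$values
  fixed_rhs <- paste(c(paste0(predictor, " * half"), covariates),
                     collapse = " + ")
  fml <- stats::as.formula(paste(
    ".y ~", fixed_rhs, "+ (1 | family_id) + (1 | subject_id)"))
  fit <- suppressMessages(
    lmerTest::lmer(fml, data = data,
                   control = lme4::lmerControl(calc.derivs = FALSE)))
  ct <- stats::coef(summary(fit))
  irow <- grep(":", rownames(ct))[1L]
  interaction <- model_result(
    outcome_name = outcome,
    term = rownames(ct)[irow],
    coefficient = ct[irow, "Estimate"],
    se = ct[irow, "Std. Error"],
    p_value = ct[irow, "Pr(>|t|)"],
    residual_sd = stats::sigma(fit),
    n_subjects = length(unique(data$subject_id)),
    n_observations = nrow(data),
    transformed_flag = tr$transformed,
    model_descriptor = sprintf(
      "LME (lmerTest): .y ~ %s + (1|family_id) + (1|subject_id); Wald 95%% CI",
      fixed_rhs),
    notes = "")

  contrasts <- list()
  for (lev in levels(droplevels(data[[predictor]]))) {
    sub <- data[data[[predictor]] == lev, , drop = FALSE]
    contrasts[[paste0("half_effect_in_", lev)]] <-
      suppressMessages(fit_group_comparison(
        sub, outcome = outcome, predictor = "half",
        covariates = covariates, random = "subject_id",
        transform = transform))
  }
  for (hf in c("first", "second")) {
    sub <- data[data$half == hf, , drop = FALSE]
    contrasts[[paste0(predictor, "_diff_in_", hf, "_half")]] <-
      suppressMessages(fit_group_comparison(
        sub, outcome = outcome, predictor = predictor,
        covariates = covariates, random = "family_id",
        transform = transform))
  }
  structure(list(outcome = outcome, interaction = interaction,
                 contrasts = contrasts),
            class = "split_night_models")
}

#' @export
print.split_night_models <- function(x, ...) {
  cat(sprintf("<split-night models> outcome: %s\n", x$outcome))
  cat(sprintf("  interaction %s: beta %.4f, p = %.4g, d = %.3f\n",
              x$interaction$term, x$interaction$coefficient,
              x$interaction$p_value, x$interaction$cohens_d))
  for (nm in names(x$contrasts)) {
    m <- x$contrasts[[nm]]
    cat(sprintf("  %-28s beta %.4f, p = %.4g, d = %.3f\n",
                nm, m$coefficient, m$p_value, m$cohens_d))
  }
  invisible(x)
}

#' @export
as.data.frame.split_night_models <- function(x, ...) {
  out <- rbind(
    cbind(contrast = "interaction", as.data.frame(x$interaction)),
    do.call(rbind, lapply(names(x$contrasts), function(nm)
      cbind(contrast = nm, as.data.frame(x$contrasts[[nm]])))))
  rownames(out) <- NULL
  out
}
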