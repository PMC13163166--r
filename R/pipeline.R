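#' Write a cohort to disk (canonical CSVs plus ground truth)
#'
#' Writes one canonical hypnogram CSV per subject and resolution
#' (`<subject>_<resolution>.csv`), the cohort covariate table
#' (`covariates.csv`) and, for synthetic cohorts, the realized
#' generating parameters (`ground_truth.json`).
#'
#' @param cohort a `synthetic_cohort` (or a list with the same fields).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (h in c(cohort$hypnograms_5s, cohort$hypnograms_30s))
    write_hypnogram(h, file.path(dir, paste0(h$subject_id, "_",
                                             h$resolution_tag, ".csv")))
  write.csv(cohort$cohort_table, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  if (!is.null(cohort$ground_truth))
    jsonlite::write_json(
      lapply(cohort$ground_truth, function(gt)
        list(subject_id = gt$subject_id, group = gt$group,
             family_multiplier = gt$family_multiplier,
             matrix_first = gt$matrix_first,
             matrix_second = gt$matrix_second)),
      file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort of canonical hypnogram CSVs
#'
#' Reads every `*_epoch30.csv` / `*_miniepoch5.csv` / `*_other.csv`
#' hypnogram in `dir` plus the covariate table.
#'
#' @param dir directory of canonical hypnogram CSVs.
#' @param covariates_path path to the covariate CSV (default
#'   `covariates.csv` inside `dir`).
#' @return List with `hypnograms_5s`, `hypnograms_30s`, `cohort_table`.
#' @export
read_cohort <- function(dir, covariates_path = file.path(dir, "covariates.csv")) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != basename(covariates_path)]
  failures <- list()
  hyps <- list()
  for (f in files) {
    h <- tryCatch(read_hypnogram(f), error = function(e) e)
    if (inherits(h, "error"))
      failures[[length(failures) + 1L]] <- list(
        file = f, reason = conditionMessage(h))
    else hyps[[length(hyps) + 1L]] <- h
  }
  tags <- vapply(hyps, `[[`, "", "resolution_tag")
  structure(
    list(hypnograms_5s = hyps[tags == "miniepoch5"],
         hypnograms_30s = hyps[tags == "epoch30"],
         cohort_table = read.csv(covariates_path, stringsAsFactors = FALSE)),
    read_failures = failures)
}

## Apply `fn` per hypnogram, collecting rows and per-subject failures.
safe_rows <- function(hyps, fn) {
  rows <- list(); failures <- list()
  for (h in hyps) {
    out <- tryCatch(fn(h), error = function(e) e)
    if (inherits(out, "error")) {
      failures[[length(failures) + 1L]] <- list(
        subject_id = h$subject_id, resolution_tag = h$resolution_tag,
        reason = conditionMessage(out))
    } else {
      rows[[length(rows) + 1L]] <- out
    }
  }
  list(rows = if (length(rows)) do.call(rbind, rows) else NULL,
       failures = failures)
}

index_outcomes <- function(resolution) {
  out <- c("index_all_stages", "index_nrem_rem", "index_sleep_wake")
  if (resolution == "miniepoch5")
    out <- c(out, "wp_short_rate", "wp_intermediate_rate", "wp_long_rate")
  out
}

#' Run the full fragmentation analysis pipeline
#'
#' Orchestrates the end-to-end analysis: obtain hypnograms (simulate a
#' synthetic cohort or read canonical CSVs), validate, compute sleep
#' architecture, fragmentation indices, per-subject transition matrices
#' and split-night metrics, then fit the cohort models: full-night
#' mixed-effects group comparisons per index, the per-cell
#' transition-probability grid with Benjamini-Hochberg control, and
#' split-night interaction models with post-hoc contrasts. All tidy
#' tables plus a JSON run summary are written to `output_dir`; rerunning
#' with the same configuration and seed reproduces the CSVs byte for
#' byte.
#'
#' @param output_dir directory for the result bundle (created).
#' @param generator a [generator_config()] to simulate from (exactly one
#'   of `generator` / `input_dir`).
#' @param input_dir directory of canonical hypnogram CSVs.
#' @param covariates_path covariate CSV when reading from `input_dir`.
#' @param resolutions resolutions to analyze (default both).
#' @param split_night fit the split-night layer (default `TRUE`).
#' @param wake_region wake-run counting region for full nights.
#' @param transform log-transform policy for model outcomes.
#' @param fdr_q false discovery rate for the transition grid.
#' @param min_cell_subjects minimum complete observations per grid cell.
#' @param seed integer seed governing simulation (overrides the
#'   generator config seed).
#' @param strict abort on the first invalid hypnogram instead of
#'   excluding it.
#' @return Invisibly, a list with the output paths, the tables, the
#'   fitted models and the run summary.
#' @export
run_pipeline <- function(output_dir,
                         generator = NULL, input_dir = NULL,
                         covariates_path = NULL,
                         resolutions = c("epoch30", "miniepoch5"),
                         split_night = TRUE,
                         wake_region = "post-onset",
                         transform = "auto",
                         fdr_q = 0.05, min_cell_subjects = 10,
                         seed = NULL, strict = FALSE) {
  if (is.null(generator) == is.null(input_dir))
    stop("exactly one of `generator` and `input_dir` must be given")
  t0 <- Sys.time()
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(generator)) {
    if (!is.null(seed)) generator$seed <- seed
    cohort <- generate_cohort(generator)
  } else {
    cohort <- if (is.null(covariates_path)) read_cohort(input_dir)
              else read_cohort(input_dir, covariates_path)
  }
  read_failures <- attr(cohort, "read_failures")
  if (length(read_failures)) {
    if (strict)
      stop("failed to read hypnogram file '", read_failures[[1L]]$file,
           "': ", read_failures[[1L]]$reason)
    message(length(read_failures), " hypnogram file(s) failed to read; excluded")
  }
  hyps <- c(if ("miniepoch5" %in% resolutions) cohort$hypnograms_5s,
            if ("epoch30" %in% resolutions) cohort$hypnograms_30s)

  invalid <- list()
  ok <- vapply(hyps, function(h) {
    issues <- validate_hypnogram(h)
    if (length(issues)) {
      if (strict)
        stop("invalid hypnogram '", h$subject_id, "': ",
             paste(issues, collapse = "; "))
      invalid[[length(invalid) + 1L]] <<- list(
        subject_id = h$subject_id, issues = issues)
      FALSE
    } else TRUE
  }, NA)
  hyps <- hyps[ok]

  arch <- safe_rows(hyps, function(h) architecture_table(list(h)))
  frag <- safe_rows(hyps, function(h)
    fragmentation_table(list(h), wake_region = wake_region))
  mats <- safe_rows(hyps, function(h) matrices_long(list(h)))
  spl <- if (split_night) safe_rows(hyps, function(h)
    splitnight_table(list(h))) else list(rows = NULL, failures = list())

  cov_tab <- cohort$cohort_table
  paths <- list(
    architecture = file.path(output_dir, "architecture.csv"),
    fragmentation = file.path(output_dir, "fragmentation.csv"),
    matrices_long = file.path(output_dir, "matrices_long.csv"),
    splitnight_long = file.path(output_dir, "splitnight_long.csv"),
    models = file.path(output_dir, "models.csv"),
    grid = file.path(output_dir, "grid.csv"),
    summary = file.path(output_dir, "summary.json"))
  write.csv(arch$rows, paths$architecture, row.names = FALSE)
  write.csv(frag$rows, paths$fragmentation, row.names = FALSE)
  write.csv(mats$rows, paths$matrices_long, row.names = FALSE)

  ## full-night group models per resolution and outcome
  model_rows <- list()
  frag_cov <- merge(frag$rows, cov_tab, by = "subject_id")
  for (res in intersect(resolutions, unique(frag_cov$resolution_tag))) {
    d <- frag_cov[frag_cov$resolution_tag == res, , drop = FALSE]
    for (outc in index_outcomes(res)) {
      mr <- tryCatch(suppressMessages(fit_group_comparison(
        d, outcome = outc, predictor = "group",
        covariates = c("age_years", "sex"), random = "family_id",
        transform = transform)), error = function(e) NULL)
      if (!is.null(mr))
        model_rows[[length(model_rows) + 1L]] <- cbind(
          analysis = "full_night_group", resolution_tag = res,
          contrast = "group", as.data.frame(mr))
    }
  }

  ## split-night interaction + post-hoc contrasts
  sn_models <- list()
  if (split_night && !is.null(spl$rows)) {
    spl_cov <- merge(spl$rows, cov_tab, by = "subject_id")
    write.csv(spl$rows, paths$splitnight_long, row.names = FALSE)
    for (res in intersect(resolutions, unique(spl_cov$resolution_tag))) {
      d <- spl_cov[spl_cov$resolution_tag == res, , drop = FALSE]
      for (outc in index_outcomes(res)) {
        if (all(is.na(d[[outc]]))) next
        snm <- tryCatch(suppressMessages(split_night_model(
          d[!is.na(d[[outc]]), , drop = FALSE], outcome = outc,
          predictor = "group", covariates = c("age_years", "sex"),
          transform = transform)), error = function(e) NULL)
        if (!is.null(snm)) {
          sn_models[[paste(res, outc)]] <- snm
          model_rows[[length(model_rows) + 1L]] <- cbind(
            analysis = "split_night", resolution_tag = res,
            as.data.frame(snm))
        }
      }
    }
  }
  models_df <- if (length(model_rows)) do.call(rbind, model_rows) else NULL
  write.csv(models_df, paths$models, row.names = FALSE)

  ## transition-probability grid with BH control
  grid <- suppressMessages(compare_transition_probabilities(
    mats$rows, cov_tab, q = fdr_q, min_subjects = min_cell_subjects,
    transform = transform))
  write.csv(as.data.frame(grid), paths$grid, row.names = FALSE)

  n_failures <- length(arch$failures) + length(frag$failures) +
    length(mats$failures) + length(spl$failures)
  summary <- list(
    package_version = as.character(packageVersion("sleepfrag")),
    seed = if (is.null(seed)) NA else seed,
    simulated = !is.null(generator),
    n_hypnograms = length(hyps),
    n_subjects = length(unique(cov_tab$subject_id)),
    resolutions = resolutions,
    wake_region = wake_region,
    transform_policy = transform,
    fdr_q = fdr_q,
    min_cell_subjects = min_cell_subjects,
    n_read_failures = length(read_failures),
    read_failures = read_failures,
    n_invalid_hypnograms = length(invalid),
    invalid = invalid,
    n_metric_failures = n_failures,
    grid_models_attempted = attr(grid, "n_models"),
    grid_models_fitted = attr(grid, "n_fitted"),
    grid_cells_rejected = sum(grid$bh_rejected, na.rm = TRUE),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(summary, paths$summary, digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(list(paths = paths,
                 architecture = arch$rows, fragmentation = frag$rows,
                 matrices_long = mats$rows, splitnight = spl$rows,
                 models = models_df, split_night_models = sn_models,
                 grid = grid, summary = summary))
}
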