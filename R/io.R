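#' Read a hypnogram from the canonical CSV dialect
#'
#' The canonical file is UTF-8, comma-separated, LF-terminated: three
#' header key-value rows (`subject_id`, `epoch_seconds`, `lights` with
#' 0-based off/on offsets), then one `index,stage` row per unit with a
#' 0-based monotone index. Stage tokens may be letters
#' (`W,N1,N2,N3,R,U`) or AASM-style numerals (`0,1,2,3,5` with unscored
#' sentinel `9`); the two encodings read to identical objects.
#'
#' @param path path to a hypnogram CSV.
#' @return A validated `hypnogram`.
#' @seealso [write_hypnogram()]
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 4L)
    stop("malformed hypnogram file (need 3 header rows + data): ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  keys <- vapply(fields[1:3], `[[`, "", 1L)
  hdr <- function(key, n_values) {
    i <- match(key, keys)
    if (is.na(i)) stop("missing '", key, "' header row in ", path)
    v <- fields[[i]][-1L]
    if (length(v) != n_values)
      stop("header row '", key, "' needs ", n_values, " value(s) in ", path)
    v
  }
  subject_id <- hdr("subject_id", 1L)
  epoch_seconds <- as.numeric(hdr("epoch_seconds", 1L))
  lights <- as.integer(hdr("lights", 2L))
  if (anyNA(lights)) stop("missing lights markers in ", path)

  data <- fields[-(1:3)]
  idx <- suppressWarnings(as.integer(vapply(data, `[[`, "", 1L)))
  tok <- vapply(data, function(f) if (length(f) >= 2L) f[[2L]] else NA_character_, "")
  if (anyNA(idx) || any(idx != seq_along(idx) - 1L))
    stop("non-monotone or malformed epoch indices in ", path)
  stages <- ifelse(tok %in% STAGE_TOKENS, tok, unname(NUMERIC_CODE[tok]))
  bad <- which(is.na(stages))
  if (length(bad))
    stop(sprintf("unknown stage token '%s' at data row %d of %s",
                 tok[bad[1]], bad[1], path))
  hypnogram(stages, epoch_seconds, lights[1], lights[2], subject_id)
}

#' Write a hypnogram in the canonical CSV dialect
#'
#' @param h a `hypnogram`.
#' @param path output path.
#' @param tokens `"letter"` (default) or `"numeric"` stage encoding.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path, tokens = c("letter", "numeric")) {
  stopifnot(inherits(h, "hypnogram"))
  tokens <- match.arg(tokens)
  stg <- h$stages
  if (tokens == "numeric")
    stg <- names(NUMERIC_CODE)[match(stg, NUMERIC_CODE)]
  lines <- c(
    paste0("subject_id,", h$subject_id),
    paste0("epoch_seconds,", format(h$epoch_seconds, scientific = FALSE)),
    paste0("lights,", h$lights_off, ",", h$lights_on),
    paste0(seq_along(stg) - 1L, ",", stg))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
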