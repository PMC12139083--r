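#' Long-format cross-over trial data
#'
#' A `long_trial` is a tibble holding one row per subject x period x
#' assessment occasion x outcome from a 2-period, 2-sequence cross-over
#' trial. The canonical columns are:
#'
#' * `subject_id` -- opaque subject label (character).
#' * `sequence` -- treatment order, `"AB"` (active first) or `"BA"`.
#' * `period` -- 1 or 2.
#' * `time` -- assessment occasion within period, 1..4; occasion 1 is the
#'   within-period baseline, occasion 3 the end of treatment and occasion 4
#'   the follow-up.
#' * `treatment` -- `"active"` or `"placebo"`; fully determined by
#'   `(sequence, period)` and validated against it.
#' * `outcome` -- outcome name (e.g. `"pain_vas"`, `"blister_count"`).
#' * `value` -- numeric measurement; `NA` encodes a missing value, which is
#'   propagated (never imputed) by every downstream method.
#'
#' Additional columns (e.g. a stratification factor) are preserved untouched.
#'
#' @param data A data frame with the columns above (`treatment` may be
#'   omitted, in which case it is derived from `sequence` and `period`).
#' @returns A tibble of class `long_trial`.
#' @examples
#' df <- expand.grid(subject_id = "s1", period = 1:2, time = 1:4,
#'                   outcome = "pain_vas", stringsAsFactors = FALSE)
#' df$sequence <- "AB"
#' df$value <- 5
#' as_long_trial(df)
#' @export
as_long_trial <- function(data) {
  required <- c("subject_id", "sequence", "period", "time", "outcome", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  out$subject_id <- as.character(out$subject_id)
  out$sequence <- as.character(out$sequence)
  out$period <- as.integer(out$period)
  out$time <- as.integer(out$time)
  out$outcome <- as.character(out$outcome)
  out$value <- as.numeric(out$value)

  if (!all(out$sequence %in% c("AB", "BA"))) {
    abort("`sequence` must be \"AB\" or \"BA\"")
  }
  if (!all(out$period %in% 1:2)) abort("`period` must be 1 or 2")
  if (!all(out$time %in% 1:4)) abort("`time` must be in 1..4")

  seq_per_subject <- tapply(out$sequence, out$subject_id,
                            function(s) length(unique(s)))
  if (any(seq_per_subject > 1)) {
    bad <- names(seq_per_subject)[seq_per_subject > 1]
    abort(paste0("subject(s) with more than one sequence label: ",
                 paste(bad, collapse = ", ")))
  }

  expected <- expected_treatment(out$sequence, out$period)
  if (!("treatment" %in% names(out))) {
    out$treatment <- expected
  } else {
    out$treatment <- as.character(out$treatment)
    if (!all(out$treatment %in% c("active", "placebo"))) {
      abort("`treatment` must be \"active\" or \"placebo\"")
    }
    bad <- out$treatment != expected
    if (any(bad)) {
      abort(paste0(
        "treatment inconsistent with sequence/period for subject(s): ",
        paste(unique(out$subject_id[bad]), collapse = ", ")))
    }
  }

  key <- paste(out$subject_id, out$period, out$time, out$outcome, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("duplicate (subject, period, time, outcome) record: ",
                 gsub("\r", " / ", dup)))
  }

  canon <- c("subject_id", "sequence", "period", "time", "treatment",
             "outcome", "value")
  out <- out[, c(canon, setdiff(names(out), canon))]
  class(out) <- c("long_trial", class(tibble::tibble()))
  out
}

#' Treatment implied by sequence and period
#'
#' In a 2x2 cross-over, sequence `"AB"` receives the active treatment in
#' period 1 and placebo in period 2; `"BA"` the reverse.
#'
#' @param sequence Character vector of `"AB"` / `"BA"`.
#' @param period Integer vector of 1 / 2.
#' @returns Character vector of `"active"` / `"placebo"`.
#' @export
expected_treatment <- function(sequence, period) {
  ifelse((sequence == "AB") == (period == 1), "active", "placebo")
}

#' Read a long-format trial CSV
#'
#' Reads comma-separated, UTF-8, header-first trial data into a validated
#' [as_long_trial()] tibble. Cells in the value column that cannot be parsed
#' as numbers (including blanks) become missing values; their count is
#' recorded in the load report available via [load_report()].
#'
#' @param file Path or connection to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(subject_id = "patient", value = "score")`. Unmapped canonical names
#'   are looked up verbatim.
#' @returns A `long_trial` tibble with a `"load_report"` attribute.
#' @seealso [write_long_trial()], [load_report()]
#' @export
read_long_trial <- function(file, schema = character()) {
  raw <- readr::read_csv(file, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  canon <- c("subject_id", "sequence", "period", "time", "treatment",
             "outcome", "value")
  lookup <- setNames(canon, canon)
  if (length(schema) > 0) lookup[names(schema)] <- unname(schema)
  have <- lookup[lookup %in% names(raw)]
  need <- setdiff(canon, c(names(have), "treatment"))
  if (length(need) > 0) {
    abort(paste0("CSV is missing column(s) for: ", paste(need, collapse = ", ")))
  }
  df <- raw[, unname(have)]
  names(df) <- names(have)

  parsed <- suppressWarnings(readr::parse_double(df$value))
  raw_val <- df$value
  n_unparseable <- sum(!is.na(raw_val) & raw_val != "" & is.na(parsed))
  n_blank <- sum(is.na(raw_val) | raw_val == "")
  df$value <- parsed

  out <- as_long_trial(df)
  attr(out, "load_report") <- list(
    n_records = nrow(out),
    n_missing = sum(is.na(out$value)),
    n_blank = n_blank,
    n_unparseable = n_unparseable
  )
  out
}

#' Retrieve the load report attached by [read_long_trial()]
#'
#' @param data A `long_trial` read from file.
#' @returns A list with record and missing-value counts, or `NULL`.
#' @export
load_report <- function(data) attr(data, "load_report")

#' Write a long-format trial CSV
#'
#' Inverse of [read_long_trial()]: comma-separated, UTF-8, `"."` decimal,
#' header included. Missing values are written as empty cells.
#'
#' @param data A `long_trial` (or coercible data frame).
#' @param file Path to write to.
#' @returns `data`, invisibly.
#' @export
write_long_trial <- function(data, file) {
  data <- as_long_trial(data)
  readr::write_csv(data, file, na = "")
  invisible(data)
}

#' @export
print.long_trial <- function(x, ...) {
  n_sub <- length(unique(x$subject_id))
  cat(sprintf("<long_trial> %d records, %d subjects, outcomes: %s\n",
              nrow(x), n_sub, paste(unique(x$outcome), collapse = ", ")))
  NextMethod()
}
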