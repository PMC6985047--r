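#' Case-level input and results output
#'
#' Case tables are CSV/TSV with a header; the canonical columns are
#' `case_id`, `age`, `er_percent`, `esr1_raw`, `pam50`, `race`, `grade`,
#' `tumor_size`, `node_status`. Only `age` is mandatory. Empty cells, "NA"
#' and "NaN" all parse as missing. Ages may be non-integer; no binning is
#' applied at read time.
#'
#' @name data_io
NULL

canonical_columns <- c("case_id", "age", "er_percent", "esr1_raw", "pam50",
                       "race", "grade", "tumor_size", "node_status")

#' Read a case-level table
#'
#' @param path CSV or TSV file (delimiter auto-detected)
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(age = "age_dx")`; unmapped canonical
#'   columns are taken verbatim when present
#' @param strict if TRUE, unparseable ages and ages outside `age_range` are
#'   errors; if FALSE they yield a row-listing warning (unparseable ages
#'   become NA and are kept)
#' @param age_range ascertainment window used for the range check,
#'   default `c(20, 74)`
#' @param age_action what to do with out-of-range ages in non-strict mode:
#'   `"warn"` keeps them with a warning, `"drop"` removes them
#' @return data.frame of case records (class `case_table`), one row per
#'   input data row (minus drops)
#' @export
read_cases <- function(path, column_map = NULL, strict = FALSE,
                       age_range = c(20, 74), age_action = c("warn", "drop")) {
  age_action <- match.arg(age_action)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, na.strings = c("", "NA", "NaN"),
                           colClasses = "character", data.table = FALSE)
  # fread keeps "" in character columns even when listed in na.strings
  raw[] <- lapply(raw, function(x) { x[x %in% c("", "NA", "NaN")] <- NA; x })
  cols <- stats::setNames(canonical_columns, canonical_columns)
  if (!is.null(column_map)) cols[names(column_map)] <- column_map
  if (!cols[["age"]] %in% names(raw))
    stop("schema error: mandatory age column '", cols[["age"]],
         "' not found in ", path, call. = FALSE)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (cn in canonical_columns) {
    src <- cols[[cn]]
    out[[cn]] <- if (src %in% names(raw)) raw[[src]] else NA_character_
  }
  for (cn in c("age", "er_percent", "esr1_raw", "tumor_size")) {
    num <- suppressWarnings(as.numeric(out[[cn]]))
    bad <- which(!is.na(out[[cn]]) & is.na(num))
    if (length(bad) > 0L && cn == "age") {
      msg <- paste0("unparseable age in row(s): ", paste(bad, collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
    out[[cn]] <- num
  }
  if (anyNA(out$age) && strict)
    stop("missing age in row(s): ", paste(which(is.na(out$age)), collapse = ", "),
         call. = FALSE)
  oor <- which(!is.na(out$age) & (out$age < age_range[1] | out$age > age_range[2]))
  if (length(oor) > 0L) {
    msg <- sprintf("%d age(s) outside [%g, %g] (rows: %s)", length(oor),
                   age_range[1], age_range[2],
                   paste(utils::head(oor, 10L), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    if (age_action == "drop") {
      warning(msg, "; dropped", call. = FALSE)
      out <- out[-oor, , drop = FALSE]
    } else {
      warning(msg, "; kept", call. = FALSE)
    }
  }
  bad_er <- which(!is.na(out$er_percent) &
                  (out$er_percent < 0 | out$er_percent > 100))
  if (length(bad_er) > 0L)
    stop("er_percent outside [0, 100] in row(s): ",
         paste(bad_er, collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("case_table", "data.frame")
  out
}

summary_columns <- c("stratum_label", "n", "median_age", "mode_early",
                     "mode_late", "p_early", "p_late", "selected_model",
                     "delta_aic")

#' Write stratum summaries
#'
#' Format follows the extension: `.json` (one object per stratum, full
#' precision) or `.csv`. Both round-trip through [read_summaries()] without
#' precision loss.
#'
#' @param summaries data.frame of stratum summaries (rbind of
#'   [summarize_stratum()] rows)
#' @param path output file ending in `.json` or `.csv`
#' @return `path`, invisibly
#' @export
write_summaries <- function(summaries, path) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0L)
  missing_cols <- setdiff(summary_columns, names(summaries))
  if (length(missing_cols) > 0L)
    stop("summaries missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(summaries)[, intersect(c(summary_columns, "verdict", "flagged"),
                                             names(summaries))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    data.table::fwrite(df, path)
  } else {
    stop("unsupported summary format (use .json or .csv): ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read stratum summaries written by [write_summaries()]
#' @param path `.json` or `.csv` summaries file
#' @return data.frame of summaries
#' @export
read_summaries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- jsonlite::fromJSON(path)
  } else {
    out <- data.table::fread(path, data.table = FALSE)
  }
  as.data.frame(out)
}

#' Write a case table as CSV
#' @param records case data.frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_cases <- function(records, path) {
  data.table::fwrite(as.data.frame(records), path)
  invisible(path)
}
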