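#' Read and write cohort tables
#'
#' The fixture format is a plain CSV with one row per patient and
#' timepoint and columns `patient_id, sex, age, timepoint, Q1..Q25,
#' completion_time_min, sbp, dbp`. `read_cohort_csv()` validates every
#' row against the record invariants (item scores are integers in 1..5,
#' completion time is nonnegative, `sbp > dbp > 0`) and reports the first
#' offending row and field.
#'
#' @param records a cohort data.frame as returned by [generate_cohort()].
#' @param path file path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns the validated data.frame.
#' @export
write_cohort_csv <- function(records, path) {
  validate_cohort_records(records)
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_records(df)
  df
}

validate_cohort_records <- function(df) {
  needed <- c("patient_id", "sex", "age", "timepoint", questionnaire_items,
              "completion_time_min", "sbp", "dbp")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("cohort table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  for (q in questionnaire_items) {
    v <- df[[q]]
    bad <- which(!is.finite(v) | v != as.integer(v) | v < 1 | v > 5)
    if (length(bad))
      stop(sprintf("row %d, field %s: item score %s is not an integer in 1..5",
                   bad[1], q, format(v[bad[1]])))
  }
  bad <- which(!is.finite(df$completion_time_min) | df$completion_time_min < 0)
  if (length(bad))
    stop(sprintf("row %d, field completion_time_min: negative or missing value",
                 bad[1]))
  bad <- which(!is.finite(df$sbp) | !is.finite(df$dbp) |
                 df$dbp <= 0 | df$sbp <= df$dbp)
  if (length(bad))
    stop(sprintf("row %d, field sbp/dbp: requires sbp > dbp > 0 (got %s/%s)",
                 bad[1], format(df$sbp[bad[1]]), format(df$dbp[bad[1]])))
  invisible(df)
}
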