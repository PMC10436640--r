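#' Reverse-code the negatively worded items
#'
#' Items Q1 and Q6--Q13 are phrased so that a high raw score means poor
#' adherence; they are flipped with the standard 5-point reversal
#' `x -> 6 - x` before any score is computed, so that higher always means
#' better.
#'
#' @param items named vector (or one-row data.frame) with raw scores for
#'   all 25 items `Q1..Q25`, each in 1..5.
#' @return Named integer vector of adjusted item scores.
#' @export
apply_reverse_scoring <- function(items) {
  x <- as_item_vector(items)
  x[reverse_items] <- 6 - x[reverse_items]
  x
}

as_item_vector <- function(items) {
  if (is.data.frame(items)) {
    if (nrow(items) != 1) stop("expected a single record")
    items <- unlist(items[questionnaire_items[questionnaire_items %in%
                                                names(items)]])
  }
  missing <- setdiff(questionnaire_items, names(items))
  if (length(missing))
    stop("missing item(s): ", paste(missing, collapse = ", "))
  x <- items[questionnaire_items]
  bad <- which(!is.finite(x) | x != as.integer(x) | x < 1 | x > 5)
  if (length(bad))
    stop("item ", questionnaire_items[bad[1]], " has value ",
         format(x[bad[1]]), "; scores must be integers in 1..5")
  storage.mode(x) <- "integer"
  x
}

#' Total questionnaire score
#'
#' Sum of the 25 adjusted item scores; by construction lies in
#' \[25, 125\].
#'
#' @param adjusted named vector of 25 adjusted item scores.
#' @return Integer total score.
#' @export
total_score <- function(adjusted) {
  if (length(adjusted) != 25)
    stop("expected 25 adjusted item scores, got ", length(adjusted))
  if (any(!is.finite(adjusted) | adjusted < 1 | adjusted > 5))
    stop("adjusted item scores must lie in 1..5")
  as.integer(sum(adjusted))
}

#' Blood-pressure control classification
#'
#' A record is controlled iff systolic pressure is at most 120 mmHg *and*
#' diastolic pressure is at most 90 mmHg (both thresholds inclusive,
#' home nighttime measurement).
#'
#' @param sbp,dbp blood pressures in mmHg (vectorised).
#' @param sbp_limit,dbp_limit inclusive thresholds.
#' @return Logical vector.
#' @export
classify_bp_control <- function(sbp, dbp, sbp_limit = 120, dbp_limit = 90) {
  if (any(sbp <= 0 | dbp <= 0)) stop("blood pressures must be positive")
  sbp <= sbp_limit & dbp <= dbp_limit
}

#' Blood-pressure control rate
#'
#' Percentage of controlled records, rounded half-up to 2 decimals
#' (69 controlled of 96 gives 71.88).
#'
#' @param flags logical vector of control flags.
#' @return Percentage in \[0, 100\].
#' @export
control_rate <- function(flags) {
  if (length(flags) == 0) stop("empty flag list")
  if (any(is.na(flags))) stop("control flags must not be missing")
  round_half_up(100 * mean(flags), 2)
}

#' Completion-time acceptability
#'
#' A questionnaire is acceptable when it took strictly less than `limit`
#' minutes (default 10) to complete.
#'
#' @param minutes completion time in minutes (vectorised).
#' @param limit acceptability limit, minutes.
#' @return Logical vector: `TRUE` when acceptable.
#' @export
flag_completion_time <- function(minutes, limit = 10) {
  if (any(minutes < 0)) stop("completion time must be nonnegative")
  minutes < limit
}

#' Score a whole cohort table
#'
#' Applies reverse coding, total-score computation, blood-pressure control
#' classification and the completion-time rule to every record of a cohort
#' table. In the returned table the item columns `Q1..Q25` hold the
#' *adjusted* (reverse-coded) scores.
#'
#' @param cohort data.frame as returned by [generate_cohort()] /
#'   [read_cohort_csv()].
#' @param time_limit completion-time acceptability limit, minutes.
#' @return The cohort data.frame with adjusted item columns and added
#'   `total_score`, `controlled`, `time_ok` columns.
#' @export
score_cohort <- function(cohort, time_limit = 10) {
  validate_cohort_records(cohort)
  out <- cohort
  adj <- as.matrix(cohort[questionnaire_items])
  adj[, reverse_items] <- 6 - adj[, reverse_items]
  out[questionnaire_items] <- adj
  out$total_score <- as.integer(rowSums(adj))
  out$controlled <- classify_bp_control(cohort$sbp, cohort$dbp)
  out$time_ok <- flag_completion_time(cohort$completion_time_min, time_limit)
  out
}
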