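#' Configuration for a synthetic questionnaire cohort
#'
#' Defines the statistical structure of a simulated IPC study cohort:
#' sex-stratified baseline distributions of age, blood pressure and total
#' questionnaire score, the intervention effects embedded after baseline,
#' the set of items that carry the score improvement, and the follow-up
#' schedule. Defaults reproduce the published study conditions: 96 patients
#' (49 male / 47 female), four questionnaires at months 0/3/6/12, a
#' 13/7 mmHg SBP/DBP decrease from the second questionnaire onwards, a
#' 15-point total-score gain realised at 12 months through 10 items, and a
#' single dropout missing the last two questionnaires.
#'
#' @param n_patients,n_male,n_female cohort size and sex split
#'   (`n_male + n_female` must equal `n_patients`).
#' @param age_mean,age_sd named numeric vectors (`male`, `female`), years.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd baseline blood-pressure moments
#'   by sex, mmHg.
#' @param sbp_effect_3mo,dbp_effect_3mo mmHg decrease embedded in every
#'   record from the second questionnaire (month 3) onwards.
#' @param score_mean,score_sd baseline total-score moments by sex, points
#'   on the 25--125 scale.
#' @param score_effect_12mo total-score increase (points) fully realised at
#'   12 months; intermediate timepoints receive a proportional fraction
#'   (`month / 12`).
#' @param improved_items labels of the items that carry the injected score
#'   effect. Reverse-coded members improve by *decreasing* their raw score.
#' @param dropout_count number of patients lost after the second
#'   questionnaire (missing timepoints 3 and 4).
#' @param timepoints month offsets of the questionnaires.
#' @param time_mean,time_sd completion-time moments (minutes) per
#'   questionnaire.
#' @param rho within-patient correlation of repeated scores and blood
#'   pressures across timepoints (not reported by the study; exposed as a
#'   knob rather than asserted).
#' @param seed integer seed; the generator is deterministic given the
#'   config.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 96, n_male = 49, n_female = 47,
                          age_mean = c(male = 45.84, female = 47.33),
                          age_sd = c(male = 9.62, female = 10.84),
                          sbp_mean = c(male = 143.04, female = 133.66),
                          sbp_sd = c(male = 16.41, female = 16.63),
                          dbp_mean = c(male = 94.71, female = 88.77),
                          dbp_sd = c(male = 12.71, female = 12.81),
                          sbp_effect_3mo = 13, dbp_effect_3mo = 7,
                          score_mean = c(male = 93.78, female = 99.02),
                          score_sd = c(male = 12.90, female = 15.17),
                          score_effect_12mo = 15,
                          improved_items = c("Q1", "Q6", "Q9", "Q15", "Q16",
                                             "Q18", "Q20", "Q22", "Q24", "Q25"),
                          dropout_count = 1,
                          timepoints = c(0, 3, 6, 12),
                          time_mean = c(1.95, 6.25, 5.03, 4.20),
                          time_sd = c(2.55, 3.19, 2.66, 3.07),
                          rho = 0.5, seed = 1) {
  cfg <- list(n_patients = n_patients, n_male = n_male, n_female = n_female,
              age_mean = age_mean, age_sd = age_sd,
              sbp_mean = sbp_mean, sbp_sd = sbp_sd,
              dbp_mean = dbp_mean, dbp_sd = dbp_sd,
              sbp_effect_3mo = sbp_effect_3mo, dbp_effect_3mo = dbp_effect_3mo,
              score_mean = score_mean, score_sd = score_sd,
              score_effect_12mo = score_effect_12mo,
              improved_items = improved_items, dropout_count = dropout_count,
              timepoints = timepoints, time_mean = time_mean, time_sd = time_sd,
              rho = rho, seed = seed)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_male + n_female != n_patients)
      stop("n_male + n_female must equal n_patients")
    sds <- c(age_sd, sbp_sd, dbp_sd, score_sd)
    if (any(sds <= 0))
      stop("all standard deviations must be positive")
    if (any(time_sd < 0))
      stop("completion-time standard deviations must be nonnegative")
    if (any(time_mean < 0))
      stop("completion-time means must be nonnegative")
    if (dropout_count >= n_patients)
      stop("dropout_count must be smaller than n_patients")
    if (!all(improved_items %in% questionnaire_items))
      stop("improved_items must be a subset of Q1..Q25")
    if (score_effect_12mo != 0 && length(improved_items) == 0)
      stop("improved_items must be non-empty when score_effect_12mo is nonzero: ",
           "the score effect is realised only through those items")
    for (nm in c("age_mean", "age_sd", "sbp_mean", "sbp_sd", "dbp_mean",
                 "dbp_sd", "score_mean", "score_sd"))
      if (!all(c("male", "female") %in% names(get(nm))))
        stop(nm, " must be a named vector with 'male' and 'female' entries")
    if (length(time_mean) != length(timepoints) ||
        length(time_sd) != length(timepoints))
      stop("time_mean/time_sd must have one entry per timepoint")
    invisible(TRUE)
  })
}

# Expected value of an item generated as 1 + Binomial(4, clamp(p, 0, 1))
# where p = (latent - 1)/4 and latent ~ N(m, tau/25). Used to calibrate the
# latent item means so that expected totals hit the configured moments
# despite the bounded 1..5 scale.
expected_item <- function(m, tau) {
  mu <- (m - 1) / 4
  s <- tau / 100           # tau/25 on the item scale, /4 on the p scale
  if (s < 1e-12) return(1 + 4 * pmin(pmax(mu, 0), 1))
  a <- (0 - mu) / s
  b <- (1 - mu) / s
  ecl <- mu * (pnorm(b) - pnorm(a)) + s * (dnorm(a) - dnorm(b)) +
    (1 - pnorm(b))
  1 + 4 * ecl
}

# latent item means per sex: improved items sit lower at baseline (they are
# the ones with room to improve); a global offset is solved so the expected
# discretised total equals the target mean
calibrate_item_means <- function(base_total, effect_per_item, improved, tau) {
  k <- length(improved)
  items <- questionnaire_items
  m <- rep(base_total / 25, 25)
  names(m) <- items
  if (k > 0) {
    m[improved] <- m[improved] - 0.5 * effect_per_item
    m[setdiff(items, improved)] <- m[setdiff(items, improved)] +
      0.5 * effect_per_item * k / (25 - k)
  }
  off <- uniroot(function(l) sum(expected_item(m + l, tau)) - base_total,
                 c(-4, 4), tol = 1e-9)$root
  m + off
}

# extra latent shift on improved items so the expected total gain equals
# `gain` at the given ramp
calibrate_effect_shift <- function(m, improved, gain, tau) {
  if (gain == 0 || length(improved) == 0) return(0)
  base <- sum(expected_item(m[improved], tau))
  uniroot(function(l) sum(expected_item(m[improved] + l, tau)) - base - gain,
          c(0, 8), tol = 1e-9, extendInt = "upX")$root
}

#' Generate a synthetic IPC cohort
#'
#' Simulates one patient-by-timepoint table with the statistical structure
#' assumed by the downstream pipeline. Total questionnaire scores follow a
#' latent-trait model: each patient carries a latent adherence level,
#' per-item latent means are calibrated so that the *expected* discretised
#' total score (after reverse coding) equals the configured sex-specific
#' mean at every timepoint, and item scores are drawn as
#' `1 + Binomial(4, p)` around the latent value, so every score lies in
#' 1..5 by construction. The configured score effect is injected only
#' through `improved_items`; reverse-coded members of that set improve by
#' decreasing their raw score. Blood pressures are Gaussian with a patient
#' random intercept; records from the second questionnaire onwards embed
#' the configured SBP/DBP decrease.
#'
#' @param config a [cohort_config()].
#' @return A data.frame with one row per patient and retained timepoint:
#'   `patient_id`, `sex`, `age`, `timepoint` (1-based questionnaire index),
#'   raw item scores `Q1..Q25`, `completion_time_min`, `sbp`, `dbp`.
#'   Dropout patients lack timepoints 3 and 4.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  ntp <- length(config$timepoints)
  sex <- c(rep("male", config$n_male), rep("female", config$n_female))
  ids <- sprintf("P%03d", seq_len(n))

  age <- round(pmin(pmax(rnorm(n, config$age_mean[sex], config$age_sd[sex]),
                         18), 65), 1)
  # patient latent traits: adherence (scores) and BP intercepts
  u <- rnorm(n)
  v_sbp <- rnorm(n)
  v_dbp <- rnorm(n)

  k <- length(config$improved_items)
  eff_item <- if (k > 0) config$score_effect_12mo / k else 0
  rho <- config$rho
  rows <- vector("list", n * ntp)
  ri <- 1L
  # per-sex calibration of latent item means (timepoint-independent part)
  cal <- lapply(c(male = "male", female = "female"), function(s) {
    tau <- sqrt(max(config$score_sd[s]^2 - 25 * 0.8, 1))
    m0 <- calibrate_item_means(config$score_mean[s], eff_item,
                               config$improved_items, tau)
    list(tau = tau, m0 = m0)
  })
  max_month <- max(config$timepoints)
  for (tp in seq_len(ntp)) {
    month <- config$timepoints[tp]
    ramp <- if (max_month > 0) month / max_month else 0
    bp_on <- as.numeric(tp >= 2)
    shift <- vapply(cal, function(cc)
      calibrate_effect_shift(cc$m0, config$improved_items,
                             config$score_effect_12mo * ramp, cc$tau),
      numeric(1))
    times <- generate_completion_times(config, tp)
    for (i in seq_len(n)) {
      s <- sex[i]
      cc <- cal[[s]]
      m <- cc$m0
      if (k > 0) m[config$improved_items] <- m[config$improved_items] + shift[s]
      tdev <- cc$tau * (sqrt(rho) * u[i] + sqrt(1 - rho) * rnorm(1))
      p <- pmin(pmax((m + tdev / 25 - 1) / 4, 0), 1)
      adj <- 1 + rbinom(25, 4, p)
      names(adj) <- questionnaire_items
      raw <- adj
      raw[reverse_items] <- 6 - raw[reverse_items]
      sbp <- config$sbp_mean[s] - bp_on * config$sbp_effect_3mo +
        config$sbp_sd[s] * (sqrt(rho) * v_sbp[i] + sqrt(1 - rho) * rnorm(1))
      dbp <- config$dbp_mean[s] - bp_on * config$dbp_effect_3mo +
        config$dbp_sd[s] * (sqrt(rho) * v_dbp[i] + sqrt(1 - rho) * rnorm(1))
      sbp <- max(sbp, 60)
      dbp <- min(max(dbp, 30), sbp - 5)
      rows[[ri]] <- data.frame(patient_id = ids[i], sex = s, age = age[i],
                               timepoint = tp, t(raw),
                               completion_time_min = round(times[i], 2),
                               sbp = round(sbp, 1), dbp = round(dbp, 1),
                               stringsAsFactors = FALSE)
      ri <- ri + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (config$dropout_count > 0 && ntp > 2) {
    drop_ids <- ids[sample.int(n, config$dropout_count)]
    out <- out[!(out$patient_id %in% drop_ids & out$timepoint >= 3), ]
    rownames(out) <- NULL
    attr(out, "dropout_ids") <- drop_ids
  }
  out
}

#' Simulate questionnaire completion times
#'
#' Draws completion times (minutes) for one questionnaire from a normal
#' distribution censored at zero -- a simple right-skewed nonnegative model
#' matching the reported per-questionnaire mean and SD. Draws use the
#' current RNG state; [generate_cohort()] seeds once per cohort.
#'
#' @param config a [cohort_config()].
#' @param timepoint questionnaire index in `1..length(config$timepoints)`.
#' @param n number of draws (defaults to the cohort size).
#' @return Numeric vector of nonnegative minutes.
#' @export
generate_completion_times <- function(config, timepoint,
                                      n = config$n_patients) {
  stopifnot(inherits(config, "cohort_config"))
  if (!(timepoint %in% seq_along(config$timepoints)))
    stop("timepoint must be in 1..", length(config$timepoints))
  m <- config$time_mean[timepoint]
  s <- config$time_sd[timepoint]
  if (m < 0) stop("completion-time mean must be nonnegative")
  if (s < 0) stop("completion-time sd must be nonnegative")
  if (s == 0) return(rep(max(m, 0), n))
  pmax(rnorm(n, m, s), 0)
}
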