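#' Mortality inputs for the cohort model
#'
#' The published epidemiological constants behind the transition
#' probabilities: hypertension incidence (27.50\%), hypertension control
#' rate in the general population (11.00\%), annual deaths attributable to
#' hypertension (1.8279 per mille) and to cardiovascular disease (2.815
#' per mille), and the 2021 all-cause mortality rate (7.18 per mille).
#'
#' @param p_ir hypertension incidence rate (fraction).
#' @param p_cdmr cardiovascular mortality factor (fraction).
#' @param hyp_death_rate,cvd_death_rate hypertension- and CVD-attributable
#'   death rates, per mille.
#' @param natural_mortality all-cause mortality, per mille.
#' @return A validated list of class `mortality_inputs`.
#' @export
mortality_inputs <- function(p_ir = 0.2750, p_cdmr = 0.455,
                             hyp_death_rate = 1.8279, cvd_death_rate = 2.815,
                             natural_mortality = 7.18) {
  if (cvd_death_rate <= 0) stop("cvd_death_rate must be positive")
  if (hyp_death_rate > cvd_death_rate)
    stop("hypertension-attributable deaths cannot exceed CVD deaths")
  frac <- c(p_ir = p_ir, p_cdmr = p_cdmr,
            hyp = hyp_death_rate / 1000, cvd = cvd_death_rate / 1000,
            nat = natural_mortality / 1000)
  if (any(frac < 0 | frac >= 1))
    stop("all rates must lie in [0, 1) after unit conversion")
  structure(list(p_ir = p_ir, p_cdmr = p_cdmr,
                 hyp_death_rate = hyp_death_rate,
                 cvd_death_rate = cvd_death_rate,
                 natural_mortality = natural_mortality),
            class = "mortality_inputs")
}

#' Average annual mortality of hypertensive disease
#'
#' `P_MH = P_IR x P_CDMR x P_MACD`, where `P_MACD` is the fraction of
#' cardiovascular deaths attributable to hypertension
#' (`hyp_death_rate / cvd_death_rate`). With the published inputs this is
#' 0.2750 x 0.455 x (1.8279 / 2.815) = 0.0812.
#'
#' @param inputs a [mortality_inputs()] object.
#' @param digits decimals the result is rounded (half-up) to, as printed.
#' @return Per-cycle death probability of the poorly controlled state.
#' @export
hypertension_mortality <- function(inputs = mortality_inputs(), digits = 4) {
  stopifnot(inherits(inputs, "mortality_inputs"))
  if (inputs$p_ir == 0) return(0)
  p <- inputs$p_ir * inputs$p_cdmr *
    (inputs$hyp_death_rate / inputs$cvd_death_rate)
  round_half_up(p, digits)
}

#' Fraction of cardiovascular mortality attributable to hypertension
#'
#' `hyp_death_rate / cvd_death_rate`, reported as a percentage
#' (1.8279 / 2.815 gives 64.93\%).
#'
#' @inheritParams hypertension_mortality
#' @return Percentage, half-up to 2 decimals.
#' @export
attributable_mortality_fraction <- function(inputs = mortality_inputs()) {
  stopifnot(inherits(inputs, "mortality_inputs"))
  round_half_up(100 * inputs$hyp_death_rate / inputs$cvd_death_rate, 2)
}

#' Parameters of the 3-state Markov cohort model
#'
#' States are poorly controlled blood pressure, well controlled blood
#' pressure, and death (absorbing). Within a cycle deaths occur first
#' (poor at `mort_poor`, well at `mort_well`), then the survivors
#' transition. Three transition styles are available:
#' \describe{
#'   \item{`"relapse"` (default)}{poor survivors reach control with
#'     probability `control_prob`; well survivors relapse to the poorly
#'     controlled state with probability `relapse_prob`. With the default
#'     relapse probability 0.275 (the population hypertension incidence
#'     rate) this reproduces the published 28-cycle trace of both arms.}
#'   \item{`"redistribute"`}{all survivors are re-allocated each cycle:
#'     well with probability `control_prob`, poor otherwise (equivalent to
#'     relapse at `1 - control_prob`).}
#'   \item{`"incremental"`}{poor survivors move to well at `control_prob`;
#'     well survivors stay well (relapse 0).}
#' }
#'
#' @param arm `"ipc"` (control probability 0.7188, the one-year control
#'   rate under the intervention) or `"none"` (0.11, the population
#'   control rate); sets the default `control_prob`.
#' @param control_prob per-cycle probability that a surviving poorly
#'   controlled patient reaches control.
#' @param relapse_prob per-cycle probability that a surviving controlled
#'   patient relapses (used by the `"relapse"` style).
#' @param mort_poor per-cycle death probability of the poorly controlled
#'   state (default `P_MH` = 0.0812, see [hypertension_mortality()]).
#' @param mort_well per-cycle death probability of the controlled state
#'   (default the natural mortality 7.18 per mille).
#' @param add_natural_to_poor if `TRUE`, natural mortality is added to
#'   `mort_poor` (a documented calibration switch; default `FALSE`).
#' @param cohort_size,start_age,horizon,cycle_length cohort of 96 starting
#'   at the mean enrollment age 46.63, simulated for 28 annual cycles.
#' @param u_poor,u_well health-state utilities (QALY weights); defaults 1.
#' @param transition_style see above.
#' @return A validated list of class `markov_params`.
#' @export
markov_params <- function(arm = c("ipc", "none"),
                          control_prob = NULL,
                          relapse_prob = 0.275,
                          mort_poor = hypertension_mortality(),
                          mort_well = mortality_inputs()$natural_mortality / 1000,
                          add_natural_to_poor = FALSE,
                          cohort_size = 96, start_age = 46.63,
                          horizon = 28, cycle_length = 1,
                          u_poor = 1, u_well = 1,
                          transition_style = c("relapse", "redistribute",
                                               "incremental")) {
  arm <- match.arg(arm)
  transition_style <- match.arg(transition_style)
  if (is.null(control_prob))
    control_prob <- switch(arm, ipc = 0.7188, none = 0.11)
  if (add_natural_to_poor)
    mort_poor <- mort_poor + mortality_inputs()$natural_mortality / 1000
  p <- list(arm = arm, control_prob = control_prob,
            relapse_prob = relapse_prob, mort_poor = mort_poor,
            mort_well = mort_well, cohort_size = cohort_size,
            start_age = start_age, horizon = horizon,
            cycle_length = cycle_length, u_poor = u_poor, u_well = u_well,
            transition_style = transition_style)
  probs <- c(control_prob, relapse_prob, mort_poor, mort_well)
  if (any(probs < 0 | probs > 1))
    stop("all transition probabilities must lie in [0, 1]")
  if (horizon < 1) stop("horizon must be at least 1 cycle")
  if (any(c(u_poor, u_well) < 0 | c(u_poor, u_well) > 1))
    stop("utilities must lie in [0, 1]")
  class(p) <- "markov_params"
  p
}

#' One-cycle transition matrix
#'
#' Row-stochastic 3x3 matrix over (poor, well, dead) implementing the
#' deaths-first within-cycle ordering of [markov_params()]; the dead row
#' is absorbing.
#'
#' @param params a [markov_params()] object.
#' @return 3x3 matrix with rows/columns `poor`, `well`, `dead`.
#' @export
build_transition_matrix <- function(params) {
  stopifnot(inherits(params, "markov_params"))
  c_ <- params$control_prob
  r <- switch(params$transition_style,
              relapse = params$relapse_prob,
              redistribute = 1 - c_,
              incremental = 0)
  dp <- params$mort_poor; dw <- params$mort_well
  M <- rbind(poor = c((1 - dp) * (1 - c_), (1 - dp) * c_, dp),
             well = c((1 - dw) * r, (1 - dw) * (1 - r), dw),
             dead = c(0, 0, 1))
  colnames(M) <- c("poor", "well", "dead")
  M
}

# half-up rounding with largest-remainder repair so counts always re-sum
# to the cohort size
round_counts <- function(frac, total) {
  raw <- frac * total
  cnt <- floor(raw + 0.5)
  diff <- total - sum(cnt)
  if (diff != 0) {
    rem <- raw - floor(raw)
    ord <- if (diff > 0) order(rem, decreasing = TRUE) else order(rem)
    i <- 1
    while (diff != 0) {
      cnt[ord[i]] <- cnt[ord[i]] + sign(diff)
      diff <- diff - sign(diff)
      i <- i + 1
    }
  }
  as.integer(cnt)
}

#' Run the Markov cohort
#'
#' Starts the whole cohort in the poorly controlled state and iterates the
#' one-cycle transition matrix for `horizon` cycles, recording state
#' occupancy fractions and patient counts (half-up rounding with
#' largest-remainder repair, so counts re-sum to the cohort size every
#' cycle).
#'
#' @param params a [markov_params()] object.
#' @return An object of class `markov_trace`: a data.frame with columns
#'   `cycle`, fractions `poor`, `well`, `dead`, and counts `n_poor`,
#'   `n_well`, `n_dead`; the parameters are kept as an attribute.
#' @export
run_markov_cohort <- function(params) {
  stopifnot(inherits(params, "markov_params"))
  M <- build_transition_matrix(params)
  H <- params$horizon
  v <- c(1, 0, 0)
  fr <- matrix(0, H + 1, 3, dimnames = list(NULL, c("poor", "well", "dead")))
  fr[1, ] <- v
  for (t in seq_len(H)) {
    v <- as.vector(v %*% M)
    fr[t + 1, ] <- v
  }
  cnt <- t(apply(fr, 1, round_counts, total = params$cohort_size))
  out <- data.frame(cycle = 0:H, fr, n_poor = cnt[, 1], n_well = cnt[, 2],
                    n_dead = cnt[, 3])
  attr(out, "params") <- params
  class(out) <- c("markov_trace", "data.frame")
  out
}

#' @export
print.markov_trace <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Markov cohort trace: arm '%s', %d cycles, cohort %d\n",
              p$arm, p$horizon, p$cohort_size))
  print.data.frame(x[c(1, 2, nrow(x)), ], row.names = FALSE, digits = 4)
  invisible(x)
}
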