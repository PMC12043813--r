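#' Discount factor for a model cycle
#'
#' `(1 + rate)^(-t)` with `t` the cycle's start time in years, or its
#' mid-cycle time when the half-cycle convention is active for flows.
#'
#' @param cycle Cycle index, 0-based (vectorised).
#' @param annual_rate Annual discount rate (>= 0).
#' @param cycle_length_years Cycle length in years (default 0.25).
#' @param half_cycle Evaluate at mid-cycle time (default `FALSE`).
#' @return Discount factor(s).
#' @export
discount_factor <- function(cycle, annual_rate, cycle_length_years = 0.25,
                            half_cycle = FALSE) {
  stopifnot(annual_rate >= 0)
  t <- (cycle + if (half_cycle) 0.5 else 0) * cycle_length_years
  (1 + annual_rate)^(-t)
}

## schedule rate applying in a given (0-based) model year; the last entry
## persists for all later years
rate_for_year <- function(schedule, year) {
  schedule[pmin(floor(year) + 1L, length(schedule))]
}

#' Weighted anti-VEGF administration cost per visit
#'
#' Each injection visit carries an OCT scan (100% of visits) plus an
#' outpatient procedure (95%) or day-case procedure (5%).
#'
#' @param costs The `costs` element of a model configuration (component
#'   costs under `admin_components`, weights under `admin_weights`).
#' @return Cost per administration visit.
#' @export
admin_cost_per_visit <- function(costs) {
  comp <- vapply(costs$admin_components, p_val, numeric(1))
  sum(comp[names(costs$admin_weights)] * costs$admin_weights)
}

#' Utility values by band for a treated worst-seeing eye
#'
#' The two best bands share the best-state utility; from the second band a
#' fixed total decrement is spread linearly over the six remaining steps
#' down to the worst band.
#'
#' @param u_best Utility of the best band.
#' @param decrement_total Total utility decrement between best and worst
#'   bands (default 0.1).
#' @return Numeric vector of 8 per-band utilities, best to worst.
#' @export
#' @examples
#' round(wse_utility_vector(0.839, 0.1), 3)
wse_utility_vector <- function(u_best, decrement_total = 0.1) {
  stopifnot(u_best >= 0, u_best <= 1, decrement_total <= u_best)
  steps <- c(0, 0:(N_BANDS - 2L))
  setNames(u_best - steps * decrement_total / (N_BANDS - 2L), bcva_bands)
}

## per-band utility mix given the both-eye fraction: both-eye patients use
## BSE utilities; single-eye patients mix WSE/BSE by the treated-eye split
band_utilities <- function(config, fraction_both) {
  u_bse <- vapply(config$utilities$bse, p_val, numeric(1))
  u_wse <- vapply(config$utilities$wse, p_val, numeric(1))
  wse_share <- p_val(config$fellow_eye$p_treated_wse)[1]
  single <- (1 - wse_share) * u_bse + wse_share * u_wse
  outer(fraction_both, u_bse) + outer(1 - fraction_both, single)
}

#' Quality-adjusted life-years accrued in one cycle
#'
#' Each band's utility is the both-eye fraction weighted best-seeing-eye
#' utility plus the single-eye fraction weighted mix of best-/worst-seeing
#' treated-eye utilities; occupancy is weighted by utility and the cycle
#' length, minus any adverse-event disutility flow. Death contributes
#' nothing. Undiscounted; discounting and half-cycle correction are applied
#' by [value_trace()].
#'
#' @param occupancy Occupancy vector over the 9 states.
#' @param fraction_both Fraction of patients treated in both eyes.
#' @param config Model configuration (utilities and treated-eye mix).
#' @param ae_disutility_flow QALY decrement for this cycle (default 0).
#' @return QALYs for the cycle.
#' @export
cycle_qaly <- function(occupancy, fraction_both, config,
                       ae_disutility_flow = 0) {
  u <- band_utilities(config, fraction_both)[1L, ]
  sum(occupancy[seq_len(N_BANDS)] * u) * config$cycle_length_years -
    ae_disutility_flow
}

## Vectorised cost kernel. occ: n x 9 occupancy rows; fon, fb: length-n
## channels; years: cycle-start years; subseq_active: length-n fraction in
## the subsequent-treatment window. Returns an n x 7 component matrix of
## undiscounted per-cycle costs.
cost_components <- function(occ, fon, fb, strategy, config, years,
                            subseq_active = 0) {
  n <- nrow(occ)
  alive <- 1 - occ[, DEATH]
  costs <- config$costs
  sch <- config$schedules
  cyl <- config$cycle_length_years

  drug <- admin <- prp <- numeric(n)
  inj <- rate_for_year(sch$injections_per_year, years) * cyl
  if (strategy$uses_anti_vegf) {
    price <- p_val(costs$drug[[strategy$drug]])
    drug <- inj * price * fon * (1 + fb) * alive
    admin <- inj * admin_cost_per_visit(costs) * fon * alive
  }
  if (strategy$uses_prp) {
    sess <- rate_for_year(sch$prp_sessions_per_year, years) * cyl
    prp <- sess * p_val(costs$prp_per_session) * fon * alive
  }

  v_on <- rate_for_year(sch$monitoring_on_treatment_per_year, years)
  if (strategy$uses_anti_vegf && !config$scenario$treatment_separate_visit)
    v_on <- pmax(0, v_on - rate_for_year(sch$injections_per_year, years))
  v_post <- rate_for_year(sch$monitoring_post_treatment_per_year, years)
  monitoring <- (v_on * cyl * p_val(costs$monitoring_on_treatment) * fon +
                 v_post * cyl * p_val(costs$monitoring_post_treatment) *
                   (1 - fon)) * alive

  low_vision <- (occ[, N_BANDS - 1L] + occ[, N_BANDS]) *
    p_val(costs$low_vision_per_cycle)

  ae <- numeric(n)
  y1 <- years < 1
  if (any(y1)) {
    ae_rate <- sum(vapply(names(config$ae_profile), function(a)
      p_val(config$ae_profile[[a]]) * p_val(costs$ae[[a]]), numeric(1)))
    ae[y1] <- ae_rate * cyl * fon[y1] * alive[y1]
  }

  subsequent <- subseq_active * subsequent_cycle_cost(strategy, config, fb) *
    alive

  cbind(drug = drug, administration = admin, prp = prp,
        monitoring = monitoring, low_vision = low_vision, ae = ae,
        subsequent = subsequent)
}

## Per-cycle, per-person cost of the subsequent treatment a discontinuing
## patient switches to: anti-VEGF arms switch to PRP, PRP alone switches to
## bevacizumab (no within-class switches). Cost-only, no effect change.
subsequent_cycle_cost <- function(strategy, config, fb) {
  cyl <- config$cycle_length_years
  sch <- config$schedules
  if (strategy$uses_anti_vegf) {
    rate_for_year(sch$prp_sessions_per_year, 0) * cyl *
      p_val(config$costs$prp_per_session)
  } else {
    inj <- rate_for_year(sch$injections_per_year, 0) * cyl
    inj * (p_val(config$costs$drug$bevacizumab) * (1 + fb) +
             admin_cost_per_visit(config$costs))
  }
}

#' Undiscounted cost components for one cycle
#'
#' @param occupancy Occupancy vector over the 9 states.
#' @param fraction_on Fraction of survivors on treatment.
#' @param fraction_both Fraction treated in both eyes.
#' @param strategy A strategy definition (or its name in
#'   `config$strategies`).
#' @param config Model configuration.
#' @param cycle Cycle index, 0-based (determines the schedule year and the
#'   adverse-event window).
#' @return Named vector of cost components (`drug`, `administration`,
#'   `prp`, `monitoring`, `low_vision`, `ae`, `subsequent`).
#' @export
cycle_cost <- function(occupancy, fraction_on, fraction_both, strategy,
                       config, cycle = 0) {
  if (is.character(strategy)) {
    nm <- vapply(config$strategies, `[[`, "", "name")
    strategy <- config$strategies[[match(strategy, nm)]]
  }
  year <- cycle * config$cycle_length_years
  cost_components(matrix(occupancy, 1L), fraction_on, fraction_both,
                  strategy, config, year)[1L, ]
}

#' Value a cohort trace in discounted costs and QALYs
#'
#' Applies the half-cycle correction by trapezoidal averaging of
#' cycle-start and cycle-end occupancy (and bookkeeping channels), values
#' each cycle's costs and QALYs, discounts at the mid-cycle time, and sums.
#' Subsequent-treatment costs accrue only within the configured cap after
#' discontinuation.
#'
#' @param trace A [run_trace()] result.
#' @param strategy The matching strategy definition (or name).
#' @param config Model configuration.
#' @return An object of class `pdr_ce_result`: list with `strategy`,
#'   `cost`, `qalys`, `life_years` (discounted), and `breakdown` (named
#'   cost components summing to `cost`).
#' @export
value_trace <- function(trace, strategy, config) {
  if (is.character(strategy)) {
    nm <- vapply(config$strategies, `[[`, "", "name")
    strategy <- config$strategies[[match(strategy, nm)]]
  }
  n <- trace$n_cycles
  cyl <- trace$cycle_length_years
  occ <- trace$occupancy
  occ_mid <- (occ[seq_len(n), , drop = FALSE] +
              occ[seq_len(n) + 1L, , drop = FALSE]) / 2
  fon_mid <- (trace$fraction_on_treatment[seq_len(n)] +
              trace$fraction_on_treatment[seq_len(n) + 1L]) / 2
  fb_mid <- (trace$fraction_both[seq_len(n)] +
             trace$fraction_both[seq_len(n) + 1L]) / 2
  years <- trace$years[seq_len(n)]

  ## fraction inside the subsequent-treatment window: switchers are the
  ## configured share of each cycle's newly discontinued fraction, active
  ## for at most cap_cycles cycles
  st <- config$subsequent_treatment
  flow <- st$fraction *
    pmax(0, -diff(trace$fraction_on_treatment))
  cum <- cumsum(flow)
  lag <- c(rep(0, st$cap_cycles), head(cum, -st$cap_cycles))[seq_len(n)]
  subseq_active <- cum - lag

  cost_mat <- cost_components(occ_mid, fon_mid, fb_mid, strategy, config,
                              years, subseq_active)

  u <- band_utilities(config, fb_mid)
  qaly_cycle <- rowSums(occ_mid[, seq_len(N_BANDS), drop = FALSE] * u) * cyl
  y1 <- years < 1
  if (any(y1)) {
    dis_rate <- sum(vapply(names(config$ae_profile), function(a)
      p_val(config$ae_profile[[a]]) *
        p_val(config$utilities$ae_disutilities[[a]]), numeric(1)))
    qaly_cycle[y1] <- qaly_cycle[y1] -
      dis_rate * cyl * fon_mid[y1] * (1 - occ_mid[y1, DEATH])
  }

  df <- discount_factor(seq_len(n) - 1L, config$discount_rate_annual,
                        cyl, half_cycle = TRUE)
  breakdown <- colSums(cost_mat * df)
  structure(list(strategy = strategy$name,
                 label = if (is.null(strategy$label)) strategy$name else
                   strategy$label,
                 cost = sum(breakdown),
                 qalys = sum(qaly_cycle * df),
                 life_years = sum(trace$life_years * df),
                 breakdown = breakdown),
            class = "pdr_ce_result")
}

#' @export
print.pdr_ce_result <- function(x, ...) {
  cat(sprintf("%s: cost %.2f | QALYs %.4f | discounted life-years %.3f\n",
              x$label, x$cost, x$qalys, x$life_years))
  invisible(x)
}
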