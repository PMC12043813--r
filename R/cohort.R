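#' Per-cycle death probability at a given age
#'
#' The sex-specific annual probabilities are mixed by the male fraction,
#' the diabetes hazard ratio is applied on the hazard scale
#' (`q_adj = 1 - (1 - q_mix)^hr`), and the result is converted to the cycle
#' length as `1 - (1 - q_adj)^(1/cycles_per_year)`. Mortality uses the
#' integer age floor.
#'
#' @param age Age in years (vectorised); must lie within the life-table
#'   range.
#' @param mortality Mortality model: list with `life_table` (columns `age`,
#'   `sex`, `qx`) and `hr_diabetes`.
#' @param male_fraction Proportion of the cohort that is male.
#' @param cycles_per_year Model cycles per year (default 4).
#' @return Per-cycle death probability (same length as `age`).
#' @export
cycle_death_prob <- function(age, mortality, male_fraction = 0.576,
                             cycles_per_year = 4L) {
  lt <- mortality$life_table
  hr <- p_val(mortality$hr_diabetes)
  a <- floor(age)
  ages_m <- lt$age[lt$sex == "male"]
  qm_tab <- lt$qx[lt$sex == "male"][order(ages_m)]
  ages_f <- lt$age[lt$sex == "female"]
  qf_tab <- lt$qx[lt$sex == "female"][order(ages_f)]
  amin <- min(ages_m); amax <- max(ages_m)
  if (any(a < amin | a > amax))
    stop("age outside life-table range [", amin, ", ", amax, "]",
         call. = FALSE)
  q_mix <- male_fraction * qm_tab[a - amin + 1L] +
    (1 - male_fraction) * qf_tab[a - amin + 1L]
  q_adj <- 1 - (1 - q_mix)^hr
  1 - (1 - q_adj)^(1 / cycles_per_year)
}

#' Fraction of the cohort remaining on treatment at a given time
#'
#' Right-continuous step function over the discontinuation breakpoints:
#' the fraction attached to the last breakpoint at or before `year`
#' applies.
#'
#' @param schedule Discontinuation schedule: list with a `breakpoints` data
#'   frame (columns `year`, `fraction`).
#' @param year Time since baseline in years (vectorised).
#' @return Fraction on treatment in (0, 1\].
#' @export
fraction_on_treatment <- function(schedule, year) {
  bp <- schedule$breakpoints
  idx <- findInterval(year, bp$year)
  idx[idx < 1L] <- 1L
  bp$fraction[idx]
}

#' Update the fraction of patients treated in both eyes
#'
#' Each cycle, the single-eye fraction acquires fellow-eye disease with the
#' per-cycle probability; both-eye involvement is absorbing.
#'
#' @param fraction_both Current fraction treated in both eyes.
#' @param p_fellow_per_cycle Per-cycle probability of fellow-eye
#'   involvement.
#' @return Updated fraction.
#' @export
update_fellow_eye <- function(fraction_both, p_fellow_per_cycle) {
  fraction_both + (1 - fraction_both) * p_fellow_per_cycle
}

## Vectorised per-cycle (gain, loss) probabilities for a strategy across
## all cycle-start years. Mirrors effect_trajectory()/cycle_change_probs()
## but computed with vector arithmetic for speed.
trajectory_probs <- function(config, strategy, years) {
  th <- config$threshold_letters
  cpy <- config$cycles_per_year
  prp_m <- p_val(config$prp_acuity$annual_mean)
  prp_s <- p_val(config$prp_acuity$annual_sd)
  m_arm <- if (is.null(strategy$effect_name)) prp_m else
    prp_m - p_val(config$treatment_effects[[strategy$effect_name]]) *
      LETTERS_PER_LOGMAR

  mean_v <- rep(m_arm, length(years))
  sd_v <- rep(prp_s, length(years))
  stab <- rep(FALSE, length(years))

  if (config$scenario$effect_trajectory == "stabilised") {
    if (!strategy$uses_anti_vegf) {
      stab <- years >= 1
    } else {
      stab <- years >= 2
      ramp <- years >= 1 & years < 2
      mean_v[ramp] <- m_arm * (2 - years[ramp])
    }
  }
  onset <- config$scenario$natural_history_onset_years
  if (!is.null(onset)) {
    nh <- years >= onset
    mean_v[nh] <- p_val(config$natural_history$annual_mean)
    sd_v[nh] <- p_val(config$natural_history$annual_sd)
    stab[nh] <- FALSE
  }

  pg <- annual_to_cycle(pnorm(th, mean_v, sd_v, lower.tail = FALSE), cpy)
  pl <- annual_to_cycle(pnorm(-th, mean_v, sd_v), cpy)
  sp <- config$scenario$stabilised_probs
  if (is.null(sp)) sp <- c(0, 0)
  pg[stab] <- sp[1]
  pl[stab] <- sp[2]
  cbind(gain = pg, loss = pl)
}

#' Run the Markov cohort trace for one strategy
#'
#' Starts the cohort at the baseline BCVA distribution (nobody dead) and
#' iterates the 3-monthly transition dynamics to the horizon age, combining
#' the strategy's effect-trajectory band-change probabilities with the
#' age-specific per-cycle death probability. Bookkeeping channels (fraction
#' on treatment, fraction treated in both eyes, cohort age, per-cycle
#' life-years) are updated alongside.
#'
#' @param config A model configuration (see [default_parameter_set()]).
#' @param strategy A strategy definition from `config$strategies`, or its
#'   name.
#' @param validate Validate the configuration before running (default
#'   `TRUE`; PSA draws skip re-validation for speed).
#' @return An object of class `pdr_trace`: list with `occupancy`
#'   (`(n_cycles+1) x 9` matrix, rows are cycle starts), `years`, `age`,
#'   `fraction_on_treatment`, `fraction_both`, `life_years` (per cycle,
#'   half-cycle corrected), `strategy`.
#' @export
run_trace <- function(config, strategy, validate = TRUE) {
  if (is.character(strategy)) {
    nm <- vapply(config$strategies, `[[`, "", "name")
    idx <- match(strategy, nm)
    if (is.na(idx)) stop("unknown strategy: ", strategy, call. = FALSE)
    strategy <- config$strategies[[idx]]
  }
  if (validate) {
    bad <- validate_config(config, strict = FALSE)
    if (nrow(bad))
      stop("invalid configuration: ", paste(bad$field, collapse = ", "),
           call. = FALSE)
  }

  cyl <- config$cycle_length_years
  n <- as.integer(round((config$horizon_age - config$start_age) / cyl))
  years <- (seq_len(n) - 1L) * cyl           # cycle-start times
  age <- config$start_age + years

  probs <- trajectory_probs(config, strategy, years)
  q <- cycle_death_prob(age, config$mortality, config$male_fraction,
                        config$cycles_per_year)

  dsc <- config$discontinuation
  over <- config$scenario$post5y_continuation_override
  if (!is.null(over)) {
    last <- nrow(dsc$breakpoints)
    dsc$breakpoints$fraction[last] <- over
  }
  frac_on <- fraction_on_treatment(dsc, c(years, n * cyl))

  p_fellow <- p_val(config$fellow_eye$p_fellow_per_cycle)
  frac_both <- numeric(n + 1L)
  frac_both[1L] <- p_val(config$fellow_eye$p_both_at_baseline)
  for (t in seq_len(n))
    frac_both[t + 1L] <- update_fellow_eye(frac_both[t], p_fellow)

  occ <- matrix(0, n + 1L, N_STATES,
                dimnames = list(NULL, c(bcva_bands, "death")))
  occ[1L, seq_len(N_BANDS)] <- p_val(config$baseline_band_distribution)

  for (t in seq_len(n)) {
    b <- occ[t, seq_len(N_BANDS)]
    pg <- probs[t, 1L]; pl <- probs[t, 2L]
    stay <- rep.int(1 - pg - pl, N_BANDS)
    stay[1L] <- stay[1L] + pg
    stay[N_BANDS] <- stay[N_BANDS] + pl
    nb <- b * stay
    nb[1:(N_BANDS - 1L)] <- nb[1:(N_BANDS - 1L)] + b[2:N_BANDS] * pg
    nb[2:N_BANDS] <- nb[2:N_BANDS] + b[1:(N_BANDS - 1L)] * pl
    occ[t + 1L, seq_len(N_BANDS)] <- (1 - q[t]) * nb
    occ[t + 1L, DEATH] <- occ[t, DEATH] + sum(b) * q[t]
  }

  alive <- 1 - occ[, DEATH]
  life_years <- (head(alive, -1L) + tail(alive, -1L)) / 2 * cyl

  structure(list(occupancy = occ, years = c(years, n * cyl),
                 age = c(age, config$horizon_age),
                 fraction_on_treatment = frac_on,
                 fraction_both = frac_both,
                 life_years = life_years,
                 n_cycles = n, cycle_length_years = cyl,
                 strategy = strategy$name),
            class = "pdr_trace")
}

#' @export
print.pdr_trace <- function(x, ...) {
  cat("Markov cohort trace:", x$strategy, "|", x$n_cycles, "cycles of",
      x$cycle_length_years, "years\n")
  cat(sprintf("  surviving at horizon: %.3f | undiscounted life-years: %.2f\n",
              1 - x$occupancy[nrow(x$occupancy), DEATH],
              sum(x$life_years)))
  invisible(x)
}

#' @export
as.data.frame.pdr_trace <- function(x, ...) {
  data.frame(cycle = 0:x$n_cycles, year = x$years, age = x$age,
             x$occupancy,
             fraction_on_treatment = x$fraction_on_treatment,
             fraction_both = x$fraction_both,
             check.names = FALSE)
}
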