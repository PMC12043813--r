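#' Annual acuity-change model
#'
#' The generative assumption behind all visual transitions: annual change in
#' BCVA (ETDRS letters) is normally distributed, and a change of at least
#' `threshold_letters` in either direction crosses one 10-letter band
#' boundary.
#'
#' @param annual_mean Mean annual BCVA change in letters (negative =
#'   worsening).
#' @param annual_sd Standard deviation of annual change in letters (> 0).
#' @param threshold_letters Letters needed to change band (default 5, the
#'   minimal band-crossing change).
#' @param cycles_per_year Model cycles per year (default 4, 3-monthly).
#' @param stabilised If `TRUE` the state is frozen: per-cycle gain and loss
#'   probabilities are both zero (mortality still applies).
#' @return An object of class `pdr_acuity_model`.
#' @export
#' @examples
#' natural_history <- acuity_model(-1.30, 4.90)
#' annual_change_probs(natural_history)
acuity_model <- function(annual_mean, annual_sd, threshold_letters = 5,
                         cycles_per_year = 4L, stabilised = FALSE) {
  if (annual_sd <= 0) stop("annual_sd must be > 0", call. = FALSE)
  if (threshold_letters <= 0) stop("threshold_letters must be > 0",
                                   call. = FALSE)
  if (cycles_per_year < 1) stop("cycles_per_year must be >= 1",
                                call. = FALSE)
  structure(list(annual_mean = annual_mean, annual_sd = annual_sd,
                 threshold_letters = threshold_letters,
                 cycles_per_year = as.integer(cycles_per_year),
                 stabilised = stabilised),
            class = "pdr_acuity_model")
}

#' @export
print.pdr_acuity_model <- function(x, ...) {
  cat(sprintf("Acuity-change model: N(%.4g, %.4g) letters/yr, threshold %g%s\n",
              x$annual_mean, x$annual_sd, x$threshold_letters,
              if (x$stabilised) " [stabilised]" else ""))
  invisible(x)
}

#' Annual probabilities of gaining or losing one BCVA band
#'
#' With annual change X ~ Normal(annual_mean, annual_sd) in letters,
#' the gain probability is P(X >= threshold) and the loss probability
#' P(X <= -threshold).
#'
#' @param model An [acuity_model()].
#' @return Named numeric vector `c(gain = , loss = )`.
#' @export
annual_change_probs <- function(model) {
  stopifnot(inherits(model, "pdr_acuity_model"))
  if (model$stabilised) return(c(gain = 0, loss = 0))
  th <- model$threshold_letters
  c(gain = pnorm(th, model$annual_mean, model$annual_sd, lower.tail = FALSE),
    loss = pnorm(-th, model$annual_mean, model$annual_sd))
}

#' Convert an annual probability to a per-cycle probability
#'
#' Conversion on the constant-rate scale: `1 - (1 - p)^(1/cycles_per_year)`.
#' This is the convention that reproduces the published quarterly
#' natural-history probabilities from the annual tail probabilities; simple
#' division by the number of cycles does not.
#'
#' @param p_annual Annual probability in \[0,1\] (vectorised).
#' @param cycles_per_year Cycles per year (default 4).
#' @return Per-cycle probability.
#' @export
annual_to_cycle <- function(p_annual, cycles_per_year = 4L) {
  if (any(p_annual < 0 | p_annual > 1))
    stop("p_annual must be in [0,1]", call. = FALSE)
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' Per-cycle band gain/loss probabilities for an acuity model
#'
#' @param model An [acuity_model()].
#' @return Named numeric vector `c(gain = , loss = )` of per-cycle
#'   probabilities.
#' @export
cycle_change_probs <- function(model) {
  if (model$stabilised) return(c(gain = 0, loss = 0))
  annual_to_cycle(annual_change_probs(model), model$cycles_per_year)
}

#' Back-solve an acuity model from per-cycle band-change probabilities
#'
#' Inverts the derivation chain: per-cycle probabilities are converted back
#' to annual tail probabilities (rate scale), then the two normal tail
#' conditions P(X >= threshold) and P(X <= -threshold) are solved for the
#' mean and SD. Used to recover the PRP-arm annual change model from its
#' published quarterly transition probabilities.
#'
#' @param p_gain_cycle,p_loss_cycle Per-cycle probabilities in (0, 1).
#' @inheritParams acuity_model
#' @return An [acuity_model()].
#' @export
#' @examples
#' m <- acuity_model_from_cycle_probs(0.0479, 0.0848)
#' round(cycle_change_probs(m), 4)
acuity_model_from_cycle_probs <- function(p_gain_cycle, p_loss_cycle,
                                          threshold_letters = 5,
                                          cycles_per_year = 4L) {
  stopifnot(p_gain_cycle > 0, p_gain_cycle < 1,
            p_loss_cycle > 0, p_loss_cycle < 1)
  p_gain <- 1 - (1 - p_gain_cycle)^cycles_per_year
  p_loss <- 1 - (1 - p_loss_cycle)^cycles_per_year
  z_hi <- qnorm(1 - p_gain)   # (threshold - mean) / sd
  z_lo <- qnorm(p_loss)       # (-threshold - mean) / sd
  s <- 2 * threshold_letters / (z_hi - z_lo)
  m <- threshold_letters - z_hi * s
  acuity_model(m, s, threshold_letters, cycles_per_year)
}

#' Shift an acuity model by a treatment effect
#'
#' Treatment effects are expressed as the 1-year mean LogMAR difference
#' versus PRP (negative = better vision than PRP). With the standard ETDRS
#' equivalence of 5 letters per 0.1 LogMAR (1 letter = 0.02 LogMAR), the
#' arm's annual mean change is the PRP mean shifted by
#' `-mean_logmar_diff / 0.02` letters; the SD is unchanged (the evidence
#' synthesis provides only the dispersion of the mean difference, not
#' arm-level change SDs).
#'
#' @param prp_model The PRP-arm [acuity_model()].
#' @param mean_logmar_diff Mean LogMAR difference versus PRP at 1 year.
#' @return A shifted [acuity_model()].
#' @export
apply_treatment_effect <- function(prp_model, mean_logmar_diff) {
  m <- prp_model
  m$annual_mean <- prp_model$annual_mean -
    mean_logmar_diff * LETTERS_PER_LOGMAR
  m
}

#' Acuity model applying to a strategy at a given model time
#'
#' Implements the two treatment-effect trajectory scenarios:
#' \describe{
#'   \item{continued}{the year-1 arm model applies for the whole lifetime;}
#'   \item{stabilised}{the year-1 arm model applies in year 1; PRP alone is
#'     frozen (no further acuity movement) from year 1; anti-VEGF arms
#'     decline linearly between the year-1 mean and the stabilised value
#'     (zero mean change) across years 1-2, then freeze from year 2.}
#' }
#' If the scenario sets `natural_history_onset_years`, years at or beyond
#' the onset use the natural-history model instead.
#'
#' @param config A model configuration.
#' @param strategy A strategy definition from `config$strategies`.
#' @param year Model time in years since baseline (vectorised).
#' @return For scalar `year`, an [acuity_model()]; for vector `year`, a
#'   list of models of the same length.
#' @export
effect_trajectory <- function(config, strategy, year) {
  if (length(year) > 1)
    return(lapply(year, function(y) effect_trajectory(config, strategy, y)))
  stopifnot(year >= 0)

  nh <- acuity_model(p_val(config$natural_history$annual_mean),
                     p_val(config$natural_history$annual_sd),
                     config$threshold_letters, config$cycles_per_year)
  onset <- config$scenario$natural_history_onset_years
  if (!is.null(onset) && year >= onset) return(nh)

  prp_model <- acuity_model(p_val(config$prp_acuity$annual_mean),
                            p_val(config$prp_acuity$annual_sd),
                            config$threshold_letters, config$cycles_per_year)
  arm <- if (is.null(strategy$effect_name)) prp_model else
    apply_treatment_effect(
      prp_model, p_val(config$treatment_effects[[strategy$effect_name]]))

  if (config$scenario$effect_trajectory == "continued" || year < 1)
    return(arm)

  ## stabilised scenario
  if (!strategy$uses_anti_vegf) {            # PRP alone: frozen from year 1
    arm$stabilised <- TRUE
    return(arm)
  }
  if (year >= 2) {
    arm$stabilised <- TRUE
    return(arm)
  }
  ## linear decline of the mean between years 1 and 2 toward zero change
  arm$annual_mean <- arm$annual_mean * (2 - year)
  arm
}

#' Build a per-cycle transition matrix
#'
#' Nine states: eight BCVA bands (best to worst) plus death. Only
#' adjacent-band moves, self-loops and death transitions are possible. For
#' interior bands the row is
#' `(1-q)*p_gain` (one band better), `(1-q)*(1-p_gain-p_loss)` (stay),
#' `(1-q)*p_loss` (one band worse), `q` (death); the best band redirects the
#' blocked gain into staying, the worst band the blocked loss; death is
#' absorbing.
#'
#' @param probs Named vector `c(gain = , loss = )` of per-cycle band-change
#'   probabilities with `gain + loss <= 1`.
#' @param q_death_cycle Per-cycle death probability in \[0,1\].
#' @return A 9x9 row-stochastic matrix with band labels plus `"death"`.
#' @export
build_matrix <- function(probs, q_death_cycle = 0) {
  pg <- unname(probs["gain"]); pl <- unname(probs["loss"])
  if (is.na(pg) || is.na(pl)) { pg <- probs[1]; pl <- probs[2] }
  if (pg < 0 || pl < 0 || pg + pl > 1)
    stop("gain/loss probabilities must be non-negative with gain + loss <= 1",
         call. = FALSE)
  if (q_death_cycle < 0 || q_death_cycle > 1)
    stop("q_death_cycle must be in [0,1]", call. = FALSE)
  q <- q_death_cycle
  M <- matrix(0, N_STATES, N_STATES,
              dimnames = list(c(bcva_bands, "death"),
                              c(bcva_bands, "death")))
  for (i in seq_len(N_BANDS)) {
    stay <- 1 - pg - pl
    gain <- pg; loss <- pl
    if (i == 1L) { stay <- stay + gain; gain <- 0 }
    if (i == N_BANDS) { stay <- stay + loss; loss <- 0 }
    if (gain > 0) M[i, i - 1L] <- (1 - q) * gain
    M[i, i] <- (1 - q) * stay
    if (loss > 0) M[i, i + 1L] <- (1 - q) * loss
    M[i, DEATH] <- q
  }
  M[DEATH, DEATH] <- 1
  M
}
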