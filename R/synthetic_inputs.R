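## Gamma specs follow the +/-20% convention: shape (1.96/0.2)^2 = 96.036 so
## that 1.96 coefficients of variation span 20% of the mean; scale carries
## the mean.
gamma20 <- function(scale) dist_spec("gamma", shape = 96.036, scale = scale)

cost_param <- function(value, scale, provenance = "paper")
  param(value, gamma20(scale), provenance)

beta_param <- function(value, alpha, beta)
  param(value, dist_spec("beta", alpha = alpha, beta = beta))

#' Default parameter set (base case)
#'
#' Builds the complete base-case configuration: the baseline BCVA band
#' distribution, 1-year treatment effects versus PRP (LogMAR), the
#' discontinuation schedule, fellow-eye model, mortality inputs with a
#' synthetic life table, all costs and utilities with their sampling
#' distributions, and the six treatment strategies (optionally eight, with
#' the ranibizumab biosimilar pair).
#'
#' Resource-use schedules (injections, PRP sessions, monitoring visits),
#' adverse-event frequencies/costs/disutilities and the subsequent-treatment
#' rule are only reported in supplementary material in the source study;
#' here they are documented plausible stand-ins tagged
#' `provenance = "placeholder"`.
#'
#' @param include_biosimilar Add the ranibizumab biosimilar and biosimilar +
#'   PRP strategies (default `FALSE`, giving six strategies).
#' @param life_table Optional life table data frame (columns `age`, `sex`,
#'   `qx`); defaults to [generate_life_table()] with default parameters.
#' @return A `pdr_config` object passing [validate_config()].
#' @export
#' @examples
#' cfg <- default_parameter_set()
#' p_val(cfg$baseline_band_distribution)
default_parameter_set <- function(include_biosimilar = FALSE,
                                  life_table = NULL) {
  baseline <- c(0, 0.11, 0.39, 0.27, 0.15, 0.08, 0, 0)
  if (is.null(life_table))
    life_table <- generate_life_table(synthetic_life_table_spec())

  ## PRP-arm annual acuity-change model, back-solved from its quarterly
  ## transition probabilities (4.79% gain, 8.48% loss)
  prp <- acuity_model_from_cycle_probs(0.0479, 0.0848)

  effects <- list(
    aflibercept       = param(-0.088, dist_spec("normal", mean = -0.088, sd = 0.070)),
    ranibizumab       = param(-0.123, dist_spec("normal", mean = -0.123, sd = 0.058)),
    ranibizumab_prp   = param(-0.080, dist_spec("normal", mean = -0.080, sd = 0.042)),
    bevacizumab       = param(-0.193, dist_spec("normal", mean = -0.193, sd = 0.499)),
    bevacizumab_prp   = param(-0.172, dist_spec("normal", mean = -0.172, sd = 0.055)))
  effects$ranibizumab_biosimilar <- effects$ranibizumab
  effects$ranibizumab_biosimilar_prp <- effects$ranibizumab_prp

  strategy <- function(name, label, drug = NULL, vegf = !is.null(drug),
                       prp = grepl("_prp$", name) || name == "prp")
    list(name = name, label = label, uses_anti_vegf = vegf, uses_prp = prp,
         drug = drug, effect_name = if (name == "prp") NULL else name)

  strategies <- list(
    strategy("prp", "PRP"),
    strategy("bevacizumab", "Bevacizumab", "bevacizumab"),
    strategy("bevacizumab_prp", "Bevacizumab plus PRP", "bevacizumab"),
    strategy("ranibizumab", "Ranibizumab (Lucentis)", "ranibizumab"),
    strategy("ranibizumab_prp", "Ranibizumab (Lucentis) plus PRP",
             "ranibizumab"),
    strategy("aflibercept", "Aflibercept (Eylea)", "aflibercept"))
  if (include_biosimilar) {
    strategies <- c(strategies, list(
      strategy("ranibizumab_biosimilar", "Ranibizumab biosimilar (Ongavia)",
               "ranibizumab_biosimilar"),
      strategy("ranibizumab_biosimilar_prp",
               "Ranibizumab biosimilar (Ongavia) plus PRP",
               "ranibizumab_biosimilar")))
  }

  u_bse <- list(
    beta_param(0.839, 42.697, 8.193),   # >85
    beta_param(0.839, 42.697, 8.193),   # 76-85
    beta_param(0.783, 141.181, 39.127), # 66-75
    beta_param(0.783, 141.181, 39.127), # 56-65
    beta_param(0.732, 44.858, 16.423),  # 46-55
    beta_param(0.681, 46.286, 21.682),  # 36-45
    beta_param(0.630, 45.992, 27.011),  # 26-35
    beta_param(0.579, 3.604, 2.621))    # <=25
  u_wse <- list(
    beta_param(0.839, 42.697, 8.193),
    beta_param(0.839, 42.697, 8.193),
    beta_param(0.822, 45.330, 9.794),
    beta_param(0.806, 47.651, 11.494),
    beta_param(0.789, 49.669, 13.283),
    beta_param(0.772, 51.396, 15.150),
    beta_param(0.756, 52.841, 17.085),
    beta_param(0.739, 54.016, 19.077))
  names(u_bse) <- names(u_wse) <- bcva_bands

  cfg <- list(
    start_age = 56,
    horizon_age = 100,
    cycle_length_years = 0.25,
    discount_rate_annual = 0.035,
    wtp_threshold = 20000,
    male_fraction = 0.576,
    threshold_letters = 5,
    cycles_per_year = 4L,

    baseline_band_distribution = param(
      baseline,
      dist_spec("dirichlet", concentration = baseline * 100)),

    fellow_eye = list(
      p_both_at_baseline = beta_param(0.22, 75.900, 269.100),
      p_fellow_per_cycle = beta_param(0.054, 7.900, 138.397),
      ## pair (WSE, BSE); the dirichlet draw replaces both components
      p_treated_wse = param(c(0.672, 0.328),
                            dist_spec("dirichlet",
                                      concentration = c(67.2, 32.8))),
      p_treated_bse = param(0.328)),

    mortality = list(
      hr_diabetes = param(1.95, dist_spec("lognormal", mu = 0.668,
                                          sigma = 0.090)),
      life_table = life_table),

    natural_history = list(
      annual_mean = param(-1.30, dist_spec("normal", mean = -1.300,
                                           sd = 0.364)),
      annual_sd = param(4.90)),

    prp_acuity = list(
      annual_mean = param(prp$annual_mean, provenance = "derived"),
      annual_sd = param(prp$annual_sd, provenance = "derived")),

    treatment_effects = effects,

    discontinuation = list(
      breakpoints = data.frame(year = c(0, 1, 3, 5),
                               fraction = c(1.00, 0.87, 0.75, 0.50))),

    costs = list(
      drug = list(
        aflibercept = cost_param(816.00, 8.497),
        ranibizumab = cost_param(551.00, 5.737),
        ranibizumab_biosimilar = cost_param(523.45, 5.451),
        bevacizumab = cost_param(50.00, 0.521)),
      prp_per_session = cost_param(126.77, 1.320),
      admin_components = list(
        oct = cost_param(101.804, 1.060),
        outpatient = cost_param(129.616, 1.350),
        day_case = cost_param(660.838, 6.881)),
      admin_weights = c(oct = 1.00, outpatient = 0.95, day_case = 0.05),
      monitoring_on_treatment = cost_param(101.804, 1.060),
      monitoring_post_treatment = cost_param(38.344, 0.399),
      low_vision_per_cycle = param(421.609,
                                   dist_spec("gamma", shape = 25.003,
                                             scale = 16.862)),
      ae = list(
        endophthalmitis = cost_param(1200, 12.495, "placeholder"),
        vitreous_haemorrhage = cost_param(600, 6.248, "placeholder"))),

    utilities = list(
      bse = u_bse,
      wse = u_wse,
      ae_disutilities = list(
        endophthalmitis = param(0.10, provenance = "placeholder"),
        vitreous_haemorrhage = param(0.05, provenance = "placeholder"))),

    ## per-year resource-use rates; last entry persists for later years
    schedules = list(
      injections_per_year = c(7, 4, 3, 3, 2),
      prp_sessions_per_year = c(3, 0.5),
      monitoring_on_treatment_per_year = 4,
      monitoring_post_treatment_per_year = 2),

    ## annual per-patient probabilities, applied in year 1 only
    ae_profile = list(
      endophthalmitis = param(0.005, provenance = "placeholder"),
      vitreous_haemorrhage = param(0.015, provenance = "placeholder")),

    subsequent_treatment = list(fraction = 0.25, cap_cycles = 8L),

    strategies = strategies,

    scenario = list(effect_trajectory = "continued",
                    natural_history_onset_years = NULL,
                    treatment_separate_visit = FALSE,
                    post5y_continuation_override = NULL,
                    stabilised_probs = c(gain = 0, loss = 0)))
  class(cfg) <- "pdr_config"
  cfg
}

#' Specification for the synthetic life table
#'
#' A Gompertz-Makeham hazard, h(age) = makeham + a * exp(b * age), split
#' into male/female hazards by a multiplicative ratio applied symmetrically
#' (male x sqrt(ratio), female / sqrt(ratio)). Defaults are calibrated so
#' that sex-mixed life expectancy at age 56 is about 27 years before the
#' diabetes hazard ratio, a plausible national-life-table magnitude; this is
#' a synthetic stand-in, and users with a real life table can load one via
#' [read_life_table()].
#'
#' @param makeham Age-independent baseline hazard per year.
#' @param gompertz_a Hazard scale per year.
#' @param gompertz_b Log-hazard slope per year of age.
#' @param sex_ratio_adjustment Male/female hazard ratio (> 0).
#' @return A list of class `pdr_life_table_spec`.
#' @export
synthetic_life_table_spec <- function(makeham = 2e-4, gompertz_a = 2.2e-5,
                                      gompertz_b = 0.095,
                                      sex_ratio_adjustment = 1.45) {
  stopifnot(makeham >= 0, gompertz_a > 0, gompertz_b > 0,
            sex_ratio_adjustment > 0)
  structure(list(makeham = makeham, gompertz_a = gompertz_a,
                 gompertz_b = gompertz_b,
                 sex_ratio_adjustment = sex_ratio_adjustment),
            class = "pdr_life_table_spec")
}

#' Generate a synthetic life table
#'
#' Annual death probabilities q(age, sex) = 1 - exp(-h(age) * s), for ages
#' 0 to 100, with h the Gompertz-Makeham hazard and s the sex adjustment
#' (sqrt of the male/female ratio for males, its inverse for females).
#'
#' @param spec A [synthetic_life_table_spec()].
#' @return Data frame with columns `age` (0-100), `sex`
#'   (`"male"`/`"female"`) and `qx` (annual death probability).
#' @export
generate_life_table <- function(spec = synthetic_life_table_spec()) {
  stopifnot(inherits(spec, "pdr_life_table_spec"))
  ages <- 0:100
  h <- spec$makeham + spec$gompertz_a * exp(spec$gompertz_b * ages)
  adj <- sqrt(spec$sex_ratio_adjustment)
  qm <- 1 - exp(-h * adj)
  qf <- 1 - exp(-h / adj)
  if (any(qm >= 1) || any(qf >= 1))
    stop("life-table spec implies death probability >= 1 before age 100",
         call. = FALSE)
  data.frame(age = rep(ages, 2),
             sex = rep(c("male", "female"), each = length(ages)),
             qx = c(qm, qf), stringsAsFactors = FALSE)
}

#' Write / read a life table as tab-delimited text
#'
#' Columns `age`, `sex`, `qx`; probabilities serialised with 17 significant
#' digits so a generate-write-read cycle reproduces every double exactly.
#'
#' @param life_table Data frame with columns `age`, `sex`, `qx`.
#' @param path File path.
#' @return `write_life_table`: `path` invisibly; `read_life_table`: the
#'   life table data frame.
#' @export
write_life_table <- function(life_table, path) {
  out <- life_table
  out$qx <- sprintf("%.17g", out$qx)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  lt <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("integer", "character", "numeric"),
                   stringsAsFactors = FALSE)
  if (!identical(names(lt), c("age", "sex", "qx")))
    stop("life table must have columns age, sex, qx", call. = FALSE)
  lt
}

#' Rescale every sampling distribution's dispersion
#'
#' Returns a copy of the configuration in which each parameter's sampling
#' distribution has its standard deviation multiplied by `scale` while
#' keeping its mean: normal `sd` and lognormal `sigma` scale directly; gamma
#' keeps `shape * scale` fixed while multiplying the coefficient of
#' variation; beta and dirichlet rescale their effective sample size.
#' `scale = 0` collapses every distribution to a point mass at the point
#' estimate, which makes probabilistic analysis reproduce the deterministic
#' run exactly; `scale = 1` is the identity.
#'
#' @param config A model configuration.
#' @param scale Non-negative dispersion multiplier.
#' @return A `pdr_config` with rescaled distributions.
#' @export
generate_psa_fixture <- function(config, scale = 0) {
  stopifnot(scale >= 0)
  rescale <- function(x) {
    if (is_param(x)) {
      d <- x$dist
      if (d$family == "fixed") return(x)
      if (scale == 0) {
        x$dist <- dist_spec("fixed", value = x$value)
        return(x)
      }
      x$dist <- switch(d$family,
        normal = dist_spec("normal", mean = d$mean, sd = d$sd * scale),
        lognormal = dist_spec("lognormal", mu = d$mu,
                              sigma = d$sigma * scale),
        gamma = dist_spec("gamma", shape = d$shape / scale^2,
                          scale = d$scale * scale^2),
        beta = {
          m <- d$alpha / (d$alpha + d$beta)
          nu <- (d$alpha + d$beta + 1) / scale^2 - 1
          nu <- max(nu, 1e-6)
          dist_spec("beta", alpha = m * nu, beta = (1 - m) * nu)
        },
        dirichlet = dist_spec("dirichlet",
                              concentration = d$concentration / scale^2),
        d)
      return(x)
    }
    if (is.list(x) && !is.data.frame(x)) {
      cl <- class(x)
      x <- lapply(x, rescale)
      class(x) <- cl
      return(x)
    }
    x
  }
  rescale(config)
}

#' Write the default configuration and life table to a directory
#'
#' Regenerates the shipped fixtures deterministically: `default_config.yaml`
#' plus its life-table companion file.
#'
#' @param dir Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
make_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(dir, "default_config.yaml")
  save_config(default_parameter_set(), cfg_path)
  invisible(c(cfg_path,
              file.path(dir, "default_config_life_table.tsv")))
}
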