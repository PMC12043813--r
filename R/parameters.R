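#' BCVA band labels, best to worst
#'
#' Eight 10-letter bands of best corrected visual acuity (ETDRS letters).
#' Index 1 is the best band (">85"), index 8 the worst ("<=25"); the ninth
#' model state is death.
#'
#' @format Character vector of length 8.
#' @export
bcva_bands <- c(">85", "76-85", "66-75", "56-65", "46-55", "36-45",
                "26-35", "<=25")

#' Number of live health states and total states (including death)
#' @keywords internal
N_BANDS <- 8L
N_STATES <- 9L
DEATH <- 9L

## LogMAR <-> ETDRS letters: 5 letters per 0.1 LogMAR line
LETTERS_PER_LOGMAR <- 50

#' Distribution specification for probabilistic sensitivity analysis
#'
#' Describes the sampling distribution attached to a model parameter. The
#' point estimate of the parameter is expected to equal the distribution's
#' mean (for lognormal, `exp(mu)`, matching the convention under which the
#' printed hazard ratio 1.950 equals exp(0.668)).
#'
#' @param family One of `"beta"`, `"gamma"`, `"normal"`, `"lognormal"`,
#'   `"dirichlet"`, `"fixed"`.
#' @param ... Family-specific parameters: `alpha`, `beta` (beta); `shape`,
#'   `scale` (gamma); `mean`, `sd` (normal); `mu`, `sigma` (lognormal);
#'   `concentration` (dirichlet, numeric vector).
#' @return An object of class `pdr_dist`.
#' @export
#' @examples
#' dist_spec("beta", alpha = 7.9, beta = 138.397)
dist_spec <- function(family, ...) {
  family <- match.arg(family,
                      c("beta", "gamma", "normal", "lognormal", "dirichlet",
                        "fixed"))
  spec <- c(list(family = family), list(...))
  class(spec) <- "pdr_dist"
  validate_dist(spec)
  spec
}

validate_dist <- function(spec) {
  f <- spec$family
  chk <- function(ok, what)
    if (!isTRUE(ok)) stop("invalid ", f, " distribution: ", what,
                          call. = FALSE)
  switch(f,
    beta = chk(spec$alpha > 0 && spec$beta > 0, "alpha and beta must be > 0"),
    gamma = chk(spec$shape > 0 && spec$scale > 0,
                "shape and scale must be > 0"),
    normal = chk(spec$sd >= 0, "sd must be >= 0"),
    lognormal = chk(spec$sigma >= 0, "sigma must be >= 0"),
    dirichlet = chk(length(spec$concentration) >= 2 &&
                    all(spec$concentration >= 0) &&
                    any(spec$concentration > 0),
                    "concentration must be a non-negative vector"),
    fixed = invisible(NULL))
  invisible(spec)
}

#' Analytic mean of a distribution specification
#'
#' Beta: alpha/(alpha+beta); gamma: shape*scale; normal: mean; lognormal:
#' exp(mu) (the convention matching the printed point estimates, e.g.
#' exp(0.668) = 1.950); dirichlet: component-wise concentration /
#' sum(concentration); fixed: its constant.
#'
#' @param spec A [dist_spec()] object.
#' @return Numeric scalar (vector for dirichlet).
#' @export
distribution_mean <- function(spec) {
  validate_dist(spec)
  switch(spec$family,
    beta = spec$alpha / (spec$alpha + spec$beta),
    gamma = spec$shape * spec$scale,
    normal = spec$mean,
    lognormal = exp(spec$mu),
    dirichlet = spec$concentration / sum(spec$concentration),
    fixed = spec$value)
}

#' Model parameter with point estimate and sampling distribution
#'
#' @param value Numeric point estimate (vector allowed, e.g. a probability
#'   simplex paired with a dirichlet distribution).
#' @param dist A [dist_spec()]; defaults to a fixed (non-sampled) parameter.
#' @param provenance `"paper"` for values printed in the source tables,
#'   `"placeholder"` for documented stand-ins for quantities only available
#'   in supplementary material, `"derived"` for values computed from printed
#'   quantities.
#' @return An object of class `pdr_param`.
#' @export
param <- function(value, dist = NULL, provenance = "paper") {
  if (is.null(dist)) dist <- dist_spec("fixed", value = value)
  structure(list(value = value, dist = dist, provenance = provenance),
            class = "pdr_param")
}

#' Extract the point estimate from a parameter (or pass plain numerics)
#' @param x A `pdr_param` or numeric.
#' @return Numeric value.
#' @export
p_val <- function(x) if (inherits(x, "pdr_param")) x$value else x

is_param <- function(x) inherits(x, "pdr_param")

#' @export
print.pdr_param <- function(x, ...) {
  cat(format(x$value), " [", x$dist$family, ", ", x$provenance, "]\n",
      sep = "")
  invisible(x)
}

## ---- validation -----------------------------------------------------------

viol <- function(field, rule, observed) {
  data.frame(field = field, rule = rule,
             observed = paste(format(observed), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the configuration and returns the
#' violations as data, not errors: an empty data frame means the
#' configuration is valid.
#'
#' With `strict = TRUE` (the default, for point-estimate configurations) two
#' additional rule families apply: per-band utilities must be non-increasing
#' with worsening acuity, and every sampled parameter's distribution mean
#' must agree with its point estimate to within 0.5%. Sampled configurations
#' (PSA draws) are checked with `strict = FALSE`, since independent draws
#' legitimately break those consistency rules.
#'
#' @param config A model configuration (see [default_parameter_set()]).
#' @param strict Apply point-estimate consistency rules (default `TRUE`).
#' @return A data frame with columns `field`, `rule`, `observed`; zero rows
#'   if valid.
#' @export
validate_config <- function(config, strict = TRUE) {
  v <- list()
  add <- function(x) v[[length(v) + 1L]] <<- x
  in01 <- function(x) all(x >= 0 & x <= 1)

  bd <- p_val(config$baseline_band_distribution)
  if (length(bd) != N_BANDS)
    add(viol("baseline_band_distribution", "length 8", length(bd)))
  if (abs(sum(bd) - 1) > 1e-8)
    add(viol("baseline_band_distribution", "sums to 1", sum(bd)))
  if (any(bd < 0))
    add(viol("baseline_band_distribution", "non-negative", min(bd)))

  if (config$horizon_age <= config$start_age)
    add(viol("horizon_age", "greater than start_age", config$horizon_age))
  if (config$discount_rate_annual < 0)
    add(viol("discount_rate_annual", ">= 0", config$discount_rate_annual))
  if (config$wtp_threshold < 0)
    add(viol("wtp_threshold", ">= 0", config$wtp_threshold))
  if (!in01(config$male_fraction))
    add(viol("male_fraction", "in [0,1]", config$male_fraction))

  fe <- config$fellow_eye
  for (f in c("p_both_at_baseline", "p_fellow_per_cycle", "p_treated_wse"))
    if (!in01(p_val(fe[[f]])))
      add(viol(paste0("fellow_eye$", f), "in [0,1]", p_val(fe[[f]])))
  wse_pair <- p_val(fe$p_treated_wse)
  wse_sum <- if (length(wse_pair) > 1) sum(wse_pair) else
    wse_pair + p_val(fe$p_treated_bse)
  if (abs(wse_sum - 1) > 1e-8)
    add(viol("fellow_eye", "p_treated_wse + p_treated_bse = 1", wse_sum))

  if (p_val(config$mortality$hr_diabetes) <= 0)
    add(viol("mortality$hr_diabetes", "> 0",
             p_val(config$mortality$hr_diabetes)))
  lt <- config$mortality$life_table
  if (!all(c("age", "sex", "qx") %in% names(lt))) {
    add(viol("mortality$life_table", "columns age, sex, qx", names(lt)))
  } else {
    if (!in01(lt$qx)) add(viol("mortality$life_table$qx", "in [0,1]",
                               range(lt$qx)))
    for (s in c("male", "female"))
      if (!all(0:100 %in% lt$age[lt$sex == s]))
        add(viol("mortality$life_table", paste("ages 0-100 for", s), s))
  }

  for (nm in c("natural_history", "prp_acuity")) {
    if (p_val(config[[nm]]$annual_sd) <= 0)
      add(viol(paste0(nm, "$annual_sd"), "> 0",
               p_val(config[[nm]]$annual_sd)))
  }
  if (config$threshold_letters <= 0)
    add(viol("threshold_letters", "> 0", config$threshold_letters))

  dsc <- config$discontinuation$breakpoints
  if (dsc$fraction[1] != 1 || dsc$year[1] != 0)
    add(viol("discontinuation", "first entry (year 0, fraction 1)",
             paste(dsc$year[1], dsc$fraction[1])))
  if (any(diff(dsc$fraction) > 0))
    add(viol("discontinuation", "fractions non-increasing", dsc$fraction))
  if (!all(dsc$fraction > 0 & dsc$fraction <= 1))
    add(viol("discontinuation", "fractions in (0,1]", dsc$fraction))
  if (is.unsorted(dsc$year, strictly = TRUE))
    add(viol("discontinuation", "years strictly increasing", dsc$year))

  walk_costs <- function(x, path) {
    if (is_param(x) || is.numeric(x)) {
      if (any(p_val(x) < 0)) add(viol(path, ">= 0", p_val(x)))
    } else if (is.list(x)) {
      for (nm in names(x)) walk_costs(x[[nm]], paste0(path, "$", nm))
    }
  }
  walk_costs(config$costs, "costs")

  for (eye in c("bse", "wse")) {
    u <- vapply(config$utilities[[eye]], p_val, numeric(1))
    if (!in01(u))
      add(viol(paste0("utilities$", eye), "in [0,1]", range(u)))
    if (strict && any(diff(u) > 1e-9))
      add(viol(paste0("utilities$", eye),
               "non-increasing with worsening band", u))
  }
  for (ae in names(config$utilities$ae_disutilities)) {
    d <- p_val(config$utilities$ae_disutilities[[ae]])
    if (!in01(d))
      add(viol(paste0("utilities$ae_disutilities$", ae), "in [0,1]", d))
  }

  if (anyDuplicated(vapply(config$strategies, `[[`, "", "name")))
    add(viol("strategies", "unique names",
             vapply(config$strategies, `[[`, "", "name")))
  for (s in config$strategies) {
    if (!s$uses_anti_vegf && !s$uses_prp)
      add(viol(paste0("strategies$", s$name),
               "uses_anti_vegf or uses_prp", "neither"))
  }
  sch <- config$schedules
  for (nm in names(sch))
    if (any(unlist(sch[[nm]]) < 0))
      add(viol(paste0("schedules$", nm), "non-negative", sch[[nm]]))
  for (ae in names(config$ae_profile))
    if (!in01(p_val(config$ae_profile[[ae]])))
      add(viol(paste0("ae_profile$", ae), "in [0,1]",
               p_val(config$ae_profile[[ae]])))
  st <- config$subsequent_treatment
  if (!in01(st$fraction))
    add(viol("subsequent_treatment$fraction", "in [0,1]", st$fraction))
  if (st$cap_cycles < 0)
    add(viol("subsequent_treatment$cap_cycles", ">= 0", st$cap_cycles))

  if (strict) {
    check_mean <- function(x, path) {
      if (is_param(x)) {
        if (x$dist$family != "fixed") {
          m <- distribution_mean(x$dist)
          pe <- x$value
          rel <- abs(m - pe) / pmax(abs(pe), 1e-12)
          rel <- rel[pe != 0]          # structural zeros (dirichlet) exempt
          if (length(rel) && max(rel) > 0.005)
            add(viol(path, "distribution mean within 0.5% of point estimate",
                     max(rel)))
        }
      } else if (is.list(x) && !is.data.frame(x)) {
        for (nm in names(x)) check_mean(x[[nm]], paste0(path, "$", nm))
      }
    }
    check_mean(config, "config")
  }

  if (length(v)) do.call(rbind, v) else
    data.frame(field = character(), rule = character(),
               observed = character(), stringsAsFactors = FALSE)
}

## ---- config serialisation -------------------------------------------------

param_to_list <- function(x) {
  d <- unclass(x$dist)
  list(value = x$value, dist = d, provenance = x$provenance)
}

list_to_param <- function(x, path) {
  if (is.null(x$value))
    stop("schema error: missing required field 'value' at ", path,
         call. = FALSE)
  d <- x$dist
  if (is.null(d)) d <- list(family = "fixed", value = x$value)
  if (!is.numeric(unlist(x$value)))
    stop("parse error at ", path, ": value is not numeric", call. = FALSE)
  dist <- do.call(dist_spec, d)
  param(unlist(x$value), dist,
        if (is.null(x$provenance)) "paper" else x$provenance)
}

config_to_plain <- function(config) {
  walk <- function(x) {
    if (is_param(x)) return(param_to_list(x))
    if (is.data.frame(x)) return(c(list(.df = TRUE), as.list(x)))
    if (is.list(x)) return(lapply(x, walk))
    ## YAML has no named sequences: named numeric vectors become maps with
    ## a marker so their names survive the round trip
    if (is.numeric(x) && !is.null(names(x)))
      return(c(list(.vec = TRUE), as.list(x)))
    x
  }
  walk(config)
}

plain_to_config <- function(x, path = "config") {
  walk <- function(x, path) {
    if (is.list(x)) {
      if (!is.null(x$dist) || (!is.null(x$provenance) && !is.null(x$value)))
        return(list_to_param(x, path))
      if (isTRUE(x$.df)) {
        x$.df <- NULL
        return(as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE))
      }
      if (isTRUE(x$.vec)) {
        x$.vec <- NULL
        return(unlist(x))
      }
      out <- lapply(seq_along(x), function(i)
        walk(x[[i]], paste0(path, "$", names(x)[i])))
      names(out) <- names(x)
      return(out)
    }
    if (is.character(x) || is.logical(x) || is.null(x)) return(x)
    unlist(x)
  }
  cfg <- walk(x, path)
  class(cfg) <- "pdr_config"
  cfg
}

#' Write a model configuration to a YAML file
#'
#' The life table is written alongside the YAML file as tab-delimited text
#' (columns `age`, `sex`, `qx`) and referenced from the YAML by file name, so
#' both artefacts stay plain text and human-diffable.
#'
#' @param config A model configuration.
#' @param path Output YAML file path.
#' @return `path`, invisibly.
#' @seealso [load_config()]
#' @export
save_config <- function(config, path) {
  plain <- config_to_plain(config)
  lt_file <- paste0(sub("\\.ya?ml$", "", basename(path)), "_life_table.tsv")
  write_life_table(config$mortality$life_table,
                   file.path(dirname(path), lt_file))
  plain$mortality$life_table <- NULL
  plain$mortality$life_table_file <- lt_file
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

## Deep merge: user leaves (params, data frames, atomics, strategy lists)
## replace defaults wholesale; plain named lists merge recursively.
merge_config <- function(default, user) {
  if (is.null(user)) return(default)
  if (is_param(user) || is.data.frame(user) || !is.list(user) ||
      is.null(names(user)) || is.null(default) || !is.list(default) ||
      is_param(default) || is.data.frame(default))
    return(user)
  for (nm in names(user))   # [nm] <- list(...) keeps NULL-valued entries
    default[nm] <- list(merge_config(default[[nm]], user[[nm]]))
  default
}

#' Load a model configuration from a YAML file
#'
#' Fields omitted from the file are filled from [default_parameter_set()],
#' so a partial configuration (for example one that only overrides costs)
#' is valid. The loaded configuration must pass [validate_config()].
#'
#' @param path YAML file written by [save_config()] (or hand-written in the
#'   same schema).
#' @return A validated `pdr_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  lt <- NULL
  if (!is.null(raw$mortality$life_table_file)) {
    lt <- read_life_table(file.path(dirname(path),
                                    raw$mortality$life_table_file))
    raw$mortality$life_table_file <- NULL
  }
  user <- plain_to_config(raw)
  cfg <- merge_config(default_parameter_set(), user)
  if (!is.null(lt)) cfg$mortality$life_table <- lt
  class(cfg) <- "pdr_config"
  bad <- validate_config(cfg)
  if (nrow(bad))
    stop("invalid configuration:\n",
         paste0("  ", bad$field, ": ", bad$rule, " (observed ", bad$observed,
                ")", collapse = "\n"), call. = FALSE)
  cfg
}

#' @export
print.pdr_config <- function(x, ...) {
  cat("PDR cost-effectiveness model configuration\n")
  cat("  cohort: start age", x$start_age, "to", x$horizon_age,
      "| male fraction", x$male_fraction, "\n")
  cat("  cycle:", x$cycle_length_years, "years | discount",
      x$discount_rate_annual, "| WTP", x$wtp_threshold, "per QALY\n")
  cat("  strategies:",
      paste(vapply(x$strategies, `[[`, "", "name"), collapse = ", "), "\n")
  cat("  scenario:", x$scenario$effect_trajectory, "\n")
  invisible(x)
}
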