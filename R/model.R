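#' Fit the cost-effectiveness model
#'
#' Runs the deterministic Markov cohort model for every strategy in the
#' configuration under the requested treatment-effect scenario and returns
#' the valued results with the incremental cost-effectiveness frontier.
#'
#' @param config A model configuration (default [default_parameter_set()]).
#' @param scenario Treatment-effect trajectory: `"continued"` (year-1
#'   effects persist for life) or `"stabilised"` (acuity freezes beyond
#'   year 1 for PRP, beyond year 2 for anti-VEGF arms with a linear decline
#'   between years 1 and 2). Defaults to the configuration's setting.
#' @param keep_traces Keep the per-strategy cohort traces in the returned
#'   object (default `TRUE`).
#' @return An object of class `pdr_cea`: list with `results` (per-strategy
#'   data frame of discounted cost, QALYs, life-years and NMB), `frontier`
#'   (a [incremental_frontier()] table), `ce` (the `pdr_ce_result`
#'   objects), `traces`, `config`, `scenario`.
#' @export
#' @examples
#' fit <- pdr_cea(default_parameter_set())
#' fit
pdr_cea <- function(config = default_parameter_set(), scenario = NULL,
                    keep_traces = TRUE) {
  stopifnot(inherits(config, "pdr_config"))
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, c("continued", "stabilised"))
    config$scenario$effect_trajectory <- scenario
  }
  bad <- validate_config(config)
  if (nrow(bad))
    stop("invalid configuration:\n",
         paste0("  ", bad$field, ": ", bad$rule, collapse = "\n"),
         call. = FALSE)

  traces <- lapply(config$strategies, function(s)
    run_trace(config, s, validate = FALSE))
  ce <- Map(function(tr, s) value_trace(tr, s, config),
            traces, config$strategies)
  results <- data.frame(
    strategy = vapply(ce, `[[`, "", "strategy"),
    label = vapply(ce, `[[`, "", "label"),
    cost = vapply(ce, `[[`, 0, "cost"),
    qalys = vapply(ce, `[[`, 0, "qalys"),
    life_years = vapply(ce, `[[`, 0, "life_years"),
    stringsAsFactors = FALSE)
  results$nmb <- nmb(results$cost, results$qalys, config$wtp_threshold)
  front <- incremental_frontier(
    data.frame(name = results$strategy, cost = results$cost,
               qalys = results$qalys, stringsAsFactors = FALSE),
    threshold = config$wtp_threshold)

  structure(list(results = results, frontier = front, ce = ce,
                 traces = if (keep_traces) traces,
                 config = config,
                 scenario = config$scenario$effect_trajectory,
                 call = match.call()),
            class = "pdr_cea")
}

#' @export
print.pdr_cea <- function(x, ...) {
  cat("PDR cost-effectiveness model |", nrow(x$results),
      "strategies | scenario:", x$scenario, "\n\n")
  print(x$frontier)
  invisible(x)
}

#' @export
summary.pdr_cea <- function(object, ...) {
  bk <- t(vapply(object$ce, `[[`, numeric(7), "breakdown"))
  rownames(bk) <- object$results$strategy
  out <- list(results = object$results, frontier = object$frontier,
              cost_breakdown = bk, scenario = object$scenario)
  class(out) <- "summary.pdr_cea"
  out
}

#' @export
print.summary.pdr_cea <- function(x, ...) {
  cat("Scenario:", x$scenario, "\n\n")
  print(x$frontier)
  cat("\nDiscounted cost breakdown per person:\n")
  print(round(x$cost_breakdown, 2))
  invisible(x)
}

#' @export
coef.pdr_cea <- function(object, ...) {
  setNames(object$results$nmb, object$results$strategy)
}

#' Cost-effectiveness plane
#'
#' Plots each strategy's discounted cost against QALYs and draws the
#' efficiency frontier through the undominated strategies.
#'
#' @param x A [pdr_cea()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pdr_cea <- function(x, ...) {
  r <- x$results
  f <- x$frontier
  on_f <- f$label %in% c("reference", "on-frontier")
  plot(r$qalys, r$cost, pch = 19,
       xlab = "Discounted QALYs per person",
       ylab = "Discounted cost per person",
       main = paste("Cost-effectiveness plane -", x$scenario, "effects"),
       ...)
  lines(f$qalys[on_f], f$cost[on_f], lty = 2)
  points(f$qalys[on_f], f$cost[on_f], pch = 19, cex = 1.3)
  text(r$qalys, r$cost, r$strategy, pos = 3, cex = 0.7)
  invisible(x)
}

#' Simulate probabilistic draws from a fitted model
#'
#' Each simulation samples one parameter set from the configured
#' distributions and re-runs the full pipeline, returning per-draw costs
#' and QALYs per strategy (the raw material of a probabilistic sensitivity
#' analysis; see [run_psa()] for the summarised form).
#'
#' @param object A [pdr_cea()] fit.
#' @param nsim Number of draws.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return Data frame with columns `draw`, `strategy`, `cost`, `qalys`,
#'   `nmb`.
#' @export
simulate.pdr_cea <- function(object, nsim = 100, seed = 1, ...) {
  psa <- run_psa(object$config, n_draws = nsim, seed = seed)
  psa$draws
}

#' Deterministic one-way scenario battery
#'
#' Runs the six one-way analyses (treatment in a separate visit to
#' monitoring; 25% and 75% continuation after year 5; natural-history onset
#' at 20, 10 and 5 years) under both treatment-effect trajectory scenarios
#' — twelve runs — and summarises the top three strategies by NMB for each.
#'
#' @param config A model configuration.
#' @param psa_draws If > 0, rank by probabilistic mean NMB from this many
#'   draws per run instead of the deterministic NMB.
#' @param seed RNG seed (used only when `psa_draws > 0`).
#' @return An object of class `pdr_dsa`: list with `summary` (one row per
#'   run: scenario, analysis, best/2nd/3rd strategies and their NMBs) and
#'   `runs` (the fitted objects).
#' @export
dsa_battery <- function(config = default_parameter_set(), psa_draws = 0,
                        seed = 1) {
  analyses <- list(
    "Treatment occurs in a separate visit to monitoring" =
      function(cfg) { cfg$scenario$treatment_separate_visit <- TRUE; cfg },
    "25% of patients continue to receive treatment after 5 years" =
      function(cfg) { cfg$scenario$post5y_continuation_override <- 0.25; cfg },
    "75% of patients continue to receive treatment after 5 years" =
      function(cfg) { cfg$scenario$post5y_continuation_override <- 0.75; cfg },
    "Natural history of PDR starts from 20 years" =
      function(cfg) { cfg$scenario$natural_history_onset_years <- 20; cfg },
    "Natural history of PDR starts from 10 years" =
      function(cfg) { cfg$scenario$natural_history_onset_years <- 10; cfg },
    "Natural history of PDR starts from 5 years" =
      function(cfg) { cfg$scenario$natural_history_onset_years <- 5; cfg })

  rows <- list(); runs <- list()
  for (sc in c("continued", "stabilised")) {
    for (nm in names(analyses)) {
      cfg <- analyses[[nm]](config)
      cfg$scenario$effect_trajectory <- sc
      if (psa_draws > 0) {
        psa <- run_psa(cfg, n_draws = psa_draws, seed = seed)
        rk <- rank_by_nmb(data.frame(name = psa$summary$strategy,
                                     cost = psa$summary$mean_cost,
                                     qalys = psa$summary$mean_qalys,
                                     stringsAsFactors = FALSE),
                          cfg$wtp_threshold)
        runs[[paste(sc, nm)]] <- psa
      } else {
        fit <- pdr_cea(cfg, keep_traces = FALSE)
        rk <- rank_by_nmb(data.frame(name = fit$results$strategy,
                                     cost = fit$results$cost,
                                     qalys = fit$results$qalys,
                                     stringsAsFactors = FALSE),
                          cfg$wtp_threshold)
        runs[[paste(sc, nm)]] <- fit
      }
      rows[[paste(sc, nm)]] <- data.frame(
        scenario = sc, analysis = nm,
        best = rk$name[1], best_nmb = rk$nmb[1],
        second = rk$name[2], second_nmb = rk$nmb[2],
        third = rk$name[3], third_nmb = rk$nmb[3],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, rows), runs = runs),
            class = "pdr_dsa")
}

#' @export
print.pdr_dsa <- function(x, ...) {
  s <- x$summary
  out <- data.frame(scenario = s$scenario, analysis = s$analysis,
                    best = sprintf("%s (%.0f)", s$best, s$best_nmb),
                    second = sprintf("%s (%.0f)", s$second, s$second_nmb),
                    third = sprintf("%s (%.0f)", s$third, s$third_nmb))
  print(out, row.names = FALSE, right = FALSE)
  invisible(x)
}
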