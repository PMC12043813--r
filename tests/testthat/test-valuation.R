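test_that("discount factors follow the 3.5% annual convention", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(4, 0.035), 1 / 1.035)
  expect_equal(discount_factor(0:40, 0), rep(1, 41))
  expect_equal(discount_factor(0, 0.035, half_cycle = TRUE),
               1.035^-0.125)
})

test_that("the weighted administration cost reproduces the published value", {
  expect_equal(admin_cost_per_visit(default_cfg$costs), 257.981,
               tolerance = 1e-6)

  costs0 <- default_cfg$costs
  for (nm in names(costs0$admin_components))
    costs0$admin_components[[nm]] <- param(0)
  expect_equal(admin_cost_per_visit(costs0), 0)

  costs1 <- default_cfg$costs
  costs1$admin_weights <- c(oct = 1, outpatient = 1, day_case = 0)
  expect_equal(admin_cost_per_visit(costs1), 231.420)
})

test_that("worst-seeing-eye utilities interpolate linearly to the published values", {
  v <- wse_utility_vector(0.839, 0.1)
  expect_equal(unname(round(v, 3)),
               c(0.839, 0.839, 0.822, 0.806, 0.789, 0.772, 0.756, 0.739))
  expect_equal(v[["46-55"]], 0.789, tolerance = 5e-4)
  expect_equal(v[["<=25"]], 0.739)
  expect_equal(unname(wse_utility_vector(0.7, 0)), rep(0.7, 8))
})

test_that("per-cycle QALYs weight occupancy by the eye-mix utilities", {
  cfg <- default_cfg
  dead <- c(rep(0, 8), 1)
  expect_equal(cycle_qaly(dead, 0.22, cfg), 0)

  # everyone in the best band, all treated in both eyes: BSE utility applies
  best <- c(1, rep(0, 8))
  expect_equal(cycle_qaly(best, 1, cfg) * 4, 0.839)

  # hand-computed three-band example
  occ <- c(0, 0.5, 0.3, 0, 0, 0, 0, 0, 0.2)
  fb <- 0.25
  u_bse <- vapply(cfg$utilities$bse, p_val, numeric(1))
  u_wse <- vapply(cfg$utilities$wse, p_val, numeric(1))
  u <- fb * u_bse + (1 - fb) * (0.328 * u_bse + 0.672 * u_wse)
  expect_equal(cycle_qaly(occ, fb, cfg),
               unname(0.5 * u[2] + 0.3 * u[3]) * 0.25)
})

test_that("per-cycle costs decompose as published unit costs times use", {
  cfg <- default_cfg
  dead <- c(rep(0, 8), 1)
  expect_equal(sum(cycle_cost(dead, 1, 0.22, "prp", cfg)), 0)

  # everyone alive in the worst band, nobody on treatment: low vision only
  worst <- c(rep(0, 7), 1, 0)
  cc <- cycle_cost(worst, 0, 0, "prp", cfg)
  expect_equal(cc[["low_vision"]], 421.609)
  expect_equal(sum(cc) - cc[["low_vision"]] - cc[["monitoring"]], 0)

  # one bevacizumab dose, one eye, everything else zeroed
  cfg1 <- cfg
  cfg1$schedules$injections_per_year <- 4          # one dose per cycle
  cfg1$schedules$monitoring_on_treatment_per_year <- 0
  cfg1$schedules$monitoring_post_treatment_per_year <- 0
  for (nm in names(cfg1$costs$admin_components))
    cfg1$costs$admin_components[[nm]] <- param(0)
  cfg1$ae_profile <- list()
  alive_best <- c(1, rep(0, 8))
  cc1 <- cycle_cost(alive_best, 1, 0, "bevacizumab", cfg1)
  expect_equal(cc1[["drug"]], 50.00)
  expect_equal(sum(cc1), 50.00)

  # drug cost doubles for the both-eye fraction; administration does not
  cc2 <- cycle_cost(alive_best, 1, 1, "bevacizumab", cfg)
  cc3 <- cycle_cost(alive_best, 1, 0, "bevacizumab", cfg)
  expect_equal(cc2[["drug"]], 2 * cc3[["drug"]])
  expect_equal(cc2[["administration"]], cc3[["administration"]])
})

test_that("valuing a trace sums discounted flows with half-cycle correction", {
  # zero-cost, zero-utility configuration values to (0, 0)
  cfg <- immortal_config()
  zero_costs <- function(x) {
    if (inherits(x, "pdr_param")) return(param(0))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, zero_costs))
    if (is.numeric(x)) return(x * 0)
    x
  }
  cfg$costs <- zero_costs(cfg$costs)
  cfg$costs$admin_weights <- default_cfg$costs$admin_weights
  for (eye in c("bse", "wse"))
    for (nm in names(cfg$utilities[[eye]]))
      cfg$utilities[[eye]][[nm]] <- param(0)
  cfg$utilities$ae_disutilities <- lapply(cfg$utilities$ae_disutilities,
                                          function(...) param(0))
  tr <- run_trace(cfg, cfg$strategies[[1]], validate = FALSE)
  ce <- value_trace(tr, cfg$strategies[[1]], cfg)
  expect_equal(ce$cost, 0)
  expect_equal(ce$qalys, 0)

  # utilities one, immortal cohort, no discounting, 10-year horizon: 10 QALYs
  cfg2 <- immortal_config(horizon_age = 66)
  cfg2$discount_rate_annual <- 0
  for (eye in c("bse", "wse"))
    for (nm in names(cfg2$utilities[[eye]]))
      cfg2$utilities[[eye]][[nm]] <- param(1)
  cfg2$ae_profile <- list()
  tr2 <- run_trace(cfg2, cfg2$strategies[[1]], validate = FALSE)
  ce2 <- value_trace(tr2, cfg2$strategies[[1]], cfg2)
  expect_equal(ce2$qalys, 10, tolerance = 1e-10)

  # constant annual flow against a closed-form annuity oracle: freeze the
  # acuity dynamics so the whole cohort stays in the worst band
  cfg3 <- immortal_config(horizon_age = 76)
  cfg3$prp_acuity$annual_mean <- param(0)
  cfg3$prp_acuity$annual_sd <- param(0.1)
  cfg3$baseline_band_distribution <- param(c(rep(0, 7), 1))
  cfg3$schedules$monitoring_post_treatment_per_year <- 0
  cfg3$subsequent_treatment$fraction <- 0
  tr3 <- run_trace(cfg3, cfg3$strategies[[1]], validate = FALSE)
  ce3 <- value_trace(tr3, cfg3$strategies[[1]], cfg3)
  C <- 4 * p_val(cfg3$costs$low_vision_per_cycle)
  annuity <- C * sum(1.035^-(0:19 + 0.5))
  expect_equal(ce3$breakdown[["low_vision"]], annuity,
               tolerance = 0.005)
})

test_that("cost and QALY totals are monotone in unit costs and utilities", {
  base <- pdr_cea(default_cfg, keep_traces = FALSE)
  i_bev <- match("bevacizumab", base$results$strategy)

  up <- default_cfg
  up$costs$drug$bevacizumab <- param(60, provenance = "paper")
  fit_up <- pdr_cea(up, keep_traces = FALSE)
  expect_gt(fit_up$results$cost[i_bev], base$results$cost[i_bev])
  expect_equal(fit_up$results$qalys[i_bev], base$results$qalys[i_bev])

  uu <- default_cfg
  uu$utilities$wse[["<=25"]] <- param(0.749,
    dist_spec("beta", alpha = 74.9, beta = 25.1))
  fit_uu <- pdr_cea(uu, keep_traces = FALSE)
  expect_gt(fit_uu$results$qalys[i_bev], base$results$qalys[i_bev])

  # removing discounting can only increase totals
  nod <- default_cfg
  nod$discount_rate_annual <- 0
  fit_nod <- pdr_cea(nod, keep_traces = FALSE)
  expect_true(all(fit_nod$results$cost >= base$results$cost))
  expect_true(all(fit_nod$results$qalys >= base$results$qalys))
})

test_that("valuation results are internally consistent", {
  fit <- pdr_cea(default_cfg)
  for (i in seq_along(fit$ce)) {
    ce <- fit$ce[[i]]
    expect_equal(ce$cost, sum(ce$breakdown), tolerance = 1e-6)
    expect_true(all(ce$breakdown >= 0))
    u_max <- max(vapply(default_cfg$utilities$bse, p_val, numeric(1)))
    expect_lte(ce$qalys, ce$life_years * u_max)
  }
})
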