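rdirichlet1 <- function(concentration) {
  g <- numeric(length(concentration))
  pos <- concentration > 0
  g[pos] <- rgamma(sum(pos), shape = concentration[pos])
  g / sum(g)          # structural zeros stay exactly zero
}

draw_dist <- function(spec) {
  switch(spec$family,
    fixed = spec$value,
    beta = rbeta(1, spec$alpha, spec$beta),
    gamma = rgamma(1, shape = spec$shape, scale = spec$scale),
    normal = rnorm(1, spec$mean, spec$sd),
    lognormal = rlnorm(1, spec$mu, spec$sigma),
    dirichlet = rdirichlet1(spec$concentration),
    stop("unknown distribution family: ", spec$family, call. = FALSE))
}

#' Draw one probabilistic parameter set
#'
#' Every parameter carrying a non-fixed distribution is replaced by one
#' draw from it; fixed parameters are unchanged. Draws are independent
#' across parameters (no correlations are modelled). Dirichlet draws
#' already sum to one, so the sampled baseline band distribution needs no
#' renormalisation and structurally-zero bands remain zero. Draws are
#' reproducible given the RNG state.
#'
#' @param config A model configuration.
#' @return A `pdr_config` with sampled values.
#' @export
sample_parameters <- function(config) {
  walk <- function(x) {
    if (is_param(x)) {
      if (x$dist$family != "fixed") x$value <- draw_dist(x$dist)
      return(x)
    }
    if (is.list(x) && !is.data.frame(x)) {
      cl <- class(x)
      x <- lapply(x, walk)
      class(x) <- cl
      return(x)
    }
    x
  }
  cfg <- walk(config)
  ## keep the scalar BSE share consistent with the sampled (WSE, BSE) pair
  pair <- p_val(cfg$fellow_eye$p_treated_wse)
  if (length(pair) > 1) cfg$fellow_eye$p_treated_bse$value <- pair[2]
  cfg
}

## One full deterministic evaluation of every strategy under a given
## (possibly sampled) configuration.
evaluate_strategies <- function(config, validate = FALSE) {
  res <- lapply(config$strategies, function(s) {
    tr <- run_trace(config, s, validate = validate)
    value_trace(tr, s, config)
  })
  data.frame(strategy = vapply(res, `[[`, "", "strategy"),
             cost = vapply(res, `[[`, 0, "cost"),
             qalys = vapply(res, `[[`, 0, "qalys"),
             stringsAsFactors = FALSE)
}

#' Probabilistic sensitivity analysis
#'
#' Samples `n_draws` parameter sets from the configured distributions, runs
#' the full deterministic pipeline per draw and strategy, and summarises:
#' per-strategy mean cost, mean QALYs, mean NMB and a percentile NMB
#' interval, plus the incremental frontier computed on the mean costs and
#' QALYs (the standard convention for reporting probabilistic totals).
#'
#' Draws failing structural validation are rejected and counted; more than
#' 1% rejections aborts the run.
#'
#' @param config A model configuration.
#' @param n_draws Number of draws (>= 1).
#' @param seed RNG seed for reproducibility.
#' @param ci Percentile interval coverage (default 0.95).
#' @return An object of class `pdr_psa`: list with `summary` (per-strategy
#'   data frame), `frontier`, `draws` (per-draw results), `n_draws`,
#'   `n_rejected`, `seed`.
#' @export
run_psa <- function(config, n_draws = 5000, seed = 1, ci = 0.95) {
  stopifnot(n_draws >= 1)
  set.seed(seed)
  draws <- vector("list", n_draws)
  n_rejected <- 0L
  for (i in seq_len(n_draws)) {
    repeat {
      cfg_i <- sample_parameters(config)
      bad <- validate_config(cfg_i, strict = FALSE)
      if (!nrow(bad)) break
      n_rejected <- n_rejected + 1L
      if (n_rejected > max(1, 0.01 * n_draws))
        stop("more than 1% of PSA draws rejected by validation; ",
             "first failing rule: ", bad$field[1], " (", bad$rule[1], ")",
             call. = FALSE)
    }
    d <- evaluate_strategies(cfg_i)
    d$draw <- i
    draws[[i]] <- d
  }
  draws <- do.call(rbind, draws)
  draws$nmb <- nmb(draws$cost, draws$qalys, config$wtp_threshold)

  strat <- vapply(config$strategies, `[[`, "", "name")
  alpha <- (1 - ci) / 2
  summ <- do.call(rbind, lapply(strat, function(s) {
    d <- draws[draws$strategy == s, ]
    data.frame(strategy = s,
               mean_cost = mean(d$cost), mean_qalys = mean(d$qalys),
               mean_nmb = mean(d$nmb),
               nmb_lo = unname(quantile(d$nmb, alpha)),
               nmb_hi = unname(quantile(d$nmb, 1 - alpha)),
               stringsAsFactors = FALSE)
  }))
  front <- incremental_frontier(
    data.frame(name = summ$strategy, cost = summ$mean_cost,
               qalys = summ$mean_qalys, stringsAsFactors = FALSE),
    threshold = config$wtp_threshold)

  structure(list(summary = summ, frontier = front, draws = draws,
                 n_draws = n_draws, n_rejected = n_rejected, seed = seed,
                 ci = ci, wtp_threshold = config$wtp_threshold),
            class = "pdr_psa")
}

#' @export
print.pdr_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_draws, "draws (seed",
      x$seed, ",", x$n_rejected, "rejected)\n")
  s <- x$summary
  f <- x$frontier
  lab <- f$label[match(s$strategy, f$name)]
  ic <- f$icer[match(s$strategy, f$name)]
  out <- data.frame(strategy = s$strategy,
                    cost = sprintf("%.0f", s$mean_cost),
                    QALYs = sprintf("%.3f", s$mean_qalys),
                    `ICER/label` = ifelse(is.na(ic), lab,
                                          sprintf("%.0f", ic)),
                    NMB = sprintf("%.0f [%.0f-%.0f]", s$mean_nmb, s$nmb_lo,
                                  s$nmb_hi),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.pdr_psa <- function(object, ...) object$summary
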