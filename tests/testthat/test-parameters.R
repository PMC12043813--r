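test_that("distribution means match the published point estimates", {
  expect_equal(distribution_mean(dist_spec("beta", alpha = 7.900,
                                           beta = 138.397)),
               0.0540, tolerance = 1e-3)
  expect_equal(distribution_mean(dist_spec("beta", alpha = 75.900,
                                           beta = 269.100)),
               0.220, tolerance = 1e-6)
  expect_equal(distribution_mean(dist_spec("gamma", shape = 96.036,
                                           scale = 8.497)),
               816.02, tolerance = 1e-4)
  expect_equal(distribution_mean(dist_spec("lognormal", mu = 0.668,
                                           sigma = 0.090)),
               1.9503, tolerance = 1e-4)
  expect_equal(distribution_mean(dist_spec("normal", mean = -0.088,
                                           sd = 0.07)), -0.088)
  expect_equal(distribution_mean(dist_spec("dirichlet",
                                           concentration = c(3, 1))),
               c(0.75, 0.25))
})

test_that("invalid distribution parameters are rejected", {
  expect_error(dist_spec("beta", alpha = -1, beta = 2), "alpha")
  expect_error(dist_spec("gamma", shape = 0, scale = 1), "shape")
  expect_error(dist_spec("weibull", shape = 1))
})

test_that("every sampled parameter's distribution mean agrees with its point estimate within 0.5%", {
  check <- function(x, path) {
    if (inherits(x, "pdr_param")) {
      if (x$dist$family != "fixed") {
        m <- distribution_mean(x$dist)
        pe <- x$value
        keep <- pe != 0
        if (any(keep))
          expect_lt(max(abs(m[keep] - pe[keep]) / abs(pe[keep])), 0.005,
                    label = paste("relative mean error at", path))
      }
    } else if (is.list(x) && !is.data.frame(x)) {
      for (nm in names(x)) check(x[[nm]], paste0(path, "$", nm))
    }
  }
  check(default_cfg, "config")
})

test_that("gamma cost distributions follow the +/-20% coefficient-of-variation convention", {
  shapes <- c()
  walk <- function(x) {
    if (inherits(x, "pdr_param")) {
      if (x$dist$family == "gamma") shapes <<- c(shapes, x$dist$shape)
    } else if (is.list(x) && !is.data.frame(x)) lapply(x, walk)
  }
  walk(default_cfg$costs)
  # the low-vision cost carries source-reported dispersion, not +/-20%
  pm20 <- shapes[abs(shapes - 96.036) < 1]
  expect_gte(length(pm20), 10)
  expect_true(all(abs(pm20 - (1.96 / 0.2)^2) < 0.1))
})

test_that("validation reports violations as data and accepts the defaults", {
  expect_identical(nrow(validate_config(default_cfg)), 0L)

  bad <- default_cfg
  bad$utilities$bse[["66-75"]] <- param(1.2)
  v <- validate_config(bad)
  expect_true(any(grepl("utilities\\$bse", v$field) &
                  grepl("\\[0,1\\]", v$rule)))

  bad2 <- default_cfg
  bad2$baseline_band_distribution <- param(c(0, 0.1, 0.3, 0.2, 0.15,
                                             0.15, 0, 0))
  expect_true(any(grepl("sums to 1",
                        validate_config(bad2)$rule)))
})

test_that("utility monotonicity is a strict-only rule (PSA draws exempt)", {
  cfg <- default_cfg
  cfg$utilities$bse[["76-85"]] <- param(0.70)   # out of order
  expect_true(any(grepl("non-increasing", validate_config(cfg)$rule)))
  expect_false(any(grepl("non-increasing",
                         validate_config(cfg, strict = FALSE)$rule)))
})

test_that("configuration round-trips through YAML idempotently", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "cfg.yaml")
  save_config(default_cfg, p1)
  cfg2 <- load_config(p1)
  expect_equal(cfg2, default_cfg, tolerance = 1e-12)

  dir2 <- withr::local_tempdir()
  p2 <- file.path(dir2, "cfg.yaml")
  save_config(cfg2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(nrow(validate_config(cfg2)), 0L)
})

test_that("partial configurations are completed from defaults", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "partial.yaml")
  writeLines(c("start_age: 60.0", "male_fraction: 0.5"), p)
  cfg <- load_config(p)
  expect_equal(cfg$start_age, 60)
  expect_equal(cfg$male_fraction, 0.5)
  expect_equal(cfg$wtp_threshold, 20000)
  expect_equal(cfg$discount_rate_annual, 0.035)
})

test_that("invalid configuration files fail with a named field", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.yaml")
  writeLines(c("baseline_band_distribution:",
               "  value: [0.0, 0.1, 0.3, 0.2, 0.15, 0.15, 0.0, 0.0]",
               "  provenance: paper"), p)
  expect_error(load_config(p), "baseline_band_distribution")
  expect_error(load_config(file.path(dir, "nope.yaml")), "not found")
})
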