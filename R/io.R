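write_manifest <- function(dir, config_path, scenario, seed, n_draws) {
  manifest <- list(config = config_path %||% "default_parameter_set()",
                   scenario = scenario, seed = seed, n_draws = n_draws,
                   package_version =
                     as.character(packageVersion("pdrcea")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the deterministic analysis and write its outputs
#'
#' Writes, per strategy, the cohort trace as tab-delimited text, plus the
#' results table, the frontier table and a run manifest recording the
#' inputs needed to reproduce the run.
#'
#' @param config_path Path to a YAML configuration ([load_config()]), or
#'   `NULL` for [default_parameter_set()].
#' @param scenario `"continued"` or `"stabilised"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Recorded in the manifest (the deterministic run uses no
#'   randomness).
#' @return The fitted [pdr_cea()] object, invisibly.
#' @export
run_analysis <- function(config_path = NULL, scenario = "continued",
                         out_dir = "pdrcea_out", seed = 1) {
  config <- if (is.null(config_path)) default_parameter_set() else
    load_config(config_path)
  fit <- pdr_cea(config, scenario = scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fit$traces))
    write.table(as.data.frame(fit$traces[[i]]),
                file.path(out_dir, paste0("trace_",
                                          fit$results$strategy[i], ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fit$results, file.path(out_dir, "results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(fit$frontier),
              file.path(out_dir, "frontier.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, config_path, scenario, seed, 0)
  invisible(fit)
}

#' Run the probabilistic analysis and write its outputs
#'
#' @inheritParams run_analysis
#' @param n_draws Number of PSA draws.
#' @param stream_draws Also write the per-draw results (default `TRUE`).
#' @return The [run_psa()] object, invisibly.
#' @export
run_psa_analysis <- function(config_path = NULL, scenario = "continued",
                             out_dir = "pdrcea_out", n_draws = 5000,
                             seed = 1, stream_draws = TRUE) {
  config <- if (is.null(config_path)) default_parameter_set() else
    load_config(config_path)
  config$scenario$effect_trajectory <-
    match.arg(scenario, c("continued", "stabilised"))
  psa <- run_psa(config, n_draws = n_draws, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(psa$summary, file.path(out_dir, "psa_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(psa$frontier),
              file.path(out_dir, "psa_frontier.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (stream_draws)
    write.table(psa$draws, file.path(out_dir, "psa_draws.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, config_path, scenario, seed, n_draws)
  invisible(psa)
}

#' Run the deterministic scenario battery and write its summary
#'
#' @inheritParams run_psa_analysis
#' @param psa_draws Draws per battery run (0 = deterministic ranking).
#' @return The [dsa_battery()] object, invisibly.
#' @export
run_dsa_battery <- function(config_path = NULL, out_dir = "pdrcea_out",
                            psa_draws = 0, seed = 1) {
  config <- if (is.null(config_path)) default_parameter_set() else
    load_config(config_path)
  dsa <- dsa_battery(config, psa_draws = psa_draws, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(dsa$summary, file.path(out_dir, "dsa_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, config_path, "battery", seed, psa_draws)
  invisible(dsa)
}
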