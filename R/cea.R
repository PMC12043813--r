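#' Net monetary benefit
#'
#' `qalys * threshold - cost`: the strategy with the maximum NMB at a given
#' willingness-to-pay threshold is the most cost-effective.
#'
#' @param cost Total cost per person (vectorised).
#' @param qalys Total QALYs per person.
#' @param threshold Willingness-to-pay threshold (currency per QALY).
#' @return Net monetary benefit.
#' @export
#' @examples
#' nmb(15926, 11.865, 20000)
nmb <- function(cost, qalys, threshold) {
  qalys * threshold - cost
}

#' Fully incremental cost-effectiveness frontier
#'
#' Sorts strategies by cost, removes strictly dominated strategies (another
#' strategy costs no more and yields at least as many QALYs, one strictly),
#' then iteratively removes extendedly dominated strategies (those whose
#' ICER against the previous frontier point exceeds the next ICER along the
#' chain — a mix of their neighbours would beat them), and reports ICERs
#' along the remaining chain. The cheapest strategy is the reference.
#'
#' Equal-cost strategies are compared as one group: only the highest-QALY
#' one can reach the frontier. Strategies with identical cost and QALYs are
#' both retained and flagged.
#'
#' @param results Data frame with columns `name`, `cost`, `qalys` (extra
#'   columns are carried through), or a list of `pdr_ce_result` objects.
#' @param threshold Willingness-to-pay threshold used for the NMB column
#'   (default 20000).
#' @return A `pdr_frontier` data frame: `name`, `cost`, `qalys`, `label`
#'   (`"reference"`, `"on-frontier"`, `"dominated"`,
#'   `"extendedly dominated"`, `"tied"`), `icer` (versus the previous
#'   frontier strategy; `NA` off-frontier and for the reference), `nmb`.
#' @export
incremental_frontier <- function(results, threshold = 20000) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, TRUE, "pdr_ce_result")))
    results <- data.frame(
      name = vapply(results, `[[`, "", "strategy"),
      cost = vapply(results, `[[`, 0, "cost"),
      qalys = vapply(results, `[[`, 0, "qalys"),
      stringsAsFactors = FALSE)
  stopifnot(nrow(results) >= 1, all(c("name", "cost", "qalys") %in%
                                      names(results)))
  if (anyDuplicated(results$name))
    stop("duplicate strategy names", call. = FALSE)

  d <- results[order(results$cost, -results$qalys), , drop = FALSE]
  n <- nrow(d)
  label <- rep("on-frontier", n)

  ## strict dominance (and equal-cost grouping; exact ties flagged)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (d$cost[j] <= d$cost[i] && d$qalys[j] >= d$qalys[i] &&
          (d$cost[j] < d$cost[i] || d$qalys[j] > d$qalys[i])) {
        label[i] <- "dominated"
        break
      }
      if (d$cost[j] == d$cost[i] && d$qalys[j] == d$qalys[i] && j < i)
        label[i] <- "tied"
    }
  }

  ## extended dominance: non-increasing ICERs along the cost-ordered chain
  repeat {
    idx <- which(label %in% c("on-frontier"))
    if (length(idx) < 3L) break
    icers <- diff(d$cost[idx]) / diff(d$qalys[idx])
    bad <- which(diff(icers) <= 0)
    if (!length(bad)) break
    label[idx[bad[1L] + 1L]] <- "extendedly dominated"
  }

  idx <- which(label == "on-frontier")
  icer <- rep(NA_real_, n)
  if (length(idx) >= 2L)
    icer[idx[-1L]] <- diff(d$cost[idx]) / diff(d$qalys[idx])
  label[idx[1L]] <- "reference"

  d$label <- label
  d$icer <- icer
  d$nmb <- nmb(d$cost, d$qalys, threshold)
  rownames(d) <- NULL
  class(d) <- c("pdr_frontier", "data.frame")
  attr(d, "threshold") <- threshold
  d
}

#' @export
print.pdr_frontier <- function(x, digits = 4, ...) {
  out <- data.frame(strategy = x$name,
                    cost = sprintf("%.0f", x$cost),
                    QALYs = sprintf("%.3f", x$qalys),
                    `ICER/label` = ifelse(is.na(x$icer), x$label,
                                          sprintf("%.0f", x$icer)),
                    NMB = sprintf("%.0f", x$nmb),
                    check.names = FALSE)
  cat("Incremental cost-effectiveness frontier (WTP",
      attr(x, "threshold"), "per QALY)\n")
  print(out, row.names = FALSE)
  invisible(x)
}

#' Rank strategies by net monetary benefit
#'
#' @inheritParams incremental_frontier
#' @param threshold Willingness-to-pay threshold (currency per QALY).
#' @return The input data frame ordered by descending NMB (stable for
#'   ties), with an `nmb` column.
#' @export
rank_by_nmb <- function(results, threshold) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, TRUE, "pdr_ce_result")))
    results <- data.frame(
      name = vapply(results, `[[`, "", "strategy"),
      cost = vapply(results, `[[`, 0, "cost"),
      qalys = vapply(results, `[[`, 0, "qalys"),
      stringsAsFactors = FALSE)
  results$nmb <- nmb(results$cost, results$qalys, threshold)
  results[order(-results$nmb), , drop = FALSE]
}
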