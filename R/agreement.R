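# Agreement statistics between predicted and true compositions: mean
# absolute percentage error (MAPE), Bland-Altman analysis with limits of
# agreement (LoA = mean difference +/- 1.96 x SD of the differences), and
# cumulative difference tables. Differences are always prediction - truth.

#' Agreement statistics container
#'
#' @param mean_difference Mean of (predicted - truth).
#' @param sd_difference Sample SD (n - 1 denominator) of the differences.
#' @param mape_percent Mean absolute percentage error, in percent.
#' @param n Number of paired observations.
#' @return A list of class `agreement_stats` with the LoA bounds filled in
#'   as `mean_difference +/- 1.96 * sd_difference`.
#' @export
agreement_stats <- function(mean_difference, sd_difference, mape_percent, n) {
  stopifnot(sd_difference >= 0, mape_percent >= 0, n >= 1)
  out <- list(mean_difference = mean_difference,
              sd_difference = sd_difference,
              loa_lower = mean_difference - 1.96 * sd_difference,
              loa_upper = mean_difference + 1.96 * sd_difference,
              mape_percent = mape_percent, n = as.integer(n))
  stopifnot(out$loa_lower <= out$loa_upper)
  class(out) <- "agreement_stats"
  out
}

#' Mean absolute percentage error
#'
#' `mean(|predicted - truth| / truth) * 100` over entries with nonzero
#' truth; zero-truth entries are excluded with a message reporting the
#' count (a relative error against a zero truth is undefined).
#'
#' @param predicted,truth Equal-length numeric vectors.
#' @return MAPE in percent.
#' @export
mape <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) >= 1L)
  zero <- truth == 0
  if (all(zero)) stop("all truth entries are zero: MAPE undefined", call. = FALSE)
  if (any(zero)) message(sum(zero), " zero-truth entr(ies) excluded from MAPE")
  mean(abs(predicted[!zero] - truth[!zero]) / truth[!zero]) * 100
}

#' Bland-Altman agreement analysis
#'
#' Computes per-point differences (predicted - truth) and averages
#' ((predicted + truth)/2), and summarizes them as mean difference, sample
#' SD, and the 95% limits of agreement.
#'
#' @param predicted,truth Equal-length numeric vectors, n >= 2.
#' @return List: `stats` (an [agreement_stats()]) and `points` (data.frame
#'   `average`, `difference`, plot-ready).
#' @export
bland_altman <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (length(truth) < 2L) stop("need n >= 2 (SD undefined)", call. = FALSE)
  d <- predicted - truth
  a <- (predicted + truth) / 2
  mp <- if (any(truth != 0)) suppressMessages(mape(predicted, truth)) else 0
  list(stats = agreement_stats(mean(d), sd(d), mp, length(d)),
       points = data.frame(average = a, difference = d))
}

#' Cumulative table of absolute prediction-truth differences
#'
#' For each bin edge, the percentage of observations whose absolute
#' difference is at or below the edge; a final open bin (`Inf`) covers the
#' remainder, so the table always ends at 100%.
#'
#' @param predicted,truth Equal-length numeric vectors.
#' @param bin_edges Ascending positive edges (default
#'   `c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5)`).
#' @return data.frame `edge`, `cumulative_percent` (non-decreasing).
#' @export
cumulative_difference_table <- function(predicted, truth,
                                        bin_edges = c(0.01, 0.02, 0.05,
                                                      0.1, 0.2, 0.5)) {
  stopifnot(length(predicted) == length(truth), length(truth) >= 1L,
            !is.unsorted(bin_edges, strictly = TRUE))
  ad <- abs(predicted - truth)
  pct <- vapply(bin_edges, function(e) 100 * mean(ad <= e), numeric(1))
  data.frame(edge = c(bin_edges, Inf), cumulative_percent = c(pct, 100))
}

#' Agreement report over a benchmark ledger
#'
#' Groups a prediction/truth ledger (as produced by
#' [run_mixture_benchmark()]) either by cell type (one Bland-Altman
#' analysis per type, across runs) or by sample (one per run x tissue
#' fraction, across its cell types), and returns one row of agreement
#' statistics per group plus the plot-ready long tables. Groups with fewer
#' than 2 observations are skipped with a warning.
#'
#' @param ledger data.frame with columns `cell_type`, `truth`, `predicted`
#'   and — for `group_by = "sample"` — `run` (and optionally
#'   `tissue_fraction`).
#' @param group_by `"cell_type"` or `"sample"`.
#' @return List: `stats` (data.frame, one row per group: `group`, `n`,
#'   `mean_difference`, `sd_difference`, `loa_lower`, `loa_upper`,
#'   `mape_percent`), `ba_points` (long data.frame `group`, `average`,
#'   `difference`).
#' @export
agreement_report <- function(ledger, group_by = c("cell_type", "sample")) {
  group_by <- match.arg(group_by)
  stopifnot(is.data.frame(ledger), nrow(ledger) >= 1L)
  key <- if (group_by == "cell_type") {
    ledger$cell_type
  } else {
    if (is.null(ledger$run)) stop("ledger lacks a 'run' column", call. = FALSE)
    if (!is.null(ledger$tissue_fraction))
      paste0("run", ledger$run, "_tf", ledger$tissue_fraction)
    else paste0("run", ledger$run)
  }
  groups <- unique(key)
  stats_rows <- list(); pts_rows <- list(); skipped <- character()
  for (g in groups) {
    idx <- key == g
    if (sum(idx) < 2L) { skipped <- c(skipped, g); next }
    ba <- bland_altman(ledger$predicted[idx], ledger$truth[idx])
    s <- ba$stats
    stats_rows[[g]] <- data.frame(group = g, n = s$n,
                                  mean_difference = s$mean_difference,
                                  sd_difference = s$sd_difference,
                                  loa_lower = s$loa_lower,
                                  loa_upper = s$loa_upper,
                                  mape_percent = s$mape_percent,
                                  stringsAsFactors = FALSE)
    pts_rows[[g]] <- cbind(group = g, ba$points)
  }
  if (length(skipped))
    warning("group(s) with n < 2 skipped: ", paste(skipped, collapse = ", "),
            call. = FALSE)
  if (!length(stats_rows)) stop("no group with n >= 2", call. = FALSE)
  out <- list(stats = do.call(rbind, c(stats_rows, make.row.names = FALSE)),
              ba_points = do.call(rbind, c(pts_rows, make.row.names = FALSE)))
  out
}
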