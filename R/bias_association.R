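#' Extreme-transcript sets for a coverage metric
#'
#' Builds the two groups compared in the sequence-feature association
#' analysis: after excluding transcripts with FPKM at or below `fpkm_min`,
#' transcripts are sorted by the metric (ties broken by transcript id) and
#' the first and last `n` form the low and high sets.
#'
#' @param metrics Data frame with columns `transcript_id`, `fpkm` and the
#'   metric column.
#' @param metric Name of the metric column (e.g. `"base_cv"` or `"fpkm"`).
#' @param fpkm_min Expression filter; transcripts at or below it are
#'   excluded.
#' @param n Size of each extreme set.
#' @return An `extreme_sets` list with `metric`, `low` and `high`
#'   (character vectors of transcript ids, disjoint).
#' @export
extreme_sets <- function(metrics, metric, fpkm_min = 5, n = 100L) {
  stopifnot(metric %in% names(metrics))
  keep <- metrics[metrics$fpkm > fpkm_min & !is.na(metrics[[metric]]), ]
  if (nrow(keep) < 2 * n) {
    stop("only ", nrow(keep), " transcripts pass the FPKM filter; ",
         2 * n, " needed (", 2 * n - nrow(keep), " short)")
  }
  ord <- order(keep[[metric]], keep$transcript_id)
  ids <- keep$transcript_id[ord]
  structure(list(metric = metric,
                 low = ids[seq_len(n)],
                 high = ids[(length(ids) - n + 1L):length(ids)]),
            class = "extreme_sets")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided unpaired rank-sum test with midrank ties: exact p-value by
#' enumeration when `n + m <= 12` and there are no ties, normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y Numeric value vectors for the two groups (both non-empty).
#' @return List with `statistic` (Mann-Whitney U for `x`), `p_value` and
#'   `exact` (logical).
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12) && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = exact)
}

#' Per-transcript effect-size ratios against a simulated baseline
#'
#' Ratio of each transcript's coefficient of variation in a library to its
#' CV in the fragmentation-only simulation; a mean ratio of 1.6 means the
#' library is 60% more variable than fragmentation alone explains.
#'
#' @param lib_cv,sim_cv Named numeric vectors of per-transcript CVs.
#' @return List with `ratios` (named, over shared transcripts), `mean`,
#'   `median` and `quantiles` (5%, 25%, 75%, 95%).
#' @export
effect_size_ratios <- function(lib_cv, sim_cv) {
  ids <- intersect(names(lib_cv), names(sim_cv))
  ids <- ids[!is.na(lib_cv[ids]) & !is.na(sim_cv[ids]) & sim_cv[ids] > 0]
  if (length(ids) == 0) stop("no shared transcripts with defined CVs")
  ratios <- lib_cv[ids] / sim_cv[ids]
  list(ratios = ratios, mean = mean(ratios), median = stats::median(ratios),
       quantiles = stats::quantile(ratios, c(0.05, 0.25, 0.75, 0.95)))
}

#' Squared Pearson correlation
#'
#' @param x,y Paired numeric vectors, at least 3 complete pairs, both
#'   non-constant.
#' @return R squared in `[0, 1]`, or `NA` for constant input.
#' @export
pearson_r2 <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Association report between coverage metrics and sequence features
#'
#' For each requested metric, builds the extreme-transcript sets and
#' compares every sequence feature between the low and high sets with
#' [rank_sum_test()]. No multiple-testing correction is applied; raw
#' p-values are reported together.
#'
#' @param metrics Per-transcript metrics data frame (needs
#'   `transcript_id`, `fpkm` and the metric columns).
#' @param features Per-transcript feature data frame from
#'   [sequence_feature_table()].
#' @param metric_cols Metric columns to analyse.
#' @param fpkm_min,n Passed to [extreme_sets()].
#' @return Data frame: metric, feature, group medians, U statistic,
#'   p-value, direction (`"higher_in_high"` or `"higher_in_low"`).
#' @export
association_report <- function(metrics, features,
                               metric_cols = c("base_cv", "fpkm"),
                               fpkm_min = 5, n = 100L) {
  feat_cols <- setdiff(names(features), "transcript_id")
  rows <- list()
  for (metric in metric_cols) {
    sets <- extreme_sets(metrics, metric, fpkm_min = fpkm_min, n = n)
    for (feat in feat_cols) {
      v <- stats::setNames(features[[feat]], features$transcript_id)
      lo <- v[sets$low]; hi <- v[sets$high]
      ht <- rank_sum_test(hi, lo)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, feature = feat,
        median_low = stats::median(lo, na.rm = TRUE),
        median_high = stats::median(hi, na.rm = TRUE),
        statistic = ht$statistic, p_value = ht$p_value,
        direction = ifelse(stats::median(hi, na.rm = TRUE) >=
                             stats::median(lo, na.rm = TRUE),
                           "higher_in_high", "higher_in_low"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
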