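#' Coverage-metrics configuration
#'
#' Thresholds and window definitions for the per-transcript coverage
#' statistics.
#'
#' @param fpkm_detect_threshold FPKM at or above which a transcript counts
#'   as detected.
#' @param fc_trim Bases trimmed from each transcript end before the
#'   fold-change statistic, against fragmentation edge effects.
#' @param fc_min_length Transcripts shorter than this (before trimming) are
#'   excluded from the fold-change statistic.
#' @param fc_low_pct,fc_high_pct Percentiles defining the low and high
#'   coverage bins.
#' @param fc_thresholds Fold-change thresholds for the summary counts.
#' @param fc_method `"decile_bin"` (mean of the lowest/highest 10% of
#'   bases) or `"percentile_cutoff"` (mean of bases at or below/above the
#'   percentile cutoffs).
#' @param proc_5p_window,proc_3p_window Fractional spans of the 5' and 3'
#'   windows of the processivity ratio.
#' @param proc_min_fpkm Transcripts at or below this FPKM are excluded from
#'   the processivity ratio.
#' @return A `metrics_config` list.
#' @export
metrics_config <- function(fpkm_detect_threshold = 5,
                           fc_trim = 200L,
                           fc_min_length = 500L,
                           fc_low_pct = 10,
                           fc_high_pct = 90,
                           fc_thresholds = c(2, 10, 100),
                           fc_method = c("decile_bin", "percentile_cutoff"),
                           proc_5p_window = c(0.05, 0.15),
                           proc_3p_window = c(0.85, 0.95),
                           proc_min_fpkm = 5) {
  stopifnot(fc_low_pct > 0, fc_low_pct < fc_high_pct, fc_high_pct < 100,
            fc_trim >= 0, all(diff(fc_thresholds) > 0))
  stopifnot(proc_5p_window[1] < proc_5p_window[2],
            proc_3p_window[1] < proc_3p_window[2],
            proc_5p_window[2] <= proc_3p_window[1])
  structure(list(fpkm_detect_threshold = fpkm_detect_threshold,
                 fc_trim = as.integer(fc_trim),
                 fc_min_length = as.integer(fc_min_length),
                 fc_low_pct = fc_low_pct, fc_high_pct = fc_high_pct,
                 fc_thresholds = fc_thresholds,
                 fc_method = match.arg(fc_method),
                 proc_5p_window = proc_5p_window,
                 proc_3p_window = proc_3p_window,
                 proc_min_fpkm = proc_min_fpkm),
            class = "metrics_config")
}

#' Compute FPKM
#'
#' Fragments per kilobase of exon per million mapped fragments:
#' `count / ((length/1000) * (total/1e6))`. Fragments (read pairs) are
#' counted, not reads.
#'
#' @param fragment_count Uniquely mapped fragments on the transcript.
#' @param length Transcript length in bases.
#' @param total_mapped_fragments Total uniquely mapped fragments in the
#'   sample.
#' @return FPKM value.
#' @export
compute_fpkm <- function(fragment_count, length, total_mapped_fragments) {
  if (any(length < 1)) stop("transcript length must be >= 1")
  if (any(total_mapped_fragments < 1)) stop("total fragments must be >= 1")
  fragment_count / ((length / 1000) * (total_mapped_fragments / 1e6))
}

#' Count detected transcripts per sample
#'
#' @param fpkm_table Data frame with columns `transcript_id`, `sample`,
#'   `fpkm`.
#' @param threshold Detection threshold; transcripts with FPKM greater than
#'   or equal to it are counted.
#' @return Named integer vector of detected-transcript counts per sample.
#' @export
detect_expressed <- function(fpkm_table, threshold = 5) {
  stopifnot(threshold >= 0)
  if (nrow(fpkm_table) == 0) return(stats::setNames(integer(), character()))
  vapply(split(fpkm_table$fpkm, fpkm_table$sample),
         function(v) sum(v >= threshold), 0L)
}

#' Base-level coefficient of variation
#'
#' Sample standard deviation of per-base depths divided by their mean; the
#' per-transcript coverage-variability measure. Undefined (NA) at zero mean.
#'
#' @param depths Per-base depth vector.
#' @return CV, or `NA` for all-zero coverage.
#' @export
base_cv <- function(depths) {
  m <- mean(depths)
  if (m == 0) return(NA_real_)
  stats::sd(depths) / m
}

#' Within-transcript fold-change in coverage
#'
#' Trims `fc_trim` bases from each end, sorts the remaining per-base
#' depths, and divides the mean of the top coverage bin by the mean of the
#' bottom bin. With the default `decile_bin` method the bins are the
#' `floor(n/10)` lowest and highest bases. Transcripts shorter than
#' `fc_min_length` (before trimming) are excluded (`NA`); a zero bottom-bin
#' mean returns `Inf`, which counts in every summary bucket.
#'
#' @param depths Per-base depth vector (5' to 3').
#' @param cfg A [metrics_config()].
#' @return Fold-change ratio (>= 1), `Inf`, or `NA` if excluded.
#' @export
within_transcript_fold_change <- function(depths, cfg = metrics_config()) {
  L <- length(depths)
  if (L < cfg$fc_min_length) return(NA_real_)
  d <- depths[(cfg$fc_trim + 1L):(L - cfg$fc_trim)]
  n <- length(d)
  s <- sort(d)
  if (cfg$fc_method == "decile_bin") {
    k_low <- max(1L, floor(n * cfg$fc_low_pct / 100))
    k_high <- max(1L, floor(n * (100 - cfg$fc_high_pct) / 100))
    low <- mean(s[seq_len(k_low)])
    high <- mean(s[(n - k_high + 1L):n])
  } else {
    q <- stats::quantile(s, c(cfg$fc_low_pct, cfg$fc_high_pct) / 100,
                         names = FALSE)
    low <- mean(s[s <= q[1]])
    high <- mean(s[s >= q[2]])
  }
  if (low == 0) return(Inf)
  high / low
}

#' Summarize fold-change values at nested thresholds
#'
#' Counts values strictly greater than each threshold; a transcript above
#' 100 is also counted above 10 and above 2 (nested columns). `NA`
#' (excluded) values are dropped; `Inf` counts everywhere.
#'
#' @param values Fold-change values.
#' @param thresholds Ascending thresholds.
#' @return Named integer vector of counts.
#' @export
fold_change_summary <- function(values, thresholds = c(2, 10, 100)) {
  stopifnot(all(diff(thresholds) > 0))
  v <- values[!is.na(values)]
  stats::setNames(vapply(thresholds, function(t) sum(v > t), 0L),
                  paste0(">", thresholds))
}

#' 3'/5' processivity ratio
#'
#' Mean depth over the 3' fractional window (default 85--95% of the
#' transcript by length) divided by mean depth over the 5' window (default
#' 5--15%). Near 1 indicates fully processive transcription. Fractional
#' bounds are converted to half-open base windows by `floor(L * frac)`, so
#' a 1,000-base transcript uses bases `[50, 150)` and `[850, 950)`.
#' Transcripts at or below `proc_min_fpkm` are excluded.
#'
#' @param depths Per-base depth vector (5' to 3').
#' @param fpkm Transcript FPKM used for the expression filter.
#' @param cfg A [metrics_config()].
#' @return Ratio, or `NA` if excluded or the 5' mean is zero.
#' @export
processivity_ratio <- function(depths, fpkm, cfg = metrics_config()) {
  if (fpkm <= cfg$proc_min_fpkm) return(NA_real_)
  L <- length(depths)
  win <- function(span) {
    lo <- floor(L * span[1])
    hi <- floor(L * span[2])
    depths[(lo + 1L):hi]
  }
  m5 <- mean(win(cfg$proc_5p_window))
  m3 <- mean(win(cfg$proc_3p_window))
  if (m5 == 0) return(NA_real_)
  m3 / m5
}

#' Per-position nucleotide frequencies of read 5' ends
#'
#' Frequencies over A/C/G/T at each position of fixed-length read prefixes;
#' N bases are excluded from the denominator. Reveals the random-priming
#' signature at cDNA fragment ends.
#'
#' @param read_prefixes Character vector of equal-length 5' read sequences
#'   (alphabet A, C, G, T, N).
#' @return Matrix of frequencies, positions in rows, bases A/C/G/T in
#'   columns; each row sums to 1 where any non-N base exists.
#' @export
read_end_nt_frequencies <- function(read_prefixes) {
  if (length(read_prefixes) == 0) stop("no read prefixes supplied")
  if (length(unique(nchar(read_prefixes))) != 1) {
    stop("all read prefixes must have the same length")
  }
  cm <- Biostrings::consensusMatrix(
    Biostrings::DNAStringSet(read_prefixes), baseOnly = TRUE)
  counts <- t(cm[c("A", "C", "G", "T"), , drop = FALSE])
  tot <- rowSums(counts)
  freq <- counts / ifelse(tot == 0, NA_real_, tot)
  rownames(freq) <- seq_len(nrow(freq))
  freq
}

#' Per-transcript metrics table
#'
#' Convenience wrapper computing base-level CV, within-transcript
#' fold-change and processivity for a set of transcript coverage vectors.
#'
#' @param coverage Named list of per-base depth vectors.
#' @param fpkm Named numeric vector of FPKM values (same names).
#' @param cfg A [metrics_config()].
#' @return Data frame with columns `transcript_id`, `length`, `fpkm`,
#'   `base_cv`, `fold_change`, `processivity`, `excluded_reason`.
#' @export
coverage_metrics_table <- function(coverage, fpkm, cfg = metrics_config()) {
  ids <- names(coverage)
  rows <- lapply(ids, function(id) {
    d <- coverage[[id]]
    f <- unname(fpkm[id])
    fc <- within_transcript_fold_change(d, cfg)
    pr <- processivity_ratio(d, f, cfg)
    reason <- ""
    if (length(d) < cfg$fc_min_length) reason <- "short_transcript"
    else if (f <= cfg$proc_min_fpkm) reason <- "low_fpkm"
    data.frame(transcript_id = id, length = length(d), fpkm = f,
               base_cv = base_cv(d), fold_change = fc, processivity = pr,
               excluded_reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
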