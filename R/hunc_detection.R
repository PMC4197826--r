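#' Hunc-detection configuration
#'
#' Thresholds of the sliding-window MAD caller for regions of high,
#' unpredictable coverage (hunc regions) across a dilution series.
#'
#' @param window Sliding-window width in bases.
#' @param trim_head,trim_tail Number of leading/trailing window scores
#'   dropped per transcript, against end and fragmentation artifacts.
#' @param mad_quantile Quantile of the pooled window scores used as the
#'   per-replicate cutoff.
#' @param min_contiguous Minimum run length, in windows, of above-cutoff
#'   scores for a candidate region.
#' @param diff_quantiles Low/high quantiles of the replicate score
#'   differences used by [difference_regions()].
#' @param mouse_fpkm_max Regions on transcripts with background-only FPKM
#'   at or above this, in either replicate, are discarded.
#' @param mouse_cov_max Regions whose mean background-only depth exceeds
#'   this (in the region or its flanks) are discarded.
#' @param flank Flank width in bases for the background-coverage filter.
#' @param hunc_exclusion_distance Difference regions within this distance
#'   of a called hunc region are discarded as extensions of it.
#' @return A `hunc_config` list.
#' @export
hunc_config <- function(window = 100L, trim_head = 300L, trim_tail = 250L,
                        mad_quantile = 0.95, min_contiguous = 20L,
                        diff_quantiles = c(0.025, 0.975),
                        mouse_fpkm_max = 5, mouse_cov_max = 10,
                        flank = 100L, hunc_exclusion_distance = 200L) {
  stopifnot(window >= 2, mad_quantile > 0, mad_quantile < 1,
            all(diff_quantiles > 0), all(diff_quantiles < 1),
            diff_quantiles[1] < diff_quantiles[2], min_contiguous >= 1)
  structure(list(window = as.integer(window),
                 trim_head = as.integer(trim_head),
                 trim_tail = as.integer(trim_tail),
                 mad_quantile = mad_quantile,
                 min_contiguous = as.integer(min_contiguous),
                 diff_quantiles = diff_quantiles,
                 mouse_fpkm_max = mouse_fpkm_max,
                 mouse_cov_max = mouse_cov_max,
                 flank = as.integer(flank),
                 hunc_exclusion_distance = as.integer(hunc_exclusion_distance)),
            class = "hunc_config")
}

#' Median absolute deviation with scale constant 1
#'
#' `median(|x - median(x)|)`, the robust per-base spread measure used
#' across dilution conditions. No consistency constant is applied.
#'
#' @param values Numeric vector, length >= 1.
#' @return Non-negative scalar.
#' @export
mad_constant1 <- function(values) {
  if (length(values) < 1) stop("mad_constant1 requires at least one value")
  stats::mad(values, constant = 1)
}

#' Min-max normalize a coverage vector to [0, 1]
#'
#' Constant vectors (including all-zero) map to all zeros, so a
#' background-only sample with no signal contributes zeros rather than NaN.
#' The result is quantized to 9 decimal places: two profiles that differ
#' only by a positive scale factor then normalize to exactly equal vectors
#' regardless of floating-point rounding, so exactly proportional
#' conditions contribute exactly zero MAD.
#'
#' @param x Numeric vector.
#' @return Vector rescaled to `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(numeric(length(x)))
  round((x - r[1]) / (r[2] - r[1]), 9L)
}

# column medians of a matrix; fast sorting-network path for 5 rows
# (the 5-condition dilution series), generic apply fallback otherwise
col_medians <- function(m) {
  if (nrow(m) == 5L) {
    a <- m[1L, ]; b <- m[2L, ]; c <- m[3L, ]; d <- m[4L, ]; e <- m[5L, ]
    cx <- function(x, y) list(lo = pmin(x, y), hi = pmax(x, y))
    s <- cx(a, b); a <- s$lo; b <- s$hi
    s <- cx(d, e); d <- s$lo; e <- s$hi
    s <- cx(c, e); c <- s$lo; e <- s$hi
    s <- cx(c, d); c <- s$lo; d <- s$hi
    s <- cx(a, d); a <- s$lo; d <- s$hi
    s <- cx(a, c); a <- s$lo; c <- s$hi
    s <- cx(b, e); b <- s$lo; e <- s$hi
    s <- cx(b, d); b <- s$lo; d <- s$hi
    s <- cx(b, c); b <- s$lo; c <- s$hi
    return(c)
  }
  apply(m, 2L, stats::median)
}

#' Windowed MAD scores for one transcript
#'
#' The detector's per-transcript scoring: (1) min-max normalize each
#' condition's coverage to `[0, 1]`; (2) per-base MAD (constant 1) across
#' conditions; (3) mean over the `window`-base window centered on each base,
#' full windows only (centers `window/2 ... L - window/2`, 0-based);
#' (4) drop the first `trim_head` and last `trim_tail` window scores.
#'
#' @param cond_coverage List of per-base coverage vectors, one per
#'   condition, equal lengths (a dilution series for one transcript in one
#'   replicate).
#' @param cfg A [hunc_config()].
#' @return List with `centers` (0-based window centers), `scores` (window
#'   mean MADs) and `length` (transcript length), or `NULL` if the
#'   transcript is too short to retain any window after trimming.
#' @export
windowed_mad_scores <- function(cond_coverage, cfg = hunc_config()) {
  lens <- lengths(cond_coverage)
  stopifnot(length(unique(lens)) == 1L)
  L <- lens[[1L]]
  w <- cfg$window
  n_scores <- L - w + 1L
  if (n_scores <= cfg$trim_head + cfg$trim_tail) return(NULL)
  m <- do.call(rbind, lapply(cond_coverage, minmax_normalize))
  med <- col_medians(m)
  dev <- abs(m - rep(med, each = nrow(m)))
  madv <- col_medians(dev)
  cs <- c(0, cumsum(madv))
  scores <- (cs[(w + 1L):(L + 1L)] - cs[1L:n_scores]) / w
  centers <- (seq_len(n_scores) - 1L) + w %/% 2L
  keep <- (cfg$trim_head + 1L):(n_scores - cfg$trim_tail)
  list(centers = centers[keep], scores = scores[keep], length = L)
}

#' Score every transcript of one replicate
#'
#' @param series A `dilution_series` object.
#' @param replicate Replicate index (1 or 2).
#' @param cfg A [hunc_config()].
#' @return Named list of [windowed_mad_scores()] results; transcripts too
#'   short to score are recorded in the `excluded` attribute with a reason.
#' @export
score_dilution_replicate <- function(series, replicate,
                                     cfg = hunc_config()) {
  conds <- series$replicates[[replicate]]
  missing <- setdiff(names(dilution_conditions()), names(conds))
  if (length(missing) > 0) {
    stop("config error: replicate ", replicate,
         " is missing condition(s): ", paste(missing, collapse = ", "))
  }
  conds <- conds[names(dilution_conditions())]
  ids <- names(conds[[1L]])
  out <- list()
  excluded <- character()
  for (id in ids) {
    sc <- windowed_mad_scores(lapply(conds, `[[`, id), cfg)
    if (is.null(sc)) excluded <- c(excluded, id) else out[[id]] <- sc
  }
  attr(out, "excluded") <- excluded
  out
}

# runs of at least min_len consecutive TRUEs -> first/last index pairs
contiguous_runs <- function(flag, min_len) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(first = starts[keep], last = ends[keep])
}

# candidate intervals from a scored transcript: runs of windows above
# cutoff; span = [first_center - w/2, last_center + w/2), clipped
candidate_intervals <- function(scored, cutoff, cfg,
                                side = c("above", "below")) {
  side <- match.arg(side)
  out <- list()
  for (id in names(scored)) {
    sc <- scored[[id]]
    flag <- if (side == "above") sc$scores > cutoff else sc$scores < cutoff
    runs <- contiguous_runs(flag, cfg$min_contiguous)
    if (nrow(runs) == 0L) next
    half <- cfg$window %/% 2L
    out[[id]] <- data.frame(
      transcript_id = id,
      start = pmax(0L, sc$centers[runs$first] - half),
      end = pmin(sc$length, sc$centers[runs$last] + half),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# intersect candidate interval sets per transcript; >= 1 base overlap,
# emitted interval = the intersection
intersect_candidates <- function(c1, c2) {
  out <- list()
  for (id in intersect(unique(c1$transcript_id), unique(c2$transcript_id))) {
    a <- c1[c1$transcript_id == id, ]
    b <- c2[c2$transcript_id == id, ]
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      lo <- max(a$start[i], b$start[j])
      hi <- min(a$end[i], b$end[j])
      if (lo < hi) {
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = id, start = lo, end = hi,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, out))
  rownames(df) <- NULL
  df
}

region_mean_mad <- function(df, scored_list) {
  vapply(seq_len(nrow(df)), function(i) {
    vals <- unlist(lapply(scored_list, function(scored) {
      sc <- scored[[df$transcript_id[i]]]
      if (is.null(sc)) return(numeric())
      sc$scores[sc$centers >= df$start[i] & sc$centers < df$end[i]]
    }))
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, 0)
}

mean_region_cov <- function(cov, start, end) {
  lo <- max(0L, start)
  hi <- min(length(cov), end)
  if (lo >= hi) return(0)
  mean(cov[(lo + 1L):hi])
}

# background filters shared by hunc and difference calls; returns the
# provenance label per region ("pass", "mouse_fpkm", "mouse_coverage")
apply_mouse_filters <- function(df, mouse_fpkm, mouse_cov1, mouse_cov2,
                                cfg) {
  vapply(seq_len(nrow(df)), function(i) {
    id <- df$transcript_id[i]
    row <- mouse_fpkm[mouse_fpkm$transcript_id == id, ]
    if (nrow(row) > 0 && max(row$rep1, row$rep2) >= cfg$mouse_fpkm_max) {
      return("mouse_fpkm")
    }
    for (cov in list(mouse_cov1[[id]], mouse_cov2[[id]])) {
      if (is.null(cov)) next
      spans <- list(c(df$start[i], df$end[i]),
                    c(df$start[i] - cfg$flank, df$start[i]),
                    c(df$end[i], df$end[i] + cfg$flank))
      for (sp in spans) {
        if (mean_region_cov(cov, sp[1], sp[2]) > cfg$mouse_cov_max) {
          return("mouse_coverage")
        }
      }
    }
    "pass"
  }, "")
}

#' Call hunc regions across a replicated dilution series
#'
#' Per replicate, the cutoff is the `mad_quantile` quantile (type 7) of all
#' window scores pooled over transcripts; runs of at least `min_contiguous`
#' above-cutoff windows become candidate intervals. Candidates are
#' intersected across replicates (at least one shared base; the emitted
#' interval is the intersection), then filtered against background
#' misalignment: regions on transcripts with background-only FPKM at or
#' above `mouse_fpkm_max` in either replicate are dropped, as are regions
#' whose mean background-only depth exceeds `mouse_cov_max` inside the
#' region or within `flank` bases on either side.
#'
#' @param scored1,scored2 Outputs of [score_dilution_replicate()] for
#'   replicates 1 and 2 (same transcript set).
#' @param mouse_fpkm Data frame `transcript_id`, `rep1`, `rep2` of
#'   background-only FPKM values.
#' @param mouse_cov1,mouse_cov2 Named lists of background-only coverage
#'   vectors per transcript, one per replicate.
#' @param cfg A [hunc_config()].
#' @return A `hunc_calls` list: `regions` (surviving calls with
#'   `transcript_id`, `start`, `end`, `mean_mad`, `filter = "pass"`),
#'   `dropped` (filtered candidates with the filter that removed them) and
#'   `cutoffs` (per-replicate score cutoffs).
#' @export
call_hunc_regions <- function(scored1, scored2, mouse_fpkm,
                              mouse_cov1, mouse_cov2,
                              cfg = hunc_config()) {
  cut1 <- stats::quantile(unlist(lapply(scored1, `[[`, "scores")),
                          cfg$mad_quantile, names = FALSE, type = 7)
  cut2 <- stats::quantile(unlist(lapply(scored2, `[[`, "scores")),
                          cfg$mad_quantile, names = FALSE, type = 7)
  c1 <- candidate_intervals(scored1, cut1, cfg)
  c2 <- candidate_intervals(scored2, cut2, cfg)
  df <- intersect_candidates(c1, c2)
  if (nrow(df) > 0) {
    df$mean_mad <- region_mean_mad(df, list(scored1, scored2))
    df$filter <- apply_mouse_filters(df, mouse_fpkm, mouse_cov1,
                                     mouse_cov2, cfg)
  } else {
    df$mean_mad <- numeric()
    df$filter <- character()
  }
  structure(list(regions = df[df$filter == "pass", , drop = FALSE],
                 dropped = df[df$filter != "pass", , drop = FALSE],
                 cutoffs = c(rep1 = cut1, rep2 = cut2)),
            class = "hunc_calls")
}

#' Call replicate-difference regions
#'
#' Finds regions whose windowed MAD scores diverge between replicates:
#' per-window differences (replicate 1 minus replicate 2) are pooled over
#' transcripts, the `diff_quantiles` quantiles serve as low/high cutoffs,
#' and runs of at least `min_contiguous` windows beyond either cutoff
#' become candidates. Candidates pass the same background filters as hunc
#' regions, and those within `hunc_exclusion_distance` bases of a called
#' hunc region on the same transcript are discarded as extensions of it.
#'
#' @inheritParams call_hunc_regions
#' @param hunc A `hunc_calls` object from [call_hunc_regions()].
#' @return A `hunc_calls`-like list with `regions`, `dropped` and
#'   `cutoffs` (low/high difference cutoffs).
#' @export
difference_regions <- function(scored1, scored2, hunc, mouse_fpkm,
                               mouse_cov1, mouse_cov2,
                               cfg = hunc_config()) {
  ids <- intersect(names(scored1), names(scored2))
  diffs <- lapply(ids, function(id) {
    s1 <- scored1[[id]]; s2 <- scored2[[id]]
    stopifnot(length(s1$scores) == length(s2$scores))
    list(centers = s1$centers, scores = s1$scores - s2$scores,
         length = s1$length)
  })
  names(diffs) <- ids
  cuts <- stats::quantile(unlist(lapply(diffs, `[[`, "scores")),
                          cfg$diff_quantiles, names = FALSE, type = 7)
  lo <- candidate_intervals(diffs, cuts[1], cfg, side = "below")
  hi <- candidate_intervals(diffs, cuts[2], cfg, side = "above")
  df <- unique(rbind(lo, hi))
  rownames(df) <- NULL
  if (nrow(df) > 0) {
    df$mean_mad <- abs(region_mean_mad(df, list(diffs)))
    df$filter <- apply_mouse_filters(df, mouse_fpkm, mouse_cov1,
                                     mouse_cov2, cfg)
    near_hunc <- vapply(seq_len(nrow(df)), function(i) {
      h <- hunc$regions[hunc$regions$transcript_id == df$transcript_id[i], ]
      if (nrow(h) == 0) return(FALSE)
      gap <- pmax(0, pmax(h$start - df$end[i], df$start[i] - h$end))
      any(gap <= cfg$hunc_exclusion_distance)
    }, TRUE)
    df$filter[df$filter == "pass" & near_hunc] <- "near_hunc"
  } else {
    df$mean_mad <- numeric()
    df$filter <- character()
  }
  structure(list(regions = df[df$filter == "pass", , drop = FALSE],
                 dropped = df[df$filter != "pass", , drop = FALSE],
                 cutoffs = c(low = cuts[1], high = cuts[2])),
            class = "hunc_calls")
}

#' Score recovery of injected anomalies
#'
#' Compares called regions against a simulation truth record: an injected
#' anomaly counts as recovered when a call on its transcript covers at
#' least `min_truth_overlap` of the truth interval; calls on transcripts
#' without any injected anomaly count as false positives.
#'
#' Decoy transcripts (whose anomalies the background filters are supposed
#' to remove) are excluded from the sensitivity denominator.
#'
#' @param regions Data frame of calls (`transcript_id`, `start`, `end`).
#' @param truth A `sim_truth` record.
#' @param min_truth_overlap Minimum fraction of the truth interval covered.
#' @return List with `sensitivity`, `n_truth`, `n_recovered`,
#'   `false_positive_regions` and per-truth `overlap` / `jaccard` vectors.
#' @export
score_recovery <- function(regions, truth, min_truth_overlap = 0.5) {
  th <- truth$hunc[!(truth$hunc$transcript_id %in%
                       truth$decoys$transcript_id), , drop = FALSE]
  overlap <- jaccard <- numeric(nrow(th))
  for (i in seq_len(nrow(th))) {
    r <- regions[regions$transcript_id == th$transcript_id[i], ]
    if (nrow(r) == 0) next
    inter <- pmax(0, pmin(r$end, th$end[i]) - pmax(r$start, th$start[i]))
    uni <- (r$end - r$start) + (th$end[i] - th$start[i]) - inter
    overlap[i] <- max(inter) / (th$end[i] - th$start[i])
    jaccard[i] <- max(inter / uni)
  }
  fp <- sum(!(regions$transcript_id %in% th$transcript_id))
  n_rec <- sum(overlap >= min_truth_overlap)
  list(sensitivity = if (nrow(th)) n_rec / nrow(th) else NA_real_,
       n_truth = nrow(th), n_recovered = n_rec,
       false_positive_regions = fp, overlap = overlap, jaccard = jaccard)
}
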