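# Independent brute-force oracles used by the equivalence suites.
# These deliberately avoid the code paths of the implementation.

# median absolute deviation, constant 1, written out longhand
oracle_mad <- function(x) {
  m <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0) {
    s <- sort(x)
    m <- (s[length(x) / 2] + s[length(x) / 2 + 1]) / 2
  }
  d <- sort(abs(x - m))
  if (length(d) %% 2 == 1) d[(length(d) + 1) / 2] else
    (d[length(d) / 2] + d[length(d) / 2 + 1]) / 2
}

# windowed MAD scores recomputed with naive loops (normalization mirrors
# the contract: min-max to [0,1], quantized to 9 decimals, constant -> 0)
oracle_windowed_mad <- function(cond_coverage, window, trim_head,
                                trim_tail) {
  L <- length(cond_coverage[[1]])
  norm <- lapply(cond_coverage, function(x) {
    if (max(x) == min(x)) rep(0, L) else
      round((x - min(x)) / (max(x) - min(x)), 9)
  })
  madv <- numeric(L)
  for (p in seq_len(L)) {
    madv[p] <- oracle_mad(vapply(norm, `[`, 0, p))
  }
  n_scores <- L - window + 1
  scores <- numeric(n_scores)
  for (i in seq_len(n_scores)) scores[i] <- mean(madv[i:(i + window - 1)])
  centers <- (seq_len(n_scores) - 1) + window %/% 2
  keep <- (trim_head + 1):(n_scores - trim_tail)
  list(centers = centers[keep], scores = scores[keep])
}

# local alignment score by exhaustive enumeration of monotone matchings:
# choose r positions in each string (paired in order); unmatched positions
# inside the matched spans pay the linear gap penalty
oracle_local_align <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- 0
  for (r in seq_len(min(length(av), length(bv)))) {
    ia <- utils::combn(length(av), r)
    ib <- utils::combn(length(bv), r)
    for (i in seq_len(ncol(ia))) for (j in seq_len(ncol(ib))) {
      pa <- ia[, i]; pb <- ib[, j]
      sub <- sum(ifelse(av[pa] == bv[pb], match, mismatch))
      gaps <- (pa[r] - pa[1] + 1 - r) + (pb[r] - pb[1] + 1 - r)
      best <- max(best, sub + gap * gaps)
    }
  }
  best
}

# decile-bin fold change by explicit repeated min/max extraction
oracle_fold_change <- function(depths, trim = 200, min_length = 500) {
  if (length(depths) < min_length) return(NA_real_)
  d <- depths[(trim + 1):(length(depths) - trim)]
  k <- max(1, floor(length(d) / 10))
  lows <- highs <- numeric(k)
  pool <- d
  for (i in seq_len(k)) {
    j <- which.min(pool); lows[i] <- pool[j]; pool <- pool[-j]
  }
  pool <- d
  for (i in seq_len(k)) {
    j <- which.max(pool); highs[i] <- pool[j]; pool <- pool[-j]
  }
  if (mean(lows) == 0) return(Inf)
  mean(highs) / mean(lows)
}

# exact two-sided rank-sum p-value by enumeration of all group labelings
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  labelings <- utils::combn(length(pooled), n)
  us <- apply(labelings, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# small builders shared across test files
single_exon_models <- function(lens, gap = 500L, chrom = "chrS",
                               prefix = "T") {
  starts <- cumsum(c(0L, utils::head(lens, -1) + gap))
  out <- lapply(seq_along(lens), function(i) {
    transcript_model(sprintf("%s%03d", prefix, i), chrom, "+",
                     data.frame(start = starts[i],
                                end = starts[i] + lens[i]))
  })
  names(out) <- vapply(out, `[[`, "", "transcript_id")
  structure(out, class = "transcript_models")
}

random_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
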