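#' Simulation configuration
#'
#' Parameters of the synthetic transcriptome and of the fragmentation-based
#' coverage simulator. Defaults emulate a paired-end 100 bp TruSeq-style
#' library: fragments drawn with Gaussian length (mean 250, sd 25) truncated
#' to `[read_length, transcript length]`, both read ends contributing depth.
#'
#' @param n_transcripts Number of transcripts in the pool.
#' @param length_range Min/max transcript length in bases; the minimum must
#'   be at least `500 + 2 * read_length` so that end-trimmed statistics stay
#'   defined.
#' @param gc_target Per-base probability of G or C in simulated sequences.
#' @param read_length Read length in bases.
#' @param fragment_length Mean and sd of the fragment length distribution.
#' @param n_fragments Total number of fragments to simulate.
#' @param seed Integer seed; identical configs and seeds give identical
#'   output (base R Mersenne-Twister stream).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 30L,
                       length_range = c(1500L, 3000L),
                       gc_target = 0.5,
                       read_length = 100L,
                       fragment_length = c(250, 25),
                       n_fragments = 1e5,
                       seed = 1L) {
  if (gc_target < 0 || gc_target > 1) stop("gc_target must be in [0, 1]")
  if (n_fragments < 0) stop("n_fragments must be >= 0")
  if (length_range[1] < 500 + 2 * read_length) {
    stop("minimum transcript length must be >= 500 + 2*read_length")
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 length_range = as.integer(length_range),
                 gc_target = gc_target,
                 read_length = as.integer(read_length),
                 fragment_length = fragment_length,
                 n_fragments = n_fragments,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Dilution-series condition labels
#'
#' The five mixing conditions of an IVT:background dilution series, in
#' series order, with the IVT fraction of each pool.
#'
#' @return Named numeric vector of IVT fractions.
#' @export
dilution_conditions <- function() {
  c(ivt_only = 1, mix_1_1 = 1 / 2, mix_1_2 = 1 / 3, mix_1_10 = 1 / 11,
    mouse_only = 0)
}

#' Generate a synthetic control transcriptome
#'
#' Draws single-exon transcript models placed non-overlapping on one
#' synthetic chromosome, with random sequences at a target GC fraction.
#' Optionally replaces a segment of some transcripts with low-complexity
#' sequence (homopolymer or dinucleotide repeat) at recorded positions, for
#' sequence-feature tests.
#'
#' @param cfg A [sim_config()].
#' @param weights Per-transcript expression weights (FPKM-like seeds);
#'   recycled scalar or length `n_transcripts`. Equal by default, matching a
#'   pool transcribed from equimolar templates; quantity-matched seeds can
#'   be supplied from an FPKM table instead.
#' @param n_low_complexity Number of transcripts given a planted
#'   low-complexity segment.
#' @param low_complexity_width Width of each planted segment.
#' @return List with `models` (a `transcript_models` object), `sequences`
#'   (a [Biostrings::DNAStringSet]) and `truth` (list with `weights` and a
#'   `low_complexity` data frame of planted segments).
#' @export
generate_transcriptome <- function(cfg, weights = 1,
                                   n_low_complexity = 0L,
                                   low_complexity_width = 200L) {
  set.seed(cfg$seed)
  n <- cfg$n_transcripts
  if (n == 0L) {
    return(list(models = structure(list(), class = "transcript_models"),
                sequences = Biostrings::DNAStringSet(),
                truth = list(weights = numeric(),
                             low_complexity = data.frame())))
  }
  lens <- sample(cfg$length_range[1]:cfg$length_range[2], n, replace = TRUE)
  p <- c(A = (1 - cfg$gc_target) / 2, C = cfg$gc_target / 2,
         G = cfg$gc_target / 2, T = (1 - cfg$gc_target) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, "")
  ids <- sprintf("TX%04d", seq_len(n))
  # planted low-complexity segments, recorded for downstream feature tests
  lc <- data.frame(transcript_id = character(), start = integer(),
                   end = integer(), motif = character(),
                   stringsAsFactors = FALSE)
  if (n_low_complexity > 0L) {
    pick <- sample(n, min(n_low_complexity, n))
    for (i in pick) {
      w <- min(low_complexity_width, lens[i] - 2L)
      at <- sample(0:(lens[i] - w), 1L)
      motif <- sample(c("A", "T", "AC", "AG", "CT"), 1L)
      rep_seq <- substr(strrep(motif, ceiling(w / nchar(motif))), 1L, w)
      substr(seqs[i], at + 1L, at + w) <- rep_seq
      lc <- rbind(lc, data.frame(transcript_id = ids[i], start = at,
                                 end = at + w, motif = motif,
                                 stringsAsFactors = FALSE))
    }
  }
  gap <- 1000L
  starts <- cumsum(c(0L, lens[-n] + gap))
  models <- lapply(seq_len(n), function(i) {
    transcript_model(ids[i], "chrS", "+",
                     data.frame(start = starts[i], end = starts[i] + lens[i]))
  })
  names(models) <- ids
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- ids
  w <- rep_len(weights, n)
  names(w) <- ids
  list(models = structure(models, class = "transcript_models"),
       sequences = sequences,
       truth = list(weights = w, low_complexity = lc))
}

#' Simulate fragmentation-based coverage
#'
#' A minimal fragmentation sampler: each fragment picks a transcript with
#' probability proportional to `weight * length`, a Gaussian length
#' truncated to `[read_length, transcript length]`, and a uniform start
#' among eligible positions; both 100 bp read ends increment per-base depth.
#' Coverage therefore deviates from uniform only by fragmentation
#' randomness. No sequencing errors, intronic reads or polymorphisms are
#' modeled.
#'
#' @param models A `transcript_models` object.
#' @param weights Per-transcript expression weights (recycled).
#' @param cfg A [sim_config()].
#' @param seed Seed for this draw; defaults to `cfg$seed`.
#' @return List with `coverage` (named list of per-base depth vectors, 5'
#'   to 3') and `counts` (named integer vector of fragments per transcript,
#'   summing to `n_fragments`).
#' @export
simulate_fragment_coverage <- function(models, weights, cfg,
                                       seed = cfg$seed) {
  set.seed(seed)
  n <- length(models)
  ids <- names(models)
  lens <- vapply(models, `[[`, 0L, "length")
  w <- rep_len(weights, n)
  prob <- w * lens
  if (cfg$n_fragments > 0 && sum(prob) <= 0) {
    stop("simulation error: all weights are zero with n_fragments > 0")
  }
  counts <- if (cfg$n_fragments > 0) {
    as.integer(stats::rmultinom(1L, cfg$n_fragments, prob))
  } else integer(n)
  names(counts) <- ids
  rl <- cfg$read_length
  coverage <- vector("list", n)
  names(coverage) <- ids
  for (i in seq_len(n)) {
    L <- lens[i]
    k <- counts[i]
    if (k == 0L) { coverage[[i]] <- numeric(L); next }
    fl <- round(stats::rnorm(k, cfg$fragment_length[1],
                             cfg$fragment_length[2]))
    fl <- pmin(pmax(fl, rl), L)
    s <- floor(stats::runif(k, 0, L - fl + 1))  # 0-based fragment start
    # read 1: [s, s+rl); read 2: [s+fl-rl, s+fl). 1-based delta indices.
    up <- c(s + 1, s + fl - rl + 1)
    down <- c(s + rl + 1, s + fl + 1)
    delta <- tabulate(up, nbins = L + 1L) - tabulate(down, nbins = L + 1L)
    coverage[[i]] <- cumsum(delta)[seq_len(L)]
  }
  list(coverage = coverage, counts = counts)
}

#' Define ground truth for a dilution-series simulation
#'
#' Chooses transcripts to carry injected "hunc" anomalies - intervals whose
#' coverage, relative to the rest of the transcript, follows a different
#' condition-specific multiplier in each mixing condition - and background
#' "decoy" transcripts with recorded mouse-only signal that must be removed
#' by the detector's background filters.
#'
#' Anomaly multipliers form a geometric ladder from 1 down to
#' `1/amplitude`, randomly assigned to the four IVT-containing conditions,
#' so at least one condition deviates `amplitude`-fold from another. The
#' multipliers never exceed 1: under per-condition min-max normalization an
#' interval raised above the transcript's maximum rescales the whole
#' profile and smears the anomaly over the full transcript, whereas
#' condition-specific local suppression (the depletion-type bias the
#' detector targets) stays localized.
#'
#' @param models A `transcript_models` object.
#' @param n_hunc Number of transcripts given one injected anomaly each.
#' @param hunc_width Anomaly width in bases (>= 100).
#' @param amplitude Maximum fold-difference across conditions (>= 3 for a
#'   detectable anomaly).
#' @param margin Distance kept between an anomaly and each transcript end,
#'   clear of the detector's end-trimming.
#' @param n_decoys_fpkm,n_decoys_cov Numbers of anomaly-carrying transcripts
#'   additionally given mouse-only background: uniform background with
#'   mouse FPKM above the detection filter (`fpkm` type), or a localized
#'   coverage spike over the anomaly with low transcript FPKM (`cov` type).
#' @param seed Integer seed.
#' @return A `sim_truth` list with elements `weights`, `hunc` (data frame:
#'   transcript_id, start, end, one multiplier column per IVT condition)
#'   and `decoys` (data frame: transcript_id, type, mouse_fpkm, depth,
#'   spike_start, spike_end).
#' @export
make_sim_truth <- function(models, n_hunc = 0L, hunc_width = 150L,
                           amplitude = 5, margin = 700L,
                           n_decoys_fpkm = 0L, n_decoys_cov = 0L,
                           seed = 1L) {
  set.seed(seed)
  ids <- names(models)
  lens <- vapply(models, `[[`, 0L, "length")
  eligible <- ids[lens >= 2 * margin + hunc_width]
  n_inject <- n_hunc + n_decoys_fpkm + n_decoys_cov
  if (n_inject > length(eligible)) {
    stop("config error: only ", length(eligible),
         " transcripts are long enough for anomaly injection")
  }
  pick <- sample(eligible, n_inject)
  conds <- setdiff(names(dilution_conditions()), "mouse_only")
  hunc <- NULL
  if (n_inject > 0L) {
    rows <- lapply(pick, function(id) {
      L <- lens[[id]]
      at <- sample(margin:(L - margin - hunc_width), 1L)
      mult <- amplitude^(-(0:3) / 3)  # 1 .. 1/amplitude, geometric
      mult <- sample(mult)            # random condition assignment
      out <- data.frame(transcript_id = id, start = at,
                        end = at + hunc_width, stringsAsFactors = FALSE)
      out[conds] <- as.list(mult)
      out
    })
    hunc <- do.call(rbind, rows)
  } else {
    hunc <- data.frame(transcript_id = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
    hunc[conds] <- list(numeric(), numeric(), numeric(), numeric())
  }
  decoys <- data.frame(transcript_id = character(), type = character(),
                       mouse_fpkm = numeric(), depth = numeric(),
                       spike_start = integer(), spike_end = integer(),
                       stringsAsFactors = FALSE)
  take <- function(k) {
    got <- utils::tail(pick, k)
    pick <<- utils::head(pick, length(pick) - k)
    got
  }
  for (id in take(n_decoys_cov)) {
    h <- hunc[hunc$transcript_id == id, ]
    decoys <- rbind(decoys, data.frame(
      transcript_id = id, type = "cov", mouse_fpkm = 2, depth = 30,
      spike_start = h$start - 50L, spike_end = h$end + 50L,
      stringsAsFactors = FALSE))
  }
  for (id in take(n_decoys_fpkm)) {
    decoys <- rbind(decoys, data.frame(
      transcript_id = id, type = "fpkm", mouse_fpkm = 20, depth = 3,
      spike_start = NA_integer_, spike_end = NA_integer_,
      stringsAsFactors = FALSE))
  }
  structure(list(weights = stats::setNames(rep(1, length(ids)), ids),
                 hunc = hunc, decoys = decoys),
            class = "sim_truth")
}

apply_hunc_multiplier <- function(depths, start, end, mult) {
  if (start < 0 || end > length(depths)) {
    stop("config error: hunc interval out of transcript bounds")
  }
  depths[(start + 1L):end] <- depths[(start + 1L):end] * mult
  depths
}

#' Simulate a replicate dilution-series experiment
#'
#' For each replicate one fragmentation realization is drawn and shared by
#' all conditions of that replicate (all pools derive from the same IVT
#' RNA); each condition scales it by its IVT mixing fraction and applies
#' the truth's condition-specific anomaly multipliers. The mouse-only
#' condition has zero coverage on control transcripts except recorded
#' decoys, which receive uniform background or a localized spike. The truth
#' record is carried along for recovery scoring.
#'
#' @param models A `transcript_models` object.
#' @param truth A [make_sim_truth()] record.
#' @param cfg A [sim_config()].
#' @return A `dilution_series` object: list with `replicates` (per
#'   replicate, a named list of conditions, each a named list of per-base
#'   coverage vectors), `mouse_fpkm` (data frame transcript_id, rep1,
#'   rep2), `counts` (base fragment counts per replicate) and `truth`.
#' @export
simulate_dilution_experiment <- function(models, truth, cfg) {
  ratios <- dilution_conditions()
  ids <- names(models)
  replicates <- list()
  counts <- list()
  for (rep_i in 1:2) {
    base <- simulate_fragment_coverage(models, truth$weights, cfg,
                                       seed = cfg$seed + rep_i)
    conds <- list()
    for (cond in names(ratios)) {
      cov <- lapply(base$coverage, function(v) v * ratios[[cond]])
      if (cond != "mouse_only" && nrow(truth$hunc) > 0) {
        for (j in seq_len(nrow(truth$hunc))) {
          h <- truth$hunc[j, ]
          cov[[h$transcript_id]] <- apply_hunc_multiplier(
            cov[[h$transcript_id]], h$start, h$end, h[[cond]])
        }
      }
      if (cond == "mouse_only" && nrow(truth$decoys) > 0) {
        for (j in seq_len(nrow(truth$decoys))) {
          d <- truth$decoys[j, ]
          v <- cov[[d$transcript_id]]
          if (d$type == "fpkm") {
            v <- v + d$depth
          } else {
            lo <- max(0L, d$spike_start)
            hi <- min(length(v), d$spike_end)
            v[(lo + 1L):hi] <- v[(lo + 1L):hi] + d$depth
          }
          cov[[d$transcript_id]] <- v
        }
      }
      conds[[cond]] <- cov
    }
    replicates[[rep_i]] <- conds
    counts[[rep_i]] <- base$counts
  }
  mouse_fpkm <- data.frame(transcript_id = ids,
                           rep1 = 0, rep2 = 0, stringsAsFactors = FALSE)
  if (nrow(truth$decoys) > 0) {
    m <- match(truth$decoys$transcript_id, mouse_fpkm$transcript_id)
    mouse_fpkm$rep1[m] <- truth$decoys$mouse_fpkm
    mouse_fpkm$rep2[m] <- truth$decoys$mouse_fpkm
  }
  structure(list(replicates = replicates, mouse_fpkm = mouse_fpkm,
                 counts = counts, truth = truth),
            class = "dilution_series")
}

#' Write simulated truth records to TSV
#'
#' @param truth A `sim_truth` record.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  utils::write.table(truth$hunc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
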