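#' Local-alignment scoring scheme
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (<= 0).
#' @param gap Linear per-base gap penalty (<= 0).
#' @return An `align_scoring` list.
#' @export
align_scoring <- function(match = 2, mismatch = -1, gap = -2) {
  stopifnot(match > 0, mismatch <= 0, gap <= 0)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "align_scoring")
}

#' Hexamer Shannon entropy of a sequence
#'
#' Counts all overlapping hexamers (step 1), converts the counts to
#' frequencies, and returns the Shannon entropy
#' `H = -sum(p * log2(p))` over observed hexamers, in bits. A measure of
#' sequence complexity: low entropy indicates repeat-rich sequence. The
#' maximum is `log2(4096) = 12` bits. Hexamer windows containing letters
#' outside A/C/G/T are skipped.
#'
#' @param seq Nucleotide string, length >= 6.
#' @return Entropy in bits.
#' @export
hexamer_entropy <- function(seq) {
  if (nchar(seq) < 6) stop("sequence shorter than one hexamer")
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = 6L)
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("no A/C/G/T hexamers in sequence")
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' GC fraction of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; letters outside A/C/G/T are excluded
#' from the denominator.
#'
#' @param seq Nucleotide string.
#' @return Fraction in `[0, 1]`, or `NA` if the sequence has no A/C/G/T.
#' @export
gc_fraction <- function(seq) {
  if (nchar(seq) == 0) stop("empty sequence")
  f <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                   c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  unname((f[["C"]] + f[["G"]]) / tot)
}

#' Smith-Waterman local alignment score
#'
#' Best local-alignment score between two sequences under a linear gap
#' penalty, computed with [Biostrings::pairwiseAlignment()] and floored at
#' 0 (the empty local alignment).
#'
#' @param a,b Nucleotide strings.
#' @param scoring An [align_scoring()] scheme.
#' @return Maximum local alignment score (>= 0).
#' @export
smith_waterman_score <- function(a, b, scoring = align_scoring()) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  sc <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = abs(scoring$gap), scoreOnly = TRUE)
  max(0, sc)
}

#' Best local-alignment score of a transcript against rRNA references
#'
#' Strand-agnostic: the maximum [smith_waterman_score()] over every
#' reference, for the transcript and its reverse complement. In practice
#' the references are the 45S and 5S rRNA sequences targeted by depletion
#' probes.
#'
#' @param seq Transcript sequence.
#' @param rrna_refs Character vector (or `DNAStringSet`) of reference
#'   sequences, length >= 1.
#' @param scoring An [align_scoring()] scheme.
#' @return Best score over references and strands.
#' @export
rrna_similarity <- function(seq, rrna_refs, scoring = align_scoring()) {
  refs <- as.character(rrna_refs)
  if (length(refs) == 0) stop("no rRNA reference sequences supplied")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  max(vapply(refs, function(r) {
    max(smith_waterman_score(seq, r, scoring),
        smith_waterman_score(rc, r, scoring))
  }, 0))
}

#' Per-transcript coverage drop between two libraries
#'
#' Quantifies the loss of coverage between a no-selection library and an
#' rRNA-depleted library. Each sample is first scaled so that its pooled
#' mean depth over all transcripts is 1 (library-size normalization); the
#' per-transcript drop is then `max(0, 1 - depleted mean / no-selection
#' mean)`. A drop of 1 means coverage vanished after depletion; 0 means no
#' difference.
#'
#' @param no_sel,depleted Named lists of per-base coverage vectors over the
#'   same transcripts.
#' @return Named numeric vector of drop scores in `[0, 1]`; `NA` where the
#'   no-selection mean is 0.
#' @export
coverage_drop <- function(no_sel, depleted) {
  ids <- names(no_sel)
  stopifnot(setequal(ids, names(depleted)))
  depleted <- depleted[ids]
  stopifnot(all(lengths(no_sel) == lengths(depleted)))
  s_ns <- mean(unlist(no_sel, use.names = FALSE))
  s_dep <- mean(unlist(depleted, use.names = FALSE))
  if (s_ns == 0) stop("no-selection library has zero coverage overall")
  vapply(ids, function(id) {
    m_ns <- mean(no_sel[[id]]) / s_ns
    if (m_ns == 0) return(NA_real_)
    m_dep <- if (s_dep == 0) 0 else mean(depleted[[id]]) / s_dep
    max(0, 1 - m_dep / m_ns)
  }, 0)
}

#' Sequence-feature table for a transcript set
#'
#' @param sequences Named character vector or `DNAStringSet` of transcript
#'   sequences.
#' @param rrna_refs rRNA reference sequences for [rrna_similarity()];
#'   `NULL` to skip the alignment column.
#' @param scoring An [align_scoring()] scheme.
#' @return Data frame with columns `transcript_id`, `hexamer_entropy`,
#'   `gc_fraction` and (if references are given) `rrna_score`.
#' @export
sequence_feature_table <- function(sequences, rrna_refs = NULL,
                                   scoring = align_scoring()) {
  seqs <- as.character(sequences)
  df <- data.frame(
    transcript_id = names(seqs),
    hexamer_entropy = vapply(seqs, hexamer_entropy, 0),
    gc_fraction = vapply(seqs, gc_fraction, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(rrna_refs)) {
    df$rrna_score <- vapply(seqs, rrna_similarity, 0, rrna_refs = rrna_refs,
                            scoring = scoring)
  }
  df
}
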