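#' Read a bedGraph coverage track
#'
#' Parses a 4-column bedGraph file (chrom, start, end, depth; 0-based,
#' half-open) into a [genome_coverage] track. `track`, `browser` and `#`
#' comment lines are skipped. Intervals on a chromosome must be
#' non-overlapping; depth may be fractional (normalized tracks) but never
#' negative.
#'
#' @param path Path to a bedGraph file.
#' @return A `genome_coverage` object: a data frame of intervals with
#'   columns `chrom`, `start`, `end`, `depth`, sorted by chrom and start.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(genome_coverage(empty_track_df()))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- idx[which(nf != 4L)[1L]]
    stop("malformed bedGraph line ", bad, ": expected 4 fields, got ",
         nf[which(nf != 4L)[1L]])
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  depth <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start >= end | is.na(depth) | depth < 0)
  if (length(bad) > 0L) {
    stop("malformed bedGraph line ", idx[bad[1L]],
         ": coordinates must be integers with start < end and depth >= 0")
  }
  df <- data.frame(chrom = m[, 1L], start = as.integer(start),
                   end = as.integer(end), depth = depth,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop("bedGraph format error: overlapping intervals on ", ch)
    }
  }
  genome_coverage(df)
}

empty_track_df <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             depth = numeric(), stringsAsFactors = FALSE)
}

#' Construct a genome coverage track
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`, `depth`
#'   (0-based, half-open, non-overlapping within a chromosome).
#' @return A `genome_coverage` object.
#' @export
genome_coverage <- function(intervals) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end", "depth") %in% names(intervals)))
  if (nrow(intervals) > 0) {
    stopifnot(all(intervals$start < intervals$end),
              all(intervals$depth >= 0))
  }
  structure(intervals, class = c("genome_coverage", "data.frame"))
}

#' Write a coverage track as bedGraph
#'
#' Inverse of [read_bedgraph()]: writing then re-reading reproduces the same
#' per-base depths.
#'
#' @param track A `genome_coverage` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- as.data.frame(track)
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end,
                   format(df$depth, trim = TRUE, scientific = FALSE,
                          drop0trailing = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from a BED12 file
#'
#' Each BED12 line becomes one transcript model: exon structure from the
#' block columns, strand from column 6, transcript length equal to the sum
#' of block sizes. Transcript-space position 0 is the 5' end (leftmost base
#' of the first exon on `+`, rightmost base of the last exon on `-`).
#'
#' @param path Path to a BED12 file.
#' @return A `transcript_models` object: a named list of `transcript_model`
#'   entries, each a list with `transcript_id`, `chrom`, `strand`,
#'   `exons` (data frame of genomic `start`/`end`, 0-based half-open,
#'   sorted) and `length`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("BED12 file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  models <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    f <- strsplit(trimws(lines[idx[j]]), "\t| +")[[1L]]
    if (length(f) < 12L) {
      stop("BED12 format error at line ", idx[j], ": expected 12 fields")
    }
    chrom_start <- as.integer(f[2L])
    chrom_end <- as.integer(f[3L])
    n_blocks <- as.integer(f[10L])
    sizes <- as.integer(strsplit(sub(",$", "", f[11L]), ",")[[1L]])
    starts <- as.integer(strsplit(sub(",$", "", f[12L]), ",")[[1L]])
    if (length(sizes) != n_blocks || length(starts) != n_blocks) {
      stop("BED12 format error at line ", idx[j],
           ": blockCount does not match blockSizes/blockStarts")
    }
    ex_start <- chrom_start + starts
    ex_end <- ex_start + sizes
    if (any(ex_end > chrom_end)) {
      stop("BED12 format error at line ", idx[j],
           ": blocks extend past chromEnd")
    }
    models[[j]] <- transcript_model(
      transcript_id = f[4L], chrom = f[1L], strand = f[6L],
      exons = data.frame(start = ex_start, end = ex_end)
    )
  }
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  structure(models, class = "transcript_models")
}

#' Construct a transcript model
#'
#' @param transcript_id Transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame of genomic exon intervals (`start`, `end`;
#'   0-based half-open), non-overlapping.
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1,
            all(exons$end > exons$start))
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("transcript model '", transcript_id, "': overlapping exons")
  }
  structure(
    list(transcript_id = transcript_id, chrom = chrom, strand = strand,
         exons = exons, length = as.integer(sum(exons$end - exons$start))),
    class = "transcript_model"
  )
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models: ", length(x), " models\n", sep = "")
  invisible(x)
}

models_as_granges <- function(models) {
  ex <- do.call(rbind, lapply(models, function(m) {
    data.frame(chrom = m$chrom, start = m$exons$start, end = m$exons$end,
               id = m$transcript_id, stringsAsFactors = FALSE)
  }))
  GenomicRanges::GRanges(ex$chrom,
                         IRanges::IRanges(ex$start + 1L, ex$end),
                         transcript_id = ex$id)
}

#' Find transcripts whose models overlap another model
#'
#' Overlap means any shared genomic base on the same chromosome, on either
#' strand. Used to exclude IVT transcripts at overlapping loci before
#' coverage analysis.
#'
#' @param models A `transcript_models` object.
#' @return Character vector of transcript ids involved in at least one
#'   overlap.
#' @export
overlapping_transcripts <- function(models) {
  if (length(models) < 2L) return(character())
  gr <- models_as_granges(models)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ids_q <- gr$transcript_id[qh]
  ids_s <- gr$transcript_id[sh]
  sort(unique(ids_q[ids_q != ids_s]))
}

#' Exclude transcripts from a model set
#'
#' Removes transcripts by id, e.g. those aligning to multiple loci or
#' overlapping other control transcripts, before any coverage statistic is
#' computed.
#'
#' @param models A `transcript_models` object.
#' @param remove_ids Character vector of transcript ids to drop.
#' @return The filtered `transcript_models` object.
#' @export
exclude_transcripts <- function(models, remove_ids) {
  keep <- setdiff(names(models), remove_ids)
  structure(models[keep], class = "transcript_models")
}

chrom_depth_rle <- function(track, chrom, min_width) {
  df <- as.data.frame(track)
  sub <- df[df$chrom == chrom, , drop = FALSE]
  width <- max(min_width, if (nrow(sub)) max(sub$end) else 0L)
  if (nrow(sub) == 0L) {
    return(S4Vectors::Rle(0, width))
  }
  IRanges::coverage(IRanges::IRanges(sub$start + 1L, sub$end),
                    weight = sub$depth, width = width)
}

#' Project genome-space coverage into transcript space
#'
#' Walks the model's exons 5' to 3' and collects the per-base genomic depth;
#' intronic coverage is ignored. For `-` strand models the exon walk is
#' reversed, so element 1 of the result is always the 5' end. A chromosome
#' absent from the track yields all-zero coverage with a warning (expected
#' for background-only samples).
#'
#' @param track A `genome_coverage` object.
#' @param model A `transcript_model`.
#' @return Numeric vector of per-base depths, length `model$length`,
#'   oriented 5' to 3'.
#' @export
project_to_transcript <- function(track, model) {
  df <- as.data.frame(track)
  if (!(model$chrom %in% df$chrom)) {
    warning("chromosome ", model$chrom, " absent from track; transcript ",
            model$transcript_id, " gets zero coverage")
    return(numeric(model$length))
  }
  rle <- chrom_depth_rle(track, model$chrom, max(model$exons$end))
  pieces <- lapply(seq_len(nrow(model$exons)), function(i) {
    as.numeric(S4Vectors::window(rle, model$exons$start[i] + 1L,
                                 model$exons$end[i]))
  })
  depths <- unlist(pieces, use.names = FALSE)
  if (model$strand == "-") depths <- rev(depths)
  depths
}

#' Map a transcript-space interval back to genomic blocks
#'
#' Inverse of the exon walk used by [project_to_transcript()]. An interval
#' spanning an exon junction yields one genomic block per exon crossed.
#'
#' @param model A `transcript_model`.
#' @param start,end Transcript-space interval (0-based, half-open).
#' @return Data frame of genomic blocks (`start`, `end`), sorted by start.
#' @export
transcript_to_genome <- function(model, start, end) {
  if (start < 0 || end > model$length || start >= end) {
    stop("region [", start, ",", end, ") outside transcript bounds of ",
         model$transcript_id, " (length ", model$length, ")")
  }
  sizes <- model$exons$end - model$exons$start
  # exon order along the transcript (5'->3')
  ord <- if (model$strand == "+") seq_len(nrow(model$exons)) else
    rev(seq_len(nrow(model$exons)))
  offs <- cumsum(c(0L, sizes[ord]))[seq_along(ord)]
  blocks <- list()
  for (k in seq_along(ord)) {
    i <- ord[k]
    lo <- max(start, offs[k])
    hi <- min(end, offs[k] + sizes[i])
    if (lo >= hi) next
    if (model$strand == "+") {
      gs <- model$exons$start[i] + (lo - offs[k])
      ge <- gs + (hi - lo)
    } else {
      ge <- model$exons$end[i] - (lo - offs[k])
      gs <- ge - (hi - lo)
    }
    blocks[[length(blocks) + 1L]] <- c(gs, ge)
  }
  out <- do.call(rbind, blocks)
  out <- data.frame(start = out[, 1L], end = out[, 2L])
  out[order(out$start), , drop = FALSE]
}

#' Write called regions to a BED6 file
#'
#' Regions are given in transcript space and inverse-projected to genomic
#' coordinates; a region spanning an exon junction produces one BED line per
#' genomic block. The score column carries the region's mean windowed MAD
#' scaled to 0--1000.
#'
#' @param regions Data frame with columns `transcript_id`, `start`, `end`
#'   (transcript space) and `mean_mad`, e.g. the `regions` element of
#'   [call_hunc_regions()].
#' @param models A `transcript_models` object covering every region.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(regions, models, path) {
  lines <- "# hunc regions (BED6); score = mean windowed MAD scaled to [0,1000]"
  if (nrow(regions) > 0) {
    for (i in seq_len(nrow(regions))) {
      id <- regions$transcript_id[i]
      model <- models[[id]]
      if (is.null(model)) stop("no model for transcript ", id)
      blocks <- transcript_to_genome(model, regions$start[i], regions$end[i])
      score <- min(1000L, max(0L, as.integer(round(regions$mean_mad[i] * 1000))))
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%d\t%s", model$chrom,
                                blocks$start, blocks$end,
                                sprintf("%s:%d-%d", id, regions$start[i],
                                        regions$end[i]),
                                score, model$strand))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcript-level FPKM table
#'
#' @param path Tab-delimited file with header columns `transcript_id`,
#'   `sample`, `fpkm`.
#' @return Data frame with those columns.
#' @export
read_fpkm_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "sample", "fpkm")
  if (!all(need %in% names(df))) {
    stop("FPKM table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$fpkm < 0)) stop("FPKM values must be >= 0")
  df
}
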