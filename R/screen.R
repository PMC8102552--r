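#' Construct a splice-site score track
#'
#' Per-position splice acceptor and donor probabilities in [0, 1], as
#' produced by sequence-based splice-site predictors.  The track is an
#' input to the screen; this package never computes the scores itself.
#'
#' @param contig Contig name (recycled).
#' @param position 1-based genomic positions, strictly increasing within
#'   a contig/strand.
#' @param strand `"+"` or `"-"` (recycled).
#' @param acceptor_score,donor_score Numeric vectors in [0, 1].
#' @return A data frame of class `splice_score_track`.
#' @export
splice_score_track <- function(contig, position, strand, acceptor_score, donor_score) {
  df <- data.frame(contig = contig, position = as.integer(position),
                   strand = strand, acceptor_score = acceptor_score,
                   donor_score = donor_score, stringsAsFactors = FALSE)
  validate_score_track(df)
  df <- df[order(df$contig, df$strand, df$position), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("splice_score_track", "data.frame")
  df
}

validate_score_track <- function(df) {
  need <- c("contig", "position", "strand", "acceptor_score", "donor_score")
  if (!all(need %in% names(df))) {
    stopf("score track must have columns: %s", paste(need, collapse = ", "))
  }
  sc <- c(df$acceptor_score, df$donor_score)
  if (anyNA(sc) || any(sc < 0) || any(sc > 1)) {
    stopf("splice-site scores must lie in [0, 1]")
  }
  if (!all(df$strand %in% c("+", "-"))) stopf("track strand must be '+' or '-'")
  key <- paste(df$contig, df$strand)
  for (k in unique(key)) {
    p <- df$position[key == k]
    if (anyDuplicated(p)) stopf("duplicated track position on %s", k)
  }
  invisible(df)
}

#' Read a splice-site score track from TSV
#'
#' Expected columns: `contig`, `position`, `strand`, `acceptor_score`,
#' `donor_score`.
#'
#' @param path Path to a tab-separated file with header.
#' @return A `splice_score_track`.
#' @export
read_score_track <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  splice_score_track(df$contig, df$position, df$strand,
                     df$acceptor_score, df$donor_score)
}

#' Write a splice-site score track to TSV
#' @param track A `splice_score_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  write.table(as.data.frame(track), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify a splice-site score pair into a score band
#'
#' An exon needs both a functional acceptor and a functional donor, so the
#' band is determined by the smaller of the two scores: at least 0.9 is
#' called `constitutive`, from 0.1 up to (but excluding) 0.9 is
#' `alternative` (an exon under substantial alternative-splicing
#' regulation), and below 0.1 is `reject`.
#'
#' @param acceptor_score,donor_score Numeric vectors in [0, 1] (recycled
#'   to a common length).
#' @param lower,upper Band boundaries (defaults 0.1 and 0.9).
#' @return A character vector over `c("constitutive", "alternative", "reject")`.
#' @export
classify_band <- function(acceptor_score, donor_score, lower = 0.1, upper = 0.9) {
  sc <- c(acceptor_score, donor_score)
  if (anyNA(sc) || any(sc < 0) || any(sc > 1)) {
    stopf("splice-site scores must lie in [0, 1]")
  }
  m <- pmin(acceptor_score, donor_score)
  ifelse(m >= upper, "constitutive", ifelse(m >= lower, "alternative", "reject"))
}

#' Nominate novel intron-internal exon candidates from a score track
#'
#' For every annotated intron of every transcript, each pair of scored
#' positions with acceptor and donor scores at least `min_score`, with the
#' acceptor upstream of the donor in transcription order, and with a
#' resulting exon length within `[min_len, max_len]`, yields one
#' candidate.  All qualifying pairs are reported (no greedy selection);
#' annotated exon boundaries never participate because only positions
#' strictly inside introns are scanned.  Acceptor/donor orientation
#' follows the transcript strand: on the minus strand the acceptor lies
#' at the genomically higher coordinate.
#'
#' @param track A `splice_score_track`.
#' @param transcripts A list of [transcript_model] objects.
#' @param min_score Minimum score for both sites (default 0.1, the floor
#'   of the alternative band).
#' @param min_len,max_len Candidate exon length bounds (defaults 25 and
#'   500 nt).
#' @return A data frame of class `exon_candidates` with columns `contig`,
#'   `start`, `end`, `strand`, `length`, `acceptor_score`, `donor_score`,
#'   `band`, `gene_id`, `transcript_id`, `intron_start`, `intron_end`,
#'   sorted by genomic start.  Zero rows (with a warning) when the
#'   transcripts contain no introns.
#' @export
find_exon_candidates <- function(track, transcripts, min_score = 0.1,
                                 min_len = 25, max_len = 500) {
  validate_score_track(track)
  if (inherits(transcripts, "transcript_model")) transcripts <- list(transcripts)
  if (min_len < 1 || max_len < min_len) stopf("require 1 <= min_len <= max_len")
  if (min_score < 0 || min_score > 1) stopf("min_score must lie in [0, 1]")

  empty <- data.frame(contig = character(0), start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      acceptor_score = numeric(0), donor_score = numeric(0),
                      band = character(0), gene_id = character(0),
                      transcript_id = character(0), intron_start = integer(0),
                      intron_end = integer(0), stringsAsFactors = FALSE)

  any_introns <- FALSE
  out <- list()
  for (tm in transcripts) {
    introns <- transcript_introns(tm)
    if (nrow(introns) == 0L) next
    any_introns <- TRUE
    trk <- track[track$contig == tm$contig & track$strand == tm$strand, , drop = FALSE]
    if (nrow(trk) == 0L) next
    for (i in seq_len(nrow(introns))) {
      is0 <- introns$start[i]; ie0 <- introns$end[i]
      inside <- trk[trk$position >= is0 & trk$position <= ie0, , drop = FALSE]
      acc <- inside[inside$acceptor_score >= min_score, , drop = FALSE]
      don <- inside[inside$donor_score >= min_score, , drop = FALSE]
      if (nrow(acc) == 0L || nrow(don) == 0L) next
      for (a in seq_len(nrow(acc))) {
        for (d in seq_len(nrow(don))) {
          ap <- acc$position[a]; dp <- don$position[d]
          if (tm$strand == "+") {
            if (dp < ap) next
            cs <- ap; ce <- dp
          } else {
            if (ap < dp) next
            cs <- dp; ce <- ap
          }
          len <- ce - cs + 1L
          if (len < min_len || len > max_len) next
          out[[length(out) + 1L]] <- data.frame(
            contig = tm$contig, start = cs, end = ce, strand = tm$strand,
            length = len,
            acceptor_score = acc$acceptor_score[a],
            donor_score = don$donor_score[d],
            band = classify_band(acc$acceptor_score[a], don$donor_score[d]),
            gene_id = tm$gene_id, transcript_id = tm$transcript_id,
            intron_start = is0, intron_end = ie0,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!any_introns) {
    warnf("no annotated introns among the supplied transcripts")
    return(structure(empty, class = c("exon_candidates", "data.frame")))
  }
  if (length(out) == 0L) {
    return(structure(empty, class = c("exon_candidates", "data.frame")))
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[c("contig", "start", "end", "strand")]), , drop = FALSE]
  res <- res[order(res$contig, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("exon_candidates", "data.frame"))
}

#' Write exon candidates as BED6 and/or TSV
#'
#' BED output converts to the BED convention (0-based half-open); the BED
#' score column carries the candidate's minimum splice-site score scaled
#' to 0-1000.
#'
#' @param candidates An `exon_candidates` data frame.
#' @param bed,tsv Output paths (either may be `NULL` to skip).
#' @return Invisibly, a character vector of the paths written.
#' @export
write_candidates <- function(candidates, bed = NULL, tsv = NULL) {
  written <- character(0)
  if (!is.null(tsv)) {
    write.table(as.data.frame(candidates), tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, tsv)
  }
  if (!is.null(bed)) {
    if (nrow(candidates) == 0L) {
      writeLines(character(0), bed)
    } else {
      bed_df <- data.frame(
        chrom = candidates$contig,
        chromStart = candidates$start - 1L,
        chromEnd = candidates$end,
        name = sprintf("%s_candidate_%d", candidates$gene_id, seq_len(nrow(candidates))),
        score = as.integer(round(1000 * pmin(candidates$acceptor_score,
                                             candidates$donor_score))),
        strand = candidates$strand)
      write.table(bed_df, bed, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
    written <- c(written, bed)
  }
  invisible(written)
}
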