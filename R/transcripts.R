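#' Construct a transcript model
#'
#' A transcript model is the substrate for event enumeration, splicing
#' quantification and translation: an ordered set of exons on one strand
#' of one contig, with optional CDS boundaries.  All coordinates are
#' 1-based and closed.  Exons are stored in genomic order; transcription
#' order is derived from the strand where needed.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of equal length; exons
#'   must be non-overlapping and separated by at least one intronic base.
#' @param cds_start,cds_end Genomic coordinates of the translated region
#'   (start codon boundary through stop codon boundary, genomic order).
#'   Both `NA` for non-coding models.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand,
                             exon_starts, exon_ends,
                             cds_start = NA_integer_, cds_end = NA_integer_) {
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) == 0L) {
    stopf("transcript '%s': exon_starts and exon_ends must be non-empty and of equal length",
          transcript_id)
  }
  ord <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[ord])
  exon_ends <- as.integer(exon_ends[ord])
  tm <- structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         contig = as.character(contig),
         strand = as.character(strand),
         exon_starts = exon_starts,
         exon_ends = exon_ends,
         cds_start = as.integer(cds_start),
         cds_end = as.integer(cds_end)),
    class = "transcript_model")
  validate_transcript_model(tm)
  tm
}

validate_transcript_model <- function(tm) {
  if (!tm$strand %in% c("+", "-")) {
    stopf("transcript '%s': strand must be '+' or '-'", tm$transcript_id)
  }
  s <- tm$exon_starts
  e <- tm$exon_ends
  if (any(is.na(s)) || any(is.na(e)) || any(s < 1L) || any(e < s)) {
    stopf("transcript '%s': malformed exon coordinates", tm$transcript_id)
  }
  if (length(s) > 1L && any(s[-1L] <= e[-length(e)] + 1L)) {
    stopf("transcript '%s': exons must be disjoint and separated by at least one intronic base",
          tm$transcript_id)
  }
  if (xor(is.na(tm$cds_start), is.na(tm$cds_end))) {
    stopf("transcript '%s': cds_start and cds_end must both be set or both NA",
          tm$transcript_id)
  }
  if (!is.na(tm$cds_start)) {
    if (tm$cds_start > tm$cds_end) {
      stopf("transcript '%s': cds_start must not exceed cds_end", tm$transcript_id)
    }
    for (p in c(tm$cds_start, tm$cds_end)) {
      if (!any(s <= p & p <= e)) {
        stopf("transcript '%s': CDS boundary %d falls outside the exon union",
              tm$transcript_id, p)
      }
    }
  }
  invisible(tm)
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "non-coding" else
    sprintf("CDS %d-%d", x$cds_start, x$cds_end)
  cat(sprintf("transcript_model %s (gene %s) %s:%s, %d exons, %s\n",
              x$transcript_id, x$gene_id, x$contig, x$strand,
              length(x$exon_starts), cds))
  invisible(x)
}

#' Number of exons in a transcript model
#' @param tm A `transcript_model`.
#' @return Integer exon count.
#' @export
n_exons <- function(tm) length(tm$exon_starts)

#' Introns of a transcript model
#'
#' @param tm A `transcript_model`.
#' @return A data frame with columns `start`, `end` (1-based closed,
#'   genomic order); zero rows for single-exon models.
#' @export
transcript_introns <- function(tm) {
  k <- n_exons(tm)
  if (k < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = tm$exon_ends[-k] + 1L, end = tm$exon_starts[-1L] - 1L)
}

#' Spliced (mature mRNA) length of a transcript model
#' @param tm A `transcript_model`.
#' @return Total exonic length in nucleotides.
#' @export
spliced_length <- function(tm) sum(tm$exon_ends - tm$exon_starts + 1L)

#' Spliced sequence of a transcript
#'
#' Exon sequences are concatenated in transcription order; minus-strand
#' transcripts are reverse-complemented.  The result has length equal to
#' the sum of the exon lengths.
#'
#' @param tm A `transcript_model`.
#' @param genome A named [Biostrings::DNAStringSet].
#' @return A character scalar (the mature mRNA, sense strand).
#' @export
spliced_sequence <- function(tm, genome) {
  pieces <- vapply(seq_len(n_exons(tm)), function(i) {
    genome_subseq(genome, tm$contig, tm$exon_starts[i], tm$exon_ends[i])
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (tm$strand == "-") s <- revcomp_chr(s)
  s
}

#' Map a genomic position to a spliced (transcript) coordinate
#'
#' @param tm A `transcript_model`.
#' @param gpos A genomic position that must fall within an exon.
#' @return The 1-based position of that base in the spliced transcript
#'   (transcription orientation).
#' @export
genomic_to_spliced <- function(tm, gpos) {
  hit <- which(tm$exon_starts <= gpos & gpos <= tm$exon_ends)
  if (length(hit) != 1L) {
    stopf("position %d is not exonic in transcript '%s'", gpos, tm$transcript_id)
  }
  widths <- tm$exon_ends - tm$exon_starts + 1L
  if (tm$strand == "+") {
    sum(widths[seq_len(hit - 1L)]) + (gpos - tm$exon_starts[hit]) + 1L
  } else {
    k <- n_exons(tm)
    downstream <- if (hit < k) sum(widths[(hit + 1L):k]) else 0L
    downstream + (tm$exon_ends[hit] - gpos) + 1L
  }
}

## spliced span (transcription orientation) of each exon; rows in
## transcription order with columns first, last, genomic index
exon_spliced_spans <- function(tm) {
  widths <- tm$exon_ends - tm$exon_starts + 1L
  idx <- if (tm$strand == "+") seq_len(n_exons(tm)) else rev(seq_len(n_exons(tm)))
  w <- widths[idx]
  last <- cumsum(w)
  data.frame(first = last - w + 1L, last = last, exon = idx)
}
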