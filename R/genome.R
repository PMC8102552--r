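#' Read a multi-contig genome from a FASTA file
#'
#' Contig names are truncated at the first whitespace, as is conventional
#' for FASTA headers.  The sequence alphabet is restricted to A, C, G, T
#' and N; any other letter is an error.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A named [Biostrings::DNAStringSet] with one element per contig.
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  validate_genome(genome)
  genome
}

#' Write a genome to a FASTA file
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  validate_genome(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

validate_genome <- function(genome) {
  if (!methods::is(genome, "DNAStringSet")) {
    stopf("genome must be a DNAStringSet (see read_genome_fasta)")
  }
  if (length(genome) == 0L) stopf("genome has no contigs")
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == "")) {
    stopf("all genome contigs must be named")
  }
  if (any(Biostrings::width(genome) == 0L)) stopf("genome contigs must be non-empty")
  ok <- Biostrings::letterFrequency(genome, letters = "ACGTN")
  bad <- Biostrings::width(genome) - as.vector(ok)
  if (any(bad > 0L)) {
    stopf("contig '%s' contains letters outside {A,C,G,T,N}",
          names(genome)[which(bad > 0L)[1L]])
  }
  invisible(genome)
}

#' Extract a genomic subsequence
#'
#' Coordinates are 1-based and closed; the returned string has exactly
#' `end - start + 1` characters.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param contig Contig name.
#' @param start,end 1-based closed coordinates, `start <= end`.
#' @return A character scalar.
#' @export
genome_subseq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) stopf("contig '%s' not present in genome", contig)
  if (!is_scalar_number(start) || !is_scalar_number(end) || start < 1 || end < start) {
    stopf("invalid coordinates: start=%s end=%s", format(start), format(end))
  }
  len <- length(genome[[contig]])
  if (end > len) {
    stopf("interval %d-%d extends beyond end of contig '%s' (length %d)",
          start, end, contig, len)
  }
  as.character(Biostrings::subseq(genome[[contig]], start, end))
}
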