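## small internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

DNA_BASES <- c("A", "C", "G", "T")

## all 61 sense (non-stop) codons, used by the generators
sense_codons <- function() {
  all <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  setdiff(all, STOP_CODONS)
}

## random DNA string of length n (uses the R RNG; callers manage seeding)
rand_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## n random non-stop codons as one string
rand_sense_codons <- function(n) {
  if (n <= 0) return("")
  paste(sample(sense_codons(), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
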