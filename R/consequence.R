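#' Insert a novel exon into a transcript model
#'
#' The novel exon must lie strictly inside one intron of the transcript;
#' the returned model carries it between the flanking exons.  The
#' annotated CDS boundaries are inherited for reference — the actual
#' reading frame after insertion is recomputed by
#' [annotate_orf_consequence].
#'
#' @param tm A [transcript_model].
#' @param novel_start,novel_end 1-based closed genomic coordinates of the
#'   novel exon.
#' @param suffix Appended to the transcript id of the variant (default
#'   `".var"`).
#' @return A new [transcript_model] with one additional exon.
#' @export
build_variant_transcript <- function(tm, novel_start, novel_end, suffix = ".var") {
  if (!is_scalar_number(novel_start) || !is_scalar_number(novel_end) ||
      novel_start > novel_end) {
    stopf("invalid novel exon coordinates")
  }
  introns <- transcript_introns(tm)
  inside <- which(introns$start <= novel_start & novel_end <= introns$end)
  if (length(inside) != 1L) {
    stopf("novel exon %d-%d is not strictly inside one intron of transcript '%s'",
          novel_start, novel_end, tm$transcript_id)
  }
  if (novel_start == introns$start[inside] && novel_end == introns$end[inside]) {
    stopf("novel exon %d-%d fills intron %d-%d completely; that is intron retention, not a novel exon",
          novel_start, novel_end, introns$start[inside], introns$end[inside])
  }
  ## keep at least one intronic base on each side so the variant still
  ## has two junctions around the novel exon
  if (novel_start == introns$start[inside] || novel_end == introns$end[inside]) {
    stopf("novel exon %d-%d touches an annotated exon boundary", novel_start, novel_end)
  }
  transcript_model(paste0(tm$transcript_id, suffix), tm$gene_id, tm$contig,
                   tm$strand,
                   c(tm$exon_starts, as.integer(novel_start)),
                   c(tm$exon_ends, as.integer(novel_end)),
                   tm$cds_start, tm$cds_end)
}

## spliced position of the translation start (first base of ATG) of a
## transcript in its own spliced coordinates
translation_start_spliced <- function(tm) {
  g <- if (tm$strand == "+") tm$cds_start else tm$cds_end
  genomic_to_spliced(tm, g)
}

## first-stop scan: codons of s starting at p0; returns list(index of
## first stop codon (NA if none), codon start positions)
first_stop_scan <- function(s, p0) {
  n_codons <- floor((nchar(s) - p0 + 1) / 3)
  if (n_codons <= 0L) return(list(stop_index = NA_integer_, starts = integer(0)))
  starts <- p0 + 3L * (seq_len(n_codons) - 1L)
  aa <- translate_string(substr(s, p0, p0 + 3L * n_codons - 1L))
  hit <- regexpr("*", aa, fixed = TRUE)
  list(stop_index = if (hit > 0L) as.integer(hit) else NA_integer_,
       starts = starts)
}

## translate a DNA string (length a multiple of 3) to one-letter amino
## acids; codons containing N become "X" and never read as stops
translate_string <- function(x) {
  if (nchar(x) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     if.fuzzy.codon = "X"))
}

#' Annotate the coding consequence of a novel exon insertion
#'
#' Translation starts at the canonical start codon mapped into the
#' variant's spliced sequence; the first stop codon encountered
#' determines the category:
#' \describe{
#'   \item{`ptc_in_novel_exon`}{the first stop codon overlaps the novel
#'     exon in the incoming reading frame; `added_codons_before_stop`
#'     counts the codons preceding it whose third base lies within the
#'     novel exon;}
#'   \item{`in_frame_addition`}{the exon length is a multiple of 3 and
#'     contains no stop in the incoming frame, so translation continues
#'     to the canonical stop with a peptide inserted;}
#'   \item{`frameshift_ptc`}{the exon length is not a multiple of 3 and
#'     the first novel stop lies downstream of the exon;}
#'   \item{`no_change`}{the exon was inserted into an untranslated-region
#'     intron, leaving the protein unchanged.}
#' }
#' A frameshifted open reading frame that runs off the transcript end
#' without a stop is reported as `frameshift_ptc` with an absent stop
#' position (nonstop decay is not modelled).
#'
#' NMD sensitivity follows the 50-nt rule (see [predict_nmd]); a domain
#' is reported lost exactly when its `aa_end` exceeds the truncated
#' protein length.
#'
#' @param variant The variant [transcript_model] (canonical exons plus
#'   one novel exon, e.g. from [build_variant_transcript]).
#' @param canonical The canonical [transcript_model] with a valid CDS
#'   (starts ATG, length a multiple of 3, ends at a stop).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param domains Optional data frame with columns `domain_name`,
#'   `aa_start`, `aa_end` on the canonical protein.
#' @param rule_distance NMD last-junction rule distance in nt (default 50).
#' @return An object of class `orf_consequence`: a list with `category`,
#'   `added_codons_before_stop`, `ptc_spliced_position` (first base of
#'   the premature stop in variant spliced coordinates),
#'   `distance_ptc_to_last_junction`, `nmd_sensitive`,
#'   `truncated_protein_length`, `lost_domains`, `novel_exon`
#'   (genomic start/end) and `canonical_protein_length`.
#' @export
annotate_orf_consequence <- function(variant, canonical, genome, domains = NULL,
                                     rule_distance = 50) {
  if (variant$gene_id != canonical$gene_id ||
      variant$contig != canonical$contig ||
      variant$strand != canonical$strand) {
    stopf("variant and canonical transcripts must share gene, contig and strand")
  }
  if (is.na(canonical$cds_start)) stopf("canonical transcript has no CDS")

  ## validate the canonical CDS: ATG ... stop, length a multiple of 3
  can_seq <- spliced_sequence(canonical, genome)
  p0_can <- translation_start_spliced(canonical)
  can_cds_len <- spliced_length(canonical) -
    (p0_can - 1L) -
    (spliced_length(canonical) - genomic_to_spliced(
      canonical, if (canonical$strand == "+") canonical$cds_end else canonical$cds_start))
  if (can_cds_len %% 3L != 0L) {
    stopf("canonical CDS of '%s' has length %d, not a multiple of 3",
          canonical$transcript_id, can_cds_len)
  }
  can_cds <- substr(can_seq, p0_can, p0_can + can_cds_len - 1L)
  if (substr(can_cds, 1L, 3L) != "ATG") {
    stopf("canonical CDS of '%s' does not begin with ATG", canonical$transcript_id)
  }
  if (!substr(can_cds, can_cds_len - 2L, can_cds_len) %in% STOP_CODONS) {
    stopf("canonical CDS of '%s' does not end at a stop codon", canonical$transcript_id)
  }
  canonical_protein_length <- as.integer(can_cds_len / 3L) - 1L

  ## identify the novel exon as the exon of the variant absent from the
  ## canonical model
  key_can <- paste(canonical$exon_starts, canonical$exon_ends)
  key_var <- paste(variant$exon_starts, variant$exon_ends)
  extra <- which(!(key_var %in% key_can))
  if (length(extra) != 1L) {
    stopf("variant must differ from canonical by exactly one novel exon (found %d)",
          length(extra))
  }
  nov_s <- variant$exon_starts[extra]
  nov_e <- variant$exon_ends[extra]
  exon_len <- nov_e - nov_s + 1L

  S <- spliced_sequence(variant, genome)
  p0 <- translation_start_spliced(variant)
  b1 <- genomic_to_spliced(variant, if (variant$strand == "+") nov_s else nov_e)
  b2 <- b1 + exon_len - 1L

  base <- list(category = NA_character_,
               added_codons_before_stop = NA_integer_,
               ptc_spliced_position = NA_integer_,
               distance_ptc_to_last_junction = NA_integer_,
               nmd_sensitive = FALSE,
               truncated_protein_length = NA_integer_,
               lost_domains = character(0),
               novel_exon = c(start = nov_s, end = nov_e),
               canonical_protein_length = canonical_protein_length,
               gene_id = variant$gene_id,
               transcript_id = variant$transcript_id)

  ## insertion outside the translated region leaves the protein unchanged
  ## (an exon past the canonical stop cannot shift it, so no length
  ## correction is needed for the comparison below)
  q_can_in_var <- p0 + can_cds_len - 3L
  if (b2 < p0 || b1 > q_can_in_var + 2L) {
    base$category <- "no_change"
    base$truncated_protein_length <- canonical_protein_length
    if (b2 < p0) {
      warnf("novel exon %d-%d lies in an untranslated-region intron of '%s'; protein unchanged",
            nov_s, nov_e, variant$gene_id)
    }
    return(structure(base, class = "orf_consequence"))
  }

  scan <- first_stop_scan(S, p0)
  spans <- exon_spliced_spans(variant)
  last_junction <- spans$last[nrow(spans) - 1L]

  finish <- function(x) {
    if (!is.null(domains) && nrow(domains) > 0L &&
        !is.na(x$truncated_protein_length)) {
      x$lost_domains <- domains$domain_name[domains$aa_end > x$truncated_protein_length]
    }
    structure(x, class = "orf_consequence")
  }

  if (is.na(scan$stop_index)) {
    ## ran off the transcript end without a stop: only possible after a
    ## frameshift (the canonical frame always reaches its stop)
    base$category <- "frameshift_ptc"
    base$truncated_protein_length <- as.integer(length(scan$starts))
    return(finish(base))
  }

  q <- scan$starts[scan$stop_index]
  base$truncated_protein_length <- as.integer(scan$stop_index - 1L)

  if (q <= b2 && (q + 2L) >= b1) {
    ## first stop overlaps the novel exon in the incoming frame
    before <- scan$starts[seq_len(scan$stop_index - 1L)]
    third <- before + 2L
    base$category <- "ptc_in_novel_exon"
    base$added_codons_before_stop <- sum(third >= b1 & third <= b2)
  } else if (exon_len %% 3L == 0L) {
    base$category <- "in_frame_addition"
    return(finish(base))
  } else {
    base$category <- "frameshift_ptc"
  }
  base$ptc_spliced_position <- as.integer(q)
  base$distance_ptc_to_last_junction <- as.integer(last_junction - (q + 2L))
  out <- finish(base)
  out$nmd_sensitive <- predict_nmd(out, rule_distance)
  out
}

#' @export
print.orf_consequence <- function(x, ...) {
  cat(sprintf("orf_consequence (%s): %s\n", x$gene_id, x$category))
  if (x$category == "ptc_in_novel_exon") {
    cat(sprintf("  added codons before stop: %d\n", x$added_codons_before_stop))
  }
  if (!is.na(x$ptc_spliced_position)) {
    cat(sprintf("  PTC at spliced position %d (%d nt upstream of last junction); NMD-sensitive: %s\n",
                x$ptc_spliced_position, x$distance_ptc_to_last_junction,
                x$nmd_sensitive))
  }
  cat(sprintf("  truncated protein: %d aa (canonical %d aa); lost domains: %s\n",
              x$truncated_protein_length, x$canonical_protein_length,
              if (length(x$lost_domains)) paste(x$lost_domains, collapse = ", ") else "none"))
  invisible(x)
}

#' Predict NMD sensitivity by the 50-nt last-junction rule
#'
#' A PTC-bearing transcript is predicted NMD-sensitive when the premature
#' stop codon lies more than `rule_distance` nucleotides upstream of the
#' final exon–exon junction (strict inequality); a stop in the last exon
#' is never NMD-sensitive.
#'
#' @param consequence An `orf_consequence` whose category involves a PTC.
#' @param rule_distance Rule distance in nucleotides (default 50).
#' @return Logical.
#' @export
predict_nmd <- function(consequence, rule_distance = 50) {
  if (!inherits(consequence, "orf_consequence")) stopf("not an orf_consequence")
  if (!consequence$category %in% c("ptc_in_novel_exon", "frameshift_ptc")) {
    stopf("NMD prediction applies only to PTC-bearing categories (got '%s')",
          consequence$category)
  }
  if (is.na(consequence$distance_ptc_to_last_junction)) {
    stopf("no stop codon position available for NMD prediction")
  }
  consequence$distance_ptc_to_last_junction > rule_distance
}

#' PTC versus in-frame fractions among exon-gain consequences
#'
#' @param consequences A list of `orf_consequence` objects for
#'   significant exon-gain events.
#' @return A list with `ptc_fraction` (categories `ptc_in_novel_exon`
#'   plus `frameshift_ptc`), `in_frame_fraction`, the separate
#'   `ptc_in_novel_exon_fraction` and `frameshift_ptc_fraction`,
#'   `n_classified` and the raw category `counts`.  Fractions are over
#'   classified events (category `no_change` is excluded) and sum to 1.
#' @export
ptc_fraction <- function(consequences) {
  if (length(consequences) == 0L) stopf("no consequences supplied")
  cats <- vapply(consequences, `[[`, character(1), "category")
  counts <- table(factor(cats, levels = c("ptc_in_novel_exon", "frameshift_ptc",
                                          "in_frame_addition", "no_change")))
  n_classified <- sum(counts[c("ptc_in_novel_exon", "frameshift_ptc",
                               "in_frame_addition")])
  if (n_classified == 0L) stopf("no classified (coding-region) consequences supplied")
  list(ptc_fraction = unname((counts[["ptc_in_novel_exon"]] +
                                counts[["frameshift_ptc"]]) / n_classified),
       in_frame_fraction = unname(counts[["in_frame_addition"]] / n_classified),
       ptc_in_novel_exon_fraction = unname(counts[["ptc_in_novel_exon"]] / n_classified),
       frameshift_ptc_fraction = unname(counts[["frameshift_ptc"]] / n_classified),
       n_classified = as.integer(n_classified),
       counts = counts)
}

#' Estimate stage-wise NMD efficiency from a translation-inhibitor assay
#'
#' Blocking translation blocks NMD, so the ratio of untreated to treated
#' steady-state abundance of a PTC-bearing transcript measures how much
#' of it NMD removes: `efficiency = 1 - untreated/treated`, clipped to
#' [0, 1).  Replicates are averaged per arm before forming the ratio.
#' Stages whose efficiency falls below `low_nmd_threshold` are flagged as
#' low-NMD.
#'
#' @param assay A data frame with columns `stage`, `replicate`, `treated`
#'   (0 = untreated, 1 = inhibitor-treated) and `abundance` (positive,
#'   arbitrary units).
#' @param low_nmd_threshold Efficiency below which a stage is flagged
#'   (default 0.2).
#' @return A data frame with one row per stage (input order preserved):
#'   `stage`, `abundance_untreated`, `abundance_treated`, `efficiency`,
#'   `flagged_low_nmd`.
#' @export
estimate_nmd_efficiency <- function(assay, low_nmd_threshold = 0.2) {
  need <- c("stage", "replicate", "treated", "abundance")
  if (!all(need %in% names(assay))) {
    stopf("assay must have columns: %s", paste(need, collapse = ", "))
  }
  if (anyNA(assay$abundance) || any(assay$abundance <= 0)) {
    stopf("all abundances must be positive")
  }
  if (!all(assay$treated %in% c(0L, 1L))) stopf("treated must be 0 or 1")
  stages <- unique(assay$stage)
  rows <- lapply(stages, function(st) {
    sub <- assay[assay$stage == st, , drop = FALSE]
    u <- sub$abundance[sub$treated == 0L]
    t <- sub$abundance[sub$treated == 1L]
    if (length(u) == 0L || length(t) == 0L) {
      stopf("stage '%s' needs both treated and untreated measurements", st)
    }
    eff <- min(max(0, 1 - mean(u) / mean(t)), 1 - .Machine$double.eps)
    data.frame(stage = st, abundance_untreated = mean(u),
               abundance_treated = mean(t), efficiency = eff,
               flagged_low_nmd = eff < low_nmd_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a translation-inhibitor assay table
#'
#' Expected columns: `stage`, `replicate`, `treated` (0/1), `abundance`.
#'
#' @param path Path to a tab-separated file with header.
#' @return The validated data frame.
#' @export
read_nmd_assay <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("stage", "replicate", "treated", "abundance")
  if (!all(need %in% names(df))) {
    stopf("assay table '%s' must have columns: %s", path, paste(need, collapse = ", "))
  }
  df
}
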