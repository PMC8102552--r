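#' Read transcript models from a GFF3 file
#'
#' Expects the conventional gene -> mRNA -> exon/CDS hierarchy with
#' 1-based closed coordinates (the GFF3 standard).  Coordinates are kept
#' 1-based closed internally, so no conversion is applied.  Exons are
#' sorted genomically and all `transcript_model` invariants are enforced;
#' a CDS segment that is not contained in an exon of its transcript is a
#' validation error.
#'
#' @param path Path to a GFF3 file.
#' @return A list of [transcript_model] objects.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stopf("GFF3 file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  feature_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(feature_lines) == 0L) {
    warnf("GFF3 file '%s' contains no features; returning an empty list", path)
    return(list())
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))
  df$type <- as.character(df$type)

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  parts <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(mrnas) == 0L) stopf("GFF3 file '%s' contains no mRNA/transcript features", path)

  orphan <- !(mrnas$Parent %in% genes$ID) & !is.na(mrnas$Parent)
  if (nrow(genes) > 0L && any(orphan)) {
    stopf("mRNA feature '%s' references unknown gene parent '%s'",
          mrnas$ID[orphan][1L], mrnas$Parent[orphan][1L])
  }
  bad_part <- is.na(parts$Parent) | !(parts$Parent %in% mrnas$ID)
  if (any(bad_part)) {
    off <- parts[bad_part, , drop = FALSE][1L, ]
    stopf("%s feature at %s:%d-%d has no mRNA parent in this file",
          off$type, off$seqnames, off$start, off$end)
  }

  lapply(seq_len(nrow(mrnas)), function(i) {
    m <- mrnas[i, ]
    ex <- parts[parts$Parent == m$ID & parts$type == "exon", , drop = FALSE]
    cds <- parts[parts$Parent == m$ID & parts$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) stopf("mRNA '%s' has no exon features", m$ID)
    cds_start <- NA_integer_
    cds_end <- NA_integer_
    if (nrow(cds) > 0L) {
      cds_start <- min(cds$start)
      cds_end <- max(cds$end)
      contained <- vapply(seq_len(nrow(cds)), function(j) {
        any(ex$start <= cds$start[j] & cds$end[j] <= ex$end)
      }, logical(1))
      if (!all(contained)) {
        stopf("CDS segment %d-%d of mRNA '%s' lies outside its exons",
              cds$start[which(!contained)[1L]], cds$end[which(!contained)[1L]], m$ID)
      }
    }
    gene_id <- if (!is.na(m$Parent)) m$Parent else as.character(m$ID)
    transcript_model(as.character(m$ID), gene_id, as.character(m$seqnames),
                     as.character(m$strand), ex$start, ex$end,
                     cds_start, cds_end)
  })
}

#' Write transcript models to a GFF3 file
#'
#' Emits a gene -> mRNA -> exon/CDS hierarchy.  CDS segments are the
#' per-exon intersections of the CDS span with the exons, with phase
#' computed in transcription order.
#'
#' @param transcripts A list of [transcript_model] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(transcripts, path) {
  if (length(transcripts) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rows <- list()
  add <- function(contig, start, end, strand, type, id, parent, phase = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = contig, start = start, end = end, strand = strand,
      type = type, ID = id, Parent = parent, phase = phase,
      stringsAsFactors = FALSE)
  }
  gene_ids <- unique(vapply(transcripts, `[[`, character(1), "gene_id"))
  for (g in gene_ids) {
    tms <- Filter(function(t) t$gene_id == g, transcripts)
    add(tms[[1L]]$contig,
        min(vapply(tms, function(t) min(t$exon_starts), integer(1))),
        max(vapply(tms, function(t) max(t$exon_ends), integer(1))),
        tms[[1L]]$strand, "gene", g, NA_character_)
    for (tm in tms) {
      add(tm$contig, min(tm$exon_starts), max(tm$exon_ends), tm$strand,
          "mRNA", tm$transcript_id, g)
      for (i in seq_len(n_exons(tm))) {
        add(tm$contig, tm$exon_starts[i], tm$exon_ends[i], tm$strand, "exon",
            sprintf("%s.exon%d", tm$transcript_id, i), tm$transcript_id)
      }
      if (!is.na(tm$cds_start)) {
        seg_s <- pmax(tm$exon_starts, tm$cds_start)
        seg_e <- pmin(tm$exon_ends, tm$cds_end)
        keep <- which(seg_s <= seg_e)
        seg_s <- seg_s[keep]; seg_e <- seg_e[keep]
        ord <- if (tm$strand == "+") order(seg_s) else order(-seg_s)
        before <- c(0L, cumsum((seg_e - seg_s + 1L)[ord]))[seq_along(ord)]
        phase <- (3L - before %% 3L) %% 3L
        for (j in seq_along(ord)) {
          i <- ord[j]
          add(tm$contig, seg_s[i], seg_e[i], tm$strand, "CDS",
              sprintf("%s.cds%d", tm$transcript_id, j), tm$transcript_id,
              phase[j])
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$source <- "novexon"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA_character_, df$Parent)
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
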