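#' Pipeline configuration
#'
#' Collects the thresholds used across the pipeline stages; every value
#' is validated and errors name the offending field.
#'
#' @param bf_threshold Bayes-factor significance threshold (default 10).
#' @param band_lower,band_upper Splice-site score band boundaries
#'   (defaults 0.1 and 0.9).
#' @param min_score Minimum score for candidate nomination (default 0.1).
#' @param min_exon_len,max_exon_len Candidate exon length bounds.
#' @param nmd_rule_distance NMD last-junction rule distance in nt.
#' @param maintenance_margin PSI margin for persistence calls.
#' @param low_nmd_threshold Efficiency below which a stage is flagged.
#' @param stages Ordered stage names.
#' @param seed Integer seed for the simulation stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bf_threshold = 10, band_lower = 0.1,
                            band_upper = 0.9, min_score = 0.1,
                            min_exon_len = 25, max_exon_len = 500,
                            nmd_rule_distance = 50, maintenance_margin = 0.05,
                            low_nmd_threshold = 0.2,
                            stages = c("SG_und", "SG_diff", "SC_preL",
                                       "SC_pachy", "RS"),
                            seed = 1) {
  check <- function(value, field, lo, hi) {
    if (!is_scalar_number(value) || value < lo || value > hi) {
      stopf("invalid config value for '%s': %s", field, format(value))
    }
    value
  }
  cfg <- list(
    bf_threshold = check(bf_threshold, "bf_threshold", 1e-12, Inf),
    band_lower = check(band_lower, "band_lower", 0, 1),
    band_upper = check(band_upper, "band_upper", 0, 1),
    min_score = check(min_score, "min_score", 0, 1),
    min_exon_len = check(min_exon_len, "min_exon_len", 1, Inf),
    max_exon_len = check(max_exon_len, "max_exon_len", 1, Inf),
    nmd_rule_distance = check(nmd_rule_distance, "nmd_rule_distance", 0, Inf),
    maintenance_margin = check(maintenance_margin, "maintenance_margin", 0, 1),
    low_nmd_threshold = check(low_nmd_threshold, "low_nmd_threshold", 0, 1),
    stages = stages,
    seed = check(seed, "seed", -2^31, 2^31))
  if (cfg$band_lower >= cfg$band_upper) {
    stopf("invalid config: band_lower must be below band_upper")
  }
  if (cfg$min_exon_len > cfg$max_exon_len) {
    stopf("invalid config: min_exon_len must not exceed max_exon_len")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path Path to a JSON object of [pipeline_config] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  do.call(pipeline_config, vals)
}

#' Write the Mga-like simulation bundle to an output directory
#'
#' Generates the packaged fixture (genome, annotation, score track,
#' domain table), simulates staged junction counts and a paired
#' translation-inhibitor assay, and writes everything as plain text.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config].
#' @return Invisibly, a named character vector of paths written.
#' @export
run_simulate <- function(out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_mga_fixture(config$seed)
  records <- simulate_junction_counts(fx$stages, "Mga_like:SE:3600:3744",
                                      n_inc = 2, n_skip = 1,
                                      seed = config$seed + 1L)
  assay <- simulate_nmd_assay(fx$stages$nmd_efficiency, seed = config$seed + 2L)
  paths <- c(fasta = file.path(out_dir, "genome.fa"),
             gff3 = file.path(out_dir, "annotation.gff3"),
             track = file.path(out_dir, "score_track.tsv"),
             domains = file.path(out_dir, "domains.tsv"),
             counts = file.path(out_dir, "junction_counts.tsv"),
             assay = file.path(out_dir, "nmd_assay.tsv"))
  write_genome_fasta(fx$genome, paths[["fasta"]])
  write_gff3(list(fx$canonical), paths[["gff3"]])
  write_score_track(fx$track, paths[["track"]])
  write.table(fx$domains, paths[["domains"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_junction_counts(records, paths[["counts"]])
  write.table(assay, paths[["assay"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Screen a score track for novel exon candidates and write results
#'
#' @param gff,fasta,scores Input paths (annotation, genome, score track).
#' @param out_dir Output directory.
#' @param config A [pipeline_config].
#' @return Invisibly, the paths written (`candidates.tsv`,
#'   `candidates.bed`).
#' @export
run_screen <- function(gff, fasta, scores, out_dir, config = pipeline_config()) {
  for (p in c(gff, fasta, scores)) {
    if (!file.exists(p)) stopf("input file '%s' does not exist", p)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  transcripts <- read_gff3(gff)
  read_genome_fasta(fasta)  # validates the genome the track refers to
  track <- read_score_track(scores)
  cands <- find_exon_candidates(track, transcripts,
                                min_score = config$min_score,
                                min_len = config$min_exon_len,
                                max_len = config$max_exon_len)
  paths <- c(tsv = file.path(out_dir, "candidates.tsv"),
             bed = file.path(out_dir, "candidates.bed"))
  write_candidates(cands, bed = paths[["bed"]], tsv = paths[["tsv"]])
  invisible(paths)
}

#' PSI estimation and differential-splicing calls from a counts table
#'
#' @param counts Path to a junction-counts TSV (see
#'   [read_junction_counts]).
#' @param out_dir Output directory.
#' @param config A [pipeline_config] (stage order and Bayes-factor
#'   threshold are taken from it).
#' @return Invisibly, the paths written (`psi.tsv`, `diff_splice.tsv`).
#' @export
run_diff <- function(counts, out_dir, config = pipeline_config()) {
  if (!file.exists(counts)) stopf("input file '%s' does not exist", counts)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- read_junction_counts(counts)
  psi <- psi_table(records)
  diffs <- diff_splice_table(records, config$stages,
                             bf_threshold = config$bf_threshold)
  paths <- c(psi = file.path(out_dir, "psi.tsv"),
             diff = file.path(out_dir, "diff_splice.tsv"))
  write.table(psi, paths[["psi"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(diffs, paths[["diff"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' ORF-consequence annotation of screened candidates
#'
#' Builds a variant transcript for every candidate exon falling inside an
#' intron of an annotated coding transcript, annotates the coding
#' consequence and NMD sensitivity, and writes one row per candidate.
#'
#' @param gff,fasta,candidates Input paths; `candidates` is the TSV
#'   written by [run_screen].
#' @param domains Optional domain-table path (see [read_domain_table]).
#' @param out_dir Output directory.
#' @param config A [pipeline_config].
#' @return Invisibly, the path written (`consequences.tsv`).
#' @export
run_consequence <- function(gff, fasta, candidates, out_dir, domains = NULL,
                            config = pipeline_config()) {
  for (p in c(gff, fasta, candidates)) {
    if (!file.exists(p)) stopf("input file '%s' does not exist", p)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  transcripts <- read_gff3(gff)
  genome <- read_genome_fasta(fasta)
  cands <- read.delim(candidates, stringsAsFactors = FALSE)
  dom <- if (!is.null(domains)) read_domain_table(domains) else NULL
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    tm <- Filter(function(t) t$transcript_id == cands$transcript_id[i],
                 transcripts)
    if (length(tm) != 1L) {
      stopf("candidate %d references unknown transcript '%s'",
            i, cands$transcript_id[i])
    }
    tm <- tm[[1L]]
    variant <- build_variant_transcript(tm, cands$start[i], cands$end[i])
    d <- if (!is.null(dom)) dom[dom$gene_id == tm$gene_id, , drop = FALSE] else NULL
    cons <- annotate_orf_consequence(variant, tm, genome, d,
                                     rule_distance = config$nmd_rule_distance)
    data.frame(gene_id = tm$gene_id, transcript_id = tm$transcript_id,
               exon_start = cands$start[i], exon_end = cands$end[i],
               band = cands$band[i], category = cons$category,
               added_codons = cons$added_codons_before_stop,
               ptc_distance = cons$distance_ptc_to_last_junction,
               nmd_sensitive = cons$nmd_sensitive,
               truncated_protein_length = cons$truncated_protein_length,
               lost_domains = paste(cons$lost_domains, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0))
  path <- file.path(out_dir, "consequences.tsv")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(consequences = path))
}

#' Aggregate pipeline outputs into a human-readable report
#'
#' Reads whichever result tables exist under `dir` (`candidates.tsv`,
#' `diff_splice.tsv`, `consequences.tsv`, `nmd_assay.tsv`) and writes
#' `report.md` plus a machine-readable `summary.tsv`.  Missing tables are
#' simply skipped, so an empty directory yields a valid (empty) report.
#'
#' @param dir Directory holding pipeline outputs.
#' @param config A [pipeline_config].
#' @return Invisibly, the paths written.
#' @export
run_report <- function(dir, config = pipeline_config()) {
  md <- c("# Splicing pipeline report", "")
  summary_rows <- list()
  note <- function(metric, value) {
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(metric = metric, value = as.character(value),
                 stringsAsFactors = FALSE)
  }

  cand_path <- file.path(dir, "candidates.tsv")
  if (file.exists(cand_path)) {
    cands <- read.delim(cand_path, stringsAsFactors = FALSE)
    md <- c(md, "## Novel exon candidates",
            sprintf("- %d candidate(s); bands: %s", nrow(cands),
                    if (nrow(cands)) paste(sprintf("%s (%d)",
                                                   names(table(cands$band)),
                                                   table(cands$band)),
                                           collapse = ", ") else "none"), "")
    note("n_candidates", nrow(cands))
    if (nrow(cands)) {
      md <- c(md, sprintf("  - %s:%d-%d (%s, %d nt, acceptor %.3f / donor %.3f)",
                          cands$contig, cands$start, cands$end, cands$band,
                          cands$length, cands$acceptor_score,
                          cands$donor_score), "")
    }
  }

  diff_path <- file.path(dir, "diff_splice.tsv")
  if (file.exists(diff_path)) {
    diffs <- read.delim(diff_path, stringsAsFactors = FALSE)
    sig <- diffs[diffs$significant, , drop = FALSE]
    md <- c(md, "## Differential splicing",
            sprintf("- %d significant call(s) at Bayes factor >= %g",
                    nrow(sig), config$bf_threshold))
    note("n_significant_calls", nrow(sig))
    if (nrow(sig)) {
      md <- c(md, sprintf("  - %s %s: dPSI %+.3f (log10 BF %.2f)",
                          sig$event_id, sig$transition, sig$delta_psi,
                          sig$log10_bf))
    }
    md <- c(md, "")
  }

  cons_path <- file.path(dir, "consequences.tsv")
  if (file.exists(cons_path)) {
    cons <- read.delim(cons_path, stringsAsFactors = FALSE)
    md <- c(md, "## Coding consequences")
    if (nrow(cons)) {
      md <- c(md, sprintf("  - %s %d-%d: %s%s; NMD-sensitive: %s; lost domains: %s",
                          cons$gene_id, cons$exon_start, cons$exon_end,
                          cons$category,
                          ifelse(is.na(cons$added_codons), "",
                                 sprintf(" (%d added codons)", cons$added_codons)),
                          cons$nmd_sensitive,
                          ifelse(cons$lost_domains == "", "none",
                                 cons$lost_domains)))
    } else {
      md <- c(md, "- none")
    }
    note("n_consequences", nrow(cons))
    md <- c(md, "")
  }

  assay_path <- file.path(dir, "nmd_assay.tsv")
  if (file.exists(assay_path)) {
    eff <- estimate_nmd_efficiency(read_nmd_assay(assay_path),
                                   low_nmd_threshold = config$low_nmd_threshold)
    md <- c(md, "## NMD efficiency by stage",
            sprintf("  - %s: efficiency %.2f%s", eff$stage, eff$efficiency,
                    ifelse(eff$flagged_low_nmd, " (low NMD)", "")), "")
    note("low_nmd_stages",
         paste(eff$stage[eff$flagged_low_nmd], collapse = ","))
  }

  paths <- c(report = file.path(dir, "report.md"),
             summary = file.path(dir, "summary.tsv"))
  writeLines(md, paths[["report"]])
  summary_df <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame(metric = character(0), value = character(0))
  write.table(summary_df, paths[["summary"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Dispatch a pipeline subcommand
#'
#' Thin programmatic counterpart of the command-line interface: runs one
#' of `simulate`, `screen`, `diff`, `consequence` or `report` with the
#' given arguments.
#'
#' @param name Subcommand name.
#' @param args Named list of arguments forwarded to the corresponding
#'   `run_*` function.
#' @param config A [pipeline_config].
#' @return The invisible return value of the dispatched function.
#' @export
run_subcommand <- function(name, args = list(), config = pipeline_config()) {
  fun <- switch(name,
                simulate = run_simulate,
                screen = run_screen,
                diff = run_diff,
                consequence = run_consequence,
                report = run_report,
                stopf("unknown subcommand '%s'", name))
  do.call(fun, c(args, list(config = config)))
}
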