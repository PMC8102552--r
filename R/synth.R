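#' Construct a stage series (synthetic ground truth for one event)
#'
#' Describes one splicing event across an ordered series of cell stages:
#' the true inclusion level (PSI) per stage, the per-stage NMD efficiency
#' acting on the PTC-bearing isoform, and the expected informative read
#' depth.  The default stage names encode a five-stage male germ-cell
#' differentiation series: undifferentiated and differentiated
#' spermatogonia, preleptotene and pachytene spermatocytes, and round
#' spermatids.
#'
#' @param stage_names Ordered character vector of stage names (>= 2).
#' @param true_psi Numeric vector in [0, 1], one value per stage.
#' @param nmd_efficiency Numeric vector in [0, 1), one value per stage.
#' @param depth Expected informative reads per event and stage (> 0).
#' @param ptc_bearing Does the inclusion isoform carry a PTC (so that NMD
#'   suppresses it)?
#' @return An object of class `stage_series`.
#' @export
stage_series <- function(stage_names = c("SG_und", "SG_diff", "SC_preL",
                                         "SC_pachy", "RS"),
                         true_psi, nmd_efficiency = rep(0, length(stage_names)),
                         depth = 300, ptc_bearing = FALSE) {
  k <- length(stage_names)
  if (k < 2L) stopf("a stage series needs at least two stages")
  if (length(true_psi) != k) stopf("true_psi must have one value per stage")
  if (length(nmd_efficiency) != k) stopf("nmd_efficiency must have one value per stage")
  if (any(true_psi < 0) || any(true_psi > 1)) stopf("true_psi must lie in [0, 1]")
  if (any(nmd_efficiency < 0) || any(nmd_efficiency >= 1)) {
    stopf("nmd_efficiency must lie in [0, 1)")
  }
  if (depth <= 0) stopf("depth must be positive")
  structure(
    list(stage_names = stage_names,
         true_psi = setNames(as.numeric(true_psi), stage_names),
         nmd_efficiency = setNames(as.numeric(nmd_efficiency), stage_names),
         depth = depth, ptc_bearing = isTRUE(ptc_bearing)),
    class = "stage_series")
}

#' Simulate junction count records along a stage series
#'
#' Steady-state model: the effective abundance of the inclusion isoform
#' at a stage is `true_psi * (1 - nmd_efficiency)` when it carries a PTC
#' (NMD acts multiplicatively on its abundance), otherwise `true_psi`;
#' the skipping isoform has abundance `1 - true_psi`.  Each isoform
#' exposes its own junctions, so an informative read supports inclusion
#' with probability `J_inc * a / (J_inc * a + J_skip * b)` where `a`, `b`
#' are the isoform abundances — the sampling counterpart of the
#' junction-count normalization used by [estimate_psi].  Read totals are
#' binomial at the event depth and distributed multinomially over the
#' junctions of each side.
#'
#' @param series A [stage_series].
#' @param event_id Event identifier stamped on the records.
#' @param n_inc,n_skip Number of inclusion / skipping junctions (defaults
#'   2 and 1: a cassette exon).
#' @param seed Optional integer seed for reproducibility.
#' @return A list of [junction_count_record]s, one per stage, with
#'   `sample_id` set to the stage name.
#' @export
simulate_junction_counts <- function(series, event_id = "event1",
                                     n_inc = 2, n_skip = 1, seed = NULL) {
  stopifnot(inherits(series, "stage_series"))
  if (!is.null(seed)) set.seed(seed)
  lapply(series$stage_names, function(st) {
    psi <- series$true_psi[[st]]
    a <- if (series$ptc_bearing) psi * (1 - series$nmd_efficiency[[st]]) else psi
    b <- 1 - psi
    denom <- n_inc * a + n_skip * b
    p <- if (denom > 0) n_inc * a / denom else 0
    n <- as.integer(round(series$depth))
    k <- rbinom(1L, n, p)
    inc <- as.integer(rmultinom(1L, k, rep(1, n_inc)))
    skp <- as.integer(rmultinom(1L, n - k, rep(1, n_skip)))
    junction_count_record(event_id, st, inc, skp)
  })
}

#' Simulate a paired translation-inhibitor (±CHX-style) assay
#'
#' Each replicate represents one cell preparation split into an untreated
#' and an inhibitor-treated aliquot, so the replicate-level biological
#' factor (log-normal, coefficient of variation `rep_cv`) is shared
#' within the pair, while measurement noise (`tech_cv`) is independent
#' per measurement.  NMD removes a fraction `efficiency` of the
#' PTC-bearing transcript in the untreated arm only.
#'
#' @param efficiencies Named numeric vector of true NMD efficiencies in
#'   [0, 1), one per stage.
#' @param baseline Expected treated-arm abundance (arbitrary units).
#' @param replicates Paired replicates per stage (default 3).
#' @param rep_cv Replicate-level multiplicative noise (default 0.1).
#' @param tech_cv Measurement-level multiplicative noise (default 0.03).
#' @param seed Optional integer seed.
#' @return A data frame with columns `stage`, `replicate`, `treated`,
#'   `abundance`, suitable for [estimate_nmd_efficiency].
#' @export
simulate_nmd_assay <- function(efficiencies, baseline = 100, replicates = 3,
                               rep_cv = 0.1, tech_cv = 0.03, seed = NULL) {
  if (is.null(names(efficiencies))) stopf("efficiencies must be named by stage")
  if (any(efficiencies < 0) || any(efficiencies >= 1)) {
    stopf("efficiencies must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (st in names(efficiencies)) {
    for (r in seq_len(replicates)) {
      b <- baseline * exp(rnorm(1, 0, rep_cv))
      u <- b * (1 - efficiencies[[st]]) * exp(rnorm(1, 0, tech_cv))
      t <- b * exp(rnorm(1, 0, tech_cv))
      rows[[length(rows) + 1L]] <- data.frame(
        stage = st, replicate = r, treated = c(0L, 1L),
        abundance = c(u, t), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The Mga-like test fixture
#'
#' A deterministic (per seed) condensed analog of the *Mga* locus: a
#' plus-strand three-exon gene (analogs of exons 17, 18 and 19) whose
#' second intron hides a 145-nt exon that contributes five complete
#' codons followed by an in-frame TAA.  The CDS spans all three exons; a
#' T-box-like domain lies upstream of the insertion point and a
#' bHLHZ-like domain near the C terminus, downstream of the premature
#' stop.  The splice-site score track scores the annotated boundaries
#' above 0.9 (constitutive band) and the hidden exon's acceptor/donor at
#' 0.695/0.761 (alternative band), with sub-0.1 intronic noise positions.
#'
#' @param seed Integer seed (default 1).
#' @return A list with elements `genome` (DNAStringSet, contig `chrT`),
#'   `canonical` (the three-exon [transcript_model]), `novel_exon`
#'   (genomic start/end of the hidden 145-nt exon), `domains` (data
#'   frame), `track` (a `splice_score_track`) and `stages`
#'   (a [stage_series] with high NMD efficiency in spermatogonia and
#'   near-zero NMD in spermatocytes/spermatids).
#' @export
make_mga_fixture <- function(seed = 1) {
  set.seed(seed)
  ## CDS: ATG + 498 sense codons + TAA = 1500 nt = 500 codons
  cds <- paste0("ATG", rand_sense_codons(498), "TAA")
  novel <- paste0("GCTGGATCCAAAGAG", "TAA", rand_dna(127))  # 5 codons, stop, filler
  contig <- paste0(
    rand_dna(2049),                 # lead + 5'UTR (exon starts at 2001)
    substr(cds, 1, 351),            # 2050-2400: CDS in exon-17 analog
    rand_dna(600),                  # intron 17-analog
    substr(cds, 352, 651),          # 3001-3300: CDS in exon-18 analog
    rand_dna(299),
    novel,                          # 3600-3744: hidden exon (145 nt)
    rand_dna(756),
    substr(cds, 652, 1500),         # 4501-5349: CDS in exon-19 analog
    rand_dna(651))                  # 3'UTR + tail (exon ends at 5400)
  genome <- Biostrings::DNAStringSet(setNames(contig, "chrT"))

  canonical <- transcript_model("Mga_like.t1", "Mga_like", "chrT", "+",
                                exon_starts = c(2001L, 3001L, 4501L),
                                exon_ends = c(2400L, 3300L, 5400L),
                                cds_start = 2050L, cds_end = 5349L)
  domains <- data.frame(
    gene_id = "Mga_like",
    domain_name = c("T-box", "bHLHZ"),
    aa_start = c(50L, 420L), aa_end = c(180L, 480L),
    stringsAsFactors = FALSE)
  track <- splice_score_track(
    contig = "chrT",
    position = c(2001L, 2400L, 2700L, 3001L, 3300L, 3600L, 3744L, 4100L,
                 4501L, 5400L),
    strand = "+",
    acceptor_score = c(0.97, 0.01, 0.04, 0.98, 0.01, 0.695, 0.02, 0.08,
                       0.99, 0.01),
    donor_score = c(0.01, 0.96, 0.02, 0.01, 0.95, 0.01, 0.761, 0.05,
                    0.01, 0.97))
  stages <- stage_series(
    true_psi = rep(0.5, 5),
    nmd_efficiency = c(0.8, 0.8, 0.05, 0.05, 0.05),
    depth = 1000, ptc_bearing = TRUE)
  list(genome = genome, canonical = canonical,
       novel_exon = c(start = 3600L, end = 3744L),
       domains = domains, track = track, stages = stages)
}

## exact integer allocation of n items to fractions (largest remainder)
allocate_exact <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Configuration of a synthetic splicing cohort
#'
#' @param n_genes Number of genes (one splicing event each).
#' @param event_type_mixture Named fractions over SE, RI, A5SS, A3SS and
#'   MXE; must sum to 1.
#' @param gain_loss_ratio Ratio of exon gains to exon losses among SE
#'   events (default 2, i.e. gains twice as frequent).
#' @param ptc_fraction_among_gains Fraction of gained exons that
#'   introduce a PTC (default 0.75).
#' @param maintained_fraction Fraction of changed events whose new form
#'   persists through all later stages (default 0.8).
#' @param depth Expected informative reads per event and stage.
#' @param minus_strand_fraction Fraction of genes placed on the minus
#'   strand (default 0.3).
#' @param stage_names Ordered stage names (default: the five-stage
#'   germ-cell series).
#' @param change_index The splicing change happens between stage
#'   `change_index` and `change_index + 1` (default 2: the transition of
#'   differentiated spermatogonia to preleptotene spermatocytes).
#' @param nmd_efficiency Per-stage NMD efficiencies applied to
#'   PTC-bearing inclusion isoforms (default high in spermatogonia,
#'   near zero afterwards).
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 2000,
                          event_type_mixture = c(SE = 0.55, RI = 0.15,
                                                 A5SS = 0.10, A3SS = 0.10,
                                                 MXE = 0.10),
                          gain_loss_ratio = 2,
                          ptc_fraction_among_gains = 0.75,
                          maintained_fraction = 0.8,
                          depth = 300,
                          minus_strand_fraction = 0.3,
                          stage_names = c("SG_und", "SG_diff", "SC_preL",
                                          "SC_pachy", "RS"),
                          change_index = 2L,
                          nmd_efficiency = c(0.8, 0.8, 0.05, 0.05, 0.05),
                          seed = 1) {
  types <- c("SE", "RI", "A5SS", "A3SS", "MXE")
  if (!setequal(names(event_type_mixture), types)) {
    stopf("event_type_mixture must be named over %s", paste(types, collapse = ", "))
  }
  event_type_mixture <- event_type_mixture[types]
  if (abs(sum(event_type_mixture) - 1) > 1e-9) {
    stopf("event_type_mixture must sum to 1")
  }
  for (f in c(ptc_fraction_among_gains, maintained_fraction, minus_strand_fraction)) {
    if (f < 0 || f > 1) stopf("fractions must lie in [0, 1]")
  }
  if (gain_loss_ratio < 0) stopf("gain_loss_ratio must be non-negative")
  if (n_genes < 1) stopf("n_genes must be positive")
  if (ptc_fraction_among_gains > 0 &&
      (event_type_mixture[["SE"]] == 0 || gain_loss_ratio == 0)) {
    stopf("ptc_fraction_among_gains > 0 requires SE events with gains in the mixture")
  }
  if (change_index < 1L || change_index >= length(stage_names)) {
    stopf("change_index must name a transition within the stage series")
  }
  structure(
    list(n_genes = as.integer(n_genes), event_type_mixture = event_type_mixture,
         gain_loss_ratio = gain_loss_ratio,
         ptc_fraction_among_gains = ptc_fraction_among_gains,
         maintained_fraction = maintained_fraction, depth = depth,
         minus_strand_fraction = minus_strand_fraction,
         stage_names = stage_names, change_index = as.integer(change_index),
         nmd_efficiency = setNames(nmd_efficiency, stage_names),
         seed = as.integer(seed)),
    class = "cohort_config")
}

## build one synthetic gene of the requested event type on the plus
## strand; returns contig sequence, two transcript models and per-gene
## truth needed downstream.  SE genes are coding with a designed cassette.
build_cohort_gene <- function(gene_id, type, se_kind = NA_character_) {
  lead <- 100L
  if (is.na(se_kind)) se_kind <- "random"
  if (type == "SE") {
    r <- sample(0:2, 1)
    u5 <- 12L
    cds <- paste0("ATG", rand_sense_codons(18), "TAA")  # 60 nt
    cds_a <- 27L + r
    a_start <- lead + 1L
    a_end <- a_start + u5 + cds_a - 1L
    b_start <- a_end + 21L
    lb <- 90L
    pad_in <- (3L - r) %% 3L
    b_seq <- switch(
      se_kind,
      ptc = paste0(strrep("C", pad_in), "GGAAAA", "TAA",
                   rand_dna(lb - pad_in - 9L)),
      inframe = paste0(strrep("C", pad_in),
                       rand_sense_codons((lb - pad_in - (r %% 3L)) %/% 3L),
                       strrep("C", r %% 3L)),
      rand_dna(lb))
    b_end <- b_start + lb - 1L
    c_start <- b_end + 31L
    cds_c <- 60L - cds_a
    u3 <- 80L
    c_end <- c_start + cds_c + u3 - 1L
    contig <- paste0(rand_dna(lead + u5), substr(cds, 1L, cds_a),
                     rand_dna(20L), b_seq, rand_dna(30L),
                     substr(cds, cds_a + 1L, 60L), rand_dna(u3 + 60L))
    stopifnot(nchar(contig) == c_end + 60L)
    canonical <- transcript_model(paste0(gene_id, ".t1"), gene_id, gene_id, "+",
                                  c(a_start, c_start), c(a_end, c_end),
                                  cds_start = a_start + u5,
                                  cds_end = c_start + cds_c - 1L)
    variant <- transcript_model(paste0(gene_id, ".t2"), gene_id, gene_id, "+",
                                c(a_start, b_start, c_start),
                                c(a_end, b_end, c_end),
                                cds_start = a_start + u5,
                                cds_end = c_start + cds_c - 1L)
    added_truth <- if (identical(se_kind, "ptc")) 2L + (r > 0L) else NA_integer_
    return(list(contig = contig, t1 = canonical, t2 = variant,
                n_inc = 2L, n_skip = 1L, added_truth = added_truth))
  }
  contig_len <- 700L
  contig <- rand_dna(contig_len)
  mk <- function(id, starts, ends) {
    transcript_model(id, gene_id, gene_id, "+", starts, ends)
  }
  t1 <- t2 <- NULL
  if (type == "RI") {
    t1 <- mk(paste0(gene_id, ".t1"), c(101L, 301L), c(200L, 400L))
    t2 <- mk(paste0(gene_id, ".t2"), 101L, 400L)
    jn <- c(2L, 1L)
  } else if (type == "A5SS") {
    t1 <- mk(paste0(gene_id, ".t1"), c(101L, 301L), c(200L, 400L))
    t2 <- mk(paste0(gene_id, ".t2"), c(101L, 301L), c(260L, 400L))
    jn <- c(1L, 1L)
  } else if (type == "A3SS") {
    t1 <- mk(paste0(gene_id, ".t1"), c(101L, 301L), c(200L, 400L))
    t2 <- mk(paste0(gene_id, ".t2"), c(101L, 241L), c(200L, 400L))
    jn <- c(1L, 1L)
  } else if (type == "MXE") {
    t1 <- mk(paste0(gene_id, ".t1"), c(101L, 251L, 401L), c(200L, 310L, 500L))
    t2 <- mk(paste0(gene_id, ".t2"), c(101L, 331L, 401L), c(200L, 390L, 500L))
    jn <- c(2L, 2L)
  } else {
    stopf("unknown event type '%s'", type)
  }
  list(contig = contig, t1 = t1, t2 = t2, n_inc = jn[1L], n_skip = jn[2L],
       added_truth = NA_integer_)
}

## remap a transcript model through a coordinate flip
remap_transcript <- function(tm, map, W) {
  transcript_model(tm$transcript_id, tm$gene_id, tm$contig, "-",
                   rev(map(tm$exon_ends)), rev(map(tm$exon_starts)),
                   if (is.na(tm$cds_start)) NA_integer_ else map(tm$cds_end),
                   if (is.na(tm$cds_end)) NA_integer_ else map(tm$cds_start))
}

#' Simulate a full synthetic splicing cohort with known ground truth
#'
#' Generates one gene (a transcript pair realizing one splicing event)
#' per configured event, junction counts for the five-stage series with
#' the configured change at the chosen transition, and a ground-truth
#' table.  The configured composition is planted exactly (largest
#' remainder allocation), so recovery error reflects only estimation and
#' sampling noise downstream.  SE genes are coding; their cassette exon
#' is designed to be PTC-bearing or frame-preserving according to the
#' configured fraction, and PTC-bearing inclusion isoforms are suppressed
#' by the per-stage NMD efficiencies.  Some genes are mirrored to the
#' minus strand.
#'
#' @param cfg A [cohort_config].
#' @return A list with `config`, `genome` (DNAStringSet, one contig per
#'   gene), `transcripts` (named list of transcript-model pairs),
#'   `events` (row-bound [enumerate_as_events] output), `records` (flat
#'   list of [junction_count_record]s) and `truth` (data frame with the
#'   planted type, direction, PTC status, maintenance flag and per-stage
#'   true PSI for every event).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  types <- rep(names(cfg$event_type_mixture),
               allocate_exact(n, cfg$event_type_mixture))
  ## SE direction: gains : losses = gain_loss_ratio : 1, planted exactly
  n_se <- sum(types == "SE")
  n_gain <- as.integer(round(n_se * cfg$gain_loss_ratio / (cfg$gain_loss_ratio + 1)))
  se_dir <- sample(rep(c("gain", "loss"), c(n_gain, n_se - n_gain)))
  n_ptc <- as.integer(round(n_gain * cfg$ptc_fraction_among_gains))
  ptc_flags <- sample(rep(c(TRUE, FALSE), c(n_ptc, n_gain - n_ptc)))
  maintained <- sample(rep(c(TRUE, FALSE),
                           c(round(n * cfg$maintained_fraction),
                             n - round(n * cfg$maintained_fraction))))
  minus <- sample(rep(c(TRUE, FALSE),
                      c(round(n * cfg$minus_strand_fraction),
                        n - round(n * cfg$minus_strand_fraction))))
  types <- sample(types)

  k_stage <- length(cfg$stage_names)
  ci <- cfg$change_index
  nmd <- cfg$nmd_efficiency
  ## observed (abundance-level) inclusion fraction after NMD suppression
  eff_psi <- function(psi, E) psi * (1 - E) / (psi * (1 - E) + 1 - psi)
  psi_profile <- function(direction, maint, ptc) {
    lo <- 0.1; hi <- 0.7
    pre <- if (direction == "gain") lo else hi
    post <- if (direction == "gain") hi else lo
    psi <- c(rep(pre, ci), rep(post, k_stage - ci))
    if (!maint && ci + 2L <= k_stage) {
      if (ptc) {
        ## NMD efficiency varies across stages, so "return to baseline"
        ## must hold on the observed scale: choose the production PSI
        ## whose NMD-suppressed inclusion fraction matches the
        ## pre-transition observation
        t_pre <- eff_psi(pre, nmd[[ci]])
        for (s in (ci + 2L):k_stage) {
          psi[s] <- t_pre / ((1 - nmd[[s]]) * (1 - t_pre) + t_pre)
        }
      } else {
        psi[(ci + 2L):k_stage] <- pre
      }
    }
    psi
  }

  contigs <- character(n)
  transcripts <- vector("list", n)
  events_rows <- vector("list", n)
  records <- vector("list", n)
  truth_rows <- vector("list", n)
  i_se <- 0L; i_gain <- 0L

  for (i in seq_len(n)) {
    gene_id <- sprintf("g%04d", i)
    type <- types[i]
    direction <- NA_character_
    ptc <- FALSE
    se_kind <- NA_character_
    if (type == "SE") {
      i_se <- i_se + 1L
      direction <- se_dir[i_se]
      if (direction == "gain") {
        i_gain <- i_gain + 1L
        ptc <- ptc_flags[i_gain]
        se_kind <- if (ptc) "ptc" else "inframe"
      }
    }
    g <- build_cohort_gene(gene_id, type, se_kind)
    if (minus[i]) {
      W <- nchar(g$contig)
      map <- function(pos) W - pos + 1L
      g$contig <- revcomp_chr(g$contig)
      g$t1 <- remap_transcript(g$t1, map, W)
      g$t2 <- remap_transcript(g$t2, map, W)
    }
    contigs[i] <- g$contig
    transcripts[[i]] <- list(t1 = g$t1, t2 = g$t2)
    ev <- enumerate_as_events(list(g$t1, g$t2))
    ev <- ev[ev$event_type == type, , drop = FALSE]
    if (nrow(ev) != 1L) {
      stopf("gene '%s' (%s) yielded %d events of its type", gene_id, type, nrow(ev))
    }
    events_rows[[i]] <- ev
    dir_eff <- if (is.na(direction)) sample(c("gain", "loss"), 1L) else direction
    psi <- psi_profile(dir_eff, maintained[i], ptc)
    series <- stage_series(cfg$stage_names, psi, cfg$nmd_efficiency,
                           depth = cfg$depth, ptc_bearing = ptc)
    records[[i]] <- simulate_junction_counts(series, ev$event_id[1L],
                                             n_inc = g$n_inc, n_skip = g$n_skip)
    tr <- data.frame(gene_id = gene_id, event_id = ev$event_id[1L],
                     event_type = type,
                     strand = if (minus[i]) "-" else "+",
                     direction = direction, ptc = ptc,
                     added_codons = g$added_truth,
                     maintained = maintained[i], stringsAsFactors = FALSE)
    for (s in seq_len(k_stage)) tr[[paste0("psi_", cfg$stage_names[s])]] <- psi[s]
    truth_rows[[i]] <- tr
  }

  genome <- Biostrings::DNAStringSet(setNames(contigs, sprintf("g%04d", seq_len(n))))
  list(config = cfg, genome = genome,
       transcripts = setNames(transcripts, sprintf("g%04d", seq_len(n))),
       events = do.call(rbind, events_rows),
       records = do.call(c, records),
       truth = do.call(rbind, truth_rows))
}

#' ORF consequences for exon-gain events of a cohort
#'
#' Runs [annotate_orf_consequence] for each requested event, inserting
#' the gene's cassette exon into its canonical (skipping) transcript.
#'
#' @param bundle A [simulate_cohort] result.
#' @param event_ids Event identifiers (SE events of the bundle).
#' @return A named list of `orf_consequence` objects.
#' @export
cohort_gain_consequences <- function(bundle, event_ids) {
  ev <- bundle$events
  out <- lapply(event_ids, function(id) {
    row <- ev[ev$event_id == id, , drop = FALSE]
    if (nrow(row) != 1L || row$event_type != "SE") {
      stopf("event '%s' is not a unique SE event of this cohort", id)
    }
    pair <- bundle$transcripts[[row$gene_id]]
    annotate_orf_consequence(pair$t2, pair$t1, bundle$genome)
  })
  setNames(out, event_ids)
}

#' Simulate one random multi-exon coding gene
#'
#' Stress-test generator: a coding gene with 2–4 exons, a random reading
#' frame at each intron (introns cut the CDS at arbitrary codon offsets),
#' optionally an extra non-coding leading exon (so that the first intron
#' lies in the 5' UTR), random intron and UTR lengths, and a random
#' strand (minus-strand genes are exact mirror images).  Also picks a
#' random intronic interval to serve as a novel-exon insertion, with
#' unconstrained (already random) sequence content.
#'
#' @param seed Optional integer seed.
#' @return A list with `genome`, `canonical` (a [transcript_model] with
#'   valid CDS), `novel_start`, `novel_end`.
#' @export
simulate_random_coding_gene <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_codons <- sample(15:40, 1)
  cds <- paste0("ATG", rand_sense_codons(n_codons - 2L), "TAA")
  cds_len <- 3L * n_codons
  n_cds_exons <- sample(2:4, 1)
  cuts <- sort(sample(seq_len(cds_len - 1L), n_cds_exons - 1L))
  piece_len <- diff(c(0L, cuts, cds_len))
  u5 <- sample(6:20, 1)
  u3 <- sample(40:120, 1)
  lead_exon <- runif(1) < 0.25   # extra non-coding first exon

  pos <- 101L
  starts <- integer(0); ends <- integer(0)
  seqs <- character(0)
  add_exon <- function(seq) {
    starts <<- c(starts, pos)
    ends <<- c(ends, pos + nchar(seq) - 1L)
    seqs <<- c(seqs, seq)
    pos <<- pos + nchar(seq)
  }
  add_intron <- function() {
    len <- sample(50:120, 1)
    seqs <<- c(seqs, rand_dna(len))
    pos <<- pos + len
  }
  if (lead_exon) {
    add_exon(rand_dna(sample(10:30, 1)))
    add_intron()
  }
  piece_start <- cumsum(c(1L, piece_len))[seq_len(n_cds_exons)]
  for (j in seq_len(n_cds_exons)) {
    piece <- substr(cds, piece_start[j], piece_start[j] + piece_len[j] - 1L)
    seq <- piece
    if (j == 1L) seq <- paste0(rand_dna(u5), seq)
    if (j == n_cds_exons) seq <- paste0(seq, rand_dna(u3))
    add_exon(seq)
    if (j < n_cds_exons) add_intron()
  }
  cds_start <- starts[if (lead_exon) 2L else 1L] + u5
  cds_end <- ends[length(ends)] - u3
  contig <- paste0(rand_dna(100L), paste(seqs, collapse = ""), rand_dna(60L))
  gene_id <- "rnd"
  tm <- transcript_model("rnd.t1", gene_id, "rnd", "+", starts, ends,
                         cds_start, cds_end)
  introns <- transcript_introns(tm)
  repeat {
    ii <- sample(nrow(introns), 1)
    ilen <- introns$end[ii] - introns$start[ii] + 1L
    len <- sample(6:min(80L, ilen - 2L), 1)
    off <- sample(seq_len(ilen - len - 1L), 1)
    ns <- introns$start[ii] + off
    ne <- ns + len - 1L
    break
  }
  if (runif(1) < 0.5) {
    W <- nchar(contig)
    map <- function(p) W - p + 1L
    contig <- revcomp_chr(contig)
    tm <- remap_transcript(tm, map, W)
    tmp <- ns; ns <- map(ne); ne <- map(tmp)
  }
  list(genome = Biostrings::DNAStringSet(setNames(contig, "rnd")),
       canonical = tm, novel_start = ns, novel_end = ne)
}

#' Write a simulated cohort bundle to plain-text files
#'
#' Writes `genome.fa`, `annotation.gff3`, `junction_counts.tsv` and
#' `truth.tsv` under `dir`.
#'
#' @param bundle A [simulate_cohort] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gff3 = file.path(dir, "annotation.gff3"),
             counts = file.path(dir, "junction_counts.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_genome_fasta(bundle$genome, paths[["fasta"]])
  write_gff3(unlist(bundle$transcripts, recursive = FALSE, use.names = FALSE),
             paths[["gff3"]])
  write_junction_counts(bundle$records, paths[["counts"]])
  write.table(bundle$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
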