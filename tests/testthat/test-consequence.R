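## small explicit coding gene used by several tests: two exons, CDS
## aligned so that the intron falls exactly between codons
toy_coding_gene <- function(novel_seq, utr3 = 70L) {
  ## exon1: 10 nt UTR + ATG + 4 codons (start 101); intron1 hosts the
  ## novel exon; exon2: 5 codons + TAA + 3' UTR
  set.seed(99)
  e1_cds <- paste0("ATG", "GCTGCAAAAGAG")     # 15 nt, 5 codons
  e2_cds <- paste0("CATCACGATGTTGGT", "TAA")  # 18 nt
  lead <- rand_dna(100)
  u5 <- rand_dna(10)
  i1a <- rand_dna(40)
  i1b <- rand_dna(40)
  tail <- rand_dna(utr3 + 20)
  contig <- paste0(lead, u5, e1_cds, i1a, novel_seq, i1b, e2_cds,
                   substr(tail, 1, utr3))
  e1_start <- 101L
  e1_end <- e1_start + 10L + 15L - 1L
  nov_start <- e1_end + 41L
  nov_end <- nov_start + nchar(novel_seq) - 1L
  e2_start <- nov_end + 41L
  e2_end <- e2_start + 18L + utr3 - 1L
  genome <- Biostrings::DNAStringSet(setNames(contig, "c"))
  canonical <- transcript_model("t1", "g", "c", "+",
                                c(e1_start, e2_start), c(e1_end, e2_end),
                                cds_start = e1_start + 10L,
                                cds_end = e2_start + 17L)
  list(genome = genome, canonical = canonical,
       nov_start = nov_start, nov_end = nov_end)
}

test_that("variant construction inserts the exon between its flanks", {
  tm <- transcript_model("t", "g", "c", "+", c(101, 301, 501), c(200, 400, 600))
  v <- build_variant_transcript(tm, 430, 470)
  expect_identical(n_exons(v), 4L)
  expect_identical(v$exon_starts, c(101L, 301L, 430L, 501L))
  ## minus strand: same genomic insertion, exon order still genomic
  tmm <- transcript_model("t", "g", "c", "-", c(101, 301, 501), c(200, 400, 600))
  vm <- build_variant_transcript(tmm, 430, 470)
  expect_identical(vm$exon_starts, c(101L, 301L, 430L, 501L))
  ## overlap with an annotated exon is rejected
  expect_error(build_variant_transcript(tm, 390, 430), "not strictly inside")
  expect_error(build_variant_transcript(tm, 401, 470), "boundary")
})

test_that("the Mga-like fixture gains 145 nt and a PTC after five codons", {
  fx <- make_mga_fixture(1)
  v <- build_variant_transcript(fx$canonical, fx$novel_exon[["start"]],
                                fx$novel_exon[["end"]])
  expect_identical(spliced_length(v), spliced_length(fx$canonical) + 145L)
  cons <- annotate_orf_consequence(v, fx$canonical, fx$genome, fx$domains)
  expect_identical(cons$category, "ptc_in_novel_exon")
  expect_identical(cons$added_codons_before_stop, 5L)
  expect_true("bHLHZ" %in% cons$lost_domains)
  expect_false("T-box" %in% cons$lost_domains)
  expect_true(cons$nmd_sensitive)
  expect_gt(cons$distance_ptc_to_last_junction, 50L)
})

test_that("a frame-preserving stop-free exon is an in-frame addition", {
  g <- toy_coding_gene("GCAGCAGCA")
  v <- build_variant_transcript(g$canonical, g$nov_start, g$nov_end)
  cons <- annotate_orf_consequence(v, g$canonical, g$genome)
  expect_identical(cons$category, "in_frame_addition")
  expect_identical(cons$truncated_protein_length,
                   cons$canonical_protein_length + 3L)
  expect_identical(cons$lost_domains, character(0))
  ## frame identity: the variant transcript is the canonical one with a
  ## contiguous inserted block; prefix and suffix match exactly
  S_can <- oracle_splice(g$canonical, g$genome)
  S_var <- oracle_splice(v, g$genome)
  p0 <- oracle_map(g$canonical, g$canonical$cds_start)
  b1 <- oracle_map(v, g$nov_start)
  expect_identical(substr(S_var, 1, b1 - 1), substr(S_can, 1, b1 - 1))
  expect_identical(substr(S_var, b1 + 9, nchar(S_var)),
                   substr(S_can, b1, nchar(S_can)))
})

test_that("an exon with a codon containing N never reads as a stop", {
  g <- toy_coding_gene("GCANNAGCA")
  v <- build_variant_transcript(g$canonical, g$nov_start, g$nov_end)
  cons <- annotate_orf_consequence(v, g$canonical, g$genome)
  expect_identical(cons$category, "in_frame_addition")
})

test_that("a frame-breaking exon yields a downstream frameshift PTC", {
  ## 10 nt, no stop in the incoming frame inside the exon
  g <- toy_coding_gene("GCAGCAGCAG")
  v <- build_variant_transcript(g$canonical, g$nov_start, g$nov_end)
  cons <- annotate_orf_consequence(v, g$canonical, g$genome)
  expect_identical(cons$category, "frameshift_ptc")
  expect_true(is.na(cons$added_codons_before_stop))
})

test_that("insertion into a UTR intron leaves the protein unchanged", {
  ## gene with a non-coding leading exon: force an insertion upstream of
  ## the start codon
  set.seed(123)
  repeat {
    g <- simulate_random_coding_gene()
    cds_exon1 <- which(g$canonical$exon_starts <= g$canonical$cds_start &
                       g$canonical$cds_start <= g$canonical$exon_ends)
    if (cds_exon1 == 2L) break
  }
  introns <- transcript_introns(g$canonical)
  v <- build_variant_transcript(g$canonical, introns$start[1] + 3L,
                                introns$start[1] + 12L)
  expect_warning(cons <- annotate_orf_consequence(v, g$canonical, g$genome),
                 "untranslated")
  expect_identical(cons$category, "no_change")
  expect_identical(cons$truncated_protein_length, cons$canonical_protein_length)
})

test_that("an invalid canonical CDS is rejected", {
  g <- toy_coding_gene("GCAGCAGCA")
  broken <- g$canonical
  broken$cds_start <- broken$cds_start + 3L  # no longer starts at ATG
  v <- build_variant_transcript(g$canonical, g$nov_start, g$nov_end)
  expect_error(annotate_orf_consequence(v, broken, g$genome), "ATG")
})

test_that("consequence categories agree with the brute-force oracle", {
  set.seed(57)
  agree <- 0L
  n <- 150L
  for (i in seq_len(n)) {
    gn <- simulate_random_coding_gene()
    v <- build_variant_transcript(gn$canonical, gn$novel_start, gn$novel_end)
    got <- suppressWarnings(annotate_orf_consequence(v, gn$canonical, gn$genome))
    want <- orf_oracle(v, gn$canonical, gn$genome)
    expect_identical(got$category, want$category)
    if (got$category == "ptc_in_novel_exon") {
      expect_identical(got$added_codons_before_stop, want$added)
    }
    if (got$category %in% c("ptc_in_novel_exon", "frameshift_ptc") &&
        !is.na(got$ptc_spliced_position)) {
      expect_identical(got$nmd_sensitive, want$nmd)
    }
    agree <- agree + 1L
  }
  expect_identical(agree, n)
})

test_that("the 50-nt rule uses a strict boundary and spares last-exon stops", {
  mk <- function(dist) {
    structure(list(category = "ptc_in_novel_exon",
                   distance_ptc_to_last_junction = dist),
              class = "orf_consequence")
  }
  expect_true(predict_nmd(mk(200)))
  expect_false(predict_nmd(mk(50)))   # exactly at the rule distance
  expect_true(predict_nmd(mk(51)))
  expect_false(predict_nmd(mk(-10)))  # stop in the last exon
  no_ptc <- structure(list(category = "in_frame_addition",
                           distance_ptc_to_last_junction = NA_integer_),
                      class = "orf_consequence")
  expect_error(predict_nmd(no_ptc), "PTC")
})

test_that("domain loss is reported iff aa_end exceeds the truncation", {
  fx <- make_mga_fixture(1)
  v <- build_variant_transcript(fx$canonical, 3600, 3744)
  set.seed(5)
  doms <- data.frame(gene_id = "Mga_like",
                     domain_name = sprintf("d%02d", 1:20),
                     aa_start = sample(1:400, 20), stringsAsFactors = FALSE)
  doms$aa_end <- doms$aa_start + sample(10:90, 20)
  cons <- annotate_orf_consequence(v, fx$canonical, fx$genome, doms)
  expect_setequal(cons$lost_domains,
                  doms$domain_name[doms$aa_end > cons$truncated_protein_length])
})

test_that("PTC fractions are computed over classified gain events", {
  mk <- function(cat) structure(list(category = cat), class = "orf_consequence")
  four <- list(mk("ptc_in_novel_exon"), mk("frameshift_ptc"),
               mk("in_frame_addition"), mk("in_frame_addition"))
  f <- ptc_fraction(four)
  expect_equal(f$ptc_fraction, 0.5)
  expect_equal(f$in_frame_fraction, 0.5)
  expect_equal(f$ptc_fraction + f$in_frame_fraction, 1)
  all_inframe <- list(mk("in_frame_addition"), mk("in_frame_addition"))
  expect_equal(ptc_fraction(all_inframe)$ptc_fraction, 0)
  expect_error(ptc_fraction(list()), "no consequences")
})

test_that("NMD efficiency is the clipped 1 - untreated/treated ratio", {
  assay <- data.frame(stage = c("a", "a", "b", "b", "c", "c"),
                      replicate = 1L, treated = c(0L, 1L, 0L, 1L, 0L, 1L),
                      abundance = c(1, 4, 3, 3, 5, 4))
  est <- estimate_nmd_efficiency(assay)
  expect_equal(est$efficiency, c(0.75, 0, 0))
  expect_identical(est$flagged_low_nmd, c(FALSE, TRUE, TRUE))
  bad <- assay; bad$abundance[1] <- 0
  expect_error(estimate_nmd_efficiency(bad), "positive")
})
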