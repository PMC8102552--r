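test_that("genome readers enforce the {A,C,G,T,N} alphabet and bounds", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "ACGTNACGT"), fa)
  g <- read_genome_fasta(fa)
  expect_identical(names(g), "chr1")
  expect_identical(genome_subseq(g, "chr1", 2, 5), "CGTN")
  expect_identical(nchar(genome_subseq(g, "chr1", 1, 9)), 9L)
  expect_error(genome_subseq(g, "chr1", 5, 20), "beyond")
  expect_error(genome_subseq(g, "chrX", 1, 2), "not present")

  bad <- tempfile(fileext = ".fa")
  writeLines(c(">c", "ACGRT"), bad)
  expect_error(read_genome_fasta(bad), "outside")
})

test_that("transcript models enforce exon and CDS invariants", {
  expect_error(transcript_model("t", "g", "c", "*", 1, 10), "strand")
  expect_error(transcript_model("t", "g", "c", "+", c(1, 15), c(20, 30)),
               "disjoint")
  expect_error(transcript_model("t", "g", "c", "+", c(1, 25), c(20, 40),
                                cds_start = 5, cds_end = 50),
               "outside the exon union")
  tm <- transcript_model("t", "g", "c", "+", c(21, 1), c(30, 18))  # unsorted input
  expect_identical(tm$exon_starts, c(1L, 21L))
  expect_identical(transcript_introns(tm),
                   data.frame(start = 19L, end = 20L))
  expect_identical(spliced_length(tm), 28L)
})

test_that("spliced_sequence concatenates in transcription order", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c", "TTATGGGTAATT"), fa)
  g <- read_genome_fasta(fa)
  plus <- transcript_model("p", "g", "c", "+", c(3, 8), c(5, 10))
  expect_identical(spliced_sequence(plus, g), "ATGTAA")
  ## the same gene encoded on the minus strand of the mirrored contig
  ## yields the identical mature sequence (strand symmetry)
  flipped <- chartr("ACGT", "TGCA",
                    paste(rev(strsplit("TTATGGGTAATT", "")[[1]]), collapse = ""))
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">c", flipped), fa2)
  g2 <- read_genome_fasta(fa2)
  minus <- transcript_model("m", "g", "c", "-", c(13 - 10, 13 - 5), c(13 - 8, 13 - 3))
  expect_identical(spliced_sequence(minus, g2), "ATGTAA")
  ## out-of-bounds exon
  oob <- transcript_model("o", "g", "c", "+", c(3, 8), c(5, 40))
  expect_error(spliced_sequence(oob, g), "beyond")
})

test_that("spliced length equals the sum of exon lengths on random genes", {
  set.seed(42)
  for (i in 1:100) {
    gn <- simulate_random_coding_gene()
    s <- spliced_sequence(gn$canonical, gn$genome)
    expect_identical(nchar(s), as.integer(spliced_length(gn$canonical)))
  }
})

test_that("genomic_to_spliced agrees with an explicit recount on both strands", {
  set.seed(7)
  for (i in 1:25) {
    gn <- simulate_random_coding_gene()
    tm <- gn$canonical
    for (p in c(tm$exon_starts, tm$exon_ends, tm$cds_start, tm$cds_end)) {
      expect_identical(genomic_to_spliced(tm, p), oracle_map(tm, p))
    }
    intron1 <- transcript_introns(tm)[1, ]
    expect_error(genomic_to_spliced(tm, intron1$start), "not exonic")
  }
})

test_that("GFF3 read -> write -> read is a fixed point", {
  fx <- make_mga_fixture(1)
  p1 <- tempfile(fileext = ".gff3")
  write_gff3(list(fx$canonical), p1)
  t1 <- read_gff3(p1)
  expect_length(t1, 1L)
  expect_identical(t1[[1]]$exon_starts, fx$canonical$exon_starts)
  expect_identical(t1[[1]]$cds_start, fx$canonical$cds_start)
  p2 <- tempfile(fileext = ".gff3")
  write_gff3(t1, p2)
  expect_identical(readLines(p1), readLines(p2))

  ## also on a small simulated cohort with both strands and CDS features
  b <- simulate_cohort(cohort_config(n_genes = 12, seed = 5))
  tms <- unlist(b$transcripts, recursive = FALSE, use.names = FALSE)
  p3 <- tempfile(fileext = ".gff3")
  write_gff3(tms, p3)
  t3 <- read_gff3(p3)
  expect_length(t3, length(tms))
  p4 <- tempfile(fileext = ".gff3")
  write_gff3(t3, p4)
  expect_identical(readLines(p3), readLines(p4))
})

test_that("GFF3 reader flags malformed hierarchies and degenerate files", {
  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_warning(res <- read_gff3(empty), "no features")
  expect_identical(res, list())

  orphan <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c\tx\texon\t1\t10\t.\t+\t.\tID=e1;Parent=ghost"), orphan)
  expect_error(suppressWarnings(read_gff3(orphan)), "no mRNA")

  bad_cds <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c\tx\tgene\t1\t100\t.\t+\t.\tID=g1",
               "c\tx\tmRNA\t1\t100\t.\t+\t.\tID=m1;Parent=g1",
               "c\tx\texon\t1\t40\t.\t+\t.\tID=e1;Parent=m1",
               "c\tx\tCDS\t30\t60\t.\t+\t0\tID=c1;Parent=m1"), bad_cds)
  expect_error(read_gff3(bad_cds), "outside its exons")
})

test_that("junction count records validate their inputs", {
  expect_error(junction_count_record("e", "s", integer(0), 5), "non-empty")
  expect_error(junction_count_record("e", "s", c(3, -1), 5), "non-negative")
  r <- junction_count_record("e", "s", c(3, 4), 5)
  expect_identical(r$inclusion, c(3L, 4L))

  tsv <- tempfile(fileext = ".tsv")
  write_junction_counts(list(r), tsv)
  back <- read_junction_counts(tsv)
  expect_length(back, 1L)
  expect_identical(back[[1]]$inclusion, r$inclusion)
  expect_identical(back[[1]]$skipping, r$skipping)
})
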