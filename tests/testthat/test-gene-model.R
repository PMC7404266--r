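test_that("TSS is the 5'-most exon boundary in transcription direction", {
  gm <- readGeneModel(two_exon_gtf("+"))
  expect_equal(transcriptSummary(gm)$tss, 1001)
  gm <- readGeneModel(two_exon_gtf("-"))
  expect_equal(transcriptSummary(gm)$tss, 1800)
})

test_that("empty input yields an empty model; malformed input is diagnosed", {
  gm <- readGeneModel(character(0))
  expect_s4_class(gm, "GeneModel")
  expect_length(geneIds(gm), 0)
  bad <- c(two_exon_gtf("+"), "chr1\tonly\tthree")
  expect_error(readGeneModel(bad), "line 3")
  orphan <- c(two_exon_gtf("+"),
              gtf_line("chr1", "transcript", 5000, 6000, "+", "g2", "t2"))
  expect_error(readGeneModel(orphan), "zero exons.*t2")
})

test_that("promoter windows match the fixed coordinate conventions", {
  # plus strand, TSS 1001: proximal covers 0-based [800,1050) = 1-based 801..1050
  gm <- readGeneModel(two_exon_gtf("+"))
  p <- derivePromoters(gm, "proximal")
  expect_equal(c(start(p), end(p)), c(801, 1050))
  expect_equal(GenomicRanges::width(p), 250)
  t <- derivePromoters(gm, "typical")
  expect_equal(c(start(t), end(t)), c(1, 1000))  # clipped at chromosome start
  # expanded: upstream bound clips at chromosome start; first intron is
  # 1-based 1201..1500, so the region ends at 1500
  e <- derivePromoters(gm, "expanded")
  expect_equal(c(start(e), end(e)), c(1, 1500))
  expect_false(mcols(e)$no_first_intron)

  # minus strand, TSS 1-based 2000: proximal = 0-based [1950,2200)
  gtf <- c(gtf_line("chr1", "exon", 1001, 1400, "-", "g1", "t1"),
           gtf_line("chr1", "exon", 1701, 2000, "-", "g1", "t1"))
  gmm <- readGeneModel(gtf)
  expect_equal(transcriptSummary(gmm)$tss, 2000)
  pm <- derivePromoters(gmm, "proximal")
  expect_equal(c(start(pm), end(pm)), c(1951, 2200))
  tm <- derivePromoters(gmm, "typical")
  expect_equal(c(start(tm), end(tm)), c(2001, 4000))
  # first intron in transcription direction: genomic 1401..1700
  em <- derivePromoters(gmm, "expanded")
  expect_equal(c(start(em), end(em)), c(1401, 4000))
})

test_that("single-exon transcripts get a flagged expanded region to the 3' end", {
  gm <- readGeneModel(gtf_line("chr1", "exon", 5001, 6000, "+", "g1", "t1"))
  e <- derivePromoters(gm, "expanded")
  expect_true(mcols(e)$no_first_intron)
  expect_equal(c(start(e), end(e)), c(3001, 6000))
})

test_that("representative transcript is the 5'-most TSS, ties by transcript id", {
  gtf <- c(two_exon_gtf("+", "g1", "tB"),
           gtf_line("chr1", "exon", 901, 1200, "+", "g1", "tA2"),
           gtf_line("chr1", "exon", 901, 1200, "+", "g1", "tA1"))
  rep <- representativeTranscripts(readGeneModel(gtf))
  expect_equal(rep$transcript_id, "tA1")  # TSS 901 beats 1001; tie -> tA1
  # minus strand: largest TSS wins
  gtf2 <- c(gtf_line("chr1", "exon", 1001, 2000, "-", "g2", "tX"),
            gtf_line("chr1", "exon", 1001, 2500, "-", "g2", "tY"))
  expect_equal(representativeTranscripts(readGeneModel(gtf2))$transcript_id, "tY")
})

test_that("strand mirror property holds on random gene models", {
  set.seed(42)
  L <- 100000L
  for (rep_i in 1:20) {
    e1s <- sample(5000:50000, 1)
    e1w <- sample(100:400, 1); intr <- sample(200:800, 1); e2w <- sample(100:600, 1)
    e1 <- c(e1s, e1s + e1w)
    e2 <- c(e1[2] + intr, e1[2] + intr + e2w)
    fw <- readGeneModel(c(gtf_line("chr1", "exon", e1[1], e1[2], "+", "g", "t"),
                          gtf_line("chr1", "exon", e2[1], e2[2], "+", "g", "t")))
    # reflect: x -> L + 1 - x, flip strand
    rv <- readGeneModel(c(
      gtf_line("chr1", "exon", L + 1 - e2[2], L + 1 - e2[1], "-", "g", "t"),
      gtf_line("chr1", "exon", L + 1 - e1[2], L + 1 - e1[1], "-", "g", "t")))
    for (kind in c("proximal", "typical", "expanded")) {
      a <- derivePromoters(fw, kind)
      b <- derivePromoters(rv, kind)
      expect_equal(start(b), L + 1 - end(a))
      expect_equal(end(b), L + 1 - start(a))
    }
  }
})

test_that("proximal lies within expanded for multi-exon genes and spans hold", {
  set.seed(7)
  for (rep_i in 1:10) {
    s <- sample(10000:40000, 1)
    gtf <- c(gtf_line("chr1", "exon", s, s + 150, "+", "g", "t"),
             gtf_line("chr1", "exon", s + 500, s + 900, "+", "g", "t"))
    gm <- readGeneModel(gtf)
    p <- derivePromoters(gm, "proximal")
    e <- derivePromoters(gm, "expanded")
    expect_true(start(e) <= start(p) && end(p) <= end(e))
    expect_equal(GenomicRanges::width(p), 250)
    expect_equal(GenomicRanges::width(derivePromoters(gm, "typical")), 2000)
    expect_gte(GenomicRanges::width(e), 2000)
  }
})

test_that("BED round trip preserves intervals and metadata", {
  gm <- readGeneModel(two_exon_gtf("+"))
  p <- derivePromoters(gm, "proximal")
  f <- tempfile(fileext = ".bed")
  exportPromotersBed(p, f)
  # BED is 0-based half-open: first line should carry 800 and 1050
  fields <- strsplit(readLines(f)[1], "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(800L, 1050L))
  expect_equal(fields[4], "g1|proximal")
  back <- importPromotersBed(f)
  expect_equal(start(back), start(p))
  expect_equal(end(back), end(p))
  expect_equal(mcols(back)$gene_id, "g1")
  expect_equal(mcols(back)$kind, "proximal")
})
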