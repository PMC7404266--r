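test_that("readCpgCalls applies the depth filter and rejects bad ratios", {
  lines <- c(call_line("chr1", 100, 0.5, 9),
             call_line("chr1", 200, 0.5, 10),
             call_line("chr1", 150, 0.4, 30))
  calls <- readCpgCalls(lines, min_depth = 10)
  expect_equal(start(calls), c(150, 200))  # depth 9 excluded, sorted
  expect_equal(mcols(calls)$depth, c(30L, 10L))

  expect_warning(bad <- readCpgCalls(c(call_line("chr1", 10, 1.2, 30),
                                       call_line("chr1", 20, 0.9, 30))),
                 "outside \\[0,1\\]")
  expect_equal(start(bad), 20)

  expect_length(readCpgCalls(character(0)), 0)

  # header line tolerated
  withhdr <- c("chr\tpos\tstrand\tcontext\tratio\teff_CT_count", lines)
  expect_equal(length(readCpgCalls(withhdr, min_depth = 10)), 2L)
})

test_that("bedGraph input is position-normalized and skips the depth filter", {
  bg <- c("chr1\t99\t100\t0.25", "chr1\t199\t200\t0.75")
  expect_warning(calls <- readCpgCalls(bg), "depth filter skipped")
  expect_equal(start(calls), c(100, 200))  # 0-based start -> 1-based pos
  expect_equal(mcols(calls)$ratio, c(0.25, 0.75))
  expect_true(all(is.na(mcols(calls)$depth)))
})

test_that("region aggregation means ratios of in-region CpGs", {
  region <- GRanges("chr1", IRanges(801, 1050), strand = "+",
                    gene_id = "g1", kind = "proximal")
  calls <- readCpgCalls(c(call_line("chr1", 900, 0.2, 30),
                          call_line("chr1", 1000, 0.4, 30),
                          call_line("chr1", 1051, 0.9, 30)))  # outside
  se <- aggregateRegionMethylation(list(sA = calls), region)
  expect_equal(unname(methLevels(se)[1, 1]), 0.3)
  expect_equal(unname(nCpgs(se)[1, 1]), 2L)

  # zero CpGs in region -> missing cell; absent chromosome -> missing cell
  far <- GRanges(c("chr1", "chr9"), IRanges(c(5000, 10), c(6000, 400)),
                 gene_id = c("g2", "g3"), kind = "proximal")
  se2 <- aggregateRegionMethylation(list(sA = calls), far)
  expect_true(all(is.na(methLevels(se2))))
  expect_equal(unname(nCpgs(se2)[, 1]), c(0L, 0L))
})

test_that("aggregation agrees with a naive per-base scan on random genomes", {
  set.seed(99)
  for (rep_i in 1:5) {
    n_cpg <- 200
    pos <- sort(sample.int(10000L, n_cpg))
    ratio <- round(runif(n_cpg), 4)
    lines <- vapply(seq_len(n_cpg), function(i)
      call_line("chrR", pos[i], ratio[i], 30), character(1))
    calls <- readCpgCalls(lines)
    rs <- sort(sample.int(9000L, 10))
    regions <- GRanges("chrR", IRanges(rs, rs + sample(100:900, 10, TRUE)),
                       gene_id = paste0("g", 1:10), kind = "proximal")
    se <- aggregateRegionMethylation(list(s = calls), regions, min_cpgs = 1)
    # oracle: exhaustive membership scan over every base of every region
    for (j in seq_along(regions)) {
      member <- ratio[pos %in% seq(start(regions)[j], end(regions)[j])]
      if (length(member) == 0) {
        expect_true(is.na(methLevels(se)[j, 1]))
      } else {
        expect_equal(unname(methLevels(se)[j, 1]), mean(member), tolerance = 1e-12)
        expect_equal(unname(nCpgs(se)[j, 1]), length(member))
      }
    }
    # order invariance
    sh <- sample(n_cpg)
    se_sh <- aggregateRegionMethylation(list(s = readCpgCalls(lines[sh])), regions)
    expect_equal(methLevels(se_sh), methLevels(se))
  }
})

test_that("raising min_depth never increases CpG counts and weighting works", {
  lines <- c(call_line("chr1", 10, 0.2, 10), call_line("chr1", 20, 0.8, 40))
  region <- GRanges("chr1", IRanges(1, 100), gene_id = "g", kind = "proximal")
  n1 <- nCpgs(aggregateRegionMethylation(list(s = readCpgCalls(lines, 10)), region))
  n2 <- nCpgs(aggregateRegionMethylation(list(s = readCpgCalls(lines, 20)), region))
  expect_true(all(n2 <= n1))
  w <- aggregateRegionMethylation(list(s = readCpgCalls(lines, 10)), region,
                                  weighted = TRUE)
  expect_equal(unname(methLevels(w)[1, 1]), (10 * 0.2 + 40 * 0.8) / 50)
})

test_that("promoter methylation summary reports percentages per kind", {
  m <- matrix(0.10, 2, 3)
  expect_equal(unname(promoterMethylationSummary(prox = m)), 10)
  expect_equal(unname(promoterMethylationSummary(x = matrix(c(0, 1), 1))), 50)
  expect_error(promoterMethylationSummary(x = matrix(NA_real_, 2, 2)), "missing")
})

test_that("simulated proximal promoters are hypomethylated relative to typical", {
  sim <- simulateMultiomics(simConfig(seed = 21, n_tsg_negative = 10,
                                      n_tsg_positive = 5, n_null_genes = 30,
                                      samples_per_tissue = 3))
  gm <- readGeneModel(sim$gtf)
  regions <- c(derivePromoters(gm, "proximal"), derivePromoters(gm, "typical"))
  calls <- lapply(sim$calls, function(df) {
    readCpgCalls(vapply(seq_len(nrow(df)), function(i)
      call_line(df$chr[i], df$pos[i], df$ratio[i], df$eff_CT_count[i]),
      character(1)))
  })
  se <- aggregateRegionMethylation(calls, regions)
  s <- promoterMethylationSummary(se)
  expect_lt(s["proximal"], s["typical"])
  expect_true(all(methLevels(se) >= 0 & methLevels(se) <= 1, na.rm = TRUE))
})
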