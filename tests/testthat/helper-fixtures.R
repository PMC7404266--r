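# small in-code fixture builders shared across test files

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

gtf_line <- function(chrom, type, start, end, strand, gene, tx) {
  sprintf('%s\tsrc\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
          chrom, type, start, end, strand, gene, tx)
}

# a two-exon transcript: exons [1001,1200] and [1501,1800]
two_exon_gtf <- function(strand = "+", gene = "g1", tx = "t1", chrom = "chr1") {
  c(gtf_line(chrom, "exon", 1001, 1200, strand, gene, tx),
    gtf_line(chrom, "exon", 1501, 1800, strand, gene, tx))
}

call_line <- function(chrom, pos, ratio, depth, strand = "+") {
  paste(chrom, pos, strand, "CG", ratio, depth, sep = "\t")
}

tiny_tpm <- function() {
  m <- matrix(c(0, 2, 4, 1, 3, 5, 10, 0, 1, 2, 8, 0), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2", "s3", "s4")))
  m
}

tiny_sheet <- function(samples = c("s1", "s2", "s3", "s4"),
                       tissue = c("liver", "liver", "brain", "brain")) {
  data.frame(sample = samples, tissue = tissue,
             batch = rep("b1", length(samples)), stringsAsFactors = FALSE)
}

tiny_experiment <- function() {
  TPMExperiment(tiny_tpm(), tiny_sheet())
}

write_tsv_tmp <- function(df, ...) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  f
}

# textbook Pearson correlation, written out from the definition; serves as
# the independent oracle for every cor()-based code path
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# exhaustive hypergeometric upper tail by enumerating all draws of size n
# from the background; feasible for N <= 12
hyper_tail_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # treat items 1..K as the set members
  mean(hits >= k)
}
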