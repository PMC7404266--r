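#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end strand granges findOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames rowData colData
NULL

#' GeneModel: transcript structures parsed from a GTF annotation
#'
#' Holds exon intervals grouped by transcript and gene, plus a per-transcript
#' summary (span and transcription start site). Coordinates are 1-based closed
#' genomic intervals, the Bioconductor convention; BED interchange converts to
#' 0-based half-open on export.
#'
#' @slot exons A [GenomicRanges::GRanges] of exons with metadata columns
#'   `transcript_id` and `gene_id`.
#' @slot transcripts A [GenomicRanges::GRanges] with one range per transcript
#'   (the exon span) and metadata columns `transcript_id`, `gene_id`, `tss`
#'   (1-based transcription start site) and `n_exons`.
#'
#' @seealso [readGeneModel()], [derivePromoters()]
#' @export
setClass("GeneModel",
  representation(exons = "GRanges", transcripts = "GRanges"))

setValidity("GeneModel", function(object) {
  ex <- object@exons
  tx <- object@transcripts
  msgs <- character()
  need_ex <- c("transcript_id", "gene_id")
  if (!all(need_ex %in% colnames(mcols(ex))))
    msgs <- c(msgs, "exons must carry transcript_id and gene_id")
  need_tx <- c("transcript_id", "gene_id", "tss", "n_exons")
  if (!all(need_tx %in% colnames(mcols(tx))))
    msgs <- c(msgs, "transcripts must carry transcript_id, gene_id, tss, n_exons")
  if (length(msgs) == 0L && length(tx) > 0L) {
    if (any(mcols(tx)$n_exons < 1L))
      msgs <- c(msgs, "every transcript must have at least one exon")
    # non-overlapping exons within each transcript
    sp <- split(ex, mcols(ex)$transcript_id)
    ovl <- vapply(sp, function(g) {
      if (length(g) < 2L) return(FALSE)
      o <- order(start(g))
      any(start(g)[o][-1L] <= end(g)[o][-length(g)])
    }, logical(1))
    if (any(ovl))
      msgs <- c(msgs, paste0("overlapping exons in transcript(s): ",
                             paste(names(sp)[ovl], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' TPMExperiment: a gene x sample TPM matrix with sample annotation
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `"tpm"` assay holds
#' non-negative transcripts-per-million values; `colData` carries `tissue`
#' and `batch` labels from the sample sheet.
#'
#' @seealso [TPMExperiment()], [loadExpression()]
#' @export
setClass("TPMExperiment", contains = "SummarizedExperiment")

setValidity("TPMExperiment", function(object) {
  msgs <- character()
  if (!"tpm" %in% assayNames(object))
    msgs <- c(msgs, "assay 'tpm' is required")
  else {
    v <- assay(object, "tpm")
    if (anyNA(v) || any(v < 0))
      msgs <- c(msgs, "TPM values must be non-negative and non-missing")
  }
  if (!all(c("tissue", "batch") %in% colnames(colData(object))))
    msgs <- c(msgs, "colData must have 'tissue' and 'batch' columns")
  if (length(msgs)) msgs else TRUE
})

#' RegionMethExperiment: promoter-region mean methylation per sample
#'
#' A [SummarizedExperiment::SummarizedExperiment] with assays `"meth"`
#' (mean methylation level per region and sample, in [0,1] or `NA` when too
#' few CpGs contribute) and `"n_cpgs"` (the count of contributing CpGs).
#' `rowData` carries `gene_id` and promoter `kind`.
#'
#' @seealso [aggregateRegionMethylation()]
#' @export
setClass("RegionMethExperiment", contains = "SummarizedExperiment")

setValidity("RegionMethExperiment", function(object) {
  msgs <- character()
  if (!all(c("meth", "n_cpgs") %in% assayNames(object)))
    msgs <- c(msgs, "assays 'meth' and 'n_cpgs' are required")
  else {
    m <- assay(object, "meth")
    ok <- is.na(m) | (m >= 0 & m <= 1)
    if (!all(ok)) msgs <- c(msgs, "methylation values must be in [0,1] or NA")
  }
  if (!all(c("gene_id", "kind") %in% colnames(rowData(object))))
    msgs <- c(msgs, "rowData must have 'gene_id' and 'kind' columns")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GeneModel-class Number of genes, transcripts and exons.
#' @param object A `GeneModel`.
#' @export
setMethod("show", "GeneModel", function(object) {
  cat("GeneModel with", length(unique(mcols(object@transcripts)$gene_id)),
      "genes,", length(object@transcripts), "transcripts,",
      length(object@exons), "exons\n")
  invisible(NULL)
})
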