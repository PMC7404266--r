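#' Read a gene model from GTF annotation
#'
#' Parses exon features from a GENCODE-like GTF and assembles one record per
#' transcript with its transcription start site (TSS): the 5'-most exon
#' boundary in transcription direction (minimum exon start on `+`, maximum
#' exon end on `-`). Genes are ordered deterministically by chromosome and
#' gene start.
#'
#' @param annotation Path to a GTF file, or a character vector of GTF lines.
#' @return A [GeneModel-class] object.
#' @details Only `exon` features are used to build transcript structures;
#'   `transcript` features that have no exon records are rejected with a
#'   diagnostic. Malformed lines (fewer than 9 tab-delimited fields) raise a
#'   parse error naming the line number. An empty input yields an empty
#'   `GeneModel`.
#' @examples
#' gtf <- c(
#'   'chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
#'   'chr1\tsrc\texon\t1501\t1800\t.\t+\t.\tgene_id "g1"; transcript_id "t1";')
#' gm <- readGeneModel(gtf)
#' transcriptSummary(gm)$tss  # 1001
#' @export
readGeneModel <- function(annotation) {
  if (length(annotation) == 1L && !grepl("\n", annotation) && file.exists(annotation)) {
    lines <- readLines(annotation)
  } else {
    lines <- as.character(unlist(strsplit(as.character(annotation), "\n", fixed = TRUE)))
  }
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-delimited fields, got ",
         nf[which(nf < 9L)[1L]])
  }
  if (!any(body)) return(emptyGeneModel())

  tf <- tempfile(fileext = ".gtf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  gr <- rtracklayer::import(tf, format = "gtf")

  if (!all(c("gene_id", "transcript_id") %in% colnames(mcols(gr))))
    stop("GTF attributes must include gene_id and transcript_id")
  ex <- gr[mcols(gr)$type == "exon"]
  # transcript features with zero exon records are structural errors
  tx_feat <- unique(mcols(gr)$transcript_id[mcols(gr)$type == "transcript"])
  tx_feat <- tx_feat[!is.na(tx_feat)]
  orphan <- setdiff(tx_feat, unique(mcols(ex)$transcript_id))
  if (length(orphan))
    stop("transcript(s) with zero exons: ", paste(orphan, collapse = ", "))
  if (length(ex) == 0L) return(emptyGeneModel())
  if (anyNA(mcols(ex)$gene_id) || anyNA(mcols(ex)$transcript_id))
    stop("exon feature missing gene_id or transcript_id attribute")

  mcols(ex) <- mcols(ex)[, c("transcript_id", "gene_id")]
  ex <- sort(ex, ignore.strand = TRUE)

  txid <- mcols(ex)$transcript_id
  tx_start <- tapply(start(ex), txid, min)
  tx_end <- tapply(end(ex), txid, max)
  ids <- names(tx_start)
  first <- ex[!duplicated(txid)]
  info <- data.frame(
    transcript_id = ids,
    gene_id = mcols(first)$gene_id[match(ids, mcols(first)$transcript_id)],
    chrom = as.character(seqnames(first))[match(ids, mcols(first)$transcript_id)],
    strand = as.character(strand(first))[match(ids, mcols(first)$transcript_id)],
    start = as.integer(tx_start[ids]),
    end = as.integer(tx_end[ids]),
    n_exons = as.integer(table(txid)[ids]),
    stringsAsFactors = FALSE)
  info$tss <- ifelse(info$strand == "-", info$end, info$start)

  # deterministic ordering: (chrom, gene start), then transcript_id
  gstart <- tapply(info$start, info$gene_id, min)
  info <- info[order(info$chrom, gstart[info$gene_id], info$gene_id,
                     info$transcript_id), , drop = FALSE]
  tx <- GRanges(info$chrom, IRanges(info$start, info$end), strand = info$strand,
                transcript_id = info$transcript_id, gene_id = info$gene_id,
                tss = info$tss, n_exons = info$n_exons)
  new("GeneModel", exons = ex, transcripts = tx)
}

emptyGeneModel <- function() {
  ex <- GRanges()
  mcols(ex) <- DataFrame(transcript_id = character(), gene_id = character())
  tx <- GRanges()
  mcols(tx) <- DataFrame(transcript_id = character(), gene_id = character(),
                         tss = integer(), n_exons = integer())
  new("GeneModel", exons = ex, transcripts = tx)
}

#' GeneModel accessors
#'
#' `geneIds` returns the gene identifiers in deterministic (chromosome, gene
#' start) order; `transcriptSummary` returns the per-transcript table
#' (transcript_id, gene_id, chrom, strand, span, tss, n_exons);
#' `exonRanges` returns the exon [GenomicRanges::GRanges].
#'
#' @param x A `GeneModel`.
#' @return A character vector, `data.frame`, or `GRanges` respectively.
#' @name GeneModel-accessors
NULL

#' @rdname GeneModel-accessors
#' @export
setMethod("geneIds", "GeneModel", function(x)
  unique(mcols(x@transcripts)$gene_id))

#' @rdname GeneModel-accessors
#' @export
setMethod("transcriptSummary", "GeneModel", function(x) {
  tx <- x@transcripts
  data.frame(transcript_id = mcols(tx)$transcript_id,
             gene_id = mcols(tx)$gene_id,
             chrom = as.character(seqnames(tx)),
             strand = as.character(strand(tx)),
             start = start(tx), end = end(tx),
             tss = mcols(tx)$tss, n_exons = mcols(tx)$n_exons,
             stringsAsFactors = FALSE)
})

#' @rdname GeneModel-accessors
#' @export
setMethod("exonRanges", "GeneModel", function(x) x@exons)

#' Representative transcript per gene
#'
#' Selects, for each gene, the transcript whose TSS is 5'-most in
#' transcription direction (smallest TSS on `+`, largest on `-`); ties are
#' broken by lexicographically smallest `transcript_id`.
#'
#' @param model A `GeneModel`.
#' @return A `data.frame` with one row per gene: gene_id, transcript_id,
#'   chrom, strand, start, end, tss, n_exons.
#' @export
representativeTranscripts <- function(model) {
  ts <- transcriptSummary(model)
  if (nrow(ts) == 0L) return(ts[, c(2, 1, 3:8)])
  key <- ifelse(ts$strand == "-", -ts$tss, ts$tss)
  o <- order(ts$gene_id, key, ts$transcript_id)
  ts <- ts[o, , drop = FALSE]
  rep <- ts[!duplicated(ts$gene_id), , drop = FALSE]
  # restore deterministic gene order
  rep <- rep[order(match(rep$gene_id, geneIds(model))), , drop = FALSE]
  rownames(rep) <- NULL
  rep[, c("gene_id", "transcript_id", "chrom", "strand", "start", "end",
          "tss", "n_exons")]
}

# first intron of a transcript, 1-based closed genomic interval, in
# transcription direction; NULL for single-exon transcripts
firstIntron <- function(model, transcript_id) {
  ex <- model@exons[mcols(model@exons)$transcript_id == transcript_id]
  if (length(ex) < 2L) return(NULL)
  o <- order(start(ex))
  s <- start(ex)[o]; e <- end(ex)[o]
  if (as.character(strand(ex))[1] == "-") {
    k <- length(ex)  # first intron in transcription direction is the rightmost
    c(e[k - 1L] + 1L, s[k] - 1L)
  } else {
    c(e[1L] + 1L, s[2L] - 1L)
  }
}

#' Derive strand-aware promoter regions
#'
#' Computes promoter windows anchored on each gene's representative
#' transcript TSS (see [representativeTranscripts()]). With a 1-based TSS `t`
#' on the `+` strand:
#' \describe{
#'   \item{proximal}{`[t-200, t+49]` — 200 bases strictly upstream, the TSS
#'     base, and 49 further downstream bases (250 bp).}
#'   \item{typical}{`[t-2000, t-1]` — the 2 kb immediately upstream (2000 bp).}
#'   \item{expanded}{`[t-2000, end of first intron]`.}
#' }
#' On the `-` strand the windows are mirrored in transcription direction.
#' Coordinates are clipped at position 1 (chromosome start). For a
#' single-exon representative transcript, the expanded region runs to the
#' transcript 3' end and is flagged `no_first_intron`.
#'
#' @param model A `GeneModel`.
#' @param kind One of `"proximal"`, `"typical"`, `"expanded"`.
#' @param ... Unused.
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `kind` and `no_first_intron`; names are `gene_id|kind`.
#' @examples
#' gtf <- c(
#'   'chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
#'   'chr1\tsrc\texon\t1501\t1800\t.\t+\t.\tgene_id "g1"; transcript_id "t1";')
#' derivePromoters(readGeneModel(gtf), "proximal")  # chr1:801-1050
#' @rdname derivePromoters
#' @export
setMethod("derivePromoters", "GeneModel", function(model,
    kind = c("proximal", "typical", "expanded"), ...) {
  kind <- match.arg(kind)
  rep <- representativeTranscripts(model)
  if (nrow(rep) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(gene_id = character(), kind = character(),
                           no_first_intron = logical())
    return(gr)
  }
  n <- nrow(rep)
  s <- integer(n); e <- integer(n); flag <- logical(n)
  for (i in seq_len(n)) {
    t <- rep$tss[i]
    minus <- rep$strand[i] == "-"
    if (kind == "proximal") {
      win <- if (minus) c(t - 49L, t + 200L) else c(t - 200L, t + 49L)
    } else if (kind == "typical") {
      win <- if (minus) c(t + 1L, t + 2000L) else c(t - 2000L, t - 1L)
    } else {
      fi <- firstIntron(model, rep$transcript_id[i])
      if (is.null(fi)) {
        flag[i] <- TRUE
        win <- if (minus) c(rep$start[i], t + 2000L) else c(t - 2000L, rep$end[i])
      } else {
        win <- if (minus) c(fi[1L], t + 2000L) else c(t - 2000L, fi[2L])
      }
    }
    s[i] <- max(1L, win[1L]); e[i] <- win[2L]
  }
  gr <- GRanges(rep$chrom, IRanges(s, e), strand = rep$strand,
                gene_id = rep$gene_id, kind = kind, no_first_intron = flag)
  names(gr) <- paste(rep$gene_id, kind, sep = "|")
  gr
})

#' Write promoter regions to BED6
#'
#' Exports regions in BED's 0-based half-open convention, with
#' `name = gene_id|kind`, `score = 0` and the strand column populated.
#'
#' @param regions A `GRanges` from [derivePromoters()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
exportPromotersBed <- function(regions, path) {
  out <- granges(regions)
  mcols(out)$name <- paste(mcols(regions)$gene_id, mcols(regions)$kind, sep = "|")
  mcols(out)$score <- 0
  names(out) <- NULL
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read promoter regions from BED
#'
#' @param path A BED file written by [exportPromotersBed()] (or any BED whose
#'   name column is `gene_id|kind`).
#' @return A `GRanges` with `gene_id` and `kind` metadata columns.
#' @export
importPromotersBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- mcols(gr)$name
  parts <- strsplit(nm, "|", fixed = TRUE)
  mcols(gr)$gene_id <- vapply(parts, `[`, character(1), 1L)
  mcols(gr)$kind <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                           character(1))
  gr
}
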