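#' Read per-CpG methylation calls
#'
#' Reads whole-genome bisulfite methylation calls either from a BSMAP-ratio
#' style TSV — columns `(chrom, pos, strand, context, ratio, eff_CT_count)`,
#' extra columns tolerated, header optional — or from a 4-column bedGraph
#' (`chrom, start, end, ratio`; 0-based half-open, no coverage column, so the
#' depth filter is skipped with a warning). Calls with effective coverage
#' below `min_depth` are excluded. Records whose ratio falls outside [0,1]
#' are rejected individually with a diagnostic warning. Input need not be
#' sorted; calls are sorted internally.
#'
#' @param path Path to the calls file, or a character vector of lines.
#' @param min_depth Minimum effective coverage (default 10).
#' @param format `"auto"`, `"tsv"`, or `"bedgraph"`.
#' @return A [GenomicRanges::GRanges] of width-1 CpG positions (1-based) with
#'   metadata columns `ratio` and `depth` (`NA` depth for bedGraph input).
#' @export
readCpgCalls <- function(path, min_depth = 10, format = c("auto", "tsv", "bedgraph")) {
  format <- match.arg(format)
  if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    lines <- readLines(path)
  } else {
    lines <- unlist(strsplit(as.character(path), "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(lines) & !grepl("^(#|track)", lines)]
  if (length(lines) == 0L) return(emptyCpgCalls())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "auto") {
    f1 <- fields[[1L]]
    is_bg <- nf[1L] == 4L && !is.na(suppressWarnings(as.numeric(f1[2L]))) &&
      !is.na(suppressWarnings(as.numeric(f1[3L])))
    format <- if (is_bg) "bedgraph" else "tsv"
  }
  if (format == "bedgraph") {
    if (any(nf < 4L)) stop("bedGraph line with fewer than 4 fields")
    chrom <- vapply(fields, `[`, character(1), 1L)
    startv <- as.integer(vapply(fields, `[`, character(1), 2L))
    ratio <- as.numeric(vapply(fields, `[`, character(1), 4L))
    pos <- startv + 1L  # 0-based start -> 1-based position
    depth <- rep(NA_integer_, length(pos))
    str <- rep("*", length(pos))
    warning("bedGraph input carries no coverage column; depth filter skipped")
    keep_depth <- rep(TRUE, length(pos))
  } else {
    # drop a header line if the position field is non-numeric
    if (is.na(suppressWarnings(as.numeric(fields[[1L]][2L])))) {
      fields <- fields[-1L]; nf <- nf[-1L]
      if (length(fields) == 0L) return(emptyCpgCalls())
    }
    if (any(nf < 6L)) stop("methylation TSV line with fewer than 6 fields")
    chrom <- vapply(fields, `[`, character(1), 1L)
    pos <- as.integer(vapply(fields, `[`, character(1), 2L))
    str <- vapply(fields, `[`, character(1), 3L)
    str[!str %in% c("+", "-")] <- "*"
    ratio <- as.numeric(vapply(fields, `[`, character(1), 5L))
    depth <- as.integer(round(as.numeric(vapply(fields, `[`, character(1), 6L))))
    keep_depth <- depth >= min_depth
  }
  bad <- is.na(ratio) | ratio < 0 | ratio > 1
  if (any(bad)) {
    warning(sum(bad), " record(s) with methylation ratio outside [0,1] rejected, e.g. ",
            chrom[which(bad)[1L]], ":", pos[which(bad)[1L]])
  }
  keep <- !bad & keep_depth
  gr <- GRanges(chrom[keep], IRanges(pos[keep], pos[keep]), strand = str[keep],
                ratio = ratio[keep], depth = depth[keep])
  sort(gr, ignore.strand = TRUE)
}

emptyCpgCalls <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(ratio = numeric(), depth = integer())
  gr
}

#' Aggregate CpG calls to promoter-region mean methylation
#'
#' For every (region, sample) cell, takes the arithmetic mean of the
#' methylation ratios of the CpGs lying inside the region (unweighted by
#' default; optionally coverage-weighted). Cells with fewer than `min_cpgs`
#' contributing CpGs are `NA`. Calls on the `+` and `-` strands are treated
#' as independent records (no CpG-dyad merging). A region on a chromosome
#' absent from a sample's calls simply yields a missing cell.
#'
#' @param calls_by_sample Named list of `GRanges` from [readCpgCalls()], one
#'   per sample.
#' @param regions Promoter `GRanges` from [derivePromoters()] (metadata
#'   columns `gene_id`, `kind`).
#' @param min_cpgs Minimum CpGs per cell (default 1).
#' @param weighted Weight the mean by per-CpG coverage (default `FALSE`).
#' @return A [RegionMethExperiment-class] with assays `meth` and `n_cpgs`;
#'   rows are named `gene_id|kind`.
#' @export
aggregateRegionMethylation <- function(calls_by_sample, regions, min_cpgs = 1,
                                       weighted = FALSE) {
  stopifnot(is.list(calls_by_sample), length(calls_by_sample) > 0L)
  if (is.null(names(calls_by_sample)))
    stop("calls_by_sample must be a named list (names = sample ids)")
  nr <- length(regions); ns <- length(calls_by_sample)
  rn <- names(regions)
  if (is.null(rn)) rn <- paste(mcols(regions)$gene_id, mcols(regions)$kind, sep = "|")
  meth <- matrix(NA_real_, nr, ns, dimnames = list(rn, names(calls_by_sample)))
  ncp <- matrix(0L, nr, ns, dimnames = dimnames(meth))
  for (j in seq_len(ns)) {
    calls <- calls_by_sample[[j]]
    if (length(calls) == 0L) next
    hits <- findOverlaps(regions, calls, ignore.strand = TRUE)
    if (length(hits) == 0L) next
    ri <- S4Vectors::queryHits(hits)
    r <- mcols(calls)$ratio[S4Vectors::subjectHits(hits)]
    if (weighted) {
      w <- mcols(calls)$depth[S4Vectors::subjectHits(hits)]
      if (anyNA(w)) stop("coverage-weighted mean requested but depth is missing")
      sw <- tapply(w, ri, sum)
      swr <- tapply(w * r, ri, sum)
      idx <- as.integer(names(sw))
      meth[idx, j] <- as.numeric(swr / sw)
    } else {
      mv <- tapply(r, ri, mean)
      idx <- as.integer(names(mv))
      meth[idx, j] <- as.numeric(mv)
    }
    cnt <- table(ri)
    ncp[as.integer(names(cnt)), j] <- as.integer(cnt)
  }
  meth[ncp < min_cpgs] <- NA_real_
  rr <- granges(regions)
  mcols(rr) <- DataFrame(gene_id = mcols(regions)$gene_id,
                         kind = mcols(regions)$kind)
  names(rr) <- rn
  se <- SummarizedExperiment(assays = list(meth = meth, n_cpgs = ncp),
                             rowRanges = rr)
  metadata(se)$min_cpgs <- min_cpgs
  metadata(se)$weighted <- weighted
  new("RegionMethExperiment", se)
}

#' RegionMethExperiment accessors
#'
#' `methLevels` returns the region x sample mean-methylation matrix;
#' `nCpgs` the matrix of contributing CpG counts.
#'
#' @param x A `RegionMethExperiment`.
#' @name RegionMethExperiment-accessors
NULL

#' @rdname RegionMethExperiment-accessors
#' @export
setMethod("methLevels", "RegionMethExperiment", function(x) assay(x, "meth"))

#' @rdname RegionMethExperiment-accessors
#' @export
setMethod("nCpgs", "RegionMethExperiment", function(x) assay(x, "n_cpgs"))

#' Grand mean methylation per promoter kind
#'
#' Grand mean over all non-missing cells of each matrix, reported as a
#' percentage. Used to contrast proximal against typical promoter
#' methylation levels.
#'
#' @param ... Named region x sample methylation matrices or
#'   `RegionMethExperiment` objects; names default to the promoter kinds in
#'   `rowData`.
#' @return Named numeric vector of percentages.
#' @export
promoterMethylationSummary <- function(...) {
  args <- list(...)
  out <- numeric(0)
  for (i in seq_along(args)) {
    a <- args[[i]]
    if (is(a, "RegionMethExperiment")) {
      kinds <- unique(rowData(a)$kind)
      for (k in kinds) {
        m <- methLevels(a)[rowData(a)$kind == k, , drop = FALSE]
        if (all(is.na(m))) stop("all cells missing for kind '", k, "'")
        out[k] <- 100 * mean(m, na.rm = TRUE)
      }
    } else {
      m <- as.matrix(a)
      if (all(is.na(m))) stop("all cells missing in matrix ", i)
      nm <- names(args)[i]
      if (is.null(nm) || !nzchar(nm)) nm <- paste0("matrix", i)
      out[nm] <- 100 * mean(m, na.rm = TRUE)
    }
  }
  out
}

#' Write a RegionMethExperiment to TSV
#'
#' Writes the methylation matrix and a companion CpG-count matrix.
#'
#' @param x A `RegionMethExperiment`.
#' @param prefix Output path prefix; writes `<prefix>_meth.tsv` and
#'   `<prefix>_ncpgs.tsv`.
#' @return The two paths, invisibly.
#' @export
exportRegionMethylation <- function(x, prefix) {
  p1 <- paste0(prefix, "_meth.tsv")
  p2 <- paste0(prefix, "_ncpgs.tsv")
  writeMatrixTsv(methLevels(x), p1, id_col = "region")
  writeMatrixTsv(nCpgs(x), p2, id_col = "region")
  invisible(c(p1, p2))
}
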