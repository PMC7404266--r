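#' Construct a TPMExperiment
#'
#' @param tpm Numeric gene x sample matrix of TPM values (non-negative);
#'   rownames are gene ids, colnames sample ids.
#' @param sampleSheet `data.frame` with columns `sample`, `tissue`, `batch`.
#'   Every matrix sample must appear in the sheet; extra sheet rows are
#'   ignored.
#' @return A [TPMExperiment-class].
#' @export
TPMExperiment <- function(tpm, sampleSheet) {
  tpm <- as.matrix(tpm)
  need <- c("sample", "tissue", "batch")
  if (!all(need %in% colnames(sampleSheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(colnames(tpm), sampleSheet$sample)
  if (length(missing))
    stop("sample(s) in matrix absent from sample sheet: ",
         paste(missing, collapse = ", "))
  cd <- sampleSheet[match(colnames(tpm), sampleSheet$sample), , drop = FALSE]
  cd <- DataFrame(tissue = cd$tissue, batch = cd$batch, row.names = colnames(tpm))
  new("TPMExperiment",
      SummarizedExperiment(assays = list(tpm = tpm), colData = cd))
}

#' Load an expression matrix and sample sheet from TSV
#'
#' The matrix TSV has a header row of sample ids and gene ids in the first
#' column; the sheet TSV has columns `sample`, `tissue`, `batch`. Row and
#' column order are preserved from the input.
#'
#' @param matrixPath,sheetPath File paths.
#' @return A [TPMExperiment-class].
#' @export
loadExpression <- function(matrixPath, sheetPath) {
  raw <- utils::read.delim(matrixPath, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (anyDuplicated(raw[[1L]]))
    stop("duplicate gene_id row(s): ",
         paste(unique(raw[[1L]][duplicated(raw[[1L]])]), collapse = ", "))
  genes <- raw[[1L]]
  vals <- raw[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric expression value at gene '", genes[bad[1L, 1L]],
         "', sample '", colnames(vals)[bad[1L, 2L]], "': ",
         vals[bad[1L, 1L], bad[1L, 2L]])
  rownames(num) <- genes
  sheet <- utils::read.delim(sheetPath, stringsAsFactors = FALSE)
  TPMExperiment(num, sheet)
}

#' TPMExperiment accessors
#'
#' `tpm` returns the TPM assay matrix; `tissues` the per-sample tissue labels
#' (named by sample).
#'
#' @param x A `TPMExperiment`.
#' @name TPMExperiment-accessors
NULL

#' @rdname TPMExperiment-accessors
#' @export
setMethod("tpm", "TPMExperiment", function(x) assay(x, "tpm"))

#' @rdname TPMExperiment-accessors
#' @export
setMethod("tissues", "TPMExperiment", function(x) {
  tt <- colData(x)$tissue
  names(tt) <- colnames(x)
  tt
})

#' Filter genes by expression level
#'
#' `any_positive` keeps genes with maximum TPM > 0 across samples (genes with
#' TPM > 0 in at least one sample); `max_ge_one` keeps genes with maximum
#' TPM >= 1, i.e. drops genes whose TPM is below 1 in all samples (a gene
#' whose maximum equals exactly 1 is kept). Row order is preserved and the
#' operation is idempotent; an empty result is permitted.
#'
#' @param x A `TPMExperiment`.
#' @param mode `"any_positive"` or `"max_ge_one"`.
#' @return The filtered `TPMExperiment`.
#' @rdname filterExpressed
#' @export
setMethod("filterExpressed", "TPMExperiment", function(x,
    mode = c("any_positive", "max_ge_one")) {
  mode <- match.arg(mode)
  mx <- apply(tpm(x), 1L, max)
  keep <- if (mode == "any_positive") mx > 0 else mx >= 1
  x[keep, ]
})

#' Log-transform expression values
#'
#' Applies `log2(x + 1)`: zeros map to 0 and the transform is monotone.
#' Negative input is an error.
#'
#' @param x A numeric matrix/vector or a `TPMExperiment`.
#' @return An object of the same shape; for a `TPMExperiment`, a plain
#'   matrix of log2(TPM + 1) values.
#' @rdname logTransform
#' @export
setMethod("logTransform", "ANY", function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("negative values cannot be log-transformed")
  log2(x + 1)
})

#' @rdname logTransform
#' @export
setMethod("logTransform", "TPMExperiment", function(x) log2(tpm(x) + 1))

#' Pairwise sample correlation summary
#'
#' Computes the Pearson correlation matrix over samples and summarizes the
#' unordered off-diagonal pairs as mean within-tissue and mean between-tissue
#' correlation. Samples with zero variance across genes have their
#' correlations reported as `NA`, are excluded from the means, and trigger a
#' warning.
#'
#' @param x A `TPMExperiment` or a gene x sample numeric matrix.
#' @param use_log Correlate log2(TPM + 1) values (default) rather than raw.
#' @param tissue Per-sample tissue labels; taken from `colData` when `x` is a
#'   `TPMExperiment`.
#' @param ... Passed through between methods.
#' @return A list of class `SampleCorrelationSummary` with elements `r`
#'   (sample x sample matrix), `mean_within`, `mean_between`, and `use_log`.
#' @rdname sampleCorrelation
#' @export
setMethod("sampleCorrelation", "TPMExperiment", function(x, use_log = TRUE, ...) {
  sampleCorrelation(if (use_log) logTransform(x) else tpm(x),
                    tissue = as.character(colData(x)$tissue), use_log = use_log)
})

#' @rdname sampleCorrelation
#' @export
setMethod("sampleCorrelation", "matrix", function(x, tissue, use_log = NA, ...) {
  if (ncol(x) < 2L) stop("need at least 2 samples")
  if (length(tissue) != ncol(x)) stop("one tissue label per sample required")
  sds <- apply(x, 2L, stats::sd)
  degenerate <- sds == 0 | is.na(sds)
  r <- matrix(NA_real_, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
  ok <- which(!degenerate)
  if (length(ok) >= 2L) r[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
  diag(r)[!degenerate] <- 1
  if (any(degenerate))
    warning("zero-variance sample(s) excluded from correlation means: ",
            paste(colnames(x)[degenerate], collapse = ", "))
  same <- outer(tissue, tissue, "==")
  ut <- upper.tri(r)
  within <- mean(r[ut & same], na.rm = TRUE)
  between <- if (any(ut & !same)) mean(r[ut & !same], na.rm = TRUE) else NA_real_
  structure(list(r = r, mean_within = within, mean_between = between,
                 use_log = use_log),
            class = "SampleCorrelationSummary")
})

#' @export
print.SampleCorrelationSummary <- function(x, ...) {
  cat("Pairwise sample correlation over", nrow(x$r), "samples\n")
  cat(sprintf("  mean within-tissue r:  %.3f\n", x$mean_within))
  cat(sprintf("  mean between-tissue r: %.3f\n", x$mean_between))
  invisible(x)
}
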