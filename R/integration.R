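#' Correlate gene expression with promoter methylation
#'
#' For each gene present in both inputs, computes the Pearson correlation
#' between log-scale expression and proximal-promoter mean methylation over
#' the matched samples, pooling samples across all tissues (tissue-driven
#' variation is the signal of interest). Missing methylation cells are
#' handled by pairwise deletion. The correlation is reported as `NA` when
#' fewer than `min_pairs` complete pairs remain or when either variable has
#' zero variance.
#'
#' @param expr Log-transformed gene x sample expression matrix (e.g. from
#'   [logTransform()]) or a `TPMExperiment` (log2(TPM+1) applied internally).
#' @param meth A `RegionMethExperiment` (rows matched to genes through
#'   `rowData(meth)$gene_id`) or a gene x sample methylation matrix with
#'   gene ids as rownames.
#' @param min_pairs Minimum complete sample pairs (default 10).
#' @param kind Promoter kind to use when `meth` covers several (default
#'   `"proximal"`).
#' @return `data.frame` with columns gene_id, r, n_pairs.
#' @export
correlateExpressionMethylation <- function(expr, meth, min_pairs = 10,
                                           kind = "proximal") {
  if (is(expr, "TPMExperiment")) expr <- logTransform(expr)
  if (is(meth, "RegionMethExperiment")) {
    sel <- rowData(meth)$kind == kind
    gm <- methLevels(meth)[sel, , drop = FALSE]
    rownames(gm) <- rowData(meth)$gene_id[sel]
    meth <- gm
  }
  shared <- intersect(colnames(expr), colnames(meth))
  if (length(shared) == 0L) stop("no overlapping samples between expression and methylation")
  genes <- intersect(rownames(expr), rownames(meth))
  r <- rep(NA_real_, length(genes))
  np <- integer(length(genes))
  for (i in seq_along(genes)) {
    e <- expr[genes[i], shared]
    m <- meth[genes[i], shared]
    ok <- !is.na(e) & !is.na(m)
    np[i] <- sum(ok)
    if (np[i] >= min_pairs &&
        stats::sd(e[ok]) > 0 && stats::sd(m[ok]) > 0) {
      r[i] <- stats::cor(e[ok], m[ok])
    }
  }
  data.frame(gene_id = genes, r = r, n_pairs = np, stringsAsFactors = FALSE)
}

#' Classify correlation direction
#'
#' A gene is classified `negative` when `r <= -threshold`, `positive` when
#' `r >= threshold` (boundary inclusive on both sides), and `none` otherwise
#' or when `r` is undefined.
#'
#' @param records Output of [correlateExpressionMethylation()].
#' @param threshold Absolute correlation threshold (default 0.3).
#' @return `records` with a `direction` factor column added.
#' @export
classifyCorrelations <- function(records, threshold = 0.3) {
  stopifnot(is.data.frame(records), "r" %in% colnames(records))
  dir <- rep("none", nrow(records))
  dir[!is.na(records$r) & records$r <= -threshold] <- "negative"
  dir[!is.na(records$r) & records$r >= threshold] <- "positive"
  records$direction <- factor(dir, levels = c("negative", "positive", "none"))
  records
}

#' K-means clustering of row-scaled promoter methylation
#'
#' Rows (genes) are z-scaled (mean 0, sd 1) before clustering with the
#' standard Euclidean K-means objective (10 random restarts, best inertia
#' kept), so assignments are invariant to per-gene affine transforms of the
#' raw methylation row. Columns (samples) are grouped by tissue label — a
#' supervised axis — and rows are ordered within each cluster by average-
#' linkage hierarchical clustering on 1 - Pearson distance. Genes with any
#' missing value or zero variance across the rendered samples are dropped
#' with a warning. Deterministic given `seed`.
#'
#' @param meth Gene x sample methylation matrix (e.g. proximal promoter
#'   levels restricted to selected genes).
#' @param k Number of clusters (default 5).
#' @param seed Random seed for the K-means restarts (required).
#' @param tissue Optional per-sample tissue labels used to group columns.
#' @return A list of class `ClusterResult`: `cluster` (named integer vector),
#'   `row_order` (gene ids in rendering order), `col_order` (sample ids
#'   grouped by tissue), `scaled` (the row-scaled matrix), `k`, `seed`.
#' @export
clusterMethylation <- function(meth, k = 5, seed, tissue = NULL) {
  if (missing(seed)) stop("a seed is required for K-means clustering")
  meth <- as.matrix(meth)
  complete <- rowSums(is.na(meth)) == 0L
  if (any(!complete))
    warning(sum(!complete), " gene(s) with missing cells dropped before clustering")
  meth <- meth[complete, , drop = FALSE]
  sds <- apply(meth, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene row(s) excluded from clustering")
    meth <- meth[sds > 0, , drop = FALSE]
  }
  if (nrow(meth) == 0L) stop("no usable rows left for clustering")
  k_eff <- min(k, nrow(meth))
  scaled <- t(scale(t(meth)))
  set.seed(seed)
  if (k_eff == nrow(scaled)) {
    # one gene per cluster: the zero-inertia optimum, no search needed
    cl <- seq_len(nrow(scaled))
    names(cl) <- rownames(scaled)
  } else {
    km <- stats::kmeans(scaled, centers = k_eff, nstart = 10)
    cl <- km$cluster
  }
  col_order <- if (!is.null(tissue)) colnames(meth)[order(factor(tissue, levels = unique(tissue)))]
               else colnames(meth)
  row_order <- unlist(lapply(sort(unique(cl)), function(ci) {
    rows <- names(cl)[cl == ci]
    if (length(rows) < 3L) return(rows)
    d <- stats::as.dist(1 - stats::cor(t(scaled[rows, , drop = FALSE])))
    d[is.na(d)] <- 2
    rows[stats::hclust(d, method = "average")$order]
  }), use.names = FALSE)
  structure(list(cluster = cl, row_order = row_order, col_order = col_order,
                 scaled = scaled, k = k_eff, seed = seed),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("K-means clustering of", length(x$cluster), "genes into", x$k, "clusters\n")
  print(table(cluster = x$cluster))
  invisible(x)
}
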