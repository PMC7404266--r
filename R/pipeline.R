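#' Per-tissue direction counts with accounting identities
#'
#' Tabulates classified correlation records (tissue-specific genes with a
#' `direction` of `negative` or `positive`) into a tissue x direction count
#' table with a `Total` row, plus the derived totals and the negative share
#' as a percentage. Column sums are checked against the `Total` row — the
#' accounting identity the summary report relies on.
#'
#' @param records `data.frame` with columns `assigned_tissue` and
#'   `direction` (from [classifyCorrelations()] joined to TSG calls); rows
#'   with direction `none` or no assigned tissue are excluded from the table.
#' @return A list of class `DirectionSummary`: `table` (data.frame tissue,
#'   negative, positive, incl. Total row), `n_negative`, `n_positive`,
#'   `n_total`, `pct_negative`.
#' @export
summarizeDirections <- function(records) {
  stopifnot(all(c("assigned_tissue", "direction") %in% colnames(records)))
  keep <- records$direction %in% c("negative", "positive") &
    !is.na(records$assigned_tissue)
  r <- records[keep, , drop = FALSE]
  tissues <- unique(r$assigned_tissue)
  tab <- data.frame(
    tissue = tissues,
    negative = vapply(tissues, function(t)
      sum(r$assigned_tissue == t & r$direction == "negative"), integer(1)),
    positive = vapply(tissues, function(t)
      sum(r$assigned_tissue == t & r$direction == "positive"), integer(1)),
    stringsAsFactors = FALSE)
  n_neg <- sum(tab$negative); n_pos <- sum(tab$positive)
  tab <- rbind(tab, data.frame(tissue = "Total", negative = n_neg,
                               positive = n_pos))
  rownames(tab) <- NULL
  total_row <- tab[tab$tissue == "Total", ]
  stopifnot(total_row$negative == sum(tab$negative[tab$tissue != "Total"]),
            total_row$positive == sum(tab$positive[tab$tissue != "Total"]))
  n_total <- n_neg + n_pos
  structure(list(table = tab, n_negative = n_neg, n_positive = n_pos,
                 n_total = n_total,
                 pct_negative = if (n_total > 0) percentShare(n_neg, n_total) else NA_real_),
            class = "DirectionSummary")
}

#' @export
print.DirectionSummary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("%d correlated genes: %d negative (%s%%), %d positive\n",
              x$n_total, x$n_negative, format(x$pct_negative), x$n_positive))
  invisible(x)
}

readPipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(tau = 0.8, r = 0.3, min_depth = 10, min_cpgs = 1,
                   min_pairs = 10, alpha = 0.05, nominal = 0.05, k = 5,
                   ewas_tissue = "adipocyte")
  th <- utils::modifyList(defaults, config$thresholds %||% list())
  if (th$tau < 0 || th$tau > 1 || th$r < 0 || th$r > 1 ||
      th$alpha <= 0 || th$alpha >= 1 || th$k < 1 || th$min_depth < 0)
    stop("threshold out of valid range")
  config$thresholds <- th
  if (is.null(config$seed)) stop("pipeline config requires a seed")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the integrated analysis pipeline
#'
#' Executes the full analysis from a single configuration: gene model ->
#' expression QC -> tissue specificity -> promoter methylation ->
#' expression-methylation integration -> optional enrichment -> optional
#' region-restricted EWAS. Every output file is accompanied by a provenance
#' JSON recording thresholds, seed and input digests. Stage failures abort
#' with the stage name; outputs written so far are retained.
#'
#' @param config A YAML file path or a list with elements: `gtf`,
#'   `expression`, `sample_sheet`, `calls_dir` (directory of per-sample call
#'   TSVs named `<sample>.tsv`), `seed`, `out_dir`, optional `thresholds`
#'   (tau, r, min_depth, min_cpgs, min_pairs, alpha, nominal, k,
#'   ewas_tissue), optional `gmt` + `background` (file of gene ids, one per
#'   line), optional `ewas` (betas, manifest, pheno, betas_replication,
#'   pheno_replication).
#' @return An `AnalysisReport` list: `n_tsg_per_tissue`, `n_tsg`,
#'   `direction_summary`, `n_negative`, `n_positive`, `n_discovery_pass`,
#'   `n_validated` (NA when no EWAS inputs), plus the per-stage objects
#'   (`tsg`, `correlations`, `meth_summary_pct`, `sample_correlation`,
#'   `clusters`, `enrichment`, `ewas`).
#' @export
runPipeline <- function(config) {
  config <- readPipelineConfig(config)
  th <- config$thresholds
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  model <- stage("gene_model", readGeneModel(config$gtf))
  prox <- stage("gene_model", derivePromoters(model, "proximal"))
  typ <- stage("gene_model", derivePromoters(model, "typical"))
  expd <- stage("gene_model", derivePromoters(model, "expanded"))

  expr <- stage("expression", {
    if (is.null(config$expression) || is.null(config$sample_sheet))
      stop("expression matrix and sample sheet paths are required")
    loadExpression(config$expression, config$sample_sheet)
  })
  expr <- stage("expression", filterExpressed(expr, "any_positive"))
  scor <- stage("expression", sampleCorrelation(expr, use_log = TRUE))

  tsg <- stage("specificity", {
    expr1 <- filterExpressed(expr, "max_ge_one")
    callTSGs(tissueMeans(expr1), tau_threshold = th$tau)
  })

  meth <- stage("methylation", {
    if (is.null(config$calls_dir)) stop("methylation calls_dir is required")
    files <- file.path(config$calls_dir, paste0(colnames(expr), ".tsv"))
    missing <- !file.exists(files)
    if (any(missing))
      stop("missing call file(s): ", paste(basename(files[missing]), collapse = ", "))
    calls <- lapply(files, readCpgCalls, min_depth = th$min_depth)
    names(calls) <- colnames(expr)
    aggregateRegionMethylation(calls, c(prox, typ), min_cpgs = th$min_cpgs)
  })
  meth_summary <- stage("methylation", promoterMethylationSummary(meth))

  tsg_ids <- tsg$gene_id[tsg$is_tsg]
  records <- stage("integration", {
    sub <- meth[rowData(meth)$kind == "proximal" &
                rowData(meth)$gene_id %in% tsg_ids, ]
    rec <- correlateExpressionMethylation(expr, sub, min_pairs = th$min_pairs)
    rec <- classifyCorrelations(rec, threshold = th$r)
    rec$assigned_tissue <- tsg$assigned_tissue[match(rec$gene_id, tsg$gene_id)]
    rec
  })
  dir_summary <- stage("integration", summarizeDirections(records))
  clusters <- stage("integration", {
    neg <- records$gene_id[records$direction == "negative"]
    if (length(neg) >= th$k) {
      m <- methLevels(meth)[match(paste(neg, "proximal", sep = "|"),
                                  rownames(meth)), , drop = FALSE]
      rownames(m) <- neg
      suppressWarnings(clusterMethylation(m, k = th$k, seed = config$seed,
                                          tissue = as.character(colData(expr)$tissue)))
    } else NULL
  })

  enr <- NULL
  if (!is.null(config$gmt)) {
    enr <- stage("enrichment", {
      coll <- readGmt(config$gmt)
      bg <- if (!is.null(config$background)) readLines(config$background)
            else rownames(expr)
      neg <- records$gene_id[records$direction == "negative"]
      overrepresentationTest(neg, coll, bg)
    })
  }

  ewas <- NULL
  if (!is.null(config$ewas)) {
    ewas <- stage("ewas", {
      ew <- config$ewas
      inp <- loadEwasInputs(ew$betas, ew$manifest, ew$pheno)
      tissue_genes <- tsg$gene_id[tsg$is_tsg &
                                  tsg$assigned_tissue == th$ewas_tissue]
      regions <- expd[mcols(expd)$gene_id %in% tissue_genes]
      sel <- selectProbesInRegions(inp$manifest, regions)
      if (length(sel$probes) == 0L) stop("no probes fall inside the expanded promoters")
      disc <- dmpAssociation(inp$betas[sel$probes, , drop = FALSE], inp$pheno,
                             outcome = "obesity", covariates = c("age", "sex"))
      res <- list(selected = sel, discovery = disc)
      if (!is.null(ew$betas_replication)) {
        rin <- loadEwasInputs(ew$betas_replication, ew$manifest,
                              ew$pheno_replication)
        repl <- dmpAssociation(rin$betas[sel$probes, , drop = FALSE], rin$pheno,
                               outcome = "obesity", covariates = c("age", "sex"))
        res$replication <- repl
        res$validated <- discoveryReplication(disc, repl, alpha = th$alpha,
                                              nominal = th$nominal)
      }
      res
    })
  }

  report <- list(
    n_tsg_per_tissue = table(tsg$assigned_tissue[tsg$is_tsg]),
    n_tsg = sum(tsg$is_tsg),
    sample_correlation = scor,
    meth_summary_pct = meth_summary,
    direction_summary = dir_summary,
    n_negative = dir_summary$n_negative,
    n_positive = dir_summary$n_positive,
    n_discovery_pass = if (!is.null(ewas$validated))
      sum(ewas$validated$discovery_pass) else NA_integer_,
    n_validated = if (!is.null(ewas$validated))
      sum(ewas$validated$validated) else NA_integer_,
    tsg = tsg, correlations = records, clusters = clusters,
    enrichment = enr, ewas = ewas,
    thresholds = th, seed = config$seed)
  class(report) <- "AnalysisReport"

  if (!is.null(out_dir)) stage("report", writeReport(report, config, out_dir,
                                                     prox, typ, expd, meth))
  report
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat("AnalysisReport\n")
  cat("  TSGs (tau >=", x$thresholds$tau, "):", x$n_tsg, "\n")
  cat("  correlated genes: ", x$direction_summary$n_total,
      " (", x$n_negative, " negative / ", x$n_positive, " positive)\n", sep = "")
  if (!is.na(x$n_discovery_pass))
    cat("  EWAS: ", x$n_discovery_pass, " discovery-significant, ",
        x$n_validated, " validated\n", sep = "")
  invisible(x)
}

writeReport <- function(report, config, out_dir, prox, typ, expd, meth) {
  exportPromotersBed(prox, file.path(out_dir, "promoters_proximal.bed"))
  exportPromotersBed(typ, file.path(out_dir, "promoters_typical.bed"))
  exportPromotersBed(expd, file.path(out_dir, "promoters_expanded.bed"))
  exportRegionMethylation(meth, file.path(out_dir, "region_methylation"))
  writeTsv(report$tsg, file.path(out_dir, "tsg.tsv"))
  writeTsv(report$correlations, file.path(out_dir, "correlations.tsv"))
  writeTsv(report$direction_summary$table, file.path(out_dir, "direction_summary.tsv"))
  if (!is.null(report$enrichment))
    writeTsv(report$enrichment, file.path(out_dir, "enrichment.tsv"))
  if (!is.null(report$ewas$validated))
    writeTsv(report$ewas$validated, file.path(out_dir, "ewas_validated.tsv"))
  inputs <- unlist(config[c("gtf", "expression", "sample_sheet")], use.names = TRUE)
  digests <- tryCatch(tools::md5sum(inputs), error = function(e) NULL)
  prov <- list(package = "tsmeth",
               version = as.character(utils::packageVersion("tsmeth")),
               thresholds = report$thresholds, seed = report$seed,
               input_md5 = as.list(digests),
               summary = list(n_tsg = report$n_tsg,
                              n_negative = report$n_negative,
                              n_positive = report$n_positive,
                              pct_negative = report$direction_summary$pct_negative,
                              n_discovery_pass = report$n_discovery_pass,
                              n_validated = report$n_validated))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}
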