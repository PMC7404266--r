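#' Select array probes lying inside promoter regions
#'
#' Keeps the probes whose 1-based genomic position falls inside any of the
#' supplied regions, recording every gene whose region contains the probe.
#' Probes hit by several genes' regions are returned once.
#'
#' @param manifest `data.frame` with columns `probe`, `chrom`, `pos`
#'   (1-based).
#' @param regions Promoter `GRanges` (typically expanded promoters from
#'   [derivePromoters()]).
#' @return A list with `probes` (character vector, deduplicated, in manifest
#'   order) and `map` (`data.frame` probe, gene_id — one row per
#'   probe-gene hit).
#' @export
selectProbesInRegions <- function(manifest, regions) {
  stopifnot(all(c("probe", "chrom", "pos") %in% colnames(manifest)))
  if (nrow(manifest) == 0L || length(regions) == 0L)
    return(list(probes = character(), map = data.frame(probe = character(),
                gene_id = character(), stringsAsFactors = FALSE)))
  pgr <- GRanges(manifest$chrom, IRanges(manifest$pos, manifest$pos))
  hits <- findOverlaps(pgr, regions, ignore.strand = TRUE)
  map <- data.frame(probe = manifest$probe[S4Vectors::queryHits(hits)],
                    gene_id = mcols(regions)$gene_id[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  map <- unique(map)
  list(probes = manifest$probe[manifest$probe %in% map$probe], map = map)
}

#' Per-probe association between methylation and a phenotype
#'
#' Fits, for every probe, a regression of the methylation beta value on the
#' outcome indicator plus covariates (methylation-as-response, the dominant
#' EWAS convention): `beta ~ status + age + sex + ...`. The reported effect
#' is the outcome coefficient and the p-value the two-sided Wald test on
#' that coefficient. Samples with missing covariates are dropped listwise.
#' A logistic model with case/control status as the response is available
#' via `model = "logistic"`, and an M-value transform
#' (`log2(beta/(1-beta))`, beta clipped to [1e-3, 1-1e-3]) via
#' `mvalues = TRUE`.
#'
#' @param betas Probe x sample matrix of beta values in [0,1].
#' @param pheno `data.frame` with columns `sample`, `status` (case/control),
#'   `age`, `sex` (F/M), `bmi`, and optionally `t2d` (case/control/NA).
#' @param outcome `"obesity"` (uses `status`) or `"t2d"` (uses `t2d`;
#'   samples with missing T2D status are dropped).
#' @param covariates Character vector of covariate column names
#'   (default `c("age", "sex")`; the secondary-trait T2D analysis adds `"bmi"`).
#' @param model `"linear"` (default) or `"logistic"`.
#' @param mvalues Analyze M-values instead of betas (default `FALSE`).
#' @return `data.frame`: probe, effect, se, p, n, flag (`""` or
#'   `"constant_beta"`).
#' @export
dmpAssociation <- function(betas, pheno, outcome = c("obesity", "t2d"),
                           covariates = c("age", "sex"),
                           model = c("linear", "logistic"), mvalues = FALSE) {
  outcome <- match.arg(outcome)
  model <- match.arg(model)
  stopifnot(is.matrix(betas), "sample" %in% colnames(pheno))
  ph <- pheno[match(colnames(betas), pheno$sample), , drop = FALSE]
  if (anyNA(ph$sample))
    stop("sample(s) in beta matrix absent from phenotype table: ",
         paste(colnames(betas)[is.na(ph$sample)], collapse = ", "))
  ycol <- if (outcome == "obesity") "status" else "t2d"
  if (!ycol %in% colnames(ph)) stop("phenotype table lacks column '", ycol, "'")
  y <- ph[[ycol]]
  keep <- !is.na(y) & y %in% c("case", "control")
  covs <- lapply(covariates, function(cv) {
    if (!cv %in% colnames(ph)) stop("missing covariate column '", cv, "'")
    v <- ph[[cv]]
    if (cv == "sex") v <- ifelse(v == "M", 1, ifelse(v == "F", 0, NA))
    as.numeric(v)
  })
  names(covs) <- covariates
  for (cv in covariates) keep <- keep & !is.na(covs[[cv]])
  if (sum(keep) == 0L) stop("no analyzable samples")
  status <- as.numeric(y[keep] == "case")
  if (min(table(status)) < 2L || length(unique(status)) < 2L)
    stop("each outcome class needs at least 2 samples")
  X <- cbind(intercept = 1, status = status)
  for (cv in covariates) X <- cbind(X, covs[[cv]][keep])
  colnames(X) <- c("intercept", "status", covariates)
  vals <- betas[, keep, drop = FALSE]
  if (mvalues) {
    vv <- pmin(pmax(vals, 1e-3), 1 - 1e-3)
    vals <- log2(vv / (1 - vv))
  }
  np <- nrow(vals)
  eff <- rep(NA_real_, np); se <- rep(NA_real_, np); p <- rep(NA_real_, np)
  flag <- rep("", np)
  if (model == "linear") {
    XtXi <- solve(crossprod(X))
    H <- XtXi %*% t(X)
    df <- ncol(vals) - ncol(X)
    for (i in seq_len(np)) {
      b <- vals[i, ]
      if (stats::sd(b) == 0) { flag[i] <- "constant_beta"; next }
      co <- H %*% b
      res <- b - X %*% co
      s2 <- sum(res^2) / df
      eff[i] <- co["status", 1L]
      se[i] <- sqrt(s2 * XtXi["status", "status"])
      p[i] <- 2 * stats::pt(abs(eff[i] / se[i]), df, lower.tail = FALSE)
    }
  } else {
    for (i in seq_len(np)) {
      b <- vals[i, ]
      if (stats::sd(b) == 0) { flag[i] <- "constant_beta"; next }
      dat <- data.frame(status = status, b = b, X[, covariates, drop = FALSE])
      fit <- stats::glm(status ~ ., data = dat, family = stats::binomial())
      sm <- summary(fit)$coefficients
      eff[i] <- sm["b", 1L]; se[i] <- sm["b", 2L]; p[i] <- sm["b", 4L]
    }
  }
  data.frame(probe = rownames(betas), effect = eff, se = se, p = p,
             n = sum(keep), flag = flag, stringsAsFactors = FALSE)
}

#' Bonferroni family-wise significance threshold
#'
#' @param alpha Family-wise error rate (0 < alpha < 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroniThreshold(0.05, 4443)  # 1.125366e-05, i.e. 1.13e-5 at 3 s.f.
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (length(m) != 1L || is.na(m) || m < 1) stop("m must be a positive count")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  alpha / m
}

#' Two-stage discovery / replication validation
#'
#' A probe is validated when (i) its discovery p-value passes the Bonferroni
#' threshold `alpha / m` with `m` the number of probes actually tested in
#' discovery, (ii) its replication p-value is below the nominal level, and
#' (iii) the effect direction is concordant between stages (standard
#' practice; switch off with `require_concordance = FALSE`). Probes present
#' in the replication results but not in discovery are ignored with a
#' warning.
#'
#' @param discovery,replication Outputs of [dmpAssociation()] on independent
#'   cohorts.
#' @param alpha Family-wise error rate for the discovery stage (default 0.05).
#' @param nominal Nominal replication level (default 0.05, strict `<`).
#' @param require_concordance Require same effect sign (default `TRUE`).
#' @return `data.frame` per discovery-tested probe: probe, effect, p,
#'   rep_effect, rep_p, discovery_pass, replication_pass, validated; with
#'   attributes `m_tested` and `threshold`.
#' @export
discoveryReplication <- function(discovery, replication, alpha = 0.05,
                                 nominal = 0.05, require_concordance = TRUE) {
  extra <- setdiff(replication$probe, discovery$probe)
  if (length(extra))
    warning("probe(s) present in replication but not discovery ignored: ",
            paste(extra, collapse = ", "))
  tested <- !is.na(discovery$p)
  m <- sum(tested)
  if (m == 0L) stop("no probes tested in discovery")
  thr <- bonferroniThreshold(alpha, m)
  out <- discovery[, c("probe", "effect", "p")]
  ri <- match(out$probe, replication$probe)
  out$rep_effect <- replication$effect[ri]
  out$rep_p <- replication$p[ri]
  out$discovery_pass <- !is.na(out$p) & out$p <= thr
  out$replication_pass <- !is.na(out$rep_p) & out$rep_p < nominal
  if (require_concordance) {
    out$replication_pass <- out$replication_pass &
      !is.na(out$rep_effect) & sign(out$rep_effect) == sign(out$effect)
  }
  out$validated <- out$discovery_pass & out$replication_pass
  attr(out, "m_tested") <- m
  attr(out, "threshold") <- thr
  out
}

#' Load a probe beta matrix, manifest and phenotype table from TSV
#'
#' @param betasPath Probe x sample TSV (header = sample ids, first column =
#'   probe ids).
#' @param manifestPath TSV with columns probe, chrom, pos.
#' @param phenoPath TSV with columns sample, status, age, sex, bmi and
#'   optionally t2d.
#' @return list(betas = matrix, manifest = data.frame, pheno = data.frame).
#' @export
loadEwasInputs <- function(betasPath, manifestPath, phenoPath) {
  raw <- utils::read.delim(betasPath, check.names = FALSE, stringsAsFactors = FALSE)
  betas <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(betas) <- raw[[1L]]
  if (anyNA(betas) || any(betas < 0) || any(betas > 1))
    stop("beta values must lie in [0,1]")
  manifest <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  off <- setdiff(rownames(betas), manifest$probe)
  if (length(off))
    stop("probe(s) missing from manifest: ", paste(off, collapse = ", "))
  pheno <- utils::read.delim(phenoPath, stringsAsFactors = FALSE)
  list(betas = betas, manifest = manifest, pheno = pheno)
}
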