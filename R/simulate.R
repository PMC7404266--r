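#' Simulation configuration
#'
#' Collects every tunable of the synthetic multi-omics and EWAS-cohort
#' generators, with defaults that emulate the study design the pipeline
#' assumes: five tissues with matched expression and whole-genome bisulfite
#' samples, tissue-specific genes whose proximal-promoter methylation is
#' anti-coupled (or, less often, positively coupled) to expression, and an
#' obesity-style case/control methylation-array cohort with a handful of
#' planted differentially methylated probes.
#'
#' @param seed Integer seed; mandatory — both generators are fully
#'   deterministic given the seed.
#' @param n_tissues,samples_per_tissue Cohort layout (default 5 x 10 matched
#'   samples).
#' @param tissue_names Tissue labels (first `n_tissues` used).
#' @param n_tsg_negative,n_tsg_positive,n_null_genes Planted gene classes:
#'   negatively coupled TSGs, positively coupled TSGs, and null genes with
#'   tissue-independent expression and methylation (defaults 40/20/140,
#'   a 2:1 negative:positive ratio).
#' @param mu_on,mu_off,mu_null,sigma Expression means (log2(TPM+1) scale) for
#'   a TSG in its target tissue, a TSG elsewhere, and null genes, plus the
#'   common noise sd (defaults 6, 0.5, 3, 0.5).
#' @param beta_low,beta_high Beta-distribution shape pairs for hypo- and
#'   hyper-methylated promoter states (defaults Beta(2,18), mean 0.10, and
#'   Beta(18,2), mean 0.90).
#' @param typical_beta Shape pair for the (uncoupled) typical-promoter
#'   baseline, default Beta(8,12) (mean 0.40), higher than the proximal
#'   baseline so the proximal < typical contrast holds.
#' @param jitter_sd Per-CpG Gaussian jitter around the region level
#'   (default 0.03); CpG ratios are clipped to [0,1].
#' @param cpgs_per_promoter CpGs simulated per promoter region (default 8).
#' @param depth_mean Poisson mean of per-CpG effective coverage (default 30).
#' @param single_exon_frac Fraction of null genes generated without an
#'   intron, to exercise the degenerate expanded-promoter path (default 0.05).
#' @param n_cases,n_controls Discovery EWAS cohort (defaults 200/250).
#' @param n_cases_rep,n_controls_rep Replication cohort (defaults 337/422,
#'   n = 759 split in the discovery proportions).
#' @param n_probes,n_true_dmps Array probes and planted DMPs (defaults
#'   500/3).
#' @param delta_beta Planted case-control methylation difference
#'   (default 0.08).
#' @param beta_mean,beta_sd Target mean/sd of null-probe beta values
#'   (defaults 0.5/0.05; matched by moments to a Beta distribution).
#' @param age_mean,age_sd,sex_p Covariate generators: age ~ Normal(50, 8),
#'   sex ~ Bernoulli(0.5).
#' @param confounding Make age shift both case probability and beta values,
#'   to test covariate adjustment (default `FALSE`).
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(seed,
                      n_tissues = 5, samples_per_tissue = 10,
                      tissue_names = c("adipocyte", "fibroblast", "islet",
                                       "kidney", "smc"),
                      n_tsg_negative = 40, n_tsg_positive = 20,
                      n_null_genes = 140,
                      mu_on = 6, mu_off = 0.5, mu_null = 3, sigma = 0.5,
                      beta_low = c(2, 18), beta_high = c(18, 2),
                      typical_beta = c(8, 12), jitter_sd = 0.03,
                      cpgs_per_promoter = 8, depth_mean = 30,
                      single_exon_frac = 0.05,
                      n_cases = 200, n_controls = 250,
                      n_cases_rep = 337, n_controls_rep = 422,
                      n_probes = 500, n_true_dmps = 3, delta_beta = 0.08,
                      beta_mean = 0.5, beta_sd = 0.05,
                      age_mean = 50, age_sd = 8, sex_p = 0.5,
                      confounding = FALSE) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  counts <- c(cfg$n_tissues, cfg$samples_per_tissue, cfg$n_tsg_negative,
              cfg$n_tsg_positive, cfg$n_null_genes, cfg$n_cases,
              cfg$n_controls, cfg$n_probes, cfg$n_true_dmps)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (cfg$n_tissues < 2 || cfg$samples_per_tissue < 1)
    stop("need >= 2 tissues with >= 1 sample each")
  if (cfg$n_true_dmps > cfg$n_probes)
    stop("n_true_dmps cannot exceed n_probes")
  if (length(cfg$tissue_names) < cfg$n_tissues)
    stop("not enough tissue names")
  cfg$tissue_names <- cfg$tissue_names[seq_len(cfg$n_tissues)]
  if (cfg$jitter_sd < 0 || cfg$sex_p < 0 || cfg$sex_p > 1 ||
      cfg$beta_mean <= 0 || cfg$beta_mean >= 1 || cfg$beta_sd <= 0)
    stop("invalid probability parameter")
  structure(cfg, class = "SimConfig")
}

# method-of-moments Beta shapes for a target mean and sd
betaShapes <- function(mean, sd) {
  v <- sd^2
  if (v >= mean * (1 - mean)) stop("sd too large for a Beta distribution")
  nu <- mean * (1 - mean) / v - 1
  c(mean * nu, (1 - mean) * nu)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate matched multi-tissue expression and methylation data
#'
#' Generates, deterministically from the seed, a synthetic gene annotation
#' (two-exon transcripts on one synthetic chromosome, plus a fraction of
#' single-exon genes), a gene x sample TPM matrix, a sample sheet, per-sample
#' CpG methylation calls covering the proximal and typical promoters, and a
#' truth table of the planted gene classes.
#'
#' Negatively coupled TSGs are highly expressed in their target tissue with
#' hypo-methylated proximal promoters there and hyper-methylated promoters
#' elsewhere; positively coupled TSGs have the reversed methylation pattern;
#' null genes are moderately expressed everywhere with tissue-independent
#' promoter methylation. Per-CpG methylated fractions are the region level
#' plus Gaussian jitter, clipped to [0,1]; coverage is Poisson.
#'
#' @param config A [simConfig()] object.
#' @param out_dir Optional directory; when given, writes `genes.gtf`,
#'   `expression.tsv`, `sample_sheet.tsv`, `truth_genes.tsv`, and
#'   `calls/<sample>.tsv`, and is byte-identical across runs at the same
#'   seed.
#' @return A list: `gtf` (character lines), `tpm` (matrix), `sample_sheet`,
#'   `calls` (named list of per-sample call `data.frame`s), `truth`
#'   (gene_id, class, target_tissue).
#' @export
simulateMultiomics <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n_genes <- config$n_tsg_negative + config$n_tsg_positive + config$n_null_genes
  if (n_genes < 1L) stop("no genes configured")
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  classes <- rep(c("tsg_negative", "tsg_positive", "null"),
                 c(config$n_tsg_negative, config$n_tsg_positive, config$n_null_genes))
  target <- rep(NA_character_, n_genes)
  is_tsg <- classes != "null"
  target[is_tsg] <- rep(config$tissue_names, length.out = sum(is_tsg))
  n_single <- round(config$single_exon_frac * config$n_null_genes)
  single_exon <- logical(n_genes)
  if (n_single > 0) single_exon[rev(which(classes == "null"))[seq_len(n_single)]] <- TRUE

  # gene structures on one synthetic chromosome, alternating strand
  span <- 8000L
  anchor <- 10000L + (seq_len(n_genes) - 1L) * span
  strand <- rep(c("+", "-"), length.out = n_genes)
  gtf <- character(0)
  tss <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    a <- anchor[i]
    if (single_exon[i]) {
      ex <- list(c(a, a + 999L))
    } else {
      ex <- list(c(a, a + 199L), c(a + 500L, a + 999L))
    }
    tss[i] <- if (strand[i] == "-") a + 999L else a
    att <- sprintf('gene_id "%s"; transcript_id "%s.t1";', gene_ids[i], gene_ids[i])
    for (e in ex) {
      gtf <- c(gtf, paste("chrS", "sim", "exon", e[1], e[2], ".", strand[i],
                          ".", att, sep = "\t"))
    }
  }

  # samples
  tissue <- rep(config$tissue_names, each = config$samples_per_tissue)
  sample_ids <- sprintf("%s_s%02d", tissue,
                        rep(seq_len(config$samples_per_tissue), times = config$n_tissues))
  sheet <- data.frame(sample = sample_ids, tissue = tissue,
                      batch = rep(c("b1", "b2"), length.out = length(sample_ids)),
                      stringsAsFactors = FALSE)
  ns <- length(sample_ids)

  # expression on log2(TPM+1) scale
  mu <- matrix(config$mu_null, n_genes, ns)
  for (i in which(is_tsg)) {
    mu[i, ] <- ifelse(tissue == target[i], config$mu_on, config$mu_off)
  }
  y <- mu + matrix(stats::rnorm(n_genes * ns, 0, config$sigma), n_genes, ns)
  tpm <- pmax(2^y - 1, 0)
  dimnames(tpm) <- list(gene_ids, sample_ids)

  # proximal region methylation level per gene x sample
  lowshape <- config$beta_low; highshape <- config$beta_high
  lev <- matrix(NA_real_, n_genes, ns)
  for (i in seq_len(n_genes)) {
    if (classes[i] == "tsg_negative") {
      on_t <- tissue == target[i]
      lev[i, on_t] <- stats::rbeta(sum(on_t), lowshape[1], lowshape[2])
      lev[i, !on_t] <- stats::rbeta(sum(!on_t), highshape[1], highshape[2])
    } else if (classes[i] == "tsg_positive") {
      on_t <- tissue == target[i]
      lev[i, on_t] <- stats::rbeta(sum(on_t), highshape[1], highshape[2])
      lev[i, !on_t] <- stats::rbeta(sum(!on_t), lowshape[1], lowshape[2])
    } else {
      lev[i, ] <- stats::rbeta(ns, lowshape[1], lowshape[2])
    }
  }
  tlev <- matrix(stats::rbeta(n_genes * ns, config$typical_beta[1],
                              config$typical_beta[2]), n_genes, ns)

  # CpG positions inside each promoter window
  k <- config$cpgs_per_promoter
  prox_pos <- matrix(0L, n_genes, k); typ_pos <- matrix(0L, n_genes, k)
  for (i in seq_len(n_genes)) {
    t <- tss[i]
    if (strand[i] == "+") {
      prox <- c(t - 200L, t + 49L); typ <- c(t - 2000L, t - 1L)
    } else {
      prox <- c(t - 49L, t + 200L); typ <- c(t + 1L, t + 2000L)
    }
    prox_pos[i, ] <- as.integer(round(seq(prox[1] + 2, prox[2] - 2, length.out = k)))
    typ_pos[i, ] <- as.integer(round(seq(typ[1] + 10, typ[2] - 10, length.out = k)))
  }

  calls <- vector("list", ns)
  names(calls) <- sample_ids
  for (j in seq_len(ns)) {
    pr <- clip01(rep(lev[, j], each = k) +
                 stats::rnorm(n_genes * k, 0, config$jitter_sd))
    tr <- clip01(rep(tlev[, j], each = k) +
                 stats::rnorm(n_genes * k, 0, config$jitter_sd))
    pos <- c(as.vector(t(prox_pos)), as.vector(t(typ_pos)))
    ratio <- c(pr, tr)
    depth <- stats::rpois(length(pos), config$depth_mean)
    o <- order(pos)
    calls[[j]] <- data.frame(chr = "chrS", pos = pos[o], strand = "+",
                             context = "CG", ratio = round(ratio[o], 6),
                             eff_CT_count = depth[o], stringsAsFactors = FALSE)
  }

  truth <- data.frame(gene_id = gene_ids, class = classes,
                      target_tissue = target, single_exon = single_exon,
                      stringsAsFactors = FALSE)
  out <- list(gtf = gtf, tpm = tpm, sample_sheet = sheet, calls = calls,
              truth = truth)
  if (!is.null(out_dir)) writeMultiomics(out, out_dir)
  out
}

writeMultiomics <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "calls"), showWarnings = FALSE)
  writeLines(sim$gtf, file.path(out_dir, "genes.gtf"))
  writeMatrixTsv(sim$tpm, file.path(out_dir, "expression.tsv"), id_col = "gene_id")
  writeTsv(sim$sample_sheet, file.path(out_dir, "sample_sheet.tsv"))
  writeTsv(sim$truth, file.path(out_dir, "truth_genes.tsv"))
  for (s in names(sim$calls))
    writeTsv(sim$calls[[s]], file.path(out_dir, "calls", paste0(s, ".tsv")))
  invisible(out_dir)
}

#' Simulate a case/control methylation-array cohort
#'
#' Generates a probe manifest, independent discovery and replication
#' cohorts of beta values, phenotype tables (status, age, sex, BMI, T2D
#' status), and a probe truth table. Null probes draw beta values from a
#' Beta distribution moment-matched to `beta_mean`/`beta_sd`, independent of
#' status; planted DMPs shift the case mean by `delta_beta` (clipped to
#' [0,1]). By default age and sex are independent of status; with
#' `confounding = TRUE`, age shifts both the case probability and the beta
#' values of every probe, so that only the covariate-adjusted analysis is
#' calibrated.
#'
#' @param config A [simConfig()] object.
#' @param regions Optional promoter `GRanges`: probe positions are then
#'   placed inside these regions (cycled), otherwise spread along a
#'   synthetic chromosome.
#' @param out_dir Optional output directory (`manifest.tsv`,
#'   `betas_discovery.tsv`, `pheno_discovery.tsv`, `betas_replication.tsv`,
#'   `pheno_replication.tsv`, `truth_probes.tsv`).
#' @return A list: `manifest`, `discovery` (list `betas`, `pheno`),
#'   `replication` (same shape), `truth` (probe, is_dmp, delta).
#' @export
simulateEwasCohort <- function(config, regions = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  np <- config$n_probes
  probes <- sprintf("cgS%06d", seq_len(np))
  if (!is.null(regions) && length(regions) > 0L) {
    ri <- rep(seq_along(regions), length.out = np)
    pos <- start(regions)[ri] +
      floor(stats::runif(np) * (end(regions)[ri] - start(regions)[ri] + 1L))
    manifest <- data.frame(probe = probes,
                           chrom = as.character(seqnames(regions))[ri],
                           pos = as.integer(pos), stringsAsFactors = FALSE)
  } else {
    manifest <- data.frame(probe = probes, chrom = "chrS",
                           pos = sort(sample.int(2000000L, np)),
                           stringsAsFactors = FALSE)
  }
  dmp_idx <- if (config$n_true_dmps > 0) sort(sample.int(np, config$n_true_dmps))
             else integer(0)
  truth <- data.frame(probe = probes, is_dmp = seq_len(np) %in% dmp_idx,
                      delta = ifelse(seq_len(np) %in% dmp_idx,
                                     config$delta_beta, 0),
                      stringsAsFactors = FALSE)
  shapes <- betaShapes(config$beta_mean, config$beta_sd)

  makeCohort <- function(nca, nco, prefix) {
    n <- nca + nco
    age <- stats::rnorm(n, config$age_mean, config$age_sd)
    sex <- ifelse(stats::runif(n) < config$sex_p, "M", "F")
    if (config$confounding) {
      p_case <- stats::plogis((age - config$age_mean) / 5) * 2 * nca / n
      status <- ifelse(stats::runif(n) < p_case, "case", "control")
    } else {
      status <- rep(c("case", "control"), c(nca, nco))
    }
    bmi <- ifelse(status == "case", stats::rnorm(n, 31.6, 1.6),
                  stats::rnorm(n, 21.4, 1.1))
    t2d <- ifelse(stats::runif(n) < stats::plogis((bmi - 28) / 3), "case", "control")
    betas <- matrix(stats::rbeta(np * n, shapes[1], shapes[2]), np, n)
    case_col <- status == "case"
    if (length(dmp_idx))
      betas[dmp_idx, case_col] <- clip01(betas[dmp_idx, case_col] + config$delta_beta)
    if (config$confounding)
      betas <- clip01(sweep(betas, 2L, 0.004 * (age - config$age_mean), "+"))
    ids <- sprintf("%s%04d", prefix, seq_len(n))
    dimnames(betas) <- list(probes, ids)
    pheno <- data.frame(sample = ids, status = status, age = round(age, 2),
                        sex = sex, bmi = round(bmi, 2), t2d = t2d,
                        stringsAsFactors = FALSE)
    list(betas = betas, pheno = pheno)
  }
  disc <- makeCohort(config$n_cases, config$n_controls, "D")
  repl <- makeCohort(config$n_cases_rep, config$n_controls_rep, "R")

  out <- list(manifest = manifest, discovery = disc, replication = repl,
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeTsv(manifest, file.path(out_dir, "manifest.tsv"))
    writeMatrixTsv(round(disc$betas, 6), file.path(out_dir, "betas_discovery.tsv"),
                   id_col = "probe")
    writeTsv(disc$pheno, file.path(out_dir, "pheno_discovery.tsv"))
    writeMatrixTsv(round(repl$betas, 6), file.path(out_dir, "betas_replication.tsv"),
                   id_col = "probe")
    writeTsv(repl$pheno, file.path(out_dir, "pheno_replication.tsv"))
    writeTsv(truth, file.path(out_dir, "truth_probes.tsv"))
  }
  out
}
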