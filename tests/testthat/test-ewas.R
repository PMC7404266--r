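make_pheno <- function(n, n_cases = n / 2, seed = 1) {
  set.seed(seed)
  data.frame(sample = sprintf("s%04d", 1:n),
             status = rep(c("case", "control"), c(n_cases, n - n_cases)),
             age = rnorm(n, 50, 8),
             sex = sample(c("F", "M"), n, TRUE),
             bmi = rnorm(n, 26, 4),
             t2d = sample(c("case", "control"), n, TRUE),
             stringsAsFactors = FALSE)
}

test_that("probe selection honours region boundaries and multi-gene hits", {
  regions <- GRanges("chr1", IRanges(c(801, 1000), c(1050, 1040)),
                     gene_id = c("g1", "g2"), kind = "expanded")
  manifest <- data.frame(probe = c("p1", "p2", "p3"),
                         chrom = "chr1", pos = c(900, 1051, 1020),
                         stringsAsFactors = FALSE)
  sel <- selectProbesInRegions(manifest, regions)
  # p1 at 900 is inside [800,1050); p2 at 1051 is outside the half-open end
  expect_true("p1" %in% sel$probes)
  expect_false("p2" %in% sel$probes)
  # p3 falls in both genes' regions: included once, both genes recorded
  expect_equal(sum(sel$probes == "p3"), 1L)
  expect_setequal(sel$map$gene_id[sel$map$probe == "p3"], c("g1", "g2"))
})

test_that("dmpAssociation detects a planted shift and matches lm", {
  n <- 400
  ph <- make_pheno(n, 200, seed = 2)
  set.seed(3)
  betas <- matrix(rbeta(5 * n, 50, 50), 5, n,
                  dimnames = list(paste0("p", 1:5), ph$sample))
  betas <- 0.5 + (betas - 0.5) * (0.03 / sd(betas))  # sd approx 0.03
  betas[1, ph$status == "case"] <- betas[1, ph$status == "case"] + 0.08
  res <- dmpAssociation(betas, ph, outcome = "obesity",
                        covariates = c("age", "sex"))
  expect_lt(res$p[1], 1e-10)
  expect_gt(res$effect[1], 0)
  expect_true(all(res$p[2:5] > 1e-4))

  # independent oracle: stats::lm on the same design
  fit <- stats::lm(betas[1, ] ~ I(ph$status == "case") + ph$age + I(ph$sex == "M"))
  sm <- summary(fit)$coefficients
  expect_equal(res$effect[1], unname(sm[2, 1]), tolerance = 1e-10)
  expect_equal(res$se[1], unname(sm[2, 2]), tolerance = 1e-10)
  expect_equal(res$p[1], unname(sm[2, 4]), tolerance = 1e-8)

  # location invariance: adding a constant leaves p unchanged
  res_shift <- dmpAssociation(betas + 0.01, ph, covariates = c("age", "sex"))
  expect_equal(res_shift$p, res$p, tolerance = 1e-10)
})

test_that("covariate adjustment removes an age-driven artefact", {
  n <- 400
  ph <- make_pheno(n, 200, seed = 4)
  set.seed(5)
  # age drives beta; age is balanced between classes, outcome orthogonal
  b <- 0.5 + 0.01 * (ph$age - 50) + rnorm(n, 0, 0.02)
  betas <- matrix(pmin(pmax(b, 0), 1), 1, n, dimnames = list("p1", ph$sample))
  res <- dmpAssociation(betas, ph, covariates = c("age", "sex"))
  expect_lt(abs(res$effect), 0.01)
  expect_gt(res$p, 0.01)
})

test_that("degenerate inputs are flagged or rejected", {
  ph <- make_pheno(20, 10, seed = 6)
  betas <- matrix(0.5, 2, 20, dimnames = list(c("c1", "c2"), ph$sample))
  res <- dmpAssociation(betas, ph, covariates = c("age", "sex"))
  expect_true(all(res$flag == "constant_beta"))
  expect_true(all(is.na(res$p)))
  ph1 <- ph; ph1$status <- "case"
  expect_error(dmpAssociation(betas, ph1, covariates = "age"), "at least 2")
  # missing covariates are dropped listwise
  ph2 <- ph; ph2$age[1:3] <- NA
  set.seed(7)
  b2 <- matrix(runif(20), 1, 20, dimnames = list("p", ph$sample))
  expect_equal(dmpAssociation(b2, ph2, covariates = c("age", "sex"))$n, 17)
})

test_that("logistic and M-value variants run and agree in direction", {
  n <- 300
  ph <- make_pheno(n, 150, seed = 8)
  set.seed(9)
  betas <- matrix(rbeta(n, 50, 50), 1, n, dimnames = list("p1", ph$sample))
  betas[1, ph$status == "case"] <- pmin(betas[1, ph$status == "case"] + 0.05, 1)
  lin <- dmpAssociation(betas, ph, covariates = c("age", "sex"))
  logi <- dmpAssociation(betas, ph, covariates = c("age", "sex"), model = "logistic")
  mv <- dmpAssociation(betas, ph, covariates = c("age", "sex"), mvalues = TRUE)
  expect_lt(lin$p, 0.01)
  expect_lt(logi$p, 0.01)
  expect_lt(mv$p, 0.01)
  expect_true(lin$effect > 0 && logi$effect > 0 && mv$effect > 0)
})

test_that("Bonferroni threshold follows alpha/m", {
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 5), 0.01)
  expect_error(bonferroniThreshold(0.05, 0), "positive count")
  # strictly decreasing in m
  ms <- c(1, 10, 100, 4443)
  expect_true(all(diff(vapply(ms, bonferroniThreshold, numeric(1),
                              alpha = 0.05)) < 0))
})

test_that("discovery/replication requires both stages and sign concordance", {
  disc <- data.frame(probe = c("p1", "p2", "p3"),
                     effect = c(0.1, 0.1, 0.05),
                     p = c(1e-6, 1e-6, 0.2), stringsAsFactors = FALSE)
  repl <- data.frame(probe = c("p1", "p2", "p3"),
                     effect = c(0.08, -0.09, 0.05),
                     p = c(0.01, 0.04, 0.01), stringsAsFactors = FALSE)
  repl2 <- rbind(repl, data.frame(probe = "p4", effect = 1, p = 0.001))
  expect_warning(out <- discoveryReplication(disc, repl2, alpha = 0.05), "p4")
  # m = 3 tested, threshold = 0.05/3
  expect_equal(attr(out, "threshold"), 0.05 / 3)
  expect_equal(out$validated, c(TRUE, FALSE, FALSE))  # p2 fails sign concordance
  out2 <- suppressWarnings(
    discoveryReplication(disc, repl2, require_concordance = FALSE))
  expect_equal(out2$validated, c(TRUE, TRUE, FALSE))
  # discovery-pass set shrinks weakly as m grows with fixed p-values
  disc_big <- rbind(disc, data.frame(probe = paste0("x", 1:50),
                                     effect = 0, p = 0.5))
  out3 <- suppressWarnings(discoveryReplication(disc_big, repl))
  expect_lte(sum(out3$discovery_pass), sum(out$discovery_pass))
})

test_that("planted DMPs are exactly recovered end to end", {
  cfg <- simConfig(seed = 12, n_probes = 300, n_true_dmps = 3,
                   n_cases = 120, n_controls = 150,
                   n_cases_rep = 150, n_controls_rep = 180)
  sim <- simulateEwasCohort(cfg)
  disc <- dmpAssociation(sim$discovery$betas, sim$discovery$pheno,
                         covariates = c("age", "sex"))
  repl <- dmpAssociation(sim$replication$betas, sim$replication$pheno,
                         covariates = c("age", "sex"))
  out <- discoveryReplication(disc, repl)
  expect_setequal(out$probe[out$validated], sim$truth$probe[sim$truth$is_dmp])
})

test_that("T2D association adjusted for BMI uses the t2d outcome", {
  cfg <- simConfig(seed = 13, n_probes = 20, n_true_dmps = 0,
                   n_cases = 100, n_controls = 120)
  sim <- simulateEwasCohort(cfg)
  res <- dmpAssociation(sim$discovery$betas, sim$discovery$pheno,
                        outcome = "t2d", covariates = c("age", "sex", "bmi"))
  expect_equal(nrow(res), 20L)
  expect_true(all(!is.na(res$p)))
})
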