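# cohort with a planted trans network: driver SNP -> mediator gene ->
# module factor -> member genes
make_modqtl_cohort <- function(seed, n_ind = 300, n_snps = 12,
                               mediation_fraction = 0.85,
                               beta_mediator = 0.8) {
  geno <- simulate_genotypes(n_ind, n_snps, maf_range = c(0.25, 0.35),
                             ld_rho = 0, seed = seed)
  bundle <- simulate_cohort(
    geno,
    design = list(n_genes = 40, n_geno_pcs = 0),
    truth_config = list(modules = list(list(
      genes = 1:21, driver_snp = 5L, mediator_gene = 21L,
      mediation_fraction = mediation_fraction,
      beta_mediator = beta_mediator))),
    seed = seed + 1)
  samples <- build_covariates(bundle$expression, bundle$samples, n_hidden = 0)
  members <- paste0("g_", 1:20)
  labels <- stats::setNames(rep(1L, 21), paste0("g_", 1:21))
  eig <- module_eigengenes(bundle$expression$values[names(labels), ],
                           labels)$eigengenes
  list(geno = geno, bundle = bundle, samples = samples, labels = labels,
       eigengenes = eig, members = members)
}

test_that("the Bonferroni threshold and homozygote filter govern the scan", {
  expect_equal(modqtl_threshold(12335, 106, 0.05), 0.05 / (12335 * 106))
  expect_error(modqtl_threshold(0, 10), "n_snps")

  fx <- make_modqtl_cohort(seed = 90)
  # a SNP with <= 3 minor-allele homozygotes is excluded
  geno2 <- fx$geno
  rare <- c(rep(1L, 3), rep(0L, nrow(geno2$dosage) - 3))
  geno2$dosage <- cbind(geno2$dosage, snp_rare = rare)
  geno2$snp_meta <- rbind(geno2$snp_meta,
                          data.frame(id = "snp_rare", chrom = "1",
                                     pos = 99000, ref = "A", alt = "G",
                                     maf = mean(rare) / 2))
  expect_message(
    res <- map_modqtl(fx$eigengenes, c(colnames(fx$geno$dosage), "snp_rare"),
                      geno2, fx$samples),
    "excluded")
  expect_false("snp_rare" %in% res$table$snp)
  expect_equal(res$threshold, 0.05 / (res$n_snps * res$n_modules))

  # the planted driver is the strongest association and passes
  drv <- res$table[res$table$snp == "snp_5", ]
  expect_true(drv$passes_bonferroni)
  expect_equal(res$table$snp[which.min(res$table$p)], "snp_5")
  expect_false(is.na(drv$locus_id))
})

test_that("significant SNPs half a window apart merge into one locus", {
  fx <- make_modqtl_cohort(seed = 91)
  # duplicate the driver 0.5 Mb away: same association, overlapping windows
  geno2 <- fx$geno
  geno2$dosage <- cbind(geno2$dosage,
                        snp_dup = fx$geno$dosage[, "snp_5"])
  geno2$snp_meta <- rbind(geno2$snp_meta,
                          data.frame(id = "snp_dup", chrom = "1",
                                     pos = geno2$snp_meta$pos[5] + 5e5,
                                     ref = "A", alt = "G",
                                     maf = geno2$snp_meta$maf[5]))
  res <- map_modqtl(fx$eigengenes, c("snp_5", "snp_dup"), geno2, fx$samples)
  sig <- res$table[res$table$passes_bonferroni, ]
  expect_equal(nrow(sig), 2L)
  expect_equal(length(unique(sig$locus_id)), 1L)
})

test_that("replication across platforms follows coverage, correlation and
           sign rules", {
  fx <- make_modqtl_cohort(seed = 92)
  smp <- fx$samples
  expr_a <- fx$bundle$expression$values[names(fx$labels), ]
  leads <- data.frame(module = "M1", snp = "snp_5",
                      beta = 1, stringsAsFactors = FALSE)
  overlap <- smp$sample_id[1:100]

  rep1 <- replicate_modqtl(list(M1 = names(fx$labels)), expr_a, smp,
                           fx$geno, leads, fx$eigengenes, overlap)
  expect_true(rep1$replicable)
  expect_equal(abs(rep1$rho), 1, tolerance = 1e-10)
  expect_true(rep1$replicated)

  # an anti-correlated platform stays direction-concordant via the sign
  # product rule
  rep2 <- replicate_modqtl(list(M1 = names(fx$labels)), -expr_a, smp,
                           fx$geno, leads, fx$eigengenes, overlap)
  expect_true(rep2$direction_concordant == rep1$direction_concordant)

  # fewer than 5 covered genes: non-replicable
  rep3 <- replicate_modqtl(list(M1 = names(fx$labels)),
                           expr_a[1:4, , drop = FALSE], smp, fx$geno, leads,
                           fx$eigengenes, overlap)
  expect_false(rep3$replicable)
  expect_true(is.na(rep3$p_b))
})

test_that("sensitivity analysis separates cis artifacts from trans networks", {
  # trans network: excluding the mediator leaves the module association
  fx <- make_modqtl_cohort(seed = 93)
  res <- map_modqtl(fx$eigengenes, colnames(fx$geno$dosage), fx$geno,
                    fx$samples)
  thr <- res$threshold
  expr_vals <- fx$bundle$expression$values
  sens <- sensitivity_analysis(1L, fx$labels, cis_egenes = "g_21",
                               data = expr_vals, lead_snp = "snp_5",
                               geno = fx$geno, samples = fx$samples,
                               threshold = thr)
  expect_false(sens$indeterminate)
  expect_equal(sens$n_removed, 1L)
  expect_true(sens$robust)

  # cis-only artifact: module signal enters through one cis member gene
  geno <- simulate_genotypes(300, 8, maf_range = c(0.25, 0.35), ld_rho = 0,
                             seed = 94)
  bundle <- simulate_cohort(
    geno,
    design = list(n_genes = 20, n_geno_pcs = 0),
    truth_config = list(
      cis = data.frame(gene = 5, snp = 3, beta = 2.5),
      modules = list(list(genes = 1:10, loading_range = c(0.3, 0.4)))),
    seed = 95)
  smp <- build_covariates(bundle$expression, bundle$samples, n_hidden = 0)
  labels <- stats::setNames(rep(1L, 10), paste0("g_", 1:10))
  eig <- module_eigengenes(bundle$expression$values[names(labels), ],
                           labels)$eigengenes
  res2 <- map_modqtl(eig, "snp_3", geno, smp, alpha = 0.05)
  sens2 <- sensitivity_analysis(1L, labels, cis_egenes = "g_5",
                                data = bundle$expression$values,
                                lead_snp = "snp_3", geno = geno,
                                samples = smp, threshold = res2$threshold)
  expect_false(sens2$robust)
  # module never grows
  expect_gte(sens2$n_removed, 1L)

  # too few genes left: indeterminate
  tiny <- stats::setNames(rep(1L, 2), paste0("g_", 1:2))
  s3 <- sensitivity_analysis(1L, tiny, cis_egenes = "g_1",
                             data = bundle$expression$values,
                             lead_snp = "snp_3", geno = geno, samples = smp,
                             threshold = 0.05)
  expect_true(s3$indeterminate)
})

test_that("quasi-Bayesian mediation recovers planted product effects", {
  set.seed(96)
  n <- 500
  g <- rbinom(n, 2, 0.3)
  M <- 0.5 * g + rnorm(n)
  Y <- 0.2 * g + 0.6 * M + rnorm(n)
  med <- mediation_analysis(g, M, Y, n_sims = 1000, seed = 97)
  # analytic oracle: ACME = a*b = 0.30, total 0.50, proportion 0.6
  mc_se <- sd(c(med$acme$ci)) / 4 + 0.02
  expect_lt(abs(med$acme$estimate - 0.3), 0.1)
  expect_lt(abs(med$total$estimate - 0.5), 0.1)
  expect_lt(abs(med$prop_mediated$estimate - 0.6), 0.15)
  expect_lt(med$acme$p, 0.01)
  # linear identity: total = ACME + ADE within Monte Carlo error
  expect_lt(abs(med$total$estimate -
                  (med$acme$estimate + med$ade$estimate)), 1e-10)
  expect_true(med$acme$ci[1] < med$acme$ci[2])

  # zero mediator path: ACME interval covers 0
  Y0 <- 0.4 * g + rnorm(n)
  med0 <- mediation_analysis(g, M, Y0, n_sims = 1000, seed = 98)
  expect_lt(med0$acme$ci[1], 0)
  expect_gt(med0$acme$ci[2], 0)
  expect_lt(abs(med0$acme$estimate), 0.05)

  # collinear mediator is unidentified
  expect_error(mediation_analysis(g, g + rnorm(n, 0, 1e-4), Y), "collinear")
})

test_that("mediation is deterministic under a fixed seed", {
  set.seed(99)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  M <- 0.5 * g + rnorm(n)
  Y <- 0.6 * M + rnorm(n)
  m1 <- mediation_analysis(g, M, Y, n_sims = 200, seed = 123)
  m2 <- mediation_analysis(g, M, Y, n_sims = 200, seed = 123)
  expect_identical(m1, m2)
})

test_that("colocalization posteriors behave across the five hypotheses", {
  mk <- function(z, se = 0.1) data.frame(snp = paste0("s", seq_along(z)),
                                         beta = z * se, se = se)
  # one SNP with z = 10 in both traits among 99 nulls
  z1 <- c(10, rnorm(99, 0, 0.5))
  res <- coloc_abf(mk(z1), mk(c(10, rnorm(99, 0, 0.5))))
  expect_gt(res$pp[["PP4"]], 0.9)
  expect_equal(sum(res$pp), 1, tolerance = 1e-9)

  # everything null
  set.seed(100)
  res0 <- coloc_abf(mk(rnorm(50, 0, 0.3)), mk(rnorm(50, 0, 0.3)))
  expect_gt(res0$pp[["PP0"]], 0.9)

  # signal in trait 1 only
  res1 <- coloc_abf(mk(c(10, rnorm(49, 0, 0.3))), mk(rnorm(50, 0, 0.3)))
  expect_gt(res1$pp[["PP1"]], 0.9)

  # distinct causal SNPs
  res3 <- coloc_abf(mk(c(10, rnorm(49, 0, 0.3))),
                    mk(c(rnorm(49, 0, 0.3), 10)))
  expect_gt(res3$pp[["PP3"]], 0.9)

  expect_error(coloc_abf(mk(1), mk(1)), "at least 2")

  # Wakefield formula oracle on a single SNP
  W <- 0.15^2; se <- 0.1; b <- 0.5
  V <- se^2; z <- b / se
  expect_equal(unname(res$labf1[1]),
               0.5 * log((0.1^2) / (0.1^2 + W)) +
                 (10^2 / 2) * (W / (0.1^2 + W)), tolerance = 1e-12)
})
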