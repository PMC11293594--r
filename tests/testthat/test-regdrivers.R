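# a sharp 4-long motif with consensus ACGT
toy_pwm <- matrix(c(20, 0, 0, 0,
                    0, 20, 0, 0,
                    0, 0, 20, 0,
                    0, 0, 0, 20), 4, 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL))

revcomp <- function(s) chartr("ACGT", "TGCA",
                              paste(rev(strsplit(s, "")[[1]]), collapse = ""))

test_that("allele-specific PWM scan calls interrupted and introduced sites", {
  # ref completes the consensus ACGT; alt destroys position 2
  call <- scan_motif_alteration("TTTA", "C", "T", "GTTTT", toy_pwm)
  expect_equal(call, "interrupted")
  # swapping alleles turns the interrupted site into an introduced one
  call2 <- scan_motif_alteration("TTTA", "T", "C", "GTTTT", toy_pwm)
  expect_equal(call2, "introduced")
  # SNP far from any scoring window: none
  call3 <- scan_motif_alteration("TTTT", "T", "A", "TTTT", toy_pwm)
  expect_equal(call3, "none")
  # both alleles hit (SNP outside the motif match but inside the window)
  call4 <- scan_motif_alteration("ACGTTTT", "T", "A", "TTTACGT",
                                 toy_pwm)
  expect_equal(call4, "none")
  expect_error(scan_motif_alteration("TT", "A", "C", "T", toy_pwm), "flank")
})

test_that("motif calls are strand-symmetric", {
  f5 <- "TTTA"; f3 <- "GTTTT"
  fwd <- scan_motif_alteration(f5, "C", "T", f3, toy_pwm)
  rev <- scan_motif_alteration(revcomp(f3), "G", "A", revcomp(f5), toy_pwm)
  expect_equal(fwd, rev)
})

test_that("JASPAR matrices round-trip through the reader", {
  tmp <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 TOY",
               "A [ 20  0  0  0 ]",
               "C [  0 20  0  0 ]",
               "G [  0  0 20  0 ]",
               "T [  0  0  0 20 ]",
               ">MA0002.1 BARE",
               "1 2 3", "4 5 6", "7 8 9", "10 11 12"), tmp)
  pwms <- read_jaspar(tmp)
  expect_named(pwms, c("MA0001.1", "MA0002.1"))
  expect_equal(unname(pwms[["MA0001.1"]]), unname(toy_pwm))
  expect_equal(dim(pwms[["MA0002.1"]]), c(4L, 3L))
})

test_that("motif enrichment reproduces the hypergeometric tail", {
  # 10 signals: 5 with an interaction; motif altered in 4 of those and 1
  # other -> one-sided p = 26/252
  A <- matrix(c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0), ncol = 1,
              dimnames = list(NULL, "M1"))
  flags <- c(rep(TRUE, 5), rep(FALSE, 5))
  res <- motif_enrichment(A, flags, n_perm = 50, seed = 70)
  expect_equal(res$table$p, 26 / 252, tolerance = 1e-12)
  # identical alteration rates in both classes give no enrichment
  A2 <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0), ncol = 1,
               dimnames = list(NULL, "M1"))
  flags2 <- c(rep(TRUE, 4), rep(FALSE, 4))
  res2 <- motif_enrichment(A2, flags2, n_perm = 20, seed = 71)
  expect_gte(res2$table$p, 0.5)
})

test_that("planted motif enrichment is detected with a calibrated null", {
  set.seed(72)
  n_sig <- 400
  flags <- rep(c(TRUE, FALSE), each = n_sig / 2)
  A <- cbind(
    enriched = ifelse(flags, rbinom(n_sig, 1, 0.4), rbinom(n_sig, 1, 0.05)),
    flat1 = rbinom(n_sig, 1, 0.2),
    flat2 = rbinom(n_sig, 1, 0.2))
  res <- motif_enrichment(A, flags, n_perm = 200, seed = 73)
  expect_lt(res$table$q[res$table$motif == "enriched"], 0.05)
  expect_lt(res$perm_p, 0.05)
  expect_lt(res$expected_significant, res$observed_significant)
})

test_that("LD proxies collapse alterations onto the signal lead", {
  geno <- simulate_genotypes(400, 10, ld_rho = 0.995, block_size = 5,
                             seed = 74)
  # alteration carried by a proxy of snp_2 (same block), not the lead itself
  r2 <- ld_r2(geno$dosage[, "snp_2"], geno$dosage[, "snp_3"])
  expect_gte(r2, 0.8)
  alt <- data.frame(snp = "snp_3", motif = "M1")
  sig <- data.frame(lead_snp = c("snp_2", "snp_7"))
  M <- motif_alteration_matrix(sig, alt, geno)
  expect_equal(unname(M[1, "M1"]), 1L)   # proxy carries the change
  expect_equal(unname(M[2, "M1"]), 0L)   # different block: no proxy
})

test_that("regulon activity is linear in the mode vector and calibrated", {
  set.seed(75)
  G <- 200; S <- 20
  vals <- matrix(rnorm(G * S), G, S,
                 dimnames = list(paste0("g", 1:G), paste0("s", 1:S)))
  up <- paste0("g", 1:10); down <- paste0("g", 11:20)
  # sample 1: activated targets high, repressed low
  vals[up, 1] <- vals[up, 1] + 3
  vals[down, 1] <- vals[down, 1] - 3
  reg <- data.frame(tf = "TF1", target = c(up, down),
                    mode = c(rep(1, 10), rep(-1, 10)), evidence = "A")
  expr <- structure(list(values = vals,
                         gene_meta = data.frame(id = rownames(vals),
                                                chrom = "1", tss = 1:G)),
                    class = "expression_matrix")
  act <- regulon_activity(expr, reg)
  expect_gt(act$scores["TF1", 1], 5)
  # permuted (unrelated) samples give small scores
  expect_gt(mean(abs(act$scores["TF1", -1]) < 3), 0.9)
  # negating the modes exactly negates the activity
  reg2 <- transform(reg, mode = -mode)
  act2 <- regulon_activity(expr, reg2)
  expect_equal(act2$scores, -act$scores, tolerance = 1e-12)
  # regulons below the size floor are dropped
  reg3 <- reg[1:4, ]
  expect_error(regulon_activity(expr, reg3), "regulon")
  # evidence filter
  reg4 <- transform(reg, evidence = "D")
  expect_error(regulon_activity(expr, reg4), "regulon")
})

test_that("differential activity finds planted SRS shifts and stays
           calibrated under the null", {
  set.seed(76)
  n_tf <- 40; n_ind <- 120
  ind <- rep(sprintf("i%d", 1:n_ind), each = 2)
  S <- length(ind)
  srs <- rbinom(n_ind, 1, 0.4)[rep(1:n_ind, each = 2)]
  scores <- matrix(rnorm(n_tf * S), n_tf, S,
                   dimnames = list(paste0("TF", 1:n_tf), paste0("s", 1:S)))
  planted <- 1:8
  scores[planted, srs == 1] <- scores[planted, srs == 1] + 1.5
  acts <- structure(list(scores = scores,
                         regulons = data.frame(tf = rownames(scores),
                                               size = 10),
                         estimator = "univariate_lm_tstat"),
                    class = "activity_matrix")
  smp <- data.frame(sample_id = paste0("s", 1:S), individual_id = ind,
                    time_point = rep(c(1, 3), n_ind), srs1 = srs)
  res <- differential_activity(acts, smp)
  expect_gte(sum(res$table$q[planted] < 0.05), 7)
  expect_lte(sum(res$table$q[-planted] < 0.05), 3)
  expect_error(differential_activity(acts, transform(smp, srs1 = 1)),
               "both SRS groups")
})

test_that("activity-cell correlations use the first sample per patient", {
  set.seed(77)
  n_ind <- 40
  smp <- data.frame(sample_id = paste0("s", 1:(2 * n_ind)),
                    individual_id = rep(sprintf("i%02d", 1:n_ind), each = 2),
                    time_point = rep(c(3, 1), n_ind),   # later listed first
                    neutrophils = runif(2 * n_ind),
                    lymphocytes = runif(2 * n_ind),
                    monocytes = runif(2 * n_ind))
  first_rows <- seq(2, 2 * n_ind, by = 2)               # the t=1 samples
  scores <- matrix(rnorm(2 * 2 * n_ind), 2, 2 * n_ind,
                   dimnames = list(c("TF1", "TF2"), smp$sample_id))
  # TF1 activity is a monotone transform of neutrophils at the first sample
  scores["TF1", first_rows] <- exp(smp$neutrophils[first_rows])
  acts <- structure(list(scores = scores, estimator = "univariate_lm_tstat"),
                    class = "activity_matrix")
  res <- activity_cell_correlation(acts, smp)
  r <- res[res$tf == "TF1" & res$cell_type == "neutrophils", ]
  expect_equal(r$rho, 1)
  expect_true(r$significant)
  # independent columns stay non-significant for most pairs
  null_rows <- res[res$tf == "TF2", ]
  expect_true(all(abs(null_rows$rho) < 0.5))
})

test_that("set enrichment matches closed-form tails and handles edge cases", {
  # identical sets: no enrichment signal
  u <- paste0("g", 1:20)
  full <- set_enrichment(u, u, u[1:10], method = "hypergeometric")
  expect_equal(full$effect, 1)
  expect_equal(full$p, 1)
  # the shared 2x2 example
  hits <- paste0("g", 1:5); ann <- paste0("g", c(1:4, 10))
  e <- set_enrichment(hits, u[1:10], ann, method = "hypergeometric")
  expect_equal(e$p, 26 / 252, tolerance = 1e-12)
  ef <- set_enrichment(hits, u[1:10], ann, method = "fisher_one_sided")
  expect_equal(ef$p, e$p)
  # binomial interval convention: 8 of 10 hits at null rate 0.5
  hits_b <- paste0("g", 1:10)
  ann_b <- paste0("g", c(1:8, 11:12))
  eb <- set_enrichment(hits_b, u, ann_b, method = "binomial")
  expect_equal(eb$p, sum(choose(10, 8:10)) / 2^10, tolerance = 1e-12)
  expect_error(set_enrichment("x", character(0), "x"), "universe")
  expect_error(set_enrichment("zz", u, u[1:2]), "subset")
  # family wrapper: q monotone in p
  fam <- set_enrichment_family(hits, u[1:10],
                               list(a = ann, b = u[6:10], c = u[1:2]))
  expect_equal(order(fam$q), order(fam$p))
})
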