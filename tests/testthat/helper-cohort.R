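# Shared fixtures: small synthetic cohorts built in code.

# cohort with one (or two) planted cis effects at ~0.3 MAF SNPs, covariates
# already assembled; small enough for per-test use
make_cis_cohort <- function(seed, n_ind = 300, n_snps = 40, n_genes = 30,
                            beta = 0.8, two_signals = FALSE) {
  geno <- simulate_genotypes(n_ind, n_snps, maf_range = c(0.25, 0.35),
                             block_size = 10, seed = seed)
  # a weak additional eGene keeps the BH boundary (q*) at a realistic level,
  # as in a genome-wide scan where thousands of eGenes span the whole
  # significance range; without it the lone strong eGene sets its own
  # microscopic threshold and secondary signals are undiscoverable
  weak <- data.frame(gene = min(25L, n_genes), snp = min(20L, n_snps),
                     beta = 0.35)
  cis <- if (two_signals)
    data.frame(gene = c(15L, 15L), snp = c(15L, 35L), beta = beta)
  else data.frame(gene = 15L, snp = 15L, beta = beta)
  cis <- rbind(cis, weak)
  # no genotype PCs or hidden factors: computed from a panel this small
  # (one LD region, few genes) they align with the tested SNPs / planted
  # genes themselves and soak up the signal, which genome-wide PCs never do
  bundle <- simulate_cohort(geno,
                            design = list(n_genes = n_genes, n_geno_pcs = 0),
                            truth_config = list(cis = cis), seed = seed + 1)
  samples <- build_covariates(bundle$expression, bundle$samples, n_hidden = 0)
  list(geno = geno, bundle = bundle, samples = samples,
       expr = bundle$expression, cis = cis)
}

# hand-built genotype_matrix from a dosage matrix
as_genotype_matrix <- function(D, chrom = "1", spacing = 1000L) {
  n <- nrow(D); p <- ncol(D)
  ids <- sprintf("ind_%d", seq_len(n))
  snp_ids <- sprintf("snp_%d", seq_len(p))
  dimnames(D) <- list(ids, snp_ids)
  structure(list(dosage = D,
                 snp_meta = data.frame(id = snp_ids, chrom = chrom,
                                       pos = seq_len(p) * spacing,
                                       ref = "A", alt = "G",
                                       maf = pmin(colMeans(D) / 2,
                                                  1 - colMeans(D) / 2),
                                       stringsAsFactors = FALSE),
                 individual_ids = ids),
            class = "genotype_matrix")
}

# correlated gene block data for co-expression tests
make_block_data <- function(bsize = 50, n_noise = 100, n = 150, r = 0.8,
                            seed = 1, n_block = 2) {
  set.seed(seed)
  X <- NULL
  for (b in seq_len(n_block)) {
    f <- rnorm(n)
    lam <- sqrt(r)
    X <- rbind(X, t(vapply(seq_len(bsize),
                           function(i) lam * f + sqrt(1 - lam^2) * rnorm(n),
                           numeric(n))))
  }
  if (n_noise > 0) X <- rbind(X, matrix(rnorm(n_noise * n), n_noise, n))
  rownames(X) <- paste0("g", seq_len(nrow(X)))
  X
}
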