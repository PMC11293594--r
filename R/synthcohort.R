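## Synthetic cohort generation with planted, recorded ground truth.
##
## The generator emulates the observational design of a serially sampled
## sepsis cohort: a few hundred genotyped individuals, one to three blood
## transcriptome samples each, binary sepsis-response-signature (SRS1)
## status that can change between time points, source of sepsis
## (community-acquired pneumonia vs faecal peritonitis) fixed per patient,
## measured cell proportions, and 28-day survival. Expression is built
## gene-by-gene from planted additive cis effects, context interactions,
## latent co-expression module factors (optionally driven by a SNP through
## a cis mediator gene), an individual random intercept, and residual noise.

#' Simulate HWE genotypes with block-autoregressive LD
#'
#' Two haplotypes per individual are drawn under Hardy-Weinberg equilibrium.
#' Within an LD block, each SNP's haplotype allele copies the previous SNP's
#' allele with probability \code{ld_rho} and is otherwise redrawn at its own
#' minor allele frequency; block boundaries reset the chain, so LD decays
#' geometrically inside blocks and is zero across them. Dosage counts the
#' minor allele; columns are re-oriented (and monomorphic draws rejected and
#' resampled) so the recorded MAF is always in (0, 0.5].
#'
#' @param n_individuals number of individuals (rows).
#' @param n_snps number of SNPs (columns).
#' @param maf_range interval in (0, 0.5] from which per-SNP MAFs are drawn
#'   uniformly.
#' @param ld_rho haplotype copying probability in [0, 1).
#' @param block_size SNPs per LD block.
#' @param seed integer seed; identical seed and settings give an identical
#'   matrix.
#' @param chrom chromosome label for all SNPs.
#' @param spacing base-pair spacing between consecutive SNPs.
#' @return a \code{genotype_matrix}: list with \code{dosage} (individuals x
#'   SNPs), \code{snp_meta} (id, chrom, pos, ref, alt, maf) and
#'   \code{individual_ids}.
#' @export
simulate_genotypes <- function(n_individuals, n_snps,
                               maf_range = c(0.05, 0.5),
                               ld_rho = 0.8, block_size = 20L,
                               seed = NULL, chrom = "1", spacing = 2500L) {
  stopifnot(n_individuals >= 2, n_snps >= 1, block_size >= 1)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be a non-empty interval within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  nh <- 2L * n_individuals
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  H <- matrix(0L, nh, n_snps)
  for (j in seq_len(n_snps)) {
    new_block <- ((j - 1L) %% block_size) == 0L
    draw <- stats::rbinom(nh, 1L, maf[j])
    if (new_block || ld_rho == 0) {
      H[, j] <- draw
    } else {
      copy <- stats::runif(nh) < ld_rho
      H[, j] <- ifelse(copy, H[, j - 1L], draw)
    }
    ## reject monomorphic columns so every SNP is polymorphic
    tries <- 0L
    while (length(unique(H[, j])) == 1L && tries < 50L) {
      H[, j] <- stats::rbinom(nh, 1L, max(maf[j], 0.5 / nh))
      tries <- tries + 1L
    }
  }
  odd <- seq(1L, nh, by = 2L)
  D <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]

  af <- colMeans(D) / 2
  ref <- rep("A", n_snps); alt <- rep("G", n_snps)
  flip <- af > 0.5
  if (any(flip)) {
    D[, flip] <- 2L - D[, flip]
    ref[flip] <- "G"; alt[flip] <- "A"
    af[flip] <- 1 - af[flip]
  }
  snp_meta <- data.frame(
    id = sprintf("snp_%d", seq_len(n_snps)),
    chrom = chrom,
    pos = as.integer(seq_len(n_snps)) * as.integer(spacing),
    ref = ref, alt = alt, maf = af, stringsAsFactors = FALSE)
  ids <- sprintf("ind_%d", seq_len(n_individuals))
  dimnames(D) <- list(ids, snp_meta$id)
  structure(list(dosage = D, snp_meta = snp_meta, individual_ids = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (MAF %.3f-%.3f)\n",
              nrow(x$dosage), ncol(x$dosage),
              min(x$snp_meta$maf), max(x$snp_meta$maf)))
  invisible(x)
}

default_design <- function() {
  list(n_genes = 100L,
       timepoint_probs = c(1, 1, 1) / 3,  # P(1, 2 or 3 serial samples)
       srs_prev = 0.35, srs_indiv_sd = 1.5,
       fp_prev = 0.4,
       cell_alpha = c(neutrophils = 10.5, lymphocytes = 3, monocytes = 1.5),
       cell_srs_shift = 2,        # added to the neutrophil Dirichlet weight in SRS1
       cell_missing_rate = 0.01,
       sigma2_u = 0.3, sigma2_e = 0.7,
       env_main_beta = 0.3,       # main effect given to genes with a planted interaction
       n_geno_pcs = 7L,
       surv_base_rate = 0.0103,   # ~25% 28-day event rate at baseline
       surv_loghr = 0.5)          # per-SD log hazard ratio on the linked module factor
}

env_values <- function(env, samples) {
  switch(env,
         srs1 = as.numeric(samples$srs1),
         diagnosis = as.numeric(samples$diagnosis == "FP"),
         sex = as.numeric(samples$sex),
         neutrophils = , lymphocytes = , monocytes = {
           v <- samples[[env]]
           v[is.na(v)] <- stats::median(v, na.rm = TRUE)
           as.numeric(scale(v))
         },
         stop("unknown environment variable: ", env))
}

#' Simulate a serially sampled cohort with planted effects
#'
#' Builds expression for every gene as
#' \deqn{y = \mu_g + \sum_k \beta_k G + \sum_e (\beta_E E + \beta_{GxE} G E)
#'   + \ell_g F_m + u_i + \epsilon}
#' where \eqn{F_m} is a latent module factor (individual-level), \eqn{u_i}
#' an individual random intercept and \eqn{\epsilon} residual noise. For a
#' module with a planted driver SNP, the mediator gene receives a cis effect
#' from the driver and the factor is
#' \eqn{F_m = \rho\,\mathrm{std}(y_{mediator}) + \sqrt{1-\rho^2}\, z}
#' with \eqn{\rho} the mediation fraction and \eqn{z} independent
#' individual-level noise, so the driver acts on the module only through the
#' mediator.
#'
#' @param geno a \code{genotype_matrix}.
#' @param design named list of cohort settings; see Details of the package
#'   vignette. Unset entries take the package defaults.
#' @param truth_config named list of planted effects with optional elements
#'   \code{cis} (data.frame gene, snp, beta), \code{gxe} (data.frame gene,
#'   snp, env, beta) and \code{modules} (list of lists with genes,
#'   driver_snp, mediator_gene, mediation_fraction, beta_mediator,
#'   loading_range). Genes and SNPs may be given as integer indices or ids.
#' @param seed integer seed.
#' @return a \code{cohort_bundle}: genotypes, expression
#'   (\code{expression_matrix}), samples (data.frame), truth (list), seed.
#' @export
simulate_cohort <- function(geno, design = list(), truth_config = list(),
                            seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  d <- utils::modifyList(default_design(), design)
  G <- as.integer(d$n_genes)
  N <- nrow(geno$dosage)
  ind_ids <- geno$individual_ids

  gene_ids <- sprintf("g_%d", seq_len(G))
  resolve <- function(x, ids, what) {
    if (is.numeric(x)) {
      if (any(x < 1 | x > length(ids))) stop("out-of-range ", what, " index")
      ids[x]
    } else {
      if (!all(x %in% ids)) stop("unknown ", what, " id(s)")
      as.character(x)
    }
  }

  ## ---- samples -------------------------------------------------------
  n_samp_per <- sample.int(3L, N, replace = TRUE, prob = d$timepoint_probs)
  ind_of_sample <- rep(seq_len(N), n_samp_per)
  tp_codes <- c(1L, 3L, 5L)
  time_point <- unlist(lapply(n_samp_per, function(k) tp_codes[seq_len(k)]))
  S <- length(ind_of_sample)
  sample_id <- sprintf("%s_t%d", ind_ids[ind_of_sample], time_point)

  srs_eta <- stats::qlogis(d$srs_prev) + stats::rnorm(N, 0, d$srs_indiv_sd)
  srs1 <- stats::rbinom(S, 1L, stats::plogis(srs_eta[ind_of_sample]))
  diagnosis <- ifelse(stats::rbinom(N, 1L, d$fp_prev) == 1L, "FP", "CAP")[ind_of_sample]
  sex <- stats::rbinom(N, 1L, 0.5)[ind_of_sample]

  alpha <- matrix(rep(d$cell_alpha, each = S), nrow = S)
  colnames(alpha) <- names(d$cell_alpha)
  alpha[srs1 == 1L, "neutrophils"] <- alpha[srs1 == 1L, "neutrophils"] + d$cell_srs_shift
  gam <- matrix(stats::rgamma(S * 3L, shape = alpha), nrow = S)
  cells <- gam / rowSums(gam)
  colnames(cells) <- names(d$cell_alpha)
  miss <- stats::runif(S) < d$cell_missing_rate
  cells[miss, ] <- NA_real_

  samples <- data.frame(sample_id = sample_id,
                        individual_id = ind_ids[ind_of_sample],
                        time_point = time_point,
                        srs1 = srs1, diagnosis = diagnosis, sex = sex,
                        cells, stringsAsFactors = FALSE)

  ## genotype PCs (standardized scores)
  npc <- min(d$n_geno_pcs, N - 1L, ncol(geno$dosage))
  if (npc > 0L) {
    pcs <- stats::prcomp(geno$dosage, center = TRUE, scale. = FALSE,
                         rank. = npc)$x
    pcs <- scale(pcs)
    for (k in seq_len(npc)) samples[[sprintf("PC%d", k)]] <- pcs[ind_of_sample, k]
  }

  ## ---- planted truth -------------------------------------------------
  cis <- truth_config$cis
  if (!is.null(cis)) {
    cis <- as.data.frame(cis)
    cis$gene <- resolve(cis$gene, gene_ids, "gene")
    cis$snp <- resolve(cis$snp, geno$snp_meta$id, "SNP")
    if (anyDuplicated(cis[, c("gene", "snp")]))
      stop("conflicting truth entries: same gene and SNP listed twice")
  } else cis <- data.frame(gene = character(0), snp = character(0), beta = numeric(0))

  gxe <- truth_config$gxe
  if (!is.null(gxe)) {
    gxe <- as.data.frame(gxe)
    gxe$gene <- resolve(gxe$gene, gene_ids, "gene")
    gxe$snp <- resolve(gxe$snp, geno$snp_meta$id, "SNP")
  } else gxe <- data.frame(gene = character(0), snp = character(0),
                           env = character(0), beta = numeric(0))

  modules <- truth_config$modules
  if (is.null(modules)) modules <- list()
  modules <- lapply(seq_along(modules), function(m) {
    mod <- modules[[m]]
    mod$module_id <- if (is.null(mod$module_id)) sprintf("M%d", m) else mod$module_id
    mod$genes <- resolve(mod$genes, gene_ids, "gene")
    if (!is.null(mod$driver_snp) && !is.na(mod$driver_snp)) {
      mod$driver_snp <- resolve(mod$driver_snp, geno$snp_meta$id, "SNP")
      mod$mediator_gene <- resolve(mod$mediator_gene, gene_ids, "gene")
      if (is.null(mod$mediation_fraction)) mod$mediation_fraction <- 0.85
      if (is.null(mod$beta_mediator)) mod$beta_mediator <- 0.8
      if (mod$mediation_fraction < 0 || mod$mediation_fraction > 1)
        stop("mediation_fraction must be in [0, 1]")
    } else {
      mod$driver_snp <- NA_character_; mod$mediator_gene <- NA_character_
      mod$mediation_fraction <- NA_real_
    }
    if (is.null(mod$loading_range)) mod$loading_range <- c(0.4, 0.8)
    mod
  })

  ## mediator cis effects implied by driven modules
  for (mod in modules) {
    if (!is.na(mod$driver_snp)) {
      hit <- cis$gene == mod$mediator_gene & cis$snp == mod$driver_snp
      if (!any(hit))
        cis <- rbind(cis, data.frame(gene = mod$mediator_gene,
                                     snp = mod$driver_snp,
                                     beta = mod$beta_mediator))
    }
  }
  ## signal ranks within gene, by listing order
  cis$signal_rank <- stats::ave(seq_len(nrow(cis)), cis$gene,
                                FUN = seq_along)

  ## ---- expression ----------------------------------------------------
  gidx <- match(cis$gene, gene_ids)
  sidx <- match(cis$snp, geno$snp_meta$id)
  Y <- matrix(0, G, S, dimnames = list(gene_ids, sample_id))

  dos_s <- geno$dosage[ind_of_sample, , drop = FALSE]  # samples x SNPs

  for (r in seq_len(nrow(cis)))
    Y[gidx[r], ] <- Y[gidx[r], ] + cis$beta[r] * dos_s[, sidx[r]]

  if (nrow(gxe)) {
    for (r in seq_len(nrow(gxe))) {
      gi <- match(gxe$gene[r], gene_ids)
      ev <- env_values(gxe$env[r], samples)
      g <- dos_s[, match(gxe$snp[r], geno$snp_meta$id)]
      Y[gi, ] <- Y[gi, ] + d$env_main_beta * ev + gxe$beta[r] * g * ev
    }
  }

  u <- matrix(stats::rnorm(G * N, 0, sqrt(d$sigma2_u)), G, N)
  eps <- matrix(stats::rnorm(G * S, 0, sqrt(d$sigma2_e)), G, S)

  loadings <- data.frame(module_id = character(0), gene = character(0),
                         loading = numeric(0))
  F_ind <- matrix(numeric(0), nrow = 0, ncol = N)  # per-module individual factor means
  for (mod in modules) {
    if (!is.na(mod$driver_snp)) {
      mi <- match(mod$mediator_gene, gene_ids)
      y_med <- Y[mi, ] + u[mi, ind_of_sample] + eps[mi, ]
      z <- stats::rnorm(N)[ind_of_sample]
      rho <- mod$mediation_fraction
      f <- rho * as.numeric(scale(y_med)) + sqrt(max(0, 1 - rho^2)) * z
    } else {
      f <- stats::rnorm(N)[ind_of_sample]
    }
    members <- setdiff(mod$genes, mod$mediator_gene)
    l <- stats::runif(length(members), mod$loading_range[1], mod$loading_range[2])
    for (k in seq_along(members))
      Y[match(members[k], gene_ids), ] <-
        Y[match(members[k], gene_ids), ] + l[k] * f
    loadings <- rbind(loadings,
                      data.frame(module_id = mod$module_id, gene = members,
                                 loading = l))
    F_ind <- rbind(F_ind, rowsum(f, ind_of_sample)[, 1] / n_samp_per)
  }

  Y <- Y + u[, ind_of_sample] + eps

  ## ---- survival ------------------------------------------------------
  eta <- if (length(modules)) d$surv_loghr * as.numeric(scale(F_ind[1, ])) else rep(0, N)
  t_raw <- stats::rexp(N, rate = d$surv_base_rate * exp(eta))
  surv_event <- as.integer(t_raw <= 28)
  surv_time <- pmin(t_raw, 28)
  samples$surv_time <- surv_time[ind_of_sample]
  samples$surv_event <- surv_event[ind_of_sample]

  ## ---- gene annotation: spread TSS across the SNP span ----------------
  span <- range(geno$snp_meta$pos)
  gene_meta <- data.frame(id = gene_ids,
                          chrom = geno$snp_meta$chrom[1],
                          tss = as.integer(round(seq(span[1], span[2],
                                                     length.out = G))),
                          stringsAsFactors = FALSE)
  expr <- structure(list(values = Y, gene_meta = gene_meta),
                    class = "expression_matrix")

  truth <- list(
    cis_effects = cis,
    interaction_effects = if (nrow(gxe))
      data.frame(gene = gxe$gene, snp = gxe$snp, env_name = gxe$env,
                 beta_gxe = gxe$beta) else
      data.frame(gene = character(0), snp = character(0),
                 env_name = character(0), beta_gxe = numeric(0)),
    module_truth = lapply(modules, function(mod)
      mod[c("module_id", "genes", "driver_snp", "mediator_gene",
            "mediation_fraction")]),
    loadings = loadings,
    variance_components = data.frame(gene = gene_ids,
                                     sigma2_u = d$sigma2_u,
                                     sigma2_e = d$sigma2_e))

  structure(list(genotypes = geno, expression = expr, samples = samples,
                 truth = truth, seed = seed, design = d),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle: %d individuals, %d samples, %d genes, %d SNPs\n",
              nrow(x$genotypes$dosage), nrow(x$samples),
              nrow(x$expression$values), ncol(x$genotypes$dosage)))
  cat(sprintf("  planted: %d cis effects, %d interactions, %d modules\n",
              nrow(x$truth$cis_effects), nrow(x$truth$interaction_effects),
              length(x$truth$module_truth)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Genotypes are written as an uncompressed VCF 4.2 with a GT-only FORMAT
#' field (ALT is the minor allele, so dosage equals the ALT allele count);
#' expression, gene annotation, sample metadata and the planted-truth tables
#' are written as TSV. Reading the files back reproduces dosages and values
#' exactly.
#'
#' @param bundle a \code{cohort_bundle}.
#' @param out_dir output directory (created if missing).
#' @return named character vector of the files written (the manifest).
#' @export
write_cohort <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)

  geno <- bundle$genotypes
  vcf <- file.path(out_dir, "genotypes.vcf")
  meta <- geno$snp_meta
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_codes[t(geno$dosage) + 1L], nrow = nrow(meta))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(meta$chrom)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$individual_ids), collapse = "\t"))
  body <- paste(meta$chrom, meta$pos, meta$id, meta$ref, meta$alt, ".", "PASS",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf)

  wtsv <- function(x, f, rn = FALSE)
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = rn,
                       col.names = TRUE)
  expr_f <- file.path(out_dir, "expression.tsv")
  wtsv(bundle$expression$values, expr_f, rn = TRUE)
  genes_f <- file.path(out_dir, "genes.tsv")
  wtsv(bundle$expression$gene_meta, genes_f)
  samples_f <- file.path(out_dir, "samples.tsv")
  wtsv(bundle$samples, samples_f)
  cis_f <- file.path(out_dir, "truth_cis.tsv")
  wtsv(bundle$truth$cis_effects, cis_f)
  gxe_f <- file.path(out_dir, "truth_interactions.tsv")
  wtsv(bundle$truth$interaction_effects, gxe_f)
  mod_rows <- do.call(rbind, lapply(bundle$truth$module_truth, function(m)
    data.frame(module_id = m$module_id, gene = m$genes,
               driver_snp = m$driver_snp, mediator_gene = m$mediator_gene,
               mediation_fraction = m$mediation_fraction)))
  mod_f <- file.path(out_dir, "truth_modules.tsv")
  if (is.null(mod_rows))
    mod_rows <- data.frame(module_id = character(0), gene = character(0),
                           driver_snp = character(0),
                           mediator_gene = character(0),
                           mediation_fraction = numeric(0))
  wtsv(mod_rows, mod_f)

  c(vcf = vcf, expression = expr_f, genes = genes_f, samples = samples_f,
    truth_cis = cis_f, truth_interactions = gxe_f, truth_modules = mod_f)
}
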