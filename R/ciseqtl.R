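## Genome-wide cis-eQTL scan: per-gene mixed-model association within a
## 1 Mb TSS window, effective-test local correction, hierarchical FDR
## across genes, and forward-backward conditional discovery of independent
## signals.

## expand individual-level dosages to the sample level
sample_dosage <- function(geno, samples, snp_ids) {
  ridx <- match(samples$individual_id, geno$individual_ids)
  if (anyNA(ridx)) stop("samples reference individuals absent from genotypes")
  geno$dosage[ridx, snp_ids, drop = FALSE]
}

## index of the most significant SNP; ties broken by smaller position
peak_index <- function(p, pos) {
  cand <- which(p == min(p, na.rm = TRUE))
  cand[which.min(pos[cand])]
}

#' Mixed-model cis scan for one gene
#'
#' Tests every SNP within \code{window_bp} of the gene's TSS with a
#' random-intercept LMM: fixed covariates plus dosage, random intercept per
#' individual, p-value from a 1-df likelihood-ratio test against the model
#' without the dosage term. SNPs used as conditioning covariates score
#' p = 1 (they carry no additional signal by construction).
#'
#' @param gene gene id present in \code{expr$gene_meta}.
#' @param geno a \code{genotype_matrix}.
#' @param expr an \code{expression_matrix}.
#' @param samples sample data.frame (rows match expression columns).
#' @param window_bp cis window half-width around the TSS (default 1 Mb).
#' @param extra_covariate_snps SNP ids whose dosages are added to the fixed
#'   covariates (conditional scans).
#' @param covariates optional precomputed covariate matrix; defaults to the
#'   standard design from \code{standard_covariates()}.
#' @param compute_meff whether to estimate the effective test count
#'   (skipped in conditional rescans).
#' @return a \code{gene_scan}: gene, table (snp, pos, beta, se, p), m_eff,
#'   p_local_peak, n_tested.
#' @export
map_cis_gene <- function(gene, geno, expr, samples, window_bp = 1e6,
                         extra_covariate_snps = NULL, covariates = NULL,
                         compute_meff = TRUE) {
  gm <- expr$gene_meta
  gi <- match(gene, gm$id)
  if (is.na(gi)) stop("gene ", gene, " has no annotation")
  meta <- geno$snp_meta
  in_win <- meta$chrom == gm$chrom[gi] & abs(meta$pos - gm$tss[gi]) <= window_bp
  if (!any(in_win)) {
    return(structure(list(gene = gene, table = NULL, m_eff = NA_real_,
                          p_local_peak = NA_real_, n_tested = 0L),
                     class = "gene_scan"))
  }
  snp_ids <- meta$id[in_win]
  pos <- meta$pos[in_win]
  y <- expr$values[gi, ]
  if (is.null(covariates)) covariates <- standard_covariates(samples)
  X0 <- cbind(`(Intercept)` = 1, covariates)
  if (length(extra_covariate_snps))
    X0 <- cbind(X0, sample_dosage(geno, samples, extra_covariate_snps))
  groups <- samples$individual_id
  null_fit <- suppressWarnings(fit_lmm(y, X0, groups))
  dos <- sample_dosage(geno, samples, snp_ids)

  nt <- length(snp_ids)
  beta <- se <- p <- rep(NA_real_, nt)
  for (j in seq_len(nt)) {
    if (snp_ids[j] %in% extra_covariate_snps) { p[j] <- 1; next }
    X <- cbind(X0, dosage = dos[, j])
    fit <- suppressWarnings(fit_lmm(y, X, groups))
    if (!("dosage" %in% names(fit$beta))) { p[j] <- 1; next }
    beta[j] <- fit$beta[["dosage"]]
    se[j] <- fit$se[["dosage"]]
    p[j] <- lrt_nested(fit, null_fit, df = 1L)$p
  }
  m_eff <- if (compute_meff)
    effective_tests(geno$dosage[, snp_ids, drop = FALSE]) else NA_real_
  tab <- data.frame(snp = snp_ids, pos = pos, beta = beta, se = se, p = p,
                    stringsAsFactors = FALSE)
  structure(list(gene = gene, table = tab, m_eff = m_eff,
                 p_local_peak = if (compute_meff)
                   min(1, min(p, na.rm = TRUE) * m_eff) else NA_real_,
                 n_tested = nt),
            class = "gene_scan")
}

#' @export
print.gene_scan <- function(x, ...) {
  cat(sprintf("gene_scan %s: %d SNPs tested, M_eff = %.1f, local peak p = %.3g\n",
              x$gene, x$n_tested, x$m_eff, x$p_local_peak))
  invisible(x)
}

#' Effective number of independent tests in a SNP window
#'
#' Eigendecomposition of the shrunk dosage correlation matrix, computed on
#' consecutive partitions of at most \code{partition_size} SNPs. Shrinkage
#' toward the identity uses the Ledoit-Wolf/Schafer-Strimmer intensity
#' estimated from the data. The per-partition effective count is the
#' smallest number of eigenvalues whose cumulative fraction reaches
#' \code{var_explained}; partition counts are summed and capped at the SNP
#' count.
#'
#' @param window_dosages individuals x SNPs dosage matrix.
#' @param var_explained eigenvalue mass threshold (default 0.99).
#' @param partition_size maximum SNPs per partition (default 200).
#' @return effective test count (integer-valued numeric, in [1, n_snps]).
#' @export
effective_tests <- function(window_dosages, var_explained = 0.99,
                            partition_size = 200L) {
  p <- ncol(window_dosages)
  if (is.null(p) || p == 0L) stop("empty SNP window")
  if (p == 1L) return(1)
  n <- nrow(window_dosages)
  parts <- split(seq_len(p), ceiling(seq_len(p) / partition_size))
  total <- 0
  for (idx in parts) {
    X <- window_dosages[, idx, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    const <- sds == 0
    Xs <- scale(X[, !const, drop = FALSE])
    k <- ncol(Xs)
    if (k == 0L) { total <- total + sum(const); next }
    if (k == 1L) { total <- total + 1 + sum(const); next }
    r <- crossprod(Xs) / (n - 1)
    ## Schafer-Strimmer variance of the correlation entries
    V <- (n / (n - 1)^3) * (crossprod(Xs^2) - (n - 1)^2 * r^2 / n)
    off <- upper.tri(r)
    denom <- sum(r[off]^2)
    lam <- if (denom > 0) min(1, max(0, sum(V[off]) / denom)) else 1
    rs <- (1 - lam) * r
    diag(rs) <- 1
    ev <- eigen(rs, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    cum <- cumsum(ev) / sum(ev)
    total <- total + which(cum >= var_explained)[1] + sum(const)
  }
  min(total, p)
}

#' Hierarchical multiple-testing correction across genes
#'
#' Gene-level peak p-values (already Bonferroni-adjusted by the effective
#' local test count) are adjusted across genes by Benjamini-Hochberg.
#' eGenes are genes with adjusted value below \code{fdr}. The per-gene
#' nominal threshold for calling additional significant SNPs is
#' \eqn{q^*/M_{eff,g}}, where \eqn{q^*} is the largest locally adjusted
#' peak p among passing genes.
#'
#' @param scans list of \code{gene_scan} objects.
#' @param fdr global false discovery rate (default 0.05).
#' @return data.frame with gene, m_eff, p_local_peak, q_global, egene,
#'   p_threshold_gene (NA for non-eGenes).
#' @export
hierarchical_fdr <- function(scans, fdr = 0.05) {
  scans <- Filter(function(s) !is.na(s$p_local_peak), scans)
  if (length(scans) == 0L) stop("no scans with a local peak p-value")
  genes <- vapply(scans, function(s) s$gene, character(1))
  pk <- vapply(scans, function(s) s$p_local_peak, numeric(1))
  meff <- vapply(scans, function(s) s$m_eff, numeric(1))
  q <- stats::p.adjust(pk, method = "BH")
  egene <- q < fdr
  qstar <- if (any(egene)) max(pk[egene]) else NA_real_
  thr <- ifelse(egene, qstar / meff, NA_real_)
  data.frame(gene = genes, m_eff = meff, p_local_peak = pk, q_global = q,
             egene = egene, p_threshold_gene = thr, stringsAsFactors = FALSE)
}

#' Forward-backward discovery of conditionally independent signals
#'
#' Forward pass: rescan the cis window conditioning on all previously found
#' lead SNPs; adopt the new peak while its nominal p stays below the gene's
#' threshold. Backward pass: re-test each forward signal conditioning on
#' all other retained leads, replacing the lead with the most significant
#' passing SNP, or dropping the signal if none passes. Finally a single
#' joint model containing all retained leads yields joint effects; each
#' lead's joint p comes from a 1-df LRT dropping that lead.
#'
#' @param gene eGene id.
#' @param geno,expr,samples as in \code{map_cis_gene}.
#' @param threshold the gene's nominal significance threshold
#'   (\code{p_threshold_gene} from \code{hierarchical_fdr}).
#' @param first_scan optional unconditional \code{gene_scan} already
#'   computed for this gene (saves one scan).
#' @param window_bp,covariates passed to \code{map_cis_gene}.
#' @param max_iter forward-pass iteration cap.
#' @return data.frame of independent signals: gene, lead_snp, rank,
#'   beta_joint, se_joint, p_joint, discovery_p; zero rows when nothing
#'   passes.
#' @export
conditional_signals <- function(gene, geno, expr, samples, threshold,
                                first_scan = NULL, window_bp = 1e6,
                                covariates = NULL, max_iter = 20L) {
  if (is.na(threshold)) return(empty_signals(gene))
  if (is.null(covariates)) covariates <- standard_covariates(samples)
  scan0 <- if (is.null(first_scan))
    map_cis_gene(gene, geno, expr, samples, window_bp,
                 covariates = covariates, compute_meff = FALSE) else first_scan
  tab <- scan0$table
  if (is.null(tab)) return(empty_signals(gene))

  ## forward: the primary lead is the unconditional peak (the gene is
  ## already an eGene); the threshold gates additional signals only
  pk <- peak_index(tab$p, tab$pos)
  if (is.na(tab$p[pk])) return(empty_signals(gene))
  leads <- tab$snp[pk]
  disc_p <- tab$p[pk]
  for (it in seq_len(max_iter)) {
    sc <- map_cis_gene(gene, geno, expr, samples, window_bp,
                       extra_covariate_snps = leads, covariates = covariates,
                       compute_meff = FALSE)$table
    pk <- peak_index(sc$p, sc$pos)
    if (sc$p[pk] >= threshold || sc$snp[pk] %in% leads) break
    leads <- c(leads, sc$snp[pk])
    disc_p <- c(disc_p, sc$p[pk])
  }

  ## backward
  kept <- character(0); kept_p <- numeric(0)
  if (length(leads) == 1L) {
    kept <- leads; kept_p <- disc_p
  } else {
    for (s in seq_along(leads)) {
      others <- setdiff(leads, leads[s])
      sc <- map_cis_gene(gene, geno, expr, samples, window_bp,
                         extra_covariate_snps = others,
                         covariates = covariates, compute_meff = FALSE)$table
      pk <- peak_index(sc$p, sc$pos)
      if (sc$p[pk] < threshold) {
        kept <- c(kept, sc$snp[pk]); kept_p <- c(kept_p, sc$p[pk])
      }
    }
    dup <- duplicated(kept)
    if (any(dup)) {
      warning("backward pass converged on duplicate leads for ", gene,
              "; keeping first occurrence")
      kept <- kept[!dup]; kept_p <- kept_p[!dup]
    }
  }
  if (length(kept) == 0L) return(empty_signals(gene))

  ## final joint model
  y <- expr$values[match(gene, expr$gene_meta$id), ]
  groups <- samples$individual_id
  X0 <- cbind(`(Intercept)` = 1, covariates)
  dos <- sample_dosage(geno, samples, kept)
  colnames(dos) <- kept
  joint <- suppressWarnings(fit_lmm(y, cbind(X0, dos), groups))
  in_joint <- kept %in% names(joint$beta)
  if (!all(in_joint)) {
    warning("collinear leads dropped from the joint model for ", gene)
    kept <- kept[in_joint]; kept_p <- kept_p[in_joint]
    dos <- dos[, kept, drop = FALSE]
    joint <- suppressWarnings(fit_lmm(y, cbind(X0, dos), groups))
  }
  p_joint <- vapply(kept, function(s) {
    red <- suppressWarnings(
      fit_lmm(y, cbind(X0, dos[, setdiff(kept, s), drop = FALSE]), groups))
    lrt_nested(joint, red, df = 1L)$p
  }, numeric(1))

  data.frame(gene = gene, lead_snp = kept, rank = seq_along(kept),
             beta_joint = unname(joint$beta[kept]),
             se_joint = unname(joint$se[kept]),
             p_joint = unname(p_joint),
             discovery_p = kept_p, stringsAsFactors = FALSE)
}

empty_signals <- function(gene) {
  data.frame(gene = character(0), lead_snp = character(0), rank = integer(0),
             beta_joint = numeric(0), se_joint = numeric(0),
             p_joint = numeric(0), discovery_p = numeric(0),
             stringsAsFactors = FALSE)
}
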