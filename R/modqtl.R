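## Module eigengene QTL mapping with a genome-wide Bonferroni threshold,
## 1 Mb locus merging, cross-platform replication, a cis-eGene-exclusion
## sensitivity analysis, quasi-Bayesian causal mediation, and
## approximate-Bayes-factor colocalization.

#' Map SNPs to module eigengenes
#'
#' Candidate SNPs (typically the unique lead eSNPs from conditional cis
#' mapping) are filtered to those with more than \code{min_hom}
#' minor-allele homozygotes; each retained SNP is tested against every
#' module eigengene with the standard-covariate random-intercept LMM. The
#' genome-wide threshold is \code{alpha / (n_snps x n_modules)} on the
#' filtered counts. Significant SNPs define per-module loci as merged 1 Mb
#' windows.
#'
#' @param eigengenes modules x samples matrix.
#' @param candidate_snps character vector of SNP ids.
#' @param geno,samples cohort objects.
#' @param alpha family-wise error rate (default 0.05).
#' @param min_hom homozygote count strictly required (default 3, i.e. >3).
#' @param covariates optional covariate matrix (standard design default).
#' @param locus_window_bp locus window width (default 1 Mb).
#' @return list: table (module, snp, beta, se, p, passes_bonferroni,
#'   locus_id), threshold, n_snps, n_modules.
#' @export
map_modqtl <- function(eigengenes, candidate_snps, geno, samples,
                       alpha = 0.05, min_hom = 3L, covariates = NULL,
                       locus_window_bp = 1e6) {
  hom <- colSums(geno$dosage[, candidate_snps, drop = FALSE] == 2)
  dropped <- candidate_snps[hom <= min_hom]
  if (length(dropped))
    message(length(dropped), " SNP(s) excluded by the >", min_hom,
            " minor-allele-homozygote filter")
  snps <- candidate_snps[hom > min_hom]
  if (length(snps) == 0L) stop("no candidate SNP passes the homozygote filter")
  n_modules <- nrow(eigengenes)
  threshold <- modqtl_threshold(length(snps), n_modules, alpha)

  if (is.null(covariates)) covariates <- standard_covariates(samples)
  X0 <- cbind(`(Intercept)` = 1, covariates)
  groups <- samples$individual_id
  dos <- sample_dosage(geno, samples, snps)

  rows <- list()
  for (m in rownames(eigengenes)) {
    y <- eigengenes[m, ]
    null_fit <- suppressWarnings(fit_lmm(y, X0, groups))
    for (j in seq_along(snps)) {
      fit <- suppressWarnings(fit_lmm(y, cbind(X0, dosage = dos[, j]), groups))
      if (!("dosage" %in% names(fit$beta))) next
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, snp = snps[j],
        beta = fit$beta[["dosage"]], se = fit$se[["dosage"]],
        p = lrt_nested(fit, null_fit, df = 1L)$p,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$passes_bonferroni <- tab$p < threshold

  ## per-module loci: merge overlapping 1 Mb windows around significant SNPs
  tab$locus_id <- NA_character_
  half <- locus_window_bp / 2
  for (m in unique(tab$module)) {
    sig <- which(tab$module == m & tab$passes_bonferroni)
    if (!length(sig)) next
    pos <- geno$snp_meta$pos[match(tab$snp[sig], geno$snp_meta$id)]
    chrom <- geno$snp_meta$chrom[match(tab$snp[sig], geno$snp_meta$id)]
    for (ch in unique(chrom)) {
      ix <- sig[chrom == ch][order(pos[chrom == ch])]
      px <- sort(pos[chrom == ch])
      locus <- cumsum(c(1, diff(px) > locus_window_bp))
      tab$locus_id[ix] <- sprintf("%s_%s_L%d", m, ch, locus)
    }
  }
  list(table = tab, threshold = threshold, n_snps = length(snps),
       n_modules = n_modules, dropped = dropped)
}

#' Replicate module QTLs on a second expression platform
#'
#' Modules with fewer than \code{min_genes} genes measured on platform B
#' are non-replicable. Otherwise the eigengene is recomputed from the
#' platform-B genes, compared with the discovery eigengene by Spearman
#' correlation on the overlapping samples, and the lead SNP association is
#' retested in the independent samples with the same mixed-model design.
#' Direction concordance requires
#' \eqn{\mathrm{sign}(\beta_A)\,\mathrm{sign}(\rho)\,\mathrm{sign}(\beta_B) = +1}.
#'
#' @param module_genes named list: module -> member gene ids.
#' @param expr_b platform-B genes x samples matrix (all platform-B
#'   samples; column names are sample ids).
#' @param samples_b platform-B sample data.frame (same columns as the
#'   discovery SampleFrame).
#' @param geno_b genotypes covering the platform-B individuals.
#' @param leads data.frame: module, snp, beta (discovery direction).
#' @param eigengenes_a discovery eigengene matrix (for the cross-platform
#'   correlation; columns named by sample id).
#' @param overlap_ids sample ids present on both platforms.
#' @param min_genes minimum platform-B gene coverage (default 5).
#' @param p_rep replication significance level (default 0.05).
#' @return data.frame: module, snp, replicable, rho, beta_b, p_b,
#'   replicated, direction_concordant.
#' @export
replicate_modqtl <- function(module_genes, expr_b, samples_b, geno_b, leads,
                             eigengenes_a, overlap_ids, min_genes = 5L,
                             p_rep = 0.05) {
  covb <- standard_covariates(samples_b)
  out <- list()
  for (i in seq_len(nrow(leads))) {
    m <- leads$module[i]
    genes_b <- intersect(module_genes[[m]], rownames(expr_b))
    row <- data.frame(module = m, snp = leads$snp[i], replicable = FALSE,
                      rho = NA_real_, beta_b = NA_real_, p_b = NA_real_,
                      replicated = NA, direction_concordant = NA,
                      stringsAsFactors = FALSE)
    if (length(genes_b) < min_genes) { out[[i]] <- row; next }
    row$replicable <- TRUE
    lab <- stats::setNames(rep(1L, length(genes_b)), genes_b)
    eig_b <- module_eigengenes(expr_b[genes_b, , drop = FALSE], lab)$eigengenes[1, ]

    ov <- intersect(intersect(overlap_ids, colnames(expr_b)),
                    colnames(eigengenes_a))
    if (length(ov) >= 3L) {
      row$rho <- suppressWarnings(
        stats::cor(eigengenes_a[m, ov], eig_b[ov], method = "spearman"))
    }
    indep <- setdiff(colnames(expr_b), overlap_ids)
    sb <- samples_b[match(indep, samples_b$sample_id), , drop = FALSE]
    y <- eig_b[indep]
    X0 <- cbind(1, covb[match(indep, samples_b$sample_id), , drop = FALSE])
    g <- sample_dosage(geno_b, sb, leads$snp[i])[, 1]
    f1 <- suppressWarnings(fit_lmm(y, cbind(X0, dosage = g), sb$individual_id))
    f0 <- suppressWarnings(fit_lmm(y, X0, sb$individual_id))
    if ("dosage" %in% names(f1$beta)) {
      row$beta_b <- f1$beta[["dosage"]]
      row$p_b <- lrt_nested(f1, f0, df = 1L)$p
      row$replicated <- row$p_b < p_rep
      if (!is.na(row$rho) && row$rho != 0)
        row$direction_concordant <-
          sign(leads$beta[i]) * sign(row$rho) * sign(row$beta_b) == 1
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Sensitivity of a module QTL to its cis-eGene members
#'
#' Recomputes the module eigengene after removing member genes that are
#' cis-eGenes of any module QTL SNP and retests the lead SNP association.
#' A robust (trans-network) association stays below the genome-wide
#' threshold; an association driven only by cis members does not.
#'
#' @param module_id integer module label.
#' @param labels module labels named by gene.
#' @param cis_egenes character vector of genes to exclude (cis-eGenes of
#'   the module's QTL SNPs).
#' @param data genes x samples matrix for eigengene recomputation.
#' @param lead_snp SNP id retested.
#' @param geno,samples cohort objects.
#' @param threshold genome-wide significance threshold.
#' @param covariates optional covariate matrix.
#' @return list: eigengene (or NULL), p, robust, n_removed,
#'   indeterminate.
#' @export
sensitivity_analysis <- function(module_id, labels, cis_egenes, data,
                                 lead_snp, geno, samples, threshold,
                                 covariates = NULL) {
  members <- names(labels)[labels == module_id]
  keep <- setdiff(members, cis_egenes)
  if (length(keep) < 2L)
    return(list(eigengene = NULL, p = NA_real_, robust = NA,
                n_removed = length(members) - length(keep),
                indeterminate = TRUE))
  lab <- stats::setNames(rep(1L, length(keep)), keep)
  eig <- module_eigengenes(data[keep, , drop = FALSE], lab)$eigengenes[1, ]
  if (is.null(covariates)) covariates <- standard_covariates(samples)
  X0 <- cbind(1, covariates)
  g <- sample_dosage(geno, samples, lead_snp)[, 1]
  f1 <- suppressWarnings(fit_lmm(eig, cbind(X0, dosage = g),
                                 samples$individual_id))
  f0 <- suppressWarnings(fit_lmm(eig, X0, samples$individual_id))
  p <- lrt_nested(f1, f0, df = 1L)$p
  list(eigengene = eig, p = p, robust = p < threshold,
       n_removed = length(members) - length(keep), indeterminate = FALSE)
}

#' Quasi-Bayesian causal mediation of a module QTL through a cis gene
#'
#' Linear mediator and outcome models are fitted on one sample per
#' individual (the first available): \eqn{M \sim G + C} and
#' \eqn{Y \sim G + M + C}. Coefficients are drawn from their asymptotic
#' normal distributions; each draw yields an indirect effect
#' \eqn{ACME = a b}, a direct effect \eqn{ADE = c'}, the total effect and
#' the proportion mediated. Point estimates are the draw means (median for
#' the proportion), intervals are percentile, p-values are two-sided
#' empirical sign probabilities. Effects are per additional copy of the
#' minor allele.
#'
#' @param snp_dosage dosage per individual (first-sample subset).
#' @param mediator_expr mediator gene expression, same individuals.
#' @param eigengene outcome eigengene values, same individuals.
#' @param covariates covariate matrix (same individuals) or NULL.
#' @param n_sims quasi-Bayesian draws (default 1000).
#' @param seed integer seed.
#' @return list of class \code{mediation_result}: acme, ade, total,
#'   prop_mediated, each with estimate/ci/p; n_sims.
#' @export
mediation_analysis <- function(snp_dosage, mediator_expr, eigengene,
                               covariates = NULL, n_sims = 1000L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(snp_dosage)
  if (stats::var(snp_dosage) > 0 && stats::var(mediator_expr) > 0 &&
      stats::cor(snp_dosage, mediator_expr)^2 > 0.99)
    stop("mediator and genotype nearly collinear; mediation unidentified")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  Xm <- cbind(1, G = snp_dosage, C)
  Xy <- cbind(1, G = snp_dosage, M = mediator_expr, C)

  fit_ols <- function(X, y) {
    f <- stats::lm.fit(X, y)
    s2 <- sum(f$residuals^2) / (n - ncol(X))
    V <- s2 * chol2inv(chol(crossprod(X)))
    list(coef = f$coefficients, vcov = V)
  }
  fm <- fit_ols(Xm, mediator_expr)
  fy <- fit_ols(Xy, eigengene)

  dm <- MASS::mvrnorm(n_sims, fm$coef, fm$vcov)
  dy <- MASS::mvrnorm(n_sims, fy$coef, fy$vcov)
  a <- dm[, "G"]; b <- dy[, "M"]; cp <- dy[, "G"]
  acme <- a * b
  ade <- cp
  total <- acme + ade
  prop <- acme / total

  summarize <- function(x, point = mean) {
    list(estimate = point(x),
         ci = stats::quantile(x, c(0.025, 0.975), names = FALSE),
         p = min(1, 2 * min(mean(x <= 0), mean(x >= 0))))
  }
  structure(list(acme = summarize(acme),
                 ade = summarize(ade),
                 total = summarize(total),
                 prop_mediated = summarize(prop, point = stats::median),
                 n_sims = n_sims),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  f <- function(nm, s) sprintf("  %-16s %8.4f [%7.4f, %7.4f]  p = %.3g\n",
                               nm, s$estimate, s$ci[1], s$ci[2], s$p)
  cat("Quasi-Bayesian mediation (", x$n_sims, " simulations)\n", sep = "")
  cat(f("ACME", x$acme), f("ADE", x$ade), f("Total effect", x$total),
      f("Prop. mediated", x$prop_mediated), sep = "")
  invisible(x)
}

#' Colocalization of two association signals by approximate Bayes factors
#'
#' Per SNP and trait, the Wakefield log approximate Bayes factor is
#' \eqn{\tfrac12\log\frac{V}{V+W} + \tfrac{z^2}{2}\frac{W}{V+W}} with
#' \eqn{V = se^2}, \eqn{z = \beta/se} and prior effect variance \code{W}.
#' Posterior probabilities over the five hypotheses (no association,
#' trait-1 only, trait-2 only, two distinct variants, one shared variant)
#' are computed with the standard single-causal-variant priors.
#'
#' @param stats1,stats2 data.frames with columns snp, beta, se on a shared
#'   SNP set.
#' @param p1,p2,p12 prior probabilities of association (defaults 1e-4,
#'   1e-4, 1e-5).
#' @param W prior effect-size variance (default 0.15^2, standardized
#'   quantitative traits).
#' @return list of class \code{coloc_result}: pp (PP0..PP4), labf1, labf2,
#'   n_snps, priors.
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      W = 0.15^2) {
  shared <- intersect(stats1$snp, stats2$snp)
  if (length(shared) < 2L) stop("need at least 2 shared SNPs")
  s1 <- stats1[match(shared, stats1$snp), ]
  s2 <- stats2[match(shared, stats2$snp), ]
  labf <- function(beta, se) {
    V <- se^2; z <- beta / se
    0.5 * log(V / (V + W)) + (z^2 / 2) * (W / (V + W))
  }
  l1 <- labf(s1$beta, s1$se)
  l2 <- labf(s2$beta, s2$se)
  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)                    # same SNP for both traits
  ## distinct SNPs: sum_{i != j} = (sum_i)(sum_j) - sum_i(same)
  lsum_pairs <- lsum1 + lsum2
  ldiff <- lsum_pairs + log1p(-exp(lsum12 - lsum_pairs))
  lh <- c(H0 = 0,
          H1 = log(p1) + lsum1,
          H2 = log(p2) + lsum2,
          H3 = log(p1) + log(p2) + ldiff,
          H4 = log(p12) + lsum12)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, labf1 = stats::setNames(l1, shared),
                 labf2 = stats::setNames(l2, shared),
                 n_snps = length(shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12, W = W)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("ABF colocalization over %d SNPs (W = %.4f)\n",
              x$n_snps, x$priors[["W"]]))
  print(round(x$pp, 4))
  invisible(x)
}
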