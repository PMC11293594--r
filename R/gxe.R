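## Genotype-by-context interaction testing for independent eQTL signals:
## eligibility filtering on minor-allele-homozygote counts, 1-df LRT on the
## G:E term, BH correction within each environment family, magnifier /
## dampener classification, and a permutation null for the number of
## significant interactions.

## per-sample environment vector, coded so SRS1 = 1, FP = 1, female = 1;
## cell proportions are used on the inverse-normal scale
interaction_env <- function(env, samples) {
  if (env %in% c("srs1", "diagnosis", "sex"))
    return(list(values = env_values(env, samples), binary = TRUE))
  if (env %in% c("neutrophils", "lymphocytes", "monocytes")) {
    col <- paste0("int_", env)
    v <- if (col %in% names(samples)) samples[[col]] else {
      raw <- samples[[env]]
      raw[is.na(raw)] <- stats::median(raw, na.rm = TRUE)
      rank_int(raw)
    }
    return(list(values = as.numeric(v), binary = FALSE))
  }
  stop("unknown environment: ", env)
}

## >=2 minor-allele-homozygote individuals in each subgroup (binary env) or
## each half of the distribution split at the median (ties to the lower half)
interaction_eligible <- function(dos_sample, env_vals, binary, samples) {
  hom <- dos_sample == 2
  grp <- if (binary) env_vals == 1 else env_vals > stats::median(env_vals)
  n_hi <- length(unique(samples$individual_id[hom & grp]))
  n_lo <- length(unique(samples$individual_id[hom & !grp]))
  n_hi >= 2 && n_lo >= 2
}

#' Test one independent eQTL signal for a genotype-by-context interaction
#'
#' Fits the standard covariates (with the environment removed from the
#' covariate list if already present), any other same-gene signal leads,
#' genotype, environment, and their product, with a random intercept per
#' individual; the interaction p-value is a 1-df LRT on the product term.
#' Ineligible signals (fewer than two minor-allele-homozygote individuals
#' in an environment subgroup or distribution half) are returned untested.
#' For sex, the main eQTL must remain significant once sex enters the
#' model (nominal p below \code{main_threshold}) before the interaction is
#' tested.
#'
#' @param gene,lead_snp the signal being tested.
#' @param env one of srs1, diagnosis, sex, neutrophils, lymphocytes,
#'   monocytes.
#' @param geno,expr,samples cohort objects.
#' @param other_leads other independent leads for the same gene, entered as
#'   covariates.
#' @param covariates optional precomputed covariate matrix *excluding* the
#'   environment variable.
#' @param main_threshold nominal threshold for the sex re-verification
#'   step (the gene's \code{p_threshold_gene}).
#' @return one-row data.frame: gene, lead_snp, env_name, beta_g, beta_gxe,
#'   se_gxe, p_interaction, eligible.
#' @export
test_interaction <- function(gene, lead_snp, env, geno, expr, samples,
                             other_leads = NULL, covariates = NULL,
                             main_threshold = 0.05) {
  ev <- interaction_env(env, samples)
  if (is.null(covariates))
    covariates <- standard_covariates(samples,
                                      exclude = c(env, paste0("int_", env)))
  g <- sample_dosage(geno, samples, lead_snp)[, 1]
  out <- data.frame(gene = gene, lead_snp = lead_snp, env_name = env,
                    beta_g = NA_real_, beta_gxe = NA_real_,
                    se_gxe = NA_real_, p_interaction = NA_real_,
                    eligible = FALSE, stringsAsFactors = FALSE)
  if (!interaction_eligible(g, ev$values, ev$binary, samples)) return(out)
  out$eligible <- TRUE

  y <- expr$values[match(gene, expr$gene_meta$id), ]
  groups <- samples$individual_id
  X_base <- cbind(`(Intercept)` = 1, covariates)
  if (length(other_leads))
    X_base <- cbind(X_base, sample_dosage(geno, samples, other_leads))

  if (env == "sex") {
    with_g <- suppressWarnings(fit_lmm(y, cbind(X_base, E = ev$values,
                                                dosage = g), groups))
    without_g <- suppressWarnings(fit_lmm(y, cbind(X_base, E = ev$values),
                                          groups))
    if (lrt_nested(with_g, without_g, df = 1L)$p >= main_threshold) {
      out$eligible <- FALSE
      return(out)
    }
  }

  Xn <- cbind(X_base, dosage = g, E = ev$values)
  Xf <- cbind(Xn, GxE = g * ev$values)
  full <- suppressWarnings(fit_lmm(y, Xf, groups))
  null <- suppressWarnings(fit_lmm(y, Xn, groups))
  if (!("GxE" %in% names(full$beta))) return(out)
  out$beta_g <- full$beta[["dosage"]]
  out$beta_gxe <- full$beta[["GxE"]]
  out$se_gxe <- full$se[["GxE"]]
  out$p_interaction <- lrt_nested(full, null, df = 1L)$p
  out
}

#' Interaction scan over a set of independent signals
#'
#' Runs \code{test_interaction} for every signal, applies Benjamini-Hochberg
#' within the environment family (eligible signals only), and classifies
#' significant interactions: \emph{magnifier} when the interaction carries
#' the same sign as the genotype main effect (the effect is larger when the
#' environment indicator is 1), \emph{dampener} otherwise.
#'
#' @param signals data.frame with columns gene, lead_snp (e.g. from
#'   \code{conditional_signals}); same-gene companions are conditioned on.
#' @param env environment name.
#' @param geno,expr,samples cohort objects.
#' @param fdr FDR level for the significance class (default 0.05).
#' @param main_thresholds optional named vector (by gene) of nominal
#'   thresholds for the sex re-verification.
#' @return data.frame of \code{test_interaction} rows plus q_bh and class.
#' @export
interaction_scan <- function(signals, env, geno, expr, samples, fdr = 0.05,
                             main_thresholds = NULL) {
  covariates <- standard_covariates(samples,
                                    exclude = c(env, paste0("int_", env)))
  rows <- lapply(seq_len(nrow(signals)), function(i) {
    gene <- signals$gene[i]
    others <- setdiff(signals$lead_snp[signals$gene == gene],
                      signals$lead_snp[i])
    thr <- if (!is.null(main_thresholds) && gene %in% names(main_thresholds))
      main_thresholds[[gene]] else 0.05
    test_interaction(gene, signals$lead_snp[i], env, geno, expr, samples,
                     other_leads = others, covariates = covariates,
                     main_threshold = thr)
  })
  res <- do.call(rbind, rows)
  res$q_bh <- NA_real_
  ok <- res$eligible & !is.na(res$p_interaction)
  res$q_bh[ok] <- stats::p.adjust(res$p_interaction[ok], method = "BH")
  res$class <- "none"
  sig <- ok & res$q_bh < fdr
  res$class[sig] <- ifelse(sign(res$beta_g[sig]) == sign(res$beta_gxe[sig]),
                           "magnifier", "dampener")
  res
}

#' Permutation null for the number of significant interactions
#'
#' SRS status is permuted across samples; diagnosis is permuted across
#' patients (stays constant within a patient). Each permutation repeats the
#' interaction analysis and records the number of BH-significant signals.
#' The headline empirical p uses the add-one count estimator on that
#' number; a refined p that breaks count ties by the smallest nominal
#' interaction p (lexicographic extremeness) is also returned, and is the
#' quantity that is uniformly distributed under the null.
#'
#' @param signals data.frame with gene, lead_snp.
#' @param env "srs1" or "diagnosis".
#' @param geno,expr,samples cohort objects.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param fdr FDR level defining "significant" (default 0.05).
#' @return list with observed_count, perm_counts, expected_count,
#'   p_count (spec add-one estimator on counts), p (tie-refined).
#' @export
permutation_null <- function(signals, env, geno, expr, samples,
                             n_perm = 1000L, seed = NULL, fdr = 0.05) {
  if (!env %in% c("srs1", "diagnosis"))
    stop("permutation null is defined for srs1 and diagnosis")
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  score <- function(smp) {
    res <- interaction_scan(signals, env, geno, expr, smp, fdr = fdr)
    ok <- res$eligible & !is.na(res$p_interaction)
    c(count = sum(ok & res$q_bh < fdr),
      minp = if (any(ok)) min(res$p_interaction[ok]) else 1)
  }
  obs <- score(samples)

  perm <- matrix(NA_real_, n_perm, 2, dimnames = list(NULL, c("count", "minp")))
  inds <- unique(samples$individual_id)
  for (b in seq_len(n_perm)) {
    smp <- samples
    if (env == "srs1") {
      smp$srs1 <- sample(smp$srs1)
    } else {
      ind_diag <- samples$diagnosis[match(inds, samples$individual_id)]
      smp$diagnosis <- sample(ind_diag)[match(smp$individual_id, inds)]
    }
    perm[b, ] <- score(smp)
  }
  more_extreme <- perm[, "count"] > obs[["count"]] |
    (perm[, "count"] == obs[["count"]] & perm[, "minp"] <= obs[["minp"]])
  list(observed_count = unname(obs[["count"]]),
       perm_counts = unname(perm[, "count"]),
       expected_count = mean(perm[, "count"]),
       p_count = (1 + sum(perm[, "count"] >= obs[["count"]])) / (n_perm + 1),
       p = (1 + sum(more_extreme)) / (n_perm + 1))
}
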