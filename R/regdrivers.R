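## Candidate upstream regulators: allele-specific PWM scanning for binding
## sites introduced or interrupted by eSNPs, motif enrichment among
## interaction eQTLs with a permutation check, regulon-based TF activity,
## differential activity between SRS groups, and activity-cell-proportion
## correlation.

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

## position log-odds matrix against a uniform background, with a small
## pseudocount so zero counts stay finite
pwm_logodds <- function(pwm, pseudocount = 0.25) {
  pwm <- as.matrix(pwm)
  if (nrow(pwm) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  probs <- sweep(pwm + pseudocount, 2, colSums(pwm) + 4 * pseudocount, "/")
  log(probs / 0.25)
}

score_windows <- function(seq_chars, lo, snp_pos) {
  L <- ncol(lo)
  n <- length(seq_chars)
  starts <- max(1L, snp_pos - L + 1L):min(n - L + 1L, snp_pos)
  best <- -Inf
  rc <- unname(REVCOMP[rev(seq_chars)])
  rc_pos <- n - snp_pos + 1L
  rc_starts <- max(1L, rc_pos - L + 1L):min(n - L + 1L, rc_pos)
  for (s in starts) {
    idx <- cbind(match(seq_chars[s:(s + L - 1L)], rownames(lo)), seq_len(L))
    best <- max(best, sum(lo[idx]))
  }
  for (s in rc_starts) {
    idx <- cbind(match(rc[s:(s + L - 1L)], rownames(lo)), seq_len(L))
    best <- max(best, sum(lo[idx]))
  }
  best
}

#' Classify a SNP's effect on a transcription factor binding motif
#'
#' Scores the reference and alternate alleles of a single-nucleotide
#' variant against a position weight matrix over every window overlapping
#' the SNP, on both strands, using uniform-background log-odds. A "hit" is
#' a window scoring at least \code{hit_fraction} of the maximum achievable
#' PWM score. A motif is \emph{interrupted} when only the reference allele
#' yields a hit, \emph{introduced} when only the alternate does.
#'
#' @param flank5,flank3 flanking sequence on each side of the SNP (each at
#'   least motif length - 1 bases).
#' @param ref,alt single-base alleles.
#' @param pwm 4 x L count or frequency matrix (rows A, C, G, T), e.g. from
#'   \code{read_jaspar}.
#' @param hit_fraction fraction of the maximum achievable score that
#'   defines a binding-site hit (default 0.8).
#' @return one of "introduced", "interrupted", "none".
#' @export
scan_motif_alteration <- function(flank5, ref, alt, flank3, pwm,
                                  hit_fraction = 0.8) {
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("only single-nucleotide variants are scanned")
  lo <- pwm_logodds(pwm)
  L <- ncol(lo)
  if (nchar(flank5) < L - 1L || nchar(flank3) < L - 1L)
    stop("flanks must each cover at least motif length - 1 bases")
  thr <- hit_fraction * sum(apply(lo, 2, max))
  mk <- function(allele) toupper(strsplit(paste0(flank5, allele, flank3),
                                          "")[[1]])
  snp_pos <- nchar(flank5) + 1L
  hit_ref <- score_windows(mk(ref), lo, snp_pos) >= thr
  hit_alt <- score_windows(mk(alt), lo, snp_pos) >= thr
  if (hit_ref && !hit_alt) "interrupted"
  else if (!hit_ref && hit_alt) "introduced"
  else "none"
}

#' Build the signal x motif alteration matrix
#'
#' Collapses per-SNP motif alteration calls over each signal's lead SNP and
#' its LD proxies (r-squared at or above \code{r2_min} within the window):
#' an entry is 1 when at least one proxy alters the motif.
#'
#' @param signals data.frame with a \code{lead_snp} column (one row per
#'   independent signal).
#' @param snp_alterations data.frame with columns snp, motif (one row per
#'   altered motif call, e.g. accumulated from
#'   \code{scan_motif_alteration}).
#' @param geno a \code{genotype_matrix} used to find LD proxies.
#' @param r2_min LD proxy threshold (default 0.8).
#' @param proxy_window_bp proxy search window around the lead (default
#'   1 Mb).
#' @return binary matrix, signals x motifs.
#' @export
motif_alteration_matrix <- function(signals, snp_alterations, geno,
                                    r2_min = 0.8, proxy_window_bp = 1e6) {
  motifs <- sort(unique(snp_alterations$motif))
  meta <- geno$snp_meta
  out <- matrix(0L, nrow(signals), length(motifs),
                dimnames = list(signals$lead_snp, motifs))
  for (i in seq_len(nrow(signals))) {
    lead <- signals$lead_snp[i]
    li <- match(lead, meta$id)
    near <- which(meta$chrom == meta$chrom[li] &
                    abs(meta$pos - meta$pos[li]) <= proxy_window_bp)
    g0 <- geno$dosage[, li]
    proxies <- meta$id[near][vapply(near, function(j) {
      gj <- geno$dosage[, j]
      stats::var(gj) > 0 && stats::var(g0) > 0 && ld_r2(g0, gj) >= r2_min
    }, logical(1))]
    hits <- unique(snp_alterations$motif[snp_alterations$snp %in% proxies])
    out[i, match(hits, motifs)] <- 1L
  }
  out
}

#' Motif enrichment among interaction eQTLs
#'
#' One-sided Fisher's exact test per motif on the 2x2 table of altered
#' status against interaction status, BH-adjusted across motifs altered in
#' at least one signal. Permuting the interaction flags gives the null
#' distribution of the number of significant motifs.
#'
#' @param alterations binary signal x motif matrix
#'   (\code{motif_alteration_matrix}).
#' @param interaction_flags logical/0-1 vector, one per signal.
#' @param n_perm permutations of the interaction flags (default 1000).
#' @param seed integer seed.
#' @param fdr FDR level defining an enriched motif (default 0.05).
#' @return list: table (motif, odds_ratio, p, q), observed_significant,
#'   expected_significant, perm_p.
#' @export
motif_enrichment <- function(alterations, interaction_flags, n_perm = 1000L,
                             seed = NULL, fdr = 0.05) {
  flags <- as.logical(interaction_flags)
  if (!any(flags) || all(flags))
    stop("both interaction classes must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  keep <- colSums(alterations) >= 1L
  if (!all(keep))
    message(sum(!keep), " motif(s) altered in zero signals excluded")
  A <- alterations[, keep, drop = FALSE]

  test_all <- function(fl) {
    apply(A, 2, function(a) {
      tab <- matrix(c(sum(a == 1 & fl), sum(a == 1 & !fl),
                      sum(a == 0 & fl), sum(a == 0 & !fl)), 2, byrow = TRUE)
      stats::fisher.test(tab, alternative = "greater")$p.value
    })
  }
  or_all <- apply(A, 2, function(a) {
    x11 <- sum(a == 1 & flags); x10 <- sum(a == 1 & !flags)
    x01 <- sum(a == 0 & flags); x00 <- sum(a == 0 & !flags)
    (x11 * x00) / max(x10 * x01, .Machine$double.xmin)
  })
  p <- test_all(flags)
  q <- stats::p.adjust(p, method = "BH")
  obs <- sum(q < fdr)
  perm_counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    pq <- stats::p.adjust(test_all(sample(flags)), method = "BH")
    perm_counts[b] <- sum(pq < fdr)
  }
  list(table = data.frame(motif = colnames(A), odds_ratio = or_all,
                          p = p, q = q, stringsAsFactors = FALSE,
                          row.names = NULL),
       observed_significant = obs,
       expected_significant = mean(perm_counts),
       perm_p = (1 + sum(perm_counts >= obs)) / (n_perm + 1))
}

#' Infer per-sample transcription factor activity from regulons
#'
#' Expression is standardized within each sample across genes; a TF's
#' activity in a sample is the t-statistic of the slope from regressing
#' the standardized expression on the regulon mode vector (+1 activated
#' targets, -1 repressed, 0 elsewhere) - a univariate linear-model activity
#' estimator (recorded in the output metadata). TFs keep only regulons
#' with the stated evidence levels and at least \code{min_size} targets
#' present in the expression matrix.
#'
#' @param expr an \code{expression_matrix}.
#' @param regulons data.frame with columns tf, target, mode (+1/-1) and
#'   optionally evidence (levels A..E).
#' @param min_size minimum regulon size after matching (default 5).
#' @param evidence_levels retained evidence codes (default A, B, C).
#' @return an \code{activity_matrix}: list with \code{scores} (TFs x
#'   samples), \code{regulons} metadata, \code{estimator}.
#' @export
regulon_activity <- function(expr, regulons, min_size = 5L,
                             evidence_levels = c("A", "B", "C")) {
  vals <- expr$values
  genes <- rownames(vals)
  if ("evidence" %in% names(regulons))
    regulons <- regulons[regulons$evidence %in% evidence_levels, , drop = FALSE]
  regulons <- regulons[regulons$target %in% genes, , drop = FALSE]
  sizes <- table(regulons$tf)
  keep_tfs <- names(sizes)[sizes >= min_size]
  if (length(keep_tfs) == 0L) stop("no regulon retains >= ", min_size, " targets")

  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) stop("all-constant sample; activity undefined")
  Z <- scale(vals)                           # per-sample standardization
  G <- nrow(vals)
  scores <- matrix(NA_real_, length(keep_tfs), ncol(vals),
                   dimnames = list(keep_tfs, colnames(vals)))
  for (tf in keep_tfs) {
    sub <- regulons[regulons$tf == tf, ]
    m <- numeric(G)
    m[match(sub$target, genes)] <- sub$mode
    mc <- m - mean(m)
    r <- as.numeric(crossprod(mc, Z)) / (sqrt(sum(mc^2)) * sqrt(G - 1))
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    scores[tf, ] <- r * sqrt((G - 2) / (1 - r^2))
  }
  structure(list(scores = scores,
                 regulons = data.frame(tf = keep_tfs,
                                       size = as.integer(sizes[keep_tfs])),
                 estimator = "univariate_lm_tstat"),
            class = "activity_matrix")
}

#' Differential TF activity between SRS groups
#'
#' Random-intercept LMM of activity on SRS1 per TF, 1-df LRT, BH across
#' TFs; optionally permutes SRS labels to report how many TFs would be
#' significant by chance.
#'
#' @param acts an \code{activity_matrix}.
#' @param samples sample data.frame with srs1 and individual_id.
#' @param n_perm SRS-label permutations (0 to skip).
#' @param seed integer seed for the permutations.
#' @param fdr FDR level (default 0.05).
#' @return list: table (tf, effect, p, q), expected_significant (NA when
#'   n_perm = 0).
#' @export
differential_activity <- function(acts, samples, n_perm = 0L, seed = NULL,
                                  fdr = 0.05) {
  if (length(unique(samples$srs1)) < 2L)
    stop("both SRS groups must be represented")
  if (!is.null(seed)) set.seed(seed)
  groups <- samples$individual_id
  one_pass <- function(srs) {
    X1 <- cbind(1, srs1 = srs)
    X0 <- matrix(1, length(srs))
    t(apply(acts$scores, 1, function(a) {
      f1 <- fit_lmm(a, X1, groups)
      f0 <- fit_lmm(a, X0, groups)
      c(effect = unname(f1$beta[["srs1"]]),
        p = lrt_nested(f1, f0, df = 1L)$p)
    }))
  }
  res <- one_pass(samples$srs1)
  tab <- data.frame(tf = rownames(acts$scores), effect = res[, "effect"],
                    p = res[, "p"],
                    q = stats::p.adjust(res[, "p"], method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  expected <- NA_real_
  if (n_perm > 0L) {
    counts <- vapply(seq_len(n_perm), function(b) {
      pr <- one_pass(sample(samples$srs1))
      sum(stats::p.adjust(pr[, "p"], method = "BH") < fdr)
    }, numeric(1))
    expected <- mean(counts)
  }
  list(table = tab, expected_significant = expected)
}

#' Spearman correlation of TF activity with cell proportions
#'
#' Uses the first available sample (earliest time point) per patient.
#'
#' @param acts an \code{activity_matrix}.
#' @param samples sample data.frame.
#' @param cell_estimates optional patient-level table of cell-type
#'   estimates (rownames or \code{sample_id} column matching samples);
#'   defaults to the measured proportions in \code{samples}.
#' @return data.frame: tf, cell_type, rho, p, q, significant.
#' @export
activity_cell_correlation <- function(acts, samples, cell_estimates = NULL) {
  ord <- order(samples$individual_id, samples$time_point)
  first <- ord[!duplicated(samples$individual_id[ord])]
  if (is.null(cell_estimates)) {
    cols <- intersect(c("neutrophils", "lymphocytes", "monocytes"),
                      names(samples))
    cell_estimates <- samples[first, cols, drop = FALSE]
  } else {
    cell_estimates <- cell_estimates[first, , drop = FALSE]
  }
  A <- acts$scores[, first, drop = FALSE]
  out <- expand.grid(tf = rownames(A), cell_type = colnames(cell_estimates),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rho <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- A[out$tf[i], ]
    y <- cell_estimates[[out$cell_type[i]]]
    ok <- !is.na(y)
    if (stats::sd(y[ok]) == 0) next  # undefined, left flagged NA
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    out$rho[i] <- unname(ct$estimate); out$p[i] <- ct$p.value
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$q) & out$q < 0.05
  out
}

#' Set enrichment of hits against a universe
#'
#' Hypergeometric (identical to one-sided Fisher) enrichment of a hit set
#' in an annotation within a stated universe, or a one-tailed binomial test
#' using the universe annotation rate as the null probability (the interval
#' -annotation convention). The enrichment effect is the hit-fraction over
#' universe-fraction ratio.
#'
#' @param hits character vector, a subset of \code{universe}.
#' @param universe character vector of all tested elements.
#' @param annotation character vector of annotated elements.
#' @param method "hypergeometric", "fisher_one_sided" or "binomial".
#' @return list: effect, overlap, p.
#' @export
set_enrichment <- function(hits, universe, annotation,
                           method = c("hypergeometric", "fisher_one_sided",
                                      "binomial")) {
  method <- match.arg(method)
  if (length(universe) == 0L) stop("empty universe")
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  universe <- unique(universe)
  hits <- unique(hits)
  ann <- intersect(unique(annotation), universe)
  x <- length(intersect(hits, ann))
  k <- length(hits); m <- length(ann); N <- length(universe)
  effect <- if (k == 0L || m == 0L) NA_real_ else (x / k) / (m / N)
  p <- switch(method,
    hypergeometric = ,
    fisher_one_sided = stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE),
    binomial = stats::pbinom(x - 1, k, m / N, lower.tail = FALSE))
  list(effect = effect, overlap = x, p = p)
}

#' Enrichment across a family of annotation sets with BH correction
#'
#' @param hits,universe,method as in \code{set_enrichment}.
#' @param annotations named list of annotation sets.
#' @return data.frame: set, effect, overlap, p, q.
#' @export
set_enrichment_family <- function(hits, universe, annotations,
                                  method = "hypergeometric") {
  rows <- lapply(names(annotations), function(nm) {
    e <- set_enrichment(hits, universe, annotations[[nm]], method)
    data.frame(set = nm, effect = e$effect, overlap = e$overlap, p = e$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
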