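## Co-expression module discovery: nuisance-PC removal and per-individual
## averaging, biweight midcorrelation, spatial quantile normalization of
## the correlation matrix against a reference expression block, soft-
## threshold unsigned adjacency, topological overlap, average-linkage tree
## cutting with a minimum module size, eigengene merging, and module-
## phenotype annotation.

#' Preprocess expression for module discovery
#'
#' Removes the top \code{n_pcs_remove} expression principal components
#' (sample-space nuisance axes) from every gene, then collapses serial
#' samples to one column per individual by averaging, so downstream
#' correlations are between-individual.
#'
#' @param expr an \code{expression_matrix}.
#' @param samples sample data.frame aligned with the expression columns.
#' @param n_pcs_remove number of leading PCs to regress out (0 disables).
#' @return genes x individuals matrix.
#' @export
preprocess_expression <- function(expr, samples, n_pcs_remove = 20L) {
  Y <- expr$values
  S <- ncol(Y)
  if (n_pcs_remove >= S) stop("n_pcs_remove must be below the sample count")
  if (!all(is.finite(Y))) stop("expression must be finite")
  if (n_pcs_remove > 0L) {
    Yc <- Y - rowMeans(Y)
    sv <- svd(Yc, nu = 0, nv = n_pcs_remove)
    V <- sv$v
    Y <- Yc - (Yc %*% V) %*% t(V)   # residuals, gene-centered
  }
  ind <- samples$individual_id
  sums <- rowsum(t(Y), ind)                 # individuals (sorted) x genes
  counts <- as.numeric(table(ind)[rownames(sums)])
  t(sums / counts)                          # genes x individuals
}

#' Biweight midcorrelation matrix
#'
#' Robust correlation: per gene, deviations from the median are weighted by
#' \eqn{w = (1-u^2)^2 1[|u|<1]} with \eqn{u = (x - \mathrm{med})/(9\,
#' \mathrm{MAD})} (MAD unscaled), and the correlation is the normalized
#' cross-product of the weighted deviations. Genes with zero MAD fall back
#' to Pearson (median-unbiased genes are flagged via the
#' \code{"pearson_fallback"} attribute); constant genes are an error.
#'
#' @param data genes x individuals matrix (at least 3 columns).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
bicor_matrix <- function(data) {
  if (ncol(data) < 3L) stop("need at least 3 columns")
  med <- apply(data, 1, stats::median)
  dev <- data - med
  mad0 <- apply(abs(dev), 1, stats::median)
  const <- apply(data, 1, stats::sd) == 0
  if (any(const)) stop("constant gene(s): ",
                       paste(utils::head(rownames(data)[const]), collapse = ", "))
  fallback <- mad0 == 0
  u <- dev / (9 * mad0)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- dev * w
  if (any(fallback)) xt[fallback, ] <- data[fallback, ] -
      rowMeans(data[fallback, , drop = FALSE])
  nrm <- sqrt(rowSums(xt^2))
  bad <- nrm == 0
  if (any(bad)) {  # all weight lost: fall back to Pearson for those genes too
    xt[bad, ] <- data[bad, , drop = FALSE] - rowMeans(data[bad, , drop = FALSE])
    nrm[bad] <- sqrt(rowSums(xt[bad, , drop = FALSE]^2))
    fallback <- fallback | bad
  }
  C <- tcrossprod(xt / nrm)
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  attr(C, "pearson_fallback") <- which(fallback)
  C
}

#' Spatial quantile normalization of a correlation matrix
#'
#' Genes are ranked by mean expression and split into \code{n_blocks}
#' contiguous groups (the last absorbs the remainder). For every group
#' pair, the off-diagonal correlations are quantile-mapped onto the
#' empirical distribution of the reference group's within-block
#' correlations, removing the mean-correlation bias while preserving rank
#' order within each block pair. The diagonal stays exactly 1 and symmetry
#' is preserved.
#'
#' @param corr symmetric correlation matrix.
#' @param mean_expr per-gene mean expression used for ranking.
#' @param n_blocks number of blocks (default 21).
#' @param ref_block index of the reference block on the expression ranking
#'   (default 18, i.e. a high-expression block).
#' @return normalized correlation matrix in the original gene order.
#' @export
spqn_normalize <- function(corr, mean_expr, n_blocks = 21L, ref_block = 18L) {
  G <- nrow(corr)
  if (length(mean_expr) != G) stop("mean_expr must match the matrix size")
  if (ref_block < 1L || ref_block > n_blocks) stop("ref_block out of range")
  if (n_blocks > G) stop("more blocks than genes")
  ord <- order(mean_expr)
  base <- floor(G / n_blocks)
  sizes <- rep(base, n_blocks)
  sizes[n_blocks] <- G - base * (n_blocks - 1L)
  grp_sorted <- rep(seq_len(n_blocks), sizes)
  grp <- integer(G); grp[ord] <- grp_sorted

  Cn <- corr
  ref_idx <- which(grp == ref_block)
  Rblock <- corr[ref_idx, ref_idx]
  ref_vals <- sort(Rblock[upper.tri(Rblock)])
  qmap <- function(v) {
    pr <- (rank(v, ties.method = "average") - 0.5) / length(v)
    stats::quantile(ref_vals, probs = pr, names = FALSE, type = 7)
  }
  for (i in seq_len(n_blocks)) {
    gi <- which(grp == i)
    for (j in i:n_blocks) {
      gj <- which(grp == j)
      if (i == j) {
        sub <- corr[gi, gi]
        ut <- upper.tri(sub)
        if (!any(ut)) next
        sub[ut] <- qmap(sub[ut])
        sub[lower.tri(sub)] <- t(sub)[lower.tri(sub)]
        diag(sub) <- 1
        Cn[gi, gi] <- sub
      } else {
        v <- as.vector(corr[gi, gj])
        Cn[gi, gj] <- matrix(qmap(v), length(gi), length(gj))
        Cn[gj, gi] <- t(Cn[gi, gj])
      }
    }
  }
  diag(Cn) <- 1
  Cn
}

scale_free_r2 <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(c(r2 = 0, slope = 0))
  lk <- log10(k)
  br <- seq(min(lk), max(lk), length.out = n_bins + 1L)
  bin <- cut(lk, br, include.lowest = TRUE)
  pk <- tapply(lk, bin, length) / length(lk)
  mk <- tapply(lk, bin, mean)
  ok <- !is.na(pk) & pk > 0
  if (sum(ok) < 3L) return(c(r2 = 0, slope = 0))
  x <- mk[ok]; y <- log10(pk[ok])
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  c(r2 = r2, slope = fit$coefficients[2])
}

#' Soft-threshold network and topological overlap
#'
#' Unsigned adjacency \eqn{a_{ij} = |\rho_{ij}|^{power}} (zero diagonal for
#' TOM purposes). With \code{power = "auto"} the smallest power in 1..20
#' whose connectivity distribution gives a scale-free log-log fit with
#' \eqn{R^2 \ge} \code{rsq_target} (and negative slope) is chosen; if none
#' qualifies the power maximizing \eqn{R^2} is used with a warning. The
#' topological overlap is
#' \eqn{TOM_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 -
#' a_{ij})} with unit diagonal.
#'
#' @param corr (normalized) correlation matrix.
#' @param power soft threshold exponent or "auto".
#' @param rsq_target scale-free fit target for the automatic choice.
#' @return list: adjacency, tom, power, fit_table (for auto).
#' @export
build_network <- function(corr, power = 4, rsq_target = 0.8) {
  absC <- abs(corr)
  diag(absC) <- 0
  fit_table <- NULL
  if (identical(power, "auto")) {
    fit_table <- t(vapply(1:20, function(pw)
      scale_free_r2(rowSums(absC^pw)), c(r2 = 0, slope = 0)))
    ok <- fit_table[, "r2"] >= rsq_target & fit_table[, "slope"] < 0
    if (any(ok)) {
      power <- which(ok)[1]
    } else {
      power <- which.max(fit_table[, "r2"])
      warning("no power reaches scale-free R^2 ", rsq_target,
              "; using power ", power)
    }
  }
  A <- absC^power
  k <- rowSums(A)
  L <- A %*% A
  kmin <- outer(k, k, pmin)
  TOM <- (L + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(corr)
  list(adjacency = A, tom = TOM, power = power, fit_table = fit_table)
}

#' Module eigengenes: first principal component per module
#'
#' Member genes are standardized; the eigengene is the first right singular
#' vector of the member matrix (unit-norm sample scores), sign-aligned so
#' its correlation with the module's mean standardized profile is
#' non-negative. Constant member genes are dropped before the SVD.
#'
#' @param data genes x samples (or individuals) matrix.
#' @param labels integer module labels named by gene (0 = unassigned).
#' @return list: eigengenes (modules x samples, rows "M<label>"),
#'   var_explained (fraction of member variance captured).
#' @export
module_eigengenes <- function(data, labels) {
  mods <- sort(unique(labels[labels > 0]))
  E <- matrix(NA_real_, length(mods), ncol(data),
              dimnames = list(paste0("M", mods), colnames(data)))
  ve <- stats::setNames(numeric(length(mods)), paste0("M", mods))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    X <- data[genes, , drop = FALSE]
    sds <- apply(X, 1, stats::sd)
    X <- X[sds > 0, , drop = FALSE]
    if (nrow(X) < 2L) stop("module ", mods[i], " has fewer than 2 usable genes")
    Xs <- t(scale(t(X)))
    sv <- svd(Xs, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (stats::cor(v, colMeans(Xs)) < 0) v <- -v
    E[i, ] <- v
    ve[i] <- sv$d[1]^2 / sum(svd(Xs, nu = 0, nv = 0)$d^2)
  }
  list(eigengenes = E, var_explained = ve)
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on 1 - TOM, cut at
#' \code{cut_fraction} of the maximum merge height (a static variant of
#' dynamic tree cutting: tight co-expression branches join far below the
#' root, while unclustered genes chain in just beneath it, so a cut just
#' under the root detaches them); clusters below \code{min_size} stay
#' unassigned (label 0). Modules whose eigengenes are closer than \code{merge_height}
#' (1 - correlation) are merged iteratively until stable, and labels are
#' renumbered by decreasing size.
#'
#' @param tom topological overlap matrix (genes named).
#' @param data genes x individuals matrix used for eigengenes.
#' @param min_size minimum module size (default 10).
#' @param cut_fraction fraction of the maximum merge height at which the
#'   tree is cut (default 0.98).
#' @param merge_height eigengene dissimilarity below which modules merge.
#' @return a \code{module_set}: labels, eigengenes, module_info, params.
#' @export
detect_modules <- function(tom, data, min_size = 10L, cut_fraction = 0.98,
                           merge_height = 0.1) {
  genes <- rownames(tom)
  if (is.null(genes)) genes <- rownames(data)
  if (nrow(tom) < min_size) {
    labels <- stats::setNames(rep(0L, nrow(tom)), genes)
    return(structure(list(labels = labels,
                          eigengenes = NULL, module_info = NULL,
                          params = list(min_size = min_size)),
                     class = "module_set"))
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cuth <- cut_fraction * max(h$height)
  raw <- stats::cutree(h, h = cuth)
  tab <- table(raw)
  small <- as.integer(names(tab)[tab < min_size])
  labels <- ifelse(raw %in% small, 0L, raw)
  names(labels) <- genes
  labels <- renumber_by_size(labels)
  if (!any(labels > 0))
    return(structure(list(labels = labels, eigengenes = NULL,
                          module_info = NULL,
                          params = list(min_size = min_size)),
                     class = "module_set"))

  repeat {
    eg <- module_eigengenes(data, labels)
    E <- eg$eigengenes
    if (nrow(E) < 2L) break
    cc <- stats::cor(t(E))
    diss <- 1 - cc
    diag(diss) <- Inf
    mn <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    if (diss[mn[1], mn[2]] >= merge_height) break
    ids <- as.integer(sub("^M", "", rownames(E)[mn]))
    keep_id <- ids[which.max(c(sum(labels == ids[1]), sum(labels == ids[2])))]
    drop_id <- setdiff(ids, keep_id)[1]
    labels[labels == drop_id] <- keep_id
    labels <- renumber_by_size(labels)
  }
  eg <- module_eigengenes(data, labels)
  sizes <- table(labels[labels > 0])
  info <- data.frame(module = rownames(eg$eigengenes),
                     size = as.integer(sizes[sub("^M", "", rownames(eg$eigengenes))]),
                     var_explained = unname(eg$var_explained),
                     stringsAsFactors = FALSE)
  structure(list(labels = labels, eigengenes = eg$eigengenes,
                 module_info = info,
                 params = list(min_size = min_size,
                               cut_fraction = cut_fraction,
                               merge_height = merge_height)),
            class = "module_set")
}

renumber_by_size <- function(labels) {
  pos <- labels[labels > 0]
  if (!length(pos)) return(labels)
  sizes <- sort(table(pos), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes), names(sizes))
  out <- labels
  out[labels > 0] <- remap[as.character(pos)]
  out
}

#' @export
print.module_set <- function(x, ...) {
  nm <- sum(x$labels == 0)
  cat(sprintf("module_set: %d modules, %d genes (%d unassigned)\n",
              length(unique(x$labels[x$labels > 0])), length(x$labels), nm))
  if (!is.null(x$module_info)) print(utils::head(x$module_info, 10))
  invisible(x)
}

#' Associate module eigengenes with phenotypes, survival and marker sets
#'
#' Phenotypes (SRS1, diagnosis, time point, transformed cell proportions)
#' are tested per module with a random-intercept LMM; 28-day survival with
#' a Cox proportional hazards model (Efron ties) on each patient's
#' last-time-point eigengene value; cell-marker sets with hypergeometric
#' enrichment against the full gene universe. BH correction is applied
#' within each family.
#'
#' @param eigengenes modules x samples matrix (sample-level scores).
#' @param samples sample data.frame.
#' @param labels module labels (for marker enrichment); optional.
#' @param marker_sets named list of marker gene sets (e.g. from
#'   \code{read_gmt}); optional.
#' @param phenotypes character vector of sample columns to test.
#' @return list: phenotype (data.frame), survival (data.frame or NULL),
#'   markers (data.frame or NULL).
#' @export
module_associations <- function(eigengenes, samples, labels = NULL,
                                marker_sets = NULL,
                                phenotypes = NULL) {
  if (is.null(phenotypes)) {
    phenotypes <- intersect(c("srs1", "diagnosis", "time_point",
                              "int_neutrophils", "int_lymphocytes",
                              "int_monocytes"), names(samples))
  }
  groups <- samples$individual_id
  rows <- list()
  for (ph in phenotypes) {
    v <- if (ph == "diagnosis") as.numeric(samples[[ph]] == "FP")
         else as.numeric(samples[[ph]])
    if (anyNA(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    X1 <- cbind(1, pheno = v); X0 <- matrix(1, length(v))
    for (m in rownames(eigengenes)) {
      f1 <- fit_lmm(eigengenes[m, ], X1, groups)
      f0 <- fit_lmm(eigengenes[m, ], X0, groups)
      rows[[length(rows) + 1L]] <-
        data.frame(module = m, phenotype = ph,
                   effect = unname(f1$beta[["pheno"]]),
                   p = lrt_nested(f1, f0, df = 1L)$p,
                   stringsAsFactors = FALSE)
    }
  }
  pheno_tab <- do.call(rbind, rows)
  pheno_tab$q <- stats::ave(pheno_tab$p, pheno_tab$phenotype,
                            FUN = function(p) stats::p.adjust(p, "BH"))

  surv_tab <- NULL
  if (all(c("surv_time", "surv_event") %in% names(samples))) {
    ord <- order(samples$individual_id, samples$time_point)
    ## last time point per patient
    last <- vapply(split(ord, samples$individual_id[ord]),
                   function(ix) ix[length(ix)], integer(1))
    sdat <- samples[last, ]
    if (sum(sdat$surv_event) == 0) {
      message("no survival events; Cox stage skipped")
    } else {
      srows <- lapply(rownames(eigengenes), function(m) {
        d <- data.frame(time = sdat$surv_time, event = sdat$surv_event,
                        eig = eigengenes[m, last])
        cf <- summary(survival::coxph(
          survival::Surv(time, event) ~ eig, data = d))$coefficients
        data.frame(module = m, loghr = cf[1, "coef"],
                   p = cf[1, "Pr(>|z|)"], stringsAsFactors = FALSE)
      })
      surv_tab <- do.call(rbind, srows)
      surv_tab$q <- stats::p.adjust(surv_tab$p, "BH")
    }
  }

  marker_tab <- NULL
  if (!is.null(marker_sets) && !is.null(labels)) {
    universe <- names(labels)
    mrows <- list()
    for (m in rownames(eigengenes)) {
      id <- as.integer(sub("^M", "", m))
      members <- names(labels)[labels == id]
      fam <- set_enrichment_family(members, universe, marker_sets,
                                   method = "hypergeometric")
      fam$module <- m
      mrows[[m]] <- fam
    }
    marker_tab <- do.call(rbind, mrows)
    marker_tab$q <- stats::p.adjust(marker_tab$p, "BH")
    rownames(marker_tab) <- NULL
  }
  list(phenotype = pheno_tab, survival = surv_tab, markers = marker_tab)
}
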