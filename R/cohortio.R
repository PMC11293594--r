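## Loading and coding of genotypes and expression, and assembly of the
## fixed-covariate design shared by all association stages.

#' Read genotypes from VCF and code minor-allele dosage
#'
#' Keeps biallelic SNVs with cohort MAF at or above \code{maf_min} (the
#' conventional 1\% floor by default). Dosage is re-oriented to count the
#' minor allele *in this cohort*: when the ALT allele frequency exceeds 0.5
#' the coding is flipped so 2 always means homozygous for the rarer allele.
#'
#' @param vcf path to a VCF file with a diploid GT field.
#' @param maf_min minimum minor allele frequency (sites below are dropped).
#' @return a \code{genotype_matrix} (dosage individuals x SNPs, snp_meta,
#'   individual_ids).
#' @export
read_genotypes <- function(vcf, maf_min = 0.01) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0L) stop("no records in ", vcf)
  fmt <- v@gt[, 1]
  if (!all(grepl("GT", fmt))) stop("VCF records lack a GT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt)) stop("missing genotypes are not supported; filter upstream")

  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "." &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  if (nrow(fix) == 0L) stop("all records removed by the biallelic filter")

  count_alt <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(a, function(al) sum(al == "1"), integer(1))
  }
  dos <- t(apply(gt, 1, count_alt))          # SNPs x individuals
  if (anyNA(dos)) stop("unparseable GT entries")
  af <- rowMeans(dos) / 2
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  flip <- af > 0.5
  if (any(flip)) {
    dos[flip, ] <- 2L - dos[flip, , drop = FALSE]
    tmp <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmp
    af[flip] <- 1 - af[flip]
  }
  keep <- af >= maf_min & af > 0
  if (!any(keep)) stop("all records removed by the MAF filter")
  dos <- dos[keep, , drop = FALSE]

  snp_meta <- data.frame(id = fix[keep, "ID"], chrom = fix[keep, "CHROM"],
                         pos = as.integer(fix[keep, "POS"]),
                         ref = ref[keep], alt = alt[keep], maf = af[keep],
                         stringsAsFactors = FALSE)
  noid <- snp_meta$id == "." | is.na(snp_meta$id)
  snp_meta$id[noid] <- paste0(snp_meta$chrom[noid], ":", snp_meta$pos[noid])
  D <- t(dos)
  dimnames(D) <- list(colnames(gt), snp_meta$id)
  structure(list(dosage = D, snp_meta = snp_meta,
                 individual_ids = colnames(gt)),
            class = "genotype_matrix")
}

#' Squared dosage correlation (LD r-squared) between two SNPs
#'
#' @param g1,g2 dosage vectors of equal length (at least 3).
#' @return squared Pearson correlation in [0, 1]; symmetric and invariant to
#'   allele flips.
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2) || length(g1) < 3L)
    stop("dosage vectors must have equal length >= 3")
  if (stats::var(g1) == 0 || stats::var(g2) == 0)
    stop("LD undefined for a monomorphic dosage vector")
  stats::cor(g1, g2)^2
}

#' Augment the sample table with transformed cell proportions and hidden
#' expression factors
#'
#' Measured cell proportions are median-imputed (cohort median, before any
#' transformation) and then rank-based inverse-normal transformed into
#' \code{int_*} columns. Hidden factors \code{HF1..HFk} are the top
#' principal components of the expression matrix after regressing out the
#' held-out known covariates gene-by-gene; they are deterministic nuisance
#' covariates standing in for a Bayesian factor model, standardized to unit
#' variance, mutually orthogonal and orthogonal in-sample to the held-out
#' covariates.
#'
#' @param expr an \code{expression_matrix} (genes x samples).
#' @param samples sample data.frame; rows match the columns of \code{expr}.
#' @param n_hidden number of hidden factors to retain.
#' @param holdout character vector of column names held out of the factor
#'   computation (regressed out first). Defaults to the genotype PCs, SRS1,
#'   diagnosis and the transformed cell proportions.
#' @return the augmented sample data.frame.
#' @export
build_covariates <- function(expr, samples, n_hidden = 20,
                             holdout = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  S <- nrow(samples)
  if (ncol(expr$values) != S) stop("samples do not match expression columns")
  if (n_hidden >= S) stop("n_hidden must be below the number of samples")

  for (cc in c("neutrophils", "lymphocytes", "monocytes")) {
    if (cc %in% names(samples)) {
      v <- samples[[cc]]
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      samples[[paste0("int_", cc)]] <- rank_int(v)
    }
  }

  if (is.null(holdout)) {
    nm <- names(samples)
    holdout <- c(grep("^PC[0-9]+$", nm, value = TRUE),
                 grep("^int_", nm, value = TRUE),
                 intersect(c("srs1", "diagnosis"), nm))
  }
  missing_h <- setdiff(holdout, names(samples))
  if (length(missing_h))
    stop("holdout covariate(s) absent from samples: ",
         paste(missing_h, collapse = ", "))
  H <- cbind(1, standard_covariates(samples[, holdout, drop = FALSE]))
  if (ncol(H) == 1L && length(holdout))  # holdout columns given explicitly
    H <- cbind(1, as.matrix(data.frame(lapply(samples[holdout], as.numeric))))

  if (n_hidden > 0) {
    Y <- expr$values
    ## residualize every gene on the holdout design in one projection
    qrh <- qr(H)
    R <- t(Y) - qr.fitted(qrh, t(Y))     # samples x genes residuals
    sv <- svd(R, nu = n_hidden, nv = 0)
    hf <- sv$u[, seq_len(n_hidden), drop = FALSE]
    hf <- scale(hf)                      # unit variance, mean zero
    for (k in seq_len(n_hidden)) samples[[sprintf("HF%d", k)]] <- hf[, k]
  }
  samples
}
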