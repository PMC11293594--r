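#' Rank-based inverse normal transform
#'
#' Maps a numeric vector onto normal quantiles of its ranks using the Blom
#' offset: \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}. Ties receive the average
#' rank. Missing values propagate as \code{NA} (impute before calling if a
#' complete vector is required).
#'
#' @param x numeric vector.
#' @param offset rank offset; 3/8 (Blom) by default.
#' @return numeric vector of the same length, an exact permutation of the
#'   normal quantiles when there are no ties.
#' @export
rank_int <- function(x, offset = 3/8) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0L) return(out)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

## log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Deterministic column pruning: keep the leftmost maximal independent set.
## Returns indices of kept columns.
independent_columns <- function(X, tol = 1e-9) {
  p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank == p) return(seq_len(p))
  keep <- integer(0)
  for (j in seq_len(p)) {
    cand <- c(keep, j)
    if (qr(X[, cand, drop = FALSE])$rank == length(cand)) keep <- cand
  }
  keep
}

#' Read gene sets in GMT format
#'
#' @param path path to a GMT file (one set per line: name, description,
#'   then member genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Parses the plain-text JASPAR exchange format: a header line starting with
#' \code{>} (identifier and optional name), followed by four rows for
#' A, C, G, T. Rows may be bare numbers or of the bracketed form
#' \code{A [ 4 19 0 ... ]}.
#'
#' @param path path to a JASPAR-format file containing one or more matrices.
#' @return named list of 4 x L numeric matrices with rownames A, C, G, T
#'   (counts or frequencies as given in the file).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no JASPAR records (no '>' header) in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    name <- strsplit(header, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) < 4L) stop("JASPAR record ", name, " has fewer than 4 rows")
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) stop("ragged matrix in JASPAR record ", name)
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[name]] <- m
  }
  out
}

#' Read a BED-like gene annotation table
#'
#' Reads a headerless tab-separated table with columns chrom, start, end,
#' name (0-based half-open intervals, BED convention) and returns 1-based
#' TSS points: the interval start for \code{strand == "+"} or when no strand
#' column is present; the interval end when \code{strand == "-"}.
#'
#' @param path path to the annotation file.
#' @return data.frame with columns \code{id}, \code{chrom}, \code{tss}.
#' @export
read_gene_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("gene annotation needs at least 4 columns (chrom, start, end, name)")
  strand <- if (ncol(tab) >= 6L) tab[[6]] else rep("+", nrow(tab))
  tss <- ifelse(strand == "-", tab[[3]], tab[[2]] + 1L)
  data.frame(id = as.character(tab[[4]]), chrom = as.character(tab[[1]]),
             tss = as.integer(tss), stringsAsFactors = FALSE)
}

## shared assembly of the standard fixed-covariate matrix:
## genotype PCs (PC*), hidden expression factors (HF*), inverse-normal cell
## proportions (int_*), SRS1 and diagnosis indicators. Used by the eQTL,
## interaction and modQTL stages.
standard_covariates <- function(samples, exclude = character(0)) {
  nm <- names(samples)
  pick <- c(grep("^PC[0-9]+$", nm, value = TRUE),
            grep("^HF[0-9]+$", nm, value = TRUE),
            grep("^int_", nm, value = TRUE))
  cols <- list()
  for (v in pick) if (!(v %in% exclude)) cols[[v]] <- as.numeric(samples[[v]])
  if ("srs1" %in% nm && !("srs1" %in% exclude))
    cols[["srs1"]] <- as.numeric(samples$srs1)
  if ("diagnosis" %in% nm && !("diagnosis" %in% exclude))
    cols[["diagnosis"]] <- as.numeric(samples$diagnosis == "FP")
  if (length(cols) == 0L) return(matrix(numeric(0), nrow = nrow(samples), ncol = 0))
  do.call(cbind, cols)
}

## Bonferroni threshold for the module QTL scan.
#' Genome-wide Bonferroni threshold for module QTL testing
#'
#' @param n_snps number of candidate SNPs tested.
#' @param n_modules number of module eigengenes tested.
#' @param alpha family-wise error rate (default 0.05).
#' @return the per-test significance threshold \code{alpha / (n_snps * n_modules)}.
#' @export
modqtl_threshold <- function(n_snps, n_modules, alpha = 0.05) {
  stopifnot(n_snps >= 1, n_modules >= 1, alpha > 0, alpha < 1)
  alpha / (n_snps * n_modules)
}
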