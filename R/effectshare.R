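## Empirical-Bayes comparison of effect sizes measured in two conditions
## (e.g. a sepsis cohort vs a healthy reference): a mixture of bivariate
## normals over canonical sharing patterns is fitted by EM to "random"
## test pairs, then posterior effects and local false sign rates on the
## "strong" pairs drive categorization into shared / magnified / dampened /
## opposite.

canonical_components <- function() {
  het <- function(rho) matrix(c(1, rho, rho, 1), 2)
  list(equal = matrix(c(1, 1, 1, 1), 2),
       independent = diag(2),
       cond1_only = matrix(c(1, 0, 0, 0), 2),
       cond2_only = matrix(c(0, 0, 0, 1), 2),
       het_0.25 = het(0.25), het_0.5 = het(0.5), het_0.75 = het(0.75))
}

## log N(x; 0, U + diag(se^2)) for an n x 2 matrix of estimates, vectorized
logdens2 <- function(betas, ses, U) {
  a <- U[1, 1] + ses[, 1]^2
  b <- U[2, 2] + ses[, 2]^2
  cc <- U[1, 2]
  det <- a * b - cc^2
  q <- (b * betas[, 1]^2 - 2 * cc * betas[, 1] * betas[, 2] +
          a * betas[, 2]^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

default_omega_grid <- function(betas, ses) {
  lo <- min(ses[ses > 0]) / 10
  hi <- 2 * max(abs(betas), lo)
  k <- ceiling(2 * log2(hi / lo)) + 1L
  (lo * sqrt(2)^(seq_len(k) - 1L))^2
}

#' Fit the effect-sharing mixture model on random test pairs
#'
#' Maximizes \eqn{\sum_j \log \sum_{k,\omega} \pi_{k\omega}
#' N(\hat b_j; 0, \omega U_k + V_j)} over the mixture weights by EM, with
#' \eqn{V_j = \mathrm{diag}(se_j^2)}. Components are the point-mass null,
#' the canonical sharing patterns (equal effects, condition-1-only,
#' condition-2-only) scaled over an automatic geometric grid of
#' \eqn{\omega}, and optionally a rank-1 data-driven pattern estimated from
#' the strong pairs by SVD.
#'
#' @param random_betas n x 2 matrix of effect estimates for random pairs.
#' @param random_ses n x 2 matrix of standard errors (positive).
#' @param omegas optional scale grid (variances); automatic if NULL.
#' @param strong_betas optional strong-set estimates used only to add a
#'   rank-1 data-driven covariance component.
#' @param max_iter,tol EM controls (default 500 iterations, relative
#'   log-likelihood change below 1e-6).
#' @param null_bias Dirichlet-style pseudo-count favouring the point-mass
#'   null (default 10, the usual null-biased prior), so that weight not
#'   demanded by the data lands on the null rather than spreading over
#'   indistinguishable near-null scales.
#' @return a \code{sharing_model}: components (list of 2x2 matrices),
#'   weights, loglik trace, converged flag.
#' @export
fit_sharing_model <- function(random_betas, random_ses, omegas = NULL,
                              strong_betas = NULL, max_iter = 500L,
                              tol = 1e-6, null_bias = 10) {
  random_betas <- as.matrix(random_betas); random_ses <- as.matrix(random_ses)
  n <- nrow(random_betas)
  if (n < 100L) stop("need at least 100 random pairs to fit the model")
  if (any(random_ses <= 0)) stop("standard errors must be positive")
  if (is.null(omegas)) omegas <- default_omega_grid(random_betas, random_ses)
  if (length(omegas) == 0L || any(omegas <= 0)) stop("degenerate omega grid")

  Us <- list(null = matrix(0, 2, 2))
  base <- canonical_components()
  if (!is.null(strong_betas)) {
    v <- svd(scale(as.matrix(strong_betas), scale = FALSE))$v[, 1]
    base$data_driven <- tcrossprod(v)
  }
  for (nm in names(base))
    for (w in seq_along(omegas))
      Us[[sprintf("%s_w%d", nm, w)]] <- omegas[w] * base[[nm]]

  C <- length(Us)
  L <- vapply(Us, function(U) logdens2(random_betas, random_ses, U),
              numeric(n))
  pi_c <- rep(1 / C, C)
  prior_extra <- c(null_bias - 1, rep(0, C - 1L))  # null is component 1
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- sweep(L, 2, log(pi_c), "+")
    m <- apply(A, 1, max)
    lse <- m + log(rowSums(exp(A - m)))
    ## penalized (MAP) objective: monotone under the Dirichlet-biased M-step
    ll <- sum(lse) + sum(prior_extra * log(pmax(pi_c, 1e-300)))
    R <- exp(A - lse)
    pi_c <- (colSums(R) + prior_extra) / (n + sum(prior_extra))
    ll_trace <- c(ll_trace, ll)
    if (it > 1L &&
        abs(ll - ll_trace[it - 1L]) < tol * abs(ll_trace[it - 1L])) {
      converged <- TRUE
      break
    }
  }
  structure(list(components = Us, weights = stats::setNames(pi_c, names(Us)),
                 omegas = omegas, loglik = ll_trace, converged = converged),
            class = "sharing_model")
}

#' @export
print.sharing_model <- function(x, ...) {
  cat(sprintf("sharing_model: %d components, loglik %.2f (%s)\n",
              length(x$components), utils::tail(x$loglik, 1),
              if (x$converged) "converged" else "max iterations"))
  top <- sort(x$weights, decreasing = TRUE)[1:min(5, length(x$weights))]
  print(round(top, 4))
  invisible(x)
}

## mixture posterior summaries for one set of pairs under a fitted model
sharing_posterior <- function(betas, ses, model) {
  betas <- as.matrix(betas); ses <- as.matrix(ses)
  n <- nrow(betas)
  C <- length(model$components)
  L <- vapply(model$components, function(U) logdens2(betas, ses, U),
              numeric(n))
  if (n == 1L) L <- matrix(L, nrow = 1L)
  A <- sweep(L, 2, log(model$weights), "+")
  m <- apply(A, 1, max)
  W <- exp(A - (m + log(rowSums(exp(A - m)))))   # n x C responsibilities

  pm <- matrix(0, n, 2)
  p_neg <- matrix(0, n, 2); p_pos <- matrix(0, n, 2); p_zero <- matrix(0, n, 2)
  for (ci in seq_len(C)) {
    U <- model$components[[ci]]
    a <- U[1, 1] + ses[, 1]^2; b <- U[2, 2] + ses[, 2]^2; cc <- U[1, 2]
    det <- a * b - cc^2
    M11 <- (U[1, 1] * b - U[1, 2] * cc) / det
    M12 <- (-U[1, 1] * cc + U[1, 2] * a) / det
    M21 <- (U[1, 2] * b - U[2, 2] * cc) / det
    M22 <- (-U[1, 2] * cc + U[2, 2] * a) / det
    mu1 <- M11 * betas[, 1] + M12 * betas[, 2]
    mu2 <- M21 * betas[, 1] + M22 * betas[, 2]
    v1 <- pmax(U[1, 1] - (M11 * U[1, 1] + M12 * U[1, 2]), 0)
    v2 <- pmax(U[2, 2] - (M21 * U[1, 2] + M22 * U[2, 2]), 0)
    w <- W[, ci]
    pm[, 1] <- pm[, 1] + w * mu1
    pm[, 2] <- pm[, 2] + w * mu2
    for (d in 1:2) {
      Udd <- U[d, d]
      mu <- if (d == 1) mu1 else mu2
      v <- if (d == 1) v1 else v2
      if (Udd == 0) {
        p_zero[, d] <- p_zero[, d] + w
      } else {
        s <- sqrt(pmax(v, 1e-300))
        p_neg[, d] <- p_neg[, d] + w * stats::pnorm(0, mu, s)
        p_pos[, d] <- p_pos[, d] + w * stats::pnorm(0, mu, s,
                                                    lower.tail = FALSE)
      }
    }
  }
  lfsr <- pmin(p_neg, p_pos) + p_zero
  list(post_mean = pm, lfsr = lfsr)
}

#' Categorize strong pairs by cross-condition effect sharing
#'
#' Posterior means and local false sign rates for the strong pairs are
#' computed under the fitted mixture. Pairs significant in condition 1
#' (lfsr below \code{lfsr_cut}) are labelled: \emph{opposite} when
#' significant in both conditions with opposite posterior signs;
#' \emph{shared} when same-signed with magnitudes within the sharing band;
#' \emph{magnified} when the condition-1 magnitude exceeds the band or the
#' pair is significant only in condition 1; \emph{dampened} otherwise.
#' The default band is the ratio reading of "within a factor of 0.5":
#' \eqn{|b_1|/|b_2| \in [1/\mathrm{factor}, \mathrm{factor}]} with
#' factor = 2; \code{rule = "difference"} selects the alternative reading
#' \eqn{|b_1 - b_2| \le 0.5 |b_2|}.
#'
#' @param strong_betas,strong_ses n x 2 matrices for the strong pairs.
#' @param model a fitted \code{sharing_model}.
#' @param lfsr_cut significance cut on the local false sign rate.
#' @param factor sharing band factor (ratio rule).
#' @param rule "ratio" (default) or "difference".
#' @param labels condition labels used in category names.
#' @return data.frame: post_mean1, post_mean2, lfsr1, lfsr2, category.
#' @export
categorize_sharing <- function(strong_betas, strong_ses, model,
                               lfsr_cut = 0.05, factor = 2,
                               rule = c("ratio", "difference"),
                               labels = c("sepsis_magnified",
                                          "sepsis_dampened")) {
  rule <- match.arg(rule)
  post <- sharing_posterior(strong_betas, strong_ses, model)
  m1 <- post$post_mean[, 1]; m2 <- post$post_mean[, 2]
  l1 <- post$lfsr[, 1]; l2 <- post$lfsr[, 2]
  n <- length(m1)
  cat_out <- rep("not_significant", n)
  sig1 <- l1 < lfsr_cut
  sig2 <- l2 < lfsr_cut
  for (j in which(sig1)) {
    if (sig2[j] && sign(m1[j]) != sign(m2[j]) && m2[j] != 0) {
      cat_out[j] <- "opposite"
    } else if (!sig2[j]) {
      cat_out[j] <- labels[1]
    } else {
      in_band <- if (rule == "ratio") {
        r <- abs(m1[j]) / abs(m2[j])
        r >= 1 / factor && r <= factor
      } else {
        abs(m1[j] - m2[j]) <= 0.5 * abs(m2[j])
      }
      bigger1 <- abs(m1[j]) > abs(m2[j])
      cat_out[j] <- if (in_band) "shared" else if (bigger1) labels[1] else labels[2]
    }
  }
  data.frame(post_mean1 = m1, post_mean2 = m2, lfsr1 = l1, lfsr2 = l2,
             category = cat_out, stringsAsFactors = FALSE)
}
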