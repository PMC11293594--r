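#' Random-intercept linear mixed model fit by maximum likelihood
#'
#' Fits \eqn{y = X\beta + u_{g} + \epsilon} with a single random intercept
#' per group (individual) by maximum likelihood. The likelihood is profiled
#' over the variance ratio \eqn{\lambda = \sigma^2_u / \sigma^2_e}: for a
#' candidate \eqn{\lambda} the model reduces, after the standard group-mean
#' shrinkage transform, to ordinary least squares, so only a one-dimensional
#' optimization over \eqn{\log\lambda} is required. The boundary
#' \eqn{\lambda = 0} (no between-individual variance) is admitted, where the
#' fit equals OLS exactly. ML rather than REML is used throughout so that
#' likelihood-ratio tests between nested fixed-effect specifications are
#' valid.
#'
#' Exactly collinear columns of \code{X} are dropped deterministically
#' (leftmost kept) with a warning; dropped coefficients are absent from the
#' output rather than set to \code{NA}.
#'
#' @param y numeric response vector.
#' @param X fixed-effects design matrix (including the intercept column if
#'   one is wanted); rows match \code{y}.
#' @param groups grouping labels (individual identifiers), one per row.
#' @param lambda_max upper bound of the variance-ratio search grid.
#' @return an object of class \code{lmm_fit} with components \code{beta},
#'   \code{se}, \code{sigma2_u}, \code{sigma2_e}, \code{lambda},
#'   \code{loglik_ml}, \code{converged}, \code{n_obs}, \code{n_groups},
#'   \code{vcov}, \code{dropped}.
#' @export
fit_lmm <- function(y, X, groups, lambda_max = 1e4) {
  y <- as.numeric(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || length(groups) != n)
    stop("rows of X and groups must match y")
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  dropped <- character(0)
  keep <- independent_columns(X)
  if (length(keep) < ncol(X)) {
    dropped <- colnames(X)[-keep]
    warning("dropping collinear column(s): ", paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  if (p == 0L) stop("empty design after deduplication")
  if (n <= p) stop("more coefficients than observations")

  gi <- match(groups, unique(groups))
  ni <- tabulate(gi)
  n_groups <- length(ni)

  ybar <- rowsum(y, gi) / ni
  Xbar <- rowsum(X, gi) / ni

  ## profile log-likelihood at variance ratio lambda
  prof <- function(lam) {
    th <- 1 - 1 / sqrt(1 + ni * lam)
    ys <- y - th[gi] * ybar[gi]
    Xs <- X - th[gi] * Xbar[gi, , drop = FALSE]
    fit <- stats::.lm.fit(Xs, ys)
    rss <- sum(fit$residuals^2)
    if (rss < 1e-300) rss <- 1e-300
    -0.5 * (n * log(2 * pi) + n * log(rss / n) + n + sum(log(1 + ni * lam)))
  }

  ll0 <- prof(0)
  lambda <- 0
  ll <- ll0
  converged <- TRUE
  if (any(ni > 1L)) {
    opt <- stats::optimize(function(u) prof(exp(u)),
                           interval = c(log(1e-8), log(lambda_max)),
                           maximum = TRUE, tol = 1e-6)
    if (opt$objective > ll0 + 1e-10) {
      lambda <- exp(opt$maximum)
      ll <- opt$objective
      ## flag hitting the upper bound of the search interval
      if (opt$maximum > log(lambda_max) - 1e-3) converged <- FALSE
    }
  }

  th <- 1 - 1 / sqrt(1 + ni * lambda)
  ys <- y - th[gi] * ybar[gi]
  Xs <- X - th[gi] * Xbar[gi, , drop = FALSE]
  fit <- stats::.lm.fit(Xs, ys)
  beta <- fit$coefficients
  names(beta) <- colnames(X)
  rss <- sum(fit$residuals^2)
  sigma2_e <- rss / n
  degenerate <- FALSE
  if (sigma2_e < 1e-12) {
    sigma2_e <- 1e-12
    degenerate <- TRUE
    converged <- FALSE
  }
  XtX <- crossprod(Xs)
  V <- sigma2_e * chol2inv(chol(XtX))
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))

  structure(list(beta = beta, se = se,
                 sigma2_u = lambda * sigma2_e, sigma2_e = sigma2_e,
                 lambda = lambda, loglik_ml = ll,
                 converged = converged, degenerate = degenerate,
                 n_obs = n, n_groups = n_groups,
                 vcov = V, dropped = dropped,
                 fitted = as.numeric(X %*% beta)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept linear mixed model (ML)\n")
  cat(sprintf("  %d observations, %d individuals\n", x$n_obs, x$n_groups))
  cat(sprintf("  sigma2_u = %.4g, sigma2_e = %.4g, logLik = %.4f\n",
              x$sigma2_u, x$sigma2_e, x$loglik_ml))
  print(round(cbind(beta = x$beta, se = x$se), 4))
  if (!x$converged) cat("  [fit flagged: boundary or degenerate]\n")
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$beta

#' @export
vcov.lmm_fit <- function(object, ...) object$vcov

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik_ml, df = length(object$beta) + 2L,
            nobs = object$n_obs, class = "logLik")
}

#' @export
summary.lmm_fit <- function(object, ...) {
  z <- object$beta / object$se
  tab <- cbind(Estimate = object$beta, `Std. Error` = object$se, z = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, fit = object), class = "summary.lmm_fit")
}

#' @export
print.summary.lmm_fit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' @export
residuals.lmm_fit <- function(object, ...) {
  stop("marginal residuals require the original y; keep y - fitted(object)")
}

#' @export
fitted.lmm_fit <- function(object, ...) object$fitted

#' Likelihood-ratio test between nested mixed-model fits
#'
#' @param full \code{lmm_fit} for the larger model.
#' @param null \code{lmm_fit} for the smaller model (same y and groups).
#' @param df degrees of freedom; defaults to the difference in the number of
#'   estimated fixed-effect coefficients.
#' @return list with \code{statistic} (2 x log-likelihood difference, clipped
#'   at 0) and \code{p} (upper chi-squared tail).
#' @export
lrt_nested <- function(full, null, df = NULL) {
  stopifnot(inherits(full, "lmm_fit"), inherits(null, "lmm_fit"))
  if (full$n_obs != null$n_obs || full$n_groups != null$n_groups)
    stop("full and null fits are not on the same data")
  if (is.null(df)) df <- length(full$beta) - length(null$beta)
  if (df < 1L) stop("null model is not nested in full (df < 1)")
  stat <- max(0, 2 * (full$loglik_ml - null$loglik_ml))
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}
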