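# Fixed-effect regression models for the first-spring analyses, and AICc
# model ranking. Log-likelihoods are full maximum likelihood (the Gaussian
# fit reports the ML, not REML, likelihood) so that AICc values are
# comparable across candidate models; parameter counts include scale
# parameters (residual variance, count dispersion) where the family has one.

#' Standardize a covariate to z-scores
#'
#' Centers by the mean and scales by the standard deviation (n - 1
#' denominator), both computed on the analysis subset supplied.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Numeric vector with mean 0 and unit standard deviation.
#' @export
standardize <- function(x) {
  if (any(!is.finite(x))) abort_validation("`x` must be finite")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    abort_validation("`x` has zero variance; cannot standardize")
  }
  (x - mean(x)) / s
}

as_design <- function(X, n) {
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  X
}

#' Binomial GLM with logit link, fitted by IRLS
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares, iterated to a score (gradient) norm below 1e-10. If the
#' coefficients diverge (complete separation) a warning of class
#' `partmigr_separation` is signalled and the fit is flagged.
#'
#' @param y Binary (0/1) response vector; both classes must be present.
#' @param X Design matrix (default intercept only).
#' @return An object of class `glm_fit` with `family = "binomial-logit"`,
#'   `coefficients`, `loglik`, `k` (number of estimated parameters), `n`,
#'   `fitted`, and `separation` flag.
#' @export
fit_binomial <- function(y, X = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort_validation("`y` must be binary 0/1")
  if (length(unique(y)) < 2) abort_validation("both outcome classes must be present")
  X <- as_design(X, length(y))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) rlang::abort("design is rank deficient", class = "partmigr_singular_design")
  p <- ncol(X)
  beta <- rep(0, p)
  separation <- FALSE
  converged <- FALSE
  for (it in seq_len(200)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- crossprod(X, y - mu)
    if (max(abs(grad)) < 1e-10) {
      converged <- TRUE
      break
    }
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    beta <- drop(solve(crossprod(X, X * w), crossprod(X, w * z)))
    if (max(abs(drop(X %*% beta))) > 40) {
      separation <- TRUE
      break
    }
  }
  if (separation || !converged) {
    separation <- TRUE
    rlang::warn("possible complete separation: coefficients diverging",
      class = "partmigr_separation"
    )
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  ll <- sum(stats::dbinom(y, 1, mu, log = TRUE))
  names(beta) <- colnames(X)
  structure(
    list(
      family = "binomial-logit", coefficients = beta, loglik = ll,
      k = p, n = length(y), fitted = mu, separation = separation
    ),
    class = "glm_fit"
  )
}

#' Gaussian linear model with full-ML log-likelihood
#'
#' Ordinary least squares; the reported log-likelihood is the maximized
#' full likelihood (residual variance estimated with denominator n), so the
#' fit is directly comparable with other families under AICc. The parameter
#' count `k` includes the residual variance. An exact fit (zero residual
#' variance) is flagged `degenerate` and carries an infinite log-likelihood.
#'
#' @param y Numeric response.
#' @param X Design matrix (default intercept only).
#' @return A `glm_fit` with `family = "gaussian-identity"`, `sigma2` (ML
#'   estimate), and `degenerate` flag.
#' @export
fit_gaussian <- function(y, X = NULL) {
  y <- as.numeric(y)
  X <- as_design(X, length(y))
  n <- length(y)
  p <- ncol(X)
  if (n <= p) abort_validation("need more observations than coefficients")
  qrX <- qr(X)
  if (qrX$rank < p) rlang::abort("design is rank deficient", class = "partmigr_singular_design")
  beta <- qr.coef(qrX, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  sigma2 <- rss / n
  degenerate <- rss < 1e-12 * max(1, sum(y^2))
  ll <- if (degenerate) Inf else -n / 2 * (log(2 * pi * sigma2) + 1)
  structure(
    list(
      family = "gaussian-identity", coefficients = beta, loglik = ll,
      k = p + 1L, n = n, sigma2 = sigma2, fitted = drop(X %*% beta),
      degenerate = degenerate
    ),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, k = %d, logLik = %.4f\n", x$family, x$n, x$k, x$loglik))
  print(x$coefficients)
  if (!is.null(x$nu)) cat("  dispersion nu =", format(x$nu), "\n")
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik Maximized full log-likelihood.
#' @param k Number of estimated parameters (including any scale parameter).
#' @param n Number of observations; must exceed `k + 1`.
#' @return Numeric AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) abort_validation("AICc requires n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc
#'
#' Builds the standard candidate-model table: AICc, delta AICc relative to
#' the best model, Akaike weights and cumulative weights, sorted by
#' ascending AICc (ties broken by smaller `k`, then label).
#'
#' @param fits Named list of `glm_fit` objects fitted to the same
#'   observations.
#' @return A tibble with columns `model`, `k`, `AICc`, `delta_AICc`,
#'   `weight`, `cum_weight`.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  n <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(n)) != 1) {
    abort_validation("all candidate models must be fitted to the same observations")
  }
  tab <- tibble::tibble(
    model = names(fits),
    k = unname(vapply(fits, function(f) as.numeric(f$k), numeric(1))),
    AICc = unname(vapply(fits, function(f) aicc(f$loglik, f$k, f$n), numeric(1)))
  )
  tab <- tab[order(tab$AICc, tab$k, tab$model), ]
  delta <- tab$AICc - tab$AICc[1]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab$delta_AICc <- delta
  tab$weight <- w
  tab$cum_weight <- cumsum(w)
  tab
}
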