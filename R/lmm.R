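# One-random-intercept linear mixed model fitted by REML, the repeatability
# it implies, and a parametric-bootstrap confidence interval.
#
# The model is y = X beta + b[group] + e with b ~ N(0, sigma2_alpha) and
# e ~ N(0, sigma2_eps). REML is computed by profiling the variance ratio
# gamma = sigma2_alpha / sigma2_eps: for fixed gamma both beta and sigma2_eps
# have closed forms, so the fit reduces to a bracketed 1-D search on
# log(gamma). Because the random effect is a single intercept per group, the
# marginal covariance is block diagonal with blocks I + gamma * J, whose
# inverse and determinant are available in closed form from per-group sums;
# each likelihood evaluation is O(number of groups).

# Precompute group structure and design cross-products reused across
# evaluations (and across bootstrap refits, which share X and groups).
lmm_precompute <- function(X, groups) {
  X <- as.matrix(X)
  g <- factor(groups)
  n <- nrow(X)
  p <- ncol(X)
  if (length(g) != n) abort_validation("`groups` length must match rows of X")
  if (nlevels(g) < 2) abort_validation("at least 2 groups are required")
  sizes <- as.numeric(table(g))
  if (max(sizes) < 2) {
    abort_validation("all groups are singletons; variance components are not separable")
  }
  qrX <- qr(X)
  if (qrX$rank < p) rlang::abort("fixed-effect design is singular", class = "partmigr_singular_design")
  Sx <- rowsum(X, g) # G x p group sums
  list(
    X = X, g = g, n = n, p = p, sizes = sizes,
    XtX = crossprod(X), Sx = Sx
  )
}

# Profiled restricted log-likelihood and closed-form (beta, sigma2) at a
# given gamma, from sufficient statistics of y.
lmm_profile_eval <- function(gamma, pre, Sy, Xty, yty) {
  ci <- gamma / (1 + gamma * pre$sizes)
  XtVX <- pre$XtX - crossprod(pre$Sx, pre$Sx * ci)
  XtVy <- Xty - crossprod(pre$Sx, ci * Sy)
  yVy <- yty - sum(ci * Sy^2)
  ch <- chol(XtVX)
  beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
  rss <- max(yVy - sum(beta * XtVy), 0)
  df <- pre$n - pre$p
  sigma2 <- rss / df
  logdet_v <- sum(log1p(gamma * pre$sizes))
  logdet_xvx <- 2 * sum(log(diag(ch)))
  reml <- -0.5 * (df * (log(2 * pi * max(sigma2, 1e-300)) + 1) + logdet_v + logdet_xvx)
  list(reml = reml, beta = drop(beta), sigma2 = sigma2)
}

# Core REML fit from precomputed structure; returns variance components.
lmm_profile_fit <- function(pre, y, tol = 1e-10) {
  Sy <- drop(rowsum(y, pre$g))
  Xty <- crossprod(pre$X, y)
  yty <- sum(y^2)
  obj <- function(u) -lmm_profile_eval(exp(u), pre, Sy, Xty, yty)$reml
  opt <- stats::optimize(obj, interval = c(-30, 30), tol = tol)
  # compare against the gamma -> 0 boundary (no between-group variance)
  at0 <- lmm_profile_eval(0, pre, Sy, Xty, yty)
  if (at0$reml >= -opt$objective) {
    gamma <- 0
    sol <- at0
  } else {
    gamma <- exp(opt$minimum)
    sol <- lmm_profile_eval(gamma, pre, Sy, Xty, yty)
  }
  list(
    gamma = gamma,
    sigma2_eps = sol$sigma2,
    sigma2_alpha = gamma * sol$sigma2,
    beta = sol$beta,
    reml_loglik = sol$reml
  )
}

#' Fit a one-random-intercept linear mixed model by REML
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (include an intercept column); a
#'   vector is treated as a one-column matrix. Default: intercept only.
#' @param groups Grouping factor (one random intercept per level).
#' @return An object of class `lmm_fit`: list with `coefficients`,
#'   `sigma2_alpha`, `sigma2_eps`, `gamma` (their ratio), `reml_loglik`,
#'   `n_obs`, `n_groups`.
#' @export
fit_lmm <- function(y, X = NULL, groups) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) abort_validation("`y` must be finite")
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) abort_validation("rows of `X` must match length of `y`")
  pre <- lmm_precompute(X, groups)
  fit <- lmm_profile_fit(pre, y)
  coefs <- fit$beta
  names(coefs) <- colnames(X) %||% paste0("b", seq_along(coefs))
  structure(
    list(
      coefficients = coefs,
      sigma2_alpha = fit$sigma2_alpha,
      sigma2_eps = fit$sigma2_eps,
      gamma = fit$gamma,
      reml_loglik = fit$reml_loglik,
      n_obs = pre$n,
      n_groups = nlevels(pre$g),
      pre = pre
    ),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "REML linear mixed model: %d obs, %d groups\n", x$n_obs, x$n_groups
  ))
  cat("  sigma2_alpha =", format(x$sigma2_alpha), " sigma2_eps =", format(x$sigma2_eps), "\n")
  cat("  fixed effects:", paste(names(x$coefficients), format(x$coefficients), collapse = ", "), "\n")
  invisible(x)
}

#' Repeatability from a fitted mixed model
#'
#' The proportion of total variance attributable to between-individual
#' variance: `sigma2_alpha / (sigma2_alpha + sigma2_eps)`.
#'
#' @param fit An [fit_lmm()] object.
#' @return Numeric in `[0, 1]`.
#' @export
repeatability <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  tot <- fit$sigma2_alpha + fit$sigma2_eps
  if (tot <= 0) {
    rlang::abort("total variance is zero; repeatability undefined",
      class = "partmigr_zero_variance"
    )
  }
  fit$sigma2_alpha / tot
}

#' Parametric-bootstrap confidence interval for repeatability
#'
#' Simulates `n_boot` datasets from the fitted model (group intercepts and
#' residuals drawn from the estimated normal components), refits each, and
#' returns the percentile interval of the recomputed repeatabilities.
#'
#' @inheritParams fit_lmm
#' @param n_boot Number of bootstrap replicates (1000 in the standard
#'   workflow).
#' @param seed Integer seed; the interval is reproducible given the seed.
#' @param level Confidence level (default 0.95).
#' @param kind Label stored on the result (`"agreement"` for an
#'   intercept-only fixed part, `"adjusted"` when covariates are included).
#' @return An object of class `repeatability_result`: list with `R`,
#'   `ci_low`, `ci_high`, `kind`, `n_boot`, `seed`, `level`, `n_obs`,
#'   `n_groups`, `n_failed`, and the bootstrap draws `boot_R`.
#' @export
bootstrap_ci <- function(y, X = NULL, groups, n_boot = 1000, seed = 1,
                         level = 0.95, kind = "agreement") {
  fit <- fit_lmm(y, X, groups)
  r_hat <- repeatability(fit)
  pre <- fit$pre
  mu <- drop(pre$X %*% fit$coefficients)
  gi <- as.integer(pre$g)
  ng <- nlevels(pre$g)
  sd_a <- sqrt(fit$sigma2_alpha)
  sd_e <- sqrt(fit$sigma2_eps)
  boot_R <- rep(NA_real_, n_boot)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      yb <- mu + stats::rnorm(ng, 0, sd_a)[gi] + stats::rnorm(pre$n, 0, sd_e)
      fb <- tryCatch(lmm_profile_fit(pre, yb), error = function(e) NULL)
      if (!is.null(fb)) {
        tot <- fb$sigma2_alpha + fb$sigma2_eps
        if (tot > 0) boot_R[b] <- fb$sigma2_alpha / tot
      }
    }
  })
  n_failed <- sum(is.na(boot_R))
  if (n_failed > 0.1 * n_boot) {
    rlang::abort(
      sprintf("%d of %d bootstrap refits failed", n_failed, n_boot),
      class = "partmigr_bootstrap_failure"
    )
  }
  ok <- boot_R[!is.na(boot_R)]
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(ok, c(alpha, 1 - alpha)))
  structure(
    list(
      R = r_hat, ci_low = ci[1], ci_high = ci[2], kind = kind,
      n_boot = n_boot, seed = seed, level = level,
      n_obs = fit$n_obs, n_groups = fit$n_groups,
      n_failed = n_failed, boot_R = ok, fit = fit
    ),
    class = "repeatability_result"
  )
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf(
    "%s repeatability: R = %.3f, %d%% CI = %.3f-%.3f (parametric bootstrap, n = %d)\n",
    x$kind, x$R, round(100 * x$level), x$ci_low, x$ci_high, x$n_boot
  ))
  cat(sprintf("  %d observations of %d individuals\n", x$n_obs, x$n_groups))
  invisible(x)
}

#' Agreement and adjusted repeatability of seasonal movement distances
#'
#' Computes the repeatability of log-transformed seasonal movement distance
#' across the repeated migratory decisions of individual birds. Only birds
#' with two or more observed transitions are included. The response is
#' `log(distance_m + 1)`; the 1 m offset accommodates exact-zero
#' displacements and is orders of magnitude below typical migration
#' distances. Agreement repeatability uses an intercept-only fixed part;
#' adjusted repeatability adds age class as a fixed effect.
#'
#' @param transitions Transition table from [build_transitions()].
#' @param birds Bird attribute table with `bird_id` and `age_class`.
#' @param n_boot,seed,level Passed to [bootstrap_ci()].
#' @return List with elements `agreement` and `adjusted`, each a
#'   `repeatability_result`.
#' @export
agreement_and_adjusted <- function(transitions, birds, n_boot = 1000,
                                   seed = 1, level = 0.95) {
  dat <- transitions |>
    dplyr::inner_join(
      dplyr::select(birds, bird_id, age_class),
      by = "bird_id"
    ) |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::ungroup()
  if (dplyr::n_distinct(dat$bird_id) < 2) {
    abort_validation("fewer than 2 birds with repeated observations")
  }
  yy <- log(dat$distance_m + 1)
  x_adj <- stats::model.matrix(~age_class, data = dat)
  list(
    agreement = bootstrap_ci(yy, NULL, dat$bird_id,
      n_boot = n_boot, seed = seed, level = level, kind = "agreement"
    ),
    adjusted = bootstrap_ci(yy, x_adj, dat$bird_id,
      n_boot = n_boot, seed = seed, level = level, kind = "adjusted"
    )
  )
}
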