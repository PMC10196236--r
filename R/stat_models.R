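#' Fit a zero-inflated Poisson distribution
#'
#' Maximum-likelihood fit of the ZIP model with Poisson mean `lambda` and
#' structural-zero fraction `pi`:
#' `P(0) = pi + (1 - pi) exp(-lambda)`,
#' `P(k > 0) = (1 - pi) exp(-lambda) lambda^k / k!`.
#' When the observed zero fraction does not exceed `exp(-mean(counts))`
#' the data carry no evidence of zero inflation and a plain Poisson fit
#' is returned with `pi_hat = 0`. Wald 95% intervals come from the
#' observed Fisher information on the (log lambda, logit pi) scale.
#'
#' @param counts Non-negative integer vector.
#' @param min_n Minimum sample size (default 10).
#' @return An object of class `zip_fit` with `lambda_hat`, `pi_hat`,
#'   `loglik`, `ci_lambda`, `ci_pi`, `n`, and a `degenerate` flag (TRUE
#'   when all counts are zero, in which case `lambda_hat` is NA).
#' @export
fit_zip <- function(counts, min_n = 10L) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (any(counts != floor(counts)))
    stop("counts must be integers", call. = FALSE)
  n <- length(counts)
  if (n < min_n) stop("need at least ", min_n, " counts, got ", n, call. = FALSE)
  n0 <- sum(counts == 0)
  if (n0 == n) {
    return(structure(list(lambda_hat = NA_real_, pi_hat = 1, loglik = 0,
                          ci_lambda = c(NA_real_, NA_real_), ci_pi = c(1, 1),
                          n = n, degenerate = TRUE), class = "zip_fit"))
  }
  xbar <- mean(counts)
  pos <- counts[counts > 0]
  sum_x <- sum(pos)
  sum_lgam <- sum(lgamma(pos + 1))
  npos <- n - n0
  if (n0 / n <= exp(-xbar)) {
    # no excess zeros: plain Poisson MLE
    lam <- xbar
    ll <- -n * lam + sum(counts) * log(lam) - sum(lgamma(counts + 1))
    se <- sqrt(lam / n)
    return(structure(list(lambda_hat = lam, pi_hat = 0, loglik = ll,
                          ci_lambda = c(lam - 1.96 * se, lam + 1.96 * se),
                          ci_pi = c(0, 0), n = n, degenerate = FALSE),
                     class = "zip_fit"))
  }
  negll <- function(theta) {
    lam <- exp(theta[1]); p <- stats::plogis(theta[2])
    p0 <- p + (1 - p) * exp(-lam)
    -(n0 * log(p0) + npos * log1p(-p) - npos * lam + sum_x * log(lam) - sum_lgam)
  }
  lam0 <- mean(pos)
  p0_obs <- n0 / n
  pi0 <- min(0.99, max(1e-3, (p0_obs - exp(-lam0)) / (1 - exp(-lam0))))
  opt <- stats::optim(c(log(lam0), stats::qlogis(pi0)), negll,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  lam <- exp(opt$par[1]); p <- stats::plogis(opt$par[2])
  se <- tryCatch(sqrt(diag(solve(opt$hessian))),
                 error = function(e) c(NA_real_, NA_real_))
  ci_lambda <- exp(opt$par[1] + c(-1.96, 1.96) * se[1])
  ci_pi <- stats::plogis(opt$par[2] + c(-1.96, 1.96) * se[2])
  structure(list(lambda_hat = lam, pi_hat = p, loglik = -opt$value,
                 ci_lambda = ci_lambda, ci_pi = ci_pi, n = n,
                 degenerate = FALSE), class = "zip_fit")
}

#' @export
print.zip_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("zip_fit (degenerate): all counts zero, pi = 1, lambda unidentifiable\n")
  } else {
    cat(sprintf("zip_fit: lambda = %.4g [%.4g, %.4g], pi = %.4g [%.4g, %.4g], n = %d\n",
                x$lambda_hat, x$ci_lambda[1], x$ci_lambda[2],
                x$pi_hat, x$ci_pi[1], x$ci_pi[2], x$n))
  }
  invisible(x)
}

# sinh-arcsinh transform of x under (location, scale, skew, tailweight):
# the result is standard normal when x follows the fitted SHASH law.
shash_z <- function(x, mu, sigma, nu, tau) {
  r <- (x - mu) / sigma
  sinh(tau * asinh(r) - nu)
}

#' Fit a sinh-arcsinh (SHASH) transform to normality
#'
#' Maximum-likelihood fit of the four-parameter sinh-arcsinh family
#' (location, scale, skew, tailweight); the fitted transform maps the
#' data to an approximately standard normal scale while preserving
#' ranks. A final exact centering/scaling of the transformed training
#' values is stored so that [standardize()] returns zero-mean,
#' unit-variance scores. When the likelihood fit fails, or for short
#' inputs, a rank-based inverse-normal transform is used instead
#' (`method = "rank"`).
#'
#' @param values Finite numeric vector, `n >= 8`, non-constant.
#' @param fitted_on Tag recording the transform applied upstream
#'   (e.g. `"log2(1+count)"` or `"Ln(ic50)"`).
#' @return An object of class `shash_fit` with fields `location`,
#'   `scale`, `skew`, `tailweight`, `method`, `fitted_on`, plus the
#'   affine standardization constants.
#' @export
fit_shash <- function(values, fitted_on = "values") {
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  n <- length(values)
  if (n < 8L) stop("need at least 8 values, got ", n, call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant input: SHASH standardization is degenerate", call. = FALSE)
  negll <- function(theta) {
    mu <- theta[1]; sigma <- exp(theta[2]); nu <- theta[3]; tau <- exp(theta[4])
    r <- (values - mu) / sigma
    s <- tau * asinh(r) - nu
    z <- sinh(s)
    # log-density of SHASH: dnorm(z) * tau * cosh(s) / (sigma * sqrt(1 + r^2));
    # log(cosh(s)) written in overflow-safe form
    logcosh <- abs(s) + log1p(exp(-2 * abs(s))) - log(2)
    ll <- sum(stats::dnorm(z, log = TRUE) + log(tau) + logcosh -
                log(sigma) - 0.5 * log1p(r^2))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  start <- c(stats::median(values), log(max(stats::IQR(values) / 1.349, 1e-6)), 0, 0)
  opt <- tryCatch({
    o <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    stats::optim(o$par, negll, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-12))
  }, error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e10) {
    mu <- opt$par[1]; sigma <- exp(opt$par[2])
    nu <- opt$par[3]; tau <- exp(opt$par[4])
    z <- shash_z(values, mu, sigma, nu, tau)
    fit <- list(location = mu, scale = sigma, skew = nu, tailweight = tau,
                method = "shash", fitted_on = fitted_on,
                z_center = mean(z), z_scale = stats::sd(z))
  } else {
    fit <- rank_inverse_normal_fit(values, fitted_on)
  }
  structure(fit, class = "shash_fit")
}

# Blom-score fallback: monotone interpolation of sorted values onto
# normal quantiles; used when the SHASH likelihood cannot be maximized.
rank_inverse_normal_fit <- function(values, fitted_on) {
  n <- length(values)
  z <- stats::qnorm((rank(values, ties.method = "average") - 0.375) / (n + 0.25))
  ord <- order(values)
  knots_x <- values[ord]; knots_z <- z[ord]
  keep <- !duplicated(knots_x)
  list(location = NA_real_, scale = NA_real_, skew = NA_real_,
       tailweight = NA_real_, method = "rank", fitted_on = fitted_on,
       knots_x = knots_x[keep], knots_z = knots_z[keep],
       z_center = mean(z), z_scale = stats::sd(z))
}

#' Standardize values through a fitted SHASH transform
#'
#' Applies the strictly monotone transform of a [fit_shash()] fit and
#' the stored affine normalization, yielding zero-mean unit-variance
#' scores on the training data (rank-preserving for any data).
#'
#' @param values Numeric vector.
#' @param fit A `shash_fit`.
#' @return Numeric z-scores.
#' @export
standardize <- function(values, fit) {
  stopifnot(inherits(fit, "shash_fit"))
  z <- if (fit$method == "shash") {
    shash_z(values, fit$location, fit$scale, fit$skew, fit$tailweight)
  } else {
    stats::approx(fit$knots_x, fit$knots_z, xout = values, rule = 2)$y
  }
  if (is.na(fit$z_scale) || fit$z_scale == 0) return(z - fit$z_center)
  (z - fit$z_center) / fit$z_scale
}

#' Standardize Ln(ic50) predictions within protein and allele
#'
#' Applies SHASH standardization to the `ln_ic50` column independently
#' within each `(protein_id, allele)` group, placing predictions for
#' different alleles on a common within-protein Zscale. Groups with
#' fewer than `min_group` values, or where the SHASH fit fails, fall
#' back to the rank-based inverse-normal transform and are listed in the
#' `flagged_groups` attribute.
#'
#' @param predictions Data frame with columns `protein_id`, `allele`,
#'   `ln_ic50` (other columns pass through).
#' @param min_group Minimum group size for the SHASH fit (default 8).
#' @return The input with an added `zscore` column; attribute
#'   `flagged_groups` names fallback groups.
#' @export
zscale_within_protein <- function(predictions, min_group = 8L) {
  req <- c("protein_id", "allele", "ln_ic50")
  if (!all(req %in% names(predictions)))
    stop("predictions must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  key <- interaction(predictions$protein_id, predictions$allele, drop = TRUE)
  z <- numeric(nrow(predictions))
  flagged <- character()
  for (g in levels(key)) {
    idx <- which(key == g)
    v <- predictions$ln_ic50[idx]
    if (length(idx) >= min_group && stats::sd(v) > 0) {
      fit <- fit_shash(v, fitted_on = "Ln(ic50)")
      if (fit$method != "shash") flagged <- c(flagged, g)
      z[idx] <- standardize(v, fit)
    } else {
      flagged <- c(flagged, g)
      if (length(idx) == 1L || stats::sd(v) == 0) {
        z[idx] <- 0
      } else {
        f <- structure(rank_inverse_normal_fit(v, "Ln(ic50)"), class = "shash_fit")
        z[idx] <- standardize(v, f)
      }
    }
  }
  predictions$zscore <- z
  attr(predictions, "flagged_groups") <- flagged
  predictions
}

#' Convert a Zscale value to a percentile
#'
#' Standard normal cumulative probability expressed in percent; the
#' working binding threshold of -1 sigma corresponds to roughly the 16th
#' percentile.
#'
#' @param z Finite numeric vector.
#' @return Percentile(s) in `[0, 100]`.
#' @export
#' @examples
#' normal_percentile(-1)  # 15.87
normal_percentile <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  stats::pnorm(z) * 100
}

# Deterministic multi-start Levenberg-Marquardt helper. `resid_fn` maps
# a named parameter vector to residuals; each start is tried and the
# converged fit with lowest RMSE kept, ties broken by the smaller
# parameter norm.
multistart_nls <- function(resid_fn, starts, lower = NULL, upper = NULL) {
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                     ptol = 1e-12)
  for (st in starts) {
    st <- unlist(st)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(par = st, fn = resid_fn,
                                          lower = lower[names(st)],
                                          upper = upper[names(st)],
                                          control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$par))) next
    res <- resid_fn(fit$par)
    if (any(!is.finite(res))) next
    rmse <- sqrt(mean(res^2))
    pnorm2 <- sqrt(sum(fit$par^2))
    if (is.null(best) || rmse < best$rmse - 1e-12 ||
        (abs(rmse - best$rmse) <= 1e-12 && pnorm2 < best$pnorm)) {
      best <- list(par = fit$par, rmse = rmse, pnorm = pnorm2)
    }
  }
  best
}

#' Fit a 4-parameter logistic (Hill) curve
#'
#' Least-squares fit of
#' `y = lower + (upper - lower) / (1 + exp(-hill * (x - inflection_x)))`
#' with five deterministic starts taken from data quantiles.
#'
#' @param x,y Numeric vectors, at least 6 points spanning both shoulders.
#' @return An object of class `fourpl_fit` with `lower`, `upper`,
#'   `inflection_x`, `hill`, `rmse`, and `fitted`.
#' @export
fit_4pl <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 6L) stop("need at least 6 points", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response: 4PL fit is degenerate", call. = FALSE)
  rng <- diff(range(x))
  # primary start: linearize via the empirical logit against x
  eps <- 0.05 * diff(range(y))
  t0 <- (y - min(y) + eps) / (diff(range(y)) + 2 * eps)
  lf <- stats::lm(stats::qlogis(t0) ~ x)
  hill0 <- unname(stats::coef(lf)[2])
  infl0 <- if (abs(hill0) > 1e-12) -unname(stats::coef(lf)[1]) / hill0 else
    stats::median(x)
  infl0 <- min(max(infl0, min(x)), max(x))
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  starts <- c(list(list(lower = min(y), upper = max(y),
                        inflection_x = infl0, hill = hill0),
                   list(lower = min(y), upper = max(y),
                        inflection_x = infl0, hill = -hill0)),
              lapply(qs, function(q)
                list(lower = min(y), upper = max(y), inflection_x = q,
                     hill = 4 / rng)))
  model_4pl <- function(p)
    p["lower"] + (p["upper"] - p["lower"]) /
      (1 + exp(-p["hill"] * (x - p["inflection_x"])))
  best <- multistart_nls(function(p) y - model_4pl(p), starts)
  if (is.null(best))
    stop("4PL fit did not converge from any start", call. = FALSE)
  cf <- best$par
  structure(list(lower = unname(cf["lower"]), upper = unname(cf["upper"]),
                 inflection_x = unname(cf["inflection_x"]),
                 hill = unname(cf["hill"]), rmse = best$rmse,
                 fitted = unname(model_4pl(cf))),
            class = "fourpl_fit")
}

#' Fit a Weibull growth curve
#'
#' Least-squares fit of `y = a * (1 - exp(-(x / c)^b))` with `a` the
#' upper asymptote, `b` the growth rate and `c` the inflection point.
#' With `bound_a = TRUE` the asymptote is constrained to `[0, 1]`, the
#' appropriate bound when `y` are cumulative fractions.
#'
#' @param x Non-negative numeric vector.
#' @param y Numeric response, at least 5 points.
#' @param bound_a Constrain `a <= 1` (default FALSE).
#' @return An object of class `weibull_fit` with `a`, `b`, `c`, `rmse`.
#' @export
fit_weibull_growth <- function(x, y, bound_a = FALSE) {
  stopifnot(length(x) == length(y))
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  if (length(x) < 5L) stop("need at least 5 points", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response: Weibull fit is degenerate", call. = FALSE)
  xpos <- x[x > 0]
  cq <- stats::quantile(xpos, c(0.25, 0.5, 0.75), names = FALSE)
  a0 <- max(y)
  starts <- c(lapply(cq, function(cc) list(a = a0, b = 1.5, c = cc)),
              list(list(a = a0, b = 1, c = stats::median(xpos)),
                   list(a = a0, b = 3, c = stats::median(xpos))))
  lower <- c(a = 0, b = 1e-8, c = 1e-8)
  upper <- if (bound_a) c(a = 1, b = Inf, c = Inf) else
    c(a = Inf, b = Inf, c = Inf)
  model_wb <- function(p) p["a"] * (1 - exp(-(x / p["c"])^p["b"]))
  best <- multistart_nls(function(p) y - model_wb(p), starts,
                         lower = lower, upper = upper)
  if (is.null(best))
    stop("Weibull growth fit did not converge from any start", call. = FALSE)
  cf <- best$par
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
                 rmse = best$rmse, fitted = unname(model_wb(cf))),
            class = "weibull_fit")
}
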