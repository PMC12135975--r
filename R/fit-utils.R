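#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

#' Bounded Levenberg-Marquardt least squares with covariance
#'
#' Thin wrapper around [minpack.lm::nls.lm()] used by every fitting routine
#' in the package.  The caller supplies a function returning the (already
#' weighted) residual vector; the wrapper returns parameter estimates,
#' 1-sigma uncertainties from the local covariance `(J'WJ)^-1` scaled by the
#' reduced chi-square, the full covariance matrix, and a convergence flag.
#'
#' @param resid_fn function(par) -> numeric residual vector.
#' @param start named numeric vector of starting values.
#' @param lower,upper bounds (recycled); defaults unbounded.
#' @param maxiter maximum LM iterations.
#' @return list with elements `par`, `se`, `cov`, `redchi2`, `deviance`,
#'   `converged`, `nobs`, `npar`, `message`.
#' @keywords internal
wnls_fit <- function(resid_fn, start, lower = NULL, upper = NULL,
                     maxiter = 200L) {
  if (is.null(lower)) lower <- rep(-Inf, length(start))
  if (is.null(upper)) upper <- rep(Inf, length(start))
  fit <- tryCatch(
    nls.lm(par = start, lower = lower, upper = upper, fn = resid_fn,
           control = nls.lm.control(maxiter = maxiter)),
    error = function(e) e
  )
  npar <- length(start)
  if (inherits(fit, "error")) {
    return(list(par = start,
                se = stats::setNames(rep(NA_real_, npar), names(start)),
                cov = matrix(NA_real_, npar, npar), redchi2 = NA_real_,
                deviance = NA_real_, converged = FALSE,
                nobs = NA_integer_, npar = npar, message = conditionMessage(fit)))
  }
  par <- stats::setNames(fit$par, names(start))
  nobs <- length(fit$fvec)
  dof <- max(nobs - npar, 1L)
  redchi2 <- fit$deviance / dof
  cov <- tryCatch(solve(fit$hessian) * redchi2, error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov)))) {
    cov <- tryCatch(pracma::pinv(fit$hessian) * redchi2,
                    error = function(e) matrix(NA_real_, npar, npar))
  }
  se <- sqrt(pmax(diag(cov), 0))
  converged <- fit$info %in% 1:3
  list(par = par, se = stats::setNames(se, names(start)), cov = cov,
       redchi2 = redchi2, deviance = fit$deviance, converged = converged,
       nobs = nobs, npar = npar, message = fit$message)
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' Tests whether the signs of a residual sequence are randomly ordered.
#' Too few runs indicate structured (correlated) residuals, the signature
#' of a misspecified kinetic model.  Normal approximation to the null
#' distribution of the number of runs.
#'
#' @param x numeric residual vector (zeros dropped).
#' @return list with `runs`, `statistic` (z value) and `p.value` (two-sided).
#' @export
#' @examples
#' runs_test(rnorm(50))
runs_test <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  n <- n1 + n2
  if (n1 == 0 || n2 == 0) {
    return(list(runs = 1L, statistic = NA_real_, p.value = NA_real_))
  }
  runs <- 1L + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  list(runs = runs, statistic = z, p.value = 2 * stats::pnorm(-abs(z)))
}
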