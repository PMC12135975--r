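#' A single DLS correlogram
#'
#' Holds one normalized intensity correlation function `g2 - 1` versus lag
#' time at one scattering angle and sample age.  The momentum transfer is
#' derived from the angle via [q_from_angle_light()].
#'
#' @param angle_deg scattering angle in degrees.
#' @param lag_s lag times in seconds, strictly increasing and positive.
#' @param g2m1 normalized `g2 - 1` values.
#' @param error optional per-point 1-sigma.
#' @param age_h sample age in hours.
#' @param lambda_m laser wavelength in metres.
#' @param n solvent refractive index.
#' @return object of class `correlogram`.
#' @export
correlogram <- function(angle_deg, lag_s, g2m1, error = NULL, age_h = NA_real_,
                        lambda_m = 633e-9, n = 1.333) {
  stopifnot(length(lag_s) == length(g2m1))
  if (any(diff(lag_s) <= 0) || any(lag_s <= 0)) {
    stop("lag_s must be positive and strictly increasing")
  }
  structure(list(angle_deg = angle_deg,
                 q_m_inv = q_from_angle_light(angle_deg, lambda_m, n),
                 lag_s = lag_s, g2m1 = g2m1, error = error, age_h = age_h),
            class = "correlogram")
}

#' Average repeated correlograms with outlier rejection
#'
#' Repeated acquisitions on an identical lag grid are combined pointwise:
#' per lag, points deviating from the median by more than `mad_k` times the
#' median absolute deviation (scaled) across the repeats are discarded as
#' dust-induced outliers, then the remaining points are averaged with a
#' propagated standard error.
#'
#' @param repeats list of at least two [correlogram()]s on identical lag grids.
#' @param mad_k outlier threshold in scaled MAD units.
#' @return a [correlogram()] with the averaged values; attributes
#'   `n_rejected` and `fraction_rejected` report the outlier count.
#' @export
preprocess_correlograms <- function(repeats, mad_k = 5) {
  stopifnot(length(repeats) >= 2)
  lag <- repeats[[1]]$lag_s
  for (r in repeats) {
    if (length(r$lag_s) != length(lag) || any(r$lag_s != lag)) {
      stop("all repeats must share an identical lag grid")
    }
  }
  g <- vapply(repeats, function(r) r$g2m1, numeric(length(lag)))
  keep <- matrix(TRUE, nrow(g), ncol(g))
  # scale per lag: the stated instrument error when available (a MAD over
  # a handful of repeats is noisy and would falsely reject good points),
  # otherwise the MAD across repeats
  err <- vapply(repeats, function(r) {
    if (is.null(r$error)) rep(NA_real_, length(lag)) else r$error
  }, numeric(length(lag)))
  inst <- apply(err, 1, function(x) stats::median(x, na.rm = TRUE))
  mads <- apply(g, 1, stats::mad)
  for (i in seq_len(nrow(g))) {
    med <- stats::median(g[i, ])
    s <- if (is.finite(inst[i]) && inst[i] > 0) max(mads[i], inst[i]) else mads[i]
    if (s > 0) keep[i, ] <- abs(g[i, ] - med) <= mad_k * s
  }
  mean_g <- vapply(seq_len(nrow(g)), function(i) mean(g[i, keep[i, ]]), 1)
  se_g <- vapply(seq_len(nrow(g)), function(i) {
    gi <- g[i, keep[i, ]]
    if (length(gi) > 1) stats::sd(gi) / sqrt(length(gi)) else NA_real_
  }, 1)
  out <- correlogram(repeats[[1]]$angle_deg, lag, mean_g, error = se_g,
                     age_h = repeats[[1]]$age_h)
  out$q_m_inv <- repeats[[1]]$q_m_inv
  attr(out, "n_rejected") <- sum(!keep)
  attr(out, "fraction_rejected") <- mean(!keep)
  out
}

.dls_model <- function(lag, beta, a, g1, g2, squared = TRUE) {
  field <- a * exp(-g1 * lag) + (1 - a) * exp(-g2 * lag)
  if (squared) beta * field^2 else beta * field
}

#' Double-exponential decomposition of a correlogram
#'
#' Fits the Siegert-squared double exponential
#' `g2 - 1 = beta * (a exp(-Gamma1 tau) + (1 - a) exp(-Gamma2 tau))^2`,
#' separating the slow contribution of small crystals or precursors
#' (`Gamma1`, weight `a`) from the fast decay of dissolved proteins
#' (`Gamma2`).  Labels are swapped after the fit if needed so that
#' `Gamma1 <= Gamma2`.  `squared = FALSE` fits the plain (unsquared) sum
#' for sensitivity checks.
#'
#' @param cg a [correlogram()] with at least 8 lag points.
#' @param squared use the Siegert-squared form (default) or a plain sum.
#' @return list of class `dls_fit` with `a`, `gamma1`, `gamma2`, `beta`,
#'   their 1-sigma uncertainties, `redchi2`, `converged` and `flags`.
#' @export
fit_correlogram <- function(cg, squared = TRUE) {
  lag <- cg$lag_s; y <- cg$g2m1
  stopifnot(length(lag) >= 8)
  w <- if (is.null(cg$error) || any(!is.finite(cg$error)) || any(cg$error <= 0)) {
    rep(1, length(y))
  } else 1 / cg$error

  beta0 <- max(y[seq_len(min(3, length(y)))])
  if (beta0 <= 0) beta0 <- max(y, 1e-3)
  # crude decay-time guesses from where the normalized field drops
  gnorm <- pmax(y / beta0, 0)
  if (squared) gnorm <- sqrt(gnorm)
  t_fast <- lag[which(gnorm < 0.4)[1]]
  if (is.na(t_fast)) t_fast <- lag[ceiling(length(lag) / 2)]
  t_slow <- lag[which(gnorm < 0.05)[1]]
  if (is.na(t_slow)) t_slow <- max(lag)

  resid_fn <- function(p) (y - .dls_model(lag, p[1], p[2], p[3], p[4], squared)) * w
  lower <- c(1e-6, 0, 1e-9, 1e-9)
  upper <- c(2, 1, 1e9, 1e9)
  best <- NULL
  for (a0 in c(0.5, 0.2, 0.8)) {
    start <- c(beta = beta0, a = a0, g1 = 1 / t_slow, g2 = 1 / t_fast)
    f <- wnls_fit(resid_fn, start, lower, upper)
    if (is.null(best) || (is.finite(f$deviance) && f$deviance < best$deviance)) best <- f
  }
  p <- best$par; se <- best$se
  flags <- character(0)
  if (!best$converged) flags <- c(flags, "non-convergence")
  # label the slow decay 1: swap and flip the weight if needed
  if (p[["g1"]] > p[["g2"]]) {
    p[c("g1", "g2")] <- p[c("g2", "g1")]
    se[c("g1", "g2")] <- se[c("g2", "g1")]
    p[["a"]] <- 1 - p[["a"]]
  }
  if (p[["a"]] <= 1e-6 || p[["a"]] >= 1 - 1e-6) flags <- c(flags, "a-at-bound")

  structure(list(a = p[["a"]], gamma1 = p[["g1"]], gamma2 = p[["g2"]],
                 beta = p[["beta"]],
                 se = c(a = se[["a"]], gamma1 = se[["g1"]],
                        gamma2 = se[["g2"]], beta = se[["beta"]]),
                 redchi2 = best$redchi2, converged = best$converged,
                 flags = flags, squared = squared,
                 q_m_inv = cg$q_m_inv, age_h = cg$age_h),
            class = "dls_fit")
}

#' Collective diffusion coefficients from decay rates across angles
#'
#' Fits `Gamma = D q^2` (weighted linear fit through the origin, the
#' Fickian assumption) separately for the slow and fast decay branch of a
#' set of correlogram fits taken at one sample age.
#'
#' @param fits list of `dls_fit` objects at >= 3 distinct q values.
#' @return one-row [tibble::tibble()] with `age_h`, `D1`, `D1_err`, `D2`,
#'   `D2_err` (m^2/s) and a `flags` list-column.
#' @export
diffusion_from_rates <- function(fits) {
  q <- vapply(fits, function(f) f$q_m_inv, 1)
  if (length(unique(round(q, 3))) < 3) stop("need >= 3 distinct q values")
  flags <- character(0)
  fit_branch <- function(gamma, gerr) {
    w <- if (all(is.finite(gerr)) && all(gerr > 0)) 1 / gerr^2 else rep(1, length(gamma))
    fit <- stats::lm(gamma ~ 0 + I(q^2), weights = w)
    co <- suppressWarnings(summary(fit))$coefficients
    c(D = unname(co[1, 1]), err = unname(co[1, 2]))
  }
  b1 <- fit_branch(vapply(fits, function(f) f$gamma1, 1),
                   vapply(fits, function(f) f$se[["gamma1"]], 1))
  b2 <- fit_branch(vapply(fits, function(f) f$gamma2, 1),
                   vapply(fits, function(f) f$se[["gamma2"]], 1))
  if (b1[["D"]] < 0 || b2[["D"]] < 0) flags <- c(flags, "negative-slope")
  tibble::tibble(age_h = fits[[1]]$age_h,
                 D1 = b1[["D"]], D1_err = b1[["err"]],
                 D2 = b2[["D"]], D2_err = b2[["err"]],
                 flags = list(flags))
}

#' Two-sigmoid kinetics of the DLS diffusion series
#'
#' The long-duration DLS experiment resolves two consecutive kinetic
#' processes in the fast (monomer) diffusion coefficient; its time
#' dependence is therefore described by the sum of two sigmoid functions.
#'
#' @param age_h sample age in hours.
#' @param D diffusion coefficients (m^2/s).
#' @param error optional 1-sigma per point.
#' @param n_components number of sigmoid terms (default 2).
#' @param with_background include a constant offset (default TRUE: the
#'   initial diffusion coefficient).
#' @return a [fit_kinetics()] result.
#' @export
dls_kinetics <- function(age_h, D, error = NULL, n_components = 2L,
                         with_background = TRUE) {
  fit_kinetics(age_h, D, error, n_components = n_components,
               with_background = with_background)
}

#' Full DLS analysis chain on a set of correlograms
#'
#' Groups correlograms by sample age, decomposes each into two decays,
#' extracts `D1`/`D2` per age from the Fickian `Gamma = D q^2` fits, and
#' returns the diffusion time series.
#'
#' @param correlograms list of [correlogram()] objects.
#' @param squared Siegert-squared model (see [fit_correlogram()]).
#' @return tibble with one row per age: `age_h`, `D1`, `D1_err`, `D2`, `D2_err`.
#' @export
analyze_dls_dataset <- function(correlograms, squared = TRUE) {
  ages <- vapply(correlograms, function(cg) cg$age_h, 1)
  out <- lapply(sort(unique(ages)), function(a) {
    fits <- lapply(correlograms[ages == a], fit_correlogram, squared = squared)
    diffusion_from_rates(fits)
  })
  do.call(rbind, out)
}
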