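#' One intermediate-scattering-function curve
#'
#' A resolution-normalized, buffer-corrected spin-echo curve
#' `I(q, tau)/I(q, 0)` versus Fourier time at one momentum transfer and
#' sample age.
#'
#' @param q_A_inv momentum transfer in 1/angstrom.
#' @param tau_ns Fourier times in ns, positive and ascending.
#' @param isf normalized ISF values.
#' @param error per-point 1-sigma.
#' @param age_h sample age in hours.
#' @param is_bragg TRUE if `q` sits on the Bragg peak.
#' @return object of class `isf_curve`.
#' @export
isf_curve <- function(q_A_inv, tau_ns, isf, error = NULL, age_h = NA_real_,
                      is_bragg = FALSE) {
  stopifnot(length(tau_ns) == length(isf))
  if (any(tau_ns <= 0) || any(diff(tau_ns) <= 0)) {
    stop("tau_ns must be positive and ascending")
  }
  structure(list(q_A_inv = q_A_inv, tau_ns = tau_ns, isf = isf,
                 error = error, age_h = age_h, is_bragg = is_bragg),
            class = "isf_curve")
}

#' Mixed coherent/incoherent ISF model
#'
#' `I(tau) = a_coh * I_coh(tau) - a_inc * exp(-gamma_inc tau)` with
#' `I_coh(tau) = s + (1 - s) * exp(-gamma_coh tau)`.  The incoherent term
#' enters with a minus sign (spin-flip polarization factor), which produces
#' the characteristic initial rise of the signal at short Fourier times
#' when `a_inc > 0` and `gamma_inc > gamma_coh`.  The immobile fraction `s`
#' is non-zero only on a Bragg peak, where the crystals contribute a
#' non-decaying coherent plateau.
#'
#' @param tau_ns Fourier times in ns.
#' @param a_coh,a_inc non-negative amplitudes.
#' @param gamma_coh,gamma_inc decay rates in 1/ns (>= 0).
#' @param s immobile (crystal) fraction in `[0, 1]`.
#' @return model values.
#' @export
isf_model <- function(tau_ns, a_coh, a_inc, gamma_coh, gamma_inc, s = 0) {
  stopifnot(gamma_coh >= 0, gamma_inc >= 0)
  i_coh <- s + (1 - s) * exp(-gamma_coh * tau_ns)
  a_coh * i_coh - a_inc * exp(-gamma_inc * tau_ns)
}

#' Constrained fit of an ISF curve
#'
#' Weighted fit of [isf_model()] with the amplitude combination fixed to
#' the measured ISF value at the shortest Fourier time (which must satisfy
#' `tau < 15 ps`): in the default `"difference"` convention
#' `a_coh - a_inc = constraint` (the model value at `tau -> 0+` with `s`
#' folded in), matching the minus sign of the incoherent term; the `"sum"`
#' convention `a_coh + a_inc = constraint` is available as a switch.
#' On a Bragg curve the free-protein coherent rate is *held fixed* at
#' `gamma_free` (from [fickian_interpolate_rate()]) and only the immobile
#' fraction `s`, the amplitudes and the incoherent rate vary, avoiding the
#' `s`/rate degeneracy.
#'
#' @param curve an [isf_curve()].
#' @param constraint the fixed amplitude combination; default: the measured
#'   ISF at the smallest tau.
#' @param gamma_free coherent decay rate in 1/ns; required (fixed) for
#'   Bragg curves, optional initial value otherwise.
#' @param gamma_inc_fixed optional incoherent rate in 1/ns to hold fixed on
#'   Bragg curves (from the same Fickian interpolation), leaving only the
#'   immobile fraction and the amplitude free.
#' @param constraint_mode `"difference"` (default) or `"sum"`.
#' @param tau_max_constraint_ns largest tau admissible for setting the
#'   constraint (default 0.015 ns = 15 ps).
#' @param s_bounds fitting bounds for the immobile fraction.  The physical
#'   parameter lives in `[0, 1]`, but when the per-curve estimates feed a
#'   kinetic series, truncating them at the bounds biases the series ends;
#'   relaxed bounds keep the estimator unbiased there.
#' @return list of class `isf_fit` with the parameters (`a_coh`, `a_inc`,
#'   `gamma_coh`, `gamma_inc`, `s`), `se`, `redchi2`, `converged`, `flags`.
#' @export
fit_isf <- function(curve, constraint = NULL, gamma_free = NULL,
                    gamma_inc_fixed = NULL,
                    constraint_mode = c("difference", "sum"),
                    tau_max_constraint_ns = 0.015, s_bounds = c(0, 1)) {
  constraint_mode <- match.arg(constraint_mode)
  tau <- curve$tau_ns; y <- curve$isf
  if (min(tau) >= tau_max_constraint_ns) {
    stop("no Fourier time below ", tau_max_constraint_ns,
         " ns available to set the amplitude constraint")
  }
  # average all points below the cut: the constraint is the model value at
  # tau -> 0+, and using every admissible echo point reduces its noise
  if (is.null(constraint)) constraint <- mean(y[tau < tau_max_constraint_ns])
  if (curve$is_bragg && is.null(gamma_free)) {
    stop("Bragg curves require a fixed gamma_free from the adjacent q values")
  }
  w <- if (is.null(curve$error) || any(!is.finite(curve$error)) ||
           any(curve$error <= 0)) rep(1, length(y)) else 1 / curve$error

  amp <- function(a_inc) {
    if (constraint_mode == "difference") constraint + a_inc else constraint - a_inc
  }
  if (curve$is_bragg) {
    # a_coh stays tied by the constraint (I_coh -> 1 at tau -> 0 for any s),
    # the free-protein coherent rate is always fixed; the incoherent rate is
    # either fixed from the same interpolation or co-fitted
    if (!is.null(gamma_inc_fixed)) {
      resid_fn <- function(p) {
        m <- isf_model(tau, amp(p[1]), p[1], gamma_free, gamma_inc_fixed, p[2])
        (y - m) * w
      }
      start <- c(a_inc = 0.2, s = mean(s_bounds))
      lower <- c(0, s_bounds[1]); upper <- c(5, s_bounds[2])
    } else {
      resid_fn <- function(p) {
        m <- isf_model(tau, amp(p[1]), p[1], gamma_free, p[2], p[3])
        (y - m) * w
      }
      start <- c(a_inc = 0.2, gamma_inc = 5, s = mean(pmin(pmax(s_bounds, 0), 1)))
      lower <- c(0, 0, s_bounds[1]); upper <- c(5, 1e3, s_bounds[2])
    }
  } else if (!is.null(gamma_inc_fixed)) {
    resid_fn <- function(p) {
      m <- isf_model(tau, amp(p[1]), p[1], p[2], gamma_inc_fixed, 0)
      (y - m) * w
    }
    g0 <- if (is.null(gamma_free)) 0.5 else gamma_free
    start <- c(a_inc = 0.2, gamma_coh = g0)
    lower <- c(0, 0); upper <- c(5, 1e3)
  } else {
    resid_fn <- function(p) {
      m <- isf_model(tau, amp(p[1]), p[1], p[2], p[3], 0)
      (y - m) * w
    }
    g0 <- if (is.null(gamma_free)) 0.5 else gamma_free
    start <- c(a_inc = 0.2, gamma_coh = g0, gamma_inc = 5)
    lower <- c(0, 0, 0); upper <- c(5, 1e3, 1e3)
  }
  fit <- wnls_fit(resid_fn, start, lower, upper)
  flags <- if (fit$converged) character(0) else "non-convergence"
  p <- fit$par; se <- fit$se
  if (curve$is_bragg) {
    g_inc <- if (is.null(gamma_inc_fixed)) p[["gamma_inc"]] else gamma_inc_fixed
    g_inc_se <- if (is.null(gamma_inc_fixed)) se[["gamma_inc"]] else 0
    out <- list(a_coh = amp(p[["a_inc"]]), a_inc = p[["a_inc"]],
                gamma_coh = gamma_free, gamma_inc = g_inc,
                s = p[["s"]],
                se = c(a_coh = se[["a_inc"]], a_inc = se[["a_inc"]],
                       gamma_coh = 0, gamma_inc = g_inc_se,
                       s = se[["s"]]))
  } else {
    g_inc <- if (is.null(gamma_inc_fixed)) p[["gamma_inc"]] else gamma_inc_fixed
    g_inc_se <- if (is.null(gamma_inc_fixed)) se[["gamma_inc"]] else 0
    out <- list(a_coh = amp(p[["a_inc"]]), a_inc = p[["a_inc"]],
                gamma_coh = p[["gamma_coh"]], gamma_inc = g_inc,
                s = 0,
                se = c(a_coh = se[["a_inc"]], a_inc = se[["a_inc"]],
                       gamma_coh = se[["gamma_coh"]],
                       gamma_inc = g_inc_se, s = 0))
  }
  structure(c(out, list(constraint = constraint,
                        constraint_mode = constraint_mode,
                        redchi2 = fit$redchi2, converged = fit$converged,
                        flags = flags, q_A_inv = curve$q_A_inv,
                        age_h = curve$age_h, is_bragg = curve$is_bragg)),
            class = "isf_fit")
}

#' Fickian interpolation of the free-protein rate at the Bragg position
#'
#' Weighted fit of `gamma = D q^2` over the non-Bragg neighbours, evaluated
#' at `q_bragg`.
#'
#' @param q_bragg Bragg-peak position in 1/angstrom.
#' @param q,gamma neighbour momentum transfers (1/angstrom) and coherent
#'   rates (1/ns); at least two.
#' @param gamma_err optional 1-sigma on the rates.
#' @return interpolated rate `gamma_free` in 1/ns, with attribute `D`
#'   (angstrom^2/ns).
#' @export
fickian_interpolate_rate <- function(q_bragg, q, gamma, gamma_err = NULL) {
  stopifnot(length(q) == length(gamma))
  if (length(q) < 2) stop("need >= 2 neighbour q values")
  w <- if (is.null(gamma_err)) rep(1, length(q)) else 1 / gamma_err^2
  fit <- stats::lm(gamma ~ 0 + I(q^2), weights = w)
  D <- unname(stats::coef(fit)[1])
  structure(D * q_bragg^2, D = D)
}

#' Crystal-fraction kinetics from the NSE immobile fraction
#'
#' Turns the fitted immobile fractions `s(t)` into the normalized crystal
#' fraction `c_NSE(t)`: the value at the first time point is subtracted,
#' the series is scaled so its maximum becomes 1, and a single sigmoid with
#' free amplitude is fitted to extract `t0` and `dt`.
#'
#' @param age_h sample ages in hours (>= 4 points).
#' @param s immobile fractions.
#' @param error optional 1-sigma per point.
#' @param redchi2_flag threshold on the reduced chi-square above which the
#'   fit is flagged.
#' @return list with `series` (tibble `age_h`, `fraction`, `error`), `fit`
#'   (a [fit_kinetics()] result) and `flags`.
#' @export
nse_crystal_series <- function(age_h, s, error = NULL, redchi2_flag = 10) {
  stopifnot(length(age_h) >= 4, length(s) == length(age_h))
  o <- order(age_h)
  age_h <- age_h[o]; s <- s[o]
  if (!is.null(error)) error <- error[o]
  y <- s - s[1]
  flags <- character(0)
  sc <- max(abs(y))
  if (sc == 0) {
    flags <- c(flags, "degenerate-normalization")
    sc <- 1
  }
  y <- y / sc
  err <- if (is.null(error)) NULL else error / sc
  # free scale and free offset: the t = 0 reference value is itself noisy
  fit <- fit_kinetics(age_h, y, err, n_components = 1L, with_background = TRUE)
  if (is.finite(fit$redchi2) && fit$redchi2 > redchi2_flag) {
    flags <- c(flags, "poor-fit")
  }
  flags <- union(flags, fit$flags)
  list(series = tibble::tibble(age_h = age_h, fraction = y,
                               error = if (is.null(err)) NA_real_ else err),
       fit = fit, flags = flags, label = "c_NSE")
}

#' Full NSE analysis chain
#'
#' For each sample age: fit all non-Bragg curves with `s = 0`, interpolate
#' the free-protein rate to the Bragg position assuming Fickian diffusion,
#' fit the Bragg curve for the immobile fraction `s`, then summarize
#' `s(t)` as the normalized crystal fraction `c_NSE(t)` with its sigmoid
#' kinetics.
#'
#' @param curves list of [isf_curve()] objects (one Bragg curve per age).
#' @param constraint_mode see [fit_isf()].
#' @param pool_rates estimate the free-protein rates once from all ages
#'   (error-weighted; default) instead of per age.  The immobile fraction
#'   responds strongly to the fixed rate, and the free-protein diffusion
#'   varies slowly compared with the crystallization, so pooling
#'   stabilizes `s(t)` considerably.
#' @return list with `s_series` (tibble `age_h`, `s`, `s_err`), `crystal`
#'   (result of [nse_crystal_series()]) and `fits` (all per-curve fits).
#' @export
analyze_nse_dataset <- function(curves, constraint_mode = "difference",
                                pool_rates = TRUE) {
  ages <- vapply(curves, function(cv) cv$age_h, 1)
  uages <- sort(unique(ages))
  all_fits <- list()

  # interpolate a rate to q_bragg from neighbour fits, screening out
  # neighbours whose own rate is essentially undetermined
  interp <- function(qb, qn, g, gse) {
    ok <- is.finite(g) & is.finite(gse) & gse > 0 & gse / pmax(g, 1e-12) < 0.5
    if (sum(ok) < 2) ok <- is.finite(g) & is.finite(gse) & gse > 0
    if (sum(ok) < 2) ok <- rep(TRUE, length(g))
    as.numeric(fickian_interpolate_rate(qb, qn[ok], g[ok],
                                        pmax(gse[ok], 1e-12)))
  }

  # pass 1: unconstrained free-curve fits everywhere; at low q the slow
  # incoherent decay is degenerate with the coherent one, so the first
  # pass only serves to pin down the incoherent (self) rate at high q
  pass1 <- lapply(uages, function(a) {
    cs <- curves[ages == a]
    bragg <- vapply(cs, function(cv) isTRUE(cv$is_bragg), TRUE)
    if (sum(bragg) != 1) stop("need exactly one Bragg curve per age")
    lapply(cs[!bragg], fit_isf, constraint_mode = constraint_mode)
  })
  qb <- curves[[which(vapply(curves, function(cv) isTRUE(cv$is_bragg), TRUE))[1]]]$q_A_inv

  gi_age <- vapply(seq_along(uages), function(i) {
    ff <- pass1[[i]]
    qn <- vapply(ff, function(f) f$q_A_inv, 1)
    interp(qb, qn, vapply(ff, function(f) f$gamma_inc, 1),
           vapply(ff, function(f) f$se[["gamma_inc"]], 1))
  }, 1)
  if (pool_rates) gi_age <- rep(stats::median(gi_age), length(uages))

  # pass 2: refit the free curves with the incoherent rate fixed to its
  # Fickian interpolation, removing the low-q rate degeneracy, then
  # interpolate the coherent rate to the Bragg position
  free_by_age <- lapply(seq_along(uages), function(i) {
    cs <- curves[ages == uages[i]]
    bragg <- vapply(cs, function(cv) isTRUE(cv$is_bragg), TRUE)
    lapply(cs[!bragg], function(cv) {
      fit_isf(cv, gamma_inc_fixed = gi_age[i] * (cv$q_A_inv / qb)^2,
              constraint_mode = constraint_mode)
    })
  })
  gf_age <- vapply(seq_along(uages), function(i) {
    ff <- free_by_age[[i]]
    qn <- vapply(ff, function(f) f$q_A_inv, 1)
    interp(qb, qn, vapply(ff, function(f) f$gamma_coh, 1),
           vapply(ff, function(f) f$se[["gamma_coh"]], 1))
  }, 1)
  if (pool_rates) gf_age <- rep(stats::median(gf_age), length(uages))

  rows <- lapply(seq_along(uages), function(i) {
    a <- uages[i]
    cs <- curves[ages == a]
    bragg <- vapply(cs, function(cv) isTRUE(cv$is_bragg), TRUE)
    bf <- fit_isf(cs[bragg][[1]], gamma_free = gf_age[i],
                  gamma_inc_fixed = gi_age[i],
                  constraint_mode = constraint_mode,
                  s_bounds = c(-0.5, 1.5))
    all_fits[[length(all_fits) + 1]] <<- c(free_by_age[[i]], list(bf))
    tibble::tibble(age_h = a, s = bf$s, s_err = bf$se[["s"]])
  })
  s_series <- do.call(rbind, rows)
  # points stuck at the s bounds report zero curvature uncertainty; treat
  # them as no better than the worst regular point rather than as exact
  err <- s_series$s_err
  ok <- is.finite(err) & err > 0
  if (any(ok)) err[!ok] <- max(err[ok]) else err <- NULL
  crystal <- nse_crystal_series(s_series$age_h, s_series$s, err)
  list(s_series = s_series, crystal = crystal, fits = all_fits)
}
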