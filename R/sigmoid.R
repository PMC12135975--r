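#' Logistic (sigmoid) growth component
#'
#' The universal kinetic descriptor of the crystallization process:
#' `f(t) = f0 / (1 + exp(-(t - t0) / dt))`.
#' `f0` is the saturation amplitude (negative for a decaying contribution),
#' `t0` the inflection time at which growth is fastest, and `dt` the
#' characteristic time; the maximum rate is `f'(t0) = f0 / (4 dt)`.
#'
#' @param f0 amplitude in the observable's units.
#' @param t0 inflection time in hours.
#' @param dt characteristic time in hours (> 0).
#' @return object of class `sigmoid_component`.
#' @export
#' @examples
#' sc <- sigmoid_component(1, 40, 10)
#' sigmoid_eval(40, sc)   # f0/2
sigmoid_component <- function(f0, t0, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive finite number")
  structure(list(f0 = f0, t0 = t0, dt = dt), class = "sigmoid_component")
}

#' Evaluate a sigmoid component
#'
#' @param t time in hours (vector).
#' @param comp a [sigmoid_component()].
#' @return model values at `t`.
#' @export
sigmoid_eval <- function(t, comp) {
  if (!inherits(comp, "sigmoid_component")) comp <- do.call(sigmoid_component, as.list(comp))
  comp$f0 * stats::plogis((t - comp$t0) / comp$dt)
}

#' Multi-component kinetic model
#'
#' A sum of one or more sigmoid components plus a constant background.
#' The model tends to `background` for `t -> -Inf` and to
#' `background + sum(f0)` for `t -> +Inf`.
#'
#' @param components list of [sigmoid_component()] objects (at least one).
#' @param background constant offset in observable units.
#' @return object of class `kinetic_model`.
#' @export
kinetic_model <- function(components, background = 0) {
  if (inherits(components, "sigmoid_component")) components <- list(components)
  if (length(components) < 1) stop("at least one component required")
  components <- lapply(components, function(co) {
    if (inherits(co, "sigmoid_component")) co else do.call(sigmoid_component, as.list(co))
  })
  structure(list(components = components, background = background),
            class = "kinetic_model")
}

#' Evaluate a kinetic model
#'
#' @param t time in hours.
#' @param model a [kinetic_model()].
#' @return model values at `t`.
#' @export
kinetic_eval <- function(t, model) {
  out <- rep(model$background, length(t))
  for (comp in model$components) out <- out + sigmoid_eval(t, comp)
  out
}

# pack/unpack between a kinetic_model and a named parameter vector
.kin_par_names <- function(n_components, with_background) {
  nm <- as.vector(vapply(seq_len(n_components), function(i)
    paste0(c("f0_", "t0_", "dt_"), i), character(3)))
  if (with_background) nm <- c(nm, "bg")
  nm
}

.kin_unpack <- function(par, n_components, with_background) {
  comps <- lapply(seq_len(n_components), function(i) {
    sigmoid_component(par[[3 * i - 2]], par[[3 * i - 1]], max(par[[3 * i]], 1e-12))
  })
  bg <- if (with_background) par[[3 * n_components + 1]] else 0
  kinetic_model(comps, bg)
}

# heuristic starting values: t0 at the steepest finite-difference slope,
# dt = span/10, f0 = net change; for several components the span is split
.kin_init <- function(time, value, n_components, with_background) {
  span <- diff(range(time))
  o <- order(time)
  tt <- time[o]; yy <- value[o]
  sl <- diff(yy) / pmax(diff(tt), 1e-12)
  tm <- (tt[-1] + tt[-length(tt)]) / 2
  par <- numeric(0)
  edges <- seq(min(time), max(time), length.out = n_components + 1)
  at_time <- function(t) yy[which.min(abs(tt - t))]
  for (i in seq_len(n_components)) {
    inwin <- tm >= edges[i] & tm <= edges[i + 1]
    t0i <- if (any(inwin)) tm[inwin][which.max(abs(sl[inwin]))] else mean(edges[i:(i + 1)])
    # net change across the window carries the component's sign
    f0i <- at_time(edges[i + 1]) - at_time(edges[i])
    if (abs(f0i) < 1e-12) f0i <- diff(range(yy)) / n_components + 1e-12
    par <- c(par, f0i, t0i, span / 10)
  }
  if (with_background) par <- c(par, yy[1])
  stats::setNames(par, .kin_par_names(n_components, with_background))
}

#' Fit sigmoid kinetics to a time trace
#'
#' Weighted least-squares fit of a sum of `n_components` logistic growth
#' terms (plus an optional constant background) to an observable measured
#' over sample age.  Uncertainties come from the local covariance of the
#' Levenberg-Marquardt fit scaled by the reduced chi-square.  Components
#' are returned sorted by inflection time `t0`.  Multi-component fits use
#' multiple jittered starts to avoid label switching and local minima.
#'
#' @param time sample age in hours.
#' @param value observable.
#' @param error optional 1-sigma per point (> 0); when supplied the fit is
#'   error-weighted, otherwise unweighted.
#' @param n_components number of sigmoid terms.
#' @param with_background fit a constant background term as well.
#' @param init optional named start vector (`f0_1, t0_1, dt_1, ..., bg`).
#' @param n_starts number of jittered restarts for multi-component fits.
#' @return object of class `kinetic_fit`: a list with `model`
#'   ([kinetic_model()]), `par`, `se`, `cov`, `redchi2`, `converged`,
#'   `flags` (character), and the data used.
#' @export
#' @examples
#' t <- seq(0, 100, length.out = 50)
#' y <- sigmoid_eval(t, sigmoid_component(1, 40, 10))
#' fit_kinetics(t, y)$par
fit_kinetics <- function(time, value, error = NULL, n_components = 1L,
                         with_background = FALSE, init = NULL, n_starts = 5L) {
  stopifnot(length(time) == length(value))
  if (!is.null(error)) {
    stopifnot(length(error) == length(value), all(error > 0))
  }
  npar <- 3L * n_components + as.integer(with_background)
  if (length(time) < npar + 1L) {
    stop("need at least ", npar + 1L, " points for ", npar, " free parameters")
  }
  flags <- character(0)
  if (stats::sd(value) == 0) flags <- c(flags, "degenerate-data")

  # normalize the observable scale so amplitudes and times are of
  # comparable magnitude inside the optimizer (rescaled back afterwards)
  y_scale <- max(abs(value), .Machine$double.eps)
  raw_value <- value; raw_error <- error
  value <- value / y_scale
  if (!is.null(error)) error <- error / y_scale

  span <- diff(range(time))
  w <- if (is.null(error)) rep(1, length(value)) else 1 / error
  resid_fn <- function(p) {
    m <- .kin_unpack(p, n_components, with_background)
    (value - kinetic_eval(time, m)) * w
  }

  lower <- rep(c(-Inf, min(time) - span, 1e-6 * span), n_components)
  upper <- rep(c(Inf, max(time) + span, span), n_components)
  if (with_background) { lower <- c(lower, -Inf); upper <- c(upper, Inf) }

  start0 <- if (is.null(init)) .kin_init(time, value, n_components, with_background)
            else stats::setNames(as.numeric(init), .kin_par_names(n_components, with_background))
  starts <- list(start0)
  if (is.null(init)) {
    # deterministic restarts: scatter the inflection times over the window
    # and rescale amplitudes/widths by fixed factors (no RNG involved)
    amp_fac <- c(0.5, 1.5, 1, 0.75, 1.25)
    for (k in seq_len(n_starts - 1L)) {
      s <- start0
      probs <- (seq_len(n_components) - 0.5) / n_components
      shift <- (k - (n_starts - 1) / 2) / n_starts
      for (i in seq_len(n_components)) {
        s[[3 * i - 1]] <- min(time) + span * min(max(probs[i] + shift, 0.02), 0.98)
        s[[3 * i - 2]] <- s[[3 * i - 2]] * amp_fac[(k + i) %% length(amp_fac) + 1]
        s[[3 * i]] <- s[[3 * i]] * amp_fac[k %% length(amp_fac) + 1]
      }
      if (k %% 2 == 0 && n_components > 1L) s[[1]] <- -s[[1]]
      starts[[k + 1L]] <- pmin(pmax(s, lower + 1e-9), upper - 1e-9)
    }
    if (n_components == 2L) {
      # coarse grid over inflection-time placement and the sign of the
      # first component, to catch decay-then-growth shapes
      rng <- diff(range(value))
      for (sgn in c(1, -1)) for (pp in list(c(0.1, 0.5), c(0.2, 0.7),
                                            c(0.35, 0.85))) {
        s <- start0
        s[[1]] <- sgn * rng; s[[4]] <- rng
        s[[2]] <- min(time) + span * pp[1]
        s[[5]] <- min(time) + span * pp[2]
        s[[3]] <- s[[6]] <- span / 15
        starts[[length(starts) + 1L]] <- pmin(pmax(s, lower + 1e-9),
                                              upper - 1e-9)
      }
    }
  }

  best <- NULL
  for (s in starts) {
    f <- wnls_fit(resid_fn, s, lower, upper)
    if (is.null(best) || (is.finite(f$deviance) &&
                          (!is.finite(best$deviance) || f$deviance < best$deviance))) {
      best <- f
    }
  }
  if (!best$converged) flags <- c(flags, "non-convergence")

  # sort components by t0 and permute parameters/covariance to match
  ord <- order(vapply(seq_len(n_components), function(i) best$par[[3 * i - 1]], 1))
  perm <- as.vector(vapply(ord, function(i) (3 * i - 2):(3 * i), integer(3)))
  if (with_background) perm <- c(perm, npar)
  nms <- .kin_par_names(n_components, with_background)
  par <- stats::setNames(best$par[perm], nms)
  se <- stats::setNames(best$se[perm], nms)
  cov <- best$cov[perm, perm, drop = FALSE]
  dimnames(cov) <- list(nms, nms)

  # undo the observable-scale normalization on amplitude-like parameters
  amp_idx <- 3 * seq_len(n_components) - 2
  if (with_background) amp_idx <- c(amp_idx, npar)
  par[amp_idx] <- par[amp_idx] * y_scale
  se[amp_idx] <- se[amp_idx] * y_scale
  cov[amp_idx, ] <- cov[amp_idx, , drop = FALSE] * y_scale
  cov[, amp_idx] <- cov[, amp_idx, drop = FALSE] * y_scale

  model <- .kin_unpack(par, n_components, with_background)
  structure(list(model = model, par = par, se = se, cov = cov,
                 redchi2 = best$redchi2, converged = best$converged,
                 flags = flags, nobs = length(raw_value), npar = npar,
                 time = time, value = raw_value, error = raw_error),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Sigmoid kinetic fit:", length(x$model$components), "component(s)")
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  tab <- data.frame(estimate = signif(x$par, 5), se = signif(x$se, 3))
  print(tab)
  cat("reduced chi-square:", signif(x$redchi2, 4), "\n")
  invisible(x)
}

#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time else newdata
  kinetic_eval(t, object$model)
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$value - kinetic_eval(object$time, object$model)
}
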