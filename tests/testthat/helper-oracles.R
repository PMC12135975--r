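# independent oracles used across the tests

# five-point central numeric derivative
num_deriv <- function(f, x, h = 1e-3) {
  (-f(x + 2 * h) + 8 * f(x + h) - 8 * f(x - h) + f(x - 2 * h)) / (12 * h)
}

# brute-force grid search for the double-exponential correlogram model
# (beta held at its true value); returns the best grid point
dls_grid_search <- function(lag, y, beta, a_grid, g1_grid, g2_grid) {
  best <- NULL
  for (a in a_grid) for (g1 in g1_grid) for (g2 in g2_grid) {
    if (g1 > g2) next
    m <- beta * (a * exp(-g1 * lag) + (1 - a) * exp(-g2 * lag))^2
    ss <- sum((y - m)^2)
    if (is.null(best) || ss < best$ss) best <- list(a = a, g1 = g1, g2 = g2, ss = ss)
  }
  best
}

# unconstrained ISF fit with a quadratic penalty enforcing
# a_coh - a_inc = constraint (Lagrange-style route, independent of the
# constrained parameterization used by fit_isf)
isf_penalty_fit <- function(tau, y, constraint, lambda = 1e8) {
  obj <- function(p) {
    m <- p[1] * exp(-p[3] * tau) - p[2] * exp(-p[4] * tau)
    sum((y - m)^2) + lambda * (p[1] - p[2] - constraint)^2
  }
  fit <- stats::optim(c(0.8, 0.2, 0.5, 5), obj, method = "L-BFGS-B",
                      lower = c(0, 0, 0, 0), upper = c(5, 5, 100, 100),
                      control = list(maxit = 2000, factr = 10))
  stats::setNames(fit$par, c("a_coh", "a_inc", "gamma_coh", "gamma_inc"))
}

# exact Lorentzian fixed-window ratio inverted by brute-force root finding
# (independent of the closed form)
gamma_root_oracle <- function(R, omega1 = 1, omega3 = 3) {
  stats::uniroot(function(g) (omega3^2 + g^2) / (omega1^2 + g^2) - R,
                 lower = 1e-8, upper = 1e6, tol = 1e-14)$root
}
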