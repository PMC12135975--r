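# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.truth <- function(modality, parameters, seed, noise) {
  list(modality = modality, parameters = parameters, seed = seed,
       noise = noise)
}

#' Simulate a sigmoid kinetic trace
#'
#' Forward model of the logistic crystallization kinetics with additive
#' Gaussian noise; the ground truth travels with the data.
#'
#' @param components list of [sigmoid_component()]s.
#' @param background constant offset.
#' @param noise_sd additive Gaussian sigma (0 for noiseless).
#' @param n number of points.
#' @param span length-2 time window in hours.
#' @param seed RNG seed.
#' @return tibble `time_h`, `value`, `error` with attribute `truth`.
#' @export
#' @examples
#' tr <- gen_kinetic_trace(list(sigmoid_component(1, 40, 10)), seed = 1)
gen_kinetic_trace <- function(components, background = 0, noise_sd = 0.03,
                              n = 60, span = c(0, 100), seed = 1) {
  model <- kinetic_model(components, background)
  time <- seq(span[1], span[2], length.out = n)
  clean <- kinetic_eval(time, model)
  value <- .with_seed(seed, clean + stats::rnorm(n, 0, noise_sd))
  out <- tibble::tibble(time_h = time, value = value,
                        error = rep(max(noise_sd, 1e-12), n))
  attr(out, "truth") <- .truth("kinetics", list(model = model), seed,
                               sprintf("additive Gaussian sd = %g", noise_sd))
  out
}

#' Default DLS kinetic truth: monomer diffusion with two growth steps
#'
#' The fast (monomer) collective diffusion coefficient rises in two
#' consecutive sigmoid steps while the slow (cluster) coefficient
#' decreases; amplitudes and characteristic times mimic the long-duration
#' DLS experiment on the crystallizing albumin solution.
#'
#' @return list of functions `D1`, `D2`, `a` of time (hours) and the
#'   underlying `d2_components`.
#' @export
dls_default_truth <- function() {
  d2_comp <- list(sigmoid_component(0.6e-11, 96.93, 3.21),
                  sigmoid_component(1.0e-11, 108.19, 14.65))
  list(
    D2 = function(t) 3.5e-11 + kinetic_eval(t, kinetic_model(d2_comp)),
    D1 = function(t) 8e-12 * (1 - 0.5 * stats::plogis((t - 100) / 10)),
    a = function(t) rep(0.4, length(t)),
    d2_components = d2_comp,
    d2_background = 3.5e-11
  )
}

#' Simulate a DLS dataset
#'
#' Siegert-squared double-exponential correlograms with Fickian rates
#' `Gamma_i = D_i(t) q^2` over the goniometer's angular range, with
#' multiplicative Gaussian noise.
#'
#' @param ages_h sample ages in hours (default: half-hour cadence over a
#'   week, the experiment's kinetic resolution).
#' @param truth list of functions `D1(t)`, `D2(t)`, `a(t)` (m^2/s and
#'   weight); default [dls_default_truth()].
#' @param angles_deg scattering angles.
#' @param lambda_m,n_ref wavelength and refractive index.
#' @param lag_s lag-time grid in seconds.
#' @param beta intercept of the correlation function.
#' @param noise relative (multiplicative) noise level.
#' @param seed RNG seed.
#' @return list of [correlogram()]s with attribute `truth`.
#' @export
gen_dls_dataset <- function(ages_h = seq(0, 160, by = 0.5),
                            truth = dls_default_truth(),
                            angles_deg = seq(30, 150, by = 10),
                            lambda_m = 633e-9, n_ref = 1.333,
                            lag_s = exp(seq(log(1e-6), log(1), length.out = 60)),
                            beta = 0.8, noise = 0.01, seed = 1) {
  out <- .with_seed(seed, {
    res <- list()
    for (age in ages_h) {
      d1 <- truth$D1(age); d2 <- truth$D2(age); aa <- truth$a(age)[1]
      stopifnot(d2 >= d1, d1 > 0)
      for (ang in angles_deg) {
        q <- q_from_angle_light(ang, lambda_m, n_ref)
        g1 <- d1 * q^2; g2 <- d2 * q^2
        clean <- .dls_model(lag_s, beta, aa, g1, g2, squared = TRUE)
        y <- clean * (1 + stats::rnorm(length(lag_s), 0, noise))
        cg <- correlogram(ang, lag_s, y,
                          error = pmax(abs(clean) * noise, 1e-6),
                          age_h = age, lambda_m = lambda_m, n = n_ref)
        res[[length(res) + 1L]] <- cg
      }
    }
    res
  })
  attr(out, "truth") <- .truth("dls", truth, seed,
                               sprintf("multiplicative Gaussian %g", noise))
  out
}

#' Default NSE truth for the crystallizing sample
#'
#' Coherent Fickian diffusion on the nanosecond scale with coherent
#' scattering dominating at low q and incoherent above 0.3 1/angstrom,
#' and an immobile fraction at the Bragg position growing sigmoidally.
#' The incoherent (self-correlation) signal relaxes much faster than the
#' coherent one — rotational and internal motions add to self-diffusion —
#' producing the characteristic subnanosecond initial rise of the mixed
#' signal; `D_inc` is therefore an effective relaxation constant well
#' above the center-of-mass value.
#'
#' @return list with `D_coh`, `D_inc` (angstrom^2/ns), amplitude functions
#'   `a_coh(q)`, `a_inc(q)`, the immobile-fraction function `s(t)` and its
#'   `s_component`.
#' @export
nse_default_truth <- function() {
  s_comp <- sigmoid_component(0.75, 45.24, 11.65)
  # the Bragg reflection enhances the coherent fraction at q = 0.149
  q_ref <- c(0.10, 0.13, 0.149, 0.21, 0.30)
  ac <- c(0.90, 0.75, 0.80, 0.35, 0.20)
  ai <- c(0.08, 0.12, 0.12, 0.30, 0.45)
  list(D_coh = 3, D_inc = 80,
       a_coh = function(q) stats::approx(q_ref, ac, q, rule = 2)$y,
       a_inc = function(q) stats::approx(q_ref, ai, q, rule = 2)$y,
       s = function(t) sigmoid_eval(t, s_comp),
       s_component = s_comp)
}

#' Simulate an NSE dataset
#'
#' Intermediate scattering functions with mixed coherent/incoherent
#' exponential decays entering with opposite signs; the Bragg curve mixes
#' in the immobile crystal fraction `s(t)`.  Additive Gaussian noise.
#'
#' @param ages_h sample ages (default: two-hour spectra).
#' @param truth see [nse_default_truth()].
#' @param q_free non-Bragg momentum transfers in 1/angstrom.
#' @param q_bragg Bragg-peak position.
#' @param tau_ns Fourier-time grid (must reach below 15 ps).
#' @param noise additive Gaussian sigma.
#' @param seed RNG seed.
#' @return list of [isf_curve()]s with attribute `truth`.
#' @export
gen_nse_dataset <- function(ages_h = seq(0, 80, by = 2),
                            truth = nse_default_truth(),
                            q_free = c(0.10, 0.13, 0.21, 0.30),
                            q_bragg = 0.149,
                            tau_ns = exp(seq(log(0.005), log(10), length.out = 30)),
                            noise = 0.03, seed = 1) {
  out <- .with_seed(seed, {
    res <- list()
    for (age in ages_h) {
      s_now <- truth$s(age)
      for (q in c(q_free, q_bragg)) {
        is_bragg <- q == q_bragg
        g_coh <- truth$D_coh * q^2
        g_inc <- truth$D_inc * q^2
        clean <- isf_model(tau_ns, truth$a_coh(q), truth$a_inc(q),
                           g_coh, g_inc, s = if (is_bragg) s_now else 0)
        y <- clean + stats::rnorm(length(tau_ns), 0, noise)
        res[[length(res) + 1L]] <- isf_curve(q, tau_ns, y,
                                             error = rep(noise, length(tau_ns)),
                                             age_h = age, is_bragg = is_bragg)
      }
    }
    res
  })
  attr(out, "truth") <- .truth("nse", truth, seed,
                               sprintf("additive Gaussian sd = %g", noise))
  out
}

#' Default backscattering truth
#'
#' A slight slowing down of the effective short-time diffusion coefficient
#' and a sigmoidally growing elastic fraction on top of a constant
#' container contribution.
#'
#' @return list with functions `D(t)` (angstrom^2/ns), `c_e(t)` (elastic
#'   spectral weight), the linewidth offset `c_gamma` (ueV), and the
#'   `ce_component`.
#' @export
fws_default_truth <- function() {
  ce_comp <- sigmoid_component(0.4, 40.0, 11.48)
  list(D = function(t) 4 - 0.4 * stats::plogis((t - 40) / 11.48),
       c_e = function(t) 0.25 + sigmoid_eval(t, ce_comp),
       c_gamma = 0.3,
       ce_component = ce_comp)
}

#' Simulate a fixed-window-scan dataset
#'
#' For every time and q the spectrum is an elastic line of weight `c_e(t)`
#' plus a resolution-convolved Lorentzian of weight `1 - c_e(t)` and half
#' width `gamma = hbar D(t) q^2 + c_gamma`; the three fixed windows sample
#' it at 0, `omega1` and `omega3` ueV.  Poisson counting noise at
#' `counts_scale` mean counts per unit spectral density.
#'
#' @param times_h kinetic time grid (default: half-hour cadence).
#' @param truth see [fws_default_truth()].
#' @param q_A_inv q grid in 1/angstrom.
#' @param resolution a [resolution_model()].
#' @param omega1,omega3 inelastic offsets in ueV.
#' @param counts_scale mean counts per unit spectral density (0 disables
#'   noise).
#' @param seed RNG seed.
#' @return list of [fws_frame()]s with attribute `truth`.
#' @export
gen_fws_dataset <- function(times_h = seq(0, 80, by = 0.5),
                            truth = fws_default_truth(),
                            q_A_inv = seq(0.2, 1.9, by = 0.05),
                            resolution = resolution_model(),
                            omega1 = 1, omega3 = 3,
                            counts_scale = 1e4, seed = 1) {
  hbar <- unit_constants$hbar_uev_ns
  out <- .with_seed(seed, {
    res <- list()
    for (tt in times_h) {
      ce <- truth$c_e(tt)
      gam <- hbar * truth$D(tt) * q_A_inv^2 + truth$c_gamma
      qe <- 1 - ce
      # the inelastic windows sit outside the instrument resolution, so the
      # elastic line contributes to the elastic channel only
      I0 <- ce * resolution$r0 + qe * conv_lorentz_gauss(0, gam, resolution)
      I1 <- qe * conv_lorentz_gauss(omega1, gam, resolution)
      I3 <- qe * conv_lorentz_gauss(omega3, gam, resolution)
      if (counts_scale > 0) {
        I0 <- stats::rpois(length(I0), I0 * counts_scale) / counts_scale
        I1 <- stats::rpois(length(I1), I1 * counts_scale) / counts_scale
        I3 <- stats::rpois(length(I3), I3 * counts_scale) / counts_scale
      }
      err <- function(x) sqrt(pmax(x, 1 / counts_scale^2) / counts_scale)
      res[[length(res) + 1L]] <- fws_frame(tt, q_A_inv, I0, I1, I3,
                                           err0 = err(I0), err1 = err(I1),
                                           err3 = err(I3),
                                           omega1 = omega1, omega3 = omega3)
    }
    res
  })
  attr(out, "truth") <- .truth("fws", truth, seed,
                               sprintf("Poisson, %g counts/unit density",
                                       counts_scale))
  out
}

#' Default diffraction truth
#'
#' A Gaussian Bragg peak whose integrated area grows sigmoidally on a
#' power-law baseline whose low-q amplitude follows its own (slower)
#' sigmoid, reproducing the distinct kinetics of the Bragg-peak and low-q
#' channels.
#'
#' @return list with `peak_center`, `peak_sigma`, `peak_area(t)` and its
#'   `peak_component`, `baseline(q, t)` and the low-q `lowq_component`.
#' @export
diffraction_default_truth <- function() {
  peak_comp <- sigmoid_component(1, 48.98, 7.15)
  lowq_comp <- sigmoid_component(0.8, 74.20, 13.47)
  list(peak_center = 0.15, peak_sigma = 0.008,
       peak_area = function(t) sigmoid_eval(t, peak_comp),
       peak_component = peak_comp,
       baseline = function(q, t) {
         0.002 * q^-2 * (1 + sigmoid_eval(t, lowq_comp))
       },
       lowq_component = lowq_comp)
}

# Gaussian wavelength-spread smearing: convolve I(q) with a Gaussian of
# sigma = q * dll / 2.3548 (FWHM relative width dll), row-normalized
.smear_matrix <- function(q, dll) {
  sig <- pmax(q * dll / (2 * sqrt(2 * log(2))), 1e-9)
  K <- outer(seq_along(q), seq_along(q),
             function(i, j) stats::dnorm(q[j], q[i], sig[i]))
  K / rowSums(K)
}

#' Simulate an in situ diffraction movie
#'
#' @param times_h kinetic time grid.
#' @param truth see [diffraction_default_truth()].
#' @param q_A_inv q grid.
#' @param dll optional relative wavelength spread (e.g. 0.08) for Gaussian
#'   q-smearing; `NULL` for none.
#' @param noise relative Gaussian noise.
#' @param seed RNG seed.
#' @return list of [diffraction_frame()]s with attribute `truth`.
#' @export
gen_diffraction_series <- function(times_h = seq(0, 100, by = 0.5),
                                   truth = diffraction_default_truth(),
                                   q_A_inv = seq(0.05, 0.25, by = 0.002),
                                   dll = NULL, noise = 0.03, seed = 1) {
  K <- if (!is.null(dll)) .smear_matrix(q_A_inv, dll) else NULL
  dq <- c(diff(q_A_inv), utils::tail(diff(q_A_inv), 1))
  out <- .with_seed(seed, {
    res <- list()
    for (tt in times_h) {
      peak <- truth$peak_area(tt) *
        stats::dnorm(q_A_inv, truth$peak_center, truth$peak_sigma)
      I <- truth$baseline(q_A_inv, tt) + peak
      if (!is.null(K)) I <- as.vector(K %*% I)
      y <- pmax(I * (1 + stats::rnorm(length(I), 0, noise)), 0)
      res[[length(res) + 1L]] <- diffraction_frame(tt, q_A_inv, y,
                                                   error = pmax(I * noise, 1e-9))
    }
    res
  })
  attr(out, "truth") <- .truth("diffraction", truth, seed,
                               sprintf("multiplicative Gaussian %g", noise))
  out
}

#' Simulate per-crystal microscopy area traces (and optional image stacks)
#'
#' Each crystal grows as a sigmoid in projected area with its own
#' `(A0, t0, dt)` drawn from the population distributions; relative
#' Gaussian noise is added to the areas.  Optionally renders square
#' crystals on a pixel grid for the synthetic segmenter.
#'
#' @param n_crystals number of crystals.
#' @param t0_mean,t0_sd population distribution of the inflection time (h).
#' @param dt_mean,dt_sd population distribution of the characteristic time.
#' @param A0_meanlog,A0_sdlog log-normal maximum-area parameters (um^2).
#' @param times_h observation grid (half-hour cadence by default).
#' @param noise relative noise on the areas.
#' @param seed RNG seed.
#' @param images render image stacks as well.
#' @param img_size image side length in pixels.
#' @param pixel_area_um2 area of one pixel.
#' @return tibble `crystal_id`, `time_h`, `area_um2`, `error` with
#'   attributes `truth` and (if requested) `stack`.
#' @export
gen_microscopy <- function(n_crystals = 50, t0_mean = 31.92, t0_sd = 5,
                           dt_mean = 7.08, dt_sd = 1,
                           A0_meanlog = log(300), A0_sdlog = 0.7,
                           times_h = seq(0, 80, by = 0.5), noise = 0.03,
                           seed = 1, images = FALSE, img_size = 256,
                           pixel_area_um2 = 4) {
  out <- .with_seed(seed, {
    if (n_crystals == 0) {
      traces <- tibble::tibble(crystal_id = integer(), time_h = numeric(),
                               area_um2 = numeric(), error = numeric())
      pars <- tibble::tibble(crystal_id = integer(), A0 = numeric(),
                             t0 = numeric(), dt = numeric())
      list(traces = traces, pars = pars, stack = NULL)
    } else {
      pars <- tibble::tibble(
        crystal_id = seq_len(n_crystals),
        A0 = stats::rlnorm(n_crystals, A0_meanlog, A0_sdlog),
        t0 = stats::rnorm(n_crystals, t0_mean, t0_sd),
        dt = pmax(stats::rnorm(n_crystals, dt_mean, dt_sd), 0.5))
      rows <- lapply(seq_len(n_crystals), function(i) {
        a <- sigmoid_eval(times_h, sigmoid_component(pars$A0[i], pars$t0[i],
                                                     pars$dt[i]))
        tibble::tibble(crystal_id = i, time_h = times_h,
                       area_um2 = pmax(a * (1 + stats::rnorm(length(a), 0, noise)), 0),
                       error = pmax(pars$A0[i] * noise, 1e-9))
      })
      traces <- do.call(rbind, rows)
      stack <- NULL
      if (images) {
        # place non-overlapping square crystals on the pixel grid
        margin <- ceiling(sqrt(max(pars$A0) / pixel_area_um2)) + 2
        cx <- round(stats::runif(n_crystals, margin, img_size - margin))
        cy <- round(stats::runif(n_crystals, margin, img_size - margin))
        stack <- lapply(times_h, function(tt) {
          img <- matrix(0, img_size, img_size)
          for (i in seq_len(n_crystals)) {
            a_px <- sigmoid_eval(tt, sigmoid_component(pars$A0[i], pars$t0[i],
                                                       pars$dt[i])) / pixel_area_um2
            side <- floor(sqrt(max(a_px, 0)))
            if (side >= 1) {
              h <- side %/% 2
              xs <- max(1, cx[i] - h):min(img_size, cx[i] - h + side - 1)
              ys <- max(1, cy[i] - h):min(img_size, cy[i] - h + side - 1)
              img[xs, ys] <- 1
            }
          }
          img
        })
      }
      list(traces = traces, pars = pars, stack = stack)
    }
  })
  traces <- out$traces
  attr(traces, "truth") <- .truth(
    "microscopy",
    list(pars = out$pars, t0_mean = t0_mean, t0_sd = t0_sd,
         dt_mean = dt_mean, dt_sd = dt_sd,
         A0_meanlog = A0_meanlog, A0_sdlog = A0_sdlog),
    seed, sprintf("relative Gaussian %g", noise))
  if (images) attr(traces, "stack") <- out$stack
  traces
}
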