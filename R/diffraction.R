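#' One diffraction frame
#'
#' An `I(q)` snapshot at one kinetic time point.
#'
#' @param time_h sample age in hours.
#' @param q_A_inv ascending q grid in 1/angstrom.
#' @param intensity intensities (>= 0).
#' @param error optional 1-sigma.
#' @return object of class `diffraction_frame`.
#' @export
diffraction_frame <- function(time_h, q_A_inv, intensity, error = NULL) {
  stopifnot(length(q_A_inv) == length(intensity))
  if (any(diff(q_A_inv) <= 0)) stop("q grid must be ascending")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(time_h = time_h, q_A_inv = q_A_inv, intensity = intensity,
                 error = error),
            class = "diffraction_frame")
}

#' Locate the Bragg peak in a diffraction frame
#'
#' Subtracts a linear baseline anchored on the window edges, requires the
#' maximum excess to exceed 3 sigma of the off-peak residuals, and refines
#' the peak position by local quadratic interpolation through the maximum
#' and its two neighbours.
#'
#' @param frame a [diffraction_frame()].
#' @param window length-2 q window to search, inside the grid.
#' @return `q_Bragg` in 1/angstrom, with attribute `at_edge` set if the
#'   maximum sits on the window boundary.
#' @export
find_bragg_peak <- function(frame, window) {
  q <- frame$q_A_inv; I <- frame$intensity
  if (window[1] < min(q) || window[2] > max(q)) stop("window outside q grid")
  inwin <- q >= window[1] & q <= window[2]
  qi <- q[inwin]; Ii <- I[inwin]
  if (length(qi) < 3) stop("window too narrow")
  # robust linear baseline through the sub-median window points, so that a
  # peak sitting anywhere in the window (edges included) stands out
  low <- Ii <= stats::median(Ii)
  bfit <- stats::lm(Ii[low] ~ qi[low])
  base <- stats::coef(bfit)[1] + stats::coef(bfit)[2] * qi
  excess <- Ii - base
  noise <- stats::sd(excess[excess <= stats::median(excess)])
  imax <- which.max(excess)
  if (!is.finite(noise)) noise <- 0
  if (excess[imax] <= 3 * max(noise, .Machine$double.eps)) {
    stop("no peak above 3 sigma of the baseline found in the window")
  }
  at_edge <- imax == 1 || imax == length(qi)
  q_peak <- qi[imax]
  if (!at_edge) {
    # quadratic refinement through the three points around the maximum
    y <- excess[(imax - 1):(imax + 1)]
    x <- qi[(imax - 1):(imax + 1)]
    denom <- (y[1] - 2 * y[2] + y[3])
    if (denom < 0) {
      q_peak <- x[2] - 0.5 * (x[3] - x[1]) / 2 * (y[3] - y[1]) / denom
    }
  }
  structure(q_peak, at_edge = at_edge)
}

# linear baseline under the exclusion window from the mean of `n_flank`
# points on each side
.peak_baseline <- function(q, I, exclude) {
  left <- which(q < exclude[1])
  right <- which(q > exclude[2])
  if (length(left) < 1 || length(right) < 1) {
    stop("exclusion window must lie strictly inside the q grid")
  }
  nf <- 3L
  li <- utils::tail(left, nf); ri <- utils::head(right, nf)
  x1 <- mean(q[li]); y1 <- mean(I[li])
  x2 <- mean(q[ri]); y2 <- mean(I[ri])
  function(qq) y1 + (y2 - y1) * (qq - x1) / (x2 - x1)
}

#' Crystal-fraction kinetics from the Bragg-peak excess
#'
#' Per frame, the dissolved-protein signal under the Bragg peak is
#' estimated by linear interpolation across the exclusion window from the
#' mean of three flanking points per side; the integrated excess above
#' that baseline is the crystal signal.  The resulting series is
#' baseline-subtracted at `t = 0` (homogeneous solution, no crystals),
#' normalized by the final frame (fully crystallized), and fitted with a
#' single sigmoid.
#'
#' @param frames list of >= 3 [diffraction_frame()]s on a common q grid.
#' @param q_bragg Bragg-peak position in 1/angstrom.
#' @param exclude_halfwidth half width of the exclusion window in
#'   1/angstrom.
#' @param quantity `"area"` (integrated excess, default) or `"height"`
#'   (peak maximum of the excess).
#' @return list with `series` (tibble `time_h`, `fraction`), `fit` and
#'   `flags`; label `c_Diff`.
#' @export
bragg_crystal_fraction <- function(frames, q_bragg, exclude_halfwidth,
                                   quantity = c("area", "height")) {
  quantity <- match.arg(quantity)
  stopifnot(length(frames) >= 3)
  times <- vapply(frames, function(f) f$time_h, 1)
  o <- order(times)
  frames <- frames[o]; times <- times[o]
  exclude <- q_bragg + c(-1, 1) * exclude_halfwidth
  raw <- vapply(frames, function(fr) {
    q <- fr$q_A_inv; I <- fr$intensity
    base_fn <- .peak_baseline(q, I, exclude)
    inwin <- q >= exclude[1] & q <= exclude[2]
    ex <- I[inwin] - base_fn(q[inwin])
    if (quantity == "area") sum(ex) else max(ex)
  }, 1)
  y <- raw - raw[1]
  flags <- character(0)
  final <- y[length(y)]
  if (final == 0) {
    flags <- c(flags, "degenerate-normalization")
    final <- 1
  }
  y <- y / final
  fit <- tryCatch(fit_kinetics(times, y, n_components = 1L),
                  error = function(e) NULL)
  if (is.null(fit)) flags <- c(flags, "fit-failed") else flags <- union(flags, fit$flags)
  list(series = tibble::tibble(time_h = times, fraction = y),
       fit = fit, flags = flags, label = "c_Diff")
}

#' Low-q intensity kinetics
#'
#' The time dependence of the diffraction intensity at the lowest recorded
#' momentum transfer, `I(q0, t)/I(q0, 0)`, fitted with a sigmoid plus a
#' constant background.  Independent of the presence of Bragg peaks in the
#' observed q range.
#'
#' @param frames list of [diffraction_frame()]s.
#' @param q0 target momentum transfer in 1/angstrom (default 0.096).
#' @param q_tol nearest-grid-point tolerance in 1/angstrom.
#' @return list with `series` (tibble `time_h`, `ratio`) and `fit`.
#' @export
lowq_kinetics <- function(frames, q0 = 0.096, q_tol = 0.01) {
  times <- vapply(frames, function(f) f$time_h, 1)
  o <- order(times)
  frames <- frames[o]; times <- times[o]
  q <- frames[[1]]$q_A_inv
  i0 <- which.min(abs(q - q0))
  if (abs(q[i0] - q0) > q_tol) {
    stop("q0 = ", q0, " not on the grid within tolerance ", q_tol)
  }
  I <- vapply(frames, function(fr) fr$intensity[i0], 1)
  ratio <- I / I[1]
  fit <- fit_kinetics(times, ratio, n_components = 1L, with_background = TRUE)
  list(series = tibble::tibble(time_h = times, ratio = ratio),
       fit = fit, q_used = q[i0], label = "lowq")
}
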