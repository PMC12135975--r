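#' Per-crystal sigmoid fits of projected-area traces
#'
#' Fits the sigmoid growth law to the 2D-projected area of each crystal
#' individually, yielding the maximum area `A0 = f0`, the time of fastest
#' growth `t0` and the characteristic time `dt` per crystal, together with
#' Freedman-Diaconis histograms and error-weighted population means
#' `m = sum(x/sigma^2) / sum(1/sigma^2)`.
#'
#' @param traces data frame with columns `crystal_id`, `time_h`,
#'   `area_um2` and optionally `error`.
#' @param min_points traces with fewer points are skipped (default 5).
#' @return list of class `population_summary`: `per_crystal` (tibble with
#'   `crystal_id`, `A0`, `t0`, `dt` and their 1-sigma), `means` (tibble of
#'   error-weighted means with 1-sigma), `histograms` (named list of
#'   `hist` objects), `n_fitted`, `n_failed`.
#' @export
fit_area_traces <- function(traces, min_points = 5L) {
  stopifnot(all(c("crystal_id", "time_h", "area_um2") %in% names(traces)))
  ids <- unique(traces$crystal_id)
  rows <- list(); n_failed <- 0L
  for (id in ids) {
    tr <- traces[traces$crystal_id == id, ]
    if (nrow(tr) < min_points) { n_failed <- n_failed + 1L; next }
    err <- if ("error" %in% names(tr) && all(is.finite(tr$error)) &&
               all(tr$error > 0)) tr$error else NULL
    fit <- tryCatch(fit_kinetics(tr$time_h, tr$area_um2, err),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { n_failed <- n_failed + 1L; next }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      crystal_id = id,
      A0 = fit$par[["f0_1"]], A0_err = fit$se[["f0_1"]],
      t0 = fit$par[["t0_1"]], t0_err = fit$se[["t0_1"]],
      dt = fit$par[["dt_1"]], dt_err = fit$se[["dt_1"]])
  }
  if (!length(rows)) stop("no trace could be fitted")
  per_crystal <- do.call(rbind, rows)

  wmean <- function(x, s) {
    s <- pmax(s, .Machine$double.eps)
    w <- 1 / s^2
    c(mean = sum(w * x) / sum(w), err = sqrt(1 / sum(w)))
  }
  means <- do.call(rbind, lapply(c("A0", "t0", "dt"), function(p) {
    m <- wmean(per_crystal[[p]], per_crystal[[paste0(p, "_err")]])
    tibble::tibble(parameter = p, mean = m[["mean"]], err = m[["err"]])
  }))
  histograms <- lapply(stats::setNames(c("A0", "t0", "dt"), c("A0", "t0", "dt")),
                       function(p) {
    x <- per_crystal[[p]]
    brk <- if (length(unique(x)) > 1) "FD" else 1
    graphics::hist(x, breaks = brk, plot = FALSE)
  })
  structure(list(per_crystal = per_crystal, means = means,
                 histograms = histograms, n_fitted = nrow(per_crystal),
                 n_failed = n_failed),
            class = "population_summary")
}

#' Area to volume conversion for cubic crystallites
#'
#' For cube-shaped crystallites the observed 2D-projected face area `A`
#' corresponds to a volume `V = A^(3/2)` (a cube of side `sqrt(A)`).
#' Refitting the sigmoid to `V(t)` yields the volume-corrected kinetic
#' parameters.
#'
#' @param area_um2 areas (>= 0).
#' @return volumes in um^3.
#' @export
area_to_volume <- function(area_um2) {
  stopifnot(all(area_um2 >= 0))
  area_um2^1.5
}

#' Segment synthetic microscopy frames into per-crystal area traces
#'
#' Threshold + connected-component labelling + centroid tracking, intended
#' for the synthetic square-crystal image stacks produced by
#' [gen_microscopy()] (not a general micrograph segmenter).  Crystal
#' identity is carried between frames by nearest-centroid matching; frames
#' in which two crystals merge into one component are flagged.
#'
#' @param stack list of numeric image matrices (one per time point).
#' @param time_h time of each frame.
#' @param threshold intensity threshold separating crystal from background.
#' @param pixel_area_um2 area of one pixel in um^2.
#' @param max_jump_px maximum centroid displacement for identity tracking.
#' @return tibble with `crystal_id`, `time_h`, `area_um2`, `flagged`.
#' @export
segment_synthetic_frames <- function(stack, time_h, threshold = 0.5,
                                     pixel_area_um2 = 1, max_jump_px = 10) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("segment_synthetic_frames requires the EBImage package")
  }
  stopifnot(length(stack) == length(time_h))
  next_id <- 0L
  centroids <- NULL   # data frame id, x, y
  rows <- list()
  for (i in seq_along(stack)) {
    lab <- EBImage::bwlabel(stack[[i]] > threshold)
    nlab <- max(lab)
    if (nlab == 0) next
    for (l in seq_len(nlab)) {
      px <- which(lab == l, arr.ind = TRUE)
      cx <- mean(px[, 1]); cy <- mean(px[, 2])
      area <- nrow(px) * pixel_area_um2
      id <- NA_integer_; flagged <- FALSE
      if (!is.null(centroids) && nrow(centroids)) {
        d <- sqrt((centroids$x - cx)^2 + (centroids$y - cy)^2)
        near <- which(d <= max_jump_px)
        if (length(near) == 1) {
          id <- centroids$id[near]
        } else if (length(near) > 1) {
          id <- centroids$id[near[which.min(d[near])]]
          flagged <- TRUE   # components merged
        }
      }
      if (is.na(id)) { next_id <- next_id + 1L; id <- next_id }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        crystal_id = id, time_h = time_h[i], area_um2 = area,
        flagged = flagged)
      if (is.null(centroids)) {
        centroids <- data.frame(id = id, x = cx, y = cy)
      } else if (id %in% centroids$id) {
        centroids[centroids$id == id, c("x", "y")] <- c(cx, cy)
      } else {
        centroids <- rbind(centroids, data.frame(id = id, x = cx, y = cy))
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(crystal_id = integer(), time_h = numeric(),
                          area_um2 = numeric(), flagged = logical()))
  }
  do.call(rbind, rows)
}
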