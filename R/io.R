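#' Read and write kinetic traces as delimited text
#'
#' Kinetic traces travel as CSV with columns `time_h`, `value`, `error`.
#'
#' @param path file path.
#' @return tibble with columns `time_h`, `value`, `error`.
#' @export
read_kinetic_trace <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_h", "value") %in% names(df)))
  if (!"error" %in% names(df)) df$error <- NA_real_
  tibble::as_tibble(df[, c("time_h", "value", "error")])
}

#' @rdname read_kinetic_trace
#' @param trace data frame with `time_h`, `value` and optionally `error`.
#' @export
write_kinetic_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a kinetic fit as JSON
#'
#' Parameter names, estimates, 1-sigma uncertainties, the covariance
#' matrix, reduced chi-square and flags, written with full precision.
#'
#' @param fit a [fit_kinetics()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(parameters = as.list(fit$par),
              se = as.list(fit$se),
              covariance = fit$cov,
              redchi2 = fit$redchi2,
              converged = fit$converged,
              flags = fit$flags)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
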