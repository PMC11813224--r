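## Internal-standard calibration of MS responses.
##
## MALDI-TOF / LC-MS/MS responses are quantified against standard curves
## of the intensity ratio of the analyte to a spiked internal standard
## (insulin for the AICDs) over a known concentration series; samples
## that invert below the lowest standard are censored (nd).

#' Response ratio relative to the internal standard
#'
#' @param analyte_response Raw instrument response of the analyte
#'   (non-negative).
#' @param is_response Raw response of the internal standard (must be
#'   strictly positive).
#' @return Dimensionless ratio `analyte_response / is_response`
#'   (vectorised).
#' @export
internal_standard_ratio <- function(analyte_response, is_response) {
  if (any(!is.finite(is_response)) || any(is_response <= 0)) {
    stop("internal-standard response must be positive", call. = FALSE)
  }
  if (any(!is.finite(analyte_response)) || any(analyte_response < 0)) {
    stop("analyte response must be finite and non-negative", call. = FALSE)
  }
  analyte_response / is_response
}

#' Fit a standard curve
#'
#' Ordinary least-squares line `response_ratio = slope * concentration +
#' intercept` over a concentration series of synthetic peptide standards
#' (for the AICDs: 2500 down to 62.5 nM, insulin internal standard).
#' The lowest standard concentration is retained as the censoring limit
#' for [invert_curve()].
#'
#' @param points Data.frame (or matrix) with columns `concentration`
#'   (nM, strictly positive, at least three distinct values) and
#'   `response` (internal-standard response ratio).
#' @param analyte Analyte identifier stored on the curve.
#' @param force_origin Fit `response = slope * concentration` without an
#'   intercept.
#' @param log_log Fit the line on log10 concentration vs log10 response
#'   (for detectors that are linear only on a log scale); responses must
#'   then be strictly positive.
#' @return An object of class `standard_curve`: `analyte`, `points`,
#'   `slope`, `intercept`, `r_squared`, `lowest_standard`,
#'   `force_origin`, `log_log`.
#' @examples
#' pts <- data.frame(concentration = c(100, 200, 400), response = c(1, 2, 4))
#' fit_standard_curve(pts)  # slope 0.01, intercept 0, r^2 = 1
#' @export
fit_standard_curve <- function(points, analyte = "", force_origin = FALSE,
                               log_log = FALSE) {
  points <- as.data.frame(points)
  if (!all(c("concentration", "response") %in% names(points))) {
    stop("`points` needs columns `concentration` and `response`", call. = FALSE)
  }
  conc <- as.numeric(points$concentration)
  resp <- as.numeric(points$response)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("standard concentrations must be finite and strictly positive",
         call. = FALSE)
  }
  if (length(unique(conc)) < 3L) {
    stop("need at least 3 distinct standard concentrations", call. = FALSE)
  }
  if (log_log) {
    if (any(resp <= 0)) stop("log-log fit needs positive responses", call. = FALSE)
    x <- log10(conc); y <- log10(resp)
  } else {
    x <- conc; y <- resp
  }
  fit <- if (force_origin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  co <- stats::coef(fit)
  slope <- unname(co[["x"]])
  intercept <- if (force_origin) 0 else unname(co[["(Intercept)"]])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(analyte = analyte,
         points = data.frame(concentration = conc, response = resp),
         slope = slope, intercept = intercept, r_squared = r2,
         lowest_standard = min(conc),
         force_origin = force_origin, log_log = log_log),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> ", x$analyte,
      if (x$log_log) " (log-log)" else "",
      ": slope ", signif(x$slope, 6),
      ", intercept ", signif(x$intercept, 6),
      ", r^2 ", round(x$r_squared, 4),
      ", LOD ", x$lowest_standard, " nM\n", sep = "")
  invisible(x)
}

#' Invert a standard curve to a concentration
#'
#' Maps a measured response ratio back to a concentration,
#' `(ratio - intercept) / slope`.  Concentrations below the lowest
#' standard cannot be quantified and are returned as
#' [censored()]`(lowest_standard)` - the censoring threshold always
#' equals the curve's lowest standard, never a hard-coded constant.
#'
#' @param curve A `standard_curve` with non-zero slope.
#' @param response_ratio Measured internal-standard response ratio.
#' @return Concentration in nM, or a `censored_value` when below the
#'   lowest standard.
#' @examples
#' pts <- data.frame(concentration = c(100, 200, 400), response = c(1, 2, 4))
#' invert_curve(fit_standard_curve(pts), 5.579)  # 557.9 nM
#' @export
invert_curve <- function(curve, response_ratio) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("cannot invert a zero-slope curve", call. = FALSE)
  stopifnot(length(response_ratio) == 1L, is.finite(response_ratio))
  if (curve$log_log) {
    if (response_ratio <= 0) return(censored(curve$lowest_standard))
    conc <- 10^((log10(response_ratio) - curve$intercept) / curve$slope)
  } else {
    conc <- (response_ratio - curve$intercept) / curve$slope
  }
  # the lowest standard itself is quantifiable: guard the boundary
  # against round-off from the fit-then-invert arithmetic
  cutoff <- curve$lowest_standard * (1 - 1e-9)
  if (conc < cutoff) censored(curve$lowest_standard) else conc
}
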