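#' Fit a phosphate standard curve
#'
#' Ordinary least-squares line through absorbance readings of known
#' orthophosphate concentrations (the malachite-green calibration, typically
#' 0-100 uM). The fitted line converts absorbance to phosphate concentration
#' via [invert_curve()].
#'
#' @param conc Known concentrations (uM), at least 3 distinct values.
#' @param absorbance Matching absorbance readings.
#' @return Object of class `std_curve`: `slope` (absorbance per uM),
#'   `intercept`, `r_squared`, the underlying `lm` fit, and the calibration
#'   data.
#' @export
fit_standard_curve <- function(conc, absorbance) {
  stopifnot(length(conc) == length(absorbance))
  if (length(conc) < 3L) stop("need at least 3 calibration points")
  if (stats::var(conc) == 0) stop("calibration concentrations do not vary")
  fit <- stats::lm(absorbance ~ conc)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         # summary.lm warns on zero-residual data; perfect synthetic
         # calibrations are legitimate here
         r_squared = suppressWarnings(summary(fit)$r.squared),
         lm = fit,
         data = data.frame(conc = conc, absorbance = absorbance)),
    class = "std_curve")
}

#' Convert absorbance to concentration with a standard curve
#'
#' @param object A `std_curve` fit.
#' @param absorbance Absorbance readings.
#' @return Concentrations (uM).
#' @export
invert_curve <- function(object, absorbance) {
  stopifnot(inherits(object, "std_curve"))
  if (object$slope <= 0) {
    stop("calibration slope is not positive; curve cannot be inverted")
  }
  (absorbance - object$intercept) / object$slope
}

#' @export
predict.std_curve <- function(object, newdata, ...) {
  conc <- if (missing(newdata)) object$data$conc else newdata
  object$intercept + object$slope * conc
}

#' @export
print.std_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: A = %.4g * [Pi] + %.4g  (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' Initial velocity from a progress series
#'
#' Slope of response (product concentration in uM after standard-curve
#' conversion) versus time by least squares, restricted to the configured
#' window — by default the 30-150 s quench span of the malachite-green
#' protocol. The regression intercept is left free. When the enzyme
#' concentration is given, the per-enzyme turnover `v0 / enzyme_conc` is
#' reported as well.
#'
#' @param time Time points (s), strictly increasing.
#' @param response Responses at each time (uM product).
#' @param window Length-2 numeric, inclusive time window (default
#'   `c(30, 150)`).
#' @param enzyme_conc Optional enzyme concentration in uM for per-enzyme
#'   normalization.
#' @return List with `v0` (uM/s), `intercept`, `n_points`, and `per_enzyme`
#'   (1/s, `NA` if `enzyme_conc` not given).
#' @export
initial_velocity <- function(time, response, window = c(30, 150),
                             enzyme_conc = NULL) {
  stopifnot(length(time) == length(response), length(window) == 2L)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time points must be strictly increasing")
  }
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 2L) stop("fewer than 2 time points inside the window")
  fit <- stats::lm(response[keep] ~ time[keep])
  v0 <- unname(stats::coef(fit)[2L])
  list(v0 = v0,
       intercept = unname(stats::coef(fit)[1L]),
       n_points = sum(keep),
       per_enzyme = if (is.null(enzyme_conc)) NA_real_ else {
         stopifnot(enzyme_conc > 0)
         v0 / enzyme_conc
       })
}
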