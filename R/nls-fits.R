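# shared scaffolding for the two hyperbolic fits: run nlsLM from a
# data-driven start, flag non-convergence instead of erroring mid-pipeline
.run_nls <- function(formula, data, start, lower) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(fit = NULL, converged = FALSE, message = conditionMessage(fit)))
  }
  list(fit = fit, converged = fit$convInfo$isConv, message = NULL)
}

.assay_fit_object <- function(class1, model, fit_info, data, extra = list()) {
  est <- se <- stats::setNames(rep(NA_real_, 2L),
                               switch(model,
                                      michaelis_menten = c("Vmax", "Km"),
                                      single_site_binding = c("Bmax", "Kd")))
  sigma <- NA_real_
  if (fit_info$converged) {
    sm <- summary(fit_info$fit)
    est[] <- sm$coefficients[names(est), "Estimate"]
    se[] <- sm$coefficients[names(est), "Std. Error"]
    sigma <- sm$sigma
    if (any(est <= 0)) {
      fit_info$converged <- FALSE
      fit_info$message <- "non-positive parameter estimate"
    }
  }
  structure(
    c(list(model = model, estimate = est, se = se, sigma = sigma,
           converged = fit_info$converged, message = fit_info$message,
           nls = fit_info$fit, data = data),
      extra),
    class = c(class1, "assay_fit"))
}

#' Fit the Michaelis-Menten equation to initial velocities
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)` over
#' (substrate, velocity) pairs, all replicate points jointly. Starting
#' values are data-driven (`Vmax` from the largest velocity, `Km` from the
#' median substrate concentration) so the fit does not depend on user
#' guesses. When the total enzyme concentration is supplied, the turnover
#' number `kcat = Vmax / enzyme_conc` is derived with its delta-method
#' standard error. Non-convergence and non-positive estimates are flagged on
#' the returned object (`converged = FALSE`), mirroring how a basal
#' condition with no saturable signal disallows a fit — they are not raised
#' as errors.
#'
#' @param substrate Substrate concentrations (uM), `>= 0`, at least 4
#'   distinct values.
#' @param v0 Initial velocities (uM/s), same length.
#' @param enzyme_conc Optional total enzyme concentration (uM).
#' @return Object of class `c("mm_fit", "assay_fit")` with elements
#'   `estimate` (`Vmax`, `Km`), `se`, `kcat`, `kcat_se`, `converged`,
#'   and the fitted `nls` object. Methods: `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `simulate`.
#' @export
fit_michaelis_menten <- function(substrate, v0, enzyme_conc = NULL) {
  stopifnot(length(substrate) == length(v0))
  if (any(substrate < 0)) stop("substrate concentrations must be >= 0")
  if (length(unique(substrate)) < 4L) {
    stop("need at least 4 distinct substrate concentrations")
  }
  data <- data.frame(S = substrate, v = v0)
  start <- list(Vmax = max(v0), Km = stats::median(substrate[substrate > 0]))
  info <- .run_nls(v ~ Vmax * S / (Km + S), data, start,
                   lower = c(Vmax = 0, Km = 0))
  extra <- list(enzyme_conc = enzyme_conc, kcat = NA_real_,
                kcat_se = NA_real_)
  obj <- .assay_fit_object("mm_fit", "michaelis_menten", info, data, extra)
  if (obj$converged && !is.null(enzyme_conc)) {
    stopifnot(enzyme_conc > 0)
    obj$kcat <- unname(obj$estimate["Vmax"]) / enzyme_conc
    obj$kcat_se <- unname(obj$se["Vmax"]) / enzyme_conc
  }
  obj
}

#' Fit a single-site saturation binding model to anisotropy data
#'
#' Nonlinear least squares of the simple hyperbola
#' `dr = Bmax * P / (Kd + P)` over (titrant concentration, change in
#' anisotropy) pairs, all replicates jointly. `Kd` starts at the
#' concentration nearest half-maximal signal, `Bmax` at the largest signal.
#' With `quadratic = TRUE` the ligand-depletion (tight-binding) form is
#' fitted instead, accounting for a fluorescent probe concentration
#' comparable to `Kd`:
#' `dr = Bmax * (P + probe + Kd - sqrt((P + probe + Kd)^2 - 4 P probe)) /
#' (2 probe)`.
#'
#' @param conc Titrant (protein) concentrations, `>= 0`, at least 5 points
#'   spanning the eventual `Kd`. Units set the unit of `Kd` (typically nM).
#' @param dr Change in anisotropy relative to free probe.
#' @param probe_conc Fluorescent probe concentration in the same units as
#'   `conc` (default 10, i.e. 10 nM probe); used by the quadratic model.
#' @param quadratic Fit the ligand-depletion model instead of the simple
#'   hyperbola.
#' @return Object of class `c("binding_fit", "assay_fit")` with `estimate`
#'   (`Bmax`, `Kd`), `se`, `converged`, and the fitted `nls` object.
#' @export
fit_binding <- function(conc, dr, probe_conc = 10, quadratic = FALSE) {
  stopifnot(length(conc) == length(dr))
  if (any(conc < 0)) stop("titrant concentrations must be >= 0")
  if (length(unique(conc)) < 5L) {
    stop("need at least 5 distinct titrant concentrations")
  }
  data <- data.frame(P = conc, dr = dr)
  half <- max(dr) / 2
  kd0 <- conc[which.min(abs(dr - half))]
  if (kd0 <= 0) kd0 <- stats::median(conc[conc > 0])
  start <- list(Bmax = max(dr), Kd = kd0)
  formula <- if (quadratic) {
    stopifnot(probe_conc > 0)
    pr <- probe_conc
    dr ~ Bmax * (P + pr + Kd - sqrt((P + pr + Kd)^2 - 4 * P * pr)) / (2 * pr)
  } else {
    dr ~ Bmax * P / (Kd + P)
  }
  info <- .run_nls(formula, data, start, lower = c(Bmax = 0, Kd = 0))
  .assay_fit_object("binding_fit", "single_site_binding", info, data,
                    list(probe_conc = probe_conc, quadratic = quadratic))
}

#' @export
coef.assay_fit <- function(object, ...) object$estimate

#' @export
predict.assay_fit <- function(object, newdata, ...) {
  if (!object$converged) stop("fit did not converge; no predictions")
  x <- if (missing(newdata)) object$data[[1L]] else newdata
  if (inherits(object, "binding_fit") && isTRUE(object$quadratic)) {
    p <- object$estimate; pr <- object$probe_conc
    return(p[["Bmax"]] *
             (x + pr + p[["Kd"]] - sqrt((x + pr + p[["Kd"]])^2 -
                                          4 * x * pr)) / (2 * pr))
  }
  pars <- as.list(object$estimate)
  .assay_model(object$model, pars, x)
}

#' @export
residuals.assay_fit <- function(object, ...) {
  object$data[[2L]] - predict(object, object$data[[1L]])
}

#' @export
simulate.assay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, object$data[[1L]])
  out <- replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma),
                   simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' Approximate Wald confidence intervals for fitted assay parameters
#' @param object An `assay_fit`.
#' @param parm Parameters to include (default all).
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @export
confint.assay_fit <- function(object, parm, level = 0.95, ...) {
  if (missing(parm)) parm <- names(object$estimate)
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = object$estimate[parm] - z * object$se[parm],
        upper = object$estimate[parm] + z * object$se[parm])
}

#' @export
print.assay_fit <- function(x, ...) {
  label <- switch(x$model,
                  michaelis_menten = "Michaelis-Menten fit",
                  single_site_binding = if (isTRUE(x$quadratic)) {
                    "Single-site binding fit (ligand depletion)"
                  } else {
                    "Single-site binding fit (hyperbola)"
                  })
  cat(label, "\n")
  if (!x$converged) {
    cat("  fit FAILED:", x$message %||% "did not converge", "\n")
    return(invisible(x))
  }
  for (nm in names(x$estimate)) {
    cat(sprintf("  %-5s = %.4g +/- %.3g\n", nm, x$estimate[nm], x$se[nm]))
  }
  if (inherits(x, "mm_fit") && !is.na(x$kcat)) {
    cat(sprintf("  kcat  = %.4g +/- %.3g 1/s (E0 = %g uM)\n",
                x$kcat, x$kcat_se, x$enzyme_conc))
  }
  invisible(x)
}

#' @export
summary.assay_fit <- function(object, ...) {
  print(object)
  if (object$converged) {
    cat(sprintf("  residual sd %.3g over %d points\n",
                object$sigma, nrow(object$data)))
  }
  invisible(object)
}

#' @export
plot.assay_fit <- function(x, n_grid = 200, ...) {
  if (!x$converged) stop("fit did not converge; nothing to plot")
  xv <- x$data[[1L]]; yv <- x$data[[2L]]
  grid <- seq(min(xv), max(xv), length.out = n_grid)
  plot(xv, yv, xlab = names(x$data)[1L], ylab = names(x$data)[2L], ...)
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
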