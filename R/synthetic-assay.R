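#' Ground truth for a simulated quantitative assay
#'
#' Declares the generating model and parameters for a synthetic plate-reader
#' or gel time-course dataset. Supported models:
#' \describe{
#'   \item{`michaelis_menten`}{`v = Vmax * S / (Km + S)`; parameters `Vmax`
#'     (uM/s), `Km` (uM).}
#'   \item{`single_site_binding`}{`dr = Bmax * P / (Kd + P)` (+ optional
#'     baseline `r0`); parameters `Kd` (nM), `Bmax` (anisotropy units),
#'     `r0` (default 0).}
#'   \item{`exponential_unwinding`}{`y = plateau * (1 - exp(-k * t))`;
#'     parameters `plateau` (percent), `k` (per min).}
#'   \item{`linear_progress`}{`y = slope * t + intercept`; parameters
#'     `slope`, `intercept` (default 0).}
#' }
#' Noise is multiplicative Gaussian — observed `y = model(x) * (1 + e)`,
#' `e ~ N(0, noise_sd^2)` — reflecting plate-reader error that scales with
#' signal.
#'
#' @param model Model name, one of the four above.
#' @param parameters Named list/vector of the model's parameters, all
#'   concentration/rate parameters strictly positive.
#' @param noise_sd Relative noise standard deviation, `>= 0` (e.g. 0.05 for
#'   5% noise).
#' @param seed Integer seed; identical truths and designs give identical
#'   tables.
#' @return Object of class `assay_truth`.
#' @export
assay_truth <- function(model = c("michaelis_menten", "single_site_binding",
                                  "exponential_unwinding", "linear_progress"),
                        parameters, noise_sd = 0, seed = 1L) {
  model <- match.arg(model)
  parameters <- as.list(parameters)
  required <- switch(model,
    michaelis_menten = c("Vmax", "Km"),
    single_site_binding = c("Kd", "Bmax"),
    exponential_unwinding = c("plateau", "k"),
    linear_progress = "slope")
  missing_par <- setdiff(required, names(parameters))
  if (length(missing_par)) {
    stop("missing parameters for ", model, ": ",
         paste(missing_par, collapse = ", "))
  }
  if (any(unlist(parameters[required]) <= 0)) {
    stop("concentration/rate parameters must be strictly positive")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(model = model, parameters = parameters,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "assay_truth")
}

# noiseless model evaluation shared by the generator and the fit methods
.assay_model <- function(model, parameters, x) {
  p <- parameters
  switch(model,
    michaelis_menten = p$Vmax * x / (p$Km + x),
    single_site_binding =
      (if (is.null(p$r0)) 0 else p$r0) + p$Bmax * x / (p$Kd + x),
    exponential_unwinding = p$plateau * (1 - exp(-p$k * x)),
    linear_progress =
      p$slope * x + (if (is.null(p$intercept)) 0 else p$intercept),
    stop("unknown model: ", model))
}

#' Simulate observations from an assay truth
#'
#' Evaluates the generating model over the design points and applies seeded
#' multiplicative Gaussian noise, optionally in replicate.
#'
#' @param truth An [assay_truth()] object.
#' @param design Numeric vector of non-negative x-values (substrate or
#'   titrant concentration, or time).
#' @param replicates Number of replicate observations per design point.
#' @return Data frame with columns `x`, `replicate`, `y` (long format).
#' @examples
#' tr <- assay_truth("michaelis_menten", list(Vmax = 1, Km = 100))
#' simulate_assay(tr, design = 100)$y  # 0.5, the half-saturation identity
#' @export
simulate_assay <- function(truth, design, replicates = 1L) {
  stopifnot(inherits(truth, "assay_truth"))
  if (any(design < 0)) stop("design values must be non-negative")
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  set.seed(truth$seed)
  x <- rep(design, times = replicates)
  rep_id <- rep(seq_len(replicates), each = length(design))
  mu <- .assay_model(truth$model, truth$parameters, x)
  eps <- if (truth$noise_sd > 0) {
    stats::rnorm(length(x), 0, truth$noise_sd)
  } else {
    numeric(length(x))
  }
  data.frame(x = x, replicate = rep_id, y = mu * (1 + eps))
}
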