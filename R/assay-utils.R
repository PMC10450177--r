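#' Beer-Lambert concentration from absorbance
#'
#' `c = A / (epsilon * l)`. With the ATP molar extinction coefficient
#' 15 400 1/(M cm) at 260 nm and a 1 cm path, an absorbance of 1.54
#' corresponds to 100 uM ATP.
#'
#' @param A Absorbance, `>= 0` (vectorized).
#' @param epsilon Molar extinction coefficient, 1/(M cm), `> 0`.
#' @param pathlength Path length in cm, `> 0` (default 1).
#' @return Concentration in M.
#' @seealso [beer_lambert_absorbance()] for the inverse.
#' @export
beer_lambert <- function(A, epsilon, pathlength = 1) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (pathlength <= 0) stop("pathlength must be > 0")
  if (any(A < 0)) stop("absorbance must be >= 0")
  A / (epsilon * pathlength)
}

#' @rdname beer_lambert
#' @param conc Concentration in M, `>= 0`.
#' @export
beer_lambert_absorbance <- function(conc, epsilon, pathlength = 1) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (pathlength <= 0) stop("pathlength must be > 0")
  if (any(conc < 0)) stop("concentration must be >= 0")
  epsilon * pathlength * conc
}

#' Percent of duplex unwound from gel band intensities
#'
#' `100 * unwound / (unwound + duplex)` for paired band intensities of the
#' displaced (unwound) strand and the remaining duplex.
#'
#' @param unwound,duplex Non-negative band intensities (vectorized); no pair
#'   may be (0, 0).
#' @return Percent unwound in [0, 100].
#' @export
percent_unwound <- function(unwound, duplex) {
  stopifnot(length(unwound) == length(duplex))
  if (any(unwound < 0) || any(duplex < 0)) {
    stop("band intensities must be >= 0")
  }
  if (any(unwound + duplex == 0)) {
    stop("both band intensities are zero: fraction undefined")
  }
  100 * unwound / (unwound + duplex)
}

#' Summarize an unwinding time course across replicates
#'
#' Converts replicate band-intensity pairs to percent unwound at each time
#' point and reports the mean and standard deviation across replicates,
#' together with whether the endpoint mean exceeds 50% — the cutoff used to
#' classify a substrate as productively unwound.
#'
#' @param time Time points, one per row (any unit; typically min).
#' @param unwound,duplex Matrices (time x replicate) of band intensities, or
#'   vectors for a single replicate.
#' @return List with `summary` (data frame: `time`, `mean`, `sd`),
#'   `percent` (time x replicate matrix), and `endpoint_gt50` (logical).
#' @export
unwinding_course <- function(time, unwound, duplex) {
  unwound <- as.matrix(unwound); duplex <- as.matrix(duplex)
  stopifnot(nrow(unwound) == length(time),
            identical(dim(unwound), dim(duplex)))
  pct <- matrix(percent_unwound(as.vector(unwound), as.vector(duplex)),
                nrow = nrow(unwound))
  mean_pct <- rowMeans(pct)
  sd_pct <- apply(pct, 1L, stats::sd)
  list(summary = data.frame(time = time, mean = mean_pct, sd = sd_pct),
       percent = pct,
       endpoint_gt50 = mean_pct[length(mean_pct)] > 50)
}

#' Convert CD machine units to per-residue molar circular dichroism
#'
#' Converts spectropolarimeter readings theta (mdeg) to delta-epsilon
#' (1/(M cm) per residue). The default evaluates the conversion exactly as
#' commonly printed, left to right:
#' `de = theta * (0.1 * MRW) / (P * Conc) * 3298`, i.e. with the factor 3298
#' multiplying. The conventional form of the conversion instead divides by
#' 3298 (`de = theta * 0.1 * MRW / (P * Conc * 3298)`); select it with
#' `divide_by_3298 = TRUE`. Both are linear in theta and differ only by the
#' constant factor 3298^2.
#'
#' @param theta Machine readings in mdeg (vectorized over wavelength).
#' @param mrw Mean residue weight (g/mol per residue), `> 0`.
#' @param pathlength Cuvette path length in cm, `> 0` (typically 0.1).
#' @param conc Protein concentration in mg/ml, `> 0`.
#' @param divide_by_3298 Use the conventional division by 3298.
#' @return Delta-epsilon values, same length as `theta`.
#' @export
cd_convert <- function(theta, mrw, pathlength, conc,
                       divide_by_3298 = FALSE) {
  if (mrw <= 0 || pathlength <= 0 || conc <= 0) {
    stop("mrw, pathlength and conc must be > 0")
  }
  base <- theta * (0.1 * mrw) / (pathlength * conc)
  if (divide_by_3298) base / 3298 else base * 3298
}
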