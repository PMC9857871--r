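# Preprocessing chain: Savitzky-Golay smoothing -> standard normal variate
# -> per-spectrum min-max rescale to [epsilon, 1]. The rescale floor epsilon
# keeps every band strictly positive so that divergence-based measures never
# see a zero or negative value.

#' Preprocessing configuration
#'
#' @param sgWindow odd Savitzky-Golay window length in bands (>= 5). The
#'   default 9 spans 45 nm on the 5 nm grid, wide enough to suppress sensor
#'   noise while preserving the narrow hemoglobin features near 540-580 nm.
#' @param sgOrder polynomial order of the Savitzky-Golay fit (default 3).
#' @param minmaxEpsilon lower bound of the min-max rescale (default 1e-6);
#'   must be positive so divergence terms never take log of zero.
#' @param steps ordered subset of \code{c("sg", "snv", "minmax")}; the chain
#'   is always applied in that order.
#' @return an object of class \code{PreprocessConfig}.
#' @export
preprocessConfig <- function(sgWindow = 9L, sgOrder = 3L,
                             minmaxEpsilon = 1e-6,
                             steps = c("sg", "snv", "minmax")) {
  sgWindow <- as.integer(sgWindow)
  sgOrder <- as.integer(sgOrder)
  if (sgWindow < 5L || sgWindow %% 2L == 0L)
    stop("configuration error: sgWindow must be an odd integer >= 5")
  if (sgOrder < 0L || sgOrder >= sgWindow)
    stop("configuration error: sgOrder must satisfy 0 <= sgOrder < sgWindow")
  if (!is.numeric(minmaxEpsilon) || minmaxEpsilon <= 0)
    stop("configuration error: minmaxEpsilon must be > 0")
  steps <- as.character(steps)
  if (!all(steps %in% c("sg", "snv", "minmax")))
    stop("configuration error: steps must be a subset of sg, snv, minmax")
  structure(list(sgWindow = sgWindow, sgOrder = sgOrder,
                 minmaxEpsilon = minmaxEpsilon, steps = steps),
            class = "PreprocessConfig")
}

#' Savitzky-Golay smoothing of one spectrum
#'
#' Replaces each band value with the value of a local least-squares
#' polynomial fit, removing high-frequency noise without distorting peak
#' shapes. Edge points use the polynomial fitted to the first/last full
#' window (no padding beyond the measured range), so any polynomial of
#' degree at most \code{order} is reproduced exactly everywhere.
#'
#' @param s numeric reflectance vector.
#' @param window odd window length in bands.
#' @param order polynomial order (< window).
#' @return smoothed numeric vector of the same length.
#' @export
savgolSmooth <- function(s, window = 9L, order = 3L) {
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L)
    stop("configuration error: Savitzky-Golay window must be odd")
  if (order >= window)
    stop("configuration error: polynomial order must be < window")
  if (length(s) < window)
    stop("configuration error: window longer than the spectrum")
  out <- as.numeric(signal::sgolayfilt(s, p = order, n = window))
  if (!all(is.finite(out))) stop("non-finite values after smoothing")
  out
}

#' Standard normal variate normalization
#'
#' Centers one spectrum to mean 0 and scales it to standard deviation 1.
#' SNV removes per-spectrum multiplicative (illumination) and additive
#' (offset) effects: any positive affine transform of a spectrum maps to the
#' same output.
#'
#' @param s numeric reflectance vector (non-constant).
#' @return normalized numeric vector.
#' @export
snvNormalize <- function(s) {
  sdev <- sd(s)
  if (!is.finite(sdev) || sdev == 0)
    stop("degenerate-input error: constant spectrum has no SNV transform")
  (s - mean(s)) / sdev
}

#' Min-max rescale to a strictly positive range
#'
#' Affinely maps \code{[min(s), max(s)]} onto \code{[epsilon, 1]}. Performed
#' per spectrum; the strictly positive floor avoids the log-of-zero failure
#' of divergence-based measures on SNV output (which is negative in roughly
#' half its bands).
#'
#' @param s numeric vector (non-constant).
#' @param epsilon positive lower bound, default \code{1e-6}.
#' @return rescaled vector with minimum \code{epsilon} and maximum 1.
#' @export
minmaxRescale <- function(s, epsilon = 1e-6) {
  if (epsilon <= 0) stop("configuration error: epsilon must be > 0")
  rng <- range(s)
  if (rng[1] == rng[2])
    stop("degenerate-input error: constant spectrum cannot be min-max rescaled")
  epsilon + (s - rng[1]) / (rng[2] - rng[1]) * (1 - epsilon)
}

#' Normalize a nonnegative spectrum to a probability distribution
#'
#' @param s numeric vector, all entries >= 0, positive sum. Callers holding
#'   spectra with negative bands must \code{\link{minmaxRescale}} first.
#' @return vector summing to 1, proportional to the input.
#' @export
toProbability <- function(s) {
  if (any(s < 0))
    stop("precondition error: negative reflectance; min-max rescale first")
  tot <- sum(s)
  if (tot <= 0) stop("degenerate-input error: all-zero spectrum")
  s / tot
}

#' Apply the preprocessing chain to a whole library
#'
#' Each spectrum passes through the enabled steps in the fixed order
#' SG smoothing, SNV, min-max rescale; labels and patients are untouched.
#'
#' @param lib a \linkS4class{SpectralLibrary}.
#' @param cfg a \code{\link{preprocessConfig}}.
#' @return a preprocessed \linkS4class{SpectralLibrary}.
#' @export
preprocessLibrary <- function(lib, cfg = preprocessConfig()) {
  stopifnot(is(lib, "SpectralLibrary"), inherits(cfg, "PreprocessConfig"))
  m <- reflectance(lib)
  order <- c("sg", "snv", "minmax")
  steps <- order[order %in% cfg$steps]
  for (j in seq_len(ncol(m))) {
    s <- m[, j]
    res <- tryCatch({
      for (st in steps) {
        s <- switch(st,
          sg = savgolSmooth(s, cfg$sgWindow, cfg$sgOrder),
          snv = snvNormalize(s),
          minmax = minmaxRescale(s, cfg$minmaxEpsilon))
      }
      s
    }, error = function(e) {
      stop(sprintf("entry %d (tissue '%s', patient '%s'): %s", j,
                   tissueLabel(lib)[j], patientId(lib)[j],
                   conditionMessage(e)), call. = FALSE)
    })
    m[, j] <- res
  }
  SpectralLibrary(m, wavelengths(lib), tissueLabel(lib), patientId(lib))
}
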