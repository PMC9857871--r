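# The eight similarity measures. All are nonnegative, symmetric and zero on
# identical inputs; smaller means more similar. SAM and SCA are angles in
# radians in [0, pi/2]; SID is in nats; JM is dimensionless in [0, 2]; the
# hybrids are products and dimensionless.

.MEASURES <- c("SAM", "SID", "SCA", "JM",
               "SID-TAN(SAM)", "SID-TAN(SCA)",
               "SID-JM-TAN(SAM)", "SID-JM-TAN(SCA)")

#' Names of the available spectral similarity measures
#' @return character vector of canonical measure names.
#' @export
spectralMeasureNames <- function() .MEASURES

#' Resolve a measure name or shell-friendly alias
#'
#' Accepts the canonical names (e.g. \code{"SID-JM-TAN(SCA)"}) in any case,
#' and parenthesis-free aliases such as \code{"sid-jm-tan-sca"}.
#'
#' @param name measure name or alias.
#' @return the canonical measure name.
#' @export
canonicalMeasureName <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(gsub("[()]", "-", name))
  key <- gsub("-+", "-", key)
  key <- sub("-$", "", key)
  tab <- setNames(.MEASURES,
                  sub("-$", "", gsub("-+", "-",
                                     tolower(gsub("[()]", "-", .MEASURES)))))
  if (!key %in% names(tab))
    stop("unknown measure '", name, "'; valid measures: ",
         paste(.MEASURES, collapse = ", "))
  unname(tab[[key]])
}

.checkPair <- function(si, sj) {
  if (length(si) != length(sj))
    stop("configuration error: spectra differ in length (grid mismatch)")
  if (!all(is.finite(si)) || !all(is.finite(sj)))
    stop("value error: non-finite reflectance")
}

#' Spectral angle mapper (SAM)
#'
#' The angle between two spectra viewed as vectors in band space,
#' \eqn{\mathrm{SAM}(s_i, s_j) = \cos^{-1}\!\big(s_i \cdot s_j /
#' (\|s_i\| \|s_j\|)\big)}, in radians in \eqn{[0, \pi/2]} for nonnegative
#' spectra. Invariant to positive scaling of either input.
#'
#' @param si,sj nonnegative reflectance vectors on the same grid.
#' @return angle in radians.
#' @export
sam <- function(si, sj) {
  .checkPair(si, sj)
  if (any(si < 0) || any(sj < 0))
    stop("precondition error: SAM requires nonnegative spectra")
  ni <- sqrt(sum(si^2)); nj <- sqrt(sum(sj^2))
  if (ni == 0 || nj == 0)
    stop("degenerate-input error: zero-norm spectrum")
  acos(min(1, max(-1, sum(si * sj) / (ni * nj))))
}

#' Spectral information divergence (SID)
#'
#' Symmetrized Kullback-Leibler divergence between the two spectra
#' normalized to probability distributions over bands:
#' \eqn{\mathrm{SID}(s_i, s_j) = D(p_i \| p_j) + D(p_j \| p_i)} in nats.
#' Probabilities are floored at \code{floor} and renormalized so the
#' divergence stays finite even when a band carries zero mass.
#'
#' @param si,sj nonnegative reflectance vectors on the same grid.
#' @param floor probability floor, default \code{1e-12}.
#' @return divergence in nats, >= 0.
#' @export
sid <- function(si, sj, floor = 1e-12) {
  .checkPair(si, sj)
  p <- toProbability(si); q <- toProbability(sj)
  p <- pmax(p, floor); p <- p / sum(p)
  q <- pmax(q, floor); q <- q / sum(q)
  sum(p * log(p / q)) + sum(q * log(q / p))
}

#' Spectral correlation angle (SCA)
#'
#' Maps the Pearson correlation \eqn{\sigma \in [-1, 1]} between two spectra
#' to an angle: \eqn{\mathrm{SCA} = \cos^{-1}((\sigma + 1)/2)}, in radians in
#' \eqn{[0, \pi/2]}. Unlike SAM it distinguishes negative from positive
#' correlation and is invariant to a positive affine transform of either
#' input. A variant using \eqn{\cos^{-1}\sqrt{(\sigma+1)/2}} (found in part
#' of the SCA literature) is available via \code{sqrtTransform = TRUE}.
#'
#' @param si,sj non-constant reflectance vectors on the same grid.
#' @param sqrtTransform use the square-root form of the argument.
#' @return angle in radians.
#' @export
sca <- function(si, sj, sqrtTransform = FALSE) {
  .checkPair(si, sj)
  if (sd(si) == 0 || sd(sj) == 0)
    stop("degenerate-input error: Pearson correlation undefined for a constant spectrum")
  sigma <- cor(si, sj)
  arg <- (sigma + 1) / 2
  if (sqrtTransform) arg <- sqrt(arg)
  acos(min(1, max(0, arg)))
}

#' Bhattacharyya coefficient
#'
#' Overlap \eqn{\sum_l \sqrt{p_{il} p_{jl}}} of the two probability-normalized
#' spectra; 1 for identical distributions, 0 for disjoint support.
#'
#' @param si,sj nonnegative reflectance vectors on the same grid.
#' @return coefficient in [0, 1].
#' @export
bhattacharyyaCoefficient <- function(si, sj) {
  .checkPair(si, sj)
  p <- toProbability(si); q <- toProbability(sj)
  min(1, sum(sqrt(p * q)))
}

#' Jeffries-Matusita (JM) distance
#'
#' Separability measure on probability-normalized spectra, scaled to
#' \eqn{[0, 2]}. The default form uses the Bhattacharyya distance
#' \eqn{B = -\ln \mathrm{BC}} in the exponent, \eqn{\mathrm{JM} =
#' 2(1 - e^{-B}) = 2(1 - \mathrm{BC})}, which attains the full stated range
#' (0 for identical distributions, 2 for disjoint support). \code{form =
#' "coefficient"} instead places the coefficient itself in the exponent,
#' \eqn{2(1 - e^{-\mathrm{BC}})}, which is capped at
#' \eqn{2(1 - e^{-1}) \approx 1.264}.
#'
#' @param si,sj nonnegative reflectance vectors on the same grid.
#' @param form \code{"distance"} (default) or \code{"coefficient"}.
#' @return JM distance.
#' @export
jmDistance <- function(si, sj, form = c("distance", "coefficient")) {
  form <- match.arg(form)
  bc <- bhattacharyyaCoefficient(si, sj)
  switch(form,
         distance = 2 * (1 - bc),
         coefficient = 2 * (1 - exp(-bc)))
}

# tan of an angle measure, saturated just below pi/2 so that hybrids of
# exactly orthogonal / anticorrelated spectra stay finite and order-preserving
.tanSat <- function(angle) tan(min(angle, pi / 2 - 1e-9))

#' Evaluate any of the eight similarity measures by name
#'
#' The hybrid measures are exact products of their constituents:
#' \eqn{\mathrm{SID{-}TAN(SAM)} = \mathrm{SID} \times \tan(\mathrm{SAM})},
#' \eqn{\mathrm{SID{-}JM{-}TAN(SCA)} = \mathrm{SID} \times \mathrm{JM}
#' \times \tan(\mathrm{SCA})}, and so on. The tangent amplifies
#' dissimilarity: near-identical spectra give near-zero products while
#' dissimilar spectra are pushed apart multiplicatively.
#'
#' @param name measure name or alias (see
#'   \code{\link{spectralMeasureNames}}).
#' @param si,sj reflectance vectors on the same grid, nonnegative (the
#'   preprocessing chain ends strictly positive).
#' @param ... passed to the underlying measure functions.
#' @return nonnegative measure value; smaller means more similar.
#' @export
spectralSimilarity <- function(name, si, sj, ...) {
  switch(canonicalMeasureName(name),
    "SAM" = sam(si, sj),
    "SID" = sid(si, sj, ...),
    "SCA" = sca(si, sj, ...),
    "JM" = jmDistance(si, sj, ...),
    "SID-TAN(SAM)" = sid(si, sj) * .tanSat(sam(si, sj)),
    "SID-TAN(SCA)" = sid(si, sj) * .tanSat(sca(si, sj)),
    "SID-JM-TAN(SAM)" = sid(si, sj) * jmDistance(si, sj) *
      .tanSat(sam(si, sj)),
    "SID-JM-TAN(SCA)" = sid(si, sj) * jmDistance(si, sj) *
      .tanSat(sca(si, sj)))
}

#' Per-(tissue, patient) mean spectra
#'
#' Collapses a library to one entry per (tissue, patient) pair, the bandwise
#' arithmetic mean of that group's spectra. Groups are ordered by tissue,
#' then patient.
#'
#' @param lib a \linkS4class{SpectralLibrary}.
#' @return a \linkS4class{SpectralLibrary} of group means.
#' @export
patientMeanSpectra <- function(lib) {
  stopifnot(is(lib, "SpectralLibrary"))
  key <- paste(tissueLabel(lib), patientId(lib), sep = "\r")
  groups <- sort(unique(key))
  m <- vapply(groups,
              function(g) rowMeans(reflectance(lib)[, key == g, drop = FALSE]),
              numeric(nBands(lib)))
  parts <- strsplit(groups, "\r", fixed = TRUE)
  SpectralLibrary(m, wavelengths(lib),
                  tissue = vapply(parts, `[`, "", 1L),
                  patient = vapply(parts, `[`, "", 2L))
}

#' Pairwise similarity matrix between two libraries
#'
#' @param targets,references \linkS4class{SpectralLibrary} objects on the
#'   same wavelength grid.
#' @param name measure name or alias.
#' @param ... passed to \code{\link{spectralSimilarity}}.
#' @return numeric |targets| x |references| matrix with
#'   \code{"tissue|patient"} dimnames and attribute \code{measure}.
#' @export
pairwiseMatrix <- function(targets, references, name, ...) {
  stopifnot(is(targets, "SpectralLibrary"), is(references, "SpectralLibrary"))
  if (!isTRUE(all.equal(wavelengths(targets), wavelengths(references))))
    stop("configuration error: wavelength grids differ")
  name <- canonicalMeasureName(name)
  tm <- reflectance(targets); rm_ <- reflectance(references)
  out <- matrix(NA_real_, ncol(tm), ncol(rm_))
  for (i in seq_len(ncol(tm)))
    for (j in seq_len(ncol(rm_)))
      out[i, j] <- spectralSimilarity(name, tm[, i], rm_[, j], ...)
  dimnames(out) <- list(
    paste(tissueLabel(targets), patientId(targets), sep = "|"),
    paste(tissueLabel(references), patientId(references), sep = "|"))
  attr(out, "measure") <- name
  out
}
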