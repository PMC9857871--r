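# Comparative statistics that put measures with different units on a common
# footing: discriminatory power (a ratio), probability (a normalized vector)
# and entropy (bits of that vector). Being ratios of measure values, all
# three are invariant to rescaling a measure by a positive constant.

#' Relative spectral discriminatory power (RSDPW)
#'
#' For a target spectrum \code{t} and two references, the larger of the two
#' ratios \eqn{m(s_i,t)/m(s_j,t)} and \eqn{m(s_j,t)/m(s_i,t)}; always
#' \eqn{\ge 1}, equal to 1 exactly when the references are equidistant from
#' the target under \code{m}. Larger values mean the measure separates the
#' two references better relative to the target.
#'
#' @param name measure name or alias.
#' @param si,sj reference spectra.
#' @param t target spectrum.
#' @param ... passed to \code{\link{spectralSimilarity}}.
#' @return RSDPW value >= 1.
#' @export
rsdpw <- function(name, si, sj, t, ...) {
  mi <- spectralSimilarity(name, si, t, ...)
  mj <- spectralSimilarity(name, sj, t, ...)
  if (mi == 0 || mj == 0)
    stop("undefined-ratio error: target identical to a reference under ",
         canonicalMeasureName(name))
  max(mi / mj, mj / mi)
}

#' Relative spectral discriminatory probability (RSDPB)
#'
#' The measure values of a target against every library entry, normalized to
#' a probability vector: \eqn{P_{t,\Delta}(k) = m(t, s_k) / \sum_i m(t, s_i)}.
#'
#' @param name measure name or alias.
#' @param t target spectrum.
#' @param refs a \linkS4class{SpectralLibrary} of K references.
#' @param ... passed to \code{\link{spectralSimilarity}}.
#' @return probability vector of length K, named \code{"tissue|patient"}.
#' @export
rsdpb <- function(name, t, refs, ...) {
  stopifnot(is(refs, "SpectralLibrary"))
  m <- reflectance(refs)
  v <- vapply(seq_len(ncol(m)),
              function(k) spectralSimilarity(name, t, m[, k], ...),
              numeric(1))
  tot <- sum(v)
  if (tot <= 0)
    stop("degenerate error: target identical to every reference")
  setNames(v / tot,
           paste(tissueLabel(refs), patientId(refs), sep = "|"))
}

#' Relative spectral discriminatory entropy (RSDE)
#'
#' Shannon entropy, in bits, of the RSDPB vector; bounded by
#' \eqn{\log_2 K} and small when the target is matched sharply by few
#' references. Zero-probability entries contribute 0.
#'
#' @inheritParams rsdpb
#' @return entropy in bits, in \eqn{[0, \log_2 K]}.
#' @export
rsde <- function(name, t, refs, ...) {
  p <- rsdpb(name, t, refs, ...)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Discrimination report for a target tissue
#'
#' For each requested measure: RSDPW over all unordered pairs of non-target
#' tissues (tissue mean spectra as references, the target tissue's mean as
#' target), plus RSDPB and RSDE of the target-tissue mean against the
#' per-(tissue, patient) mean reference library.
#'
#' @param lib a \linkS4class{SpectralLibrary}.
#' @param targetTissue tissue label present in \code{lib}.
#' @param measures character vector of measure names.
#' @return a list of per-measure reports, each a list with elements
#'   \code{measure}, \code{targetTissue}, \code{rsdpw} (data.frame
#'   tissue_i/tissue_j/value, empty when fewer than two other tissues),
#'   \code{rsdpb} and \code{rsde}.
#' @export
discriminationReport <- function(lib, targetTissue,
                                 measures = spectralMeasureNames()) {
  stopifnot(is(lib, "SpectralLibrary"))
  tissues <- sort(unique(tissueLabel(lib)))
  if (!targetTissue %in% tissues)
    stop("lookup error: tissue '", targetTissue, "' not in library")
  tissueMean <- function(tt)
    rowMeans(reflectance(lib)[, tissueLabel(lib) == tt, drop = FALSE])
  t0 <- tissueMean(targetTissue)
  others <- setdiff(tissues, targetTissue)
  pmeans <- patientMeanSpectra(lib)
  lapply(measures, function(nm) {
    nm <- canonicalMeasureName(nm)
    pw <- if (length(others) >= 2L) {
      pairs <- utils::combn(others, 2L)
      data.frame(
        tissue_i = pairs[1, ], tissue_j = pairs[2, ],
        value = vapply(seq_len(ncol(pairs)), function(c2)
          rsdpw(nm, tissueMean(pairs[1, c2]), tissueMean(pairs[2, c2]), t0),
          numeric(1)))
    } else {
      data.frame(tissue_i = character(0), tissue_j = character(0),
                 value = numeric(0))
    }
    list(measure = nm, targetTissue = targetTissue, rsdpw = pw,
         rsdpb = rsdpb(nm, t0, pmeans), rsde = rsde(nm, t0, pmeans))
  })
}
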