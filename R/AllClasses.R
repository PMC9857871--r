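#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats sd cor kmeans rnorm sd setNames
#' @importFrom utils read.csv count.fields
NULL

#' SpectralLibrary: a labeled collection of reflectance spectra
#'
#' A \code{SpectralLibrary} holds \eqn{K} reflectance spectra measured on a
#' shared wavelength grid of \eqn{L} bands, each carrying a tissue label and a
#' patient identifier. It extends
#' \linkS4class{SummarizedExperiment}: the single assay
#' \code{"reflectance"} is an \eqn{L \times K} matrix (bands in rows, spectra
#' in columns), \code{rowData} stores the wavelength grid in nm, and
#' \code{colData} stores \code{tissue} and \code{patient}.
#'
#' Invariants enforced by the validity method: the wavelength grid is strictly
#' increasing with \eqn{L \ge 2}, all reflectance values are finite,
#' \eqn{K \ge 1}, and every tissue label and patient identifier is a
#' non-empty string.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases SpectralLibrary-class
#' @exportClass SpectralLibrary
setClass("SpectralLibrary", contains = "SummarizedExperiment")

.validSpectralLibrary <- function(object) {
  msg <- character(0)
  if (!("reflectance" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'reflectance' is required")
  else {
    m <- SummarizedExperiment::assay(object, "reflectance")
    if (!is.numeric(m)) msg <- c(msg, "reflectance must be numeric")
    else if (!all(is.finite(m))) msg <- c(msg, "reflectance values must all be finite")
  }
  if (nrow(object) < 2L)
    msg <- c(msg, "a spectral library needs at least 2 wavelength bands")
  if (ncol(object) < 1L)
    msg <- c(msg, "a spectral library needs at least one spectrum (K >= 1)")
  rd <- SummarizedExperiment::rowData(object)
  if (!("wavelength" %in% colnames(rd)))
    msg <- c(msg, "rowData must contain a 'wavelength' column (nm)")
  else {
    w <- rd$wavelength
    if (!is.numeric(w) || anyNA(w) || any(diff(w) <= 0))
      msg <- c(msg, "wavelength grid must be strictly increasing")
  }
  cd <- SummarizedExperiment::colData(object)
  for (fld in c("tissue", "patient")) {
    if (!(fld %in% colnames(cd)))
      msg <- c(msg, sprintf("colData must contain '%s'", fld))
    else {
      v <- cd[[fld]]
      if (anyNA(v) || any(!nzchar(as.character(v))))
        msg <- c(msg, sprintf("'%s' entries must be non-empty", fld))
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("SpectralLibrary", .validSpectralLibrary)

#' Construct a SpectralLibrary
#'
#' @param reflectance numeric matrix, bands in rows and spectra in columns
#'   (a numeric vector is treated as a single-spectrum column).
#' @param wavelengths strictly increasing numeric vector of band centers in
#'   nm, one per row of \code{reflectance}.
#' @param tissue character vector of tissue labels, one per spectrum.
#' @param patient character vector of patient identifiers, one per spectrum.
#' @return a \linkS4class{SpectralLibrary}.
#' @examples
#' lib <- SpectralLibrary(matrix(runif(200), nrow = 100),
#'                        wavelengths = seq(500, 995, 5),
#'                        tissue = c("thyroid", "muscle"),
#'                        patient = c("p1", "p1"))
#' nSpectra(lib)
#' @export
SpectralLibrary <- function(reflectance, wavelengths, tissue, patient) {
  if (is.vector(reflectance)) reflectance <- matrix(reflectance, ncol = 1L)
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  k <- ncol(reflectance)
  tissue <- rep_len(as.character(tissue), k)
  patient <- rep_len(as.character(patient), k)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = reflectance),
    rowData = S4Vectors::DataFrame(wavelength = as.numeric(wavelengths)),
    colData = S4Vectors::DataFrame(tissue = tissue, patient = patient)
  )
  new("SpectralLibrary", se)
}

#' @describeIn SpectralLibrary number of wavelength bands L.
#' @param x a \code{SpectralLibrary}.
#' @export
nBands <- function(x) nrow(x)

#' @describeIn SpectralLibrary number of spectra K.
#' @export
nSpectra <- function(x) ncol(x)

#' @describeIn SpectralLibrary the L x K reflectance matrix.
#' @export
reflectance <- function(x) SummarizedExperiment::assay(x, "reflectance")

#' @describeIn SpectralLibrary the wavelength grid (nm).
#' @export
wavelengths <- function(x) {
  if (is(x, "SummarizedExperiment")) SummarizedExperiment::rowData(x)$wavelength
  else attr(x, "wavelengths")
}

#' @describeIn SpectralLibrary tissue label per spectrum.
#' @export
tissueLabel <- function(x) as.character(SummarizedExperiment::colData(x)$tissue)

#' @describeIn SpectralLibrary patient identifier per spectrum.
#' @export
patientId <- function(x) as.character(SummarizedExperiment::colData(x)$patient)

setMethod("show", "SpectralLibrary", function(object) {
  cat("SpectralLibrary with", ncol(object), "spectra over", nrow(object),
      "bands\n")
  w <- wavelengths(object)
  cat(sprintf("  wavelengths: %g-%g nm\n", min(w), max(w)))
  cat("  tissues:", paste(sort(unique(tissueLabel(object))), collapse = ", "),
      "\n")
  cat("  patients:", length(unique(patientId(object))), "\n")
})

#' Hypercube: a small annotated hyperspectral image
#'
#' Stores a reflectance array of shape (x, y, band), its wavelength grid, an
#' integer annotation mask of shape (x, y) with 0 meaning unlabeled, and a
#' map from mask ids to tissue names.
#'
#' @slot data 3-d numeric array (x, y, band).
#' @slot wavelengths numeric, strictly increasing, length = band dimension.
#' @slot labels integer matrix (x, y); 0 = unlabeled.
#' @slot labelNames named character vector mapping mask id (name) to tissue.
#' @exportClass Hypercube
setClass("Hypercube", representation(
  data = "array", wavelengths = "numeric",
  labels = "matrix", labelNames = "character"))

.validHypercube <- function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-d (x, y, band) array")
  else {
    if (d[3] != length(object@wavelengths))
      msg <- c(msg, "band dimension must equal length of wavelength grid")
    if (!all(dim(object@labels) == d[1:2]))
      msg <- c(msg, "labels mask must have shape (x, y)")
  }
  if (any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  ids <- setdiff(unique(as.integer(object@labels)), 0L)
  missing <- setdiff(as.character(ids), names(object@labelNames))
  if (length(missing))
    msg <- c(msg, paste("mask ids without a tissue name:",
                        paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("Hypercube", .validHypercube)

#' Construct a Hypercube
#'
#' @param data 3-d numeric array (x, y, band).
#' @param wavelengths band centers in nm.
#' @param labels integer (x, y) mask, 0 = unlabeled.
#' @param labelNames named character vector, names are mask ids as strings.
#' @return a \linkS4class{Hypercube}.
#' @export
Hypercube <- function(data, wavelengths, labels, labelNames) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  new("Hypercube", data = data, wavelengths = as.numeric(wavelengths),
      labels = labels, labelNames = labelNames)
}

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@data)
  cat(sprintf("Hypercube %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
  cat("  labeled pixels:", sum(object@labels != 0L), "of", d[1] * d[2], "\n")
  cat("  tissues:", paste(object@labelNames, collapse = ", "), "\n")
})

#' ClusterModel: per-tissue K-means reference clusters
#'
#' Reference spectra of each tissue are partitioned by K-means (Euclidean, on
#' the spectra themselves) into \code{k} clusters; each cluster is summarised
#' by its center (the bandwise mean of its members). Label checking and label
#' suggestion then compare a target spectrum to these centers under a chosen
#' spectral similarity measure.
#'
#' @slot centers L x C matrix of cluster-center spectra.
#' @slot tissue tissue label of each center.
#' @slot cluster within-tissue cluster index of each center.
#' @slot measure name of the similarity measure the model is intended for.
#' @slot assignments data.frame with one row per reference spectrum:
#'   \code{index} (column in the reference library), \code{tissue},
#'   \code{cluster}.
#' @slot k requested clusters per tissue.
#' @slot wavelengths the shared wavelength grid.
#' @exportClass ClusterModel
setClass("ClusterModel", representation(
  centers = "matrix", tissue = "character", cluster = "integer",
  measure = "character", assignments = "data.frame", k = "integer",
  wavelengths = "numeric"))

.validClusterModel <- function(object) {
  msg <- character(0)
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (ncol(object@centers) != length(object@tissue) ||
      ncol(object@centers) != length(object@cluster))
    msg <- c(msg, "centers, tissue and cluster must agree in length")
  if (nrow(object@centers) != length(object@wavelengths))
    msg <- c(msg, "center length must match wavelength grid")
  if (length(msg)) msg else TRUE
}
setValidity("ClusterModel", .validClusterModel)

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel:", ncol(object@centers), "centers over",
      length(unique(object@tissue)), "tissues (k =", object@k,
      ", measure =", object@measure, ")\n")
})
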