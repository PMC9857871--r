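# Library CSV dialect: header `tissue,patient,w500,w505,...`, one spectrum
# per row, '.' decimal separator, UTF-8, labels quoted only when they contain
# a comma, a quote or leading/trailing whitespace. Reflectance is written
# with 17 significant digits so a read/write cycle is lossless.

.quoteField <- function(x) {
  need <- grepl('[",]', x) | grepl("^\\s|\\s$", x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

.fmtNum <- function(x) {
  out <- formatC(x, digits = 17, format = "g", width = 1)
  gsub(" ", "", out)
}

#' Read a labeled spectral library from CSV/TSV
#'
#' The first two columns must be \code{tissue} and \code{patient}; every
#' remaining column is a wavelength band named \code{w<nm>} (for example
#' \code{w500}). One spectrum per row.
#'
#' @param path file to read.
#' @param sep field separator; \code{","} (default) or \code{"\t"}. Files
#'   ending in \code{.tsv} default to tab.
#' @return a \linkS4class{SpectralLibrary}.
#' @export
readSpectralLibrary <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  nf <- count.fields(path, sep = sep, quote = '"', comment.char = "")
  if (length(unique(nf)) > 1L)
    stop("format error: ragged rows in ", path,
         " (fields per row: ", paste(unique(nf), collapse = "/"), ")")
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 colClasses = "character", fileEncoding = "UTF-8")
  hdr <- colnames(df)
  if (length(hdr) < 4L || hdr[1] != "tissue" || hdr[2] != "patient")
    stop("format error: header must start with 'tissue,patient'")
  wcols <- hdr[-(1:2)]
  if (!all(grepl("^w[0-9]+(\\.[0-9]+)?$", wcols)))
    stop("format error: band columns must be named w<nm>")
  w <- as.numeric(sub("^w", "", wcols))
  if (any(diff(w) <= 0))
    stop("format error: wavelength header not strictly increasing")
  if (nrow(df) < 1L) stop("format error: no data rows")
  refl <- suppressWarnings(
    vapply(seq_len(nrow(df)), function(i) as.numeric(df[i, -(1:2)]),
           numeric(length(w))))
  if (anyNA(refl))
    stop("value error: non-numeric reflectance value in ", path)
  SpectralLibrary(refl, wavelengths = w,
                  tissue = df$tissue, patient = df$patient)
}

#' Write a spectral library in the canonical CSV dialect
#'
#' Output is deterministic: rereading with \code{\link{readSpectralLibrary}}
#' and writing again reproduces the file byte for byte.
#'
#' @param lib a \linkS4class{SpectralLibrary}.
#' @param path destination file.
#' @param sep field separator, default comma.
#' @return invisibly, \code{path}.
#' @export
writeSpectralLibrary <- function(lib, path, sep = ",") {
  stopifnot(is(lib, "SpectralLibrary"))
  validObject(lib)
  w <- wavelengths(lib)
  hdr <- paste(c("tissue", "patient", paste0("w", .fmtNum(w))),
               collapse = sep)
  m <- reflectance(lib)
  rows <- vapply(seq_len(ncol(m)), function(j) {
    paste(c(.quoteField(tissueLabel(lib)[j]), .quoteField(patientId(lib)[j]),
            .fmtNum(m[, j])), collapse = sep)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, rows), con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read / write a hypercube container
#'
#' The cube container is a compressed R serialization of a plain list with
#' keys \code{data}, \code{labels}, \code{wavelengths} and
#' \code{label_names}.
#'
#' @param path container file.
#' @return \code{readHypercube}: a \linkS4class{Hypercube}.
#' @export
readHypercube <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- readRDS(path)
  need <- c("data", "labels", "wavelengths", "label_names")
  if (!is.list(obj) || !all(need %in% names(obj)))
    stop("format error: cube container must hold keys ",
         paste(need, collapse = ", "))
  Hypercube(obj$data, obj$wavelengths, obj$labels, obj$label_names)
}

#' @rdname readHypercube
#' @param cube a \linkS4class{Hypercube}.
#' @export
writeHypercube <- function(cube, path) {
  stopifnot(is(cube, "Hypercube"))
  validObject(cube)
  saveRDS(list(data = cube@data, labels = cube@labels,
               wavelengths = cube@wavelengths,
               label_names = cube@labelNames),
          file = path, compress = "gzip")
  invisible(path)
}

#' Extract labeled spectra from an annotated hypercube
#'
#' Produces one library entry per nonzero mask pixel; per-tissue counts equal
#' the mask pixel counts and reflectance values are carried over unchanged.
#' Pixels are visited in column-major (x fastest) order.
#'
#' @param cube a \linkS4class{Hypercube}.
#' @param patient patient identifier to attach to every extracted spectrum
#'   (the mask does not carry one).
#' @return a \linkS4class{SpectralLibrary}.
#' @export
extractLabeled <- function(cube, patient = "cube") {
  stopifnot(is(cube, "Hypercube"))
  validObject(cube)
  idx <- which(cube@labels != 0L)
  if (!length(idx)) stop("empty-library error: mask has no labeled pixels")
  d <- dim(cube@data)
  xy <- arrayInd(idx, dim(cube@labels))
  refl <- vapply(seq_len(nrow(xy)),
                 function(i) cube@data[xy[i, 1], xy[i, 2], ],
                 numeric(d[3]))
  tiss <- cube@labelNames[as.character(cube@labels[idx])]
  SpectralLibrary(refl, wavelengths = cube@wavelengths,
                  tissue = unname(tiss), patient = patient)
}
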