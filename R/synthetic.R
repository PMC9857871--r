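# Deterministic synthetic spectral data with the structure the measures and
# the QC procedure assume: a smooth per-tissue characteristic curve, a
# per-(patient, tissue) multiplicative/additive perturbation, and bandwise
# Gaussian noise per spectrum. Baselines are sums of Gaussian bumps shaped
# loosely on visible hemoglobin absorption (dips near 540-580 nm) and a
# near-infrared reflectance plateau.

#' Define a synthetic tissue spectral model
#'
#' @param tissue tissue label.
#' @param bumps data.frame with columns \code{center} (nm), \code{width}
#'   (nm, Gaussian sd) and \code{amplitude} (reflectance units; negative
#'   amplitudes carve absorption dips).
#' @param offset constant reflectance offset.
#' @param patientScaleSd sd of the per-(patient, tissue) multiplicative
#'   factor (mean 1, truncated below at 0.2).
#' @param patientShiftSd sd of the per-(patient, tissue) additive offset.
#' @param noiseSd sd of the bandwise Gaussian noise per spectrum.
#' @return an object of class \code{TissueSpectralModel}.
#' @export
tissueSpectralModel <- function(tissue, bumps, offset = 0,
                                patientScaleSd = 0.08,
                                patientShiftSd = 0.01, noiseSd = 0.01) {
  stopifnot(nzchar(tissue),
            all(c("center", "width", "amplitude") %in% names(bumps)),
            patientScaleSd >= 0, patientShiftSd >= 0, noiseSd >= 0)
  structure(list(tissue = tissue, bumps = as.data.frame(bumps),
                 offset = offset, patientScaleSd = patientScaleSd,
                 patientShiftSd = patientShiftSd, noiseSd = noiseSd),
            class = "TissueSpectralModel")
}

#' Evaluate a tissue model's baseline curve on a wavelength grid
#'
#' @param model a \code{\link{tissueSpectralModel}}.
#' @param wl numeric wavelength grid in nm.
#' @return positive numeric baseline reflectance (an error if any bump
#'   combination drives the curve nonpositive).
#' @export
baselineCurve <- function(model, wl = seq(500, 995, by = 5)) {
  stopifnot(inherits(model, "TissueSpectralModel"))
  b <- rep(model$offset, length(wl))
  for (i in seq_len(nrow(model$bumps))) {
    bb <- model$bumps[i, ]
    b <- b + bb$amplitude * exp(-0.5 * ((wl - bb$center) / bb$width)^2)
  }
  if (any(b <= 0))
    stop("invalid model '", model$tissue, "': baseline nonpositive on grid")
  b
}

.bumps <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(center = m[, 1], width = m[, 2], amplitude = m[, 3])
}

#' Default synthetic tissue suite
#'
#' Ten deterministic tissue models over the 500-995 nm grid. The suite
#' encodes a documented separability ordering: thyroid and parathyroid are
#' deliberately near-identical in shape (hardest pair), colon / small
#' intestine / stomach form a second similar group, while gauze (bright,
#' flat) and instrument (dark, blue-tilted) are far from every biological
#' tissue.
#'
#' @return named list of \code{\link{tissueSpectralModel}} objects.
#' @export
defaultTissueSuite <- function() {
  suite <- list(
    tissueSpectralModel("thyroid", .bumps(
      780, 150, 0.46,  542, 12, -0.060,  576, 12, -0.062,  640, 40, 0.05),
      offset = 0.18),
    tissueSpectralModel("parathyroid", .bumps(
      790, 150, 0.48,  542, 12, -0.052,  576, 12, -0.055,  640, 40, 0.06),
      offset = 0.20),
    tissueSpectralModel("skin", .bumps(
      820, 180, 0.34,  545, 14, -0.040,  575, 14, -0.042,  960, 40, -0.03),
      offset = 0.26),
    tissueSpectralModel("muscle", .bumps(
      760, 140, 0.40,  544, 12, -0.055,  578, 12, -0.058,  900, 60, 0.04),
      offset = 0.12),
    tissueSpectralModel("nerve", .bumps(
      700, 160, 0.30,  548, 16, -0.030,  930, 30, -0.025),
      offset = 0.24),
    tissueSpectralModel("colon", .bumps(
      770, 150, 0.38,  543, 12, -0.050,  577, 12, -0.050,  700, 60, 0.06),
      offset = 0.16),
    tissueSpectralModel("small_intestine", .bumps(
      775, 150, 0.40,  543, 12, -0.046,  577, 12, -0.048,  700, 60, 0.07),
      offset = 0.17),
    tissueSpectralModel("stomach", .bumps(
      765, 150, 0.36,  544, 12, -0.052,  578, 12, -0.050,  710, 55, 0.05),
      offset = 0.15),
    tissueSpectralModel("gauze", .bumps(
      600, 300, 0.12,  850, 200, 0.05),
      offset = 0.72, patientScaleSd = 0.03, patientShiftSd = 0.005),
    tissueSpectralModel("instrument", .bumps(
      520, 120, 0.08,  950, 300, 0.04),
      offset = 0.09, patientScaleSd = 0.03, patientShiftSd = 0.005)
  )
  names(suite) <- vapply(suite, `[[`, "", "tissue")
  suite
}

#' Simulation configuration
#'
#' @param models list of \code{\link{tissueSpectralModel}} objects.
#' @param nPatients number of simulated patients (default 10); each patient
#'   contributes spectra of every tissue.
#' @param spectraPerTissue spectra per tissue per patient (default 5).
#' @param seed integer RNG seed; the full draw is deterministic in it.
#' @param mislabelFraction fraction in [0, 1) of entries whose recorded
#'   label is swapped uniformly to another tissue (truth kept separately).
#' @param wavelengths wavelength grid, default 500-995 nm at 5 nm.
#' @return an object of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(models = defaultTissueSuite(), nPatients = 10L,
                             spectraPerTissue = 5L, seed = 1L,
                             mislabelFraction = 0,
                             wavelengths = seq(500, 995, by = 5)) {
  if (!length(models)) stop("configuration error: need at least one model")
  if (nPatients < 1L || spectraPerTissue < 1L)
    stop("configuration error: nPatients and spectraPerTissue must be >= 1")
  if (mislabelFraction < 0 || mislabelFraction >= 1)
    stop("configuration error: mislabelFraction must be in [0, 1)")
  structure(list(models = models, nPatients = as.integer(nPatients),
                 spectraPerTissue = as.integer(spectraPerTissue),
                 seed = as.integer(seed),
                 mislabelFraction = mislabelFraction,
                 wavelengths = as.numeric(wavelengths)),
            class = "SimulationConfig")
}

.patientNames <- function(n) sprintf("p%02d", seq_len(n))

.drawSpectra <- function(model, wl, n) {
  base <- baselineCurve(model, wl)
  scale <- max(0.2, 1 + rnorm(1, 0, model$patientScaleSd))
  shift <- rnorm(1, 0, model$patientShiftSd)
  noise <- matrix(rnorm(length(wl) * n, 0, model$noiseSd), length(wl), n)
  pmax(scale * base + shift + noise, 1e-4)
}

#' Sample a labeled synthetic spectral library
#'
#' Each spectrum is \code{scale * baseline + shift + noise}, clipped to stay
#' positive, where scale and shift are drawn once per (patient, tissue) and
#' the noise bandwise per spectrum. When \code{mislabelFraction > 0}, a
#' uniformly chosen subset of entries has its recorded tissue label swapped
#' to a different, uniformly chosen tissue; the generating truth is returned
#' alongside.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with \code{library} (a \linkS4class{SpectralLibrary} carrying
#'   the possibly-corrupted labels) and \code{truth} (data.frame with
#'   \code{index}, \code{tissue_true}, \code{tissue_assigned},
#'   \code{mislabeled}).
#' @export
sampleLibrary <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  wl <- cfg$wavelengths
  pats <- .patientNames(cfg$nPatients)
  .withSeed(cfg$seed, {
    cols <- list(); tiss <- character(0); pat <- character(0)
    for (model in cfg$models) {
      for (p in pats) {
        cols[[length(cols) + 1L]] <-
          .drawSpectra(model, wl, cfg$spectraPerTissue)
        tiss <- c(tiss, rep(model$tissue, cfg$spectraPerTissue))
        pat <- c(pat, rep(p, cfg$spectraPerTissue))
      }
    }
    m <- do.call(cbind, cols)
    k <- ncol(m)
    truth <- data.frame(index = seq_len(k), tissue_true = tiss,
                        tissue_assigned = tiss, mislabeled = FALSE)
    nMis <- round(cfg$mislabelFraction * k)
    if (nMis > 0L) {
      allT <- vapply(cfg$models, `[[`, "", "tissue")
      idx <- sample.int(k, nMis)
      for (i in idx) {
        truth$tissue_assigned[i] <- sample(setdiff(allT, tiss[i]), 1L)
        truth$mislabeled[i] <- TRUE
      }
    }
    list(library = SpectralLibrary(m, wl, truth$tissue_assigned, pat),
         truth = truth)
  })
}

#' Sample a small annotated hypercube
#'
#' Fills rectangular regions of an otherwise-unlabeled cube with spectra
#' drawn from the corresponding tissue models; the mask matches the layout
#' exactly and unlabeled pixels hold a dim constant background.
#'
#' @param cfg a \code{\link{simulationConfig}} (its models and seed are
#'   used).
#' @param width,height cube dimensions in pixels.
#' @param layout data.frame with columns \code{tissue}, \code{x0},
#'   \code{y0}, \code{w}, \code{h} (1-based corner, block size).
#' @return a \linkS4class{Hypercube}.
#' @export
sampleCube <- function(cfg, width, height, layout) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            all(c("tissue", "x0", "y0", "w", "h") %in% names(layout)))
  wl <- cfg$wavelengths
  occ <- matrix(FALSE, width, height)
  labels <- matrix(0L, width, height)
  data <- array(0.05, dim = c(width, height, length(wl)))
  modelNames <- vapply(cfg$models, `[[`, "", "tissue")
  .withSeed(cfg$seed, {
    for (i in seq_len(nrow(layout))) {
      r <- layout[i, ]
      xs <- r$x0:(r$x0 + r$w - 1L); ys <- r$y0:(r$y0 + r$h - 1L)
      if (max(xs) > width || max(ys) > height || min(xs) < 1L || min(ys) < 1L)
        stop("layout error: region ", i, " does not fit in the cube")
      if (any(occ[xs, ys])) stop("layout error: overlapping regions")
      occ[xs, ys] <- TRUE
      mi <- match(r$tissue, modelNames)
      if (is.na(mi)) stop("layout error: no model for tissue '", r$tissue, "'")
      sp <- .drawSpectra(cfg$models[[mi]], wl, length(xs) * length(ys))
      px <- 1L
      for (y in ys) for (x in xs) {
        data[x, y, ] <- sp[, px]
        px <- px + 1L
      }
      labels[xs, ys] <- i
    }
  })
  Hypercube(data, wl, labels,
            setNames(as.character(layout$tissue), seq_len(nrow(layout))))
}
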