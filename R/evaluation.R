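# Patient-wise cross-validation: spectra of one patient never appear in both
# the reference (training) and target (test) side of a fold.

.checkFoldPlan <- function(plan, patients) {
  test <- unlist(lapply(plan, `[[`, "test"))
  if (anyDuplicated(test))
    stop("invalid fold plan: a patient appears in two test sets")
  if (!setequal(test, patients))
    stop("invalid fold plan: test sets do not cover all patients")
  invisible(TRUE)
}

#' Leave-one-patient-out cross-validation plan
#'
#' One fold per patient: fold i tests patient i against references from all
#' remaining patients.
#'
#' @param lib a \linkS4class{SpectralLibrary} with >= 2 patients.
#' @return a \code{FoldPlan}: list of folds, each a list with character
#'   vectors \code{train} and \code{test}.
#' @export
lopocvPlan <- function(lib) {
  stopifnot(is(lib, "SpectralLibrary"))
  patients <- sort(unique(patientId(lib)))
  if (length(patients) < 2L)
    stop("configuration error: leave-one-patient-out needs >= 2 patients")
  plan <- lapply(patients, function(p)
    list(train = setdiff(patients, p), test = p))
  structure(plan, class = "FoldPlan")
}

#' Patient-grouped, class-balanced k-fold plan
#'
#' Splits patients (not spectra) into k folds so no patient appears in two
#' folds, while keeping per-class spectrum proportions approximately equal
#' across folds. Exact stratification is impossible with patient-level
#' atoms, so patients are assigned greedily (largest first, ties shuffled by
#' \code{seed}) to the fold where they best reduce the squared deviation
#' from the ideal per-fold class counts.
#'
#' @param lib a \linkS4class{SpectralLibrary}.
#' @param k number of folds (<= number of patients).
#' @param seed integer seed for tie shuffling.
#' @return a \code{FoldPlan} of k folds.
#' @export
groupedKfoldPlan <- function(lib, k = 10L, seed = 1L) {
  stopifnot(is(lib, "SpectralLibrary"))
  k <- as.integer(k)
  patients <- sort(unique(patientId(lib)))
  if (length(patients) < k)
    stop("configuration error: fewer patients (", length(patients),
         ") than folds (", k, ")")
  classes <- sort(unique(tissueLabel(lib)))
  counts <- table(factor(patientId(lib), patients),
                  factor(tissueLabel(lib), classes))
  ideal <- colSums(counts) / k
  ord <- .withSeed(seed, {
    sizes <- rowSums(counts)
    patients[order(-sizes, sample.int(length(patients)))]
  })
  foldCounts <- matrix(0, k, length(classes))
  foldPatients <- vector("list", k)
  for (p in ord) {
    pc <- counts[p, ]
    score <- vapply(seq_len(k), function(f)
      sum((foldCounts[f, ] + pc - ideal)^2), numeric(1))
    # ties go to the emptiest fold so every fold is populated
    f <- which.min(score + 1e-9 * rowSums(foldCounts))
    foldCounts[f, ] <- foldCounts[f, ] + pc
    foldPatients[[f]] <- c(foldPatients[[f]], p)
  }
  if (any(lengths(foldPatients) == 0L))
    for (f in which(lengths(foldPatients) == 0L)) {
      big <- which.max(lengths(foldPatients))
      mv <- foldPatients[[big]][length(foldPatients[[big]])]
      foldPatients[[big]] <- setdiff(foldPatients[[big]], mv)
      foldPatients[[f]] <- mv
    }
  plan <- lapply(foldPatients, function(test)
    list(train = setdiff(patients, test), test = sort(test)))
  .checkFoldPlan(plan, patients)
  structure(plan, class = "FoldPlan")
}

.subsetByPatients <- function(lib, pats) {
  keep <- patientId(lib) %in% pats
  SpectralLibrary(reflectance(lib)[, keep, drop = FALSE], wavelengths(lib),
                  tissueLabel(lib)[keep], patientId(lib)[keep])
}

#' Cross-validated evaluation of the annotation QC procedure
#'
#' For each fold, reference clusters and thresholds are built from the
#' training patients' spectra and every test spectrum (or per-(tissue,
#' patient) mean spectrum, the default) is checked. The QC-predicted label
#' of a target is its claimed label when confirmed, otherwise the suggested
#' label; accuracy is the proportion of targets whose predicted label equals
#' the claimed annotation, which the evaluation treats as ground truth.
#'
#' @param lib a \linkS4class{SpectralLibrary}.
#' @param plan a fold plan from \code{\link{lopocvPlan}} or
#'   \code{\link{groupedKfoldPlan}}.
#' @param name similarity measure name or alias.
#' @param kClusters clusters per tissue.
#' @param seed integer seed.
#' @param perSpectrum evaluate every spectrum individually instead of
#'   per-(tissue, patient) means.
#' @param rule confirmation rule, see \code{\link{checkLabel}}.
#' @return list of class \code{qcEvaluation}: \code{decisions} (data.frame
#'   with fold, claimed, verdict, suggested, predicted), \code{accuracy},
#'   \code{perTissueAccuracy}, \code{nTargets}.
#' @export
evaluateAnnotationQc <- function(lib, plan, name = "SID-JM-TAN(SAM)",
                                 kClusters = 2L, seed = 1L,
                                 perSpectrum = FALSE,
                                 rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(is(lib, "SpectralLibrary"), inherits(plan, "FoldPlan"))
  .checkFoldPlan(plan, sort(unique(patientId(lib))))
  decisions <- NULL
  for (f in seq_along(plan)) {
    refs <- .subsetByPatients(lib, plan[[f]]$train)
    targets <- .subsetByPatients(lib, plan[[f]]$test)
    if (!perSpectrum) targets <- patientMeanSpectra(targets)
    dec <- qcLibrary(targets, refs, name = name, k = kClusters,
                     seed = seed, rule = rule)
    dec$fold <- f
    decisions <- rbind(decisions, dec)
  }
  decisions$predicted <- ifelse(decisions$verdict == "confirmed",
                                decisions$claimed, decisions$suggested)
  correct <- decisions$predicted == decisions$claimed
  perTissue <- tapply(correct, decisions$claimed, mean)
  structure(list(decisions = decisions,
                 accuracy = mean(correct),
                 perTissueAccuracy = perTissue,
                 nTargets = nrow(decisions)),
            class = "qcEvaluation")
}

#' @export
print.qcEvaluation <- function(x, ...) {
  cat(sprintf("Annotation QC evaluation: %d targets, accuracy %.3f\n",
              x$nTargets, x$accuracy))
  cat("Per-tissue accuracy:\n")
  print(round(x$perTissueAccuracy, 3))
  invisible(x)
}
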