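# Annotation quality control: reference spectra of each tissue are condensed
# to K-means cluster centers; a claimed label is confirmed when the target
# lies within the per-cluster mean-distance threshold of every center of the
# claimed tissue, and flagged spectra receive the label of the globally
# nearest center.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Build per-tissue K-means reference clusters
#'
#' Clustering runs in Euclidean space on the spectra themselves (standard
#' K-means); the stored \code{measure} is the one later used for thresholds
#' and decisions. A tissue with fewer spectra than \code{k} falls back to a
#' single cluster with a warning. Fixed \code{seed} gives an identical
#' partition on every run.
#'
#' @param refs reference \linkS4class{SpectralLibrary}.
#' @param k clusters per tissue (default 2).
#' @param name similarity measure name or alias.
#' @param seed integer RNG seed for the K-means starts.
#' @return a \linkS4class{ClusterModel}.
#' @export
buildReferenceClusters <- function(refs, k = 2L, name = "SID-JM-TAN(SAM)",
                                   seed = 1L) {
  stopifnot(is(refs, "SpectralLibrary"))
  name <- canonicalMeasureName(name)
  k <- as.integer(k)
  if (k < 1L) stop("configuration error: k must be >= 1")
  tissues <- sort(unique(tissueLabel(refs)))
  centers <- NULL; ctis <- character(0); cclu <- integer(0)
  assign_ <- data.frame(index = integer(0), tissue = character(0),
                        cluster = integer(0))
  .withSeed(seed, {
    for (tt in tissues) {
      idx <- which(tissueLabel(refs) == tt)
      X <- t(reflectance(refs)[, idx, drop = FALSE])
      kt <- k
      if (nrow(X) < k) {
        warning("tissue '", tt, "' has fewer than k spectra; using k = 1")
        kt <- 1L
      }
      if (kt == 1L) {
        cen <- matrix(colMeans(X), nrow = 1L)
        cl <- rep(1L, nrow(X))
      } else {
        km <- kmeans(X, centers = kt, nstart = 5L, iter.max = 100L)
        # relabel clusters deterministically: by center order along band 1
        ord <- order(km$centers[, 1L], km$centers[, min(2L, ncol(km$centers))])
        relab <- match(seq_len(kt), ord)
        cl <- relab[km$cluster]
        cen <- km$centers[ord, , drop = FALSE]
        # centers as bandwise member means (kmeans guarantees this already)
        for (ci in seq_len(kt))
          cen[ci, ] <- colMeans(X[cl == ci, , drop = FALSE])
      }
      centers <- cbind(centers, t(cen))
      ctis <- c(ctis, rep(tt, nrow(cen)))
      cclu <- c(cclu, seq_len(nrow(cen)))
      assign_ <- rbind(assign_, data.frame(index = idx, tissue = tt,
                                           cluster = cl))
    }
  })
  new("ClusterModel", centers = centers, tissue = ctis,
      cluster = as.integer(cclu), measure = name,
      assignments = assign_, k = k, wavelengths = wavelengths(refs))
}

#' Per-cluster confirmation thresholds
#'
#' The threshold of cluster center \code{r} of a tissue is the arithmetic
#' mean of the similarity measure between \code{r} and every reference
#' spectrum assigned to that cluster. A singleton cluster yields threshold 0
#' (confirmation through it is then impossible) with a warning.
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param refs the reference library the model was built from.
#' @param ... passed to \code{\link{spectralSimilarity}}.
#' @return data.frame with columns \code{tissue}, \code{cluster},
#'   \code{threshold}.
#' @export
computeThresholds <- function(model, refs, ...) {
  stopifnot(is(model, "ClusterModel"), is(refs, "SpectralLibrary"))
  m <- reflectance(refs)
  out <- data.frame(tissue = model@tissue, cluster = model@cluster,
                    threshold = NA_real_)
  for (ci in seq_along(model@tissue)) {
    members <- model@assignments$index[
      model@assignments$tissue == model@tissue[ci] &
        model@assignments$cluster == model@cluster[ci]]
    if (length(members) <= 1L) {
      warning("singleton cluster for tissue '", model@tissue[ci],
              "': threshold 0 makes confirmation impossible; consider smaller k")
      out$threshold[ci] <- 0
    } else {
      vals <- vapply(members, function(j)
        spectralSimilarity(model@measure, model@centers[, ci], m[, j], ...),
        numeric(1))
      out$threshold[ci] <- mean(vals)
    }
  }
  out
}

.thresholdFor <- function(thresholds, tissue, cluster) {
  thresholds$threshold[thresholds$tissue == tissue &
                         thresholds$cluster == cluster]
}

#' Check the claimed label of one target spectrum
#'
#' The claim is confirmed when the measure between the target and a cluster
#' center of the claimed tissue is strictly below that cluster's threshold
#' --- by default for every center of the claimed tissue (\code{rule =
#' "all"}, the strict reading); \code{rule = "any"} relaxes this to at least
#' one center.
#'
#' @param t numeric target spectrum.
#' @param claimed claimed tissue label.
#' @param model a \linkS4class{ClusterModel}.
#' @param thresholds output of \code{\link{computeThresholds}}.
#' @param rule \code{"all"} (default) or \code{"any"}.
#' @return list with \code{verdict} ("confirmed" or "flagged") and
#'   \code{values}, the per-cluster measure values of the claimed tissue.
#' @export
checkLabel <- function(t, claimed, model, thresholds,
                       rule = c("all", "any")) {
  rule <- match.arg(rule)
  sel <- which(model@tissue == claimed)
  if (!length(sel))
    stop("lookup error: tissue '", claimed, "' not in cluster model")
  vals <- vapply(sel, function(ci)
    spectralSimilarity(model@measure, t, model@centers[, ci]), numeric(1))
  thr <- vapply(sel, function(ci)
    .thresholdFor(thresholds, model@tissue[ci], model@cluster[ci]),
    numeric(1))
  ok <- vals < thr
  verdict <- if ((rule == "all" && all(ok)) || (rule == "any" && any(ok)))
    "confirmed" else "flagged"
  list(verdict = verdict,
       values = setNames(vals, paste0(claimed, "/", model@cluster[sel])),
       thresholds = setNames(thr, paste0(claimed, "/", model@cluster[sel])))
}

#' Suggest a label for a target spectrum
#'
#' Returns the tissue of the cluster center with the globally smallest
#' similarity measure value. Exact ties are broken in favour of the
#' lexicographically first tissue and reported via \code{tie}.
#'
#' @param t numeric target spectrum.
#' @param model a \linkS4class{ClusterModel}.
#' @return list with \code{label}, \code{value} (the minimal measure) and
#'   logical \code{tie}.
#' @export
suggestLabel <- function(t, model) {
  stopifnot(is(model, "ClusterModel"))
  vals <- vapply(seq_along(model@tissue), function(ci)
    spectralSimilarity(model@measure, t, model@centers[, ci]), numeric(1))
  best <- min(vals)
  cand <- sort(unique(model@tissue[vals == best]))
  list(label = cand[1L], value = best, tie = length(cand) > 1L)
}

#' Annotation QC over a whole target library
#'
#' Builds per-tissue reference clusters and thresholds from \code{refs},
#' checks every target's claimed label, and attaches a suggested label to
#' every flagged target.
#'
#' @param targets target \linkS4class{SpectralLibrary} (claimed labels in its
#'   tissue column).
#' @param refs reference \linkS4class{SpectralLibrary}.
#' @param name similarity measure name or alias.
#' @param k clusters per tissue.
#' @param seed integer seed (K-means reproducibility).
#' @param rule confirmation rule, see \code{\link{checkLabel}}.
#' @return data.frame with one row per target: \code{index}, \code{claimed},
#'   \code{patient}, \code{verdict}, \code{suggested} (NA when confirmed),
#'   \code{minValue}, \code{tie}.
#' @export
qcLibrary <- function(targets, refs, name = "SID-JM-TAN(SAM)", k = 2L,
                      seed = 1L, rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(is(targets, "SpectralLibrary"), is(refs, "SpectralLibrary"))
  if (!isTRUE(all.equal(wavelengths(targets), wavelengths(refs))))
    stop("configuration error: wavelength grids differ")
  model <- buildReferenceClusters(refs, k = k, name = name, seed = seed)
  thresholds <- computeThresholds(model, refs)
  m <- reflectance(targets)
  n <- ncol(m)
  out <- data.frame(index = seq_len(n), claimed = tissueLabel(targets),
                    patient = patientId(targets),
                    verdict = character(n), suggested = NA_character_,
                    minValue = NA_real_, tie = FALSE)
  for (j in seq_len(n)) {
    chk <- checkLabel(m[, j], out$claimed[j], model, thresholds, rule = rule)
    out$verdict[j] <- chk$verdict
    sug <- suggestLabel(m[, j], model)
    out$minValue[j] <- sug$value
    if (chk$verdict == "flagged") {
      out$suggested[j] <- sug$label
      out$tie[j] <- sug$tie
    }
  }
  out
}
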