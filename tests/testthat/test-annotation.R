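# Fixture: one tissue made of two tight, well-separated blobs, plus a
# second distant tissue. Blob geometry is known, so cluster recovery and
# the strict all-centers rule can be checked exactly.
twoBlobLibrary <- function(nPerBlob = 10, noise = 0.005, seed = 20) {
  set.seed(seed)
  wl <- defaultGrid
  blobA1 <- 0.3 + 0.4 * exp(-0.5 * ((wl - 700) / 120)^2)
  blobA2 <- blobA1 + 0.25
  blobB <- 0.8 - 0.4 * exp(-0.5 * ((wl - 700) / 120)^2)
  draw <- function(base, n) sapply(seq_len(n), function(i)
    pmax(base + rnorm(length(wl), 0, noise), 1e-4))
  m <- cbind(draw(blobA1, nPerBlob), draw(blobA2, nPerBlob),
             draw(blobB, nPerBlob))
  lib <- makeLibrary(m, tissue = rep(c("alpha", "alpha", "beta"),
                                     each = nPerBlob),
                     patient = rep("p1", 3 * nPerBlob), wl = wl)
  list(lib = lib, blobA1 = blobA1, blobA2 = blobA2, blobB = blobB)
}

test_that("K-means recovers known blob centers and is seed-deterministic", {
  fx <- twoBlobLibrary()
  model <- buildReferenceClusters(fx$lib, k = 2, name = "SAM", seed = 3)
  centersA <- model@centers[, model@tissue == "alpha"]
  # each blob mean recovered within a few noise standard errors
  errs <- apply(centersA, 2, function(cen)
    min(sqrt(mean((cen - fx$blobA1)^2)), sqrt(mean((cen - fx$blobA2)^2))))
  expect_true(all(errs < 0.005))
  # the two alpha centers sit in different blobs
  d1 <- apply(centersA, 2, function(cen) sqrt(mean((cen - fx$blobA1)^2)))
  expect_equal(sum(d1 < 0.005), 1L)
  # determinism
  model2 <- buildReferenceClusters(fx$lib, k = 2, name = "SAM", seed = 3)
  expect_identical(model@centers, model2@centers)
  expect_identical(model@assignments, model2@assignments)
})

test_that("k = 1 centers are tissue means; small tissues fall back to k = 1", {
  fx <- twoBlobLibrary()
  model <- buildReferenceClusters(fx$lib, k = 1, name = "SAM", seed = 3)
  expect_equal(model@centers[, model@tissue == "beta"],
               rowMeans(reflectance(fx$lib)[, tissueLabel(fx$lib) == "beta"]),
               ignore_attr = TRUE)
  tiny <- makeLibrary(cbind(randPositiveSpectrum(100)), tissue = "solo",
                      patient = "p1", wl = defaultGrid)
  expect_warning(buildReferenceClusters(tiny, k = 2, name = "SAM", seed = 1),
                 "fewer than k")
})

test_that("thresholds are within-cluster mean measure values", {
  fx <- twoBlobLibrary()
  model <- buildReferenceClusters(fx$lib, k = 2, name = "SAM", seed = 3)
  thr <- suppressWarnings(computeThresholds(model, fx$lib)) # beta is one tight blob: k-means isolates a singleton
  expect_equal(nrow(thr), 4L) # 2 tissues x 2 clusters
  expect_true(all(thr$threshold >= 0))
  # oracle: recompute the mean for one cluster by hand
  ci <- 1L
  members <- model@assignments$index[
    model@assignments$tissue == model@tissue[ci] &
      model@assignments$cluster == model@cluster[ci]]
  vals <- sapply(members, function(j)
    sam(model@centers[, ci], reflectance(fx$lib)[, j]))
  expect_equal(thr$threshold[ci], mean(vals), tolerance = 1e-12)
  # identical members give threshold 0 (with a singleton warning elsewhere)
  s <- randPositiveSpectrum(100)
  ident <- makeLibrary(cbind(s, s, s), tissue = "flat", patient = "p1",
                       wl = defaultGrid)
  mi <- buildReferenceClusters(ident, k = 1, name = "SAM", seed = 1)
  expect_equal(computeThresholds(mi, ident)$threshold, 0, tolerance = 1e-7)
})

test_that("label checking follows the strict all-centers rule", {
  fx <- twoBlobLibrary()
  model <- buildReferenceClusters(fx$lib, k = 2, name = "SAM", seed = 3)
  thr <- suppressWarnings(computeThresholds(model, fx$lib)) # beta is one tight blob: k-means isolates a singleton
  # a target equal to an alpha cluster center has m = 0 < T for that
  # cluster, but lies beyond the threshold of alpha's other (distant)
  # cluster: the literal all-centers rule flags it ...
  centerTarget <- model@centers[, which(model@tissue == "alpha")[1]]
  strict <- checkLabel(centerTarget, "alpha", model, thr, rule = "all")
  expect_equal(strict$verdict, "flagged")
  # ... while the relaxed any-center rule confirms it
  relaxed <- checkLabel(centerTarget, "alpha", model, thr, rule = "any")
  expect_equal(relaxed$verdict, "confirmed")
  # under all-centers, a target is confirmed when both alpha clusters hold
  # it below threshold: use a single-blob tissue (beta, k = 1 style blobs)
  modelB <- buildReferenceClusters(fx$lib, k = 1, name = "SAM", seed = 3)
  thrB <- computeThresholds(modelB, fx$lib)
  betaCenter <- modelB@centers[, modelB@tissue == "beta"]
  expect_equal(checkLabel(betaCenter, "beta", modelB, thrB)$verdict,
               "confirmed")
  # a far-away target is always flagged
  far <- rep(0.01, 100)
  expect_equal(checkLabel(far, "beta", modelB, thrB)$verdict, "flagged")
  expect_error(checkLabel(far, "gamma", model, thr), "lookup")
})

test_that("label suggestion takes the global argmin with lexicographic ties", {
  fx <- twoBlobLibrary()
  model <- buildReferenceClusters(fx$lib, k = 2, name = "SAM", seed = 3)
  # a beta center suggests beta
  betaCenter <- model@centers[, which(model@tissue == "beta")[1]]
  sug <- suggestLabel(betaCenter, model)
  expect_equal(sug$label, "beta")
  expect_equal(sug$value, 0, tolerance = 1e-9)
  expect_false(sug$tie)
  # duplicated centers across two tissues tie; lexicographic order wins
  s <- randPositiveSpectrum(100)
  dup <- new("ClusterModel",
             centers = cbind(s, s, s * 0.1 + 0.5),
             tissue = c("zeta", "acorn", "mid"),
             cluster = c(1L, 1L, 1L), measure = "SAM",
             assignments = data.frame(index = 1:3,
                                      tissue = c("zeta", "acorn", "mid"),
                                      cluster = rep(1L, 3)),
             k = 1L, wavelengths = defaultGrid)
  tied <- suggestLabel(s, dup)
  expect_equal(tied$label, "acorn")
  expect_true(tied$tie)
  # suggestion is invariant to duplicating a reference cluster
  dup2 <- new("ClusterModel",
              centers = cbind(dup@centers, s),
              tissue = c(dup@tissue, "zeta"),
              cluster = c(dup@cluster, 2L), measure = "SAM",
              assignments = dup@assignments, k = 1L,
              wavelengths = defaultGrid)
  expect_equal(suggestLabel(s, dup2)$label, "acorn")
})

test_that("qcLibrary flags permuted labels and recovers the true ones", {
  suite <- defaultTissueSuite()
  cfgT <- simulationConfig(models = suite, nPatients = 6,
                           spectraPerTissue = 4, seed = 31,
                           mislabelFraction = 0.1)
  cfgR <- simulationConfig(models = suite, nPatients = 6,
                           spectraPerTissue = 4, seed = 32)
  tl <- sampleLibrary(cfgT); rl <- sampleLibrary(cfgR)
  targets <- preprocessLibrary(tl$library)
  refs <- preprocessLibrary(rl$library)
  dec <- suppressWarnings(
    qcLibrary(targets, refs, name = "SID-JM-TAN(SAM)", k = 2, seed = 5))
  expect_equal(nrow(dec), nSpectra(targets))
  expect_true(all(dec$verdict %in% c("confirmed", "flagged")))
  expect_true(all(is.na(dec$suggested[dec$verdict == "confirmed"])))
  expect_true(all(!is.na(dec$suggested[dec$verdict == "flagged"])))
  mis <- tl$truth$mislabeled
  recovered <- dec$verdict[mis] == "flagged" &
    dec$suggested[mis] == tl$truth$tissue_true[mis]
  expect_gte(mean(recovered), 0.9)
  # determinism of the full QC decision set
  dec2 <- suppressWarnings(
    qcLibrary(targets, refs, name = "SID-JM-TAN(SAM)", k = 2, seed = 5))
  expect_identical(dec, dec2)
})
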