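test_that("SAM matches its closed-form values and preconditions", {
  s <- randPositiveSpectrum(50)
  expect_equal(sam(s, s), 0, tolerance = 1e-7)
  expect_equal(sam(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(sam(c(1, 0), c(1, 1)), pi / 4)
  expect_equal(sam(s, 3.7 * s), 0, tolerance = 1e-6) # scale invariance
  expect_error(sam(c(1, -1), c(1, 1)), "nonnegative")
  expect_error(sam(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("SID is a symmetric divergence with the hand-computed value", {
  p <- c(0.5, 0.5); q <- c(0.25, 0.75)
  # oracle: KL(p||q) + KL(q||p) with natural logs, evaluated directly
  expected <- sum(p * log(p / q)) + sum(q * log(q / p))
  expect_equal(sid(p, q), expected, tolerance = 1e-12)
  expect_equal(sid(p, q), 0.27465, tolerance = 1e-4)
  expect_equal(sid(p, p), 0)
  set.seed(8)
  for (i in 1:20) {
    a <- randPositiveSpectrum(30); b <- randPositiveSpectrum(30)
    expect_equal(sid(a, b), sid(b, a), tolerance = 1e-12)
  }
  # zero-mass bands are floored, never infinite
  expect_true(is.finite(sid(c(1, 0), c(0, 1))))
})

test_that("SCA maps Pearson correlation to [0, pi/2]", {
  s <- randPositiveSpectrum(40)
  expect_equal(sca(s, 2 * s + 1), 0)            # sigma = 1
  expect_equal(sca(c(1, 2, 3), c(3, 2, 1)), pi / 2) # sigma = -1
  expect_equal(sca(c(1, 2, 1, 2), c(1, 1, 2, 2)), pi / 3) # sigma = 0
  expect_error(sca(rep(1, 5), 1:5), "constant")
  # square-root literature variant stays in range and is smaller
  expect_equal(sca(c(1, 2, 1, 2), c(1, 1, 2, 2), sqrtTransform = TRUE),
               acos(sqrt(0.5)))
})

test_that("Bhattacharyya coefficient and JM distance match hand values", {
  p <- c(0.5, 0.5); q <- c(0.25, 0.75)
  expect_equal(bhattacharyyaCoefficient(p, p), 1, tolerance = 1e-12)
  expect_equal(bhattacharyyaCoefficient(c(1, 0), c(0, 1)), 0)
  expect_equal(bhattacharyyaCoefficient(p, q), sqrt(0.125) + sqrt(0.375),
               tolerance = 1e-12)
  expect_equal(bhattacharyyaCoefficient(p, q), 0.96593, tolerance = 1e-4)
  expect_equal(jmDistance(p, p), 0)
  expect_equal(jmDistance(c(1, 0), c(0, 1)), 2) # upper bound at disjoint support
  expect_equal(jmDistance(p, q), 2 * (1 - (sqrt(0.125) + sqrt(0.375))),
               tolerance = 1e-12)
  expect_equal(jmDistance(p, q), 0.06815, tolerance = 1e-4)
  # literal coefficient-exponent variant is capped at 2(1 - exp(-1))
  expect_equal(jmDistance(c(1, 0), c(0, 1), form = "coefficient"),
               2 * (1 - exp(-0)), tolerance = 1e-9)
  expect_lt(jmDistance(p, q, form = "coefficient"), 2 * (1 - exp(-1)) + 1e-12)
})

test_that("hybrids are exact products of their constituents", {
  set.seed(9)
  for (i in 1:20) {
    a <- randPositiveSpectrum(60); b <- randPositiveSpectrum(60)
    expect_equal(spectralSimilarity("SID-TAN(SAM)", a, b),
                 sid(a, b) * tan(sam(a, b)), tolerance = 1e-12)
    expect_equal(spectralSimilarity("SID-JM-TAN(SCA)", a, b),
                 sid(a, b) * jmDistance(a, b) * tan(sca(a, b)),
                 tolerance = 1e-12)
    # JM in [0, 2] bounds the JM-hybrid by twice its SID-TAN counterpart
    expect_lte(spectralSimilarity("SID-JM-TAN(SAM)", a, b),
               2 * spectralSimilarity("SID-TAN(SAM)", a, b) + 1e-12)
  }
  s <- randPositiveSpectrum(60)
  for (nm in spectralMeasureNames())
    expect_equal(spectralSimilarity(nm, s, s), 0, tolerance = 1e-6)
})

test_that("all eight measures are nonnegative, symmetric and bounded", {
  set.seed(10)
  for (i in 1:100) {
    a <- randPositiveSpectrum(100); b <- randPositiveSpectrum(100)
    expect_true(abs(cor(a, b)) <= 1)
    for (nm in spectralMeasureNames()) {
      v <- spectralSimilarity(nm, a, b)
      expect_true(is.finite(v) && v >= 0)
      expect_equal(v, spectralSimilarity(nm, b, a), tolerance = 1e-11)
    }
    expect_lte(sam(a, b), pi / 2)
    expect_lte(sca(a, b), pi / 2)
    expect_lte(jmDistance(a, b), 2)
  }
})

test_that("every measure matches the naive loop reference implementation", {
  set.seed(11)
  for (i in 1:100) {
    a <- randPositiveSpectrum(100); b <- randPositiveSpectrum(100)
    for (nm in spectralMeasureNames())
      expect_equal(spectralSimilarity(nm, a, b), naiveMeasure(nm, a, b),
                   tolerance = 1e-10, label = nm)
  }
})

test_that("measure names resolve through aliases and reject unknowns", {
  expect_equal(canonicalMeasureName("sid-jm-tan-sca"), "SID-JM-TAN(SCA)")
  expect_equal(canonicalMeasureName("SAM"), "SAM")
  expect_equal(canonicalMeasureName("sid-tan(sam)"), "SID-TAN(SAM)")
  expect_error(canonicalMeasureName("euclid"), "valid measures")
})

test_that("patient mean spectra aggregate by (tissue, patient)", {
  m <- cbind(rep(0, 10), rep(2, 10), rep(5, 10), rep(7, 10), rep(9, 10))
  lib <- makeLibrary(m, tissue = c("A", "A", "B", "B", "B"),
                     patient = c("p1", "p1", "p1", "p1", "p1"))
  out <- patientMeanSpectra(lib)
  expect_equal(nSpectra(out), 2L)
  expect_equal(reflectance(out)[, tissueLabel(out) == "A"], rep(1, 10),
               ignore_attr = TRUE)
  expect_equal(reflectance(out)[, tissueLabel(out) == "B"], rep(7, 10),
               ignore_attr = TRUE)
  # a group of identical spectra collapses to that spectrum
  s <- randPositiveSpectrum(10)
  lib2 <- makeLibrary(cbind(s, s, s), tissue = "A", patient = "p1")
  expect_equal(reflectance(patientMeanSpectra(lib2))[, 1], s,
               ignore_attr = TRUE)
})

test_that("pairwise matrices have the right shape and diagonal", {
  set.seed(12)
  m <- matrix(runif(300, 0.1, 1), nrow = 100)
  lib <- makeLibrary(m, tissue = c("A", "B", "C"),
                     patient = rep("p1", 3), wl = defaultGrid)
  pm <- pairwiseMatrix(lib, lib, "SAM")
  expect_equal(dim(pm), c(3L, 3L))
  expect_equal(unname(diag(pm)), rep(0, 3), tolerance = 1e-6)
  expect_equal(pm, t(pm), tolerance = 1e-11, ignore_attr = TRUE)
  sub <- makeLibrary(m[, 1:2], tissue = c("A", "B"), patient = "p1",
                     wl = defaultGrid)
  expect_equal(dim(pairwiseMatrix(sub, lib, "SID")), c(2L, 3L))
  other <- makeLibrary(m, tissue = c("A", "B", "C"), patient = "p1",
                       wl = defaultGrid + 1)
  expect_error(pairwiseMatrix(lib, other, "SAM"), "grids differ")
})
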