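# Shared fixtures and independent reference implementations.

defaultGrid <- seq(500, 995, by = 5)

randPositiveSpectrum <- function(L = 100) runif(L, min = 0.05, max = 1)

makeLibrary <- function(m, tissue, patient, wl = NULL) {
  m <- as.matrix(m)
  if (is.null(wl)) wl <- seq(500, by = 5, length.out = nrow(m))
  SpectralLibrary(m, wl, tissue, patient)
}

# Naive loop-based reference implementations, independent of the package's
# vectorized code paths.

naiveSAM <- function(si, sj) {
  num <- 0; ni <- 0; nj <- 0
  for (l in seq_along(si)) {
    num <- num + si[l] * sj[l]
    ni <- ni + si[l]^2
    nj <- nj + sj[l]^2
  }
  acos(min(1, num / sqrt(ni * nj)))
}

naiveProb <- function(s, floor = 0) {
  tot <- 0
  for (l in seq_along(s)) tot <- tot + s[l]
  p <- numeric(length(s))
  for (l in seq_along(s)) p[l] <- s[l] / tot
  if (floor > 0) {
    for (l in seq_along(p)) if (p[l] < floor) p[l] <- floor
    tot <- 0
    for (l in seq_along(p)) tot <- tot + p[l]
    for (l in seq_along(p)) p[l] <- p[l] / tot
  }
  p
}

naiveSID <- function(si, sj) {
  p <- naiveProb(si, floor = 1e-12)
  q <- naiveProb(sj, floor = 1e-12)
  acc <- 0
  for (l in seq_along(p))
    acc <- acc + p[l] * log(p[l] / q[l]) + q[l] * log(q[l] / p[l])
  acc
}

naivePearson <- function(x, y) {
  L <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y)
  sxx <- sum(x^2); syy <- sum(y^2)
  (L * sxy - sx * sy) / sqrt((L * sxx - sx^2) * (L * syy - sy^2))
}

naiveSCA <- function(si, sj) acos((naivePearson(si, sj) + 1) / 2)

naiveBC <- function(si, sj) {
  p <- naiveProb(si); q <- naiveProb(sj)
  acc <- 0
  for (l in seq_along(p)) acc <- acc + sqrt(p[l] * q[l])
  min(1, acc)
}

naiveJM <- function(si, sj) 2 * (1 - naiveBC(si, sj))

naiveTan <- function(a) tan(min(a, pi / 2 - 1e-9))

naiveMeasure <- function(name, si, sj) {
  switch(name,
    "SAM" = naiveSAM(si, sj),
    "SID" = naiveSID(si, sj),
    "SCA" = naiveSCA(si, sj),
    "JM" = naiveJM(si, sj),
    "SID-TAN(SAM)" = naiveSID(si, sj) * naiveTan(naiveSAM(si, sj)),
    "SID-TAN(SCA)" = naiveSID(si, sj) * naiveTan(naiveSCA(si, sj)),
    "SID-JM-TAN(SAM)" = naiveSID(si, sj) * naiveJM(si, sj) *
      naiveTan(naiveSAM(si, sj)),
    "SID-JM-TAN(SCA)" = naiveSID(si, sj) * naiveJM(si, sj) *
      naiveTan(naiveSCA(si, sj)))
}

naiveEntropyBits <- function(p) {
  p <- unname(p)
  acc <- 0
  for (k in seq_along(p)) if (p[k] > 0) acc <- acc - p[k] * log2(p[k])
  acc
}
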