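---
title: "Spectral similarity measures and annotation QC: models and methods"
author: "hsiSimilarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral similarity measures and annotation QC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsiSimilarity)
```

## The problem

Medical hyperspectral imaging records a full reflectance spectrum at every
pixel of a surgical scene, typically 100 bands between 500 and 1000 nm at
5 nm resolution. Discriminating tissue types (thyroid versus parathyroid,
colon versus small intestine, tissue versus gauze or instrument) from these
spectra, and checking whether a human annotator has labeled a region with
the right tissue, both reduce to the same primitive: a scalar measure of
how similar two spectra are. This package implements a family of such
measures, the statistics used to compare measures that live on different
scales, and a cluster-plus-threshold procedure that uses them to audit
tissue annotations.

## Data model

A `SpectralLibrary` extends `SummarizedExperiment`: the assay
`"reflectance"` is an $L \times K$ matrix of $K$ spectra over $L$ bands,
`rowData` holds the wavelength grid (strictly increasing, nm), and
`colData` holds a tissue label and a patient identifier per spectrum. The
patient column is mandatory because every evaluation protocol in the
package splits by patient: spectra of one patient are strongly correlated,
and letting a patient straddle the reference/target divide would leak
information. Small annotated cubes are carried by the `Hypercube` class
(an `(x, y, band)` array plus an integer mask), from which
`extractLabeled()` lifts one library entry per labeled pixel.

## Preprocessing

`preprocessLibrary()` applies up to three per-spectrum steps in a fixed
order:

1. **Savitzky–Golay smoothing** (window 9 bands = 45 nm, polynomial order
   3 by default). The filter replaces each band with the value of a local
   least-squares polynomial fit, which suppresses high-frequency sensor
   noise while reproducing any polynomial up to the filter order exactly —
   the narrow hemoglobin features near 540–580 nm survive a 45 nm window
   at this resolution. Edges use the polynomial fitted to the first/last
   full window; no reflectance is fabricated outside the measured range.
2. **Standard normal variate (SNV)**: each spectrum is centred to mean 0
   and scaled to standard deviation 1. This removes per-spectrum
   illumination (multiplicative) and offset (additive) effects; any
   positive affine transform of a spectrum maps to the same output.
3. **Min–max rescaling** onto $[\varepsilon, 1]$ with
   $\varepsilon = 10^{-6}$. SNV output is negative in roughly half its
   bands, which the divergence-based measures cannot accept; the rescale
   restores strict positivity. The floor is $\varepsilon$ rather than 0
   because an exact zero would recreate the $\log 0$ failure the rescale
   exists to prevent.

Rescaling is per spectrum. A whole-dataset variant would preserve
between-spectrum amplitude differences, but amplitude is exactly what SNV
has already discarded, so the per-spectrum form is the consistent choice.

## The measures

With $s_i, s_j \in \mathbb{R}_{\ge 0}^L$ and $p, q$ their
probability-normalised forms ($p_l = s_{il} / \sum_m s_{im}$):

* **SAM** $= \cos^{-1}\!\big(s_i \cdot s_j / (\|s_i\|\,\|s_j\|)\big)$ —
  the angle between the spectra as vectors, radians in $[0, \pi/2]$,
  invariant to positive scaling.
* **SID** $= D(p\|q) + D(q\|p)$ — symmetrised Kullback–Leibler divergence
  in nats (natural logarithm; the standard convention). Probabilities are
  floored at $10^{-12}$ and renormalised inside the divergence so the
  measure is finite even on raw inputs with empty bands.
* **SCA** $= \cos^{-1}\!\big((\sigma + 1)/2\big)$ with $\sigma$ the
  Pearson correlation — maps $[-1, 1]$ onto $[0, \pi/2]$ and, unlike SAM,
  distinguishes negative from positive correlation; invariant to positive
  affine transforms of either input. Part of the SCA literature uses
  $\cos^{-1}\sqrt{(\sigma+1)/2}$; that variant is available via
  `sqrtTransform = TRUE`.
* **Bhattacharyya coefficient** $\mathrm{BC} = \sum_l \sqrt{p_l q_l}$ and
  the **Jeffries–Matusita distance**. JM is conventionally written
  $2(1 - e^{-B})$ with $B$ the Bhattacharyya *distance*
  $-\ln \mathrm{BC}$, which simplifies to $2(1 - \mathrm{BC})$ and spans
  the full stated range $[0, 2]$ (0 for identical distributions, 2 for
  disjoint support). Placing the *coefficient* itself in the exponent
  instead would cap the measure at $2(1 - e^{-1}) \approx 1.264$ and
  contradict the $[0,2]$ range, so the distance form is the default;
  the coefficient form remains selectable with `form = "coefficient"`.
* **Hybrids**: $\mathrm{SID{\text -}TAN}(X) = \mathrm{SID} \cdot \tan X$
  and $\mathrm{SID{\text -}JM{\text -}TAN}(X) = \mathrm{SID} \cdot
  \mathrm{JM} \cdot \tan X$ for $X \in \{\mathrm{SAM}, \mathrm{SCA}\}$.
  Products of small numbers stay very small for similar spectra while the
  tangent diverges as the angle approaches $\pi/2$, so hybrids stretch the
  dynamic range between similar and dissimilar pairs far beyond any single
  constituent. At exactly $X = \pi/2$ the tangent is saturated at
  $\tan(\pi/2 - 10^{-9})$ so the product stays finite and
  order-preserving; $\pi/2$ occurs only for exactly orthogonal or
  perfectly anticorrelated inputs.

All eight measures are nonnegative, symmetric, and zero on identical
inputs; smaller means more similar. The double-index sums in the standard
typeset definitions of the spectral angle and the Bhattacharyya
coefficient are read as bandwise products over a single index — any other
reading would stop SAM being the arccosine of a cosine.

## Comparing measures across units

An angle in radians and a divergence in nats cannot be compared directly.
Three ratio-based statistics put them on one footing (all are invariant to
rescaling a measure by a positive constant):

* `rsdpw(m, si, sj, t)` — **discriminatory power**:
  $\max\{m(s_i,t)/m(s_j,t),\; m(s_j,t)/m(s_i,t)\} \ge 1$; how much better
  the measure separates two references relative to a target.
* `rsdpb(m, t, refs)` — **discriminatory probability**: the measure values
  of $t$ against a $K$-entry library, normalised to a probability vector.
* `rsde(m, t, refs)` — **discriminatory entropy**: Shannon entropy of that
  vector in bits, bounded by $\log_2 K$; small when few references match
  sharply. Base 2 is used because the upper bound $\log_2 K$ is the
  natural reading of reported entropies above $\ln K$ for $K = 8$
  reference classes.

`discriminationReport()` assembles all three per measure for a chosen
target tissue, using tissue mean spectra for the power ratios and
per-(tissue, patient) mean spectra as the reference library.

## Annotation quality control

References of each tissue are condensed by K-means (`k = 2` by default,
Euclidean, on the spectra themselves) to a handful of cluster centers, so
a target is compared against a few centers instead of every reference.
The per-cluster threshold is the *mean* similarity value between the
center and its members. A claimed label is **confirmed** when the target
is strictly below threshold for *every* center of the claimed tissue;
otherwise it is **flagged** and receives the label of the globally nearest
center (ties broken lexicographically and reported).

The all-centers rule is deliberately strict. When a tissue's two clusters
are genuinely distinct, a target inside one cluster essentially never
beats the other cluster's threshold; and even within one tight cluster, a
fresh draw is below the mean member distance only about half the time
(distances concentrate in 100 dimensions, and members were assigned to
their nearest center while the target was not). Confirmation rates well
below 100% on clean data are therefore intrinsic to the rule, not a
defect; the procedure's value is in the flag-and-suggest path, which
recovers mislabeled spectra with high accuracy. A relaxed any-center rule
is available (`rule = "any"`) for users who want a more permissive check.
A singleton cluster has threshold 0, making confirmation through it
impossible; this is warned about and argues for smaller `k`.

Reference libraries are assumed curated: the procedure compares targets
against spectra "whose labels are known". If the references themselves
contain mislabeled spectra, K-means tends to isolate them as their own
cluster, planting a wrongly-labeled center that both blocks confirmation
and misdirects suggestion — reference hygiene matters more than reference
size.

## Evaluation protocols

`lopocvPlan()` builds leave-one-patient-out folds;
`groupedKfoldPlan(k)` splits patients into `k` patient-disjoint folds
while keeping per-class spectrum proportions approximately equal. Exact
stratification is impossible when patients are atomic, so patients are
assigned greedily — largest first, each to the fold where it minimises
the squared deviation from the ideal per-fold class counts, ties to the
emptiest fold. `evaluateAnnotationQc()` runs the QC procedure fold by
fold (references = training patients, targets = test patients, by default
as per-(tissue, patient) mean spectra) and reports accuracy: the fraction
of targets whose QC-predicted label (claimed if confirmed, else
suggested) agrees with the claimed annotation, which the evaluation —
like the clinical workflow it models — treats as ground truth. Under this
definition a shuffled-label null is exactly chance: a claim drawn
independently of the spectrum agrees with any prediction with probability
$1/|\text{classes}|$.

## Synthetic data

`sampleLibrary()` draws spectra as
$\text{scale}_{pt} \cdot \text{baseline}_t(\lambda) + \text{shift}_{pt} +
\epsilon$, clipped positive: a smooth per-tissue baseline (sum of Gaussian
bumps), a per-(patient, tissue) multiplicative/additive perturbation
(sd 0.08 / 0.01 by default), and bandwise Gaussian noise (sd 0.01). The
shipped `defaultTissueSuite()` has ten deterministic models over the
500–995 nm grid whose baselines carry hemoglobin-like double dips at
542/576 nm and a near-infrared plateau, with a documented separability
ordering: thyroid/parathyroid nearly coincide, the gastrointestinal group
(colon, small intestine, stomach) is a second hard cluster, and
gauze/instrument are far from everything — mirroring the structure that
makes intraoperative discrimination hard. Defaults were set once to
values plausible for intraoperative reflectance data and are not tuned:
ten patients, five spectra per tissue per patient, everything
deterministic under a single integer seed.

What the generator does *not* emulate: wavelength-correlated sensor
noise, specular highlights, motion blur, mixed pixels at tissue
boundaries, and real biological within-tissue heterogeneity beyond one
affine patient effect. Passing tests on synthetic data therefore
demonstrate the *algorithmic* properties (axioms, recovery, determinism),
not clinical performance.

## Numerical choices and degenerate inputs

* Probability floor $10^{-12}$ inside SID only; the Bhattacharyya
  coefficient involves no logarithm and uses exact probabilities, so JM
  attains exactly 2 on disjoint support.
* Constant spectra are rejected by SNV, min–max and SCA (degenerate-input
  errors) rather than silently propagated.
* Discriminatory power is undefined when the target coincides with a
  reference (a zero measure value); this is an error, not infinity.
* K-means uses 5 restarts under a caller-supplied seed; cluster labels
  are canonicalised by center order so equal seeds give byte-identical
  models. RNG state is saved and restored around every seeded operation.
* Problem sizes used by the shipped tests: 100-band spectra; up to 1,000
  random pairs for the measure axioms; an 8-tissue, 10-patient,
  5-spectra-per-cell library (400 spectra, 5% mislabeled) for the QC
  recovery study; a 2-tissue, 160-spectrum library for the shuffled-label
  null.

## Known limitations

Measure evaluation is pairwise-loop based and intended for libraries of
patient-mean spectra (hundreds of entries), not for full 640×480 cubes
pixel by pixel. The QC procedure inherits the biases of its reference
database, and the strict confirmation rule trades sensitivity for a very
low false-confirmation rate. Wavelength grids must match exactly between
targets and references; resampling between grids is out of scope.
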