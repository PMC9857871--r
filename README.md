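# hsiSimilarity

Spectral similarity measures and annotation quality control for labeled
tissue spectra from medical hyperspectral imaging (HSI).

Intraoperative HSI cameras record a reflectance spectrum (typically 100
bands, 500–1000 nm) at every pixel. Telling tissue types apart — and
auditing whether a human annotator labeled a region with the right tissue
— both reduce to a scalar measure of similarity between two spectra
$s_i, s_j \in \mathbb{R}_{\ge 0}^L$. This package implements, for
researchers working with labeled spectral libraries:

* **Eight similarity measures** behind one registry: the spectral angle
  mapper $\mathrm{SAM} = \cos^{-1}\!\big(s_i \cdot s_j /
  (\|s_i\|\|s_j\|)\big)$; the spectral information divergence
  $\mathrm{SID} = D(p\|q) + D(q\|p)$ (symmetrised Kullback–Leibler, on
  probability-normalised spectra, in nats); the spectral correlation
  angle $\mathrm{SCA} = \cos^{-1}\!\big((\sigma+1)/2\big)$ (Pearson
  $\sigma$); the Jeffries–Matusita distance
  $\mathrm{JM} = 2(1 - \mathrm{BC}) \in [0, 2]$ (Bhattacharyya
  coefficient $\mathrm{BC} = \sum_l \sqrt{p_l q_l}$); and the tangent
  hybrids $\mathrm{SID \times \tan(SAM)}$, $\mathrm{SID \times
  \tan(SCA)}$, $\mathrm{SID \times JM \times \tan(SAM)}$ and
  $\mathrm{SID \times JM \times \tan(SCA)}$, which multiply stochastic
  and deterministic measures to amplify dissimilarity.
* **Cross-measure statistics**: relative spectral discriminatory power
  (RSDPW, a max ratio $\ge 1$), probability (RSDPB, a normalised vector)
  and entropy (RSDE, bits, $\le \log_2 K$) — all invariant to rescaling a
  measure, so measures with different units become comparable.
* **Annotation QC**: per-tissue K-means reference clusters, mean-distance
  thresholds, strict label confirmation and nearest-cluster label
  suggestion.
* **Patient-wise evaluation**: leave-one-patient-out and patient-grouped,
  class-balanced k-fold cross-validation.
* **Preprocessing**: Savitzky–Golay smoothing, standard normal variate,
  strictly positive min–max rescaling.
* **A deterministic synthetic generator** of tissue spectral libraries
  and small annotated hypercubes (ten tissue models with a documented
  separability ordering), used by the test suite in place of clinical
  data.

The central container, `SpectralLibrary`, extends Bioconductor's
`SummarizedExperiment`: bands × spectra reflectance matrix, wavelength
grid in `rowData`, tissue label and patient identifier in `colData`.

## Worked example

```r
library(hsiSimilarity)

cfg <- simulationConfig(nPatients = 5, spectraPerTissue = 4, seed = 7,
                        mislabelFraction = 0.05)
sim <- sampleLibrary(cfg)            # library + ground-truth record
lib <- preprocessLibrary(sim$library) # SG -> SNV -> min-max
lib
#> SpectralLibrary with 200 spectra over 100 bands
#>   wavelengths: 500-995 nm
#>   tissues: colon, gauze, instrument, muscle, nerve, parathyroid, skin,
#>            small_intestine, stomach, thyroid
#>   patients: 5

# hybrid measure between patient-mean spectra: tiny for the near pair
# (thyroid vs parathyroid), orders of magnitude larger for a far pair
pm <- patientMeanSpectra(lib)
m <- pairwiseMatrix(pm[, tissueLabel(pm) == "thyroid"],
                    pm[, tissueLabel(pm) %in% c("parathyroid", "gauze")],
                    "SID-JM-TAN(SCA)")
signif(m[1:2, c(1, 6)], 3)
#>             gauze|p01 parathyroid|p01
#> thyroid|p01    0.0531        2.48e-07
#> thyroid|p02    0.0460        2.71e-07

# lower discriminatory entropy = sharper identification of the target
for (r in discriminationReport(lib, "thyroid", c("SAM", "SID-JM-TAN(SCA)")))
  cat(sprintf("%-16s RSDE = %.3f bits\n", r$measure, r$rsde))
#> SAM              RSDE = 4.829 bits
#> SID-JM-TAN(SCA)  RSDE = 2.430 bits

# annotation QC against a curated reference library: every planted
# mislabel is flagged and relabeled to its true tissue
refs <- preprocessLibrary(sampleLibrary(simulationConfig(
  nPatients = 5, spectraPerTissue = 4, seed = 8))$library)
dec <- qcLibrary(lib, refs, "SID-JM-TAN(SAM)", k = 2, seed = 3)
mis <- sim$truth$mislabeled
cat(sprintf("flagged %d of %d mislabeled; %d relabeled correctly\n",
            sum(dec$verdict[mis] == "flagged"), sum(mis),
            sum(dec$suggested[mis] == sim$truth$tissue_true[mis],
                na.rm = TRUE)))
#> flagged 10 of 10 mislabeled; 10 relabeled correctly
```

The RSDE numbers illustrate why the hybrid is preferred: across the same
reference library, `SID-JM-TAN(SCA)` concentrates its discriminatory
probability on far fewer references than SAM (2.43 vs 4.83 bits), i.e. it
identifies the target more sharply.

## Command-line interface

`inst/cli/hsiqc` (installed under the package's `cli/` directory) wraps
the same functions:

```sh
hsiqc simulate  --out lib.csv --truth truth.csv --seed 1 --mislabel 0.05
hsiqc preprocess --in lib.csv --out pre.csv
hsiqc measure   --measure sid-jm-tan-sca --targets pre.csv \
                --references pre.csv --out matrix.csv
hsiqc discriminate --library pre.csv --target thyroid --out report.json
hsiqc annot-qc  --targets pre.csv --references refs.csv \
                --measure sid-jm-tan-sam --k 2 --seed 7 --out decisions.csv
hsiqc evaluate  --library pre.csv --protocol lopocv --out eval.json
```

Identical flags and seed produce byte-identical output files. Measure
names are accepted quoted (`'SID-JM-TAN(SCA)'`) or as parenthesis-free
aliases (`sid-jm-tan-sca`).

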