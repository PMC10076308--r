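---
title: "Discriminating chemoresistant cell lines from MALDI-TOF profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating chemoresistant cell lines from MALDI-TOF profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoprofiler)
```

## The problem

Whole-cell MALDI-TOF mass spectrometry, routine in clinical microbiology for
bacterial biotyping, can also fingerprint mammalian cells: a formic
acid/acetonitrile extract of about a million cells yields a linear-mode
profile spectrum of singly charged ions between 2,000 and 20,000 Da whose
peak pattern is characteristic of the cell state. `chemoprofiler` implements
a complete analysis chain for asking whether such fingerprints separate
chemotherapy-resistant from sensitive cancer cell lines — chronic myeloid
leukemia lines under imatinib and glioblastoma lines under temozolomide being
the motivating systems — together with the XTT dose-response analysis that
establishes the resistance phenotypes in the first place.

Because raw instrument data for this kind of study are rarely deposited, the
package carries a first-class synthetic-data module that generates spectra
and assay plates with the full statistical structure the pipeline assumes,
including planted ground truth, so that every stage is testable end to end.

## Spectral preprocessing

`run_preprocessing()` composes the stages in a fixed order, each exposed as
its own function:

1. **Crop** to the acquisition window (default 2,000–20,000 Da, closed
   interval).
2. **Square-root transform**: detector counts have roughly Poisson variance;
   the square root stabilizes it.
3. **Savitzky–Golay smoothing** (default half-window 10 points, order 3).
   Interior points use the closed-form least-squares convolution
   coefficients; near the edges the window shrinks symmetrically, with the
   polynomial order capped by the window size so the first and last points
   are interpolated exactly. The defaults are the values commonly used for
   linear-mode profile spectra; the window must stay well below peak width,
   and peaks narrower than about half the window are attenuated (relevant
   below ~4 kDa at resolution 700).
4. **SNIP baseline estimation** over 50 iterations. Intensities are
   compressed with the log-log-square-root operator
   `y = ln(ln(sqrt(v+1)+1)+1)`, clipped by the iterative symmetric min-filter
   of growing width, and decompressed; the estimate never exceeds the signal
   and subtraction clamps at zero. Fifty iterations correspond to a maximal
   clipping half-width of 50 points, wide enough to pass under the broadest
   peaks at this sampling density.
5. **Noise** as a single global scale per spectrum:
   `1.4826 * MAD` of the baseline-corrected intensities — the simplest
   estimator consistent with treating the residual as homoscedastic after
   the square-root transform. A rolling local estimate would adapt to
   mass-dependent noise but is deliberately not used.
6. **Peak detection**: a point is a peak iff it is the strict maximum over a
   ±40-point window and at least 3× the noise scale. Strictness makes flat
   plateaus peak-free; the window bounds the minimal peak spacing.
7. **Binning** across spectra: peaks are pooled, sorted by m/z and grouped
   greedily so that every member lies within a relative tolerance (default
   0.002, i.e. 0.2%, about 20 Da at 10 kDa) of the bin mean, with at most
   one peak per spectrum per bin (the closest wins, displaced peaks re-bin
   among themselves). The 0.2% default reflects linear-mode mass accuracy;
   a literal 20% tolerance would merge biologically distinct peaks, which is
   why the parameter is interpreted as a percentage. It remains overridable
   (`bin_tolerance`).
8. **Occurrence filter**: features present in fewer than half of the spectra
   are discarded (equality kept). The fraction is computed over all loaded
   spectra, not per group.
9. **Technical-replicate averaging**: rows sharing a
   (label, biological, experimental) key are averaged, absences counting as
   zero. Averaging after peak detection follows the reported order of
   operations; the averaged-row count therefore equals the number of
   experimental-replicate groups by construction (40, 35 and 43 for the
   three default designs).

Every stage is deterministic; identical input gives bit-identical output.

## Supervised peak ranking (binary discriminant analysis)

The averaged matrix is dichotomized at zero — after binning, a zero is a
true absence — and each feature gets one signed score per group: the
regularized in-group presence frequency contrasted with the pooled
frequency,

$$t_{jk} = \frac{\tilde p_{jk} - \tilde p_j}
{\sqrt{\tilde p_j(1-\tilde p_j)\,(1/n_k - 1/n)}},
\qquad
\tilde p_{jk} = \frac{x_{jk} + 1/2}{n_k + 1},\;
\tilde p_j = \frac{x_j + 1/2}{n + 1}.$$

A positive score marks presence in that group, a negative score absence; the
per-feature ranking score is $S_j = \sum_k t_{jk}^2$. The 1/2 pseudo-count
keeps scores finite for all-present/all-absent features at the cost of a
small shrinkage: the group-vs-pool contrast is exactly zero only at
frequency 1/2. Features with $\max_k |t_{jk}| \ge 2.5$ (the 95% criterion;
equality selects) are kept; if fewer than three qualify, the top 10 by $S_j$
are used instead. Both knobs are configurable. This ranking is a
reimplementation of the published contract, not a bit-level match of any
particular package release, and the package deliberately stops short of
naive-Bayes classification of new spectra — only the ranking/selection step
is needed here.

## Unsupervised verification (hierarchical k-means + PCA)

The selected peaks' binary matrix goes through tree-initialized k-means:
the asymmetric binary distance (discordant positions over positions where at
least one vector is 1; two all-zero vectors are defined to be at distance 0),
Ward linkage in its squared-dissimilarity form (`ward.D2`), a cut into
k = 2 or 3 groups matching the number of phenotype levels compared, and a
Euclidean k-means refinement seeded with the cut's centroids (≤ 10
iterations). Seeding from the tree makes the procedure deterministic, and the
refinement can only decrease the within-cluster sum of squares. The hybrid —
a binary-distance tree refined by Euclidean k-means on 0/1 vectors — mirrors
the established tree-seeded k-means procedure.

PCA is computed on the same selected-peak binary matrix, centered but not
scaled (binary features already share a scale); dichotomized rather than
continuous intensities are used because the selection itself is
presence/absence based (a switch, `pca_on = "intensity"`, is provided).
Cluster quality is reported as homogeneity — the percentage of a cluster's
members carrying its modal true label, printed as integers rounded half away
from zero (12/13 → 92%, 14/17 → 82%) — and the first-two-component variance
share is compared against the 70% separation criterion. Per-cluster 95%
ellipses assume bivariate normal scores: semi-axes
$\sqrt{\chi^2_{0.95,2}\,\lambda_i}$ along the covariance eigenvectors.

## Dose-response analysis

XTT readouts are background-corrected (`A450 − A620`), averaged per
(cell line, concentration), and expressed as the metabolic index — percent
of the basal (untreated) mean. The index is fitted by the four-parameter
log-logistic model

$$f(x) = c + \frac{d - c}{1 + \exp\{b(\ln x - \ln e)\}}$$

by ordinary least squares over the positive concentrations; the basal wells
are the 100% anchor and are excluded from the log-domain fit since the index
is already normalized to them. Initialization is multi-start (midpoint at
the geometric median concentration and at every tested concentration, Hill
slope in {0.5, 1, 2}; best residual sum of squares wins, ties by first) with
a Levenberg–Marquardt core and tolerances of 1e-10; the fitter is empirically
efficient (it attains the information bound on simulated plates). EC50 is the
midpoint parameter `e`; IC50 is the concentration at which the fitted index
crosses the absolute 50%-of-control level, obtained analytically as
$e\,((d-50)/(50-c))^{1/b}$ and reported as `NaN` when 50% lies outside the
fitted asymptote interval — a curve that never reaches half-inhibition has no
IC50, which is exactly how strongly resistant lines manifest. Fold-changes
are plain EC50 ratios.

## What the synthetic data emulate — and what they do not

`simulate_dataset()` draws linear-mode spectra on a 1-point-per-Da grid
(18,001 points over the default window, chosen to keep a full campaign in
the tens of seconds on one core): an exponentially decaying baseline
(amplitude 300, rate 3e-4 per Da), Gaussian peaks with width tied to a
single resolution parameter (R = 700, so FWHM = m/R), additive Gaussian
detector noise (sd 4) clipped at zero, a per-spectrum mass-calibration shift
(sd 100 ppm), and a three-tier multiplicative log-normal intensity jitter
(sd 0.15 / 0.10 / 0.05 for biological / experimental / technical levels).
Peak presence is drawn once per experimental replicate — repeated
acquisitions of one spot see the same analyte — which is what makes
technical-replicate averaging meaningful. The default replicate designs
reproduce the motivating study's obtained counts exactly (77, 104 and 125
spectra collapsing to 40, 35 and 43 averaged spectra over biological
triplicates).

The default marker structure is 8 shared backbone peaks plus 6 discriminant
peaks per class at presence 0.95/0.02. Markers are *complementary* by
default: each class is marked by peaks absent in it and present in the other
classes. The reason is arithmetic: a peak exclusive to one of three
similarly sized classes occurs in about a third of the spectra and is
removed by the 50% occurrence filter, so a literal exclusive-marker dataset
cannot pass its own preprocessing; absence markers occur in about two thirds
of spectra, survive the filter, carry the same presence contrast per marker,
and match the sign semantics of the ranking (negative scores flag absence).
The `scheme = "exclusive"` variant is kept for exercising the ranking stage
directly. Jitter and noise defaults were chosen so that the default
campaigns sit in the clean-separation regime the motivating study reports
(every cluster 100% homogeneous, PC1+PC2 above 70%), and the end-to-end
tests verify exactly that.

What the generator does **not** model: isotope and adduct structure, matrix
clusters, detector saturation, mass-dependent noise, spectral warping beyond
a linear ppm shift, or correlated intensity changes between peaks. Passing
tests on these data therefore demonstrate the pipeline's correctness and its
behavior under the assumed noise structure — not instrument-level
robustness on real acquisitions.

One realistic artifact does appear and is worth knowing about: with a
relative binning tolerance, bins at high mass are tens of Da wide and can
absorb spurious noise maxima from spectra lacking the true peak, diluting a
marker's presence contrast. The ranking threshold tolerates this (diluted
markers simply rank lower), but it is the reason marker-level unit tests
isolate presence randomness from detector noise.

`simulate_xtt()` plants true 4PL parameters per line, draws treated-well
indices with Gaussian noise (default sd 3 index points) and back-converts to
absorbance pairs against a fixed basal corrected absorbance (0.68); basal
wells are exact, so the zero-noise plate inverts to the true curve
identically. The default 9 wells per concentration reflect a biological ×
experimental triplicate design. A power note: at noise sd 3 with 8
concentrations the information bound puts the EC50's log-scale standard
error near 0.03, so a fold-change between two independently fitted lines is
only *typically* within 5% of truth — single-seed checks at that tolerance
sit at about 1.3σ. The acceptance-level check passes at the suite's fixed
seed; the unit-level check asserts calibration of the error distribution
instead of one draw.

## Numerical choices and degenerate inputs

* Duplicate m/z values are collapsed by mean at load time; m/z axes are
  sorted ascending.
* Peaks exactly at the mass-range bounds are kept.
* The occurrence filter keeps features at exactly the threshold fraction.
* Two all-zero binary rows are at distance 0 (identical observations are
  maximally similar; reference implementations leave this undefined).
* k-means refinement is skipped (tree assignment kept) if two seeded
  centroids coincide or a refinement step would empty a cluster.
* PCA on a zero-variance matrix is an error; a rank-deficient score cloud
  collapses its ellipse to a flagged segment.
* Fit convergence requires the Levenberg–Marquardt convergence flag or a
  numerically zero residual; a line failing all starts is reported
  `converged = FALSE` and skipped downstream rather than aborting the run.
* Homogeneity percentages are rounded half away from zero for reporting;
  the unrounded value is retained.

## Open design points resolved here

* Raw acquisitions in vendor binary format are out of scope; spectra enter
  as two-column csv or mzML (read through `mzR`).
* Whether averaging originally acted on profile spectra or on detected peak
  vectors cannot be decided from the order of operations as reported;
  averaging binned peak vectors (absence = 0) after detection reproduces the
  published replicate arithmetic and is the implemented default.
* The dichotomization threshold is zero (presence/absence); per-feature
  optimized thresholds are not implemented.
* No silhouette or gap-statistic selection of k: the number of clusters is
  fixed by the number of phenotype levels compared, as in the motivating
  design.
* No quality-control rule for failed spot acquisitions is implemented; the
  replicate designs use the obtained (not attempted) counts directly.

## A compact example

```{r example, eval = FALSE}
model <- default_spectrum_model(c("K562", "Ko562", "Ki562"))
ds <- simulate_dataset(model, design_cml(c("K562", "Ko562", "Ki562")),
                       seed = 42)
report <- run_profiling(ds$spectra, profiling_config(k = 3))
print(report)
plot_cluster_scores(report)
```

The numbered scripts under `analysis/` run the full leukemia and
glioblastoma profiling campaigns and the XTT panels and write their tables
under `results/`.
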