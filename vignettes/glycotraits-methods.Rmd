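---
title: "Methods: serum N-glycome traits, their statistics, and the calibrated cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum N-glycome traits, their statistics, and the calibrated cohort generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotraits)
```

## Scope and model

`glycotraits` analyses serum N-glycome profiles measured by MALDI-TOF in
positive reflector mode after PNGaseF release and methylamidation of
sialic acid carboxyls. The measurement model is deliberately simple: a
centroided peak list per spot, a library of expected glycan compositions
with theoretical `[M+Na]+` m/z values, and relative quantification by
total-area normalization. All downstream statistics operate on the
normalized abundances (percent of total annotated signal) or on the
sixteen derived traits computed from them.

### Mass chemistry

Compositions are written `H<hex>N<hexnac>[S<neu5ac>][F<dhex>]`. Neutral
monoisotopic mass is the sum of dehydrated residue masses (Hex 162.0528,
HexNAc 203.0794, dHex 146.0579, Neu5Ac 291.0954 Da) plus one water
(18.0106 Da). Methylamidation converts each sialic acid `-COOH` to
`-CONHCH3`; the elemental difference (+C +N +3H −O) is +13.0316 Da,
applied exactly once per sialic acid. Adduct m/z values are ion masses:
the electron mass (0.00055 Da) is subtracted from the sodium (or proton)
mass. The difference is far below the matching tolerance but the
convention is fixed and tested so that library m/z values are
reproducible to the microdalton against an independent elemental
summation.

### Structural classification

Composition alone cannot resolve isomers, so classification is rule
based with a curated override. The fallback rules: oligomannose when
`hexnac = 2`, `hex >= 5` and no sialic acid or fucose; hybrid when
`hexnac = 3` and `hex >= 5`; otherwise complex, with a bisecting GlcNAc
inferred when `hexnac >= 5` and `hex − 3 < hexnac − 2`, antennae
`hexnac − 2 − bisected`, and galactoses `min(max(hex − 3, 0), antennae)`.
The inequality encodes the observation that a HexNAc in excess of the
galactoses its antennae could carry is most plausibly the bisecting
residue on the core mannose. The shipped 42-entry library carries curated
flags for every composition it contains (all of which the rules
reproduce); user libraries can override any entry, which is the right
mechanism when fragmentation data settle an assignment.

### Derived traits

Traits are sums of normalized abundances: `man` over oligomannose;
`s1`–`s4` over glycans with exactly 1–4 sialic acids and `s_total` their
sum; fucosylation and bisection each split into neutral and sialylated
parts. Galactosylation (`g0`, `g1`, `g2` with `g2` meaning ≥ 2
galactoses, `g_total = g1 + g2`) is restricted to *neutral complex*
glycans: sialylated glycans are galactosylated by construction, and
hybrid hexoses are ambiguous between mannose and galactose, so counting
either would double-book the signal. With that restriction the G rows
sit in the single-digit percent range alongside `s_total` near 82%,
matching how the traits behave in published serum tables. Traits are
linear in abundances, additive (`s_total = s1+s2+s3+s4`, etc., to 1e-9
per sample) and permutation invariant; the test suite asserts all three
properties.

## Annotation parameters

* `tolerance` (0.15 Da): maximum |observed − theoretical| m/z. Generous
  for reflector TOF after internal recalibration, tight enough that the
  42 library species (minimum spacing well above 0.3 Da) cannot collide.
* `snr_threshold` (3): a peak must exceed three times the noise level to
  be quantified. `annotate_peaks()` defaults the noise to the median
  peak intensity of the spot, which is appropriate when peak picking has
  left the list dominated by baseline noise. For targeted extraction of
  a few dozen analyte peaks that median sits *on an analyte*, so the
  pipeline instead uses `estimate_noise()`: the median intensity of
  peaks that match no library m/z, a parameter-free estimate that is
  independent of the analyte dynamic range. Both entry points accept an
  explicit `noise` value.
* Recalibration (degree 1, minimum 5 calibrants): calibrants are matched
  within three times the tolerance and the least-squares polynomial of
  the mass error is removed. With fewer matches than `degree + 1` the
  degree collapses to a constant offset; with fewer than
  `min_calibrants` the spot is left untouched with a warning, since a
  bad fit is worse than no fit. Any reliably observed subset of the
  library serves as calibrant list.
* Replicates are averaged on the *normalized* scale, not raw
  intensities, so spot-to-spot differences in total desorbed material
  cancel exactly.

## Statistical workflow

Each trait is routed by a Kolmogorov–Smirnov check on its within-group
residuals (estimated mean/SD; the Lilliefors correction is available but
off by default, since the plain K-S is what the routing convention
names). Gaussian traits go to one-way ANOVA with all pairwise contrasts
on the pooled residual variance; p-values are Bonferroni adjusted
(`min(1, 3p)` for three groups) and the 95% CIs use the adjusted level.
Bonferroni is a family-wise error method, not an FDR method, but it is
what the published tables print, so it is what the package computes.
Non-Gaussian traits go to tie-corrected Kruskal–Wallis with Dunn's
z post hoc on pooled rank means; the reported interval there is a
normal-theory CI on the rank-mean difference (Dunn's statistic has no
mean-difference CI).

ROC AUC uses the rank (Mann–Whitney) formulation with half-credit for
ties — exactly the probability interpretation, invariant under monotone
transforms, and verified against brute-force pair counting. The
multiclass family is one-vs-rest: per-class AUC of each class's
predicted probability against class membership, macro AUC their
unweighted mean (asserted, not assumed), micro AUC a single binary AUC
on the flattened label-indicator matrix. Random-forest evaluation uses
stratified k-fold splits with a fixed seed; every sample is scored only
by forests that never saw it, and the AUC report pools the out-of-fold
probabilities. Feature selection ranks features by mean impurity
importance over repeated CV and traces mean macro AUC over a panel-size
grid; ties in the argmax resolve to the smaller panel.

## The synthetic cohort generator

The generator exists so the full pipeline can be exercised, and its
parameter-recovery verified, without patient data. It emulates a study
of 60 healthy controls, 70 benign neoplasms and 70 cancer patients
(split 35 early-stage / 35 late-stage, a declared convention since only
the total is published).

**Calibration.** Per-group mean abundance vectors over the library are
fitted by iterative proportional fitting: each of the twelve elementary
trait targets (the four totals follow by additivity) rescales its member
glycans to the target and the complement to the remainder, preserving
the 100% total, sweeping until every trait sum is within 1e-6. Disjoint
target families that exceed 100% are rejected up front. The benign,
early and late columns use the published group means; the benign
neutral-fucosylation mean is corrected to `F total − F sialo` = 6.80
(the printed value contradicts the additivity that every other column
obeys). The healthy-control column is not published at trait level and
is synthesised from the benign column shifted one SD in the reported
directions (lower Man, G0, B neutral; higher S total, spread
proportionally over S1–S4) — a convention, not a measurement.

**Subject variation.** Subjects are logistic-normal perturbations
`x_i ∝ mean · exp(τ z_i)` renormalized to 100%. The generator is
variance-controlled: the latent normals are centred per group and the
per-glycan cohort means are iteratively recalibrated onto the fitted
targets (the renormalization is nonlinear, so centring alone leaves an
O(τ²) drift), which pins group trait means to the calibrated values by
construction and leaves all randomness in the between-subject spread.
The single dispersion τ per group is tuned by bisection until the
subject SD of `s_total` matches its published target within 1%.

**Spectra.** Each subject yields three spots. The m/z error has two
parts: a per-spot calibration offset, Gaussian with SD `mz_jitter_ppm`
(default 30 ppm) and linear in m/z — which is what external calibration
error looks like on a TOF, and which the recalibration step is designed
to remove — plus small per-peak centroid noise (0.01 Da). A purely
per-peak 30 ppm error would be uncorrectable by any internal calibration
and is not what the jitter parameter models. Intensities are the true
abundances times one lognormal per-spot factor (CV 0.2), which
normalization cancels; five spurious noise peaks per spot appear at
uniform m/z in the 1000–4500 window with intensities near the baseline
(uniform 0.01–0.1 relative-abundance units), i.e. well below the
quantified glycans, as residual centroids after peak picking are.

**Covariates.** CA125 on the patient subset is a linear combination of
the targeted traits plus noise. The coefficients are solved against the
*empirical* trait correlation matrix (`b = R⁻¹ r`), the system is
rejected if the required signal variance `rᵀR⁻¹r` reaches 1, and the
noise is residualised against the traits — a conditional simulation that
makes the empirical marginal correlations equal their targets exactly
(−0.26 with `s_total`, +0.29 with `man`, +0.23 with `g0`, +0.28 with
`g1`). HE4 is drawn independently of the glycome with a cancer-shifted
mean. Both markers are in arbitrary linear units; Pearson correlation is
not invariant to nonlinear rescaling, so no attempt is made to mimic the
skewed clinical unit scale.

**What the generator does not emulate.** Isotope envelopes and profile
mode spectra; batch effects beyond the spot factor; inter-glycan
correlation structure beyond what renormalization induces; the clinical
marker distributions' heavy tails; and any real-data idiosyncrasies of
the deposited study spectra. Passing recovery tests therefore
demonstrates that the pipeline is correct and well-calibrated under this
noise model, not that it would reproduce any particular clinical
dataset.

## Numerical choices and degenerate inputs

* IPF runs at most 500 sweeps; non-convergence warns and returns the
  residuals rather than failing, since near-feasible targets are often
  still useful.
* Annotation ties (two glycans equidistant from one peak) resolve to the
  lower-m/z glycan; the assignment is injective in both directions and
  is checked against a brute-force matcher.
* All-zero annotated spots raise "no annotated signal" rather than
  emitting NaN profiles; constant inputs to the K-S check report
  non-Gaussian with an NA p-value; constant features are dropped from
  PCA with a warning; a singular pooled covariance in LDA is ridged
  (`εI`, escalating until the solve succeeds).
* Identical values in Kruskal–Wallis make the tie factor zero; the test
  then reports H = 0, p = 1.

## Unsupervised separation under the published effect sizes

With group SDs calibrated to the published table and a one-SD control
shift, the between-group contrast does not dominate the within-group
compositional variance: the PC1 centroid gap stays below the
within-group SD, and only the supervised Fisher direction separates
markedly. Unsupervised ordination of serum glycomes at these effect
sizes should therefore be expected to separate groups only partially,
which is why the package's PCA is positioned as a visualisation, with
classification delegated to LDA and the cross-validated forest.

## Problem sizes in the test suite

The suite regenerates everything it tests: full-size cohorts (n = 140 or
200 subjects, triplicate spectra) for recovery and correlation checks;
100 random 20-sample probability matrices for the AUC oracle; 50
label-permutation forests (n = 200) and 2000 null replicates for the
type-I calibration; and a 5-informative/50-noise feature-selection run
with twenty-repeat 5-fold CV. These sizes were chosen so each check has
the statistical resolution its tolerance needs while the whole suite
stays desk-scale.
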