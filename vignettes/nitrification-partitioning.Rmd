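---
title: "Methods: quantifying and partitioning soil nitrification with DNA-SIP and selective inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and partitioning soil nitrification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrisip)
```

# The scientific problem

Three guilds oxidize ammonia in soil: ammonia-oxidizing archaea (AOA),
ammonia-oxidizing bacteria (AOB) and complete ammonia oxidizers
(comammox *Nitrospira*). Because they share a substrate, attributing
bulk nitrification and carbon assimilation to individual guilds requires
either isotope labeling resolved by guild-specific marker genes
(DNA-SIP with *amoA* qPCR) or kinetic assays under selective inhibition.
`nitrisip` implements both inference chains, a generator of synthetic
data with recorded ground truth, and the statistics used to report the
results. This vignette documents the models, assumptions, parameter
choices and limitations.

# The gradient model and the labeled-proportion estimator

## Buoyant-density model

DNA equilibrates in a CsCl gradient at a buoyant density set by its base
composition and isotopic content. We use the classical empirical
relation for unlabeled DNA,

$$d_0 = 1.660 + 0.098 \cdot \mathrm{GC} \quad [\mathrm{g\,ml^{-1}}],$$

and a full-labeling shift of 0.036 g ml⁻¹ scaled linearly by the ¹³C
atom fraction excess of the labeled subpopulation. A population with
labeled proportion $p$ is modeled as a two-component Gaussian mixture
with weights $(1-p, p)$, common spread `peak_sd` (default 0.006 g ml⁻¹,
a typical within-population spread for environmental amplicons), and
means $d_0$ and $d_0 + 0.036\,\mathrm{AE}$. Expected copies per
fraction are the total copy number times the mixture mass integrated
over the fraction's density bin (closed-form normal CDF differences);
observed copies multiply this by lognormal noise with a configurable
coefficient of variation (default 5%, typical qPCR technical error).
This gives the generator a closed-form oracle: tests verify fraction
masses against independent adaptive quadrature of the mixture density.

Fractions are numbered densest-first (fraction 1 = bottom of the tube)
on a uniform 15-bin grid spanning 1.690–1.760 g ml⁻¹, and fractions 2–14
form the default analysis range, matching routine bottom-collected
fractionation and qPCR practice. Per-fraction densities and collection
direction are rarely reported in field studies; the uniform grid is a
stand-in, and the direction is configurable.

## Heavy window

Two definitions are provided:

* `fixed` — all analysis fractions with density ≥ 1.725 g ml⁻¹ (typical
  SIP practice).
* `adaptive` — the operational definition used when an unlabeled control
  is available: among fractions strictly denser than the ¹²C modal
  fraction, the longest contiguous run where mean ¹³C relative abundance
  exceeds mean ¹²C relative abundance (ties broken toward the larger
  summed excess). The ¹²C modal fraction is never included; an empty
  window is a valid, flagged outcome meaning "no detectable enrichment".

## Estimators

With $S_{13}$ and $S_{12}$ the replicate means of summed heavy-window
relative abundance, two estimators of the labeled proportion are
implemented:

* `raw_excess`: $\hat p = \mathrm{clamp}(S_{13} - S_{12},\,0,\,1)$;
* `normalized_excess` (default):
  $\hat p = \mathrm{clamp}\!\big((S_{13} - S_{12})/(1 - S_{12}),\,0,\,1\big)$.

The normalized form is the default because it is exactly unbiased when
the labeled DNA falls entirely inside the window: labeling a proportion
$p$ moves mass $p$ out of the light region, so
$S_{13} = p + (1-p)S_{12}$, and solving for $p$ gives the estimator.
The raw form is retained for comparability with simple excess-based
reporting. No closed formula for the labeled proportion is standard in
the field; recovery tests (mean absolute error ≤ 0.10 across the
labeling range at 5% qPCR CV, n = 3) justify the default. When partial
labeling (atom excess < 1) places the labeled peak astride the window
boundary, $\hat p$ is biased downward; this is documented, not
corrected — no quantitative-SIP atom-fraction model is attempted.

Uncertainty is a percentile bootstrap over replicates (default 1,000
seeded resamples); no analytic variance is attempted for the ratio
statistic at n = 3. Enrichment significance is a two-sided two-sample
t-test (Student by default, Welch optional) on per-replicate window
sums; identical zero-variance groups return p = 1 with a flag.

# Slurry kinetics and the partition design

NO₂⁻/NO₃⁻ concentrations in substrate-saturated shaken slurries are
modeled as linear in time over 24 h, sampled at 2, 4, 8, 20, 22 and
24 h, with additive Gaussian measurement noise (colorimetric assay error
structure). Rates are per-replicate ordinary least-squares slopes;
r² below 0.9 flags a failed fit (linearity "generally" holds in such
assays but not always — an option drops late points when NO₂⁻ plateaus).
The potential is $Np = R(0.1+V)/m \cdot 24$ in mg N kg⁻¹ d⁻¹. V and m of
the slurry subsample are required user inputs (defaults 0.005 L and
0.0095 kg correspond to a 10 g moist subsample at ~5% gravimetric water).

The inhibitor design is an efficacy matrix (suppression fraction per
inhibitor × target process), defaulting to perfect specificity:
NaClO₃ → NOB, simvastatin → AOA, DMPP → AOB, acetylene → all autotrophic
ammonia oxidation. Efficacies are continuous so incomplete or
non-specific inhibition can be stress-tested. In the simulator, the
effective NO₂⁻ rate is the surviving AOA+AOB sum (times the interaction
multiplier when both are fully active), attenuated by surviving NOB
activity, plus a heterotrophic background; the NO₃⁻ rate is the
surviving comammox rate (times the coexistence boost when AOA and AOB
are active) plus NOB-converted nitrite.

Partitioning maps five arms to named potentials — (NaClO₃, NO₂⁻) →
[AOA+AOB]; (NaClO₃, NO₃⁻) → [comammox]; (NaClO₃+Sim, NO₂⁻) → AOB;
(NaClO₃+DMPP, NO₂⁻) → AOA; (all three, NO₃⁻) → comammox alone — and
computes percentage contributions within scheme U ([AOA+AOB] vs
[comammox]) and scheme I (AOA, AOB, comammox), never mixing the two.
Negative potentials (possible after background subtraction) are
reported and flagged, and floored at zero only inside the percentage
normalization, so shares stay interpretable while diagnostics survive.

Acetylene-control subtraction is **off by default**: field protocols
describe acetylene controls without always stating numerical
subtraction, so both modes are explicit rather than silently applied.
The package's recovery tests enable it, because the generator's
heterotrophic background is exactly what the acetylene arm measures and
subtracting it makes noise-free recovery exact.

Interaction indices are `delta_AB = Np[AOA+AOB] − (Np_AOA + Np_AOB)`
and `delta_C = Np[comammox] − Np_comammox_alone`, classified as
synergy/additivity/antagonism with an additivity band of 5% of the
scheme total by default.

# ASV enrichment testing and metabolic classification

Counts are total-count normalized (each library scaled to the mean
library size), log₂-transformed with pseudocount 1 and compared by a
two-sample t-test per ASV, 13C vs 12C. The enrichment *call* is
one-sided — significance requires ¹³C mean > ¹²C mean — since depletion
has no meaning in SIP labeling. Multiplicity correction defaults to
none (matching common raw-p reporting at 0.05); Benjamini–Hochberg is
an option and can only reduce discoveries. The module also accepts
externally computed per-ASV p-values, so output from a dedicated
count-model tool can be dropped in.

Total-count normalization is deliberately simple and has a known
compositional limitation: when a large fraction of a library is
enriched, scaling deflates apparent fold changes for the enriched ASVs
and induces apparent depletion in the unenriched ones. The one-sided
call protects the false-positive rate, but sensitivity degrades as the
enriched fraction grows. The scenario generator therefore plants a
realistic minority of labeled ASVs (default 15 per labeled class against
105 unlabeled): in real SIP amplicon data most taxa do not assimilate
any one labeled substrate. Recovery tests at fold change 8, dispersion
0.1 and n = 3 reach ≥ 0.9 classification accuracy under this
composition; with half the community enriched they would not, which is a
property of total-count normalization, not of the classifier logic.

Classification is a pure function of the two context flags:
(no-inhibitor, acetylene) = (T, T) → `both`, (T, F) → `inorganic_only`,
(F, T) → `organic_only`, (F, F) → `unlabeled`. This is the mechanistic
reading — enrichment while acetylene blocks autotrophy implies organic
carbon assimilation. Verbal summaries of this logic are sometimes
internally inconsistent about the exclusive classes, so a `literal`
mapping that swaps them is exposed as a configuration switch.

# Statistical toolkit

The reporting statistics are implemented from first principles and
cross-checked in tests against independent references (`aov`, `t.test`,
`qtukey`):

* one-way fixed-effects ANOVA via the sum-of-squares decomposition,
  returning the MSE for downstream range tests;
* Student/Welch two-sample t-tests;
* studentized-range quantiles by numerical integration of the range
  CDF mixed over the chi distribution of the pooled SD, plus root
  finding (relative error ≤ 1e-4 against tabulated values; results are
  memoized since Duncan displays reuse a small set of quantiles);
* Duncan's multiple range test with the classical protection levels
  $\alpha_p = 1-(1-\alpha)^{p-1}$, critical ranges
  $R_p = q(1-\alpha_p, p, \nu)\sqrt{\mathrm{MSE}/n_h}$ (harmonic mean
  $n_h$ for unbalanced designs, flagged), the standard stepwise rule (no
  testing inside a homogeneous stretch), and insert-and-absorb compact
  letter displays. Ties in means are broken by group label order so
  letters are deterministic. With two groups the procedure reduces
  exactly to the pooled t-test. Duncan's familywise error exceeds the
  nominal level by construction; this is asserted, not hidden.
* Raw-scale analysis is the default; a log₁₀ option covers abundance
  data whose letters may be computed on the log scale.

# The synthetic generator as a measurable oracle

The generator emulates exactly the statistical structure the analysis
assumes: Gaussian density peaks shifted by ¹³C incorporation with
multiplicative lognormal qPCR noise; linear inhibitor-modulated
kinetics with additive Gaussian noise (clamped at zero and flagged);
negative-binomial ASV counts with planted fold changes per metabolic
class; and a JSON ground-truth record that round-trips losslessly. It
does **not** emulate: sequence-level artifacts (chimeras, primer bias),
ultracentrifugation physics beyond the two-Gaussian mixture, GC
heterogeneity within a guild, compositional coupling between guilds in
qPCR, Michaelis–Menten or pH-dependent kinetics, or inhibitor
cross-reactivity beyond the efficacy matrix. Passing recovery tests
therefore demonstrates the correctness of the inference chain under its
own assumptions, not robustness to every violation real soils offer.

Three presets define the study conditions: `CK` (unfertilized control;
comparable [AOA+AOB] and [comammox] contributions, no coexistence
boost), `WI1` (long-term fertilization, AOB-dominant) and `WI2`
(high organic input: AOB-dominant, strong AOA/comammox labeling, and a
comammox coexistence boost of 1.6). All presets carry an AOA×AOB
interaction multiplier of 0.7, encoding the observation that the two
guilds together underperform the sum of their single-guild potentials.
Guild rates were chosen once so that the implied potentials fall in the
low tens of mg N kg⁻¹ d⁻¹ with slurry concentration gains of roughly
0.5–2 mg N L⁻¹ over 24 h — the range where linear fits against ~2%
measurement noise are realistic for colorimetric assays.

# Numerical choices and degenerate inputs

* All randomness flows from one root seed, split deterministically per
  stage; equal seeds give byte-identical outputs.
* Gradient bins use exact normal-CDF differences; the independent test
  oracle uses adaptive quadrature (`integrate`, rel.tol 1e-10).
* The labeled-proportion ratio is undefined when the ¹²C heavy-window
  mass saturates ($S_{12} \ge 1 - 10^{-9}$); a flagged 0 is returned.
* Constant concentration series yield slope 0 with r² defined as 0 and
  a QC flag; constant time vectors are errors.
* Empty heavy windows, negative net potentials and percentage sets with
  non-positive totals are flagged, never silently repaired.
* Problem sizes in the validation suite — 200-seed recovery sweeps,
  500/2,000-pair power and calibration runs, 5,000 null ANOVA
  simulations — were chosen to keep Monte-Carlo error comfortably below
  the asserted margins while the full suite runs in a few minutes on a
  single core.

# Known limitations

* The labeled-proportion estimator assumes the labeled peak lies inside
  the heavy window; partial atom excess biases it downward.
* Total-count normalization limits differential-test sensitivity when a
  large community fraction is enriched (see above).
* Duncan's test does not control the familywise error rate; it is
  provided because it is the field's reporting convention, with its
  behavior quantified in the test suite.
* The pipeline treats guild rates as constant over the 24 h assay; no
  substrate depletion, growth or pH feedback is modeled.
* The `literal`/`mechanistic` classification switch changes only the
  two exclusive classes; users comparing against tabulated claims
  should state which mapping they used.
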