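---
title: "Methods: the damped-sine axis model and the staging enrichment cascade"
author: "smedembryo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the damped-sine axis model and the staging enrichment cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smedembryo)
```

Planarian embryos develop "anarchically": the undifferentiated,
*piwi-1*-expressing blastomeres that fuel embryogenesis occupy the
embryonic wall without a stereotyped pattern. This package implements the
two quantitative pillars of that characterization — a one-parameter
angular model for blastomere positions along the oral–aboral axis, and
the normalization-plus-threshold cascade that turns single-embryo RNA-Seq
counts into stage signatures and early-embryo-enriched (EEE) transcript
lists — together with synthetic generators that stand in for the original
microscopy and sequencing data.

## 1. The angular model

### Geometry

Each embryo contributes a cloud of 3D spots (µm) with two landmarks: the
embryo center and the temporary embryonic pharynx, which marks the oral
pole. For a cell at position $x$ the polar angle is

$$\theta = \arccos\left(\hat{u} \cdot \hat{p}\right), \qquad
\hat{u} = \frac{x - c}{\lVert x - c\rVert}, \quad
\hat{p} = \frac{p - c}{\lVert p - c\rVert},$$

with $c$ the center and $p$ the pharynx. `oral_aboral_angles()` computes
this directly by dot product; `align_to_axis()` provides the equivalent
rigid rotation (pharynx onto $+z$) for export and visualization only, the
two being mathematically identical. The arccos argument is clamped to
$[-1, 1]$ so floating-point excursions at the poles can never produce
`NaN`. Angles are invariant to rigid motion and to scaling about the
center; the tests verify both to $10^{-9}$ rad.

How the imaging software defined the exported "embryo center" (mask
centroid or manual placement) is not knowable from a spot table, so the
reader accepts either convention: a `center` landmark row when present,
or optionally the centroid of non-bead spots as a flagged fallback for
partial exports. Neither is privileged.

### The damped-sine family

Under spatial uniformity on a sphere the polar angle has density
$\sin(\theta)/2$. The observed depletion of cells near the oral pole is
modeled by one dampening term $\theta'$ (radians):

$$f(\theta;\theta') = \frac{(1 - e^{-\theta/\theta'})\,\sin\theta}{Z(\theta')},
\qquad
Z(\theta') = 2 - \frac{\theta'^2\,(1 + e^{-\pi/\theta'})}{1 + \theta'^2},$$

with $Z(0) = 2$ as the limit, so $\theta' = 0$ *is* the uniform null.
Likelihood comparison against $\sin(\theta)/2$ (itself a normalized
density) is only meaningful if the damped-sine density is normalized too,
so $Z$ is applied throughout; the closed forms for $Z$ and for the CDF

$$F(\theta;\theta') = \frac{1}{Z(\theta')}\left[(1-\cos\theta)
 - \frac{1 - e^{-a\theta}(a\sin\theta + \cos\theta)}{1 + a^2}\right],
 \qquad a = 1/\theta',$$

are derived here and cross-checked against adaptive quadrature to
$10^{-8}$ in the tests. Sampling is by exact rejection: proposals
$\theta = \arccos(1 - 2u)$ from the null envelope, accepted with
probability $1 - e^{-\theta/\theta'}$ (overall acceptance rate
$Z(\theta')/2$).

### Fitting, null comparison, uncertainty

`fit_damped_sine()` maximizes the log likelihood by bounded 1-D
optimization on $[0, \theta'_{max}]$ (default 20 rad) and records the log
likelihood at the optimum and at $\theta' = 0$. Numerical choices:

* **Pole clamping.** Measured spots can land numerically on a pole, where
  $\log\sin\theta = -\infty$; such angles are clamped inward by $10^{-9}$
  rad with a warning rather than dropped.
* **Boundary ties.** The null lies on the boundary of the parameter set,
  so the likelihood ratio $\exp(\ell_{fit} - \ell_0) \ge 1$ by
  construction; ties resolve toward $\theta' = 0$ (parsimony) and the fit
  then reports ratio exactly 1.
* **No p-value.** The evidence reported is the raw likelihood ratio and
  its $\log_{10}$; no chi-square calibration is attempted for the
  boundary case.
* **Stable logs.** $\log(1 - e^{-r})$ is evaluated via `expm1` so the
  density is accurate for both $r \to 0$ and $r \gg 1$.

Uncertainty is parametric bootstrap (`bootstrap_se()`): B datasets of the
observed size are simulated at the fitted $\theta'$, each refit, and the
SD of the refitted values reported. B defaults to 1000, which holds the
Monte-Carlo error of an SD near 2%. Replicate $b$ draws its RNG stream
from a child seed derived from $(\mathrm{seed}, b)$, so individual
replicates are reproducible regardless of B. The headline fit pools cells
across embryos (per-embryo fits remain available through
`oral_aboral_angles()` on single frames); the bootstrap likewise matches
the pooled $n$.

**Known limitation — the flat upper tail.** As $\theta' \to \infty$ the
family converges to a fixed shape ($\propto \theta\sin\theta$), so for
small samples an occasional draw yields an essentially flat likelihood
beyond $\theta' \approx 3$ and the refitted value is then only pinned by
$\theta'_{max}$. At $n \approx 200$ this affects roughly 0.1% of
bootstrap replicates and is the dominant Monte-Carlo noise in the
reported SD; a parsimony rule that snaps flat profiles to smaller
$\theta'$ was deliberately rejected because any tolerance large enough to
matter would detach the optimizer from the exact maximum-likelihood
solution that a grid search verifies.

```{r fit-example}
th <- rdsine(2000, theta_prime = 0.45, seed = 7)
fit <- fit_damped_sine(th)
summary(fit)
```

## 2. The synthetic embryo generator

`simulate_embryo()` realizes the geometry the angular analysis assumes:
labeled cells on a spherical shell (the embryonic wall), polar angle from
the damped-sine law at a known ground-truth $\theta'$, azimuth uniform,
radius uniform in the wall. Defaults and their reasoning:

* **Shell radii 100–140 µm** — the embryos in question are on the 100 µm
  scale; only the polar angle enters the analysis, so wall geometry is a
  free choice and any sensible shell works.
* **Mitotic rate 0.03** — mitotic labels are i.i.d. Bernoulli,
  independent of position, reflecting both the observed stability of the
  mitotic index across early stages and the absence of regional bias in
  mitoses; 3% is a typical low-single-digit mitotic index for a cycling
  population.
* **Beads** — real spot exports contain fiduciary beads used for image
  registration, so the generator plants uniform decoy spots labeled
  `bead`; every downstream operation must (and does) exclude them by
  label.
* **Per-embryo $\theta'$ jitter** — embryo-to-embryo variability in the
  true dampening term has never been quantified, so
  `simulate_embryo_cohort()` exposes a jitter SD but defaults it to 0.

What the generator does **not** emulate: imaging noise, segmentation
errors, anisotropic point-spread, partial occlusion of the wall, or any
coupling between cell class and position. Passing tests therefore
demonstrate correctness of the estimation machinery on data obeying the
model, not robustness to real microscopy artifacts.

## 3. The synthetic count study

`simulate_count_study()` emulates the single-embryo RNA-Seq design:
stages Y, S2–S8, C4, SX with four biological replicates each (defaults),
negative-binomial counts with a common dispersion (default 0.05, a
typical biological-replicate value), per-transcript means proportional to
transcript length so RPKM behaves sensibly, and lognormal per-sample
depth variation. Three rRNA rows (16S/18S/28S) take a configurable
fraction of each library (default 15%), with the 16S share the most
variable across samples — the behavior that motivates removing it before
RPKM. "Planted" transcripts carry a known fold in the replicates of
their planted stage(s); a multi-stage planting produces a persistent
profile, which is how EEE decoys are made. Planted transcripts are
always given an ORF and never flagged as transposons, so recovery
experiments measure the statistical cascade rather than random metadata.
The ground-truth table lists exactly the transcripts whose generating
fold differs from 1.

Not emulated: maternal-to-zygotic expression gradients, correlated
transcript modules, GC/length biases beyond the linear length factor, and
batch structure. The generator validates the pipeline's operating
characteristics under its stated model, nothing more.

## 4. The staging enrichment cascade

The cascade's thresholds are held in one object, echoed verbatim into
every report:

```{r thresholds}
staging_thresholds()
```

* **Low-expression filter** — transcripts with CPM summed over the
  comparison samples (the yolk and embryonic stages; adult samples do not
  enter) below 1 are removed, as are all three rRNA transcripts.
* **TMM-scaled RPKM** — scaling factors are precision-weighted trimmed
  means of log ratios against a reference sample (trims 0.30 on M, 0.05
  on A; reference = the sample whose 75th-percentile count/library ratio
  is closest to the mean), rescaled to geometric mean 1. The 16S
  transcript is excluded from the library-size denominator before RPKM.
  The implementation is cross-checked against edgeR's to $10^{-10}$ in
  the test suite.
* **Test engine** — a deliberately simple two-group test: counts are
  scaled to a common effective library, a single NB dispersion is
  estimated across transcripts by pooled method of moments
  ($\hat\phi = \sum(v - m) / \sum(m^2 - v/n)$, the $v/n$ term correcting
  the mean-square bias that would otherwise make the test
  anticonservative), and the rounded group sums are compared by a
  conditional two-sided NB test. The engine is pluggable — externally
  computed p-values keyed by transcript flow through the cascade
  unchanged — because the cascade, not the test, is the object of
  interest here.
* **Gates** — adjusted p-value (Benjamini–Hochberg) below 1e-5 for
  pairwise and S2–S5 mixed-reference calls, below 1e-20 for S6–S8 mixed
  calls; $|\log_2$ ratio$| \ge \log_2 5 = 2.3219\ldots$ (printed 2.322);
  average scaled RPKM $\ge 1.0$ at the focal stage; $\ge 1$ ORF;
  transposase/retrovirus exclusion. Every gate is recorded per
  transcript, so any failed call is attributable to a named gate, and
  relaxing any single threshold can only grow the survivor set.
* **Mixed reference** — each stage is contrasted against the pooled
  non-focal Y/S2–S8 samples as a group. The alternative reading
  (collapsing the reference into one averaged pseudo-sample) was
  considered and not adopted: it discards replicate-level variance and
  would make the dispersion estimate incoherent with the pairwise arm.
* **Yolk exclusion** — S2–S4 mixed calls drop transcripts that pass the
  same fold + adjusted-p gates in a yolk-versus-embryonic-stages
  contrast; the exclusion is stated in the source analyses without a
  threshold, so reusing the cascade's own gates is the least arbitrary
  operationalization.
* **Signatures and EEE** — a stage's signature is the union of its
  pairwise (versus the adjacent earlier stage; S2 versus Y) and
  mixed-reference upregulated calls. EEE transcripts are defined by
  explicit rules rather than by reproducing a hierarchical-clustering
  partition, whose cluster identities are not reproducible without the
  original matrix: a transcript is EEE when it belongs to the S2–S4
  signature union and its average RPKM at every one of S5–S8 is at most
  one fifth of its early-stage peak — the five-fold-decline constant
  taken from the published cluster descriptions. Evidence columns (S2
  versus yolk fold, adult stage averages) accompany every call.

## 5. Reproducibility and problem sizes

Every stochastic operation takes an explicit integer seed, restores the
caller's RNG state, and derives per-replicate child seeds so results do
not depend on how many replicates run. Reports are written as TSV plus a
JSON provenance block containing every threshold and seed; reruns are
byte-identical.

The test suite exercises the closed forms against quadrature on
$(\theta, \theta')$ grids, the sampler against the closed-form CDF at
$n = 10^5$ (KS distance < 0.01), the optimizer against a $10^{-3}$ grid
search, the cascade against a naive gate-by-gate reimplementation on ten
random planted studies, and planted-recovery operating characteristics
(recall, and EEE sensitivity/specificity, each at the 90% level) on
studies of 400 transcripts — sizes chosen so the full suite runs in a
couple of minutes while leaving every statistical margin wide. The two
bootstrap uncertainties the model family pins down ($\pm 0.045$ at
$\theta' = 0.45$, $n = 4411$; $\pm 0.33$ at $\theta' = 0.58$, $n = 192$)
are recomputed at B = 1000 both in the tests and by
`scripts/acceptance.R`.

## 6. Known limitations

* The likelihood ratio against the boundary null is reported raw, not
  calibrated; it is evidence, not a test.
* The flat likelihood tail at small $n$ (Section 1) makes the bootstrap
  SD at $n \approx 200$ sensitive to rare replicates; at the published
  scales this contributes a few percent of Monte-Carlo noise.
* The conditional NB test is slightly conservative for very low counts
  (discreteness) and assumes a common dispersion; the pluggable p-value
  input is the escape hatch for users holding better statistics.
* EEE classification inherits the power of the S2–S4 signatures: a
  transcript whose early enrichment misses a gate cannot be called EEE
  regardless of its decline.
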