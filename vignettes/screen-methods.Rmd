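---
title: "Scoring and classifying pharmaco-genetic interaction screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying pharmaco-genetic interaction screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgscreen)
library(dplyr)
```

## The assay and its statistic

pgscreen analyzes modifier screens built on in vitro follicle maturation.
Stage-10B *Drosophila* follicles mature overnight in culture; a COX
inhibitor (aspirin, 1.5 mM) dosed at the wild-type half-maximal level
blocks roughly half of them from completing nurse cell dumping. Each
culture well holds 20–30 follicles, scored into four stage buckets after
overnight culture: S10B and S11 (dumping not completed) versus S12 and
S13/14 (completed). For one genotype in one experiment, the package
computes

* the **dumping fraction** per well, `(n_s12 + n_s13_14) / total`;
* the **dumping index** (DI), the aspirin-well fraction divided by the
  vehicle-well fraction — a within-genotype ratio that cancels baseline
  maturation differences;
* the **normalized dumping index**, the genotype's DI minus the same
  experiment's wild-type control DI — a within-experiment difference that
  cancels batch effects such as drug potency drift.

Negative normalized indices mean the genotype *enhances* sensitivity to
COX inhibition; positive values mean it *suppresses* it. Fractions are
always computed from raw counts, never from pre-rounded percentages, so
the ratio is not doubly rounded.

## Quality control and aggregation

An experiment is usable only if its wild-type control DI lies in
[0.4, 0.6]; the band is inclusive at both ends (exclusion applies strictly
below 0.4 and strictly above 0.6). QC is judged on the control genotype
only, and a failing control invalidates every genotype scored in that
experiment. A control whose vehicle well shows no dumping at all has an
undefined DI, and the experiment is marked unusable with a diagnostic
rather than silently scored as 0 or infinity.

Replicates (one per experiment) are aggregated per genotype as mean and
sample (n − 1) SD of both the DI and the normalized index. A genotype with
a single usable replicate gets a missing SD — never 0 — and is flagged
provisional.

## Classification bands

Interactor calls compare the magnitude of a genotype's mean normalized
index against bands derived from the variability of the wild-type
controls themselves: sigma is the sample SD of the pooled, QC-passing,
*non-normalized* control DIs (normalized control values are identically
zero and carry no spread). Calls are:

| band | rule |
|---|---|
| non-interactor | \|mean\| < sigma |
| weak | sigma ≤ \|mean\| < 3·sigma |
| strong | \|mean\| ≥ 3·sigma |

with direction (enhancer/suppressor) taken from the sign. The partition is
exhaustive; we use ≥ at the 3-sigma boundary and < at the 1-sigma
boundary, which keeps the three bands mutually exclusive and matches the
stricter of the two phrasings such screens use. Sigma can either be
computed from the input screen's own controls or supplied externally
(`thresholds_from_sigma()`), e.g. to hold bands fixed at a previously
established aggregate value; every report records which source was used.

A note on replication structure: in a real campaign sigma comes from the
aggregate control pool across *all* experiments (typically dozens), while
any one genotype is tested in only a handful. Estimating sigma from just
the 3–5 experiments a genotype appeared in is markedly noisier and
inflates false strong calls; the recovery harness therefore supports an
`extra_control_experiments` argument that reproduces the pooled-control
structure.

## Inference

The tests that accompany such screens are available both from raw
replicate vectors and from summary statistics (n, mean, SD) — the form in
which aggregates are published. The two routes are algebraically identical
for one-way ANOVA and the pooled t statistic, and the suite asserts this
to 1e-10.

**Dunnett many-to-one comparisons** are authored in the package. With k
treatments against a shared control, the pooled-variance t statistics are
jointly multivariate t with equicorrelation `lambda_i * lambda_j`,
`lambda_i = sqrt(n_i / (n_i + n_0))`, on `N − k − 1` degrees of freedom.
Single-step adjusted p-values are max-|t| tail probabilities of that
distribution, computed by nested adaptive quadrature: conditioning on the
control's standardized mean (standard normal) and on the pooled-SD mixing
variable (a scaled chi), the statistics decouple into a product of normal
CDF differences. Quadrature tolerances are set so adjusted p-values are
accurate to about 1e-6, well inside the 1e-4 contract; a seeded
Monte-Carlo evaluation of the same null is available as a cross-check and
fallback. Adjusted p-values are clamped to be at least the unadjusted
pairwise p (they dominate it mathematically; the clamp only absorbs
quadrature round-off). Welch's test uses Satterthwaite degrees of freedom;
Student's test pools variances on `n_a + n_b − 2` df. Degenerate
zero-variance inputs with equal means yield statistic 0 and p = 1 rather
than NaN.

Tests run on per-experiment dumping indices — the replicate unit of the
screen — not on per-follicle outcomes.

## The simulator: what it emulates, and what it does not

`simulate_screen()` draws screens with the statistical structure the
analysis assumes:

* **Binomial wells.** Each well's dumped count is binomial on a uniform
  well size in [20, 30].
* **Calibrated control.** Wild-type vehicle maturation defaults to 0.92
  and the drug shift `beta_control = logit(0.92) − logit(0.50)` puts
  aspirin maturation at 0.50, so the expected control DI is about
  0.50/0.92 = 0.543 before QC.
* **Genotype effects.** A genotype shifts the aspirin log-odds by
  `± beta` (enhancers down, suppressors up); vehicle wells use the
  genotype's own baseline, unshifted. Any monotone link would serve; the
  logit-additive form is the conventional choice for shifting a binomial
  sensitivity.
* **Batch jitter.** One `N(0, tau)` draw per experiment perturbs the
  aspirin log-odds of *every* well in that experiment, emulating shared
  potency fluctuations (e.g. solvent evaporation). This shared structure
  is precisely what within-experiment normalization against the control
  removes.

Two consequences of this model are worth stating explicitly because they
drive the numerical behavior of the whole pipeline:

1. **QC truncation sets the aggregate control SD.** With 20–30 follicles
   per well the binomial noise alone gives a raw control DI SD of about
   0.116. The aggregate control SD that defines the classification bands
   is computed over QC-*passing* controls, i.e. DIs truncated to
   [0.4, 0.6]; truncation caps the SD at about 0.0577 (the uniform limit)
   and yields about 0.0547 at `tau = 0`, with mean about 0.509. The
   canonical published aggregate for this assay (0.505 ± 0.054, n = 59)
   is therefore reproduced by the binomial sampling model essentially
   without any extra batch variance. `calibrate_tau()` consequently
   bisects on the QC-passing SD, reports the tau = 0 floor honestly, and
   saturates with a warning for targets above the truncation ceiling.
2. **Planted effect sizes are measured against the truncated control
   mean.** A planted normalized-index effect of −0.275 (the magnitude of
   the screen's canonical strong enhancer, 0.192 vs 0.467) corresponds to
   a mutant aspirin maturation probability of `0.92 × (0.505 − 0.275)`,
   because the reference is the QC-passing control mean (≈ 0.505), not
   the untruncated expectation (0.543).

What the simulator does **not** model: dose–response across aspirin
concentrations (the assay uses one fixed dose), pharmacokinetic decay over
the overnight culture (jitter is a single scalar per experiment),
follicle-to-follicle heterogeneity beyond the binomial, and any
correlation between a genotype's vehicle baseline and its drug
sensitivity. Passing recovery tests on these simulations therefore shows
the pipeline is correct and well calibrated *under the assay's assumed
sampling model*; it cannot validate the biological assumptions of a real
screen.

The recovery harness (`recovery_experiment()`) reruns
simulate → score → aggregate → classify per repetition, re-deriving
thresholds from each repetition's own controls. Its default study-shaped
configuration uses 8 raw experiments per genotype (about 5 QC-passing
replicates at the calibrated ~59% pass rate, the replication level of
confirmed hits) and a campaign-wide control pool of about 59 passing
controls for sigma.

## Image quantification

The fluorescence module mirrors a manual line-profile workflow: maximum
projection of 2 confocal slices (2–4 supported, warned outside that
range), mean bilinear-interpolated intensity sampled at ≤ 0.5 px spacing
along a polyline membrane probe, mean intensity over a polygonal
cytoplasm region of the same cell, and the background-corrected membrane
intensity as their difference. The subtraction makes the measurement
exactly invariant to image-wide constant offsets — its stated purpose —
and negative corrected values are flagged, never clipped, so downstream
t-tests remain valid. Probes are inputs (JSON or CSV), exactly as in a
manual workflow; no segmentation is attempted. Coordinates are
pixel-based, origin top-left, probe width 1 px by default.

The synthetic fixture generator renders a polygonal nurse cell whose
boundary carries a bright membrane band over a dimmer interior. The band
has a flat core (half-width 1.6 px) with Gaussian shoulders
(`ridge_sigma = 2` px): a membrane of resolved finite thickness. The flat
core matters numerically — bilinear interpolation reads a bare Gaussian
crest a few AU (~2%) low because interpolating a concave profile
underestimates it, whereas every interpolation source under the probe
lies inside the flat core and reads exactly the membrane level. The
generator's ground truth is therefore analytic and the noiseless
measurement recovers it to well within 2 AU (far-edge shoulder tails are
below 0.1 AU at the default geometry). With additive Gaussian noise, the
maximum projection of 2 slices shifts membrane and cytoplasm means by the
same `E[max]` bias, which cancels in the subtraction; the Monte-Carlo
suite verifies the corrected intensity is recovered without material bias
over 500 noisy fixtures.

Densitometry normalization divides each lane's band by its loading
control and expresses the result relative to the mean of the designated
wild-type lanes, so common rescaling of all lanes cancels; zero loading
intensities are errors for the affected lane.

## Numerical choices and degenerate inputs

* QC band endpoints are inclusive; ties at 0.4/0.6 pass.
* `f_vehicle = 0` is an error (undefined DI), never a silent 0 or Inf.
* sigma = 0 (identical controls) produces degenerate bands with a
  warning; every nonzero effect is then "strong".
* Simulated well probabilities are clamped to [1e-6, 1 − 1e-6] with a
  warning when jitter or extreme effects push them out of range.
* Dunnett quadrature: inner/outer relative tolerances 1e-8/1e-7; the
  Monte-Carlo route is seeded and restores the RNG state.
* Validation is total: malformed counts name their rows; no row is
  silently dropped; missing paired controls are collected as structural
  problems on the returned table.

## Problem sizes used in the test suite

The suite's Monte-Carlo checks run at sizes chosen to estimate each rate
with useful precision while keeping the default run to a couple of
minutes: 1,000 simulated screens for the scoring identities, a
200,000-draw max-|t| simulation for the Dunnett oracle, 20,000
permutations for the Welch oracle, 500 repetitions for planted-interactor
recovery and all-null false-call rates, 4,000 simulated experiments per
SD evaluation in tau calibration, and 500 noisy image fixtures.

## A worked example

```{r example}
cfg <- sim_screen_config(
  genotypes = bind_rows(
    sim_genotype("enhA", beta = 1.3, direction = "enhancer"),
    sim_genotype("suppB", beta = 1.0, direction = "suppressor"),
    sim_genotype("nullC")
  ),
  tau = 0.05, n_experiments = 8, seed = 42
)
screen <- simulate_screen(cfg)
ana <- analyze_screen(screen)
ana
tidy(ana)
glance(ana)
```

```{r chart, fig.width = 6, fig.height = 3}
autoplot(ana)
```

```{r stats}
screen_stats(ana$scores)
```

## Known limitations

* Printed P-values of any particular historical screen are not
  recomputable: they depend on per-replicate values and ANOVA family
  compositions that aggregate tables do not determine. The machinery, not
  those numbers, is what the suite validates.
* The Dunnett family is all experimental genotypes passed in one call;
  other family structures must be formed by the caller.
* Single-replicate genotypes are classified but flagged provisional;
  their calls carry no variance information.
* The image module quantifies given probes; drawing the probes (membrane
  segmentation) is out of scope, as is gel band detection.
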