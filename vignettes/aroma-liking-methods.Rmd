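---
title: "Methods: aroma profiling and OPLS liking prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aroma profiling and OPLS liking prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitisaroma)
```

This vignette documents the statistical methods implemented in
`vitisaroma`, the choices made where the methodology was genuinely open,
and what the synthetic-data generator does and does not emulate.

## From concentrations to aroma profiles

**Odor activity values.** The OAV of compound $j$ in a sample is
$\mathrm{OAV}_j = c_j / T_j$ with $c_j$ the concentration and $T_j$ the
odor threshold, both in μg/kg of berry matrix. Thresholds must be
strictly positive, so OAVs are always finite; a compound that was not
detected is stored as absent and counts as concentration 0 everywhere.
OAV is homogeneous of degree one in concentration — diluting a sample
scales its whole profile — and a compound is **aroma-active** when its
OAV *strictly exceeds* 1.

**Aromatic series.** Every odor descriptor belongs to exactly one of ten
primary aromatic series; descriptors under the three broad primaries
(fruity, floral, sweet) may additionally carry secondary series. A
compound inherits the union of its descriptors' series and contributes
its **full OAV to each** of them: a compound with banana, apple and
strawberry notes feeds the fruity primary and all three secondary series
simultaneously. This double counting is deliberate — series are
descriptor-wise sums, not a partition of intensity — which is why the
conservation property (series totals equal OAV totals) holds only for
panels in which every compound has exactly one descriptor, and the tests
exercise it in exactly that setting. Series **activity** uses the
inclusive rule (value ≥ 1 in at least one sample): the two cutoff
conventions differ because compound activity and series activity are
reported with opposite inequalities in practice, and the package follows
each convention as stated.

The shipped taxonomy names the secondary series that are established for
table grapes (eight fruity, five floral, two sweet) and pads the
remaining slots to the canonical 14/13/5 counts with clearly labelled
placeholders (`fruity_placeholder_1`, ...). The full descriptor
assignment of a real panel is lab-specific configuration; users replace
the CSV, and validation enforces the structural invariants (one primary
per descriptor, secondaries only under fruity/floral/sweet, consistent
parents).

**Whole-berry blend.** Published whole-berry values rarely state how
pulp and skin were combined. The package uses a convex mass-weighted
blend, `whole = f · skin + (1 − f) · pulp` per compound, with skin mass
fraction `f = 0.2` by default (a typical skin share of table-grape berry
mass) and configurable. The blend is linear, so OAV homogeneity and
series arithmetic carry over. This is a declared stand-in, not a claim
about any particular study's aggregation.

**Ripeness.** `screen_maturity()` flags cultivars with TSS < 16 °Brix
(the OIV table-grape ripeness resolution). Screening only flags — it
never removes samples or touches concentrations; dropping unripe
cultivars is an explicit user decision.

## The OPLS core

All modelling happens in unit-variance (UV) scaled space: each variable
is centered and divided by its SD, and the response is scaled the same
way (the convention of the chemometrics software this mirrors);
zero-variance variables are dropped with a warning and recorded. Errors
are reported back on the original 1–5 sensory scale by multiplying by
the fitted response SD.

For a single response, the model is the classical O-PLS sequence:

1. predictive weight $w \propto X^\top y$, normalized to unit length;
2. for each of $A_o$ orthogonal components: loading
   $p = X^\top t / t^\top t$ of the current predictive score $t = Xw$,
   orthogonal weight $w_o \propto p - (w^\top p)\,w$, score $t_o = Xw_o$,
   loading $p_o$, and deflation $X \leftarrow X - t_o p_o^\top$;
3. final predictive score $t = Xw$ and response loading
   $q = y^\top t / t^\top t$.

By construction $w^\top w_o = 0$ and all scores are mutually orthogonal;
the tests assert these at $10^{-10}$. With $A_o = 0$ the model *is*
one-component PLS1, and the test suite checks equivalence against an
independently written textbook NIPALS implementation at $10^{-10}$.
Component labels follow the `1 + A_o + 0` convention (one predictive,
$A_o$ orthogonal, zero PLS components).

Reported statistics: R²X (cumulative X variance captured by all
components), R²Y (fitted response variance), R² (squared correlation of
fitted and observed), RMSEE $= \sqrt{SS_{res}/(N - 1 - A)}$ with
$A = 1 + A_o$ (the degrees-of-freedom convention of the originating
software; switching to $1/N$ would only rescale it), Q²Y and RMSECV from
cross-validation.

**Cross-validation.** Seven folds by default. Fold assignment is
deterministic given a seed and response-balanced: samples are ordered by
the response (random tie-break) and fold labels drawn within consecutive
blocks, so every fold spans the response range. Scaling and model are
refitted on the training part of every fold; PRESS accumulates on
held-out predictions; $Q^2Y = 1 - \mathrm{PRESS}/SS$ (the total sum of
squares about the mean — identical in raw and scaled units) and
$\mathrm{RMSECV} = \sqrt{\mathrm{PRESS}/N}$ on the sensory scale. The
orthogonal-component count grows from 0 while Q²Y improves by more than
0.01 (cap 9, both configurable). The exact component-acceptance rule of
the proprietary package this emulates is not public; the 0.01 rule is a
declared stand-in that reproduces its qualitative behavior (small
component counts on cohort-sized problems).

**Permutation test.** The response is permuted $n = 200$ times; the
model is refitted and cross-validated with the identical configuration.
Least-squares lines through the (|correlation with original y|, R²Y) and
(…, Q²Y) points — including the unpermuted model at correlation 1 —
give the R² and Q² intercepts. A valid model shows every permuted Q²Y
below the original and a clearly negative Q² intercept; a pure-noise
response is statistically indistinguishable from its own permutations.

**Outlier screening.** Before training, PCA with Hotelling's
$T^2_i = \sum_a t_{ia}^2/\lambda_a$ over $A$ components flags samples
above the F-bound $A(N-1)/(N-A) \cdot F_{1-\alpha}(A, N-A)$ at
$\alpha = 0.01$ (the 99% limit). $A$ is the smallest component count
reaching cumulative R²X ≥ 0.8, capped at 5 — the source methodology
names only "Hotelling's T² (99%)", so the component rule is the
package's own. Screening is a single pass: flag, remove, refit once.
On clean multivariate Gaussian data the empirical flag rate is ≈ 1%
(slightly below, as the F-bound is calibrated for new observations).

**VIP.** $\mathrm{VIP}_j = \sqrt{K \sum_a SSY_a (w_{aj}/\lVert w_a
\rVert)^2 / \sum_a SSY_a}$ over components, $K$ = number of variables,
$SSY_a$ the response variance explained by component $a$. Because each
weight vector is unit-norm, $\mathrm{mean}(\mathrm{VIP}^2) = 1$ exactly,
for any $SSY$ weights — the basis of the VIP > 1 selection rule. Whether
the originating software reports total or predictive-only VIP is
undocumented; the package defaults to the total variant (summing over
predictive and orthogonal components) with `type = "predictive"` as a
switch. Since orthogonal components explain essentially no response
variance, the two differ negligibly. Relationship directions come from
the sign of the model regression vector in scaled space, obtained by
folding the orthogonal deflation operators into the predictive weight.

**Prediction.** New samples are scaled with training parameters, their
orthogonal variation is removed component by component, and the
predictive projection is back-transformed. Predictions are therefore
invariant to adding model-orthogonal variation to new samples (tested by
construction from the model loadings). The pipeline predicts each
replicate separately and averages per cultivar — whether one should
average first is unknowable from published methods; per-replicate-then-
average is the declared choice, and for the linear model the two differ
only through replicate weighting.

**Quality bins and aroma combinations.** Published group definitions
("4.0–4.5", "> 4.5") leave boundaries open; the package closes them as
poor < 3.5 ≤ average < 4.0 ≤ good ≤ 4.5 < excellent, so bins partition
the line and 4.5 is good. Aroma combinations group cultivars by seeded
k-means (25 restarts) on the UV-scaled plane of (sum of positive-key
concentrations, sum of negative-key concentrations), labelled I, II, …
by increasing total key content. The published combination figure is
pictorial only; content-ordered k-means labelling is the package's
declared interpretation. Hierarchical clustering of series profiles uses
Ward linkage (`ward.D2`) on Euclidean distances of UV-scaled
replicate-mean values — linkage and metric are unstated in the source
methodology and configurable here.

**Effectiveness rule.** Models with cross-validated Q²Y ≤ 0.5 (the
conventional "good predictive ability" line) are flagged ineffective;
key-compound selection is blocked unless explicitly overridden. This
mirrors how a series-features model (aromatic-series values as X) that
cross-validates poorly should halt further interpretation; the pipeline
exposes that alternative feature block with identical diagnostics.

## The synthetic-cohort generator

The generator exists so that the full pipeline is testable without
instrument data. It emulates, per seed, a study-shaped cohort: a default
20 scored ("popular") + 19 unscored ("unfamiliar") cultivars, triplicate
pulp and skin profiles over a 100-compound panel spread across the eight
grape-volatile chemical classes with study-like proportions (terpenes
and esters dominating), odor thresholds log-uniform over 0.1–10⁴ μg/kg,
and class-typical tissue partitioning: ester mass concentrated in pulp,
terpene mass in skin, C₆ compounds high in both.

Concentrations are log-normal: per-compound log10 levels (class-typical
means ± 0.5 log units) plus bounded-uniform cultivar-level effects — a
chemical-class effect (SD 0.06 log10), a per-compound idiosyncratic
effect (SD 0.05), and two **pathway factors** loading (0.55) on the
positive-coefficient and negative-coefficient key-compound blocks
respectively. The pathway factors encode that liking-related volatiles
in fruit are biosynthetically co-regulated families rather than 26
independent compounds; they are also what makes coefficient recovery
from ~20 training cultivars well-posed — 26 independent weak effects
would be statistically unidentifiable at that sample size, in any
method. Latent factors are bounded (uniform, unit SD) so a single
cultivar cannot carry a physically absurd order-of-magnitude excursion.
Replicate noise is multiplicative with CV 10% by default; a small
zero-inflation probability (5%) removes non-key compounds from random
cultivars, mimicking non-detects.

Liking is generated in the same space the model operates in: a linear
combination (coefficients of magnitude 0.7–1.3, 17 positive and 9
negative, the negative block rescaled so both sign blocks contribute
equal response variance) of the UV-scaled whole-berry key-compound
concentrations, standardized, centered at 4 with gain 0.45 (scores
mostly 3.3–4.7), plus Gaussian noise, clipped to the 1–5 scale.
Response-orthogonal latent factors (default 2, mixed-sign loadings of
magnitude ≤ 0.25 on 30% of the non-key compounds, scores exactly
orthogonalized against the response) are added to the concentration
block only — the structured X variation that OPLS is designed to
isolate.

The default response noise SD is 0.12, calibrated once so that the
default training block reproduces the magnitude of the model statistics
reported for whole-berry cohorts of this design (seven-fold Q²Y ≈ 0.83,
RMSECV ≈ 0.2 on the sensory scale); the parameter-recovery tests use the
harsher SD 0.2 setting under which sign and VIP recovery of the injected
keys is still required to hold across seeds.

**The noiseless limit.** Several invariants are stated "in the noiseless
limit", which means *all* stochastic perturbations off: response noise,
replicate noise, orthogonal factors, zero-inflation, and the class and
idiosyncratic cultivar effects. In that limit the concentration matrix
has exactly rank two (the two pathway factors), the response is exactly
linear in it, a `1 + 1 + 0` model recovers the map to machine precision,
and predicted cultivar ranks equal the generated ranks exactly
(Spearman ρ = 1). With idiosyncratic variation switched on, a
26-coefficient map is not identifiable from 20 cultivars and rank
agreement is necessarily approximate — that is a property of the sample
size, not of the implementation.

**What the generator does not emulate:** chromatographic artifacts,
co-elution, detection limits beyond simple zero-inflation, censored or
heteroscedastic sensory scores, panel effects, or correlations between
maturity and aroma. Passing tests on synthetic cohorts therefore
demonstrates the *statistical machinery* — scaling, screening,
component selection, validation, selection rules — not that any real
cultivar's liking is predictable to the same accuracy.

## Problem sizes and numerical conventions

The test suite runs cohorts of 14–20 training cultivars with 20–100
compounds, 200-permutation tests on the default cohort, 20-seed
parameter-recovery sweeps, and 10 × 200-sample Monte-Carlo checks of the
Hotelling flag rate — sizes chosen to mirror the study design the
package targets while keeping the suite quick to run. Orthogonality
assertions use $10^{-10}$; oracle equivalences $10^{-10}$; VIP
normalization $10^{-8}$; round-trips $10^{-12}$. Ties in fold
assignment are broken by a seeded random draw; zero-variance variables
are dropped (never imputed) with their names recorded; descriptor
tokens are case-folded and whitespace-trimmed before taxonomy lookup,
since descriptor vocabularies come from heterogeneous literature
sources; unmapped descriptors warn rather than fail because real panels
always contain compounds without literature descriptors.

## Known limitations

* Single response only: no multi-response OPLS, no O2-PLS, no kernel
  variants.
* The component-acceptance rule (ΔQ²Y > 0.01) and the Hotelling
  component rule (R²X ≥ 0.8, cap 5) are declared stand-ins for
  proprietary conventions; both are configurable.
* Series values double-count multi-descriptor compounds by design;
  comparing series values across taxonomies with different descriptor
  densities is not meaningful.
* No psychophysical interaction modelling (masking, synergy): OAVs and
  series values are additive summaries.
* The whole-berry blend is a mass-fraction stand-in; if extraction
  yields differ between pulp and skin, the fraction should be
  recalibrated rather than reinterpreted.
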