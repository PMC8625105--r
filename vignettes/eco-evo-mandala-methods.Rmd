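---
title: "Methods: tail exponents, transfer entropy and the Eco-Evo Mandala"
author: "EcoMandala authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tail exponents, transfer entropy and the Eco-Evo Mandala}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EcoMandala)
```

# The model

EcoMandala condenses a bacterioplankton community's multivariate abundance
time series into three traits and places the community on a ternary plot (the
"Eco-Evo Mandala") whose geometry encodes departure from a theoretically
optimal state:

* **Structure, ε** — the density exponent of a power-law (Zipfian) fit to the
  community's abundance distribution. A scale-free abundance spectrum is read
  as the signature of a self-organized, well-balanced community; lower ε is
  closer to optimal.
* **Function, λ** — the rate of an exponential fit to the distribution of
  pairwise directed interactions, quantified as transfer entropy between OTU
  abundance series. A slowly decaying (low-λ) interaction distribution
  indicates a community whose information flow is spread over many strong
  couplings; lower λ is closer to optimal.
* **Genetics, D** — the effective phylogenetic distance: the *mean* patristic
  distance between all OTU pairs on a taxonomy-rank tree (an average rather
  than the conventional sum, so communities of different richness are
  comparable). Higher D means more genetic, hence presumably functional,
  diversity; higher is closer to optimal.

A fourth exponent, Taylor's-law ν (fluctuation scaling,
⟨x²⟩ ∼ ⟨x⟩^ν), is computed and reported alongside but deliberately excluded
from the Mandala axes: ν and ε are strongly associated (both are shaped by
the abundance distribution), so including ν would double-weight structure.

All analyses run on **raw read counts**. Relative abundances are computed
only for display (`relativeAbundance()`); normalizing to proportions would
distort both the tail fits and the variance–mean scaling.

# Interaction inference

Directed interactions are estimated with transfer entropy at history length
one,

$$TE_{X \to Y} = \sum p(y_t, y_{t-1}, x_{t-1})\,
  \log_2 \frac{p(y_t \mid y_{t-1}, x_{t-1})}{p(y_t \mid y_{t-1})},$$

using a box-kernel (Heaviside, max-norm) plug-in estimator: each probability
is the fraction of embedded sample points within a closed ball of radius
0.5 around the query point, after each series has been z-normalized so the
radius is in standard-deviation units. The estimator is fully deterministic.

Numerical conventions, chosen so results are bit-reproducible:

* points at distance exactly equal to the radius count as inside (closed
  ball);
* logarithms are base 2 throughout, so TE is in bits;
* a constant (zero-variance) series has no uncertainty to reduce, so any TE
  involving it is exactly 0;
* raw plug-in estimates can be slightly negative (finite-sample noise). The
  matrix keeps them as they are — flooring would hide estimator behavior —
  and they are floored at 0 (then zeros dropped) only when TE values enter
  tail fitting, which needs positive support;
* no Theiler window or dynamic-correlation exclusion is applied: the target
  regime is short (monthly) ecological series where temporal
  autocorrelation beyond lag 1 is weak relative to sampling noise.

The permutation-surrogate helper (`teSurrogates()`) exists for validation:
under independence, permuting the source series makes the estimate
exchangeable with its surrogates, which the test suite exploits. The
pipeline itself applies no significance filtering before fitting the TE
distribution — every positive pairwise value is fitted. This is an
interpretive choice: an alternative would be to fit only surrogate-passing
edges, which would shift λ in a sample-size-dependent way.

# Tail fits

Both tail families are fitted by closed-form maximum likelihood above a
lower cutoff `xmin`:

* power law: $\hat\epsilon = 1 + n / \sum_i \ln(y_i / x_{min})$ (continuous
  MLE; ε is the density exponent, so the exceedance curve decays as
  $y^{-(\epsilon - 1)}$);
* shifted exponential: $\hat\lambda = 1 / (\bar y_{tail} - x_{min})$.

The continuous estimator is used even for integer read counts: counts span
orders of magnitude, where the discrete correction is negligible compared
with sampling noise.

**Cutoff policy.** Abundance distributions have a noisy head (rare,
under-sampled OTUs), so the abundance ε is fitted with `xmin` scanned over
the observed values to minimize the Kolmogorov–Smirnov distance between the
fitted and empirical tail — standard power-law practice. TE values are
fitted with `xmin` fixed at the minimum positive value, keeping λ comparable
across sites (a scanned cutoff would make λ depend on how much head each
site's TE distribution happens to have). Both policies can be overridden.

**Family selection.** `selectFamily()` fits both families above one common
cutoff and compares log-likelihoods, with an indifference band (default 2
natural-log units) inside which the verdict is "inconclusive". The common
cutoff defaults to the minimum positive observation, i.e. the families are
compared over the full positive support. The design was genuinely open
here: an earlier variant reused the KS-scanned power-law cutoff for both
fits, but that scan — by construction — truncates the sample to the segment
where the power law fits best, which is precisely where the two families are
locally indistinguishable; in simulation the tail-only comparison identified
the generating family in a third of exponential samples at n = 500, while
the full-support comparison identifies it essentially always (the acceptance
suite requires ≥ 90% over 200 simulations for each family). The tail-only
variant remains available via `xminPolicy = "ks_scan"`.

**Refusal over garbage.** Any fit with fewer than `nMin` (default 8) tail
observations refuses with a classed error. Downstream, a refused fit becomes
an explicit `missing-epsilon` / `missing-lambda` flag on the Mandala point:
the point is excluded from the ternary projection but never dropped from
tabular output. This is the operational meaning of "λ was not calculable"
for small phyla or very short series.

**Taylor's law** is an ordinary least-squares regression of log2(variance)
on log2(mean), one point per OTU, using the population (divide-by-n)
variance to match the moment definition ⟨x²⟩ − ⟨x⟩²; OTUs with zero mean or
zero variance carry no scaling information and are excluded (and counted).
At least three usable OTUs are required.

Whether ε should be fitted to the pooled (OTU, time) count values or to
per-OTU time means is not determined by the method's definition; the default
is pooled values (`abundancePooling = "pooled"`), which uses all
observations, with per-OTU means available as a switch.

# Taxonomy trees and effective distances

Trees are built from ranked taxonomy, not sequences: a chain
root → kingdom → phylum → class → order → family → genus → tip per OTU, with
shared prefixes merged and **every edge of length 1** (one rank step; no
meaningful branch lengths exist without sequence data — unit lengths are the
package's declared convention). Unassigned ranks become placeholder nodes
**unique to their parent lineage**, so two OTUs unassigned at the same rank
under different parents do not merge and every tip sits at uniform depth 7.
The uniform depth matters for comparability: a site with poorer annotation
must not get systematically shorter distances.

D is the mean patristic distance over unordered distinct tip pairs. The
per-phylum distance Dp is, by default, the mean over **between-phylum**
pairs (one member in the phylum, one outside): the quantity is read as "how
unrelated is this phylum to the rest of the community", and including
same-phylum pairs would mix within-phylum cohesion into it. The alternative
reading — all pairs with at least one member in the phylum — is implemented
as `pairConvention = "all_others"`; the default is a choice, not a
resolution.

# The Mandala

Each axis is rescaled by its maximum over the plotted set (x/x_max), so the
largest observation maps to exactly 1 and the maxima are recorded for audit.
A ternary plot needs a constant-sum triplet, so the rescaled (D, λ, ε)
triplet is normalized to unit sum; the raw and rescaled values are kept
alongside the ternary coordinates so no information is lost. Axis polarity:
D as-is (high = good), λ and ε as-is (low = good); the optimal vertex is
(1, 0, 0) in (D, λ, ε) order, read counter-clockwise. The divergence score
is the Euclidean distance from that vertex in rescaled space — 0 at the
optimum, increasing in λ and ε, decreasing toward D = 1 — used for ranking,
not classification: no health thresholds are defined.

Because rescaling is per plotted set, points from different `MandalaSet`
objects are not directly comparable; the JSON sidecar records the maxima of
each set so values can be mapped back to raw units.

# The synthetic generator

`generateStudy()` emulates the shape of a seven-site reef/river monitoring
study: four habitat classes (three estuarine inshore reef sites, one lagoon,
two marine inshore reefs, one riverine), monthly series of length
t = 15, 17, 17, 15, 10, 9, 3, a shared OTU pool with Zipf-weighted phylum
sizes, and per-archetype parameters spanning density exponents of roughly
1.75–2.6 and Taylor exponents 1.5–1.7 — the ranges such communities display.
Per site:

* mean abundances are Pareto with the archetype's ε (inverse-CDF sampling
  above `minMean` = 5 reads);
* per-time counts are lognormal around each mean with variance tuned to the
  Taylor target Var = mean^ν (jittered by `noiseCv` in log space), then
  rounded to non-negative integers;
* a random directed graph of the archetype's density imposes lag-1 mixing
  y_{j,t} ← (1−s)·y_{j,t} + s·(m_j/m_i)·x_{i,t−1}, with strengths
  s ~ Exp(lambdaScale / couplingStrength): higher `lambdaScale` gives
  weaker couplings and a faster-decaying TE distribution.

Default problem sizes (pool of 240 OTUs, 12–190 per site) keep a full test
run to minutes; they are deliberately far smaller than a real OTU table and
are the package's own choice of routine-validation scale. What the generator
**does not** emulate: real taxonomic structure, zero-inflation from
detection limits, seasonality, viral or eukaryotic compartments, and
environment-driven nonstationarity. Passing recovery tests therefore shows
the estimators are correct under the generating model, not that real reef
data satisfy that model.

Recovery tests run at sizes where the estimators have power (ε at n = 2000,
ν at 200 OTUs × 100 time points, TE direction at t = 200–1000). The short
regime (t = 3, as in a real riverine site) is exercised only for
robustness: runs complete, warnings are emitted, λ is typically flagged as
not calculable. At t = 3 the kernel estimator has two embedded points per
pair; no one should read those TE values quantitatively. Similarly, the
habitat-separation validation study (used by the acceptance script) runs at
120 OTUs × t = 40 with strongly contrasted archetypes, because at t ≤ 17 the
λ axis is dominated by estimator noise and between/within separation is not
a stable property of the estimator — a genuine limitation of kernel TE on
monthly series, worth knowing before interpreting a real-data Mandala.

# Degenerate inputs and error behavior

Every user-facing failure is a classed condition (`eemMissingFile`,
`eemZeroSpread`, `eemTooFewTail`, `eemShortSeries`, ...) so pipelines can
branch on failure modes. Zero-variance series flag rather than error where a
convention exists (TE = 0); fits refuse rather than extrapolate; Mandala
points carry flags rather than disappearing. Ties at the kernel boundary
count as inside; ties in the KS scan resolve to the smallest cutoff.

# Known limitations

* Kernel TE at the target series lengths (t ≤ 17) is noisy and its bias
  depends on t; λ comparisons across sites with very different t should be
  read cautiously (the short-series warning marks t < 10).
* The ternary projection discards one degree of freedom (only ratios
  survive); the pairwise panels and the tabular raw values are the faithful
  record.
* Dp conventions differ in the literature of distance decompositions; both
  implemented readings are reported with their pair counts.
* No semiparametric bootstrap goodness-of-fit machinery is included; the KS
  distance is a diagnostic, not a p-value.
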