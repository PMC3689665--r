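---
title: "Phylodiversity, community structure and threat: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylodiversity, community structure and threat: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mangroveED` implements the analysis chain used to ask how threat is
distributed across the evolutionary tree of a regional flora — built around
the mangrove biome, but agnostic to the actual species set. This vignette is
the package's own account of the models it fits, the knobs that matter, what
the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## 1. Per-species phylodiversity

Given a rooted, time-calibrated tree (edge lengths in Myr), two per-species
quantities drive everything downstream:

* **Terminal branch length (BL)** — the pendant edge of a tip; the length of
  evolutionary history unshared with any other extant species, used as a
  proxy for species age.
* **Fair-proportion evolutionary distinctiveness (ED)** — each edge's length
  divided equally among its descendant tips and summed along the root path:
  \(ED(i) = \sum_{e \in \mathrm{path}(i)} \ell(e) / n(e)\). The scheme
  partitions the tree exactly: \(\sum_i ED(i)\) equals the total edge length.
  That conservation identity is the package's first acceptance criterion
  (relative error \(< 10^{-9}\) over 1000 random Yule trees).

Polytomies are accepted everywhere — fair proportion, patristic distances
and MRCA depths are all well defined on multifurcating trees — and no
arbitrary resolution is performed, since consensus trees routinely contain
unresolved nodes. A root edge, when present in the Newick, is ignored by all
metrics: it subtends every tip and is shared by definition. Zero-length
pendant edges are legal but trigger a warning, because a "species age" of 0
both degrades covariance conditioning and breaks plain log transforms (the
offset rule in section 5 absorbs this).

The phylogenetic covariance `C` (entries = MRCA depths, diagonal =
root-to-tip depths) is computed by the package itself and checked in the
tests against `ape::vcv`; patristic distances derive from the tree-metric
identity \(d_{ij} = C_{ii} + C_{jj} - 2C_{ij}\) and are checked against
`stats::cophenetic`.

## 2. Community structure: NRI and NTI

For each regional assemblage we compare the observed mean pairwise distance
(MPD) and mean nearest-taxon distance (MNTD) with a **tip-pool null**: `k`
tips drawn uniformly without replacement from *all* tips of the tree,
`n_reps` times (default 999, always with a user-visible seed — the source
analysis does not state its replicate count, so the default is the field's
conventional 999). The indices are the negated standardized effect sizes
(NRI from MPD, NTI from MNTD), so positive values mean phylogenetic
clustering. Membership is presence/absence only; the pool is the whole tree
by construction of the null (a restricted pool would be a different null
model and is deliberately not the default).

Two p-values are always reported: the one-tailed clustering rank
probability \((1 + \#\{\text{null} \le \text{obs}\})/(n_{reps}+1)\), with
ties counted toward the clustering tail (conservative), and a two-sided
version capped at 1. Published NRI/NTI tables sometimes mix one- and
two-tailed conventions for different regions; reporting both avoids
reproducing that ambiguity silently.

Correctness is pinned two ways: on pools small enough to enumerate, the
Monte-Carlo null mean and SD must sit within three exact Monte-Carlo
standard errors of the exhaustively enumerated values (the SE of the sample
SD is computed from the exhaustive distribution's fourth central moment —
the normal-theory formula understates it for these skewed, discrete
distributions); and uniformly random assemblages must be rejected at the
nominal 5% rate (calibration criterion, 1000 assemblages × 999 reps).

## 3. Phylogenetic signal: Blomberg's K

With the phylogenetic mean \(\hat a = (1'C^{-1}y)/(1'C^{-1}1)\), K is the
observed \(MSE_0/MSE\) divided by its Brownian expectation
\([\mathrm{tr}(C) - n/\sum_{ij}(C^{-1})_{ij}]/(n-1)\). K equals 1 exactly on
a star tree (the package tests this to \(10^{-10}\)) and averages 1 for
Brownian traits; the acceptance band for the simulated Brownian mean is
[0.9, 1.1] over 500 fifty-tip trees. Significance comes from shuffling trait
values across tips and ranking the phylogenetically corrected MSE (smaller =
stronger signal); the permutation count defaults to a seeded 999. In the
pipeline, K is computed on the *raw* threat scales (decline percent,
extinction probability): K is invariant to affine but not to log
transforms, and the source tables prescribe transforms only for the
regressions.

## 4. PGLS with Pagel's lambda

The regression layer fits \(y = Xb + e\), \(e \sim N(0, \sigma^2 V(\lambda))\)
with \(V(\lambda)\) equal to `C` with off-diagonals multiplied by
\(\lambda\). Estimation is maximum likelihood throughout (matching the
"ML estimate of lambda" convention of caper-style tables, not REML);
\(\lambda\) is optimized by Brent-style bounded scalar search on [0, 1] at
tolerance \(10^{-6}\), with both boundaries evaluated explicitly since the
optimum frequently sits at 0 or 1. Standard errors use the finite-sample
scaling \(\hat\sigma^2 n/(n-q)\,(X'V^{-1}X)^{-1}\); R² is computed against
the intercept-only GLS fit in the same \(V(\hat\lambda)\) metric, and both
multiple and adjusted R² are reported because univariate and multivariate
summary tables conventionally print different ones. A condition number
above \(10^{10}\) on \(X'V^{-1}X\) is a hard collinearity error — silent
predictor dropping would corrupt a fixed model set.

Numerical anchors: at \(\lambda = 0\) on an ultrametric tree the fit must
equal OLS to \(10^{-8}\); at \(\lambda = 1\) the log-likelihood must match a
direct quadratic-form GLS evaluation; and the whole fit (λ, coefficients,
log-likelihood) is checked in the tests against the independent
`nlme::gls` + `ape::corPagel` route. Parameter recovery (planted
\(\lambda = 0.7\), slope 0.5, n = 100, 200 replicates) must come back within
±0.15 and ±0.05 respectively.

## 5. Threat transforms and tests

IUCN categories map to 50-year extinction probabilities through an
*editable* config file shipping the published IUCN50 transformation
(LC 0.00005, NT 0.004, VU 0.05, EN 0.42, CR 0.97 — Mooers et al. 2008,
PLoS ONE 3:e3700); monotonicity LC < … < CR and strict containment in (0,1)
are enforced at read time, and no number is hard-coded downstream. DD, EW
and EX records are excluded from probability-based models by default
(overridable policy), since the mapping is undefined for them.

Log10 transforms follow a fixed per-variable policy: quantities that are
legitimately zero (global decline, the human-pressure use count) are
transformed as \(\log_{10}(x+1)\); strictly positive traits (height,
propagule volume, ED, BL, extinction probability) as plain
\(\log_{10}(x)\), falling back to the +1 offset with a warning if zeros
appear (e.g. zero-length pendant edges). Model frames apply listwise
deletion, prune the covariance to the retained species, and are idempotent.

Human pressure is the cardinality of a species' use set after
canonicalization against a 16-label controlled vocabulary (fuelwood and
charcoal; building, carving and fishing gear; cultural and spiritual; food
and forage; medicinal; ornamental; shade; tannin, dye and other chemical
products; apiculture). Per-use association with decline uses the closed-form
Yates-corrected χ² on the 2×2 table (has-use × declining), with "declining"
meaning decline above a configurable threshold (default 0 — the
dichotomization used by the source analysis is unstated). The correction is
floored at zero, and the implementation must agree with an independent
expected-frequency computation to \(10^{-10}\) on 10 000 random tables.
The pipeline reports all 16 raw p-values alongside Holm-adjusted ones.

## 6. Equal-area gridding

Ranges are gridded in the Behrmann projection (cylindrical equal-area,
standard parallel 30°, authalic radius 6 371 007.181 m). Cells are **square
in projected space** with side equal to 0.25° of equatorial arc (≈27.8 km),
so every cell has exactly the area of a quarter-degree square at the
equator. This follows the "0.25° × 0.25° (≈27.5 × 27.5 km)" reading of the
gridding convention; note that a 10°-wide equatorial extent therefore spans
`ceil(10·cos30°/0.25) = 35` Behrmann columns, not 40 — the naive 40-column
arithmetic applies only in the package's optional pure-geographic mode.
Cell membership is decided by **cell-center containment** (deterministic,
resolution-stable, cheap; an any-overlap rule would make occupancy grow
without bound as cells shrink). Rows are numbered from the south-west
corner; intervals are half-open `[min, max)`; rectangles crossing the
antimeridian are split automatically in the CSV dialect, and GeoJSON
polygons are rasterized by even-odd ray casting of cell centers.

Cells with no species are *missing*, not zero, in every layer, so layer
correlations run over the occupied domain only (`min_richness` defaults
to 1). The correlation p-value uses the t transform with `n − 2` df; note
that grid cells are spatially autocorrelated, so this p is nominal — the
same caveat applies to any cell-level correlation of range-derived layers.

## 7. The synthetic-study generator

The generator emulates the *statistical structure* of the real inputs, not
their geography or taxonomy:

* **Tree** — pure-birth (Yule) at 0.1 births/Myr, 54 tips by default
  (the number of species with DNA data in the mangrove flora); pure birth
  keeps the tree ultrametric and matches the tree-prior family used for the
  real reconstruction. Crown depth lands around 45 Myr.
* **Decline** — `clamp_[0,100](5 + 2·BL + N(0, 8²))` percent. These defaults
  were fixed a priori: with the BL dispersion of a Yule(0.1) 54-tip tree
  they imply a BL-decline correlation of roughly 0.6–0.7, i.e. an effect
  strong enough that the pipeline must detect it in ≥80% of studies at
  n = 54 (the planted-effect power property). A generator calibrated to the
  *observed* effect size of the motivating analysis (R² ≈ 10%) would have
  ~60% power at n = 54 and could never meet that property; the power
  requirement was taken as defining the generator's world.
* **Categories, uses, traits** — i.i.d. Red-List draws dominated by LC
  (60%), per-use Bernoulli(0.25) over the 16-use vocabulary (mean pressure
  ≈ 4 uses), log-normal height (median 15 m) and propagule volume. None of
  these carry phylogenetic structure by default, so K on
  extinction probability is expected near 0 and PGLS λ near 0 — mirroring
  the "no signal in threat" situation rather than assuming it.
* **Regions and ranges** — six regions with Indo-Malesia richest, members
  drawn by the configurable assemblage mode (`random` for calibration,
  `clustered`/`overdispersed` to exercise the NRI/NTI sign convention:
  clustered samples within the smallest clade that can hold the assemblage,
  overdispersed uses greedy max–min patristic selection). Ranges are thin
  rectangles inside disjoint synthetic coastline strips, wider for
  less-threatened categories.

What a green run does **not** establish: nothing about real coastline
geometry, spatial autocorrelation of ranges, non-random extinction
filtering, phylogenetically structured use profiles, or the actual mangrove
tree — the generator's independence assumptions are exactly the null
hypotheses several of the statistics test. Green means the estimators are
correct and calibrated on data satisfying their assumptions.

## 8. Numerical and reproducibility choices

* All covariance solves go through Cholesky factorization; a singular `C`
  (duplicate zero-length tips) raises an error advising jitter/pruning
  rather than silently regularizing.
* Every stochastic routine takes an explicit seed and restores the caller's
  RNG state; the pipeline splits one master seed into per-stage streams via
  a fixed LCG-style scheme (`derive_seed`), so stages can be re-run in
  isolation and reports are byte-identical across reruns (acceptance
  criterion 8).
* Acceptance criterion 7 runs its spatial leg on 1° cells (the tested
  quantity is the sign of the BL–decline layer correlation, which is
  resolution-stable) to keep 100 global rasterizations inside the time
  budget; the regression leg runs at the full default study size.
* Ties in permutation and rank tests count toward the conservative tail;
  p-values use the `(1 + #)/(n + 1)` convention and can therefore never be
  exactly zero.

## 9. Known limitations

Abundance-weighted community metrics, alternative null models (independent
swap, richness-constrained shuffles), phylogenetic logistic regression for
categorical threat, coastline clipping and spatially autocorrelated range
simulation are out of scope. The `fd` column is carried as an opaque
numeric predictor: it appears in published model tables without a stated
definition, and the package deliberately does not guess one.
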