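---
title: "Screening harbour sediments for contamination point sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening harbour sediments for contamination point sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedsource)
```

## The problem

Harbour sediments accumulate heavy metals, polycyclic aromatic hydrocarbons
(PAH) and hydrocarbon fractions from two very different kinds of input:
*nonpoint* (diffuse) pollution that spreads across the whole basin, and
*point* sources -- a leaking terminal, an accidental spill -- that leave a
localized chemical anomaly at a few sampling positions.  Telling the two
apart from a monitoring matrix (positions x chemicals, mg/kg dry weight) is
the screening problem this package addresses.  The workflow is a fixed
sequence of stages:

* **Step 0** -- variance--covariance PCA with *chemicals as variables*;
  per-chemical variance weights; elimination of a dominant diffuse
  pollutant and a re-run on the reduced matrix.
* **Step 1** -- PCA with *sampling positions as variables*; positions far
  from the robust centre of the leading component space are candidate
  point sources.
* **Step 2** -- for every (position, chemical) cell, the robust score
  $O_n(x) = |x - \mathrm{median}(X)| / \mathrm{MAD}(X)$ against the
  chemical's column; positions with any score at or above a cutoff $n$ are
  flagged, together with the chemicals that make them anomalous.
* **Step 3** -- ratio matching: each sample's fingerprint is its
  upper-triangular matrix of pairwise concentration ratios
  $c_i/c_j$ ($m(m-1)/2$ entries for $m$ chemicals), which is invariant to
  dilution with inert material.  Flagged positions whose fingerprints
  agree within a tolerance band are clustered as children of one source.
* **Step 5** -- concentrations are divided by sediment PNECs (predicted
  no-effect concentrations) and the PCA ranking is repeated on the risk
  quotients to order the flagged positions by ecotoxicological relevance.

Attribution of clusters to concrete facilities (the map analysis that
would be Step 4) is interpretive work on cargo documents and harbour
charts and is deliberately out of scope; `run_pipeline()` exposes its
outputs so that a user can join them against a facility table.

## The statistics, and the choices behind them

### Covariance PCA in two orientations

Both orientations decompose the variance--covariance matrix (columns
centred, *not* scaled): chemicals at wildly different absolute levels are
the signal here, not a nuisance, so correlation scaling would discard
exactly the structure the procedure reads (a correlation mode is available
via `use_correlation = TRUE` for sensitivity analysis).  In the
samples-as-variables orientation each position is a variable observed over
the chemicals; a position's coordinate on component $j$ is its loading
scaled by $\sqrt{\lambda_j}$.  Eigenvector signs are fixed by making each
loading's largest-magnitude element positive.

Missing cells (chemicals not measured in a campaign) are handled by
pairwise-complete covariance -- an approximation that can break exact
positive semi-definiteness; tiny negative eigenvalues are therefore
tolerated and clipped when explained fractions are formed.  Cells below
the analytical detection limit enter the PCA and MAD stages at half their
detection limit, the standard censoring substitution.

### Reading the scree automatically

The scree plot is traditionally read by eye.  For reproducibility
`scree_select()` applies a deterministic rule -- smallest $k$ with
cumulative explained fraction $\ge 0.95$ by default, largest relative
eigenvalue drop as an alternative -- and the outlier ranking always
inspects at least the first two components, which is how such score plots
are read in practice.

### The robust score and its cutoff

$O_n$ uses the raw MAD (no 1.4826 consistency constant), so a score of 4
reads literally as "four typical deviations from the column median".  The
scored value stays inside its own reference column.  A zero MAD yields a
sentinel: 0 at the median, $+\infty$ elsewhere, and such columns are
reported as degenerate rather than silently dropped.  The default cutoff
is 4; raising it can only shrink the flagged set (a property the test
suite asserts).  Two deliberate refinements:

* a below-detection-limit cell is never *flagged* (its DL/2 substitute can
  sit several MADs below the median, but a non-detect is not evidence of a
  point source); censored values still belong to the reference
  distribution;
* components whose coordinates are numerically constant, or whose
  eigenvalue is negligible, contribute no outlyingness -- otherwise
  floating-point dust divided by a near-zero MAD manufactures spurious
  flags.

### Ratio matching and the acceptance band

Two fingerprints are compared element-wise; the quotient of corresponding
ratios should be 1 for samples fed by the same source, whatever their
dilution.  The conventional band 0.90--1.10 is not reciprocal-symmetric
($1/0.9 \approx 1.11$), so the default test is the symmetrised
$\min(r, 1/r) \ge 0.90$, which makes the link graph well-defined
(undirected); a literal-interval mode is kept for fidelity.  A pair is
linked when at least 90% of its jointly unmasked quotients are in band
(`link_threshold = 0.90`, chosen to tolerate a few noisy trace
chemicals), and clusters are connected components of the link graph;
average-linkage clustering on $1 - \text{in-band fraction}$ is available
as an alternative.  Masked entries (zero, censored or unmeasured
concentrations) are excluded from both numerator and denominator.

Within the pipeline, Step 3 compares each pair of flagged positions over
the *intersection of their own flagged chemicals* (`cluster_sources()`):
the fingerprint of a hypothesised source is carried by the chemicals that
made it anomalous, and comparing over any wider panel dilutes it with
background ratios that vary with each sample's dilution factor.  Pairs
sharing fewer than two flagged chemicals admit no ratio and cannot link.
Because a hazard- or risk-quotient matrix differs from the raw matrix
only by fixed per-chemical factors, the pairwise quotients -- and hence
the clustering -- are identical for any `value_kind`.

### PNEC resolution and the risk stage

Sediment PNECs resolve per chemical in a fixed order: an explicit sediment
value, then the equilibrium-partitioning product
$\mathrm{PNEC}_{sed} = K_p \cdot \mathrm{PNEC}_{water}$, then the
assessment-factor rule $\min_i(\text{endpoint}_i / \mathrm{AF}_i)$
(converted to sediment units with $K_p$).  The resolution path is
reported as an audit table.  Aggregate indicators (a PAH sum) have no
defensible PNEC and are dropped from the risk matrix with a warning.
The pipeline also removes the Step-0-eliminated dominant pollutant from
the risk matrix by default (`risk_exclude_dominant`): the risk stage
ranks the identified *point* sources, and a diffuse pollutant far above
its threshold is an area-wide management issue that would otherwise mask
them.

One caveat the test suite makes explicit: the PCA risk selection measures
outlyingness in a *combined* component direction, the MAD report in
single columns.  A borderline position can exceed four MADs in a
combination of correlated columns while staying below in each one, so the
two selections agree on genuine sources but may disagree on a fringe
position -- under one per survey on average in the recovery tests.

## What the synthetic generator emulates

`harbour_scenario()` defines, and `generate_scenario()` draws, datasets
sized like a four-campaign harbour survey: 68 positions, 28 chemicals
(11 metals, 14 PAH plus an aggregate PAH sum, 2 hydrocarbon fractions),
replicate samples at every fifth position, ~5% censoring.  Per sample
$s$ at position $p$, in hazard-quotient units,

$$\mathrm{HQ}_{si} = \left(m_i\, G_p\, W_{p,i}\, H_s +
  S_k\, s_{ki}\, \tilde m_i\, f_s\right)\,\epsilon_{si}$$

* $m_i$ -- background median HQ per chemical, a profile dominated by zinc
  (median HQ 25) with lead and heavy hydrocarbons next, the ordering
  typical of an industrial Mediterranean basin;
* $G_p$ -- a position enrichment factor *shared by all chemicals* of the
  position.  Diffuse background co-varies across chemicals (fines
  content, organic carbon), and since every position is a mixture of a
  clean-sand and a contaminated-silt end-member the factor is bounded:
  log-uniform with `position_sigma` = 0.12 on the log scale.  The bounded
  choice matters: with Gaussian log-tails, a 68-position, 27-chemical
  survey *mechanically* produces one to two background cells beyond four
  MADs somewhere -- the score is scale-free, so no variance setting
  avoids it -- and flagged-set purity would say nothing about the method.
  Real surveys read the ordered list precisely because real tails are
  uncertain; the generator's ground truth has to be unambiguous instead;
* $W_{p}$ -- extra lognormal spread on the dominant pollutant only.  Its
  standard deviation is *solved* (exact moment algebra in
  `expected_weights()`) so that zinc's expected share of the total column
  variance is 76%, making dominant-pollutant elimination a recoverable
  target.  The share of a single draw is a ratio of sample variances, so
  its mean sits a few points below the plug-in target (ratio-of-
  expectations bias) with a per-seed spread of roughly ±10 points;
  recovery tests therefore check the ensemble mean within ±10 points and
  that zinc ranks first;
* $H_s$ -- per-sample lognormal factor (`sample_sigma` = 0.03): aliquot
  heterogeneity, shared across chemicals within a sample, so it cancels
  from every ratio fingerprint;
* source term -- signature relative levels $s_{ki}$ (multiples of the
  chemical's background median, absolute HQ units where the background is
  zero) times a strength multiplier (default 50) times a per-sample
  dilution factor $f_s \sim U(0.5, 2)$.  Three sources are planted by
  default: a single-position PAH spill, a two-position Cd/Pb/Hg source
  and a three-position hydrocarbon source -- one singleton and two
  multi-position clusters, the mix the clustering stage must resolve;
* $\epsilon_{si}$ -- per-cell lognormal analytical error, `noise_cv` =
  0.01 (instrument repeatability on homogenised extracts).

The noise default is also where the method's brittleness lives: a ratio
quotient across two samples stacks four per-cell errors, so its log-sd is
$\approx 2\,\sigma_\epsilon$, while the symmetrised band admits
$|\log r| \le 0.105$.  At 1% noise a same-source pair is in band with
probability $\approx 1$; at 5% ($2\sigma_\epsilon = 0.1$) it drops to
~70% per ratio and clusters start to shatter -- the monotone degradation
that `test-synthetic.R` demonstrates by comparing `noise_cv` 0.01 against
0.25.  Fingerprint clustering with a 10% band presupposes tight
analytical repeatability.

What the generator does *not* emulate: spatial correlation beyond the
shared enrichment factor (no transport, no distance decay), campaign
effects (all samples are drawn from one protocol), matrix effects on
detection limits, and background fingerprint diversity -- background
positions share one median profile, so their mutual ratio similarity is
higher than in real sediments.  Passing recovery tests therefore shows
the machinery resolves clean, planted structure; it does not certify
performance on data whose background varies in composition.

## Problem sizes in the tests

The recovery suites run the full pipeline on ensembles of 20 default
scenarios (68 x 28, three sources) -- a few seconds in total -- plus 50
smaller scenarios for the cutoff-monotonicity property and 200 random
matrices up to 6 x 6 against a brute-force covariance/eigendecomposition
oracle.  `scripts/acceptance.R` re-runs the ensemble from scratch,
deriving its sub-seeds from the single `--seed` argument.

## Known limitations

* The flagged set at a fixed cutoff is a screening list, not an
  inference: no multiple-testing control is applied over the
  positions-x-chemicals score grid, by design.
* Connected-component clustering is order-free but greedy: one borderline
  link merges two clusters.  The average-linkage mode is less brittle but
  needs a cut height.
* Pairwise-complete covariance is only an approximation under heavy,
  structured missingness; a variable missing in most campaigns should be
  dropped rather than patched.
* The ratio band treats 0.90--1.10 as a fixed tolerance; it is not a
  confidence interval and carries no error rate.
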