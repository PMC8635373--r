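---
title: "Structure-function coupling analysis: models, parameters, and design choices"
author: "scfc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function coupling analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfc)
```

## What the package computes

`scfc` analyzes paired brain connectivity matrices on the 90-region AAL
parcellation: a structural matrix (SC) of fiber counts from diffusion
tractography and a functional matrix (FC) of Fisher-z transformed
correlations between regional resting-state fMRI time series. For each
subject and each subnetwork — default mode (DMN), executive control
(ECN), salience (SAN), and the whole brain — it derives three features:

1. **Binary global efficiency of the structural network.** The
   structural graph connects regions joined by at least one fiber
   (`threshold_structural()`). Global efficiency is the mean inverse
   shortest-path hop count over ordered node pairs,
   $E_{glob} = \frac{1}{N(N-1)}\sum_{i \neq j} 1/d(i,j)$,
   with disconnected pairs contributing 0. It is 1 exactly on a
   complete graph and decreases with sparsity and fragmentation.
2. **Binary global efficiency of the functional network.** The
   functional graph keeps edges whose Fisher-z value is positive and
   significantly nonzero under the normal approximation
   $p = 2(1 - \Phi(|z|\sqrt{T-3}))$, Benjamini–Hochberg corrected at
   `q = 0.05` across all upper-triangle edges of the matrix being
   thresholded (`threshold_functional()`).
3. **SC-FC coupling.** The Spearman rank correlation between
   $\log(\text{fiber count})$ and the FC value over the subnetwork's
   region pairs (`sc_fc_coupling()`). High coupling means the
   functional organization adheres closely to the anatomy.

Features are assembled into a features-by-subjects table
(`build_feature_table()`), harmonized across acquisition sites with
parametric empirical-Bayes ComBat (`combat_fit_transform()`), and fed
to the inferential layer: ANCOVA group tests with age and sex
covariates, Tukey/Welch post-hoc contrasts, edgewise FDR-controlled
group contrasts, per-group behavior correlations, and Fisher r-to-z
tests for differences between independent correlations.

## Thresholding and graph choices

*Binary, not weighted, efficiency.* The thresholds themselves define
adjacency — "one or more fibers" for SC, FDR-significant positive
values for FC — so hop-count distances on the binarized graph are the
natural metric. Weighted path-length variants are deliberately out of
scope. Distances come from a simultaneous breadth-first search: the
k-th frontier of every source node is expanded at once with one
boolean matrix product per level, which is exact and fast at $N = 90$.
The implementation is verified against a Floyd–Warshall oracle and
`igraph::distances()` in the test suite.

*FC degrees of freedom.* The Fisher-z edge test needs the length $T$
of the time series behind the correlations. Real acquisitions vary and
the harmonized features do not record $T$, so `t_points` is a
configuration parameter. Its default, 200 time points, is an arbitrary
but typical resting-state run length; users with known scan parameters
should set it. Only $T > 3$ is admissible (the z standard error is
$1/\sqrt{T-3}$).

*FDR family.* BH correction is applied within the matrix being
thresholded (4005 edges for a whole-brain matrix), before any
subnetwork restriction; thresholding and subnetwork extraction then
commute edge-by-edge.

*Zero-fiber pairs in the coupling.* $\log 0$ is undefined, so region
pairs without fibers are excluded before the rank correlation (the
default). A `zero_mode = "log1p"` option instead keeps all pairs and
correlates $\log(1 + \text{SC})$ with FC; because Spearman correlation
is invariant to strictly monotone maps, the two modes agree whenever
no zeros are present. Couplings estimated from fewer than 3 pairs are
reported as missing, never as 0. For the same invariance reason it is
irrelevant whether FC enters as raw correlations or Fisher-z values.

## ComBat harmonization

Site effects are modeled per feature $g$ and site $i$ as
$y_{ijg} = \alpha_g + X_j \beta_g + \gamma_{ig} + \delta_{ig}
\varepsilon_{ijg}$. The implementation follows the standard parametric
empirical-Bayes procedure: feature-wise least squares with the
batch-size-weighted constraint $\sum_i n_i \hat\gamma_{ig} = 0$,
standardization by the pooled residual SD, method-of-moments
hyperpriors (normal for locations, inverse-gamma for squared scales),
iterative conditional-posterior updates of $\gamma^*$ and
$\delta^{*2}$ (tolerance $10^{-4}$, at most 100 iterations, matching
the reference implementation's defaults), and back-transformation. The
test suite checks the output against `sva::ComBat()` to numerical
precision, and the fitted model exposes per-batch location/scale
estimates through `harmonization_report()`.

All 12 feature rows are harmonized in one joint fit: pooling
batch-effect information across features is the point of the
empirical-Bayes step. Age and sex are always protected covariates;
diagnostic group is included by default (`include_group = TRUE`) so
harmonization cannot absorb group differences, with a flag to drop it
for users who prefer the stricter covariates-of-interest-only model —
which covariate set the harmonization of a given published table used
is often ambiguous, so both are supported.

Two properties worth knowing. First, empirical-Bayes shrinkage pulls
each feature's site effect toward the across-feature mean; when every
feature carries the *same* injected shift, the prior variance is
sampling noise and individual features retain small residual gaps
(order $\sigma/\sqrt{n}$) even though the common shift itself is
removed almost exactly. Second, the per-batch scale estimates use
$n-1$ denominators (as in the reference implementation), so even two
identical batches are rescaled by the vanishing factor
$\sqrt{(n-1)/n}$ — re-running ComBat on its own output is a near-no-op
but not a byte-level identity.

## The inferential layer

The ANCOVA is the partial F test of the group factor: full model
`y ~ group + age + sex` against `y ~ age + sex`,
$F = \frac{(SSE_r - SSE_f)/\Delta df}{SSE_f/df_f}$, with raw group
means and SEMs reported alongside. Sex enters as a 0/1 indicator; age
is uncentered (centering leaves the partial F unchanged). A constant
response returns $F = 0$. Post-hoc pairwise contrasts come in three
flavors: Tukey–Kramer on the covariate-adjusted group means (the
default for table-style reports; computed via `emmeans`), unadjusted
Welch two-sample t tests (figure-style contrasts), and
Bonferroni-scaled Welch tests. The published tables this layout
mirrors do not name their multiplicity adjustment; Tukey–Kramer is
this package's documented choice.

Edgewise group contrasts run a Welch t test per upper-triangle edge —
on $\log(1+\text{count})$ for SC, on Fisher-z values for FC — with BH
correction over the tested family; zero-variance edges are excluded
and counted. Behavioral analyses correlate per-group couplings with
hyperactivity and inattention scores (Pearson by default, Spearman by
flag) and compare groups with the independent-samples Fisher r-to-z
test, $z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)/
\sqrt{1/(n_1-3) + 1/(n_2-3)}$. That classical test exactly reproduces
the printed p = 0.0057 for r = 0.25 (n = 75) vs r = 0.62 (n = 70),
which is why it was chosen over other correlation-comparison
statistics. Sensitivity re-analyses after outlier removal are
supported as explicit exclusion lists rather than an automatic
detector, whose criterion would otherwise be arbitrary.

## The synthetic cohort generator

Access-controlled imaging data cannot ship with an analysis package,
so `generate_cohort()` produces cohorts with the statistical structure
the pipeline assumes, and the test suite runs entirely on them.

* **SC**: an Erdős–Rényi graph per subject with group-specific edge
  density; edges carry fiber counts
  $\max(1, \mathrm{round}(e^{N(\mu, \sigma)}))$ with $\mu = 3$,
  $\sigma = 1$ (median ~20 fibers, heavy right tail, no zero-count
  edges — a connected pair has at least one fiber by construction).
* **FC**: the target covariance is
  $\Sigma = (1-\alpha) I + \alpha C$, where $C$ is the subject's
  standardized $\log(1+\text{SC})$ matrix projected to the nearest
  positive-definite correlation matrix (eigenvalue clipping at
  $10^{-8}$, then re-standardization to unit diagonal). `t_points`
  independent multivariate normal vectors are drawn and the Fisher-z
  of their sample correlation matrix is returned. Generating FC by
  finite-sample correlation — rather than adding noise to SC directly
  — makes FC a genuine correlation matrix and supplies exactly the
  degrees of freedom the FC thresholding assumes. The mixing weight
  $\alpha \in [0,1]$ controls the expected edgewise coupling
  monotonically: $\alpha = 0$ gives FC independent of SC.
* **Behavior**: hyperactivity is the group mean plus
  `beta_hyper[group]` times the standardized DMN coupling plus noise;
  inattention is built from standardized hyperactivity to carry the
  target correlation `rho_inatt_hyper[group]` exactly in expectation.
* **Sites**: subjects are assigned to two sites Bernoulli(0.5),
  independent of group by default (configurable to induce confounding
  for harmonization stress tests). Site location/scale effects are
  applied to the *feature table* (`inject_site_effects()`), not the
  matrices: the features are where the analysis meets the batch
  structure, and this keeps the injected ground truth exact.

### Default calibration

Defaults encode the targeted study design: group sizes 56/75/70
(TDC/ADHD-I/ADHD-C); age ranges and male fractions (0.36/0.72/0.80)
per the cohort being emulated; SWAN-like score means and SDs per
group; structural edge densities 0.32/0.28/0.26 — lower in ADHD,
lowest in ADHD-C — which put subnetwork structural efficiencies in the
high 0.5s to low 0.6s; and coupling strengths
$\alpha$ = 0.40/0.36/0.55, calibrated once (400 simulated subjects per
condition) so the group-mean DMN couplings land near 0.27/0.27/0.37.
The hyperactivity slope is negative in ADHD-I only
(`beta_hyper = -0.33`), and the inattention-hyperactivity correlation
is higher in ADHD-C (0.62) than ADHD-I (0.25). These are calibration
goals, not guarantees: a single cohort's group mean fluctuates by
roughly $\pm 0.03$ around the target (per-subject DMN coupling has SD
about 0.23 because only ~20 edge pairs inform it).

### What the generator does *not* emulate

Simulated matrices have no spatial topology (no hemispheric symmetry,
distance-dependent connection probability, or community structure
beyond what SC coupling induces), no heavy-tailed hub degree
distribution, no negative FC blocks from anti-correlated systems, no
motion or physiological artifacts, and identical $T$ for every
subject. Site effects enter as clean location/scale shifts on
features. Passing tests therefore demonstrate that the *pipeline*
recovers known structure from data satisfying its assumptions — not
that those assumptions hold for any particular real acquisition. One
visible consequence: with the default $\alpha$ values the FDR-level
FC thresholding is in a steep regime, so simulated functional-network
efficiencies are much lower than — and, unlike real cohorts, strongly
$\alpha$-dependent between — the groups; the functional-efficiency
rows of the report should be read with that in mind.

## Problem sizes used by the shipped checks

The package's verification suite runs entirely on synthetic data:
brute-force oracles (Floyd–Warshall, rank-then-Pearson, step-up BH,
normal-equations partial F) on hundreds of small random instances;
null-simulation size checks for the ANCOVA (2000 replicates at 30 per
group) and the edgewise tests; harmonization recovery at 50 subjects
per site; and 50 replicates of the full pipeline at the 201-subject
design for the end-to-end group-structure recovery check. These sizes
were chosen to make the statistical assertions sharp at interactive
run times.

## Known limitations

* Only binary global efficiency is implemented; weighted variants and
  other graph measures (clustering, modularity, node-level efficiency)
  are out of scope.
* Parametric ComBat only; no ComBat-GAM, longitudinal ComBat, or
  harmonization of raw matrices.
* The FC edge test relies on the Fisher-z normal approximation with a
  user-supplied `t_points`; it does not model autocorrelated time
  series, whose effective degrees of freedom are lower.
* The AAL-90 region-name mapping for the shipped DMN/ECN/SAN
  definitions follows standard usage and is user-overridable
  (`subnetwork_definitions(definition_file=)`) for laboratories that
  resolve names (for example, the insula or medial frontal regions)
  differently.
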