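# scfc — structure-function connectome coupling analysis

`scfc` is an R package for analyzing paired structural and functional
brain connectivity matrices in multi-site cohorts. It was built for the
kind of study that asks whether diagnostic groups — here typically
developing children (TDC) and the inattentive (ADHD-I) and combined
(ADHD-C) presentations of ADHD — differ in the network architecture of
intrinsic brain subnetworks: the default mode (DMN), executive control
(ECN), and salience (SAN) networks, defined as fixed 12-region subsets
of the AAL-90 parcellation.

From each subject's 90×90 structural connectivity matrix (SC, fiber
counts from probabilistic tractography) and functional connectivity
matrix (FC, Fisher-z correlations of resting-state fMRI), the package
computes three features per subnetwork:

* **Global efficiency of the structural network** — the structural
  graph keeps edges with one or more fibers; efficiency is the mean
  inverse shortest-path length over ordered node pairs,
  `E_glob = 1/(N(N-1)) * sum_{i!=j} 1/d(i,j)`,
  1 for a complete graph, lower for sparse or fragmented graphs.
* **Global efficiency of the functional network** — the functional
  graph keeps positive edges that survive Benjamini–Hochberg FDR
  control at q = 0.05 under the Fisher-z normal approximation
  `p = 2(1 − Φ(|z|·sqrt(T−3)))`.
* **SC-FC coupling** — the Spearman correlation between log fiber
  counts and FC values over the subnetwork's region pairs; high
  coupling means functional organization adheres closely to anatomy.

Features are harmonized across acquisition sites with parametric
empirical-Bayes **ComBat** (implemented in-package, numerically
matching the reference implementation, with age, sex, and optionally
diagnosis as protected covariates), then analyzed with **ANCOVA**
partial F tests (age and sex covariates), Tukey/Welch post-hoc
contrasts, edgewise FDR-controlled group contrasts, behavior
correlations, and the Fisher r-to-z test for a difference between two
independent correlations.

Because clinical neuroimaging biobanks of this kind are
access-controlled, the package ships a **synthetic cohort generator**
that emulates the study's statistical structure — group-dependent
structural density, FC coupled to log-SC with tunable strength
`alpha`, two-site batch effects, and behavioral scores tied to DMN
coupling — so the entire pipeline is testable end to end without any
restricted data.

## Worked example

Simulate a small two-site cohort, extract features, harmonize, and
test for group differences:

```r
library(scfc)

cfg <- pipeline_config(out_dir = "scfc_demo", seed = 7,
                       cohort = cohort_config(
                         n_per_group = c("TDC" = 20, "ADHD-I" = 20,
                                         "ADHD-C" = 20),
                         seed = 7))
res <- run_all(cfg)

subset(res$group_report, subnetwork == "DMN",
       select = c(feature, mean_TDC, `mean_ADHD-I`, `mean_ADHD-C`, F, p))
```

```
      feature mean_TDC mean_ADHD-I mean_ADHD-C      F         p
 Eglob_SC.DMN   0.5983    0.566796     0.52179  2.437 9.677e-02
 Eglob_FC.DMN   0.0063    0.003456     0.05994 30.218 1.398e-09
 coupling.DMN   0.1940    0.245043     0.42949  4.935 1.069e-02
```

Structural efficiency drops from TDC to ADHD-C (the generator's
densities are 0.32/0.28/0.26) and mean DMN coupling is highest in
ADHD-C (generator `alpha` 0.55 vs 0.40/0.36, flagged here at
p ≈ 0.01); at 20 subjects per group the structural-efficiency ANCOVA
only trends (p ≈ 0.097) — the shipped default design (56/75/70) is
what the power analyses in the test suite use. The worked behavioral
contrast:

```r
independent_corr_diff_test(0.25, 75, 0.62, 70)
```

```
Fisher r-to-z test: r1 = 0.250 (n = 75) vs r2 = 0.620 (n = 70), z = -2.766, p = 0.005668
```

i.e. an inattention-hyperactivity correlation of 0.62 in one group of
70 differs from 0.25 in an independent group of 75 at p ≈ 0.0057.

`run_all()` writes every artifact under `out_dir`: raw / observed /
harmonized feature CSVs, a harmonization report (per-site
location/scale estimates), a table-style group report, one edgewise
contrast CSV per group pair and modality, behavior-correlation CSVs,
and a run log. A thin CLI wraps the same functions:

```sh
Rscript inst/cli/scfc simulate --seed 7 --out scfc_demo
Rscript inst/cli/scfc validate --out scfc_demo
Rscript inst/cli/scfc run-all  --seed 7 --out scfc_demo
```

(After installation the script is at
`system.file("cli", "scfc", package = "scfc")`.)

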