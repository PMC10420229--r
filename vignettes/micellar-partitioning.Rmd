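---
title: "Micellar partition coefficients: models, calibration, and the descriptor workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micellar partition coefficients: models, calibration, and the descriptor workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micellogp)
```

## The problem

How strongly a neutral solute partitions from water into a surfactant
micelle — its micelle–water partition coefficient, reported as
$\log P$ — governs solubilization, drug-carrier loading, and the
environmental fate of organic compounds. Micellar electrokinetic
chromatography (MEKC) measures this equilibrium: a capillary filled with a
micellar buffer separates analytes by how much time they spend inside the
migrating micellar pseudo-phase versus the aqueous phase. `micellogp`
implements the chain of models that turns MEKC migration times into
micellar $\log P$ values, relates those values to cheaply computable bulk
solvent–water partition coefficients, and explores the compound set in
molecular-descriptor space.

The package ships an experimental table of $\log P$ values for 63 neutral
compounds — benzene derivatives, phenols, anilines, phenylurea and
triazine pesticides, and steroid hormones — in three chemically distinct
micelles: the bile-salt sodium cholate (SC), the cationic
hexadecyltrimethylammonium bromide (HTAB), and the fluorinated anionic
lithium perfluorooctanesulfonate (LPFOS).

## The MEKC retention model

Two marker compounds bracket every separation: an unretained tracer
(methanol) migrating at the electro-osmotic time $t_0$, and a fully
micelle-bound tracer (phenyl-undecyl ketone) at the micellar time $t_m$.
An analyte migrating at $t_R$ has retention factor

$$k \;=\; \frac{t_R - t_0}{t_0\,(1 - t_R/t_m)},$$

the ratio of its residence in the two phases. `retention_factor()`
implements this map and `retention_time_from_factor()` its exact inverse.
$k$ relates to the partition coefficient $P$ through the phase ratio
$\phi = \upsilon\,(C_T - \mathrm{CMC})$, the volume fraction of micellar
pseudo-phase formed by the surfactant above its critical micellar
concentration:

$$k \;=\; P\,\frac{\phi}{1-\phi},
\qquad
\log P \;=\; \log_{10} k + \log_{10}\frac{1-\phi}{\phi}.$$

The registry constants (per litre of buffer) are:

```{r registry}
for (sys in micelle_registry()) print(sys)
```

All three phase ratios are small (0.6–2 % volume fraction), so the
second term is a large, system-specific additive offset: for a common
retention factor, $\log P$ differs between systems by the log-ratio of
their phase-ratio odds — a closed-form identity the test suite checks.

Numerical behaviour at the domain boundaries is explicit: $t_R = t_0$
means $k = 0$ (no finite $\log P$; batch conversion flags the cell missing
with a warning rather than failing), while $t_R \ge t_m$ is a domain error
("analyte co-elutes with or after the micellar marker"). Replicate
injections — the bundled measurements were run in triplicate — are
averaged on the $\log P$ scale by `convert_retention_table()`, which also
reports the replicate standard deviation, since $\log P$ is the quantity
of scientific interest.

## From solvation free energies to solvent/water logP

A micelle is not a bulk solvent, but a bulk solvent can behave like one.
Continuum-solvation calculations give standard solvation free energies
$\Delta G^\circ_{solv}$ of a solute in many solvents; the transfer free
energy from water into a solvent,
$\Delta\Delta G^\circ = \Delta G^\circ_{solv} - \Delta G^\circ_{wat}$,
converts to a partition coefficient by

$$\log P \;=\; -\frac{\Delta\Delta G^\circ}{RT\,\ln 10},$$

with $RT \ln 10 = 1.36425$ kcal/mol at $T = 298.15$ K
(`logp_from_transfer()`). The default temperature is 298.15 K
(config-overridable); energies are kcal/mol natively with a kJ/mol input
flag, converting by 4.184, to avoid silent unit mixups. The
quantum-chemistry computation itself is out of scope: `micellogp`
consumes energy tables (`read_solvation_table()`) from any upstream code
and builds the solvent/water $\log P$ matrix with `logp_matrix()`.

## Surrogate solvents, the N set, and calibration

`correlation_matrix()` computes the pairwise Pearson matrix of the
experimental micellar columns and all computed solvent/water columns on
pairwise-complete observations (the experimental table has missing cells;
pairwise completion keeps the matrix maximally populated, while
calibration fits below use listwise deletion per pair — both choices are
recorded in the outputs). `rank_surrogates()` orders solvents by their
correlation with a chosen micelle, ties broken alphabetically.

A structural caveat drives the filter stage: compounds carrying a
nitrogen inside an aromatic ring (diazines, azoles, quinolines, triazine
herbicides, xanthines) or a urea group (the phenylurea herbicides)
partition anomalously in the cationic HTAB micelle. `nset_filter()`
excludes exactly these compounds using two SMARTS patterns:

* `[n]` — aromatic-ring-member nitrogen under OpenBabel aromaticity
  perception;
* `[NX3][CX3](=O)[NX3]` — the urea (carbamide) substructure, requiring a
  nitrogen on *both* sides of the carbonyl so that plain amides
  (benzamide, acetanilide) and anilines are retained.

On the bundled 63 compounds the rule excludes 14 (six aromatic-N
compounds and eight phenylurea herbicides). The exact membership of the
excluded class is defined by the SMARTS rule; the filter is idempotent
and partitions its input, and both properties are tested.

`fit_calibration()` performs the ordinary least-squares fit
$y_{micelle} = a\,x_{solvent} + b$ on complete pairs, reporting slope,
intercept, $R^2$ (squared Pearson $r$, the standard identity for simple
regression with intercept), MAE/MSE/RMSE of the residuals, and a 95 %
$t$-based confidence interval for the slope. The bundled
`reference_calibrations()` table records the published coefficients
relating computed alcohol/water $\log P$ (propan-1-ol, propan-2-ol,
methanol) to each micelle, including the HTAB refits after N-set
exclusion; these are shipped as reference data because the underlying
quantum-chemistry energies are not redistributable, and recomputing them
is declared out of scope. `predict_micellar_logp()` and
`best_micelle_system()` turn any calibration into the practical question:
*which micelle will carry this compound best?*

```{r predict}
sc <- reference_calibration_model("SC", "propan-1-ol")
predict_micellar_logp(sc, 3.0)
```

## The descriptor-space workflow

The ML stage operates on any compounds-by-descriptors matrix.
`compute_descriptors()` provides an open panel built with
ChemmineR/OpenBabel — molecular weight, Crippen-type logP, molar
refractivity, TPSA, H-bond donors/acceptors, element/ring/functional-group
counts (about 27 columns) — as a stand-in for commercial descriptor sets,
whose values cannot be redistributed; an external descriptor CSV is
accepted equally. Consequences: the workflow (standardize, cluster,
decompose, regress) is the preserved contribution, while cluster
memberships and SVM metrics obtained on the open panel are not expected
to match numbers derived from any proprietary panel.

The steps, each with its own function and contract:

* **`standardize_descriptors()`** — column z-transform with sample
  ($n-1$) standard deviation, consistent with correlation-matrix PCA;
  constant columns are dropped with a warning (they carry no information
  on a standardized scale).
* **`kmeans_cluster()`** — k-means minimizing total within-cluster squared
  Euclidean distance, best of 25 seeded random restarts
  (Hartigan–Wong, via `stats::kmeans`). A seeded-restart strategy was
  chosen over deterministic seeding heuristics: it is the standard R
  idiom, and determinism is guaranteed by the explicit seed contract —
  identical `(data, k, seed)` give identical labels. With `k = n` each
  point is its own centroid and the within-SS is exactly zero.
* **`pca_descriptors()`** — eigen-decomposition of the correlation matrix
  (covariance PCA of the standardized data); explained-variance ratios
  over all components sum to one, loadings are orthonormal.
* **`cluster_profile()`** — per-cluster descriptor means in standardized
  units, with the cluster attaining each descriptor's maximum and minimum;
  the size-weighted average of the profile rows reconstructs the zero
  grand mean.
* **`svm_regress()`** — radial-basis support-vector regression
  (`e1071`/libsvm). The data are split 85/15 by a seeded shuffle
  (unstratified; the protocol does not call for stratification),
  hyperparameters are chosen by 10-fold cross-validated RMSE *on the
  training part only*, and the winner is refit and evaluated once on the
  held-out part. The default grid is $C \in \{0.1, 1, 10, 100\}$,
  $\varepsilon \in \{0.01, 0.1, 0.5\}$, and
  $\gamma = \gamma_0 \times \{0.1, 1, 10\}$ with
  $\gamma_0 = 1/(p \cdot \overline{\mathrm{Var}})$ on the standardized
  training descriptors — standard QSPR practice, fully
  config-overridable via `svm_grid()`. Test-set $R^2$ uses the
  coefficient-of-determination convention ($1 - SS_{res}/SS_{tot}$,
  negative when worse than the mean predictor), so a no-signal fit is
  visibly penalized. Fold assignment and fitting are canonicalized by
  compound name, making all metrics invariant to input row order for a
  fixed split membership.

## What the synthetic generators emulate

Every stage is testable without external data because the generators
plant known truth with the statistical structure the analysis assumes:

* **`simulate_partition_truth()`** draws true micellar $\log P$ uniformly
  over $[0.19, 3.71]$ — the observed span of the bundled experimental
  table.
* **`simulate_retention()`** pushes truth through the *inverse* retention
  model and adds Gaussian noise on the time axis (default sd 0.05 min,
  triplicates, markers at $t_0 = 2$ and $t_m = 10$ min, typical MEKC
  marker times chosen here because the original migration times are not
  part of the bundled data). Noise enters in the measurement domain
  deliberately: it exercises the nonlinearity of the retention relations.
  Times falling outside $(t_0, t_m)$ are clipped just inside with a
  warning — an $O(n)$, deterministic choice over rejection sampling.
* **`simulate_solvation()`** inverts planted linear calibrations
  ($x = (y - b)/a$ + noise) and converts to an energy panel through
  $-x \cdot RT\ln 10$ around a random water column, so the full
  energy-to-calibration chain closes exactly at zero noise.
* **`simulate_descriptors()`** draws isotropic Gaussian blobs around
  centers at a stated pairwise separation (in within-blob sd units) along
  random orthogonal directions; the default sizes $(45, 13, 5)$ mirror
  the three-group structure — a dominant mixed group, a pesticide-like
  group, a small hormone-like outlying group — seen in the bundled
  63-compound set.

All generators are pure functions of their seed (bit-identical on
repeated calls, global RNG state untouched).

Two honest limitations of the synthetic conditions. First, near the EOF
marker ($k \to 0$, hydrophilic compounds) time noise of 0.05 min is
comparable to $t_R - t_0$ itself, so the log-scale recovery error is
heavy-tailed and the low end of the $\log P$ range is intrinsically
ill-measured — the tests therefore assert unbiasedness on the informative
range ($\log P \ge 1$) and only monotone error reduction with replicate
count globally. This mirrors the real dynamic-range limit of MEKC, not a
defect of the estimator. Second, uniform truth, isotropic blobs, and
Gaussian residuals are idealizations: passing tests demonstrate that the
chain of estimators is correct and well-calibrated under its assumed
model, not that real micellar data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Round-trip identities (time ↔ factor ↔ $\log P$; energy ↔ $\log P$) hold
  to $10^{-10}$ over $\log P \in [-1, 5]$ for all three registry systems.
* Correlations require `min_pairs` (default 3) complete pairs; cells
  below the threshold and zero-variance columns are reported missing with
  a warning, never silently zero.
* Calibration demands at least 3 complete pairs and nonzero predictor
  variance; a constant response gives slope 0 and $R^2 = 0$ by
  convention.
* Missing table cells are explicit (`NA`, written as `"-"`), never
  imputed; the five unmeasured HTAB entries of the bundled table stay
  missing through every stage.
* Partition CSVs round-trip bit-exactly (shortest round-trip double
  representation on write).
* Grid-search ties resolve to the earliest grid row; k-means ties are
  resolved by the best-of-restarts rule under the declared seed.

## The pipeline

`run_full_analysis()` chains everything — experimental table, computed
(or, absent an energy table, simulated-around-reference-calibrations)
solvent matrix, correlation heatmaps with and without the N-set filter,
all calibrations, and the descriptor workflow — writing CSV outputs plus
a JSON manifest that echoes the full configuration and seeds. A rerun
with the same configuration reproduces every output byte-identically; the
problem sizes used throughout (63 compounds, 500 calibration replicates,
100 SVM null replicates) keep a complete run in the order of a minute on
one CPU.

```{r pipeline, eval = FALSE}
res <- run_full_analysis(pipeline_config(seed = 1), outdir = "reports")
res$clusters
res$svm$SC
```

## Known limitations

* Only neutral analytes at the buffered pH are modeled; charged-analyte
  electrophoretic mobility is out of scope.
* The conversion consumes already-picked migration times; there is no
  electropherogram peak processing.
* Conformational averaging of solvation energies is not performed —
  energies are taken as given, one conformer per compound.
* The open descriptor panel is small (~27 descriptors) compared to
  commercial panels (85+); descriptor-dependent results are
  panel-specific by construction.
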