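---
title: "Interregional metabolic connectivity: model, test, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interregional metabolic connectivity: model, test, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabconn)
```

## The model

Regional FDG uptake is a per-subject scalar per volume of interest (VOI):
subject *s* contributes one value \(u_{sv}\) for each of *p* regions.
Metabolic connectivity is defined at the *group* level: for a group of
*n* subjects, the connectivity of regions *i* and *j* is the Pearson
correlation of \((\mathrm{SUVR}_{si}, \mathrm{SUVR}_{sj})\) across the
group's subjects. Each group therefore yields one \(p \times p\)
correlation matrix; no within-subject time series is involved, and with
small cohorts every correlation rests on only *n* paired points — the
reason all inference here is permutation-based rather than parametric.

### SUVR normalization

Raw uptake carries global per-subject scale (injected dose, body weight,
scanner sensitivity). Dividing each subject's row by that subject's
reference value,

\[ \mathrm{SUVR}_{sv} = u_{sv} \big/ \tfrac{1}{|R|}\textstyle\sum_{r \in R} u_{sr}, \]

with \(R\) the reference pool, removes it exactly: scaling a subject's
row by any \(c > 0\) leaves their SUVR row unchanged, and the pooled
reference SUVR mean is exactly 1 per subject.

The default pool is every atlas region flagged `is_reference` — in the
shipped 53-region atlas, the *bilateral* medulla. Pooling both medullae
instead of using a single medulla mask is a deliberate convention: a sole
reference region has SUVR identically 1, zero variance, and an undefined
correlation with every other node, which would silently knock it out of
the network. With a two-region pool each side keeps hemispheric variance
and remains a node — at the price that the two reference SUVRs satisfy
\(\mathrm{SUVR}_L + \mathrm{SUVR}_R = 2\) exactly and are perfectly
anti-correlated; their mutual edge is real but uninformative. Whether the
original acquisition convention was a single mask or a bilateral pool is
not documented for this kind of study; `reference_definition()` records
what was used. There is no volume weighting (region volumes are not
published); the pool is an unweighted mean.

### Fisher transform and clamping

Each correlation is mapped to \(z = \operatorname{atanh}(r)\), the
variance-stabilizing transform, before groups are compared. With \(n = 7\)
subjects, sample correlations of exactly \(\pm 1\) occur (and the
reference pair attains \(-1\) by construction), where \(z\) diverges.
Correlations are therefore clamped to \(\pm(1 - \varepsilon)\) with
\(\varepsilon = 10^{-6}\) (so \(|z| \le 7.254\)) before transforming —
every edge stays testable, the clamp is recorded in the run metadata, and
the same clamp is applied to observed and permuted networks alike.
Diagonal self-edges are set to \(z = 0\) and never tested.

### The permutation edge test

The per-edge statistic is \(\Delta z = z_A - z_B\), with group A the
mutant by convention, so `increased` means stronger coupling in the
mutant. The null distribution is built by permuting the group labels over
the pooled subjects, preserving group sizes (default 5000 iterations),
recomputing both correlation matrices and their transforms each time.
The two-sided p-value uses add-one smoothing,

\[ p_e = \frac{1 + \#\{k : |\Delta z^{(k)}_e| \ge |\Delta z^{\mathrm{obs}}_e|\}}{N + 1}, \]

which can never reach zero, counts ties against significance
(conservative, guaranteeing validity), and is negligible at
\(N = 5000\). Significant edges get the smallest threshold their p-value
passes strictly — the default tiers are \(p < 0.05\), \(p < 0.01\),
\(p < 0.005\) — and a direction from the sign of \(\Delta z\).

Several aspects of this procedure are genuinely open in the source
methodology and were fixed here as package design choices:

* **Statistic form and sidedness.** A plain \(\Delta z\), two-sided, with
  direction recovered from the sign — one procedure reports both
  increased and decreased edges. No studentization is applied.
* **One shared permutation stream.** All 1378 edges are evaluated against
  the same label reassignments rather than per-edge streams; this is
  cheaper, deterministic under one seed, and preserves the joint
  structure across edges.
* **Implementation of the reassignment.** Each iteration permutes the
  observed label vector over the pooled subjects in table row order.
  Because subset indices are recovered in sorted order, an iteration that
  reproduces the observed partition recomputes bit-identical correlations,
  so tie counting is exact; it also makes the test exactly antisymmetric
  in the group pair — swapping the groups negates every \(\Delta z\),
  swaps the direction labels, and leaves every p-value identical.
* **The identity assignment is not excluded** and draws are with
  replacement across iterations: with \(\binom{14}{7} = 3432\) distinct
  splits and 5000 draws, duplicates are expected and harmless.
* **No multiplicity correction by default.** The tiered per-edge
  thresholds match how such edge tables are conventionally reported; over
  1378 edges an uncorrected \(p < 0.05\) admits roughly 69 false
  positives under the null, which the type-I calibration below makes
  explicit. `bh_annotate = TRUE` adds a Benjamini–Hochberg column that
  annotates and never filters.

## The synthetic cohort generator

No uptake data are published for the motivating study design, so the
package ships a generator whose defaults emulate its stated conditions:
two groups of \(n = 7\) over 53 VOIs, strictly positive uptake, a
designated medulla reference pool, and group-specific interregional
correlation structure with injectable single-edge differences.

Subjects are drawn from a multivariate Gaussian per group: means default
to 1.0 (1.2 for reference regions, an SUVR-like scale with a slightly
hotter reference pool), per-region SD is `cv * mean` with `cv = 0.1`, and
the correlation matrix is the base structure with that group's edge
effects written in, projected to the nearest valid correlation matrix.
Draws containing a non-positive value are rejected and redrawn; at
`cv = 0.1` the acceptance rate is essentially 1 and the truncation
perturbs target correlations by far less than Monte-Carlo error (checked
empirically at n = 2000 in the test suite). A configuration whose
rejection rate exceeds 50% over 1000 attempts is refused as an error
rather than silently producing a strongly truncated — hence
mis-correlated — cohort. Gaussian-with-rejection marginals were chosen
over lognormal ones because Pearson correlation targets are exact under
the Gaussian latent model and the truncation is negligible at realistic
coefficients of variation; real PET uptake marginals are not documented,
so all marginal choices are stand-ins.

Two reproducibility contracts matter downstream. First, identical spec
and seed give bit-identical cohorts. Second, each group's stream is
derived from the root seed and a hash of the group label, so adding a
group to a spec never perturbs another group's draws.

**Projection.** Injecting, say, \(r_{ij} = -0.85\) into an exchangeable
\(\rho = 0.3\) base can leave the indefinite cone;
`nearest_correlation()` restores feasibility by iterated eigenvalue
clipping at zero followed by diagonal renormalization (convergence
tolerance \(10^{-10}\), at most 100 iterations; already-feasible input is
returned unchanged). Only the post-conditions — symmetry, unit diagonal,
eigenvalues \(\ge -10^{-10}\) — are contractual. The projection can move
an aggressive injected target substantially (the \(-0.85\) example above
lands near \(-0.54\)); the *post-projection* matrix is the ground truth,
and `cohort_ground_truth()` returns exactly it. Injections on an identity
base are feasible for any \(|r| < 1\) and survive unchanged.

**What the generator does not emulate.** Image-space effects (scanner
resolution, smoothing, partial-volume spill-over between neighboring
VOIs), kinetic or dose-dependent uptake behavior, heavy-tailed or skewed
uptake marginals, and anatomically structured covariance. Tests passing
on these cohorts certify the statistical machinery — calibration, power
ordering, determinism, invariances — not the biology of any real cohort.

## What the test suite establishes

* **Exactness at small n.** On a 6-region, 4 + 4 cohort the Monte-Carlo
  p-values (20 000 permutations) agree with the exact p-values from
  enumerating all \(\binom{8}{4} = 70\) label assignments, edge by edge,
  within the binomial 99% confidence band — the Monte-Carlo test
  converges to the exact permutation test it approximates.
* **Type-I calibration.** Over 200 null cohorts (20 regions,
  exchangeable \(\rho = 0.3\), 7 + 7, 500 permutations) the mean fraction
  of edges with \(p < 0.05\) lies in \([0.035, 0.065]\), and the pooled
  p-value distribution is not stochastically smaller than uniform
  (one-sided Kolmogorov–Smirnov at the 1% level).
* **Power ordering.** With a single injected edge (WT \(r = 0\), KO
  target \(r \in \{0, 0.3, 0.6, 0.9\}\), 7 + 7, 200 replicates per
  level, common random numbers across levels), the detection rate at
  \(p < 0.05\) is non-decreasing in the target and clearly exceeds the
  null rate at \(r = 0.9\) (about 0.56 versus 0.05 in the acceptance
  run). The flip side is worth stating plainly: at \(n = 7\) per group
  the per-edge power for even large effects is modest, and single-edge
  findings at this scale should be read accordingly.
* **Full-scale structure.** An end-to-end run at 53 regions, 7 + 7,
  5000 permutations emits exactly \(\binom{53}{2} = 1378\) edge tests,
  symmetric unit-diagonal correlation matrices, per-subject reference
  SUVR means of exactly 1, and byte-identical artifacts on rerun with the
  same seed (a few seconds of compute; the problem sizes above — 200
  replicates at 500 permutations for calibration and power — keep the
  whole suite in the low minutes).

## Numerical conventions and degenerate inputs

* Region/column matching is exact and case-sensitive; published VOI name
  lists contain near-duplicate spellings, and fuzzy matching would hide
  real mismatches. Atlas order, not file column order, fixes all matrix
  layouts.
* Uptake must be strictly positive and finite; violations are reported
  with subject and region names. Groups need at least 3 subjects for a
  correlation; a zero-variance region (the signature of a mis-specified
  sole reference) is a named error, in the observed groups and in any
  permuted pseudo-group.
* CSV output is written at 17 significant digits, so write–read round
  trips are bit-exact and reruns are byte-identical.
* Edge ordering is row-major over the upper triangle of the atlas-ordered
  matrix; ties in the significant-edge table break lexicographically by
  tier, then region pair.

## Known limitations

The atlas shipped as `default_atlas()` is an illustrative reconstruction
of a 53-VOI mouse node set, not an authoritative segmentation; analyses
of real data should supply their own atlas JSON. The pipeline begins at
the regional uptake table — image registration, smoothing, and VOI
extraction are upstream and out of scope. The uncorrected tiered
thresholds reproduce the field's reporting convention, not a
family-wise-error guarantee.
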