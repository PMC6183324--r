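---
title: "Methodology: ANP prioritization of shift-work disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methodology: ANP prioritization of shift-work disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftanp)
```

## The decision problem and the model

Shift work disrupts sleep, digestion, mental health, cardiovascular
function, the musculoskeletal system, and personal and family life.
The package weighs these disorders against each other — and ranks the
morning, evening, and night shifts by how strongly they drive them —
for three hospital worker groups with different rotation patterns
(8-hour rotating nurses, 12/24 support staff, 24/48 security staff).

The Analytic Network Process generalizes the Analytic Hierarchy
Process: decision elements are grouped into clusters (criteria,
sub-criteria, alternatives) and connected by directed dependency
edges, which may include feedback. Every set of elements sharing a
cluster and a common edge target forms a *comparison context*: the
elements are compared pairwise "with respect to" that target. A
context with judgments $a_{ij}$ on the Saaty scale yields a positive
reciprocal matrix ($a_{ii}=1$, $a_{ji}=1/a_{ij}$, entries in
$[1/9, 9]$); its normalized principal right eigenvector $w$
($Aw=\lambda_{\max}w$) is the local priority vector.

Judgment consistency is screened with
$CI = (\lambda_{\max}-n)/(n-1)$ and $CR = CI/RCI(n)$, accepting a
matrix when $CR < 0.1$ (strictly: a matrix sitting exactly at 0.1 is
rejected). $RCI(n)$ is the expected $CI$ of random reciprocal matrices
of order $n$. The package ships the reference row
(0, 0, .52, .89, 1.11, 1.25, 1.35, 1.40, 1.45, 1.49 for
$n = 1,\dots,10$) and reproduces it by simulation: upper-triangle
entries drawn i.i.d. uniformly from the 17 admissible values,
reciprocal fill, $CI$ by the eigenvector method, averaged over the
sample. This generation scheme is a documented dialect choice — it
matches the tabulated row (e.g. 0.52 at $n=3$), whereas some classical
tables print slightly different values (0.58 at $n=3$) obtained from
other sampling conventions. Orders above 10 require an explicitly
supplied or simulated index (`estimate_rci()`).

Local priorities are assembled into the supermatrix $W$: entry
(source, target) holds the source's local weight in the context
targeting that node. Cluster weights turn each nonzero column into a
convex combination of its per-cluster priority vectors, making $W$
column-stochastic; the matrix-power limit of $W$ then distributes
influence through the network. Alternative weights are read from the
limit; the desirability index

$$D_i = \sum_j \sum_k P_j \, A^D_{kj} \, A^1_{kj} \, S_{ikj}$$

(criterion importance $P_j$, sub-criterion dependency weight
$A^D_{kj}$, stabilized independent weight $A^1_{kj}$, alternative
impact $S_{ikj}$) is computed alongside as the composite-score route.
The index is agnostic about the number of alternatives: the impact
table drives the summation, and the three-shift design simply supplies
three impact rows per sub-criterion.

## Where the goal lives, and how weights are extracted

The goal is treated as a virtual comparison target, not a supermatrix
node, so the bundled network yields a supermatrix of order 30
(7 criteria + 20 sub-criteria + 3 alternatives). This has a structural
consequence: in a hierarchy the alternatives absorb all limit mass, so
the limit column carries no criterion or sub-criterion information.
The pipeline therefore reports:

* **criterion weights** — the goal-context eigenvector; when the
  network has criterion inner dependence, adjusted by one application
  of the dependency matrix (columns = the inner-dependence priority
  vectors) and renormalized;
* **sub-criterion weights** — local context priorities, reported
  within their parent criterion (each parent's block summing to 1,
  the layout of the published tables), with global weights
  (criterion × local) available via
  `extract_priorities(..., subcriteria = "global")`;
* **alternative weights** — the limit-matrix mass reaching the
  alternatives when the process is seeded at the criteria with the
  criterion weights. On a feedback-free network this reduces exactly
  to the closed-form hierarchical composition (a property the test
  suite checks to 1e-8).

`extract_priorities()` itself is agnostic about where its mass vector
comes from: a converged limit matrix, a seeded propagation, or a
published global profile used as a pseudo-limit all renormalize the
same way (per cluster, and per parent for sub-criteria). A cluster
with zero mass is an error rather than a silent empty block.

Whether the published group tables were produced by the limit route or
the desirability route is not stated in the source study, so the
pipeline computes both and reports them side by side. With a single
elicited judgment set per sub-criterion context the dependency weight
$A^D$ is trivial (1) and $A^1$ is the local priority; under that
convention the two routes coincide exactly on feedback-free networks,
which the suite also verifies. Distinct $A^D$/$A^1$ sets can be passed
to `desirability_index()` directly.

## The bundled network and its assumptions

The source study enumerates the clusters (7 criteria, 20 sub-criteria,
3 shift alternatives) but not the exact expert-elicited edge set of
its network figure. The bundled config encodes a documented,
overridable default: the goal → criteria → sub-criteria → alternatives
hierarchy plus inner dependence among the criteria (each criterion
judged with respect to every other). `shift_work_network(criteria_feedback
= FALSE)` gives the pure hierarchy; any other structure can be supplied
as YAML/JSON (`load_network()`), with cluster-level shorthand for edge
groups. Node ids are ASCII slugs; printed names live in labels.

The published weight tables are transcribed verbatim into
`inst/extdata/published_weights.csv` at their printed 3-decimal
precision. Validation warns — never fails — when a printed block does
not sum to 1 beyond rounding slack (the security group's alternative
weights sum to 1.26 as printed; the support group's evening-shift
weight was not printed at all). One printed table header repeats the
previous group's caption; fixtures are keyed by shift pattern, not by
the printed header.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `cr_threshold` | 0.1 | conventional acceptability bound; strict `<` |
| `sigma` (judgment noise, log scale) | 0.15 | keeps most perturbed judgments within one grid step of the truth, producing realistic CR distributions in which most — not all — respondents pass screening |
| cohort sizes | 3 × 100 | the emulated study design |
| `aggregation` | `"judgments"` | geometric-mean pooling of matrices (AIJ) is standard for homogeneous groups and preserves reciprocity exactly; `"priorities"` (AIP, mean of eigenvectors) is available |
| exclusion policy | whole respondent | conservative: one failing matrix drops the respondent; `per_matrix = TRUE` drops only the matrix |
| cluster weights | equal over incoming clusters | the study prints none; equal weights keep runs reproducible, and a cluster-comparison table can be supplied |
| sink policy | self-loop | guarantees column-stochasticity before limiting; `"zero"` leaves sink columns untouched |

## Numerical choices

* **Eigenvector**: power iteration with per-step normalization,
  tolerance 1e-12 on the successive-iterate max difference, cap
  10,000 iterations; $\lambda_{\max}$ from the Rayleigh-style ratio
  $\mathrm{mean}((Aw)_i/w_i)$. Verified against dense
  eigen-decomposition to 1e-8 on hundreds of random matrices.
* **Consistency edge cases**: $CI \equiv 0$ for $n \le 2$ (all 1×1 and
  2×2 reciprocal matrices are consistent); tiny negative $CI$ from
  round-off clamps to 0; the acceptability comparison guards the
  $CR = 0.1$ boundary against floating-point noise.
* **Limit matrix**: repeated squaring to entrywise tolerance 1e-10
  (cap 60 squarings ≈ powers of $2^{60}$); the classical odd-power
  prescription converges to the same limit for primitive matrices. A
  fixed point that is not invariant under one more multiplication
  signals a cyclic chain; the Cesàro average over the detected period
  is returned (a 2-cycle yields the uniform ½–½ limit). Convergence
  metadata (squarings, period, column equality) is attached.
* **Snapping**: a perturbed ratio is snapped on its ≥ 1 side (values
  below 1 are inverted, snapped, re-inverted), which keeps
  `snap(1/x) = 1/snap(x)` exact and bounds the judgment-side error by
  half the unit grid gap. Plain nearest-value snapping on the raw
  scale would treat a judgment and its reciprocal asymmetrically.
* **Ties**: alternative rankings break exact ties lexicographically by
  node id and flag them.
* **Degenerate inputs**: single-member contexts carry a forced
  priority of 1 and no matrix; ratio targets steeper than 9:1 clip at
  the scale bounds (counted, and warned about when a whole context
  clips); columns with no incoming dependency are flagged and handled
  by the sink policy.
* **Rounding for reports**: 3 decimals (round-half-even) in the
  human-readable tables; full precision in JSON.

## What the synthetic generator emulates — and what it does not

Each synthetic respondent's judgment matrix is the perfectly
consistent ratio matrix of the group's ground-truth priorities,
perturbed entrywise by $e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma^2)$ i.i.d. on the upper triangle, then
snapped to the grid. Ground truths default to the published group
profiles, so cohorts center on the reported weights; the support
group's unprinted evening-shift weight is filled with one ninth of the
block's largest weight (the smallest representable ratio) before
renormalization. For the inner-dependence contexts, which have no
published counterpart, the criterion profile restricted to the
compared criteria is used. Demographics are drawn from the study's
reported margins (all male; 72% married; 82% obligatory shift
selection; 62% satisfied; the published age and experience bands) as
independent draws — metadata only.

Limits of the emulation, and hence of what passing tests show about
real data: respondents are i.i.d. around a single group truth (no
heterogeneity, no correlated biases across contexts, no systematic
verbal-anchor preferences); noise is symmetric on the log scale;
missingness does not occur unless constructed; and the published
profiles are treated as exact truths although they are themselves
3-decimal estimates. Synthetic recovery therefore validates the
machinery, not the study's field conclusions.

Grid snapping also imposes an estimator floor: at fixed noise the
aggregated estimate converges not to the truth but to the snapped
truth, so for ground truths with off-grid ratios the error plateaus at
the snap bias once cohorts reach a few dozen respondents. The
convergence property in the acceptance suite therefore uses a
grid-representable truth (all pairwise ratios admissible), where the
floor is zero and the median error falls monotonically across cohort
sizes 5, 25, 100; the snap floor itself is covered by a separate
bounded-bias test. Exact rank-order recovery at zero noise is likewise
asserted on grid-representable truths: profiles with near-tied weights
(several published blocks sit within half a grid step) can legitimately
snap to ties.

## Problem sizes in the test suite

The suite runs entirely on synthetic data built at test time: random
reciprocal matrices up to order 7 (200 for the eigensolver
cross-check), Monte Carlo RCI at 500 samples per tabulated order (the
reference sample size) and 20,000 samples for the tighter large-sample
check, cohorts of up to 100 respondents for the recovery properties,
and pipeline runs with 3–25 respondents per group. These sizes were
chosen so each property's Monte Carlo error is small against its
assertion band while the full suite stays comfortably interactive.

## Known limitations

* The dependency adjustment for inner-dependent criteria applies the
  dependency matrix once rather than iterating it to its own fixed
  point; with the dependency matrix also embedded in the supermatrix,
  iterating both would double-count feedback.
* No BOCR merging, no fuzzy extensions, no sensitivity analysis, and
  no alternative priority-derivation methods (geometric-mean /
  log-least-squares) — the eigenvector method only.
* Missing judgments are not imputed: a respondent lacking a context is
  simply absent from that context's aggregate.
* With `sinks = "zero"` the limit of a hierarchy loses mass and the
  seeded propagation is the only meaningful readout; the default
  self-loop policy avoids this.
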