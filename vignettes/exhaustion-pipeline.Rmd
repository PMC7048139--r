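---
title: "Screening exhaustion regulators and scoring tumors by T-cell TOX"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening exhaustion regulators and scoring tumors by T-cell TOX}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scExhaust)
```

## The problem

Chronically stimulated CD8+ T cells inside tumors progressively lose
effector function — T cell exhaustion — while upregulating inhibitory
receptors (PDCD1/PD-1, HAVCR2/TIM-3, CTLA4, TIGIT, LAG3). Because PD-1
expression tracks the severity of exhaustion, genes co-expressed with
*PDCD1* across single cells are candidates for driving the exhaustion
program. scExhaust implements this idea as a reusable pipeline:

1. **QC and gating** (`filter_cells_fulllength`, `filter_cells_mad`,
   `gate_t_cells`): cell-quality filters and marker-threshold T-cell gates.
2. **Regulator screen** (`median_split`, `screen_degs`, `intersect_tfs`,
   `cross_dataset_candidates`): split CD8+ T cells at the cohort median of
   *PDCD1*, screen genes differing between the subsets, keep transcription
   factors, and intersect candidates across independent datasets.
3. **Exhaustion dynamics** (`call_state`, `branch_enrichment`,
   `dynamics_test`, `fit_expression_trend`): classify cells into
   effector/exhausted/memory states from CD62L/CD127/PD-1 positivity and
   test expression changes along a supplied trajectory.
4. **Clinical scoring** (`tcell_normalized_score`, `stratify_top_fraction`,
   `logrank_test`, `classify_response`, `response_association`): score bulk
   tumors by TOX expression normalized to T-cell content and relate the
   score to overall survival and anti-PD-1 response.
5. **Synthetic data** (`make_tcell_dataset`, `make_bulk_cohort`): generators
   with planted ground truth, so every stage is testable offline.

Trajectory inference itself (pseudotime, branch assignment) is an input
contract, not a feature: any table of per-cell branch and pseudotime is
accepted, and the synthetic generator supplies one.

## The screen model

Cells are split into *PDCD1*-low (below the median) and *PDCD1*-high
(above the median). For each gene a two-sided Wilcoxon rank-sum test
compares the two subsets; a gene is a DEG when

* raw `P < 0.001` (no multiple-testing correction — a Benjamini–Hochberg
  column is emitted for information only), and
* its mean normalized expression reaches a floor — 1 for
  `log2(TPM/10 + 1)` data, 2 for patient-centered data — in at least one
  subset. The floor removes a gene only when it is dim in *both* subsets.

Candidate regulators are DEGs intersected with a user-supplied TF catalog
(one symbol per line; the catalog is an input, not package data), and the
cross-dataset candidates are the TFs shared by all per-dataset lists,
ordered by their worst P value.

### Median ties

Zero-inflated markers make the median a mass point: with more than half
the cells at zero, every zero cell sits exactly at the median. The
original wording ("below"/"above" median) leaves these cells unassigned.
The default policy assigns at-median cells to the low subset, which keeps
both subsets populated in exactly this zero-inflation regime; a `drop`
policy is available, and a split that empties either subset is refused as
degenerate. The policy in force is recorded on the split object and in the
CLI log.

### The rank-sum test

The rank-sum test is implemented in-package because the screen needs exact
small-sample behavior under ties, which the standard exact algorithms do
not provide. Midranks are used throughout. For pooled sizes up to 12 the
permutation distribution of the rank sum is enumerated exactly by a
subset-sum dynamic program over the doubled midranks; the two-sided P is
the permutation mass at least as far from the null mean as observed.
Beyond 12 a normal approximation with tie-corrected variance and a 0.5
continuity correction is used. The cutoff of 12 keeps enumeration cheap
(at most C(12,6) = 924 subsets) while the approximation is already
accurate there; the tests pin both branches against an independent
`combn` enumeration oracle and against the reference implementation.

## State classification and dynamics

A marker is "positive" when its expression exceeds 0 (any detection on
log-scale data; configurable, and an optional indeterminate band turns
borderline values into no-calls). The rules are: effector = CD62L−,
CD127−, PD-1−; exhausted = PD-1+; memory = CD62L+ or CD127+. Cells
matching two or more rules are `ambiguous`; with the pure three-rule logic
every cell matches at least one rule, so `unknown` only arises through the
indeterminate band.

Branch enrichment uses an exact upper-tail binomial test per
(branch, state): the background proportion is the pooled frequency of the
state among all classified cells (ambiguous/unknown excluded), which is
the natural null when asking whether a branch is enriched relative to the
dataset as a whole. Dynamics tests are one-tailed Mann–Whitney tests of
the target group (exhausted or memory) against effector cells; groups may
be branch labels or per-cell state calls (both are supported; branch
labels are the default in the CLI because branch membership is the
trajectory-level question).

The trend curve is a Nadaraya–Watson kernel mean over pseudotime —
a descriptive smoother, not a branch-dependent regression model.

## QC semantics

All boundary semantics follow strict removal wording: removal conditions
are strict inequalities, so equality retains. A gene is detected when its
value is > 0 (at least one mapped read). The MAD in the
`median − 3 × MAD` rule is unscaled (no 1.4826 consistency factor).
Because re-computing the median/MAD on filtered cells would drift the
cutoff, the applied cutoff is reported and can be frozen for idempotent
re-application. The mitochondrial fraction uses raw counts when supplied
and linearized expression otherwise; the basis used is recorded in the
report.

## Clinical scoring

Bulk TOX expression confounds T-cell abundance with per-T-cell expression.
The score normalizes the target to the geometric mean of CD3D/CD3E/CD3G:

$$\mathrm{score} = \log_2(\mathrm{TOX} + 1) -
  \tfrac{1}{3}\sum_{k} \log_2(\mathrm{CD3}_k + 1)$$

The log-difference form (rather than a linear ratio) was chosen because it
is additive, robust to zeros via the pseudocount (default 1,
configurable), and invariant to per-sample scale factors; a
`linear_ratio` mode reaches the other reading of "normalized using the
geometric mean". Samples with no detectable CD3 are scored but flagged,
and a cohort whose median CD3 geometric mean falls below an advisory
floor (default: the 25th percentile of the pooled abundance) is flagged as
unreliable for this kind of scoring — cohorts poor in infiltrating T cells
carry little per-T-cell signal.

Survival stratification labels the top 30% of scores "high" (ceiling of
the fraction; boundary ties broken by stable input order with a warning)
and compares strata by the standard log-rank test; NSCLC-style cohorts are
pre-filtered to the top 25% tumor mutation burden. Response analysis maps
cohort-specific annotation dialects to responder labels (Hugo: PR/CR vs
PD; Jung: DCB vs NDB; Riaz: as Hugo with SD excluded; internal: PR or
SD > 6 months vs PD or SD ≤ 6 months), tests scores between groups with a
two-tailed Mann–Whitney test, and ranks patients by ascending score for
ROC analysis: AUROC equals the Mann–Whitney U divided by $n_1 n_2$, with
half-credit for ties. Kaplan–Meier curves and the log-rank statistic are
delegated to the `survival` package behind the module interface; the test
suite checks the log-rank output against a hand-computed
observed/expected/variance table.

## What the generator emulates — and what it does not

`make_tcell_dataset` plants a latent exhaustion level $e \in [0,1]$ that
equals pseudotime on the exhausted branch and 0 for memory cells. Gene
means follow $\log_2 \mu = \log_2(\mathrm{baseline}) +
\mathrm{mod}_{\mathrm{state}} + \mathrm{slope}\cdot g(e)$, with late-onset
genes (NR4A1, onset 0.7) rising only past their onset. Counts are negative
binomial (size 2) with logistic mean-dependent dropout, TPM-normalized per
cell, then transformed to the requested flavor. Defaults: 30 anonymous
planted PDCD1-coupled genes at slope 1.2 plus the named checkpoint/TOX
program, 200 null genes, 30 housekeeping genes, 13 mitochondrial tags,
4 patients. Effect sizes are set for comfortable recovery and are
config-exposed; they are not fitted to any real dataset's moments, which
is deliberate — no public effect-size estimates exist for this design.

The "centered" flavor subtracts each patient's grand-mean log offset from
the pooled grand mean. Real patient-centered cohort matrices are produced
by a different (undocumented) pipeline; this choice removes a patient-level
effect while keeping gene means on a scale where the published floor of 2
is meaningful.

The generator does **not** simulate doublets, batch effects, ambient RNA,
patient-specific biology beyond a global offset, or realistic gene-gene
correlation beyond the shared latent $e$. Passing tests therefore
demonstrate that the pipeline's logic and statistics behave as specified
under a faithful null/alternative structure — not that the pipeline would
reproduce any particular published number on real accession data.

`make_bulk_cohort` mixes a Beta-distributed T-cell fraction with a
log-normal within-T-cell TOX level $u$; survival is exponential
proportional hazards with hazard ratio per unit $u$ (default 2.5), and
non-response is Bernoulli with probability $\mathrm{plogis}(b\,u)$, with
$b$ solved by deterministic quadrature so the true responder-retrieval
AUROC is 0.8 by default.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 1000 cells × 2 flavors ×
20 seeds for planted-regulator recovery; 2000 null genes × 600 cells for
calibration; 300 cells per group × 20 seeds for dynamics; 100 cohorts of
300 patients for survival recovery and one cohort of 200 for AUROC
recovery — sizes at which every planted effect is comfortably detectable
while a full run stays in the tens of seconds. P values are clamped to
(0, 1]; a constant pooled sample yields P = 1; degenerate splits,
empty groups, zero-event survival comparisons, and unknown response
annotations are refused loudly rather than guessed.

## Limitations

* Trajectories are consumed, never inferred; conclusions about branch
  structure are only as good as the supplied ordering.
* The screen tests each gene marginally; co-regulated genes are recovered
  individually, and genes not co-expressed with the split marker are
  invisible to the design.
* Survival modeling is two-group log-rank only — no Cox regression or
  covariate adjustment.
* Response dialects are explicit enumerations; new cohorts need a new
  dialect rather than a heuristic string match.
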