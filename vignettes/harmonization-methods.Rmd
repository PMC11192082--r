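---
title: "Methods: harmonizing fibroblast states across single-cell datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonizing fibroblast states across single-cell datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroharmony)
```

This vignette is the package's account of its methods: the models and
procedures, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Setting

Cardiac fibroblasts (CFs) traverse discrete transcriptional states during
cardiac injury and repair: resting Sca1-high/low fibroblasts (F-SH, F-SL),
an activated state (F-Act, *Postn*/*Cilp*/*Meox1*-positive),
injury-response cells (IR), myofibroblasts (MYO, *Acta2*/*Cthrc1*), and
matrifibrocytes (MFC, *Comp*/*Sfrp2*). Comparing these states across
datasets, disease models, and species requires a chain of downstream
computations on top of a batch-corrected embedding. This package
implements that chain; it deliberately does **not** implement the
integration itself (cFIT/Harmony/Seurat/RISC), trajectory inference,
hurdle-model differential expression internals, or doublet detection —
embeddings, labels, and marker tables are its inputs and outputs.

## kNN label refinement

Given an embedding $X \in \mathbb{R}^{n \times d}$ and labels $\ell_i$,
each cell's refined label is the mode of $\{\ell_j : j \in N_k(i)\}$ over
its $k = 25$ nearest neighbors by Euclidean distance. Choices the
underlying procedure leaves open, fixed here and documented:

* **Self-exclusion.** The cell itself never votes. Including it would make
  a $k$-vote effectively $k-1$ votes plus a bias toward the input label.
* **Tie-breaking.** A tied mode resolves to the cell's original label when
  that label is among the tied modes, otherwise to the lexicographically
  smallest tied label. Refinement should be conservative: a tie is not
  evidence for change.
* **Distance ties at rank $k$.** Neighbor order is (distance, cell id),
  and exactly $k$ neighbors are kept, making results deterministic.
* **Search is exact** (full pairwise distances). This is intended for the
  dataset sizes at which these diagnostics are actually run (up to a few
  tens of thousands of cells); no approximate index is used, and all
  tests run exact.

Refinement confidence is the modal vote fraction. Cells with missing
labels are an error unless `allow_missing = TRUE`, in which case they
neither vote nor change.

## Neighbor purity and batch mixing

For label classes $A, B$, the purity matrix entry is

$$P_{AB} = \frac{100}{|A|} \sum_{i \in A} \frac{|\{j \in N_k(i) : \ell_j = B\}|}{k}, \qquad k = 200.$$

Rows sum to 100. Computed with batch labels, a diagonal matrix means the
embedding failed to mix batches; computed with state labels, a diagonal
matrix means biological structure was retained. `batch_mixing_report()`
summarizes both: batch-mixing score = mean off-diagonal batch purity,
state-retention score = mean diagonal state purity.

Under labels carrying no spatial information, each cell's $k$ neighbors
are a draw without replacement from the other $n-1$ cells, so a row
should match the global label proportions to within a few SDs of a single
hypergeometric draw, $\sqrt{p(1-p)/k \cdot (n-1-k)/(n-2)}$. The test
suite checks exactly this calibration. Note that the class-averaged row
concentrates *less* than independence would suggest: with $k = 200$ and
$n = 2000$, neighborhoods overlap heavily and the row-mean variance is
several-fold the naive $1/|A|$ scaling — which is why calibration is
asserted against the per-draw SD, a bound that holds regardless of the
overlap structure.

## State projection and cross-validation

Reference states are projected with a random forest (500 trees, ranger
backend) trained on embedding coordinates; predictions take the
highest-scoring class, ties broken lexicographically and logged, and the
top score is reported as confidence. No probability calibration or score
threshold is applied.

Reliability is assessed by stratified 10-fold cross-validation — folds
are stratified because rare fibroblast states would otherwise vanish from
folds entirely; every class must have at least as many cells as folds.
Out-of-fold predictions are pooled into one confusion matrix, from which
per-class sensitivity, specificity, and balanced accuracy
$(\text{sens} + \text{spec})/2$ are computed, plus their macro average.
The classifier sits behind a score-matrix contract
(`backend` argument), so all metrics and invariants are independent of
the forest implementation; the tests exercise this with a fixed-score
backend.

## Marker detection

`find_markers()` tests a target population against the rest (or a named
reference population) gene by gene on log-normalized expression
(counts-per-10k, `log1p`). The default test is a Wilcoxon rank-sum with
tie-corrected normal approximation and continuity correction, vectorized
over genes and verified against `stats::wilcox.test` in the tests. The
test is pluggable (`test_fun`) so a hurdle-model backend can be swapped
in; the package's contribution is the thresholding and filtering logic,
not the test internals. P-values are Bonferroni-adjusted over all tested
genes, and markers must satisfy the published filter
$p_{\text{adj}} < 10^{-5}$ and $\log_2\text{FC} > 0.5$.

The fold change is defined as
$\log_2\left[(\bar{x}_{\text{in}} + 1)/(\bar{x}_{\text{out}} + 1)\right]$
with means of `expm1`-backtransformed normalized expression and a
pseudocount of 1 on the normalized scale (configurable).

## Cross-dataset matching

Marker sets from two datasets are compared pairwise across populations
with the Jaccard coefficient $|A \cap B| / |A \cup B|$ and a one-sided
Fisher exact (hypergeometric) enrichment p-value
$P(X \ge |A \cap B|)$. Choices:

* **Universe.** The intersection of genes *tested* in both datasets
  (after ortholog mapping). Using all genes would exaggerate enrichment
  for genes that one dataset never measured.
* **Ortholog mapping.** Default is case-normalized symbol matching
  (mouse *Comp* ↔ human *COMP*), with an optional explicit `from`/`to`
  table. Symbol matching is exactly how the cross-species comparisons
  this reproduces were done; a curated ortholog table is strictly better
  when available.
* **Set size.** All markers passing the thresholds are used by default;
  a top-N cap is a caller-side choice (the defining analyses did not
  print one).

## Module scores and regulon activity

A gene set's module score per cell is the mean log-normalized expression
over the set minus the mean over control genes sampled from
average-expression bins matched to the set (24 bins, 100 controls per set
gene, sampled once per run with a seed). Two documented consequences: a
score is relative to the *current pool* — if the whole pool shifts, the
score does not move; and if the set is a large fraction of its bins, the
controls are contaminated by the set itself and the score shrinks toward
zero. Both behaviors are asserted in the tests as documented, not
idealized away.

Regulon activity is the weighted mean construction: raw statistic
$r_{tc} = \sum_g w_{tg} x_{gc}$ over a transcription factor's target
genes, normalized against `times = 100` permutations of the gene labels:
$(r - \mu_{\text{perm}})/\sigma_{\text{perm}}$. Regulons with fewer than
`minsize = 5` targets present are dropped with a warning; a zero
permutation SD yields activity 0 with a warning. Per-population summaries
are mean normalized activity over the population's cells. Two numerical
notes: the permutation null is exactly valid under gene exchangeability,
and each single run's per-regulon mean carries an irreducible estimation
noise floor of SD $\approx 0.05$ at 100 permutations (the permutation
estimate of $\mu$ is shared across cells), so calibration checks average
over a seed panel rather than demanding each run land inside the band.

## Spatial scores

Spot-level state scores are weighted sums
$s_j = \sum_g w_g \, \tilde{x}_{gj}$ of library-size-normalized log
expression. The weight source is the package's documented substitute for
an unprinted choice: the top 50 markers of the reference state ranked by
adjusted p, weighted by their log2 fold change — reproducible and
monotone in marker strength; both the count and the weight column are
configurable. Spots are first restricted to those whose majority cell
type is fibroblast, matching how the spatial maps were drawn. The
bivariate map discretizes two scores into quantile classes (default
3 × 3) — quantile rather than fixed-range classes so the map is robust
to scale differences between signatures. Spot coordinates are abstract
planar x/y; no image registration is attempted.

## Cell/nucleus partitioning

Mixed captures are split by the product of two module scores — all
ribosomal genes and all annotated lncRNAs (both supplied as data, keeping
the operation organism-agnostic) — thresholded at −0.5: product above
−0.5 is called a putative nucleus, below a putative cell, and exactly
−0.5 (a measure-zero event) is assigned nucleus and flagged. Why the
product separates the classes is not obvious from its form, and the
package documents the mechanism empirically on synthetic mixtures rather
than asserting a rationale: whole cells deviate strongly from
expression-matched background on the large ribosomal panel (positive
ribosomal score, moderately negative lncRNA score → strongly negative
product), while in a nucleus-dominant capture the nuclei sit close to the
pooled background on both panels and their product stays near zero. The
separation therefore *depends on mixture imbalance*: in a balanced 50/50
mixture the two scores become nearly antisymmetric between classes and
the product no longer discriminates at a fixed threshold. Downstream
intron-aware requantification of the nuclei is out of scope; the split
itself is the deliverable.

## The synthetic-data generator

`simulate_multibatch_counts()` draws UMI-like counts
$y_{gc} \sim \text{NB}(\mu_{gc}, \theta)$ with

$$\log \mu_{gc} = \beta_g + m_{g,p(c)} \log 2 + (\Lambda \varepsilon_c)_g + b_{g,\text{batch}(c)}$$

— a log-normal gene baseline $\beta_g$, planted marker offsets
$m_{g,p}$ (disjoint marker blocks per population, known log2FC), a
rank-15 factor term, and per-batch multiplicative log-normal gene
scalings $b$ (SD `batch_scale_sd`, the class of distortion
scaling-based integration methods are designed to remove; additive
shifts are deliberately not defaulted on). Design decisions:

* **Negative binomial with a single global dispersion** (default 0.5, 0
  gives Poisson): the field-standard model for UMI counts; the upstream
  generative model this emulates is implicit about its count law, and the
  NB choice is a documented stand-in.
* **The returned embedding is the true factor-score matrix**
  $Z = C_{p(c)} + \varepsilon_c$ (population centroids an orthogonal
  frame at distance `separation`, default 6) — the "ideal integration".
  The factor term in the counts uses only the within-population part
  $\varepsilon_c$, so population structure enters the counts *only*
  through the planted markers and empirical marker fold changes are
  uncontaminated by the factor model. `corrupt_embedding()` adds
  per-batch rotations/translations to produce a "bad integration" for
  exercising the mixing metrics.
* **Rank 15** mirrors the expected biological heterogeneity used for the
  fibroblast integrations this package serves; cell allocation to
  populations uses largest-remainder apportionment so planted sizes are
  deterministic.
* **Gene identities are plain strings** (`g0001`...), with
  ribosomal/lncRNA panels flagged in a metadata column, never by name
  prefixes.

`simulate_spot_data()` aggregates exactly `cells_per_spot = 4` cells per
spot (sampled without replacement), records the full composition with
equal weights, and derives the majority annotation from planted labels —
the ~4-nuclei-per-spot scale of the spatial platform being emulated.

`simulate_cell_nucleus_mixture()` plants expected panel shares of total
counts: ribosomal 0.40 in cells vs 0.05 in nuclei, lncRNA 0.15 in nuclei
vs 0.02 in cells, 80% nuclei, ~2500 counts per droplet. The shares
mirror real compositions (ribosomal transcripts dominate cytoplasm;
*Malat1*-like lncRNAs dominate nuclear RNA; nuclei dominate
frozen-tissue preps). As noted above, the nucleus-dominant default is
not incidental: it is the regime in which the fixed −0.5 product
threshold separates classes, and the one in which this split is needed
in practice.

What the generator does **not** emulate: ambient RNA, doublets, UMI
saturation, read-level structure, gene-gene correlation beyond the
factor term, or realistic disease-course population proportions (the
proportions table is configurable but defaults to uniform). Passing
tests on this generator therefore demonstrate correctness of the
*computations* under a clean generative model, not robustness to every
artifact of real data.

## Problem sizes and determinism

All generators and analyses are pure functions of (configuration, seed);
reruns are byte-identical, and `run_pipeline()` writes a manifest with
MD5 checksums to make that checkable. The test suite and acceptance
script use dataset sizes chosen to make each statistical check
well-powered at desk scale: 2000 genes × 600 cells for marker recovery,
2000 cells at $k = 200$ for purity calibration, 50–200 simulation seeds
for the null calibrations, 300 droplets for the cell/nucleus split. These
sizes are the package's validation design; all operations accept larger
inputs.

## Known limitations

* Exact kNN is quadratic in cells; beyond ~50k cells an approximate
  index would be needed (out of scope, and all validation runs exact).
* The Wilcoxon default ignores the zero-inflation structure a hurdle
  model captures; with very small groups (< ~20 cells) the normal
  approximation is rough. The test interface is pluggable for exactly
  this reason.
* Fisher enrichment p-values inherit all the usual caveats of
  overlap statistics on correlated gene sets; they are comparison
  statistics here, not calibrated error rates.
* The −0.5 cell/nucleus threshold is a published constant, not a fitted
  boundary; on data whose score scales differ from the defining
  dataset's (different depth, panel sizes, or mixture balance) the
  threshold should be re-examined before trusting the split.
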