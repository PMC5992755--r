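---
title: "Digital deconvolution of brain bulk RNA-seq: models, validation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital deconvolution of brain bulk RNA-seq: models, validation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Bulk RNA-seq of brain tissue measures a mixture: every library averages the
transcriptomes of neurons, astrocytes, oligodendrocytes, and microglia in
proportions that differ between samples, and that shift with
neurodegeneration. `cortexmix` estimates those relative proportions from the
bulk profile using a curated panel of cell-type marker genes, validates the
estimates on synthetic admixtures with known composition, and tests whether
the inferred proportions associate with phenotype. This vignette documents
the models, the tunable parameters, the numerical choices, and the known
limitations.

## The mixing model

All engines assume linear mixing in linear expression space (TPM-like units;
no log transform before deconvolution, since non-negativity is what makes the
factorization identifiable). For a marker-restricted bulk matrix $V$ (markers
$\times$ samples):

$$V \approx W H,$$

where $W$ (markers $\times$ cell types) holds the type-specific expression
basis and the columns of $H$ hold per-sample type abundances. Estimated
proportions are the columns of $H$ renormalized to sum to one — they are
*relative mRNA fractions*, not cell counts: no correction is made for
per-cell mRNA content or cell size.

### Engine 1: marker-constrained semi-supervised NMF (`ssnmf`)

The default engine factorizes $V$ with multiplicative Frobenius-loss updates
under a hard semi-supervised constraint: a marker of cell type $k$ may load
only on column $k$ of $W$; off-type entries are reset to zero after every
update (multiplicative updates preserve zeros, so the projection also holds
by construction). $W$ is initialized from the reference panel's per-type mean
marker expression, $H$ uniformly at a scale matched to the column sums.
Iteration stops when the relative change of $\lVert V - WH\rVert_F$ falls
below `tol` ($10^{-6}$ by default) or at `max_iter` (2000). The objective
trace is non-increasing, and the deterministic initialization makes runs
exactly reproducible; optional seeded random restarts (`n_restarts`) jitter
the basis multiplicatively and keep the best objective.

A property worth knowing: for a *single* bulk column the constrained
factorization decouples by cell type, and the first $H$ update is already the
least-squares projection of each type's marker block onto its initial basis
column — the fit then converges in a handful of iterations and is anchored by
the reference panel's scale. Multi-sample fits genuinely iterate.

### Engine 2: digital sorting (`dsa`)

For each sample, the mean expression of each type's markers is computed; the
digital-sorting model says this marker-mean signal equals an unknown
type-specific scale times the proportion. Writing $M$ (samples $\times$
types) for the marker means, the per-type inverse scales $x$ solve
$\min_x \lVert Mx - \mathbf{1}\rVert$ with $x \ge 0$ (non-negative least
squares), after which $P_{sk} \propto M_{sk} x_k$, row-renormalized. The
engine needs no labeled reference expression beyond the marker identities,
but the scale calibration is underdetermined with fewer mixture samples than
cell types (active-set NNLS then returns at most one nonzero scale per
sample); rank deficiency across samples with $n \ge K$ raises an explicit
error recommending more samples or markers. Under multiplicative noise the
digital-sorting estimate differs from the least-squares fit by roughly
$\sigma/\sqrt{\text{markers per type}}$ per entry, and because the scale
calibration pools all samples, rescaling a single column perturbs the joint
fit slightly (exact column-scale invariance holds when a column is
deconvolved alone — true of the ssNMF engine too, whose basis update couples
samples in joint fits).

### Engine 3: scaled marker means (`mean_profile`)

Each marker gene is scaled to unit maximum across samples (so high- and
low-abundance markers contribute comparably), and a type's estimate in a
sample is the mean of its scaled markers, row-renormalized. This is a
*relative index*, flagged as such in the result: because the scaling anchor
is the across-sample maximum, the index is invariant to rescaling the whole
matrix but not to rescaling a single sample, and a single-sample input is
degenerate (every gene trivially attains its own maximum). The index
coincides with absolute proportions exactly when every cell type spans the
same proportion range across the evaluated samples (each type's maximum
equal); otherwise use it for ranking and contrasts, not for absolute
composition.

### What the marker constraint costs

The hard zero constraint is also the model's main bias: any real off-type
expression of a marker (background transcription, imperfect purity) has
nowhere to go except the off-type's abundance estimate. If markers are
expressed at a fraction $1/f$ of their own-type level in other types, a pure
sample's estimated self-type proportion converges to $f/(f + K - 1)$ for $K$
types — e.g. $20/23 \approx 0.87$ at $f = 20$, and above $0.95$ only for
$f \gtrsim 60$. Well-curated brain markers (GFAP, MBP, CX3CR1, ...) are far
more specific than 20-fold, which is why leave-one-out recovery on real
purified panels is reported in the high 90s; synthetic panels generated at
fold 20 sit near the 87% ceiling by construction. The package reports
whatever the data support; exact-recovery tests use exclusive-marker
fixtures, the idealization the constraint assumes.

## The reference panel and its curation

A reference panel is labeled purified-sample expression restricted to marker
genes. Three quality-control steps are provided:

* **Species harmonization** maps symbols to a canonical uppercase namespace
  by case-insensitive identity (mouse `Gfap` and human `GFAP` merge). No
  orthology tables are used — sufficient for the curated marker namespace,
  and a documented limitation for anything beyond it.
* **Marker extraction** keeps candidates whose own-type mean is at least
  `min_specificity` (default 2) times the largest other-type mean; it only
  ever filters the candidate list.
* **PCA QC** normalizes columns to a common total, takes $\log(x+1)$, and
  scores label separation in the top-2 component space by mean silhouette
  width. The column normalization makes the score exactly invariant to
  uniform rescaling of all samples.

**Leave-one-out curation** then retains only samples the model itself can
recognize: per round, each sample is held out, the engine is fit on the
rest, the held-out sample is deconvolved as a one-column bulk, and samples
whose predicted self-type proportion is not *strictly greater* than the
threshold (default 0.80) are removed, simultaneously within a round. Rounds
repeat to a fixpoint (at most `max_rounds = 10`; a single pass is
`max_rounds = 1`). Hold-out order is lexicographic in sample id. Curation is
monotone (the retained set never grows) and idempotent at the fixpoint. If a
cell type would drop below two samples the run stops with an explicit error
carrying the partial report.

## The validation harness

**Chimeric admixtures.** Synthetic mixed libraries with known composition
are the ground truth for accuracy. A design enumerates `repeats`
$\times$ `n_distributions` tasks; the default design (32 distributions
$\times$ 720 repeats = 23,040 libraries of 400,000 reads) draws its
proportion vectors by a seeded Latin-hypercube inside per-type ranges
(neurons 2–36%, astrocytes 22–76%, oligodendrocytes 6–62%, microglia 1–5%),
renormalized to the simplex and re-checked against the ranges; explicitly
supplied vectors are validated and used verbatim. Donor samples rotate
deterministically with the task index and seed, so the full design is
reproducible without storing assignments. In read mode, per-type read counts
come from largest-remainder rounding — totals are conserved exactly — and
reads are drawn from donor pools without replacement where possible.
Expression mode (the desk-scale default) mixes donor profiles exactly.
Accuracy is the pooled root-mean-square error between estimated and true
proportions over all entries; the harness scores an oracle that returns the
truth at exactly zero.

**Gene dropout.** To check that no single marker dominates, the validation
is re-run with each marker gene removed in turn, scoring the RMSE between
full-panel and dropped-gene estimates. Genes whose type has a single marker
are skipped with a warning.

**LOOCV accuracy.** A single leave-one-out pass over the panel reports each
sample's predicted self-type proportion (mean and sd) plus the RMSE of the
predicted vectors against one-hot labels.

## The synthetic-data generator

The generator produces the statistical structure the pipeline assumes, and
nothing more:

* **Reference profiles**: marker gene of type $k$ at
  `marker_fold_change` $\times$ `baseline_expression` in its own type and at
  baseline elsewhere; background genes at baseline; per-entry multiplicative
  log-normal noise $\exp\!\big(N(0, \sigma^2)\big)$ — log-normal because it
  matches the right-skewed dispersion of RNA-seq abundances. Defaults: 4
  types, 50 markers/type, fold 20, $\sigma = 0.2$, baseline 10, 3
  replicates/type.
* **Read pools**: multinomial draws proportional to expression; pools hold
  exactly `pool_size` reads.
* **Cohorts**: control mean proportions default to neuron 0.35, astrocyte
  0.30, oligodendrocyte 0.30, microglia 0.05 (inside the chimeric ranges
  above); case means add the planted `effect_per_type` (defaults −0.17
  neurons, +0.23 astrocytes, the magnitudes of the strongest reported
  cortical AD contrasts). After the shifts the mean vector is returned to the
  simplex by rebalancing only the types *without* an explicit effect,
  proportionally to their control means — naive renormalization of the whole
  vector would silently change the planted effects (−0.17 would realize as
  about −0.13). An effect that pushes a mean outside $[0,1]$ errors before
  any sampling. Per-subject truth is a truncated-Gaussian perturbation
  (sd `proportion_noise_sd`, truncated at 0, renormalized) around the group
  mean — chosen over a Dirichlet because the planted effect size is then a
  direct mean shift. Bulk columns are the exact proportion-weighted mixture
  of type-mean profiles with multiplicative log-normal noise.

One global seed fans out to per-stage child seeds through a fixed affine
rule (a Lehmer multiplier with a distinct offset per stage), so every stage
is independently reproducible and two stages never share a stream.

What the generator does **not** emulate: splicing and isoform structure, GC
and positional bias, batch structure in the reference panel, cross-species
expression divergence beyond symbol case, disease-induced dysregulation of
marker genes, and microglial activation states. Passing tests on synthetic
data therefore demonstrate correctness of the algorithms under the stated
model, not performance on real tissue.

## Association models

Cell-type proportions are analyzed on the raw proportion scale (no logit),
so effects read directly as proportion differences. `fit_association` is
ordinary least squares per cell type with Wald p-values; no multiple-testing
correction by default (a Benjamini–Hochberg flag is provided). Covariates
(RIN, PMI, age at death, batch, ...) can be chosen by bidirectional stepwise
AIC from the full model. For multi-region or family-structured data,
`fit_mixed_association` fits a random intercept per donor (or family) —
intercept-only is the defensible default reading of "clustered" designs, and
random slopes are exposed as an option; singular fits are flagged, not
dropped. Power for a two-group contrast is estimated by Monte-Carlo
simulation of the same OLS test (the closed-form noncentral-$t$ power is the
test oracle). Meta-analysis across studies is fixed-effect inverse-variance
pooling: $k$ identical studies shrink the standard error by exactly
$1/\sqrt{k}$, and an infinite standard error contributes zero weight.

## Numerical choices and degenerate inputs

* Multiplicative-update guard of $10^{-12}$ in denominators; convergence on
  relative objective change.
* Ties in largest-remainder allocation break by index order, so allocations
  are deterministic.
* Proportion tables always order cell-type columns alphabetically, making
  every writer byte-deterministic.
* Duplicate gene rows on file read collapse by sum (read-count semantics)
  with a warning; duplicate sample ids are an error.
* All-zero proportion rows (no marker signal at all) are an error in
  renormalization, except in `mean_profile` where an all-zero sample falls
  back to the uniform index, and in `dsa` where a degenerate scale solution
  falls back to raw marker-mean shares.

## Problem sizes used in the shipped checks

The packaged validation runs at desk scale: the chimeric benchmark uses the
full 32 distributions at 45 repeats (1,440 libraries, expression mode), the
dropout analysis a 32 × 10 subset with all 200 marker genes, LOOCV a
6-replicate panel (24 samples), and the association property checks 200
simulated cohorts of n = 120 plus 1,000 null replicates. The full
23,040-library read-mode design is constructed and enumerated exactly but
not deconvolved end-to-end in the default checks; nothing in the harness
depends on the scale except runtime.

## Known limitations

* Relative mRNA fractions conflate cell-number and per-cell-expression
  changes; a shrinking neuron *proportion* can reflect either.
* The marker-zero constraint biases estimates in proportion to real off-type
  marker expression (see above); marker curation quality is the accuracy
  ceiling.
* Cross-species harmonization by symbol identity cannot catch diverged
  orthologs or renamed symbols.
* The digital-sorting scale calibration needs at least as many mixture
  samples as cell types.
* Power estimation assumes Gaussian noise on proportions and a two-group
  OLS contrast; it is a simulation stand-in, not a reproduction of any
  specific cohort's empirical power procedure.
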