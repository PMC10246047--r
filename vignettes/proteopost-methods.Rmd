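---
title: "Models and methods behind proteopost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind proteopost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteopost)
```

proteopost standardizes quantified peptide or protein tables from any
search platform into one data object and provides the post-processing
steps a label-free (or labeled) quantitative proteomics analysis needs:
curation, peptide-to-protein rollup, normalization, imputation, two-group
differential expression and term enrichment, with every transformation
recorded in an operations ledger. This vignette explains the models and
the choices behind each step — what is assumed, what is tunable, and what
the defaults mean.

## The four-table data object

A dataset is four tibbles plus a ledger. `experiments` holds one row per
LCMS run, keyed by an 8-character identifier derived from a SHA-1 digest
of the import and run file names — deterministic, so re-imports and
merges of the same files always agree. `quantitative` holds one row per
(run, identifier) with one column per abundance channel: `raw` always,
plus one channel per normalization method computed later. `accounting`
carries per-(run, identifier) bookkeeping — the fraction of values
imputed and peptide/protein counts — and `annotations` maps protein
accessions to (term, annotation) pairs one-to-many, so Gene Ontology
domains, custom categories and free-text descriptions coexist without
schema changes.

Two conventions matter everywhere downstream:

* **Missing is never zero.** Zeros and empty cells become `NA` at import;
  abundances are strictly positive where present. Intensity zero in a
  platform export means "not observed", and treating it as a measurement
  would poison means, CVs and tests.
* **A shared peptide appears once per candidate protein** with an
  identical abundance, so protein inference has the full candidate map
  without a separate structure.

## Filtering grammar

`subset()` takes one predicate: `[!] variable (== != < <= > >= %like%)
value`. `%like%` is case-insensitive unanchored regular-expression
search — the "keep everything not described as ribosome" idiom —
case-insensitive because description capitalization varies by platform
and a silent case miss is worse than an occasional broad match.
Identifier-level and annotation predicates drop whole identifiers;
experiment predicates drop whole runs. Annotation predicates match an
identifier if *any* of its rows for that term matches, and negation then
keeps identifiers with no matching row. Accounting values are per-run, so
a predicate like `num_unique_peptides >= 2` keeps an identifier if any
run satisfies it — partially supported identifiers survive, which is the
conservative direction for a filter whose purpose is curation rather
than scoring. Compound expressions are deliberately out of grammar:
chaining `subset()` calls keeps each ledger entry a single auditable
decision.

## Peptide-to-protein rollup

`collapse()` turns a peptide dataset into a protein dataset in four
steps: ownership, splitting, ranking, summary.

Ownership (`assign_peptides()`) offers three conventions. `all_possible`
keeps every candidate; `razor` gives each shared peptide wholly to the
candidate with the most unique peptides (ties: most total peptides, then
lexicographic accession), the MaxQuant-style convention; `non_homologous`
discards shared peptides. With `all_possible` and `split_abundance =
TRUE`, a shared peptide's abundance is divided per sample in proportion
to each owner's unique-peptide abundance total, falling back to an equal
split when no owner has unique evidence; contributions always sum back to
the observed value exactly, so with `summary_fn = "sum"` and all peptides
retained the per-sample protein totals equal the peptide totals to
machine precision. Unique-peptide totals for splitting are always taken
from the `raw` channel: splitting is accounting, not normalization.

`top_n` ranks peptides once per protein by mean non-missing abundance
across samples, not per sample — a per-sample ranking would let the
peptide set change between conditions and bias ratios. Missing values are
excluded from the summary function rather than zero-filled; a protein is
missing in a sample only when every contributing peptide is.

One caution that shaped our own default analysis: any scheme that lets a
shared peptide contribute to several proteins — or assigns it wholly to
one by razor — lets a differential peptide move its signal into a co-owner
protein. On simulated knockdowns this inflated the realized false
discovery rate two- to four-fold. For expression analysis we therefore
quantify on unique peptides (`non_homologous`); the splitting machinery
remains the right tool for abundance bookkeeping, e.g. proteome
composition estimates.

## Normalization

`normalize()` computes all requested channels at once on the log2 scale
against a per-identifier reference `r(i)`, the median log2 raw abundance
of identifier `i` across runs — the standard robust reference when no
run can be privileged. `median` aligns per-run medians exactly; `linear`
is the intercept-only least-squares shift (mean offset); `loess`
subtracts a local regression of `sample − r` on `r` (span 0.5, degree 1,
direct surface so extrapolation is defined); `randomforest` subtracts
`f(r) − r` for a 100-tree seeded forest, a nonparametric alternative
that tracks sharper intensity-dependent distortion. Normalization never
changes the missingness pattern or the identifier set.

The forest's flexibility needs a guard rail: with small terminal nodes
it partially memorizes per-identifier residuals, which shows up as an
impressive CV reduction that is really absorption of replicate noise —
and of genuine group effects (on simulated knockdowns an unregularized
forest halved true log2 fold changes). The default minimum node size is
therefore `max(32, 2%)` of the fitted points, and some attenuation of
large effects remains intrinsic to any flexible fit against a reference
computed across both groups; when effects are large, loess preserves
them better, and the automated selection below tends to agree.

A `basis` filter restricts the *fit* to chosen identifiers — spike-ins,
or the bait of an immunoprecipitation — and applies the fitted correction
to everything. The constant-shift methods accept any non-empty basis
(a single bait is the canonical use); the curve methods need at least 10
basis identifiers, because a curve through fewer points is not a
correction but an interpolation of noise. This split resolves an
otherwise contradictory pair of requirements (a minimum basis size
versus the one-protein bait use case) in favor of both.

### Automated selection

`select_normalization()` scores each non-raw channel by a weighted mean
of three dimensionless terms, each a relative change against raw:
`cv/cv_raw` (precision; smaller better), `|dr − dr_raw|/dr_raw`
(dynamic-range preservation: a good normalization lowers variance
*without* compressing the abundance range), and `1 − pca3/pca3_raw`
(variance concentration in the first three principal components;
losing it means structure was removed along with bias). Weights default
to equal thirds; ties resolve median < linear < loess < randomforest,
simplest first.

We first implemented the score on metric *ranks*, which seems natural
for incommensurable units, and rejected it on evidence: any smooth
per-sample bias is low-rank (a sinusoid with per-run phase spans exactly
two components), so the uncorrected channels *win* the PCA and
dynamic-range ranks by hairline margins while losing CV four-fold — and
two third-place ranks outvote one first place. Relative changes keep the
three terms on one scale, so a large precision gain cannot be outvoted
by negligible differences elsewhere; with weights `(1, 0, 0)` the
selection reduces exactly to the argmin-CV channel. On simulations with
per-run curvature of 0.5 log2 units the selection picks a curve-based
channel in 10 of 10 seeds.

The CV metric is the median over sample groups of the median
per-identifier sd/mean on the linear scale (2+ replicates required);
dynamic range is the central-95% width of log10 abundance; the PCA
fraction uses complete identifiers on the identifier-centered log2
matrix.

## Imputation

`impute()` fills missing cells of the selected channel only, on the log2
scale (all the summary statistics involved behave better there for
abundance data), and never touches observed values or other channels —
so normalization and imputation can run in either order, which remains
the analyst's choice. `within` pools an identifier's observed values in
the same sample group; `between` pools across all samples (we read
"between groups" as "all evidence available", and document it). When a
group has no observation at all — a knockout, or affinity flowthrough —
`within` falls back to the group floor, the minimum observed abundance
of any identifier in that group, on the logic that total absence in a
group with otherwise normal coverage is informative absence. Two guards
bound that logic: `strict = TRUE` disables the fallback, and an
identifier observed in *no* group never receives values — floor-filling
both groups of a never-observed identifier manufactures two constant
vectors whose ratio looks significant, which we observed directly before
adding the guard.

`randomforest` imputation is iterative matrix completion in the
missForest style: initialize missing cells with row means, then sweep
sample columns in order of ascending missingness, regressing each on all
others with a 100-tree forest and predicting its gaps, until the relative
change of the imputed values increases (the published
difference-increase rule; the previous iterate is returned) or 10
iterations. It runs sequentially and is bitwise reproducible under a
seed. On 20% missing-completely-at-random data with row/column structure
its error is about half that of mean imputation; on
missing-not-at-random dropout, minimum-within imputation remains the
recommended choice precisely because the forest will confidently impute
values that were never there.

Where should imputation sit relative to rollup? Peptide-level minimum
fills produce identical values across a group's replicates, collapsing
within-group variance and inflating the t tail (we measured a null
p < 0.005 fraction of 0.012 against a nominal 0.005). Imputing after
`collapse()` touches far fewer cells — a protein is missing only when all
its peptides are — and restored calibration in our experiments; the
worked pipelines in this package therefore impute at the protein level.

## Differential expression

`expression_analysis()` tests log2-transformed selected-channel values —
the variance-stabilized scale — while reporting fold change as the ratio
of linear-scale group means, the quantity practitioners quote.
Identifiers need two observations per group; the excluded ones are
returned in a side attribute, not dropped silently. Welch's t is the
plain option; the rank-sum test is exact for eight or fewer observations
per side and tie-corrected normal otherwise.

The moderated t shrinks per-identifier pooled variances toward a prior
estimated from all identifiers under the scaled-F model
`s² ~ s0² F(d, d0)`. The prior degrees of freedom `d0` and prior
variance `s0²` come from the method of moments on `log s²`: after
removing the digamma/trigamma contribution of the known residual degrees
of freedom, the sample mean and variance of the log variances identify
`(d0, s0²)` through a Newton inversion of the trigamma function. The
posterior variance `(d0·s0² + d·s²)/(d0 + d)` interpolates between the
observed variance (`d0 = 0`) and complete pooling (`d0 = ∞`, the branch
taken when the log-variance spread is no larger than `d` alone
explains); the moderated t has `d0 + d` degrees of freedom. The
implementation is validated against an independently coded
moment-equation solver and against the reference empirical-Bayes
implementation in the test suite. Benjamini–Hochberg is the only
multiple-testing adjustment offered.

## Term enrichment

`enrichment()` ranks identifiers by log2 fold change — enrichment here
is about the direction and size of the group ratio, not significance —
and computes, per annotation of a term, the weighted Kolmogorov–Smirnov
running sum with weight exponent 1: hits advance by `|score|` normalized
over member scores, misses retreat by `1/(N − n)`, and the enrichment
score is the signed extremum, bounded in \[−1, 1\]. The null is built by
permuting identifier labels, not sample labels: with three or four
replicates per group, sample permutation has too few distinct
arrangements to estimate tail probabilities. The permutation p-value is
`(1 + k)/(1 + m)` over same-sign permutations, so it can never be zero,
and the normalized score divides by the mean same-sign permutation
magnitude. Annotations smaller than 3, larger than 500, or covering the
whole list are skipped and reported. A rank-sum alternative
(in-term versus out-of-term fold changes) is available for terms where
the running-sum geometry is unnecessary.

## The simulator

`simulate_dataset()` is first-class, tested code that generates the
study conditions used throughout: a two-group label-free comparison
(control versus knockdown, four replicates each) of 500 proteins with
one-plus-Poisson peptides per protein (mean 3), base log2 abundances
Normal(20, 2.5), peptide offsets Normal(0, 0.5), 10% differential
proteins at |log2 effect| 2 with random sign applied to the last-listed
group, multiplicative replicate noise at CV 0.1 (log-normal, so log2
values are exactly Gaussian and test calibration can be checked against
theory), 5% shared peptides, 2% keratin contaminants, logistic
abundance-dependent dropout (midpoint 14, slope 1 per log2 unit — about
4.5% of cells overall, concentrated at low abundance) plus 2% uniform
dropout, and one annotation term whose enriched annotation collects 90%
of the up-shifted proteins. These values were chosen once as a
representative small knockdown experiment; effect size 2 with CV 0.1 is
a strong, clean signal, so recovery results on this design say "the
machinery works", not "expect 98% recall on real data".

What the simulator does not emulate — correlated peptide noise within a
protein, retention-time or charge-state structure, batch effects,
interference in labeled channels, heavy-tailed contamination — bounds
what passing tests show: correctness of the algorithms under a clean
generative model, not robustness to every pathology of real data.
`simulate_nonlinear_bias()` adds per-run smooth intensity-dependent
distortion (a sinusoid over the central abundance range with random
phase, amplitude 0.5 log2 units by default) for normalization-selection
studies.

## Numerical and interface choices

* Exports format doubles with `%.17g` and imports parse them with
  `strtod`, so export/import and bundle round trips are bitwise exact;
  the default 15-digit writer loses the last bits.
* Degenerate two-group tests (zero variance in both groups) return a
  perfect null when means agree rather than erroring.
* Tie-breaks are deterministic everywhere: peptide ranking by
  lexicographic key, channel selection by simplicity order, clustering
  leaf order by input order, enrichment sorting by |NES|.
* All randomness (forests, permutations, simulation) flows through
  explicit seeds; rerunning a pipeline config writes byte-identical
  bundles.
* Problem sizes in the test suite (hundreds of proteins, thousands for
  calibration checks, 500–1000 permutations against a 100,000-permutation
  reference) are chosen so the full suite exercises every claim in under
  a minute on a laptop-class machine.

## Known limitations

Rollup does not implement Tukey's median polish or MaxLFQ-style pairwise
ratio estimation. Expression has no PSM-count-aware model. Imputation
offers no left-censored distribution draws (QRILC/MinProb family).
Annotations come from flat files only; nothing is fetched remotely. The
Euler/Venn support computes region counts, not area-proportional
geometry. The `between` imputation scope pools all samples rather than
all *other* groups; both readings are defensible and ours is documented.
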