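---
title: "Estimating plastid MAG completeness from KEGG module coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating plastid MAG completeness from KEGG module coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidr)
```

## The problem

Plastid genomes assembled from metagenomes cannot be quality-assessed the
way bacterial or eukaryotic MAGs are. Standard completeness estimators
count single-copy marker genes; organellar genomes are reduced,
endosymbiotically derived, and have variable gene content (much of it
transferred to the nucleus), so they carry almost none of those markers
and are routinely flagged as hopeless low-quality bacterial bins.

plastidr implements an alternative: completeness is predicted from
*functional* content. A genome's KEGG Orthology (KO) annotations are
summarised as a vector of per-module completeness fractions, and a
regression model maps that vector to a completeness percentage. The model
is trained on reference plastid annotation profiles artificially degraded
across a completeness grid, so the mapping from "fraction of annotations
surviving" to "module coverage signature" is learned rather than assumed.

## Module coverage

A KEGG module DEFINITION string is an ordered list of *steps*
(space-separated at the top level). Within an expression, commas are
alternatives (OR), spaces inside parentheses and `+` are required
components (AND; `+` marks members of one protein complex), and a `-`
prefix marks an optional component. We define the completeness of module
$m$ for KO set $S$ as

$$ c_m(S) = \frac{\#\{\text{steps whose boolean expression is true under } S\}}{\#\text{steps}} $$

with optional components always treated as present, so they can neither
raise nor lower the score. Presence is binary: a KO annotated five times
contributes exactly what a KO annotated once does (module satisfaction is
a set property; counts matter only to the subsampler). This
satisfied-steps-over-total-steps convention is the de facto standard of
KEGG-module completeness tooling; because some tools instead use binary
module presence, `coverage_vector(mode = "binary")` exposes that variant,
but the fractional mode is the default and is what the bundled models are
trained on.

The feature vector of a genome is $x = (c_{m_1}, \dots, c_{m_p})$ in the
fixed order of the module catalog. Models refuse feature vectors whose
module order differs from their training catalog — reordering silently
would be a correctness trap.

The bundled catalog (36 modules) is a hand-authored *synthetic* stand-in
for a KEGG DEFINITION dump: syntactically faithful (multi-step modules,
alternatives, complexes, optional members, nesting) but with invented
module ids (M9xxxx) and KO assignments, so the package builds and tests
fully offline. Real KEGG dumps load through `load_module_catalog()`.

## Simulating incompleteness

Training labels come from subsampling, not from real partial genomes.
For a reference profile with $N$ annotation tokens (a KO with count $c$
contributes $c$ tokens), `subsample_profile(profile, f, seed)` draws a
uniform random sub-multiset of exactly $\mathrm{round}(f N)$ tokens
without replacement and labels the result $100 f$ percent complete.
Token-level sampling mirrors the loss of individual genes in a fragmented
assembly; sampling distinct KOs instead would model losing whole gene
families, which is not how assembly incompleteness behaves.

Numerical choices, fixed once:

* Rounding is half away from zero, with a $10^{-9}$ epsilon guard because
  grid fractions like 0.05 are not exactly representable in binary and
  $0.05 \times N$ can land a hair below an exact half.
* The default training grid is 0–100% in 5% increments (21 levels); the
  held-out validation grid is 10–100% in 10% increments. One subsample
  per (genome, level) cell by default; replicates are configurable.
* Each grid cell gets its own seed, derived from the master seed and the
  cell key (genome id, fraction, replicate) by a stable string hash mod
  $2^{31}-1$. Cells are therefore reproducible under reordering or
  partial re-runs, and grids are byte-identical across runs of the same
  seed.
* Reference genomes smaller than 94 kb (the median plastid genome size of
  protists) are excluded from training by
  `filter_training_references()`, so outlier reduced genomes do not
  drag the model.

## The regressors

Three regressors are supported: Ada boosting (`ada_boost`, AdaBoost.R2
with linear loss and weighted-median prediction), least-squares gradient
boosting (`gradient_boost`), and a bootstrap random forest
(`random_forest`). No tree-ensemble package ships in the supported
environment, so the package carries its own exact-greedy CART regression
tree (squared-error criterion, compiled code) and assembles the three
ensembles on top of it. Hyperparameters are frozen at the widely used
library defaults for these algorithms and recorded in every fitted
object: gradient boosting uses 100 depth-3 trees with learning rate 0.1;
the forest uses 100 unpruned bootstrap trees over all features; AdaBoost
uses 50 depth-3 trees with learning rate 1. No tuning is performed —
reproducibility is preferred over invented search. The split criterion is
plain variance reduction; ties break deterministically to the first
feature and threshold, and all randomness (bootstrap and resampling rows)
is drawn from R's seeded RNG so fits are bit-reproducible.

Training protocol (`train_model()`): genomes — never individual simulated
examples — are the unit of splitting, both for the 90:10 train/test
partition and for the 5-fold shuffled cross-validation, because all 21
degraded versions of one genome share its annotation idiosyncrasies and
would leak across folds. Each fold yields a fitted model and held-out
fold metrics; a final model is refitted on all training data. Predictions
are clamped to $[0, 100]$ after the fact; the regressors themselves are
unconstrained.

## Evaluation and model selection

`evaluate_model()` reports, on a labeled test grid: per-level median and
standard deviation of predictions (population SD, so a single-genome
level reports 0), an ordinary least-squares fit of predicted ~ expected
with adjusted $R^2$, Pearson's correlation with its p-value, mean squared
error computed on labels rescaled to $[0, 1]$ (the scale is stated
because MSE is meaningless without it), and the median signed difference
$\mathrm{expected} - \mathrm{predicted}$.

`select_best_model()` picks the algorithm with the smallest
|median difference| — the least systematic bias — breaking ties by larger
Pearson correlation and then by fixed algorithm-name order. With the
published-style inputs (median differences −2.12, 0.37, −7.5) this
selects gradient boosting. `contrast_organelles()` guards against the
known failure mode of functional-content completeness: mitochondrial
genomes share metabolic KOs with plastids, and a usable model must score
full mitochondria near 0 while scoring full plastids near 100.

## The bin retention rule

Upstream of completeness, bins are screened by plastid content. Contig
classifications (from an external contig classifier, consumed as a table)
and bin memberships (per-bin FASTAs or a two-column table) yield, per
bin, the fraction of nucleotides on plastid-classified contigs. A bin is
a probable plastid bin when that fraction **strictly** exceeds the
threshold (`min_plastid_content`, default 0.90): a bin at exactly 90%
is not retained. The fraction is nucleotide-based, not contig-count-based
(both are reported); mitochondrial and every other non-plastid class
count toward the denominator only. Bins below `min_bin_span_bp` (default
50 kb, the reduced bin size used at binning time) are kept in the output
but flagged `sub_span` rather than dropped — dropping them would hide
exactly the marginal bins a user may want to inspect.

Bin-level taxonomy is derived from contig-level calls by a span-weighted
majority walk down the lineage: at each rank the taxon holding more than
half of the bin's classified span is accepted, and the walk stops at the
first rank without a majority, so a 50/50 conflict reports the deepest
common ancestor. Marker loci (an rbcL protein-HMM hit table and an rRNA
GFF3) use GFF3 1-based inclusive coordinates; minus-strand loci are
reverse-complemented on extraction.

## The synthetic world, and what a green test establishes

All tests and the acceptance run use synthesized reference profiles, not
RefSeq annotations:

* `plastid_like` genomes retain each catalog KO independently with
  probability 0.97 (a "large random subset" — the constraint is at least
  90%; 0.97 makes the constructed mean module coverage of a fresh genome
  reliably ≥ 0.9), with $1 + \mathrm{Poisson}(1)$ copies per retained KO
  and spans uniform on 100–250 kb, the plastid genome size range.
* `mito_like` genomes draw 3–8 KOs from a fixed subpool of 5% of the
  catalog's KOs — the small metabolic overlap between organelle
  genomes — with spans uniform on 15–70 kb.

This world reproduces the *structure* of the real task (monotone
label/feature coupling, organelle contrast, grid geometry) but not its
hard parts: real plastid annotation profiles are phylogenetically
correlated, their module coverage saturates unevenly across lineages, and
annotation pipelines introduce systematic KO biases. A green
parameter-recovery test therefore establishes that the machinery —
grammar evaluation, subsampling, featurization, genome-level CV, the
regressors — is implemented correctly and recovers a known signal; it
does not certify the accuracy figures a model trained on real references
would achieve.

## Known limitations

* Completeness is functional, not structural: a genome missing only
  intergenic or repetitive sequence scores as complete.
* Bacterial bins score high by construction (shared metabolism); the
  method assumes high-quality prokaryotic MAGs were removed upstream,
  and the bin screen catches only what the contig classifier catches.
* The module grammar accepts strict KEGG DEFINITION syntax over
  K-numbers; module-in-module references and `--` gaps are not
  supported and fail loudly at parse time.
* AdaBoost.R2 may stop early (when weighted loss reaches 0.5); the
  artifact records however many rounds were kept.
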