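---
title: "Assessing GO-slim predictability from primary structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing GO-slim predictability from primary structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(GOSlimPred)
```

## The problem and the model

Functional annotation of plant proteins lags behind model organisms, and
alignment-based transfer (BLASTP-style nearest neighbour) fails exactly
where it is most needed: once close homologs are filtered away. This
package implements a protocol for measuring, category by category, how
much function signal survives in the primary structure itself. Each
GO-slim category becomes a one-vs-all binary problem over a fixed
feature map, and the outcome of interest is not a single classifier but a
*predictability landscape*: which categories, and which groups of
features, carry signal.

The method assumes (i) composition-level statistics (residue and
dipeptide frequencies, charge, hydropathy, pI, molecular weight, coarse
secondary-structure composition) capture the relevant signal, (ii) label
semantics follow the GO true-path rule, and (iii) performance must be
read under heavy class imbalance, hence the G-mean
\(\sqrt{\mathrm{sens}\cdot\mathrm{spec}}\) rather than accuracy.

## Label construction

For a slim term \(T\), positives are proteins annotated to \(T\) or to
any descendant of \(T\), *except* descendants captured by another slim
category: the walk down from \(T\) never enters a slim descendant, so a
multi-parent term is kept iff some downward path avoids every slim
descendant (path-sensitive exclusion). The alternative — excluding the
*set* of all terms below any slim descendant regardless of path — differs
only for multi-parent terms; we chose the path-sensitive reading because
it matches the intuition that such a term still carries an annotation
route of its own. Terms with slim descendants are flagged "incomplete"
and rendered with an asterisk. Categories below 30 positives are dropped:
with 5-fold stratification that floor leaves ≥ 6 positives per fold, the
minimum for fitting anything reliable. Each namespace is handled
independently; a protein with no usable annotation in a namespace is a
universal negative there. Only `is_a` edges are parsed from OBO input;
`part_of` is deliberately ignored (smallest faithful reading of the
propagation rule; a `relationship`-aware closure is a possible
extension).

## Featurization

The 438 features split 6/20/400/3/9 (physical-chemical, monomer, dimer,
SS, SS-dimer). Choices that were genuinely open:

* **Charged-residue sets.** Positive = {K, R}, negative = {D, E},
  matching common protein-parameter conventions; histidine is excluded
  from the positive set (pKa ≈ 6.5 makes it mostly neutral at
  physiological pH). Both sets are arguments of `residueTables()`.
* **Constants.** Average residue masses (Da, one water added per chain),
  Kyte–Doolittle hydropathy, and an EMBOSS-style pKa set (N/C termini
  plus C, D, E, H, K, R, Y) ship as plain-text tables under
  `inst/extdata/` and are swappable.
* **Ambiguity expectation.** B = {D, N}, Z = {E, Q}, J = {I, L}, X = all
  twenty, U → C, O → K. An ambiguous position contributes its compatible
  residues weighted by renormalized Swiss-Prot-wide abundance priors.
  Adjacent ambiguous positions are resolved *independently* in the dimer
  block — the only closed form available for a per-feature expectation —
  and the tests verify the closed form against exhaustive enumeration
  and Monte-Carlo resolution.
* **pI.** Net charge is a Henderson–Hasselbalch sum over expected
  ionizable-group counts; the root is found by bisection on pH ∈ [0, 14]
  to 1e-4 pH units (charge is monotone in pH, so bisection is exact up
  to tolerance).
* **z-score state** is fitted per training fold, not globally: global
  normalization would leak test-fold statistics into training. This is a
  deliberate deviation from one-shot global normalization, and the fold
  means of held-out data are asserted to be nonzero in the tests.
* **Secondary structure** is an *input*. The bundled
  `predictSsStub()` (propensity-table argmax with a 5-residue smoothing
  window) exists only so pipelines run without an external predictor; it
  is deterministic, length-preserving, and makes no accuracy claim.

## Feature structure

Features are grouped by Ward clustering under the absolute Pearson
correlation distance \(d_{ij} = 1 - |r_{ij}|\) (anti-correlated features
carry the same linear information). The classical Ward/Lance–Williams
update is applied to the supplied dissimilarities as-is (`ward.D`), i.e.
they are not squared first — the historical default of the environment
this method family grew up in; `ward.D2` is selectable. The default cut
is k = 15 clusters, but cluster memberships are data-dependent and k is a
free parameter.

Per-problem selection is FCBF with linear correlation replacing
symmetrical uncertainty: rank features by \(c_{iy} = |cor(f_i, y)|\),
drop those below δ, then scan top-down removing every lower-ranked
\(f_j\) with \(|cor(f_i, f_j)| \ge c_{jy}\). δ defaults to 0 — the
predominance rule alone does the pruning — because any fixed positive δ
is arbitrary without a reference dataset. Selection runs inside each
training fold (leakage-safe), not once globally.

## Classification protocol

Stratified 5-fold CV (80/20), seeded and shared byte-identically with
the alignment baseline. Per fold: normalize (train-fitted), select
(optional), SMOTE the training minority to parity with the majority
(k = 5 neighbours, the original convention; the amount is whatever
reaches parity), tune, train, score the held-out fold. Metrics are
averaged over folds, not pooled.

The SVM is kernlab's C-SVC with
\(K(x,z) = \exp(-\|x-z\|^2 / 2\sigma^2)\). Tuning is canonical PSO in
log10 space over σ ∈ [1e-3, 1e3], C ∈ [1e-2, 1e3], swarm 15, 30
iterations, w = 0.72, c1 = c2 = 1.49, maximizing mean 3-fold inner-CV
G-mean on the balanced training set. For scenario-scale runs the package
uses either a reduced swarm (6 × 6) or the median-pairwise-distance σ
heuristic with C = 1 (`tune = FALSE`): at the bundled problem sizes the
planted signals are strong enough that tuning budget is not the
bottleneck, and null-calibration runs skip tuning because no setting of
(σ, C) can make permuted labels predictable. Non-finite tuning
objectives score −∞ and the swarm continues.

## Alignment baseline

Top-1 local-alignment hit (BLOSUM62, gap open 11 / extend 1), raw score
threshold 50, transferring the full slim-label row of the best training
hit; no hit means all-negative. Top-1 (rather than top-k voting or
E-value weighting) is the simplest faithful reading of annotation
transfer; the identity filter's effect on it is the point of the
comparison. Identity for the redundancy filter is matches / alignment
length *including gaps* — stricter and argument-order-independent;
Cd-Hit divides by the shorter sequence, so our values are systematically
≤ Cd-Hit's and the same nominal cutoff is slightly more aggressive.
The greedy clustering replaces Cd-Hit's k-mer prefilter with exact
pairwise alignment: correct at package scale, quadratic at database
scale.

## What the generator emulates — and what it does not

`generateSequences()` produces: a rooted b-ary ontology per namespace
with a marked slim subset; classes attached to distinct slim terms,
annotated at terms drawn from the slim term's contributing set (so
positives arise via descendants, exercising the exclusion logic);
class-conditional residue distributions (background abundance priors
with named residues multiplied by a fold factor); sequence families
(founder + i.i.d. substitutions at a configured rate, substitutions
drawn from the class distribution, no indels); log-normal lengths
(median ≈ 300); and H/E/C strings from a first-order Markov chain
(self-transition 0.8).

It does **not** emulate: domain architecture, positional motifs,
realistic phylogeny, annotation noise or evidence-code heterogeneity,
or correlations between composition and secondary structure. Passing
tests therefore demonstrate that the *machinery* recovers planted
composition-level signal at the configured sizes — not that real
proteomes carry such signal; that question needs real data through the
same pipeline.

Bundled scenarios (seeds fixed in `inst/scenarios/*.yaml`):

* `planted-easy` — 250 positives with K/R enriched 2.5-fold vs 250
  background; balanced, strongly separable.
* `imbalanced-30` — 30 positives vs 470 background: the class-size
  floor.
* `null` — 250/250 with no planted signal; the ledger is empty. The
  null is balanced by design: the 0.5-centred chance band for the
  G-mean presumes a balanced test set, whereas an imbalanced null with
  balanced training would centre elsewhere.
* `family-bias` — two classes of 30 five-copy families each (mutation
  rate 0.25, within-family identity ≈ 0.55–0.65), signals K/R vs
  I/L/V at 2-fold. Filtering at 0.8 keeps families intact (alignment
  transfer thrives); filtering at 0.3 collapses them to representatives
  (transfer starves, composition survives).

## Problem sizes and numerical choices

Scenario runs use n ≈ 500 proteins (300 for `family-bias`), one slim
term per scenario under evaluation, 5 outer folds, and the reduced
tuning budgets above; these sizes are the package's chosen desk-scale
study conditions and are stated in the scenario files. Degenerate cases
are pinned down explicitly: zero-variance features get distance 1 in
clustering, map to 0 under z-scoring, and relevance 0 in FCBF;
sequences shorter than 2 yield all-zero dimer blocks with a warning;
missing SS strings yield zero SS features (policy configurable to
error); SMOTE lowers k to n−1 with a warning and duplicates a singleton
minority; empty PSO objectives score −∞; ties break lexicographically
(FCBF ranks, best-hit ids, greedy cluster order) so every run is
deterministic under its seed.

## Known limitations

* Quadratic exact alignment limits the redundancy filter and baseline
  to desk-scale datasets; a Cd-Hit/BLAST wrapper would be the natural
  backend for real proteome snapshots.
* The FCBF variant is linear-correlation-based by design; nonlinear
  relevance (mutual information / SU) is out of scope.
* `part_of` edges and cross-namespace links are ignored.
* Per-fold averaged metrics (not pooled confusion matrices) are
  reported; with 5 folds and small positive sets the dispersion across
  folds is itself informative and is retained in the long-format
  results.
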