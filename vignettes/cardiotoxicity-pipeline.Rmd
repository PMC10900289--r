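---
title: "Modeling drug-induced cardiotoxicity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug-induced cardiotoxicity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Drug-induced cardiotoxicity (DICT) is a leading cause of drug withdrawal.
Regulatory concern categories grade drugs as *most*, *less*, *no* or
*ambiguous* concern; adverse-event databases such as SIDER record binary
"cardiac disorders" labels for marketed drugs. `dictox` implements a
complete pipeline from raw SMILES and label tables to calibrated
Random-Forest classifiers: standardization, label assembly, feature-space
construction, per-feature association statistics, structural-alert mining,
threshold-optimized models, soft-voting ensembles, and applicability-domain
analysis. A synthetic-study generator with known planted structure makes
every stage verifiable without any external download.

## Chemical standardization

`standardize_compounds()` iterates a cleanup cycle — largest organic
fragment, charge neutralization, representation normalization,
canonicalization — until the canonical SMILES reaches a fixed point
(at most `max_iterations = 5` cycles; a non-converging input falls back to
the most frequently observed SMILES, ties broken toward the
lexicographically smallest, so the result is always deterministic).
Protonation at pH 7.4 is applied once, *after* the loop, because
re-entering the neutralization step would undo it; when the protonation
engine proposes several protomers only its first assignment is kept. The
standard InChI of the protonated structure is the match key for all joins
and duplicate detection, which makes protomers and salt forms of one parent
collapse to one compound.

Design notes:

* Convergence is tested by string equality of consecutive canonical SMILES —
  the simplest criterion that is reproducible across machines.
* Salt stripping keeps the largest organic fragment (most heavy atoms;
  carbon-containing fragments preferred; lexicographic tie-break). Without
  it, InChI-based joins between datasets mismatch on salt forms.
* The chemistry engine is Open Babel (via ChemmineR/ChemmineOB). Open Babel
  has no tautomer canonicalizer, so the normalization step is a small fixed
  rewrite table (hypervalent nitro/azide forms to their charge-separated
  spellings). Tautomer pairs that differ by hydrogen placement may therefore
  map to different keys; this is a known limitation of the package, and the
  reason the overlap counts of any real-data join should be treated as
  approximate.
* Stereochemistry is retained throughout (canonical isomeric SMILES), so
  stereo-annotated duplicates only collapse when their annotations agree.

## Labels and dataset assembly

`binarize_concern()` maps most/less to 1, no to 0, and excludes ambiguous
compounds. `collapse_duplicates()` keeps one record per key; a compound is
toxic if *any* duplicate record is toxic, and the representative SMILES is
the first in sorted order. `enrich_with_sider()` builds the four dataset
variants (base; plus adverse-event toxic compounds; plus nontoxic; plus
all); on a label conflict the concern-derived label always wins.
`concordance()` reports percent agreement and the F1 of the adverse-event
labels treated as predictions of the concern-derived truth. Absence of an
adverse-event report is treated as label 0 for modeling; the `source`
column preserves the evidential asymmetry.

## Feature spaces

* **Structure**: extended-connectivity fingerprints of radius 2 (ECFP4).
  Open Babel produces 4096-bit vectors; they are folded to the 2048-bit
  contract by OR-ing the two halves, which preserves the "bit set means
  substructure environment present" reading.
* **Physicochemical**: a 2-D descriptor panel (molecular weight, logP,
  molar refractivity, TPSA, H-bond donors/acceptors, plus SMARTS-derived
  atom/bond/ring/charge counts). Columns that fail to compute on any
  compound are dropped dataset-wide; any residual non-finite value is
  clipped to the column's finite extremes — a deterministic rule that keeps
  the matrix finite without imputing implausible values. The same engine
  backs the "interpretable" descriptor view used by the statistics module.
* **Annotations** (mechanism-of-action, targets): one-hot over the sorted
  vocabulary, absence encoded as 0, then variance-filtered at population
  variance > 0.001 — for a binary column this removes features present in
  fewer than ~1 per 1000 compounds.
* **Cmax**: peak plasma concentration enters the models as log10
  micromolar, the pharmacology convention for quantities spanning orders of
  magnitude.
* **Omics profiles**: replicate profiles are aggregated by elementwise
  median per compound. Compounds without a measured profile borrow one by
  v-NN imputation: the elementwise median over all library compounds with
  Tanimoto similarity strictly above 0.70 (structure-space fingerprints),
  excluding any held-out compound from the neighbor pool so no test
  information leaks into training features. The neighbor count v varies per
  query — compounds with no qualifying neighbor are dropped rather than
  imputed from dissimilar chemistry.

## Association statistics

Feature ranking follows the column type: columns with at most two distinct
finite values take the Pearson chi-squared path (no continuity correction);
continuous columns take Kruskal–Wallis across the three concern categories,
or the two-sided Mann–Whitney U test for binary contrasts. The most-vs-no
pairwise contrast applies a Bonferroni factor of 3 (the three pairwise
concern contrasts). Multiplicity across features is reported, not
corrected — the ranking is exploratory. Mann–Whitney uses exact enumeration
for samples of at most 8 without ties and the mid-rank normal approximation
otherwise. Constant features are skipped with a message rather than
reported at p = 1, so the ranking never contains untestable columns.

## Structural-alert mining

Fragments are generated by recursively cleaving acyclic single bonds
(graph bridges of bond order 1); rings are never opened. Every connected
fragment with 2–18 heavy atoms is converted to canonical SMILES and used as
a SMARTS pattern; because open valences become implicit hydrogens, which
SMARTS treats as unconstrained, every fragment matches its parent and any
molecule that embeds it. An exhaustive bond-cut enumerator (identical
output, exponential cost) serves as the oracle for small molecules in the
tests.

Mining pools fragments from either all compounds or toxic compounds only,
counts per-compound occurrences over the full dataset (a compound counts
once however many times a pattern matches it), and retains fragments with
at least 5 occurrences. PPV = positives/occurrences. The merge step unions
the two settings (higher-occurrence record wins on collision) and applies
the filters: PPV below 0.5 dropped, fragments of four or fewer atoms
dropped, generic scaffolds (benzene by default) blocklisted. The
"minimize false negatives" adjustment is exposed as the `min_ppv`
parameter for the caller to sweep. Occurrence counting is accelerated by an
FP2 path-fingerprint prescreen — a pattern is SMARTS-verified only against
molecules whose fingerprint contains all the pattern's path bits, a
necessary condition for substructure embedding — and the tests verify the
accelerated counts equal the exact ones.

## Models

Each feature space gets a Random-Forest classifier (`ranger`). The
hyperparameter grid — trees {100, 300, 500}, depth {unlimited, 10, 20},
minimum node size {2, 5, 10}, mtry {sqrt, log2} — is searched by successive
halving: 8 seeded random configurations scored by stratified
cross-validated AUC-ROC on growing stratified data fractions (1/4, 1/2,
full), keeping the better half at each rung. The minority class is randomly
oversampled to parity with replacement *inside training folds only*, so
validation folds never contain duplicated rows. The winning configuration
is refit per fold to produce out-of-fold probabilities for every training
compound; the decision threshold maximizes Youden's J = TPR − FPR over all
distinct out-of-fold scores (prediction is positive at score ≥ threshold;
J-ties break toward the larger, more conservative cut); the final model is
refit on the full training set with the same oversampling.

Evaluation reports balanced accuracy, sensitivity, specificity, F1, MCC,
AUC-ROC (rank-based, equivalent to the tie-corrected trapezoidal area) and
AUCPR as average precision with tied scores grouped — under which a
constant classifier scores exactly the positive prevalence, the baseline
all models are judged against.

The soft-voting ensemble rescales each member's probability so its own
threshold maps to 0.5 (piecewise-linear on [0, t] and [t, 1]) and averages
the rescaled scores; a compound is toxic at ensemble score ≥ 0.5. The
rescaling is this package's reading of "probabilities scaled according to
the best threshold of each model": it makes members with different
operating points commensurable, and a single-member ensemble reproduces
that member's predictions exactly.

The applicability-domain report assigns each held-out compound the maximum
Tanimoto similarity to a *same-label* training compound and bins the test
set into five intervals ([0, 0.2), ..., [0.8, 1.0]), reporting per-bin n,
balanced accuracy at the model threshold, and AUCPR (NA for single-class
bins).

## The synthetic study

The generator emulates the statistical structure the analysis assumes,
with defaults chosen once as the study conditions:

* 1020 compounds with concern proportions 299:443:278 (most:less:no), the
  class balance of the real concern-ranked dataset, hence 742 toxic vs 278
  nontoxic after binarization.
* Molecules are assembled from a fixed ~50-block vocabulary of valid SMILES
  fragments (alkyl/ether/amine/carbonyl linkers; aromatic, halogen, nitro,
  sulfonamide terminals), each block closing its own rings so plain
  concatenation is valid; all compounds are standardized and de-duplicated
  by key at generation.
* The planted toxicophore is thiophene (`c1cccs1`) — five heavy atoms, so
  it survives the ≤4-atom alert filter, and the only aromatic sulfur in the
  vocabulary, so it cannot arise by accident. Toxic compounds carry it with
  probability 0.9 (label noise 0.1, a moderate annotation-noise rate);
  nontoxic compounds with probability 0.1.
* Cmax is lognormal with a one-log10-unit class shift (sd 1.0 log unit),
  enough for the exposure contrast to be decisively detectable at n ≈ 500.
* Annotations are sparse Bernoulli sets (base rate 0.05 over 30 terms) with
  an odds multiplier of 4 on five designated mechanism terms among toxic
  compounds.
* Omics profiles are standard Gaussian with a +1.0 SD shift on 10 of 100
  features for toxic compounds; 15% of compounds carry no profile, so v-NN
  imputation is always exercised.

What the generator does *not* emulate: realistic pharmacology, correlated
descriptors, activity cliffs, assay batch effects, or the scale of real
fingerprint space. Passing tests demonstrate that the machinery recovers
known planted structure under honest noise — not that the models would
reach any particular accuracy on real regulatory data.

## Numerical choices and degenerate inputs

* Tanimoto of two all-zero fingerprints is defined as 0.
* Youden with constant scores returns the constant with a warning (J = 0
  everywhere).
* Chi-squared errors on empty table margins, naming the degenerate margin;
  Kruskal–Wallis on fewer than three groups directs the caller to the
  Mann–Whitney path; all-tied samples return H = 0, p = 1.
* MCC with a zero denominator is reported as 0; F1 with no positive
  predictions and no positives is 0.
* Single-class evaluation returns NA for both AUC metrics and computes the
  thresholded metrics for the class present.
* All randomness is routed through explicit integer seeds (folds,
  candidate sampling, forests, generators); reruns are bit-identical, which
  the pipeline manifest hash attests.

## Problem sizes

The shipped analysis scripts and the acceptance script run the default
1020-compound study; unit tests use 40–300-compound fixtures. Alert mining
on the full study takes on the order of a minute on one core, model
training tens of seconds; the five-seed recovery check is the slowest
test at a few minutes.

## Known limitations

* Tautomer normalization is rule-based, not a canonicalizer; InChI keys of
  exotic tautomers may not collapse.
* The physicochemical panel is ~30 descriptors, not the thousand-plus of
  specialized descriptor engines; it is sufficient for the pipeline's
  statistics and modeling contracts but not a drop-in replacement for a
  full descriptor set.
* Fragment enumeration is exponential in the number of acyclic single
  bonds and is intended for drug-sized molecules (the exhaustive oracle is
  capped at 20 cleavable bonds).
* The mined alert list depends on the SMARTS dialect of the underlying
  engine; patterns are canonical SMILES, which underconstrains hydrogen
  counts by design.
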