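# dictox

Drug-induced cardiotoxicity (DICT) — arrhythmia, QT prolongation,
myocardial injury — is a leading reason drugs are withdrawn from the
market. Regulatory reviews grade drugs into *most*, *less*, *no* or
*ambiguous* concern categories, while pharmacovigilance databases record
binary "cardiac disorders" adverse-event labels. `dictox` is an R package
for analysts who want to model these labels from chemical structure and
auxiliary biological data. It implements the complete workflow:

* **Standardization** — iterative SMILES cleanup (largest organic
  fragment, neutralization, representation normalization, canonical
  SMILES) with a single protonation step at pH 7.4; the standard InChI of
  the result is the join key everywhere.
* **Label assembly** — concern categories binarized (most/less → 1,
  no → 0, ambiguous excluded), any-toxic duplicate collapse, enrichment
  with adverse-event compounds (concern labels win conflicts), and
  concordance/F1 between label sources.
* **Feature spaces** — 2048-bit ECFP4 fingerprints, a 2-D
  physicochemical descriptor panel, one-hot annotations with a 0.001
  variance filter, log10 Cmax, median-aggregated omics profiles, and
  v-NN imputation: a missing profile is the elementwise median over all
  training compounds with Tanimoto similarity > 0.70 (held-out compounds
  are barred from the neighbor pool).
* **Association statistics** — chi-squared for categorical features,
  Kruskal–Wallis across the three concern groups, two-sided Mann–Whitney U
  for binary contrasts with Bonferroni correction over the three pairwise
  concern contrasts; features ranked by p-value.
* **Structural alerts** — recursive fragmentation over acyclic single
  bonds (rings intact, 2–18 heavy atoms), per-compound occurrence and PPV
  counting under two mining settings, merge + filters (PPV ≥ 0.5, > 4
  atoms, benzene blocklisted), and alert screening of external compound
  sets with leak-avoiding key exclusion.
* **Models** — per-feature-space Random Forests tuned by successive-halving
  random search under stratified 5-fold CV with in-fold minority
  oversampling; the decision threshold maximizes Youden's J = TPR − FPR on
  out-of-fold scores; evaluation reports balanced accuracy, sensitivity,
  specificity, F1, MCC, AUC-ROC and AUCPR (average precision, so a
  constant classifier scores exactly the positive prevalence);
  threshold-rescaled soft-voting ensembles; applicability-domain reports
  over five nearest-same-label-neighbor Tanimoto similarity bins.
* **Synthetic studies** — a generator that assembles valid molecules from
  a fragment vocabulary with a planted thiophene toxicophore, the
  299:443:278 concern balance, class-shifted lognormal Cmax, enriched
  annotations and shifted omics features, so the whole pipeline runs and
  is verified offline.

Chemistry is computed with Open Babel through ChemmineR/ChemmineOB;
forests with `ranger`.

## Worked example

```r
library(dictox)

cfg  <- synthetic_study_config(n_compounds = 300, seed = 7)
comp <- generate_compounds(cfg)
table(comp$concern)
#> less most   no
#>  118   95   87

# mine structural alerts and look for the planted thiophene toxicophore
alerts <- filter_and_merge(mine_alerts(comp, min_occurrence = 5))
alerts[alerts$pattern == "c1cccs1", c("pattern", "occurrences", "ppv")]
#>   pattern occurrences       ppv
#> 1 c1cccs1         199 0.9698492

# train a structure-space model and evaluate its out-of-fold scores
fp <- structural_fingerprint(comp$std_smiles, keys = comp$key)
m  <- cv_train(fp, comp[, c("key", "label")], seed = 7)
ev <- evaluate_predictions(m$oof_scores, m$oof_labels, m$threshold)
round(unlist(ev[c("balanced_accuracy", "auc_roc", "auc_pr", "prevalence")]), 3)
#> balanced_accuracy           auc_roc            auc_pr        prevalence
#>             0.919             0.901             0.945             0.710
```

The toxicophore is recovered with high positive predictive value (97% of
the compounds containing it are toxic — the planted rate is 90% carriage
among toxic compounds with 10% label noise), and the fingerprint model
clears the prevalence baseline (0.710, what a constant classifier would
score in AUCPR) by a wide margin on out-of-fold data.

The numbered scripts under `analysis/` run the same workflow at full study
size (n = 1020) end to end — simulation, label assembly, feature
statistics, alert mining, models/ensemble/applicability domain — writing
their tables under `results/`.

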