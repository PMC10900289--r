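#!/usr/bin/env Rscript
# Stage 2: label assembly and concordance.
#
# Binarizes concern categories, collapses duplicates, builds the four
# dataset variants (base; +adverse-event toxic; +nontoxic; +all), and
# quantifies label concordance between the concern-derived labels and the
# synthetic adverse-event labels.

suppressMessages(library(dictox))
comp <- read.csv("results/compounds.csv", stringsAsFactors = FALSE)
seed <- 1L

dict <- collapse_duplicates(comp[!is.na(comp$label),
                                 c("key", "std_smiles", "concern", "label")])

# synthetic adverse-event dataset: a 60% overlapping subset with 10% label
# flips plus a handful of novel compounds (mirrors run_pipeline's assembly)
set.seed(seed + 104729L)
overlap <- dict[sample.int(nrow(dict), floor(0.6 * nrow(dict))), ]
flip <- runif(nrow(overlap)) < 0.1
sider <- data.frame(key = overlap$key, std_smiles = overlap$std_smiles,
                    concern = "unknown",
                    label = ifelse(flip, 1L - overlap$label, overlap$label))
extra <- dictox:::generate_unique_pool(50L, FALSE, "c1cccs1")
extra <- extra[!extra$std_inchi %in% dict$key, , drop = FALSE]
sider <- rbind(sider, data.frame(key = extra$std_inchi,
                                 std_smiles = extra$std_smiles,
                                 concern = "unknown",
                                 label = rep_len(c(1L, 0L), nrow(extra))))

conc <- concordance(dict, sider)
cat(sprintf("overlap %d compounds: %.2f%% concordant, F1 = %.3f\n",
            conc$n_overlap, conc$percent_concordant,
            conc$f1_of_sider_vs_dictrank))

variants <- list(
  dictrank = { d <- dict; d$source <- "DICTrank"; d },
  plus_sider_toxic = enrich_with_sider(dict, sider, "toxic_only"),
  plus_sider_nontoxic = enrich_with_sider(dict, sider, "nontoxic_only"),
  plus_sider_all = enrich_with_sider(dict, sider, "all"))
sizes <- data.frame(variant = names(variants),
                    n = vapply(variants, nrow, 1L),
                    n_toxic = vapply(variants, function(d) sum(d$label == 1L), 1L))
print(sizes)
write.csv(sizes, "results/dataset_variants.csv", row.names = FALSE)
write.csv(variants$dictrank, "results/dataset.csv", row.names = FALSE)
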