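#!/usr/bin/env Rscript
# Stage 1: simulate the default synthetic cardiotoxicity study.
#
# Generates 1020 unique standardized compounds with a 299:443:278
# most:less:no concern balance, a planted thiophene toxicophore (10% label
# noise), class-shifted Cmax, sparse annotations and omics profiles with a
# 15% missing fraction, and writes the study tables under results/.

suppressMessages(library(dictox))
dir.create("results", showWarnings = FALSE)
seed <- 1L

cfg <- synthetic_study_config(seed = seed)
comp <- generate_compounds(cfg)
aux <- generate_auxiliary(cfg, comp)

write.csv(comp, "results/compounds.csv", row.names = FALSE)
write.csv(aux$cmax, "results/cmax.csv", row.names = FALSE)
write.csv(data.frame(key = names(aux$annotations),
                     terms = vapply(aux$annotations, paste, "", collapse = ";")),
          "results/annotations.csv", row.names = FALSE)
write.csv(data.frame(key = rownames(aux$omics), aux$omics),
          "results/omics_profiles.csv", row.names = FALSE)

cat(sprintf("simulated %d compounds (%.0f%% toxic); %d with omics profiles, %d missing\n",
            nrow(comp), 100 * mean(comp$label),
            nrow(aux$omics), length(aux$missing_keys)))
print(table(comp$concern))
cat(sprintf("toxicophore carriage: %.2f among toxic, %.2f among nontoxic\n",
            mean(comp$has_toxicophore[comp$label == 1]),
            mean(comp$has_toxicophore[comp$label == 0])))
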