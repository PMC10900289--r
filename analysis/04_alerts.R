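#!/usr/bin/env Rscript
# Stage 4: structural-alert mining.
#
# Mines substructure alerts under both settings (all compounds; toxic
# only), merges and filters them (PPV >= 0.5, > 4 atoms, benzene
# blocklisted), reports whether the planted toxicophore is recovered, and
# shows the reporting view (occurrences > 10, PPV > 0.6).

suppressMessages(library(dictox))
comp <- read.csv("results/compounds.csv", stringsAsFactors = FALSE)
cfg <- synthetic_study_config(seed = 1L)

mined <- mine_alerts(comp, min_occurrence = 5L,
                     setting = c("all_compounds", "toxic_only"))
merged <- filter_and_merge(mined)
write.csv(merged, "results/alerts.csv", row.names = FALSE)

toxicophore <- dictox:::ob_convert(cfg$toxicophore_smarts, to = "CAN")
hit <- merged[merged$pattern == toxicophore, ]
cat(sprintf("%d alerts after merge/filter; planted toxicophore %s: %s (PPV %.3f, %d occurrences)\n",
            nrow(merged), toxicophore,
            if (nrow(hit)) "recovered" else "NOT recovered",
            if (nrow(hit)) hit$ppv else NA, if (nrow(hit)) hit$occurrences else 0L))

view <- merged[merged$occurrences > 10 & merged$ppv > 0.6, ]
view <- view[order(-view$ppv, -view$occurrences), ]
cat("reporting view (occurrences > 10, PPV > 0.6), top entries:\n")
print(head(view[, c("pattern", "n_atoms", "occurrences", "ppv")], 10))
write.csv(view, "results/alerts_reporting_view.csv", row.names = FALSE)
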