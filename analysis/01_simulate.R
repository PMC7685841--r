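#!/usr/bin/env Rscript
# Simulate the pan-cancer study cohort.
#
# Generates the default synthetic cohort: 13 cancer types carrying the
# 55-subtype molecular layout with planted MHC archetypes (27 low /
# 20 intermediate / 8 high), 20 tumors per subtype and 10 normals per type,
# a 162-gene immunomodulator panel (105 CAG / 25 immunoinhibitor / 32 MHC),
# methylation betas as cell-type mixtures, and nonsilent mutation tables.
# Writes the TSV file set consumed by the downstream steps.

library(mhcprofiler)

seed <- 1L
out <- "results/cohort"

cfg <- cohort_config(seed = derive_seed(seed, "simulate"))
cohort <- generate_cohort(cfg)
write_cohort(cohort, out)

print(cohort)
comp <- table(cfg$mhc_composition$archetype)
cat(sprintf("planted archetypes: %s\n",
            paste(names(comp), comp, sep = "=", collapse = ", ")))
cat(sprintf("panel: %d genes (%s)\n", nrow(cohort$panel),
            paste(names(table(cohort$panel$class)),
                  table(cohort$panel$class), sep = "=", collapse = ", ")))
cat(sprintf("mutation records: %d\n", nrow(cohort$mutations)))
cat(sprintf("cohort written to %s\n", out))
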