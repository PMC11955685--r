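#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Writes a complete synthetic cohort to results/cohort/: region table,
# per-subject cortical connectomes and subcortical-cortical connectivity,
# cohort manifest (group, age, sex), a regions x genes expression matrix
# whose signal genes track the injected effect topology, and a
# ground-truth JSON recording everything injected. The defaults are the
# reference study conditions: 100 cortical regions in 7 networks, 25
# subjects per group, a within-network connectivity increase of 40% in the
# patient group confined to the somatomotor (Smn) network, and 500 genes
# of which 20 are signal genes.

library(conngrad)

seed <- 1L
out <- "results/cohort"

params <- sim_params(seed = seed)
cohort <- simulate_cohort(params, out_dir = out)

cat("cohort written to", out, "\n")
cat(sprintf("  %d subjects (%d control / %d patient)\n",
            nrow(cohort$manifest),
            sum(cohort$manifest$group == "control"),
            sum(cohort$manifest$group == "patient")))
cat(sprintf("  %d cortical regions, %d subcortical structures\n",
            sum(cohort$region_table$is_cortical),
            sum(!cohort$region_table$is_cortical)))
cat(sprintf("  injected effect: %s network, %+.0f%% within-network connectivity\n",
            paste(params$effect_networks, collapse = ","),
            100 * params$effect_size))
cat(sprintf("  expression: %d genes, %d signal genes\n",
            params$n_genes, params$n_signal_genes))
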