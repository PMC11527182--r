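#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Generates a synthetic cohort emulating the structure of the real screen:
# 2158 samples, a seed probe, 20 planted seed-correlated genes on both signs,
# 200 background genes, skewed contaminant probes, duplicate probes, and
# annotation defects; plus a disease library (3 planted disorders with causal
# genes and planted novel genes + 20 decoys), an ontology library with
# causal/novel co-membership terms, and the causal-gene map.

library(seedcor)

rng_seed <- 20260919L
out_dir <- "results/synthetic_study"

cfg <- synthetic_config(rng_seed = rng_seed)
sim <- simulate_study(cfg, out_dir, decoys = 20)

truth <- sim$truth
cat(sprintf("wrote %d probe x %d sample expression matrix and libraries to %s\n",
            nrow(sim$matrix), ncol(sim$matrix), out_dir))
cat(sprintf("planted disorders: %s\n",
            paste(names(truth$planted_disorders), collapse = ", ")))
cat(sprintf("planted novel genes: %s\n",
            paste(unlist(truth$planted_novel), collapse = ", ")))
cat(sprintf("contaminant probes: %d, duplicate genes: %d\n",
            length(truth$contaminant_probes), length(truth$duplicate_groups)))
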