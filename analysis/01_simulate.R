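#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic input bundle.
#
# The generator emulates the structure the downstream stages assume:
# capture regions around risk signals, multi-exonic low-expression gene
# models with decoy protein-coding genes, risk signals whose CCVs carry a
# 3x exonic placement enrichment, chromatin loops joining promoters to
# CCV-bearing fragments, expression with additive genotype + copy-number
# effects, a 7-tissue panel, and paired ERCC spike-in tables.

source("analysis/00_config.R")

cfg <- analysis_sim_config()
bundle <- simulate_bundle(cfg, INPUT_DIR)

man <- bundle$manifest
cat(sprintf("wrote input bundle to %s\n", INPUT_DIR))
cat(sprintf("  regions: %d x %s bp\n", cfg$n_regions,
            format(cfg$region_length, big.mark = ",")))
cat(sprintf("  genes: %d (%d mencRNA, %d coding decoys)\n",
            nrow(man$genes), sum(man$genes$biotype == "mencRNA"),
            sum(man$genes$biotype == "protein_coding")))
cat(sprintf("  signals: %d, planted CCVs: %d\n",
            length(man$planted_ccvs),
            sum(lengths(man$planted_ccvs))))
cat(sprintf("  loops: %d (implying %d gene-signal loop links), planted eQTL genes: %d\n",
            nrow(bundle$loops$loops), nrow(man$loop_links), nrow(man$eqtl)))
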