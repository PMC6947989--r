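#!/usr/bin/env Rscript
# Stage 2 — transcript filtering and CCV derivation.
#
# Candidate captured transcripts are filtered by the annotation rules
# (multi-exonic, inside the capture universe, no same-strand coding
# overlap, max FPKM >= 0.5); each signal's credible causal variants are
# the variants with association p within two orders of magnitude of the
# lead.

source("analysis/00_config.R")
inp <- load_core_inputs()

g <- as.data.frame(inp$genes)
cand <- gene_models(g[g$biotype != "protein_coding", , drop = FALSE])
coding <- gene_models(g[g$biotype == "protein_coding", , drop = FALSE])
filt <- filter_transcripts(cand, inp$gene_fpkm, inp$universe, coding)

write_gtf(filt$genes, file.path(OUT_DIR, "filtered_genes.gtf"))
write_tsv(filt$removed, file.path(OUT_DIR, "removed_transcripts.tsv"))
cat(sprintf("retained %d / %d candidate mencRNA genes (%d removed)\n",
            length(unique(filt$genes$gene_id)),
            length(unique(cand$gene_id)), nrow(filt$removed)))

ccvs <- derive_ccvs(inp$signals)
write_ccv_bed(ccvs, file.path(OUT_DIR, "ccvs.bed"))
per_sig <- table(ccvs$signal_id)
cat(sprintf("CCVs: %d across %d signals (median %s per signal)\n",
            nrow(ccvs), length(per_sig), median(per_sig)))
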