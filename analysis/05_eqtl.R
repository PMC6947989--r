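#!/usr/bin/env Rscript
# Stage 5 — cis-eQTL scan with copy-number adjustment.
#
# Every (gene, variant) pair sharing a capture region is tested by OLS of
# expression on additive dosage plus the gene's copy-number covariate;
# discoveries at BH q < 0.05; per-gene eQTL/risk-signal overlap by the
# two-orders rule on eQTL p-values.

source("analysis/00_config.R")
p <- bundle_paths()
genes <- read_gtf(file.path(OUT_DIR, "filtered_genes.gtf"))
inp <- load_core_inputs()
expr <- read_matrix_tsv(p[["expression"]])
geno <- read_matrix_tsv(p[["genotypes"]])
cn <- read_matrix_tsv(p[["copy_number"]])
ccvs <- derive_ccvs(inp$signals)

tests <- cis_pairs(genes, as.data.frame(inp$signals), inp$universe)
tests <- tests[tests$gene_id %in% rownames(expr), , drop = FALSE]
res <- fit_eqtl(geno, expr, tests, copy_number = cn)
write_tsv(as.data.frame(res), file.path(OUT_DIR, "eqtl.tsv"))

sig_genes <- unique(res$gene_id[res$q < 0.05])
cat(sprintf("%d tests across %d genes; %d gene(s) with an eQTL at FDR 5%%\n",
            nrow(res), length(unique(res$gene_id)), length(sig_genes)))

overlap <- do.call(rbind, lapply(sig_genes, function(g) {
  ov <- eqtl_signal_overlap(res[res$gene_id == g, , drop = FALSE], ccvs)
  data.frame(gene_id = g, overlaps_signal = ov$overlaps,
             top_variant = ov$top_variant, best_ccv = ov$best_ccv,
             stringsAsFactors = FALSE)
}))
if (!is.null(overlap)) {
  write_tsv(overlap, file.path(OUT_DIR, "eqtl_signal_overlap.tsv"))
  cat(sprintf("%d of %d eQTL gene(s) overlap a risk signal (top-SNP two-orders rule)\n",
              sum(overlap$overlaps_signal), nrow(overlap)))
}

## how many planted effects were recovered
man <- jsonlite::read_json(p[["manifest"]], simplifyVector = TRUE)
if (length(man$eqtl) && nrow(as.data.frame(man$eqtl))) {
  planted <- as.data.frame(man$eqtl)
  key <- paste(res$gene_id, res$variant_id)
  q_planted <- res$q[match(paste(planted$gene_id, planted$variant_id), key)]
  cat(sprintf("planted eQTLs recovered at q < 0.05: %d / %d\n",
              sum(q_planted < 0.05, na.rm = TRUE), nrow(planted)))
}
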