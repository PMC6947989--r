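#!/usr/bin/env Rscript
# Stage 4 — CCV-to-gene linkage and multi-signal targets.
#
# Three evidence routes: CCV in a mencRNA exon, in its promoter
# (TSS +/- 500 bp), or in one anchor of a chromatin loop whose other
# anchor overlaps the promoter. Genes linked to two or more independent
# signals are the multi-signal targets.

source("analysis/00_config.R")
genes <- read_gtf(file.path(OUT_DIR, "filtered_genes.gtf"))
bed <- read_bed(file.path(OUT_DIR, "ccvs.bed"))
ccvs <- data.frame(variant_id = sub(".*:", "", bed$name),
                   signal_id = sub(":.*", "", bed$name),
                   chrom = bed$chrom, pos = bed$start)
loops <- read_bedpe(bundle_paths()[["loops"]])

records <- rbind(link_exonic(ccvs, genes),
                 link_promoter(ccvs, genes, "flank500"),
                 link_loops(ccvs, genes, loops, "flank500"))
write_tsv(records, file.path(OUT_DIR, "linkage.tsv"))

by_route <- table(records$route)
cat("linkage records by route:\n")
print(by_route)

multi <- multi_signal_targets(records)
write_tsv(multi, file.path(OUT_DIR, "multi_signal_targets.tsv"))
cat(sprintf("\n%d gene(s) are linked to >= 2 independent signals\n",
            nrow(multi)))
if (nrow(multi)) print(utils::head(multi))
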