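#!/usr/bin/env Rscript
# Stage 6 — tissue specificity and looped-pair co-expression.
#
# Tau on the 7-tissue panel (0 = broad, 1 = single-tissue); then the
# comparison of |r| between mencRNA/protein-coding pairs within 1 Mb that
# are vs are not joined by a promoter-promoter chromatin loop.

source("analysis/00_config.R")
p <- bundle_paths()

panel <- read_matrix_tsv(p[["tissue_panel"]])
tt <- tau_panel(panel)
write_tsv(tt, file.path(OUT_DIR, "tau.tsv"))
cat(sprintf("tau computed for %d genes: median %.2f (IQR %.2f-%.2f)\n",
            nrow(tt), median(tt$tau, na.rm = TRUE),
            quantile(tt$tau, 0.25, na.rm = TRUE),
            quantile(tt$tau, 0.75, na.rm = TRUE)))

genes <- read_gtf(p[["genes"]])
expr <- read_matrix_tsv(p[["expression"]])
loops <- read_bedpe(p[["loops"]])
co <- looped_pair_test(pmax(2^expr - 1, 0), genes, loops,
                       window = 1e6, apply_filter = FALSE)
if (!is.null(co$pairs))
  write_tsv(co$pairs, file.path(OUT_DIR, "coexpression_pairs.tsv"))
write_tsv(data.frame(statistic = co$statistic, p = co$p,
                     n_looped = co$n_looped, n_nonlooped = co$n_nonlooped),
          file.path(OUT_DIR, "coexpression_test.tsv"))
cat(sprintf("looped pairs: %d, non-looped: %d; Mann-Whitney p = %.3g\n",
            co$n_looped, co$n_nonlooped, co$p))
cat(sprintf("median |r|: looped %.2f vs non-looped %.2f\n",
            median(abs(co$pairs$r[co$pairs$looped])),
            median(abs(co$pairs$r[!co$pairs$looped]))))
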