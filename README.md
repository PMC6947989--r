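# menclink

Linking fine-mapped breast-cancer risk variants to multi-exonic
non-coding RNAs (mencRNAs).

GWAS fine-mapping summarises each independent risk signal by its credible
causal variants (CCVs) — the variants with association p-values within two
orders of magnitude of the signal's lead. Targeted RNA capture around the
1.5-Mb windows surrounding risk signals reveals thousands of low-abundance
multi-exonic non-coding RNA genes. `menclink` implements the computational
analysis that connects the two: are CCVs enriched in mencRNA features, and
which mencRNAs are candidate target genes of which signals? It is written
for analysts working with capture-region interval data (BED), transcript
models (GTF), per-signal association tables (TSV), chromatin loops
(BEDPE), and expression/genotype matrices.

## What it computes

* **Transcript filtering** — the mencRNA annotation rules: multi-exonic,
  inside the capture universe, no same-strand coding-exon overlap, max
  FPKM ≥ 0.5 (isoforms ≥ 0.01), with per-removal reason codes; plus
  captured/reference annotation merging with the opposite-strand
  exclusion for unstranded external RNA-seq.
* **CCV enrichment** — for feature coverage fraction *c* and *k* of *n*
  CCVs overlapping: fold = (k/n)/c; a bp-unit hypergeometric upper-tail
  test; and the headline circular permutation null, in which every
  transcript's features rotate by a uniform offset around their
  circularized capture region (sizes and intra-transcript spacing
  preserved, CCVs fixed), with empirical p = #{overlap ≥ observed}/n over
  10^5 permutations and a normal-approximation 95% CI of the expected
  overlap.
* **Linkage** — three evidence routes per (gene, signal): CCV in exon, in
  promoter (TSS ± 500 bp), or in one anchor of a chromatin loop whose
  other anchor overlaps the promoter; genes supported by ≥ 2 independent
  signals are multi-signal targets.
* **cis-eQTL** — log2 + quantile normalization, OLS of expression on
  additive dosage with per-gene copy-number adjustment within each
  capture region, Benjamini–Hochberg FDR at 5%, and the top-eQTL
  two-orders signal-overlap rule.
* **Expression metrics** — tissue-specificity tau
  (τ = Σ(1 − x_i/x_max)/(N − 1) on log2 data) and the looped vs
  non-looped mencRNA–mRNA |correlation| comparison (pairs within 1 Mb,
  Mann–Whitney).
* **Capture QC** — ERCC dose–response fits (log2 FPKM vs log2
  concentration), lower/upper limits of detection at FPKM 0.5, capture
  fold enrichment from the fitted lines, and the paired t-test of
  targeted vs non-targeted gene fold changes.
* **Synthetic data** — seeded generators for every input, with ground-truth
  manifests, so the whole pipeline is testable offline.

## Worked example

The numbered drivers under `analysis/` run the full workflow on a
synthetic bundle with a planted 3× exonic CCV enrichment and planted
eQTLs (seed 2026, 6 regions × 300 kb):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/03_enrichment.R   # after 02_filter_annotate.R
```

prints, among other stages:

```
enrichment_result [exon]: observed 8 / 96 CCVs; expected 2.33 (95% CI 2.30-2.35)
  fold 3.43; empirical p 0.0033 (n = 10000, seed 2026); hypergeometric p 0.00244
enrichment_result [intron]: observed 16 / 96 CCVs; expected 17.21 (95% CI 17.14-17.29)
  fold 0.86; empirical p 0.675 (n = 10000, seed 2026); hypergeometric p 0.786
```

Read: 8 of 96 CCVs fall in mencRNA exons where the rotation null expects
2.33, a 3.4-fold enrichment the permutation test rejects at p ≈ 0.003 —
recovering the planted 3× placement bias — while introns show no
enrichment (fold 0.86, p 0.68), as constructed. Later stages report the
planted eQTLs recovered at FDR 5% (9/9 in this bundle), the looped-pair
co-expression contrast (median |r| 0.53 vs 0.03, p 7 × 10⁻⁴), and the
ERCC capture QC (fold enrichment 300, LLD ratio ≈ 336×).

`run_end_to_end()` runs the same stages in one call from a `run_config()`;
outputs are TSV/BED/GTF tables plus a JSON run manifest.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

generates a fresh synthetic bundle from the seed, runs every pipeline
stage end-to-end against the installed package (filtering, CCVs,
enrichment with 10^4 permutations, linkage, eQTL, tau, co-expression,
capture QC), and writes the acceptance JSON to `--out`.

## Layout

```
R/                  package code (intervals, gene models, enrichment,
                    linkage, eqtl, metrics, capture QC, simulators, pipeline)
src/                circular-permutation kernel (Rcpp)
analysis/           numbered workflow drivers writing results/analysis/
scripts/acceptance.R
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette
```
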