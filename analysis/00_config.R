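# Shared settings for the analysis drivers. Run the scripts in order from
# the repository root:  Rscript analysis/01_simulate.R  etc.
# All computation lives in the menclink package; these drivers only wire
# stages together and write tables under results/analysis/.

suppressPackageStartupMessages(library(menclink))

ANALYSIS_SEED <- 2026
INPUT_DIR <- "results/analysis/inputs"
OUT_DIR <- "results/analysis"

# a compact instance of the stated world: 1.5-Mb capture regions are the
# real scale; 6 x 300 kb keeps every driver under a minute while preserving
# the regional structure (signals, genes and loops per region)
analysis_sim_config <- function() {
  sim_config(seed = ANALYSIS_SEED, n_regions = 6, region_length = 3e5,
             genes_per_region = 5, coding_per_region = 2,
             ccvs_per_signal = 8, ccv_exon_enrichment = 3,
             n_loops = 40, eqtl_beta = 0.8, eqtl_gene_fraction = 0.3,
             n_samples = 500)
}

bundle_paths <- function() {
  files <- c(universe = "universe.bed", genes = "genes.gtf",
             gene_fpkm = "gene_fpkm.tsv", variants = "variants.tsv",
             loops = "loops.bedpe", expression = "expression.tsv",
             genotypes = "genotypes.tsv", copy_number = "copy_number.tsv",
             tissue_panel = "tissue_panel.tsv",
             ercc_captured = "ercc_captured.tsv",
             ercc_noncaptured = "ercc_noncaptured.tsv",
             manifest = "manifest.json")
  stats::setNames(file.path(INPUT_DIR, files), names(files))
}

load_core_inputs <- function() {
  p <- bundle_paths()
  fpkm_tab <- read_tsv(p[["gene_fpkm"]])
  list(universe = capture_universe(read_bed(p[["universe"]])),
       genes = read_gtf(p[["genes"]]),
       gene_fpkm = stats::setNames(fpkm_tab$max_fpkm, fpkm_tab$gene_id),
       signals = read_variants(p[["variants"]]))
}
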