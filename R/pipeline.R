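#' Run configuration for the end-to-end pipeline
#'
#' Paths to the input bundle plus stage toggles and thresholds. Every
#' threshold default is the value used in the headline analysis
#' (gene FPKM 0.5, isoform FPKM 0.01, FDR 0.05, 1-Mb correlation window,
#' 1e5 permutations).
#'
#' @param universe,genes,gene_fpkm,variants paths (required): capture BED,
#'   gene GTF, per-gene max-FPKM TSV, variant TSV.
#' @param loops,expression,genotypes,copy_number,tissue_panel,
#'   ercc_captured,ercc_noncaptured optional stage input paths; stages
#'   lacking inputs are skipped.
#' @param n_permutations permutations for the enrichment null (default 1e5;
#'   turn down for smoke tests).
#' @param seed integer seed.
#' @param enrichment_promoter_mode promoter definition for enrichment
#'   (default `"upstream500"`).
#' @param linkage_promoter_mode promoter definition for linkage (default
#'   `"flank500"`).
#' @param gene_min_fpkm,isoform_min_fpkm,fdr,correlation_window thresholds.
#' @param expression_scale `"analysis"` (matrix already log-scale) or
#'   `"fpkm"` (log2 + quantile normalize first).
#' @return list of class `run_config`.
#' @export
run_config <- function(universe, genes, gene_fpkm, variants,
                       loops = NULL, expression = NULL, genotypes = NULL,
                       copy_number = NULL, tissue_panel = NULL,
                       ercc_captured = NULL, ercc_noncaptured = NULL,
                       n_permutations = 1e5, seed = 1,
                       enrichment_promoter_mode = "upstream500",
                       linkage_promoter_mode = "flank500",
                       gene_min_fpkm = 0.5, isoform_min_fpkm = 0.01,
                       fdr = 0.05, correlation_window = 1e6,
                       expression_scale = "analysis") {
  cfg <- as.list(environment())
  for (f in c("universe", "genes", "gene_fpkm", "variants")) {
    if (!file.exists(cfg[[f]])) stop("missing required input: ", f, " (",
                                     cfg[[f]], ")")
  }
  for (f in c("loops", "expression", "genotypes", "copy_number",
              "tissue_panel", "ercc_captured", "ercc_noncaptured")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured input file does not exist: ", f, " (", cfg[[f]], ")")
  }
  stopifnot(cfg$fdr > 0, cfg$fdr < 1, cfg$gene_min_fpkm >= 0,
            cfg$correlation_window > 0)
  class(cfg) <- "run_config"
  cfg
}

stage_msg <- function(...) message("[menclink] ", ...)

#' Run the whole analysis end-to-end
#'
#' Stage order mirrors the study: load + filter annotation, derive CCVs,
#' feature enrichment (exon / intron / promoter), three-route linkage and
#' multi-signal targets, cis-eQTL scan with signal-overlap verdicts,
#' tissue-specificity and looped-pair co-expression, capture QC. Outputs
#' are written as TSV/BED under `out_dir` together with a JSON run
#' manifest (seed, thresholds, input hashes).
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @return (invisibly) named list of all stage results.
#' @export
run_end_to_end <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  o <- function(f) file.path(out_dir, f)

  stage_msg("loading inputs")
  universe <- capture_universe(read_bed(cfg$universe))
  genes_raw <- read_gtf(cfg$genes)
  fpkm_tab <- read_tsv(cfg$gene_fpkm)
  gene_fpkm <- stats::setNames(fpkm_tab$max_fpkm, fpkm_tab$gene_id)
  signals <- read_variants(cfg$variants)

  stage_msg("filtering transcripts")
  coding <- as.data.frame(genes_raw)
  coding <- gene_models(coding[coding$biotype == "protein_coding", ,
                               drop = FALSE])
  cand <- as.data.frame(genes_raw)
  cand <- gene_models(cand[cand$biotype != "protein_coding", , drop = FALSE])
  filt <- filter_transcripts(cand, gene_fpkm, universe, coding,
                             gene_min_fpkm = cfg$gene_min_fpkm,
                             isoform_min_fpkm = cfg$isoform_min_fpkm)
  genes <- filt$genes
  write_tsv(filt$removed, o("removed_transcripts.tsv"))
  write_gtf(genes, o("filtered_genes.gtf"))

  stage_msg("deriving CCVs")
  ccvs <- derive_ccvs(signals)
  write_ccv_bed(ccvs, o("ccvs.bed"))

  stage_msg("enrichment (", format(cfg$n_permutations, scientific = FALSE),
            " permutations per feature)")
  enr <- lapply(c("exon", "intron", "promoter"), function(kind)
    permutation_test(ccvs, genes, kind, universe,
                     n = cfg$n_permutations, seed = cfg$seed,
                     promoter_mode = cfg$enrichment_promoter_mode))
  enr_tab <- do.call(rbind, lapply(enr, enrichment_row))
  write_tsv(enr_tab, o("enrichment.tsv"))

  stage_msg("linkage routes")
  loops <- if (!is.null(cfg$loops)) read_bedpe(cfg$loops) else NULL
  records <- rbind(link_exonic(ccvs, genes),
                   link_promoter(ccvs, genes, cfg$linkage_promoter_mode),
                   if (!is.null(loops))
                     link_loops(ccvs, genes, loops,
                                cfg$linkage_promoter_mode))
  write_tsv(records, o("linkage.tsv"))
  multi <- multi_signal_targets(records)
  write_tsv(multi, o("multi_signal_targets.tsv"))

  eqtl_res <- NULL; overlaps <- NULL
  if (!is.null(cfg$expression) && !is.null(cfg$genotypes)) {
    stage_msg("cis-eQTL scan")
    expr <- read_matrix_tsv(cfg$expression)
    if (cfg$expression_scale == "fpkm") expr <- normalize_expression(expr)
    geno <- read_matrix_tsv(cfg$genotypes)
    cn <- if (!is.null(cfg$copy_number)) read_matrix_tsv(cfg$copy_number)
    vtab <- as.data.frame(signals)
    tests <- cis_pairs(genes, vtab, universe)
    tests <- tests[tests$gene_id %in% rownames(expr), , drop = FALSE]
    eqtl_res <- fit_eqtl(geno, expr, tests, copy_number = cn)
    write_tsv(as.data.frame(eqtl_res), o("eqtl.tsv"))
    sig_genes <- unique(eqtl_res$gene_id[eqtl_res$q < cfg$fdr])
    overlaps <- do.call(rbind, lapply(unique(eqtl_res$gene_id), function(g) {
      ov <- eqtl_signal_overlap(eqtl_res[eqtl_res$gene_id == g, ,
                                         drop = FALSE], ccvs)
      data.frame(gene_id = g, significant = g %in% sig_genes,
                 overlaps_signal = ov$overlaps, top_variant = ov$top_variant,
                 best_ccv = ov$best_ccv, reason = ov$reason,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(overlaps, o("eqtl_signal_overlap.tsv"))
  }

  tau_tab <- NULL
  if (!is.null(cfg$tissue_panel)) {
    stage_msg("tissue specificity (tau)")
    tau_tab <- tau_panel(read_matrix_tsv(cfg$tissue_panel))
    write_tsv(tau_tab, o("tau.tsv"))
  }

  coexpr <- NULL
  if (!is.null(loops) && !is.null(cfg$expression)) {
    stage_msg("looped-pair co-expression")
    expr_raw <- read_matrix_tsv(cfg$expression)
    all_genes <- genes_raw
    coexpr <- looped_pair_test(pmax(2^expr_raw - 1, 0), all_genes, loops,
                               window = cfg$correlation_window,
                               apply_filter = FALSE)
    if (!is.null(coexpr$pairs)) write_tsv(coexpr$pairs, o("coexpression_pairs.tsv"))
    write_tsv(data.frame(statistic = coexpr$statistic, p = coexpr$p,
                         n_looped = coexpr$n_looped,
                         n_nonlooped = coexpr$n_nonlooped),
              o("coexpression_test.tsv"))
  }

  qc <- NULL
  if (!is.null(cfg$ercc_captured) && !is.null(cfg$ercc_noncaptured)) {
    stage_msg("capture QC")
    cap <- spikein_table(read_tsv(cfg$ercc_captured))
    non <- spikein_table(read_tsv(cfg$ercc_noncaptured))
    qc <- capture_qc_report(cap, non)
    write_tsv(data.frame(
      library = c(qc$captured_fit$library_id, qc$noncaptured_fit$library_id),
      slope = c(qc$captured_fit$slope, qc$noncaptured_fit$slope),
      intercept = c(qc$captured_fit$intercept, qc$noncaptured_fit$intercept),
      r2 = c(qc$captured_fit$r2, qc$noncaptured_fit$r2),
      lld = c(qc$lld_captured, qc$lld_noncaptured)), o("capture_qc.tsv"))
  }

  run_manifest <- list(
    seed = cfg$seed, n_permutations = cfg$n_permutations,
    thresholds = cfg[c("gene_min_fpkm", "isoform_min_fpkm", "fdr",
                       "correlation_window")],
    promoter_modes = cfg[c("enrichment_promoter_mode",
                           "linkage_promoter_mode")],
    inputs = lapply(cfg[c("universe", "genes", "gene_fpkm", "variants",
                          "loops", "expression", "genotypes", "copy_number",
                          "tissue_panel", "ercc_captured",
                          "ercc_noncaptured")],
                    function(p) if (is.null(p)) NULL else
                      unname(tools::md5sum(p))))
  jsonlite::write_json(run_manifest, o("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(universe = universe, genes = genes, filter = filt,
                 ccvs = ccvs, enrichment = enr, enrichment_table = enr_tab,
                 linkage = records, multi_signal = multi, eqtl = eqtl_res,
                 eqtl_overlap = overlaps, tau = tau_tab, coexpression = coexpr,
                 capture_qc = qc))
}
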