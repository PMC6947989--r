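#' Simulation configuration
#'
#' The generator defaults state the world the analyses assume: 1.5-Mb
#' capture regions around risk signals, multi-exonic low-expression gene
#' models, signals whose CCVs are placed with a tunable exonic-bp odds
#' multiplier (`ccv_exon_enrichment = 1` is the uniform null), loops joining
#' promoters to CCV-bearing fragments, and expression with additive
#' genotype effects plus a copy-number covariate and Gaussian noise.
#'
#' @param seed integer seed; every generator is deterministic under it.
#' @param n_regions number of capture regions (default 10).
#' @param region_length region length in bp (default 1.5e6).
#' @param genes_per_region mencRNA genes per region (default 5).
#' @param coding_per_region decoy protein-coding genes per region (default 2).
#' @param exons_per_gene integer range, >= 2 (default 2:6).
#' @param exon_length_meanlog,exon_length_sdlog lognormal exon lengths
#'   (defaults log(300), 0.6 — mencRNA transcripts are short, median ~1.5 kb).
#' @param intron_length_meanlog,intron_length_sdlog lognormal intron lengths
#'   (defaults log(3000), 0.8).
#' @param signals_per_region independent risk signals per region (default 2).
#' @param variants_per_signal variants per signal (default 30).
#' @param ccvs_per_signal planted CCVs per signal incl. lead (default 8;
#'   most real signals have <= 10).
#' @param ccv_exon_enrichment odds multiplier for exonic bp when placing
#'   CCVs (default 1 = uniform).
#' @param n_loops chromatin loops (default 40).
#' @param loop_promoter_fraction fraction of loops planted to join a gene
#'   promoter anchor to a CCV-bearing anchor (default 0.5).
#' @param loop_anchor_bp anchor width (default 5000, restriction-fragment
#'   scale).
#' @param n_samples samples for the eQTL stage (default 500).
#' @param eqtl_beta additive dosage effect of planted eQTLs (default 0.5).
#' @param eqtl_gene_fraction fraction of mencRNA genes planted as eQTL
#'   genes (default 0.3).
#' @param noise_sd residual sd of expression (default 1).
#' @param copy_number_effect effect of the per-gene copy-number covariate
#'   (default 0.3).
#' @param tissue_count tissues in the tau panel (default 7, as in the
#'   seven-cohort comparison).
#' @param tissue_specific_fraction fraction of tau-panel genes in the
#'   tissue-specific regime (default 0.5).
#' @param n_tissue_genes genes in the tau panel (default 200).
#' @param n_coexpr_loops promoter-promoter loops joining a mencRNA to a
#'   protein-coding gene whose expression shares a latent factor (default
#'   5).
#' @param coexpr_latent_sd sd of the shared latent factor (default 1.2,
#'   giving pair correlation ~ 0.6 at `noise_sd = 1`).
#' @param ercc_n spike-in transcripts (default 92).
#' @param ercc_slope,ercc_intercept_captured,ercc_intercept_noncaptured
#'   dose-response parameters (defaults 1, 2, -6.23: a ~2^8.23 = 300-fold
#'   capture enrichment, matching the observed ~300x LLD shift).
#' @param ercc_noise_sd sd of log2 FPKM noise (default 0 = noiseless).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_regions = 10, region_length = 1.5e6,
                       genes_per_region = 5, coding_per_region = 2,
                       exons_per_gene = 2:6,
                       exon_length_meanlog = log(300), exon_length_sdlog = 0.6,
                       intron_length_meanlog = log(3000),
                       intron_length_sdlog = 0.8,
                       signals_per_region = 2, variants_per_signal = 30,
                       ccvs_per_signal = 8, ccv_exon_enrichment = 1,
                       n_loops = 40, loop_promoter_fraction = 0.5,
                       loop_anchor_bp = 5000,
                       n_samples = 500, eqtl_beta = 0.5,
                       eqtl_gene_fraction = 0.3, noise_sd = 1,
                       copy_number_effect = 0.3,
                       tissue_count = 7, tissue_specific_fraction = 0.5,
                       n_tissue_genes = 200,
                       n_coexpr_loops = 5, coexpr_latent_sd = 1.2,
                       ercc_n = 92, ercc_slope = 1,
                       ercc_intercept_captured = 2,
                       ercc_intercept_noncaptured = -6.23,
                       ercc_noise_sd = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_regions >= 1, cfg$region_length > 0,
            all(cfg$exons_per_gene >= 2), cfg$ccv_exon_enrichment >= 1,
            cfg$ccvs_per_signal >= 1,
            cfg$ccvs_per_signal <= cfg$variants_per_signal,
            cfg$loop_promoter_fraction >= 0, cfg$loop_promoter_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

## tagged-interval membership scan used for manifest bookkeeping —
## deliberately plain base R, independent of the GRanges overlap machinery
## the analysis code uses.
locate_position <- function(pos, chrom, iv, tag = "gene_id") {
  hit <- iv$chrom == chrom & iv$start <= pos & pos < iv$end
  unique(iv[[tag]][hit])
}

#' Simulate a capture universe and gene models
#'
#' Places non-overlapping multi-exonic mencRNA genes and decoy
#' protein-coding genes along each capture region with >= 2 kb spacing (so
#' promoters never collide with neighbouring genes), plus a max-FPKM table
#' guaranteeing the planted mencRNAs pass the expression filter.
#'
#' @param cfg a [sim_config()].
#' @return list: `universe`, `genes` ([gene_models()]), `gene_fpkm` (named
#'   numeric), `manifest` (per-gene placement table).
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  regions <- genomic_intervals(paste0("chr", seq_len(cfg$n_regions)),
                               rep(0, cfg$n_regions),
                               rep(cfg$region_length, cfg$n_regions))
  universe <- capture_universe(regions)
  exon_rows <- list(); manifest <- list()
  gi <- 0
  for (r in seq_len(cfg$n_regions)) {
    chrom <- regions$chrom[r]
    cursor <- 2000
    biotypes <- sample(c(rep("mencRNA", cfg$genes_per_region),
                         rep("protein_coding", cfg$coding_per_region)))
    for (b in biotypes) {
      gi <- gi + 1
      n_ex <- sample(cfg$exons_per_gene, 1)
      ex_len <- pmax(50, round(stats::rlnorm(n_ex, cfg$exon_length_meanlog,
                                             cfg$exon_length_sdlog)))
      in_len <- if (n_ex > 1)
        pmax(200, round(stats::rlnorm(n_ex - 1, cfg$intron_length_meanlog,
                                      cfg$intron_length_sdlog))) else integer(0)
      glen <- sum(ex_len) + sum(in_len)
      gap <- round(stats::runif(1, 2000, 20000))
      start <- cursor + gap
      ## a draw too long for the remaining space is skipped, not fatal:
      ## later (possibly shorter) genes may still fit
      if (start + glen > cfg$region_length - 2000) next
      cursor <- start + glen
      starts <- start + cumsum(c(0, utils::head(ex_len, -1) + in_len))
      gene_id <- sprintf("XLOC-%06d", gi)
      strand <- sample(c("+", "-"), 1)
      exon_rows[[gi]] <- data.frame(
        gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
        chrom = chrom, start = starts, end = starts + ex_len,
        strand = strand, biotype = b, stringsAsFactors = FALSE)
      manifest[[gi]] <- data.frame(
        gene_id = gene_id, region = chrom, biotype = b, strand = strand,
        n_exons = n_ex, start = start, end = start + glen,
        tss = if (strand == "+") start else start + glen - 1,
        stringsAsFactors = FALSE)
    }
  }
  placed_regions <- unique(vapply(Filter(Negate(is.null), manifest),
                                  function(m) m$region, character(1)))
  if (length(placed_regions) < cfg$n_regions)
    stop("infeasible packing: no gene fits in region(s) ",
         paste(setdiff(regions$chrom, placed_regions), collapse = ", "),
         " (genes too long for region_length)")
  genes <- gene_models(do.call(rbind, exon_rows))
  man <- do.call(rbind, manifest)
  fpkm <- stats::setNames(0.5 + stats::rlnorm(nrow(man), log(3), 1),
                          man$gene_id)
  list(universe = universe, genes = genes, gene_fpkm = fpkm, manifest = man)
}

#' Simulate risk signals with planted CCV structure
#'
#' Per signal: a lead p log-uniform in `[1e-12, 1e-8]`; planted CCVs with p
#' within two orders of magnitude of the lead; remaining variants with p at
#' least ~316x the lead so [derive_ccvs()] recovers exactly the planted
#' set. CCV positions are drawn with exonic-bp odds multiplied by
#' `ccv_exon_enrichment` over the mencRNA exon set of the signal's region;
#' other variants are uniform. The manifest annotates every CCV with the
#' gene whose exon or promoter it hits (by an independent base-R scan).
#'
#' @param cfg a [sim_config()].
#' @param genome a [simulate_genome()] result.
#' @return list: `signals` ([risk_signals()]), `ccvs` (planted CCV
#'   annotation table), `manifest` (list with per-signal planted CCV ids).
#' @export
simulate_signals <- function(cfg, genome) {
  set.seed(cfg$seed + 1)
  regions <- genome$universe$regions
  g <- as.data.frame(genome$genes)
  menc_ex <- g[g$biotype == "mencRNA", , drop = FALSE]
  ## annotation bookkeeping is against mencRNA features only — the target
  ## set downstream linkage runs on
  menc_genes <- gene_models(menc_ex)
  prom_flank <- derive_features(menc_genes, promoter_mode = "flank500")$promoters
  prom_up <- derive_features(menc_genes, promoter_mode = "upstream500")$promoters

  rows <- list(); ann <- list(); idx <- 0
  e <- cfg$ccv_exon_enrichment
  for (r in seq_len(nrow(regions))) {
    chrom <- regions$chrom[r]
    L <- regions$end[r] - regions$start[r]
    ex_r <- merge_intervals(menc_ex[menc_ex$chrom == chrom, , drop = FALSE])
    ex_bp <- if (nrow(ex_r)) sum(ex_r$end - ex_r$start) else 0
    p_exonic <- e * ex_bp / (e * ex_bp + (L - ex_bp))
    draw_pos <- function(n, weighted) {
      vapply(seq_len(n), function(i) {
        if (weighted && ex_bp > 0 && stats::runif(1) < p_exonic) {
          ## uniform within merged exonic bp
          off <- floor(stats::runif(1) * ex_bp)
          cum <- cumsum(ex_r$end - ex_r$start)
          j <- findInterval(off, c(0, cum), rightmost.closed = FALSE)
          ex_r$start[j] + (off - c(0, cum)[j])
        } else {
          ## uniform over the region minus (when weighted) exonic bp
          repeat {
            p <- regions$start[r] + floor(stats::runif(1) * L)
            if (!weighted || ex_bp == 0 ||
                !any(ex_r$start <= p & p < ex_r$end)) return(p)
          }
        }
      }, numeric(1))
    }
    for (s in seq_len(cfg$signals_per_region)) {
      idx <- idx + 1
      signal_id <- sprintf("signal_%03d", idx)
      lead_lp <- stats::runif(1, -12, -8)
      n_ccv <- cfg$ccvs_per_signal
      n_other <- cfg$variants_per_signal - n_ccv
      ccv_lp <- c(lead_lp, stats::runif(n_ccv - 1, lead_lp, lead_lp + 2))
      other_lp <- stats::runif(n_other, lead_lp + 2.5, -0.5)
      pos_ccv <- draw_pos(n_ccv, weighted = TRUE)
      pos_other <- draw_pos(n_other, weighted = FALSE)
      vid <- sprintf("%s_v%02d", signal_id, seq_len(n_ccv + n_other))
      rows[[idx]] <- data.frame(
        signal_id = signal_id,
        variant_id = vid, chrom = chrom,
        pos = c(pos_ccv, pos_other),
        p_assoc = 10^c(ccv_lp, other_lp),
        planted_ccv = c(rep(TRUE, n_ccv), rep(FALSE, n_other)),
        stringsAsFactors = FALSE)
      ann[[idx]] <- data.frame(
        signal_id = signal_id, variant_id = vid[seq_len(n_ccv)],
        pos = pos_ccv,
        exon_gene = vapply(pos_ccv, function(p) {
          h <- locate_position(p, chrom, menc_ex)
          if (length(h)) paste(sort(h), collapse = ",") else NA_character_
        }, character(1)),
        promoter_gene_flank500 = vapply(pos_ccv, function(p) {
          h <- locate_position(p, chrom, prom_flank)
          if (length(h)) paste(sort(h), collapse = ",") else NA_character_
        }, character(1)),
        promoter_gene_upstream500 = vapply(pos_ccv, function(p) {
          h <- locate_position(p, chrom, prom_up)
          if (length(h)) paste(sort(h), collapse = ",") else NA_character_
        }, character(1)),
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rows)
  signals <- risk_signals(variants[, c("signal_id", "variant_id", "chrom",
                                       "pos", "p_assoc")])
  planted <- split(variants$variant_id[variants$planted_ccv],
                   variants$signal_id[variants$planted_ccv])
  list(signals = signals, variants = variants,
       ccv_annotation = do.call(rbind, ann),
       manifest = list(planted_ccvs = planted))
}

#' Simulate chromatin loops with planted promoter-CCV links
#'
#' A `loop_promoter_fraction` share of loops joins a mencRNA promoter
#' anchor to an anchor centred on a CCV of a same-region signal; the rest
#' are decoys placed uniformly. The manifest records, for *every* loop, the
#' (gene, signal) pairs its geometry actually implies — computed by an
#' independent base-R overlap scan — so accidental decoy links are part of
#' the recorded truth.
#'
#' @param cfg a [sim_config()].
#' @param genome a [simulate_genome()] result.
#' @param signals a [simulate_signals()] result.
#' @return list: `loops` ([chromatin_loops()]), `manifest` (data frame of
#'   implied gene/signal loop links).
#' @export
simulate_loops <- function(cfg, genome, signals) {
  set.seed(cfg$seed + 2)
  regions <- genome$universe$regions
  gman <- genome$manifest
  menc <- gman[gman$biotype == "mencRNA", , drop = FALSE]
  ccvs <- derive_ccvs(signals$signals)
  half <- cfg$loop_anchor_bp / 2
  cell_lines <- c("B80T5", "MCF7", "T47D", "MDAMB231")

  n_planted <- round(cfg$n_loops * cfg$loop_promoter_fraction)
  loops <- list()
  for (i in seq_len(cfg$n_loops)) {
    if (i <= n_planted) {
      gene <- menc[sample(nrow(menc), 1), ]
      cc_r <- ccvs[ccvs$chrom == gene$region, , drop = FALSE]
      if (nrow(cc_r) == 0) next
      cc <- cc_r[sample(nrow(cc_r), 1), ]
      a1 <- c(gene$tss - half, gene$tss + half)
      a2 <- c(cc$pos - half, cc$pos + half + 1)
      chrom <- gene$region
    } else {
      r <- sample(nrow(regions), 1)
      chrom <- regions$chrom[r]
      c1 <- regions$start[r] + floor(stats::runif(1) *
                                       (regions$end[r] - regions$start[r]))
      c2 <- regions$start[r] + floor(stats::runif(1) *
                                       (regions$end[r] - regions$start[r]))
      a1 <- c(c1 - half, c1 + half)
      a2 <- c(c2 - half, c2 + half)
    }
    a1 <- pmax(a1, 0); a2 <- pmax(a2, 0)
    if (a1[2] <= a1[1] || a2[2] <= a2[1]) next
    if (all(a1 == a2)) next
    loops[[length(loops) + 1]] <- data.frame(
      chrom1 = chrom, start1 = a1[1], end1 = a1[2],
      chrom2 = chrom, start2 = a2[1], end2 = a2[2],
      name = sprintf("loop%04d", i), score = round(stats::runif(1, 5, 50)),
      cell_line = sample(cell_lines, 1), stringsAsFactors = FALSE)
  }

  ## promoter-promoter loops joining mencRNA / protein-coding gene pairs
  ## (the co-expression scenario); their expression shares a latent factor
  coding <- gman[gman$biotype == "protein_coding", , drop = FALSE]
  pp_pairs <- list()
  used <- character()
  for (i in seq_len(cfg$n_coexpr_loops)) {
    cand <- merge(menc[, c("gene_id", "region", "tss")],
                  coding[, c("gene_id", "region", "tss")],
                  by = "region", suffixes = c("_menc", "_coding"))
    cand <- cand[abs(cand$tss_menc - cand$tss_coding) <= 1e6 &
                   !(cand$gene_id_menc %in% used) &
                   !(cand$gene_id_coding %in% used), , drop = FALSE]
    if (nrow(cand) == 0) break
    pick <- cand[sample(nrow(cand), 1), ]
    used <- c(used, pick$gene_id_menc, pick$gene_id_coding)
    a1 <- pmax(c(pick$tss_menc - half, pick$tss_menc + half), 0)
    a2 <- pmax(c(pick$tss_coding - half, pick$tss_coding + half), 0)
    loops[[length(loops) + 1]] <- data.frame(
      chrom1 = pick$region, start1 = a1[1], end1 = a1[2],
      chrom2 = pick$region, start2 = a2[1], end2 = a2[2],
      name = sprintf("looppp%02d", i), score = round(stats::runif(1, 5, 50)),
      cell_line = sample(cell_lines, 1), stringsAsFactors = FALSE)
    pp_pairs[[i]] <- data.frame(gene_menc = pick$gene_id_menc,
                                gene_coding = pick$gene_id_coding,
                                stringsAsFactors = FALSE)
  }
  pp_pairs <- if (length(pp_pairs)) unique(do.call(rbind, pp_pairs)) else
    data.frame(gene_menc = character(), gene_coding = character(),
               stringsAsFactors = FALSE)
  loops <- chromatin_loops(do.call(rbind, loops))

  ## implied truth: independent scan of every loop against mencRNA flank500
  ## promoters and CCV positions
  menc_models <- gene_models(as.data.frame(genome$genes)[
    as.data.frame(genome$genes)$biotype == "mencRNA", , drop = FALSE])
  prom <- derive_features(menc_models, promoter_mode = "flank500")$promoters
  implied <- list()
  overlaps_iv <- function(iv, chrom, s, e) iv$chrom == chrom &
    iv$start < e & s < iv$end
  for (i in seq_len(nrow(loops))) {
    l <- loops[i, ]
    for (side in list(c(1, 2), c(2, 1))) {
      ps <- l[[paste0("start", side[1])]]; pe <- l[[paste0("end", side[1])]]
      vs <- l[[paste0("start", side[2])]]; ve <- l[[paste0("end", side[2])]]
      genes_hit <- unique(prom$gene_id[overlaps_iv(prom, l$chrom1, ps, pe)])
      vhit <- ccvs$chrom == l$chrom1 & vs <= ccvs$pos & ccvs$pos < ve
      sigs_hit <- unique(ccvs$signal_id[vhit])
      if (length(genes_hit) && length(sigs_hit))
        implied[[length(implied) + 1]] <- expand.grid(
          gene_id = genes_hit, signal_id = sigs_hit, loop = l$name,
          cell_line = l$cell_line, stringsAsFactors = FALSE)
    }
  }
  man <- if (length(implied)) unique(do.call(rbind, implied)) else
    data.frame(gene_id = character(), signal_id = character(),
               loop = character(), cell_line = character(),
               stringsAsFactors = FALSE)
  list(loops = loops, manifest = man, coexpr_pairs = pp_pairs)
}

#' Simulate genotypes, expression and covariates with planted eQTLs
#'
#' Dosages are binomial(2, maf) with maf uniform on `[0.05, 0.5]`.
#' A planted fraction of mencRNA genes receives an additive effect
#' `eqtl_beta` of one CCV in its region; every gene gets a copy-number
#' covariate effect and Gaussian noise:
#' `expr = baseline + beta * dosage + gamma * copy_number + N(0, noise_sd)`.
#' The `expression` matrix is on the analysis (log2-like) scale.
#'
#' @param cfg a [sim_config()].
#' @param genome a [simulate_genome()] result.
#' @param signals a [simulate_signals()] result.
#' @param coexpr_pairs optional data frame (`gene_menc`, `gene_coding`)
#'   of looped pairs that share a latent expression factor (from
#'   [simulate_loops()]).
#' @return list: `expression`, `genotypes`, `copy_number` (matrices over
#'   all genes), `manifest` (planted gene/variant/beta table and the
#'   correlated pairs).
#' @export
simulate_expression <- function(cfg, genome, signals, coexpr_pairs = NULL) {
  set.seed(cfg$seed + 3)
  gman <- genome$manifest
  v <- signals$variants
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))

  maf <- stats::runif(nrow(v), 0.05, 0.5)
  geno <- t(vapply(maf, function(m) stats::rbinom(cfg$n_samples, 2, m),
                   numeric(cfg$n_samples)))
  dimnames(geno) <- list(v$variant_id, samples)

  n_genes <- nrow(gman)
  cn <- matrix(stats::rnorm(n_genes * cfg$n_samples, 2, 0.3),
               nrow = n_genes, dimnames = list(gman$gene_id, samples))
  menc_ids <- gman$gene_id[gman$biotype == "mencRNA"]
  n_eqtl <- round(cfg$eqtl_gene_fraction * length(menc_ids))
  eqtl_genes <- sample(menc_ids, n_eqtl)
  ccvs <- v[v$planted_ccv, , drop = FALSE]

  ## per-pair latent factors for looped co-expression
  latent <- NULL
  if (!is.null(coexpr_pairs) && nrow(coexpr_pairs) > 0) {
    latent <- matrix(stats::rnorm(nrow(coexpr_pairs) * cfg$n_samples),
                     nrow = nrow(coexpr_pairs))
  }

  expr <- matrix(0, n_genes, cfg$n_samples,
                 dimnames = list(gman$gene_id, samples))
  planted <- list()
  for (i in seq_len(n_genes)) {
    gid <- gman$gene_id[i]
    base <- stats::runif(1, 3, 7)
    mu <- base + cfg$copy_number_effect * cn[gid, ]
    if (gid %in% eqtl_genes) {
      cc_r <- ccvs[ccvs$chrom == gman$region[i], , drop = FALSE]
      if (nrow(cc_r) > 0) {
        ev <- cc_r$variant_id[sample(nrow(cc_r), 1)]
        mu <- mu + cfg$eqtl_beta * geno[ev, ]
        planted[[gid]] <- data.frame(gene_id = gid, variant_id = ev,
                                     beta = cfg$eqtl_beta,
                                     stringsAsFactors = FALSE)
      }
    }
    if (!is.null(latent)) {
      j <- which(coexpr_pairs$gene_menc == gid | coexpr_pairs$gene_coding == gid)
      if (length(j)) mu <- mu + cfg$coexpr_latent_sd * latent[j[1], ]
    }
    expr[i, ] <- mu + stats::rnorm(cfg$n_samples, 0, cfg$noise_sd)
  }
  man <- if (length(planted)) do.call(rbind, planted) else
    data.frame(gene_id = character(), variant_id = character(),
               beta = numeric(), stringsAsFactors = FALSE)
  rownames(man) <- NULL
  list(expression = expr, genotypes = geno, copy_number = cn,
       manifest = man, coexpr_pairs = coexpr_pairs)
}

#' Simulate a tissue panel with planted broad / tissue-specific regimes
#'
#' Broad genes express near-uniformly across tissues (tau near 0);
#' specific genes express in a single tissue (tau near 1).
#'
#' @param cfg a [sim_config()].
#' @return list: `panel` (genes x tissues mean FPKM), `manifest` (regime
#'   per gene).
#' @export
simulate_tissue_panel <- function(cfg) {
  set.seed(cfg$seed + 4)
  n <- cfg$n_tissue_genes; k <- cfg$tissue_count
  n_spec <- round(cfg$tissue_specific_fraction * n)
  regime <- sample(c(rep("specific", n_spec), rep("broad", n - n_spec)))
  panel <- matrix(0, n, k,
                  dimnames = list(sprintf("TG%04d", seq_len(n)),
                                  sprintf("tissue%02d", seq_len(k))))
  for (i in seq_len(n)) {
    if (regime[i] == "specific") {
      hi <- sample(k, 1)
      panel[i, ] <- stats::runif(k, 0, 0.05)
      panel[i, hi] <- stats::rlnorm(1, log(20), 0.5)
    } else {
      level <- stats::rlnorm(1, log(10), 0.5)
      panel[i, ] <- level * stats::runif(k, 0.85, 1.15)
    }
  }
  list(panel = panel,
       manifest = data.frame(gene_id = rownames(panel), regime = regime,
                             stringsAsFactors = FALSE))
}

#' Simulate paired captured / non-captured ERCC spike-in tables
#'
#' FPKM follows the planted dose-response
#' `log2 FPKM = intercept + slope * log2(concentration) (+ noise)`; the
#' intercept gap between captured and non-captured libraries is the planted
#' capture enrichment. With zero noise the planted detection boundary
#' (lowest concentration with FPKM >= 0.5) is recorded exactly.
#'
#' @param cfg a [sim_config()].
#' @return list: `captured`, `noncaptured` ([spikein_table()]s),
#'   `manifest` (planted parameters and per-table LLD boundary).
#' @export
simulate_ercc <- function(cfg) {
  set.seed(cfg$seed + 5)
  n <- cfg$ercc_n
  conc <- 10^stats::runif(n, -3, 3)
  ids <- sprintf("ERCC-%05d", seq_len(n))
  mk <- function(intercept, lib, captured) {
    noise <- if (cfg$ercc_noise_sd > 0)
      stats::rnorm(n, 0, cfg$ercc_noise_sd) else 0
    fpkm <- 2^(intercept + cfg$ercc_slope * log2(conc) + noise)
    spikein_table(data.frame(transcript_id = ids, concentration = conc,
                             fpkm = fpkm, library_id = lib,
                             captured = captured, stringsAsFactors = FALSE))
  }
  cap <- mk(cfg$ercc_intercept_captured, "lib_captured", TRUE)
  non <- mk(cfg$ercc_intercept_noncaptured, "lib_noncaptured", FALSE)
  boundary <- function(intercept)
    2^((log2(0.5) - intercept) / cfg$ercc_slope)
  planted_lld <- function(tab, intercept) {
    det <- tab$concentration[tab$concentration >= boundary(intercept)]
    if (length(det)) min(det) else NA_real_
  }
  list(captured = cap, noncaptured = non,
       manifest = list(slope = cfg$ercc_slope,
                       intercept_captured = cfg$ercc_intercept_captured,
                       intercept_noncaptured = cfg$ercc_intercept_noncaptured,
                       lld_captured = planted_lld(cap, cfg$ercc_intercept_captured),
                       lld_noncaptured = planted_lld(non, cfg$ercc_intercept_noncaptured)))
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs every generator and writes the full input set (BED universe, GTF
#' gene models, variant TSV, BEDPE loops, expression/genotype/copy-number
#' TSVs, ERCC tables, tissue panel) plus a JSON manifest of all planted
#' ground truth to `out_dir`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list of all in-memory pieces incl. `paths`.
#' @export
simulate_bundle <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(cfg)
  sig <- simulate_signals(cfg, genome)
  loops <- simulate_loops(cfg, genome, sig)
  eq <- simulate_expression(cfg, genome, sig, coexpr_pairs = loops$coexpr_pairs)
  tp <- simulate_tissue_panel(cfg)
  ercc <- simulate_ercc(cfg)

  p <- function(f) file.path(out_dir, f)
  write_bed(genome$universe$regions, p("universe.bed"))
  write_gtf(genome$genes, p("genes.gtf"))
  write_tsv(data.frame(gene_id = names(genome$gene_fpkm),
                       max_fpkm = unname(genome$gene_fpkm)),
            p("gene_fpkm.tsv"))
  write_variants(sig$signals, p("variants.tsv"))
  write_bedpe(loops$loops, p("loops.bedpe"))
  write_matrix_tsv(eq$expression, p("expression.tsv"))
  write_matrix_tsv(eq$genotypes, p("genotypes.tsv"))
  write_matrix_tsv(eq$copy_number, p("copy_number.tsv"))
  write_matrix_tsv(tp$panel, p("tissue_panel.tsv"))
  write_tsv(as.data.frame(ercc$captured), p("ercc_captured.tsv"))
  write_tsv(as.data.frame(ercc$noncaptured), p("ercc_noncaptured.tsv"))
  manifest <- list(seed = cfg$seed,
                   genes = genome$manifest,
                   planted_ccvs = sig$manifest$planted_ccvs,
                   ccv_annotation = sig$ccv_annotation,
                   loop_links = loops$manifest,
                   coexpr_pairs = loops$coexpr_pairs,
                   eqtl = eq$manifest,
                   tissue_regimes = tp$manifest,
                   ercc = ercc$manifest)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(list(cfg = cfg, genome = genome, signals = sig, loops = loops,
                 eqtl = eq, tissue = tp, ercc = ercc,
                 manifest = manifest,
                 paths = stats::setNames(
                   file.path(out_dir, c("universe.bed", "genes.gtf",
                                        "gene_fpkm.tsv", "variants.tsv",
                                        "loops.bedpe", "expression.tsv",
                                        "genotypes.tsv", "copy_number.tsv",
                                        "tissue_panel.tsv",
                                        "ercc_captured.tsv",
                                        "ercc_noncaptured.tsv",
                                        "manifest.json")),
                   c("universe", "genes", "gene_fpkm", "variants", "loops",
                     "expression", "genotypes", "copy_number",
                     "tissue_panel", "ercc_captured", "ercc_noncaptured",
                     "manifest"))))
}
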