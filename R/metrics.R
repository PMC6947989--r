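#' Tissue-specificity index tau
#'
#' tau = sum_i (1 - x_i / x_max) / (N - 1) over N >= 2 tissues: 0 for
#' uniformly (broadly) expressed genes, 1 for single-tissue expression.
#' The index is scale-invariant; the panel wrapper applies it to
#' log2(x + 1) mean expression per tissue.
#'
#' @param x non-negative per-tissue expression vector for one gene.
#' @return tau in `[0, 1]`; `NA` for an all-zero vector.
#' @export
tau <- function(x) {
  if (length(x) < 2) stop("tau needs at least two tissues")
  if (any(x < 0)) stop("tau is defined for non-negative expression")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  val <- sum(1 - x / mx) / (length(x) - 1)
  min(max(val, 0), 1)
}

#' Tau for every gene of a tissue panel
#' @param panel genes x tissues matrix of mean expression (raw scale).
#' @param log2_transform apply log2(x + 1) first (default TRUE).
#' @return data frame `gene_id`, `tau`.
#' @export
tau_panel <- function(panel, log2_transform = TRUE) {
  m <- as.matrix(panel)
  if (log2_transform) m <- log2(m + 1)
  data.frame(gene_id = rownames(m),
             tau = apply(m, 1, tau),
             stringsAsFactors = FALSE)
}

#' Co-expression gene filter
#'
#' Keeps genes expressed (nonzero) in at least 20% of samples and with raw
#' median absolute deviation (no consistency factor) of at least 1 across
#' samples.
#'
#' @param m genes x samples matrix (counts or FPKM).
#' @param min_nonzero_fraction default 0.2.
#' @param min_mad default 1.
#' @return character vector of retained gene ids.
#' @export
filter_coexpression_genes <- function(m, min_nonzero_fraction = 0.2,
                                      min_mad = 1) {
  m <- as.matrix(m)
  nz <- rowMeans(m > 0)
  mads <- apply(m, 1, function(x) stats::median(abs(x - stats::median(x))))
  rownames(m)[nz >= min_nonzero_fraction & mads >= min_mad]
}

#' Looped vs non-looped mencRNA-mRNA co-expression comparison
#'
#' Candidate pairs are every (mencRNA, protein-coding) gene pair passing
#' [filter_coexpression_genes()] whose TSSs lie within `window` bp on the
#' same chromosome. A pair is "looped" when some chromatin loop joins the
#' two genes' promoters (one promoter overlapping each anchor). Pairwise
#' correlation is computed on log2-normalized expression and the absolute
#' correlation coefficients of looped vs non-looped pairs are compared by a
#' two-sided Mann-Whitney test.
#'
#' @param m genes x samples expression matrix (raw; normalized internally).
#' @param genes [gene_models()] with `biotype` distinguishing `mencRNA`
#'   from `protein_coding`.
#' @param loops a [chromatin_loops()] table.
#' @param window maximum TSS-to-TSS distance (default 1e6 bp).
#' @param method correlation method (default `"pearson"`).
#' @param apply_filter drop genes failing the co-expression filter
#'   (default TRUE).
#' @return list: `pairs` (data frame gene_a, gene_b, r, looped, distance),
#'   `statistic`, `p`, `n_looped`, `n_nonlooped`.
#' @export
looped_pair_test <- function(m, genes, loops, window = 1e6,
                             method = "pearson", apply_filter = TRUE) {
  keep <- if (apply_filter) filter_coexpression_genes(m) else rownames(m)
  tssall <- transcript_tss(genes, require_strand = FALSE)
  ## gene-level TSS: first transcript's (single-transcript genes typical)
  tss <- tssall[!duplicated(tssall$gene_id), , drop = FALSE]
  bt <- unique(as.data.frame(genes)[, c("gene_id", "biotype")])
  tss <- merge(tss, bt, by = "gene_id")
  tss <- tss[tss$gene_id %in% keep, , drop = FALSE]
  menc <- tss[tss$biotype == "mencRNA", , drop = FALSE]
  codg <- tss[tss$biotype == "protein_coding", , drop = FALSE]
  if (nrow(menc) == 0 || nrow(codg) == 0)
    return(list(pairs = NULL, statistic = NA_real_, p = NA_real_,
                n_looped = 0L, n_nonlooped = 0L))

  cand <- merge(menc[, c("gene_id", "chrom", "tss")],
                codg[, c("gene_id", "chrom", "tss")],
                by = "chrom", suffixes = c("_a", "_b"))
  cand$distance <- abs(cand$tss_a - cand$tss_b)
  cand <- cand[cand$distance <= window, , drop = FALSE]
  if (nrow(cand) == 0)
    return(list(pairs = NULL, statistic = NA_real_, p = NA_real_,
                n_looped = 0L, n_nonlooped = 0L))

  ## looped pairs: promoters of a and b on opposite anchors of one loop
  feats <- derive_features(genes, promoter_mode = "flank500")
  prom <- feats$promoters
  loops <- chromatin_loops(as.data.frame(loops))
  p_gr <- gi_to_gr(prom)
  anchor <- function(side) GenomicRanges::GRanges(
    loops[[paste0("chrom", side)]],
    IRanges::IRanges(loops[[paste0("start", side)]] + 1,
                     loops[[paste0("end", side)]]))
  hit_genes <- function(gr) {
    h <- GenomicRanges::findOverlaps(p_gr, gr, ignore.strand = TRUE)
    split(prom$gene_id[S4Vectors::queryHits(h)],
          S4Vectors::subjectHits(h))
  }
  g1 <- hit_genes(anchor(1)); g2 <- hit_genes(anchor(2))
  looped_keys <- character()
  for (l in intersect(names(g1), names(g2))) {
    pairs_l <- expand.grid(a = unique(g1[[l]]), b = unique(g2[[l]]),
                           stringsAsFactors = FALSE)
    looped_keys <- c(looped_keys,
                     paste(pairs_l$a, pairs_l$b), paste(pairs_l$b, pairs_l$a))
  }
  cand$looped <- paste(cand$gene_id_a, cand$gene_id_b) %in% looped_keys

  norm <- normalize_expression(m[unique(c(cand$gene_id_a, cand$gene_id_b)), ,
                                 drop = FALSE])
  cand$r <- vapply(seq_len(nrow(cand)), function(i)
    stats::cor(norm[cand$gene_id_a[i], ], norm[cand$gene_id_b[i], ],
               method = method), numeric(1))
  pairs <- data.frame(gene_a = cand$gene_id_a, gene_b = cand$gene_id_b,
                      r = cand$r, looped = cand$looped,
                      distance = cand$distance, stringsAsFactors = FALSE)
  lo <- abs(pairs$r[pairs$looped]); nl <- abs(pairs$r[!pairs$looped])
  if (length(lo) == 0 || length(nl) == 0)
    return(list(pairs = pairs, statistic = NA_real_, p = NA_real_,
                n_looped = length(lo), n_nonlooped = length(nl)))
  wt <- stats::wilcox.test(lo, nl, alternative = "two.sided", exact = FALSE)
  list(pairs = pairs, statistic = unname(wt$statistic), p = wt$p.value,
       n_looped = length(lo), n_nonlooped = length(nl))
}
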