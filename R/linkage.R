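#' CCV-to-gene linkage routes
#'
#' Three evidence routes connect a risk signal's CCVs to a candidate target
#' gene: the CCV falls in an exon, in the promoter, or in one anchor of a
#' chromatin loop whose other anchor overlaps the gene's promoter.
#' Records are data frames with `gene_id`, `signal_id`, `route`,
#' `cell_line` (NA except for loops) and `evidence_variants`
#' (comma-separated variant ids).
#'
#' @name linkage
NULL

new_linkage_records <- function(gene_id = character(), signal_id = character(),
                                route = character(), cell_line = NA_character_,
                                evidence_variants = character(),
                                evidence_loops = NA_character_) {
  data.frame(gene_id = gene_id, signal_id = signal_id, route = route,
             cell_line = rep_len(cell_line, length(gene_id)),
             evidence_variants = evidence_variants,
             evidence_loops = rep_len(evidence_loops, length(gene_id)),
             stringsAsFactors = FALSE)
}

## overlap join: variants x tagged intervals -> (gene, signal) records
link_by_intervals <- function(ccvs, iv, route) {
  if (nrow(ccvs) == 0 || nrow(iv) == 0) return(new_linkage_records())
  v_gr <- GenomicRanges::GRanges(ccvs$chrom,
                                 IRanges::IRanges(ccvs$pos + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(v_gr, gi_to_gr(iv), ignore.strand = TRUE)
  if (length(hits) == 0) return(new_linkage_records())
  d <- data.frame(gene_id = iv$gene_id[S4Vectors::subjectHits(hits)],
                  signal_id = ccvs$signal_id[S4Vectors::queryHits(hits)],
                  variant_id = ccvs$variant_id[S4Vectors::queryHits(hits)],
                  stringsAsFactors = FALSE)
  agg <- stats::aggregate(variant_id ~ gene_id + signal_id, data = d,
                          FUN = function(v) paste(sort(unique(v)),
                                                  collapse = ","))
  new_linkage_records(agg$gene_id, agg$signal_id, route,
                      NA_character_, agg$variant_id)
}

#' @rdname linkage
#' @param ccvs a [derive_ccvs()] table (needs `signal_id`, `variant_id`,
#'   `chrom`, `pos`).
#' @param genes a [gene_models()] table.
#' @return data frame of linkage records (one per gene x signal with >= 1
#'   qualifying CCV).
#' @export
link_exonic <- function(ccvs, genes) {
  feats <- derive_features(genes, promoter_mode = "flank500")
  link_by_intervals(ccvs, feats$exons, "exon")
}

#' @rdname linkage
#' @param promoter_mode promoter definition; linkage defaults to
#'   `"flank500"` (TSS +/- 500 bp).
#' @export
link_promoter <- function(ccvs, genes, promoter_mode = "flank500") {
  feats <- derive_features(genes, promoter_mode = promoter_mode)
  link_by_intervals(ccvs, feats$promoters, "promoter")
}

#' Read/validate chromatin loops
#'
#' Loops are data frames with `chrom1`, `start1`, `end1`, `chrom2`,
#' `start2`, `end2` (0-based half-open anchors), `name`, `cell_line`, and
#' optionally `score`.
#'
#' @param loops data frame.
#' @return validated loop data frame of class `chromatin_loops`.
#' @export
chromatin_loops <- function(loops) {
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  stopifnot(all(req %in% names(loops)))
  if (is.null(loops$name))
    loops$name <- sprintf("loop%05d", seq_len(nrow(loops)))
  if (is.null(loops$cell_line)) loops$cell_line <- "NA"
  validate_intervals(data.frame(chrom = loops$chrom1, start = loops$start1,
                                end = loops$end1))
  validate_intervals(data.frame(chrom = loops$chrom2, start = loops$start2,
                                end = loops$end2))
  same <- loops$chrom1 == loops$chrom2 & loops$start1 == loops$start2 &
    loops$end1 == loops$end2
  if (any(same)) stop("loop with identical anchors: ",
                      loops$name[same][1])
  class(loops) <- c("chromatin_loops", "data.frame")
  loops
}

#' @rdname linkage
#' @param loops a [chromatin_loops()] table.
#' @details For the loop route a record is emitted when a gene promoter
#'   overlaps (>= 1 bp) one anchor and at least one CCV lies in the other
#'   anchor; the rule is symmetric in anchor order. A promoter and CCV in
#'   the same anchor with the other anchor empty do not qualify. One record
#'   is kept per (gene, signal, cell line).
#' @export
link_loops <- function(ccvs, genes, loops, promoter_mode = "flank500") {
  loops <- chromatin_loops(as.data.frame(loops))
  feats <- derive_features(genes, promoter_mode = promoter_mode)
  prom <- feats$promoters
  if (nrow(ccvs) == 0 || nrow(prom) == 0 || nrow(loops) == 0)
    return(new_linkage_records())
  v_gr <- GenomicRanges::GRanges(ccvs$chrom,
                                 IRanges::IRanges(ccvs$pos + 1, width = 1))
  p_gr <- gi_to_gr(prom)
  anchor_gr <- function(side) {
    GenomicRanges::GRanges(loops[[paste0("chrom", side)]],
      IRanges::IRanges(loops[[paste0("start", side)]] + 1,
                       loops[[paste0("end", side)]]))
  }
  a1 <- anchor_gr(1); a2 <- anchor_gr(2)

  one_direction <- function(prom_anchor, ccv_anchor) {
    ph <- GenomicRanges::findOverlaps(p_gr, prom_anchor, ignore.strand = TRUE)
    vh <- GenomicRanges::findOverlaps(v_gr, ccv_anchor, ignore.strand = TRUE)
    if (length(ph) == 0 || length(vh) == 0) return(NULL)
    pd <- data.frame(loop = S4Vectors::subjectHits(ph),
                     gene_id = prom$gene_id[S4Vectors::queryHits(ph)],
                     stringsAsFactors = FALSE)
    vd <- data.frame(loop = S4Vectors::subjectHits(vh),
                     signal_id = ccvs$signal_id[S4Vectors::queryHits(vh)],
                     variant_id = ccvs$variant_id[S4Vectors::queryHits(vh)],
                     stringsAsFactors = FALSE)
    merge(unique(pd), vd, by = "loop")
  }
  both <- rbind(one_direction(a1, a2), one_direction(a2, a1))
  if (is.null(both) || nrow(both) == 0) return(new_linkage_records())
  both$cell_line <- loops$cell_line[both$loop]
  both$loop_name <- loops$name[both$loop]
  agg <- stats::aggregate(cbind(variant_id, loop_name) ~
                            gene_id + signal_id + cell_line,
                          data = both,
                          FUN = function(v) paste(sort(unique(v)),
                                                  collapse = ","))
  new_linkage_records(agg$gene_id, agg$signal_id, "loop", agg$cell_line,
                      agg$variant_id, agg$loop_name)
}

#' Genes targeted by two or more independent risk signals
#'
#' Pools linkage records from all routes and reports genes whose records
#' span at least `min_signals` distinct signals.
#'
#' @param records pooled linkage record data frame.
#' @param min_signals minimum distinct signals (default 2).
#' @return data frame: `gene_id`, `n_signals`, `signals`, `routes`.
#' @export
multi_signal_targets <- function(records, min_signals = 2) {
  if (nrow(records) == 0)
    return(data.frame(gene_id = character(), n_signals = integer(),
                      signals = character(), routes = character(),
                      stringsAsFactors = FALSE))
  per_gene <- split(records, records$gene_id)
  out <- do.call(rbind, lapply(per_gene, function(d) {
    sig <- sort(unique(d$signal_id))
    data.frame(gene_id = d$gene_id[1], n_signals = length(sig),
               signals = paste(sig, collapse = ","),
               routes = paste(sort(unique(d$route)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_signals >= min_signals, , drop = FALSE]
  rownames(out) <- NULL
  out[order(-out$n_signals, out$gene_id), , drop = FALSE]
}
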