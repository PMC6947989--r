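#' Filter candidate capture transcripts into the retained mencRNA set
#'
#' Applies the annotation filters for de novo captured transcripts:
#' isoforms with maximum FPKM across libraries below `isoform_min_fpkm` are
#' dropped first; then genes are removed when (in this order of reason
#' codes) they are single-exon (no remaining transcript with >= 2 exons), do
#' not overlap the capture universe by >= 1 bp, overlap a protein-coding
#' exon on the same strand by >= 1 bp, or have maximum gene FPKM below
#' `gene_min_fpkm`.
#'
#' @param candidates [gene_models()] table of captured candidate genes.
#' @param gene_fpkm named numeric: maximum FPKM across all libraries per
#'   gene_id.
#' @param isoform_fpkm optional named numeric: max FPKM per transcript_id.
#' @param universe a [capture_universe()].
#' @param coding [gene_models()] of protein-coding genes (their exons are the
#'   "protein-coding sequences"); may be empty.
#' @param gene_min_fpkm,isoform_min_fpkm expression thresholds (defaults 0.5
#'   and 0.01).
#' @return list of class `transcript_filter`: `genes` (retained
#'   [gene_models()]), `removed` (data frame `id`, `level`, `reason`).
#' @export
filter_transcripts <- function(candidates, gene_fpkm, universe, coding = NULL,
                               isoform_fpkm = NULL,
                               gene_min_fpkm = 0.5, isoform_min_fpkm = 0.01) {
  g <- as.data.frame(candidates)
  ids <- unique(g$gene_id)
  missing_expr <- setdiff(ids, names(gene_fpkm))
  if (length(missing_expr))
    stop("no expression for gene(s): ",
         paste(utils::head(missing_expr, 3), collapse = ", "))
  log <- data.frame(id = character(), level = character(),
                    reason = character(), stringsAsFactors = FALSE)
  note <- function(id, level, reason)
    rbind(log, data.frame(id = id, level = level, reason = reason,
                          stringsAsFactors = FALSE))

  ## isoform-level drop
  if (!is.null(isoform_fpkm)) {
    tx_ids <- unique(g$transcript_id)
    known <- intersect(tx_ids, names(isoform_fpkm))
    low_tx <- known[isoform_fpkm[known] < isoform_min_fpkm]
    if (length(low_tx)) {
      log <- note(low_tx, "isoform", "low_isoform_expression")
      g <- g[!(g$transcript_id %in% low_tx), , drop = FALSE]
    }
  }

  per_gene <- split(g, g$gene_id)
  coding_gr <- NULL
  if (!is.null(coding) && nrow(coding) > 0) {
    ce <- as.data.frame(coding)
    ce <- ce[ce$biotype == "protein_coding", , drop = FALSE]
    if (nrow(ce)) coding_gr <- gi_to_gr(ce)
  }
  uni_gr <- gi_to_gr(universe$regions)

  keep <- character()
  for (gid in names(per_gene)) {
    d <- per_gene[[gid]]
    n_ex <- table(d$transcript_id)
    if (nrow(d) == 0 || max(n_ex) < 2) {
      log <- note(gid, "gene", "single_exon"); next
    }
    gr <- gi_to_gr(d)
    if (!any(suppressWarnings(
      IRanges::overlapsAny(gr, uni_gr, ignore.strand = TRUE)))) {
      log <- note(gid, "gene", "outside_universe"); next
    }
    if (!is.null(coding_gr) &&
        any(suppressWarnings(
          IRanges::overlapsAny(gr, coding_gr, ignore.strand = FALSE)))) {
      log <- note(gid, "gene", "coding_overlap"); next
    }
    if (gene_fpkm[[gid]] < gene_min_fpkm) {
      log <- note(gid, "gene", "low_expression"); next
    }
    keep <- c(keep, gid)
  }
  retained <- g[g$gene_id %in% keep, , drop = FALSE]
  retained <- if (nrow(retained)) gene_models(retained) else
    gene_models(g[0, , drop = FALSE])
  structure(list(genes = retained, removed = log), class = "transcript_filter")
}

#' Merge a captured annotation with a reference annotation
#'
#' Resolution rules for building one combined annotation out of the captured
#' transcripts and a reference (e.g. GENCODE) annotation, for use with
#' unstranded external RNA-seq: (1) captured transcripts overlapping a
#' reference protein-coding exon on the *opposite* strand by >= 1 bp are
#' excluded (expression would be confounded); (2) where a captured gene and
#' a reference gene overlap (>= 1 exon bp, either strand), the lowly
#' expressed captured gene (max FPKM < `gene_min_fpkm`) is removed,
#' otherwise the reference gene is excluded.
#'
#' @param captured [gene_models()] of captured genes.
#' @param gene_fpkm named numeric, max FPKM per captured gene_id.
#' @param reference [gene_models()] reference annotation.
#' @param gene_min_fpkm threshold (default 0.5).
#' @return list: `genes` (merged [gene_models()]), `dropped_captured`,
#'   `dropped_reference` (character ids), `log` (data frame).
#' @export
merge_annotations <- function(captured, gene_fpkm, reference,
                              gene_min_fpkm = 0.5) {
  cap <- as.data.frame(captured)
  ref <- as.data.frame(reference)
  drop_cap <- character(); drop_ref <- character()
  log <- data.frame(id = character(), reason = character(),
                    stringsAsFactors = FALSE)

  if (nrow(cap) && nrow(ref)) {
    cap_gr <- gi_to_gr(cap)
    ref_coding <- ref[ref$biotype == "protein_coding", , drop = FALSE]
    if (nrow(ref_coding)) {
      ## opposite strand: flip captured strand then require same-strand hits
      flipped <- cap
      flipped$strand <- ifelse(cap$strand == "+", "-",
                        ifelse(cap$strand == "-", "+", "*"))
      opp <- IRanges::overlapsAny(gi_to_gr(flipped), gi_to_gr(ref_coding),
                                  ignore.strand = FALSE)
      opp_genes <- unique(cap$gene_id[opp])
      if (length(opp_genes)) {
        drop_cap <- c(drop_cap, opp_genes)
        log <- rbind(log, data.frame(id = opp_genes,
                                     reason = "opposite_strand_coding_overlap",
                                     stringsAsFactors = FALSE))
      }
    }
    cap_left <- cap[!(cap$gene_id %in% drop_cap), , drop = FALSE]
    if (nrow(cap_left)) {
      hits <- GenomicRanges::findOverlaps(gi_to_gr(cap_left), gi_to_gr(ref),
                                          ignore.strand = TRUE)
      pairs <- unique(data.frame(
        cap_gene = cap_left$gene_id[S4Vectors::queryHits(hits)],
        ref_gene = ref$gene_id[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE))
      for (i in seq_len(nrow(pairs))) {
        cg <- pairs$cap_gene[i]
        fpkm <- if (cg %in% names(gene_fpkm)) gene_fpkm[[cg]] else 0
        if (fpkm < gene_min_fpkm) {
          if (!(cg %in% drop_cap)) {
            drop_cap <- c(drop_cap, cg)
            log <- rbind(log, data.frame(id = cg, reason = "low_expression_vs_reference",
                                         stringsAsFactors = FALSE))
          }
        } else if (!(pairs$ref_gene[i] %in% drop_ref)) {
          drop_ref <- c(drop_ref, pairs$ref_gene[i])
          log <- rbind(log, data.frame(id = pairs$ref_gene[i],
                                       reason = "reference_superseded",
                                       stringsAsFactors = FALSE))
        }
      }
    }
  }
  merged <- rbind(cap[!(cap$gene_id %in% drop_cap), , drop = FALSE],
                  ref[!(ref$gene_id %in% drop_ref), , drop = FALSE])
  list(genes = gene_models(merged), dropped_captured = drop_cap,
       dropped_reference = drop_ref, log = log)
}
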