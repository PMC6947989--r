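#' Derive exon / intron / promoter feature sets from gene models
#'
#' Introns are exactly the gaps between consecutive exons of a transcript.
#' Promoters come in the two definitions used for different analyses:
#' `"upstream500"` — the 500 bp strictly upstream of the strand-aware TSS
#' (used for enrichment); `"flank500"` — TSS base +/- 500 bp, a 1001-bp
#' window (used for chromatin-loop assignment). Promoters are truncated at
#' position 0; coordinates are never negative.
#'
#' @param genes a [gene_models()] table.
#' @param promoter_mode `"upstream500"` or `"flank500"`.
#' @return list of class `feature_set` with elements `exons`, `introns`,
#'   `promoters`, each a data frame with `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id`, plus `promoter_mode`.
#' @export
derive_features <- function(genes, promoter_mode = c("upstream500", "flank500")) {
  promoter_mode <- match.arg(promoter_mode)
  g <- as.data.frame(genes)
  tag <- function(d) d[, c("chrom", "start", "end", "strand",
                           "gene_id", "transcript_id")]
  exons <- tag(g)

  introns <- do.call(rbind, lapply(split(g, g$transcript_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    n <- nrow(d)
    if (n < 2) return(NULL)
    data.frame(chrom = d$chrom[1],
               start = d$end[-n], end = d$start[-1],
               strand = d$strand[1], gene_id = d$gene_id[1],
               transcript_id = d$transcript_id[1], stringsAsFactors = FALSE)
  }))
  if (is.null(introns))
    introns <- exons[0, , drop = FALSE]

  tss <- transcript_tss(genes, require_strand = (promoter_mode == "upstream500"))
  if (promoter_mode == "upstream500") {
    p_start <- ifelse(tss$strand == "-", tss$tss + 1, tss$tss - 500)
    p_end <- ifelse(tss$strand == "-", tss$tss + 501, tss$tss)
  } else {
    p_start <- tss$tss - 500
    p_end <- tss$tss + 501
  }
  promoters <- data.frame(chrom = tss$chrom,
                          start = pmax(p_start, 0), end = pmax(p_end, 0),
                          strand = tss$strand, gene_id = tss$gene_id,
                          transcript_id = tss$transcript_id,
                          stringsAsFactors = FALSE)
  promoters <- promoters[promoters$end > promoters$start, , drop = FALSE]
  rownames(exons) <- rownames(introns) <- rownames(promoters) <- NULL
  structure(list(exons = exons, introns = introns, promoters = promoters,
                 promoter_mode = promoter_mode),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set (promoter_mode=%s): %d exons, %d introns, %d promoters\n",
              x$promoter_mode, nrow(x$exons), nrow(x$introns), nrow(x$promoters)))
  invisible(x)
}

#' Extract one feature kind from a feature set as an interval table
#' @param features a [derive_features()] result (or a plain interval df,
#'   returned unchanged).
#' @param kind `"exon"`, `"intron"` or `"promoter"`.
#' @export
feature_intervals <- function(features, kind = c("exon", "intron", "promoter")) {
  if (!inherits(features, "feature_set")) return(features)
  kind <- match.arg(kind)
  switch(kind, exon = features$exons, intron = features$introns,
         promoter = features$promoters)
}
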