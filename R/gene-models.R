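#' Gene models as an exon table
#'
#' A gene model set is a data frame with one row per exon:
#' `gene_id`, `transcript_id`, `chrom`, `start`, `end` (0-based half-open),
#' `strand` and `biotype` (`"mencRNA"`, `"protein_coding"` or `"other"`).
#' Within a transcript exons must share chrom/strand and be non-overlapping;
#' they are stored sorted by start.
#'
#' @param exons data frame with the columns above (`biotype` defaults to
#'   `"other"`).
#' @return data frame of class `gene_models`.
#' @export
gene_models <- function(exons) {
  req <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  stopifnot(all(req %in% names(exons)))
  if (is.null(exons$biotype)) exons$biotype <- "other"
  exons <- exons[, c(req, "biotype")]
  exons$gene_id <- as.character(exons$gene_id)
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  validate_intervals(exons)
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  ## per-transcript invariants
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (tx in names(by_tx)) {
    i <- by_tx[[tx]]
    if (length(unique(exons$chrom[i])) > 1 || length(unique(exons$strand[i])) > 1)
      stop("transcript ", tx, " mixes chromosomes or strands")
    if (length(i) > 1) {
      s <- exons$start[i]; e <- exons$end[i]
      if (any(s[-1] < e[-length(e)]))
        stop("transcript ", tx, " has overlapping exons")
    }
  }
  ## one gene -> one biotype
  bt <- unique(exons[, c("gene_id", "biotype")])
  if (anyDuplicated(bt$gene_id))
    stop("gene with conflicting biotypes")
  class(exons) <- c("gene_models", "data.frame")
  exons
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d exon(s), %d transcript(s), %d gene(s)\n",
              nrow(x), length(unique(x$transcript_id)),
              length(unique(x$gene_id))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Per-transcript span (first exon start to last exon end)
#' @param genes a [gene_models()] table.
#' @return data frame: transcript_id, gene_id, chrom, start, end, strand,
#'   n_exons, biotype.
#' @export
transcript_spans <- function(genes) {
  sp <- do.call(rbind, lapply(split(as.data.frame(genes), genes$transcript_id),
    function(d) data.frame(transcript_id = d$transcript_id[1],
                           gene_id = d$gene_id[1], chrom = d$chrom[1],
                           start = min(d$start), end = max(d$end),
                           strand = d$strand[1], n_exons = nrow(d),
                           biotype = d$biotype[1],
                           stringsAsFactors = FALSE)))
  rownames(sp) <- NULL
  sp[order(sp$chrom, sp$start), , drop = FALSE]
}

#' Strand-aware transcription start sites
#'
#' TSS base of each transcript: first base of the 5'-most exon (`start` on
#' `+`, `end - 1` on `-`). Unstranded transcripts are an error when
#' `require_strand` is TRUE.
#'
#' @param genes [gene_models()] table.
#' @param require_strand error on `"*"` strand?
#' @return data frame: transcript_id, gene_id, chrom, tss (0-based base
#'   position), strand.
#' @export
transcript_tss <- function(genes, require_strand = TRUE) {
  sp <- transcript_spans(genes)
  unk <- !(sp$strand %in% c("+", "-"))
  if (any(unk) && require_strand)
    stop("unstranded transcript(s): ",
         paste(utils::head(sp$transcript_id[unk], 3), collapse = ", "))
  tss <- ifelse(sp$strand == "-", sp$end - 1, sp$start)
  data.frame(transcript_id = sp$transcript_id, gene_id = sp$gene_id,
             chrom = sp$chrom, tss = tss, strand = sp$strand,
             stringsAsFactors = FALSE)
}
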