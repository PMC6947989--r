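#' File formats
#'
#' On-disk conventions: BED (0-based half-open) is read/written natively;
#' GTF stores 1-based inclusive coordinates and is converted on read/write;
#' loops are BEDPE (10 standard columns plus `cell_line`); tables are TSV
#' with a header. Variant TSVs store 1-based positions (`pos` column) and
#' are converted to the internal 0-based convention on read.
#'
#' @name menclink-io
NULL

#' @describeIn menclink-io read a BED3/BED6 file into an interval table.
#' @param path file path.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(d) <- c("chrom", "start", "end", "name", "score",
                "strand")[seq_len(min(6, ncol(d)))]
  strand <- if ("strand" %in% names(d))
    ifelse(d$strand == ".", "*", d$strand) else "*"
  gi <- genomic_intervals(d$chrom, d$start, d$end, strand)
  if ("name" %in% names(d)) gi$name <- d$name
  gi
}

#' @describeIn menclink-io write intervals as BED (BED6 when `name`
#'   present).
#' @param intervals interval data frame.
#' @export
write_bed <- function(intervals, path) {
  d <- as.data.frame(intervals)
  out <- data.frame(chrom = d$chrom, start = format(d$start, scientific = FALSE, trim = TRUE),
                    end = format(d$end, scientific = FALSE, trim = TRUE))
  if (!is.null(d$name)) {
    out$name <- d$name
    out$score <- if (is.null(d$score)) 0 else d$score
    out$strand <- if (is.null(d$strand)) "." else
      ifelse(d$strand == "*", ".", d$strand)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @describeIn menclink-io write gene models as GTF2.2 (exon rows with
#'   gene_id/transcript_id attributes; 1-based inclusive on disk).
#' @param genes a [gene_models()] table.
#' @export
write_gtf <- function(genes, path) {
  g <- as.data.frame(genes)
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                   g$gene_id, g$transcript_id, g$biotype)
  out <- data.frame(seqname = g$chrom, source = "menclink", feature = "exon",
                    start = format(g$start + 1, scientific = FALSE, trim = TRUE),
                    end = format(g$end, scientific = FALSE, trim = TRUE),
                    score = ".",
                    strand = ifelse(g$strand == "*", ".", g$strand),
                    frame = ".", attribute = attrs)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

gtf_attr <- function(attr, key) {
  m <- regmatches(attr, regexpr(paste0(key, ' "[^"]*"'), attr))
  ifelse(lengths(regmatches(attr, gregexpr(paste0(key, ' "'), attr))) > 0,
         sub(paste0(key, ' "([^"]*)"'), "\\1", m), NA_character_)
}

#' @describeIn menclink-io read exon rows of a GTF into a [gene_models()]
#'   table (converted to 0-based half-open).
#' @export
read_gtf <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "#", stringsAsFactors = FALSE,
                         col.names = c("seqname", "source", "feature", "start",
                                       "end", "score", "strand", "frame",
                                       "attribute"))
  d <- d[d$feature == "exon", , drop = FALSE]
  bio <- gtf_attr(d$attribute, "gene_biotype")
  bio[is.na(bio)] <- "other"
  gene_models(data.frame(gene_id = gtf_attr(d$attribute, "gene_id"),
                         transcript_id = gtf_attr(d$attribute, "transcript_id"),
                         chrom = d$seqname, start = d$start - 1, end = d$end,
                         strand = ifelse(d$strand == ".", "*", d$strand),
                         biotype = bio, stringsAsFactors = FALSE))
}

#' @describeIn menclink-io read a variant TSV (`signal_id`, `variant_id`,
#'   `chrom`, `pos` 1-based, `p_assoc`) into a [risk_signals()] table.
#' @export
read_variants <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  d$pos <- d$pos - 1
  risk_signals(d)
}

#' @describeIn menclink-io write a [risk_signals()]/CCV table as TSV
#'   (positions back to 1-based).
#' @param variants variant data frame.
#' @export
write_variants <- function(variants, path) {
  d <- as.data.frame(variants)
  d$pos <- d$pos + 1
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn menclink-io write CCVs as BED6 with the signal id in the
#'   name field.
#' @param ccvs a [derive_ccvs()] table.
#' @export
write_ccv_bed <- function(ccvs, path) {
  iv <- genomic_intervals(ccvs$chrom, ccvs$pos, ccvs$pos + 1, "*")
  iv$name <- paste0(ccvs$signal_id, ":", ccvs$variant_id)
  write_bed(iv, path)
}

#' @describeIn menclink-io read loops from BEDPE
#'   (chrom1,start1,end1,chrom2,start2,end2,name,score,strand1,strand2,
#'   cell_line).
#' @export
read_bedpe <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2", "cell_line")
  names(d) <- cols[seq_len(ncol(d))]
  if (is.null(d$cell_line)) d$cell_line <- "NA"
  chromatin_loops(d)
}

#' @describeIn menclink-io write loops as BEDPE.
#' @param loops a [chromatin_loops()] table.
#' @export
write_bedpe <- function(loops, path) {
  d <- as.data.frame(loops)
  if (is.null(d$score)) d$score <- 0
  out <- d[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
               "name")]
  out$score <- d$score
  out$strand1 <- "."
  out$strand2 <- "."
  out$cell_line <- d$cell_line
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @describeIn menclink-io read a TSV with rownames in the first column as
#'   a numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(d)
}

#' @describeIn menclink-io write a numeric matrix as TSV (rownames in
#'   column `id`).
#' @param m matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn menclink-io write any data frame as a TSV with header.
#' @param df data frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn menclink-io read a TSV with header.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
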