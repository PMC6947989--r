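#' Genomic intervals
#'
#' Intervals throughout this package are plain data frames with columns
#' `chrom`, `start`, `end` (0-based, half-open: `start` inclusive, `end`
#' exclusive) and optionally `strand` (`"+"`, `"-"` or `"*"`). BED files map
#' onto this convention directly; GTF is converted on read/write.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `start < end`.
#' @param strand strand vector, recycled; defaults to `"*"` (unstranded).
#' @return A data.frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), strand = "*") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop("interval start must be non-negative")
  bad <- df$start >= df$end
  if (any(bad)) {
    stop("invalid interval (start >= end): ",
         paste0(df$chrom[bad][1], ":", df$start[bad][1], "-", df$end[bad][1]))
  }
  invisible(df)
}

as_intervals <- function(df) {
  if (is.null(df$strand)) df$strand <- "*"
  genomic_intervals(df$chrom, df$start, df$end, df$strand)
}

## conversion to/from GRanges (1-based closed)
gi_to_gr <- function(df) {
  strand <- if (is.null(df$strand)) "*" else df$strand
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end),
                         strand = strand)
}

gr_to_gi <- function(gr) {
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1,
                    GenomicRanges::end(gr),
                    as.character(GenomicRanges::strand(gr)))
}

#' Merge intervals into a disjoint sorted set
#'
#' Union of the input base-pair set: overlapping and book-ended (abutting)
#' intervals are merged, output sorted by (chrom, start). Strand is ignored
#' and dropped.
#'
#' @param intervals interval data frame (`chrom`, `start`, `end`).
#' @return `genomic_intervals` data frame, pairwise disjoint and sorted.
#' @export
merge_intervals <- function(intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) {
    return(genomic_intervals())
  }
  gr <- GenomicRanges::reduce(gi_to_gr(intervals), ignore.strand = TRUE)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  out <- gr_to_gi(gr)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Intersect two interval sets
#'
#' @param a,b interval data frames.
#' @return merged `genomic_intervals` covering the bp common to both.
#' @export
intersect_intervals <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(genomic_intervals())
  ## suppressWarnings: disjoint chromosome sets are a legitimate empty
  ## intersection, not a genome mismatch
  gr <- suppressWarnings(
    GenomicRanges::intersect(gi_to_gr(a), gi_to_gr(b), ignore.strand = TRUE))
  if (length(gr) == 0) return(genomic_intervals())
  out <- gr_to_gi(GenomicRanges::sort(gr, ignore.strand = TRUE))
  out[order(out$chrom, out$start), , drop = FALSE]
}

total_bp <- function(intervals) {
  if (nrow(intervals) == 0) return(0)
  m <- merge_intervals(intervals)
  sum(m$end - m$start)
}

#' Capture universe
#'
#' The union of the capture-probe target regions (the 1.5-Mb windows tiled
#' around GWAS risk signals). All enrichment statistics are conditioned on
#' this universe.
#'
#' @param regions interval data frame of capture regions.
#' @return list of class `capture_universe` with merged `regions` and
#'   `total_bp`.
#' @export
capture_universe <- function(regions) {
  validate_intervals(regions)
  if (nrow(regions) == 0) stop("capture universe must contain at least one region")
  merged <- merge_intervals(regions)
  structure(list(regions = merged, total_bp = sum(merged$end - merged$start)),
            class = "capture_universe")
}

#' @export
print.capture_universe <- function(x, ...) {
  cat(sprintf("capture_universe: %d region(s), %s bp\n",
              nrow(x$regions), format(x$total_bp, big.mark = ",")))
  invisible(x)
}

#' Base-pair coverage of a feature set within the capture universe
#'
#' The proportion of universe bp covered by the (merged) feature set — the
#' denominator of the fold-enrichment statistic.
#'
#' @param feature interval data frame.
#' @param universe a [capture_universe()].
#' @return list with `bp` (integer overlap) and `fraction` (`bp / total_bp`).
#' @export
coverage_within <- function(feature, universe) {
  stopifnot(inherits(universe, "capture_universe"))
  if (universe$total_bp <= 0) stop("empty capture universe")
  inter <- intersect_intervals(feature, universe$regions)
  bp <- if (nrow(inter) == 0) 0 else sum(inter$end - inter$start)
  list(bp = bp, fraction = bp / universe$total_bp)
}
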