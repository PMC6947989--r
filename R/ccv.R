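#' Risk signals and credible causal variants (CCVs)
#'
#' A risk-signal table has one row per variant: `signal_id`, `variant_id`,
#' `chrom`, `pos` (0-based base position; variants are treated as 1-bp
#' points), `p_assoc` in (0, 1]. A signal's lead variant is its minimum-p
#' variant (ties broken by lexicographic `variant_id`).
#'
#' @param variants data frame with the columns above.
#' @return data frame of class `risk_signals`.
#' @export
risk_signals <- function(variants) {
  req <- c("signal_id", "variant_id", "chrom", "pos", "p_assoc")
  stopifnot(all(req %in% names(variants)))
  if (nrow(variants) == 0) stop("empty variant list")
  if (any(variants$p_assoc <= 0 | variants$p_assoc > 1))
    stop("p_assoc must lie in (0, 1]")
  if (any(variants$pos < 0)) stop("variant pos must be non-negative")
  v <- variants[, req]
  v$signal_id <- as.character(v$signal_id)
  v$variant_id <- as.character(v$variant_id)
  v$chrom <- as.character(v$chrom)
  v <- v[order(v$signal_id, v$p_assoc, v$variant_id), , drop = FALSE]
  rownames(v) <- NULL
  class(v) <- c("risk_signals", "data.frame")
  v
}

#' Lead variant per signal (argmin p, ties by variant_id)
#' @param signals a [risk_signals()] table.
#' @return data frame, one row per signal.
#' @export
signal_leads <- function(signals) {
  v <- as.data.frame(signals)
  v <- v[order(v$signal_id, v$p_assoc, v$variant_id), , drop = FALSE]
  leads <- v[!duplicated(v$signal_id), , drop = FALSE]
  rownames(leads) <- NULL
  leads
}

#' Derive CCV sets: variants within two orders of magnitude of the lead p
#'
#' A variant belongs to the signal's credible causal variant (CCV) set iff
#' `p_assoc <= 100 * p_lead` (boundary inclusive). The lead always
#' qualifies.
#'
#' @param signals a [risk_signals()] table (one or many signals).
#' @return data frame of class `ccv_set`: the qualifying rows plus a logical
#'   `is_lead` column.
#' @export
derive_ccvs <- function(signals) {
  v <- as.data.frame(risk_signals(signals))
  leads <- signal_leads(v)
  p_lead <- stats::setNames(leads$p_assoc, leads$signal_id)
  lead_id <- stats::setNames(leads$variant_id, leads$signal_id)
  keep <- v$p_assoc <= 100 * p_lead[v$signal_id]
  out <- v[keep, , drop = FALSE]
  out$is_lead <- out$variant_id == lead_id[out$signal_id]
  rownames(out) <- NULL
  class(out) <- c("ccv_set", "data.frame")
  out
}

#' Intersect CCVs with a feature set
#'
#' A variant overlaps a feature iff its half-open 1-bp interval
#' `[pos, pos + 1)` intersects the feature interval.
#'
#' @param ccvs data frame with `variant_id`, `chrom`, `pos`.
#' @param features a `feature_set` (see [derive_features()]) or an interval
#'   data frame.
#' @param kind feature kind when `features` is a `feature_set`.
#' @return list: `variant_ids` (distinct overlapping variants), `count`.
#' @export
ccvs_in_feature <- function(ccvs, features, kind = "exon") {
  iv <- feature_intervals(features, kind)
  if (nrow(ccvs) == 0 || nrow(iv) == 0)
    return(list(variant_ids = character(), count = 0L))
  v_gr <- GenomicRanges::GRanges(ccvs$chrom,
                                 IRanges::IRanges(ccvs$pos + 1, width = 1))
  hit <- IRanges::overlapsAny(v_gr, gi_to_gr(iv), ignore.strand = TRUE)
  ids <- unique(ccvs$variant_id[hit])
  list(variant_ids = ids, count = length(ids))
}
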