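#' Fold enrichment of CCVs in an annotation, conditioned on the universe
#'
#' The proportion of CCVs overlapping the annotation divided by the
#' proportion of universe bp the (merged, universe-restricted) annotation
#' covers. CCVs outside the universe are dropped with a warning.
#'
#' @param ccvs data frame with `variant_id`, `chrom`, `pos`.
#' @param feature interval data frame.
#' @param universe a [capture_universe()].
#' @return fold enrichment (0 when both overlap and coverage are 0; `Inf`
#'   with a warning when coverage is 0 but overlap positive).
#' @export
fold_enrichment <- function(ccvs, feature, universe) {
  ccvs <- drop_outside_universe(ccvs, universe)
  n <- length(unique(ccvs$variant_id))
  if (n == 0) stop("no CCVs inside the capture universe")
  feat_in <- intersect_intervals(feature, universe$regions)
  k <- ccvs_in_feature(ccvs, feat_in)$count
  cov <- coverage_within(feature, universe)$fraction
  if (cov == 0) {
    if (k == 0) return(0)
    warning("CCV overlap with a zero-coverage feature; inconsistent inputs")
    return(Inf)
  }
  (k / n) / cov
}

drop_outside_universe <- function(ccvs, universe) {
  if (nrow(ccvs) == 0) return(ccvs)
  gr <- GenomicRanges::GRanges(ccvs$chrom,
                               IRanges::IRanges(ccvs$pos + 1, width = 1))
  inside <- IRanges::overlapsAny(gr, gi_to_gr(universe$regions),
                                 ignore.strand = TRUE)
  if (any(!inside))
    warning(sum(!inside), " CCV(s) outside the capture universe dropped")
  ccvs[inside, , drop = FALSE]
}

#' Base-pair hypergeometric overlap test
#'
#' Upper-tail probability of observing at least `k_in` of `n_ccv` CCV
#' positions inside the feature when positions are drawn without replacement
#' from the universe bp, of which `bp_feature_in_universe` are feature bp
#' (a bedtools-fisher-style contingency on bp units).
#'
#' @param k_in observed CCVs inside the feature.
#' @param n_ccv total CCVs in the universe.
#' @param bp_feature_in_universe feature bp within the universe.
#' @param bp_universe total universe bp.
#' @return one-sided p-value, P(X >= k_in).
#' @export
hypergeom_test <- function(k_in, n_ccv, bp_feature_in_universe, bp_universe) {
  if (bp_universe <= 0 || n_ccv <= 0)
    stop("degenerate totals for hypergeometric test")
  if (k_in > n_ccv || bp_feature_in_universe > bp_universe)
    stop("inconsistent hypergeometric arguments")
  stats::phyper(k_in - 1, m = bp_feature_in_universe,
                n = bp_universe - bp_feature_in_universe,
                k = n_ccv, lower.tail = FALSE)
}

## --- circular permutation machinery ------------------------------------

## Assign each transcript to the single capture region containing its
## feature pieces; returns per-transcript region index plus region-relative
## feature pieces clipped to the region.
prepare_permutation <- function(feature_df, universe) {
  regions <- universe$regions
  if (nrow(feature_df) == 0)
    return(list(pieces = data.frame(), tx = character(0), tx_region = integer(0)))
  f_gr <- gi_to_gr(feature_df)
  r_gr <- gi_to_gr(regions)
  hits <- GenomicRanges::findOverlaps(f_gr, r_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep <- qh[!duplicated(qh)]
  pieces <- feature_df[keep, c("chrom", "start", "end", "transcript_id"),
                       drop = FALSE]
  pieces$region <- sh[!duplicated(qh)]
  ## clip to region
  pieces$start <- pmax(pieces$start, regions$start[pieces$region])
  pieces$end <- pmin(pieces$end, regions$end[pieces$region])
  pieces <- pieces[pieces$end > pieces$start, , drop = FALSE]
  if (nrow(pieces) == 0)
    return(list(pieces = pieces, tx = character(0), tx_region = integer(0)))
  tx_reg <- tapply(pieces$region, pieces$transcript_id,
                   function(r) unique(r), simplify = FALSE)
  multi <- names(tx_reg)[vapply(tx_reg, length, 1L) > 1]
  if (length(multi))
    stop("transcript(s) span more than one capture region: ",
         paste(utils::head(multi, 3), collapse = ", "))
  tx <- names(tx_reg)
  tx_region <- vapply(tx_reg, `[[`, 1L, 1)
  ## transcript extent must fit its region
  for (t in tx) {
    i <- pieces$transcript_id == t
    r <- tx_region[[t]]
    L <- regions$end[r] - regions$start[r]
    if (max(pieces$end[i]) - min(pieces$start[i]) > L)
      stop("transcript longer than its capture region: ", t)
  }
  pieces$rel_start <- pieces$start - regions$start[pieces$region]
  list(pieces = pieces, tx = tx, tx_region = tx_region)
}

#' Circularly shift a transcript-grouped annotation within its capture region
#'
#' Reference (pure R) implementation of one structure-preserving
#' permutation: all feature pieces belonging to the same transcript move by
#' one shared offset, wrapping around the circularized capture region
#' containing the transcript. A piece crossing the region end splits in two.
#'
#' @param feature_df interval data frame with a `transcript_id` column.
#' @param universe a [capture_universe()].
#' @param delta optional named numeric (per transcript_id) of shift offsets;
#'   drawn uniformly on `[0, region_length)` when NULL.
#' @return shifted interval data frame (columns `chrom`, `start`, `end`,
#'   `transcript_id`).
#' @export
permute_annotation <- function(feature_df, universe, delta = NULL) {
  prep <- prepare_permutation(feature_df, universe)
  pieces <- prep$pieces
  if (nrow(pieces) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), transcript_id = character(),
                      stringsAsFactors = FALSE))
  regions <- universe$regions
  L_of <- regions$end - regions$start
  if (is.null(delta)) {
    delta <- vapply(prep$tx, function(t)
      floor(stats::runif(1) * L_of[prep$tx_region[[t]]]), numeric(1))
    names(delta) <- prep$tx
  }
  out <- vector("list", nrow(pieces))
  for (i in seq_len(nrow(pieces))) {
    r <- pieces$region[i]
    L <- L_of[r]
    d <- delta[[pieces$transcript_id[i]]] %% L
    len <- pieces$end[i] - pieces$start[i]
    ns <- (pieces$rel_start[i] + d) %% L
    ne <- ns + len
    base <- regions$start[r]
    if (ne <= L) {
      out[[i]] <- data.frame(chrom = pieces$chrom[i], start = base + ns,
                             end = base + ne,
                             transcript_id = pieces$transcript_id[i],
                             stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(chrom = pieces$chrom[i],
                             start = base + c(ns, 0),
                             end = base + c(L, ne - L),
                             transcript_id = pieces$transcript_id[i],
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Circular-permutation enrichment test for CCV/feature overlap
#'
#' The observed number of distinct CCVs overlapping the chosen feature kind
#' is compared against a null in which every transcript's features are
#' independently rotated around their circularized capture region
#' (`n` permutations; CCVs stay fixed). The empirical p is the fraction of
#' permutations with overlap >= observed; `add_one = TRUE` applies the
#' permutation-inclusive (n+1) correction.
#'
#' @param ccvs data frame (`variant_id`, `chrom`, `pos`), e.g. a
#'   [derive_ccvs()] result.
#' @param genes [gene_models()] providing the annotations.
#' @param feature_kind `"exon"`, `"intron"` or `"promoter"`.
#' @param universe [capture_universe()].
#' @param n number of permutations (default 1e5, as in the headline
#'   analysis).
#' @param seed integer seed; stored in the result for exact replay.
#' @param promoter_mode promoter definition when `feature_kind="promoter"`.
#' @param add_one use the (k+1)/(n+1) empirical p.
#' @return list of class `enrichment_result`: `feature_name`, `observed`,
#'   `expected_mean`, `ci95` (normal-approximation CI of the mean), `fold`,
#'   `p_empirical`, `p_hypergeom`, `n_permutations`, `seed`, `n_ccv`,
#'   `perm_counts`.
#' @export
permutation_test <- function(ccvs, genes, feature_kind = c("exon", "intron",
                                                           "promoter"),
                             universe, n = 1e5, seed = 1,
                             promoter_mode = "upstream500", add_one = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (n < 100) warning("fewer than 100 permutations; p estimate is coarse")
  feats <- derive_features(genes, promoter_mode = promoter_mode)
  feature_df <- feature_intervals(feats, feature_kind)

  ccvs <- drop_outside_universe(ccvs, universe)
  ccvs <- ccvs[!duplicated(ccvs$variant_id), , drop = FALSE]
  n_ccv <- nrow(ccvs)
  if (n_ccv == 0) stop("no CCVs inside the capture universe")

  prep <- prepare_permutation(feature_df, universe)
  pieces <- prep$pieces
  regions <- universe$regions

  feat_clipped <- if (nrow(pieces)) {
    genomic_intervals(pieces$chrom, pieces$start, pieces$end)
  } else genomic_intervals()
  observed <- ccvs_in_feature(ccvs, feat_clipped)$count

  ## map CCVs to their regions (region-relative coordinates)
  v_gr <- GenomicRanges::GRanges(ccvs$chrom,
                                 IRanges::IRanges(ccvs$pos + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(v_gr, gi_to_gr(regions),
                                      ignore.strand = TRUE)
  ccv_region <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]

  if (nrow(pieces)) {
    tx_index <- stats::setNames(seq_along(prep$tx) - 1L, prep$tx)
    withr_seed <- seed
    set.seed(withr_seed)
    counts <- perm_overlap_counts(
      feat_start = as.integer(pieces$rel_start),
      feat_len = as.integer(pieces$end - pieces$start),
      feat_tx = as.integer(tx_index[pieces$transcript_id]),
      tx_region = as.integer(unlist(prep$tx_region[prep$tx]) - 1L),
      ccv_pos = as.integer(ccvs$pos - regions$start[ccv_region]),
      ccv_region = as.integer(ccv_region - 1L),
      region_len = as.numeric(regions$end - regions$start),
      n_perm = as.integer(n))
  } else {
    counts <- integer(n)
  }

  expected_mean <- mean(counts)
  se <- stats::sd(counts) / sqrt(n)
  ge <- sum(counts >= observed)
  p_emp <- if (add_one) (ge + 1) / (n + 1) else ge / n
  cov <- coverage_within(feat_clipped, universe)
  structure(list(
    feature_name = feature_kind,
    observed = observed,
    expected_mean = expected_mean,
    ci95 = c(low = expected_mean - 1.96 * se, high = expected_mean + 1.96 * se),
    fold = fold_enrichment(ccvs, feat_clipped, universe),
    p_empirical = p_emp,
    p_hypergeom = hypergeom_test(observed, n_ccv, cov$bp, universe$total_bp),
    n_permutations = n, seed = seed, n_ccv = n_ccv,
    perm_counts = counts), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result [%s]: observed %d / %d CCVs; expected %.2f (95%% CI %.2f-%.2f)\n  fold %.3g; empirical p %.3g (n = %d, seed %d); hypergeometric p %.3g\n",
    x$feature_name, x$observed, x$n_ccv, x$expected_mean, x$ci95[["low"]],
    x$ci95[["high"]], x$fold, x$p_empirical, x$n_permutations, x$seed,
    x$p_hypergeom))
  invisible(x)
}

#' Tidy one-row summary of an enrichment result
#' @param x an `enrichment_result`.
#' @export
enrichment_row <- function(x) {
  data.frame(feature = x$feature_name, observed = x$observed,
             n_ccv = x$n_ccv, expected_mean = x$expected_mean,
             ci95_low = x$ci95[["low"]], ci95_high = x$ci95[["high"]],
             fold = x$fold, p_empirical = x$p_empirical,
             p_hypergeom = x$p_hypergeom, n_permutations = x$n_permutations,
             seed = x$seed, stringsAsFactors = FALSE)
}
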