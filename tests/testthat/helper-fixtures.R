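# shared in-code fixtures: tiny gene models, universes and oracles

toy_universe <- function(len = 1000, chrom = "chr1") {
  capture_universe(genomic_intervals(chrom, 0, len))
}

# one + strand transcript with two exons 1000-1100, 1200-1300
toy_gene <- function(strand = "+", gene_id = "G1", chrom = "chr1") {
  gene_models(data.frame(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".1"), chrom = chrom,
    start = c(1000, 1200), end = c(1100, 1300), strand = strand,
    biotype = "mencRNA", stringsAsFactors = FALSE))
}

toy_ccvs <- function(pos, chrom = "chr1", signal = "s1") {
  data.frame(signal_id = signal,
             variant_id = sprintf("%s_v%d", signal, seq_along(pos)),
             chrom = chrom, pos = pos,
             p_assoc = 1e-9, stringsAsFactors = FALSE)
}

# brute-force bp-set oracle: explicit per-bp membership over small regions
bp_set <- function(iv) {
  if (nrow(iv) == 0) return(character())
  unlist(lapply(seq_len(nrow(iv)), function(i)
    if (iv$end[i] > iv$start[i])
      paste0(iv$chrom[i], ":", seq(iv$start[i], iv$end[i] - 1)) else character()))
}

random_intervals <- function(n, max_pos = 500, chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(50, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + len)
}

# exact circular-rotation null: enumerate all L shifts of the annotation
# and return P(overlap >= observed) using the pure-R shift reference
exact_rotation_p <- function(ccvs, genes, feature_kind, universe,
                             promoter_mode = "upstream500") {
  feats <- derive_features(genes, promoter_mode = promoter_mode)
  fdf <- feature_intervals(feats, feature_kind)
  L <- universe$regions$end[1] - universe$regions$start[1]
  stopifnot(nrow(universe$regions) == 1)
  tx <- unique(fdf$transcript_id)
  stopifnot(length(tx) == 1)
  observed <- ccvs_in_feature(ccvs, fdf)$count
  overlaps <- vapply(seq_len(L) - 1, function(d) {
    shifted <- permute_annotation(fdf, universe,
                                  delta = stats::setNames(d, tx))
    ccvs_in_feature(ccvs, shifted)$count
  }, numeric(1))
  list(p = mean(overlaps >= observed), observed = observed,
       overlaps = overlaps)
}
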