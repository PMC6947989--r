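test_that("merge_intervals unions overlapping and abutting intervals", {
  expect_equal(nrow(merge_intervals(genomic_intervals())), 0)

  m <- merge_intervals(genomic_intervals("chr1", c(10, 15), c(20, 30)))
  expect_equal(as.data.frame(m)[, 1:3],
               data.frame(chrom = "chr1", start = 10, end = 30))

  ## half-open abutting intervals merge; chromosomes stay separate
  m2 <- merge_intervals(genomic_intervals(c("chr1", "chr2", "chr1"),
                                          c(0, 0, 5), c(5, 5, 8)))
  expect_equal(as.data.frame(m2)[, 1:3],
               data.frame(chrom = c("chr1", "chr2"), start = c(0, 0),
                          end = c(8, 5)))

  expect_error(merge_intervals(data.frame(chrom = "chr1", start = 5, end = 5)),
               "invalid interval")
})

test_that("coverage_within measures merged feature bp inside the universe", {
  u <- toy_universe(1000)
  expect_equal(coverage_within(u$regions, u)$fraction, 1.0)
  expect_equal(coverage_within(genomic_intervals("chr9", 0, 100), u)$fraction, 0)

  ## overlapping feature pieces are unioned before measuring
  cov <- coverage_within(genomic_intervals("chr1", c(100, 150), c(200, 250)), u)
  expect_equal(cov$bp, 150)
  expect_equal(cov$fraction, 0.15)
})

test_that("interval algebra agrees with the brute-force bp-set oracle", {
  set.seed(42)
  for (i in 1:20) {
    a <- random_intervals(sample(0:8, 1))
    b <- random_intervals(sample(1:8, 1))
    expect_setequal(bp_set(merge_intervals(a)), unique(bp_set(a)))
    expect_setequal(bp_set(intersect_intervals(a, b)),
                    intersect(unique(bp_set(a)), unique(bp_set(b))))
    u <- capture_universe(b)
    expect_equal(coverage_within(a, u)$bp,
                 length(intersect(unique(bp_set(a)), unique(bp_set(b)))))
  }
})

test_that("coverage fraction is additive over disjoint universes", {
  feat <- genomic_intervals("chr1", c(50, 700), c(150, 760))
  u1 <- capture_universe(genomic_intervals("chr1", 0, 500))
  u2 <- capture_universe(genomic_intervals("chr1", 500, 1000))
  u <- capture_universe(genomic_intervals("chr1", c(0, 500), c(500, 1000)))
  expect_equal(coverage_within(feat, u)$bp,
               coverage_within(feat, u1)$bp + coverage_within(feat, u2)$bp)
})

test_that("derive_features computes introns and strand-aware promoters", {
  g <- toy_gene("+")
  f <- derive_features(g, "upstream500")
  expect_equal(f$introns[, c("start", "end")], data.frame(start = 1100, end = 1200))
  expect_equal(f$promoters[, c("start", "end")], data.frame(start = 500, end = 1000))

  f2 <- derive_features(g, "flank500")
  expect_equal(f2$promoters[, c("start", "end")],
               data.frame(start = 500, end = 1501))
  expect_equal(f2$promoters$end - f2$promoters$start, 1001)

  gm <- toy_gene("-")
  fm <- derive_features(gm, "upstream500")
  expect_equal(fm$promoters[, c("start", "end")],
               data.frame(start = 1300, end = 1800))

  gu <- toy_gene("*")
  expect_error(derive_features(gu, "upstream500"), "unstranded.*G1.1")
  expect_silent(derive_features(gu, "flank500"))
})

test_that("promoters are truncated at position zero", {
  g <- gene_models(data.frame(gene_id = "G", transcript_id = "G.1",
                              chrom = "chr1", start = 100, end = 300,
                              strand = "+", biotype = "mencRNA"))
  f <- derive_features(g, "upstream500")
  expect_equal(f$promoters$start, 0)
  expect_equal(f$promoters$end, 100)
})

test_that("exon plus intron intervals reconstruct each transcript span", {
  set.seed(11)
  cfg <- sim_config(seed = 11, n_regions = 2, region_length = 1e5)
  genes <- simulate_genome(cfg)$genes
  f <- derive_features(genes, "flank500")
  span <- transcript_spans(genes)
  for (tx in span$transcript_id) {
    both <- rbind(f$exons[f$exons$transcript_id == tx, 1:3],
                  f$introns[f$introns$transcript_id == tx, 1:3])
    m <- merge_intervals(both)
    expect_equal(nrow(m), 1)
    expect_equal(m$start, span$start[span$transcript_id == tx])
    expect_equal(m$end, span$end[span$transcript_id == tx])
  }
})

test_that("filter_transcripts applies the removal rules with reason codes", {
  u <- toy_universe(1e5)
  cand <- gene_models(data.frame(
    gene_id = c("single",
                "low", "low",
                "ok", "ok",
                "outside", "outside",
                "coding_hit", "coding_hit"),
    transcript_id = c("single.1",
                      "low.1", "low.1",
                      "ok.1", "ok.1",
                      "outside.1", "outside.1",
                      "coding_hit.1", "coding_hit.1"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr9", "chr9",
              "chr1", "chr1"),
    start = c(100, 200, 400, 1000, 3000, 100, 300, 5000, 5300),
    end = c(150, 260, 460, 1200, 3200, 200, 400, 5100, 5400),
    strand = "+", biotype = "mencRNA", stringsAsFactors = FALSE))
  coding <- gene_models(data.frame(gene_id = "PC1", transcript_id = "PC1.1",
                                   chrom = "chr1", start = 5050, end = 5080,
                                   strand = "+", biotype = "protein_coding"))
  fpkm <- c(single = 10, low = 0.4, ok = 3, outside = 3, coding_hit = 3)
  res <- filter_transcripts(cand, fpkm, u, coding)
  expect_setequal(unique(res$genes$gene_id), "ok")
  reasons <- setNames(res$removed$reason, res$removed$id)
  expect_equal(reasons[["low"]], "low_expression")
  expect_equal(reasons[["outside"]], "outside_universe")
  expect_equal(reasons[["coding_hit"]], "coding_overlap")

  ## single-exon removal dominates even at high expression
  single_only <- gene_models(data.frame(gene_id = "s", transcript_id = "s.1",
                                        chrom = "chr1", start = 10, end = 400,
                                        strand = "+", biotype = "mencRNA"))
  r2 <- filter_transcripts(single_only, c(s = 10), u)
  expect_equal(nrow(r2$genes), 0)
  expect_equal(r2$removed$reason, "single_exon")

  ## coding overlap counts only on the same strand
  opp_coding <- gene_models(data.frame(gene_id = "PC1", transcript_id = "PC1.1",
                                       chrom = "chr1", start = 5050, end = 5080,
                                       strand = "-", biotype = "protein_coding"))
  r3 <- filter_transcripts(cand, fpkm, u, opp_coding)
  expect_true("coding_hit" %in% r3$genes$gene_id)
})

test_that("filter_transcripts drops low-FPKM isoforms and is idempotent", {
  u <- toy_universe(1e5)
  g <- gene_models(data.frame(
    gene_id = "G", transcript_id = c("G.1", "G.1", "G.2", "G.2"),
    chrom = "chr1", start = c(100, 300, 100, 500), end = c(150, 350, 150, 560),
    strand = "+", biotype = "mencRNA", stringsAsFactors = FALSE))
  res <- filter_transcripts(g, c(G = 5), u,
                            isoform_fpkm = c(G.1 = 2, G.2 = 0.005))
  expect_setequal(unique(res$genes$transcript_id), "G.1")
  expect_true(any(res$removed$reason == "low_isoform_expression"))

  again <- filter_transcripts(res$genes, c(G = 5), u,
                              isoform_fpkm = c(G.1 = 2, G.2 = 0.005))
  expect_equal(as.data.frame(again$genes), as.data.frame(res$genes))
  expect_equal(nrow(again$removed), 0)
})

test_that("merge_annotations resolves overlaps by captured expression", {
  cap <- toy_gene(gene_id = "CAP")
  ref <- gene_models(data.frame(gene_id = "REF", transcript_id = "REF.1",
                                chrom = "chr1", start = c(1050, 1250),
                                end = c(1150, 1350), strand = "+",
                                biotype = "other", stringsAsFactors = FALSE))
  lowly <- merge_annotations(cap, c(CAP = 0.3), ref)
  expect_false("CAP" %in% lowly$genes$gene_id)
  expect_true("REF" %in% lowly$genes$gene_id)

  highly <- merge_annotations(cap, c(CAP = 2), ref)
  expect_true("CAP" %in% highly$genes$gene_id)
  expect_false("REF" %in% highly$genes$gene_id)
})

test_that("merge_annotations excludes opposite-strand coding-exon overlap of 1 bp", {
  cap <- toy_gene(gene_id = "CAP", strand = "+")
  ## minus-strand coding exon sharing exactly 1 bp with CAP's first exon
  ref <- gene_models(data.frame(gene_id = "PC", transcript_id = "PC.1",
                                chrom = "chr1", start = 1099, end = 1180,
                                strand = "-", biotype = "protein_coding"))
  res <- merge_annotations(cap, c(CAP = 5), ref)
  expect_false("CAP" %in% res$genes$gene_id)
  expect_equal(res$log$reason[res$log$id == "CAP"],
               "opposite_strand_coding_overlap")

  ## no shared bp (half-open: coding starts at CAP's exon end) -> kept
  ref2 <- gene_models(data.frame(gene_id = "PC", transcript_id = "PC.1",
                                 chrom = "chr1", start = 1100, end = 1180,
                                 strand = "-", biotype = "protein_coding"))
  res2 <- merge_annotations(cap, c(CAP = 5), ref2)
  expect_true("CAP" %in% res2$genes$gene_id)
})
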