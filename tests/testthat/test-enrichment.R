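test_that("fold_enrichment is the CCV proportion over the coverage proportion", {
  ## feature covering 10% of the universe with 10% of CCVs inside -> 1.0
  u <- toy_universe(1000)
  feat <- genomic_intervals("chr1", 0, 100)
  ccvs <- toy_ccvs(c(50, seq(150, 950, by = 100)))  # 1 of 10 inside
  expect_equal(fold_enrichment(ccvs, feat, u), 1.0)

  ## 1 Mb universe, 50 kb feature, 20/100 CCVs inside -> 0.20/0.05 = 4
  u2 <- toy_universe(1e6)
  feat2 <- genomic_intervals("chr1", 0, 50000)
  pos <- c(seq(0, 49999, length.out = 20),            # inside feature
           seq(50000, 999999, length.out = 80))       # outside
  expect_equal(fold_enrichment(toy_ccvs(round(pos)), feat2, u2), 4.0)

  ## zero-coverage, zero-overlap -> 0 by convention
  expect_equal(fold_enrichment(toy_ccvs(500), genomic_intervals(), u), 0)

  ## CCVs outside the universe are dropped with a warning
  expect_warning(f <- fold_enrichment(toy_ccvs(c(50, 5000)), feat, u),
                 "outside")
  expect_equal(f, (1 / 1) / 0.1)
  expect_error(suppressWarnings(fold_enrichment(toy_ccvs(5000), feat, u)),
               "no CCVs")
})

test_that("hypergeometric test matches closed form and brute enumeration", {
  ## P(X >= 0) = 1 always
  expect_equal(hypergeom_test(0, 5, 10, 100), 1)
  ## feature = universe -> certain event
  expect_equal(hypergeom_test(3, 3, 50, 50), 1)

  ## 20-bp universe, 10-bp feature, both of 2 CCVs inside:
  ## closed form C(10,2)/C(20,2) = 45/190
  p <- hypergeom_test(2, 2, 10, 20)
  expect_equal(p, 45 / 190)

  ## brute force: enumerate all 190 unordered position pairs
  pairs <- t(utils::combn(20, 2))
  both_in <- rowSums(pairs <= 10) == 2
  expect_equal(p, mean(both_in))

  expect_error(hypergeom_test(2, 2, 30, 20), "inconsistent")
  expect_error(hypergeom_test(0, 0, 10, 20), "degenerate")
})

test_that("permute_annotation preserves sizes, spacing, and wraps modulo the region", {
  u <- toy_universe(10)
  exon <- data.frame(chrom = "chr1", start = 2, end = 4, strand = "+",
                     gene_id = "g", transcript_id = "t")

  ## delta = 0 is the identity
  s0 <- permute_annotation(exon, u, delta = c(t = 0))
  expect_equal(s0[, c("start", "end")], data.frame(start = 2, end = 4))

  ## delta = 7 wraps into two pieces {9-10, 0-1}
  s7 <- permute_annotation(exon, u, delta = c(t = 7))
  expect_setequal(paste(s7$start, s7$end), c("9 10", "0 1"))
  expect_equal(sum(s7$end - s7$start), 2)

  ## intra-transcript spacing is preserved under any shift (mod wrap)
  u2 <- toy_universe(1000)
  two <- data.frame(chrom = "chr1", start = c(100, 120), end = c(110, 130),
                    strand = "+", gene_id = "g",
                    transcript_id = c("t", "t"))
  for (d in c(0, 1, 500, 880, 999)) {
    s <- permute_annotation(two, u2, delta = c(t = d))
    expect_equal(sum(s$end - s$start), 20)  # total bp conserved
    covered <- sort(unlist(Map(seq, s$start, s$end - 1)))
    starts_mod <- sort((c(100, 120) + d) %% 1000)
    expect_true(all(((covered - d) %% 1000) %in%
                      c(100:109, 120:129)))
  }
})

test_that("transcripts spanning regions or exceeding region length error", {
  u <- capture_universe(genomic_intervals(c("chr1", "chr1"), c(0, 100),
                                          c(50, 200)))
  spanning <- data.frame(chrom = "chr1", start = c(10, 120),
                         end = c(20, 130), strand = "+", gene_id = "g",
                         transcript_id = c("t", "t"))
  expect_error(permute_annotation(spanning, u), "span more than one")
})

test_that("Monte-Carlo empirical p matches the exact rotation null on a toy region", {
  ## single region of length 10, single-exon transcript 0-2, CCV at 5:
  ## exact enumeration of all 10 rotations
  u <- toy_universe(10)
  g <- gene_models(data.frame(gene_id = "g", transcript_id = "g.1",
                              chrom = "chr1", start = 0, end = 2,
                              strand = "+", biotype = "mencRNA"))
  outside <- toy_ccvs(5)
  ex <- exact_rotation_p(outside, g, "exon", u)
  expect_equal(ex$observed, 0)
  expect_equal(ex$p, 1)  # every rotation overlaps >= 0

  res <- permutation_test(outside, g, "exon", u, n = 2000, seed = 9)
  expect_equal(res$p_empirical, 1)

  ## CCV placed inside the exon: observed 1; rotations hitting pos 1 are
  ## delta in {0, 1} -> exact p = 2/10
  inside <- toy_ccvs(1)
  ex2 <- exact_rotation_p(inside, g, "exon", u)
  expect_equal(ex2$observed, 1)
  expect_equal(ex2$p, 2 / 10)
  res2 <- permutation_test(inside, g, "exon", u, n = 20000, seed = 9)
  se <- sqrt(ex2$p * (1 - ex2$p) / 20000)
  expect_lt(abs(res2$p_empirical - ex2$p), 3 * se)
})

test_that("a feature saturating the universe gives empirical p 1", {
  u <- toy_universe(100)
  g <- gene_models(data.frame(gene_id = "g", transcript_id = "g.1",
                              chrom = "chr1", start = 0, end = 100,
                              strand = "+", biotype = "mencRNA"))
  res <- permutation_test(toy_ccvs(c(10, 60)), g, "exon", u, n = 500,
                          seed = 1)
  expect_equal(res$observed, 2)
  expect_equal(res$expected_mean, 2)
  expect_equal(res$p_empirical, 1)
})

test_that("permutation replay is deterministic and CIs bracket the mean", {
  u <- toy_universe(5000)
  g <- toy_gene()
  ccvs <- toy_ccvs(c(1050, 1150, 2500, 4000))
  a <- permutation_test(ccvs, g, "exon", u, n = 1000, seed = 42)
  b <- permutation_test(ccvs, g, "exon", u, n = 1000, seed = 42)
  expect_identical(a, b)
  c2 <- permutation_test(ccvs, g, "exon", u, n = 1000, seed = 43)
  expect_false(identical(a$perm_counts, c2$perm_counts))
  expect_lte(a$ci95[["low"]], a$expected_mean)
  expect_gte(a$ci95[["high"]], a$expected_mean)
  expect_warning(permutation_test(ccvs, g, "exon", u, n = 50, seed = 1),
                 "fewer than 100")
})

test_that("long-run permutation mean approaches CCV count times coverage", {
  ## law of large numbers: expected overlap per CCV converges to the
  ## feature's coverage fraction under the circular null
  u <- toy_universe(2000)
  g <- toy_gene()  # 200 exonic bp / 2000 -> coverage 0.1
  ccvs <- toy_ccvs(c(300, 700, 1500, 1900, 550))
  cov <- coverage_within(derive_features(g, "flank500")$exons, u)$fraction
  means <- vapply(1:10, function(s)
    permutation_test(ccvs, g, "exon", u, n = 4000, seed = s)$expected_mean,
    numeric(1))
  expected <- nrow(ccvs) * cov
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se + 1e-9)
})

test_that("every permutation conserves total feature bp (kernel vs R reference)", {
  ## cross-check the compiled kernel against the pure-R shift on a grid of
  ## deterministic offsets: per-offset overlap counts must agree
  u <- capture_universe(genomic_intervals(c("chr1", "chr2"), c(0, 0),
                                          c(60, 40)))
  g <- gene_models(data.frame(
    gene_id = c("a", "a", "b"), transcript_id = c("a.1", "a.1", "b.1"),
    chrom = c("chr1", "chr1", "chr2"), start = c(5, 20, 10),
    end = c(10, 28, 18), strand = "+", biotype = "mencRNA",
    stringsAsFactors = FALSE))
  feats <- derive_features(g, "flank500")$exons
  ccvs <- toy_ccvs(c(7, 25, 50), chrom = "chr1")
  ccvs <- rbind(ccvs, toy_ccvs(c(12, 30), chrom = "chr2", signal = "s2"))
  for (d in list(c(a.1 = 0, b.1 = 0), c(a.1 = 13, b.1 = 33),
                 c(a.1 = 57, b.1 = 5))) {
    shifted <- permute_annotation(feats, u, delta = d)
    expect_equal(sum(shifted$end - shifted$start),
                 sum(feats$end - feats$start))
    ## R-reference overlap equals direct point-in-interval recount
    cnt <- ccvs_in_feature(ccvs, shifted)$count
    manual <- sum(vapply(seq_len(nrow(ccvs)), function(i)
      any(shifted$chrom == ccvs$chrom[i] &
            shifted$start <= ccvs$pos[i] & ccvs$pos[i] < shifted$end),
      logical(1)))
    expect_equal(cnt, manual)
  }
})
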