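test_that("link_exonic reports gene x signal records for exonic CCVs only", {
  g <- toy_gene()
  in_exon <- toy_ccvs(1050, signal = "s1")
  rec <- link_exonic(in_exon, g)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$route, "exon")
  expect_equal(rec$gene_id, "G1")
  expect_equal(rec$evidence_variants, "s1_v1")

  in_intron <- toy_ccvs(1150, signal = "s1")
  expect_equal(nrow(link_exonic(in_intron, g)), 0)

  ## CCVs of two signals in different exons of the same gene -> two records
  two <- rbind(toy_ccvs(1050, signal = "s2"), toy_ccvs(1250, signal = "s3"))
  rec2 <- link_exonic(two, g)
  expect_equal(nrow(rec2), 2)
  expect_setequal(rec2$signal_id, c("s2", "s3"))
  expect_equal(unique(rec2$gene_id), "G1")
})

test_that("link_promoter honours the promoter definition in use", {
  g <- toy_gene()  # + strand TSS at 1000
  up100 <- toy_ccvs(900)
  expect_equal(nrow(link_promoter(up100, g, "upstream500")), 1)
  up600 <- toy_ccvs(400)
  expect_equal(nrow(link_promoter(up600, g, "upstream500")), 0)

  down300 <- toy_ccvs(1300 - 1)  # 299 bp downstream of TSS, inside exon 1? no: pos 1299 is exon2; use 1200 < flank end 1501
  down300 <- toy_ccvs(1000 + 300)
  expect_equal(nrow(link_promoter(down300, g, "flank500")), 1)
  expect_equal(nrow(link_promoter(down300, g, "upstream500")), 0)
})

test_that("link_loops requires promoter and CCV on opposite anchors", {
  g <- toy_gene()  # flank500 promoter: 500-1501
  loops <- data.frame(chrom1 = "chr1", start1 = 400, end1 = 1600,
                      chrom2 = "chr1", start2 = 8000, end2 = 9000,
                      name = "L1", cell_line = "MCF7")
  ccv_far <- toy_ccvs(8500)
  rec <- link_loops(ccv_far, g, loops)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$route, "loop")
  expect_equal(rec$cell_line, "MCF7")
  expect_equal(rec$evidence_loops, "L1")

  ## CCV and promoter in the same anchor, other anchor empty -> no record
  ccv_same <- toy_ccvs(600)
  expect_equal(nrow(link_loops(ccv_same, g, loops)), 0)

  ## anchor order is irrelevant
  swapped <- data.frame(chrom1 = "chr1", start1 = 8000, end1 = 9000,
                        chrom2 = "chr1", start2 = 400, end2 = 1600,
                        name = "L1", cell_line = "MCF7")
  rec_sw <- link_loops(ccv_far, g, swapped)
  expect_equal(rec_sw[, c("gene_id", "signal_id", "route", "cell_line",
                          "evidence_variants")],
               rec[, c("gene_id", "signal_id", "route", "cell_line",
                       "evidence_variants")])

  ## same link seen in two cell lines -> one record per cell line
  twocl <- rbind(loops, transform(loops, name = "L2", cell_line = "T47D"))
  rec2 <- link_loops(ccv_far, g, twocl)
  expect_equal(nrow(rec2), 2)
  expect_setequal(rec2$cell_line, c("MCF7", "T47D"))
})

test_that("loop records verify against their stated geometry", {
  ## re-intersecting each record's evidence reproduces the record
  set.seed(21)
  cfg <- sim_config(seed = 21, n_regions = 3, region_length = 2e5,
                    n_loops = 30)
  genome <- simulate_genome(cfg)
  sig <- simulate_signals(cfg, genome)
  loops <- simulate_loops(cfg, genome, sig)
  menc <- as.data.frame(genome$genes)
  menc <- gene_models(menc[menc$biotype == "mencRNA", ])
  ccvs <- derive_ccvs(sig$signals)
  rec <- link_loops(ccvs, menc, loops$loops)
  prom <- derive_features(menc, "flank500")$promoters
  for (i in seq_len(nrow(rec))) {
    vids <- strsplit(rec$evidence_variants[i], ",")[[1]]
    lids <- strsplit(rec$evidence_loops[i], ",")[[1]]
    l <- as.data.frame(loops$loops)
    l <- l[l$name %in% lids, , drop = FALSE]
    v <- ccvs[ccvs$variant_id %in% vids, , drop = FALSE]
    p <- prom[prom$gene_id == rec$gene_id[i], , drop = FALSE]
    ok <- FALSE
    for (j in seq_len(nrow(l))) {
      p_in_1 <- any(p$start < l$end1[j] & l$start1[j] < p$end)
      p_in_2 <- any(p$start < l$end2[j] & l$start2[j] < p$end)
      v_in_1 <- any(l$start1[j] <= v$pos & v$pos < l$end1[j])
      v_in_2 <- any(l$start2[j] <= v$pos & v$pos < l$end2[j])
      if ((p_in_1 && v_in_2) || (p_in_2 && v_in_1)) ok <- TRUE
    }
    expect_true(ok, info = paste("record", i))
  }
})

test_that("multi_signal_targets needs records from two distinct signals", {
  rec <- rbind(
    data.frame(gene_id = "G1", signal_id = "s1", route = "exon",
               cell_line = NA, evidence_variants = "v1",
               evidence_loops = NA),
    data.frame(gene_id = "G1", signal_id = "s2", route = "loop",
               cell_line = "MCF7", evidence_variants = "v2",
               evidence_loops = "L1"),
    data.frame(gene_id = "G2", signal_id = "s3", route = "exon",
               cell_line = NA, evidence_variants = "v3",
               evidence_loops = NA),
    data.frame(gene_id = "G2", signal_id = "s3", route = "promoter",
               cell_line = NA, evidence_variants = "v4",
               evidence_loops = NA))
  out <- multi_signal_targets(rec)
  expect_equal(out$gene_id, "G1")
  expect_equal(out$n_signals, 2L)
  expect_equal(out$routes, "exon,loop")

  expect_equal(nrow(multi_signal_targets(rec[0, ])), 0)
})

test_that("planted linkage triples are recovered exactly from a synthetic bundle", {
  cfg <- sim_config(seed = 31, n_regions = 4, region_length = 2e5,
                    n_loops = 24, loop_promoter_fraction = 0.5)
  genome <- simulate_genome(cfg)
  sig <- simulate_signals(cfg, genome)
  loops <- simulate_loops(cfg, genome, sig)
  menc <- as.data.frame(genome$genes)
  menc <- gene_models(menc[menc$biotype == "mencRNA", ])
  ccvs <- derive_ccvs(sig$signals)

  rec <- rbind(link_exonic(ccvs, menc),
               link_promoter(ccvs, menc, "flank500"),
               link_loops(ccvs, menc, loops$loops))

  ann <- sig$ccv_annotation
  truth <- rbind(
    do.call(rbind, lapply(which(!is.na(ann$exon_gene)), function(i)
      data.frame(gene_id = strsplit(ann$exon_gene[i], ",")[[1]],
                 signal_id = ann$signal_id[i], route = "exon"))),
    do.call(rbind, lapply(which(!is.na(ann$promoter_gene_flank500)),
      function(i)
        data.frame(gene_id = strsplit(ann$promoter_gene_flank500[i], ",")[[1]],
                   signal_id = ann$signal_id[i], route = "promoter"))),
    if (nrow(loops$manifest))
      data.frame(gene_id = loops$manifest$gene_id,
                 signal_id = loops$manifest$signal_id, route = "loop"))
  truth_keys <- sort(unique(paste(truth$gene_id, truth$signal_id,
                                  truth$route)))
  got_keys <- sort(unique(paste(rec$gene_id, rec$signal_id, rec$route)))
  expect_identical(got_keys, truth_keys)
})
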