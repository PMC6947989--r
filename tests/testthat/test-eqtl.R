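test_that("normalize_expression matches the hand-worked quantile example", {
  ## samples {0,3} and {1,7}: log2(+1) -> {0,2} and {1,3};
  ## mean order statistics {0.5, 2.5} replace both samples' sorted values
  m <- cbind(s1 = c(0, 3), s2 = c(1, 7))
  out <- normalize_expression(m)
  expect_equal(unname(out[, "s1"]), c(0.5, 2.5))
  expect_equal(unname(out[, "s2"]), c(0.5, 2.5))

  ## identical samples: quantile step is a fixed point
  m2 <- cbind(a = c(0, 3, 8), b = c(0, 3, 8))
  expect_equal(unname(normalize_expression(m2)), unname(log2(m2 + 1)))

  expect_warning(normalize_expression(matrix(1:3, ncol = 1)),
                 "single-sample")
  expect_error(normalize_expression(matrix(-1)), "non-negative")
})

test_that("after quantile normalization every sample has identical sorted values", {
  set.seed(3)
  m <- matrix(rexp(500, 1 / 5), nrow = 50)
  out <- normalize_expression(m)
  sorted <- apply(out, 2, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])
})

test_that("fit_eqtl recovers a noiseless linear effect exactly", {
  set.seed(8)
  n <- 60
  dose <- rbinom(n, 2, 0.4)
  expr <- matrix(0.5 * dose, nrow = 1,
                 dimnames = list("g1", sprintf("s%02d", 1:n)))
  geno <- matrix(dose, nrow = 1,
                 dimnames = list("v1", sprintf("s%02d", 1:n)))
  r <- fit_eqtl(geno, expr, data.frame(gene_id = "g1", variant_id = "v1"))
  expect_equal(r$beta, 0.5, tolerance = 1e-10)
  expect_lt(r$p, 1e-12)
})

test_that("fit_eqtl equals the closed-form OLS with one covariate", {
  set.seed(12)
  n <- 80
  dose <- rbinom(n, 2, 0.3)
  cn <- rnorm(n, 2, 0.4)
  y <- 1 + 0.6 * dose + 0.4 * cn + rnorm(n)
  sn <- sprintf("s%02d", 1:n)
  r <- fit_eqtl(matrix(dose, 1, dimnames = list("v", sn)),
                matrix(y, 1, dimnames = list("g", sn)),
                data.frame(gene_id = "g", variant_id = "v"),
                copy_number = matrix(cn, 1, dimnames = list("g", sn)))
  ref <- summary(lm(y ~ dose + cn))$coefficients["dose", ]
  expect_equal(r$beta, unname(ref["Estimate"]), tolerance = 1e-12)
  expect_equal(r$se, unname(ref["Std. Error"]), tolerance = 1e-12)
  expect_equal(r$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-12)
})

test_that("fit_eqtl skips monomorphic variants and misaligned samples error", {
  sn <- sprintf("s%02d", 1:10)
  geno <- matrix(c(rep(1, 10), rbinom(10, 2, .5)), 2, byrow = TRUE,
                 dimnames = list(c("mono", "ok"), sn))
  expr <- matrix(rnorm(10), 1, dimnames = list("g", sn))
  r <- fit_eqtl(geno, expr, data.frame(gene_id = "g",
                                       variant_id = c("mono", "ok")))
  expect_equal(r$variant_id, "ok")
  expect_true(any(grepl("monomorphic", attr(r, "skipped"))))

  bad <- expr; colnames(bad) <- rev(sn)
  expect_error(fit_eqtl(geno, bad, data.frame(gene_id = "g",
                                              variant_id = "ok")),
               "align")
})

test_that("permuted dosage gives approximately uniform p-values", {
  set.seed(77)
  n <- 100
  y <- rnorm(n)
  sn <- sprintf("s%03d", 1:n)
  ps <- replicate(400, {
    dose <- rbinom(n, 2, 0.3)
    fit_eqtl(matrix(dose, 1, dimnames = list("v", sn)),
             matrix(y, 1, dimnames = list("g", sn)),
             data.frame(gene_id = "g", variant_id = "v"))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("planted beta 0.5 is recovered at the OLS standard-error rate", {
  ## maf 0.4, n 500, noise sd 1: se = 1/sqrt(n * 2*maf*(1-maf)) = 0.0645,
  ## so |error| <= 0.15 = 2.33 se in ~98% of draws — require >= 95%
  maf <- 0.4; n <- 500
  est <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    dose <- rbinom(n, 2, maf)
    y <- 2 + 0.5 * dose + rnorm(n, 0, 1)
    sn <- sprintf("s%03d", 1:n)
    fit_eqtl(matrix(dose, 1, dimnames = list("v", sn)),
             matrix(y, 1, dimnames = list("g", sn)),
             data.frame(gene_id = "g", variant_id = "v"))$beta
  }, numeric(1))
  expect_gte(mean(abs(est - 0.5) <= 0.15), 0.95)
  ## spread of estimates matches the theoretical standard error
  se_theory <- 1 / sqrt(n * 2 * maf * (1 - maf))
  expect_equal(sd(est), se_theory, tolerance = 0.35)
})

test_that("bh_fdr reproduces the step-up worked examples", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  ## monotone in ranked p
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("eqtl_signal_overlap applies the two-orders rule on eQTL p-values", {
  gr <- data.frame(gene_id = "g", variant_id = c("top", "cc1", "other"),
                   beta = 1, se = 1, p = c(1e-10, 5e-9, 1e-3),
                   stringsAsFactors = FALSE)
  ccvs <- data.frame(variant_id = "cc1")
  ov <- eqtl_signal_overlap(gr, ccvs)
  expect_true(ov$overlaps)          # 5e-9 <= 100 * 1e-10
  expect_equal(ov$top_variant, "top")
  expect_equal(ov$best_ccv, "cc1")

  gr$p <- c(1e-10, 5e-7, 1e-3)
  expect_false(eqtl_signal_overlap(gr, ccvs)$overlaps)

  ## the top variant itself a CCV always overlaps
  expect_true(eqtl_signal_overlap(gr, data.frame(variant_id = "top"))$overlaps)

  ## no CCV among tested variants
  ov2 <- eqtl_signal_overlap(gr, data.frame(variant_id = "absent"))
  expect_false(ov2$overlaps)
  expect_equal(ov2$reason, "no_ccv_tested")
})

test_that("cis_pairs pairs genes with variants of the same capture region", {
  u <- capture_universe(genomic_intervals(c("chr1", "chr2"), c(0, 0),
                                          c(1e4, 1e4)))
  g <- gene_models(rbind(as.data.frame(toy_gene(gene_id = "A", chrom = "chr1")),
                         as.data.frame(toy_gene(gene_id = "B", chrom = "chr2"))))
  v <- data.frame(variant_id = c("v1", "v2"), chrom = c("chr1", "chr2"),
                  pos = c(5000, 7000))
  cp <- cis_pairs(g, v, u)
  expect_equal(cp$variant_id[cp$gene_id == "A"], "v1")
  expect_equal(cp$variant_id[cp$gene_id == "B"], "v2")
})
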