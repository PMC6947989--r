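#' Log2 + quantile normalization of an expression matrix
#'
#' FPKM (or count) values are log2-transformed with a pseudocount and then
#' quantile normalized across samples: every sample's sorted values are
#' replaced by the cross-sample mean of order statistics, ties receiving
#' the mean of their tied ranks' reference values (limma's
#' `normalizeQuantiles(ties = TRUE)`).
#'
#' @param m numeric matrix, genes x samples, non-negative.
#' @param pseudocount added before log2 (default 1).
#' @return normalized matrix with the same dimnames.
#' @export
normalize_expression <- function(m, pseudocount = 1) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("expression values must be non-negative")
  lg <- log2(m + pseudocount)
  if (ncol(lg) < 2) {
    warning("single-sample matrix: quantile normalization is the identity")
    return(lg)
  }
  out <- limma::normalizeQuantiles(lg, ties = TRUE)
  dimnames(out) <- dimnames(lg)
  out
}

## fast OLS for one response on (intercept, dosage, covariates);
## returns beta/se/p for the dosage column
ols_dosage <- function(y, dosage, covars = NULL) {
  X <- cbind(1, dosage, covars)
  colnames(X)[1:2] <- c("intercept", "dosage")
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  df <- length(y) - r
  if (df <= 0 || r < ncol(X)) return(NULL)  # rank-deficient
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE])
  ## column 2 is dosage (pivoting: locate it)
  j <- which(fit$qr$pivot == 2)
  beta <- fit$coefficients[["dosage"]]
  se <- sqrt(sigma2 * XtX_inv[j, j])
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(beta = beta, se = se, p = max(p, .Machine$double.xmin))
}

#' Per-gene cis-eQTL scan by ordinary least squares
#'
#' For every (gene, variant) pair in `tests`, regresses normalized
#' expression on additive genotype dosage plus covariates — always
#' including the gene's per-sample copy-number estimate when supplied —
#' and reports the dosage effect with its two-sided t-test p-value.
#'
#' @param genotypes variants x samples dosage matrix (0-2), rownames =
#'   variant ids.
#' @param expression genes x samples normalized expression matrix.
#' @param tests data frame `gene_id`, `variant_id`: the cis pairs to test
#'   (e.g. from [cis_pairs()]).
#' @param copy_number optional genes x samples matrix of per-gene copy
#'   number, aligned with `expression`.
#' @param covariates optional samples x k matrix of additional covariates.
#' @return data frame of class `eqtl_results`: `gene_id`, `variant_id`,
#'   `beta`, `se`, `p`, `q` (global BH), plus a `skipped` attribute listing
#'   untestable pairs.
#' @export
fit_eqtl <- function(genotypes, expression, tests, copy_number = NULL,
                     covariates = NULL) {
  samples <- colnames(expression)
  if (is.null(samples) || is.null(colnames(genotypes)))
    stop("expression and genotype matrices need sample column names")
  if (!identical(samples, colnames(genotypes)))
    stop("sample columns of expression and genotypes must align")
  if (!is.null(copy_number) && !identical(colnames(copy_number), samples))
    stop("copy-number matrix must align with expression samples")
  res <- vector("list", nrow(tests))
  skipped <- character()
  for (i in seq_len(nrow(tests))) {
    gid <- tests$gene_id[i]; vid <- tests$variant_id[i]
    if (!(gid %in% rownames(expression)) || !(vid %in% rownames(genotypes))) {
      skipped <- c(skipped, paste0(gid, "/", vid, ":missing")); next
    }
    y <- expression[gid, ]
    dose <- genotypes[vid, ]
    if (stats::var(dose) == 0) {
      skipped <- c(skipped, paste0(gid, "/", vid, ":monomorphic")); next
    }
    cv <- covariates
    if (!is.null(copy_number))
      cv <- cbind(cn = copy_number[gid, ], cv)
    fit <- ols_dosage(y, dose, cv)
    if (is.null(fit)) {
      skipped <- c(skipped, paste0(gid, "/", vid, ":rank_deficient")); next
    }
    res[[i]] <- data.frame(gene_id = gid, variant_id = vid, beta = fit$beta,
                           se = fit$se, p = fit$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene_id = character(), variant_id = character(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("eqtl_results", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#' @param pvals numeric p-values in (0, 1].
#' @return step-up BH q-values (significance at q < 0.05 controls FDR at
#'   5%).
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

#' Cis test pairs: variants sharing a capture region with the gene
#'
#' The cis window is the capture region itself — a gene is tested against
#' every variant falling in the same capture region as the gene's span,
#' with no further distance cutoff.
#'
#' @param genes [gene_models()] table.
#' @param variants data frame with `variant_id`, `chrom`, `pos`.
#' @param universe [capture_universe()].
#' @return data frame `gene_id`, `variant_id`.
#' @export
cis_pairs <- function(genes, variants, universe) {
  sp <- transcript_spans(genes)
  regions <- universe$regions
  r_gr <- gi_to_gr(regions)
  g_hit <- GenomicRanges::findOverlaps(gi_to_gr(sp), r_gr,
                                       ignore.strand = TRUE)
  v_gr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos + 1, width = 1))
  v_hit <- GenomicRanges::findOverlaps(v_gr, r_gr, ignore.strand = TRUE)
  gd <- unique(data.frame(gene_id = sp$gene_id[S4Vectors::queryHits(g_hit)],
                          region = S4Vectors::subjectHits(g_hit),
                          stringsAsFactors = FALSE))
  vd <- unique(data.frame(variant_id = variants$variant_id[S4Vectors::queryHits(v_hit)],
                          region = S4Vectors::subjectHits(v_hit),
                          stringsAsFactors = FALSE))
  out <- merge(gd, vd, by = "region")[, c("gene_id", "variant_id")]
  out <- unique(out)
  rownames(out) <- NULL
  out[order(out$gene_id, out$variant_id), , drop = FALSE]
}

#' eQTL / risk-signal overlap rule
#'
#' A gene's eQTL is considered to overlap the risk signal when the eQTL
#' p-value of some CCV is within two orders of magnitude of the top eQTL
#' variant's p-value (`p_ccv <= 100 * p_top`).
#'
#' @param gene_results [fit_eqtl()] rows for one gene.
#' @param ccvs a CCV table (`variant_id`); only CCVs among the tested
#'   variants count.
#' @return list: `overlaps` (logical), `top_variant`, `best_ccv` (NA when
#'   absent), `reason`.
#' @export
eqtl_signal_overlap <- function(gene_results, ccvs) {
  if (nrow(gene_results) == 0) stop("no tested variants for gene")
  top <- gene_results[which.min(gene_results$p), , drop = FALSE]
  in_ccv <- gene_results$variant_id %in% ccvs$variant_id
  if (!any(in_ccv))
    return(list(overlaps = FALSE, top_variant = top$variant_id,
                best_ccv = NA_character_, reason = "no_ccv_tested"))
  cc <- gene_results[in_ccv, , drop = FALSE]
  best <- cc[which.min(cc$p), , drop = FALSE]
  list(overlaps = best$p <= 100 * top$p, top_variant = top$variant_id,
       best_ccv = best$variant_id, reason = "ok")
}
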