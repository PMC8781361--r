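# Count normalization, fold change, and differential-expression calling.
#
# Normalization is the median-of-log-ratios scheme: per sample j,
#   d_kj  = ln( C_kj / geomean_j(C_k.) )   over reference genes k,
#   eta_j = median_k d_kj,   s_j = exp(eta_j),   NC_kj = round(C_kj / s_j).
# Reference genes are those with positive counts in every sample (the
# geometric mean, and hence d_kj, is undefined otherwise).

#' Per-sample size factors by median of log-ratios
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @return list with `s` (named size factors, exp of `eta`), `eta` (median
#'   log-ratios) and `n_reference` (genes used).
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no reference gene: at least one gene must have positive counts in ",
         "every sample for the geometric-mean reference")
  lc <- log(counts[ref, , drop = FALSE])
  d <- lc - rowMeans(lc)
  eta <- apply(d, 2, stats::median)
  list(s = exp(eta), eta = eta, n_reference = sum(ref))
}

#' Normalize counts by size factors
#'
#' Elementwise division by the sample's size factor, then rounding
#' (round-half-to-even, the default rounding of R).
#'
#' @param counts genes x samples count matrix.
#' @param factors result of [size_factors()], or a numeric vector of
#'   per-sample factors.
#' @return matrix of normalized (integer-valued) counts.
#' @export
normalize_counts <- function(counts, factors) {
  s <- if (is.list(factors)) factors$s else factors
  if (length(s) != ncol(counts))
    stop("size factors do not match the sample set")
  round(sweep(counts, 2, s, "/"))
}

#' Cancer/paracancer fold change per gene
#'
#' `FC_k` = mean normalized count over cancer samples divided by the mean over
#' paracancer samples. A zero paracancer mean with a positive cancer mean
#' yields `Inf`; 0/0 yields `NaN`. Both cases are flagged in the
#' `zero_denominator` attribute and logged.
#'
#' @param norm normalized count matrix.
#' @param sheet sample sheet covering its columns.
#' @return numeric vector of per-gene fold changes with attribute
#'   `zero_denominator`.
#' @export
fold_change <- function(norm, sheet) {
  sheet <- sheet[match(colnames(norm), sheet$sample_id), ]
  tc <- sheet$condition == "cancer"
  pc <- sheet$condition == "paracancer"
  if (!any(tc) || !any(pc)) stop("both conditions must be present")
  mt <- rowMeans(norm[, tc, drop = FALSE])
  mp <- rowMeans(norm[, pc, drop = FALSE])
  fc <- mt / mp
  zero <- mp == 0
  if (any(zero))
    message(sum(zero), " gene(s) with zero paracancer mean (FC = Inf or NaN)")
  attr(fc, "zero_denominator") <- zero
  fc
}

# Method-of-moments NB dispersion per gene, pooled across conditions and
# floored. var = mu + a * mu^2 within each group.
mom_dispersion <- function(norm, tc, pc, floor = 1e-8) {
  disp_group <- function(x) {
    mu <- rowMeans(x)
    v <- apply(x, 1, stats::var)
    a <- (v - mu) / mu^2
    a[!is.finite(a)] <- NA
    list(a = a, w = ncol(x) - 1)
  }
  gt <- disp_group(norm[, tc, drop = FALSE])
  gp <- disp_group(norm[, pc, drop = FALSE])
  num <- ifelse(is.na(gt$a), 0, gt$a) * gt$w + ifelse(is.na(gp$a), 0, gp$a) * gp$w
  den <- (!is.na(gt$a)) * gt$w + (!is.na(gp$a)) * gp$w
  a <- ifelse(den > 0, num / den, NA)
  pmax(a, floor)
}

#' Negative-binomial Wald test for differential expression
#'
#' Per gene, a two-sided Wald test on the log ratio of group means of
#' normalized counts, with a method-of-moments NB dispersion (pooled across
#' conditions, floored at `dispersion_floor`). p-values are adjusted by
#' Benjamini-Hochberg over tested genes. Genes with zero counts in all
#' samples are `untested` (NA p-value). A 0.5 pseudocount enters the group
#' means only when one of them is zero.
#'
#' @param norm normalized count matrix.
#' @param sheet sample sheet.
#' @param dispersion_floor lower bound for the dispersion estimate.
#' @return data.frame with `gene_id`, `pval`, `padj`, `tested`.
#' @export
de_test <- function(norm, sheet, dispersion_floor = 1e-8) {
  sheet <- sheet[match(colnames(norm), sheet$sample_id), ]
  tc <- sheet$condition == "cancer"
  pc <- sheet$condition == "paracancer"
  if (sum(tc) < 2 || sum(pc) < 2)
    stop("at least 2 samples per condition are required for a dispersion ",
         "estimate")
  tested <- rowSums(norm) > 0
  mt <- rowMeans(norm[, tc, drop = FALSE])
  mp <- rowMeans(norm[, pc, drop = FALSE])
  a <- mom_dispersion(norm, tc, pc, floor = dispersion_floor)
  a[is.na(a)] <- dispersion_floor
  ps <- ifelse(mt == 0 | mp == 0, 0.5, 0)
  mt2 <- mt + ps
  mp2 <- mp + ps
  se2 <- (mt2 + a * mt2^2) / (sum(tc) * mt2^2) +
         (mp2 + a * mp2^2) / (sum(pc) * mp2^2)
  z <- (log(mt2) - log(mp2)) / sqrt(se2)
  pval <- 2 * stats::pnorm(-abs(z))
  pval[!tested] <- NA
  padj <- rep(NA_real_, length(pval))
  padj[tested] <- stats::p.adjust(pval[tested], method = "BH")
  data.frame(gene_id = rownames(norm), pval = pval, padj = padj,
             tested = tested, row.names = NULL)
}

#' Full differential-expression call
#'
#' Runs size-factor normalization, fold change and the NB Wald test, and
#' classifies genes: `up` iff FC > `fc_up` and padj < `alpha`; `down` iff
#' FC < `fc_down` and padj < `alpha` (strict inequalities); `untested` for
#' all-zero genes; `unchanged` otherwise. An infinite FC gene can still be
#' called up on the padj criterion.
#'
#' @param counts raw count matrix.
#' @param sheet sample sheet.
#' @param fc_up,fc_down fold-change thresholds (defaults 1.25 and 0.8).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return list with `table` (per-gene data.frame: gene_id, FC, log2FC, pval,
#'   padj, status), `size_factors`, and the `normalized` matrix.
#' @export
de_results <- function(counts, sheet, fc_up = 1.25, fc_down = 0.8,
                       alpha = 0.05) {
  sf <- size_factors(counts)
  nc <- normalize_counts(counts, sf)
  fc <- fold_change(nc, sheet)
  tt <- de_test(nc, sheet)
  status <- rep("unchanged", nrow(nc))
  sig <- !is.na(tt$padj) & tt$padj < alpha
  status[sig & fc > fc_up] <- "up"
  status[sig & fc < fc_down & !is.nan(fc)] <- "down"
  status[!tt$tested] <- "untested"
  tab <- data.frame(gene_id = rownames(nc), FC = as.numeric(fc),
                    log2FC = log2(as.numeric(fc)), pval = tt$pval,
                    padj = tt$padj, status = status, row.names = NULL)
  list(table = tab, size_factors = sf, normalized = nc)
}
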