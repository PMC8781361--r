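# Probe-level beta values, probe QC, gene-promoter methylation and the
# relative-difference (RD) statistic.
#
#   beta = max(y_m, 0) / (max(y_m, 0) + max(y_u, 0) + alpha)
#   RD_k = (beta_k,t - beta_k,p) / (beta_k,p + delta)
#
# |RD| > 0.2 defines abnormal (hyper/hypo) methylation throughout.

#' Beta value from methylated/unmethylated intensities
#'
#' Negative (background-corrected) intensities are clamped to zero; the
#' offset `alpha` keeps the value defined and shrinks it toward zero when
#' both channels are dim.
#'
#' @param y_methy,y_umethy numeric vectors or matrices of signal intensities.
#' @param alpha stabilizing offset (default 100).
#' @return beta values in \[0, 1).
#' @export
beta_from_intensities <- function(y_methy, y_umethy, alpha = 100) {
  m <- pmax(y_methy, 0)
  u <- pmax(y_umethy, 0)
  m / (m + u + alpha)
}

#' Probe QC: remove non-CpG probes, then probes with any missing value
#'
#' Filter order matters for the logged counts and mirrors standard HM450K
#' preprocessing: the CpG filter runs first, then any probe with at least one
#' NA across the retained samples is dropped (missing cells on this platform
#' typically flag SNP-affected probes, so the whole probe is distrusted).
#'
#' @param beta probes x samples beta matrix (possibly with NAs).
#' @param manifest probe manifest covering all probes in `beta`.
#' @return filtered beta matrix with attribute `filter_counts`
#'   (`n_non_cpg`, `n_na` probes removed, `n_kept`).
#' @export
filter_probes <- function(beta, manifest) {
  mf <- manifest[match(rownames(beta), manifest$probe_id), ]
  if (anyNA(mf$probe_id))
    stop("manifest does not cover all probes in the beta matrix")
  keep_cpg <- mf$is_cpg
  n_non_cpg <- sum(!keep_cpg)
  b <- beta[keep_cpg, , drop = FALSE]
  has_na <- rowSums(is.na(b)) > 0
  n_na <- sum(has_na)
  out <- b[!has_na, , drop = FALSE]
  message("probe QC: ", n_non_cpg, " non-CpG removed, then ", n_na,
          " with NA removed; ", nrow(out), " retained")
  if (nrow(out) == 0) warning("no probes survived QC")
  attr(out, "filter_counts") <- c(n_non_cpg = n_non_cpg, n_na = n_na,
                                  n_kept = nrow(out))
  out
}

# Per-probe condition means (probes x 2): mean over cancer and paracancer
# samples. Assumes an NA-free (filtered) matrix.
probe_condition_means <- function(beta, sheet) {
  sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
  cbind(t = rowMeans(beta[, sheet$condition == "cancer", drop = FALSE]),
        p = rowMeans(beta[, sheet$condition == "paracancer", drop = FALSE]))
}

#' Relative difference of methylation
#'
#' @param beta_t,beta_p pooled cancer / paracancer methylation levels.
#' @param delta denominator guard (default 1e-9). Note that a zero
#'   paracancer level with nonzero cancer level yields a huge RD; that is a
#'   documented property of the statistic, not an error.
#' @return RD values.
#' @export
rd_stat <- function(beta_t, beta_p, delta = 1e-9) {
  (beta_t - beta_p) / (beta_p + delta)
}

#' Classify RD values as hyper/hypo/normal
#'
#' Strict thresholds: hyper iff RD > `threshold`, hypo iff RD < -`threshold`.
#'
#' @param rd numeric RD values (NA allowed).
#' @param threshold abnormality threshold (default 0.2).
#' @return character vector in \{hyper, hypo, normal\} (NA preserved).
#' @export
classify_rd <- function(rd, threshold = 0.2) {
  out <- ifelse(rd > threshold, "hyper",
                ifelse(rd < -threshold, "hypo", "normal"))
  out
}

#' Gene-promoter methylation and RD classification
#'
#' For each gene, probes whose position lies in \[tss - flank, tss + flank\]
#' (inclusive; probe strand ignored, the promoter window is symmetric about
#' the TSS) are averaged in two stages: per-probe condition mean first, then
#' the mean over the gene's promoter probes. Genes with no promoter probe get
#' status `no_probes`.
#'
#' @param beta filtered (NA-free) beta matrix.
#' @param manifest probe manifest.
#' @param annotation gene annotation (one TSS per gene).
#' @param sheet sample sheet.
#' @param flank promoter half-width in bp (default 1500).
#' @param threshold RD abnormality threshold (default 0.2).
#' @param delta RD denominator guard.
#' @return data.frame: `gene_id`, `m_r` (promoter probe count), `beta_t`,
#'   `beta_p`, `rd`, `status`.
#' @export
gene_promoter_beta <- function(beta, manifest, annotation, sheet,
                               flank = 1500, threshold = 0.2, delta = 1e-9) {
  mf <- manifest[match(rownames(beta), manifest$probe_id), ]
  pm <- probe_condition_means(beta, sheet)
  hits <- overlap_points_windows(mf$chrom, mf$pos, annotation$chrom,
                                 annotation$tss - flank,
                                 annotation$tss + flank)
  bt <- bp <- rep(NA_real_, nrow(annotation))
  mr <- integer(nrow(annotation))
  if (nrow(hits)) {
    agg_t <- tapply(pm[hits$point, "t"], hits$window, mean)
    agg_p <- tapply(pm[hits$point, "p"], hits$window, mean)
    cnt <- tapply(hits$point, hits$window, length)
    idx <- as.integer(names(agg_t))
    bt[idx] <- agg_t
    bp[idx] <- agg_p
    mr[idx] <- cnt
  }
  rd <- rd_stat(bt, bp, delta)
  status <- classify_rd(rd, threshold)
  status[mr == 0] <- "no_probes"
  data.frame(gene_id = annotation$gene_id, m_r = mr, beta_t = bt,
             beta_p = bp, rd = rd, status = status, row.names = NULL)
}

# Overlap points (chrom, pos) with windows (chrom, start, end), 1-based
# inclusive. Returns data.frame(point, window) of index pairs.
overlap_points_windows <- function(p_chrom, p_pos, w_chrom, w_start, w_end) {
  pts <- GenomicRanges::GRanges(p_chrom, IRanges::IRanges(p_pos, width = 1))
  win <- GenomicRanges::GRanges(w_chrom,
                                IRanges::IRanges(pmax(w_start, 1), w_end))
  ov <- GenomicRanges::findOverlaps(pts, win)
  data.frame(point = S4Vectors::queryHits(ov),
             window = S4Vectors::subjectHits(ov))
}
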