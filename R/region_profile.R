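# Binned methylation profiles over genomic functional regions.
#
# The promoter (TSS +/- 1500 bp) is cut into 30 bins of 100 bp in
# transcription orientation; every other region (5'UTR, exon, intron, 3'UTR,
# intergenic, enhancer) is cut into 10 bins over its concatenated length,
# the last bin absorbing the remainder. Bin numbering follows transcription:
# bin 16 covers transcription offsets [0, 100) downstream of the TSS, bin 15
# covers [-100, 0), so the "key bins" 14-17 span exactly (-200, +200) bp.
# Boundary probes fall in the downstream-numbered bin (bins are half-open at
# their upstream edge).

#' Build the bin scheme for gene regions (and optionally enhancers)
#'
#' @param annotation gene annotation data.frame (see [read_gene_annotation()]).
#' @param enhancers optional enhancer data.frame (see [read_enhancers()]);
#'   each enhancer becomes its own 10-bin unit with region `"enhancer"`.
#' @param promoter_bins,region_bins bin counts (defaults 30 and 10).
#' @param promoter_flank promoter half-width in bp (default 1500).
#' @return A `bin_scheme` data.frame of region segments with the cumulative
#'   transcription offset (`offset0`) of each segment, the unit's total
#'   length, bin count and bin width.
#' @export
build_bins <- function(annotation, enhancers = NULL, promoter_bins = 30,
                       region_bins = 10, promoter_flank = 1500) {
  segs <- vector("list", nrow(annotation) + 1)
  for (g in seq_len(nrow(annotation))) {
    gene <- annotation[g, ]
    plus <- gene$strand == "+"
    plen <- 2L * promoter_flank
    prom <- data.frame(
      unit_id = gene$gene_id, region = "promoter", chrom = gene$chrom,
      start = if (plus) gene$tss - promoter_flank else gene$tss - promoter_flank + 1L,
      end = if (plus) gene$tss + promoter_flank - 1L else gene$tss + promoter_flank,
      strand = gene$strand, offset0 = 0L, total_len = plen,
      n_bins = promoter_bins, bin_width = plen %/% promoter_bins)
    reg <- gene$regions[[1]]
    other <- NULL
    if (!is.null(reg) && nrow(reg)) {
      parts <- lapply(split(reg, factor(reg$kind, unique(reg$kind))), function(d) {
        d <- d[order(d$start, decreasing = !plus), ]
        len <- d$end - d$start + 1L
        total <- sum(len)
        if (total < region_bins)
          warning("region ", d$kind[1], " of ", gene$gene_id, " shorter than ",
                  region_bins, " bp; some bins will be empty")
        data.frame(unit_id = gene$gene_id, region = d$kind, chrom = gene$chrom,
                   start = d$start, end = d$end, strand = gene$strand,
                   offset0 = cumsum(c(0L, len))[seq_along(len)],
                   total_len = total, n_bins = region_bins,
                   bin_width = max(1L, total %/% region_bins))
      })
      other <- do.call(rbind, parts)
    }
    segs[[g]] <- rbind(prom, other)
  }
  if (!is.null(enhancers) && nrow(enhancers)) {
    len <- enhancers$end - enhancers$start + 1L
    segs[[length(segs)]] <- data.frame(
      unit_id = enhancers$enhancer_id, region = "enhancer",
      chrom = enhancers$chrom, start = enhancers$start, end = enhancers$end,
      strand = "+", offset0 = 0L, total_len = len, n_bins = region_bins,
      bin_width = pmax(1L, len %/% region_bins))
  }
  out <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("bin_scheme", "data.frame")
  out
}

#' Assign probes to bins
#'
#' @param scheme a `bin_scheme` from [build_bins()].
#' @param manifest probe manifest (only probes present here are assigned).
#' @return data.frame: `probe_id`, `unit_id`, `region`, `bin`. A probe may
#'   land in several region tracks (e.g. promoter and 5'UTR); each hit is a
#'   row. Within one region it lands in exactly one bin.
#' @export
assign_bins <- function(scheme, manifest) {
  hits <- overlap_points_windows(manifest$chrom, manifest$pos,
                                 scheme$chrom, scheme$start, scheme$end)
  if (!nrow(hits))
    return(data.frame(probe_id = character(), unit_id = character(),
                      region = character(), bin = integer()))
  seg <- scheme[hits$window, ]
  pos <- manifest$pos[hits$point]
  off <- ifelse(seg$strand == "+", pos - seg$start, seg$end - pos) + seg$offset0
  bin <- pmin(seg$n_bins, off %/% seg$bin_width + 1L)
  data.frame(probe_id = manifest$probe_id[hits$point], unit_id = seg$unit_id,
             region = seg$region, bin = as.integer(bin), row.names = NULL)
}

#' Per-bin methylation levels
#'
#' The bin level is the mean, over the probes in the bin, of each probe's
#' condition-mean beta (probe-then-bin averaging, the same two-stage order as
#' the gene-promoter level). Bins containing no probe are absent from the
#' output, never zero-filled.
#'
#' @param beta filtered (NA-free) beta matrix.
#' @param scheme bin scheme from [build_bins()].
#' @param manifest probe manifest.
#' @param sheet sample sheet.
#' @return data.frame: `unit_id`, `region`, `bin`, `m_r` (probe count),
#'   `beta_t`, `beta_p`.
#' @export
bin_beta <- function(beta, scheme, manifest, sheet) {
  mf <- manifest[match(rownames(beta), manifest$probe_id), ]
  asg <- assign_bins(scheme, mf)
  if (!nrow(asg))
    return(data.frame(unit_id = character(), region = character(),
                      bin = integer(), m_r = integer(), beta_t = numeric(),
                      beta_p = numeric()))
  pm <- probe_condition_means(beta, sheet)
  i <- match(asg$probe_id, rownames(beta))
  key <- paste(asg$unit_id, asg$region, asg$bin, sep = "\r")
  key <- factor(key, unique(key))
  first <- !duplicated(key)
  out <- data.frame(unit_id = asg$unit_id[first], region = asg$region[first],
                    bin = asg$bin[first],
                    m_r = as.integer(tabulate(key)),
                    beta_t = as.numeric(tapply(pm[i, "t"], key, mean)),
                    beta_p = as.numeric(tapply(pm[i, "p"], key, mean)),
                    row.names = NULL)
  out[order(out$unit_id, out$region, out$bin), , drop = FALSE]
}

#' Per-bin RD and abnormality flags
#'
#' @param profile output of [bin_beta()].
#' @param threshold abnormality threshold on |RD| (default 0.2, strict).
#' @param delta RD denominator guard.
#' @return `profile` with added `rd` and `abnormal` (|RD| > threshold)
#'   columns.
#' @export
bin_rd <- function(profile, threshold = 0.2, delta = 1e-9) {
  profile$rd <- rd_stat(profile$beta_t, profile$beta_p, delta)
  profile$abnormal <- abs(profile$rd) > threshold
  profile
}

#' Per-bin density of abnormally methylated genes
#'
#' For each (region, bin), the number and fraction of genes in `genes` whose
#' bin is abnormal. Genes without probes in a bin are excluded from that
#' bin's denominator.
#'
#' @param profile output of [bin_rd()].
#' @param genes gene/unit ids to summarize (default: all units in profile).
#' @return data.frame: `region`, `bin`, `n_genes`, `n_abnormal`, `fraction`.
#' @export
abnormal_density <- function(profile, genes = NULL) {
  if (!is.null(genes)) profile <- profile[profile$unit_id %in% genes, ]
  if (!nrow(profile))
    return(data.frame(region = character(), bin = integer(),
                      n_genes = integer(), n_abnormal = integer(),
                      fraction = numeric()))
  key <- factor(paste(profile$region, profile$bin, sep = "\r"))
  n <- as.integer(table(key))
  ab <- as.integer(tapply(profile$abnormal, key, sum))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(region = vapply(parts, `[`, "", 1L),
                    bin = as.integer(vapply(parts, `[`, "", 2L)),
                    n_genes = n, n_abnormal = ab, fraction = ab / n,
                    row.names = NULL)
  out[order(out$region, out$bin), , drop = FALSE]
}

#' Genes with abnormal methylation in the promoter key bins
#'
#' The key bins (default 14-17) are the four 100-bp promoter bins spanning
#' TSS - 200 bp to TSS + 200 bp. A gene passes if at least one key bin has
#' |RD| above the abnormality threshold.
#'
#' @param profile output of [bin_rd()] including promoter rows.
#' @param genes gene ids to consider (default: all).
#' @param key_bins promoter bin numbers (default `14:17`).
#' @return character vector of passing gene ids.
#' @export
key_bin_filter <- function(profile, genes = NULL, key_bins = 14:17) {
  p <- profile[profile$region == "promoter" & profile$bin %in% key_bins &
                 profile$abnormal, ]
  hit <- unique(p$unit_id)
  if (!is.null(genes)) hit <- intersect(genes, hit)
  hit
}
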