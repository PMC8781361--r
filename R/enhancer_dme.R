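# Enhancer -> target-gene assignment and calling of differentially
# methylated enhancers (DME) whose methylation change anti-correlates with
# the target gene's expression change across matched patients.
#
# A DME-gene pair is called when (1) the pooled enhancer |RD| > 0.2,
# (2) Spearman r between per-patient enhancer RD and per-patient expression
# fold change is < -0.4, and (3) the gene's pooled promoter |RD| <= 0.2
# (the expression change is attributable to the enhancer, not the promoter).

#' Assign each enhancer its nearest-TSS target gene
#'
#' Distance is |TSS - enhancer center|, unsigned; only genes on the same
#' chromosome within `max_dist` (inclusive) qualify. Ties are broken by
#' smaller TSS, then lexicographic gene_id, so assignment is deterministic.
#' Enhancers with no gene in range are omitted (count logged).
#'
#' @param enhancers enhancer data.frame (see [read_enhancers()]).
#' @param annotation gene annotation.
#' @param max_dist maximum TSS-to-center distance in bp (default 1e6).
#' @return data.frame: `enhancer_id`, `gene_id`, `distance`.
#' @export
assign_targets <- function(enhancers, annotation, max_dist = 1e6) {
  res <- vector("list", nrow(enhancers))
  for (e in seq_len(nrow(enhancers))) {
    g <- annotation[annotation$chrom == enhancers$chrom[e], ]
    if (!nrow(g)) next
    d <- abs(g$tss - enhancers$center[e])
    dmin <- min(d)
    if (dmin > max_dist) next
    cand <- g[d == dmin, ]
    cand <- cand[order(cand$tss, cand$gene_id), ]
    res[[e]] <- data.frame(enhancer_id = enhancers$enhancer_id[e],
                           gene_id = cand$gene_id[1], distance = dmin)
  }
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped)
    message(skipped, " enhancer(s) with no gene within ", max_dist,
            " bp left unassigned")
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(enhancer_id = character(), gene_id = character(),
                      distance = numeric())
  rownames(out) <- NULL
  out
}

# Probe indices (rows of beta) inside each enhancer, as a list keyed by
# enhancer_id. Uses all filtered probes in [start, end], unbinned.
enhancer_probe_index <- function(beta, manifest, enhancers) {
  mf <- manifest[match(rownames(beta), manifest$probe_id), ]
  hits <- overlap_points_windows(mf$chrom, mf$pos, enhancers$chrom,
                                 enhancers$start, enhancers$end)
  idx <- split(hits$point, enhancers$enhancer_id[hits$window])
  idx[enhancers$enhancer_id[enhancers$enhancer_id %in% names(idx)]]
}

#' Per-patient enhancer RD and expression fold-change vectors
#'
#' For each enhancer/target pair and each matched patient, the enhancer RD is
#' computed from that patient's cancer vs paracancer mean probe beta over the
#' enhancer's probes, and the expression fold change is
#' `(NC_cancer + 1) / (NC_para + 1)` for the target gene (the pseudocount
#' keeps single-patient ratios defined at zero counts). Enhancers containing
#' no probe are dropped with a log message.
#'
#' @param beta filtered (NA-free) beta matrix.
#' @param manifest probe manifest.
#' @param norm normalized count matrix.
#' @param sheet sample sheet (matched pairs are auto-detected).
#' @param enhancers enhancer data.frame.
#' @param targets output of [assign_targets()].
#' @param delta RD denominator guard.
#' @return data.frame: `enhancer_id`, `gene_id`, `patient_id`, `rd`, `fc`.
#' @export
patient_vectors <- function(beta, manifest, norm, sheet, enhancers, targets,
                            delta = 1e-9) {
  pairs <- matched_pairs(sheet)
  if (nrow(pairs) < 3)
    stop("at least 3 matched patients are required")
  pidx <- enhancer_probe_index(beta, manifest, enhancers)
  no_probe <- setdiff(targets$enhancer_id, names(pidx))
  if (length(no_probe))
    message(length(no_probe), " enhancer(s) without probes dropped from ",
            "patient vectors")
  tg <- targets[targets$enhancer_id %in% names(pidx), ]
  if (!nrow(tg))
    return(data.frame(enhancer_id = character(), gene_id = character(),
                      patient_id = character(), rd = numeric(),
                      fc = numeric()))
  bt <- beta[, pairs$cancer, drop = FALSE]
  bp <- beta[, pairs$paracancer, drop = FALSE]
  out <- vector("list", nrow(tg))
  for (k in seq_len(nrow(tg))) {
    rows <- pidx[[tg$enhancer_id[k]]]
    mt <- colMeans(bt[rows, , drop = FALSE])
    mp <- colMeans(bp[rows, , drop = FALSE])
    fc <- (norm[tg$gene_id[k], pairs$cancer] + 1) /
          (norm[tg$gene_id[k], pairs$paracancer] + 1)
    out[[k]] <- data.frame(enhancer_id = tg$enhancer_id[k],
                           gene_id = tg$gene_id[k],
                           patient_id = pairs$patient_id,
                           rd = rd_stat(mt, mp, delta), fc = as.numeric(fc),
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Spearman rank correlation via the rank-difference shortcut
#'
#' With tie-free inputs this is exactly `1 - 6 * sum(d^2) / (n (n^2 - 1))`
#' where `d` is the difference of ranks. With ties it falls back to the
#' Pearson correlation of midranks (the shortcut formula assumes distinct
#' ranks). A constant vector has no defined rank correlation and returns NA
#' with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation, or NA.
#' @export
spearman_shortcut <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("at least 3 observations are required")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant vector: rank correlation undefined")
    return(NA_real_)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (anyDuplicated(rx) || anyDuplicated(ry))
    return(stats::cor(rx, ry))
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

#' Call DME-gene pairs
#'
#' Pipeline order: (1) pooled enhancer RD over all cancer vs all paracancer
#' samples; enhancers with pooled |RD| <= `rd_threshold` are screened out;
#' (2) Spearman correlation of per-patient enhancer RD vs target-gene fold
#' change; keep `r < r_threshold`; (3) genes whose pooled promoter |RD|
#' exceeds `rd_threshold` are removed (their expression change may be driven
#' by the promoter). All assigned pairs with probes are returned with a
#' `call` flag; a gene may appear in several called pairs.
#'
#' @param beta filtered beta matrix.
#' @param manifest probe manifest.
#' @param norm normalized count matrix.
#' @param sheet sample sheet.
#' @param enhancers enhancer data.frame.
#' @param annotation gene annotation.
#' @param promoter_meth output of [gene_promoter_beta()].
#' @param rd_threshold pooled-RD screen threshold (default 0.2).
#' @param r_threshold Spearman threshold (default -0.4, strict).
#' @param max_dist nearest-gene search radius (default 1e6).
#' @param delta RD denominator guard.
#' @return data.frame: `enhancer_id`, `gene_id`, `distance`, `enhancer_rd`,
#'   `r`, `n` (matched patients), `promoter_rd`, `call`.
#' @export
call_dme <- function(beta, manifest, norm, sheet, enhancers, annotation,
                     promoter_meth, rd_threshold = 0.2, r_threshold = -0.4,
                     max_dist = 1e6, delta = 1e-9) {
  targets <- assign_targets(enhancers, annotation, max_dist)
  targets <- targets[order(targets$enhancer_id, targets$gene_id), ]
  pidx <- enhancer_probe_index(beta, manifest, enhancers)
  targets <- targets[targets$enhancer_id %in% names(pidx), ]
  if (!nrow(targets))
    return(data.frame(enhancer_id = character(), gene_id = character(),
                      distance = numeric(), enhancer_rd = numeric(),
                      r = numeric(), n = integer(), promoter_rd = numeric(),
                      call = logical()))
  pm <- probe_condition_means(beta, sheet)
  pooled <- vapply(targets$enhancer_id, function(eid) {
    rows <- pidx[[eid]]
    rd_stat(mean(pm[rows, "t"]), mean(pm[rows, "p"]), delta)
  }, 0)
  pass1 <- abs(pooled) > rd_threshold
  r <- rep(NA_real_, nrow(targets))
  npat <- matched_pairs(sheet)
  if (any(pass1)) {
    vec <- patient_vectors(beta, manifest, norm, sheet, enhancers,
                           targets[pass1, , drop = FALSE], delta)
    rr <- vapply(split(vec, paste(vec$enhancer_id, vec$gene_id, sep = "\r")),
                 function(d) spearman_shortcut(d$fc, d$rd), 0)
    key <- paste(targets$enhancer_id, targets$gene_id, sep = "\r")
    r[match(names(rr), key)] <- rr
  }
  prd <- promoter_meth$rd[match(targets$gene_id, promoter_meth$gene_id)]
  pass3 <- is.na(prd) | abs(prd) <= rd_threshold
  call <- pass1 & !is.na(r) & r < r_threshold & pass3
  out <- data.frame(enhancer_id = targets$enhancer_id,
                    gene_id = targets$gene_id, distance = targets$distance,
                    enhancer_rd = as.numeric(pooled), r = r,
                    n = nrow(npat), promoter_rd = prd, call = call,
                    row.names = NULL)
  out
}
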