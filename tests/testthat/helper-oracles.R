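# Independent brute-force oracles, coded literally from the definitions and
# kept free of the package's implementation paths.

# median-of-log-ratios size factors: explicit per-sample loop
oracle_size_factors <- function(counts) {
  ref <- apply(counts, 1, function(x) all(x > 0))
  s <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    d <- numeric(sum(ref))
    i <- 1
    for (k in which(ref)) {
      geo <- prod(counts[k, ])^(1 / ncol(counts))
      d[i] <- log(counts[k, j] / geo)
      i <- i + 1
    }
    s[j] <- exp(median(d))
  }
  s
}

# textbook Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# promoter membership + two-stage mean by linear scan
oracle_gene_promoter <- function(beta, manifest, annotation, sheet,
                                 flank = 1500) {
  t_s <- sheet$sample_id[sheet$condition == "cancer"]
  p_s <- sheet$sample_id[sheet$condition == "paracancer"]
  out <- data.frame(gene_id = annotation$gene_id, m_r = 0L,
                    beta_t = NA_real_, beta_p = NA_real_)
  for (g in seq_len(nrow(annotation))) {
    bt <- bp <- c()
    for (i in seq_len(nrow(manifest))) {
      if (manifest$chrom[i] == annotation$chrom[g] &&
          manifest$pos[i] >= annotation$tss[g] - flank &&
          manifest$pos[i] <= annotation$tss[g] + flank &&
          manifest$probe_id[i] %in% rownames(beta)) {
        row <- beta[manifest$probe_id[i], ]
        bt <- c(bt, mean(row[t_s]))
        bp <- c(bp, mean(row[p_s]))
      }
    }
    out$m_r[g] <- length(bt)
    if (length(bt)) {
      out$beta_t[g] <- mean(bt)
      out$beta_p[g] <- mean(bp)
    }
  }
  out
}

# bin index of a transcription offset, straight from the bin convention:
# promoter bin mu covers offsets [100 (mu - 16), 100 (mu - 15)).
oracle_promoter_bin <- function(offset) {
  for (mu in 1:30) {
    lo <- 100 * (mu - 16)
    if (offset >= lo && offset < lo + 100) return(mu)
  }
  NA_integer_
}

# per-bin means by full enumeration (promoter track only)
oracle_promoter_bin_beta <- function(beta, manifest, annotation, sheet) {
  t_s <- sheet$sample_id[sheet$condition == "cancer"]
  p_s <- sheet$sample_id[sheet$condition == "paracancer"]
  rows <- list()
  for (g in seq_len(nrow(annotation))) {
    for (mu in 1:30) {
      bt <- bp <- c()
      for (i in seq_len(nrow(manifest))) {
        if (manifest$chrom[i] != annotation$chrom[g]) next
        off <- if (annotation$strand[g] == "+")
          manifest$pos[i] - annotation$tss[g]
        else annotation$tss[g] - manifest$pos[i]
        mu_i <- oracle_promoter_bin(off)
        if (!is.na(mu_i) && mu_i == mu &&
            manifest$probe_id[i] %in% rownames(beta)) {
          row <- beta[manifest$probe_id[i], ]
          bt <- c(bt, mean(row[t_s]))
          bp <- c(bp, mean(row[p_s]))
        }
      }
      if (length(bt))
        rows[[length(rows) + 1]] <- data.frame(
          unit_id = annotation$gene_id[g], bin = mu, m_r = length(bt),
          beta_t = mean(bt), beta_p = mean(bp))
    }
  }
  do.call(rbind, rows)
}

# all-pairs nearest-TSS assignment
oracle_assign_targets <- function(enhancers, annotation, max_dist = 1e6) {
  rows <- list()
  for (e in seq_len(nrow(enhancers))) {
    best <- NULL
    for (g in seq_len(nrow(annotation))) {
      if (annotation$chrom[g] != enhancers$chrom[e]) next
      d <- abs(annotation$tss[g] - enhancers$center[e])
      if (d > max_dist) next
      cand <- list(gene_id = annotation$gene_id[g], tss = annotation$tss[g],
                   d = d)
      if (is.null(best) || d < best$d ||
          (d == best$d && (cand$tss < best$tss ||
                           (cand$tss == best$tss &&
                              cand$gene_id < best$gene_id))))
        best <- cand
    }
    if (!is.null(best))
      rows[[length(rows) + 1]] <- data.frame(
        enhancer_id = enhancers$enhancer_id[e], gene_id = best$gene_id,
        distance = best$d)
  }
  if (!length(rows))
    return(data.frame(enhancer_id = character(), gene_id = character(),
                      distance = numeric()))
  do.call(rbind, rows)
}

# Pearson correlation of ranks, computed from first principles
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
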