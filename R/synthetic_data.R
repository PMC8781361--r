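# Seeded synthetic study generator with planted ground truth.
#
# Emulates the statistical structure the pipeline assumes: matched
# tumor/normal pairs plus unmatched extras; negative-binomial counts with
# log-normal gene baselines and per-sample depth factors; beta-distributed
# probe methylation (bounded, heteroskedastic) with planted promoter
# hyper/hypo effects concentrated in the TSS +/- 200 bp key bins; and
# enhancer-only methylation shifts anti-monotone, patient by patient, to the
# patient's planted expression change. Promoter probes are placed with
# CpG-island-like density (most probes near the TSS), matching the probe
# geography of 450K-style arrays; without that enrichment a key-bin-only
# effect could never move the whole-promoter mean appreciably.

#' Simulation configuration
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_genes number of genes (default 300).
#' @param n_matched_pairs matched tumor/normal patients (default 9; at least
#'   3, the minimum for a rank correlation).
#' @param n_extra_cancer,n_extra_para unmatched extra samples (defaults 11
#'   and 3, keeping cancer samples in excess as in tumor cohorts).
#' @param probes_per_promoter_bin mean probes per 100-bp promoter bin.
#' @param probes_per_region_bin mean probes per non-promoter region bin.
#' @param probes_per_enhancer mean probes per enhancer.
#' @param frac_dhyper,frac_uhypo,frac_dme planted gene fractions; the
#'   remainder is null.
#' @param lfc_mean planted |log2 fold change| for D-Hyper/U-Hypo genes.
#' @param beta_shift planted methylation shift (delta beta, default 0.25).
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param beta_concentration concentration of the Beta noise on probe
#'   methylation (higher = less noise).
#' @param key_bin_only plant promoter effects only in bins 14-17 (TSS +/-
#'   200 bp) rather than across the whole promoter (default TRUE).
#' @param tss_focus fraction of promoter probes placed within TSS +/- 200 bp.
#' @param na_rate fraction of beta cells set to NA (SNP-like dropout).
#' @param non_cpg_rate fraction of probes flagged non-CpG.
#' @param decoy_enhancer_frac fraction of non-DME genes given an (inactive)
#'   nearby enhancer.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_genes = 300, n_matched_pairs = 9,
                       n_extra_cancer = 11, n_extra_para = 3,
                       probes_per_promoter_bin = 2,
                       probes_per_region_bin = 0.5, probes_per_enhancer = 8,
                       frac_dhyper = 0.1, frac_uhypo = 0.1, frac_dme = 0.1,
                       lfc_mean = 1.5, beta_shift = 0.25,
                       nb_dispersion = 0.05, beta_concentration = 30,
                       key_bin_only = TRUE, tss_focus = 0.7,
                       na_rate = 0.005, non_cpg_rate = 0.01,
                       decoy_enhancer_frac = 0.2) {
  cfg <- as.list(environment())
  if (frac_dhyper + frac_uhypo + frac_dme > 1)
    stop("planted gene fractions must sum to at most 1")
  if (n_matched_pairs < 3)
    stop("at least 3 matched pairs are required (rank correlation needs ",
         ">= 3 points)")
  cfg$frac_null <- 1 - frac_dhyper - frac_uhypo - frac_dme
  class(cfg) <- "sim_config"
  cfg
}

# Genomic layout constants: one toy chromosome, genes tiled every 50 kb so
# the nearest-gene rule is unambiguous for enhancers placed within 25 kb.
.sim_chrom <- "chrS"
.sim_tss0 <- 40000L
.sim_spacing <- 50000L

sim_gene_annotation <- function(n_genes) {
  tss <- .sim_tss0 + .sim_spacing * (seq_len(n_genes) - 1L)
  strand <- rep(c("+", "-"), length.out = n_genes)
  regions <- lapply(seq_len(n_genes), function(i) {
    s <- if (strand[i] == "+") 1L else -1L
    iv <- function(a, b) if (s > 0) c(tss[i] + a, tss[i] + b)
                         else c(tss[i] - b, tss[i] - a)
    k <- rbind(c("utr5", iv(0L, 499L)), c("exon", iv(500L, 899L)),
               c("intron", iv(900L, 1499L)), c("exon", iv(1500L, 2099L)),
               c("utr3", iv(2100L, 2599L)))
    data.frame(kind = k[, 1], start = as.integer(k[, 2]),
               end = as.integer(k[, 3]))
  })
  out <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                    symbol = sprintf("SYM%04d", seq_len(n_genes)),
                    chrom = .sim_chrom, strand = strand,
                    tss = as.integer(tss))
  out$regions <- regions
  out
}

#' Simulate a complete study with planted ground truth
#'
#' @param cfg a [sim_config()].
#' @return list: `sheet`, `counts`, `beta`, `manifest`, `annotation`,
#'   `enhancers`, `gene_sets`, `truth` (per-gene label, planted effect sizes
#'   and, for DME genes, the causal enhancer id).
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  anno <- sim_gene_annotation(n)

  # planted labels
  n_dh <- round(cfg$frac_dhyper * n)
  n_uh <- round(cfg$frac_uhypo * n)
  n_dm <- round(cfg$frac_dme * n)
  lab <- rep("null", n)
  idx <- sample.int(n, n_dh + n_uh + n_dm)
  lab[idx[seq_len(n_dh)]] <- "D-Hyper"
  lab[idx[n_dh + seq_len(n_uh)]] <- "U-Hypo"
  lab[idx[n_dh + n_uh + seq_len(n_dm)]] <- "DME"

  # sample sheet: matched pairs first, then unmatched extras
  np <- cfg$n_matched_pairs
  pats <- sprintf("P%02d", seq_len(np))
  sheet <- rbind(
    data.frame(sample_id = sprintf("T%02d", seq_len(np)), patient_id = pats,
               condition = "cancer"),
    data.frame(sample_id = sprintf("N%02d", seq_len(np)), patient_id = pats,
               condition = "paracancer"),
    if (cfg$n_extra_cancer > 0)
      data.frame(sample_id = sprintf("TX%02d", seq_len(cfg$n_extra_cancer)),
                 patient_id = sprintf("PX%02d", seq_len(cfg$n_extra_cancer)),
                 condition = "cancer"),
    if (cfg$n_extra_para > 0)
      data.frame(sample_id = sprintf("NX%02d", seq_len(cfg$n_extra_para)),
                 patient_id = sprintf("PY%02d", seq_len(cfg$n_extra_para)),
                 condition = "paracancer"))
  ns <- nrow(sheet)
  cancer <- sheet$condition == "cancer"

  # expression: NB counts around log-normal baselines with per-sample depth
  base <- exp(stats::rnorm(n, log(300), 0.8))
  depth <- exp(stats::rnorm(ns, 0, 0.2))
  lfc <- numeric(n)
  lfc[lab == "D-Hyper"] <- -(cfg$lfc_mean + abs(stats::rnorm(n_dh, 0, 0.2)))
  lfc[lab == "U-Hypo"] <- cfg$lfc_mean + abs(stats::rnorm(n_uh, 0, 0.2))
  mult <- matrix(1, n, ns)
  mult[, cancer] <- 2^lfc
  # DME genes: patient-specific expression effects in cancer tissue
  dme_expr <- matrix(stats::rnorm(n_dm * np, 0, 1), n_dm, np)
  dme_rows <- which(lab == "DME")
  for (d in seq_len(n_dm)) {
    mult[dme_rows[d], match(sprintf("T%02d", seq_len(np)), sheet$sample_id)] <-
      2^dme_expr[d, ]
    extra <- grepl("^TX", sheet$sample_id)
    mult[dme_rows[d], extra] <- 2^stats::rnorm(sum(extra), 0, 1)
  }
  mu <- (base * mult) %*% diag(depth)
  counts <- matrix(stats::rnbinom(n * ns, mu = mu, size = 1 / cfg$nb_dispersion),
                   n, ns, dimnames = list(anno$gene_id, sheet$sample_id))
  storage.mode(counts) <- "integer"

  # enhancers: one causal enhancer per DME gene, decoys near non-DME genes
  mk_enh <- function(gene_row) {
    repeat {
      len <- sample(400:1200, 1)
      dist <- sample(5000:20000, 1)
      side <- sample(c(-1L, 1L), 1)
      center <- anno$tss[gene_row] + side * dist
      start <- center - len %/% 2L
      end <- start + len - 1L
      if (start >= 1L) return(c(start, end))
    }
  }
  dme_enh <- t(vapply(dme_rows, mk_enh, c(0L, 0L)))
  n_decoy <- round(cfg$decoy_enhancer_frac * sum(lab != "DME"))
  decoy_rows <- sample(which(lab != "DME"), n_decoy)
  decoy_enh <- if (n_decoy) t(vapply(decoy_rows, mk_enh, c(0L, 0L)))
               else matrix(integer(), 0, 2)
  enh_rows <- c(dme_rows, decoy_rows)
  enh <- data.frame(
    enhancer_id = paste0("E_", anno$gene_id[enh_rows]),
    chrom = .sim_chrom,
    start = c(dme_enh[, 1], decoy_enh[, 1]),
    end = c(dme_enh[, 2], decoy_enh[, 2]))
  enh$center <- (enh$start - 1L + enh$end) %/% 2L
  causal <- rep(c(TRUE, FALSE), c(length(dme_rows), length(decoy_rows)))

  # probes: promoter (TSS-focused), other regions, enhancers
  probe_pos <- integer(0); probe_gene <- integer(0)
  probe_track <- character(0); probe_base <- numeric(0)
  prom_base <- ifelse(lab == "D-Hyper", stats::runif(n, 0.20, 0.35),
               ifelse(lab == "U-Hypo", stats::runif(n, 0.45, 0.60),
                      stats::runif(n, 0.25, 0.55)))
  for (g in seq_len(n)) {
    k <- stats::rpois(1, 30 * cfg$probes_per_promoter_bin)
    if (k > 0) {
      focus <- stats::runif(k) < cfg$tss_focus
      off <- ifelse(focus, sample(-200:199, k, replace = TRUE),
                    sample(-1500:1499, k, replace = TRUE))
      pos <- if (anno$strand[g] == "+") anno$tss[g] + off else anno$tss[g] - off
      probe_pos <- c(probe_pos, pos)
      probe_gene <- c(probe_gene, rep(g, k))
      probe_track <- c(probe_track, ifelse(off >= -200 & off < 200,
                                           "key", "promoter"))
      probe_base <- c(probe_base, pmin(0.95, pmax(0.05,
        prom_base[g] + stats::rnorm(k, 0, 0.05))))
    }
    reg <- anno$regions[[g]]
    for (kind in unique(reg$kind)) {
      iv <- reg[reg$kind == kind, ]
      all_pos <- unlist(mapply(seq, iv$start, iv$end, SIMPLIFY = FALSE))
      k2 <- stats::rpois(1, 10 * cfg$probes_per_region_bin)
      if (k2 > 0) {
        pos <- sample(all_pos, k2, replace = TRUE)
        probe_pos <- c(probe_pos, pos)
        probe_gene <- c(probe_gene, rep(g, k2))
        probe_track <- c(probe_track, rep("region", k2))
        probe_base <- c(probe_base, pmin(0.95, pmax(0.05,
          stats::runif(1, 0.25, 0.55) + stats::rnorm(k2, 0, 0.05))))
      }
    }
  }
  enh_probe_of <- integer(0)
  for (e in seq_len(nrow(enh))) {
    k3 <- if (causal[e]) 3 + stats::rpois(1, max(0, cfg$probes_per_enhancer - 3))
          else stats::rpois(1, cfg$probes_per_enhancer)
    if (k3 > 0) {
      probe_pos <- c(probe_pos, sample(enh$start[e]:enh$end[e], k3,
                                       replace = TRUE))
      probe_gene <- c(probe_gene, rep(enh_rows[e], k3))
      probe_track <- c(probe_track, rep("enhancer", k3))
      probe_base <- c(probe_base, pmin(0.95, pmax(0.05,
        stats::runif(1, 0.30, 0.45) + stats::rnorm(k3, 0, 0.04))))
      enh_probe_of <- c(enh_probe_of, rep(e, k3))
    }
  }
  m <- length(probe_pos)
  manifest <- data.frame(probe_id = sprintf("cg%06d", seq_len(m)),
                         chrom = .sim_chrom, pos = probe_pos,
                         is_cpg = stats::runif(m) >= cfg$non_cpg_rate)

  # target methylation matrix: baseline everywhere, shifts in cancer columns
  tgt <- matrix(probe_base, m, ns, dimnames = list(manifest$probe_id,
                                                   sheet$sample_id))
  shift_dir <- ifelse(lab == "D-Hyper", 1, ifelse(lab == "U-Hypo", -1, 0))
  prom_rows <- if (cfg$key_bin_only) probe_track == "key"
               else probe_track %in% c("key", "promoter")
  planted <- prom_rows & shift_dir[probe_gene] != 0
  tgt[planted, cancer] <- tgt[planted, cancer] +
    cfg$beta_shift * shift_dir[probe_gene[planted]]
  # DME: per-patient enhancer shifts, anti-monotone in the patient's planted
  # expression effect (largest expression gain -> smallest methylation gain)
  t_cols <- match(sprintf("T%02d", seq_len(np)), sheet$sample_id)
  tx_cols <- which(grepl("^TX", sheet$sample_id))
  enh_probe_rows <- which(probe_track == "enhancer")
  for (d in seq_len(n_dm)) {
    e <- d  # causal enhancers are listed first, one per DME gene
    rows <- enh_probe_rows[enh_probe_of == e]
    if (!length(rows)) next
    rk <- rank(-dme_expr[d, ], ties.method = "first")
    shift <- pmax(0, 0.05 + cfg$beta_shift * (rk - 1) / (np - 1) +
                       stats::rnorm(np, 0, 0.02))
    tgt[rows, t_cols] <- tgt[rows, t_cols] +
      matrix(shift, length(rows), np, byrow = TRUE)
    tgt[rows, tx_cols] <- tgt[rows, tx_cols] + 0.05 + cfg$beta_shift / 2
  }
  tgt <- pmin(pmax(tgt, 0.02), 0.98)
  cc <- cfg$beta_concentration
  beta <- matrix(stats::rbeta(m * ns, tgt * cc, (1 - tgt) * cc), m, ns,
                 dimnames = dimnames(tgt))
  beta[stats::runif(m * ns) < cfg$na_rate] <- NA

  # cancer gene sets: mostly planted genes plus null contamination & overlap
  pick <- function(rows, frac) {
    k <- round(frac * length(rows))
    anno$symbol[rows[sample.int(length(rows), k)]]
  }
  null_rows <- which(lab == "null")
  tsgs <- c(pick(which(lab == "D-Hyper"), 0.7),
            pick(dme_rows, 0.5), pick(null_rows, 0.05))
  oncs <- c(pick(which(lab == "U-Hypo"), 0.7), pick(null_rows, 0.05))
  if (length(tsgs)) oncs <- c(oncs, tsgs[1])  # deliberate overlap case
  gene_sets <- list(oncogenes = sort(unique(oncs)), tsgs = sort(unique(tsgs)),
                    both = sort(intersect(unique(oncs), unique(tsgs))))

  truth <- data.frame(gene_id = anno$gene_id, label = lab, lfc = lfc,
                      beta_shift = ifelse(lab == "null", 0, cfg$beta_shift),
                      causal_enhancer = NA_character_)
  truth$causal_enhancer[dme_rows] <- enh$enhancer_id[seq_len(n_dm)]

  list(sheet = sheet, counts = counts, beta = beta, manifest = manifest,
       annotation = anno, enhancers = enh, gene_sets = gene_sets,
       truth = truth, config = cfg)
}

#' Write a study to a directory of plain-text files
#'
#' Creates the directory if missing and writes the standard file set
#' (`sample_sheet.tsv`, `counts.tsv`, `beta.tsv`, `manifest.tsv`,
#' `gene_model.tsv`, `enhancers.bed`, `oncogenes.txt`, `tsgs.txt`,
#' `ground_truth.tsv`) readable by [read_study()].
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sample_sheet(study$sheet, file.path(dir, "sample_sheet.tsv"))
  write_counts(study$counts, file.path(dir, "counts.tsv"))
  write_beta_table(study$beta, file.path(dir, "beta.tsv"))
  write_manifest(study$manifest, file.path(dir, "manifest.tsv"))
  write_gene_annotation(study$annotation, file.path(dir, "gene_model.tsv"))
  write_enhancers(study$enhancers, file.path(dir, "enhancers.bed"))
  writeLines(study$gene_sets$oncogenes, file.path(dir, "oncogenes.txt"))
  writeLines(study$gene_sets$tsgs, file.path(dir, "tsgs.txt"))
  utils::write.table(study$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Tabulate planted gene labels
#'
#' @param truth ground-truth data.frame from [simulate_study()].
#' @return data.frame with one row per label (all four labels always
#'   present) and the planted gene count.
#' @export
summarize_truth <- function(truth) {
  labs <- c("D-Hyper", "U-Hypo", "DME", "null")
  data.frame(label = labs,
             n = vapply(labs, function(l) sum(truth$label == l), 0L),
             row.names = NULL)
}
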