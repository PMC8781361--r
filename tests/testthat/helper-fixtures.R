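# Small in-code fixtures shared across test files.

tiny_sheet <- function() {
  data.frame(sample_id = c("T1", "T2", "N1", "N2"),
             patient_id = c("P1", "P2", "P1", "P2"),
             condition = c("cancer", "cancer", "paracancer", "paracancer"))
}

# a one-gene annotation with no extra regions
one_gene <- function(tss = 10000, strand = "+", chrom = "chr1",
                     gene_id = "G1", symbol = "SYM1") {
  a <- data.frame(gene_id = gene_id, symbol = symbol, chrom = chrom,
                  strand = strand, tss = as.integer(tss))
  a$regions <- list(data.frame(kind = character(), start = integer(),
                               end = integer()))
  a
}

# manifest of CpG probes at the given positions
probes_at <- function(pos, chrom = "chr1", prefix = "cg") {
  data.frame(probe_id = sprintf("%s%03d", prefix, seq_along(pos)),
             chrom = chrom, pos = as.integer(pos), is_cpg = TRUE)
}

# beta matrix with given per-probe values replicated across samples
flat_beta <- function(manifest, sheet, t_val, p_val) {
  ns <- nrow(sheet)
  b <- matrix(NA_real_, nrow(manifest), ns,
              dimnames = list(manifest$probe_id, sheet$sample_id))
  b[, sheet$condition == "cancer"] <- t_val
  b[, sheet$condition == "paracancer"] <- p_val
  b
}

# random small beta matrix/manifest pair for oracle comparisons
random_meth_study <- function(seed, n_probes = 40, n_genes = 4,
                              span = 20000) {
  set.seed(seed)
  sheet <- tiny_sheet()
  manifest <- data.frame(probe_id = sprintf("cg%03d", seq_len(n_probes)),
                         chrom = "chr1",
                         pos = sample.int(span, n_probes),
                         is_cpg = TRUE)
  beta <- matrix(runif(n_probes * nrow(sheet)), n_probes, nrow(sheet),
                 dimnames = list(manifest$probe_id, sheet$sample_id))
  anno <- data.frame(gene_id = sprintf("G%02d", seq_len(n_genes)),
                     symbol = sprintf("S%02d", seq_len(n_genes)),
                     chrom = "chr1",
                     strand = sample(c("+", "-"), n_genes, replace = TRUE),
                     tss = as.integer(sample(2000:(span - 2000), n_genes)))
  anno$regions <- replicate(n_genes, data.frame(kind = character(),
                                                start = integer(),
                                                end = integer()),
                            simplify = FALSE)
  list(sheet = sheet, manifest = manifest, beta = beta, annotation = anno)
}
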