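test_that("promoter bin numbering is anchored at the TSS", {
  anno <- one_gene(tss = 10000, strand = "+")
  scheme <- build_bins(anno)
  asg <- assign_bins(scheme, probes_at(c(10000, 10099, 10100, 9999, 9901)))
  expect_equal(asg$bin, c(16L, 16L, 17L, 15L, 15L))  # bin 16 = [tss, tss+99]

  # minus strand: downstream in transcription orientation is lower coords
  anno2 <- one_gene(tss = 10000, strand = "-")
  asg2 <- assign_bins(build_bins(anno2), probes_at(9950))
  expect_equal(asg2$bin[asg2$region == "promoter"], 16L)

  # key bins 14-17 cover exactly (-200, +200) around the TSS
  asg3 <- assign_bins(scheme, probes_at(c(9800, 10199, 9799, 10200)))
  expect_equal(asg3$bin, c(14L, 17L, 13L, 18L))
})

test_that("a 1000 bp region splits into 10 equal 100 bp bins", {
  anno <- one_gene(tss = 10000, strand = "+")
  anno$regions <- list(data.frame(kind = "utr5", start = 10000L,
                                  end = 10999L))
  scheme <- build_bins(anno)
  seg <- scheme[scheme$region == "utr5", ]
  expect_equal(seg$bin_width, 100L)
  asg <- assign_bins(scheme, probes_at(c(10000, 10099, 10100, 10999)))
  u <- asg[asg$region == "utr5", ]
  expect_equal(u$bin, c(1L, 1L, 2L, 10L))
})

test_that("multi-interval regions are binned over the concatenated length", {
  anno <- one_gene(tss = 1000, strand = "+")
  anno$regions <- list(data.frame(kind = "exon",
                                  start = c(2000L, 5000L),
                                  end = c(2399L, 5599L)))  # 400 + 600 bp
  scheme <- build_bins(anno)
  # offset of 5000 within the concatenated exon is 400 -> bin 5 (width 100)
  asg <- assign_bins(scheme, probes_at(c(2000, 2399, 5000, 5599)))
  ex <- asg[asg$region == "exon", ]
  expect_equal(ex$bin, c(1L, 4L, 5L, 10L))

  anno$regions <- list(data.frame(kind = "utr3", start = 100L, end = 105L))
  expect_warning(build_bins(anno), "shorter")
})

test_that("promoter bins partition the promoter on both strands", {
  set.seed(21)
  for (i in 1:20) {
    tss <- sample(5000:50000, 1)
    strand <- sample(c("+", "-"), 1)
    anno <- one_gene(tss = tss, strand = strand)
    scheme <- build_bins(anno)
    pos <- (tss - 1600):(tss + 1600)
    asg <- assign_bins(scheme[scheme$region == "promoter", ], probes_at(pos))
    # each in-window position falls in exactly one bin 1..30
    expect_identical(anyDuplicated(asg$probe_id), 0L)
    expect_true(all(asg$bin %in% 1:30))
    expect_identical(nrow(asg), 3000L)       # the full 3000 bp, nothing more
    expect_equal(sort(unique(asg$bin)), 1:30)
    expect_true(all(table(asg$bin) == 100))  # equal 100 bp bins
  }
})

test_that("reversing the strand mirrors bin mu to 31 - mu", {
  set.seed(22)
  tss <- 20000
  off <- sample(setdiff(-1499:1499, seq(-1500, 1500, by = 100)), 200)
  mf <- probes_at(tss + off)
  plus <- assign_bins(build_bins(one_gene(tss = tss, strand = "+")), mf)
  minus <- assign_bins(build_bins(one_gene(tss = tss, strand = "-")), mf)
  m <- merge(plus, minus, by = "probe_id")
  expect_identical(nrow(m), 200L)
  expect_true(all(m$bin.x + m$bin.y == 31L))
})

test_that("bin means average probe condition-means and skip empty bins", {
  sheet <- tiny_sheet()
  anno <- one_gene(tss = 10000)
  mf <- probes_at(c(10010, 10020))     # both in bin 16
  b <- rbind(cg001 = c(0.2, 0.2, 0.2, 0.2), cg002 = c(0.4, 0.4, 0.4, 0.4))
  colnames(b) <- sheet$sample_id
  prof <- bin_beta(b, build_bins(anno), mf, sheet)
  expect_identical(nrow(prof), 1L)     # bins without probes are absent
  expect_equal(prof$bin, 16L)
  expect_equal(prof$beta_t, 0.3)
  expect_equal(prof$m_r, 2L)
})

test_that("promoter bin means match the enumeration oracle", {
  for (seed in 1:4) {
    s <- random_meth_study(seed, n_probes = 60, n_genes = 3)
    prof <- bin_beta(s$beta, build_bins(s$annotation), s$manifest, s$sheet)
    prof <- prof[prof$region == "promoter", ]
    want <- oracle_promoter_bin_beta(s$beta, s$manifest, s$annotation,
                                     s$sheet)
    key <- function(d) paste(d$unit_id, d$bin)
    want <- want[order(key(want)), ]
    prof <- prof[order(key(prof)), ]
    expect_equal(key(prof), key(want))
    expect_equal(prof$m_r, want$m_r)
    expect_equal(prof$beta_t, want$beta_t, tolerance = 1e-12)
    expect_equal(prof$beta_p, want$beta_p, tolerance = 1e-12)
  }
})

test_that("bin means pooled by probe count reduce to the gene promoter mean", {
  s <- random_meth_study(31, n_probes = 80, n_genes = 3)
  # keep probes clear of the promoter edges so both definitions agree
  keep <- rep(TRUE, nrow(s$manifest))
  for (g in seq_len(nrow(s$annotation)))
    keep <- keep & abs(s$manifest$pos - s$annotation$tss[g]) != 1500
  mf <- s$manifest[keep, ]
  beta <- s$beta[mf$probe_id, ]
  prof <- bin_beta(beta, build_bins(s$annotation), mf, s$sheet)
  prof <- prof[prof$region == "promoter", ]
  gene <- gene_promoter_beta(beta, mf, s$annotation, s$sheet)
  for (g in gene$gene_id[gene$m_r > 0]) {
    p <- prof[prof$unit_id == g, ]
    expect_equal(sum(p$beta_t * p$m_r) / sum(p$m_r),
                 gene$beta_t[gene$gene_id == g], tolerance = 1e-12)
  }
})

test_that("per-bin RD is strict at the threshold and sign-consistent", {
  prof <- data.frame(unit_id = "G1", region = "promoter", bin = 1:3,
                     m_r = 1L, beta_t = c(0.36, 0.5, 0.2),
                     beta_p = c(0.3, 0.5, 0.4))
  out <- bin_rd(prof)
  expect_equal(out$rd[1], 0.2, tolerance = 1e-7)
  expect_false(out$abnormal[1])        # exactly 0.2 is NOT abnormal
  expect_equal(out$rd[2], 0)
  expect_true(out$abnormal[3])
  set.seed(23)
  bt <- runif(100); bp <- runif(100)
  p2 <- data.frame(unit_id = "G", region = "x", bin = 1:100, m_r = 1L,
                   beta_t = bt, beta_p = bp)
  expect_true(all(sign(bin_rd(p2)$rd) == sign(bt - bp)))
})

test_that("key-bin filter keeps only genes abnormal in bins 14-17", {
  prof <- data.frame(
    unit_id = c("G1", "G2", "G3", "G4"), region = "promoter",
    bin = c(3L, 15L, 14L, 20L), m_r = 1L,
    beta_t = c(0.9, 0.9, 0.25, 0.9), beta_p = 0.3)
  out <- bin_rd(prof)
  expect_setequal(key_bin_filter(out), "G2")   # G3's key bin is not abnormal
  expect_identical(key_bin_filter(out, genes = "G1"), character(0))
  # abnormality in an enhancer track never satisfies the promoter filter
  out$region <- "enhancer"
  expect_identical(key_bin_filter(out), character(0))
})

test_that("abnormal density counts genes per bin with correct denominators", {
  prof <- bin_rd(data.frame(
    unit_id = c("G1", "G2", "G1"), region = "promoter",
    bin = c(15L, 15L, 16L), m_r = 1L,
    beta_t = c(0.9, 0.3, 0.3), beta_p = 0.3))
  d <- abnormal_density(prof)
  expect_equal(d$n_genes[d$bin == 15], 2L)
  expect_equal(d$n_abnormal[d$bin == 15], 1L)
  expect_equal(d$fraction[d$bin == 15], 0.5)
  expect_equal(d$n_genes[d$bin == 16], 1L)   # G2 missing from bin 16
  expect_identical(nrow(abnormal_density(prof, genes = character(0))), 0L)
})
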