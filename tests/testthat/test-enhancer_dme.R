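mk_enhancers <- function(center, half = 100, chrom = "chr1") {
  data.frame(enhancer_id = sprintf("E%02d", seq_along(center)),
             chrom = chrom, start = center - half, end = center + half,
             center = center)
}

mk_genes <- function(tss, chrom = "chr1") {
  a <- data.frame(gene_id = sprintf("G%02d", seq_along(tss)),
                  symbol = sprintf("S%02d", seq_along(tss)), chrom = chrom,
                  strand = "+", tss = as.integer(tss))
  a$regions <- replicate(length(tss),
                         data.frame(kind = character(), start = integer(),
                                    end = integer()), simplify = FALSE)
  a
}

test_that("nearest-TSS assignment with deterministic tie-breaking", {
  tg <- assign_targets(mk_enhancers(1800), mk_genes(c(1000, 5000)))
  expect_equal(tg$gene_id, "G01")
  expect_equal(tg$distance, 800)

  # equidistant genes: the smaller TSS wins
  tg2 <- assign_targets(mk_enhancers(2000), mk_genes(c(1000, 3000)))
  expect_equal(tg2$gene_id, "G01")

  # out of range: unassigned, logged
  expect_message(
    tg3 <- assign_targets(mk_enhancers(5e6), mk_genes(1000)),
    "unassigned")
  expect_identical(nrow(tg3), 0L)

  # wrong chromosome never matches
  tg4 <- assign_targets(mk_enhancers(1800, chrom = "chr2"),
                        mk_genes(c(1000, 5000)))
  expect_identical(nrow(tg4), 0L)
})

test_that("nearest-TSS assignment matches the all-pairs oracle", {
  set.seed(33)
  for (i in 1:20) {
    genes <- mk_genes(sample.int(2e6, 15))
    enh <- mk_enhancers(sample.int(2e6, 10))
    got <- assign_targets(enh, genes)
    want <- oracle_assign_targets(enh, genes)
    got <- got[order(got$enhancer_id), ]
    want <- want[order(want$enhancer_id), ]
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$distance, want$distance)
  }
})

test_that("rank-difference shortcut reproduces Spearman exactly", {
  expect_equal(spearman_shortcut(1:3, c(6, 5, 4)), -1)  # sum d^2 = 8
  expect_equal(spearman_shortcut(c(2, 5, 9, 11), c(1, 4, 16, 25)), 1)
  set.seed(34)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    x <- sample(100, n); y <- sample(100, n)   # tie-free
    r <- spearman_shortcut(x, y)
    expect_equal(r, oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(r, cor(x, y, method = "spearman"), tolerance = 1e-12)
    expect_equal(r, spearman_shortcut(y, x))            # symmetry
    expect_equal(r, spearman_shortcut(exp(x / 20), y))  # monotone invariance
  }
  # ties: midrank fallback agrees with cor() on ranks
  x <- c(1, 1, 2, 3); y <- c(4, 3, 2, 1)
  expect_equal(spearman_shortcut(x, y), cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  expect_warning(r0 <- spearman_shortcut(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(r0))
  expect_error(spearman_shortcut(1:2, 1:2), "at least 3")
})

test_that("patient vectors recompute per-patient RD and pseudocounted FC", {
  st <- simulate_study(sim_config(seed = 41, n_genes = 40, frac_dme = 0.2,
                                  n_extra_cancer = 0, n_extra_para = 0))
  fb <- suppressMessages(filter_probes(st$beta, st$manifest))
  nc <- normalize_counts(st$counts, size_factors(st$counts))
  targets <- assign_targets(st$enhancers, st$annotation)
  vec <- suppressMessages(patient_vectors(fb, st$manifest, nc, st$sheet,
                                          st$enhancers, targets))
  pairs <- matched_pairs(st$sheet)
  # brute-force recomputation for a handful of rows
  for (i in sample(nrow(vec), 20)) {
    row <- vec[i, ]
    pr <- pairs[pairs$patient_id == row$patient_id, ]
    e <- st$enhancers[st$enhancers$enhancer_id == row$enhancer_id, ]
    mf <- st$manifest[match(rownames(fb), st$manifest$probe_id), ]
    inside <- mf$chrom == e$chrom & mf$pos >= e$start & mf$pos <= e$end
    rd <- (mean(fb[inside, pr$cancer]) - mean(fb[inside, pr$paracancer])) /
      (mean(fb[inside, pr$paracancer]) + 1e-9)
    fc <- (nc[row$gene_id, pr$cancer] + 1) / (nc[row$gene_id, pr$paracancer] + 1)
    expect_equal(row$rd, rd, tolerance = 1e-12)
    expect_equal(row$fc, unname(fc), tolerance = 1e-12)
  }
  # a patient with equal methylation in both tissues has RD exactly 0
  b0 <- fb; b0[, pairs$cancer[1]] <- b0[, pairs$paracancer[1]]
  v0 <- suppressMessages(patient_vectors(b0, st$manifest, nc, st$sheet,
                                         st$enhancers, targets))
  expect_true(all(v0$rd[v0$patient_id == pairs$patient_id[1]] == 0))
  # zero counts on both sides give FC = 1 through the pseudocount
  nc0 <- nc; nc0[targets$gene_id[1], c(pairs$cancer[1], pairs$paracancer[1])] <- 0
  v1 <- suppressMessages(patient_vectors(fb, st$manifest, nc0, st$sheet,
                                         st$enhancers, targets))
  expect_equal(v1$fc[v1$gene_id == targets$gene_id[1] &
                       v1$patient_id == pairs$patient_id[1]], 1)
})

test_that("a promoter-abnormal gene is never called as a DME target", {
  st <- simulate_study(sim_config(seed = 42, n_genes = 40, frac_dme = 0.2))
  fb <- suppressMessages(filter_probes(st$beta, st$manifest))
  nc <- normalize_counts(st$counts, size_factors(st$counts))
  meth <- gene_promoter_beta(fb, st$manifest, st$annotation, st$sheet)
  # force every DME target's promoter to look hypermethylated
  meth$rd[] <- 0.5
  dme <- suppressMessages(call_dme(fb, st$manifest, nc, st$sheet,
                                   st$enhancers, st$annotation, meth))
  expect_false(any(dme$call))
  # with genuine promoter RD, planted pairs are called
  meth2 <- gene_promoter_beta(fb, st$manifest, st$annotation, st$sheet)
  dme2 <- suppressMessages(call_dme(fb, st$manifest, nc, st$sheet,
                                    st$enhancers, st$annotation, meth2))
  expect_true(any(dme2$call))
})

test_that("DME calling is invariant to input row order", {
  st <- simulate_study(sim_config(seed = 43, n_genes = 40, frac_dme = 0.2))
  fb <- suppressMessages(filter_probes(st$beta, st$manifest))
  nc <- normalize_counts(st$counts, size_factors(st$counts))
  meth <- gene_promoter_beta(fb, st$manifest, st$annotation, st$sheet)
  a <- suppressMessages(call_dme(fb, st$manifest, nc, st$sheet,
                                 st$enhancers, st$annotation, meth))
  set.seed(1)
  enh2 <- st$enhancers[sample(nrow(st$enhancers)), ]
  anno2 <- st$annotation[sample(nrow(st$annotation)), ]
  b <- suppressMessages(call_dme(fb, st$manifest, nc, st$sheet,
                                 enh2, anno2, meth))
  expect_equal(a[order(a$enhancer_id), ], b[order(b$enhancer_id), ],
               ignore_attr = TRUE)
})
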