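# Combine differential expression, promoter methylation, bin profiles and
# DME calls into gene classes and candidate key genes.
#
# U-Hypo: up-regulated AND promoter-hypomethylated gene.
# D-Hyper: down-regulated AND promoter-hypermethylated gene.
# Candidate key gene: (U-Hypo or D-Hyper or DME gene) that is a known
# oncogene/TSG and shows abnormal methylation in a promoter key bin.

#' Classify genes by expression and promoter methylation
#'
#' @param de per-gene DE table (from [de_results()]`$table`).
#' @param meth per-gene promoter methylation (from [gene_promoter_beta()]).
#' @param dme DME pair table (from [call_dme()]); genes from called pairs are
#'   deduplicated (one gene may be targeted by several enhancers).
#' @return data.frame: `gene_id`, `de_status`, `meth_status`, `is_U_Hypo`,
#'   `is_D_Hyper`, `is_DME_gene`.
#' @export
classify_genes <- function(de, meth, dme = NULL) {
  genes <- de$gene_id
  ms <- meth$status[match(genes, meth$gene_id)]
  dme_genes <- if (!is.null(dme) && nrow(dme)) unique(dme$gene_id[dme$call])
               else character()
  data.frame(gene_id = genes, de_status = de$status, meth_status = ms,
             is_U_Hypo = de$status == "up" & !is.na(ms) & ms == "hypo",
             is_D_Hyper = de$status == "down" & !is.na(ms) & ms == "hyper",
             is_DME_gene = genes %in% dme_genes, row.names = NULL)
}

#' Candidate key genes by cancer-gene intersection and the key-bin filter
#'
#' A candidate must belong to one of the three classes (U-Hypo, D-Hyper, DME
#' gene), be listed as an oncogene or TSG (by symbol), and carry abnormal
#' methylation in at least one promoter key bin. Genes present in both
#' cancer-gene lists get role `"both"` and are reported, never silently
#' assigned. Role/direction concordance (e.g. a TSG being D-Hyper) is
#' reported as a column, not enforced as a filter.
#'
#' @param classes output of [classify_genes()].
#' @param cancer_sets list with `oncogenes` and `tsgs` symbol vectors.
#' @param key_genes gene ids passing [key_bin_filter()].
#' @param annotation gene annotation (symbol map).
#' @return data.frame: `gene_id`, `symbol`, `class`, `cancer_role`,
#'   `key_bin_abnormal`, `candidate`, `concordant`.
#' @export
candidate_key_genes <- function(classes, cancer_sets, key_genes, annotation) {
  sym <- annotation$symbol[match(classes$gene_id, annotation$gene_id)]
  unmapped <- sum(is.na(sym))
  if (unmapped)
    message(unmapped, " gene(s) without symbol mapping")
  onc <- !is.na(sym) & sym %in% cancer_sets$oncogenes
  tsg <- !is.na(sym) & sym %in% cancer_sets$tsgs
  role <- rep("none", nrow(classes))
  role[onc] <- "oncogene"
  role[tsg] <- "TSG"
  role[onc & tsg] <- "both"
  cls <- rep(NA_character_, nrow(classes))
  cls[classes$is_DME_gene] <- "DME"
  cls[classes$is_U_Hypo] <- "U-Hypo"
  cls[classes$is_D_Hyper] <- "D-Hyper"
  in_class <- classes$is_U_Hypo | classes$is_D_Hyper | classes$is_DME_gene
  keyb <- classes$gene_id %in% key_genes
  cand <- in_class & role != "none" & keyb
  concord <- (role %in% c("TSG", "both") & classes$is_D_Hyper) |
             (role %in% c("oncogene", "both") & classes$is_U_Hypo)
  out <- data.frame(gene_id = classes$gene_id, symbol = sym, class = cls,
                    cancer_role = role, key_bin_abnormal = keyb,
                    candidate = cand, concordant = concord, row.names = NULL)
  out[order(!out$candidate, out$gene_id), , drop = FALSE]
}

#' Count summary of a pipeline run
#'
#' @param results a [run_study()] result.
#' @return named list of counts (up/down/hyper/hypo, class sizes, DME pairs
#'   and genes, oncogene/TSG overlaps, key-bin candidates).
#' @export
summarize_run <- function(results) {
  cl <- results$classes
  cand <- results$candidates
  list(n_genes = nrow(cl),
       n_up = sum(cl$de_status == "up"),
       n_down = sum(cl$de_status == "down"),
       n_hyper = sum(cl$meth_status == "hyper", na.rm = TRUE),
       n_hypo = sum(cl$meth_status == "hypo", na.rm = TRUE),
       n_U_Hypo = sum(cl$is_U_Hypo),
       n_D_Hyper = sum(cl$is_D_Hyper),
       n_dme_pairs = sum(results$dme$call),
       n_dme_genes = sum(cl$is_DME_gene),
       n_class_oncogene = sum(cand$cancer_role %in% c("oncogene", "both") &
                                !is.na(cand$class)),
       n_class_tsg = sum(cand$cancer_role %in% c("TSG", "both") &
                           !is.na(cand$class)),
       n_key_bin_genes = length(results$key_genes),
       n_candidates = sum(cand$candidate))
}

#' Run the full integration pipeline on an in-memory study
#'
#' Executes differential expression, probe QC, gene-promoter methylation,
#' bin profiling, DME calling, gene classification and candidate selection.
#' The run is a pure function of the study object and the thresholds:
#' rerunning on the same inputs reproduces every table exactly.
#'
#' @param study list with elements `sheet`, `counts`, `beta`, `manifest`,
#'   `annotation`, `enhancers`, `gene_sets` (as produced by
#'   [simulate_study()] or [read_study()]).
#' @param fc_up,fc_down,alpha DE thresholds.
#' @param rd_threshold abnormal-methylation threshold on |RD|.
#' @param r_threshold DME Spearman threshold.
#' @param key_bins promoter key bins (default 14-17, TSS +/- 200 bp).
#' @return list with `de`, `meth`, `profile`, `density`, `key_genes`, `dme`,
#'   `classes`, `candidates`, `summary`.
#' @export
run_study <- function(study, fc_up = 1.25, fc_down = 0.8, alpha = 0.05,
                      rd_threshold = 0.2, r_threshold = -0.4,
                      key_bins = 14:17) {
  de <- de_results(study$counts, study$sheet, fc_up, fc_down, alpha)
  fb <- filter_probes(study$beta, study$manifest)
  meth <- gene_promoter_beta(fb, study$manifest, study$annotation,
                             study$sheet, threshold = rd_threshold)
  scheme <- build_bins(study$annotation, study$enhancers)
  profile <- bin_rd(bin_beta(fb, scheme, study$manifest, study$sheet),
                    threshold = rd_threshold)
  density <- abnormal_density(profile, study$annotation$gene_id)
  key_genes <- key_bin_filter(profile, study$annotation$gene_id, key_bins)
  dme <- call_dme(fb, study$manifest, de$normalized, study$sheet,
                  study$enhancers, study$annotation, meth,
                  rd_threshold = rd_threshold, r_threshold = r_threshold)
  classes <- classify_genes(de$table, meth, dme)
  candidates <- candidate_key_genes(classes, study$gene_sets, key_genes,
                                    study$annotation)
  res <- list(de = de$table, normalized = de$normalized,
              size_factors = de$size_factors, meth = meth, profile = profile,
              density = density, key_genes = key_genes, dme = dme,
              classes = classes, candidates = candidates)
  res$summary <- summarize_run(res)
  res
}

#' Read a study directory written by [write_study()]
#'
#' @param dir directory containing the standard study files.
#' @return study list usable by [run_study()].
#' @export
read_study <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  list(sheet = sheet,
       counts = read_counts(file.path(dir, "counts.tsv"), sheet),
       beta = read_beta_table(file.path(dir, "beta.tsv"), manifest),
       manifest = manifest,
       annotation = read_gene_annotation(file.path(dir, "gene_model.tsv")),
       enhancers = read_enhancers(file.path(dir, "enhancers.bed")),
       gene_sets = read_gene_sets(file.path(dir, "oncogenes.txt"),
                                  file.path(dir, "tsgs.txt")))
}

#' Load a YAML run configuration
#'
#' The YAML names the input paths (`sample_sheet`, `counts`, `beta`,
#' `manifest`, `annotation`, `enhancers`, `oncogenes`, `tsgs`) and optional
#' thresholds (`fc_up`, `fc_down`, `alpha`, `rd_threshold`, `r_threshold`).
#'
#' @param path YAML file path.
#' @return list with `study` and `opts`, ready for
#'   `do.call(run_study, c(list(study), opts))`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sheet <- read_sample_sheet(cfg$sample_sheet)
  manifest <- read_manifest(cfg$manifest)
  study <- list(sheet = sheet,
                counts = read_counts(cfg$counts, sheet),
                beta = read_beta_table(cfg$beta, manifest),
                manifest = manifest,
                annotation = read_gene_annotation(cfg$annotation),
                enhancers = read_enhancers(cfg$enhancers),
                gene_sets = read_gene_sets(cfg$oncogenes, cfg$tsgs))
  opts <- cfg[intersect(names(cfg), c("fc_up", "fc_down", "alpha",
                                      "rd_threshold", "r_threshold"))]
  list(study = study, opts = opts)
}
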