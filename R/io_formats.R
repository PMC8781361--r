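# Readers/writers for every external table the pipeline touches. All other
# modules operate on the in-memory objects returned here. Internal coordinates
# are 1-based inclusive (HM450K manifest convention); BED files are converted
# at this boundary and nowhere else.

NA_TOKENS <- c("NA", "", "NaN")

#' Convert BED (0-based half-open) coordinates to internal 1-based inclusive
#'
#' @param start,end integer vectors of BED start/end.
#' @return A data.frame with 1-based inclusive `start` and `end`.
#' @export
bed_to_internal <- function(start, end) {
  stopifnot(all(end > start))
  data.frame(start = start + 1L, end = as.integer(end))
}

#' Convert internal 1-based inclusive coordinates to BED (0-based half-open)
#'
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @return A data.frame with BED `start` and `end`.
#' @export
internal_to_bed <- function(start, end) {
  stopifnot(all(end >= start), all(start >= 1))
  data.frame(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `sample_id`, `patient_id`, `condition`.
#' `condition` must be `"cancer"` or `"paracancer"`. A matched pair is a
#' patient with exactly one sample of each condition.
#'
#' @param path path to the TSV file.
#' @return A data.frame with columns `sample_id`, `patient_id`, `condition`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  need <- c("sample_id", "patient_id", "condition")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$condition), c("cancer", "paracancer"))
  if (length(bad))
    stop("unknown condition value(s): ", paste(bad, collapse = ", "))
  df
}

#' Matched tumor/normal pairs in a sample sheet
#'
#' @param sheet a sample sheet data.frame.
#' @return data.frame with one row per matched patient: `patient_id`,
#'   `cancer` and `paracancer` sample ids.
#' @export
matched_pairs <- function(sheet) {
  out <- lapply(split(sheet, sheet$patient_id), function(d) {
    ca <- d$sample_id[d$condition == "cancer"]
    pa <- d$sample_id[d$condition == "paracancer"]
    if (length(ca) == 1L && length(pa) == 1L)
      data.frame(patient_id = d$patient_id[1], cancer = ca, paracancer = pa)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(patient_id = character(), cancer = character(),
                      paracancer = character())
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}

#' Read a gene-by-sample count matrix
#'
#' First column `gene_id`, remaining header fields are sample ids. Cells must
#' be nonnegative integers; any non-integer cell is a hard error naming the
#' offending gene and sample.
#'
#' @param path path to the TSV file.
#' @param sheet sample sheet; the returned columns follow its sample order.
#' @return integer matrix (genes x samples) with dimnames.
#' @export
read_counts <- function(path, sheet) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  genes <- df$gene_id
  samples <- names(df)[-1]
  unknown <- setdiff(samples, sheet$sample_id)
  if (length(unknown))
    stop("sample(s) in counts header absent from sample sheet: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(sheet$sample_id, samples)
  if (length(missing))
    stop("sample(s) in sample sheet absent from counts file: ",
         paste(missing, collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 ncol = length(samples)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count '%s' at gene %s, sample %s",
                 mat[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
                 samples[bad[1, 2]]))
  }
  out <- matrix(as.integer(num), nrow = nrow(mat), ncol = length(samples),
                dimnames = list(genes, samples))
  out[, sheet$sample_id, drop = FALSE]
}

#' Read a probe manifest
#'
#' Columns `probe_id`, `chrom`, `pos` (1-based), `is_cpg` (TRUE/FALSE).
#'
#' @param path path to the TSV file.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path)
  need <- c("probe_id", "chrom", "pos", "is_cpg")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df$probe_id)) stop("duplicated probe_id in manifest")
  if (any(df$pos < 1)) stop("manifest pos must be >= 1")
  df$is_cpg <- as.logical(df$is_cpg)
  df
}

#' Read a probe-by-sample beta-value table
#'
#' Rows keyed by `probe_id`; cells are beta values in \[0,1\] or a missing
#' token (`NA`, empty, `NaN`). Probes absent from the manifest are dropped
#' with a logged count; beta outside \[0,1\] is a hard error.
#'
#' @param path path to the TSV file.
#' @param manifest probe manifest data.frame.
#' @return numeric matrix (probes x samples), NA where missing, with
#'   attribute `n_dropped` = probes not in the manifest.
#' @export
read_beta_table <- function(path, manifest) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (names(df)[1] != "probe_id") stop("first column must be probe_id")
  probes <- df$probe_id
  mat <- as.matrix(df[, -1, drop = FALSE])
  mat[mat %in% NA_TOKENS] <- NA
  num <- matrix(as.numeric(mat), nrow = nrow(mat),
                dimnames = list(probes, colnames(mat)))
  bad <- which(!is.na(num) & (num < 0 | num > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta value %s outside [0,1] at probe %s, sample %s",
                 num[bad[1, , drop = FALSE]], probes[bad[1, 1]],
                 colnames(num)[bad[1, 2]]))
  keep <- probes %in% manifest$probe_id
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(n_dropped, " probe(s) absent from manifest dropped")
  out <- num[keep, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a methylated/unmethylated intensity table
#'
#' First column `probe_id`; then two numeric columns per sample, methylated
#' followed by unmethylated. Negative (background-corrected) intensities are
#' accepted; clamping happens when beta is computed.
#'
#' @param path path to the TSV file.
#' @return list with matrices `methy` and `umethy` (probes x samples).
#' @export
read_intensity_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "probe_id") stop("first column must be probe_id")
  vals <- df[, -1, drop = FALSE]
  if (ncol(vals) %% 2 != 0)
    stop("intensity table must have an even number of value columns ",
         "(methylated, unmethylated per sample); got ", ncol(vals))
  mi <- seq(1, ncol(vals), by = 2)
  samples <- sub("[._](M|methy)$", "", names(vals)[mi])
  methy <- as.matrix(vals[, mi, drop = FALSE])
  umethy <- as.matrix(vals[, mi + 1, drop = FALSE])
  dimnames(methy) <- dimnames(umethy) <- list(df$probe_id, samples)
  list(methy = methy, umethy = umethy)
}

#' Read a gene-model annotation table
#'
#' Tab-separated with columns `gene_id`, `symbol`, `chrom`, `strand`, `tss`,
#' `regions`. `regions` encodes functional-region intervals as
#' `kind:start-end,start-end;kind:...` with 1-based inclusive coordinates and
#' kinds among utr5, exon, intron, utr3, intergenic (the promoter is implicit,
#' TSS +/- 1500 bp).
#'
#' @param path path to the TSV file.
#' @return data.frame with a `regions` list-column of data.frames
#'   (`kind`, `start`, `end`).
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("gene_id", "symbol", "chrom", "strand", "tss", "regions")
  if (!all(need %in% names(df)))
    stop("gene annotation must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id: one TSS per gene is required")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df$tss <- as.integer(df$tss)
  df$regions <- lapply(df$regions, parse_region_blocks)
  df[need]
}

parse_region_blocks <- function(s) {
  if (is.na(s) || s == "")
    return(data.frame(kind = character(), start = integer(), end = integer()))
  blocks <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- lapply(blocks, function(b) {
    kv <- strsplit(b, ":", fixed = TRUE)[[1]]
    ivs <- strsplit(strsplit(kv[2], ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
    data.frame(kind = kv[1],
               start = as.integer(vapply(ivs, `[`, "", 1L)),
               end = as.integer(vapply(ivs, `[`, "", 2L)))
  })
  do.call(rbind, out)
}

format_region_blocks <- function(regions) {
  if (nrow(regions) == 0) return("")
  paste(vapply(split(regions, factor(regions$kind, unique(regions$kind))),
               function(d) paste0(d$kind[1], ":",
                                  paste0(d$start, "-", d$end, collapse = ",")),
               ""), collapse = ";")
}

#' Read an enhancer BED file
#'
#' BED3+ (0-based half-open). The enhancer center is `floor((start+end)/2)` in
#' BED coordinates; internal `start`/`end` are 1-based inclusive. Enhancers
#' shorter than 50 bp or longer than 1500 bp draw a warning (enhancers are
#' short regulatory elements), not an error.
#'
#' @param path path to the BED file.
#' @return data.frame with `enhancer_id`, `chrom`, `start`, `end`, `center`.
#' @export
read_enhancers <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("failed to parse BED (check start < end): ",
                                          conditionMessage(e)))
  if (any(IRanges::width(gr) < 1))
    stop("enhancer with start >= end in ", path)
  bed_start <- GenomicRanges::start(gr) - 1L
  bed_end <- GenomicRanges::end(gr)
  ids <- if (!is.null(gr$name) && !all(is.na(gr$name))) as.character(gr$name)
         else paste0(GenomicRanges::seqnames(gr), ":", bed_start, "-", bed_end)
  out <- data.frame(enhancer_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = bed_end,
                    center = (bed_start + bed_end) %/% 2L)
  len <- out$end - out$start + 1L
  n_odd <- sum(len < 50 | len > 1500)
  if (n_odd)
    warning(n_odd, " enhancer(s) outside the typical 50-1500 bp length range")
  out
}

#' Read oncogene and tumor-suppressor gene lists
#'
#' One gene symbol per line. The two sets may overlap; the overlap size is
#' reported, never silently resolved.
#'
#' @param oncogene_path,tsg_path paths to the symbol lists.
#' @return list with `oncogenes`, `tsgs` (character vectors) and `both`
#'   (their intersection).
#' @export
read_gene_sets <- function(oncogene_path, tsg_path) {
  rd <- function(p) unique(trimws(readLines(p)))
  onc <- setdiff(rd(oncogene_path), "")
  tsg <- setdiff(rd(tsg_path), "")
  both <- intersect(onc, tsg)
  if (length(both))
    message(length(both), " symbol(s) present in both oncogene and TSG lists")
  list(oncogenes = onc, tsgs = tsg, both = both)
}

# ---- writers (round-trip partners of the readers) --------------------------

#' @rdname read_sample_sheet
#' @param sheet,path object to write and destination path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_counts
#' @param counts matrix to write.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_beta_table
#' @param beta matrix to write (NA written as the literal token `NA`).
#' @export
write_beta_table <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta),
                   format(beta, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname read_manifest
#' @param manifest manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_gene_annotation
#' @param annotation annotation data.frame to write.
#' @export
write_gene_annotation <- function(annotation, path) {
  df <- annotation
  df$regions <- vapply(df$regions, format_region_blocks, "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_enhancers
#' @param enhancers enhancer data.frame to write (converted back to BED).
#' @export
write_enhancers <- function(enhancers, path) {
  bed <- internal_to_bed(enhancers$start, enhancers$end)
  df <- data.frame(enhancers$chrom, bed$start, bed$end, enhancers$enhancer_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
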