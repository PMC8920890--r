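#' Allelic imbalance score
#'
#' Signed skew of expression toward the CAST allele:
#' `cast / (cast + c57) - 0.5`, in `[-0.5, +0.5]`; positive means
#' CAST-skewed. Undefined (returned as `NA`) when both counts are zero.
#'
#' @param cast,c57 non-negative allele-assigned counts (vectorised).
#' @return Numeric score(s) in `[-0.5, 0.5]`, `NA` where `cast + c57 == 0`.
#' @examples
#' allelic_imbalance(30, 10)  # +0.25
#' @export
allelic_imbalance <- function(cast, c57) {
  tot <- cast + c57
  out <- cast / tot - 0.5
  out[tot == 0] <- NA_real_
  out
}

#' Distribute total molecule counts to alleles
#'
#' Assigns a cell's UMI count for a gene to the CAST and C57 alleles in
#' proportion to the allele-informative read counts, rounding half to even;
#' the complement goes to C57 so totals are conserved exactly. A zero total
#' is a true zero on both alleles; a positive total with no
#' allele-informative reads is a missing assignment.
#'
#' @param total_umi,cast_reads,c57_reads non-negative integers (scalars,
#'   vectors or matrices of common shape).
#' @return list with `umi_cast`, `umi_c57` (integer, `NA` where missing) and
#'   logical `missing`.
#' @examples
#' distribute_umis(10, 6, 4)  # 6 CAST, 4 C57
#' distribute_umis(7, 1, 1)   # 3.5 rounds half to even: 4 CAST, 3 C57
#' @export
distribute_umis <- function(total_umi, cast_reads, c57_reads) {
  reads <- cast_reads + c57_reads
  missing <- total_umi > 0 & reads == 0
  frac <- ifelse(reads > 0, cast_reads / reads, 0)
  umi_cast <- round(total_umi * frac)  # round() is half-to-even in R
  umi_c57 <- total_umi - umi_cast
  umi_cast[missing] <- NA_real_
  umi_c57[missing] <- NA_real_
  list(umi_cast = umi_cast, umi_c57 = umi_c57, missing = missing)
}

#' Cell quality-control presets
#'
#' Threshold sets for the supported library types: `smartseq2_fibro`
#' (at least 500,000 reads; 4,000 genes at 5+ counts; autosomal allelic
#' balance within (-0.10, 0.10); at most 20% of allelic counts on the
#' imprinted X), `smartseq3_fibro` (at least 100,000 exon reads; 50,000
#' UMIs; 5,000 genes at 1+ UMI), `hek_ss3` (at least 500,000 exon reads;
#' 7,500 genes at 1+ count) and `mesc_ss2` (at least 400,000 exon reads;
#' 8,000 genes at 5+ counts).
#'
#' @return Named list of preset threshold lists.
#' @export
qc_presets <- function() {
  list(
    smartseq2_fibro = list(min_reads = 5e5, min_genes = 4000,
                           gene_count_threshold = 5,
                           balance_range = c(-0.10, 0.10),
                           max_imprinted_x_fraction = 0.20),
    smartseq3_fibro = list(min_reads = 1e5, min_umis = 5e4, min_genes = 5000,
                           gene_count_threshold = 1),
    hek_ss3 = list(min_reads = 5e5, min_genes = 7500,
                   gene_count_threshold = 1),
    mesc_ss2 = list(min_reads = 4e5, min_genes = 8000,
                    gene_count_threshold = 5))
}

#' Cell-level quality control
#'
#' Evaluates per-cell metrics against a named preset and reports every
#' violated threshold; a cell passes iff no reason is recorded.
#'
#' @param metrics data frame with one row per cell and columns `cell_id`,
#'   `total_reads`, `genes_detected` (at the preset's count threshold) and,
#'   for presets that use them, `allelic_balance` (mean autosomal allelic
#'   imbalance, see [cell_allelic_balance()]), `imprinted_x_fraction` and
#'   `total_umis`.
#' @param preset one of `names(qc_presets())`.
#' @return data frame of class `cell_qc_report`: the metrics plus `pass` and
#'   a `reasons` character column (comma-separated failed checks).
#' @export
cell_qc <- function(metrics, preset = "smartseq2_fibro") {
  presets <- qc_presets()
  if (!preset %in% names(presets)) {
    stop("config error: unknown preset '", preset, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  th <- presets[[preset]]
  reasons <- vector("list", nrow(metrics))
  add <- function(reasons, bad, label) {
    for (i in which(bad)) reasons[[i]] <- c(reasons[[i]], label)
    reasons
  }
  reasons <- add(reasons, metrics$total_reads < th$min_reads, "reads")
  reasons <- add(reasons, metrics$genes_detected < th$min_genes, "genes")
  if (!is.null(th$min_umis)) {
    reasons <- add(reasons, metrics$total_umis < th$min_umis, "umis")
  }
  if (!is.null(th$balance_range)) {
    bal <- metrics$allelic_balance
    reasons <- add(reasons,
                   !(bal > th$balance_range[1] & bal < th$balance_range[2]),
                   "allelic balance")
  }
  if (!is.null(th$max_imprinted_x_fraction)) {
    reasons <- add(reasons,
                   metrics$imprinted_x_fraction > th$max_imprinted_x_fraction,
                   "imprinted X fraction")
  }
  out <- metrics
  out$reasons <- vapply(reasons, function(r) paste(r, collapse = ","),
                        character(1))
  out$pass <- !nzchar(out$reasons)
  class(out) <- c("cell_qc_report", "data.frame")
  out
}

#' Per-cell allelic-balance statistic
#'
#' Mean, over autosomal non-imprinted genes with allele-informative reads,
#' of the per-gene allelic imbalance in that cell. This aggregate is the
#' cell-level "distribution of allelic counts" statistic tested against the
#' (-0.10, 0.10) window.
#'
#' @param acs an [allelic_count_set()].
#' @param genes a [gene_table()] covering the rows of `acs`.
#' @return Named numeric vector, one balance score per cell.
#' @export
cell_allelic_balance <- function(acs, genes) {
  stopifnot(inherits(acs, "allelic_count_set"), inherits(genes, "gene_table"))
  keep <- genes$gene_id[!genes$imprinted & !genes$chrX]
  keep <- intersect(keep, rownames(acs$totals))
  ai <- allelic_imbalance(acs$cast_reads[keep, , drop = FALSE],
                          acs$c57_reads[keep, , drop = FALSE])
  colMeans(ai, na.rm = TRUE)
}

#' Gene-level expression filter
#'
#' Keeps genes with at least `min_count` counts in at least `min_cells`
#' cells (default: >= 5 counts in >= 2 cells).
#'
#' @param counts gene x cell count matrix.
#' @param min_count,min_cells thresholds, >= 0.
#' @return Character vector of retained gene identifiers.
#' @export
gene_filter <- function(counts, min_count = 5, min_cells = 2) {
  stopifnot(min_count >= 0, min_cells >= 0)
  keep <- rowSums(counts >= min_count) >= min_cells
  rownames(counts)[keep]
}
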