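#' Allele-resolved count set
#'
#' The pipeline's central input: per-gene, per-cell total molecule counts
#' (UMIs or reads) together with CAST- and C57-assigned read counts. UMIs are
#' distributed to alleles by the fraction of allele-informative reads
#' ([distribute_umis()]); entries with molecules but no allele-informative
#' reads are flagged missing, entries with zero molecules are true zeros on
#' both alleles.
#'
#' @param totals gene x cell non-negative integer matrix with unique row
#'   (gene) and column (cell) names.
#' @param cast_reads,c57_reads matrices of allele-assigned read counts with
#'   identical dimensions and dimnames; `cast_reads + c57_reads` must never
#'   exceed `totals`.
#' @return Object of class `allelic_count_set`: a list with `totals`,
#'   `cast_reads`, `c57_reads`, derived `umi_cast`, `umi_c57` and logical
#'   `missing` mask.
#' @export
allelic_count_set <- function(totals, cast_reads, c57_reads) {
  totals <- as.matrix(totals); cast_reads <- as.matrix(cast_reads)
  c57_reads <- as.matrix(c57_reads)
  if (!identical(dim(totals), dim(cast_reads)) ||
      !identical(dim(totals), dim(c57_reads))) {
    stop("validation error: count matrices must share dimensions")
  }
  for (m in list(totals, cast_reads, c57_reads)) {
    if (any(m < 0) || any(m != floor(m))) {
      stop("validation error: counts must be non-negative integers")
    }
  }
  gn <- rownames(totals); cn <- colnames(totals)
  if (is.null(gn) || is.null(cn)) {
    stop("validation error: gene and cell identifiers required as dimnames")
  }
  if (anyDuplicated(gn)) stop("validation error: duplicate gene identifiers")
  if (anyDuplicated(cn)) stop("validation error: duplicate cell identifiers")
  if (any(cast_reads + c57_reads > totals)) {
    stop("validation error: allele-assigned counts exceed totals")
  }
  alle <- distribute_umis(totals, cast_reads, c57_reads)
  out <- list(totals = totals, cast_reads = cast_reads,
              c57_reads = c57_reads, umi_cast = alle$umi_cast,
              umi_c57 = alle$umi_c57, missing = alle$missing)
  for (m in c("totals", "cast_reads", "c57_reads", "umi_cast", "umi_c57")) {
    storage.mode(out[[m]]) <- "integer"
  }
  structure(out, class = "allelic_count_set")
}

#' @export
print.allelic_count_set <- function(x, ...) {
  cat(sprintf(
    "Allele-resolved count set: %d genes x %d cells (%.1f%% entries missing allelic assignment)\n",
    nrow(x$totals), ncol(x$totals), 100 * mean(x$missing)))
  invisible(x)
}

#' @export
dim.allelic_count_set <- function(x) dim(x$totals)

.acs_files <- list(
  mtx = c(totals = "totals.mtx", cast = "cast.mtx", c57 = "c57.mtx",
          genes = "genes.tsv", cells = "cells.tsv"),
  tsv = c(totals = "totals.tsv", cast = "cast.tsv", c57 = "c57.tsv"))

#' Read an allele-resolved count set from disk
#'
#' Two plain-text layouts are supported inside a directory `path`:
#' MatrixMarket triplets (`totals.mtx`, `cast.mtx`, `c57.mtx` with
#' accompanying `genes.tsv` and `cells.tsv` identifier files) or wide
#' tab-separated matrices (`totals.tsv`, `cast.tsv`, `c57.tsv` with gene
#' rows and cell columns).
#'
#' @param path directory containing the count files.
#' @param format `"mtx"` (MatrixMarket) or `"tsv"` (wide matrices).
#' @return An [allelic_count_set()].
#' @export
read_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  files <- file.path(path, .acs_files[[format]])
  miss <- !file.exists(files)
  if (any(miss)) {
    stop("format error: missing input file(s): ",
         paste(basename(files[miss]), collapse = ", "))
  }
  if (format == "mtx") {
    genes <- readLines(file.path(path, "genes.tsv"))
    cells <- readLines(file.path(path, "cells.tsv"))
    rd <- function(f) {
      m <- tryCatch(as.matrix(Matrix::readMM(file.path(path, f))),
                    error = function(e) {
                      stop("format error in ", f, ": ", conditionMessage(e))
                    })
      if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
        stop("validation error: matrix dimensions do not match identifier files")
      }
      dimnames(m) <- list(genes, cells)
      m
    }
    allelic_count_set(rd("totals.mtx"), rd("cast.mtx"), rd("c57.mtx"))
  } else {
    rd <- function(f) {
      as.matrix(read.delim(file.path(path, f), row.names = 1,
                           check.names = FALSE))
    }
    allelic_count_set(rd("totals.tsv"), rd("cast.tsv"), rd("c57.tsv"))
  }
}

#' Write an allele-resolved count set to disk
#'
#' Inverse of [read_counts()]; gene and cell order is canonicalised
#' (sorted) so that write-read round trips are byte-stable.
#'
#' @param x an [allelic_count_set()].
#' @param path output directory (created if absent).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "allelic_count_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ord_g <- order(rownames(x$totals)); ord_c <- order(colnames(x$totals))
  mats <- lapply(x[c("totals", "cast_reads", "c57_reads")],
                 function(m) m[ord_g, ord_c, drop = FALSE])
  if (format == "mtx") {
    writeLines(rownames(mats$totals), file.path(path, "genes.tsv"))
    writeLines(colnames(mats$totals), file.path(path, "cells.tsv"))
    Matrix::writeMM(methods::as(Matrix::Matrix(mats$totals, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "totals.mtx"))
    Matrix::writeMM(methods::as(Matrix::Matrix(mats$cast_reads, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "cast.mtx"))
    Matrix::writeMM(methods::as(Matrix::Matrix(mats$c57_reads, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "c57.mtx"))
  } else {
    wr <- function(m, f) {
      df <- data.frame(gene = rownames(m), m, check.names = FALSE)
      write.table(df, file.path(path, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    wr(mats$totals, "totals.tsv")
    wr(mats$cast_reads, "cast.tsv")
    wr(mats$c57_reads, "c57.tsv")
  }
  invisible(path)
}
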