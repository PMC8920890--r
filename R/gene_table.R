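#' Gene annotation table
#'
#' Genomic metadata per gene: coordinates in the internal 0-based half-open
#' convention, strand, biotype, imprinting and X-chromosome flags, and the
#' derived transcription start site (TSS): `start` on the plus strand,
#' `end - 1` on the minus strand.
#'
#' @param df data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"` or `"-"`); optional `biotype`
#'   (default `"protein_coding"`), `imprinted`, `chrX` (defaults `FALSE`).
#' @return data frame of class `gene_table` with a derived `tss` column.
#' @export
gene_table <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop("validation error: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stop("validation error: duplicate gene identifiers")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("validation error: strand must be '+' or '-'")
  }
  if (any(df$start >= df$end)) {
    stop("validation error: start must be < end (0-based half-open)")
  }
  if (is.null(df$biotype)) df$biotype <- "protein_coding"
  if (is.null(df$imprinted)) df$imprinted <- FALSE
  if (is.null(df$chrX)) df$chrX <- df$chrom %in% c("chrX", "X")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df <- df[, c("gene_id", "chrom", "start", "end", "strand", "tss",
               "biotype", "imprinted", "chrX")]
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Read a gene annotation table
#'
#' Supported formats: package TSV (columns as in [gene_table()], already
#' 0-based half-open), BED6 (0-based half-open by definition) and GFF3
#' (1-based closed, converted on read). In every case coordinates end up in
#' the internal 0-based half-open convention and the TSS is `start` on `+`
#' and `end - 1` on `-`.
#'
#' @param path file path.
#' @param format `"tsv"`, `"bed6"` or `"gff3"`.
#' @return A [gene_table()].
#' @export
read_gene_table <- function(path, format = c("tsv", "bed6", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("format error: file not found: ", path)
  df <- switch(format,
    tsv = {
      d <- read.delim(path, stringsAsFactors = FALSE)
      d
    },
    bed6 = {
      gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                     error = function(e) {
                       stop("format error: ", conditionMessage(e))
                     })
      data.frame(gene_id = gr$name,
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,  # GRanges is 1-based
                 end = GenomicRanges::end(gr),
                 strand = as.character(GenomicRanges::strand(gr)),
                 stringsAsFactors = FALSE)
    },
    gff3 = {
      gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                     error = function(e) {
                       stop("format error: ", conditionMessage(e))
                     })
      ids <- if (!is.null(gr$gene_id)) gr$gene_id
             else if (!is.null(gr$ID)) gr$ID else gr$Name
      if (is.null(ids) || anyNA(ids)) {
        stop("format error: GFF3 attributes lack ID/gene_id")
      }
      data.frame(gene_id = as.character(ids),
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,  # 1-based -> 0-based
                 end = GenomicRanges::end(gr),
                 strand = as.character(GenomicRanges::strand(gr)),
                 biotype = if (!is.null(gr$biotype)) as.character(gr$biotype)
                           else as.character(gr$type),
                 stringsAsFactors = FALSE)
    })
  gene_table(df)
}

#' Write a gene table as package TSV
#'
#' @param x a [gene_table()].
#' @param path output file.
#' @export
write_gene_table <- function(x, path) {
  stopifnot(inherits(x, "gene_table"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
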