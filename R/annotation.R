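# distance from each gene's TSS to the nearest TSS of the reference set
# (excluding itself); Inf when alone on its chromosome
.nearest_tss <- function(genes, ref) {
  out_dist <- rep(Inf, nrow(genes))
  out_partner <- rep(NA_character_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    cand <- ref[ref$chrom == genes$chrom[i] &
                ref$gene_id != genes$gene_id[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    d <- abs(cand$tss - genes$tss[i])
    j <- which.min(d)
    out_dist[i] <- d[j]
    out_partner[i] <- cand$gene_id[j]
  }
  data.frame(gene_id = genes$gene_id, distance = out_dist,
             partner = out_partner, stringsAsFactors = FALSE)
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Classify loci by promoter architecture
#'
#' Assigns each gene a locus category relative to the expressed gene set:
#' `divergent` (no gene-body overlap, opposite strand, TSSs within 500 bp),
#' `convergent` (gene-body overlap, TSSs within 2 kb), `intergenic` (no
#' overlap with any expressed gene and gene bodies at least 4 kb apart) and
#' `separated_unit` (TSS at least 4 kb from any other expressed TSS);
#' `other` when none applies. Categories are evaluated in that order for the
#' single `class` label; each rule is additionally reported as a logical
#' column since a gene can be, for example, both intergenic and a separated
#' unit.
#'
#' @param genes a [gene_table()].
#' @param expressed character vector of expressed gene ids (must be a subset
#'   of `genes$gene_id`).
#' @return data frame: `gene_id`, `class`, `partner` (for
#'   divergent/convergent), `tss_distance` to the nearest expressed TSS, and
#'   logical columns `divergent`, `convergent`, `intergenic`,
#'   `separated_unit`.
#' @export
classify_loci <- function(genes, expressed) {
  stopifnot(inherits(genes, "gene_table"))
  if (!all(expressed %in% genes$gene_id)) {
    stop("validation error: expressed ids absent from the gene table")
  }
  ref <- genes[genes$gene_id %in% expressed, , drop = FALSE]
  nt <- .nearest_tss(genes, ref)
  n <- nrow(genes)
  divergent <- convergent <- intergenic <- separated <- logical(n)
  partner <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    cand <- ref[ref$chrom == g$chrom & ref$gene_id != g$gene_id, ,
                drop = FALSE]
    if (nrow(cand) > 0) {
      ov <- .overlaps(g$start, g$end, cand$start, cand$end)
      d <- abs(cand$tss - g$tss)
      div_hit <- !ov & d <= 500 & cand$strand != g$strand
      con_hit <- ov & d <= 2000
      if (any(div_hit)) {
        divergent[i] <- TRUE
        partner[i] <- cand$gene_id[div_hit][which.min(d[div_hit])]
      } else if (any(con_hit)) {
        convergent[i] <- TRUE
        partner[i] <- cand$gene_id[con_hit][which.min(d[con_hit])]
      }
      body_gap <- pmax(cand$start - g$end, g$start - cand$end)
      intergenic[i] <- !any(ov) && all(body_gap >= 4000)
      separated[i] <- all(d >= 4000)
    } else {
      intergenic[i] <- TRUE
      separated[i] <- TRUE
    }
  }
  cls <- rep("other", n)
  cls[separated] <- "separated_unit"
  cls[intergenic] <- "intergenic"
  cls[convergent] <- "convergent"
  cls[divergent] <- "divergent"
  data.frame(gene_id = genes$gene_id, class = cls, partner = partner,
             tss_distance = nt$distance, divergent = divergent,
             convergent = convergent, intergenic = intergenic,
             separated_unit = separated, stringsAsFactors = FALSE)
}

#' Divergent and unidirectional promoter classes for mRNAs
#'
#' Classifies expressed protein-coding genes by promoter arrangement:
#' `divergent_mRNA_mRNA` or `divergent_mRNA_lncRNA` when an opposite-strand,
#' non-overlapping partner TSS lies within 500 bp (partner biotype decides
#' the label), `unidirectional` when the nearest expressed TSS is at least
#' 10 kb away, and `none` for the excluded middle ground.
#'
#' @inheritParams classify_loci
#' @return data frame: `gene_id`, `pair_class`, `partner`, `tss_distance`.
#' @export
promoter_pair_classes <- function(genes, expressed) {
  stopifnot(inherits(genes, "gene_table"))
  ref <- genes[genes$gene_id %in% expressed, , drop = FALSE]
  mrna <- ref[ref$biotype == "protein_coding", , drop = FALSE]
  nt <- .nearest_tss(mrna, ref)
  cls <- rep("none", nrow(mrna))
  partner <- rep(NA_character_, nrow(mrna))
  for (i in seq_len(nrow(mrna))) {
    g <- mrna[i, ]
    cand <- ref[ref$chrom == g$chrom & ref$gene_id != g$gene_id, ,
                drop = FALSE]
    if (nrow(cand) == 0) {
      cls[i] <- "unidirectional"
      next
    }
    d <- abs(cand$tss - g$tss)
    ov <- .overlaps(g$start, g$end, cand$start, cand$end)
    div_hit <- !ov & d <= 500 & cand$strand != g$strand
    if (any(div_hit)) {
      j <- which(div_hit)[which.min(d[div_hit])]
      partner[i] <- cand$gene_id[j]
      cls[i] <- if (cand$biotype[j] == "protein_coding")
        "divergent_mRNA_mRNA" else "divergent_mRNA_lncRNA"
    } else if (min(d) >= 10000) {
      cls[i] <- "unidirectional"
    }
  }
  data.frame(gene_id = mrna$gene_id, pair_class = cls, partner = partner,
             tss_distance = nt$distance, stringsAsFactors = FALSE)
}

#' Rolling-median expression against TSS distance
#'
#' Orders genes by the distance from their TSS to the nearest TSS among the
#' genes supplied and returns the rolling median of mean expression (window
#' centred, valid positions only) together with the window-centre distances.
#' Used to locate the distance below which promoter proximity inflates
#' expression.
#'
#' @param genes a [gene_table()] restricted to the genes of interest.
#' @param mean_expression named numeric vector of per-gene mean expression
#'   covering `genes$gene_id`.
#' @param window odd integer window width >= 3 (defaults to the 51 used for
#'   the 4-kb threshold analysis; 31 is used for the promoter-pair figure).
#' @return data frame: `distance` (window-centre TSS distance) and
#'   `median_expression`.
#' @export
expression_vs_tss_distance <- function(genes, mean_expression, window = 51) {
  stopifnot(inherits(genes, "gene_table"))
  if (window < 3 || window %% 2 != 1) stop("window must be odd and >= 3")
  if (nrow(genes) < window) stop("fewer genes than window width")
  nt <- .nearest_tss(genes, genes)
  expr <- mean_expression[genes$gene_id]
  ord <- order(nt$distance)
  d <- nt$distance[ord]
  e <- expr[ord]
  n <- length(e)
  idx <- seq_len(n - window + 1)
  half <- (window - 1) / 2
  data.frame(
    distance = d[idx + half],
    median_expression = vapply(idx, function(i) {
      median(e[i:(i + window - 1)])
    }, numeric(1)))
}
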