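.cis_biotypes <- c(
  "protein_coding", "lncRNA", "pseudogene", "processed_pseudogene",
  "transcribed_processed_pseudogene", "transcribed_unitary_pseudogene",
  "unitary_pseudogene", "unprocessed_pseudogene",
  "transcribed_unprocessed_pseudogene")

#' Eligibility filter for cis-interaction analyses
#'
#' Keeps genes with at least `min_reads` allele-informative reads in at
#' least `min_cells` cells, that are non-imprinted, autosomal and of an
#' allowed biotype.
#'
#' @param acs an [allelic_count_set()].
#' @param genes a [gene_table()].
#' @param min_reads,min_cells detection thresholds (default: at least 3 reads
#'   in 20 or more cells).
#' @param biotypes allowed biotypes.
#' @return Character vector of eligible gene ids.
#' @export
cis_eligible_genes <- function(acs, genes, min_reads = 3, min_cells = 20,
                               biotypes = .cis_biotypes) {
  allelic <- acs$cast_reads + acs$c57_reads
  enough <- rowSums(allelic >= min_reads) >= min_cells
  ok <- genes$gene_id %in% rownames(acs$totals)[enough] &
    !genes$imprinted & !genes$chrX & genes$biotype %in% biotypes
  genes$gene_id[ok]
}

#' Population-level allelic imbalance per gene
#'
#' Aggregates allele-informative reads over all cells and returns
#' `cast / (cast + c57) - 0.5` per gene.
#'
#' @param acs an [allelic_count_set()].
#' @return Named numeric vector of allelic-imbalance scores.
#' @export
gene_allelic_imbalance <- function(acs) {
  allelic_imbalance(rowSums(acs$cast_reads), rowSums(acs$c57_reads))
}

#' Enumerate candidate lncRNA-mRNA pairs within a genomic window
#'
#' All (lncRNA, mRNA) pairs on the same chromosome whose TSSs are within
#' `window` base pairs (default 500 kb).
#'
#' @param genes a [gene_table()].
#' @param lnc_ids,mrna_ids eligible gene ids of each class (see
#'   [cis_eligible_genes()]).
#' @param window maximum TSS distance in bp.
#' @return data frame: `lnc_id`, `mrna_id`, `distance`.
#' @export
enumerate_pairs <- function(genes, lnc_ids, mrna_ids, window = 5e5) {
  gl <- genes[match(lnc_ids, genes$gene_id), , drop = FALSE]
  gm <- genes[match(mrna_ids, genes$gene_id), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(gl))) {
    hit <- gm$chrom == gl$chrom[i] & abs(gm$tss - gl$tss[i]) <= window
    if (!any(hit)) next
    out[[length(out) + 1]] <- data.frame(
      lnc_id = gl$gene_id[i], mrna_id = gm$gene_id[hit],
      distance = abs(gm$tss[hit] - gl$tss[i]), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(lnc_id = character(), mrna_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Allelic score of a gene pair
#'
#' `score = ai_lnc + ai_mrna - |ai_lnc - ai_mrna|`: large and positive only
#' when both genes are imbalanced toward the CAST allele together; the
#' absolute-difference term penalises discordant skews.
#'
#' @param ai_lnc,ai_mrna allelic-imbalance scores (vectorised).
#' @return Numeric score(s).
#' @examples
#' allelic_score(0.3, 0.2)   # 0.4
#' allelic_score(0.3, -0.3)  # -0.6
#' @export
allelic_score <- function(ai_lnc, ai_mrna) {
  ai_lnc + ai_mrna - abs(ai_lnc - ai_mrna)
}

# sample random lncRNA placements: positions of eligible mRNA genes with at
# least `min_neighbours` other eligible genes within the window; drawn once,
# shared by all lncRNAs
.random_locations <- function(genes, mrna_ids, eligible_ids, window,
                              n_locations, min_neighbours = 2) {
  gm <- genes[match(mrna_ids, genes$gene_id), , drop = FALSE]
  ge <- genes[match(eligible_ids, genes$gene_id), , drop = FALSE]
  n_near <- vapply(seq_len(nrow(gm)), function(i) {
    sum(ge$chrom == gm$chrom[i] & abs(ge$tss - gm$tss[i]) <= window &
          ge$gene_id != gm$gene_id[i])
  }, numeric(1))
  ok <- which(n_near >= min_neighbours)
  if (!length(ok)) stop("no eligible random locations")
  idx <- ok[sample.int(length(ok), n_locations, replace = TRUE)]
  gm[idx, , drop = FALSE]
}

#' Gene-relocation permutation test of allelic scores
#'
#' Each lncRNA is moved, in silico, to randomly selected mRNA gene positions
#' (the same locations for all lncRNAs, each required to have at least two
#' other eligible genes within the window); its allelic imbalance is
#' re-paired with every eligible mRNA within the window at each location.
#' For each real pair, the p-value is the fraction of that lncRNA's random
#' pairs whose allelic score is greater than or equal to the real score.
#'
#' @param pairs data frame from [enumerate_pairs()].
#' @param gene_ai named allelic-imbalance vector ([gene_allelic_imbalance()]).
#' @param genes a [gene_table()].
#' @param mrna_ids eligible mRNA ids (random placement positions and
#'   re-pairing partners).
#' @param window TSS window in bp.
#' @param n_locations random placements (default 1,000).
#' @param seed integer seed.
#' @param alpha significance level on the permutation p (default 0.05).
#' @return `pairs` with `ai_lnc`, `ai_mrna`, `score`, `n_random`, `p_min`
#'   (smallest attainable p, `1 / n_random`), `p` and `significant`.
#'   lncRNAs with zero random pairs are dropped with a warning.
#' @export
score_permutation <- function(pairs, gene_ai, genes, mrna_ids, window = 5e5,
                              n_locations = 1000, seed = NULL, alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  pairs$ai_lnc <- unname(gene_ai[pairs$lnc_id])
  pairs$ai_mrna <- unname(gene_ai[pairs$mrna_id])
  pairs$score <- allelic_score(pairs$ai_lnc, pairs$ai_mrna)
  eligible_ids <- union(unique(pairs$lnc_id), mrna_ids)
  loc <- .random_locations(genes, mrna_ids, eligible_ids, window,
                           n_locations)
  gm <- genes[match(mrna_ids, genes$gene_id), , drop = FALSE]
  # AI values of eligible mRNAs within the window of each random location
  partner_ai <- lapply(seq_len(nrow(loc)), function(i) {
    hit <- gm$chrom == loc$chrom[i] & abs(gm$tss - loc$tss[i]) <= window &
      gm$gene_id != loc$gene_id[i]
    unname(gene_ai[gm$gene_id[hit]])
  })
  partner_ai <- unlist(partner_ai)
  lncs <- unique(pairs$lnc_id)
  p <- rep(NA_real_, nrow(pairs))
  n_random <- rep(0L, nrow(pairs))
  for (l in lncs) {
    rnd <- allelic_score(gene_ai[[l]], partner_ai)
    rows <- which(pairs$lnc_id == l)
    n_random[rows] <- length(rnd)
    if (!length(rnd)) next
    for (r in rows) p[r] <- mean(rnd >= pairs$score[r])
  }
  empty <- n_random == 0
  if (any(empty)) {
    warning(length(unique(pairs$lnc_id[empty])),
            " lncRNA(s) skipped: no random pairs")
    pairs <- pairs[!empty, , drop = FALSE]
    p <- p[!empty]; n_random <- n_random[!empty]
  }
  pairs$n_random <- n_random
  pairs$p_min <- 1 / n_random
  pairs$p <- p
  pairs$significant <- p < alpha
  pairs
}

# cells where a gene has >= threshold allele-informative reads on one allele
.detection_matrix <- function(acs, allele = c("cast", "c57"), threshold = 3) {
  allele <- match.arg(allele)
  m <- if (allele == "cast") acs$cast_reads else acs$c57_reads
  m >= threshold
}

# two-sided Fisher p for detection co-occurrence; degenerate margins -> p = 1
.fisher_pair <- function(det_l, det_m) {
  if (all(det_l) || !any(det_l) || all(det_m) || !any(det_m)) {
    return(list(p = 1, degenerate = TRUE))
  }
  tab <- table(factor(det_l, c(FALSE, TRUE)), factor(det_m, c(FALSE, TRUE)))
  list(p = fisher.test(tab)$p.value, degenerate = FALSE)
}

#' Per-allele detection coordination via Fisher's exact test
#'
#' For one allele, builds the per-cell detection indicator (allele-assigned
#' read count at or above `threshold`) for each gene of a pair and tests
#' independence of the 2x2 detection table with a two-sided Fisher's exact
#' test; p-values are Benjamini-Hochberg-adjusted across pairs. Pairs where
#' either gene is never (or always) detected are degenerate with p = 1.
#'
#' @param acs an [allelic_count_set()].
#' @param pairs data frame with `lnc_id`, `mrna_id`.
#' @param allele `"cast"` or `"c57"`.
#' @param threshold detection threshold in allele-assigned reads.
#' @return `pairs` with `p_real`, `p_real_adj`, `degenerate`.
#' @export
fisher_coordination <- function(acs, pairs, allele = c("cast", "c57"),
                                threshold = 3) {
  allele <- match.arg(allele)
  det <- .detection_matrix(acs, allele, threshold)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    .fisher_pair(det[pairs$lnc_id[i], ], det[pairs$mrna_id[i], ])
  })
  pairs$p_real <- vapply(res, `[[`, numeric(1), "p")
  pairs$degenerate <- vapply(res, `[[`, logical(1), "degenerate")
  pairs$p_real_adj <- p.adjust(pairs$p_real, method = "BH")
  pairs$allele <- allele
  pairs
}

#' Permutation background for the Fisher coordination test
#'
#' Moves each lncRNA to random mRNA gene locations (shared across lncRNAs)
#' and applies the same Fisher detection test to every random pair; the
#' random p-values are BH-adjusted per allele and returned per lncRNA.
#'
#' @inheritParams fisher_coordination
#' @param genes a [gene_table()].
#' @param mrna_ids eligible mRNA ids.
#' @param window TSS window in bp.
#' @param n_locations random placements (default 1,000).
#' @param seed integer seed.
#' @return Named list: per lncRNA, the vector of BH-adjusted random
#'   p-values.
#' @export
fisher_permutation_background <- function(acs, genes, pairs, mrna_ids,
                                          allele = c("cast", "c57"),
                                          threshold = 3, window = 5e5,
                                          n_locations = 1000, seed = NULL) {
  allele <- match.arg(allele)
  if (!is.null(seed)) set.seed(seed)
  det <- .detection_matrix(acs, allele, threshold)
  lncs <- unique(pairs$lnc_id)
  eligible_ids <- union(lncs, mrna_ids)
  loc <- .random_locations(genes, mrna_ids, eligible_ids, window,
                           n_locations)
  gm <- genes[match(mrna_ids, genes$gene_id), , drop = FALSE]
  partners <- lapply(seq_len(nrow(loc)), function(i) {
    gm$gene_id[gm$chrom == loc$chrom[i] &
                 abs(gm$tss - loc$tss[i]) <= window &
                 gm$gene_id != loc$gene_id[i]]
  })
  partners <- unlist(partners)
  p_rand <- lapply(lncs, function(l) {
    vapply(partners, function(m) .fisher_pair(det[l, ], det[m, ])$p,
           numeric(1), USE.NAMES = FALSE)
  })
  names(p_rand) <- lncs
  # BH within each lncRNA's placement set
  lapply(p_rand, p.adjust, method = "BH")
}

#' Significance call for coordinated allelic expression
#'
#' A pair is significant on an allele when its BH-adjusted Fisher p-value is
#' below `alpha_real` (default 0.01) and the fraction of the lncRNA's
#' adjusted random p-values below the real one is under
#' `background_fraction` (default 1%).
#'
#' @param pairs output of [fisher_coordination()].
#' @param background output of [fisher_permutation_background()] for the
#'   same allele.
#' @param alpha_real significance level on the adjusted real p.
#' @param background_fraction maximum tolerated fraction of random p-values
#'   below the real one.
#' @return `pairs` with `background_frac` and `significant`.
#' @export
coordination_significance <- function(pairs, background, alpha_real = 0.01,
                                      background_fraction = 0.01) {
  pairs$background_frac <- vapply(seq_len(nrow(pairs)), function(i) {
    rnd <- background[[pairs$lnc_id[i]]]
    if (is.null(rnd) || !length(rnd)) return(NA_real_)
    mean(rnd < pairs$p_real_adj[i])
  }, numeric(1))
  pairs$significant <- pairs$p_real_adj < alpha_real &
    pairs$background_frac < background_fraction
  pairs
}

#' Rank significant pairs by coordinated allelic imbalance
#'
#' Aligns each pair to the lncRNA's dominant allele (flipping both signs
#' when the lncRNA is C57-skewed) and recomputes the allelic score: the
#' ranking value is positive when both genes skew toward the same parental
#' allele and negative when they skew toward opposite alleles, with
#' magnitude given by the aligned score.
#'
#' @param pairs data frame with `ai_lnc` and `ai_mrna` columns.
#' @return `pairs` with a `ranking_value` column, ordered decreasingly.
#' @export
rank_interactions <- function(pairs) {
  flip <- ifelse(pairs$ai_lnc < 0, -1, 1)
  pairs$ranking_value <- allelic_score(flip * pairs$ai_lnc,
                                       flip * pairs$ai_mrna)
  pairs[order(-pairs$ranking_value), , drop = FALSE]
}
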