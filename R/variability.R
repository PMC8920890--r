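#' Squared coefficient of variation
#'
#' `CV^2 = var(x) / mean(x)^2` with the sample (n-1) variance; the standard
#' scale-free measure of cell-to-cell expression variability. Undefined
#' (`NA`) at zero mean.
#'
#' @param values numeric expression vector, length >= 2.
#' @return CV-squared, or `NA` when the mean is zero.
#' @examples
#' cv2(c(0, 0, 10, 10))  # 4/3
#' @export
cv2 <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  var(values) / m^2
}

#' Select expression-matched control genes
#'
#' Returns the `k` candidates whose mean expression is closest to the
#' target's (smallest absolute difference); exact ties resolve to the
#' lexicographically lower gene id. The same candidate may be matched to
#' multiple targets (sampling with replacement across targets).
#'
#' @param target_mean numeric scalar.
#' @param candidate_means named numeric vector (gene id -> mean).
#' @param k number of matches.
#' @return Character vector of `k` gene ids.
#' @export
match_expression <- function(target_mean, candidate_means, k = 10) {
  if (length(candidate_means) == 0) stop("empty candidate pool")
  k <- min(k, length(candidate_means))
  d <- abs(candidate_means - target_mean)
  ord <- order(d, names(candidate_means))
  names(candidate_means)[ord][seq_len(k)]
}

# 50 nearest candidates with higher mean + 50 with lower mean; NULL with a
# warning when either side is short
.match_balanced <- function(target_mean, candidate_means, k_each = 50) {
  hi <- candidate_means[candidate_means >= target_mean]
  lo <- candidate_means[candidate_means < target_mean]
  if (length(hi) < k_each || length(lo) < k_each) return(NULL)
  c(match_expression(target_mean, hi, k_each),
    match_expression(target_mean, lo, k_each))
}

#' Permutation test of lncRNA CV-squared against matched mRNAs
#'
#' Each permutation samples one expression-matched mRNA per lncRNA and
#' records the median CV-squared of the sampled set. The p-value is the
#' frequency of permutations whose sampled median strictly exceeds the
#' observed lncRNA median.
#'
#' @param lnc_cv2 named numeric vector of lncRNA CV-squared values.
#' @param matched_sets named list (per lncRNA) of matched mRNA ids.
#' @param mrna_cv2 named numeric vector covering all matched mRNA ids.
#' @param n_perm number of permutations (default 10,000).
#' @param seed integer seed.
#' @return list: `p_value`, `observed_median`, `null_medians` (length
#'   `n_perm`) and `degenerate` (TRUE when all values coincide, where the
#'   strict inequality forces p = 0).
#' @export
cv2_permutation_test <- function(lnc_cv2, matched_sets, mrna_cv2,
                                 n_perm = 10000, seed = NULL) {
  stopifnot(all(names(lnc_cv2) %in% names(matched_sets)))
  if (!is.null(seed)) set.seed(seed)
  matched_sets <- matched_sets[names(lnc_cv2)]
  obs <- median(lnc_cv2)
  sets <- lapply(matched_sets, function(ids) unname(mrna_cv2[ids]))
  null_medians <- vapply(seq_len(n_perm), function(i) {
    median(vapply(sets, function(v) v[sample.int(length(v), 1)], numeric(1)))
  }, numeric(1))
  degenerate <- length(unique(c(obs, null_medians))) == 1
  list(p_value = mean(null_medians > obs), observed_median = obs,
       null_medians = null_medians, degenerate = degenerate)
}

#' Rank a lncRNA's CV-squared against matched mRNAs
#'
#' Fraction of a balanced matched set (by construction 50 mRNAs of higher
#' and 50 of lower mean expression) whose CV-squared lies strictly below the
#' lncRNA's.
#'
#' @param lnc_cv2 scalar CV-squared of the lncRNA.
#' @param matched_cv2 CV-squared values of the matched mRNAs.
#' @return Rank fraction in `[0, 1]`.
#' @export
rank_cv2 <- function(lnc_cv2, matched_cv2) {
  mean(matched_cv2 < lnc_cv2)
}

#' CV-squared rank fractions for a set of lncRNAs
#'
#' For each lncRNA, selects 100 expression-matched mRNAs (50 of higher and
#' 50 of lower mean expression) and computes the fraction with CV-squared
#' below the lncRNA's. lncRNAs without 50 candidates on each side are
#' skipped with a warning.
#'
#' @param lnc_means,lnc_cv2 named vectors over lncRNAs.
#' @param mrna_means,mrna_cv2 named vectors over candidate mRNAs.
#' @param k_each matched genes per side (default 50).
#' @return Named numeric vector of rank fractions for the rankable lncRNAs.
#' @export
cv2_rank_fractions <- function(lnc_means, lnc_cv2, mrna_means, mrna_cv2,
                               k_each = 50) {
  out <- numeric(0)
  skipped <- character(0)
  for (g in names(lnc_means)) {
    ids <- .match_balanced(lnc_means[[g]], mrna_means, k_each)
    if (is.null(ids)) {
      skipped <- c(skipped, g)
      next
    }
    out[g] <- rank_cv2(lnc_cv2[[g]], mrna_cv2[ids])
  }
  if (length(skipped)) {
    warning(length(skipped), " lncRNA(s) skipped: fewer than ", k_each,
            " matched candidates on one side")
  }
  out
}

#' Top-ranked variable lncRNAs per allele
#'
#' The `n_top` lncRNAs with the highest CV-squared rank fraction; ties at
#' the cutoff resolve to the lexicographically lower gene id. When fewer
#' than `n_top` are eligible, all are returned with a warning.
#'
#' @param rank_fractions named numeric vector (from [cv2_rank_fractions()]).
#' @param n_top number to select (default 50).
#' @return Character vector of lncRNA ids.
#' @export
select_top_variable_lncRNAs <- function(rank_fractions, n_top = 50) {
  if (length(rank_fractions) < n_top) {
    warning("only ", length(rank_fractions), " eligible lncRNAs (< ", n_top,
            "); returning all")
    n_top <- length(rank_fractions)
  }
  ord <- order(-rank_fractions, names(rank_fractions))
  names(rank_fractions)[ord][seq_len(n_top)]
}

#' Detection power of the CV-squared permutation test by lncRNA count
#'
#' Repeatedly subsamples lncRNAs (with their matched sets), reruns the
#' permutation test, and per repetition records the fraction of
#' permutations in which the lncRNA median CV-squared exceeded the sampled
#' mRNA median. The detection frequency at the 50% (and 95%) criterion is
#' the fraction of repetitions where that fraction reached 0.5 (0.95).
#'
#' @inheritParams cv2_permutation_test
#' @param sizes integer vector of subsample sizes (default range 10..200).
#' @param reps repetitions per size (default 100).
#' @param n_perm permutations per test.
#' @return data frame: `size`, `detect50`, `detect95`.
#' @export
subsample_power <- function(lnc_cv2, matched_sets, mrna_cv2,
                            sizes = seq(10, 200, by = 10), reps = 100,
                            n_perm = 1000, seed = NULL) {
  stopifnot(max(sizes) <= length(lnc_cv2))
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(sizes, function(sz) {
    frac <- vapply(seq_len(reps), function(r) {
      pick <- sample(names(lnc_cv2), sz)
      pt <- cv2_permutation_test(lnc_cv2[pick], matched_sets[pick], mrna_cv2,
                                 n_perm = n_perm)
      # fraction of permutations with lncRNA median above the sampled median
      mean(pt$null_medians < pt$observed_median)
    }, numeric(1))
    data.frame(size = sz, detect50 = mean(frac >= 0.5),
               detect95 = mean(frac >= 0.95))
  })
  do.call(rbind, res)
}

#' Permutation test of burst kinetics for matched lncRNA/mRNA sets
#'
#' One-sided permutation tests mirroring the CV-squared machinery on kinetic
#' parameters: each permutation samples one expression-matched mRNA per
#' lncRNA; `p_frequency` is the frequency of permutations where the lncRNA
#' median burst frequency exceeded the sampled mRNA median (small when
#' lncRNAs burst less often), and `p_size` the frequency where the lncRNA
#' median burst size fell below the sampled median (small when lncRNA bursts
#' are larger).
#'
#' @param lnc_freq,lnc_size named vectors of lncRNA burst parameters.
#' @param matched_sets named list (per lncRNA) of matched mRNA ids.
#' @param mrna_freq,mrna_size named vectors over candidate mRNAs.
#' @param n_perm permutations (default 10,000).
#' @param seed integer seed.
#' @return list: `p_frequency`, `p_size`, observed medians and the null
#'   median distributions.
#' @export
kinetics_permutation_matched <- function(lnc_freq, lnc_size, matched_sets,
                                         mrna_freq, mrna_size,
                                         n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matched_sets <- matched_sets[names(lnc_freq)]
  obs_f <- median(lnc_freq)
  obs_s <- median(lnc_size)
  nulls <- vapply(seq_len(n_perm), function(i) {
    pick <- vapply(matched_sets,
                   function(ids) ids[sample.int(length(ids), 1)],
                   character(1))
    c(median(mrna_freq[pick]), median(mrna_size[pick]))
  }, numeric(2))
  list(p_frequency = mean(obs_f > nulls[1, ]),
       p_size = mean(obs_s < nulls[2, ]),
       observed_freq_median = obs_f, observed_size_median = obs_s,
       null_freq_medians = nulls[1, ], null_size_medians = nulls[2, ])
}

#' Eligibility filter for variability analyses
#'
#' Restricts to non-imprinted autosomal genes classified as separated
#' transcriptional units.
#'
#' @param genes a [gene_table()].
#' @param locus_class output of [classify_loci()].
#' @return Character vector of eligible gene ids.
#' @export
variability_eligible <- function(genes, locus_class) {
  ok <- !genes$imprinted & !genes$chrX &
    genes$gene_id %in% locus_class$gene_id[locus_class$separated_unit]
  genes$gene_id[ok]
}
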