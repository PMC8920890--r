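test_that("cv2 follows its estimator convention and scale invariance", {
  expect_equal(cv2(c(4, 4, 4, 4)), 0)
  # var = 100/3 (n-1), mean = 5
  expect_equal(cv2(c(0, 0, 10, 10)), (100 / 3) / 25)
  set.seed(1)
  x <- rpois(50, 4) + 1
  expect_equal(cv2(x * 7.3), cv2(x))
  expect_true(is.na(cv2(c(0, 0, 0))))
  expect_error(cv2(5), "two values")
})

test_that("expression matching picks nearest means with a stable tie rule", {
  cand <- c(a = 1.0, b = 1.9, c = 2.05, d = 3.0)
  expect_setequal(match_expression(2.0, cand, 2), c("c", "b"))
  expect_equal(match_expression(2.0, cand, 4), c("c", "b", "a", "d"))
  # exact tie in |diff| resolves to the lower gene id
  tied <- c(z = 1.5, a = 2.5)
  expect_equal(match_expression(2.0, tied, 1), "a")
  expect_error(match_expression(1, numeric(0), 3), "empty")
})

test_that("permutation p-value hits its extremes and degenerate case", {
  lnc <- c(l1 = 5, l2 = 6)
  mrna_lo <- c(m1 = 1, m2 = 2)
  mrna_hi <- c(m1 = 50, m2 = 60)
  sets <- list(l1 = c("m1", "m2"), l2 = c("m1", "m2"))
  expect_equal(cv2_permutation_test(lnc, sets, mrna_lo, 200, seed = 1)$p_value,
               0)
  expect_equal(cv2_permutation_test(lnc, sets, mrna_hi, 200, seed = 1)$p_value,
               1)
  # all values equal: strict ">" forces p = 0 and the run is flagged
  same <- c(m1 = 5.5, m2 = 5.5)
  res <- cv2_permutation_test(c(l1 = 5.5, l2 = 5.5), sets, same, 100,
                              seed = 1)
  expect_equal(res$p_value, 0)
  expect_true(res$degenerate)
})

test_that("null permutation p-values are uniform on average", {
  # lncRNA values drawn from the same distribution as their matches
  set.seed(21)
  ps <- replicate(50, {
    pool <- rlnorm(80, 0, 0.5)
    names(pool) <- sprintf("m%02d", 1:80)
    lnc <- setNames(sample(pool, 15), sprintf("l%02d", 1:15))
    sets <- lapply(setNames(1:15, names(lnc)), function(i) {
      sample(names(pool), 10)
    })
    cv2_permutation_test(lnc, sets, pool, n_perm = 200)$p_value
  })
  expect_lt(abs(mean(ps) - 0.5), 0.06)
})

test_that("rank fractions behave at extremes and under monotone maps", {
  expect_equal(rank_cv2(10, 1:100 / 100), 1)
  expect_equal(rank_cv2(0, 1:100 / 100), 0)
  v <- (1:101)[-51]
  expect_equal(rank_cv2(51, v), 0.5)
  # invariance under a monotone transform applied to all values
  set.seed(2)
  m <- runif(100)
  x <- 0.7
  expect_equal(rank_cv2(x, m), rank_cv2(exp(3 * x), exp(3 * m)))
})

test_that("balanced matching and top selection respect their rules", {
  set.seed(5)
  mrna_means <- setNames(seq(0.1, 20, length.out = 300),
                         sprintf("m%03d", 1:300))
  mrna_cv2 <- setNames(rlnorm(300), names(mrna_means))
  lnc_means <- c(l1 = 10, l2 = 10.5)
  lnc_cv2 <- c(l1 = 100, l2 = 1e-6)
  rf <- cv2_rank_fractions(lnc_means, lnc_cv2, mrna_means, mrna_cv2)
  expect_equal(unname(rf["l1"]), 1)
  expect_equal(unname(rf["l2"]), 0)
  # lncRNA too close to the pool edge is skipped with a warning
  expect_warning(
    cv2_rank_fractions(c(edge = 20), c(edge = 1), mrna_means, mrna_cv2),
    "skipped")
  ranks <- setNames(c(0.9, 0.8, 0.8, 0.1), c("b", "a", "c", "d"))
  expect_equal(select_top_variable_lncRNAs(ranks, 3), c("b", "a", "c"))
  expect_equal(select_top_variable_lncRNAs(ranks, 2), c("b", "a"))
  expect_warning(out <- select_top_variable_lncRNAs(ranks, 10), "eligible")
  expect_length(out, 4)
})

test_that("kinetics permutation is one-sided in the documented directions", {
  lnc_f <- c(l1 = 0.5, l2 = 0.6)
  lnc_s <- c(l1 = 20, l2 = 25)
  mf <- c(m1 = 2, m2 = 2.4, m3 = 2.2)
  ms <- c(m1 = 5, m2 = 6, m3 = 5.5)
  sets <- list(l1 = names(mf), l2 = names(mf))
  res <- kinetics_permutation_matched(lnc_f, lnc_s, sets, mf, ms,
                                      n_perm = 300, seed = 3)
  # lncRNA frequencies uniformly lower -> p_frequency = 0
  expect_equal(res$p_frequency, 0)
  # lncRNA sizes uniformly larger -> p_size = 0
  expect_equal(res$p_size, 0)
  # identical distributions -> p near 0.5 for both
  set.seed(31)
  pool_f <- rlnorm(60); names(pool_f) <- sprintf("m%02d", 1:60)
  pool_s <- rlnorm(60); names(pool_s) <- names(pool_f)
  pick <- sample(names(pool_f), 12)
  lncs <- setNames(pool_f[pick], sprintf("l%02d", 1:12))
  sizes <- setNames(pool_s[pick], names(lncs))
  sets2 <- lapply(setNames(seq_along(lncs), names(lncs)),
                  function(i) sample(names(pool_f), 10))
  res2 <- kinetics_permutation_matched(lncs, sizes, sets2, pool_f, pool_s,
                                       n_perm = 400, seed = 4)
  expect_gt(res2$p_frequency, 0.1)
  expect_lt(res2$p_frequency, 0.9)
})

test_that("subsampling power is high under strong inflation, null near 0.5", {
  set.seed(8)
  pool <- rlnorm(100, 0, 0.3)
  names(pool) <- sprintf("m%03d", 1:100)
  # strongly inflated lncRNA class
  lnc <- setNames(rlnorm(40, 2, 0.3), sprintf("l%02d", 1:40))
  sets <- lapply(setNames(seq_along(lnc), names(lnc)),
                 function(i) sample(names(pool), 10))
  pw <- subsample_power(lnc, sets, pool, sizes = c(10, 40), reps = 20,
                        n_perm = 100, seed = 9)
  expect_equal(pw$detect95[pw$size == 40], 1)
  # null class: detection frequency at the 50% criterion stays intermediate
  lnc0 <- setNames(sample(pool, 90, replace = TRUE),
                   sprintf("n%02d", 1:90))
  sets0 <- lapply(setNames(seq_along(lnc0), names(lnc0)),
                  function(i) sample(names(pool), 10))
  pw0 <- subsample_power(lnc0, sets0, pool, sizes = c(30), reps = 40,
                         n_perm = 100, seed = 10)
  expect_gt(pw0$detect50, 0.1)
  expect_lt(pw0$detect50, 0.9)
  expect_lte(pw0$detect95, 0.2)
})

test_that("eligibility filter keeps autosomal separated non-imprinted genes", {
  g <- gene_table(data.frame(
    gene_id = c("a", "b", "c", "d"), chrom = c("chr1", "chr1", "chrX",
                                               "chr1"),
    start = c(0, 100000, 200000, 300000) + 1,
    end = c(0, 100000, 200000, 300000) + 500,
    strand = "+", imprinted = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE))
  cls <- data.frame(gene_id = c("a", "b", "c", "d"),
                    separated_unit = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(variability_eligible(g, cls), "a")
})
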