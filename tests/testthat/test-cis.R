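test_that("pair enumeration respects the window and eligibility", {
  g <- gene_table(data.frame(
    gene_id = c("lnc", "m1", "m2", "m3"), chrom = "chr1",
    start = c(1.0e6, 0.6e6, 1.4e6, 1.6e6),
    end = c(1.0e6, 0.6e6, 1.4e6, 1.6e6) + 1000,
    strand = "+",
    biotype = c("lncRNA", rep("protein_coding", 3)),
    stringsAsFactors = FALSE))
  p <- enumerate_pairs(g, "lnc", c("m1", "m2", "m3"), window = 5e5)
  expect_setequal(p$mrna_id, c("m1", "m2"))
  expect_equal(nrow(enumerate_pairs(g, "lnc", c("m1", "m2", "m3"),
                                    window = 0)), 0)
  # eligibility: >= 3 allelic reads in >= 20 cells
  n_cells <- 30
  tot <- matrix(5L, 2, n_cells,
                dimnames = list(c("ok", "sparse"),
                                sprintf("c%02d", 1:n_cells)))
  cast <- matrix(0L, 2, n_cells, dimnames = dimnames(tot))
  cast["ok", 1:25] <- 3L
  cast["sparse", 1:19] <- 3L
  acs <- allelic_count_set(tot, cast, matrix(0L, 2, n_cells,
                                             dimnames = dimnames(tot)))
  gt <- gene_table(data.frame(gene_id = c("ok", "sparse"), chrom = "chr1",
                              start = c(1, 10001), end = c(1000, 11000),
                              strand = "+", stringsAsFactors = FALSE))
  expect_equal(cis_eligible_genes(acs, gt), "ok")
})

test_that("the allelic score rewards concordant imbalance", {
  expect_equal(allelic_score(0.3, 0.2), 0.4)
  expect_equal(allelic_score(0.3, -0.3), -0.6)
  for (x in c(-0.4, 0, 0.25)) expect_equal(allelic_score(x, x), 2 * x)
})

test_that("score permutation hits its extremes on constructed AI fields", {
  # one strongly coordinated lncRNA among mRNAs with null AI
  n_m <- 40
  starts <- c(1e6, 1e6 + 2e4, seq(2e6, by = 1e5, length.out = n_m - 1))
  g <- gene_table(data.frame(
    gene_id = c("lnc", sprintf("m%02d", 1:n_m)), chrom = "chr1",
    start = starts, end = starts + 500, strand = "+",
    biotype = c("lncRNA", rep("protein_coding", n_m)),
    stringsAsFactors = FALSE))
  mrna <- sprintf("m%02d", 1:n_m)
  ai <- c(lnc = 0.45, setNames(rep(0, n_m), mrna))
  ai["m01"] <- 0.45
  pairs <- enumerate_pairs(g, "lnc", mrna, window = 5e5)
  res <- score_permutation(pairs, ai, g, mrna, window = 5e5,
                           n_locations = 100, seed = 1)
  # real score 0.9 exceeds every random score (max 0.9 - |0.45| = 0)
  expect_equal(res$p[res$mrna_id == "m01"], 0)
  expect_true(res$significant[res$mrna_id == "m01"])
  # a pair whose score ties every random score has p = 1 by the ">=" rule
  ai2 <- c(lnc = 0, setNames(rep(0, n_m), mrna))
  res2 <- score_permutation(pairs, ai2, g, mrna, window = 5e5,
                            n_locations = 50, seed = 2)
  expect_equal(res2$p, rep(1, nrow(res2)))
  expect_equal(res2$p_min, 1 / res2$n_random)
})

test_that("Fisher coordination matches exact enumeration and symmetry", {
  # against the brute-force hypergeometric oracle on all margins <= 30
  set.seed(13)
  for (i in 1:40) {
    tab <- matrix(rpois(4, sample(3:8, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher.test(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-9, label = paste(tab, collapse = ","))
    # row/column swap invariance
    expect_equal(fisher.test(tab)$p.value, fisher.test(t(tab))$p.value)
  }
  expect_equal(fisher_oracle(matrix(c(10, 10, 10, 10), 2)), 1)
  # package route on detection matrices agrees with fisher.test
  n <- 40
  tot <- matrix(10L, 2, n, dimnames = list(c("lnc1", "mrna1"),
                                           sprintf("c%02d", 1:n)))
  cast <- matrix(0L, 2, n, dimnames = dimnames(tot))
  cast["lnc1", 1:20] <- 5L
  cast["mrna1", c(1:15, 21:25)] <- 5L
  acs <- allelic_count_set(tot, cast, matrix(0L, 2, n,
                                             dimnames = dimnames(tot)))
  pairs <- data.frame(lnc_id = "lnc1", mrna_id = "mrna1",
                      stringsAsFactors = FALSE)
  out <- fisher_coordination(acs, pairs, "cast")
  man <- fisher.test(table(cast["lnc1", ] >= 3, cast["mrna1", ] >= 3))
  expect_equal(out$p_real, man$p.value)
  expect_false(out$degenerate)
  # degenerate margin: gene never detected on that allele
  out57 <- fisher_coordination(acs, pairs, "c57")
  expect_equal(out57$p_real, 1)
  expect_true(out57$degenerate)
})

test_that("coordination significance needs both the p and background rule", {
  pairs <- data.frame(lnc_id = c("a", "a", "b"), mrna_id = c("x", "y", "z"),
                      p_real_adj = c(0.005, 0.005, 0.02),
                      stringsAsFactors = FALSE)
  background <- list(a = c(rep(0.5, 995), rep(1e-4, 5)),
                     b = rep(0.5, 1000))
  bg_lo <- list(a = rep(0.5, 1000), b = rep(0.5, 1000))
  out <- coordination_significance(pairs, bg_lo)
  expect_equal(out$significant, c(TRUE, TRUE, FALSE))  # p rule kills "b"
  out2 <- coordination_significance(pairs, background)
  # 0.5% of background below 0.005 -> still significant; threshold is 1%
  expect_true(all(out2$significant[1:2]))
  bg_many <- list(a = c(rep(1e-4, 50), rep(0.5, 950)), b = rep(0.5, 1000))
  out3 <- coordination_significance(pairs, bg_many)
  expect_false(any(out3$significant[1:2]))  # 5% of background below
})

test_that("interaction ranking is allele-aligned", {
  pairs <- data.frame(lnc_id = c("p", "q", "r"), mrna_id = c("x", "y", "z"),
                      ai_lnc = c(0.3, 0.3, -0.3),
                      ai_mrna = c(0.25, -0.25, -0.25),
                      stringsAsFactors = FALSE)
  out <- rank_interactions(pairs)
  val <- setNames(out$ranking_value, out$lnc_id)
  expect_gt(val["p"], 0)
  expect_lt(val["q"], 0)
  # same-allele C57 coordination ranks positive after alignment
  expect_gt(val["r"], 0)
  expect_equal(unname(val["p"]), unname(val["r"]))
})
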