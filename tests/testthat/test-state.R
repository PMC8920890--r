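test_that("log-normalisation matches its formula and is invertible", {
  counts <- matrix(c(1, 9999, 0, 5000, 5000, 0), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  norm <- log_normalize(counts)
  expect_equal(norm["g1", "c1"], log(2))   # 1/10000 * 10000 -> ln(1 + 1)
  expect_equal(norm["g3", "c1"], 0)
  # depth invariance: doubling all counts in a cell changes nothing
  norm2 <- log_normalize(counts * 2)
  expect_equal(norm2, norm)
  # exact inversion given the totals
  back <- (exp(norm) - 1) / 10000 * rep(colSums(counts), each = 3)
  expect_equal(back, counts)
  expect_error(log_normalize(cbind(counts, c0 = c(0, 0, 0))), "zero-total")
})

test_that("standardised variance ranks a planted variable gene first", {
  set.seed(41)
  n_cells <- 150
  mu <- runif(100, 2, 20)
  counts <- t(sapply(mu, function(m) rpois(n_cells, m)))
  rownames(counts) <- sprintf("g%03d", 1:100)
  # plant one gene with the same mean but 10x inflated variance
  m0 <- 10
  counts["g001", ] <- rpois(n_cells, rgamma(n_cells, shape = 1,
                                            scale = m0))
  top <- select_variable_genes(counts, n_top = 5, min_count = 1)
  expect_equal(top[1], "g001")
  all_ranked <- select_variable_genes(counts, n_top = 100, min_count = 1)
  expect_length(all_ranked, 100)
  expect_warning(select_variable_genes(counts, n_top = 500, min_count = 1),
                 "universe smaller")
})

test_that("the principal curve preserves order on linear data", {
  set.seed(42)
  n <- 60
  t_true <- seq(0, 1, length.out = n)
  # 5 genes varying linearly along a latent coordinate + small noise
  expr <- rbind(
    outer(c(3, -2, 1.5, 2.5, -1), t_true) + rnorm(5 * n, 0, 0.01))
  rownames(expr) <- paste0("g", 1:5)
  colnames(expr) <- paste0("c", 1:n)
  lam <- fit_trajectory(expr, rownames(expr), n_pcs = 2)
  r <- cor(lam, t_true, method = "spearman")
  expect_gt(abs(r), 0.999)
  # duplicate points land on identical coordinates
  expr2 <- cbind(expr, dup = expr[, 10])
  lam2 <- fit_trajectory(expr2, rownames(expr2), n_pcs = 2)
  expect_equal(unname(lam2["dup"]), unname(lam2[10]), tolerance = 1e-8)
})

test_that("trajectory recovers circular phase structure", {
  cc <- generate_cell_cycle_dataset(n_cells = 250, seed = 17)
  norm <- log_normalize(cc$counts)
  lam <- fit_trajectory(norm, unlist(cc$marker_sets))
  expect_gt(circular_rank_cor(lam, cc$truth$theta), 0.8)
})

test_that("phase assignment follows the dominant smoothed marker", {
  cfg <- cell_cycle_config(base_mean = 0, peak_mean = 25)
  cc <- generate_cell_cycle_dataset(n_cells = 250, config = cfg, seed = 18)
  norm <- log_normalize(cc$counts + 0L)
  # order cells by the true circular coordinate to isolate the labelling
  lam <- setNames(cc$truth$theta, cc$truth$cell_id)
  ph <- assign_phase(lam, norm, cc$marker_sets, window = 15)
  acc <- mean(ph$phase == cc$truth$phase)
  expect_gt(acc, 0.9)
  expect_error(assign_phase(lam, norm, list(G0 = "absent_gene")),
               "absent_gene")
  expect_error(assign_phase(lam[1:10], norm[, 1:10], cc$marker_sets,
                            window = 15), "window larger")
  # constant markers degenerate to a single phase with a warning
  flat <- norm
  flat[unlist(cc$marker_sets), ] <- 1
  expect_warning(phf <- assign_phase(lam, flat, cc$marker_sets, 15),
                 "degenerate")
  expect_equal(length(unique(phf$phase)), 1)
})

test_that("phase ANOVA detects planted induction and is calibrated", {
  set.seed(51)
  n_per <- 60
  phases <- rep(c("G0", "G1", "G1/S", "G2/M"), each = n_per)
  n_null <- 300
  counts <- t(sapply(seq_len(n_null), function(i) rpois(4 * n_per, 5)))
  rownames(counts) <- sprintf("null%03d", 1:n_null)
  planted <- t(sapply(1:10, function(i) {
    mu <- rep(5, 4 * n_per)
    mu[phases == "G1/S"] <- 25
    rpois(4 * n_per, mu)
  }))
  rownames(planted) <- sprintf("plant%02d", 1:10)
  m <- rbind(counts, planted)
  colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  de <- anova_phase_de(log_normalize(m), phases)
  expect_true(all(de$significant[grepl("plant", de$gene_id)]))
  expect_equal(de$top_phase[grepl("plant", de$gene_id)], rep("G1/S", 10))
  expect_lte(mean(de$significant[grepl("null", de$gene_id)]), 0.01)
  expect_gt(min(de$fold_induction[grepl("plant", de$gene_id)]), 1.3)
  expect_error(anova_phase_de(m, rep("G1", ncol(m))), "two phases")
})

test_that("apoptosis clustering recovers a planted cell cluster", {
  set.seed(61)
  n_cells <- 150
  apo_genes <- sprintf("apo%02d", 1:40)
  bg_genes <- sprintf("bg%03d", 1:200)
  truth <- rep(1L, n_cells)
  truth[1:30] <- 2L          # 20% planted programme-high cells
  truth[31:50] <- 3L         # second shifted group
  counts <- matrix(rpois(240 * n_cells, 3), 240, n_cells,
                   dimnames = list(c(apo_genes, bg_genes),
                                   sprintf("c%03d", 1:n_cells)))
  counts[apo_genes[1:20], truth == 2] <-
    rpois(20 * sum(truth == 2), 15)
  counts[apo_genes[21:40], truth == 3] <-
    rpois(20 * sum(truth == 3), 15)
  norm <- log_normalize(counts)
  res <- apoptosis_cluster(norm, apo_genes, n_top = 30, k = 3)
  expect_gt(adjusted_rand_index(res$cluster, truth), 0.7)
  expect_true(all(res$genes %in% apo_genes))
  # k = 1 puts every cell in one cluster
  res1 <- apoptosis_cluster(norm, apo_genes, n_top = 30, k = 1)
  expect_equal(unname(unique(res1$cluster)), 1L)
})

test_that("guilt-by-association applies the sign-consistency rule", {
  set.seed(71)
  n <- 120
  target <- rpois(n, 6)
  twin <- target                             # identical to the target
  anti <- max(target) - target               # strongly anti-correlated
  indep <- rpois(n, 6)
  m <- rbind(tgt = target, twin = twin, anti = anti, indep = indep,
             pos_up = target + rpois(n, 1))
  colnames(m) <- sprintf("c%03d", 1:n)
  fc <- c(twin = -1, anti = 1, indep = -1, pos_up = 1)
  res <- guilt_by_association(m, "tgt", fc)
  get <- function(g, col) res[res$gene_id == g, col]
  expect_equal(get("twin", "rho"), 1)
  expect_true(get("twin", "retained"))
  expect_true(get("anti", "retained"))
  # positively correlated but UP on knockdown: excluded
  expect_false(get("pos_up", "retained"))
  expect_error(guilt_by_association(m[, 1:5], "tgt", fc), "fewer than")
})

test_that("independent genes are rarely retained by correlation", {
  set.seed(72)
  n <- 200
  target <- rpois(n, 5)
  m <- rbind(tgt = target,
             matrix(rpois(100 * n, 5), 100, n,
                    dimnames = list(sprintf("r%03d", 1:100), NULL)))
  colnames(m) <- sprintf("c%03d", 1:n)
  fc <- setNames(rep(-1, 100), sprintf("r%03d", 1:100))
  res <- guilt_by_association(m, "tgt", fc)
  expect_lt(mean(res$retained), 0.15)
})

test_that("cluster DE flags genes elevated in the cluster of interest", {
  set.seed(81)
  n <- 120
  cl <- rep(c(1L, 2L), c(40, 80))
  up <- c(rpois(40, 15), rpois(80, 3))
  flat <- rpois(n, 5)
  m <- rbind(up = up, flat = flat,
             matrix(rpois(50 * n, 4), 50, n,
                    dimnames = list(sprintf("n%02d", 1:50), NULL)))
  colnames(m) <- sprintf("c%03d", 1:n)
  de <- cluster_de(log_normalize(m), cl, cluster = 1)
  expect_equal(de$gene_id[1], "up")
  expect_true(de$significant[de$gene_id == "up"])
  expect_gt(de$log2_ratio[de$gene_id == "up"], 0.2)
  expect_false(de$significant[de$gene_id == "flat"])
  expect_error(cluster_de(m, rep(1L, n), 1), "proper subset")
})
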