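test_that("allelic generator honours SNP capture and conservation", {
  cfg1 <- allelic_sim_config(n_mrna = 30, n_lnc = 30, n_cells = 50,
                             snp_capture = 1.0)
  ds1 <- generate_allelic_dataset(cfg1, seed = 3)
  expect_false(any(ds1$counts$missing))
  # with full capture, reads equal the true allele-level molecule counts
  expect_identical(ds1$counts$cast_reads + ds1$counts$c57_reads,
                   ds1$counts$totals)
  cfg0 <- allelic_sim_config(n_mrna = 10, n_lnc = 10, n_cells = 30,
                             snp_capture = 0.0)
  ds0 <- generate_allelic_dataset(cfg0, seed = 3)
  expect_true(all(ds0$counts$missing[ds0$counts$totals > 0]))
  # partial capture: reads never exceed molecule counts
  cfgp <- allelic_sim_config(n_mrna = 20, n_lnc = 20, n_cells = 40,
                             snp_capture = 0.5)
  dsp <- generate_allelic_dataset(cfgp, seed = 4)
  expect_true(all(dsp$counts$cast_reads + dsp$counts$c57_reads <=
                    dsp$counts$totals))
  expect_error(allelic_sim_config(snp_capture = 1.5), "config error")
})

test_that("generator truth is complete, classed and reproducible", {
  cfg <- allelic_sim_config(n_mrna = 15, n_lnc = 10, n_cells = 20)
  ds <- generate_allelic_dataset(cfg, seed = 9)
  expect_equal(nrow(ds$truth), 2 * 25)        # one record per gene x allele
  expect_equal(sort(unique(ds$truth$gene_id)), sort(ds$genes$gene_id))
  expect_setequal(unique(ds$truth$class), c("mRNA-like", "lncRNA-like"))
  ds2 <- generate_allelic_dataset(cfg, seed = 9)
  expect_identical(ds$counts$totals, ds2$counts$totals)
  expect_identical(ds$truth, ds2$truth)
})

test_that("class multipliers shift the true kinetics 4x and 2x", {
  ds <- generate_allelic_dataset(allelic_sim_config(
    n_mrna = 200, n_lnc = 200, n_cells = 1), seed = 5)
  tr <- ds$truth[ds$truth$allele == "cast", ]
  med <- function(cls, f) median(f[tr$class == cls])
  kon_ratio <- med("mRNA-like", tr$k_on) / med("lncRNA-like", tr$k_on)
  size_ratio <- med("mRNA-like", tr$k_syn / tr$k_off) /
    med("lncRNA-like", tr$k_syn / tr$k_off)
  expect_lt(abs(kon_ratio / 4 - 1), 0.25)
  expect_lt(abs(size_ratio / 2 - 1), 0.25)
})

test_that("cis-pair generator couples alleles at the requested strength", {
  # rho = 1: the latent state is shared for every cell
  p1 <- generate_cis_pairs(n_pairs = 5, rho = 1, n_cells = 100, seed = 2)
  expect_true(all(p1$latent$cast))
  p0 <- generate_cis_pairs(n_pairs = 5, rho = 0, n_cells = 100, seed = 2)
  expect_false(any(p0$latent$c57))
  expect_error(generate_cis_pairs(rho = 1.2), "rho")
  # rho = 0.6: positive detection odds ratio on an allele for most pairs
  pc <- generate_cis_pairs(n_pairs = 40, rho = 0.6, n_cells = 400,
                           seed = 6)
  det <- pc$counts$cast_reads >= 3
  or_pos <- vapply(seq_len(40), function(i) {
    l <- det[2 * i - 1, ]; m <- det[2 * i, ]
    tab <- table(factor(l, c(F, T)), factor(m, c(F, T))) + 0.5
    (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1]) > 1
  }, logical(1))
  expect_gte(mean(or_pos), 0.95)
  # rho = 0: detection independent (chi-squared p roughly uniform)
  pind <- generate_cis_pairs(n_pairs = 60, rho = 0, n_cells = 300,
                             seed = 7)
  det0 <- pind$counts$cast_reads >= 3
  ps <- vapply(seq_len(60), function(i) {
    suppressWarnings(stats::chisq.test(
      table(det0[2 * i - 1, ], det0[2 * i, ]))$p.value)
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("cis-pair generator preserves marginal means and imbalance", {
  kin <- two_state_kinetics(1, 4, 25)
  pc <- generate_cis_pairs(n_pairs = 30, rho = 0.8, n_cells = 500,
                           ai = 0.3, lnc_kin = kin, seed = 8)
  lnc_rows <- seq(1, 60, by = 2)
  # CAST fraction of lncRNA molecules near 0.5 + ai = 0.8
  cast_frac <- sum(pc$counts$cast_reads[lnc_rows, ]) /
    sum(pc$counts$totals[lnc_rows, ])
  expect_lt(abs(cast_frac - 0.8), 0.02)
  # total mean = cast + c57 = 2x the class marginal mean
  expect_lt(abs(mean(pc$counts$totals[lnc_rows, ]) /
                  (2 * mean_expr(kin)) - 1), 0.1)
})

test_that("decay generator evaluates the model exactly when noiseless", {
  sim <- generate_decay_timecourse(n_genes = 1, n_controls = 3,
                                   lambda = c(g = 0.2), noise_sd = 0,
                                   seed = 1)
  expect_equal(unname(sim$expression["g", "t10"]), exp(-2))
  expect_true(all(sim$controls$t_half > 1 & sim$controls$t_half < 8))
  expect_error(generate_decay_timecourse(time_points = c(0, -2)),
               "negative")
  # scaling applies multiplicatively to the stated time point only
  s2 <- generate_decay_timecourse(n_genes = 5, n_controls = 3,
                                  scaling = c(t0 = 1, t2 = 1, t4 = 2,
                                              t7 = 1, t10 = 1),
                                  noise_sd = 0, seed = 2)
  s1 <- generate_decay_timecourse(n_genes = 5, n_controls = 3,
                                  noise_sd = 0, seed = 2)
  expect_equal(s2$expression[, "t4"], 2 * s1$expression[, "t4"])
  expect_equal(s2$expression[, "t7"], s1$expression[, "t7"])
})

test_that("cell-cycle generator peaks markers in their phase", {
  cc <- generate_cell_cycle_dataset(n_cells = 400, seed = 30)
  cfg <- cell_cycle_config()
  # per-phase mean of each marker set: maximal in its own phase
  for (ph in names(cfg$marker_sets)) {
    own <- colMeans(cc$counts[cfg$marker_sets[[ph]],
                              cc$truth$phase == ph, drop = FALSE])
    other <- colMeans(cc$counts[unlist(cfg$marker_sets[
      setdiff(names(cfg$marker_sets), ph)]), cc$truth$phase == ph,
      drop = FALSE])
    expect_gt(mean(own), mean(other))
  }
  # phase proportions within multinomial error of the configuration
  props <- table(cc$truth$phase)[names(cfg$phase_props)] / 400
  expect_true(all(abs(props - cfg$phase_props) <
                    3.5 * sqrt(cfg$phase_props * (1 - cfg$phase_props) /
                                 400)))
  cc2 <- generate_cell_cycle_dataset(n_cells = 400, seed = 30)
  expect_identical(cc$truth$phase, cc2$truth$phase)
  expect_error(cell_cycle_config(genes_per_set = 0), "config error")
})
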