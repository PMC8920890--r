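#' Generator settings for allele-resolved synthetic datasets
#'
#' Defaults encode the simulated conditions the pipeline is tested against:
#' log-normal priors on each telegraph rate, with the lncRNA-like class
#' shifted to 4-fold lower burst frequency (`k_on` multiplier 0.25) and
#' 2-fold lower burst size (multiplier 0.5) relative to the mRNA-like
#' class; per-molecule SNP capture probability 1 (no missing assignments)
#' unless dropout is being studied. The mRNA-like priors are centred so the
#' post-inference filter windows (burst size 0.2-50, frequency 0.01-30)
#' capture well over 90% of genes.
#'
#' @param n_mrna,n_lnc genes per class.
#' @param n_cells cells.
#' @param kon_meanlog,kon_sdlog,size_meanlog,size_sdlog,koff_meanlog,koff_sdlog
#'   log-normal prior parameters for the mRNA-like class (`k_syn` is derived
#'   as `burst_size * k_off`).
#' @param lnc_kon_mult,lnc_size_mult class multipliers for the lncRNA-like
#'   class.
#' @param snp_capture per-molecule probability that a UMI yields an
#'   allele-informative read.
#' @param tss_spacing base pairs between consecutive TSSs in the synthetic
#'   layout.
#' @param frac_imprinted,frac_x fractions of genes flagged imprinted or
#'   X-linked.
#' @return list of generator settings.
#' @export
allelic_sim_config <- function(n_mrna = 200, n_lnc = 200, n_cells = 200,
                               kon_meanlog = log(2), kon_sdlog = 0.5,
                               size_meanlog = log(4), size_sdlog = 0.5,
                               koff_meanlog = log(8), koff_sdlog = 0.4,
                               lnc_kon_mult = 0.25, lnc_size_mult = 0.5,
                               snp_capture = 1.0, tss_spacing = 50000,
                               frac_imprinted = 0, frac_x = 0) {
  if (snp_capture < 0 || snp_capture > 1) {
    stop("config error: snp_capture must lie in [0, 1]")
  }
  as.list(environment())
}

#' Generate an allele-resolved dataset with known kinetics
#'
#' Simulates two independent alleles per gene from class-specific
#' telegraph-model kinetics, converts UMIs to allele-assigned read counts by
#' per-molecule binomial SNP capture, and lays the genes out on a synthetic
#' genome. Entries with UMIs but no captured allelic read are missing
#' assignments, exactly as in real data.
#'
#' @param config from [allelic_sim_config()].
#' @param seed integer seed.
#' @return list: `counts` (an [allelic_count_set()]), `genes` (a
#'   [gene_table()]), `truth` (data frame, one row per gene x allele with the
#'   true rates and class) and `seed`.
#' @export
generate_allelic_dataset <- function(config = allelic_sim_config(),
                                     seed = 1) {
  set.seed(seed)
  n_genes <- config$n_mrna + config$n_lnc
  if (n_genes < 1) stop("config error: no genes requested")
  cls <- rep(c("mRNA-like", "lncRNA-like"), c(config$n_mrna, config$n_lnc))
  kon_mult <- ifelse(cls == "lncRNA-like", config$lnc_kon_mult, 1)
  size_mult <- ifelse(cls == "lncRNA-like", config$lnc_size_mult, 1)
  k_on <- rlnorm(n_genes, config$kon_meanlog, config$kon_sdlog) * kon_mult
  size <- rlnorm(n_genes, config$size_meanlog, config$size_sdlog) * size_mult
  k_off <- rlnorm(n_genes, config$koff_meanlog, config$koff_sdlog)
  k_syn <- size * k_off
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  n_cells <- config$n_cells
  cell_id <- sprintf("cell%04d", seq_len(n_cells))

  umi_cast <- umi_c57 <- matrix(0L, n_genes, n_cells,
                                dimnames = list(gene_id, cell_id))
  for (g in seq_len(n_genes)) {
    kin <- two_state_kinetics(k_on[g], k_off[g], k_syn[g])
    umi_cast[g, ] <- sample_beta_poisson(kin, n_cells)
    umi_c57[g, ] <- sample_beta_poisson(kin, n_cells)
  }
  totals <- umi_cast + umi_c57
  cast_reads <- matrix(rbinom(length(umi_cast), umi_cast, config$snp_capture),
                       n_genes, dimnames = dimnames(totals))
  c57_reads <- matrix(rbinom(length(umi_c57), umi_c57, config$snp_capture),
                      n_genes, dimnames = dimnames(totals))

  imprinted <- runif(n_genes) < config$frac_imprinted
  on_x <- runif(n_genes) < config$frac_x
  genes <- gene_table(data.frame(
    gene_id = gene_id,
    chrom = ifelse(on_x, "chrX", "chr1"),
    start = config$tss_spacing * seq_len(n_genes),
    end = config$tss_spacing * seq_len(n_genes) + 2000L,
    strand = rep(c("+", "-"), length.out = n_genes),
    biotype = ifelse(cls == "lncRNA-like", "lncRNA", "protein_coding"),
    imprinted = imprinted, stringsAsFactors = FALSE))

  truth <- data.frame(
    gene_id = rep(gene_id, each = 2),
    allele = rep(c("cast", "c57"), n_genes),
    k_on = rep(k_on, each = 2), k_off = rep(k_off, each = 2),
    k_syn = rep(k_syn, each = 2), class = rep(cls, each = 2),
    stringsAsFactors = FALSE)

  list(counts = allelic_count_set(totals, cast_reads, c57_reads),
       genes = genes, truth = truth, seed = seed)
}

#' Generate cis-linked lncRNA-mRNA pairs with coordinated alleles
#'
#' Realises coordinated allelic expression through a shared latent promoter
#' state: per cell and allele, with probability `rho` the lncRNA and mRNA of
#' a pair share the latent ON-fraction quantile of their Beta distributions
#' (independent otherwise), so each gene's marginal Beta-Poisson kinetics
#' are preserved while detection becomes allele-wise coordinated. An
#' optional allelic imbalance `ai` skews both genes of a pair toward the
#' CAST allele by scaling the allele-specific transcription rates.
#'
#' @param n_pairs number of lncRNA-mRNA pairs.
#' @param rho per-cell, per-allele coupling probability in `[0, 1]`.
#' @param n_cells cells.
#' @param lnc_kin,mrna_kin marginal kinetics of each class
#'   ([two_state_kinetics()]).
#' @param ai common allelic imbalance in `(-0.5, 0.5)` applied to both genes
#'   (0 = balanced).
#' @param pair_tss_gap base pairs between the TSSs of a pair (default 20 kb,
#'   inside the 500-kb pairing window); pairs are spaced 2 Mb apart.
#' @param seed integer seed.
#' @return list: `counts` ([allelic_count_set()]), `genes`
#'   ([gene_table()]), `truth` (pair table with `rho`), and `latent` (list of
#'   logical coupled-state matrices per allele, cells x pairs).
#' @export
generate_cis_pairs <- function(n_pairs = 50, rho = 0.6, n_cells = 400,
                               lnc_kin = two_state_kinetics(1, 4, 25),
                               mrna_kin = two_state_kinetics(2, 4, 30),
                               ai = 0, pair_tss_gap = 20000, seed = 1) {
  if (rho < 0 || rho > 1) stop("parameter error: rho must lie in [0, 1]")
  if (abs(ai) >= 0.5) stop("parameter error: |ai| must be < 0.5")
  set.seed(seed)
  lnc_id <- sprintf("lnc%03d", seq_len(n_pairs))
  mrna_id <- sprintf("mrna%03d", seq_len(n_pairs))
  gene_id <- as.vector(rbind(lnc_id, mrna_id))
  cell_id <- sprintf("cell%04d", seq_len(n_cells))
  umi_cast <- umi_c57 <- matrix(0L, 2 * n_pairs, n_cells,
                                dimnames = list(gene_id, cell_id))
  # CAST-fraction 0.5 + ai via allele-specific k_syn scaling
  syn_scale <- c(cast = 2 * (0.5 + ai), c57 = 2 * (0.5 - ai))
  latent <- list()
  for (al in c("cast", "c57")) {
    coupled <- matrix(runif(n_cells * n_pairs) < rho, n_cells, n_pairs)
    for (p in seq_len(n_pairs)) {
      u_shared <- runif(n_cells)
      u_lnc <- ifelse(coupled[, p], u_shared, runif(n_cells))
      u_mrna <- ifelse(coupled[, p], u_shared, runif(n_cells))
      p_lnc <- stats::qbeta(u_lnc, lnc_kin$k_on, lnc_kin$k_off)
      p_mrna <- stats::qbeta(u_mrna, mrna_kin$k_on, mrna_kin$k_off)
      x_lnc <- rpois(n_cells, lnc_kin$k_syn * syn_scale[[al]] * p_lnc)
      x_mrna <- rpois(n_cells, mrna_kin$k_syn * syn_scale[[al]] * p_mrna)
      if (al == "cast") {
        umi_cast[2 * p - 1, ] <- x_lnc
        umi_cast[2 * p, ] <- x_mrna
      } else {
        umi_c57[2 * p - 1, ] <- x_lnc
        umi_c57[2 * p, ] <- x_mrna
      }
    }
    latent[[al]] <- coupled
  }
  totals <- umi_cast + umi_c57
  tss0 <- 2e6 * seq_len(n_pairs)
  starts <- as.vector(rbind(tss0, tss0 + pair_tss_gap))
  genes <- gene_table(data.frame(
    gene_id = gene_id, chrom = "chr1",
    start = starts, end = starts + 2000L, strand = "+",
    biotype = rep(c("lncRNA", "protein_coding"), n_pairs),
    stringsAsFactors = FALSE))
  truth <- data.frame(pair = seq_len(n_pairs), lnc_id = lnc_id,
                      mrna_id = mrna_id, rho = rho, ai = ai,
                      stringsAsFactors = FALSE)
  list(counts = allelic_count_set(totals, umi_cast, umi_c57),
       genes = genes, truth = truth, latent = latent, seed = seed)
}

#' Generate an exponential-decay time course with library distortions
#'
#' Simulates transcription-shutoff expression
#' `a * exp(-lambda t) * scale(t) * lognormal noise` for genes with known
#' decay rates, plus a designated control-gene subset with true half-lives
#' strictly inside (1, 8) hours, as required for normalisation-factor
#' calibration.
#'
#' @param n_genes non-control genes.
#' @param n_controls control genes with known half-lives.
#' @param lambda optional named vector of decay rates per hour for the
#'   non-control genes (default drawn so half-lives span 0.5-9 h).
#' @param time_points hours, must include 0 (default `c(0, 2, 4, 7, 10)`).
#' @param scaling named per-time-point multiplicative distortion (default
#'   all 1).
#' @param noise_sd sdlog of multiplicative log-normal noise (0 = noiseless).
#' @param amplitude common amplitude `a`.
#' @param seed integer seed.
#' @return list: `expression` (gene x time matrix, columns named `t<h>`),
#'   `time_points`, `controls` (data frame `gene_id`, `t_half`), `truth`
#'   (data frame of all true rates).
#' @export
generate_decay_timecourse <- function(n_genes = 50, n_controls = 12,
                                      lambda = NULL,
                                      time_points = c(0, 2, 4, 7, 10),
                                      scaling = NULL, noise_sd = 0.05,
                                      amplitude = 1, seed = 1) {
  if (any(time_points < 0)) stop("parameter error: negative time point")
  if (!0 %in% time_points) stop("parameter error: time points must include 0")
  set.seed(seed)
  if (is.null(lambda)) {
    lambda <- log(2) / runif(n_genes, 0.5, 9)
    names(lambda) <- sprintf("gene%03d", seq_len(n_genes))
  }
  ctl_thalf <- runif(n_controls, 1.2, 7.5)   # strictly inside (1, 8) h
  ctl_lambda <- log(2) / ctl_thalf
  names(ctl_lambda) <- sprintf("ctrl%03d", seq_len(n_controls))
  all_lambda <- c(lambda, ctl_lambda)
  if (is.null(scaling)) {
    scaling <- setNames(rep(1, length(time_points)),
                        paste0("t", time_points))
  }
  tp_names <- paste0("t", time_points)
  expr <- outer(all_lambda, time_points,
                function(l, t) amplitude * exp(-l * t))
  expr <- sweep(expr, 2, scaling[tp_names], `*`)
  if (noise_sd > 0) {
    expr <- expr * matrix(rlnorm(length(expr), 0, noise_sd), nrow(expr))
  }
  dimnames(expr) <- list(names(all_lambda), tp_names)
  list(expression = expr, time_points = time_points,
       controls = data.frame(gene_id = names(ctl_lambda),
                             t_half = ctl_thalf, stringsAsFactors = FALSE),
       truth = data.frame(gene_id = names(all_lambda),
                          lambda = unname(all_lambda),
                          t_half = log(2) / unname(all_lambda),
                          control = names(all_lambda) %in% names(ctl_lambda),
                          stringsAsFactors = FALSE),
       seed = seed)
}

#' Default cell-cycle marker configuration
#'
#' Four marker sets whose means peak in one phase each, mirroring the
#' canonical regulators: `Gas1`-like (G0), `Ccnd1`-like (G1), `Ccne2`-like
#' (G1/S) and `Ccnb1`-like (G2/M).
#'
#' @param genes_per_set marker genes per phase.
#' @param peak_mean,base_mean Poisson means inside and outside the phase
#'   window.
#' @param phase_props named phase proportions (sum to 1) in cycle order
#'   G0, G1, G1/S, G2/M.
#' @param n_background phase-independent background genes.
#' @param background_mean Poisson mean of background genes.
#' @return list of marker settings.
#' @export
cell_cycle_config <- function(genes_per_set = 5, peak_mean = 20,
                              base_mean = 0.5,
                              phase_props = c(G0 = 0.2, G1 = 0.4,
                                              `G1/S` = 0.2, `G2/M` = 0.2),
                              n_background = 50, background_mean = 5) {
  if (genes_per_set < 1) stop("config error: empty marker set")
  stopifnot(abs(sum(phase_props) - 1) < 1e-8)
  marker_sets <- list(
    G0 = sprintf("Gas1_like_%d", seq_len(genes_per_set)),
    G1 = sprintf("Ccnd1_like_%d", seq_len(genes_per_set)),
    `G1/S` = sprintf("Ccne2_like_%d", seq_len(genes_per_set)),
    `G2/M` = sprintf("Ccnb1_like_%d", seq_len(genes_per_set)))
  list(marker_sets = marker_sets, peak_mean = peak_mean,
       base_mean = base_mean, phase_props = phase_props,
       n_background = n_background, background_mean = background_mean)
}

#' Generate a cell-cycle-structured count matrix with known phases
#'
#' Places cells on a circular latent coordinate partitioned into contiguous
#' phase arcs (cycle order G0, G1, G1/S, G2/M); each phase's marker genes
#' follow a wrapped raised-cosine mean profile centred on their arc, with
#' support extending one arc width to each side so that expression overlaps
#' smoothly between neighbouring phases (as cell-cycle regulators do) and
#' the dominant marker switches exactly at the phase boundaries.
#'
#' @param n_cells cells.
#' @param config from [cell_cycle_config()].
#' @param seed integer seed.
#' @return list: `counts` (gene x cell matrix), `truth` (data frame
#'   `cell_id`, `theta` in `[0, 1)`, `phase`), `marker_sets`.
#' @export
generate_cell_cycle_dataset <- function(n_cells = 300,
                                        config = cell_cycle_config(),
                                        seed = 1) {
  set.seed(seed)
  props <- config$phase_props
  phases <- names(props)
  breaks <- cumsum(c(0, props))
  theta <- sort(runif(n_cells))
  phase <- cut(theta, breaks = breaks, labels = phases,
               include.lowest = TRUE, right = FALSE)
  cell_id <- sprintf("cell%04d", seq_len(n_cells))
  # wrapped raised cosine centred on the arc, half-width = one arc width:
  # at the boundary between two phases both neighbouring bumps equal 0.5,
  # so the dominant marker switches exactly there
  bump <- function(theta, centre, width) {
    d <- abs(theta - centre)
    d <- pmin(d, 1 - d)
    0.5 + 0.5 * cos(pi * pmin(d / width, 1))
  }
  rows <- list()
  for (k in seq_along(phases)) {
    centre <- (breaks[k] + breaks[k + 1]) / 2
    mu <- config$base_mean +
      (config$peak_mean - config$base_mean) *
      bump(theta, centre, props[k])
    for (g in config$marker_sets[[phases[k]]]) {
      rows[[g]] <- rpois(n_cells, mu)
    }
  }
  for (g in seq_len(config$n_background)) {
    rows[[sprintf("bg_%03d", g)]] <- rpois(n_cells, config$background_mean)
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- cell_id
  list(counts = counts,
       truth = data.frame(cell_id = cell_id, theta = theta,
                          phase = as.character(phase),
                          stringsAsFactors = FALSE),
       marker_sets = config$marker_sets, seed = seed)
}
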