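#' Default pipeline configuration
#'
#' Every analysis threshold is exposed as a named key with its
#' default: QC presets ([qc_presets()]), gene filter (>= 5 counts in 2
#' cells), promoter windows (divergent 500 bp, convergent 2 kb, separation
#' 4 kb, unidirectional 10 kb, cis pairing 500 kb), permutation sizes
#' (CV-squared 10,000; gene relocations 1,000; bootstrap 1,000), kinetic
#' filter bounds, decay control rules, and the generator settings used by
#' the `simulate` stage.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    qc = list(preset = "smartseq2_fibro",
              gene_min_count = 5, gene_min_cells = 2),
    windows = list(divergent = 500, convergent = 2000, separation = 4000,
                   unidirectional = 10000, cis = 500000),
    permutations = list(cv2 = 10000, cis_locations = 1000, bootstrap = 1000),
    kinetics = list(size_range = c(0.2, 50), freq_range = c(0.01, 30),
                    mean_range = c(0.01, 100), ci_ratio_max = 10^1.5,
                    min_cells = 5, max_genes = 50),
    cis = list(min_reads = 3, min_cells = 20, alpha_score = 0.05,
               alpha_real = 0.01, background_fraction = 0.01,
               detect_threshold = 3),
    decay = list(max_t_half = 10, max_burst_duration = 72,
                 control_range = c(1, 8), exclude_short_after = 7),
    state = list(scale_factor = 10000, n_variable = 50, n_pcs = 3,
                 phase_window = 15, anova_alpha = 0.01,
                 apoptosis_top = 75, apoptosis_k = 3),
    sim = list(n_mrna = 60, n_lnc = 60, n_cells = 150, snp_capture = 0.8,
               decay_genes = 40, decay_controls = 12, cc_cells = 300))
}

#' Read a YAML pipeline configuration
#'
#' Values from the file override the matching [default_config()] entries;
#' everything else keeps its default.
#'
#' @param path YAML file.
#' @return Configuration list with attribute `digest`.
#' @export
read_config <- function(path) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_lists(base[[k]], over[[k]])
      } else {
        over[[k]]
      }
    }
    base
  }
  cfg <- merge_lists(default_config(), user)
  attr(cfg, "digest") <- config_digest(cfg)
  cfg
}

#' @rdname read_config
#' @param config configuration list.
#' @return For `config_digest()`: an md5 string of the canonical YAML
#'   serialisation.
#' @export
config_digest <- function(config) {
  attributes(config) <- attributes(config)["names"]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a result table with a commented metadata header
#'
#' @param df data frame.
#' @param path output TSV.
#' @param meta named list written as `# key: value` lines (version, seed and
#'   config digest are standard).
#' @export
write_result_table <- function(df, path, meta = list()) {
  meta <- c(list(package = paste0("burstlnc ",
                                  as.character(utils::packageVersion("burstlnc")))),
            meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  }
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' @rdname write_result_table
#' @return For `read_result_table()`: the data frame (metadata in attribute
#'   `meta`).
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- sub("^# ", "", lines[hdr])
  df <- read.delim(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                collapse = "\n"),
                   stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

.stages <- c("simulate", "qc", "annotate", "variability", "kinetics",
             "decay", "cis", "state")

.stage_deps <- list(
  simulate = character(), qc = "simulate", annotate = "qc",
  variability = "qc", kinetics = "qc", decay = "simulate", cis = "qc",
  state = "simulate")

.log_line <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run one pipeline stage
#'
#' Orchestrates the analysis stages over a shared output directory. Each
#' stage reads the outputs of its upstream stages (a missing upstream stage
#' is a dependency error naming it), writes TSV tables with a commented
#' metadata header carrying the package version, seed and configuration
#' digest, and logs its boundaries to standard error. Identical
#' configuration and seed produce byte-identical outputs.
#'
#' @param stage one of `simulate`, `qc`, `annotate`, `variability`,
#'   `kinetics`, `decay`, `cis`, `state`.
#' @param config configuration list (see [read_config()]).
#' @param out_dir output directory shared by all stages.
#' @param seed integer seed; defaults to `config$seed`.
#' @return Invisibly, a character vector of the files written.
#' @export
run_stage <- function(stage, config = default_config(),
                      out_dir = "burstlnc_out", seed = NULL) {
  if (!stage %in% .stages) {
    stop("usage error: unknown stage '", stage, "'; available stages: ",
         paste(.stages, collapse = ", "))
  }
  for (dep in .stage_deps[[stage]]) {
    if (!file.exists(file.path(out_dir, paste0(dep, ".done")))) {
      stop("dependency error: stage '", dep, "' must run before '", stage,
           "'")
    }
  }
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(stage = stage, seed = seed,
               config_digest = config_digest(config))
  .log_line("stage ", stage, " started (seed ", seed, ")")
  files <- switch(stage,
    simulate = .stage_simulate(config, out_dir, seed, meta),
    qc = .stage_qc(config, out_dir, meta),
    annotate = .stage_annotate(config, out_dir, meta),
    variability = .stage_variability(config, out_dir, seed, meta),
    kinetics = .stage_kinetics(config, out_dir, seed, meta),
    decay = .stage_decay(config, out_dir, meta),
    cis = .stage_cis(config, out_dir, seed, meta),
    state = .stage_state(config, out_dir, seed, meta))
  writeLines(files, file.path(out_dir, paste0(stage, ".done")))
  .log_line("stage ", stage, " finished (", length(files), " file(s))")
  invisible(files)
}

.stage_simulate <- function(config, out_dir, seed, meta) {
  sc <- config$sim
  ds <- generate_allelic_dataset(
    allelic_sim_config(n_mrna = sc$n_mrna, n_lnc = sc$n_lnc,
                       n_cells = sc$n_cells, snp_capture = sc$snp_capture),
    seed = seed)
  write_counts(ds$counts, file.path(out_dir, "counts"), format = "tsv")
  write_gene_table(ds$genes, file.path(out_dir, "genes.tsv"))
  write_result_table(ds$truth, file.path(out_dir, "sim_truth.tsv"), meta)
  dec <- generate_decay_timecourse(n_genes = sc$decay_genes,
                                   n_controls = sc$decay_controls,
                                   seed = seed)
  write_result_table(
    data.frame(gene_id = rownames(dec$expression), dec$expression,
               check.names = FALSE),
    file.path(out_dir, "decay_expression.tsv"), meta)
  write_result_table(dec$controls, file.path(out_dir, "decay_controls.tsv"),
                     meta)
  cc <- generate_cell_cycle_dataset(n_cells = sc$cc_cells, seed = seed)
  write_result_table(
    data.frame(gene_id = rownames(cc$counts), cc$counts,
               check.names = FALSE),
    file.path(out_dir, "cc_counts.tsv"), meta)
  write_result_table(cc$truth, file.path(out_dir, "cc_truth.tsv"), meta)
  file.path(out_dir, c("counts", "genes.tsv", "sim_truth.tsv",
                       "decay_expression.tsv", "decay_controls.tsv",
                       "cc_counts.tsv", "cc_truth.tsv"))
}

.read_sim <- function(out_dir) {
  list(counts = read_counts(file.path(out_dir, "counts"), format = "tsv"),
       genes = gene_table(read.delim(file.path(out_dir, "genes.tsv"))))
}

.stage_qc <- function(config, out_dir, meta) {
  sim <- .read_sim(out_dir)
  acs <- sim$counts
  th <- qc_presets()[[config$qc$preset]]
  metrics <- data.frame(
    cell_id = colnames(acs$totals),
    total_reads = colSums(acs$totals),
    genes_detected = colSums(acs$totals >= th$gene_count_threshold),
    allelic_balance = cell_allelic_balance(acs, sim$genes),
    imprinted_x_fraction = 0,
    total_umis = colSums(acs$totals))
  report <- cell_qc(metrics, config$qc$preset)
  write_result_table(as.data.frame(report),
                     file.path(out_dir, "cell_qc.tsv"), meta)
  kept <- gene_filter(acs$totals, config$qc$gene_min_count,
                      config$qc$gene_min_cells)
  write_result_table(data.frame(gene_id = kept),
                     file.path(out_dir, "genes_kept.tsv"), meta)
  file.path(out_dir, c("cell_qc.tsv", "genes_kept.tsv"))
}

.stage_annotate <- function(config, out_dir, meta) {
  sim <- .read_sim(out_dir)
  kept <- read_result_table(file.path(out_dir, "genes_kept.tsv"))$gene_id
  cls <- classify_loci(sim$genes, kept)
  write_result_table(cls, file.path(out_dir, "locus_class.tsv"), meta)
  file.path(out_dir, "locus_class.tsv")
}

.stage_variability <- function(config, out_dir, seed, meta) {
  sim <- .read_sim(out_dir)
  kept <- read_result_table(file.path(out_dir, "genes_kept.tsv"))$gene_id
  tot <- sim$counts$totals[kept, , drop = FALSE]
  means <- rowMeans(tot)
  cv2s <- apply(tot, 1, cv2)
  bio <- sim$genes$biotype[match(kept, sim$genes$gene_id)]
  lnc <- kept[bio == "lncRNA"]
  mrna <- kept[bio == "protein_coding"]
  matched <- lapply(setNames(lnc, lnc), function(g) {
    match_expression(means[[g]], means[mrna], k = 10)
  })
  pt <- cv2_permutation_test(cv2s[lnc], matched, cv2s[mrna],
                             n_perm = config$permutations$cv2, seed = seed)
  write_result_table(
    data.frame(n_lnc = length(lnc), n_perm = config$permutations$cv2,
               observed_median = pt$observed_median, p_value = pt$p_value,
               degenerate = pt$degenerate),
    file.path(out_dir, "cv2_permutation.tsv"), meta)
  write_result_table(
    data.frame(gene_id = kept, mean = means, cv2 = cv2s, biotype = bio),
    file.path(out_dir, "cv2_table.tsv"), meta)
  file.path(out_dir, c("cv2_permutation.tsv", "cv2_table.tsv"))
}

.stage_kinetics <- function(config, out_dir, seed, meta) {
  sim <- .read_sim(out_dir)
  kept <- read_result_table(file.path(out_dir, "genes_kept.tsv"))$gene_id
  kept <- head(kept, config$kinetics$max_genes)
  set.seed(seed)
  rows <- list()
  for (g in kept) {
    for (al in c("cast", "c57")) {
      u <- if (al == "cast") sim$counts$umi_cast[g, ] else
        sim$counts$umi_c57[g, ]
      miss <- sim$counts$missing[g, ]
      u[miss] <- 0L
      fit <- fit_two_state(u, missing = miss,
                           min_cells = config$kinetics$min_cells)
      est <- coef(fit)
      flt <- if (!fit$degenerate) {
        kinetics_filter(fit, config$kinetics$size_range,
                        config$kinetics$freq_range,
                        config$kinetics$mean_range,
                        config$kinetics$ci_ratio_max,
                        config$kinetics$min_cells)
      } else list(pass = FALSE, reasons = "degenerate")
      rows[[paste(g, al)]] <- data.frame(
        gene_id = g, allele = al, k_on = est["k_on"], k_off = est["k_off"],
        k_syn = est["k_syn"], burst_size = est["burst_size"],
        mean = est["mean"], degenerate = fit$degenerate,
        pass = flt$pass,
        reasons = paste(setdiff(flt$reasons, "no_ci"), collapse = ","),
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  write_result_table(out, file.path(out_dir, "kinetic_fits.tsv"), meta)
  file.path(out_dir, "kinetic_fits.tsv")
}

.stage_decay <- function(config, out_dir, meta) {
  expr <- read_result_table(file.path(out_dir, "decay_expression.tsv"))
  mat <- as.matrix(expr[, -1, drop = FALSE])
  rownames(mat) <- expr$gene_id
  colnames(mat) <- sub("^X", "", colnames(mat))  # read.delim mangles t0 -> t0
  controls <- read_result_table(file.path(out_dir, "decay_controls.tsv"))
  rel <- normalize_to_t0(mat)
  f <- normalization_factor(rel, controls,
                            exclude_short_after =
                              config$decay$exclude_short_after)
  corrected <- apply_normalization_factor(rel, f)
  fits <- fit_decay_table(corrected, max_t_half = config$decay$max_t_half)
  write_result_table(fits, file.path(out_dir, "decay_fits.tsv"), meta)
  file.path(out_dir, "decay_fits.tsv")
}

.stage_cis <- function(config, out_dir, seed, meta) {
  sim <- .read_sim(out_dir)
  acs <- sim$counts
  elig <- cis_eligible_genes(acs, sim$genes, config$cis$min_reads,
                             config$cis$min_cells)
  bio <- sim$genes$biotype[match(elig, sim$genes$gene_id)]
  lnc <- elig[bio == "lncRNA"]
  mrna <- elig[bio == "protein_coding"]
  pairs <- enumerate_pairs(sim$genes, lnc, mrna, config$windows$cis)
  if (nrow(pairs) == 0) {
    write_result_table(pairs, file.path(out_dir, "cis_pairs.tsv"), meta)
    return(file.path(out_dir, "cis_pairs.tsv"))
  }
  ai <- gene_allelic_imbalance(acs)
  scored <- score_permutation(pairs, ai, sim$genes, mrna,
                              config$windows$cis,
                              config$permutations$cis_locations, seed,
                              config$cis$alpha_score)
  write_result_table(scored, file.path(out_dir, "cis_pairs.tsv"), meta)
  file.path(out_dir, "cis_pairs.tsv")
}

.stage_state <- function(config, out_dir, seed, meta) {
  expr <- read_result_table(file.path(out_dir, "cc_counts.tsv"))
  counts <- as.matrix(expr[, -1, drop = FALSE])
  rownames(counts) <- expr$gene_id
  norm <- log_normalize(counts, config$state$scale_factor)
  vg <- select_variable_genes(counts, n_top = config$state$n_variable,
                              min_cells = 5, min_count = 1)
  set.seed(seed)
  lambda <- fit_trajectory(norm, vg, n_pcs = config$state$n_pcs)
  markers <- cell_cycle_config()$marker_sets
  phases <- assign_phase(lambda, norm, markers, config$state$phase_window)
  de <- anova_phase_de(norm, phases$phase, alpha = config$state$anova_alpha)
  write_result_table(phases, file.path(out_dir, "phases.tsv"), meta)
  write_result_table(de, file.path(out_dir, "phase_de.tsv"), meta)
  file.path(out_dir, c("phases.tsv", "phase_de.tsv"))
}
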