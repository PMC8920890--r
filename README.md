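# burstlnc

Transcriptional burst kinetics and *cis*-regulation of long noncoding RNAs
(lncRNAs) from allele-resolved single-cell RNA-seq.

## The problem

lncRNAs are expressed far below mRNAs, and bulk averages cannot tell
whether that reflects smaller transcriptional bursts or rarer ones. In F1
hybrid cells (CAST/EiJ x C57BL/6J) the two parental alleles of each gene
are distinguishable by SNPs, so per-allele molecule counts across single
cells can be treated as independent draws from the steady state of the
two-state (telegraph) model of transcription: the promoter activates at
rate *k*<sub>on</sub> (burst frequency), inactivates at rate
*k*<sub>off</sub>, and transcribes at rate *k*<sub>syn</sub> while active
(all rates in units of the RNA degradation rate). Counts then follow the
Beta-Poisson mixture

    X | p ~ Poisson(k_syn * p),   p ~ Beta(k_on, k_off)

with burst size *k*<sub>syn</sub>/*k*<sub>off</sub> and mean
*k*<sub>syn</sub>*k*<sub>on</sub>/(*k*<sub>on</sub>+*k*<sub>off</sub>).

`burstlnc` is for computational biologists who want this inference and the
analysis chain around it as tested, reusable functions:

* maximum-likelihood telegraph-model fits per gene and allele
  (`fit_two_state()`, a classed model object with `coef`, `summary`,
  `simulate`, ... methods), cell-level bootstrap confidence intervals,
  standard post-inference filters, and a likelihood-ratio test for
  changes in burst frequency or size between conditions;
* allele-level UMI distribution, allelic imbalance, and cell/gene QC;
* promoter-architecture classification (divergent / convergent /
  intergenic / separated units) and TSS-distance analyses;
* expression-matched CV² permutation tests with a subsampling power
  analysis;
* RNA half-life estimation from transcription-shutoff time courses with
  control-gene normalisation, converting burst frequencies into hours
  between bursts;
* candidate *cis*-functioning lncRNA discovery from allelic-imbalance
  scores and per-allele detection coordination (Fisher's exact test), each
  against a gene-relocation permutation background;
* cell-state association: principal-curve cell-cycle staging,
  phase-specific ANOVA, apoptosis-programme clustering, and
  guilt-by-association refinement;
* a synthetic-data generator with known ground truth for every structure
  above, plus a staged pipeline driver (`run_stage()`, CLI wrapper in
  `inst/cli/burstlnc`).

The models, conventions, default thresholds and their rationale are
documented in the methods vignette
(`vignettes/burst-kinetics-methods.Rmd`).

## Worked example

Simulate one allele of a bursty gene, fit the telegraph model, and test it
against a condition with doubled burst frequency:

```r
library(burstlnc)

kin <- two_state_kinetics(k_on = 0.5, k_off = 6, k_syn = 45)
x   <- sample_beta_poisson(kin, n_cells = 1000, seed = 7)
fit <- bootstrap_ci(fit_two_state(x), n_boot = 200, seed = 8)
summary(fit)
#> Two-state transcriptional kinetics fit
#>   cells used: 1000 (missing excluded: 0)
#>   k_on = 0.4796  k_off = 8.092  k_syn = 62.66  (burst size 7.743, mean 3.506)
#>   logLik = -2319.948, convergence code 0
#>   95% bootstrap CI: k_on [0.422, 0.552], size [6.32, 9.46]
#>   post-inference filter: pass

y <- sample_beta_poisson(two_state_kinetics(1.0, 6, 45), 1000, seed = 9)
lrt_kinetics(x, y, parameter = "frequency")
#> Likelihood-ratio test for burst frequency
#>   lambda_LR = 80.040, theta_hat = log2 ratio = 1.320
#>   p (chi-sq, 1 df) = 3.67e-19; one-sided (>3.84): TRUE, two-sided (>7.68): TRUE

burst_duration_hours(coef(fit)["k_on"], t_half = 4)   # ~12 h between bursts
```

The true *k*<sub>on</sub> (0.5) sits inside the bootstrap interval, the
doubled frequency is detected decisively (the true log2 ratio is 1), and
with a 4-hour half-life this gene bursts roughly every 12 hours per
allele.

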