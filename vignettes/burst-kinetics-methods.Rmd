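---
title: "Models and methods behind burstlnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind burstlnc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstlnc)
```

# The scientific problem

Long noncoding RNAs (lncRNAs) are expressed at much lower levels than
mRNAs, and it is not obvious from population averages whether that reflects
fewer RNA molecules made per transcriptional episode or fewer episodes.
Allele-resolved single-cell RNA-seq of F1 hybrid cells (CAST/EiJ x
C57BL/6J) separates the two parental alleles of every gene, so each allele
can be treated as an independent realisation of a stochastic transcription
process, and per-allele molecule counts across cells carry enough
information to estimate the kinetics of that process. `burstlnc`
implements the full analysis chain around this idea: kinetic inference and
hypothesis testing, expression-matched variability statistics, absolute
burst timescales through RNA decay rates, discovery of candidate
*cis*-acting lncRNAs from allelic signal, and cell-state association.

# The two-state (telegraph) model

The promoter toggles between an inactive and an active state with
activation rate $k_{on}$ (the burst frequency) and inactivation rate
$k_{off}$; while active it produces RNA at rate $k_{syn}$. All rates are
expressed in units of the RNA degradation rate, the natural timescale of
the stationary process. Two derived quantities summarise the regime:

* burst size $= k_{syn} / k_{off}$ — the mean number of molecules made per
  active period;
* mean expression $= k_{syn}\, k_{on} / (k_{on} + k_{off})$.

At steady state the molecule count of one allele follows the Beta-Poisson
mixture
$$ X \mid p \sim \mathrm{Poisson}(k_{syn}\, p), \qquad
   p \sim \mathrm{Beta}(k_{on}, k_{off}), $$
which is the distribution `sample_beta_poisson()` draws from and
`beta_poisson_logpmf()` evaluates.

## Evaluating the likelihood

The pmf involves the confluent hypergeometric function:
$P(x) = \frac{k_{syn}^x}{x!}\frac{B(k_{on}+x,\,k_{off})}{B(k_{on},k_{off})}
M(k_{on}+x,\ k_{on}+k_{off}+x,\ -k_{syn})$. Evaluated directly this series
alternates and cancels catastrophically. We instead apply Kummer's
transformation $M(a, c, -z) = e^{-z} M(c - a, c, z)$, after which every
series term is positive and the sum is evaluated in C++ with periodic
rescaling, making the result exact to machine precision over the entire
admissible parameter range (verified against an independent
adaptive-quadrature oracle to well below $10^{-8}$ absolute probability).
We chose this closed-form series over fixed-node Gauss-Jacobi quadrature
because it has no resolution parameter to tune: quadrature with a fixed
node count loses accuracy when $k_{syn}$ or the observed count is large,
precisely the regime where genes are best measured.

## Maximum-likelihood fitting

`fit_two_state()` maximises the summed log-pmf over
$\log_{10}$-transformed parameters with a bounded quasi-Newton method
(L-BFGS-B). Bounds are $k_{on}, k_{off} \in [10^{-3}, 10^3]$ and
$k_{syn} \in [10^{-2}, 10^4]$; starts are the deterministic grid
$\{0.1, 1, 10\}^3$ plus a closed-form method-of-moments start obtained by
inverting the first three factorial moments
$E[X^{(k)}] = k_{syn}^k (k_{on})_k / (k_{on}+k_{off})_k$. Genes with fewer
than five expressing cells are flagged degenerate and never fitted. Cells
with molecules but no allele-informative reads are *missing* for the
allele in question and are excluded; cells with zero molecules are true
zeros and kept — dropping them would bias $k_{on}$ upward.

## Bootstrap confidence intervals

Profile likelihoods are replaced by a cell-level bootstrap: resample cells
with replacement, refit each replicate starting from a log-uniform random
point within the bounds (so that the replicate can escape the original
optimum's basin), and take the 2.5/97.5 percentiles. Because a single
random start occasionally terminates in a poor local optimum — which would
inflate the intervals with optimizer noise rather than sampling noise —
each replicate also tries its own moment-based start and keeps the better
optimum. A fit is flagged unstable when more than 20% of replicates fail
to converge.

## Post-inference filters

Downstream analyses only use fits with: at least 1 molecule in at least 5
cells; burst size strictly inside $(0.2, 50)$; burst frequency inside
$(0.01, 30)$; mean expression inside $(0.01, 100)$; and a bootstrap CI
width ratio $\mathrm{CI}_{high}/\mathrm{CI}_{low} < 10^{1.5}$ for both
size and frequency. These windows exclude the boundary regimes where the
telegraph parameters are weakly identified.

## Likelihood-ratio test

To test whether one burst parameter differs between two conditions,
`lrt_kinetics()` compares the free model (all three rates per sample) to a
constrained model sharing only the tested parameter — burst frequency, or
burst size parameterised as shared $s$ with $k_{syn,i} = s\,k_{off,i}$ —
while the remaining rates stay sample-specific. Which nuisance parameters
the null shares is a genuine design choice; sharing only the tested
parameter makes the test sensitive to that parameter alone.
$\lambda_{LR} = -2[\ell(\theta_0) - \ell(\hat\theta)]$ is referred to
$\chi^2_1$; the decision thresholds are 3.84 (one-sided) and, by the
convention adopted here, $7.68 = 2 \times 3.84$ (two-sided). Note that
7.68 is **not** the $\chi^2_1$ 0.975 quantile (5.02); we keep the doubled
threshold as the package's convention and additionally report the exact
$\chi^2_1$ survival p-value so users can apply either rule. The effect
size is $\hat\theta = \log_2$ of the parameter ratio.

## Absolute timescales

Fitted burst frequencies are per RNA lifetime. With a measured half-life,
$\lambda = \ln 2 / t_{1/2}$ per hour and the mean duration between two
bursts of the same allele is $1/(k_{on}\lambda)$
(`burst_duration_hours()`).

# Allele-level quantification and QC

Total UMIs are distributed to alleles in proportion to allele-informative
read counts; the CAST share is rounded half-to-even (a deterministic rule
the data do not dictate — any unbiased rounding would do) and the
remainder goes to C57 so totals are conserved exactly. Cell QC presets
carry fixed per-library-type thresholds (reads, genes detected,
allelic balance within $(-0.10, 0.10)$, imprinted-X fraction at most 20%).
The per-cell "allelic balance" aggregate is defined here as the mean over
autosomal non-imprinted genes of the per-gene allelic imbalance
$\mathrm{AI} = \mathrm{CAST}/(\mathrm{CAST}+\mathrm{C57}) - 0.5$; the mean
is this package's documented choice among the possible summaries of that
per-cell distribution.

# Promoter architecture

Coordinates are internally 0-based half-open; BED input is used as-is and
GFF3 is shifted on read. The TSS is `start` on `+` and `end - 1` on `-`.
Locus classes: divergent (no overlap, opposite strands, TSSs within
500 bp), convergent (overlap, TSSs within 2 kb), intergenic (no overlap
with any expressed gene, bodies at least 4 kb apart) and separated
transcriptional units (TSS at least 4 kb from any expressed TSS), with
ties resolved in that order. Requiring opposite strands for "divergent" is
an assumption this package makes explicit. Promoter-pair analyses contrast
divergent promoters (partner TSS within 500 bp) with unidirectional ones
(nearest TSS at least 10 kb); the 500 bp/4 kb structure can be rediscovered
from data with `expression_vs_tss_distance()` (rolling median, window 51
by default, 31 for pair-level figures).

# Cell-to-cell variability

$CV^2$ is the sample variance (denominator $n-1$) over the squared mean,
computed over all QC-passing cells including zeros; both are conventions
this package states explicitly. Each lncRNA is matched to the ten protein-coding genes closest
in mean expression (with replacement across lncRNAs; ties broken by gene
id for determinism). The permutation test samples one matched mRNA per
lncRNA, $n = 10{,}000$ times, and reports the frequency with which the
sampled median $CV^2$ strictly exceeds the observed lncRNA median; the
strict inequality is deliberate, and the degenerate all-tied case
(where it forces $p = 0$) is flagged. Rank fractions compare each lncRNA
against 100 matched mRNAs, 50 of higher and 50 of lower mean. The
subsampling power analysis reruns the permutation test 100 times per
subsample size and reports how often the lncRNA median exceeded the
sampled median at the 50% and 95% criteria.

# RNA decay

Time-course expression is first normalised per gene to the untreated
$t_0$ condition, then per time point by a control-gene factor: the median
over control genes (known half-lives strictly between 1 and 8 h; controls
shorter than 2 h excluded from the 7 h and 10 h points) of observed over
expected $e^{-k_{ctrl} t}$. The exponential $y = a e^{-kt}$ is fitted by
nonlinear least squares in the original scale — not log scale, which would
distort the error weighting near zero — initialised from the log-linear
slope. Genes pass with $t_{1/2} < 10$ h (and, downstream, burst duration
under 72 h). The default time points $\{0, 2, 4, 7, 10\}$ h are a package
choice; only the 7 h and 10 h points are fixed by the control-exclusion
rule.

# Cis-interaction discovery

Eligible genes have at least 3 allele-informative reads in at least 20
cells, are autosomal, non-imprinted and of an allowed biotype. Candidate
pairs are all lncRNA-mRNA pairs with TSSs within 500 kb.

*Population route.* The pair score is
$\mathrm{AI}_{lnc} + \mathrm{AI}_{mRNA} - |\mathrm{AI}_{lnc} -
\mathrm{AI}_{mRNA}|$; the difference term is interpreted as the absolute
difference, the only reading under which the score rewards coordinated
skew. The null moves each lncRNA to 1,000 random mRNA positions (drawn
once, shared by all lncRNAs, each required to have at least two eligible
genes within the window) and re-pairs it with every eligible mRNA in the
window; $p$ is the fraction of random pairs scoring at least the real
score, with no pseudocount — the attainable minimum $1/n_{random}$ is
reported alongside.

*Single-cell route.* Per allele, a gene is "detected" in a cell with at
least 3 allele-informative reads; each pair's 2x2 detection table is
tested with a two-sided Fisher's exact test, BH-adjusted across pairs. The
permutation background repeats this for random placements, and a pair is
significant when $p_{adj} < 0.01$ *and* fewer than 1% of its lncRNA's
background $p_{adj}$ fall below it. Calls are made separately for CAST and
C57. Detection co-occurrence per allele is the adopted contingency
structure; an allele-choice table would be the main alternative reading.

*Ranking.* The raw score is CAST-signed, which makes strong C57-C57
coordination rank negative; for ranking, pairs are first aligned to the
lncRNA's dominant allele so same-allele coordination is positive
regardless of which parental allele carries it. This is a documented
deviation that removes the asymmetry.

# Cell-state association

Counts are normalised as $\ln(1 + 10^4\, c/\mathrm{total})$. Variable
genes are ranked by the variance of trend-standardised values (local
regression of log variance on log mean; values clipped at $\sqrt{n}$) —
the procedure is defined in-package rather than delegated so that its
behaviour is part of the tested surface. The cell-cycle trajectory is a
principal curve fitted in the top-3 PC space by the classic
projection-smoothing iteration (smoothing splines per coordinate,
projection onto the resulting polyline, convergence on the relative change
in total projection distance, tolerance $10^{-3}$); no installed package
provides this primitive, so it is implemented here and tested against
constructed geometries. Phases are assigned from rolling means (window 15
cells) of the four canonical marker sets (*Gas1* G0, *Ccnd1* G1, *Ccne2*
G1/S, *Ccnb1* G2/M): each cell takes the phase of its dominant smoothed
marker, ties resolving to the earlier phase in cycle order. How curve
positions map to phase boundaries is not fully specified anywhere; the
dominant-marker segmentation is this package's explicit convention.
Phase-specific genes come from a per-gene one-way ANOVA (BH-adjusted,
significance at 0.01) with fold induction defined as top-phase mean over
the mean of the remaining phases. The apoptosis procedure restricts to G1
cells, fits the $CV^2$-mean trend with a Gamma GLM on reciprocal mean over
all genes (not only programme genes — an open choice resolved here), ranks
programme genes by observed/fitted $CV^2$, and clusters cells with
k-medoids ($k = 3$) on the leading PCs of the top 75 genes. Differential
expression between clusters uses a rank-sum test with BH adjustment, a
documented lightweight alternative to heavier model-based single-cell DE
machinery. Guilt-by-association retains genes whose Spearman
correlation with the target (double-zero cells excluded per pair) reaches
$|\rho| \ge 0.1$ with sign consistent with the knockdown direction.

# The synthetic-data generator

Every statistical structure the pipeline assumes is emulated with known
ground truth:

* **Kinetic priors.** True rates are log-normal: $k_{on} \sim
  \mathrm{LN}(\log 2, 0.5)$, burst size $\sim \mathrm{LN}(\log 4, 0.5)$,
  $k_{off} \sim \mathrm{LN}(\log 8, 0.4)$ for the mRNA-like class, chosen
  so the post-inference filter windows retain well over 90% of genes. The
  lncRNA-like class multiplies $k_{on}$ by 0.25 and burst size by 0.5 —
  the four-fold frequency and two-fold size shift the analyses are
  designed to detect. The source data constrain only these class ratios,
  not the prior family; log-normal is a modelling convention.
* **Allelic structure.** Each allele is simulated independently from the
  gene's kinetics; allele-informative reads arise from per-molecule
  binomial SNP capture (probability 1 by default, lowered to study
  missing-assignment dropout). Entries with molecules but no captured
  read are missing, exactly as in real data.
* **Cis pairs.** Coordination is realised through a shared latent state:
  with per-cell, per-allele probability $\rho$ the lncRNA and mRNA use the
  same Beta quantile for their active fraction, which preserves each
  gene's marginal kinetics exactly while coupling detection. The
  shared-quantile construction is the generator's explicit mechanistic
  model of the coordination. A common allelic
  imbalance can be imposed by scaling allele-specific $k_{syn}$.
* **Cell cycle.** Cells sit on a circular coordinate cut into phase arcs
  (G0 0.2, G1 0.4, G1/S 0.2, G2/M 0.2 by default); marker means follow
  wrapped raised-cosine bumps whose supports overlap so neighbouring
  markers cross exactly at phase boundaries — real cycle regulators
  overlap in time, and a generator with disjoint marker support would
  create unidentifiable dead zones no method could order.
* **Decay.** $a\,e^{-\lambda t}$ with per-time-point multiplicative
  distortions and log-normal noise; control genes are generated with
  half-lives strictly inside (1, 8) h.

What the generator does **not** emulate: transcript-length or GC biases,
doublets, batch effects, amplification noise beyond binomial capture, or
cell-cycle coupling of burst kinetics. Tests passing on this generator
therefore show the machinery is correct under the stated model, not that
the model captures every property of real libraries.

# Problem sizes in the test suite

The dataset-scale checks use sizes chosen to make Monte-Carlo error small
relative to the tested margins while staying comfortably runnable on one
core: 100 genes at 1,000 cells with 200 bootstrap replicates for CI
coverage; 300 null and 100 alternative replicates for LRT calibration and
power (300 and 1,000 cells per sample); 150 inflated lncRNAs against 600
mRNAs for the variability tests (1,000 permutations); 40 planted cis pairs
at 400 cells with 200 random placements; and 300-cell state datasets.
Bootstrap counts and placement numbers are scaled-down versions of the
full-scale defaults (1,000 each), which remain the package defaults for
real analyses.

# Known limitations

* The telegraph model assumes steady state and a single degradation rate
  per gene; cell-cycle-stratified kinetics are out of scope.
* Burst-size inference degrades without UMIs; the generator models UMI
  counts only.
* The principal curve is open: on genuinely circular structure one cut
  region of the cycle is ordered arbitrarily, which phase labelling
  absorbs because labels come from markers, not from the coordinate
  itself.
* Permutation p-values are lower-bounded by the background size; pairs at
  the bound should be interpreted with the reported attainable minimum in
  mind.
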