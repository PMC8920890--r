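#' Two-state (telegraph) model kinetic parameters
#'
#' Bundles the three rates of the two-state model of transcription: the
#' promoter switches ON at rate `k_on` and OFF at rate `k_off`, and while ON
#' transcribes at rate `k_syn`. All rates are expressed in units of the mRNA
#' degradation rate, the natural timescale of the steady-state distribution.
#' Burst size (`k_syn / k_off`) and the steady-state mean
#' (`k_syn * k_on / (k_on + k_off)`) are derived quantities, never stored.
#'
#' @param k_on promoter activation rate (burst frequency), > 0.
#' @param k_off promoter inactivation rate, > 0.
#' @param k_syn transcription rate while ON, > 0.
#' @return An object of class `two_state_kinetics`.
#' @examples
#' kin <- two_state_kinetics(k_on = 1, k_off = 9, k_syn = 100)
#' burst_size(kin)   # 100/9
#' mean_expr(kin)    # 10
#' @export
two_state_kinetics <- function(k_on, k_off, k_syn) {
  if (!all(is.finite(c(k_on, k_off, k_syn))) ||
      any(c(k_on, k_off, k_syn) <= 0)) {
    stop("all kinetic rates must be strictly positive and finite")
  }
  structure(list(k_on = k_on, k_off = k_off, k_syn = k_syn),
            class = "two_state_kinetics")
}

#' @rdname two_state_kinetics
#' @param kin a `two_state_kinetics` object.
#' @export
burst_size <- function(kin) kin$k_syn / kin$k_off

#' @rdname two_state_kinetics
#' @export
burst_frequency <- function(kin) kin$k_on

#' @rdname two_state_kinetics
#' @export
mean_expr <- function(kin) kin$k_syn * kin$k_on / (kin$k_on + kin$k_off)

#' @export
print.two_state_kinetics <- function(x, ...) {
  cat(sprintf(
    "Two-state kinetics: k_on = %.4g, k_off = %.4g, k_syn = %.4g\n",
    x$k_on, x$k_off, x$k_syn))
  cat(sprintf("  burst size = %.4g, mean = %.4g\n",
              burst_size(x), mean_expr(x)))
  invisible(x)
}

.as_kin <- function(kin) {
  if (inherits(kin, "two_state_kinetics")) return(kin)
  if (is.numeric(kin) && length(kin) == 3) {
    return(two_state_kinetics(kin[[1]], kin[[2]], kin[[3]]))
  }
  stop("`kin` must be a two_state_kinetics object or numeric length-3 vector")
}

#' Sample steady-state RNA counts from the two-state model
#'
#' Draws counts from the Beta-Poisson mixture: `p ~ Beta(k_on, k_off)`,
#' `x ~ Poisson(k_syn * p)`. This is the steady-state distribution of the
#' telegraph model and the shared sampler for all simulation-based checks.
#'
#' @param kin kinetics (see [two_state_kinetics()]).
#' @param n_cells number of cells (draws), >= 1.
#' @param seed optional integer seed for reproducibility.
#' @return Integer vector of length `n_cells`.
#' @export
sample_beta_poisson <- function(kin, n_cells, seed = NULL) {
  kin <- .as_kin(kin)
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1) {
    stop("`n_cells` must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- rbeta(n_cells, kin$k_on, kin$k_off)
  rpois(n_cells, kin$k_syn * p)
}

#' Beta-Poisson log probability mass function
#'
#' Evaluates the log-probability of observing `x` RNA molecules under the
#' steady state of the two-state model,
#' `log integral_0^1 Poisson(x; k_syn p) Beta(p; k_on, k_off) dp`.
#' The integral is computed exactly through the Kummer confluent
#' hypergeometric series after the transformation that renders every term
#' positive, so the evaluation is stable across the full admissible
#' parameter range (see the methods vignette).
#'
#' @param x non-negative integer count vector.
#' @param kin kinetics (see [two_state_kinetics()]).
#' @return Numeric vector of log-probabilities.
#' @export
beta_poisson_logpmf <- function(x, kin) {
  kin <- .as_kin(kin)
  if (any(x < 0) || any(x != floor(x))) {
    stop("`x` must contain non-negative integers")
  }
  .bp_logpmf_cpp(as.integer(x), kin$k_on, kin$k_off, kin$k_syn)
}

# Negative log-likelihood of counts under the model, compressed to unique
# counts for speed. Used by the optimiser and the LRT.
.bp_nll_counts <- function(counts) {
  tab <- table(counts)
  ux <- as.integer(names(tab))
  w <- as.numeric(tab)
  function(k_on, k_off, k_syn) .bp_nll_cpp(ux, w, k_on, k_off, k_syn)
}
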