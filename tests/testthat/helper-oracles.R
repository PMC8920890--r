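# Independent oracles used across tests.

# Beta-Poisson pmf by adaptive numerical integration (independent of the
# package's series evaluation). The domain is split so each piece has at
# most one (integrable) Beta endpoint singularity, which the adaptive
# quadrature's endpoint transformations handle accurately.
bp_pmf_oracle <- function(x, k_on, k_off, k_syn) {
  a <- k_on; b <- k_off
  logB <- lbeta(a, b)
  # split at p = 0.5 and substitute p = t^(1/a) on the left and
  # 1 - p = s^(1/b) on the right: the Jacobian cancels the endpoint
  # singularity of the Beta density exactly, leaving bounded integrands
  # the substitutions are applied only where a singularity exists
  left <- if (a < 1) {
    function(t) {   # p = t^(1/a), valid singular endpoint at p = 0
      p <- t^(1 / a)
      dpois(x, k_syn * p) * exp((b - 1) * log1p(-p) - logB) / a
    }
  } else {
    function(p) dpois(x, k_syn * p) * dbeta(p, a, b)
  }
  right <- if (b < 1) {
    function(s) {   # 1 - p = s^(1/b), singular endpoint at p = 1
      p <- 1 - s^(1 / b)
      dpois(x, k_syn * p) * exp((a - 1) * log(p) - logB) / b
    }
  } else {
    function(p) dpois(x, k_syn * p) * dbeta(p, a, b)
  }
  q <- function(f, lo, hi) {
    if (hi <= lo) return(0)
    integrate(f, lo, hi, rel.tol = 1e-11, abs.tol = 1e-15,
              subdivisions = 5000L)$value
  }
  # resolve the Poisson spike by splitting each piece at its image
  peak <- min(max(x / max(k_syn, 1e-12), 0), 1)
  cuts_p <- function(grid) sort(unique(pmin(pmax(grid, 0), 0.5)))
  grid_l <- cuts_p(c(0, peak / 2, peak, 2 * peak, 0.5))
  grid_r <- cuts_p(1 - c(0.5, peak, (1 + peak) / 2, 1))
  cuts_l <- if (a < 1) grid_l^a else grid_l
  cuts_r <- grid_r^b
  left_val <- sum(vapply(seq_len(length(cuts_l) - 1),
                         function(i) q(left, cuts_l[i], cuts_l[i + 1]),
                         numeric(1)))
  right_val <- if (b < 1) {
    sum(vapply(seq_len(length(cuts_r) - 1),
               function(i) q(right, cuts_r[i], cuts_r[i + 1]), numeric(1)))
  } else {
    rp <- sort(unique(pmin(pmax(c(0.5, peak, (1 + peak) / 2, 1), 0.5), 1)))
    sum(vapply(seq_len(length(rp) - 1),
               function(i) q(right, rp[i], rp[i + 1]), numeric(1)))
  }
  left_val + right_val
}

# Two-sided Fisher p by brute-force enumeration over all tables with the
# observed margins: sum the hypergeometric probabilities of every table no
# more probable than the observed one.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row-1 margin
  n <- sum(tab[2, ])
  s <- sum(tab[, 1])   # column-1 margin
  support <- max(0, s - n):min(m, s)
  probs <- dhyper(support, m, n, s)
  p_obs <- dhyper(a, m, n, s)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (max_idx - expected)
}

# Maximum |Spearman correlation| between a linear coordinate and a circular
# one over all rotations and reflections of the circle.
circular_rank_cor <- function(linear, theta) {
  best <- 0
  for (shift in seq(0, 0.95, by = 0.05)) {
    rotated <- (theta + shift) %% 1
    for (dir in c(1, -1)) {
      r <- suppressWarnings(cor(linear, dir * rotated, method = "spearman"))
      best <- max(best, abs(r))
    }
  }
  best
}
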