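# parse time in hours from column names like "t0", "t2.5"
.parse_times <- function(x) {
  t <- suppressWarnings(as.numeric(sub("^t", "", colnames(x))))
  if (anyNA(t)) stop("cannot parse time points from column names")
  t
}

#' Normalise a decay time course to the untreated condition
#'
#' Divides every gene's series by its own value at `t = 0` so the untreated
#' condition becomes 1. Genes with a zero (or missing) `t0` value are
#' dropped with a warning. Applying the operation twice is a no-op.
#'
#' @param expression gene x time matrix; time points taken from column names
#'   (`t0`, `t2`, ...) unless `time` is given.
#' @param time optional numeric time vector (hours), one entry per column,
#'   containing exactly one 0.
#' @return Matrix of relative expression with the same shape (minus dropped
#'   genes).
#' @export
normalize_to_t0 <- function(expression, time = NULL) {
  if (is.null(time)) time <- .parse_times(expression)
  stopifnot(length(time) == ncol(expression))
  i0 <- which(time == 0)
  if (length(i0) != 1) stop("exactly one t = 0 column required")
  t0 <- expression[, i0]
  bad <- !is.finite(t0) | t0 <= 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) dropped: zero expression at t0")
    expression <- expression[!bad, , drop = FALSE]
    t0 <- t0[!bad]
  }
  sweep(expression, 1, t0, `/`)
}

#' Control-gene normalisation factors for a decay time course
#'
#' For each time point, the factor is the median over eligible control genes
#' of observed / expected relative expression, where the expected value is
#' `exp(-k_control * t)` from the controls' known half-lives. Controls must
#' have `1 h < t_half < 8 h`; controls with `t_half < 2 h` are excluded from
#' time points at or beyond `exclude_short_after` hours (default 7 h), where
#' their signal is dominated by noise.
#'
#' @param rel_expression t0-normalised gene x time matrix (see
#'   [normalize_to_t0()]).
#' @param controls data frame with `gene_id` and known `t_half` (hours).
#' @param time optional time vector (hours; default from column names).
#' @param min_controls minimum eligible controls per time point (error
#'   below 3).
#' @param exclude_short_after hours from which short-lived controls are
#'   excluded.
#' @return Named numeric vector of factors, one per time point.
#' @export
normalization_factor <- function(rel_expression, controls, time = NULL,
                                 min_controls = 3, exclude_short_after = 7) {
  if (is.null(time)) time <- .parse_times(rel_expression)
  controls <- controls[controls$t_half > 1 & controls$t_half < 8, ,
                       drop = FALSE]
  controls <- controls[controls$gene_id %in% rownames(rel_expression), ,
                       drop = FALSE]
  k <- log(2) / controls$t_half
  factors <- setNames(rep(1, length(time)), colnames(rel_expression))
  for (j in seq_along(time)) {
    use <- rep(TRUE, nrow(controls))
    if (time[j] >= exclude_short_after) use <- controls$t_half >= 2
    if (sum(use) < min_controls) {
      stop("fewer than ", min_controls, " eligible control genes at t = ",
           time[j])
    }
    expected <- exp(-k[use] * time[j])
    observed <- rel_expression[controls$gene_id[use], j]
    factors[j] <- median(observed / expected)
  }
  factors
}

#' @rdname normalization_factor
#' @param factors output of `normalization_factor()`.
#' @return For `apply_normalization_factor()`: the matrix with each column
#'   divided by its factor.
#' @export
apply_normalization_factor <- function(rel_expression, factors) {
  sweep(rel_expression, 2, factors, `/`)
}

#' Fit an exponential decay curve to one gene's series
#'
#' Nonlinear least squares of `y = a * exp(-k * t)` in the original (not
#' log) space, initialised from the log-linear regression slope; the
#' half-life is `t_half = ln(2) / k`. A gene passes when the fit converged
#' and `t_half < max_t_half` (default 10 h).
#'
#' @param y relative expression values.
#' @param time hours, same length as `y`, at least 3 points.
#' @param max_t_half pass threshold in hours.
#' @return list of class `decay_fit`: `a`, `k` (per hour), `t_half`,
#'   `residual` (RSS), `converged`, `pass`, `fail_reasons`.
#' @export
fit_decay <- function(y, time, max_t_half = 10) {
  stopifnot(length(y) == length(time))
  if (length(y) < 3) stop("at least three time points required")
  eps <- 1e-12
  ll <- stats::lm(log(pmax(y, eps)) ~ time)
  k0 <- max(-unname(coef(ll)[2]), 1e-6)
  a0 <- exp(unname(coef(ll)[1]))
  fit <- tryCatch(
    nls(y ~ a * exp(-k * time), start = list(a = a0, k = k0),
        algorithm = "port", lower = c(a = 1e-12, k = 1e-9),
        control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    a <- a0; k <- k0; converged <- FALSE
    residual <- sum((y - a * exp(-k * time))^2)
  } else {
    p <- coef(fit)
    a <- unname(p["a"]); k <- unname(p["k"])
    converged <- fit$convInfo$isConv
    residual <- sum(stats::resid(fit)^2)
  }
  t_half <- log(2) / k
  reasons <- character()
  if (!converged) reasons <- c(reasons, "non_convergence")
  if (!(t_half < max_t_half)) reasons <- c(reasons, "t_half")
  structure(list(a = a, k = k, t_half = t_half, residual = residual,
                 converged = converged, pass = length(reasons) == 0,
                 fail_reasons = reasons),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential decay fit: a = %.4g, k = %.4g /h, t1/2 = %.3g h (%s)\n",
    x$a, x$k, x$t_half,
    if (x$pass) "pass" else paste("fail:", paste(x$fail_reasons,
                                                 collapse = ","))))
  invisible(x)
}

#' Fit decay curves for every gene in a normalised time course
#'
#' @param expression normalised gene x time matrix.
#' @param time optional time vector (default from column names).
#' @inheritParams fit_decay
#' @return data frame: `gene_id`, `a`, `k`, `lambda` (alias of `k`),
#'   `t_half`, `residual`, `converged`, `pass`.
#' @export
fit_decay_table <- function(expression, time = NULL, max_t_half = 10) {
  if (is.null(time)) time <- .parse_times(expression)
  rows <- lapply(rownames(expression), function(g) {
    f <- fit_decay(expression[g, ], time, max_t_half)
    data.frame(gene_id = g, a = f$a, k = f$k, lambda = f$k,
               t_half = f$t_half, residual = f$residual,
               converged = f$converged, pass = f$pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
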