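# Growth kinetics: specific growth rates from paired counts, logistic
# growth fits to abundance series, and weekly binning of replicate
# trajectories.

#' Specific growth rate from paired cell counts
#'
#' `mu = (ln N_t1 - ln N_t0) / dt`, in day^-1. Negative values indicate
#' population decline; the formula is sign-free.
#'
#' @param n_t0 Cell density at the start of the interval (cells mL^-1).
#' @param n_t1 Cell density at the end of the interval.
#' @param dt Interval length in days.
#' @return Specific growth rate(s), day^-1.
#' @examples
#' specific_growth_rate(100, 800, 3) # ln(8)/3
#' @export
specific_growth_rate <- function(n_t0, n_t1, dt) {
  if (any(n_t0 <= 0) || any(n_t1 <= 0)) stop_input("cell densities must be positive")
  if (any(dt <= 0)) stop_input("'dt' must be positive")
  (log(n_t1) - log(n_t0)) / dt
}

#' Logistic growth curve
#'
#' `N(t) = K / (1 + ((K - N0)/N0) * exp(-r t))`. Note the negative
#' exponent: with it, `N(0) = N0` and `N(t)` approaches the carrying
#' capacity `K` for `r > 0`. The variant with a positive exponent (which
#' decays towards `N0` for growing populations and appears in some
#' transcriptions of the model) is available via `sign_convention =
#' "positive_exponent"` for comparison.
#'
#' @param t Time(s) in days.
#' @param k Carrying capacity (cells mL^-1).
#' @param r Maximum growth rate (day^-1).
#' @param n0 Initial density (cells mL^-1).
#' @param sign_convention `"growth"` (default, negative exponent) or
#'   `"positive_exponent"`.
#' @return Cell densities.
#' @export
logistic_growth <- function(t, k, r, n0, sign_convention = c("growth", "positive_exponent")) {
  sign_convention <- match.arg(sign_convention)
  s <- if (sign_convention == "growth") -1 else 1
  k / (1 + ((k - n0) / n0) * exp(s * r * t))
}

#' Fit a logistic growth curve to an abundance time series
#'
#' Least squares on log counts (cytometry counts carry multiplicative
#' error), with multi-start initialisation: `N0` from the first
#' observation, `K` from the maximum, `r` from the early-phase log-linear
#' slope. Non-convergence is flagged, not raised.
#'
#' @param t Times in days, non-negative and strictly increasing.
#' @param n Cell densities (cells mL^-1), positive.
#' @return A list of class `logistic_fit` with `k`, `r`, `n0`, `rss`
#'   (on the log scale), `n_obs`, `converged`, and `plateau_observed`
#'   (`FALSE` when the series is truncated before the plateau, in which
#'   case `K` is poorly constrained).
#' @export
fit_logistic <- function(t, n) {
  if (length(t) != length(n)) stop_input("'t' and 'n' lengths differ")
  if (any(n <= 0)) stop_input("cell densities must be positive")
  if (any(diff(t) <= 0)) stop_input("times must be strictly increasing")
  if (length(unique(t)) < 4) stop_input("need at least 4 distinct time points")

  y <- log(n)
  if (sd(y) < 1e-12) {
    warning("flat series: r is not estimable, returning r = 0")
    return(structure(list(k = mean(n), r = 0, n0 = mean(n), rss = sum((y - mean(y))^2),
                          n_obs = length(n), converged = FALSE,
                          plateau_observed = FALSE),
                     class = "logistic_fit"))
  }

  obj <- function(par) {
    # par = log(K), log(r), log(N0)
    mu <- log(logistic_growth(t, exp(par[1]), exp(par[2]), exp(par[3])))
    sum((y - mu)^2)
  }
  n0_0 <- n[1]
  k_0 <- max(n) * c(1, 1.5, 4)
  early <- seq_len(max(2, min(4, length(t))))
  r_0 <- max(coef(lm(y[early] ~ t[early]))[2], 0.05)
  best <- NULL
  for (k0 in k_0) for (rf in c(1, 0.5, 2)) {
    fit <- try(optim(log(c(k0, r_0 * rf, n0_0)), obj, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-15)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  converged <- !is.null(best) && best$convergence == 0
  if (is.null(best)) {
    return(structure(list(k = NA_real_, r = NA_real_, n0 = NA_real_, rss = NA_real_,
                          n_obs = length(n), converged = FALSE,
                          plateau_observed = FALSE),
                     class = "logistic_fit"))
  }
  k_hat <- exp(best$par[1]); r_hat <- exp(best$par[2]); n0_hat <- exp(best$par[3])
  # plateau observed if the last count is within 20% of the fitted K
  plateau <- max(n) > 0.8 * k_hat
  structure(list(k = k_hat, r = r_hat, n0 = n0_hat, rss = best$value,
                 n_obs = length(n), converged = converged,
                 plateau_observed = plateau),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic growth fit: K = %.4g, r = %.4g day^-1, N0 = %.4g (RSS %.4g, n = %d)%s%s\n",
              x$k, x$r, x$n0, x$rss, x$n_obs,
              if (!x$converged) " [not converged]" else "",
              if (!x$plateau_observed) " [plateau not observed: K uncertain]" else ""))
  invisible(x)
}

#' Bin growth-rate trajectories into weekly summaries
#'
#' Groups observations into half-open time bins `[0, w), [w, 2w), ...` per
#' treatment and summarises each bin with the median, quartiles and Tukey
#' whiskers (the most extreme observation within 1.5 x IQR of the nearer
#' quartile). Empty bins are omitted.
#'
#' @param time_days Observation times (days).
#' @param value Growth-rate estimates (day^-1).
#' @param treatment Treatment labels, recycled if length 1.
#' @param bin_width Bin width in days (default 7).
#' @return A data.frame with one row per (treatment, bin): `treatment`,
#'   `bin` (1-based index), `bin_start`, `n`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`.
#' @export
bin_growth_trajectories <- function(time_days, value, treatment = "all", bin_width = 7) {
  if (bin_width <= 0) stop_input("'bin_width' must be positive")
  if (length(treatment) == 1) treatment <- rep(treatment, length(value))
  if (length(time_days) != length(value) || length(treatment) != length(value)) {
    stop_input("input lengths differ")
  }
  bin <- floor(time_days / bin_width) + 1L
  key <- split(seq_along(value), list(treatment = treatment, bin = bin), drop = TRUE)
  rows <- lapply(key, function(idx) {
    v <- value[idx]
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    in_lo <- v[v >= q[1] - 1.5 * iqr]
    in_hi <- v[v <= q[3] + 1.5 * iqr]
    data.frame(treatment = treatment[idx[1]], bin = bin[idx[1]],
               bin_start = (bin[idx[1]] - 1L) * bin_width,
               n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               whisker_low = min(in_lo), whisker_high = max(in_hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$treatment, out$bin), ]
  rownames(out) <- NULL
  out
}
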