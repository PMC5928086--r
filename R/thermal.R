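# Modified Sharpe-Schoolfield thermal performance curves.
#
# The model describes the log rate of a metabolic process (growth, gross
# photosynthesis, respiration) as a Boltzmann rise below the optimum plus a
# single high-temperature enzyme-inactivation term:
#
#   ln b(T) = Ea (1/(k Tc) - 1/(k T)) + ln b(Tc)
#             - ln(1 + exp(Eh (1/(k Th) - 1/(k T))))
#
# with k the Boltzmann constant (eV/K), Tc an arbitrary reference
# temperature at which no inactivation is felt, Ea the activation energy
# (eV), Eh the inactivation energy (eV) and Th the temperature (K) at which
# half of the rate-limiting enzyme pool is inactivated. Low-temperature
# inactivation is deliberately excluded. With the Boltzmann (rather than
# Eyring) rise term the optimum has a closed form (see compute_topt).

#' Construct a Sharpe-Schoolfield parameter set
#'
#' @param ln_b_tc Log rate at the reference temperature (log day^-1 or
#'   log ugC ugC^-1 day^-1).
#' @param ea Activation energy in eV; must be positive.
#' @param eh High-temperature inactivation energy in eV; must exceed `ea`.
#' @param th Temperature (K) at which half the enzyme pool is inactivated.
#' @param tc Reference temperature in K. Defaults to 291.15 K (18 degrees C).
#' @return An object of class `ss_params`.
#' @examples
#' p <- ss_params(ln_b_tc = 0, ea = 1.08, eh = 3.5, th = 303.15)
#' compute_topt(p$ea, p$eh, p$th)
#' @export
ss_params <- function(ln_b_tc, ea, eh, th, tc = 291.15) {
  if (!is.finite(ea) || ea <= 0) stop_input("'ea' must be a positive finite number")
  if (!is.finite(eh) || eh <= ea) stop_input("'eh' must be finite and exceed 'ea'")
  if (!is.finite(th) || th <= 0) stop_input("'th' must be a positive temperature in Kelvin")
  if (!is.finite(tc) || tc <= 0) stop_input("'tc' must be a positive temperature in Kelvin")
  structure(list(ln_b_tc = ln_b_tc, ea = ea, eh = eh, th = th, tc = tc),
            class = "ss_params")
}

#' @export
print.ss_params <- function(x, ...) {
  cat(sprintf(
    "Sharpe-Schoolfield parameters:\n  ln b(Tc) = %.4f  (Tc = %.2f K / %.2f C)\n  Ea = %.4f eV, Eh = %.4f eV, Th = %.2f K\n  T_opt = %.2f K (%.2f C)\n",
    x$ln_b_tc, x$tc, k_to_c(x$tc), x$ea, x$eh, x$th,
    compute_topt(x$ea, x$eh, x$th), k_to_c(compute_topt(x$ea, x$eh, x$th))))
  invisible(x)
}

#' Log metabolic rate under the modified Sharpe-Schoolfield model
#'
#' Evaluates `ln b(T)` at absolute temperature `temp_k`. The inactivation
#' term is evaluated with `log1p(exp(.))` switched to its linear asymptote
#' for large exponents, so extreme parameter draws do not overflow.
#'
#' @param temp_k Temperature(s) in Kelvin; must be positive.
#' @param params An [ss_params()] object.
#' @return Numeric vector of log rates.
#' @export
ss_log_rate <- function(temp_k, params) {
  stopifnot(inherits(params, "ss_params"))
  if (any(!is.finite(temp_k)) || any(temp_k <= 0)) {
    stop_input("temperatures must be positive and finite (Kelvin)")
  }
  k <- BOLTZMANN_EV
  rise <- params$ea * (1 / (k * params$tc) - 1 / (k * temp_k))
  inact_exp <- params$eh * (1 / (k * params$th) - 1 / (k * temp_k))
  rise + params$ln_b_tc - log1p_exp(inact_exp)
}

# log(1 + e^x) without overflow; for x > 35, log1p(e^x) == x to double
# precision.
log1p_exp <- function(x) {
  out <- x
  small <- x <= 35
  out[small] <- log1p(exp(x[small]))
  out
}

#' Closed-form optimum temperature of the thermal performance curve
#'
#' The Boltzmann-rise form of the model admits an explicit optimum:
#' `T_opt = Eh * Th / (Eh + k * Th * ln(Eh/Ea - 1))`.
#'
#' @param ea Activation energy (eV), positive.
#' @param eh Inactivation energy (eV), must exceed `ea`.
#' @param th Half-inactivation temperature (K).
#' @return Optimum temperature in Kelvin.
#' @examples
#' compute_topt(ea = 1.08, eh = 2.16, th = 303) # Eh = 2 Ea gives T_opt = Th
#' @export
compute_topt <- function(ea, eh, th) {
  if (any(ea <= 0) || any(eh <= ea)) {
    stop_input("compute_topt requires eh > ea > 0")
  }
  eh * th / (eh + BOLTZMANN_EV * th * log(eh / ea - 1))
}

#' Fit the modified Sharpe-Schoolfield model to rate observations
#'
#' Bounded nonlinear least squares on log rates, with multi-start
#' initialisation. Temperatures are supplied in degrees Celsius (the I/O
#' convention); all internal arithmetic is in Kelvin. `Eh > Ea` is enforced
#' by estimating the difference `Eh - Ea` on a positive bound.
#'
#' @param temp_c Assay temperatures in degrees Celsius.
#' @param rate Strictly positive rates (day^-1 or ugC ugC^-1 day^-1).
#' @param tc_c Reference temperature in degrees Celsius (default 18).
#' @param n_starts Number of multi-start initialisations (default 8).
#' @return An object of class `tpc_fit` with elements `params`
#'   ([ss_params()]), `topt` (K), `rss`, `n_obs`, `n_par`, `aicc`,
#'   `covariance` (may be `NULL` when the Hessian is singular),
#'   `converged`, and `identifiable` (`FALSE` when the data do not span
#'   the optimum, leaving `Eh`/`Th` unconstrained).
#' @export
fit_tpc <- function(temp_c, rate, tc_c = 18, n_starts = 8) {
  if (length(temp_c) != length(rate)) stop_input("'temp_c' and 'rate' lengths differ")
  keep <- is.finite(temp_c) & is.finite(rate) & rate > 0
  temp_c <- temp_c[keep]; rate <- rate[keep]
  if (length(rate) < 5) stop_input("need at least 5 positive rate observations")
  temp_k <- c_to_k(temp_c)
  tc <- c_to_k(tc_c)
  y <- log(rate)

  # identifiability: the decline limb must be observed
  t_at_max <- temp_k[which.max(y)]
  identifiable <- any(temp_k > t_at_max) && any(temp_k < t_at_max) &&
    length(unique(temp_k)) >= 5

  lo_th <- min(temp_k)
  hi_th <- max(temp_k) + 20
  obj <- function(par) {
    # penalise excursions outside the feasible box (Nelder-Mead polish
    # and finite-difference Hessians are unconstrained)
    if (par[2] <= 0 || par[3] <= 0 || par[4] <= 0 ||
        par[2] > 10 || par[3] > 30 || par[4] < lo_th - 5 || par[4] > hi_th + 5) {
      return(1e10)
    }
    p <- ss_params(par[1], par[2], par[2] + par[3], par[4], tc = tc)
    sum((y - ss_log_rate(temp_k, p))^2)
  }

  # starting grid: Ea from the rise-limb Boltzmann slope, Th near the
  # apparent optimum, Eh a multiple of Ea
  rise_idx <- temp_k <= t_at_max
  ea0 <- if (sum(rise_idx) >= 2) {
    sl <- coef(lm(y[rise_idx] ~ I(-1 / (BOLTZMANN_EV * temp_k[rise_idx]))))[2]
    min(max(as.numeric(sl), 0.2), 5)
  } else 0.6
  starts <- expand.grid(ea = c(ea0, ea0 * 2), deh = c(ea0, ea0 * 3),
                        th = c(t_at_max, min(t_at_max + 5, hi_th)))
  starts <- starts[seq_len(min(nrow(starts), n_starts)), , drop = FALSE]

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(mean(y), starts$ea[i], starts$deh[i], starts$th[i])
    fit <- try(optim(par0, obj, method = "L-BFGS-B",
                     lower = c(-Inf, 1e-4, 1e-4, lo_th),
                     upper = c(Inf, 10, 30, hi_th),
                     control = list(maxit = 500, factr = 1e4)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop_input("all optimisation starts failed")

  # polish with a derivative-free pass; L-BFGS-B occasionally stalls on
  # the flat Th/Eh ridge
  pol <- optim(best$par, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (pol$value < best$value) best <- pol

  par <- best$par
  params <- ss_params(par[1], par[2], par[2] + par[3], par[4], tc = tc)
  n <- length(y); p_n <- 4
  rss <- best$value
  covm <- tryCatch({
    h <- optimHess(par, obj)
    s2 <- rss / max(n - p_n, 1)
    v <- solve(h / 2) * s2
    dimnames(v) <- list(c("ln_b_tc", "ea", "deh", "th"),
                        c("ln_b_tc", "ea", "deh", "th"))
    v
  }, error = function(e) NULL)

  structure(list(
    params = params,
    topt = compute_topt(params$ea, params$eh, params$th),
    rss = rss, n_obs = n, n_par = p_n,
    aicc = aicc_from_rss(rss, n, p_n),
    covariance = covm,
    converged = is.finite(rss),
    identifiable = identifiable
  ), class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat("Thermal performance curve fit (modified Sharpe-Schoolfield)\n")
  cat(sprintf("  n = %d observations, RSS = %.4g, AICc = %.2f\n",
              x$n_obs, x$rss, x$aicc))
  cat(sprintf("  Ea = %.3f eV, Eh = %.3f eV, Th = %.2f K, ln b(Tc) = %.3f\n",
              x$params$ea, x$params$eh, x$params$th, x$params$ln_b_tc))
  cat(sprintf("  T_opt = %.2f K (%.2f C)%s\n", x$topt, k_to_c(x$topt),
              if (!x$identifiable) "  [Th/Eh unidentifiable: no decline limb]" else ""))
  invisible(x)
}

aicc_from_rss <- function(rss, n, p) {
  # least-squares AICc; undefined when the correction denominator vanishes
  if (n <= p + 1) return(NA_real_)
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Small-sample AIC model comparison and averaging
#'
#' Compares candidate least-squares fits of the same data via
#' `AICc = n log(RSS/n) + 2p + 2p(p+1)/(n-p-1)`, computes Akaike weights,
#' and (optionally) averages named parameters over the candidate set whose
#' `delta AICc < 2`, weighting by renormalised Akaike weights.
#'
#' @param rss Residual sums of squares, one per candidate.
#' @param n_obs Number of observations (identical across candidates).
#' @param n_par Parameter counts, one per candidate.
#' @param model Optional candidate labels.
#' @param params Optional list (one element per candidate) of named numeric
#'   parameter vectors to model-average.
#' @return A list with `table` (model, rss, n_par, aicc, delta_aicc,
#'   weight, in ascending AICc order) and `averaged` (named vector or
#'   `NULL`).
#' @export
compare_models_aicc <- function(rss, n_obs, n_par,
                                model = paste0("m", seq_along(rss)),
                                params = NULL) {
  if (length(n_obs) != 1) stop_input("candidates must be fitted to identical data (one n_obs)")
  if (length(rss) != length(n_par)) stop_input("'rss' and 'n_par' lengths differ")
  aicc <- mapply(aicc_from_rss, rss, n_obs, n_par)
  if (any(is.na(aicc))) {
    warning("AICc undefined for some candidates (n_obs <= n_par + 1); they are dropped from weighting")
  }
  delta <- aicc - min(aicc, na.rm = TRUE)
  w <- exp(-delta / 2)
  w[is.na(w)] <- 0
  w <- w / sum(w)
  tab <- data.frame(model = model, rss = rss, n_par = n_par,
                    aicc = aicc, delta_aicc = delta, weight = w,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL

  averaged <- NULL
  if (!is.null(params)) {
    sel <- which(!is.na(delta) & delta < 2)
    ws <- w[sel] / sum(w[sel])
    nm <- names(params[[sel[1]]])
    averaged <- setNames(numeric(length(nm)), nm)
    for (j in seq_along(sel)) {
      averaged <- averaged + ws[j] * params[[sel[j]]][nm]
    }
  }
  list(table = tab, averaged = averaged)
}
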