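#' Simulated FRET receptor-exchange experiment
#'
#' Reproduces, in silico, the exchange assay used to measure the ternary
#' complex dissociation rate: Cul1 is pre-incubated with an equimolar
#' competitor receptor (SR2, standing in for beta-TrCP/Skp1) and -- by
#' default -- with Cand1; at t = 0 the labelled receptor (SR1, standing in
#' for Fbxw7/Skp1) is added and the assembly of Cul1.SR1 is recorded.  The
#' model observable `[Cul1.SR1](t)` maps linearly onto the donor
#' fluorescence change.  Without Cand1 essentially no exchange occurs on
#' the minutes timescale; with Cand1 the signal rises to the pooled
#' equilibrium.
#'
#' @param params a `crl_params` object.
#' @param cul1,sr2,cand1 pre-incubated amounts (nM).
#' @param sr1_added amount of labelled receptor added at t = 0 (nM).  The
#'   source assay does not state it; the default mirrors the Cul1/SR2
#'   amounts and the fitted rate is insensitive to it.
#' @param preincubate_cand1 if `TRUE` (default) Cand1 equilibrates with
#'   Cul1 and SR2 before SR1 is added, as in the bench protocol; if
#'   `FALSE`, Cand1 and SR1 are co-injected at t = 0.
#' @param horizon trace length (s).
#' @param dt sampling interval of the returned trace (s).
#' @param rtol,atol solver tolerances.
#' @return A `crl_timecourse` for the two-receptor network; the observable
#'   is its `Cul1.SR1` column.
#' @export
simulate_fret_exchange <- function(params, cul1 = 70, sr2 = 70,
                                   cand1 = 150, sr1_added = 70,
                                   preincubate_cand1 = TRUE,
                                   horizon = 200, dt = 0.5,
                                   rtol = 1e-10, atol = 1e-12) {
  totals <- pool_totals(cul1, cand1, c(sr1_added, sr2))
  net <- build_network(params, totals)
  pre_cand1 <- if (preincubate_cand1) cand1 else 0
  pre <- solve_equilibrium(params,
                           pool_totals(cul1, pre_cand1, c(0, sr2)))
  y0 <- stats::setNames(numeric(length(state_names(net))), state_names(net))
  y0[c("Cul1.SR1", "Cul1.SR2")] <- pre$complexes$cul1_sr
  y0["Cul1.Cand1"] <- pre$complexes$cul1_cand1
  y0[c("Cul1.Cand1.SR1", "Cul1.Cand1.SR2")] <- pre$complexes$ternary
  simulate_network(net, seq(0, horizon, by = dt), y0 = y0,
                   rtol = rtol, atol = atol)
}

#' Fit a single exponential to an exchange trace
#'
#' Nonlinear least squares of `A * (1 - exp(-k * t)) + c` to the observable
#' of a rising trace (or `A * exp(-k * t) + c` for a decaying one), after
#' discarding an initial window during which fast binding transients make
#' the trace multi-exponential.
#'
#' @param trace a `crl_timecourse` or a data frame with a `time` column.
#' @param observable column name of the signal (default `"Cul1.SR1"`).
#' @param discard_window initial time excluded from the fit (s).
#' @param rising fit a rising saturation curve (default) or a decay.
#' @return An object of class `exp_fit`: `k_obs` (1/s), `amplitude`,
#'   `offset`, `discard_window`, `residual_norm` and the fitted model.
#' @export
fit_single_exponential <- function(trace, observable = "Cul1.SR1",
                                   discard_window = 5, rising = TRUE) {
  d <- data.frame(t = trace$time, y = trace[[observable]])
  d <- d[d$t >= discard_window, ]
  if (nrow(d) < 5) stop("too few points after the discard window")
  rng <- range(d$y)
  start <- list(A = diff(rng) + 1e-12,
                k = 1 / max(diff(range(d$t)) / 5, 1e-6),
                c0 = if (rising) rng[1] else rng[1])
  form <- if (rising) y ~ A * (1 - exp(-k * t)) + c0
          else y ~ A * exp(-k * t) + c0
  fit <- minpack.lm::nlsLM(form, data = d, start = start,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200))
  co <- stats::coef(fit)
  if (!is.finite(co[["k"]]) || co[["k"]] <= 0)
    stop("exponential fit did not yield a positive rate")
  out <- list(k_obs = co[["k"]], amplitude = co[["A"]],
              offset = co[["c0"]], discard_window = discard_window,
              residual_norm = sqrt(sum(stats::resid(fit)^2)),
              fit = fit)
  class(out) <- "exp_fit"
  out
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "Single-exponential fit: k_obs = %.4g 1/s (amplitude %.3g, offset %.3g, first %g s discarded)\n",
    x$k_obs, x$amplitude, x$offset, x$discard_window))
  invisible(x)
}

#' Estimate the ternary-complex Cand1 dissociation rate
#'
#' One-parameter calibration: all other rate constants fixed, the ternary
#' Cand1 dissociation rate `kca'` is varied until the single-exponential
#' rate fitted to the simulated exchange trace matches an observed
#' `k_obs`.  The fitted rate is strictly increasing in `kca'` over the
#' bracket, so a scalar root find (in log space) suffices.  Also reports
#' `beta = kca'/ksr'`.
#'
#' @param target_k_obs observed exchange rate (1/s).
#' @param params a `crl_params` object supplying every other constant.
#' @param bracket search interval for `kca'` (1/s).
#' @param ... passed to [simulate_fret_exchange()] (assay composition,
#'   horizon, ...).
#' @return List of class `kca_calibration`: `kca_prime` (1/s), `beta`,
#'   `k_obs_fit` (the fitted rate at the solution) and `target_k_obs`.
#' @export
estimate_kca_prime <- function(target_k_obs, params = default_params(),
                               bracket = c(1e-4, 10), ...) {
  kobs_of <- function(kcap) {
    p <- kinetic_params(Ksr = params$Ksr, ksr = params$ksr,
                        Ksr_prime = params$Ksr_prime,
                        ksr_prime = params$ksr_prime,
                        Kca_prime = params$Kca_prime, kca_prime = kcap,
                        kca = params$kca, gamma = params$gamma)
    fit_single_exponential(simulate_fret_exchange(p, ...))$k_obs
  }
  g <- function(lk) kobs_of(exp(lk)) - target_k_obs
  lo <- log(bracket[1]); hi <- log(bracket[2])
  if (g(lo) * g(hi) > 0)
    stop("target k_obs is not bracketed by the kca' search interval")
  lk <- stats::uniroot(g, c(lo, hi), tol = 1e-8)$root
  kcap <- exp(lk)
  out <- list(kca_prime = kcap, beta = kcap / params$ksr_prime,
              k_obs_fit = kobs_of(kcap), target_k_obs = target_k_obs)
  class(out) <- "kca_calibration"
  out
}

#' @export
print.kca_calibration <- function(x, ...) {
  cat(sprintf(
    "Calibration: kca' = %.4g 1/s (beta = %.4g) reproduces k_obs = %.4g 1/s (target %.4g)\n",
    x$kca_prime, x$beta, x$k_obs_fit, x$target_k_obs))
  invisible(x)
}
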