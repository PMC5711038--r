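#' Algebraic equilibrium of the binding-only exchange cycle
#'
#' Because the binding network obeys detailed balance, its steady state is a
#' thermodynamic equilibrium: every complex concentration is determined by
#' the free concentrations through the mass-action equilibrium relations.
#' The solver reduces the problem to two nested scalar root-finds (free
#' Cul1 in the outer loop, free Cand1 in the inner loop; free receptors are
#' closed-form given those), solved in log space so that free concentrations
#' many orders of magnitude below the totals are resolved to full relative
#' precision.
#'
#' An ODE-relaxation route (`method = "relaxation"`, or `cross_check =
#' TRUE`) integrates the same network from an empty complex pool until the
#' derivatives vanish and serves as an independent check; the two routes
#' agree to relative 1e-6 or the function fails loudly.
#'
#' @param params a `crl_params` object.
#' @param totals a `pool_totals` object (substrates, if any, are ignored:
#'   the equilibrium refers to the substrate-free binding network).
#' @param sr_scale optional per-receptor affinity scaling, as in
#'   [build_network()].
#' @param method `"algebraic"` (default) or `"relaxation"`.
#' @param cross_check verify the algebraic result against relaxation.
#' @return An object of class `crl_equilibrium`: list with `free`
#'   (`cul1`, `cand1`, `sr`), `complexes` (`cul1_sr`, `cul1_cand1`,
#'   `ternary`) and the inputs.
#' @export
solve_equilibrium <- function(params, totals, sr_scale = NULL,
                              method = c("algebraic", "relaxation"),
                              cross_check = FALSE) {
  method <- match.arg(method)
  n <- length(totals$sr)
  if (is.null(sr_scale)) sr_scale <- rep(1, n)
  eq <- if (method == "algebraic") {
    .equilibrium_algebraic(params, totals, sr_scale)
  } else {
    .equilibrium_relaxation(params, totals, sr_scale)
  }
  if (cross_check && method == "algebraic") {
    alt <- .equilibrium_relaxation(params, totals, sr_scale)
    scale <- max(totals$cul1, totals$cand1, totals$sr)
    dev <- max(abs(c(eq$complexes$cul1_sr - alt$complexes$cul1_sr,
                     eq$complexes$cul1_cand1 - alt$complexes$cul1_cand1,
                     eq$complexes$ternary - alt$complexes$ternary))) / scale
    if (dev > 1e-6)
      stop(sprintf(
        "equilibrium routes disagree: relative deviation %.3g", dev))
    eq$cross_check_dev <- dev
  }
  eq
}

.equilibrium_algebraic <- function(params, totals, sr_scale) {
  n <- length(totals$sr)
  gamma <- params$gamma
  Ksr  <- params$Ksr * sr_scale * gamma
  Ksrp <- params$Ksr_prime * sr_scale
  Kca  <- params$Kca * gamma
  SRT <- totals$sr
  cul1T <- totals$cul1
  cand1T <- totals$cand1
  if (cul1T <= 0)
    return(.equilibrium_pack(params, totals, sr_scale, 0,
                             if (cand1T > 0) cand1T else 0, SRT))
  sr_of <- function(cc, aa) SRT / (1 + cc / Ksr + cc * aa / (Kca * Ksrp))
  cand1_of <- function(cc) {
    if (cand1T <= 0) return(0)
    g <- function(u) {
      aa <- exp(u)
      si <- sr_of(cc, aa)
      aa * (cc / Kca + sum(cc * si / (Kca * Ksrp))) - (cand1T - aa)
    }
    exp(stats::uniroot(g, c(log(cand1T) - 90, log(cand1T) + 1e-6),
                       tol = 1e-15)$root)
  }
  h <- function(u) {
    cc <- exp(u)
    aa <- cand1_of(cc)
    si <- sr_of(cc, aa)
    cc * (sum(si / Ksr) + aa / Kca + sum(aa * si / (Kca * Ksrp))) -
      (cul1T - cc)
  }
  u <- stats::uniroot(h, c(log(cul1T) - 200, log(cul1T) + 1e-6),
                      tol = 1e-15)$root
  cc <- exp(u)
  aa <- cand1_of(cc)
  si <- sr_of(cc, aa)
  .equilibrium_pack(params, totals, sr_scale, cc, aa, si)
}

.equilibrium_pack <- function(params, totals, sr_scale, cc, aa, si) {
  gamma <- params$gamma
  Ksr  <- params$Ksr * sr_scale * gamma
  Ksrp <- params$Ksr_prime * sr_scale
  Kca  <- params$Kca * gamma
  out <- list(
    free = list(cul1 = cc, cand1 = aa, sr = si),
    complexes = list(cul1_sr = cc * si / Ksr,
                     cul1_cand1 = cc * aa / Kca,
                     ternary = cc * aa * si / (Kca * Ksrp)),
    params = params, totals = totals, sr_scale = sr_scale)
  class(out) <- "crl_equilibrium"
  out
}

.equilibrium_relaxation <- function(params, totals, sr_scale) {
  bare <- pool_totals(totals$cul1, totals$cand1, totals$sr)
  net <- build_network(params, bare, sr_scale = sr_scale)
  y0 <- stats::setNames(numeric(length(state_names(net))), state_names(net))
  f <- function(y) network_rhs(net, y)[[1]]
  scale <- max(totals$cul1, totals$cand1, totals$sr, 1)
  t_end <- 1e2
  for (i in 1:6) {                       # extend horizon until relaxed
    sol <- deSolve::lsoda(y0, c(0, t_end), function(t, y, p) list(f(y)),
                          NULL, rtol = 1e-11, atol = 1e-13,
                          maxsteps = 100000)
    y0 <- sol[nrow(sol), -1]
    if (max(abs(f(y0))) < 1e-11 * scale) break
    t_end <- t_end * 100
  }
  if (max(abs(f(y0))) >= 1e-11 * scale)
    stop("ODE relaxation did not converge to a steady state")
  n <- net$n_rec
  .equilibrium_pack(params, totals, sr_scale,
                    cc = free_species(net, y0)[["Cul1"]],
                    aa = free_species(net, y0)[["Cand1"]],
                    si = unname(free_species(net, y0)[2 + seq_len(n)]))
}

#' @export
print.crl_equilibrium <- function(x, ...) {
  cat("Binding-network equilibrium (nM)\n")
  cat(sprintf("  free: Cul1 = %.4g, Cand1 = %.4g\n",
              x$free$cul1, x$free$cand1))
  cat("  free SR:", paste(sprintf("%.4g", x$free$sr), collapse = ", "), "\n")
  cat("  Cul1.SR:", paste(sprintf("%.4g", x$complexes$cul1_sr),
                          collapse = ", "), "\n")
  cat(sprintf("  Cul1.Cand1 = %.4g\n", x$complexes$cul1_cand1))
  cat("  ternary:", paste(sprintf("%.4g", x$complexes$ternary),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Steady state with Jacobian spectrum and exchange rate
#'
#' Solves the binding-network equilibrium, linearises the reduced dynamics
#' there, and reports the eigenvalue spectrum.  The exchange rate is the
#' absolute real part of the leading (largest real part) eigenvalue; its
#' inverse `tau_s` is the relaxation timescale towards a new steady state
#' after a perturbation, i.e. the timescale on which receptors are
#' exchanged over the scaffold.
#'
#' @inheritParams solve_equilibrium
#' @return An object of class `crl_steady_state` with fields `equilibrium`,
#'   `state`, `jacobian`, `spectrum`, `leading_eigenvalue`,
#'   `exchange_rate` (1/s), `tau_s` (s) and `rhs_norm`.
#' @export
steady_state <- function(params, totals, sr_scale = NULL) {
  n <- length(totals$sr)
  if (is.null(sr_scale)) sr_scale <- rep(1, n)
  eq <- solve_equilibrium(params, totals, sr_scale = sr_scale)
  bare <- pool_totals(totals$cul1, totals$cand1, totals$sr)
  net <- build_network(params, bare, sr_scale = sr_scale)
  y <- stats::setNames(numeric(length(state_names(net))), state_names(net))
  y[paste0("Cul1.SR", seq_len(n))] <- eq$complexes$cul1_sr
  y["Cul1.Cand1"] <- eq$complexes$cul1_cand1
  y[paste0("Cul1.Cand1.SR", seq_len(n))] <- eq$complexes$ternary
  J <- network_jacobian(net, y)
  ev <- eigen(J, only.values = TRUE)$values
  lead <- ev[which.max(Re(ev))]
  out <- list(equilibrium = eq, state = y, jacobian = J, spectrum = ev,
              leading_eigenvalue = lead,
              exchange_rate = abs(Re(lead)),
              tau_s = 1 / abs(Re(lead)),
              rhs_norm = max(abs(network_rhs(net, y)[[1]])))
  class(out) <- "crl_steady_state"
  out
}

#' @export
print.crl_steady_state <- function(x, ...) {
  cat(sprintf(
    "Steady state: |rhs| = %.2g nM/s; exchange rate %.4g 1/s (tau_s = %.4g s)\n",
    x$rhs_norm, x$exchange_rate, x$tau_s))
  cat("  eigenvalue real parts:",
      paste(sprintf("%.3g", sort(Re(x$spectrum))), collapse = ", "), "\n")
  invisible(x)
}

#' Slope of the low-Cand1 occupancy approximation
#'
#' In the saturated regime (total receptor exceeding total Cul1) and for
#' Cand1 well below Cul1, the SCF occupancy falls linearly with total
#' Cand1; `slope_f` is the dimensionless slope
#' \deqn{f = \frac{K'_{sr} + SR_T - Cul1_T}
#'            {K'_{sr} + (1 + \eta K'_{sr}/Cul1_T)(SR_T - Cul1_T)},}
#' guaranteed to lie in (0, 1): each Cand1 molecule sequesters at most one
#' Cul1 equivalent from the SCF pool.
#'
#' @param params a `crl_params` object.
#' @param totals a `pool_totals` object with `sum(sr) > cul1`.
#' @return Dimensionless slope.
#' @export
slope_f <- function(params, totals) {
  SRT <- sum(totals$sr)
  if (SRT <= totals$cul1)
    stop("slope_f requires the saturated regime sum(sr) > cul1")
  Ksrp <- params$Ksr_prime
  (Ksrp + SRT - totals$cul1) /
    (Ksrp + (1 + params$eta * Ksrp / totals$cul1) * (SRT - totals$cul1))
}

#' Low-Cand1 linear occupancy approximation
#'
#' `[Cul1.SRi] ~ (SRi_T/SR_T) * (Cul1_T - f * Cand1_T)` with `f` from
#' [slope_f()]; valid for `Cand1_T << Cul1_T` in the saturated regime.
#'
#' @inheritParams slope_f
#' @param receptor receptor index.
#' @return Approximate occupancy (nM).
#' @export
occupancy_low_cand1 <- function(params, totals, receptor = 1L) {
  f <- slope_f(params, totals)
  (totals$sr[receptor] / sum(totals$sr)) *
    (totals$cul1 - f * totals$cand1)
}

#' High-Cand1 power-law occupancy approximation
#'
#' `[Cul1.SRi] ~ eta*Ksr' * (Cul1_T/Cand1_T) * SRi_T / (Ksr'+SR_T+Cul1_T)`;
#' the occupancy decays as 1/Cand1_T once Cand1 saturates the scaffold.
#'
#' @inheritParams occupancy_low_cand1
#' @return Approximate occupancy (nM).
#' @export
occupancy_high_cand1 <- function(params, totals, receptor = 1L) {
  params$eta * params$Ksr_prime * (totals$cul1 / totals$cand1) *
    totals$sr[receptor] /
    (params$Ksr_prime + sum(totals$sr) + totals$cul1)
}

#' Asymptotic exchange-rate approximations
#'
#' Closed-form limits of the leading-eigenvalue exchange rate: for
#' `Cand1_T << Cul1_T`,
#' `|rho_l| ~ ksr + 1/(1/ksr' + Ksr'/(kca' * Cand1_T))`
#' (as Cand1 vanishes only spontaneous Cul1.SR dissociation remains); for
#' `Cand1_T >> Cul1_T` the rate saturates at
#' `ksr' * (1 + (Cul1_T/Ksr') * (Cul1_T+Ksr')/(Cul1_T+SR_T+Ksr'))`,
#' independent of eta and Cand1_T -- the ternary complex dissociation
#' towards Cul1.Cand1 ultimately limits receptor turnover.
#'
#' @inheritParams slope_f
#' @param cand1_total total Cand1 (nM) for the low-Cand1 branch.
#' @return Named vector `c(low = ..., high = ...)` (1/s).
#' @export
exchange_rate_limits <- function(params, totals, cand1_total) {
  ksrp <- params$ksr_prime
  Ksrp <- params$Ksr_prime
  low <- params$ksr +
    1 / (1 / ksrp + Ksrp / (params$kca_prime * cand1_total))
  SRT <- sum(totals$sr)
  high <- ksrp * (1 + (totals$cul1 / Ksrp) *
                    (totals$cul1 + Ksrp) / (totals$cul1 + SRT + Ksrp))
  c(low = low, high = high)
}

#' Occupancy / exchange-rate trade-off scan
#'
#' For each value of the relative binding affinity eta, sweeps total Cand1
#' over a grid and records the equilibrium SCF occupancy `[Cul1.SR1]` and
#' the leading-eigenvalue exchange rate.  Raising Cand1 trades occupancy
#' (which falls) for exchange speed (which rises); plotted against each
#' other the curves for different eta overlap.
#'
#' @inheritParams slope_f
#' @param cand1_grid numeric vector of total Cand1 values (nM).
#' @param eta_values numeric vector of eta values to scan.
#' @return A data frame of class `tradeoff_scan` with columns `eta`,
#'   `cand1_total_nM`, `occupancy_nM`, `exchange_rate_per_s`, `tau_s_s`.
#'   Failed grid points carry `NA` instead of aborting the scan.
#' @export
tradeoff_scan <- function(params, totals,
                          cand1_grid = 10^seq(0, 4, length.out = 41),
                          eta_values = params$eta) {
  rows <- list()
  for (eta in eta_values) {
    p <- with_eta(params, eta)
    for (ca in cand1_grid) {
      tot <- pool_totals(totals$cul1, ca, totals$sr)
      rec <- tryCatch({
        ss <- steady_state(p, tot)
        data.frame(eta = eta, cand1_total_nM = ca,
                   occupancy_nM = ss$equilibrium$complexes$cul1_sr[1],
                   exchange_rate_per_s = ss$exchange_rate,
                   tau_s_s = ss$tau_s)
      }, error = function(e)
        data.frame(eta = eta, cand1_total_nM = ca, occupancy_nM = NA_real_,
                   exchange_rate_per_s = NA_real_, tau_s_s = NA_real_))
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tradeoff_scan", "data.frame")
  out
}

#' Receptor-addition transient
#'
#' Adds a bolus of receptor 1 to a pre-equilibrated mixture that contains
#' none of it, and follows the assembly of Cul1.SR1.  The equilibration
#' timescale (time to cover 1 - 1/e of the rise) is compared against the
#' post-addition steady-state `tau_s`: they agree within a factor of ~2
#' because a single slow eigenmode dominates the approach.
#'
#' @inheritParams slope_f
#' @param added_sr1 amount of receptor 1 added at t = 0 (nM).
#' @param times output grid (s); default log-spaced to 1e7 s.
#' @return List with `timecourse`, `t_relax` (s), `tau_s` (s) and
#'   `final_occupancy` (nM).
#' @export
sr_addition_transient <- function(params, totals, added_sr1,
                                  times = NULL) {
  totals0 <- pool_totals(totals$cul1, totals$cand1,
                         replace(totals$sr, 1, 0))
  eq0 <- solve_equilibrium(params, totals0)
  totals1 <- pool_totals(totals$cul1, totals$cand1,
                         replace(totals$sr, 1, added_sr1))
  net <- build_network(params, totals1)
  n <- net$n_rec
  y0 <- stats::setNames(numeric(length(state_names(net))), state_names(net))
  y0[paste0("Cul1.SR", seq_len(n))] <- eq0$complexes$cul1_sr
  y0["Cul1.Cand1"] <- eq0$complexes$cul1_cand1
  y0[paste0("Cul1.Cand1.SR", seq_len(n))] <- eq0$complexes$ternary
  if (is.null(times)) times <- c(0, 10^seq(-3, 7, length.out = 400))
  tc <- simulate_network(net, times, y0 = y0)
  ss <- steady_state(params, totals1)
  target <- ss$equilibrium$complexes$cul1_sr[1]
  y <- tc$Cul1.SR1
  t_relax <- if (added_sr1 <= 0 || target < 1e-12) {
    NA_real_
  } else {
    frac <- (y - y[1]) / (target - y[1])
    stats::approx(frac, tc$time, xout = 1 - exp(-1), ties = "ordered")$y
  }
  list(timecourse = tc, t_relax = t_relax, tau_s = ss$tau_s,
       final_occupancy = target)
}
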