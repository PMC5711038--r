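#' Substrate degradation after injection into a resting mixture
#'
#' Pre-equilibrates the binding network (without substrate), injects the
#' substrate pool(s) at t = 0, and integrates until the total substrate has
#' fallen below `stop_frac` of its initial amount or `t_max` is reached.
#' Total substrate counts every substrate-containing species (free plus all
#' bound forms).  The half-life `t_half` is the first time total substrate
#' crosses half its initial value, located by monotone (Hyman) spline
#' interpolation of the dense solver output and reported in minutes.
#'
#' @param params a `crl_params` object.
#' @param totals a `pool_totals` object including substrate totals.
#' @param substrates a `substrate_params` object or list of them (one per
#'   entry of `totals$substrate`).
#' @param cand1_total optional override of `totals$cand1` (nM), convenient
#'   for dose scans.
#' @param sr_scale optional per-receptor affinity scaling.
#' @param t_max maximum integration time (s).
#' @param n_out number of (log-spaced) output points.
#' @param stop_frac stop once total substrate falls below this fraction.
#' @param rtol,atol solver tolerances.
#' @return An object of class `degradation_run`: list with `timecourse`,
#'   `substrate_total` (matrix, one column per substrate), `t_half_min`
#'   (per substrate; `NA` when censored), `censored` flags, `engaged`
#'   (engaged-ligase pool per substrate-bearing receptor), `equilibrium`
#'   (pre-stimulus) and the inputs.
#' @export
run_degradation <- function(params, totals, substrates,
                            cand1_total = NULL, sr_scale = NULL,
                            t_max = 1e5, n_out = 400, stop_frac = 0.01,
                            rtol = 1e-8, atol = 1e-12) {
  if (inherits(substrates, "substrate_params")) substrates <- list(substrates)
  if (!is.null(cand1_total))
    totals <- pool_totals(totals$cul1, cand1_total, totals$sr,
                          totals$substrate)
  if (length(totals$substrate) != length(substrates))
    stop("one substrate_params per entry of totals$substrate is required")
  net <- build_network(params, totals, substrates, sr_scale = sr_scale)
  times <- sort(unique(c(0, 10^seq(-2, log10(t_max), length.out = n_out))))
  tc <- simulate_network(net, times, rtol = rtol, atol = atol)

  m <- length(substrates)
  ST <- sapply(seq_len(m), function(j) {
    carriers <- net$complexes[net$comp[, net$n_cons + j] > 0]
    rowSums(tc[, c(paste0("S", j), carriers), drop = FALSE])
  })
  ST <- matrix(ST, ncol = m)
  colnames(ST) <- paste0("S", seq_len(m), "_total")

  t_half <- rep(NA_real_, m)
  censored <- rep(FALSE, m)
  for (j in seq_len(m)) {
    s0 <- totals$substrate[j]
    if (substrates[[j]]$kdeg <= 0 || s0 <= 0) { censored[j] <- TRUE; next }
    if (ST[nrow(ST), j] > s0 / 2) { censored[j] <- TRUE; next }
    i <- which(ST[, j] < s0 / 2)[1]       # first crossing; ST decreasing
    sf <- stats::splinefun(tc$time, ST[, j], method = "natural")
    t_half[j] <- stats::uniroot(function(tt) sf(tt) - s0 / 2,
                                c(tc$time[max(i - 1, 1)], tc$time[i]),
                                tol = 1e-6, extendInt = "downX")$root / 60
  }

  engaged <- sapply(seq_len(m), function(j) {
    r <- substrates[[j]]$receptor
    carriers <- intersect(
      c(sprintf("Cul1.SR%d", r), sprintf("Cul1.SR%d.S%d", r, j)),
      names(tc))
    rowSums(tc[, carriers, drop = FALSE])
  })
  engaged <- matrix(engaged, ncol = m)
  colnames(engaged) <- paste0("engaged_SR",
                              vapply(substrates, `[[`, 1L, "receptor"))

  out <- list(timecourse = tc, substrate_total = ST,
              t_half_min = t_half, censored = censored, engaged = engaged,
              equilibrium = solve_equilibrium(params, totals,
                                              sr_scale = sr_scale),
              params = params, totals = totals, substrates = substrates,
              sr_scale = sr_scale)
  class(out) <- "degradation_run"
  out
}

#' @export
print.degradation_run <- function(x, ...) {
  cat("Degradation run:\n")
  for (j in seq_along(x$substrates))
    cat(sprintf("  S%d: t_half = %s min%s\n", j,
                if (is.na(x$t_half_min[j])) "--" else
                  sprintf("%.2f", x$t_half_min[j]),
                if (x$censored[j]) " (censored)" else ""))
  invisible(x)
}

#' Half-life as a function of total Cand1, with optimum detection
#'
#' Runs [run_degradation()] over a grid of total Cand1 concentrations,
#' classifies the dose-response curve as monotone or non-monotone, and --
#' when an interior minimum exists -- refines its location by golden
#' section search between the grid neighbours of the argmin.
#'
#' @inheritParams run_degradation
#' @param substrate a single `substrate_params`.
#' @param cand1_grid total Cand1 values to scan (nM).
#' @param refine golden-section refinement of an interior optimum.
#' @param refine_tol absolute tolerance of the refined optimum (nM).
#' @return List of class `dose_response` with `curve` (data frame
#'   `cand1_total_nM`, `t_half_min`, `censored`), `monotone` flag,
#'   `optimum_cand1_nM` and `optimum_t_half_min` (NA when the curve is
#'   monotone).
#' @export
cand1_dose_response <- function(params, totals, substrate, cand1_grid,
                                refine = TRUE, refine_tol = 1,
                                t_max = 1e5, ...) {
  th <- function(ca) {
    run_degradation(params, totals, substrate, cand1_total = ca,
                    t_max = t_max, ...)$t_half_min[1]
  }
  vals <- vapply(cand1_grid, th, numeric(1))
  cens <- is.na(vals)
  if (any(cens))
    warning(sprintf("%d censored grid point(s) excluded from the optimum",
                    sum(cens)))
  curve <- data.frame(cand1_total_nM = cand1_grid, t_half_min = vals,
                      censored = cens)
  ok <- which(!cens)
  i_min <- ok[which.min(vals[ok])]
  interior <- i_min > min(ok) && i_min < max(ok)
  opt_x <- NA_real_; opt_y <- NA_real_
  if (interior) {
    lo <- cand1_grid[i_min - 1]; hi <- cand1_grid[i_min + 1]
    if (refine) {
      gr <- (sqrt(5) - 1) / 2
      a <- lo; b <- hi
      x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
      f1 <- th(x1); f2 <- th(x2)
      while (b - a > refine_tol) {
        if (f1 < f2) { b <- x2; x2 <- x1; f2 <- f1
          x1 <- b - gr * (b - a); f1 <- th(x1)
        } else { a <- x1; x1 <- x2; f1 <- f2
          x2 <- a + gr * (b - a); f2 <- th(x2) }
      }
      opt_x <- (a + b) / 2; opt_y <- min(f1, f2)
    } else {
      opt_x <- cand1_grid[i_min]; opt_y <- vals[i_min]
    }
  }
  out <- list(curve = curve, monotone = !interior,
              optimum_cand1_nM = opt_x, optimum_t_half_min = opt_y)
  class(out) <- "dose_response"
  out
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Cand1 dose response over %d points: %s\n",
              nrow(x$curve),
              if (x$monotone) "monotone" else
                sprintf("interior optimum at Cand1_T ~ %.0f nM (t_half %.1f min)",
                        x$optimum_cand1_nM, x$optimum_t_half_min)))
  invisible(x)
}

#' Decompose the Cul1 redistribution feeding the engaged pool
#'
#' For a two-receptor run with one substrate on receptor 1, computes the
#' depletion curves `delta_X(t) = [X](0) - [X](t)` for the reservoir
#' complexes Cul1.SR2, Cul1.Cand1.SR1, Cul1.Cand1.SR2 and Cul1.Cand1, and
#' the engaged-pool increase
#' `Delta(t) = [Cul1.SR1](t) + [Cul1.SR1.S1](t) - [Cul1.SR1](0)`.
#' Conservation of Cul1 makes the delta curves (plus the free-Cul1
#' remainder) sum exactly to `Delta(t)`; the dominant reservoir switches
#' from Cul1.SR2 at low Cand1 to Cul1.Cand1 when Cand1 is abundant.
#'
#' @param run a `degradation_run` on 2 receptors with 1 substrate.
#' @return List of class `redistribution` with `time_s`, `delta` (one
#'   column per reservoir), `delta_free_cul1`, `Delta`, `closure_error`
#'   (max abs deviation of the sum, nM), `peak_fold` (peak engaged pool
#'   over pre-stimulus engaged pool) and `dominant` (reservoir contributing
#'   most at the engaged-pool peak).
#' @export
redistribution_analysis <- function(run) {
  tc <- run$timecourse
  net <- attr(tc, "network")
  if (net$n_rec != 2 || net$n_sub != 1)
    stop("redistribution_analysis expects 2 receptors and 1 substrate")
  reservoirs <- c("Cul1.SR2", "Cul1.Cand1.SR1", "Cul1.Cand1.SR2",
                  "Cul1.Cand1")
  delta <- sapply(reservoirs, function(sp) tc[[sp]][1] - tc[[sp]])
  dfree <- tc$Cul1[1] - tc$Cul1
  eng <- run$engaged[, 1]
  Delta <- eng - eng[1]
  closure <- max(abs(rowSums(delta) + dfree - Delta))
  ipeak <- which.max(eng)
  out <- list(time_s = tc$time, delta = delta, delta_free_cul1 = dfree,
              Delta = Delta, closure_error = closure,
              peak_fold = max(eng) / eng[1],
              peak_time_s = tc$time[ipeak],
              dominant = reservoirs[which.max(delta[ipeak, ])])
  class(out) <- "redistribution"
  out
}

#' @export
print.redistribution <- function(x, ...) {
  cat(sprintf(
    "Cul1 redistribution: engaged pool peaks %.2f-fold at t = %.1f min\n",
    x$peak_fold, x$peak_time_s / 60))
  cat(sprintf("  dominant reservoir at peak: %s (closure error %.2g nM)\n",
              x$dominant, x$closure_error))
  invisible(x)
}

#' Temporal hierarchy of substrate degradation
#'
#' Three receptor species compete for Cul1: SR1 and SR2 carry substrates
#' (300 nM each, injected at t = 0), SR3 lumps the remaining receptor pool
#' and runs the full exchange cycle without substrate.  A single asymmetry
#' between the two substrate branches sets the order of degradation:
#' \describe{
#'   \item{`reference`}{fully symmetric; both half-lives coincide.}
#'   \item{`affinity_substrate`}{substrate 1 binds its receptor 5x more
#'     weakly (`kon` 1e8 -> 2e7 /M/s, so `K_D` 10 -> 50 nM).}
#'   \item{`affinity_receptor`}{receptor 1 binds Cul1 5x more weakly
#'     (`ksr`, `Ksr`, `ksr'`, `Ksr'` all x5, preserving detailed balance).}
#'   \item{`abundance`}{unequal receptor totals (defaults 90/30 nM).}
#' }
#' In each asymmetric variant the favoured substrate (higher affinity,
#' higher-affinity receptor, or more abundant receptor) is degraded first,
#' while Cul1 is transiently redistributed out of the unused SR3 pool.
#'
#' @param variant one of `"reference"`, `"affinity_substrate"`,
#'   `"affinity_receptor"`, `"abundance"`.
#' @param params a `crl_params` object.
#' @param cul1_total,cand1_total totals (nM).
#' @param sr1_total,sr2_total receptor totals (nM); the lumped SR3 pool is
#'   `sr_pool_total - sr1_total - sr2_total`.
#' @param sr_pool_total total receptor pool (nM).
#' @param substrate_total per-substrate initial amount (nM).
#' @param kon,koff,kdeg substrate parameters (reference values; the variant
#'   applies its own modification).
#' @param t_max,n_out integration control, see [run_degradation()].
#' @return List of class `hierarchy_experiment` with the
#'   `degradation_run`, per-substrate `t_half_min`, and `occupancy_fraction`
#'   (data frame of `[Cul1.SRi(+.Si)]/SRi_T` trajectories).
#' @export
hierarchy_experiment <- function(variant = c("reference",
                                             "affinity_substrate",
                                             "affinity_receptor",
                                             "abundance"),
                                 params = default_params(),
                                 cul1_total = 300, cand1_total = 400,
                                 sr1_total = 60, sr2_total = 60,
                                 sr_pool_total = 660,
                                 substrate_total = 300,
                                 kon = 1e8, koff = 1, kdeg = 0.004,
                                 t_max = 1e5, n_out = 400) {
  variant <- match.arg(variant)
  if (variant == "abundance" && sr1_total == sr2_total) {
    sr1_total <- 90; sr2_total <- 30
  }
  sr3_total <- sr_pool_total - sr1_total - sr2_total
  if (sr3_total < 0) stop("sr1_total + sr2_total exceeds the receptor pool")
  kon1 <- if (variant == "affinity_substrate") 2e7 else kon
  sr_scale <- if (variant == "affinity_receptor") c(5, 1, 1) else c(1, 1, 1)
  totals <- pool_totals(cul1_total, cand1_total,
                        c(sr1_total, sr2_total, sr3_total),
                        c(substrate_total, substrate_total))
  subs <- list(substrate_params(kon1, koff, kdeg, receptor = 1L),
               substrate_params(kon, koff, kdeg, receptor = 2L))
  run <- run_degradation(params, totals, subs, sr_scale = sr_scale,
                         t_max = t_max, n_out = n_out)
  tc <- run$timecourse
  occ <- data.frame(
    time_s = tc$time,
    sr1 = (tc$Cul1.SR1 + tc$Cul1.SR1.S1) / sr1_total,
    sr2 = (tc$Cul1.SR2 + tc$Cul1.SR2.S2) / sr2_total,
    sr3 = tc$Cul1.SR3 / sr3_total)
  out <- list(variant = variant, run = run, t_half_min = run$t_half_min,
              occupancy_fraction = occ, totals = totals)
  class(out) <- "hierarchy_experiment"
  out
}

#' @export
print.hierarchy_experiment <- function(x, ...) {
  cat(sprintf("Hierarchy experiment (%s): t_half S1 = %.2f min, S2 = %.2f min\n",
              x$variant, x$t_half_min[1], x$t_half_min[2]))
  invisible(x)
}
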