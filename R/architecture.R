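#' Match the affinity rescale of a Cand1-free architecture
#'
#' The hypothetical exchange-factor-free design weakens the Cul1-SR (and
#' Cul1-Cand1) affinity by a factor gamma so that receptors can cycle on
#' and off the scaffold spontaneously.  For a fair comparison gamma is
#' chosen such that the pre-stimulus steady-state `[Cul1.SR1]` of the
#' Cand1-free system equals that of the reference system (Cand1 present,
#' gamma = 1); this function locates that gamma by scalar root finding on
#' log10(gamma).
#'
#' @param params a `crl_params` object (gamma is ignored; the reference
#'   uses gamma = 1).
#' @param totals a `pool_totals` object whose `cand1` is the reference
#'   Cand1 concentration.
#' @param bracket log10(gamma) search interval.
#' @param tol relative tolerance on the matched occupancy.
#' @return The matched gamma (numeric scalar).
#' @export
match_gamma <- function(params, totals, bracket = c(0, 12), tol = 1e-6) {
  bare <- pool_totals(totals$cul1, totals$cand1, totals$sr)
  ref <- solve_equilibrium(params, bare)$complexes$cul1_sr[1]
  if (totals$cand1 <= 0) return(1)
  none <- pool_totals(totals$cul1, 0, totals$sr)
  f <- function(lg) {
    p <- default_like(params, gamma = 10^lg)
    solve_equilibrium(p, none)$complexes$cul1_sr[1] - ref
  }
  if (f(bracket[1]) < 0)
    stop("no gamma >= 1 can match the reference occupancy")
  lg <- stats::uniroot(f, bracket, tol = 1e-10)$root
  g <- 10^lg
  p <- default_like(params, gamma = g)
  got <- solve_equilibrium(p, none)$complexes$cul1_sr[1]
  if (abs(got - ref) / ref > tol * 100)
    stop("gamma matching failed to converge")
  g
}

## clone a parameter set with a different gamma
default_like <- function(params, gamma) {
  kinetic_params(Ksr = params$Ksr, ksr = params$ksr,
                 Ksr_prime = params$Ksr_prime,
                 ksr_prime = params$ksr_prime,
                 Kca_prime = params$Kca_prime,
                 kca_prime = params$kca_prime,
                 kca = params$kca, gamma = gamma)
}

#' Compare the Cand1 architecture against a weak-binding architecture
#'
#' Runs the same substrate-degradation experiment in two network designs:
#' the natural one (Cand1 present, tight Cul1-SR binding, gamma = 1) and a
#' Cand1-free one with binding weakened by the matched gamma (see
#' [match_gamma()]), under either sequential or random-order substrate
#' binding.  In both designs substrate can bind the assembled ligase and
#' the ternary complex; degradation only proceeds from Cul1.SR1.S1.
#'
#' @param params a `crl_params` object.
#' @param totals a `pool_totals` object: `cand1` is the reference Cand1
#'   concentration and `substrate` the injected amount.
#' @param substrate a `substrate_params`; its `binding_mode` selects the
#'   topology (`ternary_binding` is forced on, matching the comparison's
#'   reaction scheme).
#' @param gamma optional pre-computed matched gamma (otherwise computed).
#' @param t_max integration horizon (s).
#' @param ... passed to [run_degradation()].
#' @return List of class `architecture_comparison`: per-architecture
#'   half-lives and pre-stimulus occupancies, the matched `gamma`,
#'   `fold_ratio` (larger over smaller), the directed ratios
#'   `ratio_with_over_without` and `ratio_without_over_with`, and
#'   redistribution flags (did `[Cul1.SR2]` drop by more than 5% of its
#'   pre-stimulus value).
#' @export
compare_architectures <- function(params, totals, substrate,
                                  gamma = NULL, t_max = 4e6, ...) {
  if (substrate$kdeg <= 0)
    stop("kdeg must be positive: half-life ratio undefined without degradation")
  substrate <- substrate_params(substrate$kon, substrate$koff,
                                substrate$kdeg, substrate$receptor,
                                binding_mode = substrate$binding_mode,
                                ternary_binding = TRUE)
  if (is.null(gamma)) gamma <- match_gamma(params, totals)
  p_with <- default_like(params, gamma = 1)
  p_without <- default_like(params, gamma = gamma)
  tot_with <- totals
  tot_without <- pool_totals(totals$cul1, 0, totals$sr, totals$substrate)
  run_with <- run_degradation(p_with, tot_with, substrate,
                              t_max = t_max, ...)
  run_without <- run_degradation(p_without, tot_without, substrate,
                                 t_max = t_max, ...)
  occ <- c(with = run_with$equilibrium$complexes$cul1_sr[1],
           without = run_without$equilibrium$complexes$cul1_sr[1])
  th <- c(with = run_with$t_half_min[1], without = run_without$t_half_min[1])
  if (any(is.na(th)))
    warning("censored run: half-life not reached within t_max")
  redis <- vapply(list(run_with, run_without), function(r) {
    cs2 <- r$timecourse$Cul1.SR2
    (cs2[1] - min(cs2)) > 0.05 * cs2[1]
  }, logical(1))
  out <- list(mode = substrate$binding_mode, gamma = gamma,
              t_half_min = th, pre_stimulus_occupancy = occ,
              occupancy_mismatch = abs(diff(occ)) / occ[1],
              fold_ratio = max(th) / min(th),
              ratio_with_over_without = th[["with"]] / th[["without"]],
              ratio_without_over_with = th[["without"]] / th[["with"]],
              redistribution = stats::setNames(redis, c("with", "without")),
              runs = list(with = run_with, without = run_without))
  class(out) <- "architecture_comparison"
  out
}

#' @export
print.architecture_comparison <- function(x, ...) {
  cat(sprintf("Architecture comparison (%s binding), gamma = %.4g\n",
              x$mode, x$gamma))
  cat(sprintf("  +Cand1: t_half = %.1f min (pre-stimulus Cul1.SR1 %.3g nM)\n",
              x$t_half_min[["with"]], x$pre_stimulus_occupancy[["with"]]))
  cat(sprintf("  -Cand1: t_half = %.1f min (pre-stimulus Cul1.SR1 %.3g nM)\n",
              x$t_half_min[["without"]],
              x$pre_stimulus_occupancy[["without"]]))
  cat(sprintf("  fold ratio = %.2f\n", x$fold_ratio))
  invisible(x)
}
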