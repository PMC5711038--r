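#' Kinetic parameters of the Cand1 exchange cycle
#'
#' Bundles the dissociation constants and dissociation rate constants of the
#' four binding equilibria that make up the thermodynamic cycle
#' Cul1/SR/Cand1, together with the derived dimensionless scale factors.
#' Units are nM for dissociation constants and 1/s for rate constants;
#' association rate constants are implied as k/K (nM^-1 s^-1).
#'
#' The cycle must obey detailed balance, `Kca * Ksr_prime == Kca_prime * Ksr`:
#' the free-energy change of assembling the ternary Cul1.Cand1.SR complex
#' cannot depend on the order of binding.  By default `Kca` is therefore
#' derived from the other three constants rather than supplied, which makes
#' the cycle exactly balanced and the algebraic equilibrium an exact fixed
#' point of the dynamics.  A supplied `Kca` is accepted if its detailed
#' balance residual is below `tol`.
#'
#' @param Ksr dissociation constant of SR from Cul1.SR (nM).
#' @param ksr dissociation rate constant of Cul1.SR (1/s).
#' @param Ksr_prime dissociation constant of SR from the ternary
#'   Cul1.Cand1.SR complex (nM).
#' @param ksr_prime dissociation rate constant of SR from the ternary
#'   complex (1/s).
#' @param Kca_prime dissociation constant of Cand1 from the ternary
#'   complex (nM).
#' @param kca_prime dissociation rate constant of Cand1 from the ternary
#'   complex (1/s).
#' @param kca dissociation rate constant of Cul1.Cand1 (1/s).
#' @param Kca dissociation constant of Cand1 from Cul1.Cand1 (nM); derived
#'   from detailed balance when `NULL` (the default).
#' @param gamma affinity rescale factor (dimensionless, >= 1).  `gamma`
#'   multiplies the dissociation rate constants `ksr` and `kca` jointly, so
#'   `Ksr` and `Kca` scale by `gamma` while `eta`, the ternary constants and
#'   detailed balance are preserved.  Used to construct hypothetical
#'   weak-binding architectures.
#' @param tol relative tolerance for the detailed-balance residual of a
#'   supplied `Kca`.
#'
#' @return An object of class `crl_params`: a list with the four (K, k)
#'   pairs, `gamma`, and the derived factors `eta = Kca/Ksr`,
#'   `alpha = kca/ksr`, `beta = kca_prime/ksr_prime`.
#' @seealso [default_params()] for the published parameter set,
#'   [check_detailed_balance()].
#' @export
kinetic_params <- function(Ksr, ksr, Ksr_prime, ksr_prime,
                           Kca_prime, kca_prime, kca,
                           Kca = NULL, gamma = 1, tol = 1e-3) {
  vals <- c(Ksr = Ksr, ksr = ksr, Ksr_prime = Ksr_prime,
            ksr_prime = ksr_prime, Kca_prime = Kca_prime,
            kca_prime = kca_prime, kca = kca)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rate and dissociation constants must be finite and positive")
  if (!is.finite(gamma) || gamma < 1)
    stop("gamma must be >= 1")
  derived <- Kca_prime * Ksr / Ksr_prime
  if (is.null(Kca)) {
    Kca <- derived
  } else {
    if (Kca <= 0) stop("Kca must be positive")
    res <- abs(Kca * Ksr_prime - Kca_prime * Ksr) / (Kca_prime * Ksr)
    if (res > tol)
      stop(sprintf(
        "Kca violates detailed balance: residual %.3g exceeds tolerance %.3g",
        res, tol))
  }
  p <- list(Ksr = Ksr, ksr = ksr,
            Ksr_prime = Ksr_prime, ksr_prime = ksr_prime,
            Kca = Kca, kca = kca,
            Kca_prime = Kca_prime, kca_prime = kca_prime,
            gamma = gamma,
            eta = Kca / Ksr,
            alpha = kca / ksr,
            beta = kca_prime / ksr_prime)
  class(p) <- "crl_params"
  p
}

#' Published default parameter set
#'
#' The rate constants measured for the SCF(Fbxw7) ligase by FRET:
#' Ksr = 2.25e-4 nM, Ksr' = 650 nM, Kca' = 50 nM, ksr = 9e-7 1/s,
#' ksr' = 1.3 1/s, kca = 1e-5 1/s, kca' = 0.04 1/s.  Kca is derived from
#' detailed balance (~1.73e-5 nM), giving eta ~ 0.077, alpha ~ 11.1,
#' beta ~ 0.031.
#'
#' @param gamma affinity rescale factor, see [kinetic_params()].
#' @return A `crl_params` object.
#' @export
default_params <- function(gamma = 1) {
  kinetic_params(Ksr = 2.25e-4, ksr = 9e-7,
                 Ksr_prime = 650, ksr_prime = 1.3,
                 Kca_prime = 50, kca_prime = 0.04,
                 kca = 1e-5, gamma = gamma)
}

#' Detailed balance residual of a parameter set
#'
#' Returns `|Kca*Ksr_prime - Kca_prime*Ksr| / (Kca_prime*Ksr)`, the relative
#' residual of the thermodynamic-cycle constraint.  Zero for an exactly
#' balanced cycle; the published table values, with Kca rounded to
#' 1.73e-5 nM, give about 4.4e-4.
#'
#' @param params a `crl_params` object, or a list with fields `Kca`,
#'   `Ksr_prime`, `Kca_prime`, `Ksr`.
#' @return Dimensionless residual (numeric scalar).
#' @export
check_detailed_balance <- function(params) {
  abs(params$Kca * params$Ksr_prime - params$Kca_prime * params$Ksr) /
    (params$Kca_prime * params$Ksr)
}

#' Rescale the Cand1 preference factor eta
#'
#' Builds a parameter set whose relative binding affinity
#' `eta = Kca/Ksr = Kca_prime/Ksr_prime` equals a target value, by scaling
#' both Cand1 dissociation constants (`Kca`, `Kca_prime`) while keeping all
#' dissociation rate constants fixed (the Cand1 association rates absorb the
#' change).  Detailed balance is preserved by construction.
#'
#' @param params a `crl_params` object.
#' @param eta target eta (> 0).
#' @return A `crl_params` object with the requested eta.
#' @export
with_eta <- function(params, eta) {
  if (eta <= 0) stop("eta must be positive")
  scale <- eta / params$eta
  kinetic_params(Ksr = params$Ksr, ksr = params$ksr,
                 Ksr_prime = params$Ksr_prime, ksr_prime = params$ksr_prime,
                 Kca_prime = params$Kca_prime * scale,
                 kca_prime = params$kca_prime,
                 kca = params$kca, gamma = params$gamma)
}

#' @export
print.crl_params <- function(x, ...) {
  cat("Cand1 exchange-cycle parameters (nM, 1/s)\n")
  cat(sprintf("  Cul1.SR      : Ksr  = %.4g   ksr  = %.4g\n", x$Ksr, x$ksr))
  cat(sprintf("  ternary SR   : Ksr' = %.4g   ksr' = %.4g\n",
              x$Ksr_prime, x$ksr_prime))
  cat(sprintf("  Cul1.Cand1   : Kca  = %.4g   kca  = %.4g\n", x$Kca, x$kca))
  cat(sprintf("  ternary Cand1: Kca' = %.4g   kca' = %.4g\n",
              x$Kca_prime, x$kca_prime))
  cat(sprintf("  eta = %.4g  alpha = %.4g  beta = %.4g  gamma = %.4g\n",
              x$eta, x$alpha, x$beta, x$gamma))
  cat(sprintf("  detailed-balance residual: %.3g\n",
              check_detailed_balance(x)))
  invisible(x)
}

#' Conserved pool totals
#'
#' Total concentrations of the conserved components: the Cul1 scaffold,
#' Cand1, one total per substrate receptor species, and the initial amount
#' of each substrate.  Substrates are assigned to their cognate receptor in
#' [substrate_params()]; substrate totals are only conserved while no
#' degradation occurs.
#'
#' @param cul1 total Cul1 (nM).
#' @param cand1 total Cand1 (nM).
#' @param sr numeric vector of per-receptor totals (nM), length >= 1.
#' @param substrate numeric vector of initial substrate amounts (nM), may be
#'   empty.
#' @return An object of class `pool_totals`.
#' @export
pool_totals <- function(cul1, cand1, sr, substrate = numeric(0)) {
  if (length(sr) < 1) stop("at least one substrate receptor is required")
  if (any(c(cul1, cand1, sr, substrate) < 0))
    stop("totals must be non-negative")
  t <- list(cul1 = cul1, cand1 = cand1,
            sr = as.numeric(sr), substrate = as.numeric(substrate))
  class(t) <- "pool_totals"
  t
}

#' @export
print.pool_totals <- function(x, ...) {
  cat(sprintf("Pool totals (nM): Cul1 = %g, Cand1 = %g\n", x$cul1, x$cand1))
  cat("  SR:", paste(sprintf("%g", x$sr), collapse = ", "), "\n")
  if (length(x$substrate))
    cat("  substrate:", paste(sprintf("%g", x$substrate), collapse = ", "),
        "\n")
  invisible(x)
}

#' Substrate binding and degradation parameters
#'
#' One substrate species binding its cognate receptor.  The association rate
#' constant is supplied in M^-1 s^-1 (as usually reported) and converted to
#' nM^-1 s^-1 internally.  Degradation is a lumped first-order step
#' Cul1.SR.S -> Cul1.SR that stands in for neddylation, ubiquitin transfer
#' and proteasomal digestion.
#'
#' Binding topologies:
#' \describe{
#'   \item{`sequential`}{substrate binds the assembled ligase Cul1.SR only
#'     (with `ternary_binding = TRUE`, also the ternary Cul1.Cand1.SR).}
#'   \item{`random`}{additionally the free receptor binds substrate, and the
#'     receptor-substrate module SR.S docks onto Cul1 (reversibly) and onto
#'     Cul1.Cand1; implies `ternary_binding = TRUE`.}
#' }
#' Cand1-mediated ejection of a substrate-loaded receptor module
#' (Cul1.Cand1.SR.S -> SR.S + Cul1.Cand1) is suppressed in all topologies:
#' substrate binding triggers neddylation, which shuts down the exchange
#' pathway.  Spontaneous dissociation routes remain reversible.
#'
#' @param kon association rate constant (M^-1 s^-1).
#' @param koff dissociation rate constant (1/s).
#' @param kdeg lumped degradation rate constant (1/s); 0 disables
#'   degradation.
#' @param receptor index of the cognate receptor (into `sr` of
#'   [pool_totals()]).
#' @param binding_mode `"sequential"` or `"random"`.
#' @param ternary_binding should substrate also bind the ternary
#'   Cul1.Cand1.SR complex (and Cand1 exchange on the loaded ligase stay
#'   open)?  Forced `TRUE` for `binding_mode = "random"`.
#' @return An object of class `substrate_params`; `kon_nM` carries the
#'   converted association rate and `KD` the dissociation constant in nM.
#' @export
substrate_params <- function(kon, koff, kdeg, receptor = 1L,
                             binding_mode = c("sequential", "random"),
                             ternary_binding = NULL) {
  binding_mode <- match.arg(binding_mode)
  if (kon <= 0 || koff <= 0 || kdeg < 0)
    stop("kon and koff must be positive; kdeg must be non-negative")
  if (is.null(ternary_binding)) ternary_binding <- binding_mode == "random"
  if (binding_mode == "random" && !ternary_binding)
    stop("random-order binding requires ternary_binding = TRUE")
  s <- list(kon = kon, kon_nM = kon * 1e-9, koff = koff, kdeg = kdeg,
            KD = koff / (kon * 1e-9), receptor = as.integer(receptor),
            binding_mode = binding_mode, ternary_binding = ternary_binding)
  class(s) <- "substrate_params"
  s
}

#' @export
print.substrate_params <- function(x, ...) {
  cat(sprintf(
    "Substrate for SR%d: kon = %.3g /M/s (KD = %.3g nM), koff = %.3g /s, kdeg = %.3g /s\n",
    x$receptor, x$kon, x$KD, x$koff, x$kdeg))
  cat(sprintf("  binding: %s%s\n", x$binding_mode,
              if (x$ternary_binding) " (incl. ternary complex)" else ""))
  invisible(x)
}
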