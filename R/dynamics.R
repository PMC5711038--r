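#' Mass-action right-hand side of a network
#'
#' Time derivative of the dynamic state (all complexes, then free
#' substrates) under mass-action kinetics.  Free Cul1, Cand1 and free
#' receptors are computed algebraically from the conservation laws at every
#' evaluation, so the conserved totals are constant along any trajectory by
#' construction.
#'
#' @param net a `crl_network`.
#' @param state named numeric vector in [state_names()] order.
#' @param time ignored (autonomous system); present for deSolve
#'   compatibility.
#' @return List of one numeric vector: the derivative (nM/s), as deSolve
#'   expects.
#' @export
network_rhs <- function(net, state, time = 0) {
  n_cplx <- length(net$complexes)
  yc <- state[seq_len(n_cplx)]
  sfree <- if (net$n_sub > 0) state[n_cplx + seq_len(net$n_sub)] else numeric(0)
  bound <- drop(crossprod(net$comp[, seq_len(net$n_cons), drop = FALSE], yc))
  totals_vec <- c(net$totals$cul1, net$totals$cand1, net$totals$sr)
  x <- c(totals_vec - bound, sfree, yc)
  flux <- net$rxn_kon * x[net$rxn_A] * x[net$rxn_B] -
    net$rxn_koff * x[net$rxn_C]
  dy <- drop(net$stoich %*% flux)
  if (length(net$deg_from) > 0)
    dy <- dy + drop(net$deg_stoich %*% (net$deg_k * x[net$deg_from]))
  list(dy)
}

#' Free species implied by a dynamic state
#'
#' @param net a `crl_network`.
#' @param state dynamic state vector.
#' @return Named vector of the algebraic free concentrations (Cul1, Cand1,
#'   free receptors) plus the dynamic free substrates.
#' @export
free_species <- function(net, state) {
  n_cplx <- length(net$complexes)
  yc <- state[seq_len(n_cplx)]
  bound <- drop(crossprod(net$comp[, seq_len(net$n_cons), drop = FALSE], yc))
  totals_vec <- c(net$totals$cul1, net$totals$cand1, net$totals$sr)
  out <- c(totals_vec - bound,
           if (net$n_sub > 0) state[n_cplx + seq_len(net$n_sub)])
  names(out) <- net$species[seq_len(net$n_cons + net$n_sub)]
  out
}

#' Simulate a network trajectory
#'
#' Integrates the mass-action system with a stiff solver
#' ([deSolve::lsoda()]; the implied association rates span roughly six
#' orders of magnitude against dissociation rates down to 1e-6 1/s, so
#' tight tolerances are the default contract).
#'
#' @param net a `crl_network`.
#' @param y0 initial dynamic state ([state_names()] order); defaults to the
#'   pre-equilibrated binding network with all substrate free (see
#'   [initial_state()]).
#' @param times output time grid (s).
#' @param rtol,atol solver tolerances.
#' @return A `crl_timecourse`: data frame with `time` (s), one column per
#'   dynamic species, plus the algebraic free species; the network is
#'   attached as attribute `network`.
#' @export
simulate_network <- function(net, times, y0 = initial_state(net),
                             rtol = 1e-8, atol = 1e-12) {
  nm <- state_names(net)
  stopifnot(length(y0) == length(nm))
  y0 <- stats::setNames(as.numeric(y0), nm)
  sol <- deSolve::lsoda(
    y = y0, times = times,
    func = function(t, y, p) network_rhs(net, y, t),
    parms = NULL, rtol = rtol, atol = atol, maxsteps = 50000)
  out <- as.data.frame(sol)
  fs <- t(apply(as.matrix(out[, nm, drop = FALSE]), 1,
                function(y) free_species(net, y)[seq_len(net$n_cons)]))
  out <- cbind(out, as.data.frame(fs))
  class(out) <- c("crl_timecourse", "data.frame")
  attr(out, "network") <- net
  out
}

#' Initial state with pre-equilibrated binding network
#'
#' Complexes are set to the algebraic equilibrium of the substrate-free
#' binding network (see [solve_equilibrium()]); substrates are placed fully
#' free at their pool totals, modelling injection at t = 0 into a resting
#' mixture.
#'
#' @param net a `crl_network`.
#' @return Named state vector.
#' @export
initial_state <- function(net) {
  eq <- solve_equilibrium(net$params, net$totals, sr_scale = net$sr_scale)
  y0 <- stats::setNames(numeric(length(state_names(net))), state_names(net))
  y0[paste0("Cul1.SR", seq_len(net$n_rec))] <- eq$complexes$cul1_sr
  y0["Cul1.Cand1"] <- eq$complexes$cul1_cand1
  y0[paste0("Cul1.Cand1.SR", seq_len(net$n_rec))] <- eq$complexes$ternary
  if (net$n_sub > 0)
    y0[paste0("S", seq_len(net$n_sub))] <- net$totals$substrate
  y0
}

#' Conservation residuals along a trajectory
#'
#' Relative deviation of every conserved total (Cul1, Cand1, each receptor;
#' substrates too when no degradation removes them) reconstructed from the
#' trajectory.  With conservation-law elimination these are zero up to
#' solver round-off; the function exists as an independent audit.
#'
#' @param tc a `crl_timecourse`.
#' @return Matrix of relative residuals (rows = time points).
#' @export
conservation_residuals <- function(tc) {
  net <- attr(tc, "network")
  n_cplx <- length(net$complexes)
  Y <- as.matrix(tc[, net$complexes, drop = FALSE])
  totals_vec <- c(net$totals$cul1, net$totals$cand1, net$totals$sr)
  cons_nm <- net$species[seq_len(net$n_cons)]
  bound <- Y %*% net$comp[, seq_len(net$n_cons), drop = FALSE]
  free <- as.matrix(tc[, cons_nm, drop = FALSE])
  res <- sweep(bound + free, 2, totals_vec, "-")
  res <- sweep(res, 2, pmax(totals_vec, 1e-12), "/")
  if (net$n_sub > 0 && length(net$degradations) == 0) {
    sb <- Y %*% net$comp[, net$n_cons + seq_len(net$n_sub), drop = FALSE] +
      as.matrix(tc[, paste0("S", seq_len(net$n_sub)), drop = FALSE])
    sres <- sweep(sweep(sb, 2, net$totals$substrate, "-"), 2,
                  pmax(net$totals$substrate, 1e-12), "/")
    colnames(sres) <- paste0("S", seq_len(net$n_sub))
    res <- cbind(res, sres)
  }
  colnames(res)[seq_len(net$n_cons)] <- cons_nm
  res
}

#' Jacobian of the reduced dynamics
#'
#' Central-difference Jacobian of [network_rhs()] with respect to the
#' dynamic state.  Because the free species are eliminated, this is the
#' reduced Jacobian whose spectrum carries no structural zero modes from
#' the conservation laws.
#'
#' @param net a `crl_network`.
#' @param state state vector at which to linearise.
#' @param rel_step relative finite-difference step.
#' @return Square matrix (1/s).
#' @export
network_jacobian <- function(net, state, rel_step = 1e-7) {
  n <- length(state)
  J <- matrix(0, n, n)
  f <- function(y) network_rhs(net, y)[[1]]
  for (j in seq_len(n)) {
    h <- max(rel_step, abs(state[j]) * rel_step)
    yp <- state; yp[j] <- state[j] + h
    ym <- state; ym[j] <- state[j] - h
    J[, j] <- (f(yp) - f(ym)) / (2 * h)
  }
  dimnames(J) <- list(state_names(net), state_names(net))
  J
}

#' Tidy long-format view of a timecourse
#'
#' @param tc a `crl_timecourse`.
#' @return Data frame with columns `time_s`, `species`, `conc_nM`.
#' @export
as_long_timecourse <- function(tc) {
  cols <- setdiff(names(tc), "time")
  data.frame(
    time_s = rep(tc$time, times = length(cols)),
    species = rep(cols, each = nrow(tc)),
    conc_nM = unlist(tc[cols], use.names = FALSE))
}
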