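#' Assemble the reaction network of the exchange cycle
#'
#' Builds the explicit list of reversible binding reactions (and irreversible
#' degradation steps) for a system of one Cul1 scaffold, `length(totals$sr)`
#' receptor species, Cand1, and any number of substrates.  Free species
#' (Cul1, Cand1, free receptors) are never integrated: they are eliminated
#' through the conservation laws, so conservation holds by construction.
#' Free substrate is dynamic because degradation removes substrate from the
#' system.
#'
#' Association rate constants are implied: k_on = (dissociation rate
#' constant)/(dissociation constant).  The affinity rescale `gamma`
#' multiplies the dissociation rate constants of the binary complexes
#' (`ksr`, `kca`) so that `Ksr` and `Kca` scale by `gamma` with unchanged
#' association rates, preserving `eta` and detailed balance.
#'
#' @param params a `crl_params` object.
#' @param totals a `pool_totals` object; its `sr` length fixes the number of
#'   receptor species.
#' @param substrates list of `substrate_params` (possibly empty).
#' @param sr_scale optional numeric vector (one per receptor) jointly
#'   scaling that receptor's `Ksr`, `ksr`, `Ksr_prime` and `ksr_prime`;
#'   because both halves of the cycle scale together, detailed balance and
#'   the ternary Cand1 constants are untouched.  Used for receptor-affinity
#'   hierarchy variants.
#' @return An object of class `crl_network` holding the species table,
#'   composition matrix, reaction list and stoichiometry; pass it to
#'   [simulate_network()], [network_rhs()] or [steady_state()].
#' @export
build_network <- function(params, totals, substrates = list(),
                          sr_scale = NULL) {
  stopifnot(inherits(params, "crl_params"), inherits(totals, "pool_totals"))
  if (inherits(substrates, "substrate_params")) substrates <- list(substrates)
  n_rec <- length(totals$sr)
  m <- length(substrates)
  if (m != length(totals$substrate))
    stop("length(totals$substrate) must match the number of substrates")
  for (s in substrates)
    if (s$receptor < 1 || s$receptor > n_rec)
      stop(sprintf("substrate references receptor %d; only %d receptor(s)",
                   s$receptor, n_rec))
  if (is.null(sr_scale)) sr_scale <- rep(1, n_rec)
  if (length(sr_scale) != n_rec || any(sr_scale <= 0))
    stop("sr_scale needs one positive entry per receptor")

  gamma <- params$gamma
  Ksr  <- params$Ksr  * sr_scale * gamma
  ksr  <- params$ksr  * sr_scale * gamma
  Ksrp <- params$Ksr_prime * sr_scale
  ksrp <- params$ksr_prime * sr_scale
  Kca  <- params$Kca * gamma
  kca  <- params$kca * gamma
  ## per-cycle ternary Cand1 dissociation constant from detailed balance;
  ## equals Kca_prime whenever Ksr and Ksr_prime are scaled jointly
  Kcap <- Kca * Ksrp / Ksr
  kcap <- params$kca_prime

  ## ---- species ------------------------------------------------------
  free <- c("Cul1", "Cand1", paste0("SR", seq_len(n_rec)),
            if (m > 0) paste0("S", seq_len(m)))
  n_cons <- 2L + n_rec                      # conserved (algebraic) species
  cplx <- character(0)
  comp <- NULL                              # composition over conserved+S
  add_complex <- function(name, cul = 0, can = 0, sr = NULL, sub = NULL) {
    v <- numeric(n_cons + m)
    v[1] <- cul; v[2] <- can
    if (!is.null(sr)) v[2L + sr] <- 1
    if (!is.null(sub)) v[n_cons + sub] <- 1
    cplx <<- c(cplx, name)
    comp <<- rbind(comp, v)
  }
  for (i in seq_len(n_rec)) add_complex(paste0("Cul1.SR", i), 1, 0, sr = i)
  add_complex("Cul1.Cand1", 1, 1)
  for (i in seq_len(n_rec))
    add_complex(paste0("Cul1.Cand1.SR", i), 1, 1, sr = i)
  for (j in seq_len(m)) {
    s <- substrates[[j]]; r <- s$receptor
    add_complex(sprintf("Cul1.SR%d.S%d", r, j), 1, 0, sr = r, sub = j)
    if (s$ternary_binding)
      add_complex(sprintf("Cul1.Cand1.SR%d.S%d", r, j), 1, 1, sr = r, sub = j)
    if (s$binding_mode == "random")
      add_complex(sprintf("SR%d.S%d", r, j), 0, 0, sr = r, sub = j)
  }
  species <- c(free, cplx)
  idx <- function(nm) match(nm, species)

  ## ---- reactions ----------------------------------------------------
  reactions <- list()
  add_rxn <- function(A, B, C, kon, koff, reversible = TRUE) {
    reactions[[length(reactions) + 1L]] <<- list(
      A = idx(A), B = idx(B), C = idx(C), kon = kon, koff = koff,
      reversible = reversible,
      label = sprintf("%s + %s %s %s", A, B,
                      if (reversible) "<->" else "->", C))
  }
  for (i in seq_len(n_rec)) {
    sri <- paste0("SR", i)
    add_rxn("Cul1", sri, paste0("Cul1.SR", i), ksr[i] / Ksr[i], ksr[i])
    add_rxn(paste0("Cul1.SR", i), "Cand1", paste0("Cul1.Cand1.SR", i),
            kcap / Kcap[i], kcap)
    add_rxn("Cul1.Cand1", sri, paste0("Cul1.Cand1.SR", i),
            ksrp[i] / Ksrp[i], ksrp[i])
  }
  add_rxn("Cul1", "Cand1", "Cul1.Cand1", kca / Kca, kca)

  degradations <- list()
  for (j in seq_len(m)) {
    s <- substrates[[j]]; r <- s$receptor
    Sj <- paste0("S", j)
    css <- sprintf("Cul1.SR%d.S%d", r, j)
    add_rxn(paste0("Cul1.SR", r), Sj, css, s$kon_nM, s$koff)
    if (s$ternary_binding) {
      tss <- sprintf("Cul1.Cand1.SR%d.S%d", r, j)
      add_rxn(paste0("Cul1.Cand1.SR", r), Sj, tss, s$kon_nM, s$koff)
      ## Cand1 exchange on the loaded ligase (reversible; kca', Kca')
      add_rxn(css, "Cand1", tss, kcap / Kcap[r], kcap)
    }
    if (s$binding_mode == "random") {
      srs <- sprintf("SR%d.S%d", r, j)
      tss <- sprintf("Cul1.Cand1.SR%d.S%d", r, j)
      add_rxn(paste0("SR", r), Sj, srs, s$kon_nM, s$koff)
      add_rxn(srs, "Cul1", css, ksr[r] / Ksr[r], ksr[r])
      ## neddylation proxy: the exchange pathway cannot eject a loaded
      ## receptor module, so docking onto Cul1.Cand1 is one-way
      add_rxn(srs, "Cul1.Cand1", tss, ksrp[r] / Ksrp[r], 0,
              reversible = FALSE)
    }
    if (s$kdeg > 0)
      degradations[[length(degradations) + 1L]] <- list(
        from = idx(css), to = idx(paste0("Cul1.SR", r)), kdeg = s$kdeg,
        substrate = j,
        label = sprintf("%s -> Cul1.SR%d (kdeg)", css, r))
  }

  n_cplx <- length(cplx)
  n_dyn <- n_cplx + m                       # complexes + free substrates
  ## stoichiometry of dynamic species (complexes first, then free S)
  dyn_index <- function(i) {                # species index -> dynamic index
    if (i > n_cons + m) i - (n_cons + m)    # complex
    else if (i > n_cons) n_cplx + (i - n_cons)  # free substrate
    else 0L                                 # conserved free species
  }
  S <- matrix(0, n_dyn, length(reactions))
  for (r in seq_along(reactions)) {
    rx <- reactions[[r]]
    for (i in c(rx$A, rx$B)) {
      d <- dyn_index(i); if (d > 0) S[d, r] <- S[d, r] - 1
    }
    S[dyn_index(rx$C), r] <- S[dyn_index(rx$C), r] + 1
  }
  D <- matrix(0, n_dyn, length(degradations))
  for (r in seq_along(degradations)) {
    dg <- degradations[[r]]
    D[dyn_index(dg$from), r] <- -1
    D[dyn_index(dg$to), r] <- 1
  }

  net <- list(params = params, totals = totals, substrates = substrates,
              sr_scale = sr_scale, n_rec = n_rec, n_sub = m,
              species = species, complexes = cplx, n_cons = n_cons,
              comp = comp, reactions = reactions,
              degradations = degradations, stoich = S, deg_stoich = D,
              rxn_A = vapply(reactions, `[[`, 1L, "A"),
              rxn_B = vapply(reactions, `[[`, 1L, "B"),
              rxn_C = vapply(reactions, `[[`, 1L, "C"),
              rxn_kon = vapply(reactions, `[[`, 1, "kon"),
              rxn_koff = vapply(reactions, `[[`, 1, "koff"),
              deg_from = vapply(degradations, `[[`, 1L, "from"),
              deg_k = vapply(degradations, `[[`, 1, "kdeg"))
  class(net) <- "crl_network"
  net
}

#' @export
print.crl_network <- function(x, ...) {
  nrev <- sum(vapply(x$reactions, `[[`, TRUE, "reversible"))
  cat(sprintf(
    "Exchange-cycle network: %d receptor(s), %d substrate(s)\n",
    x$n_rec, x$n_sub))
  cat(sprintf("  %d dynamic species (%d complexes), %d reactions (%d reversible), %d degradation step(s)\n",
              nrow(x$stoich), length(x$complexes), length(x$reactions), nrev,
              length(x$degradations)))
  for (r in x$reactions) cat("   ", r$label, "\n")
  for (d in x$degradations) cat("   ", d$label, "\n")
  invisible(x)
}

#' Names of the dynamic state vector of a network
#'
#' Complex species first, then free substrates.
#' @param net a `crl_network`.
#' @return Character vector of state names.
#' @export
state_names <- function(net) {
  c(net$complexes, if (net$n_sub > 0) paste0("S", seq_len(net$n_sub)))
}
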