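# Shared fixtures.  Expensive simulations are memoised so that the module
# tests and the acceptance tests reuse the same runs.

tbl_params <- default_params()
tbl_totals <- pool_totals(300, 390, c(100, 560))          # occupancy mixture
deg_totals <- pool_totals(300, 0, c(30, 630), 300)        # degradation mixture
arch_totals <- pool_totals(300, 390, c(30, 630), 300)     # architecture mixture

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

fig3_run <- function(cand1_total, ...) {
  memo(paste0("fig3_", cand1_total), {
    run_degradation(tbl_params, deg_totals,
                    substrate_params(1e8, 1, 0.004),
                    cand1_total = cand1_total, ...)
  })
}

matched_gamma <- function() {
  memo("gamma", match_gamma(tbl_params, arch_totals))
}

arch_cmp <- function(mode) {
  memo(paste0("arch_", mode), {
    compare_architectures(
      tbl_params, arch_totals,
      substrate_params(1e7, 0.01, 0.004, binding_mode = mode),
      gamma = matched_gamma())
  })
}

fret_trace <- function() {
  memo("fret", simulate_fret_exchange(tbl_params))
}

hierarchy_fix <- function(variant) {
  memo(paste0("hier_", variant), hierarchy_experiment(variant))
}

table1_steady <- function() {
  memo("ss_table1", steady_state(tbl_params, tbl_totals))
}
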