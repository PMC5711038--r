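#' Read an experiment configuration file
#'
#' Experiment configurations are YAML documents with an `experiment` field
#' naming the analysis and optional override blocks (`params`, `totals`,
#' `substrate`, `solver`, `seed`, plus experiment-specific keys).  The
#' default configuration shipped with the package
#' (`system.file("extdata", "table1.yaml", package = "cand1cycle")`)
#' carries the published parameter set.
#'
#' @param path path to a YAML file.
#' @return Named list (the parsed configuration).
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Write a timecourse as a tidy TSV
#'
#' Long format, one row per (time, species) with a unit-annotated header.
#'
#' @param tc a `crl_timecourse`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  long <- as_long_timecourse(tc)
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.known_experiments <- c("table1_consistency", "tradeoff", "degrade",
                        "dose_scan", "redistribute", "hierarchy",
                        "compare_arch", "calibrate", "recover")

.known_keys <- c("experiment", "params", "totals", "substrate", "solver",
                 "seed", "cand1_total", "cand1_grid", "eta_values",
                 "variant", "mode", "target_k_obs", "sigma",
                 "n_replicates", "kca_prime_true", "out_prefix")

.config_params <- function(config) {
  p <- config$params
  if (is.null(p)) return(default_params())
  base <- default_params()
  for (k in names(p)) {
    if (!k %in% c("Ksr", "ksr", "Ksr_prime", "ksr_prime", "Kca_prime",
                  "kca_prime", "kca", "gamma"))
      stop("unknown params override: ", k)
  }
  args <- utils::modifyList(
    list(Ksr = base$Ksr, ksr = base$ksr, Ksr_prime = base$Ksr_prime,
         ksr_prime = base$ksr_prime, Kca_prime = base$Kca_prime,
         kca_prime = base$kca_prime, kca = base$kca, gamma = base$gamma),
    p)
  do.call(kinetic_params, args)
}

.config_totals <- function(config, default) {
  t <- config$totals
  if (is.null(t)) return(default)
  for (k in names(t))
    if (!k %in% c("cul1", "cand1", "sr", "substrate"))
      stop("unknown totals override: ", k)
  args <- utils::modifyList(
    list(cul1 = default$cul1, cand1 = default$cand1, sr = default$sr,
         substrate = default$substrate), t)
  do.call(pool_totals, args)
}

.config_substrate <- function(config, default) {
  s <- config$substrate
  if (is.null(s)) return(default)
  for (k in names(s))
    if (!k %in% c("kon", "koff", "kdeg", "receptor", "binding_mode",
                  "ternary_binding"))
      stop("unknown substrate override: ", k)
  args <- utils::modifyList(
    list(kon = default$kon, koff = default$koff, kdeg = default$kdeg,
         receptor = default$receptor, binding_mode = default$binding_mode,
         ternary_binding = default$ternary_binding), s)
  do.call(substrate_params, args)
}

#' Run a configured experiment
#'
#' Dispatches a configuration (list or YAML path) to the analysis modules
#' and returns a one-row-per-result summary data frame.  When `out_dir` is
#' given, tidy TSV tables and a provenance record (configuration echo,
#' package version, seed) are written there.
#'
#' Available experiments: `table1_consistency` (scale factors and detailed
#' balance residual), `tradeoff` (occupancy / exchange-rate scan),
#' `degrade` (one degradation run), `dose_scan` (half-life vs Cand1 with
#' optimum), `redistribute` (engaged-pool decomposition), `hierarchy`
#' (three-receptor ordering), `compare_arch` (exchange-factor vs
#' weak-binding design), `calibrate` (kca' estimation), `recover`
#' (noisy-parameter recovery).
#'
#' @param config a list, or path to a YAML file.
#' @param out_dir optional output directory for TSV files.
#' @param seed RNG seed override (used by `recover`).
#' @return Summary data frame, invisibly when `out_dir` is given.
#' @export
run_experiment <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  if (is.null(config$experiment))
    stop("config must name an 'experiment'")
  if (!config$experiment %in% .known_experiments)
    stop("unknown experiment: ", config$experiment,
         " (known: ", paste(.known_experiments, collapse = ", "), ")")
  unknown <- setdiff(names(config), .known_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(seed)) config$seed <- seed
  params <- .config_params(config)

  summary <- switch(
    config$experiment,
    table1_consistency = data.frame(
      eta = params$eta, alpha = params$alpha, beta = params$beta,
      Kca_nM = params$Kca,
      detailed_balance_residual = check_detailed_balance(params)),
    tradeoff = {
      totals <- .config_totals(config, pool_totals(300, 390, c(100, 560)))
      grid <- config$cand1_grid %||% 10^seq(0, 4, length.out = 41)
      etas <- config$eta_values %||% params$eta
      sc <- tradeoff_scan(params, totals, cand1_grid = grid,
                          eta_values = etas)
      as.data.frame(sc)
    },
    degrade = {
      totals <- .config_totals(config,
                               pool_totals(300, 100, c(30, 630), 300))
      sub <- .config_substrate(config, substrate_params(1e8, 1, 0.004))
      run <- run_degradation(params, totals, sub,
                             cand1_total = config$cand1_total)
      data.frame(cand1_total_nM = config$cand1_total %||% totals$cand1,
                 t_half_min = run$t_half_min[1],
                 censored = run$censored[1])
    },
    dose_scan = {
      totals <- .config_totals(config,
                               pool_totals(300, 0, c(30, 630), 300))
      sub <- .config_substrate(config, substrate_params(1e8, 1, 0.004))
      grid <- config$cand1_grid %||% c(0, 25, 50, 100, 200, 400, 700, 1000)
      dr <- cand1_dose_response(params, totals, sub, cand1_grid = grid)
      cbind(dr$curve,
            monotone = dr$monotone,
            optimum_cand1_nM = dr$optimum_cand1_nM)
    },
    redistribute = {
      totals <- .config_totals(config,
                               pool_totals(300, 100, c(30, 630), 300))
      sub <- .config_substrate(config, substrate_params(1e8, 1, 0.004))
      run <- run_degradation(params, totals, sub,
                             cand1_total = config$cand1_total)
      rd <- redistribution_analysis(run)
      data.frame(cand1_total_nM = config$cand1_total %||% totals$cand1,
                 peak_fold = rd$peak_fold, dominant = rd$dominant,
                 closure_error_nM = rd$closure_error)
    },
    hierarchy = {
      hx <- hierarchy_experiment(config$variant %||% "reference",
                                 params = params)
      data.frame(variant = hx$variant,
                 t_half_S1_min = hx$t_half_min[1],
                 t_half_S2_min = hx$t_half_min[2])
    },
    compare_arch = {
      totals <- .config_totals(config,
                               pool_totals(300, 390, c(30, 630), 300))
      sub <- .config_substrate(
        config, substrate_params(1e7, 0.01, 0.004,
                                 binding_mode = config$mode %||%
                                   "sequential"))
      cmp <- compare_architectures(params, totals, sub)
      data.frame(mode = cmp$mode, gamma = cmp$gamma,
                 t_half_with_min = cmp$t_half_min[["with"]],
                 t_half_without_min = cmp$t_half_min[["without"]],
                 fold_ratio = cmp$fold_ratio)
    },
    calibrate = {
      est <- estimate_kca_prime(config$target_k_obs %||% 0.07,
                                params = params)
      data.frame(target_k_obs_per_s = est$target_k_obs,
                 kca_prime_per_s = est$kca_prime, beta = est$beta,
                 k_obs_fit_per_s = est$k_obs_fit)
    },
    recover = {
      rs <- parameter_recovery_suite(
        kca_prime_true = config$kca_prime_true %||% 0.04,
        sigma = config$sigma %||% 0.02,
        n_replicates = config$n_replicates %||% 10,
        seed = config$seed %||% 1L, params = params)
      data.frame(kca_prime_true = rs$kca_prime_true,
                 relative_bias = rs$relative_bias, rmse = rs$rmse,
                 n_failed = rs$n_failed)
    })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prefix <- config$out_prefix %||% config$experiment
    utils::write.table(summary,
                       file.path(out_dir, paste0(prefix, "_summary.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    prov <- c(sprintf("package: cand1cycle %s",
                      as.character(utils::packageVersion("cand1cycle"))),
              sprintf("seed: %s", config$seed %||% "none"),
              "config:", yaml::as.yaml(config))
    writeLines(prov, file.path(out_dir, paste0(prefix, "_provenance.txt")))
    return(invisible(summary))
  }
  summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a
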