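#' Additive Gaussian noise model for simulated observables
#'
#' Describes how a deterministic trajectory is turned into a synthetic
#' noisy measurement: sampling interval, i.i.d. Gaussian noise of standard
#' deviation `sigma` (in nM, or as a fraction of the trace amplitude), and
#' an RNG seed.  Identical seeds reproduce identical traces bit for bit at
#' fixed solver settings.  Real fluorescence noise (drift, photobleaching)
#' is deliberately not emulated; the model exists to exercise the
#' estimators.
#'
#' @param sigma noise standard deviation (nM, or fraction of amplitude
#'   when `relative = TRUE`); must be >= 0.
#' @param seed integer RNG seed.
#' @param sampling_interval sampling interval (s).
#' @param relative interpret `sigma` as a fraction of the trace amplitude.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma, seed = 1L, sampling_interval = 0.5,
                        relative = FALSE) {
  if (sigma < 0) stop("sigma must be non-negative")
  out <- list(sigma = sigma, seed = as.integer(seed),
              sampling_interval = sampling_interval, relative = relative)
  class(out) <- "noise_model"
  out
}

#' Sample a noisy observable trace from a timecourse
#'
#' Resamples one observable of a deterministic trajectory at the noise
#' model's interval (linear interpolation of the dense solver output) and
#' adds i.i.d. Gaussian noise.  Negative samples are clipped at zero and
#' the clipped fraction is reported.
#'
#' @param tc a `crl_timecourse` (or any data frame with a `time` column).
#' @param observable column to observe.
#' @param noise a `noise_model`.
#' @return Data frame with columns `time`, `true`, `observed`; attributes
#'   `clip_fraction` and `sigma_abs` (the absolute noise SD used).
#' @export
generate_noisy_trace <- function(tc, observable, noise) {
  stopifnot(inherits(noise, "noise_model"))
  tt <- seq(min(tc$time), max(tc$time), by = noise$sampling_interval)
  y <- stats::approx(tc$time, tc[[observable]], xout = tt)$y
  sigma <- if (noise$relative) noise$sigma * diff(range(y)) else noise$sigma
  set.seed(noise$seed)
  obs <- y + stats::rnorm(length(y), sd = sigma)
  clipped <- obs < 0
  obs[clipped] <- 0
  out <- data.frame(time = tt, true = y, observed = obs)
  attr(out, "clip_fraction") <- mean(clipped)
  attr(out, "sigma_abs") <- sigma
  out
}

#' Parameter-recovery study for the exchange-rate calibration
#'
#' End-to-end check of the one-parameter calibration under measurement
#' noise: the exchange assay is simulated at a known ternary dissociation
#' rate `kca'`, noisy replicate traces are drawn, each replicate is fitted
#' and inverted through [estimate_kca_prime()], and the bias and RMSE of
#' the recovered values are reported.  Per-replicate seeds are derived
#' deterministically from the suite seed, so the whole table is
#' reproducible.
#'
#' @param kca_prime_true the ground-truth rate (1/s).
#' @param sigma noise SD as a fraction of trace amplitude.
#' @param n_replicates number of noisy replicates.
#' @param seed suite seed.
#' @param params base parameters (every constant except `kca'`).
#' @param sampling_interval trace sampling interval (s).
#' @param ... passed to [simulate_fret_exchange()].
#' @return List of class `recovery_suite`: `replicates` (data frame with
#'   per-replicate `k_obs` and `kca_prime_hat`, `NA` on fit failure),
#'   `bias`, `relative_bias`, `rmse`, `n_failed`.
#' @export
parameter_recovery_suite <- function(kca_prime_true = 0.04, sigma = 0.02,
                                     n_replicates = 20, seed = 1L,
                                     params = default_params(),
                                     sampling_interval = 0.5, ...) {
  p_true <- kinetic_params(Ksr = params$Ksr, ksr = params$ksr,
                           Ksr_prime = params$Ksr_prime,
                           ksr_prime = params$ksr_prime,
                           Kca_prime = params$Kca_prime,
                           kca_prime = kca_prime_true,
                           kca = params$kca, gamma = params$gamma)
  tc <- simulate_fret_exchange(p_true, ...)
  reps <- lapply(seq_len(n_replicates), function(i) {
    nm <- noise_model(sigma, seed = seed + i,
                      sampling_interval = sampling_interval,
                      relative = TRUE)
    tr <- generate_noisy_trace(tc, "Cul1.SR1", nm)
    tryCatch({
      fit <- fit_single_exponential(
        data.frame(time = tr$time, Cul1.SR1 = tr$observed))
      est <- estimate_kca_prime(fit$k_obs, params = params, ...)
      data.frame(replicate = i, k_obs = fit$k_obs,
                 kca_prime_hat = est$kca_prime)
    }, error = function(e)
      data.frame(replicate = i, k_obs = NA_real_,
                 kca_prime_hat = NA_real_))
  })
  reps <- do.call(rbind, reps)
  est <- reps$kca_prime_hat[!is.na(reps$kca_prime_hat)]
  out <- list(replicates = reps,
              kca_prime_true = kca_prime_true, sigma = sigma,
              bias = mean(est) - kca_prime_true,
              relative_bias = (mean(est) - kca_prime_true) / kca_prime_true,
              rmse = sqrt(mean((est - kca_prime_true)^2)),
              n_failed = sum(is.na(reps$kca_prime_hat)))
  class(out) <- "recovery_suite"
  out
}

#' @export
print.recovery_suite <- function(x, ...) {
  cat(sprintf(
    "Recovery of kca' = %.3g (sigma = %.2g, %d replicates, %d failed)\n",
    x$kca_prime_true, x$sigma, nrow(x$replicates), x$n_failed))
  cat(sprintf("  relative bias %.2g%%, RMSE %.3g\n",
              100 * x$relative_bias, x$rmse))
  invisible(x)
}
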