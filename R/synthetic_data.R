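## Run code with a local, fully specified RNG state; the caller's global
## RNG state is left untouched. Mersenne-Twister + Inversion is pinned so
## generated fixtures are identical across platforms and R sessions.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

## Multiplicative lognormal noise with unit mean and coefficient of
## variation cv (positivity-preserving for concentration measurements).
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Configuration of the synthetic-data generator
#'
#' Defines the ground truth and measurement model for seeded synthetic
#' chemostat tables and retentostat time series. Defaults emulate the study
#' conditions: a 1.4-L reactor fed at 35 mL/h from a 1.2-L mixing vessel
#' whose reservoir glucose is switched from 10 to 5 g/L; a growth-rate
#' dependent maintenance coefficient dropping about 3-fold (0.0100 to 0.0031
#' g/(g h)) between mu = 0.06 and 0.03 1/h; a small first-order death rate
#' (6e-5 1/h); 3% multiplicative measurement noise on concentrations (the
#' tolerance within which duplicate cultures are considered at steady
#' state); and sparse sampling, about
#' 12 points over 600 h, because frequent sampling would itself deplete the
#' biomass.
#'
#' @param truth a [pirt_params()] or [maintenance_profile()] ground truth.
#' @param Y_max maximum yield used with a maintenance-profile truth.
#' @param k_d_true true first-order death rate, 1/h.
#' @param noise_cv multiplicative measurement CV for biomass and feed
#'   glucose samples.
#' @param viability_noise_sd additive (truncated Gaussian) noise on the
#'   viable fraction.
#' @param sampling_times retentostat sampling times, h, strictly increasing
#'   from 0; default twice-weekly-like coverage of a 25-day run.
#' @param reactor a [reactor_config()].
#' @param feed a [mixing_vessel_feed()].
#' @param trehalose_max,glycogen_max peak storage contents, g per g biomass.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(truth = maintenance_profile(),
                             Y_max = 0.584,
                             k_d_true = 6e-5,
                             noise_cv = 0.03,
                             viability_noise_sd = 0.005,
                             sampling_times = 24 * c(0, 1, 3, 5, 8, 11, 14,
                                                     16, 19, 21, 23, 25),
                             reactor = reactor_config(),
                             feed = mixing_vessel_feed(),
                             trehalose_max = 0.12,
                             glycogen_max = 0.07) {
  stopifnot(noise_cv >= 0, viability_noise_sd >= 0,
            !is.unsorted(sampling_times, strictly = TRUE),
            sampling_times[1] == 0)
  structure(list(truth = truth, Y_max = Y_max, k_d_true = k_d_true,
                 noise_cv = noise_cv,
                 viability_noise_sd = viability_noise_sd,
                 sampling_times = sampling_times,
                 reactor = reactor, feed = feed,
                 trehalose_max = trehalose_max, glycogen_max = glycogen_max),
            class = "synthetic_config")
}

#' Generate a synthetic chemostat steady-state table
#'
#' Duplicate glucose-limited chemostats at a set of dilution rates, with
#' biomass concentrations derived from the Herbert-Pirt steady state and
#' perturbed by multiplicative lognormal noise. Deterministic for a fixed
#' seed.
#'
#' @param config a [synthetic_config()]; a maintenance-profile truth is
#'   evaluated at each dilution rate.
#' @param D_levels dilution rates, 1/h (default the four chemostat set
#'   points 0.025-0.10).
#' @param replicates independent cultures per dilution rate (default 2).
#' @param seed integer seed.
#' @return data frame with columns `D`, `C_S_in`, `C_X`, `C_S_residual`,
#'   `replicate`.
#' @export
generate_chemostat_table <- function(config,
                                     D_levels = c(0.025, 0.05, 0.075, 0.10),
                                     replicates = 2L, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- expand.grid(replicate = seq_len(replicates), D = D_levels)
  C_S_in <- config$feed$C_S_MC
  C_X_true <- vapply(grid$D, function(D) {
    p <- pirt_params(maintenance_at(config$truth, D), config$Y_max)
    chemostat_steady_state(D, C_S_in, p)$C_X
  }, numeric(1))
  noise <- with_seed(seed, lognormal_noise(nrow(grid), config$noise_cv))
  data.frame(D = grid$D,
             C_S_in = C_S_in,
             C_X = C_X_true * noise,
             C_S_residual = 0,
             replicate = grid$replicate)
}

## Storage-content emulation: a smooth bump in log(mu) peaking at
## mu = 0.0013 1/h. Width per compound is set so that contents at the final
## near-zero growth rates fall moderately below the peak (trehalose less than
## glycogen), matching the observed shapes.
storage_content_curve <- function(mu, max_level, sigma_log) {
  mu <- pmax(mu, 1e-6)
  max_level * exp(-(log(mu / 0.0013))^2 / (2 * sigma_log^2))
}

#' Generate a synthetic retentostat time series
#'
#' Forward-simulates the ground truth (growth-rate-dependent maintenance
#' supported) with first-order death, samples the trajectory at the sparse
#' sampling times, and applies the measurement model: multiplicative
#' lognormal noise on total biomass and on the feed glucose sample drawn at
#' the mixing vessel, additive truncated-Gaussian noise on the viable
#' fraction, and smooth storage-content curves (glycogen and trehalose)
#' peaking near mu = 0.0013 1/h with the configured maxima. Deterministic for
#' a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return data frame with columns `t_h`, `C_X_gL`, `viable_fraction`,
#'   `C_S_in_gL`, `glycogen_g_per_g`, `trehalose_g_per_g`; the noiseless
#'   trajectory and the ground truth are attached as attributes `truth`
#'   and `trajectory`.
#' @export
generate_retentostat_series <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  # the culture enters the retentostat from a chemostat steady state at D,
  # with the maintenance coefficient the culture had at that growth rate
  D <- config$reactor$D
  m_S_at_D <- maintenance_at(config$truth, D)
  C_X0 <- chemostat_steady_state(D, config$feed$C_S_MC,
                                 pirt_params(m_S_at_D, config$Y_max))$C_X
  traj <- simulate_retentostat(config$reactor, config$feed, config$truth,
                               C_X0 = C_X0, k_d = config$k_d_true,
                               t_grid = config$sampling_times,
                               mode = "pseudo_steady", Y_max = config$Y_max)
  n <- nrow(traj)
  glycogen <- storage_content_curve(traj$mu_per_h, config$glycogen_max, 0.67)
  trehalose <- storage_content_curve(traj$mu_per_h, config$trehalose_max, 1.28)
  with_seed(seed, {
    biomass_obs <- traj$C_X_gL * lognormal_noise(n, config$noise_cv)
    feed_obs <- traj$C_S_in_gL * lognormal_noise(n, config$noise_cv)
    viab_obs <- traj$viability +
      stats::rnorm(n, sd = config$viability_noise_sd)
    viab_obs <- pmin(pmax(viab_obs, 0), 1)
    glycogen_obs <- glycogen * lognormal_noise(n, config$noise_cv)
    trehalose_obs <- trehalose * lognormal_noise(n, config$noise_cv)
    out <- data.frame(t_h = traj$t_h,
                      C_X_gL = biomass_obs,
                      viable_fraction = viab_obs,
                      C_S_in_gL = feed_obs,
                      glycogen_g_per_g = glycogen_obs,
                      trehalose_g_per_g = trehalose_obs)
    attr(out, "truth") <- list(truth = config$truth, Y_max = config$Y_max,
                               k_d = config$k_d_true, C_X0 = C_X0)
    attr(out, "trajectory") <- traj
    out
  })
}
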