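#' Estimate Herbert-Pirt parameters from chemostat steady states
#'
#' At steady state the specific growth rate equals the dilution rate, so a
#' set of glucose-limited chemostats at different dilution rates traces the
#' line q_S = mu / Y_max + m_S. Ordinary least squares of q_S on mu gives the
#' maintenance coefficient as the intercept and the maximum yield as the
#' reciprocal slope.
#'
#' @param observations data frame with columns `D` (1/h), `C_S_in` (g/L),
#'   `C_X` (g/L) and optionally `C_S_residual` (g/L, default 0). The specific
#'   uptake rate is derived per row as q_S = D (C_S_in - C_S_residual) / C_X.
#' @return An object of class `pirt_regression` with fields `m_S`, `Y_max`,
#'   `se_mS` (standard error of the intercept), `se_slope` (standard error of
#'   1/Y_max), `r_squared`, `n_points`, the underlying `lm` fit, and `params`
#'   (a [pirt_params()], or NULL with a warning if the fitted values fall
#'   outside the physical range, e.g. a negative intercept — never clipped).
#' @examples
#' obs <- do.call(rbind, lapply(c(0.025, 0.05, 0.075, 0.10), function(D) {
#'   ss <- chemostat_steady_state(D, 10, pirt_params(0.0100, 0.584))
#'   data.frame(D = D, C_S_in = 10, C_X = ss$C_X)
#' }))
#' fit_pirt_chemostat(obs)
#' @export
fit_pirt_chemostat <- function(observations) {
  stopifnot(is.data.frame(observations))
  req <- c("D", "C_S_in", "C_X")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols)) {
    stop("observations lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(observations) < 3L) stop("need at least 3 observations")
  if (is.null(observations$C_S_residual)) observations$C_S_residual <- 0
  if (any(observations$C_X <= 0)) stop("C_X must be positive")
  if (length(unique(observations$D)) < 2L) {
    stop("need at least 2 distinct dilution rates (singular design)")
  }
  mu <- observations$D
  qs <- observations$D * (observations$C_S_in - observations$C_S_residual) /
    observations$C_X
  fit <- stats::lm(qs ~ mu)
  co <- summary(fit)$coefficients
  m_S <- unname(co["(Intercept)", "Estimate"])
  slope <- unname(co["mu", "Estimate"])
  r2 <- summary(fit)$r.squared
  params <- NULL
  if (m_S < 0) {
    warning("fitted maintenance coefficient is negative; returned unclipped")
  } else if (slope > 0 && 1 / slope <= 1) {
    params <- pirt_params(m_S, 1 / slope)
  } else {
    warning("fitted slope implies a yield outside (0, 1]; params not constructed")
  }
  structure(list(m_S = m_S,
                 Y_max = 1 / slope,
                 se_mS = unname(co["(Intercept)", "Std. Error"]),
                 se_slope = unname(co["mu", "Std. Error"]),
                 r_squared = r2,
                 n_points = nrow(observations),
                 params = params,
                 lm = fit),
            class = "pirt_regression")
}

#' @export
print.pirt_regression <- function(x, ...) {
  cat("Herbert-Pirt chemostat regression (q_S ~ mu)\n")
  cat(sprintf("  m_S   = %.4g +/- %.2g g/(g h)  (%.0f%% relative SE)\n",
              x$m_S, x$se_mS, 100 * x$se_mS / abs(x$m_S)))
  cat(sprintf("  Y_max = %.4g g/g  (slope SE %.2g)\n", x$Y_max, x$se_slope))
  cat(sprintf("  R^2 = %.4f over %d points\n", x$r_squared, x$n_points))
  invisible(x)
}

## SSE between observed series and a simulated trajectory evaluated at the
## observation times. The simulation is anchored at C_X0 at t = 0.
retentostat_sse <- function(m_S, k_d, times, total_biomass, viable_biomass,
                            reactor, feed, Y_max, C_X0, loss) {
  # candidate parameters explored by the optimizer may transiently starve the
  # culture (mu < 0); that is a legitimate trial point, so the simulator's
  # warning is silenced here
  traj <- suppressWarnings(
    simulate_retentostat(reactor, feed, pirt_params(m_S, Y_max),
                         C_X0 = C_X0, k_d = k_d, t_grid = times,
                         mode = "pseudo_steady"))
  res_tot <- if (loss == "relative") {
    log(total_biomass) - log(traj$C_X_gL)
  } else {
    total_biomass - traj$C_X_gL
  }
  sse <- sum(res_tot^2)
  if (!is.null(viable_biomass)) {
    res_v <- if (loss == "relative") {
      log(viable_biomass) - log(traj$C_Xv_gL)
    } else {
      viable_biomass - traj$C_Xv_gL
    }
    sse <- sse + sum(res_v^2)
  }
  sse
}

#' Fit maintenance coefficient (and death rate) to retentostat time series
#'
#' Least-squares regression of observed biomass accumulation against the
#' solution of the viable/dead biomass balances
#' dC_Xv/dt = (mu - k_d) C_Xv, dC_Xd/dt = k_d C_Xv, with the specific growth
#' rate set by the Herbert-Pirt relation under pseudo-steady, fully consumed
#' substrate. The maximum yield is supplied externally (from the chemostat
#' regression); the maintenance coefficient is free, and the death rate is
#' fitted jointly when a viable-fraction series is provided, otherwise held
#' fixed. When viability is provided the objective is the unweighted sum of
#' squared errors jointly over total and viable biomass. Each independent
#' experiment should be fitted separately, never pooled.
#'
#' Optimisation is bounded (m_S in [1e-5, 0.05] g/(g h), k_d in [0, 1e-2]
#' 1/h) L-BFGS-B on log10(m_S) with three starts log-spaced in m_S to avoid
#' local minima; the fit is deterministic.
#'
#' @param times sampling times, h, strictly increasing, starting at 0.
#' @param total_biomass observed total dry biomass, g/L, same length.
#' @param viable_fraction optional observed viable fraction in (0, 1]; when
#'   given, viable biomass = viable_fraction * total_biomass enters the
#'   objective and k_d is estimated by default.
#' @param reactor a [reactor_config()].
#' @param feed a [mixing_vessel_feed()].
#' @param Y_max maximum yield on glucose, g/g, held fixed.
#' @param k_d death rate, 1/h: a number to hold it fixed (default 0 when no
#'   viability data), or `"free"` to estimate it (default when viability data
#'   are present).
#' @param C_X0 initial biomass, g/L; defaults to the first observed total
#'   biomass (the chemostat steady state preceding the switch).
#' @param loss `"absolute"` (default) or `"relative"` (log-residual) SSE.
#' @param m_S_bounds,k_d_bounds parameter boxes.
#' @return An object of class `retentostat_fit` with `m_S_hat`, `k_d_hat`,
#'   `sse`, `trajectory` (fitted trajectory on the observation grid),
#'   `convergence` and the configuration needed by [derive_rates()].
#' @export
fit_retentostat <- function(times, total_biomass, viable_fraction = NULL,
                            reactor, feed, Y_max,
                            k_d = if (is.null(viable_fraction)) 0 else "free",
                            C_X0 = total_biomass[1],
                            loss = c("absolute", "relative"),
                            m_S_bounds = c(1e-5, 0.05),
                            k_d_bounds = c(0, 1e-2)) {
  loss <- match.arg(loss)
  stopifnot(is.numeric(times), is.numeric(total_biomass),
            length(times) == length(total_biomass))
  if (length(times) < 4L) stop("need at least 4 time points")
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("times must start at 0 and be strictly increasing")
  }
  if (any(total_biomass <= 0)) stop("total biomass must be positive")
  viable_biomass <- NULL
  if (!is.null(viable_fraction)) {
    stopifnot(length(viable_fraction) == length(times))
    if (any(viable_fraction <= 0 | viable_fraction > 1)) {
      stop("viable_fraction must lie in (0, 1]")
    }
    viable_biomass <- viable_fraction * total_biomass
  }
  fit_kd <- identical(k_d, "free")
  if (fit_kd && is.null(viable_biomass)) {
    stop("k_d can only be estimated when viability data are provided")
  }
  kd_fixed <- if (fit_kd) NA_real_ else as.numeric(k_d)

  obj <- function(x) {
    m_S <- 10^x[1]
    kd <- if (fit_kd) x[2] else kd_fixed
    retentostat_sse(m_S, kd, times, total_biomass, viable_biomass,
                    reactor, feed, Y_max, C_X0, loss)
  }
  lb <- log10(m_S_bounds[1]); ub <- log10(m_S_bounds[2])
  starts <- pmin(pmax(log10(c(3e-4, 2e-3, 1.5e-2)), lb), ub)
  runs <- lapply(starts, function(s) {
    par0 <- if (fit_kd) c(s, 1e-4) else s
    lower <- if (fit_kd) c(lb, k_d_bounds[1]) else lb
    upper <- if (fit_kd) c(ub, k_d_bounds[2]) else ub
    parscale <- if (fit_kd) c(1, 1e-4) else 1
    tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500,
                                  parscale = parscale)),
      error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs) || !any(vapply(runs, `[[`, 0, "convergence") == 0)) {
    msgs <- vapply(runs, function(r) r$message %||% "", "")
    stop("optimizer failed to converge from every start: ",
         paste(unique(msgs), collapse = "; "))
  }
  # an aborted line search on a noisy objective still reports its best point;
  # keep the lowest SSE over all starts as long as at least one converged
  best <- runs[[which.min(vapply(runs, `[[`, 0, "value"))]]
  m_S_hat <- 10^best$par[1]
  k_d_hat <- if (fit_kd) best$par[2] else kd_fixed
  at_bound <- abs(best$par[1] - lb) < 1e-6 || abs(best$par[1] - ub) < 1e-6 ||
    (fit_kd && (k_d_hat <= k_d_bounds[1] + 1e-12 ||
                  k_d_hat >= k_d_bounds[2] - 1e-12))
  if (at_bound) warning("a fitted parameter sits at its bound")

  traj <- simulate_retentostat(reactor, feed, pirt_params(m_S_hat, Y_max),
                               C_X0 = C_X0, k_d = k_d_hat, t_grid = times,
                               mode = "pseudo_steady")
  structure(list(m_S_hat = m_S_hat, k_d_hat = k_d_hat, sse = best$value,
                 trajectory = traj, convergence = best$convergence,
                 reactor = reactor, feed = feed, Y_max = Y_max,
                 C_X0 = C_X0, loss = loss),
            class = "retentostat_fit")
}

#' @export
print.retentostat_fit <- function(x, ...) {
  cat("Retentostat least-squares fit (Herbert-Pirt, pseudo-steady substrate)\n")
  cat(sprintf("  m_S = %.4g g/(g h), k_d = %.3g 1/h, SSE = %.4g\n",
              x$m_S_hat, x$k_d_hat, x$sse))
  invisible(x)
}

#' Growth and uptake rates derived from a retentostat fit
#'
#' Evaluates the fitted model on a time grid and reports the instantaneous
#' specific growth rate mu(t), the specific glucose uptake rate q_S(t) (via
#' the Herbert-Pirt relation with the fitted maintenance coefficient), and
#' the corresponding doubling time ln(2)/mu. Note mu(0) reflects the fitted
#' parameters: it equals the pre-switch dilution rate only if the culture
#' starts exactly at the fixed point of the fitted model.
#'
#' @param fit a `retentostat_fit`.
#' @param t_grid evaluation times, h (default 301 points over the fitted
#'   range).
#' @return data frame with `t_h`, `mu_per_h`, `qS_g_per_g_h`,
#'   `doubling_time_h` (Inf where mu <= 0).
#' @export
derive_rates <- function(fit, t_grid = NULL) {
  stopifnot(inherits(fit, "retentostat_fit"))
  if (is.null(t_grid)) {
    t_grid <- seq(0, max(fit$trajectory$t_h), length.out = 301)
  }
  traj <- simulate_retentostat(fit$reactor, fit$feed,
                               pirt_params(fit$m_S_hat, fit$Y_max),
                               C_X0 = fit$C_X0, k_d = fit$k_d_hat,
                               t_grid = t_grid, mode = "pseudo_steady")
  data.frame(t_h = traj$t_h,
             mu_per_h = traj$mu_per_h,
             qS_g_per_g_h = traj$qS_g_per_g_h,
             doubling_time_h = ifelse(traj$mu_per_h > 0,
                                      log(2) / traj$mu_per_h, Inf))
}
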