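#' Herbert-Pirt parameters
#'
#' Bundle the two parameters of the Herbert-Pirt relation
#' \eqn{q_S = \mu / Y^{max}_{X/S} + m_S}: the maintenance coefficient and the
#' maximum biomass yield on glucose. Units are fixed package-wide: time in
#' hours, concentrations in g/L, rates in 1/h or g/(g h).
#'
#' @param m_S maintenance coefficient, g glucose per g biomass per h (>= 0).
#' @param Y_max maximum biomass yield on glucose, g biomass per g glucose,
#'   in (0, 1].
#' @return An object of class `pirt_params`.
#' @examples
#' pirt_params(m_S = 0.0100, Y_max = 0.584)
#' @export
pirt_params <- function(m_S, Y_max) {
  stopifnot(is.numeric(m_S), length(m_S) == 1L, is.finite(m_S),
            is.numeric(Y_max), length(Y_max) == 1L, is.finite(Y_max))
  if (m_S < 0) stop("m_S must be non-negative")
  if (Y_max <= 0 || Y_max > 1) stop("Y_max must be in (0, 1]")
  structure(list(m_S = m_S, Y_max = Y_max), class = "pirt_params")
}

#' @export
print.pirt_params <- function(x, ...) {
  cat("Herbert-Pirt parameters\n")
  cat(sprintf("  m_S   = %.4g g/(g h)\n", x$m_S))
  cat(sprintf("  Y_max = %.4g g/g\n", x$Y_max))
  invisible(x)
}

#' Growth-rate-dependent maintenance profile
#'
#' A smooth, monotone non-decreasing interpolant m_S(mu) with two plateaus:
#' a high one at fast growth and a low one near zero growth, joined by a
#' logistic transition centred at `mu_mid`. This parameterises the observed
#' roughly 3-fold drop of the maintenance coefficient between specific growth
#' rates of about 0.06 and 0.03 per hour.
#'
#' @param m_S_high plateau maintenance coefficient at fast growth, g/(g h).
#' @param m_S_low plateau maintenance coefficient near zero growth, g/(g h);
#'   must not exceed `m_S_high`.
#' @param mu_mid transition midpoint, 1/h (> 0).
#' @param steepness dimensionless logistic slope (> 0); larger values give a
#'   sharper transition. The default places most of the transition inside
#'   mu in [0.03, 0.06] when `mu_mid = 0.045`.
#' @return An object of class `maintenance_profile`.
#' @export
maintenance_profile <- function(m_S_high = 0.0100, m_S_low = 0.0031,
                                mu_mid = 0.045, steepness = 300) {
  stopifnot(is.finite(m_S_high), is.finite(m_S_low),
            is.finite(mu_mid), is.finite(steepness))
  if (m_S_low < 0 || m_S_high < m_S_low) {
    stop("require 0 <= m_S_low <= m_S_high")
  }
  if (mu_mid <= 0) stop("mu_mid must be positive")
  if (steepness <= 0) stop("steepness must be positive")
  structure(list(m_S_high = m_S_high, m_S_low = m_S_low,
                 mu_mid = mu_mid, steepness = steepness),
            class = "maintenance_profile")
}

#' @export
print.maintenance_profile <- function(x, ...) {
  cat("Growth-rate-dependent maintenance profile (logistic)\n")
  cat(sprintf("  m_S: %.4g -> %.4g g/(g h), midpoint mu = %.3g 1/h, steepness %.3g\n",
              x$m_S_low, x$m_S_high, x$mu_mid, x$steepness))
  invisible(x)
}

#' Evaluate a maintenance profile at given growth rates
#'
#' @param mu specific growth rate(s), 1/h (>= 0).
#' @param profile a [maintenance_profile()].
#' @return m_S(mu), g/(g h); `m_S_low` as mu -> 0 and `m_S_high` as mu grows.
#' @export
evaluate_maintenance <- function(mu, profile) {
  stopifnot(inherits(profile, "maintenance_profile"), is.numeric(mu))
  if (any(mu < 0)) stop("mu must be non-negative")
  logistic <- stats::plogis((mu - profile$mu_mid) * profile$steepness)
  profile$m_S_low + (profile$m_S_high - profile$m_S_low) * logistic
}

#' Maintenance coefficient at a growth rate, for either parameter object
#'
#' Constant `pirt_params` return their `m_S`; a `maintenance_profile` is
#' evaluated at `mu`.
#' @param params a [pirt_params()] or [maintenance_profile()].
#' @param mu specific growth rate(s), 1/h.
#' @keywords internal
maintenance_at <- function(params, mu) {
  if (inherits(params, "pirt_params")) {
    rep_len(params$m_S, length(mu))
  } else if (inherits(params, "maintenance_profile")) {
    evaluate_maintenance(mu, params)
  } else {
    stop("params must be pirt_params or maintenance_profile")
  }
}

#' Herbert-Pirt specific glucose uptake rate
#'
#' The Herbert-Pirt relation partitions substrate consumption between growth
#' and maintenance: q_S = mu / Y_max + m_S.
#'
#' @param mu specific growth rate(s), 1/h (>= 0).
#' @param params a [pirt_params()].
#' @return q_S in g glucose per g biomass per h.
#' @examples
#' pirt_qs(0.025, pirt_params(0.0100, 0.584)) # 0.05281
#' @export
pirt_qs <- function(mu, params) {
  stopifnot(inherits(params, "pirt_params"), is.numeric(mu))
  if (any(mu < 0)) stop("mu must be non-negative")
  mu / params$Y_max + params$m_S
}

#' Apparent biomass yield at a growth rate
#'
#' Y_X/S(mu) = mu / q_S(mu); below Y_max because part of the substrate is
#' burned for maintenance. Returns 0 at mu = 0.
#'
#' @inheritParams pirt_qs
#' @return apparent yield, g biomass per g glucose.
#' @export
apparent_yield <- function(mu, params) {
  qs <- pirt_qs(mu, params)
  y <- ifelse(mu == 0, 0, mu / qs)
  y
}

#' Culture doubling time
#'
#' @param mu specific growth rate(s), 1/h (> 0).
#' @return doubling time ln(2)/mu, in hours.
#' @examples
#' doubling_time(0.025) # 27.7 h
#' @export
doubling_time <- function(mu) {
  stopifnot(is.numeric(mu))
  if (any(mu <= 0)) stop("mu must be positive for a finite doubling time")
  log(2) / mu
}

#' Chemostat steady state under the Herbert-Pirt relation
#'
#' At steady state in a glucose-limited chemostat the specific growth rate
#' equals the dilution rate D, and the substrate balance fixes the biomass
#' concentration: q_S * C_X = D * (C_S_in - C_S_residual).
#'
#' The washout bound on D is deliberately not enforced; callers exploring
#' D beyond the supply-limited range get the algebraic solution.
#'
#' @param D dilution rate, 1/h (> 0).
#' @param C_S_in feed glucose concentration, g/L.
#' @param params a [pirt_params()].
#' @param C_S_residual residual glucose in the reactor, g/L (default 0:
#'   measured residuals are mg/L-scale, negligible in the yield algebra).
#' @return list with `C_X` (g/L), `q_S` (g/(g h)) and `Y_app` (g/g).
#' @examples
#' chemostat_steady_state(0.025, 10, pirt_params(0.0100, 0.584))$C_X # 4.73 g/L
#' @export
chemostat_steady_state <- function(D, C_S_in, params, C_S_residual = 0) {
  stopifnot(is.numeric(D), is.numeric(C_S_in), is.numeric(C_S_residual))
  if (any(D <= 0)) stop("D must be positive")
  if (any(C_S_residual < 0)) stop("C_S_residual must be non-negative")
  if (any(C_S_residual >= C_S_in & C_S_in > 0) || any(C_S_residual > C_S_in)) {
    stop("C_S_residual must be smaller than C_S_in")
  }
  qs <- pirt_qs(D, params)
  list(C_X = D * (C_S_in - C_S_residual) / qs,
       q_S = qs,
       Y_app = D / qs)
}
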