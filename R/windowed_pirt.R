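#' Interval specific growth rate from two biomass measurements
#'
#' mu = ln(C_X2 / C_X1) / (t2 - t1); the sign follows the direction of the
#' biomass change.
#'
#' @param t1,t2 interval bounds, h, t2 > t1; vectorised in parallel.
#' @param C_X1,C_X2 biomass concentrations at t1 and t2, g/L (> 0).
#' @return interval-average specific growth rate, 1/h.
#' @export
interval_mu <- function(t1, C_X1, t2, C_X2) {
  stopifnot(is.numeric(t1), is.numeric(t2), is.numeric(C_X1), is.numeric(C_X2))
  if (any(C_X1 <= 0) || any(C_X2 <= 0)) stop("biomass must be positive")
  if (any(t2 <= t1)) stop("t2 must exceed t1")
  log(C_X2 / C_X1) / (t2 - t1)
}

#' Interval growth rate, yield and uptake rate from a biomass pair
#'
#' Over an interval [t1, t2] between two sampling points the mass balances
#' give the interval growth rate mu = ln(C_X2/C_X1)/(t2-t1), the glucose
#' consumed S2 - S1 (from the feed integral, assuming complete consumption of
#' the glucose entering the reactor), the apparent yield
#' Y_X/S = (C_X2 - C_X1) V / (S2 - S1), and the specific uptake rate
#' q_S = mu / Y_X/S. When the biomass is constant the 0/0 expression for q_S
#' is replaced by its maintenance-only limit, the supply rate per unit
#' biomass.
#'
#' @inheritParams interval_mu
#' @param feed a [mixing_vessel_feed()].
#' @param reactor a [reactor_config()].
#' @return one-row data frame of class `interval_rates`: `t1`, `t2`, `C_X1`,
#'   `C_X2`, `mu` (1/h), `S_consumed` (g), `Y_app` (g/g), `q_S` (g/(g h)).
#' @export
interval_rates <- function(t1, C_X1, t2, C_X2, feed, reactor) {
  mu <- interval_mu(t1, C_X1, t2, C_X2)
  S <- substrate_supplied(t1, t2, feed)
  if (any(S <= 0)) stop("no substrate supplied over the interval")
  Y_app <- (C_X2 - C_X1) * reactor$V / S
  q_S <- ifelse(C_X2 == C_X1,
                # zero-growth limit: all supplied glucose goes to maintenance
                S / ((t2 - t1) * C_X1 * reactor$V),
                mu / Y_app)
  out <- data.frame(t1 = t1, t2 = t2, C_X1 = C_X1, C_X2 = C_X2,
                    mu = mu, S_consumed = S, Y_app = Y_app, q_S = q_S)
  class(out) <- c("interval_rates", "data.frame")
  out
}

#' Interval rates for all consecutive sampling points of a series
#'
#' Convenience wrapper applying [interval_rates()] between each pair of
#' consecutive sampling points of a retentostat biomass series.
#'
#' @param times sampling times, h, strictly increasing.
#' @param C_X biomass concentrations, g/L.
#' @inheritParams interval_rates
#' @return data frame with one row per interval.
#' @export
series_interval_rates <- function(times, C_X, feed, reactor) {
  stopifnot(length(times) == length(C_X), length(times) >= 2L)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  n <- length(times)
  interval_rates(times[-n], C_X[-n], times[-1], C_X[-1], feed, reactor)
}

#' Moving-window Herbert-Pirt regression over consecutive growth-rate levels
#'
#' Resolves the growth-rate dependence of the maintenance coefficient and the
#' maximum yield: (mu, q_S) points are grouped into growth-rate levels
#' (typically duplicate experiments per level), levels are ordered by
#' descending mu, and an ordinary least-squares line q_S ~ mu is fitted on
#' each window of `window` consecutive levels (all replicate points
#' included), advancing one level at a time. Each window yields the local
#' maintenance coefficient (intercept), maximum yield (reciprocal slope) and
#' fit statistics; a window is accepted only when the q_S-mu relation is
#' effectively linear, r-squared > `r2_min`.
#'
#' @param points data frame with columns `mu` (1/h) and `q_S` (g/(g h)), and
#'   optionally `level` (grouping replicates at the same growth-rate level;
#'   defaults to one level per distinct `mu` value).
#' @param window number of consecutive mu levels per regression (default 4).
#' @param r2_min acceptance threshold on r-squared (default 0.99).
#' @return data frame with one row per window: `mu_min`, `mu_max`, `m_S`,
#'   `se_mS`, `Y_max`, `se_Y` (delta-method standard error of 1/slope), `r2`,
#'   `n_points`, `accepted`.
#' @export
moving_window_regression <- function(points, window = 4L, r2_min = 0.99) {
  stopifnot(is.data.frame(points), all(c("mu", "q_S") %in% names(points)))
  if (is.null(points$level)) {
    points$level <- match(points$mu, sort(unique(points$mu), decreasing = TRUE))
  }
  lev_mu <- tapply(points$mu, points$level, mean)
  lev_order <- names(sort(lev_mu, decreasing = TRUE))
  n_lev <- length(lev_order)
  if (n_lev < window) {
    stop("need at least ", window, " distinct growth-rate levels")
  }
  counts <- table(points$level)
  if (any(counts < 2L)) {
    warning("some growth-rate levels have a single replicate")
  }
  out <- vector("list", n_lev - window + 1L)
  for (i in seq_along(out)) {
    levs <- lev_order[i:(i + window - 1L)]
    w <- points[points$level %in% levs, ]
    fit <- stats::lm(q_S ~ mu, data = w)
    co <- summary(fit)$coefficients
    slope <- unname(co["mu", "Estimate"])
    se_slope <- unname(co["mu", "Std. Error"])
    r2 <- summary(fit)$r.squared
    out[[i]] <- data.frame(
      mu_min = min(w$mu), mu_max = max(w$mu),
      m_S = unname(co["(Intercept)", "Estimate"]),
      se_mS = unname(co["(Intercept)", "Std. Error"]),
      Y_max = 1 / slope,
      se_Y = se_slope / slope^2,   # delta method for 1/slope
      r2 = r2,
      n_points = nrow(w),
      accepted = r2 > r2_min)
  }
  do.call(rbind, out)
}
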