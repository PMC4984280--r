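#' Mixing-vessel feed configuration
#'
#' The declining feed glucose profile of a retentostat is generated by a
#' constant-volume, ideally mixed vessel upstream of the bioreactor. At the
#' retentostat start (t = 0) the reservoir feeding the mixing vessel is
#' switched from the chemostat-phase concentration `C_S_MC` to the lower
#' retentostat-phase concentration `C_S_MR`, so the concentration entering
#' the reactor decays exponentially from `C_S_MC` towards `C_S_MR` with time
#' constant `V_S / phi_V`.
#'
#' @param V_S mixing-vessel working volume, L (> 0). Default 1.2 L.
#' @param phi_V medium flow rate, L/h (> 0). Default 0.035 L/h.
#' @param C_S_MC chemostat-phase reservoir glucose, g/L. Default 10.
#' @param C_S_MR retentostat-phase reservoir glucose, g/L. Default 5.
#' @return An object of class `mixing_vessel_feed`.
#' @export
mixing_vessel_feed <- function(V_S = 1.2, phi_V = 0.035,
                               C_S_MC = 10, C_S_MR = 5) {
  stopifnot(is.finite(V_S), is.finite(phi_V),
            is.finite(C_S_MC), is.finite(C_S_MR))
  if (V_S <= 0) stop("V_S must be positive")
  if (phi_V <= 0) stop("phi_V must be positive")
  if (C_S_MR < 0 || C_S_MC < C_S_MR) stop("require C_S_MC >= C_S_MR >= 0")
  structure(list(V_S = V_S, phi_V = phi_V, C_S_MC = C_S_MC, C_S_MR = C_S_MR),
            class = "mixing_vessel_feed")
}

#' @export
print.mixing_vessel_feed <- function(x, ...) {
  cat("Mixing-vessel feed\n")
  cat(sprintf("  V_S = %.3g L, phi_V = %.3g L/h (time constant %.3g h)\n",
              x$V_S, x$phi_V, x$V_S / x$phi_V))
  cat(sprintf("  reservoir glucose: %.3g -> %.3g g/L\n", x$C_S_MC, x$C_S_MR))
  invisible(x)
}

#' Feed glucose concentration entering the bioreactor
#'
#' C_S_in(t) = (C_S_MC - C_S_MR) exp(-phi_V t / V_S) + C_S_MR, with t = 0 the
#' instant of the reservoir switch. Monotone non-increasing in t.
#'
#' @param t time since the reservoir switch, h (>= 0); vectorised.
#' @param feed a [mixing_vessel_feed()].
#' @return feed glucose concentration, g/L.
#' @examples
#' feed <- mixing_vessel_feed()
#' feed_concentration(c(0, 23.77, 600), feed)
#' @export
feed_concentration <- function(t, feed) {
  stopifnot(inherits(feed, "mixing_vessel_feed"), is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  (feed$C_S_MC - feed$C_S_MR) * exp(-feed$phi_V * t / feed$V_S) + feed$C_S_MR
}

#' Glucose supplied to the bioreactor over a time interval
#'
#' Integrates the feed concentration times the constant flow rate in closed
#' form:
#' phi_V * ( C_S_MR (t2 - t1)
#'           + (C_S_MC - C_S_MR) (V_S / phi_V) (e^{-phi_V t1 / V_S} - e^{-phi_V t2 / V_S}) ).
#' Additive over adjacent intervals.
#'
#' @param t1,t2 interval bounds, h, with 0 <= t1 <= t2; vectorised in parallel.
#' @param feed a [mixing_vessel_feed()].
#' @return glucose supplied, grams.
#' @export
substrate_supplied <- function(t1, t2, feed) {
  stopifnot(inherits(feed, "mixing_vessel_feed"),
            is.numeric(t1), is.numeric(t2))
  if (any(t1 < 0)) stop("t1 must be non-negative")
  if (any(t2 < t1)) stop("t2 must be >= t1")
  b <- feed$phi_V / feed$V_S
  feed$phi_V * (feed$C_S_MR * (t2 - t1) +
                  (feed$C_S_MC - feed$C_S_MR) / b * (exp(-b * t1) - exp(-b * t2)))
}
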