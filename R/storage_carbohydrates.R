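#' Storage-carbohydrate measurement
#'
#' A time-stamped measurement of intracellular glycogen and trehalose
#' contents together with the culture biomass concentration. Glycogen is
#' expressed directly in glucose equivalents per gram dry biomass; trehalose
#' is per gram dry biomass and converted to glucose equivalents by the
#' hydrolysis stoichiometry when fractions are computed.
#'
#' @param t sampling time, h.
#' @param glycogen glycogen content, g glucose-equivalents per g biomass,
#'   in [0, 1).
#' @param trehalose trehalose content, g per g biomass, in [0, 1).
#' @param C_X total biomass concentration, g/L (> 0).
#' @return An object of class `storage_measurement`.
#' @export
storage_measurement <- function(t, glycogen, trehalose, C_X) {
  stopifnot(is.finite(t), is.finite(glycogen), is.finite(trehalose),
            is.finite(C_X))
  if (glycogen < 0 || glycogen >= 1 || trehalose < 0 || trehalose >= 1) {
    stop("storage contents must lie in [0, 1) g per g biomass")
  }
  if (C_X <= 0) stop("C_X must be positive")
  structure(list(t = t, glycogen = glycogen, trehalose = trehalose, C_X = C_X),
            class = "storage_measurement")
}

#' Default trehalose-to-glucose-equivalent conversion factor
#'
#' Hydrolysis stoichiometry: one trehalose (342.30 g/mol) yields two glucose
#' (180.16 g/mol each), i.e. 2 * 180.16 / 342.30 ~ 1.053 g glucose per g
#' trehalose.
#' @export
trehalose_glucose_factor <- 2 * 180.16 / 342.30

#' Fraction of consumed glucose diverted to storage carbohydrates
#'
#' Relates the change in total stored glucose equivalents (glycogen plus
#' trehalose, scaled by biomass and reactor volume) between two measurements
#' to the glucose supplied over the same interval (which, under complete
#' consumption, equals the glucose consumed). The fraction may be negative
#' when stores are mobilised; it is reported, not clipped.
#'
#' @param m1,m2 [storage_measurement()] objects with m2 later than m1.
#' @param feed a [mixing_vessel_feed()].
#' @param reactor a [reactor_config()].
#' @param trehalose_factor g glucose equivalents per g trehalose
#'   (default [trehalose_glucose_factor], hydrolysis stoichiometry; the
#'   conversion is configurable).
#' @return fraction of consumed glucose stored (dimensionless).
#' @examples
#' feed <- mixing_vessel_feed(); reactor <- reactor_config()
#' m1 <- storage_measurement(0, 0.01, 0.02, 5)
#' m2 <- storage_measurement(120, 0.03, 0.05, 12)
#' storage_fraction(m1, m2, feed, reactor)
#' @export
storage_fraction <- function(m1, m2, feed, reactor,
                             trehalose_factor = trehalose_glucose_factor) {
  stopifnot(inherits(m1, "storage_measurement"),
            inherits(m2, "storage_measurement"))
  if (m2$t <= m1$t) stop("m2 must be later than m1")
  S <- substrate_supplied(m1$t, m2$t, feed)
  if (S <= 0) stop("no substrate supplied over the interval")
  V <- reactor$V
  d_glycogen <- (m2$glycogen * m2$C_X - m1$glycogen * m1$C_X) * V
  d_trehalose <- (m2$trehalose * m2$C_X - m1$trehalose * m1$C_X) * V *
    trehalose_factor
  (d_glycogen + d_trehalose) / S
}
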