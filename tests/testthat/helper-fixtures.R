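# Study configuration used throughout the tests: 1.4-L reactor fed at
# 35 mL/h from a 1.2-L mixing vessel, reservoir glucose switched 10 -> 5 g/L,
# chemostat-phase Pirt parameters (0.0100, 0.584) and near-zero-growth
# maintenance 0.0031 g/(g h).
study_reactor <- function() reactor_config(V = 1.4, phi_V = 0.035)
study_feed <- function() mixing_vessel_feed(V_S = 1.2, phi_V = 0.035,
                                            C_S_MC = 10, C_S_MR = 5)
chemostat_params <- function() pirt_params(m_S = 0.0100, Y_max = 0.584)
retentostat_params <- function() pirt_params(m_S = 0.0031, Y_max = 0.584)

# initial biomass: chemostat steady state at D = 0.025 with chemostat-phase
# parameters (4.734 g/L)
study_C_X0 <- function() {
  chemostat_steady_state(0.025, 10, chemostat_params())$C_X
}

study_sampling_times <- function() 24 * c(0, 1, 3, 5, 8, 11, 14, 16, 19, 21, 23, 25)

# noise-free chemostat observations on the Herbert-Pirt line
exact_chemostat_obs <- function(params = chemostat_params(),
                                D_levels = c(0.025, 0.05, 0.075, 0.10),
                                C_S_in = 10) {
  do.call(rbind, lapply(D_levels, function(D) {
    ss <- chemostat_steady_state(D, C_S_in, params)
    data.frame(D = D, C_S_in = C_S_in, C_X = ss$C_X)
  }))
}
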