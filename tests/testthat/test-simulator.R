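test_that("the maintenance-only state is a fixed point under constant feed", {
  # with full biomass retention the culture stops changing when the whole
  # glucose supply goes to maintenance: C_X* = D C_S_in / m_S, mu = 0
  reactor <- study_reactor()
  flat <- mixing_vessel_feed(C_S_MC = 10, C_S_MR = 10)
  p <- chemostat_params()
  C_X_star <- reactor$D * 10 / p$m_S
  traj <- simulate_retentostat(reactor, flat, p, C_X0 = C_X_star,
                               t_grid = seq(0, 400, by = 10))
  expect_equal(traj$C_X_gL, rep(C_X_star, nrow(traj)), tolerance = 1e-7)
  expect_equal(traj$mu_per_h, rep(0, nrow(traj)), tolerance = 1e-9)
  # below the fixed point the culture grows towards it, never past it
  grow <- simulate_retentostat(reactor, flat, p, C_X0 = C_X_star / 2,
                               t_grid = seq(0, 2000, by = 50))
  expect_true(all(diff(grow$C_X_gL) > 0))
  expect_true(all(grow$C_X_gL <= C_X_star))
})

test_that("numeric integration matches the closed-form oracle", {
  reactor <- study_reactor(); feed <- study_feed()
  p <- retentostat_params(); C_X0 <- study_C_X0()
  tg <- seq(0, 600, by = 2)
  traj <- simulate_retentostat(reactor, feed, p, C_X0 = C_X0, t_grid = tg)
  oracle <- closed_form_biomass(tg, reactor, feed, p, C_X0)
  expect_lt(max(abs(traj$C_X_gL - oracle) / oracle), 1e-6)
})

test_that("closed-form biomass has the expected endpoints and asymptotes", {
  reactor <- study_reactor(); feed <- study_feed(); C_X0 <- study_C_X0()
  expect_equal(closed_form_biomass(0, reactor, feed, retentostat_params(), C_X0),
               C_X0)
  expect_equal(closed_form_biomass(600, reactor, feed, retentostat_params(), C_X0),
               29.2, tolerance = 1e-3)
  # asymptote D * C_S_MR / m_S
  expect_equal(closed_form_biomass(1e5, reactor, feed, retentostat_params(), C_X0),
               0.025 * 5 / 0.0031, tolerance = 1e-6)
  expect_equal(closed_form_biomass(1e5, reactor, feed, chemostat_params(), C_X0),
               12.5, tolerance = 1e-6)
})

test_that("the specific growth rate declines smoothly from D to near zero", {
  traj <- simulate_retentostat(study_reactor(), study_feed(),
                               retentostat_params(), C_X0 = study_C_X0(),
                               t_grid = seq(0, 600, by = 2))
  expect_true(all(diff(traj$mu_per_h) < 0))
  # simulated with the chemostat-phase parameters the culture leaves its
  # steady state continuously: mu(0) = D
  pred <- simulate_retentostat(study_reactor(), study_feed(),
                               chemostat_params(), C_X0 = study_C_X0(),
                               t_grid = c(0, 10))
  expect_equal(pred$mu_per_h[1], 0.025, tolerance = 1e-9)
})

test_that("viability is 1 without death and declines linearly in small k_d", {
  reactor <- study_reactor(); feed <- study_feed()
  p <- retentostat_params(); C_X0 <- study_C_X0()
  tg <- seq(0, 600, by = 5)
  no_death <- simulate_retentostat(reactor, feed, p, C_X0 = C_X0, t_grid = tg)
  expect_true(all(viability_series(no_death) == 1))

  kd1 <- simulate_retentostat(reactor, feed, p, C_X0 = C_X0, k_d = 6e-5,
                              t_grid = tg)
  v1 <- viability_series(kd1)
  expect_true(all(diff(v1) < 0))
  expect_gte(v1[length(v1)], 0.97)

  kd2 <- simulate_retentostat(reactor, feed, p, C_X0 = C_X0, k_d = 1.2e-4,
                              t_grid = tg)
  dead1 <- 1 - v1[length(v1)]
  dead2 <- 1 - viability_series(kd2)[nrow(kd2)]
  expect_equal(dead2 / dead1, 2, tolerance = 0.05)
})

test_that("full_ode agrees with pseudo_steady when residual glucose is tiny", {
  reactor <- study_reactor(); feed <- study_feed()
  p <- retentostat_params(); C_X0 <- study_C_X0()
  tg <- seq(0, 600, by = 10)
  ps <- simulate_retentostat(reactor, feed, p, C_X0 = C_X0, t_grid = tg)
  fo <- simulate_retentostat(reactor, feed, p, C_X0 = C_X0, t_grid = tg,
                             mode = "full_ode")
  expect_true(all(fo$C_S_gL < 1e-3))
  i <- nrow(ps)
  expect_lt(abs(fo$C_X_gL[i] - ps$C_X_gL[i]) / ps$C_X_gL[i], 0.01)
})

test_that("full_ode conserves mass: supply = growth + maintenance + residual", {
  reactor <- study_reactor(); feed <- study_feed()
  p <- retentostat_params(); C_X0 <- study_C_X0()
  tg <- seq(0, 600, by = 0.5)
  traj <- simulate_retentostat(reactor, feed, p, C_X0 = C_X0, t_grid = tg,
                               mode = "full_ode")
  supplied <- substrate_supplied(0, 600, feed)
  V <- reactor$V
  growth <- (traj$C_X_gL[nrow(traj)] - C_X0) * V / p$Y_max
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  maintenance <- trapz(traj$t_h, p$m_S * traj$C_Xv_gL) * V
  residual <- (traj$C_S_gL[nrow(traj)] - traj$C_S_gL[1]) * V +
    trapz(traj$t_h, reactor$D * traj$C_S_gL) * V
  expect_equal(growth + maintenance + residual, supplied,
               tolerance = 5e-3)
})

test_that("growth-rate-dependent maintenance is solved self-consistently", {
  reactor <- study_reactor(); feed <- study_feed()
  prof <- maintenance_profile()
  C_X0 <- study_C_X0()
  traj <- simulate_retentostat(reactor, feed, prof, C_X0 = C_X0,
                               Y_max = 0.584, t_grid = seq(0, 600, by = 5))
  # at every output the Pirt inversion must hold with m_S evaluated at mu
  qs_check <- traj$mu_per_h / 0.584 +
    evaluate_maintenance(pmax(traj$mu_per_h, 0), prof)
  expect_equal(traj$qS_g_per_g_h, qs_check, tolerance = 1e-8)
  # the low-mu culture accumulates more biomass than under the high plateau
  const <- simulate_retentostat(reactor, feed, chemostat_params(),
                                C_X0 = C_X0, t_grid = seq(0, 600, by = 5))
  expect_gt(traj$C_X_gL[nrow(traj)], const$C_X_gL[nrow(const)])
})

test_that("simulate_retentostat validates its inputs", {
  reactor <- study_reactor(); feed <- study_feed()
  expect_error(simulate_retentostat(reactor, feed, retentostat_params(),
                                    C_X0 = -1), "positive")
  expect_error(simulate_retentostat(reactor, feed, retentostat_params(),
                                    C_X0 = 1, t_grid = c(5, 10)), "t_grid")
  expect_error(simulate_retentostat(reactor, feed, maintenance_profile(),
                                    C_X0 = 1), "Y_max")
  expect_warning(
    simulate_retentostat(reactor, mixing_vessel_feed(C_S_MC = 0.1, C_S_MR = 0.01),
                         pirt_params(0.02, 0.584), C_X0 = 5,
                         t_grid = seq(0, 50, by = 5)),
    "insufficient")
})
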