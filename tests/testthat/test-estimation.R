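test_that("chemostat regression is exact on noise-free affine data", {
  obs <- exact_chemostat_obs()
  fit <- suppressWarnings(fit_pirt_chemostat(obs))
  expect_equal(fit$m_S, 0.0100, tolerance = 1e-12)
  expect_equal(fit$Y_max, 0.584, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_s3_class(fit$params, "pirt_params")
})

test_that("chemostat regression matches the normal-equations oracle", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    obs <- data.frame(D = runif(n, 0.01, 0.12), C_S_in = 10,
                      C_X = runif(n, 1, 8))
    # random biomass can imply negative m_S or out-of-range yield; those
    # warnings are exercised elsewhere
    fit <- suppressWarnings(fit_pirt_chemostat(obs))
    # independent oracle: solve the normal equations directly
    x <- obs$D
    y <- obs$D * obs$C_S_in / obs$C_X
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit$m_S, beta[1], tolerance = 1e-10)
    expect_equal(1 / fit$Y_max, beta[2], tolerance = 1e-10)
  }
})

test_that("chemostat regression rejects singular designs, flags bad fits", {
  obs <- data.frame(D = rep(0.05, 4), C_S_in = 10, C_X = c(5, 5.1, 4.9, 5))
  expect_error(fit_pirt_chemostat(obs), "distinct")
  expect_error(fit_pirt_chemostat(exact_chemostat_obs()[1:2, ]), "at least 3")
  # data lying below the origin-anchored line give a negative intercept,
  # which is returned unclipped with a warning
  neg <- data.frame(D = c(0.025, 0.05, 0.075, 0.10), C_S_in = 10)
  # small jitter keeps lm's summary away from the perfect-fit edge case
  neg$C_X <- neg$D * 10 / (neg$D / 0.584 - 0.002) * c(1, 1.001, 0.999, 1)
  expect_warning(fit <- fit_pirt_chemostat(neg), "negative")
  expect_lt(fit$m_S, 0)
})

test_that("the chemostat 95% CI covers the truth in most noisy replicates", {
  truth <- chemostat_params()
  obs0 <- exact_chemostat_obs(truth)
  obs0 <- rbind(obs0, obs0)  # duplicate cultures per dilution rate
  set.seed(42)
  sdlog <- sqrt(log1p(0.03^2))
  covered <- vapply(1:500, function(i) {
    obs <- obs0
    obs$C_X <- obs$C_X * rlnorm(nrow(obs), -sdlog^2 / 2, sdlog)
    fit <- fit_pirt_chemostat(obs)
    ci <- fit$m_S + c(-1, 1) * qt(0.975, fit$n_points - 2) * fit$se_mS
    ci[1] <= truth$m_S && truth$m_S <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("retentostat fit recovers the generating m_S on noise-free data", {
  reactor <- study_reactor(); feed <- study_feed()
  times <- study_sampling_times()
  traj <- simulate_retentostat(reactor, feed, retentostat_params(),
                               C_X0 = study_C_X0(), t_grid = times)
  fit <- fit_retentostat(times, traj$C_X_gL, reactor = reactor, feed = feed,
                         Y_max = 0.584)
  expect_equal(fit$m_S_hat, 0.0031, tolerance = 5e-4)  # 4 significant figures
  expect_identical(fit$k_d_hat, 0)
})

test_that("joint fit recovers m_S and k_d from biomass plus viability", {
  reactor <- study_reactor(); feed <- study_feed()
  times <- study_sampling_times()
  traj <- simulate_retentostat(reactor, feed, retentostat_params(),
                               C_X0 = study_C_X0(), k_d = 6e-5, t_grid = times)
  fit <- fit_retentostat(times, traj$C_X_gL,
                         viable_fraction = traj$viability,
                         reactor = reactor, feed = feed, Y_max = 0.584)
  expect_equal(fit$m_S_hat, 0.0031, tolerance = 1e-3)
  expect_equal(fit$k_d_hat, 6e-5, tolerance = 1e-2)
})

test_that("constant-biomass data imply m_S = supply rate per biomass", {
  reactor <- study_reactor()
  flat <- mixing_vessel_feed(C_S_MC = 5, C_S_MR = 5)
  m_S_true <- 0.0031
  C_X_fix <- reactor$D * 5 / m_S_true  # maintenance-only fixed point
  times <- study_sampling_times()
  fit <- fit_retentostat(times, rep(C_X_fix, length(times)),
                         reactor = reactor, feed = flat, Y_max = 0.584)
  expect_equal(fit$m_S_hat, m_S_true, tolerance = 1e-3)
})

test_that("the fit is invariant to a change of concentration units", {
  reactor <- study_reactor(); feed <- study_feed()
  times <- study_sampling_times()
  traj <- simulate_retentostat(reactor, feed, retentostat_params(),
                               C_X0 = study_C_X0(), t_grid = times)
  set.seed(43)
  noisy <- traj$C_X_gL * exp(rnorm(length(times), 0, 0.03))
  fit1 <- fit_retentostat(times, noisy, reactor = reactor, feed = feed,
                          Y_max = 0.584)
  # express all concentrations (biomass and reservoir glucose) in 10x units
  feed10 <- mixing_vessel_feed(V_S = feed$V_S, phi_V = feed$phi_V,
                               C_S_MC = feed$C_S_MC * 10,
                               C_S_MR = feed$C_S_MR * 10)
  fit10 <- fit_retentostat(times, noisy * 10, reactor = reactor, feed = feed10,
                           Y_max = 0.584)
  expect_equal(fit10$m_S_hat, fit1$m_S_hat, tolerance = 1e-6)
})

test_that("derived rates reach near-zero growth and long doubling times", {
  reactor <- study_reactor(); feed <- study_feed()
  times <- study_sampling_times()
  traj <- simulate_retentostat(reactor, feed, retentostat_params(),
                               C_X0 = study_C_X0(), t_grid = times)
  fit <- fit_retentostat(times, traj$C_X_gL, reactor = reactor, feed = feed,
                         Y_max = 0.584)
  rates <- derive_rates(fit, t_grid = c(0, 120, 600))
  expect_lt(rates$mu_per_h[rates$t_h == 600], 0.001)
  expect_gt(rates$doubling_time_h[rates$t_h == 600] / 24, 38)
  expect_equal(rates$qS_g_per_g_h,
               rates$mu_per_h / 0.584 + fit$m_S_hat, tolerance = 1e-8)
})

test_that("fit_retentostat validates its inputs", {
  reactor <- study_reactor(); feed <- study_feed()
  expect_error(fit_retentostat(c(0, 10, 20), c(5, 6, 7), reactor = reactor,
                               feed = feed, Y_max = 0.584), "4 time points")
  expect_error(fit_retentostat(c(5, 10, 20, 30), rep(5, 4), reactor = reactor,
                               feed = feed, Y_max = 0.584), "start at 0")
  expect_error(fit_retentostat(c(0, 10, 20, 30), rep(5, 4), k_d = "free",
                               reactor = reactor, feed = feed, Y_max = 0.584),
               "viability")
})
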