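#!/usr/bin/env Rscript
# Resolve the growth-rate dependence of the maintenance coefficient and the
# maximum yield: combine chemostat steady-state (mu, q_S) points with
# interval rates from duplicate retentostat series and run the moving-window
# regression over four consecutive growth-rate levels.

library(retentostat)
seed <- 301  # same experiments as 03
dir.create("results", showWarnings = FALSE)

reactor <- reactor_config(V = 1.4, phi_V = 0.035)
feed <- mixing_vessel_feed(V_S = 1.2, phi_V = 0.035, C_S_MC = 10, C_S_MR = 5)
truth <- maintenance_profile(0.0100, 0.0031)
cfg <- synthetic_config(truth = truth, Y_max = 0.584, k_d_true = 6e-5,
                        reactor = reactor, feed = feed)

# chemostat levels (duplicates per dilution rate)
chem <- generate_chemostat_table(cfg, seed = seed)
points <- data.frame(mu = chem$D, q_S = chem$D * chem$C_S_in / chem$C_X,
                     level = paste0("C", match(-chem$D, sort(unique(-chem$D)))),
                     source = "chemostat")

# retentostat interval levels: duplicate experiments share sampling times,
# so the i-th interval of each experiment forms one duplicate level
for (r in 1:2) {
  series <- generate_retentostat_series(cfg, seed = seed + r)
  ir <- series_interval_rates(series$t_h, series$C_X_gL, feed, reactor)
  points <- rbind(points,
                  data.frame(mu = ir$mu, q_S = ir$q_S,
                             level = paste0("R", seq_len(nrow(ir))),
                             source = "retentostat"))
}
points <- points[points$mu > 0, ]
write_timeseries(points, "results/qs_mu_points.csv")

windows <- moving_window_regression(points[, c("mu", "q_S", "level")],
                                    window = 4, r2_min = 0.99)
write_timeseries(windows, "results/windows.csv")
print(round(windows, 5))

acc <- windows[windows$accepted, ]
cat(sprintf("\n%d of %d windows accepted (r^2 > 0.99)\n", nrow(acc), nrow(windows)))
cat("At 3% CV the low-growth-rate interval estimates are noisy, so most\n")
cat("low-mu windows fail the linearity filter; windows that straddle the\n")
cat("maintenance transition keep high r^2 but blend the two plateaus.\n\n")

# noise-free control: with growth-rate levels placed entirely above 0.06 and
# entirely below 0.03 1/h the windows resolve both plateaus exactly
mus <- c(0.10, 0.088, 0.076, 0.064, 0.02, 0.012, 0.006, 0.003)
ctrl <- data.frame(mu = rep(mus, each = 2),
                   level = rep(seq_along(mus), each = 2))
ctrl$q_S <- ctrl$mu / 0.584 + evaluate_maintenance(ctrl$mu, truth)
wc <- suppressWarnings(moving_window_regression(ctrl))
cat(sprintf("Noise-free control: m_S = %.4f above mu = 0.06, %.4f below 0.03\n",
            wc$m_S[1], wc$m_S[nrow(wc)]))
cat(sprintf("-> %.1f-fold decline of the maintenance coefficient\n",
            wc$m_S[1] / wc$m_S[nrow(wc)]))
write_timeseries(wc, "results/windows_control.csv")
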