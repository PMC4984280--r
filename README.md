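# retentostat

Growth energetics of a glucose-limited *Pichia pastoris* retentostat:
simulation, parameter estimation and synthetic-data tooling around the
Herbert–Pirt substrate balance.

## The scientific problem

In a chemostat the dilution rate fixes the specific growth rate, but rates
below about 0.025 1/h are impractical. A retentostat removes that floor: a
filter returns all biomass to the vessel, so cells accumulate while the
glucose supply stays finite, and the population is pushed towards zero
growth. Once growth is negligible, essentially all substrate uptake pays for
maintenance, which makes the retentostat the instrument of choice for
measuring the **maintenance coefficient** `m_S` — the substrate flux needed
just to keep a cell alive.

The package models three coupled questions:

1. **Energetics.** The Herbert–Pirt relation partitions uptake into growth
   and maintenance,

   ```
   q_S = mu / Y_X/S^max + m_S
   ```

   with `q_S` the specific glucose uptake rate (g glucose / g dry weight /
   h), `mu` the specific growth rate (1/h) and `Y_X/S^max` the maximum
   biomass yield (g/g). The maintenance coefficient itself may depend on
   `mu`: `maintenance_profile()` describes a smooth transition from a high
   plateau (0.0100 g/(g h), ordinary chemostat growth) to a low plateau
   (0.0031 g/(g h)) as cells adapt to near-zero growth.

2. **Feed design.** To keep the biomass accumulation within the linear range
   of the balance, the glucose feed declines from 10 to 5 g/L following
   first-order mixing-vessel washout (`mixing_vessel_feed()`): a 10 g/L
   stirred vessel of 1.2 L is displaced by 5 g/L medium at 0.035 L/h, giving
   a half-decay of 23.8 h and 111.0 g of glucose supplied over 25 days.

3. **Inference.** Given noisy dry-weight and viability time series, recover
   `m_S` and the first-order death rate `k_d` by least squares against the
   simulated trajectory (`fit_retentostat()`), and resolve the
   growth-rate dependence of `m_S` with a moving-window regression over
   consecutive growth-rate levels (`moving_window_regression()`).

## Core model

With full biomass retention the viable dry weight obeys

```
dC_Xv/dt = (mu(t) - k_d) * C_Xv,      mu(t) = Y_max * (q_S(t) - m_S)
```

In the default pseudo-steady mode the residual glucose is negligible, so
uptake balances supply, `q_S * C_Xv = D * C_S_in(t)`, with
`C_S_in(t) = (C_S_MC - C_S_MR) exp(-phi_V t / V_S) + C_S_MR`. An alternative
`full_ode` mode integrates the residual-substrate balance with Monod uptake
kinetics and converges to the same trajectory. For constant `m_S` and
`k_d = 0` the model has a closed-form solution (`closed_form_biomass()`)
used as an exact oracle throughout the test suite.

## Worked example

Simulate 25 days of retentostat cultivation under the study conditions
(1.4 L vessel, D = 0.025 1/h, declining feed, low-plateau maintenance,
death rate 6e-5 1/h):

```r
library(retentostat)

reactor <- reactor_config(V = 1.4, phi_V = 0.035)          # D = 0.025 1/h
feed    <- mixing_vessel_feed(V_S = 1.2, phi_V = 0.035,
                              C_S_MC = 10, C_S_MR = 5)      # 10 -> 5 g/L glucose
params  <- pirt_params(m_S = 0.0031, Y_max = 0.584)

traj <- simulate_retentostat(reactor, feed, params,
                             C_X0 = 4.734, k_d = 6e-5)
tail(as.data.frame(traj)[, c("t_h", "C_X_gL", "mu_per_h",
                             "qS_g_per_g_h", "viability")], 3)
#>     t_h   C_X_gL     mu_per_h qS_g_per_g_h viability
#> 299 596 29.36619 0.0007369120  0.004361836 0.9758726
#> 300 598 29.40835 0.0007334745  0.004355950 0.9757902
#> 301 600 29.45038 0.0007300590  0.004350101 0.9757078

doubling_time(traj$mu_per_h[traj$t_h == 600]) / 24   # days
#> [1] 39.56
```

After 600 h the culture has grown from 4.7 to 29.5 g/L, the growth rate has
fallen below 0.001 1/h (doubling time ~40 days, versus 28 h at the start),
the uptake rate has approached the maintenance coefficient, and 97.6% of the
biomass is still viable.

## Analysis workflow

The numbered scripts under `analysis/` reproduce the study narrative; each
writes plain-text tables to `results/` and prints its headline numbers.
Run them in order from the package root, e.g. `Rscript analysis/01_chemostat_regression.R`.

1. **01_chemostat_regression.R** — duplicate chemostats at D = 0.025–0.10
   1/h; the q_S-on-mu regression gives `m_S = 0.0109 ± 0.0019 g/(g h)` (17%
   relative SE) and `Y_max = 0.594 g/g` on one synthetic realisation.
2. **02_feed_design_simulation.R** — the a-priori design prediction
   (`m_S = 0.0100`: 12.6 g/L after 600 h) versus the low-maintenance run
   (`m_S = 0.0031`: 29.5 g/L, mu(600 h) = 0.0007 1/h, viability 97.6%).
3. **03_retentostat_fit.R** — duplicate noisy retentostat series fitted
   separately recover `m_S = 0.0031 ± 0.0001 g/(g h)` and
   `k_d ≈ 5–7e-5 1/h`.
4. **04_windowed_maintenance.R** — moving-window regression over combined
   chemostat and retentostat rates; a noise-free control with growth-rate
   levels on both plateaus resolves the 3.2-fold decline of `m_S`.
5. **05_storage_fractions.R** — glycogen/trehalose balances: up to ~14% of
   the consumed glucose is transiently diverted to storage carbohydrates,
   mobilised again late in the run.

`run_pipeline()` (see `R/io.R`) chains the same steps from a YAML
configuration file into a single output directory.

## Documentation

`vignettes/methods.Rmd` describes the model, the numerical methods, the
synthetic-data generator and the design decisions in detail.
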