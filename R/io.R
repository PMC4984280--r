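#' Read and validate a delimited time-series table
#'
#' Comma-separated, UTF-8, '.' decimal. The header must contain every column
#' in `columns`; all requested columns must parse as numbers; when a time
#' column is named it must be strictly increasing. Errors name the offending
#' columns or rows.
#'
#' @param path file path.
#' @param columns required column names.
#' @param time_col optional name of the time column to check for strict
#'   monotonicity.
#' @return data frame with rows in file order.
#' @export
read_timeseries <- function(path, columns, time_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty input: ", path, " has a header but no rows")
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  for (cn in columns) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric values in column '", cn, "' of ", path,
             " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
      }
      df[[cn]] <- num
    }
  }
  if (!is.null(time_col)) {
    tv <- df[[time_col]]
    bad <- which(diff(tv) <= 0)
    if (length(bad)) {
      stop("time column '", time_col, "' not strictly increasing at row(s) ",
           paste(bad + 1L, collapse = ", "))
    }
  }
  df
}

#' Write a time-series table
#'
#' Plain CSV, UTF-8, '.' decimal, no row names; round-trips through
#' [read_timeseries()].
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_timeseries <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

known_config_keys <- c("reactor", "feed", "pirt", "maintenance", "Y_max",
                       "k_d", "seed", "noise_cv", "sampling_times", "stages")

#' Read and validate a structured run configuration
#'
#' YAML file whose top-level keys configure the pipeline: `reactor`
#' (V, phi_V), `feed` (V_S, phi_V, C_S_MC, C_S_MR), one of `pirt`
#' (m_S, Y_max) or `maintenance` (m_S_high, m_S_low, mu_mid, steepness) with
#' `Y_max`, plus optional `k_d`, `seed`, `noise_cv`, `sampling_times` and
#' `stages`. Unknown keys are rejected. All quantities use package units
#' (h, g/L, 1/h, g/(g h)).
#'
#' @param path YAML file path.
#' @return list of class `run_config` with constructed `reactor`, `feed` and
#'   parameter objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), known_config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- list()
  cfg$reactor <- do.call(reactor_config, raw$reactor %||% list())
  cfg$feed <- do.call(mixing_vessel_feed, raw$feed %||% list())
  if (!is.null(raw$pirt) && !is.null(raw$maintenance)) {
    stop("specify either 'pirt' or 'maintenance', not both")
  }
  if (!is.null(raw$pirt)) {
    cfg$params <- do.call(pirt_params, raw$pirt)
    cfg$Y_max <- cfg$params$Y_max
  } else if (!is.null(raw$maintenance)) {
    cfg$params <- do.call(maintenance_profile, raw$maintenance)
    if (is.null(raw$Y_max)) stop("Y_max is required with a maintenance profile")
    cfg$Y_max <- raw$Y_max
  }
  cfg$k_d <- raw$k_d %||% 0
  cfg$seed <- raw$seed %||% 1L
  cfg$noise_cv <- raw$noise_cv %||% 0.03
  cfg$sampling_times <- raw$sampling_times %||%
    (24 * c(0, 1, 3, 5, 8, 11, 14, 16, 19, 21, 23, 25))
  cfg$stages <- raw$stages %||% list()
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates the stages end to end on seeded synthetic data:
#' chemostat table generation and Herbert-Pirt regression; forward
#' retentostat simulation with the fitted parameters; duplicate retentostat
#' series generation and per-experiment least-squares fitting of m_S and
#' k_d; interval rates and moving-window regression combining chemostat and
#' retentostat growth-rate levels; and storage-fraction accounting. All
#' randomness derives from the configured seed, so reruns are byte-identical.
#' Per-stage CSVs and a machine-readable `summary.json` (which embeds the
#' package version and the full configuration used) are written to
#' `out_dir`.
#'
#' @param config a `run_config` from [read_run_config()], or a
#'   [synthetic_config()]-compatible list built in code.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% list()
  on_stage <- function(name) !identical(stages[[name]], FALSE)
  seed <- config$seed %||% 1L
  truth <- config$params %||% maintenance_profile()
  Y_max <- config$Y_max %||% 0.584
  scfg <- synthetic_config(truth = truth, Y_max = Y_max,
                           k_d_true = config$k_d %||% 6e-5,
                           noise_cv = config$noise_cv %||% 0.03,
                           sampling_times = config$sampling_times %||%
                             (24 * c(0, 1, 3, 5, 8, 11, 14, 16, 19, 21, 23, 25)),
                           reactor = config$reactor %||% reactor_config(),
                           feed = config$feed %||% mixing_vessel_feed())
  summary <- list(package_version = as.character(utils::packageVersion("retentostat")),
                  seed = seed)

  # -- chemostat stage: generate steady states, regress q_S on mu
  chem <- generate_chemostat_table(scfg, seed = seed)
  write_timeseries(chem, file.path(out_dir, "chemostats.csv"))
  pirt_fit <- fit_pirt_chemostat(chem)
  summary$chemostat <- list(m_S = pirt_fit$m_S, se_mS = pirt_fit$se_mS,
                            Y_max = pirt_fit$Y_max,
                            r_squared = pirt_fit$r_squared)

  # -- forward prediction with the chemostat-derived parameters
  D <- scfg$reactor$D
  pred_params <- pirt_params(max(pirt_fit$m_S, 1e-5), pirt_fit$Y_max)
  C_X0 <- chemostat_steady_state(D, scfg$feed$C_S_MC, pred_params)$C_X
  traj <- simulate_retentostat(scfg$reactor, scfg$feed, pred_params,
                               C_X0 = C_X0,
                               t_grid = seq(0, max(scfg$sampling_times), by = 2))
  write_timeseries(as.data.frame(traj), file.path(out_dir, "trajectory.csv"))
  final <- traj[nrow(traj), ]
  summary$prediction <- list(C_X_final = final$C_X_gL, mu_final = final$mu_per_h,
                             qS_final = final$qS_g_per_g_h)

  if (on_stage("retentostat")) {
    # -- duplicate retentostat experiments, fitted separately
    fits <- list()
    all_points <- list()
    for (r in 1:2) {
      series <- generate_retentostat_series(scfg, seed = seed + r)
      write_timeseries(series, file.path(out_dir,
                                         sprintf("retentostat_%d.csv", r)))
      fit <- fit_retentostat(series$t_h, series$C_X_gL,
                             viable_fraction = series$viable_fraction,
                             reactor = scfg$reactor, feed = scfg$feed,
                             Y_max = Y_max)
      fits[[r]] <- fit
      ir <- series_interval_rates(series$t_h, series$C_X_gL,
                                  scfg$feed, scfg$reactor)
      all_points[[r]] <- data.frame(mu = ir$mu, q_S = ir$q_S,
                                    level = paste0("R", seq_len(nrow(ir))),
                                    source = "retentostat")
    }
    summary$retentostat <- lapply(fits, function(f)
      list(m_S = f$m_S_hat, k_d = f$k_d_hat, sse = f$sse))

    # -- moving-window regression over chemostat + retentostat mu levels
    chem_points <- data.frame(mu = chem$D,
                              q_S = chem$D * chem$C_S_in / chem$C_X,
                              level = paste0("C", match(chem$D, sort(unique(chem$D),
                                                                     decreasing = TRUE))),
                              source = "chemostat")
    points <- rbind(chem_points, do.call(rbind, all_points))
    points <- points[points$mu > 0, ]
    windows <- moving_window_regression(points[, c("mu", "q_S", "level")])
    write_timeseries(windows, file.path(out_dir, "windows.csv"))
    summary$windows <- list(n = nrow(windows), n_accepted = sum(windows$accepted))

    # -- storage-fraction accounting on the first replicate
    series <- generate_retentostat_series(scfg, seed = seed + 1)
    n <- nrow(series)
    frac <- vapply(seq_len(n - 1L), function(i) {
      m1 <- storage_measurement(series$t_h[i], series$glycogen_g_per_g[i],
                                series$trehalose_g_per_g[i], series$C_X_gL[i])
      m2 <- storage_measurement(series$t_h[i + 1], series$glycogen_g_per_g[i + 1],
                                series$trehalose_g_per_g[i + 1],
                                series$C_X_gL[i + 1])
      storage_fraction(m1, m2, scfg$feed, scfg$reactor)
    }, numeric(1))
    storage <- data.frame(t1 = series$t_h[-n], t2 = series$t_h[-1],
                          stored_fraction = frac)
    write_timeseries(storage, file.path(out_dir, "storage_fractions.csv"))
    summary$storage <- list(max_fraction = max(frac))
  }

  summary$config <- list(reactor = unclass(scfg$reactor),
                         feed = unclass(scfg$feed),
                         truth = unclass(truth), Y_max = Y_max,
                         k_d = scfg$k_d_true, noise_cv = scfg$noise_cv,
                         sampling_times = scfg$sampling_times)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
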