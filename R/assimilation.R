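#' LAI assimilation cost
#'
#' Root-mean-square misfit between simulated and observed LAI at the
#' observation days: `J = sqrt(sum((S_i - M_i)^2) / n)`. Observation
#' days before emergence are compared against the initial LAI; days
#' after the simulation terminated against 0.
#'
#' @param par Numeric vector `c(D0, ELUE, STT)` (D0 rounded to integer).
#' @param weather A [weather_series()].
#' @param obs_days Integer observation days.
#' @param obs_lai Observed LAI values (same length).
#' @param params Baseline [safy_params()] supplying the fixed and
#'   calibrated parameters.
#' @return The scalar cost J (LAI units, >= 0).
#' @export
lai_cost <- function(par, weather, obs_days, obs_lai, params) {
  if (length(obs_days) == 0) stop("no LAI observations to assimilate",
                                  call. = FALSE)
  if (!any(obs_days >= min(weather$day) & obs_days <= max(weather$day))) {
    stop("no observation days fall inside the weather series",
         call. = FALSE)
  }
  p <- params
  p$emergence_day <- as.integer(round(par[1]))
  p$elue <- par[2]
  p$senescence_threshold <- par[3]
  st <- simulate_states(weather, p)
  d0 <- st$day[1]
  idx <- obs_days - d0 + 1L
  n_st <- length(st$lai)
  s <- numeric(length(obs_days))
  before <- idx < 1L
  inside <- !before & idx <= n_st
  s[before] <- p$initial_dam * p$sla
  s[inside] <- st$lai[idx[inside]]
  sqrt(mean((s - obs_lai)^2))
}

#' Calibrate the leaf partition coefficients
#'
#' Trial-and-error calibration of the non-sensitive parameters
#' `(Pla, Plb)` against one season of measured LAI and dry-mass series.
#' For each `Pla` on a grid, `Plb` is solved in closed form from the
#' condition that leaf allocation stops (`Pl = 0`) at the thermal time
#' of the observed LAI peak: `Plb = ln(1/Pla) / SMT_peak`, clamped into
#' its admissible range. For each candidate pair the three sensitive
#' parameters are re-optimized against the LAI series (same stopping
#' rule as the assimilation proper) and the pair minimizing the dry-mass
#' RMSE is returned.
#'
#' @param lai_days,lai_obs Measured LAI series (days, values).
#' @param dam_days,dam_obs Measured dry-mass series (days, t ha-1).
#' @param weather A [weather_series()].
#' @param params Baseline [safy_params()]; its `emergence_day` is used
#'   as the prior emergence date when accumulating thermal time to the
#'   observed LAI peak.
#' @param pla_grid Candidate `Pla` values (default 0.01 to 0.28 in steps
#'   of 0.03, spanning the admissible range).
#' @param d0_bounds Bounds for the emergence day during the inner
#'   optimization (day-of-season).
#' @param config A [spuci_config()] for the inner optimizations.
#' @return A `calibration_result`: list with `partition_a`,
#'   `partition_b`, `dam_rmse`, `smt_peak`, and a `trace` data frame
#'   (one row per grid point).
#' @export
calibrate_partition_coefficients <- function(lai_days, lai_obs,
                                             dam_days, dam_obs,
                                             weather, params,
                                             pla_grid = seq(0.01, 0.3,
                                                            by = 0.03),
                                             d0_bounds = NULL,
                                             config = spuci_config()) {
  if (length(lai_obs) < 3) stop("need at least 3 LAI observations",
                                call. = FALSE)
  ipk <- which.max(lai_obs)
  if (ipk == 1L || ipk == length(lai_obs)) {
    stop("no interior LAI peak detectable in the measured series",
         call. = FALSE)
  }
  peak_day <- lai_days[ipk]
  d0_prior <- params$emergence_day
  ii <- weather$day > d0_prior & weather$day <= peak_day
  smt_peak <- sum(pmax(weather$ta[ii] - params$t_min, 0))
  if (smt_peak <= 0) stop("no thermal time accumulated before the LAI peak",
                          call. = FALSE)
  if (is.null(d0_bounds)) d0_bounds <- d0_prior + c(-5, 15)
  plb_rng <- params$bounds$partition_b

  rows <- vector("list", length(pla_grid))
  best <- NULL
  for (g in seq_along(pla_grid)) {
    pla <- pla_grid[g]
    plb <- min(max(log(1 / pla) / smt_peak, plb_rng[1]), plb_rng[2])
    p_g <- update_params(params, partition_a = pla, partition_b = plb)
    space <- search_space(
      lower = c(d0_bounds[1], params$bounds$elue[1],
                params$bounds$senescence_threshold[1]),
      upper = c(d0_bounds[2], params$bounds$elue[2],
                params$bounds$senescence_threshold[2]),
      integer = c(TRUE, FALSE, FALSE))
    cfg <- config
    cfg$seed <- if (is.null(config$seed)) NULL else config$seed + g
    res <- spuci_optimize(
      function(x) lai_cost(x, weather, lai_days, lai_obs, p_g),
      space, cfg)
    p_best <- update_params(p_g, emergence_day = res$par[1],
                            elue = res$par[2],
                            senescence_threshold = res$par[3])
    traj <- safy_simulate(weather, p_best)
    dam_hat <- trajectory_dam_at(traj, dam_days, units = "t_ha")
    dam_rmse <- rmse(dam_obs, dam_hat)
    rows[[g]] <- data.frame(partition_a = pla, partition_b = plb,
                            lai_cost = res$value, dam_rmse = dam_rmse)
    if (is.null(best) || dam_rmse < best$dam_rmse) {
      best <- list(partition_a = pla, partition_b = plb,
                   dam_rmse = dam_rmse)
    }
  }
  structure(list(partition_a = best$partition_a,
                 partition_b = best$partition_b,
                 dam_rmse = best$dam_rmse,
                 smt_peak = smt_peak,
                 trace = do.call(rbind, rows)),
            class = "calibration_result")
}

#' Assimilate one plot's LAI observations
#'
#' Minimizes [lai_cost()] over the three sensitive parameters
#' `(D0, ELUE, STT)` with SP-UCI and returns the calibrated trajectory
#' and its derived estimates. Bounds: ELUE and STT from
#' `params$bounds`; D0 spans sowing + 5 to sowing + 25 days (emergence
#' is typically about 10 days after sowing).
#'
#' @param plot A [plot_observations()] with at least 3 LAI observations.
#' @param weather A [weather_series()].
#' @param params Baseline [safy_params()] (with calibrated Pla/Plb).
#' @param config A [spuci_config()].
#' @return A `plot_assimilation` result: list with `plot_id`, `par`
#'   (named D0/ELUE/STT), `cost`, `trajectory`, `lai_hat` (at the
#'   observation days), `dam_hat_t_ha` (at the DAM observation days, if
#'   any), `yield_t_ha`, `evaluations`, `convergence`.
#' @export
assimilate_plot <- function(plot, weather, params,
                            config = spuci_config()) {
  if (length(plot$lai_days) < 3) {
    stop(sprintf("plot %s has fewer than 3 LAI observations",
                 plot$plot_id), call. = FALSE)
  }
  d0_off <- params$bounds$emergence_offset
  space <- search_space(
    lower = c(plot$sowing_day + d0_off[1], params$bounds$elue[1],
              params$bounds$senescence_threshold[1]),
    upper = c(plot$sowing_day + d0_off[2], params$bounds$elue[2],
              params$bounds$senescence_threshold[2]),
    integer = c(TRUE, FALSE, FALSE))
  res <- tryCatch(
    spuci_optimize(
      function(x) lai_cost(x, weather, plot$lai_days, plot$lai, params),
      space, config),
    error = function(e) {
      stop(sprintf("assimilation failed for plot %s: %s",
                   plot$plot_id, conditionMessage(e)), call. = FALSE)
    })
  p_best <- update_params(params, emergence_day = res$par[1],
                          elue = res$par[2],
                          senescence_threshold = res$par[3])
  traj <- safy_simulate(weather, p_best)
  structure(list(
    plot_id = plot$plot_id,
    par = c(d0 = p_best$emergence_day, elue = p_best$elue,
            stt = p_best$senescence_threshold),
    cost = res$value,
    trajectory = traj,
    lai_hat = trajectory_lai_at(traj, plot$lai_days),
    dam_hat_t_ha = if (length(plot$dam_days)) {
      trajectory_dam_at(traj, plot$dam_days, units = "t_ha")
    } else numeric(0),
    yield_t_ha = grain_yield(traj, p_best),
    evaluations = res$evaluations,
    convergence = res$convergence
  ), class = "plot_assimilation")
}

#' Run the assimilation experiment over a set of plots
#'
#' Assimilates every plot (plots with fewer than 3 LAI observations are
#' skipped with a warning), derives per-plot parameter estimates and
#' yields, and evaluates estimated LAI, dry mass and yield against the
#' provided measurements — overall and grouped by variety, nitrogen and
#' water treatment.
#'
#' @param plots Named list of [plot_observations()].
#' @param weather A [weather_series()].
#' @param params Baseline [safy_params()].
#' @param config A [spuci_config()]; each plot uses a seed derived from
#'   `config$seed` so results are reproducible and plot-order
#'   independent.
#' @return List with `results` (data frame: plot_id, d0, elue, stt,
#'   cost, yield_t_ha, evaluations, convergence), `plot_results` (the
#'   full per-plot objects), and `evaluation` (data frame of metrics by
#'   quantity and group, or `NULL` when no measurements were supplied).
#' @export
run_experiment <- function(plots, weather, params,
                           config = spuci_config()) {
  results <- list()
  plot_results <- list()
  for (i in seq_along(plots)) {
    pl <- plots[[i]]
    if (length(pl$lai_days) < 3) {
      warning(sprintf("plot %s skipped: fewer than 3 LAI observations",
                      pl$plot_id), call. = FALSE)
      next
    }
    cfg <- config
    cfg$seed <- if (is.null(config$seed)) NULL else config$seed + i
    pr <- assimilate_plot(pl, weather, params, cfg)
    plot_results[[pl$plot_id]] <- pr
    results[[pl$plot_id]] <- data.frame(
      plot_id = pl$plot_id, d0 = unname(pr$par["d0"]),
      elue = unname(pr$par["elue"]), stt = unname(pr$par["stt"]),
      cost = pr$cost, yield_t_ha = pr$yield_t_ha,
      evaluations = pr$evaluations, convergence = pr$convergence,
      stringsAsFactors = FALSE)
  }
  results <- if (length(results)) do.call(rbind, results) else
    data.frame(plot_id = character(0), d0 = numeric(0), elue = numeric(0),
               stt = numeric(0), cost = numeric(0), yield_t_ha = numeric(0),
               evaluations = integer(0), convergence = character(0))
  rownames(results) <- NULL
  evaluation <- evaluate_experiment(plots, plot_results)
  list(results = results, plot_results = plot_results,
       evaluation = evaluation)
}

# aggregate measured-vs-estimated metrics overall and per treatment group
evaluate_experiment <- function(plots, plot_results) {
  if (!length(plot_results)) return(NULL)
  # index plots by their own plot_id (list names may differ)
  plot_ids <- vapply(plots, `[[`, character(1), "plot_id")
  recs <- list()
  for (pid in names(plot_results)) {
    pl <- plots[[match(pid, plot_ids)]]
    pr <- plot_results[[pid]]
    if (length(pl$lai_days)) {
      recs[[length(recs) + 1L]] <- data.frame(
        plot_id = pid, variety = pl$variety, nitrogen = pl$nitrogen,
        water = pl$water, quantity = "lai",
        measured = pl$lai, estimated = pr$lai_hat)
    }
    if (length(pl$dam_days)) {
      recs[[length(recs) + 1L]] <- data.frame(
        plot_id = pid, variety = pl$variety, nitrogen = pl$nitrogen,
        water = pl$water, quantity = "dam",
        measured = pl$dam_t_ha, estimated = pr$dam_hat_t_ha)
    }
    if (!is.na(pl$yield_t_ha)) {
      recs[[length(recs) + 1L]] <- data.frame(
        plot_id = pid, variety = pl$variety, nitrogen = pl$nitrogen,
        water = pl$water, quantity = "yield",
        measured = pl$yield_t_ha, estimated = pr$yield_t_ha)
    }
  }
  if (!length(recs)) return(NULL)
  long <- do.call(rbind, recs)
  metric_row <- function(df, quantity, group) {
    ok <- nrow(df) >= 2 && stats::var(df$measured) > 0 &&
      stats::var(df$estimated) > 0
    nr <- if (mean(df$estimated) != 0) nrmse(df$measured, df$estimated)
          else NA_real_
    data.frame(quantity = quantity, group = group, n = nrow(df),
               r_squared = if (ok) r_squared(df$measured, df$estimated)
                           else NA_real_,
               rmse = rmse(df$measured, df$estimated),
               nrmse_pct = nr,
               class = if (is.na(nr)) NA_character_
                       else consistency_class(nr),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (q in unique(long$quantity)) {
    dq <- long[long$quantity == q, ]
    out[[length(out) + 1L]] <- metric_row(dq, q, "overall")
    for (gv in c("variety", "nitrogen", "water")) {
      for (lev in sort(unique(dq[[gv]]))) {
        out[[length(out) + 1L]] <-
          metric_row(dq[dq[[gv]] == lev, ], q, lev)
      }
    }
  }
  do.call(rbind, out)
}

#' Write experiment outputs as CSV
#'
#' @param experiment Result of [run_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `results.csv`, `evaluation.csv`
#'   (when present) and one `trajectory_<plot>.csv` per plot.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(experiment$results, file.path(dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(experiment$evaluation)) {
    utils::write.csv(experiment$evaluation,
                     file.path(dir, "evaluation.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  for (pid in names(experiment$plot_results)) {
    traj <- experiment$plot_results[[pid]]$trajectory
    utils::write.csv(
      data.frame(day = traj$day, lai = traj$lai, dam = traj$dam,
                 smt = traj$smt),
      file.path(dir, sprintf("trajectory_%s.csv", pid)),
      row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
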