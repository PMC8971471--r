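#' Factorial trial design
#'
#' The layout of the synthetic field trial: a full factorial of
#' 2 varieties x 4 nitrogen levels x 3 water levels x 2 replicates = 48
#' plots, with ~7 canopy reflectance acquisition dates and 6
#' destructive-sampling stages over one winter-wheat season. Nitrogen
#' acts multiplicatively on the effective light-use efficiency (more
#' nitrogen, more efficient canopies); water shifts the senescence
#' threshold (better watered crops stay green longer).
#'
#' @param replicates Replicates per treatment cell (default 2 -> 48
#'   plots).
#' @param sowing_day Day-of-season of sowing (day 1 is the start of the
#'   season, early November for winter wheat).
#' @param season_length Days in the weather series.
#' @param acquisition_days Reflectance acquisition days (default 7 days
#'   roughly uniform over the spring green-up through senescence).
#' @param stage_days Destructive-sampling days for dry mass (default 6
#'   stages from turning-green to harvest).
#' @param nitrogen_elue_mult Named multipliers on base ELUE for N1..N4.
#' @param water_stt_offset Named additive offsets (degC day) on base STT
#'   for W1..W3.
#' @param base_elue Named base ELUE (g MJ-1) per variety.
#' @param base_stt Base senescence threshold (degC day).
#' @return A `trial_design` list.
#' @export
trial_design <- function(replicates = 2L,
                         sowing_day = 5L,
                         season_length = 280L,
                         acquisition_days = round(seq(150, 250,
                                                      length.out = 7)),
                         stage_days = c(130L, 160L, 180L, 195L, 210L,
                                        235L),
                         nitrogen_elue_mult = c(N1 = 0.85, N2 = 0.95,
                                                N3 = 1.05, N4 = 1.10),
                         water_stt_offset = c(W1 = -100, W2 = 0,
                                              W3 = 100),
                         base_elue = c(P1 = 1.85, P2 = 1.95),
                         base_stt = 1000) {
  if (any(acquisition_days > season_length) ||
      any(stage_days > season_length)) {
    stop("observation days must fall within the season", call. = FALSE)
  }
  grid <- expand.grid(rep = seq_len(replicates),
                      water = names(water_stt_offset),
                      nitrogen = names(nitrogen_elue_mult),
                      variety = names(base_elue),
                      stringsAsFactors = FALSE)
  grid$plot_id <- sprintf("%s_%s_%s_r%d", grid$variety, grid$nitrogen,
                          grid$water, grid$rep)
  structure(list(grid = grid, n_plots = nrow(grid),
                 sowing_day = as.integer(sowing_day),
                 season_length = as.integer(season_length),
                 acquisition_days = as.integer(acquisition_days),
                 stage_days = as.integer(stage_days),
                 nitrogen_elue_mult = nitrogen_elue_mult,
                 water_stt_offset = water_stt_offset,
                 base_elue = base_elue, base_stt = base_stt),
            class = "trial_design")
}

#' Generate a synthetic daily weather series
#'
#' Sinusoidal annual mean-temperature curve with the winter-wheat shape
#' (cold mid-season trough around day 75 ~ mid-January, warming through
#' spring) plus Gaussian day-to-day noise, and global radiation on its
#' own sinusoid with the trough at the winter solstice (day ~51), so it
#' co-varies positively with temperature with a realistic lag. Default
#' magnitudes emulate a semi-arid continental site (January mean near
#' -1 degC, June near 25 degC; radiation ~6 MJ m-2 day-1 midwinter to
#' ~23 in June). Radiation is floored at a small positive value.
#'
#' @param season_length Number of days (default 280; day 1 ~ Nov 1).
#' @param seed Integer seed.
#' @param ta_mean,ta_amplitude Annual mean and half-range of the
#'   temperature sinusoid (degC).
#' @param rg_mean,rg_amplitude Annual mean and half-range of the
#'   radiation sinusoid (MJ m-2 day-1).
#' @param ta_noise_sd Day-to-day temperature noise (degC).
#' @param rg_noise_sd Radiation noise (MJ m-2 day-1).
#' @return A [weather_series()].
#' @export
generate_weather <- function(season_length = 280L, seed = 1L,
                             ta_mean = 13, ta_amplitude = 14,
                             rg_mean = 14.5, rg_amplitude = 8.5,
                             ta_noise_sd = 1.5, rg_noise_sd = 1.5) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  day <- seq_len(season_length)
  ta <- ta_mean - ta_amplitude * cos(2 * pi * (day - 75) / 365) +
    stats::rnorm(season_length, 0, ta_noise_sd)
  rg <- pmax(rg_mean - rg_amplitude * cos(2 * pi * (day - 51) / 365) +
               stats::rnorm(season_length, 0, rg_noise_sd),
             0.5)
  weather_series(day, ta = ta, rg = rg)
}

#' Synthesize band reflectance from true LAI
#'
#' Inverts the exponential OSAVI inversion model to construct plausible
#' band reflectances whose OSAVI maps back to the requested LAI:
#' `OSAVI* = ln(max(LAI, 0.21) / 0.21) / 4.68`; red reflectance is drawn
#' from a plausible range (0.03-0.15) decreasing in LAI; NIR is solved
#' from the OSAVI definition; blue and green are fixed fractions of
#' red. Optional Gaussian reflectance noise is added and all bands are
#' clipped to \[0, 1\].
#'
#' @param lai True LAI values (vectorized).
#' @param noise_sd Reflectance noise standard deviation (default 0.002;
#'   set 0 for an exact round trip).
#' @return Data frame with columns `b_blue`, `b_green`, `b_red`,
#'   `b_nir`.
#' @export
synthesize_reflectance <- function(lai, noise_sd = 0.002) {
  if (any(lai < 0)) stop("lai must be non-negative", call. = FALSE)
  osavi <- log(pmax(lai, 0.21) / 0.21) / 4.68
  if (any(osavi >= 1)) {
    stop("requested LAI maps outside the feasible OSAVI range",
         call. = FALSE)
  }
  red <- 0.15 - 0.02 * pmin(lai, 6)
  nir <- (red + 0.16 * osavi + red * osavi) / (1 - osavi)
  nir <- pmin(pmax(nir, 0), 1)
  blue <- 0.5 * red
  green <- 0.8 * red
  out <- cbind(b_blue = blue, b_green = green, b_red = red, b_nir = nir)
  if (noise_sd > 0) {
    out <- out + stats::rnorm(length(out), 0, noise_sd)
    out <- pmin(pmax(out, 0), 1)
  }
  as.data.frame(out)
}

#' Generate a complete synthetic field trial
#'
#' Draws per-plot true sensitive parameters from the treatment
#' structure — `D0 ~ sowing + U{8..14}` days, `ELUE = base(variety) x
#' nitrogen multiplier + jitter` (clipped to its recovery bounds),
#' `STT = base + water offset + jitter` (clipped likewise) — simulates
#' the true trajectory for each plot, and emits noisy observations:
#' LAI at the acquisition days (additive Gaussian noise, floored at 0),
#' dry mass at the sampling stages (multiplicative noise), harvest
#' yield (additive noise), and band reflectances synthesized from the
#' true LAI.
#'
#' @param design A [trial_design()].
#' @param weather A [weather_series()] covering the season.
#' @param params Baseline [safy_params()]; the true partition
#'   coefficients and harvest index are taken from here.
#' @param seed Master seed; all per-plot randomness derives from it.
#' @param sigma_lai Additive LAI observation noise sd (default 0.3).
#' @param dam_cv Multiplicative dry-mass noise CV (default 0.1).
#' @param sigma_yield Additive yield noise sd, t ha-1 (default 0.3).
#' @param elue_jitter_sd,stt_jitter_sd Plot-to-plot parameter jitter
#'   within a treatment cell.
#' @param reflectance_noise_sd Reflectance noise sd (default 0.002).
#' @return List with `truth` (data frame of generating parameters and
#'   true yield per plot), `plots` (named list of
#'   [plot_observations()]), and `reflectance` (long data frame).
#' @export
generate_trial <- function(design, weather, params = safy_params(),
                           seed = 1L, sigma_lai = 0.3, dam_cv = 0.1,
                           sigma_yield = 0.3, elue_jitter_sd = 0.04,
                           stt_jitter_sd = 30,
                           reflectance_noise_sd = 0.002) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  grid <- design$grid
  elue_rng <- params$bounds$elue
  stt_rng <- params$bounds$senescence_threshold
  d0_rng <- design$sowing_day + params$bounds$emergence_offset

  truth_rows <- vector("list", nrow(grid))
  plots <- vector("list", nrow(grid))
  refl_rows <- vector("list", nrow(grid))

  for (i in seq_len(nrow(grid))) {
    d0 <- design$sowing_day + sample(8:14, 1)
    elue <- design$base_elue[[grid$variety[i]]] *
      design$nitrogen_elue_mult[[grid$nitrogen[i]]] +
      stats::rnorm(1, 0, elue_jitter_sd)
    elue <- min(max(elue, elue_rng[1]), elue_rng[2])
    stt <- design$base_stt +
      design$water_stt_offset[[grid$water[i]]] +
      stats::rnorm(1, 0, stt_jitter_sd)
    stt <- min(max(stt, stt_rng[1]), stt_rng[2])
    if (d0 < d0_rng[1] || d0 > d0_rng[2]) {
      stop("true emergence day fell outside the recovery bounds",
           call. = FALSE)
    }
    p_true <- update_params(params, emergence_day = d0, elue = elue,
                            senescence_threshold = stt)
    traj <- safy_simulate(weather, p_true)
    true_yield <- grain_yield(traj, p_true)

    lai_true <- trajectory_lai_at(traj, design$acquisition_days)
    lai_obs <- pmax(lai_true + stats::rnorm(length(lai_true), 0,
                                            sigma_lai), 0)
    dam_true <- trajectory_dam_at(traj, design$stage_days,
                                  units = "t_ha")
    dam_obs <- pmax(dam_true * (1 + stats::rnorm(length(dam_true), 0,
                                                 dam_cv)), 0)
    yield_obs <- true_yield + stats::rnorm(1, 0, sigma_yield)

    refl <- synthesize_reflectance(lai_true,
                                   noise_sd = reflectance_noise_sd)
    refl_rows[[i]] <- cbind(
      data.frame(plot_id = grid$plot_id[i],
                 day = design$acquisition_days),
      refl, lai_true = lai_true)

    truth_rows[[i]] <- data.frame(
      plot_id = grid$plot_id[i], variety = grid$variety[i],
      nitrogen = grid$nitrogen[i], water = grid$water[i],
      d0 = d0, elue = elue, stt = stt,
      partition_a = params$partition_a,
      partition_b = params$partition_b,
      harvest_index = params$harvest_index,
      dam_max_g_m2 = attr(traj, "dam_max"),
      yield_t_ha = true_yield,
      smt_at_peak_lai = attr(traj, "smt_at_peak_lai"),
      stringsAsFactors = FALSE)

    plots[[i]] <- plot_observations(
      plot_id = grid$plot_id[i], variety = grid$variety[i],
      nitrogen = grid$nitrogen[i], water = grid$water[i],
      sowing_day = design$sowing_day,
      lai_days = design$acquisition_days, lai = lai_obs,
      dam_days = design$stage_days, dam_t_ha = dam_obs,
      yield_t_ha = yield_obs)
  }
  names(plots) <- grid$plot_id
  list(truth = do.call(rbind, truth_rows), plots = plots,
       reflectance = do.call(rbind, refl_rows))
}
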