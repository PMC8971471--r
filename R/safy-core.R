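#' Temperature stress function
#'
#' Quadratic temperature response of daily biomass production: 0 at or
#' beyond the cardinal extremes `t_min`/`t_max`, 1 at the optimum
#' `t_opt`, with symmetric parabolic shoulders on each side.
#'
#' @param ta Daily mean air temperature (degC); vectorized.
#' @param params A [safy_params()] object.
#' @return Stress factor in \[0, 1\], same length as `ta`.
#' @examples
#' temperature_stress(c(-2, 9, 18, 26), safy_params())
#' @export
temperature_stress <- function(ta, params) {
  tmin <- params$t_min; topt <- params$t_opt; tmax <- params$t_max
  ft <- ifelse(ta <= topt,
               1 - ((topt - ta) / (topt - tmin))^2,
               1 - ((ta - topt) / (tmax - topt))^2)
  ft[ta <= tmin | ta >= tmax] <- 0
  ft
}

#' Absorbed photosynthetically active radiation
#'
#' APAR = (1 - exp(-K * LAI)) * eps_c * Rg: the photosynthetically
#' active fraction `eps_c` of incoming global radiation, intercepted by
#' the canopy with a Beer-Lambert extinction coefficient K.
#'
#' @param lai Leaf area index (m2 m-2, >= 0); vectorized.
#' @param rg Daily global radiation (MJ m-2 day-1, >= 0).
#' @param params A [safy_params()] object.
#' @return APAR in MJ m-2 day-1, bounded above by `eps_c * rg`.
#' @export
compute_apar <- function(lai, rg, params) {
  if (any(lai < 0)) stop("lai must be non-negative", call. = FALSE)
  if (any(rg < 0)) stop("rg must be non-negative", call. = FALSE)
  (1 - exp(-params$light_interception * lai)) *
    params$climate_efficiency * rg
}

#' Leaf partition fraction
#'
#' Fraction of the daily biomass increment allocated to leaves:
#' Pl = 1 - Pla * exp(Plb * SMT), clamped below at 0. Leaf allocation
#' therefore stops once accumulated thermal time reaches
#' ln(1/Pla)/Plb, which marks the LAI peak.
#'
#' @param smt Accumulated thermal time since emergence (degC day, >= 0);
#'   vectorized.
#' @param params A [safy_params()] object.
#' @return Partition fraction in \[0, 1 - Pla\].
#' @export
partition_fraction <- function(smt, params) {
  pmax(0, 1 - params$partition_a * exp(params$partition_b * smt))
}

#' One day of SAFY crop growth
#'
#' Advances the crop state by a single day. In order: thermal time is
#' accumulated as `max(ta - t_min, 0)`; the biomass increment
#' `dDAM = ELUE * F_T(ta) * APAR(lai, rg)` is added to dry aerial mass;
#' if the partition fraction at the updated thermal time is positive the
#' LAI grows by `dDAM * Pl * SLA`; if thermal time exceeds the
#' senescence threshold the LAI decays by `lai * (SMT - STT) / Rs`
#' (floored at 0). Growth and senescence both apply on days where both
#' conditions hold, growth first.
#'
#' @param state Named list with `day`, `lai`, `dam`, `smt`.
#' @param ta Daily mean temperature (degC).
#' @param rg Daily global radiation (MJ m-2 day-1).
#' @param params A [safy_params()] object.
#' @return Updated state list (day advanced by one) with an
#'   `in_senescence` flag.
#' @export
safy_daily_step <- function(state, ta, rg, params) {
  if (length(ta) != 1 || length(rg) != 1 || !is.finite(ta) || !is.finite(rg)) {
    stop("weather missing for requested day", call. = FALSE)
  }
  smt <- state$smt + max(ta - params$t_min, 0)
  ft <- temperature_stress(ta, params)
  apar <- compute_apar(state$lai, rg, params)
  ddam <- params$elue * ft * apar
  dam <- state$dam + ddam
  lai <- state$lai
  pl <- partition_fraction(smt, params)
  if (pl > 0) lai <- lai + ddam * pl * params$sla
  senescing <- smt > params$senescence_threshold
  if (senescing) {
    lai <- lai - lai * (smt - params$senescence_threshold) /
      params$senescence_rate
    lai <- max(lai, 0)
  }
  list(day = state$day + 1L, lai = lai, dam = dam, smt = smt,
       in_senescence = senescing)
}

#' Simulate a full SAFY growing season
#'
#' Runs the daily recurrence from emergence day `D0` (initial state
#' `dam = DAM0`, `lai = DAM0 * SLA`, `smt = 0`) until senescence is
#' complete (`SMT > STT` and `LAI < 0.1`), the weather series is
#' exhausted, or a hard cap of 300 days after emergence is reached.
#'
#' @param weather A [weather_series()] object (or equivalent data frame
#'   with columns `day`, `ta`, `rg`).
#' @param params A [safy_params()] object; `params$emergence_day` must
#'   lie within the weather series.
#' @return A `safy_trajectory`: a data frame with columns `day`, `lai`,
#'   `dam`, `smt`, `in_senescence`, carrying attributes `dam_max`,
#'   `day_of_peak_lai`, `smt_at_peak_lai`, and `params`.
#' @examples
#' w <- weather_series(1:250, ta = rep(18, 250), rg = rep(20, 250))
#' traj <- safy_simulate(w, safy_params(emergence_day = 10))
#' attr(traj, "dam_max")
#' @export
safy_simulate <- function(weather, params) {
  validate_safy_params(params)
  st <- simulate_states(weather, params)
  traj <- data.frame(day = st$day, lai = st$lai, dam = st$dam,
                     smt = st$smt, in_senescence = st$in_senescence)
  ipk <- which.max(traj$lai)
  attr(traj, "dam_max") <- max(traj$dam)
  attr(traj, "day_of_peak_lai") <- traj$day[ipk]
  attr(traj, "smt_at_peak_lai") <- traj$smt[ipk]
  attr(traj, "params") <- params
  class(traj) <- c("safy_trajectory", "data.frame")
  traj
}

# lean simulation engine: returns plain vectors, no data.frame overhead,
# so the assimilation cost can call it tens of thousands of times
simulate_states <- function(weather, params) {
  wday <- weather$day
  d0 <- params$emergence_day
  i0 <- match(d0, wday)
  if (is.na(i0)) {
    stop(sprintf("emergence day %d is outside the weather series [%d, %d]",
                 d0, min(wday), max(wday)), call. = FALSE)
  }
  ta <- weather$ta
  rg <- weather$rg
  n_w <- length(wday)
  horizon <- min(n_w - i0, 300L)

  tmin <- params$t_min; topt <- params$t_opt; tmax <- params$t_max
  k <- params$light_interception; eps_c <- params$climate_efficiency
  elue <- params$elue; sla <- params$sla
  pla <- params$partition_a; plb <- params$partition_b
  stt <- params$senescence_threshold; rs <- params$senescence_rate

  n_max <- horizon + 1L
  lai_v <- dam_v <- numeric(n_max)
  lai <- params$initial_dam * sla
  dam <- params$initial_dam
  lai_v[1] <- lai; dam_v[1] <- dam
  n_used <- 1L

  if (horizon >= 1L) {
    # everything that does not feed back through the state is
    # precomputable: thermal time, temperature stress, leaf partition
    # and the senescence decrement are functions of weather alone
    ii <- i0 + seq_len(horizon)
    ta_h <- ta[ii]; rg_h <- rg[ii]
    smt_h <- cumsum(pmax(ta_h - tmin, 0))
    ft_h <- ifelse(ta_h <= topt,
                   1 - ((topt - ta_h) / (topt - tmin))^2,
                   1 - ((ta_h - topt) / (tmax - topt))^2)
    ft_h[ta_h <= tmin | ta_h >= tmax] <- 0
    gain_h <- elue * ft_h * eps_c * rg_h
    pl_h <- pmax(1 - pla * exp(plb * smt_h), 0)
    sen_h <- smt_h > stt
    dec_h <- (smt_h - stt) / rs

    for (step in seq_len(horizon)) {
      ddam <- gain_h[step] * (1 - exp(-k * lai))
      dam <- dam + ddam
      if (pl_h[step] > 0) lai <- lai + ddam * pl_h[step] * sla
      if (sen_h[step]) {
        lai <- lai - lai * dec_h[step]
        if (lai < 0) lai <- 0
      }
      n_used <- n_used + 1L
      lai_v[n_used] <- lai; dam_v[n_used] <- dam
      if (sen_h[step] && lai < 0.1) break
    }
  }
  smt_v <- c(0, if (horizon >= 1L) smt_h[seq_len(n_used - 1L)])
  sen_v <- c(FALSE, if (horizon >= 1L) sen_h[seq_len(n_used - 1L)])

  list(day = wday[i0] + 0:(n_used - 1L),
       lai = lai_v[seq_len(n_used)],
       dam = dam_v[seq_len(n_used)],
       smt = smt_v,
       in_senescence = sen_v)
}

#' Grain yield from a simulated trajectory
#'
#' GY = HI * DAM_max, converted from g m-2 to t ha-1 (factor 0.01).
#'
#' @param traj A `safy_trajectory` from [safy_simulate()].
#' @param params A [safy_params()] object supplying the harvest index;
#'   defaults to the parameters stored in the trajectory.
#' @return Grain yield in t ha-1.
#' @export
grain_yield <- function(traj, params = attr(traj, "params")) {
  if (is.null(traj) || nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  attr(traj, "dam_max") * params$harvest_index * 0.01
}

#' Simulated LAI at arbitrary days
#'
#' Looks up the simulated LAI at the requested days-of-season. Days
#' before emergence return the initial LAI (`DAM0 * SLA`); days after
#' the simulation terminated return 0 (canopy fully senesced).
#'
#' @param traj A `safy_trajectory`.
#' @param days Integer days-of-season.
#' @return Numeric vector of LAI values.
#' @export
trajectory_lai_at <- function(traj, days) {
  params <- attr(traj, "params")
  d0 <- traj$day[1]
  idx <- days - d0 + 1L
  out <- numeric(length(days))
  before <- idx < 1L
  after <- idx > nrow(traj)
  inside <- !before & !after
  out[before] <- params$initial_dam * params$sla
  out[after] <- 0
  out[inside] <- traj$lai[idx[inside]]
  out
}

#' Simulated dry aerial mass at arbitrary days
#'
#' As [trajectory_lai_at()] but for DAM. Days before emergence return
#' `DAM0`; days after termination return the final (maximal) DAM, since
#' above-ground dry mass does not decrease in this model.
#'
#' @param traj A `safy_trajectory`.
#' @param days Integer days-of-season.
#' @param units `"g_m2"` (internal) or `"t_ha"` (reported, = g m-2 x 0.01).
#' @return Numeric vector of DAM values.
#' @export
trajectory_dam_at <- function(traj, days, units = c("g_m2", "t_ha")) {
  units <- match.arg(units)
  params <- attr(traj, "params")
  d0 <- traj$day[1]
  idx <- days - d0 + 1L
  out <- numeric(length(days))
  before <- idx < 1L
  after <- idx > nrow(traj)
  inside <- !before & !after
  out[before] <- params$initial_dam
  out[after] <- traj$dam[nrow(traj)]
  out[inside] <- traj$dam[idx[inside]]
  if (units == "t_ha") out <- out * 0.01
  out
}
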