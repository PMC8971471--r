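#' Daily weather series
#'
#' @param day Integer day-of-season, strictly increasing, no gaps.
#' @param ta Daily mean air temperature (degC). If omitted, computed as
#'   the average of `tmin` and `tmax`.
#' @param rg Daily global radiation (MJ m-2 day-1, >= 0).
#' @param tmin,tmax Optional daily extreme temperatures (degC) used to
#'   derive `ta`.
#' @return A `weather_series` data frame with columns `day`, `ta`, `rg`.
#' @export
weather_series <- function(day, ta = NULL, rg, tmin = NULL, tmax = NULL) {
  day <- as.integer(day)
  if (is.null(ta)) {
    if (is.null(tmin) || is.null(tmax)) {
      stop("supply either ta or both tmin and tmax", call. = FALSE)
    }
    ta <- (tmin + tmax) / 2
  }
  if (length(day) != length(ta) || length(day) != length(rg)) {
    stop("day, ta and rg must have equal length", call. = FALSE)
  }
  d <- diff(day)
  if (any(d != 1L)) {
    bad <- day[which(d != 1L)[1]] + 1L
    stop(sprintf("weather series has a gap: day %d is missing", bad),
         call. = FALSE)
  }
  if (any(!is.finite(ta)) || any(!is.finite(rg))) {
    stop("weather series contains non-finite values", call. = FALSE)
  }
  if (any(rg < 0)) stop("rg must be non-negative", call. = FALSE)
  w <- data.frame(day = day, ta = as.numeric(ta), rg = as.numeric(rg))
  class(w) <- c("weather_series", "data.frame")
  w
}

#' Read a weather CSV
#'
#' Expected columns: `day` plus either `ta_c` or the pair
#' `tmin_c`/`tmax_c` (mean temperature is then their average), and
#' `rg_mj_m2`. Days must be contiguous.
#'
#' @param path CSV path (header row, UTF-8).
#' @return A [weather_series()].
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop(sprintf("weather file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"day" %in% names(df)) stop("weather CSV lacks a 'day' column",
                                  call. = FALSE)
  if (!"rg_mj_m2" %in% names(df)) {
    stop("weather CSV lacks an 'rg_mj_m2' column", call. = FALSE)
  }
  if ("ta_c" %in% names(df)) {
    weather_series(df$day, ta = df$ta_c, rg = df$rg_mj_m2)
  } else if (all(c("tmin_c", "tmax_c") %in% names(df))) {
    weather_series(df$day, rg = df$rg_mj_m2,
                   tmin = df$tmin_c, tmax = df$tmax_c)
  } else {
    stop("weather CSV needs 'ta_c' or both 'tmin_c' and 'tmax_c'",
         call. = FALSE)
  }
}

#' Write a weather series to CSV
#'
#' @param weather A [weather_series()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(weather, path) {
  utils::write.csv(
    data.frame(day = weather$day, ta_c = weather$ta,
               rg_mj_m2 = weather$rg),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-plot observation container
#'
#' Bundles one plot's treatment codes and its dated observations:
#' sparse LAI (from direct measurement or reflectance inversion), dry
#' aerial mass at destructive-sampling stages, and the harvest yield.
#'
#' @param plot_id Plot identifier.
#' @param variety `"P1"` or `"P2"`.
#' @param nitrogen `"N1"`..`"N4"`.
#' @param water `"W1"`..`"W3"`.
#' @param sowing_day Day-of-season of sowing.
#' @param lai_days,lai Observation days and LAI values (m2 m-2).
#' @param dam_days,dam_t_ha Observation days and dry aerial mass
#'   (t ha-1).
#' @param yield_t_ha Harvest yield (t ha-1) or `NA`.
#' @return A `plot_observations` object.
#' @export
plot_observations <- function(plot_id, variety = "P1", nitrogen = "N1",
                              water = "W1", sowing_day = 5L,
                              lai_days = integer(0), lai = numeric(0),
                              dam_days = integer(0), dam_t_ha = numeric(0),
                              yield_t_ha = NA_real_) {
  if (!variety %in% c("P1", "P2")) stop("unknown variety code",
                                        call. = FALSE)
  if (!nitrogen %in% paste0("N", 1:4)) stop("unknown nitrogen code",
                                            call. = FALSE)
  if (!water %in% paste0("W", 1:3)) stop("unknown water code",
                                         call. = FALSE)
  if (length(lai_days) != length(lai)) {
    stop("lai_days and lai lengths disagree", call. = FALSE)
  }
  if (length(dam_days) != length(dam_t_ha)) {
    stop("dam_days and dam_t_ha lengths disagree", call. = FALSE)
  }
  structure(list(plot_id = plot_id, variety = variety,
                 nitrogen = nitrogen, water = water,
                 sowing_day = as.integer(sowing_day),
                 lai_days = as.integer(lai_days), lai = as.numeric(lai),
                 dam_days = as.integer(dam_days),
                 dam_t_ha = as.numeric(dam_t_ha),
                 yield_t_ha = yield_t_ha),
            class = "plot_observations")
}

#' Read the plot-level observation tables
#'
#' Joins the plot register with the LAI, dry-mass, yield and reflectance
#' tables by plot id (and day where applicable). Duplicate
#' `(plot_id, day)` rows are an error; plot ids present in an
#' observation table but absent from the register are dropped with a
#' warning.
#'
#' @param plots_path CSV with columns `plot_id, variety, nitrogen,
#'   water, sowing_day`.
#' @param lai_path Optional CSV `plot_id, day, lai`.
#' @param dam_path Optional CSV `plot_id, day, dam_t_ha`.
#' @param yield_path Optional CSV `plot_id, yield_t_ha`.
#' @param reflectance_path Optional CSV `plot_id, day, b_blue, b_green,
#'   b_red, b_nir`.
#' @return List with `plots` (named list of [plot_observations()]) and
#'   `reflectance` (data frame or `NULL`).
#' @export
read_plot_tables <- function(plots_path, lai_path = NULL, dam_path = NULL,
                             yield_path = NULL, reflectance_path = NULL) {
  read_tab <- function(path, required) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) stop(sprintf("input file not found: %s", path),
                                 call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols)) {
      stop(sprintf("%s lacks columns: %s", path,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    df
  }
  check_dupes <- function(df, what) {
    if (is.null(df)) return(invisible(NULL))
    key <- paste(df$plot_id, df$day)
    if (anyDuplicated(key)) {
      stop(sprintf("duplicate (plot_id, day) rows in %s table", what),
           call. = FALSE)
    }
  }
  plots_df <- read_tab(plots_path,
                       c("plot_id", "variety", "nitrogen", "water",
                         "sowing_day"))
  lai_df <- read_tab(lai_path, c("plot_id", "day", "lai"))
  dam_df <- read_tab(dam_path, c("plot_id", "day", "dam_t_ha"))
  yield_df <- read_tab(yield_path, c("plot_id", "yield_t_ha"))
  refl_df <- read_tab(reflectance_path,
                      c("plot_id", "day", "b_blue", "b_green", "b_red",
                        "b_nir"))
  check_dupes(lai_df, "LAI")
  check_dupes(dam_df, "DAM")
  check_dupes(refl_df, "reflectance")

  known <- plots_df$plot_id
  warn_unknown <- function(df, what) {
    if (is.null(df)) return(df)
    extra <- setdiff(unique(df$plot_id), known)
    if (length(extra)) {
      warning(sprintf("%s table has unknown plot ids (%s); dropped",
                      what, paste(extra, collapse = ", ")), call. = FALSE)
      df <- df[df$plot_id %in% known, , drop = FALSE]
    }
    df
  }
  lai_df <- warn_unknown(lai_df, "LAI")
  dam_df <- warn_unknown(dam_df, "DAM")
  yield_df <- warn_unknown(yield_df, "yield")
  refl_df <- warn_unknown(refl_df, "reflectance")

  plots <- lapply(seq_len(nrow(plots_df)), function(i) {
    pid <- plots_df$plot_id[i]
    li <- if (is.null(lai_df)) NULL else lai_df[lai_df$plot_id == pid, ]
    di <- if (is.null(dam_df)) NULL else dam_df[dam_df$plot_id == pid, ]
    yi <- if (is.null(yield_df)) NA_real_ else {
      v <- yield_df$yield_t_ha[yield_df$plot_id == pid]
      if (length(v)) v[1] else NA_real_
    }
    plot_observations(
      plot_id = pid, variety = plots_df$variety[i],
      nitrogen = plots_df$nitrogen[i], water = plots_df$water[i],
      sowing_day = plots_df$sowing_day[i],
      lai_days = if (is.null(li)) integer(0) else li$day,
      lai = if (is.null(li)) numeric(0) else li$lai,
      dam_days = if (is.null(di)) integer(0) else di$day,
      dam_t_ha = if (is.null(di)) numeric(0) else di$dam_t_ha,
      yield_t_ha = yi)
  })
  names(plots) <- plots_df$plot_id
  list(plots = plots, reflectance = refl_df)
}

#' Write a synthetic trial to a directory of CSV files
#'
#' Emits the same CSV dialects the readers consume: `weather.csv`,
#' `plots.csv`, `lai_observations.csv`, `dam_observations.csv`,
#' `yields.csv`, `reflectance.csv`, and `truth.csv` (the generating
#' parameters, for scoring recovery).
#'
#' @param trial A trial list from [generate_trial()].
#' @param weather The [weather_series()] used to generate it.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, weather, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  write_weather(weather, file.path(dir, "weather.csv"))
  plots <- trial$plots
  w(do.call(rbind, lapply(plots, function(p) {
    data.frame(plot_id = p$plot_id, variety = p$variety,
               nitrogen = p$nitrogen, water = p$water,
               sowing_day = p$sowing_day)
  })), "plots.csv")
  w(do.call(rbind, lapply(plots, function(p) {
    if (!length(p$lai_days)) return(NULL)
    data.frame(plot_id = p$plot_id, day = p$lai_days, lai = p$lai)
  })), "lai_observations.csv")
  w(do.call(rbind, lapply(plots, function(p) {
    if (!length(p$dam_days)) return(NULL)
    data.frame(plot_id = p$plot_id, day = p$dam_days,
               dam_t_ha = p$dam_t_ha)
  })), "dam_observations.csv")
  w(do.call(rbind, lapply(plots, function(p) {
    data.frame(plot_id = p$plot_id, yield_t_ha = p$yield_t_ha)
  })), "yields.csv")
  if (!is.null(trial$reflectance)) w(trial$reflectance, "reflectance.csv")
  if (!is.null(trial$truth)) w(trial$truth, "truth.csv")
  invisible(dir)
}
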