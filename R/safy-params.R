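#' SAFY parameter vector
#'
#' Bundles the full parameter set of the SAFY light-use-efficiency crop
#' growth model: the fixed crop/climate constants, the two calibrated
#' leaf-partition coefficients, and the three sensitive parameters that
#' the assimilation step re-estimates per plot (emergence day `D0`,
#' effective light-use efficiency `ELUE`, senescence temperature
#' threshold `STT`).
#'
#' Shipped defaults are the standard winter-wheat settings used with this
#' model: climate efficiency 0.48, light-interception coefficient 0.5,
#' cardinal temperatures 0/18/26 degC, specific leaf area 0.022 m2 g-1,
#' senescence rate 6875 degC day, initial dry aerial mass 4.2 g m-2, and
#' harvest index 0.5. The calibrated partition coefficients default to
#' Pla = 0.16, Plb = 0.0025.
#'
#' @param climate_efficiency Fraction of global radiation that is
#'   photosynthetically active (dimensionless, > 0).
#' @param light_interception Beer-Lambert light interception coefficient
#'   K (dimensionless, > 0).
#' @param t_min,t_opt,t_max Cardinal temperatures for the temperature
#'   stress function (degC); must satisfy `t_min < t_opt < t_max`.
#' @param sla Specific leaf area (m2 per g leaf dry mass, > 0).
#' @param senescence_rate Leaf senescence rate constant Rs (degC day).
#' @param initial_dam Dry aerial mass at emergence, DAM0 (g m-2).
#' @param partition_a,partition_b Leaf partition coefficients Pla
#'   (dimensionless, in \[0.01, 0.3\]) and Plb (per degC day, in
#'   \[1e-5, 1e-2\]).
#' @param emergence_day Day-of-season of crop emergence D0 (integer).
#' @param elue Effective light-use efficiency (g dry mass per MJ APAR,
#'   in \[1.3, 2.5\]).
#' @param senescence_threshold Thermal-time threshold STT at which leaf
#'   senescence begins (degC day, in \[600, 1500\]).
#' @param harvest_index Grain yield as a fraction of peak biomass
#'   (dimensionless, in (0, 1\]).
#' @param bounds Named list of `c(lower, upper)` bounds for the
#'   optimizable parameters; see [safy_default_bounds()].
#'
#' @return An object of class `safy_params` (a named list).
#' @examples
#' p <- safy_params()
#' p$elue
#' @export
safy_params <- function(climate_efficiency = 0.48,
                        light_interception = 0.5,
                        t_min = 0, t_opt = 18, t_max = 26,
                        sla = 0.022,
                        senescence_rate = 6875,
                        initial_dam = 4.2,
                        partition_a = 0.16,
                        partition_b = 0.0025,
                        emergence_day = 15L,
                        elue = 1.9,
                        senescence_threshold = 1000,
                        harvest_index = 0.5,
                        bounds = safy_default_bounds()) {
  p <- list(
    climate_efficiency = climate_efficiency,
    light_interception = light_interception,
    t_min = t_min, t_opt = t_opt, t_max = t_max,
    sla = sla,
    senescence_rate = senescence_rate,
    initial_dam = initial_dam,
    partition_a = partition_a,
    partition_b = partition_b,
    emergence_day = as.integer(round(emergence_day)),
    elue = elue,
    senescence_threshold = senescence_threshold,
    harvest_index = harvest_index,
    bounds = bounds
  )
  class(p) <- "safy_params"
  validate_safy_params(p)
  p
}

#' Default bounds for the optimizable SAFY parameters
#'
#' Lower/upper bounds for the calibrated partition coefficients and the
#' three sensitive parameters. The emergence-day bounds are relative to
#' sowing (days after sowing) and are resolved to day-of-season by the
#' assimilation step.
#'
#' @return Named list of length-2 numeric vectors.
#' @export
safy_default_bounds <- function() {
  list(
    partition_a = c(0.01, 0.3),
    partition_b = c(1e-5, 1e-2),
    elue = c(1.3, 2.5),
    senescence_threshold = c(600, 1500),
    emergence_offset = c(5, 25)
  )
}

validate_safy_params <- function(p) {
  stopifnot(inherits(p, "safy_params"))
  pos <- c("climate_efficiency", "light_interception", "sla",
           "senescence_rate", "harvest_index", "initial_dam")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop(sprintf("'%s' must be a positive finite scalar", nm), call. = FALSE)
    }
  }
  if (!(p$t_min < p$t_opt && p$t_opt < p$t_max)) {
    stop("cardinal temperatures must satisfy t_min < t_opt < t_max",
         call. = FALSE)
  }
  if (p$partition_a < 0.01 || p$partition_a > 0.3) {
    stop("partition_a (Pla) must lie in [0.01, 0.3]", call. = FALSE)
  }
  if (p$partition_b < 1e-5 || p$partition_b > 1e-2) {
    stop("partition_b (Plb) must lie in [1e-5, 1e-2]", call. = FALSE)
  }
  if (p$elue < 1.3 || p$elue > 2.5) {
    stop("elue must lie in [1.3, 2.5] g/MJ", call. = FALSE)
  }
  if (p$senescence_threshold < 600 || p$senescence_threshold > 1500) {
    stop("senescence_threshold (STT) must lie in [600, 1500] degC day",
         call. = FALSE)
  }
  if (p$harvest_index > 1) {
    stop("harvest_index must lie in (0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.safy_params <- function(x, ...) {
  cat("SAFY parameters\n")
  cat(sprintf("  fixed:      eps_c=%.3g K=%.3g T=(%g,%g,%g) degC SLA=%.4g Rs=%g DAM0=%.3g HI=%.2f\n",
              x$climate_efficiency, x$light_interception,
              x$t_min, x$t_opt, x$t_max, x$sla, x$senescence_rate,
              x$initial_dam, x$harvest_index))
  cat(sprintf("  partition:  Pla=%.4g Plb=%.4g\n",
              x$partition_a, x$partition_b))
  cat(sprintf("  sensitive:  D0=%d ELUE=%.3g g/MJ STT=%g degC day\n",
              x$emergence_day, x$elue, x$senescence_threshold))
  invisible(x)
}

#' Clone a parameter set with some fields replaced
#'
#' Convenience setter used throughout the assimilation loop, e.g.
#' `update_params(p, emergence_day = 20, elue = 2.1)`. The result is
#' revalidated.
#'
#' @param p A [safy_params()] object.
#' @param ... Named fields to replace.
#' @return A new `safy_params` object.
#' @export
update_params <- function(p, ...) {
  repl <- list(...)
  for (nm in names(repl)) p[[nm]] <- repl[[nm]]
  if (!is.null(repl$emergence_day)) {
    p$emergence_day <- as.integer(round(repl$emergence_day))
  }
  validate_safy_params(p)
  p
}
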