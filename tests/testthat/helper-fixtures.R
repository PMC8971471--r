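# shared fixtures, built once per test run and cached

const_weather <- function(n = 250, ta = 18, rg = 20) {
  weather_series(seq_len(n), ta = rep(ta, n), rg = rep(rg, n))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

season_weather <- function() cached("weather", generate_weather(280, seed = 3))

# a noise-free trial: observations equal the truth sampled at the dates
noisefree_trial <- function() {
  cached("trial0", generate_trial(
    trial_design(), season_weather(), safy_params(), seed = 5,
    sigma_lai = 0, dam_cv = 0, sigma_yield = 0,
    reflectance_noise_sd = 0))
}

# default-noise trial (sigma_lai 0.3, dam CV 10%, sigma_yield 0.3)
noisy_trial <- function() {
  cached("trial1", generate_trial(
    trial_design(), season_weather(), safy_params(), seed = 5))
}
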