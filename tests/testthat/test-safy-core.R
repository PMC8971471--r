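test_that("temperature stress matches its piecewise definition", {
  p <- safy_params()  # cardinal temperatures 0/18/26

  expect_identical(temperature_stress(18, p), 1)
  expect_equal(temperature_stress(9, p), 0.75, tolerance = 1e-12)
  expect_identical(temperature_stress(-2, p), 0)
  expect_identical(temperature_stress(30, p), 0)
  # exact zeros at the cardinal extremes, continuity at the optimum
  expect_identical(temperature_stress(c(0, 26), p), c(0, 0))
  eps <- 1e-9
  expect_equal(temperature_stress(18 - eps, p),
               temperature_stress(18 + eps, p), tolerance = 1e-6)

  ta_grid <- seq(-10, 40, by = 0.25)
  ft <- temperature_stress(ta_grid, p)
  expect_true(all(ft >= 0 & ft <= 1))
})

test_that("APAR follows Beer-Lambert interception and saturates", {
  p <- safy_params()  # K = 0.5, eps_c = 0.48
  expect_identical(compute_apar(0, 20, p), 0)
  expect_equal(compute_apar(2, 20, p), 6.06835736475415, tolerance = 1e-9)
  expect_equal(compute_apar(1e6, 20, p), 0.48 * 20, tolerance = 1e-12)
  # within [0, eps_c * rg] and strictly increasing in lai
  lai <- seq(0, 10, by = 0.1)
  a <- compute_apar(lai, 15, p)
  expect_true(all(a >= 0 & a <= 0.48 * 15))
  expect_true(all(diff(a) > 0))
  expect_error(compute_apar(-1, 20, p), "non-negative")
  expect_error(compute_apar(2, -1, p), "non-negative")
})

test_that("leaf partition fraction zeroes at ln(1/Pla)/Plb and clamps", {
  p <- safy_params()  # Pla = 0.16, Plb = 0.0025
  expect_equal(partition_fraction(0, p), 0.84, tolerance = 1e-12)
  pl733 <- partition_fraction(733, p)
  expect_lt(pl733, 1e-3)
  expect_equal(pl733, 8.14604302290522e-05, tolerance = 1e-9)
  expect_identical(partition_fraction(5000, p), 0)
})

test_that("a single daily step reproduces the hand-computed chain", {
  p <- update_params(safy_params(), elue = 2.0)
  s0 <- list(day = 10L, lai = 2, dam = 100, smt = 0)
  s1 <- safy_daily_step(s0, ta = 18, rg = 20, p)
  expect_identical(s1$day, 11L)
  expect_equal(s1$dam - s0$dam, 12.1367147295083, tolerance = 1e-9)
  # LAI increment = dDAM * Pl(smt + 18) * SLA
  expect_equal(s1$lai - s0$lai, 0.22232012114258, tolerance = 1e-9)
  expect_equal(s1$smt, 18)
  expect_false(s1$in_senescence)

  # senescence decrement, hand-evaluated
  p2 <- update_params(safy_params(), senescence_threshold = 1100)
  s <- list(day = 1L, lai = 4, dam = 500, smt = 1300)
  s2 <- safy_daily_step(s, ta = 0, rg = 0, p2)
  expect_equal(s$lai - s2$lai, 0.116363636363636, tolerance = 1e-9)
  expect_true(s2$in_senescence)

  # freezing day: no growth, no thermal-time accumulation
  s3 <- safy_daily_step(s0, ta = -5, rg = 12, p)
  expect_identical(s3$dam, s0$dam)
  expect_identical(s3$smt, s0$smt)

  expect_error(safy_daily_step(s0, ta = NA_real_, rg = 10, p), "missing")
})

test_that("trajectories respect the core state invariants", {
  w <- const_weather()
  for (stt in c(800, 1000, 1400)) {
    p <- update_params(safy_params(), emergence_day = 10, elue = 2.0,
                       senescence_threshold = stt)
    traj <- safy_simulate(w, p)
    expect_true(all(diff(traj$dam) >= 0))
    expect_true(all(diff(traj$smt) >= 0))
    expect_true(all(traj$lai >= 0))
    expect_equal(attr(traj, "dam_max"), max(traj$dam))
    # single interior peak: non-decreasing then non-increasing
    ipk <- which.max(traj$lai)
    expect_true(all(diff(traj$lai[1:ipk]) >= 0))
    expect_true(all(diff(traj$lai[ipk:nrow(traj)]) <= 0))
  }
})

test_that("simulation terminates when senescence completes", {
  w <- const_weather()
  p <- update_params(safy_params(), emergence_day = 10, elue = 2.0,
                     senescence_threshold = 1000)
  traj <- safy_simulate(w, p)
  last <- nrow(traj)
  expect_lt(traj$lai[last], 0.1)
  expect_gt(traj$smt[last], 1000)
  expect_lt(max(traj$day), max(w$day))  # stopped before weather ran out
})

test_that("no radiation means no growth", {
  n <- 120
  w <- weather_series(1:n, ta = rep(15, n), rg = rep(0, n))
  p <- update_params(safy_params(), emergence_day = 5)
  traj <- safy_simulate(w, p)
  lai0 <- p$initial_dam * p$sla
  expect_true(all(traj$dam == p$initial_dam))
  expect_true(all(traj$lai <= lai0 + 1e-12))
})

test_that("the simulation horizon is capped at 300 days", {
  n <- 400
  # stay below t_min: SMT never reaches STT, nothing ever senesces
  w <- weather_series(1:n, ta = rep(-5, n), rg = rep(10, n))
  p <- update_params(safy_params(), emergence_day = 1)
  traj <- safy_simulate(w, p)
  expect_identical(nrow(traj), 301L)
})

test_that("emergence outside the weather range errors", {
  w <- const_weather(50)
  expect_error(safy_simulate(w, update_params(safy_params(),
                                              emergence_day = 60)),
               "outside the weather series")
})

test_that("biomass increments are linear in ELUE", {
  w <- const_weather(120)
  base <- update_params(safy_params(), emergence_day = 5, elue = 1.3,
                        partition_a = 0.3)  # high Pla: slow canopy
  # one step from identical states: dDAM scales exactly with ELUE
  s0 <- list(day = 5L, lai = 1.5, dam = 50, smt = 100)
  d1 <- safy_daily_step(s0, 18, 20, base)$dam - 50
  d2 <- safy_daily_step(s0, 18, 20, update_params(base, elue = 2.5))$dam - 50
  expect_equal(d2 / d1, 2.5 / 1.3, tolerance = 1e-12)
})

test_that("grain yield is the exact harvest-index identity", {
  w <- const_weather()
  p <- update_params(safy_params(), emergence_day = 10, elue = 2.0)
  traj <- safy_simulate(w, p)
  expect_identical(grain_yield(traj, p),
                   attr(traj, "dam_max") * p$harvest_index * 0.01)
  # unit conversion anchors
  fake <- traj
  attr(fake, "dam_max") <- 1500
  expect_equal(grain_yield(fake, p), 7.5)
  attr(fake, "dam_max") <- 100
  expect_equal(grain_yield(fake, update_params(p, harvest_index = 1)), 1)
})

test_that("trajectory lookups handle days outside the simulated range", {
  w <- const_weather()
  p <- update_params(safy_params(), emergence_day = 20, elue = 2.0)
  traj <- safy_simulate(w, p)
  lai0 <- p$initial_dam * p$sla
  expect_equal(trajectory_lai_at(traj, c(1, 5)), c(lai0, lai0))
  expect_equal(trajectory_lai_at(traj, max(traj$day) + 10), 0)
  expect_equal(trajectory_dam_at(traj, 1), p$initial_dam)
  expect_equal(trajectory_dam_at(traj, max(traj$day) + 10),
               traj$dam[nrow(traj)])
  expect_equal(trajectory_dam_at(traj, traj$day[5], units = "t_ha"),
               traj$dam[5] * 0.01)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(safy_params(t_min = 20, t_opt = 18), "t_min < t_opt")
  expect_error(safy_params(elue = 3), "1.3")
  expect_error(safy_params(partition_a = 0.5), "0.3")
  expect_error(safy_params(senescence_threshold = 200), "600")
  expect_error(safy_params(harvest_index = 1.5), "0, 1")
})
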