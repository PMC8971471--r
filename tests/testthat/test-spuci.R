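sphere <- function(x) sum(x^2)

test_that("search space and config enforce their invariants", {
  expect_error(search_space(c(0, 1), c(1, 1)), "lower < upper")
  expect_error(search_space(0, Inf), "finite")
  sp <- search_space(c(-1, 0), c(1, 10), integer = c(FALSE, TRUE))
  expect_identical(sp$n, 2L)
  expect_error(spuci_config(m = 0), "m must be")
  sp5 <- search_space(rep(-1, 5), rep(1, 5))
  expect_error(spuci_optimize(sphere, sp5, spuci_config(p = 3)),
               "p must be")
  expect_error(spuci_optimize(sphere, sp5,
                              spuci_config(m = 3, maxn = 10)),
               "maxn")
})

test_that("initial population is uniform within bounds and reproducible", {
  sp <- search_space(c(-2, 10), c(3, 20))
  set.seed(5)
  pop <- initialize_population(sphere, sp, m = 2, p = 5)
  expect_identical(dim(pop$points), c(10L, 2L))
  expect_true(all(pop$points[, 1] >= -2 & pop$points[, 1] <= 3))
  expect_true(all(pop$points[, 2] >= 10 & pop$points[, 2] <= 20))
  expect_equal(pop$values, apply(pop$points, 1, sphere))
  set.seed(5)
  pop2 <- initialize_population(sphere, sp, m = 2, p = 5)
  expect_identical(pop$points, pop2$points)
  # non-finite objective values are retained as +Inf
  set.seed(5)
  pop3 <- initialize_population(function(x) NaN, sp, m = 1, p = 4)
  expect_true(all(pop3$values == Inf))
})

test_that("shuffling partitions the population and sorts each complex", {
  set.seed(8)
  pop <- initialize_population(sphere, search_space(rep(-5, 3),
                                                    rep(5, 3)),
                               m = 3, p = 7)
  cxs <- shuffle_into_complexes(pop, 3)
  expect_length(cxs, 3)
  vals <- sort(unlist(lapply(cxs, `[[`, "values"), use.names = FALSE))
  expect_equal(vals, sort(pop$values))  # conservation (multiset)
  for (cx in cxs) expect_true(!is.unsorted(cx$values))
  one <- shuffle_into_complexes(pop, 1)
  expect_equal(one[[1]]$values, sort(pop$values))
})

test_that("PCA restoration jitters collapsed dimensions only", {
  sp <- search_space(c(0, 0), c(10, 10))
  set.seed(2)
  # dimension 2 collapsed to a constant
  pts <- cbind(runif(8, 0, 10), rep(4, 8))
  vals <- apply(pts, 1, sphere)
  ord <- order(vals)
  cx <- list(points = pts[ord, ], values = vals[ord])
  fixed <- restore_lost_dimensions(cx, sp, sphere)
  expect_gt(stats::sd(fixed$points[, 2]), 0)  # restored
  expect_true(all(fixed$points >= 0 & fixed$points <= 10))
  expect_true(!is.unsorted(fixed$values))

  # healthy isotropic cloud passes through untouched
  set.seed(3)
  pts2 <- matrix(runif(16, 0, 10), 8, 2)
  vals2 <- apply(pts2, 1, sphere)
  ord2 <- order(vals2)
  cx2 <- list(points = pts2[ord2, ], values = vals2[ord2])
  same <- restore_lost_dimensions(cx2, sp, sphere)
  expect_identical(same$points, cx2$points)
})

test_that("MCCE reflection is exact vector arithmetic and never raises the best", {
  sp <- search_space(c(-10, -10), c(10, 10))
  # hand-set simplex: reflection of worst through centroid of the rest
  pts <- rbind(c(0, 0), c(2, 0), c(1, 3))
  vals <- apply(pts, 1, sphere)  # already sorted: 0, 4, 10
  cx <- list(points = pts, values = vals)
  set.seed(1)
  ev <- evolve_complex_mcce(cx, sp, sphere, n_steps = 1)
  # centroid of the two best is (1, 0); reflected worst = (1, -3),
  # same objective 10 -> not an improvement -> contraction to (1, 1.5),
  # objective 3.25 < 10, accepted
  expect_true(any(apply(ev$complex$points, 1, function(r)
    isTRUE(all.equal(r, c(1, 1.5))))))
  expect_lte(ev$complex$values[1], vals[1])

  # on a convex quadratic, repeated evolution only improves
  set.seed(4)
  pop <- initialize_population(sphere, sp, m = 1, p = 7)
  cx2 <- shuffle_into_complexes(pop, 1)[[1]]
  ev2 <- evolve_complex_mcce(cx2, sp, sphere)
  expect_lte(ev2$complex$values[1], cx2$values[1])
  expect_true(all(ev2$complex$points >= -10 & ev2$complex$points <= 10))
})

test_that("multinormal resampling stays in bounds and replaces the worst when better", {
  sp <- search_space(c(-5, -5), c(5, 5))
  # degenerate complex: all mass at one point, draw lands at the mean
  pts <- matrix(rep(c(1, 2), each = 4), 4, 2)
  cx <- list(points = pts, values = apply(pts, 1, sphere))
  set.seed(6)
  out <- resample_multinormal(cx, sp, sphere)
  expect_equal(unname(out$points[4, ]), c(1, 2), tolerance = 1e-4)
  # sphere centred at the complex mean: substitution is near-certain
  ctr <- c(0.5, -0.5)
  f_ctr <- function(x) sum((x - ctr)^2)
  set.seed(7)
  spread <- matrix(rnorm(20, rep(ctr, each = 10), 1), 10, 2)
  spread <- pmin(pmax(spread, -5), 5)
  v <- apply(spread, 1, f_ctr)
  ord <- order(v)
  cx2 <- list(points = spread[ord, ], values = v[ord])
  hits <- 0
  for (i in 1:200) {
    out2 <- resample_multinormal(cx2, sp, f_ctr)
    if (out2$values[length(out2$values)] < cx2$values[length(cx2$values)])
      hits <- hits + 1
  }
  expect_gt(hits / 200, 0.5)
})

test_that("the optimizer solves the sphere and Rosenbrock benchmarks", {
  sp5 <- search_space(rep(-5, 5), rep(5, 5))
  sphere_best <- sapply(1:10, function(s)
    spuci_optimize(sphere, sp5, spuci_config(seed = s))$value)
  expect_gte(sum(sphere_best < 1e-6), 9)

  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  sp2 <- search_space(c(-2, -2), c(2, 2))
  rosen_best <- sapply(1:10, function(s)
    spuci_optimize(rosen, sp2, spuci_config(seed = s))$value)
  expect_gte(sum(rosen_best < 1e-3), 8)
})

test_that("optimizer matches brute-force grid search on a 1-d quartic", {
  quartic <- function(x) (x - 0.7)^2 * (x + 1.1)^2 + 0.3 * x
  grid <- seq(-2, 2, length.out = 1001)
  grid_best <- min(sapply(grid, quartic))
  res <- spuci_optimize(function(x) quartic(x[1]),
                        search_space(-2, 2),
                        spuci_config(seed = 4, maxn = 3000))
  expect_lte(res$value, grid_best + 4 / 1000)
})

test_that("optimizer contracts: elitism, bounds, budget, determinism", {
  sp <- search_space(rep(-5, 3), rep(5, 3))
  trace_pts <- new.env(); trace_pts$x <- list()
  f <- function(x) { trace_pts$x[[length(trace_pts$x) + 1L]] <- x; sphere(x) }
  res <- spuci_optimize(f, sp, spuci_config(seed = 2, maxn = 1500))
  expect_true(all(diff(res$history) <= 0))  # best-ever non-increasing
  all_pts <- do.call(rbind, trace_pts$x)
  expect_true(all(all_pts >= -5 & all_pts <= 5))
  expect_identical(res$evaluations, nrow(all_pts))
  # budget respected within one shuffling-cycle granule
  # (per cycle at most m * (restore + 2 * mcce_steps + resample) evals)
  expect_lt(res$evaluations, 1500 + 3 * (4 + 2 * 13 + 1))
  res2 <- spuci_optimize(sphere, sp, spuci_config(seed = 2, maxn = 1500))
  expect_identical(res$par, res2$par)
  expect_identical(res$value, res2$value)
})

test_that("integer dimensions are evaluated on the lattice", {
  sp <- search_space(c(0, -1), c(10, 1), integer = c(TRUE, FALSE))
  f <- function(x) {
    if (x[1] != round(x[1])) stop("non-integer proposal")
    (x[1] - 7)^2 + x[2]^2
  }
  res <- spuci_optimize(f, sp, spuci_config(seed = 3, maxn = 2000))
  expect_identical(res$par[1], 7)
  expect_lt(res$value, 1e-6)
})

test_that("with m = 1, p = n + 1 and no mutation the moves reduce to simplex descent", {
  sp <- search_space(c(-5, -5), c(5, 5))
  set.seed(9)
  pop <- initialize_population(sphere, sp, m = 1, p = 3)
  cx <- shuffle_into_complexes(pop, 1)[[1]]
  for (i in 1:30) {
    cx <- evolve_complex_mcce(cx, sp, sphere, n_steps = 1,
                              mutate = FALSE)$complex
  }
  expect_lt(cx$values[1], pop$values[order(pop$values)][1])
  expect_lt(cx$values[1], 0.1)
})
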