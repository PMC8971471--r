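#' Bounded search space
#'
#' @param lower,upper Numeric vectors of equal length; `lower < upper`
#'   in every dimension.
#' @param integer Logical vector flagging dimensions that are integers
#'   (proposals are rounded before evaluation); default all continuous.
#' @return A `search_space` object.
#' @export
search_space <- function(lower, upper, integer = rep(FALSE, length(lower))) {
  if (length(lower) != length(upper) || length(integer) != length(lower)) {
    stop("lower, upper and integer must have equal length", call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("every dimension needs lower < upper", call. = FALSE)
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 integer = as.logical(integer), n = length(lower)),
            class = "search_space")
}

#' SP-UCI optimizer configuration
#'
#' @param m Number of complexes (>= 1).
#' @param p Points per complex; default `max(m + 1, 2n + 1)` resolved at
#'   optimization time (both the printed constraint `p >= m + 1` and the
#'   shuffled-complex-evolution convention `p >= n + 1` are enforced).
#' @param maxn Evaluation budget (default 10000).
#' @param tol Relative improvement per shuffling cycle counted as
#'   progress; default 1e-4 (0.01%).
#' @param patience Consecutive cycles without progress before stopping
#'   (default 20).
#' @param mcce_steps Simplex evolution steps per complex per cycle;
#'   default `2p - 1`.
#' @param seed Optional integer seed; fixing it makes the run
#'   bit-reproducible.
#' @return A `spuci_config` object.
#' @export
spuci_config <- function(m = 3L, p = NULL, maxn = 10000L, tol = 1e-4,
                         patience = 20L, mcce_steps = NULL, seed = NULL) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  structure(list(m = as.integer(m), p = p, maxn = as.integer(maxn),
                 tol = tol, patience = as.integer(patience),
                 mcce_steps = mcce_steps, seed = seed),
            class = "spuci_config")
}

# clip a point into bounds and round integer dimensions
clip_to_space <- function(x, space) {
  x <- pmin(pmax(x, space$lower), space$upper)
  if (any(space$integer)) {
    x[space$integer] <- round(x[space$integer])
  }
  x
}

# evaluation wrapper: counts calls, maps non-finite results to +Inf
make_counted_objective <- function(objective) {
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  f <- function(x) {
    env$count <- env$count + 1L
    val <- tryCatch(objective(x), error = function(e) Inf)
    if (!is.finite(val)) Inf else val
  }
  list(f = f, env = env)
}

#' Draw and evaluate the initial population
#'
#' Samples `m * p` points uniformly within the bounds and evaluates the
#' objective at each. Points where the objective is non-finite are kept
#' with value `+Inf`.
#'
#' @param objective Function of a numeric vector returning a scalar.
#' @param space A [search_space()].
#' @param m,p Complex count and points per complex.
#' @return List with `points` (matrix, one row per point) and `values`.
#' @export
initialize_population <- function(objective, space, m, p) {
  n_pts <- m * p
  pts <- matrix(stats::runif(n_pts * space$n,
                             rep(space$lower, each = n_pts),
                             rep(space$upper, each = n_pts)),
                nrow = n_pts)
  if (any(space$integer)) {
    pts[, space$integer] <- round(pts[, space$integer])
  }
  vals <- apply(pts, 1, objective)
  vals[!is.finite(vals)] <- Inf
  list(points = pts, values = vals)
}

#' Shuffle a population into sorted complexes
#'
#' Randomly partitions the population into `m` complexes of equal size
#' and sorts each complex ascending by objective value (ties broken by
#' original position, i.e. a stable sort).
#'
#' @param population List with `points` and `values`.
#' @param m Number of complexes.
#' @return List of `m` complexes, each a list with `points`, `values`.
#' @export
shuffle_into_complexes <- function(population, m) {
  n_pts <- nrow(population$points)
  if (n_pts %% m != 0) stop("population size not divisible by m",
                            call. = FALSE)
  perm <- sample.int(n_pts)
  groups <- split(perm, rep(seq_len(m), each = n_pts %/% m))
  lapply(groups, function(ii) {
    ord <- ii[order(population$values[ii])]
    list(points = population$points[ord, , drop = FALSE],
         values = population$values[ord])
  })
}

#' Detect and restore lost dimensions in a complex
#'
#' Principal component analysis of the complex's point cloud; any
#' principal direction carrying less than `threshold` of the total
#' variance is declared lost (the population has collapsed onto a
#' lower-dimensional subspace, the failure mode shuffled-complex search
#' suffers in high dimension). Lost directions are restored by adding
#' uniform jitter of 1% of the bound width along that direction to the
#' worst half of the complex; perturbed points are clipped to bounds and
#' re-evaluated.
#'
#' @param complex List with `points`, `values` (sorted ascending).
#' @param space A [search_space()].
#' @param objective Evaluation function.
#' @param threshold Variance fraction below which a direction counts as
#'   lost (default 1e-6).
#' @return The (possibly perturbed) complex, re-sorted.
#' @export
restore_lost_dimensions <- function(complex, space, objective,
                                    threshold = 1e-6) {
  pts <- complex$points
  n_pts <- nrow(pts)
  if (n_pts < 2) return(complex)
  ctr <- scale(pts, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = 0)
  var_comp <- sv$d^2
  total <- sum(var_comp)
  n_dim <- ncol(pts)
  lost <- if (total <= 0) diag(n_dim) else {
    frac <- var_comp / total
    # svd returns min(n_pts-1, n_dim) meaningful directions at most;
    # directions absent from v entirely are lost too
    v_full <- sv$v
    lost_cols <- v_full[, frac < threshold, drop = FALSE]
    if (ncol(v_full) < n_dim) {
      # complete the basis: missing directions are orthogonal complement
      qq <- qr(cbind(v_full, diag(n_dim)))
      basis <- qr.Q(qq)[, seq_len(n_dim), drop = FALSE]
      extra <- basis[, seq(ncol(v_full) + 1L, n_dim), drop = FALSE]
      lost_cols <- cbind(lost_cols, extra)
    }
    lost_cols
  }
  if (is.null(dim(lost))) lost <- matrix(lost, ncol = 1)
  if (ncol(lost) == 0) return(complex)

  width <- space$upper - space$lower
  worst <- seq.int(from = n_pts - floor(n_pts / 2) + 1L, to = n_pts)
  for (j in seq_len(ncol(lost))) {
    v <- lost[, j]
    for (i in worst) {
      eps <- stats::runif(1, -1, 1)
      pts[i, ] <- clip_to_space(pts[i, ] + eps * 0.01 * v * width, space)
    }
  }
  vals <- complex$values
  vals[worst] <- apply(pts[worst, , drop = FALSE], 1, objective)
  ord <- order(vals)
  list(points = pts[ord, , drop = FALSE], values = vals[ord])
}

#' Evolve one complex by the modified competitive complex evolution
#'
#' Per step: a sub-simplex of `n + 1` points is drawn from the complex
#' with triangular (fitness-rank) weights; the worst vertex is reflected
#' through the centroid of the others (coefficient 1); if the reflection
#' does not improve it, a half-way contraction toward the centroid is
#' tried; if that also fails, the vertex is replaced by a uniform redraw
#' within the complex's bounding box (mutation, accepted
#' unconditionally). Out-of-bounds proposals are clipped.
#'
#' @param complex List with `points`, `values` (sorted ascending).
#' @param space A [search_space()].
#' @param objective Evaluation function.
#' @param n_steps Number of evolution steps (default `2p - 1`).
#' @param mutate If `FALSE` the mutation fallback is disabled (the
#'   failed vertex is kept), reducing the move set to simplex descent.
#' @return List with the evolved `complex` and a logical `improved`
#'   (whether the complex best value decreased).
#' @export
evolve_complex_mcce <- function(complex, space, objective,
                                n_steps = NULL, mutate = TRUE) {
  pts <- complex$points
  vals <- complex$values
  p <- nrow(pts)
  n <- ncol(pts)
  if (is.null(n_steps)) n_steps <- 2L * p - 1L
  q <- min(p, n + 1L)
  best_before <- vals[1]
  tri_w <- rev(seq_len(p))  # triangular weights on rank

  for (step in seq_len(n_steps)) {
    sel <- if (q == p) seq_len(p) else sort(sample.int(p, q, prob = tri_w))
    sub_ord <- sel[order(vals[sel])]
    worst <- sub_ord[q]
    others <- sub_ord[-q]
    centroid <- colMeans(pts[others, , drop = FALSE])
    w_pt <- pts[worst, ]
    w_val <- vals[worst]

    refl <- clip_to_space(centroid + (centroid - w_pt), space)
    f_refl <- objective(refl)
    if (f_refl < w_val) {
      pts[worst, ] <- refl; vals[worst] <- f_refl
    } else {
      contr <- clip_to_space((centroid + w_pt) / 2, space)
      f_contr <- objective(contr)
      if (f_contr < w_val) {
        pts[worst, ] <- contr; vals[worst] <- f_contr
      } else if (mutate) {
        box_lo <- apply(pts, 2, min)
        box_hi <- apply(pts, 2, max)
        degenerate <- box_hi <= box_lo
        box_lo[degenerate] <- space$lower[degenerate]
        box_hi[degenerate] <- space$upper[degenerate]
        mut <- clip_to_space(stats::runif(n, box_lo, box_hi), space)
        pts[worst, ] <- mut
        vals[worst] <- objective(mut)
      }
    }
    ord <- order(vals)
    pts <- pts[ord, , drop = FALSE]
    vals <- vals[ord]
  }
  list(complex = list(points = pts, values = vals),
       improved = vals[1] < best_before)
}

#' Polynomial (multinormal) resampling of a complex
#'
#' Draws one point from the multivariate normal defined by the
#' complex's sample mean and covariance (diagonal regularized by
#' 1e-10), clips it to bounds, evaluates it, and substitutes it for the
#' worst point if it is better. Used when a shuffling cycle fails to
#' produce a better point by simplex evolution alone.
#'
#' @param complex List with `points`, `values` (sorted ascending).
#' @param space A [search_space()].
#' @param objective Evaluation function.
#' @return The (possibly updated) complex, re-sorted.
#' @export
resample_multinormal <- function(complex, space, objective) {
  pts <- complex$points
  n <- ncol(pts)
  mu <- colMeans(pts)
  S <- stats::cov(pts)
  if (anyNA(S)) S <- matrix(0, n, n)
  S <- S + diag(1e-10, n)
  L <- tryCatch(chol(S), error = function(e) chol(diag(diag(S), n)))
  draw <- clip_to_space(mu + drop(stats::rnorm(n) %*% L), space)
  f_draw <- objective(draw)
  p <- nrow(pts)
  if (f_draw < complex$values[p]) {
    pts[p, ] <- draw
    vals <- complex$values
    vals[p] <- f_draw
    ord <- order(vals)
    return(list(points = pts[ord, , drop = FALSE], values = vals[ord]))
  }
  complex
}

#' SP-UCI global minimization
#'
#' Shuffled complex evolution with PCA-based dimension restoration and
#' multinormal resampling. The population is repeatedly shuffled into
#' complexes, each complex checked for dimensional collapse and evolved
#' by the MCCE simplex moves, with a multinormal resample as a fallback
#' when a complex makes no progress. Iteration stops when the best
#' objective value fails to improve by more than `tol` (relative) for
#' `patience` consecutive cycles, or when the evaluation budget `maxn`
#' is spent.
#'
#' @param objective Deterministic function of a numeric vector.
#' @param space A [search_space()].
#' @param config A [spuci_config()].
#' @return An `optimization_result`: list with `par`, `value`,
#'   `evaluations`, `convergence` (`"tolerance"` or `"budget"`), and
#'   `history` (best value per cycle).
#' @examples
#' sp <- search_space(rep(-5, 2), rep(5, 2))
#' res <- spuci_optimize(function(x) sum(x^2), sp,
#'                       spuci_config(seed = 1, maxn = 2000))
#' res$value
#' @export
spuci_optimize <- function(objective, space, config = spuci_config()) {
  n <- space$n
  m <- config$m
  p <- if (is.null(config$p)) max(m + 1L, 2L * n + 1L) else {
    if (config$p < max(m + 1L, n + 1L)) {
      stop("p must be at least max(m + 1, n + 1)", call. = FALSE)
    }
    as.integer(config$p)
  }
  if (config$maxn <= m * p) stop("maxn must exceed m * p", call. = FALSE)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  co <- make_counted_objective(objective)
  f <- co$f
  pop <- initialize_population(f, space, m, p)
  if (all(!is.finite(pop$values))) {
    stop("objective not finite anywhere in the initial population",
         call. = FALSE)
  }
  ib <- which.min(pop$values)
  best_par <- pop$points[ib, ]
  best_val <- pop$values[ib]
  history <- numeric(0)
  stall <- 0L
  convergence <- "budget"

  repeat {
    complexes <- shuffle_into_complexes(pop, m)
    for (k in seq_along(complexes)) {
      cx <- restore_lost_dimensions(complexes[[k]], space, f)
      ev <- evolve_complex_mcce(cx, space, f, n_steps = config$mcce_steps)
      cx <- ev$complex
      if (!ev$improved) cx <- resample_multinormal(cx, space, f)
      complexes[[k]] <- cx
    }
    pop <- list(
      points = do.call(rbind, lapply(complexes, `[[`, "points")),
      values = unlist(lapply(complexes, `[[`, "values"), use.names = FALSE)
    )
    prev_best <- best_val
    ib <- which.min(pop$values)
    if (pop$values[ib] < best_val) {
      best_val <- pop$values[ib]
      best_par <- pop$points[ib, ]
    }
    history <- c(history, best_val)

    rel_impr <- (prev_best - best_val) / max(abs(prev_best), 1e-12)
    stall <- if (rel_impr < config$tol) stall + 1L else 0L
    if (stall >= config$patience) {
      convergence <- "tolerance"
      break
    }
    if (co$env$count >= config$maxn) {
      convergence <- "budget"
      break
    }
  }

  structure(list(par = best_par, value = best_val,
                 evaluations = co$env$count, convergence = convergence,
                 history = history),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("SP-UCI result: f = %.6g after %d evaluations (%s)\n",
              x$value, x$evaluations, x$convergence))
  cat("  par:", paste(signif(x$par, 6), collapse = ", "), "\n")
  invisible(x)
}
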