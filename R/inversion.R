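#' Construct an inversion model object
#'
#' @param index Vegetation index name (e.g. `"osavi"`).
#' @param form `"linear"` (y = a x + b), `"power"` (y = a x^b) or
#'   `"exponential"` (y = a exp(b x)).
#' @param a,b Model coefficients.
#' @param diagnostics Optional named list of fit diagnostics
#'   (`r_squared`, `rmse`, `nrmse_pct`).
#' @return An object of class `inversion_model`.
#' @export
new_inversion_model <- function(index, form, a, b, diagnostics = NULL) {
  form <- match.arg(form, c("linear", "power", "exponential"))
  structure(list(index = index, form = form, a = a, b = b,
                 diagnostics = diagnostics),
            class = "inversion_model")
}

#' @export
print.inversion_model <- function(x, ...) {
  eqn <- switch(x$form,
                linear = sprintf("y = %.4g x + %.4g", x$a, x$b),
                power = sprintf("y = %.4g x^%.4g", x$a, x$b),
                exponential = sprintf("y = %.4g e^(%.4g x)", x$a, x$b))
  cat(sprintf("LAI inversion model [%s, %s]: %s\n", x$index, x$form, eqn))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  R2=%.3f RMSE=%.3f nRMSE=%.1f%%\n",
                x$diagnostics$r_squared, x$diagnostics$rmse,
                x$diagnostics$nrmse_pct))
  }
  invisible(x)
}

#' Fit a univariate LAI inversion model
#'
#' Least-squares fit of one of the three empirical forms relating a
#' vegetation index `x` to measured LAI `y`. The nonlinear forms (power,
#' exponential) are initialized from the closed-form log-linear
#' regression and then refined by direct nonlinear least squares on the
#' original scale, so the minimized loss matches the RMSE diagnostics.
#'
#' @param x Vegetation index values (power form requires all `x > 0`).
#' @param y Measured LAI (power/exponential forms require all `y > 0`).
#' @param form `"linear"`, `"power"` or `"exponential"`.
#' @param index Index name stored in the model object.
#' @return An `inversion_model` with in-sample diagnostics.
#' @examples
#' x <- seq(0.1, 0.7, length.out = 20)
#' m <- fit_univariate_inversion(x, 0.21 * exp(4.68 * x), "exponential")
#' c(m$a, m$b)
#' @export
fit_univariate_inversion <- function(x, y,
                                     form = c("linear", "power",
                                              "exponential"),
                                     index = "custom") {
  form <- match.arg(form)
  check_paired(x, y, min_n = 3L)
  if (stats::var(x) == 0) {
    stop("cannot fit inversion model: constant predictor", call. = FALSE)
  }
  if (form == "linear") {
    fit <- stats::lm(y ~ x)
    a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  } else {
    if (any(y <= 0)) {
      stop(sprintf("%s form requires positive responses", form),
           call. = FALSE)
    }
    if (form == "power" && any(x <= 0)) {
      stop("power form requires positive predictors", call. = FALSE)
    }
    logfit <- if (form == "power") stats::lm(log(y) ~ log(x))
              else stats::lm(log(y) ~ x)
    a0 <- exp(unname(stats::coef(logfit)[1]))
    b0 <- unname(stats::coef(logfit)[2])
    fml <- if (form == "power") y ~ a * x^b else y ~ a * exp(b * x)
    # scaleOffset keeps the relative-offset criterion meaningful on
    # zero-residual (noise-free) data
    nls_fit <- tryCatch(
      suppressWarnings(
        stats::nls(fml, data = data.frame(x = x, y = y),
                   start = list(a = a0, b = b0),
                   control = stats::nls.control(maxiter = 200,
                                                tol = 1e-10,
                                                minFactor = 1e-12,
                                                scaleOffset = 1,
                                                warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(nls_fit)) {
      a <- a0; b <- b0
    } else {
      cf <- stats::coef(nls_fit)
      a <- unname(cf["a"]); b <- unname(cf["b"])
    }
  }
  model <- new_inversion_model(index = index, form = form, a = a, b = b)
  fitted_y <- evaluate_inversion_form(model, x)
  model$diagnostics <- list(
    r_squared = tryCatch(r_squared(y, fitted_y),
                         error = function(e) NA_real_),
    rmse = rmse(y, fitted_y),
    nrmse_pct = if (mean(fitted_y) != 0) nrmse(y, fitted_y) else NA_real_
  )
  model
}

evaluate_inversion_form <- function(model, x) {
  switch(model$form,
         linear = model$a * x + model$b,
         power = model$a * x^model$b,
         exponential = model$a * exp(model$b * x))
}

#' Predict LAI from a fitted inversion model
#'
#' Evaluates the model at new index values (or, for PLSR models, at a
#' matrix/data frame of the six indices). Negative predictions are
#' floored at 0.
#'
#' @param model An `inversion_model` or `plsr_model`.
#' @param x Index values (univariate) or index matrix (PLSR).
#' @return Predicted LAI (m2 m-2, >= 0).
#' @export
predict_lai <- function(model, x) {
  pred <- if (inherits(model, "plsr_model")) {
    predict_plsr(model, x)
  } else if (inherits(model, "inversion_model")) {
    evaluate_inversion_form(model, x)
  } else {
    stop("not a fitted inversion model", call. = FALSE)
  }
  pmax(pred, 0)
}

#' Partial least squares regression (PLS1, NIPALS)
#'
#' Fits a single-response PLS regression by NIPALS deflation: predictors
#' are centered and scaled to unit variance, latent components are
#' extracted one at a time as covariance-maximizing linear combinations,
#' and the final model is re-expressed as a linear predictor in the
#' original units. With the full number of components the predictions
#' coincide with ordinary least squares.
#'
#' @param X Numeric matrix or data frame of predictors (the six
#'   vegetation indices, typically).
#' @param y Response (measured LAI).
#' @param ncomp Number of latent components, `1 <= ncomp <=`
#'   `min(ncol(X), rank)`.
#' @return A `plsr_model` with `coefficients` (original scale),
#'   `intercept`, the centering/scaling constants, and the latent-space
#'   weights/loadings.
#' @export
fit_plsr <- function(X, y, ncomp = 2L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree", call. = FALSE)
  if (ncomp < 1 || ncomp > p) {
    stop("ncomp must lie in [1, ncol(X)]", call. = FALSE)
  }
  if (n <= ncomp) stop("need more samples than components", call. = FALSE)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  if (any(x_sd == 0)) stop("constant predictor column", call. = FALSE)
  y_mean <- mean(y)
  E <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  f <- y - y_mean

  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) {
      # residual covariance exhausted; truncate
      W <- W[, seq_len(h - 1L), drop = FALSE]
      P <- P[, seq_len(h - 1L), drop = FALSE]
      q <- q[seq_len(h - 1L)]
      ncomp <- h - 1L
      break
    }
    w <- w / wn
    t_h <- drop(E %*% w)
    tt <- sum(t_h^2)
    p_h <- drop(crossprod(E, t_h)) / tt
    q_h <- sum(f * t_h) / tt
    E <- E - tcrossprod(t_h, p_h)
    f <- f - q_h * t_h
    W[, h] <- w; P[, h] <- p_h; q[h] <- q_h
  }
  if (ncomp == 0) stop("no informative components extractable", call. = FALSE)
  # beta on the scaled predictors: W (P'W)^-1 q
  beta_scaled <- drop(W %*% solve(crossprod(P, W), q))
  coef_orig <- beta_scaled / x_sd
  intercept <- y_mean - sum(coef_orig * x_mean)
  structure(list(ncomp = ncomp, coefficients = coef_orig,
                 intercept = intercept, x_mean = x_mean, x_sd = x_sd,
                 y_mean = y_mean, weights = W, loadings = P, q = q,
                 var_names = colnames(X)),
            class = "plsr_model")
}

predict_plsr <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$var_names) && !is.null(colnames(X))) {
    X <- X[, model$var_names, drop = FALSE]
  }
  drop(X %*% model$coefficients) + model$intercept
}

#' Split-sample fitting and evaluation of inversion models
#'
#' Randomly assigns two thirds of the samples (stratified by acquisition
#' date, since dates differ strongly in LAI range) to a modeling subset
#' and the rest to validation, fits the published functional form for
#' each of the six indices on the modeling subset, and reports R2, RMSE
#' and nRMSE on both subsets. Models are ranked by validation R2,
#' ties broken by lower validation RMSE.
#'
#' @param indices Data frame of the six index columns (as produced by
#'   [compute_vegetation_indices()]).
#' @param lai Measured LAI, one value per row of `indices`.
#' @param date Acquisition date/day label per row (stratification key).
#' @param split_fraction Fraction assigned to the modeling subset.
#' @param seed Integer seed making the split reproducible.
#' @return List with `models` (named list of `inversion_model`s),
#'   `table` (one row per index: diagnostics on both subsets and rank),
#'   and the `modeling`/`validation` row indices.
#' @export
split_and_evaluate <- function(indices, lai, date = rep(1L, length(lai)),
                               split_fraction = 2 / 3, seed = 1L) {
  n <- nrow(indices)
  if (n != length(lai)) stop("indices and lai lengths disagree",
                             call. = FALSE)
  if (n < 6) stop("need at least 6 samples to split and fit", call. = FALSE)
  idx_model <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    unlist(lapply(split(seq_len(n), date), function(ii) {
      k <- max(1L, round(length(ii) * split_fraction))
      sort(sample(ii, k))
    }), use.names = FALSE)
  })
  idx_model <- sort(idx_model)
  idx_valid <- setdiff(seq_len(n), idx_model)
  if (length(idx_valid) < 2) stop("validation subset too small",
                                  call. = FALSE)
  forms <- inversion_form_table()
  idx_names <- intersect(names(forms), names(indices))
  models <- list()
  rows <- list()
  for (nm in idx_names) {
    x <- indices[[nm]]
    m <- fit_univariate_inversion(x[idx_model], lai[idx_model],
                                  form = forms[[nm]], index = nm)
    pred_v <- predict_lai(m, x[idx_valid])
    models[[nm]] <- m
    rows[[nm]] <- data.frame(
      index = nm, form = forms[[nm]], a = m$a, b = m$b,
      r2_model = m$diagnostics$r_squared,
      rmse_model = m$diagnostics$rmse,
      nrmse_model = m$diagnostics$nrmse_pct,
      r2_valid = r_squared(lai[idx_valid], pred_v),
      rmse_valid = rmse(lai[idx_valid], pred_v),
      nrmse_valid = nrmse(lai[idx_valid], pred_v),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$r2_valid, tab$rmse_valid)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(models = models, table = tab,
       modeling = idx_model, validation = idx_valid)
}

#' Serialize an inversion model to JSON
#'
#' @param model An `inversion_model`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_inversion_model <- function(model, path) {
  jsonlite::write_json(
    list(index = model$index, form = model$form,
         a = model$a, b = model$b, diagnostics = model$diagnostics),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an inversion model from JSON
#'
#' @param path File written by [write_inversion_model()].
#' @return An `inversion_model`.
#' @export
read_inversion_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_inversion_model(x$index, x$form, x$a, x$b,
                      diagnostics = as.list(x$diagnostics))
}

# save/restore the global RNG state so seeded helpers do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
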