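#' A daily time series for one location
#'
#' @param region_id character scalar.
#' @param dates `Date` vector, strictly increasing, daily (no gaps).
#' @param deaths non-negative integer counts.
#' @param temperature exposure in degrees C (missing allowed).
#' @param latitude optional region-level meta-variable (decimal degrees).
#' @return object of class `"region_series"`.
#' @export
region_series <- function(region_id, dates, deaths, temperature, latitude = NA_real_) {
  dates <- as.Date(dates)
  n <- length(dates)
  if (n < 2L) stop("a region series needs at least 2 days", call. = FALSE)
  if (any(diff(as.integer(dates)) != 1L))
    stop("dates must be strictly increasing and daily for region ", region_id,
         call. = FALSE)
  if (length(deaths) != n || length(temperature) != n)
    stop("deaths and temperature must match the dates in length for region ",
         region_id, call. = FALSE)
  if (any(deaths < 0 | deaths != round(deaths), na.rm = TRUE))
    stop("deaths must be non-negative integers for region ", region_id, call. = FALSE)
  structure(list(region_id = as.character(region_id), dates = dates,
                 deaths = as.integer(deaths), temperature = as.numeric(temperature),
                 latitude = as.numeric(latitude)),
            class = "region_series")
}

#' @export
print.region_series <- function(x, ...) {
  cat(sprintf("<region_series> %s: %d days (%s to %s), mean deaths %.1f\n",
              x$region_id, length(x$dates), min(x$dates), max(x$dates),
              mean(x$deaths, na.rm = TRUE)))
  invisible(x)
}

#' First-stage model configuration
#'
#' Defaults reproduce the standard temperature-mortality specification: a
#' quadratic B-spline for temperature (2 internal knots at equally spaced
#' values, boundary at the observed range) centered at 17 degrees C, a
#' natural cubic B-spline with intercept for lags 0..21 (3 internal knots at
#' equally spaced log-lag values), a natural cubic spline of time with
#' 10 df/year and day-of-week indicators as confounders.
#'
#' @param var_degree degree of the predictor-space B-spline.
#' @param var_nknots number of internal predictor knots (used when
#'   `var_knots` is NULL).
#' @param var_knots,boundary explicit predictor knots/boundary; when NULL they
#'   are placed from the (pooled) exposure distribution.
#' @param L maximum lag in days.
#' @param lag_nknots number of internal log-spaced lag knots (used when
#'   `lag_knots` is NULL).
#' @param lag_knots explicit lag knots.
#' @param lag_intercept keep the lag-basis intercept.
#' @param cen reference exposure (degrees C) at which RR = 1.
#' @param df_per_year df of the natural cubic time spline per 365.25 days
#'   (0 = no time spline).
#' @param dow include day-of-week indicators (Monday baseline).
#' @param x0 exposure values for predictor-specific summaries; NULL = pooled
#'   1st and 99th percentiles.
#' @param meta_vars character vector of region-level meta-variables for
#'   meta-regression (currently `"latitude"`), or NULL for simple pooling.
#' @param method second-stage estimator: `"reml"`, `"ml"` or `"fixed"`.
#' @param grid_step exposure prediction-grid step (degrees C).
#' @return a list of class `"two_stage_config"`.
#' @export
two_stage_config <- function(var_degree = 2L, var_nknots = 2L, var_knots = NULL,
                             boundary = NULL, L = 21L, lag_nknots = 3L,
                             lag_knots = NULL, lag_intercept = TRUE, cen = 17,
                             df_per_year = 10, dow = TRUE, x0 = NULL,
                             meta_vars = NULL, method = "reml",
                             grid_step = 0.1) {
  structure(as.list(environment()), class = "two_stage_config")
}

## Locale-independent day of week, Monday = 0 (1970-01-05 was a Monday).
day_of_week <- function(dates) {
  factor((as.integer(as.Date(dates)) + 3L) %% 7L, levels = 0:6,
         labels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
}

#' Fit the first-stage quasi-Poisson regression for one location
#'
#' Regresses daily counts on the cross-basis of the exposure plus the
#' configured confounders (natural cubic spline of time with
#' `df_per_year * years` df, knots at equally spaced quantiles of the time
#' index, and day-of-week indicators) with a log link and quasi-Poisson
#' variance. Rows with incomplete exposure history (the first L days, and
#' any window touching a missing exposure) are dropped (complete case).
#'
#' Only the cross-basis block of the fit is retained: the coefficient vector
#' `eta` of length `v_x * v_l` and its dispersion-scaled covariance.
#'
#' @param series a [region_series()].
#' @param var_spec,lag_spec cross-basis [basis_spec()]s; when NULL they are
#'   built from `config` and this region's exposure range (a multi-region
#'   analysis must pass common specs, see [run_two_stage()]).
#' @param config a [two_stage_config()].
#' @return object of class `"first_stage_fit"`: list with `eta`, `vcov`,
#'   `dispersion`, `n_used`, `var_spec`, `lag_spec`, `L`, `region_id`.
#' @export
fit_first_stage <- function(series, var_spec = NULL, lag_spec = NULL,
                            config = two_stage_config()) {
  stopifnot(inherits(series, "region_series"))
  if (all(is.na(series$temperature)))
    stop("all exposure values missing in region ", series$region_id, call. = FALSE)
  if (is.null(var_spec) || is.null(lag_spec)) {
    specs <- crossbasis_specs_from_config(series$temperature, config)
    if (is.null(var_spec)) var_spec <- specs$var_spec
    if (is.null(lag_spec)) lag_spec <- specs$lag_spec
  }
  cb <- build_crossbasis(series$temperature, var_spec, lag_spec, config$L)
  n <- length(series$deaths)
  dat <- data.frame(deaths = series$deaths)
  terms <- "cb"
  env <- environment()
  if (config$df_per_year > 0) {
    dft <- max(1L, round(config$df_per_year * n / 365.25))
    tspline <- splines::ns(seq_len(n), df = dft)
    terms <- c(terms, "tspline")
  }
  if (isTRUE(config$dow)) {
    dow <- day_of_week(series$dates)
    terms <- c(terms, "dow")
  }
  fml <- stats::as.formula(paste("deaths ~", paste(terms, collapse = " + ")),
                           env = env)
  fit <- tryCatch(
    stats::glm(fml, family = stats::quasipoisson(), data = dat,
               na.action = stats::na.omit),
    error = function(e) stop("first-stage model failed in region ",
                             series$region_id, ": ", conditionMessage(e),
                             call. = FALSE))
  if (!fit$converged)
    stop("first-stage IRLS did not converge in region ", series$region_id,
         call. = FALSE)
  idx <- grep("^cb", names(stats::coef(fit)))
  eta <- stats::coef(fit)[idx]
  if (anyNA(eta))
    stop("rank-deficient cross-basis in region ", series$region_id, call. = FALSE)
  sm <- summary(fit)
  v <- sm$cov.scaled[idx, idx, drop = FALSE]
  structure(list(eta = unname(eta), vcov = unname((v + t(v)) / 2),
                 dispersion = sm$dispersion, n_used = stats::nobs(fit),
                 var_spec = var_spec, lag_spec = lag_spec,
                 L = as.integer(config$L), region_id = series$region_id),
            class = "first_stage_fit")
}

#' @export
print.first_stage_fit <- function(x, ...) {
  cat(sprintf("<first_stage_fit> %s: %d cross-basis coefficients, n = %d, dispersion = %.3f\n",
              x$region_id, length(x$eta), x$n_used, x$dispersion))
  invisible(x)
}

## Common cross-basis specs from an exposure vector and a config.
crossbasis_specs_from_config <- function(x, config) {
  boundary <- config$boundary
  if (is.null(boundary)) boundary <- range(x, na.rm = TRUE)
  vk <- config$var_knots
  if (is.null(vk)) vk <- place_var_knots(x, config$var_nknots, "equal_values")
  lk <- config$lag_knots
  if (is.null(lk)) lk <- place_lag_knots(config$L, config$lag_nknots)
  list(var_spec = basis_spec("bspline", degree = config$var_degree, knots = vk,
                             boundary = boundary, intercept = FALSE,
                             center = config$cen),
       lag_spec = basis_spec("natural_cubic", knots = lk,
                             boundary = c(0, config$L),
                             intercept = config$lag_intercept))
}

#' Predict the full exposure-lag-response surface
#'
#' Evaluates the fitted bi-dimensional surface on a grid of exposure and lag
#' values, relative to the reference `cen`:
#' `matfit[x, l] = t(z(x) - z(cen)) H c(l)` with H the `v_x x v_l`
#' coefficient matrix, standard errors by the delta method, and the overall
#' cumulative curve `cumfit(x) = sum_l matfit[x, l]` (with its own delta-
#' method SE) summed over `grid_lag`. With `grid_lag = 0:L` (the default)
#' `cumfit` is exactly the overall cumulative summary.
#'
#' @param fit a [fit_first_stage()] result.
#' @param grid_x exposure grid; default: boundary range in 0.1 steps.
#' @param grid_lag lag grid; default `0:L`.
#' @param cen reference exposure; default the center of the predictor spec.
#' @return object of class `"crosspred"`: list with `grid_x`, `grid_lag`,
#'   `matfit`, `matse`, `cumfit`, `cumse`, `center`.
#' @export
crosspred <- function(fit, grid_x = NULL, grid_lag = NULL, cen = NULL) {
  stopifnot(inherits(fit, "first_stage_fit") || is.list(fit))
  vs <- fit$var_spec; ls_ <- fit$lag_spec
  if (is.null(cen)) cen <- vs$center
  if (is.null(cen)) stop("no reference value available; supply 'cen'", call. = FALSE)
  if (is.null(grid_x)) grid_x <- seq(vs$boundary[1], vs$boundary[2], by = 0.1)
  if (is.null(grid_lag)) grid_lag <- 0:fit$L
  vx <- basis_dim(vs); vl <- basis_dim(ls_)
  a <- sweep(unclass(make_basis(grid_x, vs)), 2L, drop(unclass(make_basis(cen, vs))))
  cp <- unclass(make_basis(grid_lag, ls_))
  h <- matrix(fit$eta, vx, vl)
  matfit <- a %*% h %*% t(cp)
  matse <- matrix(0, length(grid_x), length(grid_lag))
  for (l in seq_along(grid_lag)) {
    w <- matrix(0, length(grid_x), vx * vl)
    for (k in seq_len(vl)) w[, (k - 1L) * vx + seq_len(vx)] <- cp[l, k] * a
    matse[, l] <- sqrt(pmax(rowSums((w %*% fit$vcov) * w), 0))
  }
  csum <- colSums(cp)
  wc <- matrix(0, length(grid_x), vx * vl)
  for (k in seq_len(vl)) wc[, (k - 1L) * vx + seq_len(vx)] <- csum[k] * a
  cumfit <- drop(wc %*% fit$eta)
  cumse <- sqrt(pmax(rowSums((wc %*% fit$vcov) * wc), 0))
  structure(list(grid_x = grid_x, grid_lag = grid_lag, matfit = matfit,
                 matse = matse, cumfit = cumfit, cumse = cumse, center = cen),
            class = "crosspred")
}

#' Fit a moving-average comparison model
#'
#' The common simplification of the lag structure: a one-dimensional spline
#' of the exposure moving average over lags `0..window`. Implemented as a
#' cross-basis with a constant lag-space basis, so it slots into the same
#' reduction and pooling machinery; the overall cumulative reduction of this
#' model is `(window + 1) * I`, i.e. the original `v_x` coefficients
#' re-scaled by the number of lags.
#'
#' @param series a [region_series()].
#' @param window maximum lag of the moving average (e.g. 3 or 21).
#' @param var_spec predictor-space [basis_spec()] (NULL: from config).
#' @param config a [two_stage_config()]; its `L` is overridden by `window`.
#' @return a `first_stage_fit` with `v_l = 1`.
#' @export
fit_moving_average_model <- function(series, window, var_spec = NULL,
                                     config = two_stage_config()) {
  config$L <- as.integer(window)
  lag_spec <- basis_spec("constant")
  fit_first_stage(series, var_spec = var_spec, lag_spec = lag_spec, config = config)
}

#' Minimum-mortality temperature of a pooled overall curve
#'
#' Argmin of the pooled cumulative log-RR over a fine exposure grid spanning
#' the boundary knots; ties are broken toward the reference. A minimum on the
#' grid boundary (monotone curve) is returned with a warning.
#'
#' @param rf pooled overall `reduced_fit`.
#' @param step grid step in exposure units (default 0.1).
#' @param cen reference exposure (default: stored in `rf`).
#' @return the exposure value minimizing the cumulative log-RR.
#' @export
min_mortality_temperature <- function(rf, step = 0.1, cen = NULL) {
  stopifnot(inherits(rf, "reduced_fit"), rf$kind != "predictor_specific")
  if (is.null(cen)) cen <- rf$center
  b <- rf$spec$boundary
  if (is.null(b)) stop("the reduced fit's basis has no boundary knots", call. = FALSE)
  grid <- seq(b[1], b[2], by = step)
  fit <- predict_reduced(rf, grid, cen = cen)$fit
  best <- which(fit <= min(fit) + 1e-12)
  mmt <- grid[best[which.min(abs(grid[best] - cen))]]
  if (mmt %in% range(grid))
    warning("cumulative curve is monotone over the grid; boundary value returned")
  mmt
}

#' Run the full two-stage analysis
#'
#' First stage: per region, quasi-Poisson regression with a cross-basis
#' built on knots/boundary common to all regions (from the pooled exposure
#' distribution unless fixed in the config), then reduction to the overall
#' cumulative summary and to predictor-specific summaries at the configured
#' exposures. Second stage: one multivariate meta-analysis (or
#' meta-regression on `meta_vars`) per summary, with multivariate Cochran Q
#' and I-squared, pooled curves, cumulative RRs at the summary exposures and
#' the minimum-mortality temperature.
#'
#' @param dataset list of [region_series()] (>= 2 regions).
#' @param config a [two_stage_config()].
#' @return object of class `"two_stage_result"`: list with `config`,
#'   `var_spec`, `lag_spec`, `x0`, `first_stage` (per-region fits),
#'   `reduced` (per-summary lists of `reduced_fit`), `models` (per-summary
#'   `mvmeta_model`), `het` (per-summary heterogeneity stats), `pooled`
#'   (per-summary pooled `reduced_fit`), `curves` (per-summary prediction
#'   data frames), `cum_rr` (data.frame of cumulative RRs at `x0`), `mmt`.
#' @export
run_two_stage <- function(dataset, config = two_stage_config()) {
  if (length(dataset) < 2L) stop("need at least 2 regions", call. = FALSE)
  stopifnot(all(vapply(dataset, inherits, TRUE, "region_series")))
  pooled_x <- unlist(lapply(dataset, `[[`, "temperature"))
  specs <- crossbasis_specs_from_config(pooled_x, config)
  x0 <- config$x0
  if (is.null(x0))
    x0 <- unname(stats::quantile(pooled_x, c(0.01, 0.99), na.rm = TRUE))

  first_stage <- lapply(dataset, fit_first_stage, var_spec = specs$var_spec,
                        lag_spec = specs$lag_spec, config = config)
  names(first_stage) <- vapply(dataset, `[[`, "", "region_id")

  summaries <- c("overall", paste0("predictor_specific@", signif(x0, 6)))
  reduced <- list(overall = lapply(first_stage, reduce_fit, kind = "overall",
                                   cen = config$cen))
  for (j in seq_along(x0))
    reduced[[summaries[j + 1L]]] <-
      lapply(first_stage, reduce_fit, kind = "predictor_specific",
             at_value = x0[j], cen = config$cen)

  u <- NULL
  if (!is.null(config$meta_vars)) {
    mv <- sapply(config$meta_vars, function(v)
      vapply(dataset, function(s) as.numeric(s[[v]]), 0))
    if (anyNA(mv)) stop("missing meta-variable values", call. = FALSE)
    u <- cbind(1, mv)
  }

  models <- list(); het <- list(); pooled <- list(); curves <- list()
  mean_u <- if (is.null(u)) NULL else colMeans(u)
  for (s in summaries) {
    rfl <- reduced[[s]]
    inp <- mvmeta_input(lapply(rfl, `[[`, "theta"), lapply(rfl, `[[`, "vcov"), u)
    models[[s]] <- fit_mvmeta(inp, method = config$method)
    het[[s]] <- cochran_q(inp)
    pooled[[s]] <- pooled_reduced_fit(models[[s]], rfl[[1L]], u_new = mean_u)
    grid <- if (s == "overall")
      seq(specs$var_spec$boundary[1], specs$var_spec$boundary[2],
          by = config$grid_step)
    else 0:config$L
    curves[[s]] <- predict_reduced(pooled[[s]], grid,
                                   cen = if (s == "overall") config$cen else NULL)
  }

  cum <- predict_reduced(pooled$overall, x0, cen = config$cen)
  cum_rr <- data.frame(x0 = x0, rr = cum$rr, rr_low = cum$rr_low,
                       rr_high = cum$rr_high)
  mmt <- min_mortality_temperature(pooled$overall, step = config$grid_step,
                                   cen = config$cen)
  structure(list(config = config, var_spec = specs$var_spec,
                 lag_spec = specs$lag_spec, x0 = x0,
                 first_stage = first_stage, reduced = reduced, models = models,
                 het = het, pooled = pooled, curves = curves, cum_rr = cum_rr,
                 mmt = mmt),
            class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat(sprintf("<two_stage_result> %d regions, method = %s\n",
              length(x$first_stage), x$config$method))
  cat(sprintf("  reference: %.1f; minimum-mortality exposure: %.1f\n",
              x$config$cen, x$mmt))
  for (i in seq_len(nrow(x$cum_rr)))
    cat(sprintf("  cumulative RR at %5.1f vs %.1f: %.3f (95%%CI %.3f-%.3f)\n",
                x$cum_rr$x0[i], x$config$cen, x$cum_rr$rr[i],
                x$cum_rr$rr_low[i], x$cum_rr$rr_high[i]))
  for (s in names(x$het))
    cat(sprintf("  %s: Q = %.1f (df %d, p = %.3g), I2 = %.1f%%\n",
                s, x$het[[s]]$Q, x$het[[s]]$df, x$het[[s]]$p_value, x$het[[s]]$I2))
  invisible(x)
}
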