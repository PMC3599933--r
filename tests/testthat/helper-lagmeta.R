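# Shared fixtures: the reference cross-basis configuration (quadratic
# B-spline of temperature over (-4.4, 24.9), natural cubic lag spline with
# intercept over 0..21) and generators for random fits and small series.

main_var_spec <- function(center = 17)
  basis_spec("bspline", degree = 2, knots = c(5.3, 15.1),
             boundary = c(-4.4, 24.9), intercept = FALSE, center = center)

main_lag_spec <- function(L = 21)
  basis_spec("natural_cubic", knots = place_lag_knots(L, 3),
             boundary = c(0, L), intercept = TRUE)

# Assorted (var_spec, lag_spec, L) configurations for property-style loops.
assorted_configs <- function() {
  list(
    list(var = main_var_spec(), lag = main_lag_spec(), L = 21L),
    list(var = basis_spec("natural_cubic", knots = c(5, 15),
                          boundary = c(-5, 25), intercept = FALSE, center = 17),
         lag = basis_spec("bspline", degree = 2, knots = c(3, 10),
                          boundary = c(0, 21), intercept = TRUE), L = 21L),
    list(var = basis_spec("poly", degree = 3, center = 10),
         lag = basis_spec("constant"), L = 7L),
    list(var = basis_spec("linear", center = 0),
         lag = basis_spec("natural_cubic", knots = 2,
                          boundary = c(0, 5), intercept = TRUE), L = 5L),
    list(var = basis_spec("threshold", knots = c(5, 18), intercept = FALSE,
                          center = 10),
         lag = basis_spec("strata", knots = c(2, 7), intercept = TRUE), L = 10L))
}

# Random (eta, vcov) pair shaped like a first-stage fit for a configuration.
rand_fit <- function(cfg) {
  d <- basis_dim(cfg$var) * basis_dim(cfg$lag)
  a <- matrix(rnorm(d * (d + 5)), d)
  structure(list(eta = rnorm(d), vcov = crossprod(t(a)) / d,
                 var_spec = cfg$var, lag_spec = cfg$lag, L = cfg$L,
                 region_id = "synthetic"),
            class = "first_stage_fit")
}

# Independent univariate REML oracle: direct grid search over the
# between-study variance with the profiled restricted likelihood.
uni_reml_oracle <- function(y, s, upper = NULL) {
  m <- length(y)
  rl <- function(psi) {
    w <- 1 / (s + psi)
    b <- sum(w * y) / sum(w)
    -0.5 * (sum(log(s + psi)) + log(sum(w)) + sum(w * (y - b)^2)) -
      (m - 1) / 2 * log(2 * pi)
  }
  if (is.null(upper)) upper <- 10 * (var(y) + mean(s))
  g <- seq(0, upper, length.out = 4001)
  psi <- g[which.max(vapply(g, rl, 0))]
  for (it in 1:6) {  # refine around the current best
    g <- seq(max(0, psi - diff(range(g)) / 100), psi + diff(range(g)) / 100,
             length.out = 401)
    psi <- g[which.max(vapply(g, rl, 0))]
  }
  w <- 1 / (s + psi)
  list(psi = psi, beta = sum(w * y) / sum(w), loglik = rl(psi))
}
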