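# First-stage fits in this file shrink N below the reference 5113 days to
# keep the default test run fast; N is passed explicitly.

test_that("region series validation catches malformed inputs", {
  d <- as.Date("2000-01-01") + 0:9
  expect_error(region_series("a", d[c(1:5, 7:10)], rep(1, 9), rep(1, 9)), "daily")
  expect_error(region_series("a", d, rep(1, 9), rep(1, 10)), "length")
  expect_error(region_series("a", d, rep(-1, 10), rep(1, 10)), "non-negative")
})

test_that("the first stage recovers known cross-basis coefficients", {
  set.seed(31)
  sc <- sim_config(m = 1, N = 3000, psi_sd = 0, dispersion = 1,
                   seas_amp = 0, trend_slope = 0, base_count = 50, seed = 31)
  sim <- simulate_regions(sc)
  cfg <- two_stage_config(df_per_year = 0, dow = FALSE, cen = 17,
                          boundary = sc$var_spec$boundary)
  fit <- fit_first_stage(sim$regions[[1]], sc$var_spec, sc$lag_spec, cfg)
  expect_identical(length(fit$eta), 20L)
  expect_equal(dim(fit$vcov), c(20L, 20L))
  expect_gt(fit$dispersion, 0)
  # identifiable contrast: the overall cumulative curve, not raw coefficients
  rf <- reduce_fit(fit, "overall", cen = 17)
  gx <- seq(-2, 22, 2)
  pr <- predict_reduced(rf, gx, cen = 17)
  truth <- sim$truth$overall_curve(gx)
  expect_true(all(abs(pr$fit - truth) < 3.5 * pr$se))
})

test_that("dispersion scaling inflates standard errors, not the estimates' target", {
  set.seed(32)
  base <- sim_config(m = 1, N = 2500, psi_sd = 0, dispersion = 1,
                     base_count = 60, seed = 77)
  over <- base; over$dispersion <- 3
  cfg <- two_stage_config(df_per_year = 0, dow = FALSE,
                          boundary = base$var_spec$boundary)
  f1 <- fit_first_stage(simulate_regions(base)$regions[[1]],
                        base$var_spec, base$lag_spec, cfg)
  f2 <- fit_first_stage(simulate_regions(over)$regions[[1]],
                        over$var_spec, over$lag_spec, cfg)
  expect_lt(f1$dispersion, 1.3)
  expect_gt(f2$dispersion, 2)
  # same exposure realization (same seed): SEs scale with the dispersion
  expect_gt(median(sqrt(diag(f2$vcov)) / sqrt(diag(f1$vcov))), 1.2)
})

test_that("the fitted surface is flat at the reference and matches its reduction", {
  set.seed(33)
  sc <- sim_config(m = 1, N = 1500, psi_sd = 0, seed = 33)
  cfg <- two_stage_config(boundary = sc$var_spec$boundary)
  fit <- fit_first_stage(simulate_regions(sc)$regions[[1]],
                         sc$var_spec, sc$lag_spec, cfg)
  cp <- crosspred(fit, grid_x = c(0, 17, 22), cen = 17)
  expect_equal(cp$matfit[2, ], rep(0, 22))
  expect_equal(cp$matse[2, ], rep(0, 22))
  ov <- predict_reduced(reduce_fit(fit, "overall", cen = 17), c(0, 17, 22),
                        cen = 17)
  expect_equal(ov$fit, cp$cumfit, tolerance = 1e-10)
  expect_equal(ov$se, cp$cumse, tolerance = 1e-10)
})

test_that("two identical regions pool to themselves with zero heterogeneity", {
  set.seed(34)
  sc <- sim_config(m = 1, N = 1200, psi_sd = 0, seed = 34)
  sim <- simulate_regions(sc)
  r1 <- sim$regions[[1]]
  r2 <- r1; r2$region_id <- "copy"
  res <- run_two_stage(list(r1, r2),
                       two_stage_config(x0 = c(0, 22), method = "fixed",
                                        boundary = sc$var_spec$boundary))
  expect_equal(res$het$overall$Q, 0, tolerance = 1e-6)
  one <- predict_reduced(reduce_fit(res$first_stage[[1]], "overall", cen = 17),
                         res$curves$overall$grid, cen = 17)
  expect_equal(res$curves$overall$fit, one$fit, tolerance = 1e-8)
})

test_that("moving-average models are constant-lag cross-bases", {
  set.seed(35)
  sc <- sim_config(m = 1, N = 1200, psi_sd = 0, seed = 35)
  sim <- simulate_regions(sc)
  cfg <- two_stage_config(boundary = sc$var_spec$boundary)
  fit <- fit_moving_average_model(sim$regions[[1]], window = 3,
                                  var_spec = sc$var_spec, config = cfg)
  expect_identical(length(fit$eta), 4L)           # v_x * v_l = 4 x 1
  expect_identical(basis_dim(fit$lag_spec), 1L)
  rf <- reduce_fit(fit, "overall", cen = 17)
  # reduction = original coefficients re-scaled by the number of lags
  expect_equal(rf$theta, 4 * fit$eta, tolerance = 1e-12)
  expect_equal(rf$vcov, 16 * fit$vcov, tolerance = 1e-12)
})

test_that("minimum-mortality exposure finds a known symmetric minimum", {
  vs <- basis_spec("bspline", degree = 2, knots = c(10, 20), boundary = c(0, 30),
                   intercept = FALSE, center = 20)
  # theta from projecting a parabola with minimum at 20 onto the centered basis
  gx <- seq(0, 30, 0.25)
  a <- sweep(unclass(make_basis(gx, vs)), 2, drop(unclass(make_basis(20, vs))))
  theta <- qr.solve(a, 0.002 * (gx - 20)^2)
  rf <- structure(list(theta = theta, vcov = diag(4) * 1e-8, kind = "overall",
                       at_value = NULL, spec = vs, center = 20, L = 21L),
                  class = "reduced_fit")
  expect_lt(abs(min_mortality_temperature(rf, step = 0.1) - 20), 0.1 + 1e-9)
  # monotone curve: boundary value with a warning
  theta_up <- qr.solve(a, 0.01 * gx)
  rf$theta <- theta_up
  expect_warning(mmt <- min_mortality_temperature(rf, step = 0.1), "monotone")
  expect_equal(mmt, 0)
})

test_that("meta-regression on latitude runs end to end", {
  set.seed(36)
  sc <- sim_config(m = 6, N = 900, psi_sd = 0.003, lat_cold_effect = 0.05,
                   seed = 36)
  sim <- simulate_regions(sc)
  res <- run_two_stage(sim$regions,
                       two_stage_config(x0 = c(0, 22), meta_vars = "latitude",
                                        method = "reml",
                                        boundary = sc$var_spec$boundary))
  m <- res$models$overall
  expect_identical(m$input$p, 2L)
  w <- wald_test(m, meta_var_block(m, 2))
  expect_true(w$p >= 0 && w$p <= 1)
  expect_true(all(is.finite(res$curves$overall$fit)))
  expect_identical(res$het$overall$df, 6L * 4L - 4L * 2L)
})

test_that("first-stage errors carry the region name", {
  d <- as.Date("2000-01-01") + 0:99
  s <- region_series("brokenreg", d, rpois(100, 5), rep(NA_real_, 100))
  expect_error(fit_first_stage(s, config = two_stage_config(L = 10)),
               "brokenreg")
})
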