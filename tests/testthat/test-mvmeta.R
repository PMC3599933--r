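test_that("a single location under fixed effects returns its own estimate", {
  s1 <- matrix(c(2, 0.5, 0.5, 1), 2)
  inp <- mvmeta_input(list(c(1, -1)), list(s1))
  fit <- fit_mvmeta(inp, "fixed")
  expect_equal(fit$beta, c(1, -1))
  expect_equal(fit$vcov_beta, s1)
  expect_equal(fit$Psi, matrix(0, 2, 2))
})

test_that("fixed-effects GLS matches the closed-form weighted estimate", {
  set.seed(21)
  m <- 12
  s <- runif(m, 0.3, 2)
  y <- rnorm(m, 1.5, sqrt(s))
  fit <- fit_mvmeta(mvmeta_input(as.list(y), as.list(s)), "fixed")
  w <- 1 / s
  expect_equal(fit$beta, sum(w * y) / sum(w), tolerance = 1e-12)
  expect_equal(drop(fit$vcov_beta), 1 / sum(w), tolerance = 1e-12)
})

test_that("univariate REML matches an independent grid-search oracle", {
  set.seed(22)
  m <- 20
  s <- runif(m, 0.2, 0.8)
  y <- rnorm(m, 2, sqrt(s + 0.7))   # real heterogeneity: interior optimum
  inp <- mvmeta_input(as.list(y), as.list(s))
  fit <- fit_mvmeta(inp, "reml")
  orc <- uni_reml_oracle(y, s)
  expect_true(fit$converged)
  expect_equal(drop(fit$Psi), orc$psi, tolerance = 1e-6)
  expect_equal(fit$beta, orc$beta, tolerance = 1e-6)
  expect_equal(fit$loglik, orc$loglik, tolerance = 1e-8)
})

test_that("the REML log-likelihood matches a direct evaluation at the optimum", {
  set.seed(23)
  m <- 15; k <- 2
  psi_t <- matrix(c(0.3, 0.1, 0.1, 0.2), 2)
  s_list <- replicate(m, { a <- matrix(rnorm(4), 2); crossprod(a) / 3 + 0.2 * diag(2) },
                      simplify = FALSE)
  ch <- chol(psi_t)
  thetas <- lapply(seq_len(m), function(i)
    drop(c(1, -0.5) + t(ch) %*% rnorm(2) + t(chol(s_list[[i]])) %*% rnorm(2)))
  inp <- mvmeta_input(thetas, s_list)
  fit <- fit_mvmeta(inp, "reml")
  # independent evaluation of the restricted likelihood at (beta_hat, Psi_hat)
  sig <- lapply(s_list, function(s) s + fit$Psi)
  xtwx <- Reduce(`+`, lapply(sig, solve))
  quad <- sum(vapply(seq_len(m), function(i) {
    r <- thetas[[i]] - fit$beta
    drop(t(r) %*% solve(sig[[i]], r))
  }, 0))
  ll <- -0.5 * (sum(vapply(sig, function(s) determinant(s)$modulus[1], 0)) +
                  determinant(xtwx)$modulus[1] + quad) -
    (m * k - k) / 2 * log(2 * pi)
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  expect_equal(fit$vcov_beta, solve(xtwx), tolerance = 1e-8)
})

test_that("hand-computed two-study heterogeneity is reproduced exactly", {
  inp <- mvmeta_input(list(0, 2), list(1, 1))
  het <- cochran_q(inp)
  expect_equal(fit_mvmeta(inp, "fixed")$beta, 1)
  expect_equal(het$Q, 2)
  expect_equal(het$df, 1L)
  expect_equal(het$I2, 50)
  expect_equal(het$p_value, pchisq(2, 1, lower.tail = FALSE))
})

test_that("identical estimates show no heterogeneity", {
  inp <- mvmeta_input(replicate(5, c(0.5, 1), simplify = FALSE),
                      replicate(5, diag(2), simplify = FALSE))
  het <- cochran_q(inp)
  expect_equal(het$Q, 0, tolerance = 1e-12)
  expect_equal(het$I2, 0)
  expect_true(het$p_value >= 0 && het$p_value <= 1)
})

test_that("Wald tests behave on degenerate and scalar blocks", {
  set.seed(24)
  m <- 10
  thetas <- lapply(1:m, function(i) rnorm(2, c(0.8, 0)))
  s_list <- replicate(m, diag(2) * 0.5, simplify = FALSE)
  fit <- fit_mvmeta(mvmeta_input(thetas, s_list), "fixed")
  # scalar block: chi-square(1) equals the squared z-test
  w <- wald_test(fit, 1)
  z <- fit$beta[1] / sqrt(fit$vcov_beta[1, 1])
  expect_equal(w$stat, z^2, tolerance = 1e-12)
  expect_equal(w$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  # exactly zero block
  fit0 <- fit
  fit0$beta[2] <- 0
  w0 <- wald_test(fit0, 2)
  expect_equal(w0$stat, 0)
  expect_equal(w0$p, 1)
})

test_that("meta-regression pools linearly in the meta-variable", {
  set.seed(25)
  m <- 14
  u <- cbind(1, seq(-1, 1, length.out = m))
  thetas <- lapply(1:m, function(i) 1 + 0.5 * u[i, 2] + rnorm(1, 0, 0.3))
  inp <- mvmeta_input(thetas, as.list(rep(0.2, m)), u = u)
  fit <- fit_mvmeta(inp, "reml")
  p25 <- mvmeta_predict(fit, c(1, -0.5))
  p75 <- mvmeta_predict(fit, c(1, 0.5))
  pmid <- mvmeta_predict(fit, c(1, 0))
  expect_equal(pmid$theta, (p25$theta + p75$theta) / 2, tolerance = 1e-12)
  expect_equal(mvmeta_predict(fit, c(1, 0))$theta,
               fit$beta[1], tolerance = 1e-12)
  expect_identical(meta_var_block(fit, 2), 2L)
})

test_that("REML recovers known beta and Psi on synthetic vector outcomes", {
  # single-replicate sanity check; the full Monte-Carlo recovery is an
  # acceptance criterion
  set.seed(26)
  m <- 60; k <- 3
  beta_t <- c(1, -0.5, 0.25)
  psi_t <- diag(c(0.4, 0.2, 0.3)); psi_t[1, 2] <- psi_t[2, 1] <- 0.1
  chp <- chol(psi_t)
  s_list <- replicate(m, { a <- matrix(rnorm(9), 3); crossprod(a) / 6 + 0.1 * diag(3) },
                      simplify = FALSE)
  thetas <- lapply(seq_len(m), function(i)
    drop(beta_t + t(chp) %*% rnorm(3) + t(chol(s_list[[i]])) %*% rnorm(3)))
  fit <- fit_mvmeta(mvmeta_input(thetas, s_list), "reml")
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov_beta))
  expect_true(all(abs(fit$beta - beta_t) < 3 * se))
  expect_true(all(abs(diag(fit$Psi) - diag(psi_t)) < 0.25))
})

test_that("boundary heterogeneity truncates correlations but stays finite", {
  set.seed(27)
  m <- 6; k <- 2
  s_list <- replicate(m, diag(2), simplify = FALSE)
  thetas <- lapply(seq_len(m), function(i) rnorm(2, 0, 0.2))  # true Psi ~ 0
  fit <- fit_mvmeta(mvmeta_input(thetas, s_list), "reml")
  expect_true(all(is.finite(fit$beta)))
  expect_true(all(is.finite(fit$Psi)))
  d <- sqrt(diag(fit$Psi))
  if (all(d > 0)) {
    rho <- fit$Psi[1, 2] / prod(d)
    expect_true(abs(rho) <= 1 + 1e-8)
  }
})

test_that("malformed inputs are rejected with informative errors", {
  expect_error(mvmeta_input(list(1, c(1, 2)), list(1, diag(2))), "same length")
  expect_error(mvmeta_input(list(1, 2), list(1)), "one matrix per location")
  expect_error(mvmeta_input(list(c(1, 2)), list(matrix(c(1, 2, 0, 1), 2))),
               "symmetric")
  expect_error(mvmeta_input(list(1, 2), list(1, 1), u = matrix(2, 2, 1)),
               "intercept")
  bad <- mvmeta_input(list(c(1, 2), c(2, 1)),
                      list(matrix(0, 2, 2), diag(2)))
  expect_error(fit_mvmeta(bad, "fixed"), "location 1")
})
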