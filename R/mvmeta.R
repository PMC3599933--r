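#' Assemble inputs for multivariate meta-analysis
#'
#' @param thetas list of m numeric vectors (all length k), or an m x k matrix:
#'   the location-specific estimated coefficients.
#' @param S_list list of m k x k symmetric PSD within-location covariance
#'   matrices (for k = 1, scalars are accepted).
#' @param u m x p matrix of meta-variables with first column all ones, or NULL
#'   for an intercept-only (simple meta-analysis) design.
#' @return object of class `"mvmeta_input"`.
#' @export
mvmeta_input <- function(thetas, S_list, u = NULL) {
  if (is.matrix(thetas)) thetas <- lapply(seq_len(nrow(thetas)), function(i) thetas[i, ])
  m <- length(thetas)
  k <- length(thetas[[1]])
  if (!all(vapply(thetas, length, 1L) == k))
    stop("all coefficient vectors must have the same length", call. = FALSE)
  if (length(S_list) != m) stop("'S_list' must have one matrix per location", call. = FALSE)
  S_list <- lapply(S_list, function(s) {
    s <- as.matrix(s)
    if (!all(dim(s) == k)) stop("each S must be k x k", call. = FALSE)
    if (max(abs(s - t(s))) > 1e-8 * max(1, max(abs(s))))
      stop("each S must be symmetric", call. = FALSE)
    (s + t(s)) / 2
  })
  if (is.null(u)) u <- matrix(1, m, 1L)
  u <- as.matrix(u)
  if (nrow(u) != m) stop("'u' must have one row per location", call. = FALSE)
  if (any(u[, 1] != 1)) stop("first column of 'u' must be the intercept (all ones)", call. = FALSE)
  if (m < ncol(u)) stop("more meta-variables than locations", call. = FALSE)
  x_list <- lapply(seq_len(m), function(i) diag(k) %x% matrix(u[i, ], 1L))
  structure(list(thetas = lapply(thetas, as.numeric), S_list = S_list, u = u,
                 m = m, k = k, p = ncol(u), x_list = x_list),
            class = "mvmeta_input")
}

## GLS of theta_i on U_i = I_k (x) u_i' given error covariances sigma_list.
## Returns beta (length kp, ordered in k blocks of p), its covariance, the
## residual quadratic form and the two log-determinant pieces of the
## likelihood.
mv_gls <- function(input, sigma_list) {
  k <- input$k; p <- input$p
  m <- input$m
  kp <- k * p
  simple <- p == 1L                       # intercept-only: X_i = I_k
  xtwx <- matrix(0, kp, kp)
  xtwy <- numeric(kp)
  logdet_sigma <- 0
  w_list <- vector("list", m)
  for (i in seq_len(m)) {
    ch <- tryCatch(chol(sigma_list[[i]]), error = function(e) NULL)
    if (is.null(ch))
      stop("covariance matrix for location ", i, " is not positive definite",
           call. = FALSE)
    wi <- chol2inv(ch)                    # sigma_i^-1
    logdet_sigma <- logdet_sigma + 2 * sum(log(diag(ch)))
    w_list[[i]] <- wi
    if (simple) {
      xtwx <- xtwx + wi
      xtwy <- xtwy + wi %*% input$thetas[[i]]
    } else {
      xi <- input$x_list[[i]]
      wx <- wi %*% xi
      xtwx <- xtwx + crossprod(xi, wx)
      xtwy <- xtwy + crossprod(wx, input$thetas[[i]])
    }
  }
  vcov_beta <- tryCatch(solve(xtwx), error = function(e)
    stop("singular meta-regression design", call. = FALSE))
  beta <- drop(vcov_beta %*% xtwy)
  quad <- 0
  for (i in seq_len(m)) {
    r <- input$thetas[[i]] -
      (if (simple) beta else drop(input$x_list[[i]] %*% beta))
    quad <- quad + drop(crossprod(r, w_list[[i]] %*% r))
  }
  list(beta = beta, vcov_beta = vcov_beta, quad = quad,
       logdet_sigma = logdet_sigma,
       logdet_xtwx = determinant(xtwx, logarithm = TRUE)$modulus[1])
}

## Psi from the log-Cholesky parameter vector xi (length k(k+1)/2):
## lower-triangular L with exp(xi) on the diagonal, free below.
psi_from_xi <- function(xi, k) {
  l <- matrix(0, k, k)
  l[cbind(1:k, 1:k)] <- exp(xi[1:k])
  if (k > 1) l[lower.tri(l)] <- xi[-(1:k)]
  l %*% t(l)
}

#' Fit a multivariate meta-analysis / meta-regression
#'
#' Random-effects model `theta_i ~ N(U_i beta, S_i + Psi)` with
#' `U_i = I_k %x% t(u_i)`: `beta` holds the kp second-stage coefficients
#' (k blocks of p, i.e. for each first-stage coefficient the intercept and
#' meta-variable effects) and `Psi` the unstructured between-location
#' covariance. Estimation:
#' \itemize{
#'   \item `"fixed"`: Psi = 0, generalized least squares with weights
#'     `S_i^{-1}`;
#'   \item `"ml"` / `"reml"`: (restricted) maximum likelihood over the
#'     log-Cholesky parameters of Psi, with beta profiled out by GLS at each
#'     evaluation; quasi-Newton (BFGS) with numerical gradients starting from
#'     `Psi = 0.1 * diag(variance of the thetas)`.
#' }
#' With few locations or little heterogeneity the between-location
#' correlations may be truncated at +/-1 (a boundary solution); the fit still
#' converges and the pooled coefficients remain finite.
#'
#' @param input an [mvmeta_input()].
#' @param method `"reml"` (default), `"ml"` or `"fixed"`.
#' @param control list: `maxit` (default 500), `reltol` (default 1e-10).
#' @return object of class `"mvmeta_model"`: list with `beta`, `vcov_beta`,
#'   `Psi`, `xi`, `method`, `loglik` (on the restricted scale for REML),
#'   `converged`, `input`.
#' @references The model and its use for pooling reduced distributed-lag
#'   coefficients follow the standard multivariate meta-analysis literature.
#' @export
fit_mvmeta <- function(input, method = c("reml", "ml", "fixed"),
                       control = list()) {
  stopifnot(inherits(input, "mvmeta_input"))
  method <- match.arg(method)
  k <- input$k
  maxit <- if (is.null(control$maxit)) 500L else control$maxit
  reltol <- if (is.null(control$reltol)) 1e-10 else control$reltol
  n <- input$m * k
  q <- k * input$p

  loglik_at <- function(psi, restricted) {
    sigma <- lapply(input$S_list, function(s) s + psi)
    g <- mv_gls(input, sigma)
    ll <- -0.5 * (g$logdet_sigma + g$quad) -
      (if (restricted) (n - q) / 2 else n / 2) * log(2 * pi)
    if (restricted) ll <- ll - 0.5 * g$logdet_xtwx
    list(ll = ll, gls = g)
  }

  if (method == "fixed" || (input$m == 1L)) {
    res <- loglik_at(matrix(0, k, k), restricted = FALSE)
    return(structure(list(beta = res$gls$beta, vcov_beta = res$gls$vcov_beta,
                          Psi = matrix(0, k, k), xi = NULL, method = "fixed",
                          loglik = res$ll, converged = TRUE, input = input),
                     class = "mvmeta_model"))
  }
  if (input$m < 2L) stop("random-effects estimation needs at least 2 locations", call. = FALSE)

  restricted <- method == "reml"
  tmat <- do.call(rbind, input$thetas)
  v0 <- 0.1 * pmax(apply(tmat, 2L, stats::var), 1e-8)
  xi0 <- c(0.5 * log(v0), rep(0, k * (k - 1) / 2))
  negll <- function(xi) {
    psi <- psi_from_xi(xi, k)
    val <- tryCatch(loglik_at(psi, restricted)$ll, error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else -val
  }
  # analytic gradient: with beta profiled out by GLS the envelope theorem
  # gives d(-l)/dPsi = 1/2 sum_i [W_i - W_i r_i r_i' W_i - W_i X_i V X_i' W_i]
  # (last term REML only), W_i = (S_i + Psi)^-1, V = (sum X'WX)^-1; chained
  # through Psi = L L' and the log-diagonal of L.
  negll_grad <- function(xi) {
    l <- matrix(0, k, k)
    l[cbind(1:k, 1:k)] <- exp(xi[1:k])
    if (k > 1) l[lower.tri(l)] <- xi[-(1:k)]
    psi <- l %*% t(l)
    w_list <- vector("list", input$m)
    kp <- k * input$p
    xtwx <- matrix(0, kp, kp); xtwy <- numeric(kp)
    for (i in seq_len(input$m)) {
      ch <- tryCatch(chol(input$S_list[[i]] + psi), error = function(e) NULL)
      if (is.null(ch)) return(rep(0, length(xi)))  # outside feasible region
      wi <- chol2inv(ch)
      w_list[[i]] <- wi
      if (input$p == 1L) {
        xtwx <- xtwx + wi; xtwy <- xtwy + wi %*% input$thetas[[i]]
      } else {
        xi_d <- input$x_list[[i]]
        wx <- wi %*% xi_d
        xtwx <- xtwx + crossprod(xi_d, wx)
        xtwy <- xtwy + crossprod(wx, input$thetas[[i]])
      }
    }
    v <- solve(xtwx)
    beta <- drop(v %*% xtwy)
    g <- matrix(0, k, k)
    for (i in seq_len(input$m)) {
      wi <- w_list[[i]]
      r <- input$thetas[[i]] -
        (if (input$p == 1L) beta else drop(input$x_list[[i]] %*% beta))
      wr <- wi %*% r
      g <- g + wi - tcrossprod(wr)
      if (restricted) {
        wx <- if (input$p == 1L) wi else wi %*% input$x_list[[i]]
        g <- g - wx %*% v %*% t(wx)
      }
    }
    gl <- g %*% l                          # d(-l)/dL = 2 * (g/2) %*% L
    c(diag(gl) * diag(l), if (k > 1) gl[lower.tri(gl)])
  }
  opt <- stats::optim(xi0, negll, gr = negll_grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  # restart once: the value-based stopping rule can leave O(1e-6) slack in
  # the variance parameters
  opt2 <- stats::optim(opt$par, negll, gr = negll_grad, method = "BFGS",
                       control = list(maxit = 50L, reltol = 1e-15))
  if (opt2$value <= opt$value) opt$par <- opt2$par
  psi <- psi_from_xi(opt$par, k)
  res <- loglik_at(psi, restricted)
  structure(list(beta = res$gls$beta, vcov_beta = res$gls$vcov_beta,
                 Psi = psi, xi = opt$par, method = method, loglik = res$ll,
                 converged = opt$convergence == 0L, input = input),
            class = "mvmeta_model")
}

#' @export
print.mvmeta_model <- function(x, ...) {
  cat(sprintf("<mvmeta_model> method=%s, k=%d, p=%d, m=%d, loglik=%.3f%s\n",
              x$method, x$input$k, x$input$p, x$input$m, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Multivariate Cochran Q test and I-squared
#'
#' `Q = sum_i t(r_i) S_i^{-1} r_i` with residuals `r_i` from the fixed-effects
#' GLS fit on the same design (regardless of the meta-analytical model
#' eventually used for pooling), `df = m k - k p`, p-value from the chi-square
#' distribution, and `I2 = max(0, (Q - df)/Q) * 100`, the percentage of total
#' variability attributable to true between-location heterogeneity.
#'
#' @param input an [mvmeta_input()].
#' @return object of class `"heterogeneity_stats"`: list with `Q`, `df`,
#'   `p_value`, `I2`.
#' @export
cochran_q <- function(input) {
  stopifnot(inherits(input, "mvmeta_input"))
  g <- mv_gls(input, input$S_list)
  df <- input$m * input$k - input$k * input$p
  q <- g$quad
  structure(list(Q = q, df = df,
                 p_value = stats::pchisq(q, df, lower.tail = FALSE),
                 I2 = if (q > 0) max(0, (q - df) / q) * 100 else 0),
            class = "heterogeneity_stats")
}

#' @export
print.heterogeneity_stats <- function(x, ...) {
  cat(sprintf("Cochran Q = %.2f on %d df (p = %.4g); I2 = %.1f%%\n",
              x$Q, x$df, x$p_value, x$I2))
  invisible(x)
}

#' Wald test on a block of pooled coefficients
#'
#' `stat = t(beta_block) solve(vcov_block) beta_block` against a chi-square
#' with `length(block)` df; used e.g. to test all k coefficients of one
#' meta-variable jointly.
#'
#' @param model an [fit_mvmeta()] result.
#' @param block integer indices into `beta`.
#' @return list with `stat`, `df`, `p`.
#' @export
wald_test <- function(model, block) {
  stopifnot(inherits(model, "mvmeta_model"))
  b <- model$beta[block]
  v <- model$vcov_beta[block, block, drop = FALSE]
  vi <- tryCatch(solve(v), error = function(e)
    stop("singular covariance block in Wald test", call. = FALSE))
  stat <- drop(t(b) %*% vi %*% b)
  list(stat = stat, df = length(block),
       p = stats::pchisq(stat, length(block), lower.tail = FALSE))
}

#' Indices of one meta-variable's coefficients
#'
#' `beta` is ordered in k blocks of p; the j-th meta-variable's k
#' coefficients sit at positions `j, j + p, ..., j + (k-1) p`.
#'
#' @param model an [fit_mvmeta()] result.
#' @param var_index column index into the meta-variable design (1 =
#'   intercept).
#' @return integer vector of length k.
#' @export
meta_var_block <- function(model, var_index) {
  p <- model$input$p
  k <- model$input$k
  as.integer(var_index + (seq_len(k) - 1L) * p)
}

#' Pooled coefficients at given meta-variable values
#'
#' `theta = (I_k %x% t(u_new)) beta` with the matching covariance sandwich;
#' composable with [predict_reduced()] (wrap the result with the reduced
#' fit's spec) to draw pooled curves.
#'
#' @param model an [fit_mvmeta()] result.
#' @param u_new meta-variable vector of length p (first element 1).
#' @return list with `theta`, `vcov`.
#' @export
mvmeta_predict <- function(model, u_new = NULL) {
  stopifnot(inherits(model, "mvmeta_model"))
  p <- model$input$p
  if (is.null(u_new)) u_new <- c(1, rep(0, p - 1L))
  if (length(u_new) != p) stop("'u_new' must have length p", call. = FALSE)
  x <- diag(model$input$k) %x% matrix(u_new, 1L)
  list(theta = drop(x %*% model$beta),
       vcov = x %*% model$vcov_beta %*% t(x))
}

#' Build a pooled reduced fit from a meta-analysis
#'
#' Convenience wrapper: takes the template `reduced_fit` whose coefficients
#' were pooled and replaces (theta, vcov) with the pooled prediction, so the
#' pooled curve is drawn with [predict_reduced()] exactly like a
#' location-specific one.
#'
#' @param model an [fit_mvmeta()] result.
#' @param template a [reduce_fit()] result from any location.
#' @param u_new meta-variable vector (see [mvmeta_predict()]).
#' @return a `reduced_fit`.
#' @export
pooled_reduced_fit <- function(model, template, u_new = NULL) {
  stopifnot(inherits(template, "reduced_fit"))
  pr <- mvmeta_predict(model, u_new)
  out <- template
  out$theta <- pr$theta
  out$vcov <- (pr$vcov + t(pr$vcov)) / 2
  out
}
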