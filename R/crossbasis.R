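#' Matrix of lagged exposures
#'
#' Builds the N x (L+1) matrix whose row t is `(x[t], x[t-1], ..., x[t-L])`,
#' the exposure history entering the distributed-lag sum at time t. Entries
#' with `t - lag < 1` are missing, so the first L rows are incomplete.
#'
#' @param x exposure series.
#' @param L maximum lag (>= 0, < length(x)).
#' @return object of class `"lag_matrix"`: numeric matrix with attribute
#'   `lags = 0:L`.
#' @export
lag_matrix <- function(x, L) {
  x <- as.numeric(x)
  if (L < 0 || L != round(L)) stop("'L' must be a non-negative integer", call. = FALSE)
  if (L >= length(x)) stop("'L' must be smaller than the series length", call. = FALSE)
  n <- length(x)
  q <- matrix(NA_real_, n, L + 1L)
  for (l in 0:L) if (l < n) q[(l + 1L):n, l + 1L] <- x[1:(n - l)]
  structure(q, lags = 0:L, class = c("lag_matrix", "matrix", "array"))
}

#' Build a cross-basis design matrix
#'
#' Tensor-product design for a distributed lag non-linear model: the
#' predictor-space basis Z (dimension `v_x`) is applied to each lagged copy of
#' the exposure and contracted with the lag-space basis C (dimension `v_l`)
#' evaluated on the integer lags 0..L, giving the `N x (v_x * v_l)` matrix W
#' with
#' \deqn{W[t, (k-1) v_x + j] = \sum_{\ell=0}^{L} Z(x_{t-\ell})_j \, C(\ell)_k.}
#'
#' Column ordering: the predictor-basis index j varies fastest within the
#' lag-basis index k, so the coefficient vector eta stacks the `v_x x v_l`
#' coefficient matrix column-major and the reduction maps are the literal
#' Kronecker products of [reduction_matrix()]. Other implementations order
#' the opposite way; all prediction/reduction code in this package assumes
#' this convention.
#'
#' Rows with any missing lagged exposure (including the first L rows) are
#' emitted entirely missing and are dropped by the first-stage regression
#' (complete-case).
#'
#' With a linear predictor basis W reduces to the distributed lag model
#' design `Q C`; with a constant lag basis the single lag-block equals the
#' `(L+1)`-term running sum of the predictor basis, i.e. `(L+1)` times the
#' basis of the moving average model up to spline nonlinearity.
#'
#' @param x exposure series.
#' @param var_spec [basis_spec()] for the predictor space (dimension `v_x`).
#' @param lag_spec [basis_spec()] for the lag space (dimension `v_l`); must
#'   not carry a center.
#' @param L maximum lag.
#' @return object of class `"crossbasis"`: the W matrix with attributes
#'   `var_spec`, `lag_spec`, `L`, `x`.
#' @export
build_crossbasis <- function(x, var_spec, lag_spec, L) {
  stopifnot(inherits(var_spec, "basis_spec"), inherits(lag_spec, "basis_spec"))
  if (!is.null(lag_spec$center))
    stop("lag-space bases must not carry a center", call. = FALSE)
  q <- lag_matrix(x, L)
  n <- nrow(q)
  cmat <- unclass(make_basis(0:L, lag_spec))
  vx <- basis_dim(var_spec)
  vl <- basis_dim(lag_spec)
  w <- matrix(0, n, vx * vl)
  bad <- rowSums(is.na(q)) > 0L
  for (l in 0:L) {
    xl <- q[, l + 1L]
    xl[is.na(xl)] <- 0  # incomplete rows overwritten with NA below
    zl <- unclass(make_basis(xl, var_spec))
    for (k in seq_len(vl)) {
      ck <- cmat[l + 1L, k]
      if (ck != 0)
        w[, (k - 1L) * vx + seq_len(vx)] <- w[, (k - 1L) * vx + seq_len(vx)] + ck * zl
    }
  }
  w[bad, ] <- NA_real_
  colnames(w) <- paste0("cb.v", rep(seq_len(vx), vl), ".l", rep(seq_len(vl), each = vx))
  structure(w, var_spec = var_spec, lag_spec = lag_spec, L = as.integer(L),
            x = as.numeric(x), class = c("crossbasis", "matrix", "array"))
}

#' @export
print.crossbasis <- function(x, ...) {
  cat(sprintf("<crossbasis> %d x %d (v_x = %d, v_l = %d, L = %d)\n",
              nrow(x), ncol(x), basis_dim(attr(x, "var_spec")),
              basis_dim(attr(x, "lag_spec")), attr(x, "L")))
  invisible(x)
}
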