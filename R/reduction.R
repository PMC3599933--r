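#' Dimension-reducing matrix for cross-basis coefficients
#'
#' The fitted cross-basis surface is defined by `v_x * v_l` coefficients; the
#' three standard uni-dimensional summaries are linear in those coefficients
#' and are obtained by a rank-deficient matrix M:
#' \itemize{
#'   \item predictor-specific (lag curve at exposure `x0`):
#'     `M = I_{v_l} %x% t(z[x0])`, a `v_l x (v_x v_l)` matrix;
#'   \item lag-specific (exposure curve at lag `l0`):
#'     `M = t(c[l0]) %x% I_{v_x}`, a `v_x x (v_x v_l)` matrix;
#'   \item overall cumulative (exposure curve summed over lags 0..L):
#'     `M = (t(1) C) %x% I_{v_x}`, a `v_x x (v_x v_l)` matrix.
#' }
#' Here `z[x0]` and `c[l0]` are UNcentered rows of the predictor- and
#' lag-space bases, and `t(1) C` sums the lag-basis rows over the integer
#' lags 0..L. With a constant lag basis the overall matrix collapses to
#' `(L + 1) * I_{v_x}`, which is how a moving-average model's coefficients
#' relate to the cumulative summary. M has full row rank but fewer rows than
#' columns whenever `min(v_x, v_l) > 1`, so the reduction cannot be reversed.
#'
#' The Kronecker forms assume the column ordering of [build_crossbasis()]
#' (predictor index fastest).
#'
#' @param kind `"predictor_specific"`, `"lag_specific"` or `"overall"`.
#' @param var_spec,lag_spec the cross-basis [basis_spec()]s.
#' @param L maximum lag.
#' @param at_value `x0` (predictor units) or `l0` (lag units) for the
#'   predictor-/lag-specific kinds; must be absent for `"overall"`.
#' @param cen optional reference value: when supplied for
#'   `"predictor_specific"`, the centered row `z[x0] - z[cen]` is embedded in
#'   M so the reduced lag curve is expressed relative to the reference.
#' @return object of class `"reduction_matrix"`: the matrix M with attributes
#'   `kind`, `at_value`, `var_spec`, `lag_spec`, `L`.
#' @export
reduction_matrix <- function(kind = c("predictor_specific", "lag_specific", "overall"),
                             var_spec, lag_spec, L, at_value = NULL, cen = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(var_spec, "basis_spec"), inherits(lag_spec, "basis_spec"))
  vx <- basis_dim(var_spec)
  vl <- basis_dim(lag_spec)
  if (kind == "overall") {
    if (!is.null(at_value))
      stop("'at_value' must not be supplied for the overall summary", call. = FALSE)
    csum <- colSums(unclass(make_basis(0:L, lag_spec)))
    m <- matrix(csum, 1L) %x% diag(vx)
  } else if (kind == "lag_specific") {
    if (is.null(at_value))
      stop("lag-specific reduction needs 'at_value' (a lag)", call. = FALSE)
    cl <- drop(unclass(make_basis(at_value, lag_spec)))
    m <- matrix(cl, 1L) %x% diag(vx)
  } else {
    if (is.null(at_value))
      stop("predictor-specific reduction needs 'at_value' (an exposure)", call. = FALSE)
    z <- drop(unclass(make_basis(at_value, var_spec)))
    if (!is.null(cen)) z <- z - drop(unclass(make_basis(cen, var_spec)))
    m <- diag(vl) %x% matrix(z, 1L)
  }
  structure(m, kind = kind, at_value = at_value,
            var_spec = var_spec, lag_spec = lag_spec, L = as.integer(L),
            class = c("reduction_matrix", "matrix", "array"))
}

#' Reduce a first-stage fit to a one-dimensional summary
#'
#' Applies `theta = M eta` and `V(theta) = M V(eta) t(M)`. The surviving
#' dimension is spanned by the lag-space basis for predictor-specific
#' summaries and by the predictor-space basis otherwise; the matching spec is
#' stored so the reduced fit can be predicted on any grid.
#'
#' For `kind = "predictor_specific"` a reference `cen` must be supplied
#' (default: the center recorded in the predictor spec): the centered row
#' `z[x0] - z[cen]` is embedded in M, making the reduced coefficients (and
#' hence the lag curve) relative to the reference. For the other kinds the
#' reduction is reference-free and centering happens in [predict_reduced()].
#'
#' @param fit a `first_stage_fit` (see [fit_first_stage()]) or any list with
#'   elements `eta`, `vcov`, `var_spec`, `lag_spec`, `L`.
#' @param kind,at_value as in [reduction_matrix()].
#' @param cen reference exposure value.
#' @return object of class `"reduced_fit"`: list with `theta`, `vcov`,
#'   `kind`, `at_value`, `spec` (basis spanning the surviving dimension),
#'   `center`.
#' @export
reduce_fit <- function(fit, kind = c("predictor_specific", "lag_specific", "overall"),
                       at_value = NULL, cen = NULL) {
  kind <- match.arg(kind)
  if (is.null(cen)) cen <- fit$var_spec$center
  m <- reduction_matrix(kind, fit$var_spec, fit$lag_spec, fit$L,
                        at_value = at_value,
                        cen = if (kind == "predictor_specific") {
                          if (is.null(cen))
                            stop("predictor-specific reduction needs a reference 'cen'",
                                 call. = FALSE)
                          cen
                        } else NULL)
  eta <- as.numeric(fit$eta)
  if (ncol(m) != length(eta) || !all(dim(fit$vcov) == length(eta)))
    stop("reduction matrix not conformable with the fit", call. = FALSE)
  theta <- drop(m %*% eta)
  v <- m %*% fit$vcov %*% t(m)
  v <- (v + t(v)) / 2
  structure(list(theta = theta, vcov = v, kind = kind, at_value = at_value,
                 spec = if (kind == "predictor_specific") fit$lag_spec else fit$var_spec,
                 center = cen, L = fit$L),
            class = "reduced_fit")
}

#' @export
print.reduced_fit <- function(x, ...) {
  cat(sprintf("<reduced_fit> %s%s: %d coefficients (basis kind %s)\n",
              x$kind,
              if (!is.null(x$at_value)) sprintf(" at %g", x$at_value) else "",
              length(x$theta), x$spec$kind))
  invisible(x)
}

#' Predict a summary curve from a reduced fit
#'
#' For overall and lag-specific summaries the curve on an exposure grid is
#' `(Z[p] - z[cen]) theta` with the centered predictor-space basis rows; for
#' predictor-specific summaries the lag curve is `C[p] theta` (the reference
#' was embedded at reduction time). Standard errors come from the quadratic
#' form with `V(theta)`; relative risks are `exp(fit)` with normal 95%
#' confidence limits `exp(fit +/- 1.959964 se)`.
#'
#' @param rf a [reduce_fit()] result.
#' @param grid exposure values (overall/lag-specific) or lag values
#'   (predictor-specific) at which to evaluate the curve.
#' @param cen reference exposure overriding the one stored in `rf`
#'   (overall/lag-specific only; a predictor-specific fit is locked to the
#'   reference used at reduction).
#' @return data.frame with columns `grid`, `fit`, `se`, `rr`, `rr_low`,
#'   `rr_high`.
#' @export
predict_reduced <- function(rf, grid, cen = NULL) {
  stopifnot(inherits(rf, "reduced_fit"))
  zq <- stats::qnorm(0.975)
  b <- unclass(make_basis(grid, rf$spec))
  if (rf$kind == "predictor_specific") {
    if (!is.null(cen) && !isTRUE(all.equal(cen, rf$center)))
      stop("a predictor-specific reduced fit is relative to the reference ",
           "fixed at reduction time; re-reduce to change it", call. = FALSE)
    a <- b
  } else {
    if (is.null(cen)) cen <- rf$center
    if (is.null(cen)) stop("no reference value available; supply 'cen'", call. = FALSE)
    zc <- drop(unclass(make_basis(cen, rf$spec)))
    a <- sweep(b, 2L, zc)
  }
  fit <- drop(a %*% rf$theta)
  se <- sqrt(pmax(rowSums((a %*% rf$vcov) * a), 0))
  data.frame(grid = as.numeric(grid), fit = fit, se = se,
             rr = exp(fit), rr_low = exp(fit - zq * se),
             rr_high = exp(fit + zq * se))
}

#' Serialize / deserialize a reduced fit
#'
#' JSON form of a [reduce_fit()] result: the hand-off artifact between the
#' first-stage (per-location regression + reduction) and second-stage
#' (multivariate meta-analysis) of a distributed two-stage pipeline.
#'
#' @param rf a `reduced_fit`; `path` file path; `x` a parsed list.
#' @return `reduced_fit_to_json` (invisibly) the path;
#'   `reduced_fit_from_json` the restored `reduced_fit`.
#' @export
reduced_fit_to_json <- function(rf, path) {
  stopifnot(inherits(rf, "reduced_fit"))
  obj <- list(theta = rf$theta, vcov = as.vector(rf$vcov), k = length(rf$theta),
              kind = rf$kind, at_value = rf$at_value, center = rf$center,
              L = rf$L, spec = basis_spec_to_list(rf$spec))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname reduced_fit_to_json
#' @export
reduced_fit_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(theta = as.numeric(x$theta),
                 vcov = matrix(as.numeric(x$vcov), x$k, x$k),
                 kind = x$kind, at_value = x$at_value,
                 spec = basis_spec_from_list(x$spec),
                 center = x$center, L = x$L),
            class = "reduced_fit")
}
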