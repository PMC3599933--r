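#' Specify a uni-dimensional basis
#'
#' A `basis_spec` describes one of the two uni-dimensional bases entering a
#' cross-basis: the predictor-space basis (applied to the exposure, e.g. daily
#' mean temperature) or the lag-space basis (applied to the integer lags
#' 0..L). The spec fully determines the basis: evaluating it on any vector of
#' points is a pure function of the spec, so the same spec can be reused at
#' fitting, prediction and reduction time.
#'
#' @param kind one of `"bspline"`, `"natural_cubic"`, `"poly"`, `"linear"`,
#'   `"strata"`, `"threshold"`, `"constant"`.
#' @param degree polynomial degree; used by `"bspline"` (default 3) and
#'   `"poly"`.
#' @param knots internal knots, strictly increasing and strictly inside the
#'   boundary (for `"strata"`/`"threshold"`: cut points / thresholds).
#' @param boundary length-2 numeric boundary knots; required for spline kinds.
#' @param intercept logical; keep the intercept column of the basis.
#' @param center optional reference value in predictor units. Centering is
#'   never baked into evaluated basis values; it is applied as
#'   `z(x) - z(center)` at prediction/reduction time. Lag-space bases must not
#'   carry a center.
#'
#' @return an object of class `"basis_spec"`.
#' @seealso [make_basis()], [basis_dim()], [build_crossbasis()]
#' @export
basis_spec <- function(kind = c("bspline", "natural_cubic", "poly", "linear",
                                "strata", "threshold", "constant"),
                       degree = if (identical(kind, "poly")) 1L else 3L,
                       knots = numeric(0), boundary = NULL,
                       intercept = FALSE, center = NULL) {
  kind <- match.arg(kind)
  knots <- as.numeric(knots)
  if (anyNA(knots) || is.unsorted(knots, strictly = TRUE))
    stop("'knots' must be finite and strictly increasing", call. = FALSE)
  if (kind %in% c("bspline", "natural_cubic")) {
    if (is.null(boundary))
      stop("spline bases require 'boundary' knots", call. = FALSE)
    boundary <- as.numeric(boundary)
    if (length(boundary) != 2L || boundary[1] >= boundary[2])
      stop("'boundary' must be two increasing values", call. = FALSE)
    if (length(knots) && (min(knots) <= boundary[1] || max(knots) >= boundary[2]))
      stop("internal knots must lie strictly inside the boundary knots",
           call. = FALSE)
  }
  if (kind == "bspline" && (degree < 1L || degree != round(degree)))
    stop("'degree' must be a positive integer", call. = FALSE)
  if (!is.null(center) && (!is.numeric(center) || length(center) != 1L))
    stop("'center' must be a single numeric value", call. = FALSE)
  structure(list(kind = kind, degree = as.integer(degree), knots = knots,
                 boundary = boundary, intercept = isTRUE(intercept),
                 center = center),
            class = "basis_spec")
}

#' Dimension of a basis
#'
#' Number of basis functions (columns of the evaluated basis matrix); a pure
#' function of the spec.
#'
#' @param spec a [basis_spec()].
#' @return integer dimension.
#' @export
basis_dim <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  ic <- as.integer(spec$intercept)
  nk <- length(spec$knots)
  switch(spec$kind,
    bspline       = nk + spec$degree + ic,
    natural_cubic = nk + 1L + ic,
    poly          = spec$degree + ic,
    linear        = 1L + ic,
    strata        = if (spec$intercept) nk + 1L else nk,
    threshold     = nk + ic,
    constant      = 1L)
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("<basis_spec> kind=%s dim=%d", x$kind, basis_dim(x)))
  if (x$kind %in% c("bspline", "poly")) cat(" degree=", x$degree, sep = "")
  if (length(x$knots)) cat(" knots={", paste(signif(x$knots, 4), collapse = ", "), "}", sep = "")
  if (!is.null(x$boundary)) cat(" boundary=[", x$boundary[1], ", ", x$boundary[2], "]", sep = "")
  cat(" intercept=", x$intercept, sep = "")
  if (!is.null(x$center)) cat(" center=", x$center, sep = "")
  cat("\n")
  invisible(x)
}

## Full B-spline basis (intercept kept) with polynomial extension beyond the
## boundary knots: outside [b1, b2] each basis function is continued by the
## Taylor polynomial of its terminal piece, which IS the polynomial piece of
## the terminal span since the spline is piecewise polynomial of the stated
## degree.
## Anchor point strictly inside the terminal span on the given side;
## splineDesign derivatives are unreliable exactly at the last knot, and the
## Taylor expansion of the terminal polynomial piece is exact from any point
## of that span.
terminal_anchor <- function(knots, boundary, side) {
  if (side == 1) {
    upper <- if (length(knots)) min(knots) else boundary[2]
    boundary[1] + (upper - boundary[1]) / 2
  } else {
    lower <- if (length(knots)) max(knots) else boundary[1]
    boundary[2] - (boundary[2] - lower) / 2
  }
}

bspline_full <- function(x, degree, knots, boundary) {
  ak <- sort(c(rep(boundary, degree + 1L), knots))
  ord <- degree + 1L
  n <- length(x)
  out <- matrix(NA_real_, n, length(ak) - ord)
  ok <- !is.na(x)
  xo <- x[ok]
  inside <- xo >= boundary[1] & xo <= boundary[2]
  res <- matrix(0, length(xo), ncol(out))
  if (any(inside))
    res[inside, ] <- splines::splineDesign(ak, xo[inside], ord = ord)
  for (side in 1:2) {
    b <- boundary[side]
    sel <- if (side == 1) xo < b else xo > b
    if (!any(sel)) next
    xc <- terminal_anchor(knots, boundary, side)
    d <- xo[sel] - xc
    ext <- matrix(0, sum(sel), ncol(out))
    for (r in 0:degree) {
      der <- splines::splineDesign(ak, xc, ord = ord, derivs = r)
      ext <- ext + outer(d^r / factorial(r), drop(der))
    }
    res[sel, ] <- ext
  }
  out[ok, ] <- res
  out
}

## Natural cubic spline basis: cubic B-spline basis projected onto the null
## space of the second-derivative constraints at the two boundary knots, so
## the basis is linear at and beyond the boundary. Same construction as
## splines::ns but keeping the intercept-drop convention uniform with
## 'bspline' (drop the first column when intercept = FALSE) and using the
## exact first-order Taylor continuation outside the boundary.
natural_cubic_full <- function(x, knots, boundary) {
  ak <- sort(c(rep(boundary, 4L), knots))
  n <- length(x)
  ncols <- length(ak) - 4L
  ok <- !is.na(x)
  xo <- x[ok]
  const <- splines::splineDesign(ak, boundary, ord = 4L, derivs = c(2L, 2L))
  qmat <- qr.Q(qr(t(const)), complete = TRUE)[, -(1:2), drop = FALSE]
  res <- matrix(0, length(xo), ncols)
  inside <- xo >= boundary[1] & xo <= boundary[2]
  if (any(inside))
    res[inside, ] <- splines::splineDesign(ak, xo[inside], ord = 4L)
  for (side in 1:2) {
    b <- boundary[side]
    sel <- if (side == 1) xo < b else xo > b
    if (!any(sel)) next
    xc <- terminal_anchor(knots, boundary, side)
    dc <- b - xc
    der <- lapply(0:3, function(r)
      drop(splines::splineDesign(ak, xc, ord = 4L, derivs = r)))
    v0 <- der[[1]] + dc * der[[2]] + dc^2 / 2 * der[[3]] + dc^3 / 6 * der[[4]]
    v1 <- der[[2]] + dc * der[[3]] + dc^2 / 2 * der[[4]]
    d <- xo[sel] - b
    res[sel, ] <- outer(rep(1, sum(sel)), v0) + outer(d, v1)
  }
  out <- matrix(NA_real_, n, ncol(qmat))
  out[ok, ] <- res %*% qmat
  out
}

#' Evaluate a basis on a set of points
#'
#' Returns the basis matrix: rows index `eval_points`, columns index basis
#' functions. Missing evaluation points give missing rows. No centering is
#' applied here; the reference subtraction happens at prediction/reduction
#' time. B-splines follow the Cox-de Boor recursion with boundary knots
#' repeated `degree + 1` times; when `intercept = FALSE` the first basis
#' function is dropped. The natural cubic variant is linear at and beyond the
#' boundary knots. Points outside the boundary are extended polynomially
#' (linearly for natural cubic) rather than erroring, since prediction grids
#' may slightly exceed the observed range.
#'
#' @param eval_points numeric vector (NA allowed; NA rows returned).
#' @param spec a [basis_spec()].
#' @return object of class `"basis_matrix"`: the numeric matrix with
#'   attributes `spec` and `eval_points`.
#' @examples
#' sp <- basis_spec("bspline", degree = 2, knots = c(5.3, 15.1),
#'                  boundary = c(-4.4, 24.9))
#' dim(make_basis(0:21, sp))  # 22 x 4
#' @export
make_basis <- function(eval_points, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  x <- as.numeric(eval_points)
  if (length(x) == 0L) stop("'eval_points' must be non-empty", call. = FALSE)
  vals <- switch(spec$kind,
    constant = matrix(1, length(x), 1L),
    linear = {
      m <- cbind(x)
      if (spec$intercept) cbind(1, m) else m
    },
    poly = {
      m <- outer(x, seq_len(spec$degree), `^`)
      if (spec$intercept) cbind(1, m) else m
    },
    threshold = {
      m <- vapply(spec$knots, function(k) pmax(x - k, 0), numeric(length(x)))
      m <- matrix(m, length(x))
      if (spec$intercept) cbind(1, m) else m
    },
    strata = {
      if (!length(spec$knots)) stop("'strata' needs at least one knot", call. = FALSE)
      g <- findInterval(x, spec$knots) + 1L  # 1..nk+1
      full <- matrix(0, length(x), length(spec$knots) + 1L)
      ok <- !is.na(g)
      full[cbind(seq_along(x)[ok], g[ok])] <- 1
      full[!ok, ] <- NA_real_
      if (spec$intercept) full else full[, -1L, drop = FALSE]
    },
    bspline = {
      full <- bspline_full(x, spec$degree, spec$knots, spec$boundary)
      if (spec$intercept) full else full[, -1L, drop = FALSE]
    },
    natural_cubic = {
      full <- natural_cubic_full(x, spec$knots, spec$boundary)
      if (spec$intercept) full else full[, -1L, drop = FALSE]
    })
  vals[is.na(x), ] <- NA_real_
  stopifnot(ncol(vals) == basis_dim(spec))
  structure(vals, spec = spec, eval_points = x,
            class = c("basis_matrix", "matrix", "array"))
}

#' Place lag knots at equally spaced log-values
#'
#' Knots for the lag-space basis at `exp(j * log(L) / nk)`, `j = 0..nk-1`:
#' `nk + 1` points equally spaced on the log scale over `[1, L]` with the last
#' discarded. For `L = 21`, `nk = 3` this gives (1.00, 2.76, 7.61).
#'
#' @param L maximum lag (integer, >= 2).
#' @param nk number of internal knots (< L).
#' @return numeric vector of `nk` knots in lag units.
#' @export
place_lag_knots <- function(L, nk) {
  if (L < 2) stop("'L' must be at least 2 to place interior lag knots", call. = FALSE)
  if (nk < 1 || nk >= L) stop("'nk' must satisfy 1 <= nk < L", call. = FALSE)
  exp(seq(0, nk - 1) * log(L) / nk)
}

#' Place predictor knots at equally spaced values or quantiles
#'
#' @param x exposure values (missing values dropped).
#' @param nk number of internal knots.
#' @param mode `"equal_values"`: split `[min(x), max(x)]` into `nk + 1` equal
#'   intervals; `"quantiles"`: `nk` equally spaced sample quantiles.
#' @return numeric vector of `nk` knots in predictor units.
#' @export
place_var_knots <- function(x, nk, mode = c("equal_values", "quantiles")) {
  mode <- match.arg(mode)
  x <- x[is.finite(x)]
  if (!length(x)) stop("'x' has no finite values", call. = FALSE)
  if (min(x) == max(x)) stop("'x' is constant; knots are undefined", call. = FALSE)
  if (nk < 1) stop("'nk' must be >= 1", call. = FALSE)
  p <- seq_len(nk) / (nk + 1)
  if (mode == "equal_values") min(x) + p * (max(x) - min(x))
  else unname(stats::quantile(x, p, type = 7))
}

#' Serialize / deserialize a basis spec
#'
#' Plain-list form used in JSON pipeline configs and in the reduced-fit
#' hand-off artifact.
#'
#' @param spec a [basis_spec()]; `x` a plain list.
#' @return `basis_spec_to_list`: a named list; `basis_spec_from_list`: a
#'   [basis_spec()].
#' @export
basis_spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  out <- list(kind = spec$kind, degree = spec$degree, knots = spec$knots,
              boundary = spec$boundary, intercept = spec$intercept)
  if (!is.null(spec$center)) out$center <- spec$center
  out
}

#' @rdname basis_spec_to_list
#' @export
basis_spec_from_list <- function(x) {
  basis_spec(kind = x$kind,
             degree = if (is.null(x$degree)) {
               if (identical(x$kind, "poly")) 1L else 3L
             } else x$degree,
             knots = if (is.null(x$knots)) numeric(0) else unlist(x$knots),
             boundary = if (is.null(x$boundary)) NULL else unlist(x$boundary),
             intercept = isTRUE(x$intercept),
             center = x$center)
}
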