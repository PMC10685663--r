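#' Define an M-spline knot set
#'
#' A knot set fixes the basis on which spline hazard models are built: a
#' lower boundary (usually 0), an ordered sequence of internal knots, an
#' upper boundary, and the polynomial degree (cubic by default). The number
#' of basis functions is `length(internal) + degree + 1`.
#'
#' @param internal Ordered numeric vector of internal knot locations, in the
#'   same time units as the survival data. May be empty.
#' @param lower Lower boundary knot, default 0.
#' @param upper Upper boundary knot; must exceed the largest internal knot.
#'   Beyond `upper` the hazard implied by any coefficient vector is constant.
#' @param degree Polynomial degree of the basis, default 3 (cubic).
#'
#' @return An object of class `"mspline_knots"`.
#' @export
mspline_knots <- function(internal = numeric(), lower = 0, upper, degree = 3) {
  if (missing(upper)) stop("'upper' boundary knot is required")
  internal <- as.numeric(internal)
  if (is.unsorted(internal)) stop("internal knots must be ordered")
  if (lower < 0 || any(internal < 0)) stop("all knots must be >= 0")
  if (length(internal) && (internal[1] <= lower || internal[length(internal)] >= upper))
    stop("internal knots must lie strictly between the boundary knots")
  if (!length(internal) && upper <= lower) stop("upper boundary must exceed lower")
  degree <- as.integer(degree)
  if (degree < 0) stop("degree must be non-negative")
  structure(
    list(internal = internal, lower = lower, upper = upper, degree = degree),
    class = "mspline_knots"
  )
}

#' @export
print.mspline_knots <- function(x, ...) {
  cat(sprintf(
    "M-spline knots: degree %d, %d basis terms, boundaries [%g, %g]\n",
    x$degree, nbasis(x), x$lower, x$upper
  ))
  if (length(x$internal)) cat("internal:", paste(signif(x$internal, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Number of basis functions implied by a knot set
#' @param knots An `mspline_knots` object.
#' @return Integer basis count.
#' @export
nbasis <- function(knots) length(knots$internal) + knots$degree + 1L

## Full knot sequence with boundary multiplicity = order (degree + 1)
aug_knots <- function(knots, extra = 0L) {
  k <- knots$degree + 1L + extra
  c(rep(knots$lower, k), knots$internal, rep(knots$upper, k))
}

#' Default knot placement from uncensored event times
#'
#' Internal knots are placed at equally-spaced quantiles
#' (linear-interpolation type) of the uncensored survival times; the upper
#' boundary defaults to the last event time, or to the largest of any
#' user-supplied upper bound and additional knots. Additional knots beyond
#' the event times (used to span external data) are appended as internal
#' knots, with the largest becoming the upper boundary when it exceeds any
#' stated upper bound.
#'
#' @param times Numeric vector of uncensored (event) times.
#' @param n_basis Requested number of basis functions; at least `degree + 2`.
#' @param upper Optional upper boundary; ignored if smaller than the final
#'   event time or the largest of `add_knots`.
#' @param add_knots Optional extra knots, each beyond the largest event time.
#' @param degree Spline degree, default 3.
#'
#' @return An `mspline_knots` object.
#' @export
default_knots <- function(times, n_basis = 10, upper = NULL, add_knots = NULL,
                          degree = 3) {
  times <- as.numeric(times)
  if (!length(times)) stop("no events: cannot place knots without uncensored times")
  degree <- as.integer(degree)
  if (n_basis < degree + 2) stop("n_basis must be at least degree + 2")
  tmax <- max(times)
  if (!is.null(add_knots) && any(add_knots <= tmax))
    stop("add_knots must all exceed the largest event time")
  up <- max(c(tmax, upper, add_knots))
  m <- n_basis - degree - 1L
  internal <- if (m > 0) {
    unname(stats::quantile(times, probs = seq_len(m) / (m + 1), type = 7))
  } else numeric()
  internal <- internal[internal > 0 & internal < up]
  extra_internal <- setdiff(as.numeric(add_knots), up)
  internal <- sort(c(internal, extra_internal[extra_internal < up]))
  if (anyDuplicated(internal)) {
    warning("duplicate knot locations collapsed; fewer basis terms than requested")
    internal <- unique(internal)
  }
  mspline_knots(internal = internal, lower = 0, upper = up, degree = degree)
}

#' Evaluate the M-spline basis
#'
#' Each basis function is a non-negative piecewise polynomial integrating to
#' 1 over the boundary interval. The construction uses the B-spline
#' relation `M_i(t) = k B_i(t) / (t_{i+k} - t_i)` with boundary-knot
#' multiplicity equal to the order `k = degree + 1`, modified so that the
#' final basis function stays at its boundary value for times beyond the
#' upper boundary (giving a constant hazard tail), and all other basis
#' functions are 0 there.
#'
#' @param knots An `mspline_knots` object.
#' @param times Non-negative evaluation times.
#' @return Matrix with `length(times)` rows and `nbasis(knots)` columns.
#' @export
mspline_basis <- function(knots, times) {
  times <- as.numeric(times)
  if (any(times < 0)) stop("times must be non-negative")
  k <- knots$degree + 1L
  n <- nbasis(knots)
  aug <- aug_knots(knots)
  M <- matrix(0, length(times), n)
  inside <- times < knots$upper
  if (any(inside)) {
    B <- splines::splineDesign(aug, times[inside], ord = k, outer.ok = TRUE)
    M[inside, ] <- sweep(B, 2, k / (aug[(1:n) + k] - aug[1:n]), "*")
  }
  ## at and beyond the boundary: constant extension of the last basis term
  if (any(!inside)) M[!inside, n] <- k / (knots$upper - aug[n])
  M
}

#' Evaluate the integrated (I-spline) basis
#'
#' Column `i` at time `t` is the running integral of the corresponding
#' M-spline basis function. Inside the boundary this uses the exact
#' B-spline identity relating the integral of an order-`k` basis to a sum
#' of order-`k+1` basis functions; beyond the upper boundary the last
#' column continues linearly with slope equal to the boundary value of the
#' last M-spline term, and all other columns are constant at 1.
#'
#' @inheritParams mspline_basis
#' @return Matrix of the same shape as [mspline_basis()]; each column is
#'   non-decreasing in `t` and 0 at `t = 0`.
#' @export
ispline_basis <- function(knots, times) {
  times <- as.numeric(times)
  if (any(times < 0)) stop("times must be non-negative")
  k <- knots$degree + 1L
  n <- nbasis(knots)
  aug2 <- aug_knots(knots, extra = 1L)
  tc <- pmin(times, knots$upper)
  B2 <- matrix(0, length(times), n + 1L)
  ins <- tc < knots$upper
  if (any(ins))
    B2[ins, ] <- splines::splineDesign(aug2, tc[ins], ord = k + 1L, outer.ok = TRUE)
  B2[!ins, n + 1L] <- 1
  I <- matrix(0, length(times), n)
  for (i in seq_len(n))
    I[, i] <- rowSums(B2[, (i + 1L):(n + 1L), drop = FALSE])
  over <- times > knots$upper
  if (any(over)) {
    aug <- aug_knots(knots)
    I[over, n] <- I[over, n] + (times[over] - knots$upper) * k / (knots$upper - aug[n])
  }
  I
}

#' Basis coefficients representing a constant hazard
#'
#' The coefficient vector proportional to the B-spline knot spans,
#' `p_i = (t_{i+k} - t_i) / sum_j (t_{j+k} - t_j)`, makes the weighted
#' M-spline sum exactly constant over the boundary interval (by the
#' B-spline partition of unity). For unequally spaced knots these weights
#' are not equal. The constant value `c` returned satisfies
#' `sum_i p_i b_i(t) = c`, so a model with scale `eta` has hazard
#' `eta * c`.
#'
#' @param knots An `mspline_knots` object.
#' @return List with `coefs` (non-negative, summing to 1) and `value`, the
#'   constant `c(knots)`.
#' @export
constant_hazard_coefs <- function(knots) {
  k <- knots$degree + 1L
  n <- nbasis(knots)
  aug <- aug_knots(knots)
  spans <- aug[(1:n) + k] - aug[1:n]
  list(coefs = spans / sum(spans), value = k / sum(spans))
}

## Multinomial-logit prior locations implying constant-hazard weights:
## mu_i = log(p_i / p_1) for i = 2..n.
constant_logit_means <- function(knots) {
  p <- constant_hazard_coefs(knots)$coefs
  log(p[-1] / p[1])
}
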