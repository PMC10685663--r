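## Extract a named covariate value vector from x (named vector, list, or
## 1-row data.frame); missing spec covariates are an error, absent x means 0.
cov_vector <- function(spec, x, which = spec$covariates) {
  if (!length(which)) return(numeric())
  if (is.null(x)) return(stats::setNames(rep(0, length(which)), which))
  if (is.data.frame(x)) x <- unlist(x[1, , drop = FALSE])
  x <- unlist(x)
  missing <- setdiff(which, names(x))
  if (length(missing)) stop("unknown/missing covariate value(s): ",
                            paste(missing, collapse = ", "))
  stats::setNames(as.numeric(x[which]), which)
}

#' Spline weights at a covariate value
#'
#' Computes the multinomial-logistic spline weights
#' `p_i(x) = softmax(0, gamma_2 + delta_2' x, ..., gamma_n + delta_n' x)`.
#' With `delta = 0` (or no non-proportional covariates) this reduces to the
#' covariate-free weights.
#'
#' @param draw A [parameter_draw()].
#' @param spec The matching [model_spec()].
#' @param x Covariate values (named vector or 1-row data.frame); `NULL`
#'   means all zero.
#' @return Positive weight vector of length `nbasis(spec$knots)`, summing
#'   to 1.
#' @export
spline_coefs <- function(draw, spec, x = NULL) {
  g <- draw$gamma
  if (!is.null(draw$delta)) {
    xs <- cov_vector(spec, x, spec$nonph)
    g <- g + drop(draw$delta[-1, , drop = FALSE] %*% xs)
  }
  e <- exp(c(0, g) - max(0, g))
  e / sum(e)
}

## eta(x) = exp(log_eta0 + beta' x)
eta_at <- function(draw, spec, x) {
  xb <- if (length(spec$covariates)) sum(draw$beta * cov_vector(spec, x)) else 0
  exp(draw$log_eta0 + xb)
}

## Base (spline) hazard/cumulative hazard at times, before mechanisms
base_haz <- function(draw, spec, times, x) {
  p <- spline_coefs(draw, spec, x)
  eta <- eta_at(draw, spec, x)
  list(h = eta * drop(mspline_basis(spec$knots, times) %*% p),
       H = eta * drop(ispline_basis(spec$knots, times) %*% p))
}

#' Mixture cure survival and hazard
#'
#' Given an uncured survival `S0` (and for the hazard, uncured hazard
#' `h0`), the mixture cure model has survival `p + (1 - p) S0(t)` and
#' hazard `(1 - p) f0(t) / (p + (1 - p) S0(t))` with `f0 = h0 S0`. As `t`
#' grows, survival converges to the cure probability `p` and the hazard to
#' zero.
#'
#' @param S0 Uncured survival values.
#' @param h0 Uncured hazard values (same length as `S0`).
#' @param cure_p Cure probability in `[0, 1]`.
#' @return `cure_survival`: survival values; `cure_hazard`: hazard values.
#' @export
cure_survival <- function(S0, cure_p) cure_p + (1 - cure_p) * S0

#' @rdname cure_survival
#' @export
cure_hazard <- function(h0, S0, cure_p) {
  (1 - cure_p) * h0 * S0 / cure_survival(S0, cure_p)
}

#' Combine a background hazard with an excess (cause-specific) model
#'
#' Additive hazards / relative survival: the overall hazard is the sum of
#' the known piecewise-constant background hazard and the modelled excess
#' hazard, and the survivor functions multiply. The background cumulative
#' hazard is computed exactly from the rate table (rate times interval
#' overlap); beyond the last breakpoint the final rate extends.
#'
#' @param bg A [background_hazard()].
#' @param times Evaluation times.
#' @param h_excess,S_excess Excess hazard and survival at `times`.
#' @return List with overall `h` and `S` at `times`.
#' @export
additive_combine <- function(bg, times, h_excess, S_excess) {
  list(h = bg_hazard_at(bg, times) + h_excess,
       S = exp(-bg_cumhaz_at(bg, times)) * S_excess)
}

## Full mechanism-composed hazard and survival in one pass
eval_model <- function(draw, spec, times, x = NULL) {
  times <- as.numeric(times)
  if (any(times < 0)) stop("times must be non-negative")
  b <- base_haz(draw, spec, times, x)
  S0 <- exp(-b$H)
  if (spec$cure != "none") {
    S <- cure_survival(S0, draw$cure_p)
    h <- cure_hazard(b$h, S0, draw$cure_p)
  } else {
    S <- S0; h <- b$h
  }
  if (!is.null(spec$background)) {
    out <- additive_combine(spec$background, times, h, S)
    h <- out$h; S <- out$S
  }
  list(h = h, S = S)
}

#' Hazard, cumulative hazard and survival of a fully specified model
#'
#' Evaluates `h(t | x)`, `H(t | x) = -log S(t | x)` and `S(t | x)` for one
#' parameter draw, with all mechanisms in the spec applied: the base
#' M-spline hazard `eta(x) sum_i p_i(x) b_i(t)` with proportional-hazards
#' scale `eta(x) = eta_0 exp(beta' x)`, then mixture cure, then the
#' additive background hazard. (Treatment-effect waning is a prediction
#' device, applied by [waning_predict()], never here.)
#'
#' @inheritParams spline_coefs
#' @param times Non-negative evaluation times.
#' @return Numeric vector of the same length as `times`.
#' @export
hazard <- function(draw, spec, times, x = NULL) eval_model(draw, spec, times, x)$h

#' @rdname hazard
#' @export
survival <- function(draw, spec, times, x = NULL) eval_model(draw, spec, times, x)$S

#' @rdname hazard
#' @export
cumhaz <- function(draw, spec, times, x = NULL) -log(eval_model(draw, spec, times, x)$S)

#' Waning hazard ratio
#'
#' The treatment-vs-control hazard ratio is held at its fitted value
#' `hr_tmin` up to `t_min`, then `log hr(t)` declines linearly to zero at
#' `t_max`, beyond which `hr(t) = 1`.
#'
#' @param times Evaluation times.
#' @param hr_tmin Positive hazard ratio at (and before) `t_min`.
#' @param w A [waning_spec()].
#' @return Hazard ratio values at `times`.
#' @export
waning_hr <- function(times, hr_tmin, w) {
  if (hr_tmin <= 0) stop("hr_tmin must be positive")
  frac <- pmin(1, pmax(0, (w$t_max - times) / (w$t_max - w$t_min)))
  exp(log(hr_tmin) * frac)
}

#' Specify treatment-effect waning
#'
#' @param t_min Time up to which the fitted hazard ratio applies;
#'   `0 < t_min < t_max`.
#' @param t_max Time at which the hazard ratio reaches 1.
#' @param treatment Name of the binary treatment covariate in the fitted
#'   model.
#' @return An object of class `"waning_spec"`.
#' @export
waning_spec <- function(t_min, t_max, treatment) {
  if (!(t_min > 0 && t_max > t_min)) stop("need 0 < t_min < t_max")
  structure(list(t_min = t_min, t_max = t_max, treatment = treatment),
            class = "waning_spec")
}

#' Per-observation log-likelihood contributions
#'
#' `loglik_individual`: an event row at time `t` contributes
#' `log h(t | x) - H(t | x)`; a censored row contributes `-H(t | x)`, with
#' the mechanism-adjusted hazard and cumulative hazard throughout.
#'
#' `loglik_external`: row `j` contributes the binomial log-density of `r_j`
#' out of `n_j` with success probability `q_j = S(v_j | x_j) / S(u_j | x_j)`
#' (survival over the interval conditional on being alive at its start).
#' The binomial coefficient uses log-gamma functions so real-valued counts
#' (from elicited Beta judgements) are admitted.
#'
#' @param data An [individual_data()] or [external_data()] table.
#' @param draw A [parameter_draw()].
#' @param spec The matching [model_spec()].
#' @return Numeric vector, one element per data row.
#' @export
loglik_individual <- function(data, draw, spec) {
  ll <- numeric(nrow(data))
  for (grp in split(seq_len(nrow(data)), covariate_key(data, spec))) {
    x <- row_cov(data, grp[1], spec)
    m <- eval_model(draw, spec, data$time[grp], x)
    ll[grp] <- data$event[grp] * log(m$h) + log(m$S)
  }
  ll
}

#' @rdname loglik_individual
#' @export
loglik_external <- function(data, draw, spec) {
  ll <- numeric(nrow(data))
  for (j in seq_len(nrow(data))) {
    x <- row_cov(data, j, spec)
    Su <- survival(draw, spec, data$u[j], x)
    Sv <- survival(draw, spec, data$v[j], x)
    if (Su <= 0) stop("no survivors possible at interval start (S(u) = 0) in row ", j)
    ll[j] <- binom_logkernel(data$r[j], data$n[j], Sv / Su)
  }
  ll
}

## continuous-binomial log density: lgamma coefficient + kernel, with
## 0*log(0) handled as 0
binom_logkernel <- function(r, n, q) {
  lc <- lgamma(n + 1) - lgamma(r + 1) - lgamma(n - r + 1)
  t1 <- if (r > 0) r * log(q) else 0
  t2 <- if (n - r > 0) (n - r) * log1p(-q) else 0
  lc + t1 + t2
}

## grouping key over the covariates a spec uses, for vectorised evaluation
covariate_key <- function(data, spec) {
  if (!length(spec$covariates)) return(rep(1L, nrow(data)))
  do.call(paste, c(lapply(spec$covariates, function(v) data[[v]]), sep = "\r"))
}

row_cov <- function(data, i, spec) {
  if (!length(spec$covariates)) return(NULL)
  stats::setNames(as.numeric(data[i, spec$covariates, drop = FALSE]), spec$covariates)
}
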