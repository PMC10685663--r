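## ---- vectorised posterior curve evaluation -------------------------------

check_profile <- function(spec, x) {
  if (is.null(x)) return(invisible())
  bad <- setdiff(names(unlist(x)), spec$covariates)
  if (length(bad)) stop("unknown profile covariate(s): ", paste(bad, collapse = ", "))
}

## spline-weight matrix (S draws x n) and scale vector at a profile
draw_weights <- function(fit, x = NULL) {
  spec <- fit$spec
  n <- nbasis(spec$knots)
  d <- fit$draws
  G <- d[, paste0("gamma", 2:n), drop = FALSE]
  if (length(spec$nonph)) {
    xs <- cov_vector(spec, x, spec$nonph)
    for (s in seq_along(spec$nonph)) {
      if (xs[s] != 0) {
        D <- d[, paste0("delta", 2:n, ".", spec$nonph[s]), drop = FALSE]
        G <- G + D * xs[s]
      }
    }
  }
  G <- cbind(0, G)
  E <- exp(G - apply(G, 1, max))
  P <- E / rowSums(E)
  xb <- 0
  if (length(spec$covariates)) {
    xv <- cov_vector(spec, x)
    xb <- drop(d[, paste0("beta.", spec$covariates), drop = FALSE] %*% xv)
  }
  list(P = P, eta = exp(d[, "log_eta0"] + xb),
       cure_p = if (spec$cure != "none") d[, "cure_p"] else NULL)
}

## hazard and survival matrices (times x draws) with mechanisms applied
curve_mats <- function(fit, times, x = NULL) {
  spec <- fit$spec
  check_profile(spec, x)
  dw <- draw_weights(fit, x)
  B <- mspline_basis(spec$knots, times)
  I <- ispline_basis(spec$knots, times)
  h0 <- sweep(B %*% t(dw$P), 2, dw$eta, "*")
  H0 <- sweep(I %*% t(dw$P), 2, dw$eta, "*")
  S0 <- exp(-H0)
  if (!is.null(dw$cure_p)) {
    pc <- matrix(dw$cure_p, length(times), length(dw$cure_p), byrow = TRUE)
    S <- pc + (1 - pc) * S0
    h <- (1 - pc) * h0 * S0 / S
  } else {
    S <- S0; h <- h0
  }
  if (!is.null(spec$background)) {
    h <- h + bg_hazard_at(spec$background, times)
    S <- S * exp(-bg_cumhaz_at(spec$background, times))
  }
  list(h = h, S = S)
}

row_quantiles <- function(M, level) {
  probs <- c(0.5, (1 - level) / 2, 1 - (1 - level) / 2)
  q <- t(apply(M, 1, stats::quantile, probs = probs, type = 7, names = FALSE))
  data.frame(median = q[, 1], lower = q[, 2], upper = q[, 3])
}

normalise_profiles <- function(profiles) {
  if (is.null(profiles)) return(list(baseline = NULL))
  if (!is.list(profiles) || is.data.frame(profiles))
    profiles <- split(as.data.frame(profiles), seq_len(nrow(as.data.frame(profiles))))
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    names(profiles) <- paste0("profile", seq_along(profiles))
  profiles
}

#' Tidy posterior summaries of survival and hazard curves
#'
#' Pointwise posterior medians and equal-tailed credible intervals of
#' `S(t | x)` or `h(t | x)`, computed draw-wise (each summary is a
#' quantile of per-draw curve values, never a curve of parameter
#' quantiles). One row per (time, profile).
#'
#' @param fit An `mspsurv_fit`.
#' @param times Non-negative evaluation times.
#' @param profiles Named list of covariate profiles (named vectors), or
#'   `NULL` for the baseline (all covariates zero).
#' @param level Credible level, default 0.95.
#' @return A tidy data.frame with columns `quantity`, `time`, `profile`,
#'   `median`, `lower`, `upper`.
#' @export
survival_summary <- function(fit, times, profiles = NULL, level = 0.95) {
  curve_summary(fit, times, profiles, level, "survival")
}

#' @rdname survival_summary
#' @export
hazard_summary <- function(fit, times, profiles = NULL, level = 0.95) {
  curve_summary(fit, times, profiles, level, "hazard")
}

curve_summary <- function(fit, times, profiles, level, quantity) {
  profiles <- normalise_profiles(profiles)
  out <- lapply(names(profiles), function(nm) {
    cm <- curve_mats(fit, times, profiles[[nm]])
    M <- if (quantity == "survival") cm$S else cm$h
    cbind(data.frame(quantity = quantity, time = times, profile = nm),
          row_quantiles(M, level))
  })
  do.call(rbind, out)
}

## ---- quadrature helpers --------------------------------------------------

## Gauss-Legendre nodes/weights on segments delimited by `breaks`
gl_segments <- function(breaks, q) {
  gq <- statmod::gauss.quad(q, kind = "legendre")
  nodes <- weights <- numeric(0)
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]; b <- breaks[i + 1]
    if (b <= a) next
    nodes <- c(nodes, (a + b) / 2 + (b - a) / 2 * gq$nodes)
    weights <- c(weights, (b - a) / 2 * gq$weights)
  }
  list(nodes = nodes, weights = weights)
}

rmst_breaks <- function(spec, horizon, extra = numeric()) {
  k <- spec$knots
  br <- c(0, k$internal, k$upper, extra, horizon)
  sort(unique(br[br >= 0 & br <= horizon]))
}

#' Restricted mean survival time and its treatment increment
#'
#' `rmst()` computes, per posterior draw, `RMST(T | x) = integral of
#' S(t | x) from 0 to T` by Gauss-Legendre quadrature on the spline's
#' knot-delimited segments, then summarises the draws. `irmst()` is the
#' draw-wise difference `RMST(T | treated) - RMST(T | control)`,
#' preserving the posterior correlation between arms.
#'
#' With a [waning_spec()], the profile is interpreted as the treated arm:
#' its hazard follows the fitted treated model up to `t_min`, then the
#' control hazard times a hazard ratio whose log declines linearly from
#' the fitted log hazard ratio at `t_min` to zero at `t_max`.
#'
#' @param fit An `mspsurv_fit`.
#' @param horizon Positive time horizon(s).
#' @param x Covariate profile (named vector) or `NULL`.
#' @param level Credible level, default 0.95.
#' @param waning Optional [waning_spec()] applied to the profile `x`.
#' @param q_nodes Gauss-Legendre nodes per segment, default 100.
#' @return Tidy data.frame, one row per horizon, with `median`, `lower`,
#'   `upper`.
#' @export
rmst <- function(fit, horizon, x = NULL, level = 0.95, waning = NULL,
                 q_nodes = 100) {
  stopifnot(all(horizon > 0))
  out <- lapply(horizon, function(H) {
    v <- rmst_draws(fit, H, x, waning, q_nodes)
    cbind(data.frame(quantity = "rmst", horizon = H,
                     profile = profile_label(x)),
          row_quantiles(matrix(v, 1), level))
  })
  do.call(rbind, out)
}

#' @rdname rmst
#' @param x_treated,x_control Covariate profiles of the two arms.
#' @export
irmst <- function(fit, horizon, x_treated, x_control, level = 0.95,
                  waning = NULL, q_nodes = 100) {
  stopifnot(all(horizon > 0))
  out <- lapply(horizon, function(H) {
    v1 <- rmst_draws(fit, H, x_treated, waning, q_nodes)
    v0 <- rmst_draws(fit, H, x_control, NULL, q_nodes)
    cbind(data.frame(quantity = "irmst", horizon = H,
                     profile = paste(profile_label(x_treated), "-",
                                     profile_label(x_control))),
          row_quantiles(matrix(v1 - v0, 1), level))
  })
  do.call(rbind, out)
}

profile_label <- function(x) {
  if (is.null(x)) return("baseline")
  x <- unlist(x)
  paste(paste0(names(x), "=", x), collapse = ",")
}

## per-draw RMST values at one horizon
rmst_draws <- function(fit, horizon, x, waning = NULL, q_nodes = 100) {
  extra <- if (!is.null(waning)) c(waning$t_min, waning$t_max) else numeric()
  gl <- gl_segments(rmst_breaks(fit$spec, horizon, extra), q_nodes)
  S <- if (is.null(waning)) {
    curve_mats(fit, gl$nodes, x)$S
  } else {
    waning_curve_mats(fit, waning, gl$nodes, x)$S
  }
  drop(gl$weights %*% S)
}

## ---- treatment-effect waning at prediction time --------------------------

## hazard and survival matrices for the treated arm under waning
waning_curve_mats <- function(fit, w, times, x_treated = NULL, q_inner = 8) {
  spec <- fit$spec
  if (!w$treatment %in% spec$covariates)
    stop("waning treatment covariate '", w$treatment, "' is not in the fitted model")
  x1 <- unlist(x_treated)
  if (is.null(x1) || !w$treatment %in% names(x1)) x1 <- c(x1, stats::setNames(1, w$treatment))
  x0 <- x1; x0[w$treatment] <- 0

  ## fitted hazard ratio per draw, anchored at t_min
  h1_t <- curve_mats(fit, w$t_min, x1)$h
  h0_t <- curve_mats(fit, w$t_min, x0)$h
  log_hr <- log(pmax(drop(h1_t / h0_t), .Machine$double.xmin))

  hmat <- function(tt) {
    pre <- tt <= w$t_min
    out <- matrix(NA_real_, length(tt), nrow(fit$draws))
    if (any(pre)) out[pre, ] <- curve_mats(fit, tt[pre], x1)$h
    if (any(!pre)) {
      h0 <- curve_mats(fit, tt[!pre], x0)$h
      frac <- pmin(1, pmax(0, (w$t_max - tt[!pre]) / (w$t_max - w$t_min)))
      out[!pre, ] <- h0 * exp(outer(frac, log_hr))
    }
    out
  }
  h <- hmat(times)
  ## cumulative hazard at `times` by per-segment quadrature of the waned
  ## hazard (exact fitted H up to t_min would match to quadrature accuracy)
  ts <- sort(unique(c(times, w$t_min, w$t_max, fit$spec$knots$internal,
                      fit$spec$knots$upper)))
  ts <- ts[ts > 0 & ts <= max(times)]
  segs <- c(0, ts)
  gq <- statmod::gauss.quad(q_inner, kind = "legendre")
  node_list <- lapply(seq_len(length(segs) - 1), function(i) {
    a <- segs[i]; b <- segs[i + 1]
    list(nodes = (a + b) / 2 + (b - a) / 2 * gq$nodes, w = (b - a) / 2 * gq$weights)
  })
  all_nodes <- unlist(lapply(node_list, `[[`, "nodes"))
  hn <- hmat(all_nodes)
  Hend <- matrix(0, length(segs) - 1, nrow(fit$draws))
  idx <- 0
  for (i in seq_along(node_list)) {
    q <- length(node_list[[i]]$nodes)
    Hend[i, ] <- node_list[[i]]$w %*% hn[idx + seq_len(q), , drop = FALSE]
    idx <- idx + q
  }
  Hcum <- apply(Hend, 2, cumsum)
  if (length(segs) == 2) Hcum <- matrix(Hcum, 1)
  H_at <- Hcum[match(times, ts), , drop = FALSE]
  H_at[times == 0, ] <- 0
  list(h = h, S = exp(-H_at))
}

#' Treated-arm predictions under treatment-effect waning
#'
#' Summaries of the treated arm's hazard and survival when the fitted
#' treatment effect is assumed to wane: up to `t_min` the fitted treated
#' model applies; from `t_min` to `t_max` the log hazard ratio declines
#' linearly to zero; after `t_max` treated and control hazards coincide.
#' The hazard ratio at `t_min` is taken draw-wise from the fitted model
#' (for a proportional-hazards effect this is `exp(beta)`; for a
#' non-proportional effect, the fitted hazard ratio evaluated at `t_min`).
#'
#' @param fit An `mspsurv_fit` whose spec includes the treatment covariate.
#' @param w A [waning_spec()].
#' @param times Evaluation times.
#' @param x Covariate profile of the treated arm (the treatment indicator
#'   is forced to 1; other covariates default to 0).
#' @param level Credible level, default 0.95.
#' @return Tidy data.frame of hazard and survival summaries.
#' @export
waning_predict <- function(fit, w, times, x = NULL, level = 0.95) {
  cm <- waning_curve_mats(fit, w, times, x)
  rbind(
    cbind(data.frame(quantity = "hazard", time = times, profile = "treated_waned"),
          row_quantiles(cm$h, level)),
    cbind(data.frame(quantity = "survival", time = times, profile = "treated_waned"),
          row_quantiles(cm$S, level))
  )
}

#' Kaplan-Meier estimate as a tidy table
#'
#' Product-limit estimate of the survivor function, optionally stratified,
#' for plotting alongside model output.
#'
#' @param data An [individual_data()] table.
#' @param group Optional name of a column in `data` to stratify by.
#' @return Data.frame with columns `group` (if any), `time`, `n_risk`,
#'   `n_event`, `estimate`.
#' @export
kaplan_meier <- function(data, group = NULL) {
  stopifnot(nrow(data) >= 1)
  df <- as.data.frame(data)
  if (is.null(group)) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
               estimate = sf$surv)
  } else {
    df$.g <- df[[group]]
    sf <- survival::survfit(survival::Surv(time, event) ~ .g, data = df)
    g <- rep(sub("^\\.g=", "", names(sf$strata)), sf$strata)
    data.frame(group = g, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, estimate = sf$surv)
  }
}
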