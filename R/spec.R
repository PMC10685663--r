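default_priors <- function() {
  list(
    log_eta0 = c(mean = 0, sd = 20),
    beta     = c(mean = 0, sd = 2.5),
    sigma    = c(shape = 2, rate = 1),
    tau      = c(shape = 2, rate = 1),
    cure     = c(a = 1, b = 1)
  )
}

#' Specify an M-spline survival model
#'
#' Collects everything that defines a model apart from its parameter
#' values: the spline basis, which covariates act on the hazard scale
#' (proportional hazards) and which additionally shift the spline weights
#' (non-proportional hazards), the optional mechanisms (additive background
#' hazard, mixture cure), and the prior hyperparameters.
#'
#' Default priors are weakly informative: Normal(0, 20) for the baseline
#' log scale, Normal(0, 2.5) for log hazard ratios, Gamma(2, 1) for the
#' smoothness scale `sigma` and for each non-proportionality scale `tau`,
#' and Beta(1, 1) for the cure probability.
#'
#' @param knots An [mspline_knots()] object.
#' @param covariates Character vector naming the covariates entering the
#'   hazard scale multiplicatively (log hazard ratios `beta`).
#' @param nonph Subset of `covariates` whose effect is allowed to be
#'   non-proportional, via shifts `delta` on the multinomial-logit spline
#'   weights with hierarchical Normal(0, tau) priors.
#' @param cure `"none"`, `"overall"` (mixture cure on the whole model), or
#'   `"excess"` (cure on the excess hazard inside the additive model;
#'   requires `background`).
#' @param background Optional [background_hazard()]; switches on the
#'   additive-hazards (relative survival) mechanism, where the modelled
#'   spline hazard is the excess over this known background.
#' @param priors Named list overriding any of `log_eta0` (mean, sd), `beta`
#'   (mean, sd), `sigma` (shape, rate), `tau` (shape, rate), `cure` (a, b).
#'
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(knots, covariates = character(), nonph = character(),
                       cure = c("none", "overall", "excess"),
                       background = NULL, priors = list()) {
  stopifnot(inherits(knots, "mspline_knots"))
  cure <- match.arg(cure)
  if (!all(nonph %in% covariates))
    stop("nonph covariates must be a subset of covariates")
  if (cure == "excess" && is.null(background))
    stop("cure on the excess hazard requires a background hazard (additive model)")
  if (cure == "overall" && !is.null(background))
    stop("mixture cure applies either to the overall hazard (no background) or to the excess hazard")
  if (!is.null(background)) stopifnot(inherits(background, "background_hazard"))
  pr <- default_priors()
  for (nm in names(priors)) {
    if (!nm %in% names(pr)) stop("unknown prior component: ", nm)
    pr[[nm]][] <- priors[[nm]]
  }
  structure(
    list(knots = knots, covariates = covariates, nonph = nonph,
         cure = cure, background = background, priors = pr),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("M-spline survival model specification\n")
  print(x$knots)
  if (length(x$covariates))
    cat("covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (length(x$nonph))
    cat("non-proportional:", paste(x$nonph, collapse = ", "), "\n")
  if (!is.null(x$background)) cat("additive background hazard: yes\n")
  if (x$cure != "none") cat("mixture cure:", x$cure, "\n")
  invisible(x)
}

#' One realisation of the model parameters
#'
#' @param spec A [model_spec()].
#' @param log_eta0 Baseline log hazard-scale.
#' @param beta Named log hazard ratios, one per `spec$covariates`.
#' @param gamma Multinomial-logit spline coefficients for basis terms
#'   `2..n` (the first is fixed at 0); length `nbasis - 1`.
#' @param sigma Positive smoothness scale.
#' @param delta Matrix (`nbasis` rows, one column per `spec$nonph`) of
#'   non-proportionality effects; the first row must be 0. May be omitted
#'   when there are no non-proportional covariates.
#' @param tau Positive scales, one per `spec$nonph`.
#' @param cure_p Cure probability in `[0, 1]`; required iff the spec has a
#'   cure mechanism.
#' @return An object of class `"parameter_draw"`.
#' @export
parameter_draw <- function(spec, log_eta0 = 0, beta = NULL, gamma = NULL,
                           sigma = 1, delta = NULL, tau = NULL, cure_p = NULL) {
  n <- nbasis(spec$knots)
  if (is.null(gamma)) gamma <- constant_logit_means(spec$knots)
  if (length(gamma) != n - 1) stop("gamma must have length nbasis - 1")
  if (sigma <= 0) stop("sigma must be positive")
  nc <- length(spec$covariates)
  if (is.null(beta)) beta <- stats::setNames(rep(0, nc), spec$covariates)
  if (length(beta) != nc) stop("beta length must match spec covariates")
  names(beta) <- spec$covariates
  ns <- length(spec$nonph)
  if (ns) {
    if (is.null(delta)) delta <- matrix(0, n, ns)
    delta <- as.matrix(delta)
    if (!all(dim(delta) == c(n, ns))) stop("delta must be nbasis x length(nonph)")
    if (any(delta[1, ] != 0)) stop("first row of delta must be 0")
    colnames(delta) <- spec$nonph
    if (is.null(tau)) tau <- rep(1, ns)
    if (any(tau <= 0)) stop("tau must be positive")
    tau <- stats::setNames(as.numeric(tau), spec$nonph)
  } else {
    delta <- NULL; tau <- NULL
  }
  if (spec$cure != "none") {
    if (is.null(cure_p)) stop("cure mechanism requires cure_p")
    if (cure_p < 0 || cure_p > 1) stop("cure_p must be in [0, 1]")
  } else cure_p <- NULL
  structure(
    list(log_eta0 = log_eta0, beta = beta, gamma = as.numeric(gamma),
         sigma = sigma, delta = delta, tau = tau, cure_p = cure_p),
    class = "parameter_draw"
  )
}

#' A draw whose hazard is exactly constant
#'
#' Convenience constructor: spline weights at the constant-hazard
#' coefficients and scale chosen so the hazard equals `rate`.
#'
#' @param spec A [model_spec()].
#' @param rate Target constant hazard (of the spline/excess part).
#' @param ... Passed to [parameter_draw()] (e.g. `beta`, `cure_p`).
#' @return A `"parameter_draw"`.
#' @export
constant_draw <- function(spec, rate, ...) {
  ch <- constant_hazard_coefs(spec$knots)
  parameter_draw(spec,
    log_eta0 = log(rate / ch$value),
    gamma = constant_logit_means(spec$knots), ...)
}

## ---- unconstrained parameter vector for sampling -------------------------
## Layout: log_eta0 | beta (nc) | eps (n-1, std logistic) | log_sigma |
##         z (n-1)*ns (std normal) | log_tau (ns) | logit_cure (0/1)
## gamma = mu + sigma * eps ; delta[i,s] = tau_s * z[i-1,s]

par_layout <- function(spec) {
  n <- nbasis(spec$knots); nc <- length(spec$covariates); ns <- length(spec$nonph)
  nms <- c("log_eta0",
           if (nc) paste0("beta.", spec$covariates),
           paste0("eps", 2:n),
           "log_sigma",
           if (ns) paste0("z", rep(2:n, ns), ".", rep(spec$nonph, each = n - 1)),
           if (ns) paste0("log_tau.", spec$nonph),
           if (spec$cure != "none") "logit_cure")
  list(names = nms, n = n, nc = nc, ns = ns,
       i_eta = 1L,
       i_beta = if (nc) 1L + seq_len(nc) else integer(),
       i_eps = 1L + nc + seq_len(n - 1),
       i_lsig = 1L + nc + n,
       i_z = if (ns) 1L + nc + n + seq_len((n - 1) * ns) else integer(),
       i_ltau = if (ns) 1L + nc + n + (n - 1) * ns + seq_len(ns) else integer(),
       i_cure = if (spec$cure != "none") 1L + nc + n + (n - 1) * ns + ns + 1L else integer())
}

uncon_to_draw <- function(spec, th, layout = par_layout(spec)) {
  L <- layout
  sigma <- exp(th[L$i_lsig])
  mu <- constant_logit_means(spec$knots)
  gamma <- mu + sigma * th[L$i_eps]
  delta <- tau <- NULL
  if (L$ns) {
    tau <- exp(th[L$i_ltau])
    z <- matrix(th[L$i_z], L$n - 1, L$ns)
    delta <- rbind(0, sweep(z, 2, tau, "*"))
  }
  parameter_draw(spec,
    log_eta0 = th[L$i_eta],
    beta = if (L$nc) th[L$i_beta] else NULL,
    gamma = gamma, sigma = sigma, delta = delta, tau = tau,
    cure_p = if (length(L$i_cure)) stats::plogis(th[L$i_cure]) else NULL)
}

## log prior density of the unconstrained vector (includes Jacobians)
logprior_uncon <- function(spec, th, layout = par_layout(spec)) {
  L <- layout; pr <- spec$priors
  lp <- stats::dnorm(th[L$i_eta], pr$log_eta0["mean"], pr$log_eta0["sd"], log = TRUE)
  if (L$nc)
    lp <- lp + sum(stats::dnorm(th[L$i_beta], pr$beta["mean"], pr$beta["sd"], log = TRUE))
  lp <- lp + sum(stats::dlogis(th[L$i_eps], log = TRUE))
  sigma <- exp(th[L$i_lsig])
  lp <- lp + stats::dgamma(sigma, pr$sigma["shape"], pr$sigma["rate"], log = TRUE) + th[L$i_lsig]
  if (L$ns) {
    lp <- lp + sum(stats::dnorm(th[L$i_z], log = TRUE))
    tau <- exp(th[L$i_ltau])
    lp <- lp + sum(stats::dgamma(tau, pr$tau["shape"], pr$tau["rate"], log = TRUE) + th[L$i_ltau])
  }
  if (length(L$i_cure)) {
    p <- stats::plogis(th[L$i_cure])
    lp <- lp + stats::dbeta(p, pr$cure["a"], pr$cure["b"], log = TRUE) +
      log(p) + log1p(-p)
  }
  unname(lp)
}

#' Log prior density of a parameter draw
#'
#' Sum of the model's prior log-densities evaluated at the draw: logistic
#' priors `gamma_i ~ Logistic(mu_i, sigma)` with locations implying a
#' constant hazard, Normal priors for the baseline log scale and log
#' hazard ratios, Gamma for `sigma` and each `tau`, Normal(0, tau) for the
#' non-proportionality effects, and Beta for the cure probability if
#' present.
#'
#' @param draw A [parameter_draw()].
#' @param spec The matching [model_spec()].
#' @return Scalar log density; `-Inf` if `sigma <= 0`.
#' @export
logprior <- function(draw, spec) {
  if (draw$sigma <= 0) return(-Inf)
  pr <- spec$priors
  mu <- constant_logit_means(spec$knots)
  lp <- sum(stats::dlogis(draw$gamma, mu, draw$sigma, log = TRUE)) +
    stats::dnorm(draw$log_eta0, pr$log_eta0["mean"], pr$log_eta0["sd"], log = TRUE) +
    stats::dgamma(draw$sigma, pr$sigma["shape"], pr$sigma["rate"], log = TRUE)
  if (length(draw$beta))
    lp <- lp + sum(stats::dnorm(draw$beta, pr$beta["mean"], pr$beta["sd"], log = TRUE))
  if (!is.null(draw$delta)) {
    lp <- lp + sum(stats::dnorm(sweep(draw$delta[-1, , drop = FALSE], 2, draw$tau, "/"),
                                log = TRUE)) - (nrow(draw$delta) - 1) * sum(log(draw$tau))
    lp <- lp + sum(stats::dgamma(draw$tau, pr$tau["shape"], pr$tau["rate"], log = TRUE))
  }
  if (!is.null(draw$cure_p))
    lp <- lp + stats::dbeta(draw$cure_p, pr$cure["a"], pr$cure["b"], log = TRUE)
  unname(lp)
}
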