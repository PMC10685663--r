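## small reusable fixtures, all built in code

kn_toy <- function() mspline_knots(internal = c(1, 2, 4), lower = 0, upper = 8)

spec_toy <- function(...) model_spec(kn_toy(), ...)

## a random valid knot set for property-style tests
rand_knots <- function() {
  m <- sample(1:5, 1)
  internal <- sort(round(runif(m, 0.2, 9.8), 3))
  internal <- unique(internal)
  mspline_knots(internal = internal, lower = 0, upper = 10,
                degree = sample(1:3, 1))
}

## a random parameter draw for a given spec
rand_draw <- function(spec) {
  n <- nbasis(spec$knots)
  ns <- length(spec$nonph)
  parameter_draw(spec,
    log_eta0 = rnorm(1, -1, 0.5),
    beta = if (length(spec$covariates)) rnorm(length(spec$covariates), 0, 0.5) else NULL,
    gamma = rnorm(n - 1, 0, 1),
    sigma = rgamma(1, 2, 2),
    delta = if (ns) rbind(0, matrix(rnorm((n - 1) * ns, 0, 0.5), n - 1, ns)) else NULL,
    tau = if (ns) rgamma(ns, 2, 2) else NULL,
    cure_p = if (spec$cure != "none") runif(1, 0.05, 0.5) else NULL)
}

quiet_fit <- function(...) suppressWarnings(fit_mspline(...))

## a fit-like object holding given parameter draws, for draw-wise output
## machinery (posterior "collapsed" to known values)
fit_from_draws <- function(spec, draws_list) {
  n <- nbasis(spec$knots)
  rows <- lapply(draws_list, function(d) {
    row <- c(log_eta0 = d$log_eta0, sigma = d$sigma,
             stats::setNames(d$gamma, paste0("gamma", 2:n)))
    if (length(spec$covariates))
      row <- c(row, stats::setNames(d$beta, paste0("beta.", spec$covariates)))
    if (length(spec$nonph)) {
      row <- c(row, stats::setNames(d$tau, paste0("tau.", spec$nonph)))
      row <- c(row, stats::setNames(as.vector(d$delta[-1, , drop = FALSE]),
        paste0("delta", rep(2:n, length(spec$nonph)), ".",
               rep(spec$nonph, each = n - 1))))
    }
    if (spec$cure != "none") row <- c(row, cure_p = d$cure_p)
    row
  })
  draws <- do.call(rbind, rows)
  structure(list(draws = draws, chain = rep(1L, nrow(draws)),
                 iteration = seq_len(nrow(draws)), n_chains = 1L,
                 spec = spec), class = "mspsurv_fit")
}

## exponential individual data with independent exponential censoring
sim_exp_data <- function(n, rate, cens_rate = NULL, seed = 1) {
  set.seed(seed)
  tt <- rexp(n, rate)
  if (is.null(cens_rate)) return(individual_data(tt, rep(1, n)))
  cc <- rexp(n, cens_rate)
  individual_data(pmin(tt, cc), as.numeric(tt <= cc))
}
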