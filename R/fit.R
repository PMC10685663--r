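#' Fit a Bayesian M-spline survival model
#'
#' Samples the joint posterior of the model defined by `spec`, given
#' right-censored individual-level data and/or external aggregate survivor
#' counts. The posterior is proportional to
#' `exp(sum loglik_individual + sum loglik_external + logprior)`. Sampling
#' uses an in-package Hamiltonian Monte Carlo algorithm with analytic
#' gradients on an unconstrained parameterisation (non-centred spline
#' coefficients, log-transformed scales); the mass matrix and step size
#' are adapted during warmup and frozen afterwards. Convergence is summarised by the
#' potential scale reduction factor (Rhat, requires `chains >= 2`) and
#' effective sample size per parameter.
#'
#' @param individual An [individual_data()] table, or `NULL`.
#' @param external An [external_data()] table, or `NULL`.
#' @param spec A [model_spec()].
#' @param chains Number of MCMC chains (run serially), default 2.
#' @param warmup Adaptation iterations per chain, discarded; default 1000.
#' @param iter Kept iterations per chain, default 1000.
#' @param seed Integer seed; required, so that every fit is reproducible.
#' @param rhat_warn Warn if any parameter's Rhat exceeds this; default 1.05.
#'
#' @return An object of class `"mspsurv_fit"`: the posterior draws (matrix
#'   with one named column per scalar parameter plus `chain` and
#'   `iteration`), the pointwise log-likelihood matrix (one column per
#'   individual row then per external row), the spec and data, and
#'   per-parameter diagnostics.
#' @export
fit_mspline <- function(individual = NULL, external = NULL, spec,
                        chains = 2, warmup = 1000, iter = 1000, seed,
                        rhat_warn = 1.05) {
  if (missing(seed)) stop("a seed is required for a reproducible fit")
  stopifnot(inherits(spec, "model_spec"))
  ctx <- build_context(spec, individual, external)
  L <- ctx$L
  lp <- function(th) ctx_logpost(th, ctx)
  lpgrad <- function(th) ctx_logpost_grad(th, ctx)

  ## precondition the sampler with the posterior mode and curvature
  set.seed(seed)
  mode <- posterior_mode(lp, initial_values(ctx, jitter = 0))

  chain_draws <- vector("list", chains)
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    init <- if (is.null(mode$R)) {
      initial_values(ctx, jitter = 0.3)
    } else {
      mode$mode + drop(stats::rnorm(length(mode$mode)) %*% mode$R)
    }
    ## retry with smaller jitter if the start is degenerate
    tries <- 0
    while (!is.finite(lp(init)) && tries < 20) {
      init <- mode$mode + 0.01 * stats::rnorm(length(mode$mode))
      tries <- tries + 1
    }
    res <- hmc_chain(lpgrad, init, warmup, iter, R0 = mode$R)
    chain_draws[[ch]] <- res$draws
    accept[ch] <- res$accept
  }

  uncon <- do.call(rbind, chain_draws)
  colnames(uncon) <- L$names
  draws <- constrain_draws(spec, uncon, L)
  chain <- rep(seq_len(chains), each = iter)
  iteration <- rep(seq_len(iter), chains)

  ## pointwise log likelihood for cross-validation
  pw <- t(apply(uncon, 1, ctx_loglik, ctx = ctx, pointwise = TRUE))
  if (nrow(uncon) == 1) pw <- matrix(pw, nrow = 1)

  diagnostics <- mcmc_diagnostics(draws, chain, chains)
  if (any(diagnostics$rhat > rhat_warn, na.rm = TRUE))
    warning("possible non-convergence: max Rhat = ",
            round(max(diagnostics$rhat, na.rm = TRUE), 3),
            "; consider more warmup/iterations")

  structure(
    list(draws = draws, chain = chain, iteration = iteration,
         n_chains = chains, spec = spec,
         individual = individual, external = external,
         pointwise_loglik = pw, diagnostics = diagnostics,
         accept = accept, seed = seed, warmup = warmup, iter = iter),
    class = "mspsurv_fit"
  )
}

## unconstrained sample matrix -> named constrained parameter matrix
constrain_draws <- function(spec, uncon, L = par_layout(spec)) {
  mu <- constant_logit_means(spec$knots)
  n <- L$n
  sigma <- exp(uncon[, L$i_lsig])
  gamma <- uncon[, L$i_eps, drop = FALSE] * sigma + matrix(mu, nrow(uncon), n - 1, byrow = TRUE)
  colnames(gamma) <- paste0("gamma", 2:n)
  out <- cbind(log_eta0 = uncon[, L$i_eta], sigma = sigma, gamma)
  if (L$nc) {
    beta <- uncon[, L$i_beta, drop = FALSE]
    colnames(beta) <- paste0("beta.", spec$covariates)
    out <- cbind(out, beta)
  }
  if (L$ns) {
    tau <- exp(uncon[, L$i_ltau, drop = FALSE])
    colnames(tau) <- paste0("tau.", spec$nonph)
    z <- uncon[, L$i_z, drop = FALSE]
    delta <- z * tau[, rep(seq_len(L$ns), each = n - 1), drop = FALSE]
    colnames(delta) <- paste0("delta", rep(2:n, L$ns), ".", rep(spec$nonph, each = n - 1))
    out <- cbind(out, tau, delta)
  }
  if (length(L$i_cure)) out <- cbind(out, cure_p = stats::plogis(uncon[, L$i_cure]))
  out
}

mcmc_diagnostics <- function(draws, chain, chains) {
  per_chain <- lapply(split(seq_along(chain), chain), function(idx)
    coda::mcmc(draws[idx, , drop = FALSE]))
  ml <- coda::mcmc.list(per_chain)
  ess <- tryCatch(coda::effectiveSize(ml), error = function(e) rep(NA_real_, ncol(draws)))
  rhat <- rep(NA_real_, ncol(draws))
  if (chains >= 2) {
    gd <- tryCatch(coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE),
                   error = function(e) NULL)
    if (!is.null(gd)) rhat <- gd$psrf[, 1]
  }
  data.frame(parameter = colnames(draws), rhat = unname(rhat), ess = unname(ess),
             row.names = NULL)
}

#' Extract one posterior draw as a parameter object
#'
#' @param fit An `mspsurv_fit`.
#' @param i Draw index (row of the draws matrix).
#' @return A [parameter_draw()].
#' @export
posterior_draw <- function(fit, i) {
  d <- fit$draws[i, ]
  spec <- fit$spec
  n <- nbasis(spec$knots)
  ns <- length(spec$nonph)
  delta <- NULL
  if (ns) {
    delta <- rbind(0, matrix(d[paste0("delta", rep(2:n, ns), ".",
                                      rep(spec$nonph, each = n - 1))], n - 1, ns))
  }
  parameter_draw(spec,
    log_eta0 = d[["log_eta0"]],
    beta = if (length(spec$covariates)) d[paste0("beta.", spec$covariates)] else NULL,
    gamma = d[paste0("gamma", 2:n)],
    sigma = d[["sigma"]],
    delta = delta,
    tau = if (ns) d[paste0("tau.", spec$nonph)] else NULL,
    cure_p = if (spec$cure != "none") d[["cure_p"]] else NULL)
}

#' @export
print.mspsurv_fit <- function(x, ...) {
  cat("Bayesian M-spline survival model fit\n")
  cat(sprintf("  %d chains x %d kept draws (warmup %d), seed %d\n",
              x$n_chains, x$iter, x$warmup, x$seed))
  cat(sprintf("  %d individual rows, %d external rows\n",
              if (is.null(x$individual)) 0L else nrow(x$individual),
              if (is.null(x$external)) 0L else nrow(x$external)))
  cat(sprintf("  mean acceptance %.2f; max Rhat %.3f; min ESS %.0f\n",
              mean(x$accept), suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
              suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE))))
  print(x$spec)
  invisible(x)
}

#' Posterior draws as a tidy data frame
#'
#' One row per draw, one column per scalar parameter, plus `chain` and
#' `iteration` columns; suitable for writing to a draws CSV.
#'
#' @param fit An `mspsurv_fit`.
#' @return A data.frame.
#' @export
as_draws_df <- function(fit) {
  cbind(data.frame(chain = fit$chain, iteration = fit$iteration),
        as.data.frame(fit$draws))
}
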