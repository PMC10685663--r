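## Hamiltonian Monte Carlo sampler (single chain) with analytic gradients.
##
## The mass matrix is the inverse of a proposal covariance Sigma = t(R) R:
## initialised from the curvature at the posterior mode, then re-estimated
## once mid-warmup from the chain's empirical covariance. The step size is
## tuned by Nesterov dual averaging towards a target acceptance rate
## during warmup; the number of leapfrog steps is jittered uniformly to
## avoid resonance. All tuning is frozen for the sampling phase.
hmc_chain <- function(lpgrad, init, warmup, iter, R0 = NULL,
                      L_max = 15L, target_accept = 0.8) {
  d <- length(init)
  th <- init
  cur <- lpgrad(th)
  if (!is.finite(cur$lp)) stop("initial value has zero posterior density")
  R <- if (is.null(R0)) diag(d) else R0     # chol factor: Sigma = t(R) R

  ## dual averaging state (Hoffman & Gelman 2014 defaults)
  eps <- 0.5
  da_mu <- log(10 * eps); da_Hbar <- 0; da_lebar <- 0; da_m <- 0
  da_gamma <- 0.05; da_t0 <- 10; da_kappa <- 0.75

  metric_at <- max(100L, floor(0.5 * warmup))
  hist <- matrix(NA_real_, warmup, d)
  draws <- matrix(NA_real_, iter, d)
  n_acc <- 0L; n_div <- 0L

  for (i in seq_len(warmup + iter)) {
    if (i == metric_at && metric_at > 60) {
      H <- hist[floor(metric_at / 3):(i - 1), , drop = FALSE]
      R2 <- tryCatch(chol(stats::cov(H) + diag(1e-10, d)), error = function(e) NULL)
      if (!is.null(R2)) {
        R <- R2
        ## restart step-size adaptation for the new metric
        eps <- 0.5; da_mu <- log(10 * eps)
        da_Hbar <- 0; da_lebar <- 0; da_m <- 0
      }
    }
    p <- backsolve(R, stats::rnorm(d))           # momentum ~ N(0, Sigma^-1)
    Rp <- R %*% p
    K0 <- 0.5 * sum(Rp^2)
    H0 <- -cur$lp + K0

    L <- sample.int(L_max, 1)
    thp <- th; grd <- cur$grad; lp2 <- cur$lp
    pv <- p
    diverged <- FALSE
    for (s in seq_len(L)) {
      pv <- pv + 0.5 * eps * grd
      thp <- thp + eps * drop(crossprod(R, R %*% pv))   # Sigma %*% p
      nxt <- lpgrad(thp)
      if (!is.finite(nxt$lp)) { diverged <- TRUE; break }
      grd <- nxt$grad; lp2 <- nxt$lp
      pv <- pv + 0.5 * eps * grd
    }
    if (diverged) {
      acc_prob <- 0
      n_div <- n_div + 1L
    } else {
      Rp1 <- R %*% pv
      H1 <- -lp2 + 0.5 * sum(Rp1^2)
      acc_prob <- if (is.finite(H1)) min(1, exp(H0 - H1)) else 0
    }
    if (stats::runif(1) < acc_prob) {
      th <- thp
      cur <- list(lp = lp2, grad = grd)
      if (i > warmup) n_acc <- n_acc + 1L
    }
    if (i <= warmup) {
      hist[i, ] <- th
      ## dual averaging step-size update
      da_m <- da_m + 1
      da_Hbar <- (1 - 1 / (da_m + da_t0)) * da_Hbar +
        (target_accept - acc_prob) / (da_m + da_t0)
      log_eps <- da_mu - sqrt(da_m) / da_gamma * da_Hbar
      w <- da_m^(-da_kappa)
      da_lebar <- w * log_eps + (1 - w) * da_lebar
      eps <- exp(log_eps)
      if (i == warmup) eps <- exp(da_lebar)
    } else {
      draws[i - warmup, ] <- th
    }
  }
  list(draws = draws, accept = n_acc / iter, divergences = n_div,
       step_size = eps)
}

## crude but robust starting values, jittered per chain
initial_values <- function(ctx, jitter = 0.3) {
  L <- ctx$L
  th <- numeric(length(L$names))
  names(th) <- L$names
  ## start the scale near the crude event rate (constant-hazard weights)
  rate <- 0.1
  if (ctx$n_ind && sum(ctx$event) > 0) {
    rate <- sum(ctx$event) / max(sum(ctx$t_ind), 1e-8)
  } else if (ctx$n_ext) {
    q <- pmax(pmin(ctx$r / ctx$nn, 1 - 1e-6), 1e-6)
    rate <- mean(-log(q))   # per unit time if intervals are ~1 unit; crude
  }
  cc <- constant_hazard_coefs(ctx$spec$knots)$value
  th[L$i_eta] <- log(max(rate, 1e-6) / cc)
  th[L$i_lsig] <- log(0.5)
  th + stats::rnorm(length(th), 0, jitter)
}

## Locate the posterior mode and a curvature-based proposal covariance
## (inverse Hessian at the mode) to precondition the sampler's metric.
posterior_mode <- function(logpost, init) {
  neg <- function(th) {
    v <- logpost(th)
    if (!is.finite(v)) 1e10 else -v
  }
  opt <- tryCatch(
    stats::optim(init, neg, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt)) return(list(mode = init, R = NULL))
  R <- tryCatch({
    H <- pracma::hessian(neg, opt$par)
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE)
    lam <- pmax(ev$values, max(ev$values) * 1e-8, 1e-8)
    Sigma <- ev$vectors %*% (t(ev$vectors) / lam)
    chol((Sigma + t(Sigma)) / 2)
  }, error = function(e) NULL)
  list(mode = opt$par, R = R)
}
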