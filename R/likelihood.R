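## Precomputed quantities for repeated likelihood evaluation during
## sampling: spline basis matrices at the data times, covariate design
## matrices, background hazard values. Individuals sharing a
## non-proportional covariate pattern share a spline-weight vector.
build_context <- function(spec, individual = NULL, external = NULL) {
  L <- par_layout(spec)
  mu <- constant_logit_means(spec$knots)
  ctx <- list(spec = spec, L = L, mu = mu,
              n_ind = if (is.null(individual)) 0L else nrow(individual),
              n_ext = if (is.null(external)) 0L else nrow(external))
  if (ctx$n_ind + ctx$n_ext == 0) stop("no data: need at least one individual or external row")

  design <- function(data) {
    if (!length(spec$covariates)) return(matrix(0, nrow(data), 0))
    missing <- setdiff(spec$covariates, names(data))
    if (length(missing)) stop("data lack covariate(s): ", paste(missing, collapse = ", "))
    as.matrix(data[spec$covariates])
  }
  nonph_groups <- function(X) {
    if (!length(spec$nonph)) return(list(gid = rep(1L, nrow(X)), Gx = matrix(0, 1, 0)))
    Xn <- X[, spec$nonph, drop = FALSE]
    key <- do.call(paste, c(as.data.frame(Xn), sep = "\r"))
    uk <- !duplicated(key)
    list(gid = match(key, key[uk]), Gx = Xn[uk, , drop = FALSE])
  }

  if (ctx$n_ind) {
    ctx$event <- individual$event
    ctx$t_ind <- individual$time
    ctx$Xi <- design(individual)
    g <- nonph_groups(ctx$Xi)
    ctx$gid_i <- g$gid; ctx$Gx_i <- g$Gx
    ctx$B <- mspline_basis(spec$knots, individual$time)
    ctx$I <- ispline_basis(spec$knots, individual$time)
    if (!is.null(spec$background)) {
      ctx$hb <- bg_hazard_at(spec$background, individual$time)
      ctx$Hb <- bg_cumhaz_at(spec$background, individual$time)
    }
  }
  if (ctx$n_ext) {
    ctx$r <- external$r; ctx$nn <- external$n
    ctx$Xe <- design(external)
    g <- nonph_groups(ctx$Xe)
    ctx$gid_e <- g$gid; ctx$Gx_e <- g$Gx
    ctx$Iu <- ispline_basis(spec$knots, external$u)
    ctx$Iv <- ispline_basis(spec$knots, external$v)
    if (!is.null(spec$background)) {
      ctx$dHb <- bg_cumhaz_at(spec$background, external$v) -
        bg_cumhaz_at(spec$background, external$u)
    } else ctx$dHb <- rep(0, ctx$n_ext)
  }
  ctx
}

## spline-weight matrix (one row per nonph covariate pattern)
weights_by_group <- function(gamma, delta_free, Gx) {
  ng <- nrow(Gx)
  G <- matrix(gamma, ng, length(gamma), byrow = TRUE)
  if (ncol(Gx)) G <- G + Gx %*% t(delta_free)
  E <- exp(cbind(0, G) - apply(cbind(0, G), 1, max))
  E / rowSums(E)
}

## per-observation log likelihood at an unconstrained parameter vector
ctx_loglik <- function(th, ctx, pointwise = FALSE) {
  L <- ctx$L; spec <- ctx$spec
  sigma <- exp(th[L$i_lsig])
  gamma <- ctx$mu + sigma * th[L$i_eps]
  beta <- th[L$i_beta]
  delta_free <- if (L$ns) {
    sweep(matrix(th[L$i_z], L$n - 1, L$ns), 2, exp(th[L$i_ltau]), "*")
  } else matrix(0, L$n - 1, 0)
  pc <- if (length(L$i_cure)) stats::plogis(th[L$i_cure]) else NULL

  ll_ind <- numeric(0)
  if (ctx$n_ind) {
    P <- weights_by_group(gamma, delta_free, ctx$Gx_i)
    eta <- exp(th[L$i_eta] + if (L$nc) drop(ctx$Xi %*% beta) else 0)
    if (nrow(P) == 1L) {
      h0 <- eta * drop(ctx$B %*% P[1, ])
      H0 <- eta * drop(ctx$I %*% P[1, ])
    } else {
      Pi <- P[ctx$gid_i, , drop = FALSE]
      h0 <- eta * rowSums(ctx$B * Pi)
      H0 <- eta * rowSums(ctx$I * Pi)
    }
    if (!is.null(pc)) {
      S0 <- exp(-H0)
      Sc <- pc + (1 - pc) * S0
      h <- (1 - pc) * h0 * S0 / Sc
      H <- -log(Sc)
    } else {
      h <- h0; H <- H0
    }
    if (!is.null(spec$background)) {
      h <- h + ctx$hb
      H <- H + ctx$Hb
    }
    ll_ind <- ctx$event * log(h) - H
  }
  ll_ext <- numeric(0)
  if (ctx$n_ext) {
    P <- weights_by_group(gamma, delta_free, ctx$Gx_e)
    eta <- exp(th[L$i_eta] + if (L$nc) drop(ctx$Xe %*% beta) else 0)
    if (nrow(P) == 1L) {
      Hu <- eta * drop(ctx$Iu %*% P[1, ])
      Hv <- eta * drop(ctx$Iv %*% P[1, ])
    } else {
      Pe <- P[ctx$gid_e, , drop = FALSE]
      Hu <- eta * rowSums(ctx$Iu * Pe)
      Hv <- eta * rowSums(ctx$Iv * Pe)
    }
    if (!is.null(pc)) {
      Scu <- pc + (1 - pc) * exp(-Hu)
      Scv <- pc + (1 - pc) * exp(-Hv)
      q <- (Scv / Scu) * exp(-ctx$dHb)
    } else {
      q <- exp(-(Hv - Hu) - ctx$dHb)
    }
    q <- pmin(q, 1)
    lc <- lgamma(ctx$nn + 1) - lgamma(ctx$r + 1) - lgamma(ctx$nn - ctx$r + 1)
    t1 <- ifelse(ctx$r > 0, ctx$r * log(q), 0)
    t2 <- ifelse(ctx$nn - ctx$r > 0, (ctx$nn - ctx$r) * log1p(-q), 0)
    ll_ext <- lc + t1 + t2
  }
  if (pointwise) return(c(ll_ind, ll_ext))
  s <- sum(ll_ind) + sum(ll_ext)
  if (!is.finite(s)) -Inf else s
}

ctx_logpost <- function(th, ctx) {
  lp <- logprior_uncon(ctx$spec, th, ctx$L)
  if (!is.finite(lp)) return(-Inf)
  lp + ctx_loglik(th, ctx)
}

## Joint log posterior and its analytic gradient on the unconstrained
## scale, for gradient-based sampling. Derivatives propagate through the
## softmax spline weights, the non-centred (eps, log_sigma) and
## (z, log_tau) parameterisations, the logit cure fraction, and both data
## likelihoods; mechanisms (cure, additive background) follow the chain
## rule through S0 = exp(-H0).
ctx_logpost_grad <- function(th, ctx) {
  L <- ctx$L; spec <- ctx$spec; pr <- spec$priors
  n <- L$n
  sigma <- exp(th[L$i_lsig])
  eps <- th[L$i_eps]
  gamma <- ctx$mu + sigma * eps
  beta <- th[L$i_beta]
  if (L$ns) {
    tau <- exp(th[L$i_ltau])
    zmat <- matrix(th[L$i_z], n - 1, L$ns)
    delta_free <- sweep(zmat, 2, tau, "*")
  } else delta_free <- matrix(0, n - 1, 0)
  has_cure <- length(L$i_cure) > 0
  pc <- if (has_cure) stats::plogis(th[L$i_cure]) else 0

  g <- numeric(length(th))
  lp <- 0
  grad_gamma <- numeric(n - 1)
  grad_dfree <- matrix(0, n - 1, max(L$ns, 1))
  grad_pc <- 0

  piece <- function(B, I, X, gid, Gx, event = NULL, Hb = NULL, hb = NULL,
                    ext = NULL) {
    ## returns list(lp, d_a, d_beta (vec), dgvec (G x n), d_pc)
    P <- weights_by_group(gamma, delta_free, Gx)
    one <- nrow(P) == 1L
    eta <- exp(th[L$i_eta] + if (L$nc) drop(X %*% beta) else 0)
    if (is.null(ext)) {
      if (one) {
        bp <- drop(B %*% P[1, ]); ip <- drop(I %*% P[1, ])
      } else {
        Pi <- P[gid, , drop = FALSE]
        bp <- rowSums(B * Pi); ip <- rowSums(I * Pi)
      }
      h0 <- eta * bp; H0 <- eta * ip
      if (has_cure) {
        S0 <- exp(-H0)
        Sc <- pc + (1 - pc) * S0
        h <- (1 - pc) * h0 * S0 / Sc
        H <- -log(Sc)
      } else {
        h <- h0; H <- H0
      }
      if (!is.null(hb)) { h <- h + hb; H <- H + Hb }
      lpv <- sum(event * log(h) - H)
      dh <- event / h                          # dll/dh (overall)
      if (has_cure) {
        A <- dh * (1 - pc) * S0 / Sc
        C <- -dh * (1 - pc) * h0 * pc * S0 / Sc^2 - (1 - pc) * S0 / Sc
        dpc <- sum(dh * h0 * S0 * (-Sc - (1 - pc) * (1 - S0)) / Sc^2 +
                     (1 - S0) / Sc)
      } else {
        A <- dh
        C <- rep(-1, length(h))
        dpc <- 0
      }
      W <- A * h0 + C * H0
      d_a <- sum(W)
      d_beta <- if (L$nc) drop(W %*% X) else numeric()
      U <- if (one) {
        rbind(drop(crossprod(B, A * eta)) + drop(crossprod(I, C * eta)))
      } else {
        rowsum(B * (A * eta), gid) + rowsum(I * (C * eta), gid)
      }
    } else {
      ## external: ext = list(r, nn, Iu, Iv, dHb)
      if (one) {
        Hu <- eta * drop(ext$Iu %*% P[1, ]); Hv <- eta * drop(ext$Iv %*% P[1, ])
      } else {
        Pi <- P[gid, , drop = FALSE]
        Hu <- eta * rowSums(ext$Iu * Pi); Hv <- eta * rowSums(ext$Iv * Pi)
      }
      if (has_cure) {
        S0u <- exp(-Hu); S0v <- exp(-Hv)
        Scu <- pc + (1 - pc) * S0u; Scv <- pc + (1 - pc) * S0v
        q <- (Scv / Scu) * exp(-ext$dHb)
      } else {
        q <- exp(-(Hv - Hu) - ext$dHb)
      }
      q <- pmin(q, 1 - 1e-15)
      lpv <- sum(ifelse(ext$r > 0, ext$r * log(q), 0) +
                   ifelse(ext$nn - ext$r > 0, (ext$nn - ext$r) * log1p(-q), 0)) +
        sum(lgamma(ext$nn + 1) - lgamma(ext$r + 1) - lgamma(ext$nn - ext$r + 1))
      dq <- ext$r / q - (ext$nn - ext$r) / (1 - q)
      if (has_cure) {
        dHv <- -dq * q * (1 - pc) * S0v / Scv
        dHu <- dq * q * (1 - pc) * S0u / Scu
        dpc <- sum(dq * q * ((1 - S0v) / Scv - (1 - S0u) / Scu))
      } else {
        dHv <- -dq * q
        dHu <- dq * q
        dpc <- 0
      }
      W <- dHu * Hu + dHv * Hv
      d_a <- sum(W)
      d_beta <- if (L$nc) drop(W %*% X) else numeric()
      U <- if (one) {
        rbind(drop(crossprod(ext$Iu, dHu * eta)) + drop(crossprod(ext$Iv, dHv * eta)))
      } else {
        rowsum(ext$Iu * (dHu * eta), gid) + rowsum(ext$Iv * (dHv * eta), gid)
      }
    }
    ## softmax back-propagation: dll/dgvec = p * (u - p.u), drop first col
    V <- rowSums(P * U)
    dgvec <- P * (U - V)
    list(lp = lpv, d_a = d_a, d_beta = d_beta,
         dgvec = dgvec[, -1, drop = FALSE], Gx = Gx, d_pc = dpc)
  }

  acc <- function(res) {
    lp <<- lp + res$lp
    g[L$i_eta] <<- g[L$i_eta] + res$d_a
    if (L$nc) g[L$i_beta] <<- g[L$i_beta] + res$d_beta
    grad_gamma <<- grad_gamma + colSums(res$dgvec)
    if (L$ns && nrow(res$Gx) > 0 && ncol(res$Gx) > 0)
      grad_dfree[, seq_len(L$ns)] <<- grad_dfree[, seq_len(L$ns)] +
        t(res$dgvec) %*% res$Gx
    grad_pc <<- grad_pc + res$d_pc
  }

  if (ctx$n_ind)
    acc(piece(ctx$B, ctx$I, ctx$Xi, ctx$gid_i, ctx$Gx_i, event = ctx$event,
              Hb = ctx$Hb, hb = ctx$hb))
  if (ctx$n_ext)
    acc(piece(NULL, NULL, ctx$Xe, ctx$gid_e, ctx$Gx_e,
              ext = list(r = ctx$r, nn = ctx$nn, Iu = ctx$Iu, Iv = ctx$Iv,
                         dHb = ctx$dHb)))

  ## priors (with Jacobians) and reparameterisation chain rule
  lp <- lp + stats::dnorm(th[L$i_eta], pr$log_eta0["mean"], pr$log_eta0["sd"], log = TRUE)
  g[L$i_eta] <- g[L$i_eta] - (th[L$i_eta] - pr$log_eta0["mean"]) / pr$log_eta0["sd"]^2
  if (L$nc) {
    lp <- lp + sum(stats::dnorm(beta, pr$beta["mean"], pr$beta["sd"], log = TRUE))
    g[L$i_beta] <- g[L$i_beta] - (beta - pr$beta["mean"]) / pr$beta["sd"]^2
  }
  ## gamma = mu + sigma * eps
  g[L$i_eps] <- sigma * grad_gamma - tanh(eps / 2)
  lp <- lp + sum(stats::dlogis(eps, log = TRUE))
  g[L$i_lsig] <- sigma * sum(eps * grad_gamma) +
    (pr$sigma["shape"] - pr$sigma["rate"] * sigma)
  lp <- lp + stats::dgamma(sigma, pr$sigma["shape"], pr$sigma["rate"], log = TRUE) + th[L$i_lsig]
  if (L$ns) {
    dD <- grad_dfree[, seq_len(L$ns), drop = FALSE]
    g[L$i_z] <- as.vector(sweep(dD, 2, tau, "*")) - th[L$i_z]
    lp <- lp + sum(stats::dnorm(th[L$i_z], log = TRUE))
    g[L$i_ltau] <- colSums(dD * delta_free) +
      (pr$tau["shape"] - pr$tau["rate"] * tau)
    lp <- lp + sum(stats::dgamma(tau, pr$tau["shape"], pr$tau["rate"], log = TRUE) + th[L$i_ltau])
  }
  if (has_cure) {
    lp <- lp + stats::dbeta(pc, pr$cure["a"], pr$cure["b"], log = TRUE) +
      log(pc) + log1p(-pc)
    g[L$i_cure] <- grad_pc * pc * (1 - pc) +
      pr$cure["a"] * (1 - pc) - pr$cure["b"] * pc
  }
  if (!is.finite(lp)) return(list(lp = -Inf, grad = g * 0))
  list(lp = unname(lp), grad = unname(g))
}
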