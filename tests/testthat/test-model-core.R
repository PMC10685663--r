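test_that("spline weights are a softmax of shifted multinomial logits", {
  spec <- spec_toy(covariates = "x", nonph = "x")
  n <- nbasis(spec$knots)

  ## gamma = 0, delta = 0: uniform weights
  d0 <- parameter_draw(spec, gamma = rep(0, n - 1), tau = 1)
  expect_equal(spline_coefs(d0, spec, c(x = 0)), rep(1 / n, n))

  ## weights always normalise
  set.seed(3)
  for (i in 1:10) {
    d <- rand_draw(spec)
    p <- spline_coefs(d, spec, c(x = rnorm(1)))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }

  ## a unit delta column multiplies the odds p_i / p_1 by e for i >= 2
  d1 <- parameter_draw(spec, gamma = rnorm(n - 1),
                       delta = rbind(0, matrix(1, n - 1, 1)), tau = 1)
  p0 <- spline_coefs(d1, spec, c(x = 0))
  p1 <- spline_coefs(d1, spec, c(x = 1))
  expect_equal((p1[-1] / p1[1]) / (p0[-1] / p0[1]), rep(exp(1), n - 1))

  expect_error(parameter_draw(spec, gamma = rep(0, n)), "length")
})

test_that("hazard composes scale, weights and mechanisms correctly", {
  spec <- spec_toy(covariates = "treat")
  ## constant-hazard weights with eta chosen to give hazard 3
  d <- constant_draw(spec, rate = 3)
  tt <- seq(0, spec$knots$upper, length.out = 50)
  expect_equal(hazard(d, spec, tt), rep(3, 50), tolerance = 1e-10)

  ## proportional hazards: ratio exp(beta) independent of t
  set.seed(4)
  d2 <- rand_draw(spec)
  hr <- hazard(d2, spec, tt[-1], c(treat = 1)) / hazard(d2, spec, tt[-1], c(treat = 0))
  expect_equal(hr, rep(exp(unname(d2$beta["treat"])), length(tt) - 1))

  ## non-proportional model: hazard ratio varies over time
  spec_np <- spec_toy(covariates = "treat", nonph = "treat")
  n <- nbasis(spec_np$knots)
  d3 <- parameter_draw(spec_np, beta = 0.2, gamma = rnorm(n - 1),
                       delta = rbind(0, cbind(seq(0.5, 1.5, length.out = n - 1))),
                       tau = 1)
  hr1 <- hazard(d3, spec_np, 1, c(treat = 1)) / hazard(d3, spec_np, 1, c(treat = 0))
  hr10 <- hazard(d3, spec_np, 7, c(treat = 1)) / hazard(d3, spec_np, 7, c(treat = 0))
  expect_gt(abs(log(hr1 / hr10)), 0.01)

  expect_error(hazard(d, spec, -1), "non-negative")
})

test_that("cumulative hazard and survival match closed forms and quadrature", {
  spec <- spec_toy()
  lam <- 0.4
  d <- constant_draw(spec, rate = lam)
  tt <- c(0.5, 1, 3, 7, 8, 11)
  expect_equal(survival(d, spec, tt), exp(-lam * tt), tolerance = 1e-8)

  ## beyond the boundary the cumulative hazard grows linearly
  expect_equal(cumhaz(d, spec, 11) - cumhaz(d, spec, 8), lam * 3, tolerance = 1e-8)

  ## quadrature oracle on a wiggly draw
  set.seed(9)
  d2 <- rand_draw(spec)
  for (t1 in c(0.8, 3.5, 7.9)) {
    Hq <- integrate(function(s) hazard(d2, spec, s), 0, t1,
                    subdivisions = 2000, rel.tol = 1e-10)$value
    expect_equal(cumhaz(d2, spec, t1), Hq, tolerance = 1e-6)
  }
  expect_equal(survival(d2, spec, 0), 1)
  S <- survival(d2, spec, seq(0, 12, length.out = 80))
  expect_true(all(diff(S) <= 1e-14))
})

test_that("mixture cure survival and both hazard forms agree", {
  expect_equal(cure_survival(0.5, 0.3), 0.65)

  spec <- spec_toy(cure = "overall")
  set.seed(11)
  d <- rand_draw(spec)
  tt <- seq(0.01, 30, length.out = 200)
  S0 <- survival(d, mspsurv::model_spec(spec$knots), tt)  # uncured model
  h0 <- hazard(d, mspsurv::model_spec(spec$knots), tt)
  p <- d$cure_p

  ## printed form 1: (1-p) f0 / (p + (1-p) S0); form 2: f0 / (p/(1-p) + S0)
  f0 <- h0 * S0
  h_form1 <- (1 - p) * f0 / (p + (1 - p) * S0)
  h_form2 <- f0 / (p / (1 - p) + S0)
  expect_equal(h_form1, h_form2, tolerance = 1e-10)
  expect_equal(hazard(d, spec, tt), h_form1, tolerance = 1e-10)

  ## survival converges to the cure probability, and never drops below it
  expect_equal(survival(d, spec, 1e6), p, tolerance = 1e-6)
  expect_true(all(survival(d, spec, tt) >= p))

  expect_error(parameter_draw(spec), "cure_p")
})

test_that("additive background hazard adds hazards and multiplies survival", {
  bg0 <- background_hazard(0, 0)
  spec_b0 <- spec_toy(background = bg0)
  spec_pl <- spec_toy()
  set.seed(12)
  d <- rand_draw(spec_pl)
  tt <- seq(0, 10, length.out = 40)
  expect_equal(hazard(d, spec_b0, tt), hazard(d, spec_pl, tt))
  expect_equal(survival(d, spec_b0, tt), survival(d, spec_pl, tt))

  ## constant excess 0.03 + constant background 0.02
  bg <- background_hazard(0, 0.02)
  spec_b <- spec_toy(background = bg)
  dc <- constant_draw(spec_b, rate = 0.03)
  expect_equal(survival(dc, spec_b, tt), exp(-0.05 * tt), tolerance = 1e-8)
  expect_equal(hazard(dc, spec_b, tt), rep(0.05, 40), tolerance = 1e-10)

  ## two-interval background table evaluated exactly
  bg2 <- background_hazard(c(0, 10), c(0.01, 0.05))
  out <- additive_combine(bg2, 12, h_excess = 0, S_excess = 1)
  expect_equal(-log(out$S), 0.2)
})

test_that("waning hazard ratio interpolates log-linearly between t_min and t_max", {
  w <- waning_spec(5, 6, "treat")
  expect_equal(waning_hr(5.5, 0.5, w), sqrt(0.5))
  expect_equal(waning_hr(c(0, 2, 5), 0.5, w), rep(0.5, 3))
  expect_equal(waning_hr(c(6, 7, 100), 0.5, w), rep(1, 3))
  expect_equal(waning_hr(seq(0, 10, 0.1), 1, w), rep(1, 101))

  ## continuity and monotonicity towards 1
  tt <- seq(4.9, 6.1, length.out = 200)
  v <- waning_hr(tt, 0.5, w)
  expect_true(all(diff(v) >= 0))
  expect_lt(max(abs(diff(v))), 0.02)

  expect_error(waning_spec(6, 5, "treat"), "t_min < t_max")
  expect_error(waning_hr(1, -0.5, w), "positive")
})

test_that("individual log-likelihood matches censoring/event closed forms", {
  spec <- spec_toy()
  lam <- 0.3
  d <- constant_draw(spec, rate = lam)

  dat <- individual_data(c(2, 2), c(0, 1))
  ll <- loglik_individual(dat, d, spec)
  expect_equal(ll[1], -lam * 2, tolerance = 1e-8)
  expect_equal(ll[2], log(lam) - lam * 2, tolerance = 1e-8)

  ## sum over a simulated exponential sample matches the closed form
  set.seed(5)
  tt <- rexp(100, 0.5); ev <- rbinom(100, 1, 0.7)
  dat2 <- individual_data(tt, ev)
  expect_equal(sum(loglik_individual(dat2, d, spec)),
               sum(ev) * log(lam) - lam * sum(tt), tolerance = 1e-8)
})

test_that("external log-likelihood is the binomial kernel of conditional survival", {
  spec <- spec_toy()
  ## constant hazard with S(1) = 0.8, and v such that S(v) = 0.6
  lam <- -log(0.8)
  v <- -log(0.6) / lam
  d <- constant_draw(spec, rate = lam)
  ext <- external_data(u = 1, v = v, n = 4, r = 3)
  expect_equal(loglik_external(ext, d, spec),
               dbinom(3, 4, 0.75, log = TRUE), tolerance = 1e-7)

  ## all survived with certainty: zero contribution
  ext2 <- external_data(u = 8.5, v = 9, n = 10, r = 10)
  d0 <- constant_draw(spec, rate = 1e-14)
  expect_equal(loglik_external(ext2, d0, spec), 0, tolerance = 1e-8)

  ## real-valued counts are accepted via the log-gamma coefficient
  ext3 <- external_data(u = 1, v = v, n = 9.75, r = 7.25)
  ll <- loglik_external(ext3, d, spec)
  expect_true(is.finite(ll))
  expect_equal(ll,
    lgamma(10.75) - lgamma(8.25) - lgamma(3.5) +
      7.25 * log(0.75) + 2.5 * log(0.25), tolerance = 1e-7)
})

test_that("log prior density follows the stated component distributions", {
  spec <- spec_toy()
  n <- nbasis(spec$knots)
  mu <- mspsurv:::constant_logit_means(spec$knots)

  ## gamma at its prior location with sigma = 1: each term is log(1/4)
  d <- parameter_draw(spec, log_eta0 = 0, gamma = mu, sigma = 1)
  lp <- logprior(d, spec)
  expected <- (n - 1) * log(0.25) +
    dnorm(0, 0, 20, log = TRUE) + dgamma(1, 2, 1, log = TRUE)
  expect_equal(lp, expected, tolerance = 1e-12)

  ## doubling sigma at gamma = mu lowers each logistic term by log 2
  d2 <- parameter_draw(spec, log_eta0 = 0, gamma = mu, sigma = 2)
  expect_equal(logprior(d, spec) - (logprior(d2, spec) - dgamma(2, 2, 1, log = TRUE) +
                 dgamma(1, 2, 1, log = TRUE)),
               (n - 1) * log(2), tolerance = 1e-12)

  ## defaults: the baseline scale term is the Normal(0, 20) log density
  d3 <- parameter_draw(spec, log_eta0 = 3, gamma = mu, sigma = 1)
  expect_equal(logprior(d3, spec) - logprior(d, spec),
               dnorm(3, 0, 20, log = TRUE) - dnorm(0, 0, 20, log = TRUE))
})

test_that("mechanism switches reduce exactly to their null counterparts", {
  set.seed(21)
  ## non-PH with delta = 0 equals the PH likelihood bit for bit
  spec_ph <- spec_toy(covariates = "treat")
  spec_np <- spec_toy(covariates = "treat", nonph = "treat")
  n <- nbasis(spec_ph$knots)
  gam <- rnorm(n - 1); bet <- 0.4
  d_ph <- parameter_draw(spec_ph, beta = bet, gamma = gam, sigma = 1)
  d_np <- parameter_draw(spec_np, beta = bet, gamma = gam, sigma = 1,
                         delta = matrix(0, n, 1), tau = 1)
  dat <- individual_data(rexp(30, 0.4), rbinom(30, 1, 0.8),
                         covariates = data.frame(treat = rep(0:1, 15)))
  expect_identical(loglik_individual(dat, d_np, spec_np),
                   loglik_individual(dat, d_ph, spec_ph))

  ## cure with p = 0 equals the no-cure model
  spec_c <- spec_toy(cure = "overall")
  spec_0 <- spec_toy()
  d_c <- parameter_draw(spec_c, gamma = gam, sigma = 1, cure_p = 0)
  d_0 <- parameter_draw(spec_0, gamma = gam, sigma = 1)
  tt <- seq(0, 12, length.out = 30)
  expect_equal(hazard(d_c, spec_c, tt), hazard(d_0, spec_0, tt))
  expect_equal(survival(d_c, spec_c, tt), survival(d_0, spec_0, tt))
})

test_that("survival stays valid under randomised mechanism combinations", {
  set.seed(31)
  bg <- background_hazard(c(0, 4), c(0.02, 0.05))
  specs <- list(
    spec_toy(),
    spec_toy(cure = "overall"),
    spec_toy(background = bg),
    spec_toy(background = bg, cure = "excess")
  )
  tt <- seq(0, 15, length.out = 60)
  for (spec in specs) {
    for (i in 1:5) {
      d <- rand_draw(spec)
      S <- survival(d, spec, tt)
      h <- hazard(d, spec, tt)
      expect_equal(S[1], 1)
      expect_true(all(diff(S) <= 1e-14))
      expect_true(all(h >= 0))
      expect_equal(-log(S), cumhaz(d, spec, tt), tolerance = 1e-8)
      if (spec$cure == "overall") expect_true(all(S >= d$cure_p - 1e-12))
    }
  }
})
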