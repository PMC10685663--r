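test_that("fitting is deterministic given a seed and requires one", {
  dat <- sim_exp_data(40, 0.5, cens_rate = 0.1, seed = 2)
  spec <- model_spec(default_knots(dat$time[dat$event == 1], n_basis = 5))
  f1 <- quiet_fit(dat, spec = spec, chains = 2, warmup = 300, iter = 200, seed = 7)
  f2 <- quiet_fit(dat, spec = spec, chains = 2, warmup = 300, iter = 200, seed = 7)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$pointwise_loglik, f2$pointwise_loglik)

  f3 <- quiet_fit(dat, spec = spec, chains = 2, warmup = 300, iter = 200, seed = 8)
  expect_false(identical(f1$draws, f3$draws))

  expect_error(fit_mspline(dat, spec = spec), "seed")
  expect_error(fit_mspline(spec = spec, seed = 1), "no data")
})

test_that("the posterior object is coherent: draws, loglik, diagnostics", {
  dat <- sim_exp_data(50, 0.4, cens_rate = 0.1, seed = 3)
  ext <- external_data(u = c(18, 21), v = c(21, 25), n = c(60, 50), r = c(45, 35))
  spec <- model_spec(default_knots(dat$time[dat$event == 1], n_basis = 5,
                                   add_knots = 25))
  fit <- quiet_fit(dat, ext, spec = spec, chains = 2, warmup = 300, iter = 250,
                   seed = 11)
  expect_equal(nrow(fit$draws), 500)
  expect_equal(ncol(fit$pointwise_loglik), nrow(dat) + nrow(ext))
  expect_true(all(fit$draws[, "sigma"] > 0))
  expect_true(all(is.finite(fit$pointwise_loglik)))
  expect_true(all(c("rhat", "ess") %in% names(fit$diagnostics)))

  ## stored pointwise log-likelihood matches the public per-draw functions
  i <- 17
  d <- posterior_draw(fit, i)
  expect_equal(unname(fit$pointwise_loglik[i, seq_len(nrow(dat))]),
               loglik_individual(dat, d, spec), tolerance = 1e-8)
  expect_equal(unname(fit$pointwise_loglik[i, nrow(dat) + seq_len(nrow(ext))]),
               loglik_external(ext, d, spec), tolerance = 1e-8)
})

test_that("prior hazard simulation reflects the smoothness parameter", {
  spec <- spec_toy()
  ## sigma ~ 0: every curve is flat
  flat <- prior_hazard_sim(spec, n_sims = 20, seed = 4, sigma = 1e-8)
  ratios <- apply(flat, 1, function(v) max(v) / min(v))
  expect_true(all(ratios - 1 < 1e-3))
  expect_true(all(flat >= 0))
  expect_length(attr(flat, "times"), 100)

  ## larger sigma: visibly more within-curve variability
  lo <- prior_hazard_sim(spec, n_sims = 200, seed = 4, sigma = 0.1)
  hi <- prior_hazard_sim(spec, n_sims = 200, seed = 4, sigma = 1.5)
  rho_lo <- median(apply(lo, 1, hazard_variability_rho))
  rho_hi <- median(apply(hi, 1, hazard_variability_rho))
  expect_gt(rho_hi, rho_lo)
})

test_that("hazard variability ratio follows the quantile rule", {
  expect_equal(hazard_variability_rho(rep(2.5, 50)), 1)
  ## linear-interpolation quantiles of 1..100: q10 = 10.9, q90 = 90.1
  expect_equal(hazard_variability_rho(1:100), 90.1 / 10.9)
  expect_warning(r <- hazard_variability_rho(c(rep(0, 50), rep(1, 50))), "zero")
  expect_equal(r, Inf)
  expect_error(hazard_variability_rho(1), "2 grid points")
})

test_that("sigma calibration reproduces the requested rho summaries", {
  kn <- kn_toy()
  cal <- calibrate_sigma(kn, target_median = 2, target_upper = 16,
                         n_sims = 1000, seed = 6)
  expect_true(cal$shape > 0 && cal$rate > 0)
  ## self-consistency on an independent seed
  spec <- model_spec(kn, priors = list(sigma = c(cal$shape, cal$rate)))
  sims <- prior_hazard_sim(spec, n_sims = 1500, seed = 99)
  rho <- apply(sims, 1, hazard_variability_rho)
  expect_lt(abs(median(rho) / 2 - 1), 0.10)
  expect_lt(abs(log(quantile(rho, 0.975, names = FALSE)) / log(16) - 1), 0.35)
})

test_that("scale calibration yields the stated prior mean-survival beliefs", {
  cal <- calibrate_eta_prior(kn_toy(), mean_survival = 25, interval = c(5, 100),
                             seed = 2)
  ## the three targets are not exactly log-normal-compatible; the
  ## compromise should land near all of them
  expect_lt(abs(cal$achieved_mean / 25 - 1), 0.2)
  expect_lt(abs(cal$achieved_interval[1] / 5 - 1), 0.25)
  expect_lt(abs(cal$achieved_interval[2] / 100 - 1), 0.25)
})

test_that("PSIS-LOO cross-validation behaves as an elpd estimator should", {
  dat <- sim_exp_data(60, 0.4, cens_rate = 0.1, seed = 8)
  spec <- model_spec(default_knots(dat$time[dat$event == 1], n_basis = 5))
  fit <- quiet_fit(dat, spec = spec, chains = 2, warmup = 400, iter = 400, seed = 13)
  lo <- looic(fit)
  expect_length(lo$elpd, nrow(dat))
  expect_equal(lo$looic, -2 * sum(lo$elpd))

  ## identical refit gives identical LOOIC
  fit2 <- quiet_fit(dat, spec = spec, chains = 2, warmup = 400, iter = 400, seed = 13)
  expect_identical(looic(fit2)$looic, lo$looic)

  ## Jensen direction: leave-one-out elpd never beats the in-sample lpd
  lpd <- apply(fit$pointwise_loglik, 2, function(v) log(mean(exp(v))))
  expect_true(all(lo$elpd <= lpd + 1e-8))
})

test_that("posterior contracts with more data and matches the prior without data", {
  ## paired seeds: doubling the sample shrinks the 5-year survival IQR
  spec5 <- function(dat, up) model_spec(default_knots(dat$time[dat$event == 1],
                                                      n_basis = 5, upper = up))
  d_small <- sim_exp_data(60, 0.3, seed = 14)
  d_big <- sim_exp_data(240, 0.3, seed = 14)
  f_small <- quiet_fit(d_small, spec = spec5(d_small, 12), chains = 1,
                       warmup = 400, iter = 400, seed = 15)
  f_big <- quiet_fit(d_big, spec = spec5(d_big, 12), chains = 1,
                     warmup = 400, iter = 400, seed = 15)
  iqr5 <- function(f) {
    s <- mspsurv:::curve_mats(f, 5, NULL)$S
    diff(quantile(s[1, ], c(0.25, 0.75)))
  }
  expect_lt(iqr5(f_big), iqr5(f_small))

  ## a single near-zero censored observation leaves the sigma prior intact
  d0 <- individual_data(1e-4, 0)
  spec0 <- model_spec(kn_toy())
  f0 <- quiet_fit(d0, spec = spec0, chains = 2, warmup = 600, iter = 1000, seed = 16)
  set.seed(17)
  prior_sigma <- rgamma(2000, 2, 1)
  ks <- suppressWarnings(ks.test(f0$draws[, "sigma"], prior_sigma))
  expect_lt(unname(ks$statistic), 0.1)
})
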