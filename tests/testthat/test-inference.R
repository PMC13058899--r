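# Priors, posterior decomposition, sampler and diagnostics.

test_that("log prior matches generic truncated-normal evaluations", {
  dims <- ipm_dims(2003, 10)
  priors <- ipm_priors()
  pars <- random_pars(dims, 31)
  # single-term check: log_alpha at 0 contributes the untruncated normal
  p0 <- pars
  lp1 <- log_prior(p0, priors, dims)
  p0$log_alpha <- 0
  lp0 <- log_prior(p0, priors, dims)
  expect_equal(lp0 - lp1,
               dnorm(0, 0, 12.5, log = TRUE) -
                 dnorm(pars$log_alpha, 0, 12.5, log = TRUE),
               tolerance = 1e-10)
  expect_equal(dnorm(0, 0, 12.5, log = TRUE), -log(12.5 * sqrt(2 * pi)),
               tolerance = 1e-10)
  # truncation constants: the truncated-normal densities integrate to one
  # over their declared supports
  half <- Vectorize(function(s)
    exp(yukonIPM:::dtnorm_log(s, priors$sigma_R)))
  expect_equal(stats::integrate(half, 0, 80, rel.tol = 1e-8)$value, 1,
               tolerance = 1e-6)
  vband <- Vectorize(function(s) exp(yukonIPM:::dtnorm_log(s, priors$v)))
  expect_equal(stats::integrate(vband, 0.5, 1, rel.tol = 1e-8)$value, 1,
               tolerance = 1e-6)
  # bounds are closed: v at 0.5 and 1 are finite, outside is -Inf
  pv <- pars; pv$v <- c(1, 0.5, 1, 0.75, 1)
  expect_true(is.finite(log_prior(pv, priors, dims)))
  pv$v <- c(1, 0.49, 1, 0.75, 1)
  expect_identical(log_prior(pv, priors, dims), -Inf)
  # doubling prior SDs lowers the density at the mean
  expect_gt(dnorm(0, 0, 5, log = TRUE), dnorm(0, 0, 10, log = TRUE))
})

test_that("TMB posterior equals log_prior + joint_loglik + Jacobian", {
  dims <- ipm_dims(2003, 12)
  scn <- sim_scenario(dims = dims)
  sim <- simulate_ipm_data(scn, seed = 13)
  obj <- ipm_objective(sim$data)
  set.seed(41)
  for (i in 1:10) {
    u <- yukonIPM:::default_init(sim$data, dims, jitter = 0.4)
    pars <- unpack_parameters(u, dims)
    st <- simulate_population(pars, dims)
    lp <- log_prior(pars, ipm_priors(), dims)
    ll <- joint_loglik(st, sim$data, ipm_obs_config(),
                       gsi = list(muG = pars$muG, sigmaG = pars$sigmaG))
    lj <- yukonIPM:::log_jacobian(pars, dims)
    expect_equal(as.numeric(obj$fn(u)), -(lp + ll + lj), tolerance = 1e-8)
  }
  # TMB's internal states agree with the R process model
  u <- yukonIPM:::default_init(sim$data, dims)
  rep <- obj$report(u)
  st <- simulate_population(unpack_parameters(u, dims), dims)
  expect_equal(rep$run_size, st$run_size, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rep$N, st$N, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rep$BA, st$BA, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pack/unpack is a bijection preserving bounds", {
  dims <- ipm_dims(2003, 9)
  for (seed in 1:20) {
    pars <- random_pars(dims, seed + 500)
    u <- pack_parameters(pars, dims)
    expect_length(u, yukonIPM:::unconstrained_length(dims))
    p2 <- unpack_parameters(u, dims)
    for (nm in setdiff(names(pars), "rates"))
      expect_equal(pars[[nm]], p2[[nm]], tolerance = 1e-9)
    # arbitrary unconstrained vectors map into the declared bounds
    p3 <- unpack_parameters(rnorm(length(u), 0, 3), dims)
    expect_true(all(p3$sB >= 0 & p3$sB <= 1))
    expect_true(all(p3$v[-1] >= 0.5 & p3$v[-1] <= 1))
    expect_true(p3$log_lam_init > 0)
    expect_true(all(c(p3$sigma_R, p3$sigma_M, p3$sigmaG) > 0))
  }
})

test_that("NUTS recovers the moments of a known Gaussian target", {
  set.seed(10)
  d <- 8
  sds <- exp(seq(-1.5, 1.5, length.out = d))
  fn <- function(q) 0.5 * sum((q / sds)^2)
  gr <- function(q) q / sds^2
  ch <- lapply(1:2, function(i)
    nuts_chain(fn, gr, rnorm(d), n_iter = 1500, n_warmup = 750))
  flat <- do.call(rbind, lapply(ch, `[[`, "draws"))
  expect_lt(max(abs(colMeans(flat)) / sds), 0.12)
  expect_true(all(abs(apply(flat, 2, sd) / sds - 1) < 0.15))
  expect_equal(sum(sapply(ch, function(c) sum(c$divergent[751:1500]))), 0)
  # seeded determinism
  set.seed(77)
  a <- nuts_chain(fn, gr, rep(1, d), n_iter = 200, n_warmup = 100)
  set.seed(77)
  b <- nuts_chain(fn, gr, rep(1, d), n_iter = 200, n_warmup = 100)
  expect_identical(a$draws, b$draws)
})

test_that("divergences are reported on a pathological target", {
  # a funnel-like sharp wall: energy error must trigger divergence flags
  fn <- function(q) 0.5 * sum(q^2) + exp(8 * q[1])
  gr <- function(q) c(q[1] + 8 * exp(8 * q[1]), q[-1])
  set.seed(3)
  ch <- nuts_chain(fn, gr, c(-2, 0), n_iter = 400, n_warmup = 200,
                   control = nuts_control(stepsize = 0.5, max_treedepth = 6))
  expect_gt(sum(ch$divergent), 0)
})

test_that("split R-hat and ESS behave on known draw structures", {
  set.seed(8)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(iid), 1.005)
  expect_gt(ess_bulk(iid), 4000 * 0.9)
  expect_lt(ess_bulk(iid), 4000 * 1.3)
  expect_gt(ess_tail(iid), 1000)
  # separated chains are flagged
  bad <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(split_rhat(bad), 1.5)
  # strong autocorrelation collapses the ESS
  ar <- matrix(0, 1000, 4)
  for (j in 1:4) {
    x <- numeric(1000)
    for (i in 2:1000) x[i] <- 0.95 * x[i - 1] + rnorm(1, 0, 0.1)
    ar[, j] <- x
  }
  expect_lt(ess_bulk(ar), 800)
  expect_error(split_rhat(matrix(rnorm(100), 100, 1)), "2 chains")
  # BFMI: near-independent energies score high, sticky energies low
  e_good <- matrix(rnorm(2000), 1000, 2)
  expect_true(all(bfmi(e_good) > 1.5))
  e_bad <- matrix(cumsum(rnorm(2000, 0, 0.05)), 1000, 2)
  expect_true(all(bfmi(e_bad) < 0.3))
})

test_that("prior-only posterior reproduces the declared prior quantiles", {
  # mask every stream: the TMB posterior reduces to the prior; NUTS draws of
  # bounded leading parameters must match direct truncated-normal sampling
  # within Monte-Carlo error. The data-free prior is a hard (funnel-shaped)
  # target for the centred walk states, so the comparison tolerance is
  # derived from the measured effective sample size, not assumed.
  dims <- ipm_dims(2003, 4)
  scn <- sim_scenario(dims = dims)
  sim <- simulate_ipm_data(scn, seed = 17)
  d <- sim$data
  d$J[] <- NA; d$E[] <- NA; d$C[] <- NA; d$b_total[] <- NA
  d$qE[] <- NA; d$qC[] <- NA; d$qB[] <- NA; d$nB[] <- 0
  d$x[] <- NA; d$n[] <- NA
  fit <- fit_ipm(d, chains = 2, iter = 1300, warmup = 500, seed = 5,
                 quiet = TRUE,
                 control = nuts_control(adapt_delta = 0.95, metric = "diag"))
  check_quantiles <- function(param, lower, upper) {
    dr <- fit$draws[, , param]
    set.seed(2)
    ref <- qnorm(runif(1e5, pnorm(lower), pnorm(upper)))
    ess <- max(ess_bulk(dr), 5)
    for (p in c(0.25, 0.5, 0.75)) {
      qref <- quantile(ref, p)
      dens <- approx(stats::density(ref)$x, stats::density(ref)$y,
                     xout = qref)$y
      tol <- 4 * sqrt(p * (1 - p) / ess) / dens + 0.005
      expect_lt(abs(quantile(as.vector(dr), p) - qref), tol)
    }
  }
  check_quantiles("v[5]", 0.5, 1)   # Normal(0,1) truncated to [0.5, 1]
  check_quantiles("sB[4]", 0, 1)    # Normal(0,1) truncated to [0, 1]
})
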