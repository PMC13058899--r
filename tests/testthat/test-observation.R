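# Observation-model likelihood terms against generic density oracles.

test_that("lognormal index term matches a hand-written density", {
  expect_equal(loglik_lognormal_index(100, 100, 0.25),
               oracle_dlnorm(100, log(100), 0.25), tolerance = 1e-12)
  expect_equal(loglik_lognormal_index(100, 100, 0.25), -4.13782,
               tolerance = 1e-4)
  set.seed(3)
  for (i in 1:200) {
    o <- runif(1, 1, 1e6); p <- runif(1, 1, 1e6); s <- runif(1, 0.05, 1)
    expect_equal(loglik_lognormal_index(o, p, s),
                 oracle_dlnorm(o, log(p), s), tolerance = 1e-8)
  }
  # density integrates to 1 over the observation
  f <- Vectorize(function(o) exp(loglik_lognormal_index(o, 50, 0.3)))
  expect_equal(stats::integrate(f, 1e-3, 1e4, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  # maximized over obs at the lognormal mode pred * exp(-sigma^2)
  s <- 0.4
  mode <- 50 * exp(-s^2)
  expect_gt(loglik_lognormal_index(mode, 50, s),
            loglik_lognormal_index(mode * 1.01, 50, s))
  expect_gt(loglik_lognormal_index(mode, 50, s),
            loglik_lognormal_index(mode * 0.99, 50, s))
  # missing observations contribute zero
  expect_identical(loglik_lognormal_index(NA_real_, 10, 0.2), 0)
  expect_equal(loglik_lognormal_index(c(NA, 100), c(5, 100), 0.25),
               loglik_lognormal_index(100, 100, 0.25))
})

test_that("age-composition term is a proper multinomial", {
  q <- c(1, 0, 0, 0)
  expect_equal(loglik_agecomp(q, 100, rep(0.25, 4)), 100 * log(0.25),
               tolerance = 1e-10)
  expect_equal(loglik_agecomp(q, 100, rep(0.25, 4)), -138.629,
               tolerance = 1e-3)
  set.seed(4)
  for (i in 1:100) {
    pr <- as.vector(stats::rmultinom(1, 200, runif(4, 0.1, 1)))
    qv <- pr / sum(pr)
    pi <- runif(4, 0.05, 1); pi <- pi / sum(pi)
    cnt <- counts_from_props(qv, 200)
    expect_equal(loglik_agecomp(qv, 200, pi), oracle_dmultinom(cnt, pi),
                 tolerance = 1e-8)
    expect_equal(loglik_agecomp(qv, 200, pi),
                 stats::dmultinom(cnt, prob = pi, log = TRUE),
                 tolerance = 1e-8)
  }
  # q = pi maximizes over pi (multinomial MLE)
  qv <- c(0.4, 0.3, 0.2, 0.1)
  base <- loglik_agecomp(qv, 100, qv)
  for (i in 1:20) {
    alt <- runif(4); alt <- alt / sum(alt)
    expect_gte(base, loglik_agecomp(qv, 100, alt))
  }
  # joint permutation invariance
  perm <- c(3, 1, 4, 2)
  pi <- c(0.5, 0.2, 0.2, 0.1)
  expect_equal(loglik_agecomp(qv, 100, pi),
               loglik_agecomp(qv[perm], 100, pi[perm]), tolerance = 1e-12)
  # zero predicted mass in an observed class is flagged, not clamped
  expect_warning(val <- loglik_agecomp(c(0.5, 0.5, 0, 0), 10,
                                       c(0, 0.5, 0.3, 0.2)), "zero mass")
  expect_identical(val, -Inf)
  # fractional-count variant agrees when counts are already integers
  expect_equal(loglik_agecomp(qv, 100, pi, fractional = TRUE),
               loglik_agecomp(qv, 100, pi), tolerance = 1e-10)
})

test_that("largest-remainder counts sum exactly and stay close", {
  set.seed(5)
  for (i in 1:100) {
    q <- runif(4); q <- q / sum(q)
    n <- sample(10:500, 1)
    cnt <- counts_from_props(q, n)
    expect_identical(sum(cnt), as.integer(n))
    expect_true(all(abs(cnt - q * n) < 1))
  }
  expect_error(counts_from_props(c(0.5, 0.4), 100), "sum to 1")
})

test_that("binomial stock-assignment term matches the pmf", {
  expect_equal(loglik_stock_assignment(5, 10, 0.5),
               log(choose(10, 5)) + 10 * log(0.5), tolerance = 1e-10)
  expect_equal(loglik_stock_assignment(5, 10, 0.5), -1.40204,
               tolerance = 1e-4)
  set.seed(6)
  for (i in 1:100) {
    n <- sample(1:500, 1); p <- runif(1, 0.01, 0.99); x <- rbinom(1, n, p)
    expect_equal(loglik_stock_assignment(x, n, p), oracle_dbinom(x, n, p),
                 tolerance = 1e-8)
  }
  # pmf normalization
  expect_equal(sum(exp(sapply(0:10, loglik_stock_assignment, n = 10,
                              vartheta = 0.37))), 1, tolerance = 1e-10)
  # x = 0 with vanishing proportion tends to certainty
  expect_gt(loglik_stock_assignment(0, 10, 1e-9), -1e-6)
  # empty cells contribute nothing
  expect_identical(loglik_stock_assignment(NA, NA, 0.5), 0)
  expect_identical(loglik_stock_assignment(0, 0, 0.5), 0)
  expect_error(loglik_stock_assignment(11, 10, 0.5))
})

test_that("stock-composition hierarchy is a normal density on logits", {
  vt <- matrix(invlogit(0), 1, 1)
  expect_equal(loglik_stock_hierarchy(vt, 0, 1), -0.918939, tolerance = 1e-5)
  expect_equal(loglik_stock_hierarchy(vt, 0, 1), dnorm(0, 0, 1, log = TRUE),
               tolerance = 1e-10)
  # density maximized when logit vartheta sits at muG
  mu <- -2
  at_mode <- loglik_stock_hierarchy(matrix(invlogit(mu), 1, 1), mu, 0.5)
  expect_gt(at_mode,
            loglik_stock_hierarchy(matrix(invlogit(mu + 0.3), 1, 1), mu, 0.5))
  # shrinking sigmaG pulls the penalized optimum toward logistic(muG):
  # 3-year toy with a binomial observation pulling away from the mean
  x <- 6; n <- 10
  opt_vt <- function(sg) {
    stats::optimize(function(lv)
      -(loglik_stock_assignment(x, n, invlogit(lv)) +
          loglik_stock_hierarchy(matrix(invlogit(lv), 1, 1), mu, sg)),
      c(-8, 8))$minimum
  }
  expect_lt(abs(opt_vt(0.01) - mu), 0.02)
  expect_gt(abs(opt_vt(5) - mu), 1)
  expect_error(loglik_stock_hierarchy(matrix(0, 1, 1), 0, 1), "strictly")
  expect_error(loglik_stock_hierarchy(vt, 0, 0), "sigmaG")
})

test_that("joint log-likelihood decomposes into its stream terms", {
  dims <- ipm_dims(2003, 10)
  scn <- sim_scenario(dims = dims)
  sim <- simulate_ipm_data(scn, seed = 11)
  pars <- random_pars(dims, 21)
  st <- simulate_population(pars, dims)
  cfg <- ipm_obs_config()
  gsi <- list(muG = pars$muG, sigmaG = pars$sigmaG)
  jl <- joint_loglik(st, sim$data, cfg, gsi)
  # independent accumulation, oracle densities, term by term
  d <- sim$data
  acc <- 0
  for (y in 1:dims$n_years) {
    if (!is.na(d$J[y])) acc <- acc + oracle_dlnorm(d$J[y], log(st$N[y, 1]), cfg$sigma_J)
    acc <- acc + oracle_dlnorm(d$E[y], log(st$S_total[y]), cfg$sigma_E)
    acc <- acc + oracle_dlnorm(d$C[y], log(sum(st$H[y, ])), cfg$sigma_C)
    acc <- acc + oracle_dlnorm(d$b_total[y], log(sum(st$BA[y, ])), cfg$sigma_b)
    acc <- acc + oracle_dmultinom(counts_from_props(d$qE[y, ], cfg$neff_E), st$pi_S[y, ])
    acc <- acc + oracle_dmultinom(counts_from_props(d$qC[y, ], cfg$neff_C), st$pi_H[y, ])
    if (d$nB[y] > 0)
      acc <- acc + oracle_dmultinom(counts_from_props(d$qB[y, ], d$nB[y]), st$pi_B[y, ])
    for (a in 1:4) {
      if (!is.na(d$n[y, a]) && d$n[y, a] > 0)
        acc <- acc + oracle_dbinom(d$x[y, a], d$n[y, a], st$vartheta[y, a])
      acc <- acc + dnorm(logit(st$vartheta[y, a]), pars$muG[a],
                         pars$sigmaG[a], log = TRUE)
    }
  }
  expect_equal(jl, as.numeric(acc), tolerance = 1e-8)
  # masking a stream removes exactly its contribution
  d2 <- sim$data
  d2$J[] <- NA
  jl2 <- joint_loglik(st, d2, cfg, gsi)
  drop <- sum(oracle_dlnorm(sim$data$J[!is.na(sim$data$J)],
                            log(st$N[!is.na(sim$data$J), 1]), cfg$sigma_J))
  expect_equal(as.numeric(jl - jl2), as.numeric(drop), tolerance = 1e-8)
  # fully masked data leave only the hierarchy term
  d3 <- sim$data
  d3$J[] <- NA; d3$E[] <- NA; d3$C[] <- NA; d3$b_total[] <- NA
  d3$qE[] <- NA; d3$qC[] <- NA; d3$qB[] <- NA; d3$nB[] <- NA
  d3$x[] <- NA; d3$n[] <- NA
  expect_equal(joint_loglik(st, d3, cfg, gsi),
               loglik_stock_hierarchy(st$vartheta, pars$muG, pars$sigmaG),
               tolerance = 1e-10)
  # widening sigma_J lowers the peak-height contribution at obs = pred
  st2 <- st
  expect_gt(loglik_lognormal_index(1000, 1000, 0.25),
            loglik_lognormal_index(1000, 1000, 0.5))
})
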