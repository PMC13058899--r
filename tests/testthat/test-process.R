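# Process-model operations and invariants.

test_that("maturation schedule is anchored at 0.99 for age 7", {
  for (lam in c(0.01, 0.5, 1, 5, 50))
    expect_equal(maturation_prob(lam, 7), 0.99, tolerance = 1e-12)
  expect_equal(maturation_prob(1, 6), 0.97328, tolerance = 1e-4)
  # strictly increasing in age; vanishing at young ages for steep schedules
  th <- maturation_prob(1.2, 4:7)
  expect_true(all(diff(th) > 0))
  expect_lt(maturation_prob(50, 4), 1e-10)
  expect_error(maturation_prob(-1, 5), "lam")
  expect_error(maturation_prob(1, 3), "ages 4-7")
})

test_that("Ricker recruitment has the right limits and maximum", {
  la <- log(48); b <- 1 / 81178
  # low-density limit: juveniles per spawner approaches alpha
  expect_equal(recruit_juveniles(1e-6, la, b) / 1e-6, 48, tolerance = 1e-6)
  # stationary point at S = 1/beta
  smax <- recruit_juveniles(1 / b, la, b)
  expect_equal(smax, exp(la) / b * exp(-1), tolerance = 1e-12)
  expect_equal(smax, 1433497, tolerance = 1e-3)
  expect_gt(smax, recruit_juveniles(1 / b * 0.99, la, b))
  expect_gt(smax, recruit_juveniles(1 / b * 1.01, la, b))
  # recruitment collapses at very high spawner abundance
  expect_lt(recruit_juveniles(50 / b, la, b), 1)
  expect_identical(recruit_juveniles(0, la, b), 0)
  expect_error(recruit_juveniles(-1, la, b))
})

test_that("cohort advance partitions survivors exactly", {
  adv <- advance_cohort(1000, 0.1, 1, 1.0, 1, 0)
  expect_equal(adv$N_next, 1000 * exp(-1.1), tolerance = 1e-12)
  expect_equal(adv$N_next, 332.87, tolerance = 1e-4)
  expect_equal(adv$A, 0)
  # theta = 1 moves all survivors to the mature pool
  adv <- advance_cohort(1000, 0.1, 1, 1.0, 1, 1)
  expect_equal(adv$N_next, 0)
  expect_equal(adv$A, 1000 * exp(-1.1), tolerance = 1e-12)
  # zero rates: nothing happens
  adv <- advance_cohort(500, 0, 0.5, 0, 0.8, 0)
  expect_equal(adv$N_next, 500)
  # partition identity on random inputs
  set.seed(1)
  for (i in 1:50) {
    np <- runif(1, 1, 1e6); fb <- runif(1, 0, 0.5); m <- runif(1, 0, 2)
    th <- runif(1)
    a <- advance_cohort(np, fb, 1, m, 1, th)
    expect_equal(a$N_next + a$A, np * exp(-(fb + m)), tolerance = 1e-12)
  }
  expect_error(advance_cohort(-1, 0, 0, 0, 0, 0))
})

test_that("Baranov bycatch fraction behaves at limits", {
  expect_equal(bycatch_at_age(1000, 0, 0.5, 1, 1), 0)
  expect_equal(bycatch_at_age(1000, 0.3, 1, 0, 0), 1000 * (1 - exp(-0.3)),
               tolerance = 1e-12)
  expect_equal(bycatch_at_age(1000, 0.1, 1, 1, 1),
               0.1 / 1.1 * 1000 * (1 - exp(-1.1)), tolerance = 1e-12)
  expect_equal(bycatch_at_age(1000, 0.1, 1, 1, 1), 60.65, tolerance = 1e-3)
  # Z = 0 limit returns 0, no division by zero
  expect_identical(bycatch_at_age(1000, 0, 0, 0, 0), 0)
})

test_that("bycatch expansion divides by the stock proportion", {
  expect_equal(expand_bycatch(100, 1), 100)
  expect_equal(expand_bycatch(100, 0.5), 200)
  # non-increasing in vartheta
  vs <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(expand_bycatch(100, vs)) < 0))
  expect_error(expand_bycatch(100, 0))
  expect_error(expand_bycatch(100, -0.2))
})

test_that("harvest splits matures and respects limits", {
  h <- harvest_at_age(1000, 0.2, 1)
  expect_equal(h$H, 1000 * (1 - exp(-0.2)), tolerance = 1e-12)
  expect_equal(h$H, 181.27, tolerance = 1e-3)
  expect_equal(h$H + h$S, 1000)
  expect_equal(harvest_at_age(1000, 0, 0.5)$H, 0)
  expect_equal(harvest_at_age(1000, 1e8, 1)$H, 1000)
  expect_error(harvest_at_age(-1, 0.2, 1))
})

test_that("log-space random walk composes multiplicatively", {
  expect_equal(step_random_walk(1, 0), 1)
  expect_equal(step_random_walk(1, log(2)), 2)
  set.seed(2)
  eps <- rnorm(20, 0, 0.3)
  x <- 0.7
  for (e in eps) x <- step_random_walk(x, e)
  expect_equal(x, 0.7 * exp(sum(eps)), tolerance = 1e-12)
  expect_error(step_random_walk(-1, 0))
})

test_that("simulate_population matches the scalar per-cohort oracle", {
  for (seed in 1:100) {
    dims <- ipm_dims(2003, sample(c(8, 10, 14), 1))
    pars <- random_pars(dims, seed)
    st <- simulate_population(pars, dims)
    or <- oracle_simulate(pars, dims)
    for (nm in c("N", "A", "H", "S", "B", "D")) {
      rel <- abs(st[[nm]] - or[[nm]]) / pmax(abs(or[[nm]]), 1e-6)
      expect_lt(max(rel), 1e-10)
    }
    expect_lt(max(abs(st$S_total - or$S_total) /
                    pmax(or$S_total, 1e-6)), 1e-10)
  }
})

test_that("cohort accounting closes exactly, with the age-7 residual", {
  dims <- ipm_dims(2003, 12)
  pars <- random_pars(dims, 99)
  st <- simulate_population(pars, dims)
  # yearly transition identity: N[y-1,a-1] = N[y,a] + A[y,a] + B[y,a] + D[y,a]
  for (y in 2:dims$n_years) {
    for (a in 3:7) {
      lhs <- st$N[y - 1, a - 2]
      rhs <- st$N[y, a - 1] + st$D[y, a - 2] +
        (if (a >= 4) st$A[y, a - 3] else 0) +
        (if (a <= 6) st$B[y, a - 2] else 0)
      expect_lt(abs(lhs - rhs) / max(lhs, 1e-9), 1e-9)
    }
  }
  # whole-cohort conservation for an in-window cohort with full lifespan:
  # recruits = matured + bycaught + natural deaths + age-7 immature residual
  t0 <- 3  # recruited in model year 3, ages 3..7 in years 4..8
  rec <- st$N[t0, 1]
  tot <- 0
  for (a in 3:7) {
    y <- t0 + (a - 2)
    tot <- tot + st$D[y, a - 2] +
      (if (a >= 4) st$A[y, a - 3] else 0) +
      (if (a <= 6) st$B[y, a - 2] else 0)
  }
  resid7 <- st$N[t0 + 5, 6]  # never-maturing 1% of the age-7 survivors
  expect_equal(tot + resid7, rec, tolerance = 1e-9)
  expect_gt(resid7, 0)
  # the leak is exactly the 1% non-maturing share of age-7 arrivals
  expect_equal(resid7 / (resid7 + st$A[t0 + 5, 4]), 0.01, tolerance = 1e-9)
})

test_that("zero rates and zero maturation preserve cohorts", {
  dims <- ipm_dims(2003, 8)
  pars <- random_pars(dims, 5)
  pars$rates <- list(M = rep(0, 8), FB = rep(0, 8), FT = rep(0, 8),
                     lam = rep(0.5, dims$n_cohorts))
  expect_error(build_rates(pars, dims), NA)
  # with all mortality off, abundance only moves between the immature and
  # mature pools of each cohort
  st <- simulate_population(pars, dims)
  expect_equal(st$B, matrix(0, 8, 4), ignore_attr = TRUE)
  expect_equal(st$H, matrix(0, 8, 4), ignore_attr = TRUE)
  expect_equal(unname(st$D), matrix(0, 8, 5))
  # cohort recruited year 3: abundance only moves between N and A
  rec <- st$N[3, 1]
  expect_equal(st$N[4, 2], rec, tolerance = 1e-12)  # age 3, no maturation
  expect_equal(st$N[5, 3] + st$A[5, 1], rec, tolerance = 1e-12)
})

test_that("deterministic recruitment settles toward a fixed point", {
  TT <- 300  # slow spectral decay: give the age-structured lag time to damp
  dims <- ipm_dims(2003, TT)
  scn <- sim_scenario()
  r <- yukonIPM:::scenario_rates(scn)
  # freeze every rate at its initial value and zero all process errors
  pars <- ipm_parameters(
    dims, log_alpha = scn$log_alpha, beta = scn$beta,
    sB = scn$sB, v = scn$v, sT = scn$sT,
    rates = list(M = rep(r$M[1], TT), FB = rep(r$FB[1], TT),
                 FT = rep(r$FT[1], TT), lam = rep(r$lam[1], dims$n_cohorts)),
    log_N0 = log(scn$N0), log_R_init = log(scn$R_init))
  st <- simulate_population(pars, dims)
  # independent fixed-point oracle on total escapement: iterate the scalar
  # spawner -> spawner map implied by constant rates until convergence
  sB6 <- c(0, scn$sB, 0); v5 <- scn$v
  th <- maturation_prob(r$lam[1], 4:7)
  spawner_map <- function(S) {
    n <- S * exp(scn$log_alpha - scn$beta * S)  # juveniles
    out <- 0
    for (a in 3:7) {
      Z <- r$FB[1] * sB6[a - 1] + r$M[1] * v5[a - 2]
      surv <- n * exp(-Z)
      tha <- if (a >= 4) th[a - 3] else 0
      if (a >= 4) {
        A <- surv * tha
        out <- out + A * exp(-r$FT[1] * scn$sT[a - 3])
      }
      n <- surv * (1 - tha)
    }
    out
  }
  # two-year generation lag: the map composes over alternating years, so a
  # fixed point of the map is a fixed point of the dynamics
  S <- stats::uniroot(function(s) spawner_map(s) - s, c(1, 1e7),
                      tol = 1e-6)$root
  expect_equal(st$S_total[TT] / S, 1, tolerance = 1e-4)
  # late-period oscillation has died out
  expect_lt(abs(st$S_total[TT] - st$S_total[TT - 2]) / st$S_total[TT], 1e-5)
})
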