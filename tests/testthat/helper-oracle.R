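# Independent scalar oracles used across the suite.

# Per-cohort scalar bookkeeping oracle for the population dynamics: advances
# one cohort at a time with scalar arithmetic written directly from the
# stage-transition definitions (logistic maturation via plogis), independent
# of the package's vectorized year loop.
oracle_simulate <- function(pars, dims) {
  T <- dims$n_years
  if (!is.null(pars$rates)) {
    M <- pars$rates$M; FB <- pars$rates$FB; FT <- pars$rates$FT
    lam <- pars$rates$lam
  } else {
    M <- numeric(T); FB <- numeric(T); FT <- numeric(T)
    M[1] <- exp(pars$log_M_init); FB[1] <- exp(pars$log_FB_init)
    FT[1] <- exp(pars$log_FT_init)
    for (y in 2:T) {
      M[y] <- M[y - 1] * exp(pars$eps_M[y - 1])
      FB[y] <- FB[y - 1] * exp(pars$eps_B[y - 1])
      FT[y] <- FT[y - 1] * exp(pars$eps_T[y - 1])
    }
    lam <- numeric(dims$n_cohorts)
    lam[1] <- exp(pars$log_lam_init)
    for (cc in seq_len(dims$n_cohorts - 1))
      lam[cc + 1] <- lam[cc] * exp(pars$eps_lambda[cc])
  }
  sBa <- function(a) if (a >= 3 && a <= 6) pars$sB[a - 2] else 0
  va <- function(a) pars$v[a - 2]
  sTa <- function(a) pars$sT[a - 3]
  theta_f <- function(yc, a) {
    yc <- min(max(yc, 1), dims$n_cohorts)
    stats::plogis(-(lam[yc] * (7 - a) + log(1 / 0.99 - 1)))
  }
  N <- matrix(0, T, 6); A <- matrix(0, T, 4); H <- matrix(0, T, 4)
  S <- matrix(0, T, 4); B <- matrix(0, T, 4); D <- matrix(0, T, 5)
  S_total <- numeric(T)
  # one cohort: given abundance n_at at age a0 in year y0, walk it forward
  advance <- function(n, a0, y0) {
    a <- a0; y <- y0
    while (a < 7 && y < T) {
      a2 <- a + 1; y2 <- y + 1
      Z <- FB[y2] * sBa(a2) + M[y2] * va(a2)
      dead_B <- if (FB[y2] * sBa(a2) > 0)
        FB[y2] * sBa(a2) / Z * n * (1 - exp(-Z)) else 0
      dead_M <- if (M[y2] * va(a2) > 0)
        M[y2] * va(a2) / Z * n * (1 - exp(-Z)) else 0
      surv <- n * exp(-Z)
      th <- if (a2 >= 4) theta_f(y2 - (a2 - 2), a2) else 0
      mat <- surv * th
      if (a2 >= 4) {
        A[y2, a2 - 3] <<- A[y2, a2 - 3] + mat
        h <- mat * (1 - exp(-FT[y2] * sTa(a2)))
        H[y2, a2 - 3] <<- H[y2, a2 - 3] + h
        S[y2, a2 - 3] <<- S[y2, a2 - 3] + (mat - h)
      }
      if (a2 <= 6) B[y2, a2 - 2] <<- B[y2, a2 - 2] + dead_B
      D[y2, a2 - 2] <<- D[y2, a2 - 2] + dead_M
      n <- surv * (1 - th)
      N[y2, a2 - 1] <<- N[y2, a2 - 1] + n
      a <- a2; y <- y2
    }
  }
  # virtual year-0 cohorts (ages 2-6)
  N0 <- exp(pars$log_N0)
  for (a0 in 2:6) advance(N0[a0 - 1], a0, 0)
  # in-window recruits, year by year (recruitment needs escapement feedback)
  for (y in 1:T) {
    S_total[y] <- sum(S[y, ])
    rec <- if (y <= 2) exp(pars$log_R_init[y])
           else S_total[y - 2] * exp(pars$log_alpha -
                                     pars$beta * S_total[y - 2] +
                                     pars$eps_R[y - 2])
    N[y, 1] <- N[y, 1] + rec
    advance(rec, 2, y)
    # escapement from cohorts maturing later this year is already recorded
    S_total[y] <- sum(S[y, ])
  }
  list(N = N, A = A, H = H, S = S, B = B, D = D,
       S_total = S_total, run_size = rowSums(A))
}

# random but valid parameter set on a given calendar
random_pars <- function(dims, seed) {
  set.seed(seed)
  T <- dims$n_years
  ipm_parameters(
    dims,
    log_alpha = log(stats::runif(1, 15, 70)),
    beta = 1 / stats::runif(1, 4e4, 3e5),
    sigma_R = stats::runif(1, 0.2, 0.8),
    sigma_M = stats::runif(1, 0.02, 0.2),
    sigma_B = stats::runif(1, 0.05, 0.4),
    sigma_T = stats::runif(1, 0.05, 0.4),
    sigma_lambda = stats::runif(1, 0.01, 0.1),
    sB = stats::runif(4), v = c(1, stats::runif(4, 0.5, 1)),
    sT = stats::runif(4),
    log_M_init = log(stats::runif(1, 0.7, 1.6)),
    log_FB_init = log(stats::runif(1, 0.002, 0.05)),
    log_FT_init = log(stats::runif(1, 0.1, 0.8)),
    log_lam_init = stats::runif(1, 0.2, 1.4),
    eps_M = stats::rnorm(T - 1, 0, 0.1),
    eps_B = stats::rnorm(T - 1, 0, 0.2),
    eps_T = stats::rnorm(T - 1, 0, 0.2),
    eps_lambda = stats::rnorm(dims$n_cohorts - 1, 0, 0.05),
    eps_R = stats::rnorm(T - 2, 0, 0.5),
    log_N0 = log(stats::runif(5, 1e3, 1e6)),
    log_R_init = log(stats::runif(2, 1e5, 3e6)),
    muG = stats::rnorm(4, -3, 0.5),
    sigmaG = stats::runif(4, 0.1, 0.5),
    logit_vartheta = matrix(stats::rnorm(T * 4, -3, 0.5), T, 4)
  )
}

# generic density oracles, written from the pmf/pdf definitions
oracle_dlnorm <- function(x, mu, sigma)
  -log(x) - log(sigma) - 0.5 * log(2 * pi) - (log(x) - mu)^2 / (2 * sigma^2)

oracle_dmultinom <- function(cnt, pr) {
  lgamma(sum(cnt) + 1) - sum(lgamma(cnt + 1)) +
    sum(ifelse(cnt > 0, cnt * log(pr), 0))
}

oracle_dbinom <- function(x, n, p)
  lchoose(n, x) + x * log(p) + (n - x) * log1p(-p)
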