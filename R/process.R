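# Deterministic forward dynamics of the stock: Ricker spawner-to-juvenile
# recruitment, Baranov competing removals (bycatch + natural mortality) on
# immature ages, a cohort-indexed logistic maturation schedule, and terminal
# harvest on mature returns.

# logit of the age-7 maturation anchor: the schedule is constrained so that a
# fish that reaches age 7 matures with probability 0.99 regardless of lambda
.MAT_ANCHOR <- log(1 / 0.99 - 1)

#' Maturation probability at age
#'
#' Modified logistic maturation schedule. For a cohort with schedule
#' parameter \code{lam}, the probability of maturing at age \code{a} is
#' \deqn{\theta = 1 / (1 + e^{\lambda (7 - a) + \log(1/0.99 - 1)})}
#' which is anchored so that \code{theta == 0.99} at age 7 for every positive
#' \code{lam}: fish are constrained to reach maturity by age 7.
#'
#' @param lam Positive maturation-schedule parameter (larger values delay
#'   maturation at ages below 7).
#' @param a Integer age(s) in 4..7. Age-3 fish do not mature in this model.
#' @return Maturation probability in (0, 0.99].
#' @examples
#' maturation_prob(0.5, 7)  # 0.99, for any lam
#' maturation_prob(1, 4:7)
#' @export
maturation_prob <- function(lam, a) {
  if (any(lam <= 0)) stop("maturation schedule parameter lam must be > 0")
  if (any(a < 4 | a > 7)) stop("maturation is defined for ages 4-7 only")
  1 / (1 + exp(lam * (7 - a) + .MAT_ANCHOR))
}

#' Ricker spawner-to-juvenile recruitment
#'
#' Juvenile (age-2) abundance produced by the spawners of the brood year two
#' years earlier: \code{N = S * exp(log_alpha - beta * S + eps)}.
#'
#' @param S_brood Spawner (escapement) abundance in the brood year; must be
#'   positive (recruitment from an exactly empty stock is 0 by convention).
#' @param log_alpha Log of juveniles-per-spawner at low stock size.
#' @param beta Inverse-capacity parameter (>= 0).
#' @param eps Recruitment process error on the log scale (default 0).
#' @return Juvenile abundance.
#' @export
recruit_juveniles <- function(S_brood, log_alpha, beta, eps = 0) {
  if (any(S_brood < 0)) stop("spawner abundance must be non-negative")
  if (beta < 0) stop("beta must be >= 0")
  ifelse(S_brood == 0, 0, S_brood * exp(log_alpha - beta * S_brood + eps))
}

#' Advance one cohort one year
#'
#' Applies competing bycatch and natural mortality over one year and splits
#' the survivors into fish that mature (return to freshwater) and fish that
#' remain immature. Survivors = \code{N_prev * exp(-(FB*sB + M*v))};
#' \code{N_next + A} equals the survivors exactly.
#'
#' @param N_prev Abundance of the cohort at the previous age/year.
#' @param FB Fully selected bycatch mortality rate (>= 0).
#' @param sB Bycatch selectivity at this age, in [0, 1].
#' @param M Post-juvenile natural mortality rate (>= 0).
#' @param v Vulnerability to natural mortality at this age, in [0, 1].
#' @param theta Maturation probability in [0, 1].
#' @return List with \code{N_next} (immature survivors) and \code{A}
#'   (mature returns).
#' @export
advance_cohort <- function(N_prev, FB, sB, M, v, theta) {
  if (any(c(N_prev, FB, sB, M, v) < 0)) stop("negative inputs to advance_cohort")
  if (any(theta < 0 | theta > 1)) stop("theta must be in [0, 1]")
  surv <- N_prev * exp(-(FB * sB + M * v))
  list(N_next = surv * (1 - theta), A = surv * theta)
}

#' Stock-specific bycatch-at-age (Baranov catch equation)
#'
#' Bycatch removals from a cohort over one year under competing bycatch and
#' natural mortality: the bycatch fraction of the total mortality applied to
#' the fish that died. The \code{Z = 0} limit returns 0 analytically.
#'
#' @inheritParams advance_cohort
#' @return Bycatch abundance (fish), indexed to the age the cohort reaches.
#' @export
bycatch_at_age <- function(N_prev, FB, sB, M, v) {
  if (any(c(N_prev, FB, sB, M, v) < 0)) stop("negative inputs to bycatch_at_age")
  FBs <- FB * sB
  Z <- FBs + M * v
  out <- ifelse(Z > 0, (FBs / pmax(Z, .Machine$double.xmin)) * N_prev * (1 - exp(-Z)), 0)
  ifelse(FBs == 0, 0, out)
}

# natural deaths over the same transition (the competing component of Z)
natural_deaths <- function(N_prev, FB, sB, M, v) {
  Mv <- M * v
  Z <- FB * sB + Mv
  ifelse(Z > 0, (Mv / pmax(Z, .Machine$double.xmin)) * N_prev * (1 - exp(-Z)), 0)
}

#' Expand stock-specific bycatch to the aggregate bycatch scale
#'
#' Divides the model-predicted stock-specific bycatch by the proportion of
#' the age class genetically assigned to the focal stock, scaling it up to
#' the total Chinook bycatch abundance-at-age on which the count and age
#' composition data are collected.
#'
#' @param B Stock-specific bycatch abundance.
#' @param vartheta Focal-stock proportion of the age class, in (0, 1].
#' @return Total-scale bycatch abundance \code{B / vartheta}.
#' @export
expand_bycatch <- function(B, vartheta) {
  if (any(B < 0)) stop("bycatch must be non-negative")
  if (any(vartheta <= 0 | vartheta > 1)) stop("vartheta must be in (0, 1]")
  B / vartheta
}

#' Harvest and escapement of mature returns
#'
#' Terminal harvest \code{H = A * (1 - exp(-FT*sT))} and escapement
#' \code{S = A - H}.
#'
#' @param A Mature returns (pre-harvest).
#' @param FT Fully selected harvest mortality rate (>= 0).
#' @param sT Harvest selectivity at this age, in [0, 1].
#' @return List with \code{H} and \code{S}.
#' @export
harvest_at_age <- function(A, FT, sT) {
  if (any(c(A, FT) < 0) || any(sT < 0 | sT > 1)) stop("invalid inputs to harvest_at_age")
  H <- A * (1 - exp(-FT * sT))
  list(H = H, S = A - H)
}

#' One step of a log-space random walk
#'
#' @param prev Previous (positive) rate.
#' @param eps Log-scale innovation.
#' @return \code{exp(log(prev) + eps)}.
#' @export
step_random_walk <- function(prev, eps) {
  if (any(prev <= 0)) stop("random walk operates on positive rates")
  exp(log(prev) + eps)
}

#' Assemble time-varying rate series from initial values and innovations
#'
#' Builds the natural-mortality, bycatch-mortality, harvest-mortality and
#' maturation-schedule series implied by their log-space random walks. If
#' \code{pars$rates} is present (e.g., a counterfactual override), it is
#' returned as-is after validation.
#'
#' @param pars An \code{ipm_parameters} list (see \code{\link{ipm_parameters}}).
#' @param dims An \code{\link{ipm_dims}} object.
#' @return List with per-year \code{M}, \code{FB}, \code{FT} and per-cohort
#'   \code{lam}.
#' @export
build_rates <- function(pars, dims) {
  if (!is.null(pars$rates)) {
    r <- pars$rates
    stopifnot(length(r$M) == dims$n_years, length(r$FB) == dims$n_years,
              length(r$FT) == dims$n_years, length(r$lam) == dims$n_cohorts)
    if (any(r$M < 0) || any(r$FB < 0) || any(r$FT < 0) || any(r$lam <= 0))
      stop("rate overrides must be non-negative (lam strictly positive)")
    return(r)
  }
  list(
    M   = exp(pars$log_M_init  + cumsum(c(0, pars$eps_M))),
    FB  = exp(pars$log_FB_init + cumsum(c(0, pars$eps_B))),
    FT  = exp(pars$log_FT_init + cumsum(c(0, pars$eps_T))),
    lam = exp(pars$log_lam_init + cumsum(c(0, pars$eps_lambda)))
  )
}

#' Simulate the full latent population trajectory
#'
#' Runs the deterministic life-cycle dynamics for the whole model window
#' given a complete parameter set: recruits juveniles from escapement two
#' years prior (first two juvenile years are free initial recruits), advances
#' each cohort through competing bycatch/natural mortality and maturation,
#' applies terminal harvest, and accumulates spawning escapement which feeds
#' back into recruitment. Initial conditions are free abundances at ages 2-6
#' in the year preceding the first model year, so matures, escapement and
#' bycatch are defined in every modelled year.
#'
#' @param pars An \code{\link{ipm_parameters}} list.
#' @param dims An \code{\link{ipm_dims}} object.
#' @return An object of class \code{ipm_state}: year-by-age matrices
#'   \code{N} (immature abundance, ages 2-7), \code{A} (mature returns),
#'   \code{H}, \code{S} (ages 4-7), \code{B}, \code{BA} (bycatch, stock and
#'   aggregate scale, ages 3-6), \code{D} (natural deaths, ages 3-7),
#'   \code{theta} (maturation probabilities applied), predicted composition
#'   proportions \code{pi_S}, \code{pi_H}, \code{pi_B}, and the vectors
#'   \code{S_total} and \code{run_size}.
#' @export
simulate_population <- function(pars, dims) {
  T <- dims$n_years
  rates <- build_rates(pars, dims)
  M <- rates$M; FB <- rates$FB; FT <- rates$FT; lam <- rates$lam
  sB <- c(0, pars$sB, 0)            # ages 2..7 -> 0, (3..6), 0
  names(sB) <- NULL
  v  <- pars$v                      # ages 3..7 (v[1] fixed 1)
  sT <- pars$sT                     # ages 4..7

  yrs <- dims$years
  N  <- matrix(0, T, 6, dimnames = list(yrs, 2:7))
  A  <- matrix(0, T, 4, dimnames = list(yrs, 4:7))
  H  <- A; S <- A; theta <- A
  B  <- matrix(0, T, 4, dimnames = list(yrs, 3:6))
  D  <- matrix(0, T, 5, dimnames = list(yrs, 3:7))
  S_total <- numeric(T)

  N0 <- exp(pars$log_N0)            # virtual year-0 abundance at ages 2..6
  if (length(N0) != 5) stop("log_N0 must hold ages 2-6 of the initialization year")

  lam_for <- function(yc) {
    yc <- min(max(yc, 1L), dims$n_cohorts)  # pre-window cohorts share lam[1]
    lam[yc]
  }

  for (y in seq_len(T)) {
    # juvenile recruitment
    if (y <= 2) {
      N[y, 1] <- exp(pars$log_R_init[y])
    } else {
      N[y, 1] <- recruit_juveniles(S_total[y - 2], pars$log_alpha, pars$beta,
                                   pars$eps_R[y - 2])
    }
    # cohort transitions into ages 3..7
    for (a in 3:7) {
      ai <- a - 1L                      # column in N (ages 2..7)
      N_prev <- if (y == 1) N0[a - 2L] else N[y - 1, ai - 1L]
      th <- if (a >= 4) maturation_prob(lam_for(cohort_index(y, a)), a) else 0
      adv <- advance_cohort(N_prev, FB[y], sB[ai], M[y], v[a - 2L], th)
      N[y, ai] <- adv$N_next
      if (a >= 4) {
        A[y, a - 3L] <- adv$A
        theta[y, a - 3L] <- th
      }
      if (a >= 3 && a <= 6)
        B[y, a - 2L] <- bycatch_at_age(N_prev, FB[y], sB[ai], M[y], v[a - 2L])
      D[y, a - 2L] <- natural_deaths(N_prev, FB[y], sB[ai], M[y], v[a - 2L])
    }
    hv <- harvest_at_age(A[y, ], FT[y], sT)
    H[y, ] <- hv$H
    S[y, ] <- hv$S
    S_total[y] <- sum(S[y, ])
  }

  vt <- invlogit(pars$logit_vartheta)   # T x 4, ages 3..6
  BA <- B / vt

  pi_S <- S / pmax(rowSums(S), .Machine$double.xmin)
  pi_H <- H / pmax(rowSums(H), .Machine$double.xmin)
  pi_B <- BA / pmax(rowSums(BA), .Machine$double.xmin)

  structure(list(
    N = N, A = A, H = H, S = S, B = B, BA = BA, D = D, theta = theta,
    pi_S = pi_S, pi_H = pi_H, pi_B = pi_B,
    S_total = S_total, run_size = rowSums(A),
    vartheta = vt, rates = rates, dims = dims
  ), class = "ipm_state")
}

#' @export
print.ipm_state <- function(x, ...) {
  d <- x$dims
  cat("ipm_state: ", d$n_years, " years (", d$years[1], "-", d$years[d$n_years],
      ")\n", sep = "")
  cat("  run size: median ", format(round(stats::median(x$run_size))),
      ", range ", format(round(min(x$run_size))), "-",
      format(round(max(x$run_size))), " fish\n", sep = "")
  invisible(x)
}
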