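# Natural-scale parameter container and the bijection to the unconstrained
# sampling space (mirrored exactly by the TMB template).

#' Construct and validate a full parameter set
#'
#' Collects every quantity the life-cycle dynamics need on the natural scale:
#' Ricker terms, process-error SDs and innovation series, random-walk initial
#' values, selectivity/vulnerability schedules, initialization abundances and
#' the bycatch stock-composition proportions.
#'
#' @param dims An \code{\link{ipm_dims}} object.
#' @param log_alpha Log Ricker productivity.
#' @param beta Ricker inverse-capacity (>= 0).
#' @param sigma_R,sigma_M,sigma_B,sigma_T,sigma_lambda Process-error SDs
#'   (recruitment; natural-mortality, bycatch, harvest walks; maturation walk).
#' @param sB Bycatch selectivity at ages 3-6, each in [0, 1].
#' @param v Vulnerability to natural mortality at ages 3-7; the age-3 value is
#'   fixed at 1 and ages 4-7 lie in [0.5, 1].
#' @param sT Harvest selectivity at ages 4-7, each in [0, 1].
#' @param log_M_init,log_FB_init,log_FT_init,log_lam_init Initial log values
#'   of the four random walks (\code{log_lam_init} must be >= 0, i.e. the
#'   first cohort's schedule parameter is at least 1).
#' @param eps_M,eps_B,eps_T Log-space innovations, length \code{n_years - 1}.
#' @param eps_lambda Maturation-walk innovations over cohorts, length
#'   \code{n_cohorts - 1}.
#' @param eps_R Recruitment errors for model years 3..n_years (length
#'   \code{n_years - 2}); the first two juvenile years are free recruits.
#' @param log_N0 Log abundance at ages 2-6 in the virtual year preceding the
#'   first model year (length 5).
#' @param log_R_init Log juvenile abundance in the first two model years
#'   (length 2), whose brood years predate the data.
#' @param muG,sigmaG Among-year mean and SD of logit focal-stock proportions,
#'   one per bycatch age 3-6.
#' @param logit_vartheta Matrix (\code{n_years} x 4) of logit focal-stock
#'   proportions of the bycatch at ages 3-6.
#' @param rates Optional explicit rate series (list \code{M}, \code{FB},
#'   \code{FT}, \code{lam}) overriding the random-walk construction, used by
#'   counterfactual scenarios.
#' @return A validated list of class \code{ipm_parameters}.
#' @export
ipm_parameters <- function(dims,
                           log_alpha, beta,
                           sigma_R = 0.5, sigma_M = 0.1, sigma_B = 0.3,
                           sigma_T = 0.3, sigma_lambda = 0.05,
                           sB, v, sT,
                           log_M_init = log(1.1), log_FB_init = log(0.01),
                           log_FT_init = log(0.5), log_lam_init = 1,
                           eps_M = numeric(dims$n_years - 1L),
                           eps_B = numeric(dims$n_years - 1L),
                           eps_T = numeric(dims$n_years - 1L),
                           eps_lambda = numeric(dims$n_cohorts - 1L),
                           eps_R = numeric(dims$n_years - 2L),
                           log_N0 = rep(11, 5), log_R_init = rep(13, 2),
                           muG = rep(logit(0.05), 4), sigmaG = rep(0.3, 4),
                           logit_vartheta = matrix(logit(0.05), dims$n_years, 4),
                           rates = NULL) {
  p <- list(log_alpha = log_alpha, beta = beta,
            sigma_R = sigma_R, sigma_M = sigma_M, sigma_B = sigma_B,
            sigma_T = sigma_T, sigma_lambda = sigma_lambda,
            sB = sB, v = v, sT = sT,
            log_M_init = log_M_init, log_FB_init = log_FB_init,
            log_FT_init = log_FT_init, log_lam_init = log_lam_init,
            eps_M = eps_M, eps_B = eps_B, eps_T = eps_T,
            eps_lambda = eps_lambda, eps_R = eps_R,
            log_N0 = log_N0, log_R_init = log_R_init,
            muG = muG, sigmaG = sigmaG,
            logit_vartheta = logit_vartheta, rates = rates)
  validate_parameters(p, dims)
  structure(p, class = "ipm_parameters")
}

validate_parameters <- function(p, dims) {
  T <- dims$n_years
  stopifnot(
    length(p$log_alpha) == 1, p$beta >= 0,
    p$sigma_R >= 0, p$sigma_M >= 0, p$sigma_B >= 0, p$sigma_T >= 0,
    p$sigma_lambda >= 0,
    length(p$sB) == 4, all(p$sB >= 0 & p$sB <= 1),
    length(p$v) == 5, all(p$v[-1] >= 0.5 & p$v[-1] <= 1),
    length(p$sT) == 4, all(p$sT >= 0 & p$sT <= 1),
    length(p$eps_M) == T - 1, length(p$eps_B) == T - 1,
    length(p$eps_T) == T - 1, length(p$eps_lambda) == dims$n_cohorts - 1,
    length(p$eps_R) == T - 2,
    length(p$log_N0) == 5, length(p$log_R_init) == 2,
    length(p$muG) == 4, length(p$sigmaG) == 4, all(p$sigmaG >= 0),
    is.matrix(p$logit_vartheta), nrow(p$logit_vartheta) == T,
    ncol(p$logit_vartheta) == 4
  )
  if (p$v[1] != 1) stop("vulnerability at age 3 is fixed at 1")
  if (is.null(p$rates) && p$log_lam_init < 0)
    stop("log_lam_init must be >= 0 (first cohort's schedule parameter >= 1)")
  invisible(p)
}

# ---- bijection natural <-> unconstrained (order mirrors the TMB template) --

# reference spawner level for the Ricker rotation: the first unconstrained
# coordinate is the log juveniles-per-spawner at this escapement, the
# direction the data inform directly (decorrelates the alpha-beta ridge)
.S_REF <- 5e4

yukonIPM_s_ref <- function() .S_REF

unconstrained_length <- function(dims) {
  T <- dims$n_years
  1L + 1L + 5L + 4L + 4L + 4L + 4L + 3L * (T - 1L) +
    (dims$n_cohorts - 1L) + (T - 2L) + 5L + 2L + 4L + 4L + 4L * T
}

#' Map a natural-scale parameter set to the unconstrained sampling vector
#'
#' Bounded quantities are logit/log transformed and positive SDs log
#' transformed. The mortality/harvest walks, recruitment errors and
#' stock-composition logits are centred (their data streams dominate);
#' the weakly informed maturation walk is non-centred (standard-normal
#' deviates scaled by its SD). The layout matches the TMB objective
#' exactly.
#'
#' @param pars An \code{\link{ipm_parameters}} list (without rate overrides).
#' @param dims An \code{\link{ipm_dims}} object.
#' @return Numeric vector of length \code{unconstrained_length(dims)}.
#' @export
pack_parameters <- function(pars, dims) {
  p <- pars
  zdiv <- function(e, s) if (s > 0) e / s else e * 0
  c(p$log_alpha - p$beta * .S_REF,
    log(p$beta),
    log(c(p$sigma_R, p$sigma_M, p$sigma_B, p$sigma_T, p$sigma_lambda)),
    logit(p$sB),
    logit((p$v[-1] - 0.5) / 0.5),
    logit(p$sT),
    log(p$log_lam_init),
    p$log_M_init + cumsum(c(0, p$eps_M)),
    p$log_FB_init + cumsum(c(0, p$eps_B)),
    p$log_FT_init + cumsum(c(0, p$eps_T)),
    zdiv(p$eps_lambda, p$sigma_lambda),
    p$eps_R,
    p$log_N0, p$log_R_init,
    p$muG, log(p$sigmaG),
    as.vector(p$logit_vartheta))
}

#' Inverse of \code{\link{pack_parameters}}
#' @param u Unconstrained vector.
#' @param dims An \code{\link{ipm_dims}} object.
#' @return An \code{ipm_parameters} list on the natural scale.
#' @export
unpack_parameters <- function(u, dims) {
  T <- dims$n_years
  i <- 0L
  take <- function(k) { out <- u[(i + 1L):(i + k)]; i <<- i + k; out }
  u_prod <- take(1L)
  beta <- exp(take(1L))
  log_alpha <- u_prod + beta * .S_REF
  sig <- exp(take(5L))
  sB <- invlogit(take(4L))
  v <- c(1, 0.5 + 0.5 * invlogit(take(4L)))
  sT <- invlogit(take(4L))
  log_lam_init <- exp(take(1L))
  lM <- take(T); lFB <- take(T); lFT <- take(T)
  z_lam <- take(dims$n_cohorts - 1L); eps_R <- take(T - 2L)
  log_N0 <- take(5L); log_R_init <- take(2L)
  muG <- take(4L); sigmaG <- exp(take(4L))
  lv_G <- matrix(take(4L * T), T, 4)
  ipm_parameters(
    dims,
    log_alpha = log_alpha, beta = beta,
    sigma_R = sig[1], sigma_M = sig[2], sigma_B = sig[3], sigma_T = sig[4],
    sigma_lambda = sig[5],
    sB = sB, v = v, sT = sT,
    log_M_init = lM[1], log_FB_init = lFB[1],
    log_FT_init = lFT[1], log_lam_init = log_lam_init,
    eps_M = diff(lM), eps_B = diff(lFB), eps_T = diff(lFT),
    eps_lambda = sig[5] * z_lam, eps_R = eps_R,
    log_N0 = log_N0, log_R_init = log_R_init,
    muG = muG, sigmaG = sigmaG,
    logit_vartheta = lv_G
  )
}

# log |d(natural)/d(unconstrained)|: the density adjustment that, added to
# the natural-scale log prior and log likelihood, gives the unconstrained
# log posterior the sampler explores
log_jacobian <- function(pars, dims) {
  T <- dims$n_years
  p01 <- function(x) sum(log(x) + log1p(-x))
  pv <- (pars$v[-1] - 0.5) / 0.5
  sum(log(pars$beta),
      log(c(pars$sigma_R, pars$sigma_M, pars$sigma_B, pars$sigma_T,
            pars$sigma_lambda)),
      p01(pars$sB),
      4 * log(0.5) + p01(pv),
      p01(pars$sT),
      log(pars$log_lam_init),
      (dims$n_cohorts - 1) * log(pars$sigma_lambda),
      log(pars$sigmaG))
}
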