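# Prior configuration and the natural-scale log prior density.

#' Prior configuration
#'
#' One entry per estimated leading parameter: a (possibly truncated) normal
#' with the stated mean, SD and bounds. Bounds are honoured by truncation
#' (the log density includes the truncation normalization constant).
#' Initialization abundances carry diffuse lognormal priors (log-SD 5).
#'
#' @param mu_log_N0 Prior means of the log initialization abundances at ages
#'   2-6 (virtual year 0).
#' @param mu_log_R_init Prior mean of the log free juvenile recruitments in
#'   the first two model years.
#' @param sd_init Prior log-SD of all initialization abundances.
#' @return A list of class \code{ipm_priors} with elements
#'   \code{(mean, sd, lower, upper)} per parameter.
#' @export
ipm_priors <- function(mu_log_N0 = rep(11, 5), mu_log_R_init = rep(13, 2),
                       sd_init = 5) {
  tn <- function(mean, sd, lower = -Inf, upper = Inf)
    list(mean = mean, sd = sd, lower = lower, upper = upper)
  structure(list(
    log_alpha    = tn(0, 12.5),
    beta         = tn(0, 5, 0, Inf),
    sigma_R      = tn(0, 5, 0, Inf),
    sigma_M      = tn(0, 5, 0, Inf),
    sigma_B      = tn(0, 5, 0, Inf),
    sigma_T      = tn(0, 5, 0, Inf),
    sigma_lambda = tn(0, 5, 0, Inf),
    sB           = tn(0, 1, 0, 1),
    v            = tn(0, 1, 0.5, 1),
    sT           = tn(0, 1, 0, 1),
    log_M_init   = tn(0, 5),
    log_FB_init  = tn(0, 7.5),
    log_FT_init  = tn(0, 5),
    log_lam_init = tn(1, 1, 0, Inf),
    muG          = tn(0, 5),
    sigmaG       = tn(0, 5, 0, Inf),
    mu_log_N0 = mu_log_N0, mu_log_R_init = mu_log_R_init, sd_init = sd_init
  ), class = "ipm_priors")
}

# truncated normal log density, with normalization constant
dtnorm_log <- function(x, spec) {
  lo <- spec$lower; up <- spec$upper
  if (any(x < lo | x > up)) return(-Inf)
  z <- stats::pnorm(up, spec$mean, spec$sd) - stats::pnorm(lo, spec$mean, spec$sd)
  sum(stats::dnorm(x, spec$mean, spec$sd, log = TRUE)) - length(x) * log(z)
}

#' Natural-scale log prior density
#'
#' Sum of the truncated-normal log densities of every leading parameter
#' (including truncation normalization constants), the normal densities of
#' all random-walk innovations and recruitment errors given their SDs, and
#' the diffuse lognormal initialization priors. The hierarchical density of
#' the stock-composition logits belongs to the likelihood side (it is a
#' data-pooling device), not the prior.
#'
#' @param pars An \code{\link{ipm_parameters}} list.
#' @param priors An \code{\link{ipm_priors}} list.
#' @param dims An \code{\link{ipm_dims}} object.
#' @return Scalar log density (\code{-Inf} outside the declared bounds).
#' @export
log_prior <- function(pars, priors = ipm_priors(), dims) {
  lp <- dtnorm_log(pars$log_alpha, priors$log_alpha) +
    dtnorm_log(pars$beta, priors$beta) +
    dtnorm_log(pars$sigma_R, priors$sigma_R) +
    dtnorm_log(pars$sigma_M, priors$sigma_M) +
    dtnorm_log(pars$sigma_B, priors$sigma_B) +
    dtnorm_log(pars$sigma_T, priors$sigma_T) +
    dtnorm_log(pars$sigma_lambda, priors$sigma_lambda) +
    dtnorm_log(pars$sB, priors$sB) +
    dtnorm_log(pars$v[-1], priors$v) +
    dtnorm_log(pars$sT, priors$sT) +
    dtnorm_log(pars$log_M_init, priors$log_M_init) +
    dtnorm_log(pars$log_FB_init, priors$log_FB_init) +
    dtnorm_log(pars$log_FT_init, priors$log_FT_init) +
    dtnorm_log(pars$log_lam_init, priors$log_lam_init) +
    dtnorm_log(pars$muG, priors$muG) +
    dtnorm_log(pars$sigmaG, priors$sigmaG)
  if (!is.finite(lp)) return(-Inf)
  lp +
    sum(stats::dnorm(pars$eps_M, 0, pars$sigma_M, log = TRUE)) +
    sum(stats::dnorm(pars$eps_B, 0, pars$sigma_B, log = TRUE)) +
    sum(stats::dnorm(pars$eps_T, 0, pars$sigma_T, log = TRUE)) +
    sum(stats::dnorm(pars$eps_lambda, 0, pars$sigma_lambda, log = TRUE)) +
    sum(stats::dnorm(pars$eps_R, 0, pars$sigma_R, log = TRUE)) +
    sum(stats::dnorm(pars$log_N0, priors$mu_log_N0, priors$sd_init, log = TRUE)) +
    sum(stats::dnorm(pars$log_R_init, priors$mu_log_R_init, priors$sd_init,
                     log = TRUE))
}
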