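# Bridge between the R-side containers and the TMB-autodifferentiated joint
# posterior: data marshalling, parameter templates and initial values.

tmb_data <- function(data, cfg = ipm_obs_config(), priors = ipm_priors(),
                     fractional = FALSE) {
  T <- data$dims$n_years
  flg <- function(v) as.integer(!is.na(v))
  val <- function(v) ifelse(is.na(v), 1, v)
  row_ok <- function(m) as.integer(apply(m, 1, function(r) !anyNA(r)))
  cmat <- function(q, neff, ok) {
    out <- matrix(0, T, 4)
    for (y in which(ok == 1L)) {
      out[y, ] <- if (fractional) q[y, ] * neff[y]
                  else counts_from_props(q[y, ], neff[y])
    }
    out
  }
  fqE <- row_ok(data$qE); fqC <- row_ok(data$qC)
  fqB <- as.integer(row_ok(data$qB) == 1L & !is.na(data$nB) & data$nB > 0)
  list(
    J = val(data$J), fJ = flg(data$J),
    E = val(data$E), fE = flg(data$E),
    C = val(data$C), fC = flg(data$C),
    b = val(data$b_total), fb = flg(data$b_total),
    cntE = cmat(data$qE, rep(cfg$neff_E, T), fqE), fqE = fqE,
    cntC = cmat(data$qC, rep(cfg$neff_C, T), fqC), fqC = fqC,
    cntB = cmat(data$qB, val(data$nB), fqB), fqB = fqB,
    gx = ifelse(is.na(data$x) | is.na(data$n), 0, data$x),
    gn = ifelse(is.na(data$n), 0, data$n),
    sigma_J = cfg$sigma_J, sigma_E = cfg$sigma_E,
    sigma_C = cfg$sigma_C, sigma_b = cfg$sigma_b,
    mu_N0 = priors$mu_log_N0, mu_R0 = priors$mu_log_R_init,
    sd_init = priors$sd_init, S_ref = yukonIPM_s_ref()
  )
}

tmb_parameter_template <- function(dims) {
  T <- dims$n_years
  list(
    u_prod = 0, u_beta = 0,
    log_sigma_R = 0, log_sigma_M = 0, log_sigma_B = 0, log_sigma_T = 0,
    log_sigma_lam = 0,
    u_sB = numeric(4), u_v = numeric(4), u_sT = numeric(4),
    u_lam_init = 0,
    lM = numeric(T), lFB = numeric(T), lFT = numeric(T),
    z_lam = numeric(dims$n_cohorts - 1), eps_R = numeric(T - 2),
    log_N0 = numeric(5), log_R_init = numeric(2),
    muG = numeric(4), log_sigmaG = numeric(4),
    lv_G = numeric(4 * T)
  )
}

# relist an unconstrained vector into the TMB parameter template
relist_tmb <- function(u, dims) {
  tpl <- tmb_parameter_template(dims)
  utils::relist(u, tpl)
}

#' Build the TMB objective for a dataset
#'
#' Constructs the autodifferentiated negative log posterior (and gradient)
#' over the unconstrained parameter vector laid out by
#' \code{\link{pack_parameters}}.
#'
#' @param data An \code{\link{ipm_data}} object.
#' @param cfg An \code{\link{ipm_obs_config}}.
#' @param priors An \code{\link{ipm_priors}}.
#' @param fractional Use fractional-count multinomials.
#' @param init Optional unconstrained starting vector.
#' @return The object returned by \code{TMB::MakeADFun} (elements \code{fn},
#'   \code{gr}, \code{par}, \code{report}).
#' @export
ipm_objective <- function(data, cfg = ipm_obs_config(), priors = ipm_priors(),
                          fractional = FALSE, init = NULL) {
  dims <- data$dims
  par <- if (is.null(init)) tmb_parameter_template(dims)
         else relist_tmb(init, dims)
  TMB::MakeADFun(
    data = tmb_data(data, cfg, priors, fractional),
    parameters = par, DLL = "yukonIPM", silent = TRUE
  )
}

# data-informed starting point on the unconstrained scale
default_init <- function(data, dims, jitter = 0, rng_jitter = function(n) stats::rnorm(n, 0, jitter)) {
  T <- dims$n_years
  Jm <- mean(data$J, na.rm = TRUE)
  if (!is.finite(Jm)) Jm <- 1e6
  Em <- mean(data$E, na.rm = TRUE)
  if (!is.finite(Em)) Em <- 5e4
  Cm <- mean(data$C, na.rm = TRUE)
  if (!is.finite(Cm)) Cm <- 1e4
  h <- min(max(Cm / (Cm + Em), 0.02), 0.9)
  bm <- mean(data$b_total, na.rm = TRUE)
  if (!is.finite(bm)) bm <- 1e4
  ptot <- pmin(pmax(colSums(data$x, na.rm = TRUE) /
                      pmax(colSums(data$n, na.rm = TRUE), 1), 0.005), 0.6)
  beta0 <- 1 / (20 * Em)
  u <- c(
    u_prod = log(30) - beta0 * yukonIPM_s_ref(),
    u_beta = log(beta0),
    log_sigma_R = log(0.5), log_sigma_M = log(0.15), log_sigma_B = log(0.25),
    log_sigma_T = log(0.25), log_sigma_lam = log(0.08),
    u_sB = logit(c(0.05, 0.2, 0.5, 0.3)),
    u_v = rep(0, 4),
    u_sT = rep(logit(0.6), 4),
    u_lam_init = 0,
    lM = rep(log(1.1), T),
    lFB = rep(log(max(0.05 * bm * mean(ptot) / (0.3 * Jm * 0.2), 1e-4)), T),
    lFT = rep(log(-log(1 - h)), T),
    z_lam = numeric(dims$n_cohorts - 1), eps_R = numeric(T - 2),
    log_N0 = log(c(1, 0.33, 0.15, 0.05, 0.004) * Jm),
    log_R_init = rep(log(Jm), 2),
    muG = logit(ptot), log_sigmaG = rep(log(0.3), 4),
    lv_G = rep(logit(ptot), each = T)
  )
  unname(u) + rng_jitter(length(u))
}
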