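# Log-likelihood terms for the five observation streams, and their sum.

#' Lognormal index log-likelihood
#'
#' Log density of an abundance observation around a model prediction on the
#' log scale: the prediction is the lognormal median (no bias correction).
#' Missing observations (NA) contribute 0.
#'
#' @param obs Observed positive value(s); NA entries are dropped.
#' @param pred Model-predicted positive value(s).
#' @param sigma Log-scale SD.
#' @return Summed log density.
#' @export
loglik_lognormal_index <- function(obs, pred, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  keep <- !is.na(obs)
  if (!any(keep)) return(0)
  if (any(obs[keep] <= 0)) stop("observations must be positive")
  if (any(pred[keep] <= 0)) return(-Inf)
  sum(stats::dlnorm(obs[keep], log(pred[keep]), sigma, log = TRUE))
}

#' Age-composition (multinomial) log-likelihood
#'
#' Observed composition proportions are scaled by the effective sample size
#' and rounded to integer counts (largest-remainder repair) to form a proper
#' multinomial observation; a continuous fractional-count variant (gamma
#' functions in place of factorials) is available for sensitivity.
#'
#' @param q Observed proportions (simplex).
#' @param neff Effective sample size.
#' @param pi Predicted proportions (simplex on the same ages).
#' @param fractional Use fractional counts \code{q * neff} directly.
#' @return Log density; \code{-Inf} (with a warning) if a category with
#'   positive count has predicted proportion 0.
#' @export
loglik_agecomp <- function(q, neff, pi, fractional = FALSE) {
  stopifnot(length(q) == length(pi), neff > 0)
  cnt <- if (fractional) q * neff else counts_from_props(q, neff)
  pos <- cnt > 0
  if (any(pi[pos] == 0)) {
    warning("predicted composition has zero mass in an observed age class")
    return(-Inf)
  }
  lgamma(sum(cnt) + 1) - sum(lgamma(cnt + 1)) + sum(cnt[pos] * log(pi[pos]))
}

#' Genetic stock-assignment (binomial) log-likelihood
#'
#' @param x Assignments to the focal stock (0 <= x <= n); NA cells dropped.
#' @param n Genotyped sample sizes; cells with \code{n = 0} contribute 0.
#' @param vartheta Focal-stock proportions in (0, 1).
#' @return Summed binomial log-pmf.
#' @export
loglik_stock_assignment <- function(x, n, vartheta) {
  keep <- !is.na(x) & !is.na(n) & n > 0
  if (!any(keep)) return(0)
  if (any(x[keep] > n[keep])) stop("x cannot exceed n")
  sum(stats::dbinom(x[keep], n[keep], vartheta[keep], log = TRUE))
}

#' Hierarchical stock-composition log density
#'
#' Normal density of the logit focal-stock proportions around age-specific
#' among-year means, the partial-pooling device that informs years without
#' genetic assignment data.
#'
#' @param vartheta Matrix (years x ages 3-6) of proportions in (0, 1).
#' @param muG,sigmaG Age-specific among-year mean and SD of the logits.
#' @return Summed log density.
#' @export
loglik_stock_hierarchy <- function(vartheta, muG, sigmaG) {
  if (any(vartheta <= 0 | vartheta >= 1))
    stop("vartheta must lie strictly inside (0, 1)")
  if (any(sigmaG <= 0)) stop("sigmaG must be positive")
  lv <- logit(vartheta)
  if (is.null(dim(lv))) lv <- matrix(lv, ncol = length(muG))
  sum(stats::dnorm(lv, rep(muG, each = nrow(lv)),
                   rep(sigmaG, each = nrow(lv)), log = TRUE))
}

#' Joint log-likelihood of all observation streams
#'
#' Sum of the lognormal index terms (juveniles, escapement, harvest, total
#' bycatch), the multinomial age-composition terms (escapement, harvest,
#' bycatch), the binomial genetic-assignment terms, and the hierarchical
#' stock-composition density. Any missing stream-year drops only that term.
#'
#' @param state An \code{ipm_state} from \code{\link{simulate_population}}.
#' @param data An \code{\link{ipm_data}} object.
#' @param cfg An \code{\link{ipm_obs_config}} object.
#' @param gsi List with \code{muG} and \code{sigmaG} (the stock-composition
#'   hyperparameters); the proportions themselves are taken from
#'   \code{state$vartheta}.
#' @param fractional Use fractional-count multinomials (see
#'   \code{\link{loglik_agecomp}}).
#' @return Scalar joint log-likelihood.
#' @export
joint_loglik <- function(state, data, cfg = ipm_obs_config(), gsi,
                         fractional = FALSE) {
  T <- data$dims$n_years
  if (nrow(state$N) != T) stop("state and data dimensions disagree")
  ll <- loglik_lognormal_index(data$J, state$N[, 1], cfg$sigma_J) +
    loglik_lognormal_index(data$E, state$S_total, cfg$sigma_E) +
    loglik_lognormal_index(data$C, rowSums(state$H), cfg$sigma_C) +
    loglik_lognormal_index(data$b_total, rowSums(state$BA), cfg$sigma_b)
  for (y in seq_len(T)) {
    if (!anyNA(data$qE[y, ]))
      ll <- ll + loglik_agecomp(data$qE[y, ], cfg$neff_E, state$pi_S[y, ],
                                fractional)
    if (!anyNA(data$qC[y, ]))
      ll <- ll + loglik_agecomp(data$qC[y, ], cfg$neff_C, state$pi_H[y, ],
                                fractional)
    if (!is.na(data$nB[y]) && data$nB[y] > 0 && !anyNA(data$qB[y, ]))
      ll <- ll + loglik_agecomp(data$qB[y, ], data$nB[y], state$pi_B[y, ],
                                fractional)
  }
  ll <- ll + loglik_stock_assignment(data$x, data$n, state$vartheta)
  ll + loglik_stock_hierarchy(state$vartheta, gsi$muG, gsi$sigmaG)
}
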