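# Posterior predictive checks: replicate the observation streams from
# posterior draws and compare observed values with the replicated
# distributions.

#' Posterior predictive replication and coverage
#'
#' For a subset of posterior draws, simulates replicated datasets from the
#' observation model conditional on each draw's latent states (lognormal
#' indices; multinomial compositions at the configured effective sizes;
#' binomial genetic assignments at the observed genotyped sample sizes), and
#' reports, per stream, the fraction of observed years falling inside the
#' central 95\% of their replicated distribution. Masked stream-years
#' produce no replicates.
#'
#' @param fit An \code{ipm_fit}.
#' @param ndraws Number of posterior draws to replicate from.
#' @param prob Central interval probability for the coverage summary.
#' @return Object of class \code{ipm_ppc} with \code{replicates} (per-stream
#'   arrays, draws x years) and \code{coverage} (named fractions).
#' @export
posterior_predictive <- function(fit, ndraws = 200, prob = 0.95) {
  data <- fit$data
  if (is.null(data)) stop("posterior predictive checks need the fitted data")
  dims <- fit$dims
  cfg <- fit$cfg
  T <- dims$n_years
  nd <- n_draws(fit)
  idx <- if (ndraws >= nd) seq_len(nd) else round(seq(1, nd, length.out = ndraws))
  Jr <- matrix(NA_real_, length(idx), T)
  Er <- Jr; Cr <- Jr; br <- Jr
  qEr <- array(NA_real_, c(length(idx), T, 4))
  xr <- array(NA_real_, c(length(idx), T, 4))
  for (k in seq_along(idx)) {
    st <- simulate_population(get_draw(fit, idx[k]), dims)
    obsJ <- !is.na(data$J)
    Jr[k, obsJ] <- stats::rlnorm(sum(obsJ), log(st$N[obsJ, 1]), cfg$sigma_J)
    obsE <- !is.na(data$E)
    Er[k, obsE] <- stats::rlnorm(sum(obsE), log(st$S_total[obsE]), cfg$sigma_E)
    obsC <- !is.na(data$C)
    Cr[k, obsC] <- stats::rlnorm(sum(obsC), log(rowSums(st$H)[obsC]),
                                 cfg$sigma_C)
    obsb <- !is.na(data$b_total)
    br[k, obsb] <- stats::rlnorm(sum(obsb), log(rowSums(st$BA)[obsb]),
                                 cfg$sigma_b)
    for (y in seq_len(T)) {
      if (!anyNA(data$qE[y, ]))
        qEr[k, y, ] <- as.vector(stats::rmultinom(1, cfg$neff_E,
                                                  st$pi_S[y, ])) / cfg$neff_E
      gn <- data$n[y, ]
      ok <- !is.na(gn) & gn > 0
      if (any(ok))
        xr[k, y, ok] <- stats::rbinom(sum(ok), gn[ok], st$vartheta[y, ok])
    }
  }
  cov1 <- function(rep_mat, obs) {
    ok <- !is.na(obs)
    if (!any(ok)) return(NA_real_)
    lo <- apply(rep_mat[, ok, drop = FALSE], 2, stats::quantile,
                (1 - prob) / 2, na.rm = TRUE)
    hi <- apply(rep_mat[, ok, drop = FALSE], 2, stats::quantile,
                1 - (1 - prob) / 2, na.rm = TRUE)
    mean(obs[ok] >= lo & obs[ok] <= hi)
  }
  coverage <- c(
    juveniles = cov1(Jr, data$J),
    escapement = cov1(Er, data$E),
    harvest = cov1(Cr, data$C),
    bycatch_total = cov1(br, data$b_total)
  )
  structure(list(
    replicates = list(J = Jr, E = Er, C = Cr, b_total = br, qE = qEr, x = xr),
    coverage = coverage, prob = prob, draw_index = idx
  ), class = "ipm_ppc")
}

#' @export
print.ipm_ppc <- function(x, ...) {
  cat("posterior predictive coverage (central ", round(100 * x$prob),
      "% intervals)\n", sep = "")
  for (nm in names(x$coverage))
    cat(sprintf("  %-14s %.2f\n", nm, x$coverage[nm]))
  invisible(x)
}
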