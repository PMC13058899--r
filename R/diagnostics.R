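# Convergence diagnostics: rank-normalized split Gelman-Rubin statistic,
# bulk and tail effective sample sizes (Geyer initial-monotone estimator on
# rank-normalized split chains), and the Bayesian fraction of missing
# information per chain.

.split_chains <- function(m) {
  n <- nrow(m)
  h <- n %/% 2L
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1L):n, , drop = FALSE])
}

.z_scale <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

.rhat_basic <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(NA_real_)
  mns <- colMeans(m)
  vrs <- apply(m, 2, stats::var)
  W <- mean(vrs)
  B <- n * stats::var(mns)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# lag autocovariances with divisor n, via FFT
.acov <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  L <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(xc, rep(0, L - n)))
  Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / (L * n)
}

# Geyer initial-positive / initial-monotone effective sample size
.ess_basic <- function(m) {
  n <- nrow(m); M <- ncol(m)
  if (n < 4L) return(NA_real_)
  acovs <- apply(m, 2, .acov)
  mean_var <- mean(acovs[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (M > 1) var_plus <- var_plus + stats::var(colMeans(m))
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  rho <- numeric(n)
  rho[1] <- 1
  rho[2] <- 1 - (mean_var - mean(acovs[2, ])) / var_plus
  t <- 0L
  rho_even <- 1; rho_odd <- rho[2]
  while (t < n - 4L && is.finite(rho_even + rho_odd) &&
         rho_even + rho_odd > 0) {
    t <- t + 2L
    rho_even <- 1 - (mean_var - mean(acovs[t + 1L, ])) / var_plus
    rho_odd <- 1 - (mean_var - mean(acovs[t + 2L, ])) / var_plus
    if (is.finite(rho_even + rho_odd) && rho_even + rho_odd >= 0) {
      rho[t + 1L] <- rho_even
      rho[t + 2L] <- rho_odd
    }
  }
  max_t <- t
  if (is.finite(rho_even) && rho_even > 0) rho[max_t + 1L] <- rho_even
  t <- 0L
  while (t <= max_t - 4L) {
    t <- t + 2L
    if (rho[t + 1L] + rho[t + 2L] > rho[t - 1L] + rho[t]) {
      rho[t + 1L] <- (rho[t - 1L] + rho[t]) / 2
      rho[t + 2L] <- rho[t + 1L]
    }
  }
  ess <- n * M
  tau <- -1 + 2 * sum(rho[seq_len(max_t)]) + rho[max_t + 1L]
  tau <- max(tau, 1 / log10(ess))
  ess / tau
}

#' Split Gelman-Rubin statistic (rank-normalized)
#'
#' Chains are split in half, rank-normalized (and folded about the median for
#' the scale-sensitive variant), and the classic potential-scale-reduction
#' statistic computed; the reported value is the larger of the bulk and fold
#' variants.
#'
#' @param m Matrix of draws (iterations x chains).
#' @return Scalar R-hat (NA for constant quantities).
#' @export
split_rhat <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("split R-hat requires at least 2 chains")
  if (stats::sd(as.vector(m)) == 0) return(NA_real_)
  sp <- .split_chains(m)
  r1 <- .rhat_basic(.z_scale(sp))
  folded <- abs(m - stats::median(m))
  r2 <- .rhat_basic(.z_scale(.split_chains(folded)))
  max(r1, r2, na.rm = TRUE)
}

#' Bulk effective sample size
#' @param m Matrix of draws (iterations x chains).
#' @return Scalar ESS estimate.
#' @export
ess_bulk <- function(m) {
  m <- as.matrix(m)
  if (stats::sd(as.vector(m)) == 0) return(NA_real_)
  .ess_basic(.z_scale(.split_chains(m)))
}

#' Tail effective sample size
#'
#' Minimum of the effective sample sizes of the 5\% and 95\% quantile
#' exceedance indicators.
#' @param m Matrix of draws (iterations x chains).
#' @return Scalar ESS estimate.
#' @export
ess_tail <- function(m) {
  m <- as.matrix(m)
  if (stats::sd(as.vector(m)) == 0) return(NA_real_)
  q <- stats::quantile(as.vector(m), c(0.05, 0.95), names = FALSE)
  e1 <- .ess_basic(.split_chains((m <= q[1]) * 1))
  e2 <- .ess_basic(.split_chains((m >= q[2]) * 1))
  min(e1, e2, na.rm = TRUE)
}

#' Bayesian fraction of missing information, per chain
#' @param energy Matrix (iterations x chains) of Hamiltonian energies.
#' @return Numeric vector, one BFMI per chain; values well below ~0.3 signal
#'   inefficient momentum resampling.
#' @export
bfmi <- function(energy) {
  energy <- as.matrix(energy)
  apply(energy, 2, function(e) {
    n <- length(e)
    sum(diff(e)^2) / (n - 1) / stats::var(e)
  })
}

#' Convergence report for a fitted model
#'
#' Per-quantity split R-hat and bulk/tail ESS over all monitored quantities,
#' the divergence count, and per-chain BFMI, with pass/fail flags against
#' the conventional thresholds (R-hat <= 1.01, ESS >= 1000, zero
#' divergences).
#'
#' @param fit An \code{ipm_fit} object.
#' @param rhat_max,ess_min Thresholds for the pass flags.
#' @return List of class \code{ipm_diagnostics}.
#' @export
ipm_diagnostics <- function(fit, rhat_max = 1.01, ess_min = 1000) {
  if (length(dim(fit$draws)) != 3 || dim(fit$draws)[2] < 2L)
    stop("diagnostics require at least two chains")
  nm <- dimnames(fit$draws)[[3]]
  stats_tab <- data.frame(
    parameter = nm,
    rhat = vapply(nm, function(p) split_rhat(fit$draws[, , p]), 0),
    ess_bulk = vapply(nm, function(p) ess_bulk(fit$draws[, , p]), 0),
    ess_tail = vapply(nm, function(p) ess_tail(fit$draws[, , p]), 0),
    row.names = NULL
  )
  div <- sum(fit$sampler$divergent)
  bf <- bfmi(fit$sampler$energy)
  structure(list(
    summary = stats_tab,
    max_rhat = max(stats_tab$rhat, na.rm = TRUE),
    min_ess_bulk = min(stats_tab$ess_bulk, na.rm = TRUE),
    min_ess_tail = min(stats_tab$ess_tail, na.rm = TRUE),
    divergences = div, bfmi = bf,
    pass = list(
      rhat = max(stats_tab$rhat, na.rm = TRUE) <= rhat_max,
      ess = min(stats_tab$ess_bulk, na.rm = TRUE) >= ess_min,
      divergences = div == 0,
      bfmi = all(bf > 0.3)
    )
  ), class = "ipm_diagnostics")
}

#' @export
print.ipm_diagnostics <- function(x, ...) {
  cat("MCMC diagnostics\n")
  cat("  max split R-hat : ", format(round(x$max_rhat, 4)), "\n", sep = "")
  cat("  min bulk ESS    : ", format(round(x$min_ess_bulk)), "\n", sep = "")
  cat("  min tail ESS    : ", format(round(x$min_ess_tail)), "\n", sep = "")
  cat("  divergences     : ", x$divergences, "\n", sep = "")
  cat("  BFMI by chain   : ", paste(format(round(x$bfmi, 2)), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
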