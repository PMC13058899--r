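# Model fitting: NUTS over the TMB posterior, posterior assembly, and the
# ipm_fit S3 class.

# named natural-scale monitor vector for one draw
flatten_pars <- function(pars, dims, state = NULL) {
  r <- build_rates(pars, dims)
  yrs <- dims$years
  coh <- yrs[seq_len(dims$n_cohorts)]
  out <- c(
    log_alpha = pars$log_alpha, alpha = exp(pars$log_alpha), beta = pars$beta,
    sigma_R = pars$sigma_R, sigma_M = pars$sigma_M, sigma_B = pars$sigma_B,
    sigma_T = pars$sigma_T, sigma_lambda = pars$sigma_lambda,
    stats::setNames(pars$sB, paste0("sB[", 3:6, "]")),
    stats::setNames(pars$v[-1], paste0("v[", 4:7, "]")),
    stats::setNames(pars$sT, paste0("sT[", 4:7, "]")),
    log_M_init = pars$log_M_init, log_FB_init = pars$log_FB_init,
    log_FT_init = pars$log_FT_init, log_lam_init = pars$log_lam_init,
    stats::setNames(r$M, paste0("M[", yrs, "]")),
    stats::setNames(r$FB, paste0("FB[", yrs, "]")),
    stats::setNames(r$FT, paste0("FT[", yrs, "]")),
    stats::setNames(r$lam, paste0("lam[", coh, "]")),
    stats::setNames(pars$eps_R, paste0("eps_R[", yrs[-(1:2)], "]")),
    stats::setNames(pars$log_N0, paste0("log_N0[", 2:6, "]")),
    stats::setNames(pars$log_R_init, paste0("log_R_init[", yrs[1:2], "]")),
    stats::setNames(pars$muG, paste0("muG[", 3:6, "]")),
    stats::setNames(pars$sigmaG, paste0("sigmaG[", 3:6, "]")),
    stats::setNames(as.vector(invlogit(pars$logit_vartheta)),
                    paste0("vartheta[", rep(yrs, 4), ",",
                           rep(3:6, each = dims$n_years), "]"))
  )
  if (!is.null(state))
    out <- c(out, stats::setNames(state$run_size, paste0("run_size[", yrs, "]")),
             stats::setNames(state$S_total, paste0("S_total[", yrs, "]")))
  out
}

#' Fit the integrated life-cycle model
#'
#' Bayesian estimation of all leading parameters, random-walk series and
#' initial conditions by the No-U-Turn sampler over the TMB-differentiated
#' joint posterior (non-centred parameterization throughout). The reference
#' analysis used 5 chains of 15,000 iterations (5,000 warmup); the defaults
#' here are desk-scale and configurable.
#'
#' @param data An \code{\link{ipm_data}} object.
#' @param cfg Observation-error configuration.
#' @param priors Prior configuration.
#' @param chains Number of chains (>= 2 for diagnostics).
#' @param iter Iterations per chain, including warmup.
#' @param warmup Warmup iterations per chain.
#' @param seed Random seed governing initial jitter and sampling.
#' @param control A \code{\link{nuts_control}} list.
#' @param init_jitter SD of the jitter applied to the data-informed starting
#'   point, per chain.
#' @param fractional Use fractional-count multinomial likelihoods.
#' @param quiet Suppress per-chain progress messages.
#' @return An object of class \code{ipm_fit}.
#' @export
fit_ipm <- function(data, cfg = ipm_obs_config(), priors = ipm_priors(),
                    chains = 4, iter = 2000, warmup = 1000, seed = 1,
                    control = nuts_control(), init_jitter = 0.2,
                    fractional = FALSE, quiet = FALSE) {
  stopifnot(inherits(data, "ipm_data"), chains >= 1, warmup < iter)
  dims <- data$dims
  obj <- ipm_objective(data, cfg, priors, fractional)
  set.seed(seed)
  n_keep <- iter - warmup
  d <- length(obj$par)
  upars <- array(NA_real_, c(n_keep, chains, d))
  energy <- matrix(NA_real_, iter, chains)
  divergent <- matrix(FALSE, n_keep, chains)
  treedepth <- matrix(NA_integer_, n_keep, chains)
  accept <- matrix(NA_real_, n_keep, chains)
  stepsizes <- numeric(chains)
  runtimes <- numeric(chains)

  for (ch in seq_len(chains)) {
    init <- NULL
    for (try in 1:25) {
      cand <- default_init(data, dims,
                           jitter = if (try == 1 && ch == 1) 0 else init_jitter)
      if (is.finite(obj$fn(cand)) && all(is.finite(obj$gr(cand)))) {
        init <- cand; break
      }
    }
    if (is.null(init)) stop("could not find a finite starting point")
    t0 <- Sys.time()
    res <- nuts_chain(obj$fn, obj$gr, init, n_iter = iter, n_warmup = warmup,
                      control = control)
    runtimes[ch] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    upars[, ch, ] <- res$draws
    energy[, ch] <- res$energy
    post <- (warmup + 1):iter
    divergent[, ch] <- res$divergent[post]
    treedepth[, ch] <- res$treedepth[post]
    accept[, ch] <- res$accept_stat[post]
    stepsizes[ch] <- res$stepsize
    if (!quiet)
      message(sprintf(
        "chain %d: %.1fs, stepsize %.3g, %d divergent, mean accept %.2f",
        ch, runtimes[ch], res$stepsize, sum(res$divergent[post]),
        mean(res$accept_stat[post])))
  }

  # natural-scale monitored quantities (incl. derived series and run size)
  proto <- flatten_pars(unpack_parameters(upars[1, 1, ], dims), dims,
                        simulate_population(unpack_parameters(upars[1, 1, ], dims), dims))
  draws <- array(NA_real_, c(n_keep, chains, length(proto)),
                 dimnames = list(NULL, NULL, names(proto)))
  lp <- matrix(NA_real_, n_keep, chains)
  for (ch in seq_len(chains)) {
    for (i in seq_len(n_keep)) {
      p <- unpack_parameters(upars[i, ch, ], dims)
      st <- simulate_population(p, dims)
      draws[i, ch, ] <- flatten_pars(p, dims, st)
      lp[i, ch] <- -as.numeric(obj$fn(upars[i, ch, ]))
    }
  }

  fit <- structure(list(
    data = data, dims = dims, cfg = cfg, priors = priors,
    draws = draws, upars = upars, lp = lp,
    sampler = list(energy = energy, divergent = divergent,
                   treedepth = treedepth, accept_stat = accept,
                   stepsize = stepsizes, runtime = runtimes),
    mcmc = list(chains = chains, iter = iter, warmup = warmup, seed = seed,
                control = control)
  ), class = "ipm_fit")
  if (chains >= 2) fit$diagnostics <- ipm_diagnostics(fit)
  fit
}

n_draws <- function(fit) dim(fit$draws)[1] * dim(fit$draws)[2]

# i-th posterior draw (chains stacked) as natural-scale parameter list
get_draw <- function(fit, i) {
  n_keep <- dim(fit$upars)[1]
  ch <- (i - 1L) %/% n_keep + 1L
  it <- (i - 1L) %% n_keep + 1L
  unpack_parameters(fit$upars[it, ch, ], fit$dims)
}

# matrix (draw x quantity) over stacked chains for named quantities
draw_matrix <- function(fit, pattern) {
  nm <- dimnames(fit$draws)[[3]]
  sel <- grep(pattern, nm)
  m <- fit$draws[, , sel, drop = FALSE]
  dim(m) <- c(dim(fit$draws)[1] * dim(fit$draws)[2], length(sel))
  colnames(m) <- nm[sel]
  m
}

#' @export
print.ipm_fit <- function(x, ...) {
  cat("Integrated life-cycle model fit (", x$mcmc$chains, " chains x ",
      x$mcmc$iter, " iterations, ", x$mcmc$warmup, " warmup)\n", sep = "")
  key <- c("alpha", "beta", "sigma_R", "sigma_M")
  med <- apply(x$draws[, , key, drop = FALSE], 3, stats::median)
  cat("  alpha (juveniles/spawner):", format(signif(med["alpha"], 3)), "\n")
  cat("  capacity 1/beta          :", format(round(1 / med["beta"])), "\n")
  cat("  sigma_R                  :", format(signif(med["sigma_R"], 3)), "\n")
  if (!is.null(x$diagnostics)) {
    cat("  max split R-hat          :",
        format(round(x$diagnostics$max_rhat, 4)), "\n")
    cat("  divergences              :", x$diagnostics$divergences, "\n")
  }
  invisible(x)
}

#' @export
summary.ipm_fit <- function(object, pars = NULL, ...) {
  nm <- dimnames(object$draws)[[3]]
  if (!is.null(pars)) nm <- nm[nm %in% pars | grepl(paste(pars, collapse = "|"), nm)]
  qs <- t(apply(object$draws[, , nm, drop = FALSE], 3, stats::quantile,
                c(0.5, 0.025, 0.975)))
  out <- data.frame(parameter = nm, median = qs[, 1],
                    q2.5 = qs[, 2], q97.5 = qs[, 3], row.names = NULL)
  if (!is.null(object$diagnostics)) {
    dg <- object$diagnostics$summary
    out$rhat <- dg$rhat[match(nm, dg$parameter)]
    out$ess_bulk <- dg$ess_bulk[match(nm, dg$parameter)]
  }
  class(out) <- c("summary.ipm_fit", "data.frame")
  out
}

#' @export
coef.ipm_fit <- function(object, ...) {
  key <- c("alpha", "beta", "sigma_R", "sigma_M", "sigma_B", "sigma_T",
           "sigma_lambda", paste0("sB[", 3:6, "]"), paste0("v[", 4:7, "]"),
           paste0("sT[", 4:7, "]"))
  apply(object$draws[, , key, drop = FALSE], 3, stats::median)
}

#' Plot the estimated run-size trajectory
#'
#' Posterior median and 50\%/95\% credible bands of annual run size
#' (mature returns, ages 4-7, pre-harvest).
#' @param x An \code{ipm_fit}.
#' @param ... Passed to \code{plot}.
#' @export
plot.ipm_fit <- function(x, ...) {
  rs <- draw_matrix(x, "^run_size\\[")
  yrs <- x$dims$years
  qs <- apply(rs, 2, stats::quantile, c(0.025, 0.25, 0.5, 0.75, 0.975))
  graphics::plot(yrs, qs[3, ], type = "n", ylim = c(0, max(qs)),
                 xlab = "Year", ylab = "Run size (fish)", ...)
  graphics::polygon(c(yrs, rev(yrs)), c(qs[1, ], rev(qs[5, ])),
                    col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  graphics::polygon(c(yrs, rev(yrs)), c(qs[2, ], rev(qs[4, ])),
                    col = grDevices::adjustcolor("steelblue", 0.45), border = NA)
  graphics::lines(yrs, qs[3, ], lwd = 2, col = "steelblue4")
  graphics::points(yrs, qs[3, ], pch = 16, col = "steelblue4")
  invisible(qs)
}

#' Posterior-predictive replication (simulate method)
#'
#' Draws replicated observation datasets from the fitted posterior; see
#' \code{\link{posterior_predictive}}.
#' @param object An \code{ipm_fit}.
#' @param nsim Number of replicated datasets.
#' @param seed Optional seed.
#' @param ... Ignored.
#' @export
simulate.ipm_fit <- function(object, nsim = 100, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  posterior_predictive(object, ndraws = nsim)$replicates
}

#' Forward projection (predict method)
#'
#' Projects the fitted population forward; see \code{\link{project_ipm}}.
#' @param object An \code{ipm_fit}.
#' @param horizon Projection years.
#' @param ... Passed to \code{\link{project_ipm}}.
#' @export
predict.ipm_fit <- function(object, horizon = 7, ...) {
  project_ipm(object, projection_config(horizon = horizon, ...))
}
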