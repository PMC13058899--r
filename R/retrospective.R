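# Retrospective counterfactual simulations: re-run the fitted trajectory
# from each posterior draw with one or more processes overridden, all other
# parameters held at their estimated values in that draw.

#' Define a counterfactual scenario
#'
#' The five reference scenarios are: zero bycatch (\code{FB = "zero"}), zero
#' harvest (\code{FT = "zero"}), baseline natural mortality (\code{M =
#' "baseline"}: rates from \code{cutoff_year} on replaced with the draw's
#' median pre-cutoff level), favorable recruitment (\code{epsR =
#' "favorable"}: all recruitment deviations fixed at the 95th percentile of
#' the per-year posterior-median deviations), and their combinations.
#'
#' @param name Scenario label.
#' @param FB,FT \code{"none"} or \code{"zero"}.
#' @param M \code{"none"} or \code{"baseline"}.
#' @param epsR \code{"none"} or \code{"favorable"}.
#' @param cutoff_year First year whose natural mortality is replaced under
#'   the baseline-mortality override (default 2016, the heatwave onset).
#' @return List of class \code{ipm_scenario}.
#' @export
ipm_scenario <- function(name = "scenario",
                         FB = c("none", "zero"), FT = c("none", "zero"),
                         M = c("none", "baseline"),
                         epsR = c("none", "favorable"),
                         cutoff_year = 2016) {
  spec <- list(name = name, FB = match.arg(FB), FT = match.arg(FT),
               M = match.arg(M), epsR = match.arg(epsR),
               cutoff_year = cutoff_year)
  structure(spec, class = "ipm_scenario")
}

#' The five reference counterfactual scenarios plus the identity
#' @param cutoff_year Passed to \code{\link{ipm_scenario}}.
#' @return Named list of \code{ipm_scenario} objects.
#' @export
reference_scenarios <- function(cutoff_year = 2016) {
  list(
    fitted = ipm_scenario("fitted"),
    zero_bycatch = ipm_scenario("zero_bycatch", FB = "zero"),
    zero_harvest = ipm_scenario("zero_harvest", FT = "zero"),
    baseline_m = ipm_scenario("baseline_m", M = "baseline",
                              cutoff_year = cutoff_year),
    favorable_recruitment = ipm_scenario("favorable_recruitment",
                                         epsR = "favorable"),
    combined = ipm_scenario("combined", M = "baseline", epsR = "favorable",
                            cutoff_year = cutoff_year)
  )
}

#' Derive the data-dependent override values from a fitted ensemble
#'
#' @param fit An \code{ipm_fit} (or ensemble built with
#'   \code{\link{ipm_ensemble}}).
#' @param cutoff_year Year splitting the pre/post natural-mortality regimes.
#' @param pooled Use the pooled-posterior median of pre-cutoff natural
#'   mortality instead of the within-draw median.
#' @return List with \code{M_baseline} (one value per draw, or a single
#'   pooled value), \code{epsR_favorable} (the 95th percentile, linear
#'   interpolation between order statistics, of the per-year
#'   posterior-median recruitment deviations) and \code{cutoff_year}.
#' @export
derive_overrides <- function(fit, cutoff_year = 2016, pooled = FALSE) {
  pre <- fit$dims$years < cutoff_year
  if (!any(pre)) stop("no years precede the cutoff year")
  Mdr <- draw_matrix(fit, "^M\\[")
  M_base <- if (pooled) stats::median(Mdr[, pre])
            else apply(Mdr[, pre, drop = FALSE], 1, stats::median)
  eps <- draw_matrix(fit, "^eps_R\\[")
  eps_med <- apply(eps, 2, stats::median)
  list(M_baseline = M_base,
       epsR_favorable = interp_quantile(eps_med, 0.95),
       cutoff_year = cutoff_year)
}

#' Run a counterfactual scenario over the posterior
#'
#' For each draw, rebuilds that draw's rate series, applies the scenario
#' overrides, and re-runs the process model; recruitment feeds back through
#' the simulated escapements, so removals propagate to future returns.
#' Zero-bycatch runs keep the draw's harvest mortality applied to the extra
#' survivors in their return year.
#'
#' @param fit An \code{ipm_fit} or \code{\link{ipm_ensemble}}.
#' @param spec An \code{\link{ipm_scenario}}.
#' @param overrides Optional precomputed \code{\link{derive_overrides}} list.
#' @param max_draws Thin to at most this many draws (default all).
#' @param pooled Passed to \code{\link{derive_overrides}}.
#' @return Object of class \code{ipm_scenario_result}: per-draw
#'   \code{run_size} (draws x years), the fitted \code{run_size_fitted} for
#'   the same draws, and a per-year \code{summary} data frame.
#' @export
run_scenario <- function(fit, spec, overrides = NULL, max_draws = NULL,
                         pooled = FALSE) {
  stopifnot(inherits(spec, "ipm_scenario"))
  dims <- fit$dims
  nd <- n_draws(fit)
  idx <- if (is.null(max_draws) || max_draws >= nd) seq_len(nd)
         else round(seq(1, nd, length.out = max_draws))
  needs_ov <- spec$M == "baseline" || spec$epsR == "favorable"
  if (needs_ov && is.null(overrides))
    overrides <- derive_overrides(fit, spec$cutoff_year, pooled)
  T <- dims$n_years
  rs <- matrix(NA_real_, length(idx), T)
  rs_fit <- matrix(NA_real_, length(idx), T)
  post <- dims$years >= spec$cutoff_year
  for (k in seq_along(idx)) {
    pars <- get_draw(fit, idx[k])
    rates <- build_rates(pars, dims)
    st0 <- simulate_population(pars, dims)
    rs_fit[k, ] <- st0$run_size
    if (spec$FB == "zero") rates$FB[] <- 0
    if (spec$FT == "zero") rates$FT[] <- 0
    if (spec$M == "baseline") {
      mb <- if (length(overrides$M_baseline) == 1) overrides$M_baseline
            else overrides$M_baseline[idx[k]]
      rates$M[post] <- mb
    }
    if (spec$epsR == "favorable") pars$eps_R[] <- overrides$epsR_favorable
    pars$rates <- rates
    rs[k, ] <- simulate_population(pars, dims)$run_size
  }
  qs <- function(m) apply(m, 2, stats::quantile,
                          c(0.5, 0.25, 0.75, 0.025, 0.975))
  q <- qs(rs)
  dq <- apply(rs - rs_fit, 2, stats::median)
  summary <- data.frame(scenario = spec$name, year = dims$years,
                        median = q[1, ], q25 = q[2, ], q75 = q[3, ],
                        q2.5 = q[4, ], q97.5 = q[5, ], diff_median = dq,
                        row.names = NULL)
  structure(list(spec = spec, run_size = rs, run_size_fitted = rs_fit,
                 draw_index = idx, summary = summary, dims = dims),
            class = "ipm_scenario_result")
}

#' Per-year differences between a scenario and the fitted trajectory
#'
#' Differences are computed draw-wise (scenario minus fitted within the same
#' posterior draw), then summarized; signs are reported per year and may be
#' negative (e.g., Ricker overcompensation under zero harvest).
#'
#' @param result An \code{ipm_scenario_result}.
#' @return Data frame with year, median difference and 50\%/95\% intervals.
#' @export
compare_to_fitted <- function(result) {
  d <- result$run_size - result$run_size_fitted
  q <- apply(d, 2, stats::quantile, c(0.5, 0.25, 0.75, 0.025, 0.975))
  data.frame(year = result$dims$years, diff_median = q[1, ],
             q25 = q[2, ], q75 = q[3, ], q2.5 = q[4, ], q97.5 = q[5, ],
             row.names = NULL)
}

#' @export
print.ipm_scenario_result <- function(x, ...) {
  cat("scenario '", x$spec$name, "': ", nrow(x$run_size), " draws x ",
      ncol(x$run_size), " years\n", sep = "")
  cat("  final-year median run size: ",
      format(round(stats::median(x$run_size[, ncol(x$run_size)]))),
      " (fitted ",
      format(round(stats::median(x$run_size_fitted[, ncol(x$run_size)]))),
      ")\n", sep = "")
  invisible(x)
}

#' Build a posterior-like ensemble from explicit parameter draws
#'
#' Wraps a list of natural-scale parameter sets as an ensemble usable by the
#' scenario and projection machinery (e.g., a truth-centred synthetic
#' posterior for testing, or draws imported from elsewhere).
#'
#' @param pars_list List of \code{\link{ipm_parameters}}.
#' @param dims An \code{\link{ipm_dims}}.
#' @return Object of class \code{ipm_fit} (single pseudo-chain, no sampler
#'   state).
#' @export
ipm_ensemble <- function(pars_list, dims) {
  n <- length(pars_list)
  d <- unconstrained_length(dims)
  upars <- array(NA_real_, c(n, 1, d))
  proto <- flatten_pars(pars_list[[1]], dims,
                        simulate_population(pars_list[[1]], dims))
  draws <- array(NA_real_, c(n, 1, length(proto)),
                 dimnames = list(NULL, NULL, names(proto)))
  for (i in seq_len(n)) {
    upars[i, 1, ] <- pack_parameters(pars_list[[i]], dims)
    draws[i, 1, ] <- flatten_pars(pars_list[[i]], dims,
                                  simulate_population(pars_list[[i]], dims))
  }
  structure(list(dims = dims, draws = draws, upars = upars,
                 mcmc = list(chains = 1, iter = n, warmup = 0)),
            class = "ipm_fit")
}

#' Tidy scenario summary table
#'
#' The per-year summary (scenario, year, median, quartiles, 95\% bounds and
#' draw-wise median difference vs the fitted trajectory), ready for CSV
#' export.
#'
#' @param x An \code{ipm_scenario_result}.
#' @param row.names,optional,... Ignored (S3 signature).
#' @export
as.data.frame.ipm_scenario_result <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  x$summary
}
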