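# Forward projection from the terminal state of each posterior draw, with
# recovery classification and fixed-scenario grids.

#' Projection configuration
#'
#' Policy and process-continuation settings for forward simulation. By
#' default harvest mortality is fixed at zero, bycatch mortality is fixed at
#' the draw's mean estimated 2011-2023 (post-Amendment-91) value, natural
#' mortality and the maturation schedule continue their log-space random
#' walks with new innovations drawn from the estimated SDs, and recruitment
#' deviations are drawn from Normal(0, sigma_R).
#'
#' @param horizon Projection length in years (default 7, one maximum life
#'   cycle; 14 for the two-cycle sensitivity).
#' @param FT Fixed harvest mortality rate (default 0).
#' @param FB \code{"mean_recent"} (per-draw mean over \code{fb_window}) or a
#'   fixed numeric rate.
#' @param M \code{"walk"} (stochastic continuation), \code{"freeze"} (hold at
#'   the terminal value), or a fixed numeric rate for all projection years.
#' @param lam \code{"walk"} or \code{"freeze"} continuation of the
#'   maturation schedule for cohorts recruited during the projection.
#' @param epsR \code{"stochastic"} or a fixed numeric value for all
#'   projection years.
#' @param fb_window Calendar window defining the recent bycatch mean.
#' @param lower_threshold Run size at or below which a final-year outcome is
#'   classed as non-recovery (default 16,000 fish, the recent low).
#' @param upper_quantile Quantile of the projected final-year run-size
#'   distribution defining the recovery threshold (default 0.9).
#' @param seed Seed for projection process errors.
#' @return List of class \code{projection_config}.
#' @export
projection_config <- function(horizon = 7, FT = 0, FB = "mean_recent",
                              M = "walk", lam = "walk", epsR = "stochastic",
                              fb_window = c(2011, 2023),
                              lower_threshold = 16000, upper_quantile = 0.9,
                              seed = 1) {
  stopifnot(horizon >= 1)
  structure(list(horizon = as.integer(horizon), FT = FT, FB = FB, M = M,
                 lam = lam, epsR = epsR, fb_window = fb_window,
                 lower_threshold = lower_threshold,
                 upper_quantile = upper_quantile, seed = seed),
            class = "projection_config")
}

# continue one draw forward; returns run_size, M path, S_total path
.project_draw <- function(pars, dims, st, cfg) {
  T <- dims$n_years
  h <- cfg$horizon
  rates <- build_rates(pars, dims)
  # bycatch policy
  FBp <- if (is.numeric(cfg$FB)) rep(cfg$FB, h) else {
    w <- dims$years >= cfg$fb_window[1] & dims$years <= cfg$fb_window[2]
    if (!any(w)) w <- rep(TRUE, T)
    rep(mean(rates$FB[w]), h)
  }
  FTp <- rep(cfg$FT, h)
  # natural mortality continuation
  Mp <- if (is.numeric(cfg$M)) rep(cfg$M, h)
        else if (cfg$M == "freeze") rep(rates$M[T], h)
        else exp(log(rates$M[T]) + cumsum(stats::rnorm(h, 0, pars$sigma_M)))
  # maturation schedule: historical cohorts keep their estimated lam; cohorts
  # recruited during the projection continue the walk
  n_new_coh <- h  # cohorts age-2 in years T+1 .. T+h
  lam_new <- if (cfg$lam == "freeze" || pars$sigma_lambda == 0)
    rep(rates$lam[dims$n_cohorts], n_new_coh + 2L)
  else exp(log(rates$lam[dims$n_cohorts]) +
             cumsum(stats::rnorm(n_new_coh + 2L, 0, pars$sigma_lambda)))
  # cohorts T-1 and T (recruited in-window but beyond the estimated walk)
  # take the first continued values; projection-year cohorts follow
  lam_all <- c(rates$lam, lam_new)
  epsRp <- if (is.numeric(cfg$epsR)) rep(cfg$epsR, h)
           else stats::rnorm(h, 0, pars$sigma_R)

  sB <- c(0, pars$sB, 0); v <- pars$v; sT <- pars$sT
  N_prev <- st$N[T, ]                       # ages 2..7 in the terminal year
  S_hist <- c(st$S_total, numeric(h))       # indexed by model year 1..T+h
  run_size <- numeric(h); Mpath <- Mp; S_out <- numeric(h)

  for (j in seq_len(h)) {
    y <- T + j
    Nrow <- numeric(6)
    Sb <- S_hist[y - 2]
    Nrow[1] <- recruit_juveniles(Sb, pars$log_alpha, pars$beta, epsRp[j])
    Ay <- numeric(4); Hy <- numeric(4)
    for (a in 3:7) {
      ai <- a - 1L
      th <- 0
      if (a >= 4) {
        yc <- y - (a - 2L)
        lam_yc <- if (yc < 1) lam_all[1] else lam_all[min(yc, length(lam_all))]
        th <- maturation_prob(lam_yc, a)
      }
      adv <- advance_cohort(N_prev[ai - 1L], FBp[j], sB[ai], Mp[j],
                            v[a - 2L], th)
      Nrow[ai] <- adv$N_next
      if (a >= 4) Ay[a - 3L] <- adv$A
    }
    hv <- harvest_at_age(Ay, FTp[j], sT)
    S_hist[y] <- sum(hv$S)
    run_size[j] <- sum(Ay)
    S_out[j] <- S_hist[y]
    N_prev <- Nrow
  }
  list(run_size = run_size, M = Mpath, S_total = S_out)
}

#' Project the fitted population forward
#'
#' Continues each posterior draw from its terminal age structure and rates
#' under the projection policies of a \code{\link{projection_config}}.
#'
#' @param fit An \code{ipm_fit} or \code{\link{ipm_ensemble}}.
#' @param cfg A \code{\link{projection_config}}.
#' @param max_draws Thin to at most this many draws.
#' @return Object of class \code{ipm_projection}: matrices \code{run_size}
#'   and \code{M} (draws x horizon), projection \code{years}, per-draw
#'   parameter values, and the config.
#' @export
project_ipm <- function(fit, cfg = projection_config(), max_draws = NULL) {
  dims <- fit$dims
  nd <- n_draws(fit)
  idx <- if (is.null(max_draws) || max_draws >= nd) seq_len(nd)
         else round(seq(1, nd, length.out = max_draws))
  set.seed(cfg$seed)
  h <- cfg$horizon
  rs <- matrix(NA_real_, length(idx), h)
  Mm <- matrix(NA_real_, length(idx), h)
  pars_tab <- matrix(NA_real_, length(idx), 4,
                     dimnames = list(NULL, c("alpha", "inv_beta", "mean_epsR",
                                             "mean_M")))
  for (k in seq_along(idx)) {
    pars <- get_draw(fit, idx[k])
    st <- simulate_population(pars, dims)
    pr <- .project_draw(pars, dims, st, cfg)
    rs[k, ] <- pr$run_size
    Mm[k, ] <- pr$M
    pars_tab[k, ] <- c(exp(pars$log_alpha), 1 / pars$beta,
                       mean(pars$eps_R), mean(pr$M))
  }
  structure(list(run_size = rs, M = Mm, draw_pars = pars_tab,
                 years = dims$years[dims$n_years] + seq_len(h),
                 draw_index = idx, cfg = cfg, dims = dims),
            class = "ipm_projection")
}

#' Classify projection outcomes as recovery / non-recovery
#'
#' The recovery threshold is the empirical upper quantile (default 90th,
#' linear interpolation) of the projected final-year run-size distribution,
#' recomputed from the ensemble at hand; the non-recovery threshold is a
#' fixed recent-low abundance (default 16,000 fish). Draws in between are
#' labelled intermediate.
#'
#' @param proj An \code{ipm_projection}.
#' @param lower_threshold,upper_quantile Override the config values.
#' @return Object of class \code{recovery_classification}: thresholds,
#'   per-draw labels, and per-label parameter summaries.
#' @export
classify_recovery <- function(proj, lower_threshold = NULL,
                              upper_quantile = NULL) {
  lower <- lower_threshold %||% proj$cfg$lower_threshold
  uq <- upper_quantile %||% proj$cfg$upper_quantile
  final <- proj$run_size[, ncol(proj$run_size)]
  upper <- interp_quantile(final, uq)
  crossed <- upper <= lower
  if (crossed)
    warning("recovery and non-recovery thresholds coincide or cross")
  label <- ifelse(final >= upper, "recovery",
                  ifelse(final <= lower, "non-recovery", "intermediate"))
  by_label <- lapply(split(as.data.frame(proj$draw_pars), label),
                     function(df) apply(df, 2, stats::median))
  structure(list(final_run_size = final, upper_threshold = upper,
                 lower_threshold = lower, label = label,
                 crossed = crossed, params_by_label = by_label),
            class = "recovery_classification")
}

#' Recovery fraction conditional on the projected mortality path
#'
#' Among draws whose projected natural-mortality path lies entirely at or
#' below (or at or above) a reference level in every projection year, the
#' fraction whose final-year run size reaches the recovery threshold.
#'
#' @param proj An \code{ipm_projection}.
#' @param cls A \code{\link{classify_recovery}} result for the same
#'   projection.
#' @param reference Scalar reference mortality level, or one value per draw
#'   (e.g., each draw's pre-2016 median).
#' @param direction \code{"at_or_below"} or \code{"at_or_above"}.
#' @return List with the conditional \code{fraction} (NA, flagged, when no
#'   draw satisfies the condition), the number of qualifying draws, and the
#'   condition.
#' @export
conditional_recovery_fraction <- function(proj, cls, reference,
                                          direction = c("at_or_below",
                                                        "at_or_above")) {
  direction <- match.arg(direction)
  ref <- if (length(reference) == 1) rep(reference, nrow(proj$M))
         else reference[proj$draw_index]
  ok <- if (direction == "at_or_below") apply(proj$M <= ref, 1, all)
        else apply(proj$M >= ref, 1, all)
  n_ok <- sum(ok)
  frac <- if (n_ok == 0) NA_real_
          else mean(cls$label[ok] == "recovery")
  list(fraction = frac, n = n_ok, direction = direction,
       undefined = n_ok == 0)
}

#' Grid of projections with fixed recruitment errors and mortality rates
#'
#' One projected ensemble per (recruitment-error level, natural-mortality
#' level) cell, with that process fixed at the level in every projection
#' year; cells are independently re-seeded so each is reproducible.
#'
#' @param fit An \code{ipm_fit}.
#' @param epsR_levels Named or unnamed numeric vector of fixed recruitment
#'   errors.
#' @param M_levels Numeric vector of fixed natural-mortality rates.
#' @param cfg Base \code{\link{projection_config}}.
#' @param max_draws Thin draws per cell.
#' @return List of class \code{ipm_projection_grid}: a cell list plus a
#'   summary data frame of final-year median run sizes.
#' @export
fixed_scenario_grid <- function(fit, epsR_levels, M_levels,
                                cfg = projection_config(), max_draws = NULL) {
  cells <- list()
  summ <- NULL
  ci <- 0L
  for (i in seq_along(epsR_levels)) {
    for (j in seq_along(M_levels)) {
      ci <- ci + 1L
      cell_cfg <- cfg
      cell_cfg$epsR <- epsR_levels[i]
      cell_cfg$M <- M_levels[j]
      cell_cfg$seed <- cfg$seed + ci
      pr <- project_ipm(fit, cell_cfg, max_draws = max_draws)
      key <- paste0("epsR=", signif(epsR_levels[i], 3),
                    ",M=", signif(M_levels[j], 3))
      cells[[key]] <- pr
      summ <- rbind(summ, data.frame(
        epsR = epsR_levels[i], M = M_levels[j],
        final_median = stats::median(pr$run_size[, ncol(pr$run_size)])))
    }
  }
  structure(list(cells = cells, summary = summ, cfg = cfg),
            class = "ipm_projection_grid")
}

#' @export
print.ipm_projection <- function(x, ...) {
  cat("ipm_projection: ", nrow(x$run_size), " draws x ", ncol(x$run_size),
      " years (", x$years[1], "-", x$years[length(x$years)], ")\n", sep = "")
  cat("  final-year run size median ",
      format(round(stats::median(x$run_size[, ncol(x$run_size)]))),
      "\n", sep = "")
  invisible(x)
}

#' Tidy per-draw projection table
#'
#' One row per (draw, year) with the projected run size, plus the
#' recovery/non-recovery label of the draw when a classification is given.
#'
#' @param x An \code{ipm_projection}.
#' @param row.names,optional Ignored (S3 signature).
#' @param cls Optional \code{\link{classify_recovery}} result.
#' @param ... Ignored.
#' @export
as.data.frame.ipm_projection <- function(x, row.names = NULL,
                                         optional = FALSE, cls = NULL, ...) {
  nd <- nrow(x$run_size)
  out <- data.frame(
    draw = rep(x$draw_index, times = length(x$years)),
    year = rep(x$years, each = nd),
    run_size = as.vector(x$run_size)
  )
  if (!is.null(cls)) out$label <- rep(cls$label, times = length(x$years))
  out
}
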