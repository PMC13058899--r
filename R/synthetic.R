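# Synthetic-data generator: latent truth plus observation datasets with
# exactly the statistical structure the likelihoods assume, so fitting,
# retrospectives and projections are testable without the study's data.

# piecewise-linear path over calendar years, clamped outside the anchors
.path <- function(years, anchor_years, anchor_values) {
  stats::approx(anchor_years, anchor_values, xout = pmin(pmax(years,
    min(anchor_years)), max(anchor_years)))$y
}

#' Generating scenario for synthetic datasets
#'
#' Defaults are anchored to the posterior medians of the reference analysis:
#' Ricker productivity 48 juveniles/spawner and capacity 81,178 spawners;
#' bycatch selectivity (0.03, 0.15, 0.81, 0.21) on ages 3-6; vulnerability
#' (1, 0.67, 0.60, 0.64, 0.93) on ages 3-7; natural mortality near 1.1 over
#' 2003-2015 rising to 1.5 by 2020 (the post-heatwave regime). Quantities the
#' reference analysis does not print (recruitment-error SD, harvest and
#' bycatch mortality paths, maturation-schedule path, stock-composition
#' levels) are implementer choices tuned to produce data of realistic
#' magnitude (run sizes 10^4-10^5, stock-specific bycatch 10^2-10^3) and are
#' exposed here for sensitivity work.
#'
#' @param dims An \code{\link{ipm_dims}} (default the 2003-2023 study span).
#' @param log_alpha,beta Ricker parameters.
#' @param sigma_R Recruitment-error SD (log scale).
#' @param sB,v,sT Selectivity/vulnerability schedules.
#' @param M_anchors,FB_anchors,FT_anchors,lam_anchors Piecewise-linear rate
#'   paths as \code{list(years=, values=)} anchor sets.
#' @param muG,sigmaG Among-year logit mean/SD of focal-stock proportions.
#' @param N0,R_init Initialization abundances (virtual year-0 ages 2-6;
#'   first two juvenile years).
#' @param genotyping_rate Fraction of the bycatch genotyped and scaled
#'   ("1 in 10 fish").
#' @param juvenile_missing_years Calendar years with no juvenile survey.
#' @param gsi_missing_years Calendar years with no genetic assignments.
#' @param obs An \code{\link{ipm_obs_config}}.
#' @return List of class \code{sim_scenario}.
#' @export
sim_scenario <- function(dims = ipm_dims(2003, 21),
                         log_alpha = log(48), beta = 1 / 81178,
                         sigma_R = 0.5,
                         sB = c(0.03, 0.15, 0.81, 0.21),
                         v = c(1, 0.67, 0.60, 0.64, 0.93),
                         sT = c(0.5, 0.8, 1.0, 0.9),
                         M_anchors = list(years = c(2003, 2015, 2020, 2030),
                                          values = c(1.1, 1.1, 1.5, 1.5)),
                         FB_anchors = list(years = c(2003, 2006, 2011, 2030),
                                           values = c(0.006, 0.008, 0.0012, 0.0012)),
                         FT_anchors = list(years = c(2003, 2014, 2015, 2020, 2021, 2030),
                                           values = c(0.7, 0.3, 0.45, 0.45, 0.05, 0.05)),
                         lam_anchors = list(years = c(2003, 2023),
                                            values = c(2.9, 2.4)),
                         muG = rep(logit(0.05), 4), sigmaG = rep(0.3, 4),
                         N0 = c(1.3e6, 4.3e5, 2.0e5, 7.2e4, 4.7e3),
                         R_init = c(1.3e6, 1.3e6),
                         genotyping_rate = 0.1,
                         juvenile_missing_years = c(2005, 2008, 2020),
                         gsi_missing_years = integer(0),
                         obs = ipm_obs_config()) {
  scn <- list(dims = dims, log_alpha = log_alpha, beta = beta,
              sigma_R = sigma_R, sB = sB, v = v, sT = sT,
              M_anchors = M_anchors, FB_anchors = FB_anchors,
              FT_anchors = FT_anchors, lam_anchors = lam_anchors,
              muG = muG, sigmaG = sigmaG, N0 = N0, R_init = R_init,
              genotyping_rate = genotyping_rate,
              juvenile_missing_years = juvenile_missing_years,
              gsi_missing_years = gsi_missing_years, obs = obs)
  stopifnot(beta >= 0, sigma_R >= 0, length(N0) == 5, length(R_init) == 2,
            genotyping_rate > 0, genotyping_rate <= 1)
  structure(scn, class = "sim_scenario")
}

# rate paths on the scenario's calendar
scenario_rates <- function(scn) {
  d <- scn$dims
  list(M = .path(d$years, scn$M_anchors$years, scn$M_anchors$values),
       FB = .path(d$years, scn$FB_anchors$years, scn$FB_anchors$values),
       FT = .path(d$years, scn$FT_anchors$years, scn$FT_anchors$values),
       lam = .path(d$years[seq_len(d$n_cohorts)],
                   scn$lam_anchors$years, scn$lam_anchors$values))
}

#' Generate the latent truth for a scenario
#'
#' Draws recruitment errors from their generating distribution and the
#' stock-composition logits from their among-year hierarchy, assembles the
#' full parameter set (rate paths expressed exactly as log-space walks) and
#' runs the process model.
#'
#' @param scn A \code{\link{sim_scenario}}.
#' @param seed Seed for the process-error draws.
#' @return List with \code{pars} (an \code{ipm_parameters}), \code{state}
#'   (an \code{ipm_state}) and the scenario.
#' @export
generate_truth <- function(scn, seed = 1) {
  set.seed(seed)
  d <- scn$dims
  r <- scenario_rates(scn)
  eps_R <- stats::rnorm(d$n_years - 2L, 0, scn$sigma_R)
  logit_vt <- matrix(stats::rnorm(d$n_years * 4,
                                  rep(scn$muG, each = d$n_years),
                                  rep(scn$sigmaG, each = d$n_years)),
                     d$n_years, 4)
  pars <- ipm_parameters(
    d, log_alpha = scn$log_alpha, beta = scn$beta,
    sigma_R = scn$sigma_R,
    sigma_M = .sd0(diff(log(r$M))) + 1e-3,
    sigma_B = .sd0(diff(log(r$FB))) + 1e-3,
    sigma_T = .sd0(diff(log(r$FT))) + 1e-3,
    sigma_lambda = .sd0(diff(log(r$lam))) + 1e-3,
    sB = scn$sB, v = scn$v, sT = scn$sT,
    log_M_init = log(r$M[1]), log_FB_init = log(r$FB[1]),
    log_FT_init = log(r$FT[1]), log_lam_init = log(r$lam[1]),
    eps_M = diff(log(r$M)), eps_B = diff(log(r$FB)), eps_T = diff(log(r$FT)),
    eps_lambda = diff(log(r$lam)), eps_R = eps_R,
    log_N0 = log(scn$N0), log_R_init = log(scn$R_init),
    muG = scn$muG, sigmaG = scn$sigmaG, logit_vartheta = logit_vt
  )
  list(pars = pars, state = simulate_population(pars, d), scenario = scn)
}

#' Generate an observation dataset from a latent truth
#'
#' Samples every stream from the observation model: lognormal abundance
#' indices, multinomial age compositions at the configured effective sizes,
#' lognormal total bycatch counts, and binomial genetic assignments with
#' genotyped sample sizes drawn binomially from the age-specific bycatch at
#' the genotyping rate. Missing-year masks are applied afterwards.
#'
#' @param truth Output of \code{\link{generate_truth}}.
#' @param seed Seed for the observation draws.
#' @return An \code{\link{ipm_data}} object.
#' @export
generate_observations <- function(truth, seed = 1) {
  set.seed(seed)
  scn <- truth$scenario
  st <- truth$state
  d <- scn$dims
  T <- d$n_years
  cfg <- scn$obs
  rln <- function(pred, sigma) stats::rlnorm(length(pred), log(pred), sigma)
  J <- rln(st$N[, 1], cfg$sigma_J)
  E <- rln(st$S_total, cfg$sigma_E)
  C <- rln(rowSums(st$H), cfg$sigma_C)
  b <- rln(rowSums(st$BA), cfg$sigma_b)
  qE <- t(vapply(seq_len(T), function(y)
    as.vector(stats::rmultinom(1, cfg$neff_E, st$pi_S[y, ])) / cfg$neff_E,
    numeric(4)))
  qC <- t(vapply(seq_len(T), function(y)
    as.vector(stats::rmultinom(1, cfg$neff_C, st$pi_H[y, ])) / cfg$neff_C,
    numeric(4)))
  n <- matrix(stats::rbinom(T * 4, round(st$BA), scn$genotyping_rate), T, 4)
  x <- matrix(stats::rbinom(T * 4, n, st$vartheta), T, 4)
  nB <- rowSums(n)
  qB <- matrix(NA_real_, T, 4)
  for (y in seq_len(T)) {
    if (nB[y] > 0)
      qB[y, ] <- as.vector(stats::rmultinom(1, nB[y], st$pi_B[y, ])) / nB[y]
  }
  J[d$years %in% scn$juvenile_missing_years] <- NA
  gmiss <- d$years %in% scn$gsi_missing_years
  x[gmiss, ] <- NA
  n[gmiss, ] <- NA
  ipm_data(d, J = J, E = E, C = C, qE = qE, qC = qC, b_total = b,
           qB = qB, nB = nB, x = x, n = n)
}

#' One-call synthetic dataset
#'
#' @param scn A \code{\link{sim_scenario}}.
#' @param seed Single seed split between process and observation draws.
#' @return List with \code{data}, \code{truth} (pars + state), and the
#'   scenario.
#' @export
simulate_ipm_data <- function(scn = sim_scenario(), seed = 1) {
  truth <- generate_truth(scn, seed = seed)
  data <- generate_observations(truth, seed = seed + 1e6)
  list(data = data, truth = truth, scenario = scn)
}

#' Write a reproducible fixture bundle
#'
#' Generates a synthetic dataset and writes the CSV bundle (plus a JSON
#' manifest of the generating scenario) under \code{dir}.
#'
#' @param dir Output directory (created if needed).
#' @param size \code{"tiny"} (8 years, fast tests) or \code{"study_scale"}
#'   (21 years, 2003-2023 labels).
#' @param seed Seed.
#' @return Invisibly, the list from \code{\link{simulate_ipm_data}}.
#' @export
make_fixture <- function(dir, size = c("tiny", "study_scale"), seed = 1) {
  size <- match.arg(size)
  dims <- if (size == "tiny") ipm_dims(2003, 8) else ipm_dims(2003, 21)
  scn <- sim_scenario(dims = dims)
  sim <- simulate_ipm_data(scn, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ipm_data(sim$data, dir)
  manifest <- list(size = size, seed = seed, first_year = dims$first_year,
                   n_years = dims$n_years,
                   log_alpha = scn$log_alpha, beta = scn$beta,
                   sigma_R = scn$sigma_R, sB = scn$sB, v = scn$v, sT = scn$sT,
                   muG = scn$muG, sigmaG = scn$sigmaG,
                   genotyping_rate = scn$genotyping_rate,
                   juvenile_missing_years = scn$juvenile_missing_years)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    dput(manifest, file.path(dir, "manifest.R"))
  }
  invisible(sim)
}

# sd that degrades gracefully on short series
.sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
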