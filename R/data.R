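# Observation dataset container and validation.

#' Observation-error configuration
#'
#' Fixed observation SDs (log scale) and multinomial effective sample sizes
#' for the five data streams. These are measurement-model constants, not
#' estimated quantities; \code{sigma_b} is the SD of the total-bycatch count
#' likelihood and is distinct from the bycatch-mortality process SD.
#'
#' @param sigma_J Log-SD of the juvenile abundance index (default 0.25).
#' @param sigma_E Log-SD of escapement abundance (default 0.10).
#' @param sigma_C Log-SD of terminal harvest abundance (default 0.15).
#' @param sigma_b Log-SD of the total bycatch count (default 0.10).
#' @param neff_E,neff_C Effective sample sizes of the escapement and harvest
#'   age compositions (default 100 each).
#' @return List of class \code{ipm_obs_config}.
#' @export
ipm_obs_config <- function(sigma_J = 0.25, sigma_E = 0.10, sigma_C = 0.15,
                           sigma_b = 0.10, neff_E = 100, neff_C = 100) {
  cfg <- list(sigma_J = sigma_J, sigma_E = sigma_E, sigma_C = sigma_C,
              sigma_b = sigma_b, neff_E = neff_E, neff_C = neff_C)
  if (any(unlist(cfg) <= 0)) stop("all observation-error settings must be positive")
  structure(cfg, class = "ipm_obs_config")
}

#' Assemble and validate an observation dataset
#'
#' The five data streams the joint likelihood consumes, with missingness
#' encoded as \code{NA}: a juvenile abundance index, escapement and harvest
#' abundances with age compositions (ages 4-7), total Chinook bycatch counts
#' with age compositions and aging sample sizes (ages 3-6), and per-age
#' genetic assignment counts for the focal stock.
#'
#' @param dims An \code{\link{ipm_dims}} object.
#' @param J Juvenile abundance index per year (NA = survey not run).
#' @param E,C Escapement and harvest abundance per year.
#' @param qE,qC Matrices (\code{n_years} x 4) of age-composition proportions
#'   over ages 4-7 (rows sum to 1 where observed).
#' @param b_total Total Chinook bycatch count per year.
#' @param qB Matrix (\code{n_years} x 4) of bycatch age compositions over
#'   ages 3-6.
#' @param nB Number of scale (aging) samples behind \code{qB} per year.
#' @param x,n Matrices (\code{n_years} x 4): genetic assignments to the focal
#'   stock and genotyped sample sizes per year and bycatch age.
#' @return List of class \code{ipm_data}.
#' @export
ipm_data <- function(dims, J, E, C, qE, qC, b_total, qB, nB, x, n) {
  T <- dims$n_years
  chk_len <- function(v, nm) if (length(v) != T)
    stop(nm, " must have length n_years = ", T)
  for (nm in c("J", "E", "C", "b_total", "nB"))
    chk_len(get(nm), nm)
  chk_mat <- function(m, nm) if (!is.matrix(m) || nrow(m) != T || ncol(m) != 4)
    stop(nm, " must be an n_years x 4 matrix")
  for (nm in c("qE", "qC", "qB", "x", "n")) chk_mat(get(nm), nm)
  chk_simplex <- function(m, nm) {
    rs <- rowSums(m)
    bad <- which(!is.na(rs) & abs(rs - 1) > 1e-6)
    if (length(bad))
      stop(nm, " rows must sum to 1: year ", dims$years[bad[1]],
           " sums to ", format(rs[bad[1]]))
    if (any(m < -1e-12, na.rm = TRUE)) stop(nm, " has negative proportions")
  }
  chk_simplex(qE, "qE"); chk_simplex(qC, "qC"); chk_simplex(qB, "qB")
  for (nm in c("J", "E", "C", "b_total")) {
    v <- get(nm)
    if (any(v <= 0, na.rm = TRUE)) stop(nm, " must be positive where observed")
  }
  if (any(x > n, na.rm = TRUE))
    stop("genetic assignments x cannot exceed genotyped sample sizes n")
  if (any(x < 0, na.rm = TRUE) || any(n < 0, na.rm = TRUE))
    stop("genetic assignment counts must be non-negative")
  dn <- list(dims$years, NULL)
  named <- function(m, ages) { dimnames(m) <- list(dims$years, ages); m }
  structure(list(
    dims = dims, years = dims$years,
    J = stats::setNames(J, dims$years), E = stats::setNames(E, dims$years),
    C = stats::setNames(C, dims$years),
    qE = named(qE, 4:7), qC = named(qC, 4:7),
    b_total = stats::setNames(b_total, dims$years),
    qB = named(qB, 3:6), nB = stats::setNames(nB, dims$years),
    x = named(x, 3:6), n = named(n, 3:6)
  ), class = "ipm_data")
}

#' @export
print.ipm_data <- function(x, ...) {
  d <- x$dims
  cat("ipm_data: ", d$n_years, " years (", d$years[1], "-",
      d$years[d$n_years], ")\n", sep = "")
  cat("  juvenile index observed in ", sum(!is.na(x$J)), " years\n", sep = "")
  cat("  genotyped cells: ", sum(x$n > 0, na.rm = TRUE), "\n", sep = "")
  invisible(x)
}
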