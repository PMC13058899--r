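#' Model dimensions for the salmon life-cycle model
#'
#' Defines the calendar span and age structure of the model: fish recruit as
#' age-2 (ocean age-0) juveniles, remain immature over ages 3-7, mature and
#' return at ages 4-7, and are encountered in the trawl bycatch at ages 3-6.
#'
#' @param first_year First calendar year of the model (default 2003).
#' @param n_years Number of modelled years (at least 3; the study span
#'   2003-2023 is 21 years).
#' @return An object of class \code{ipm_dims}: a list with the year vector and
#'   the juvenile / immature / mature / bycatch age ranges.
#' @examples
#' d <- ipm_dims(2003, 21)
#' d$years[d$n_years]  # 2023
#' @export
ipm_dims <- function(first_year = 2003, n_years = 21) {
  n_years <- as.integer(n_years)
  if (n_years < 3) stop("n_years must be at least 3")
  structure(list(
    first_year   = as.integer(first_year),
    n_years      = n_years,
    years        = as.integer(first_year) + 0:(n_years - 1L),
    ages         = 2:7,
    juvenile_age = 2L,
    immature_ages = 3:7,
    mature_ages  = 4:7,
    bycatch_ages = 3:6,
    # cohorts indexed by the year the cohort was age 2; maturation schedules
    # are estimated for cohorts whose mature ages fall inside the window
    n_cohorts    = n_years - 2L
  ), class = "ipm_dims")
}

# cohort (juvenile year-class) index of a fish aged `a` in year index `y`:
# the year in which that cohort was age 2
cohort_index <- function(y, a) y - (a - 2L)

#' @export
print.ipm_dims <- function(x, ...) {
  cat("ipm_dims: years ", x$years[1], "-", x$years[x$n_years],
      " (", x$n_years, " years), ages 2-7\n", sep = "")
  invisible(x)
}
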