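# CSV readers/writers for the observation bundle. Dialect: UTF-8, comma
# separated, header row, integer years/ages, proportions as fractions;
# missing years are absent rows (no sentinels).

.bundle_files <- c("juveniles.csv", "adults.csv", "adult_agecomp.csv",
                   "bycatch.csv", "bycatch_agecomp.csv", "gsi.csv")

#' Write an observation dataset as a CSV bundle
#'
#' Emits six files: \code{juveniles.csv} (year, abundance),
#' \code{adults.csv} (year, escapement, harvest), \code{adult_agecomp.csv}
#' (year, age, prop_escapement, prop_harvest), \code{bycatch.csv} (year,
#' total_count, n_scales), \code{bycatch_agecomp.csv} (year, age, prop) and
#' \code{gsi.csv} (year, age, n_genotyped, n_assigned_focal). Years with a
#' missing stream are omitted from that stream's file.
#'
#' @param data An \code{\link{ipm_data}} object.
#' @param dir Output directory.
#' @return Invisibly, the vector of file paths written.
#' @export
write_ipm_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yrs <- data$years
  w <- function(df, file) utils::write.csv(df, file.path(dir, file),
                                           row.names = FALSE, quote = FALSE)
  keep <- !is.na(data$J)
  w(data.frame(year = yrs[keep], abundance = data$J[keep]), "juveniles.csv")
  keep <- !is.na(data$E) | !is.na(data$C)
  w(data.frame(year = yrs[keep], escapement = data$E[keep],
               harvest = data$C[keep]), "adults.csv")
  rows <- which(apply(!is.na(data$qE) | !is.na(data$qC), 1, any))
  w(data.frame(year = rep(yrs[rows], each = 4), age = rep(4:7, length(rows)),
               prop_escapement = as.vector(t(data$qE[rows, , drop = FALSE])),
               prop_harvest = as.vector(t(data$qC[rows, , drop = FALSE]))),
    "adult_agecomp.csv")
  keep <- !is.na(data$b_total)
  w(data.frame(year = yrs[keep], total_count = data$b_total[keep],
               n_scales = data$nB[keep]), "bycatch.csv")
  rows <- which(apply(!is.na(data$qB), 1, any))
  w(data.frame(year = rep(yrs[rows], each = 4), age = rep(3:6, length(rows)),
               prop = as.vector(t(data$qB[rows, , drop = FALSE]))),
    "bycatch_agecomp.csv")
  rows <- which(apply(!is.na(data$n), 1, any))
  w(data.frame(year = rep(yrs[rows], each = 4), age = rep(3:6, length(rows)),
               n_genotyped = as.vector(t(data$n[rows, , drop = FALSE])),
               n_assigned_focal = as.vector(t(data$x[rows, , drop = FALSE]))),
    "gsi.csv")
  invisible(file.path(dir, .bundle_files))
}

#' Load and validate an observation dataset from a CSV bundle
#'
#' Reads the schema written by \code{\link{write_ipm_data}}; missing masks
#' are inferred from absent year rows. Schema violations, non-simplex
#' compositions (tolerance 1e-6) and assignment counts exceeding sample
#' sizes raise descriptive errors.
#'
#' @param dir Directory holding the bundle.
#' @param first_year,n_years Model window; inferred from the year range in
#'   the files when NULL.
#' @return An \code{\link{ipm_data}} object.
#' @export
read_ipm_data <- function(dir, first_year = NULL, n_years = NULL) {
  p <- function(f) file.path(dir, f)
  for (f in .bundle_files)
    if (!file.exists(p(f))) stop("missing bundle file: ", f)
  rd <- function(f, cols) {
    df <- utils::read.csv(p(f))
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(f, " lacks required column(s): ", paste(miss, collapse = ", "))
    df
  }
  juv <- rd("juveniles.csv", c("year", "abundance"))
  adu <- rd("adults.csv", c("year", "escapement", "harvest"))
  aac <- rd("adult_agecomp.csv",
            c("year", "age", "prop_escapement", "prop_harvest"))
  byc <- rd("bycatch.csv", c("year", "total_count", "n_scales"))
  bac <- rd("bycatch_agecomp.csv", c("year", "age", "prop"))
  gsi <- rd("gsi.csv", c("year", "age", "n_genotyped", "n_assigned_focal"))
  all_years <- c(juv$year, adu$year, aac$year, byc$year, bac$year, gsi$year)
  if (is.null(first_year)) first_year <- min(all_years)
  if (is.null(n_years)) n_years <- max(all_years) - first_year + 1L
  dims <- ipm_dims(first_year, n_years)
  T <- dims$n_years
  vec <- function(df, col) {
    out <- rep(NA_real_, T)
    idx <- match(df$year, dims$years)
    if (anyNA(idx)) stop("year outside the model window in ", col)
    out[idx] <- df[[col]]
    out
  }
  mat <- function(df, col, ages) {
    out <- matrix(NA_real_, T, 4)
    yi <- match(df$year, dims$years)
    ai <- match(df$age, ages)
    if (anyNA(yi) || anyNA(ai))
      stop("year/age outside the model window in ", col)
    out[cbind(yi, ai)] <- df[[col]]
    out
  }
  ipm_data(dims,
           J = vec(juv, "abundance"),
           E = vec(adu, "escapement"), C = vec(adu, "harvest"),
           qE = mat(aac, "prop_escapement", 4:7),
           qC = mat(aac, "prop_harvest", 4:7),
           b_total = vec(byc, "total_count"),
           qB = mat(bac, "prop", 3:6),
           nB = vec(byc, "n_scales"),
           x = mat(gsi, "n_assigned_focal", 3:6),
           n = mat(gsi, "n_genotyped", 3:6))
}
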