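logit <- function(p) log(p) - log1p(-p)

invlogit <- function(x) 1 / (1 + exp(-x))

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Convert observed composition proportions to integer counts
#'
#' Multiplies a simplex of observed proportions by an effective sample size
#' and rounds to integers with largest-remainder repair, so the resulting
#' counts sum to \code{neff} exactly and define a proper multinomial
#' observation.
#'
#' @param q Numeric vector of proportions (must sum to 1 within 1e-6).
#' @param neff Effective sample size (positive integer).
#' @return Integer vector of counts summing to \code{round(neff)}.
#' @export
counts_from_props <- function(q, neff) {
  stopifnot(neff > 0, all(q >= 0))
  if (abs(sum(q) - 1) > 1e-6)
    stop("composition proportions must sum to 1 (got ", format(sum(q)), ")")
  neff <- round(neff)
  raw <- q * neff
  cnt <- floor(raw)
  short <- neff - sum(cnt)
  if (short > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(short)]] <- cnt[ord[seq_len(short)]] + 1
  }
  as.integer(cnt)
}

# quantile type 7 (linear interpolation between order statistics); kept as a
# named wrapper so the convention is a single visible choice
interp_quantile <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

`%||%` <- function(a, b) if (is.null(a)) b else a
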