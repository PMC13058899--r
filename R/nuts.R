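# No-U-Turn Hamiltonian Monte Carlo over an arbitrary differentiable
# negative-log-density (here the TMB-autodifferentiated joint posterior).
# Multinomial trajectory sampling, dual-averaging step-size adaptation and
# windowed diagonal mass-matrix estimation, following the standard adaptive
# HMC recipe used by Stan and by the TMB/ADMB assessment-model samplers.

#' Sampler control settings
#'
#' @param max_treedepth Maximum trajectory doublings per iteration.
#' @param adapt_delta Target average acceptance statistic for step-size
#'   adaptation; random-walk hierarchies typically need high targets.
#' @param max_deltaH Energy error declaring a divergent transition.
#' @param init_buffer,term_buffer,base_window Warmup schedule: step-size-only
#'   opening phase, closing phase, and first mass-matrix window (doubling).
#' @param stepsize Optional fixed initial step size (found heuristically if
#'   NULL).
#' @param metric \code{"diag"} or \code{"dense"} mass matrix. The dense
#'   metric estimates the full posterior covariance during warmup windows
#'   (regularized toward the diagonal), which pays off in strongly
#'   correlated posteriors such as state-space random-walk models.
#' @return List of class \code{nuts_control}.
#' @export
nuts_control <- function(max_treedepth = 10, adapt_delta = 0.95,
                         max_deltaH = 1000, init_buffer = 75,
                         term_buffer = 50, base_window = 25,
                         stepsize = NULL, metric = c("dense", "diag")) {
  structure(list(max_treedepth = max_treedepth, adapt_delta = adapt_delta,
                 max_deltaH = max_deltaH, init_buffer = init_buffer,
                 term_buffer = term_buffer, base_window = base_window,
                 stepsize = stepsize, metric = match.arg(metric),
                 gamma = 0.05, t0 = 10, kappa = 0.75),
            class = "nuts_control")
}

# mass-matrix adaptation windows: iterations (within warmup) at which the
# diagonal metric is re-estimated
.adapt_windows <- function(n_warmup, ctrl) {
  if (n_warmup < ctrl$init_buffer + ctrl$term_buffer + ctrl$base_window)
    return(integer(0))
  ends <- integer(0)
  lo <- ctrl$init_buffer
  w <- ctrl$base_window
  repeat {
    hi <- lo + w
    if (hi + 2L * w + ctrl$term_buffer > n_warmup) {
      hi <- n_warmup - ctrl$term_buffer
      ends <- c(ends, hi)
      break
    }
    ends <- c(ends, hi)
    lo <- hi
    w <- 2L * w
  }
  ends
}

# crude reasonable first step size: scale until a single leapfrog's
# acceptance probability crosses 1/2
.init_stepsize <- function(U, grad, q, inv_M) {
  d <- length(q)
  eps <- 0.1
  p <- stats::rnorm(d) / sqrt(inv_M)
  u0 <- U(q); g0 <- grad(q)
  H0 <- u0 + 0.5 * sum(inv_M * p^2)
  onestep <- function(eps) {
    p1 <- p - 0.5 * eps * g0
    q1 <- q + eps * inv_M * p1
    u1 <- U(q1)
    if (!is.finite(u1)) return(-Inf)
    p1 <- p1 - 0.5 * eps * grad(q1)
    -(u1 + 0.5 * sum(inv_M * p1^2)) + H0
  }
  a0 <- onestep(eps)
  dir <- if (is.finite(a0) && a0 > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^dir
    a <- onestep(eps)
    if ((dir == 1 && !(is.finite(a) && a > log(0.5))) ||
        (dir == -1 && (is.finite(a) && a > log(0.5)))) break
  }
  eps
}

#' Run one NUTS chain
#'
#' @param fn Negative log density (energy) taking the position vector.
#' @param gr Its gradient.
#' @param init Initial position (must have finite energy and gradient).
#' @param n_iter Total iterations, including warmup.
#' @param n_warmup Warmup (adaptation) iterations; warmup draws discarded.
#' @param control A \code{\link{nuts_control}} list.
#' @return List with post-warmup \code{draws} (matrix), per-iteration
#'   \code{energy}, \code{divergent}, \code{treedepth}, \code{accept_stat},
#'   \code{n_leapfrog}, and the adapted \code{stepsize} and \code{inv_metric}.
#' @export
nuts_chain <- function(fn, gr, init, n_iter = 2000, n_warmup = 1000,
                       control = nuts_control()) {
  ctrl <- control
  d <- length(init)
  U <- function(q) { v <- tryCatch(as.numeric(fn(q)), error = function(e) NaN)
                     if (!length(v) || !is.finite(v)) Inf else v }
  grad <- function(q) { g <- tryCatch(as.numeric(gr(q)), error = function(e) rep(NaN, d))
                        if (anyNA(g) || any(!is.finite(g))) rep(Inf, d) else g }
  q <- init
  u_cur <- U(q); g_cur <- grad(q)
  if (!is.finite(u_cur) || any(!is.finite(g_cur)))
    stop("non-finite posterior density or gradient at the initial point")

  # metric state: velocity M^-1 p, kinetic energy, momentum draw. The inverse
  # mass is the (regularized) posterior variance (diag) or covariance (dense).
  dense <- ctrl$metric == "dense"
  inv_M <- rep(1, d)          # diagonal inverse mass
  Sig <- NULL; Sig_chol <- NULL  # dense inverse mass and its factor
  vel <- function(p) if (is.null(Sig)) inv_M * p else drop(Sig %*% p)
  kin <- function(p) 0.5 * sum(p * vel(p))
  draw_p <- function() {
    z <- stats::rnorm(d)
    if (is.null(Sig)) z / sqrt(inv_M) else backsolve(Sig_chol, z)
  }
  eps <- ctrl$stepsize %||% .init_stepsize(U, grad, q, inv_M)

  # dual averaging state
  mu <- log(10 * eps); Hbar <- 0; log_ebar <- log(eps); m_adapt <- 0
  windows <- .adapt_windows(n_warmup, ctrl)
  w_buf <- matrix(NA_real_, n_warmup, d); w_n <- 0  # window draw buffer

  n_keep <- n_iter - n_warmup
  div_pos <- list()
  draws <- matrix(NA_real_, n_keep, d)
  energy <- numeric(n_iter); divergent <- logical(n_iter)
  treedepth <- integer(n_iter); accept_stat <- numeric(n_iter)
  n_leapfrog <- integer(n_iter)

  max_dH <- ctrl$max_deltaH

  for (it in seq_len(n_iter)) {
    p0 <- draw_p()
    H0 <- u_cur + kin(p0)
    # trajectory state: edges and current sample
    qm <- q; pm <- p0; gm <- g_cur
    qp <- q; pp <- p0; gp <- g_cur
    q_prop <- q; u_prop <- u_cur; g_prop <- g_cur; H_prop <- H0
    logw <- 0
    s_alpha <- 0; n_alpha <- 0; nleap <- 0
    div <- FALSE; depth <- 0; div_at <- NULL

    leap <- function(q, p, g, e) {
      p1 <- p - 0.5 * e * g
      q1 <- q + e * vel(p1)
      u1 <- U(q1)
      if (!is.finite(u1)) return(list(ok = FALSE))
      g1 <- grad(q1)
      if (any(!is.finite(g1))) return(list(ok = FALSE))
      p1 <- p1 - 0.5 * e * g1
      list(ok = TRUE, q = q1, p = p1, g = g1, u = u1,
           H = u1 + kin(p1))
    }
    uturn <- function(qm, pm, qp, pp) {
      dq <- qp - qm
      sum(dq * vel(pm)) < 0 || sum(dq * vel(pp)) < 0
    }
    # recursive subtree builder; returns NULL weightable info plus edges
    build <- function(q, p, g, dir, depth) {
      if (depth == 0L) {
        st <- leap(q, p, g, dir * eps)
        nleap <<- nleap + 1L
        if (!st$ok || (st$H - H0) > max_dH) {
          s_alpha <<- s_alpha + 0; n_alpha <<- n_alpha + 1
          div_at <<- q
          return(list(div = TRUE))
        }
        s_alpha <<- s_alpha + min(1, exp(H0 - st$H)); n_alpha <<- n_alpha + 1
        list(div = FALSE, turned = FALSE,
             qm = st$q, pm = st$p, gm = st$g,
             qp = st$q, pp = st$p, gp = st$g,
             q_prop = st$q, u_prop = st$u, g_prop = st$g, H_prop = st$H,
             logw = H0 - st$H)
      } else {
        t1 <- build(q, p, g, dir, depth - 1L)
        if (t1$div || t1$turned) return(t1)
        edge <- if (dir == 1L) list(q = t1$qp, p = t1$pp, g = t1$gp)
                else list(q = t1$qm, p = t1$pm, g = t1$gm)
        t2 <- build(edge$q, edge$p, edge$g, dir, depth - 1L)
        if (t2$div) return(list(div = TRUE))
        out <- t1
        if (dir == 1L) { out$qp <- t2$qp; out$pp <- t2$pp; out$gp <- t2$gp }
        else { out$qm <- t2$qm; out$pm <- t2$pm; out$gm <- t2$gm }
        tot <- logsumexp(c(t1$logw, t2$logw))
        if (log(stats::runif(1)) < t2$logw - tot) {
          out$q_prop <- t2$q_prop; out$u_prop <- t2$u_prop
          out$g_prop <- t2$g_prop; out$H_prop <- t2$H_prop
        }
        out$logw <- tot
        out$turned <- t2$turned || uturn(out$qm, out$pm, out$qp, out$pp)
        out
      }
    }

    repeat {
      dir <- if (stats::runif(1) < 0.5) -1L else 1L
      sub <- if (dir == 1L) build(qp, pp, gp, dir, depth)
             else build(qm, pm, gm, dir, depth)
      if (sub$div) { div <- TRUE; break }
      if (!sub$turned) {
        # biased progressive sampling: favour the new, larger subtree
        if (log(stats::runif(1)) < sub$logw - logw) {
          q_prop <- sub$q_prop; u_prop <- sub$u_prop
          g_prop <- sub$g_prop; H_prop <- sub$H_prop
        }
      }
      if (dir == 1L) { qp <- sub$qp; pp <- sub$pp; gp <- sub$gp }
      else { qm <- sub$qm; pm <- sub$pm; gm <- sub$gm }
      logw <- logsumexp(c(logw, sub$logw))
      depth <- depth + 1L
      if (sub$turned || uturn(qm, pm, qp, pp) || depth >= ctrl$max_treedepth)
        break
    }

    q <- q_prop; u_cur <- u_prop; g_cur <- g_prop
    if (div && length(div_pos) < 50L) div_pos[[length(div_pos) + 1L]] <- div_at
    energy[it] <- H_prop
    divergent[it] <- div
    treedepth[it] <- depth
    accept_stat[it] <- if (n_alpha > 0) s_alpha / n_alpha else 0
    n_leapfrog[it] <- nleap

    if (it <= n_warmup) {
      # dual averaging toward the target acceptance statistic
      m_adapt <- m_adapt + 1
      a <- accept_stat[it]
      Hbar <- (1 - 1 / (m_adapt + ctrl$t0)) * Hbar +
        (ctrl$adapt_delta - a) / (m_adapt + ctrl$t0)
      log_eps <- mu - sqrt(m_adapt) / ctrl$gamma * Hbar
      eta <- m_adapt^(-ctrl$kappa)
      log_ebar <- eta * log_eps + (1 - eta) * log_ebar
      eps <- exp(log_eps)
      # mass-matrix accumulation in the current window
      if (it > ctrl$init_buffer && length(windows) &&
          it <= windows[length(windows)]) {
        w_n <- w_n + 1
        w_buf[w_n, ] <- q
      }
      if (length(windows) && it == windows[1]) {
        if (w_n > 4) {
          shrink <- w_n / (w_n + 5)
          draws_w <- w_buf[seq_len(w_n), , drop = FALSE]
          dvar <- apply(draws_w, 2, stats::var) * shrink +
            1e-3 * (1 - shrink)
          if (dense && w_n > d + 10) {
            # full covariance only once the window can support a full-rank
            # estimate; regularized with a small ridge. Short windows would
            # leave rank-deficient directions frozen, so they stay diagonal.
            Sg <- shrink * stats::cov(draws_w) +
              diag(1e-3 * (1 - shrink), d)
            ch <- tryCatch(chol(Sg), error = function(e) NULL)
            if (!is.null(ch)) { Sig <- Sg; Sig_chol <- ch }
            else { inv_M <- dvar; Sig <- NULL; Sig_chol <- NULL }
          } else {
            inv_M <- dvar
            Sig <- NULL; Sig_chol <- NULL
          }
        }
        w_n <- 0
        windows <- windows[-1]
        # re-anchor step-size adaptation under the new metric
        mu <- log(10 * eps); Hbar <- 0; m_adapt <- 0
      }
      if (it == n_warmup) eps <- exp(log_ebar)
    } else {
      draws[it - n_warmup, ] <- q
    }
  }

  list(draws = draws, energy = energy, divergent = divergent,
       treedepth = treedepth, accept_stat = accept_stat,
       n_leapfrog = n_leapfrog, stepsize = eps,
       inv_metric = if (is.null(Sig)) inv_M else Sig,
       divergence_positions = div_pos, n_warmup = n_warmup)
}
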