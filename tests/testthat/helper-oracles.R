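# Independent oracles, hand-coded from the distribution definitions --
# deliberately not routed through the package's own lms_* functions.

# BCCG log-density written out directly: z-kernel x Jacobian / truncation
oracle_bccg_logpdf <- function(y, L, M, S) {
  z <- if (abs(L) < 1e-12) log(y / M) / S else ((y / M)^L - 1) / (L * S)
  trunc <- if (abs(L) < 1e-12) 0 else pnorm(1 / (S * abs(L)), log.p = TRUE)
  dnorm(z, log = TRUE) + (L - 1) * log(y / M) - log(M * S) - trunc
}

# CDF of the truncated Box-Cox normal, for finite-difference density checks
oracle_bccg_cdf <- function(y, L, M, S) {
  z <- if (abs(L) < 1e-12) log(y / M) / S else ((y / M)^L - 1) / (L * S)
  if (abs(L) < 1e-12) return(pnorm(z))
  lim <- 1 / (S * abs(L))
  if (L > 0) (pnorm(z) - pnorm(-lim)) / pnorm(lim)
  else pnorm(z) / pnorm(lim)
}

# BCT CDF (truncated Box-Cox t); used to invert quantiles numerically
oracle_bct_cdf <- function(y, L, M, S, tau) {
  z <- if (abs(L) < 1e-12) log(y / M) / S else ((y / M)^L - 1) / (L * S)
  if (abs(L) < 1e-12) return(pt(z, tau))
  lim <- 1 / (S * abs(L))
  if (L > 0) (pt(z, tau) - pt(-lim, tau)) / pt(lim, tau)
  else pt(z, tau) / pt(lim, tau)
}

# Brute-force constant-parameter MLE over a coarse (L, M, S) lattice
oracle_lattice_mle <- function(y, Ls, Ms, Ss) {
  best <- NULL; best_ll <- -Inf
  for (L in Ls) for (M in Ms) for (S in Ss) {
    ll <- sum(oracle_bccg_logpdf(y, L, M, S))
    if (ll > best_ll) { best_ll <- ll; best <- c(L = L, M = M, S = S) }
  }
  best
}

# OLS through the normal equations, on the same standardized scales the
# package uses
oracle_ols_standardized <- function(y, X) {
  ys <- (y - mean(y)) / sd(y)
  Xs <- X
  for (j in seq_len(ncol(X))) {
    cj <- X[, j]
    if (length(unique(cj)) > 2 && sd(cj) > 0)
      Xs[, j] <- (cj - mean(cj)) / sd(cj)
  }
  Xs <- cbind(1, Xs)
  drop(solve(t(Xs) %*% Xs, t(Xs) %*% ys))[-1]
}

# Benjamini-Yekutieli by the printed formula, via a j >= i minimization loop
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * cm * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# iid draws from LMS truth curves at uniform ages (no clustering)
draw_from_curves <- function(curves, n, seed) {
  set.seed(seed)
  age <- runif(n, curves$age_range[1], curves$age_range[2])
  z <- rnorm(n)
  ev <- pedmetref::eval_curves(curves, age)
  if (!is.null(curves$tau)) z <- qt(pnorm(z), df = curves$tau)
  lb <- -0.999 / (ev$L * ev$S)
  y <- ev$M * (1 + ev$L * ev$S * pmax(z, lb))^(1 / ev$L)
  data.frame(age = age, y = y)
}
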