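# Box-Cox Cole-Green (BCCG) and Box-Cox t (BCT) distribution machinery.
# The LMS parameterization: L (Box-Cox power / skewness), M (median, > 0),
# S (coefficient of variation, > 0), and for BCT an extra tau (> 0) degrees
# of freedom governing kurtosis. z is referred to a standard normal (BCCG)
# or a Student t with tau df (BCT).

.LMS_L_EPS <- 1e-5  # |L| below this uses the log-form branch (cancellation)

#' LMS distribution parameters
#'
#' Bundle pointwise LMS parameters: the Box-Cox power `L` (dimensionless
#' skewness), the median `M` (concentration units), the coefficient of
#' variation `S`, and optionally `tau`, the Student-t degrees of freedom.
#' `tau` present selects the Box-Cox t (BCT) family; absent, the Box-Cox
#' Cole-Green (BCCG, transformed-normal) family.
#'
#' Fields may be vectors of a common length (age-varying parameters); they
#' are recycled against data vectors by the `lms_*` functions.
#'
#' @param L Box-Cox power (numeric).
#' @param M median, strictly positive.
#' @param S coefficient of variation, strictly positive.
#' @param tau optional degrees of freedom, strictly positive (BCT only).
#' @return An object of class `lms_params`.
#' @examples
#' p <- lms_params(L = 1, M = 100, S = 0.1)
#' lms_z(110, p)
#' @export
lms_params <- function(L, M, S, tau = NULL) {
  stopifnot(is.numeric(L), is.numeric(M), is.numeric(S))
  if (any(!is.finite(L)) || any(!is.finite(M)) || any(!is.finite(S)))
    stop("LMS parameters must be finite")
  if (any(M <= 0)) stop("M must be > 0")
  if (any(S <= 0)) stop("S must be > 0")
  if (!is.null(tau)) {
    if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0))
      stop("tau must be finite and > 0")
  }
  structure(list(L = as.numeric(L), M = as.numeric(M), S = as.numeric(S),
                 tau = if (is.null(tau)) NULL else as.numeric(tau)),
            class = "lms_params")
}

.as_lms_params <- function(p) {
  if (inherits(p, "lms_params")) return(p)
  if (is.list(p) && all(c("L", "M", "S") %in% names(p)))
    return(lms_params(p$L, p$M, p$S, p$tau))
  stop("expected an 'lms_params' object or a list with L, M, S")
}

#' Box-Cox z-transform (LMS standard deviation score on the kernel scale)
#'
#' Computes `z = ((y/M)^L - 1) / (L * S)` for `L != 0` and
#' `z = log(y/M) / S` for `L = 0`. Under BCCG the null distribution of z is
#' standard normal; under BCT it is Student t with `tau` degrees of freedom.
#'
#' @param y positive concentrations (vector).
#' @param p an [lms_params()] object (fields recycled against `y`).
#' @return numeric vector of z-scores.
#' @export
lms_z <- function(y, p) {
  p <- .as_lms_params(p)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("y must be finite and > 0 (handle non-detects upstream)")
  n <- max(length(y), length(p$L), length(p$M), length(p$S))
  y <- rep_len(y, n); L <- rep_len(p$L, n)
  M <- rep_len(p$M, n); S <- rep_len(p$S, n)
  r <- y / M
  z <- log(r) / S                      # L == 0 branch
  big <- abs(L) >= .LMS_L_EPS
  if (any(big)) z[big] <- (r[big]^L[big] - 1) / (L[big] * S[big])
  z
}

#' LMS quantile (centile) function
#'
#' Inverts the Box-Cox transform at a probability:
#' `C_alpha = M * (1 + L * S * z_alpha)^(1/L)` for `L != 0`, and
#' `M * exp(S * z_alpha)` for `L = 0`, where `z_alpha` is the standard
#' normal quantile (BCCG) or the Student-t quantile with `tau` df (BCT).
#'
#' @param alpha probability in (0, 1) (vector).
#' @param p an [lms_params()] object.
#' @return concentrations (same units as `M`), strictly increasing in alpha.
#' @export
lms_quantile <- function(alpha, p) {
  p <- .as_lms_params(p)
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1))
    stop("alpha must lie strictly inside (0, 1)")
  n <- max(length(alpha), length(p$L), length(p$M), length(p$S))
  alpha <- rep_len(alpha, n); L <- rep_len(p$L, n)
  M <- rep_len(p$M, n); S <- rep_len(p$S, n)
  z <- if (is.null(p$tau)) stats::qnorm(alpha)
       else stats::qt(alpha, df = rep_len(p$tau, n))
  y <- M * exp(S * z)                  # L == 0 branch
  big <- abs(L) >= .LMS_L_EPS
  if (any(big)) {
    arg <- 1 + L[big] * S[big] * z[big]
    if (any(arg <= 0)) stop("percentile outside support")
    y[big] <- M[big] * arg^(1 / L[big])
  }
  y
}

#' Log-density of the Box-Cox normal / Box-Cox t distribution
#'
#' Density of `y > 0` under BCCG or BCT, including the Jacobian
#' `(L - 1) * log(y/M) - log(M * S)` and the exact renormalization for the
#' truncation of the kernel to the support `y > 0` (mass
#' `F_kernel(1 / (S * |L|))` for `L != 0`; no truncation for `L = 0`).
#'
#' @param y positive concentrations (vector).
#' @param p an [lms_params()] object.
#' @return log-density values.
#' @export
lms_logpdf <- function(y, p) {
  p <- .as_lms_params(p)
  if (any(!is.finite(y)) || any(y <= 0)) stop("y must be finite and > 0")
  n <- max(length(y), length(p$L), length(p$M), length(p$S))
  y <- rep_len(y, n); L <- rep_len(p$L, n)
  M <- rep_len(p$M, n); S <- rep_len(p$S, n)
  z <- lms_z(y, lms_params(L, M, S))
  jac <- (L - 1) * log(y / M) - log(M * S)
  big <- abs(L) >= .LMS_L_EPS
  if (is.null(p$tau)) {
    kern <- stats::dnorm(z, log = TRUE)
    ltrunc <- rep(0, n)
    if (any(big))
      ltrunc[big] <- stats::pnorm(1 / (S[big] * abs(L[big])), log.p = TRUE)
  } else {
    tau <- rep_len(p$tau, n)
    kern <- stats::dt(z, df = tau, log = TRUE)
    ltrunc <- rep(0, n)
    if (any(big))
      ltrunc[big] <- stats::pt(1 / (S[big] * abs(L[big])), df = tau[big],
                               log.p = TRUE)
  }
  kern + jac - ltrunc
}
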