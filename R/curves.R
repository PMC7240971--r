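# Smooth age-functions of the LMS parameters over a cubic B-spline basis.
# Knots are equally spaced on sqrt(age) so infancy, where metabolite levels
# move fastest, gets more resolution than adolescence. Links: identity for
# L, log for M and S (positivity), tau constant on the log scale.

.AGE_RANGE <- c(0.25, 18)

#' B-spline basis specification on a square-root age axis
#'
#' `df` counts basis functions (model coefficients). `df = 1` is a constant;
#' `df >= 2` uses a B-spline of degree `min(3, df - 1)` with `df - degree - 1`
#' interior knots equally spaced on `sqrt(age)` between the boundaries.
#'
#' @param df number of basis functions (>= 1).
#' @param age_range numeric length-2, the supported age interval in years.
#' @return a list describing the basis (degree, interior knots, boundary).
#' @export
lms_basis <- function(df, age_range = .AGE_RANGE) {
  df <- as.integer(df)
  stopifnot(df >= 1, length(age_range) == 2, age_range[1] > 0,
            age_range[2] > age_range[1])
  b <- sqrt(age_range)
  if (df == 1)
    return(list(df = 1L, degree = 0L, knots = numeric(0), boundary = b,
                age_range = age_range))
  degree <- min(3L, df - 1L)
  n_int <- df - degree - 1L
  interior <- if (n_int > 0)
    seq(b[1], b[2], length.out = n_int + 2L)[-c(1L, n_int + 2L)]
  else numeric(0)
  list(df = df, degree = degree, knots = interior, boundary = b,
       age_range = age_range)
}

#' Evaluate a basis at ages
#'
#' @param basis from [lms_basis()].
#' @param age ages in years; must lie within the basis age range
#'   (a tolerance of 1e-8 absorbs round-off).
#' @return matrix with `length(age)` rows and `basis$df` columns.
#' @export
eval_basis <- function(basis, age) {
  rng <- basis$age_range
  if (any(age < rng[1] - 1e-8) || any(age > rng[2] + 1e-8))
    stop(sprintf("age outside supported range [%g, %g]", rng[1], rng[2]))
  x <- pmin(pmax(sqrt(age), basis$boundary[1]), basis$boundary[2])
  if (basis$df == 1L) return(matrix(1, length(age), 1L))
  ord <- basis$degree + 1L
  kn <- c(rep(basis$boundary[1], ord), basis$knots, rep(basis$boundary[2], ord))
  splines::splineDesign(kn, x, ord = ord)
}

.LINKS <- list(
  identity = list(g = identity, ginv = identity),
  log      = list(g = log,      ginv = exp)
)

#' Age-varying LMS parameter curves
#'
#' Container for smooth L(age), M(age), S(age) (and a constant tau for the
#' BCT family): one basis and coefficient vector per parameter, with the
#' identity link for L and the log link for M, S and tau.
#'
#' @param family `"BCCG"` or `"BCT"`.
#' @param bases named list of [lms_basis()] specs for `L`, `M`, `S`.
#' @param coef named list of numeric coefficient vectors matching the bases.
#' @param tau constant degrees of freedom (> 0) when `family = "BCT"`.
#' @return object of class `lms_curves`.
#' @export
lms_curves <- function(family = c("BCCG", "BCT"), bases, coef, tau = NULL) {
  family <- match.arg(family)
  stopifnot(all(c("L", "M", "S") %in% names(bases)),
            all(c("L", "M", "S") %in% names(coef)))
  for (pn in c("L", "M", "S"))
    stopifnot(length(coef[[pn]]) == bases[[pn]]$df)
  if (family == "BCT") {
    if (is.null(tau) || tau <= 0) stop("BCT curves require tau > 0")
  } else tau <- NULL
  structure(list(family = family, bases = bases[c("L", "M", "S")],
                 coef = lapply(coef[c("L", "M", "S")], as.numeric),
                 links = list(L = "identity", M = "log", S = "log"),
                 tau = tau, age_range = bases$M$age_range),
            class = "lms_curves")
}

#' Evaluate LMS curves at ages
#'
#' @param curves an `lms_curves` object.
#' @param age ages in years within the supported range.
#' @return data.frame with columns `age`, `L`, `M`, `S` and, for BCT, `tau`.
#' @export
eval_curves <- function(curves, age) {
  stopifnot(inherits(curves, "lms_curves"))
  out <- data.frame(age = age)
  for (pn in c("L", "M", "S")) {
    eta <- drop(eval_basis(curves$bases[[pn]], age) %*% curves$coef[[pn]])
    out[[pn]] <- .LINKS[[curves$links[[pn]]]]$ginv(eta)
  }
  if (!is.null(curves$tau)) out$tau <- curves$tau
  out
}

#' Pointwise LMS parameters at given ages
#'
#' @param curves an `lms_curves` object.
#' @param age ages in years.
#' @return an [lms_params()] object with vector fields aligned to `age`.
#' @export
curve_params <- function(curves, age) {
  ev <- eval_curves(curves, age)
  lms_params(ev$L, ev$M, ev$S, tau = if (is.null(curves$tau)) NULL
                                     else rep(curves$tau, length(age)))
}

# Least-squares projection of a target function (values on a fine age grid,
# link scale) onto a basis. Used to embed closed-form truth curves and to
# re-smooth resampled median curves.
.project_curve <- function(basis, age_grid, link_values) {
  B <- eval_basis(basis, age_grid)
  qr.coef(qr(B), link_values)
}

#' Build LMS curves from pointwise parameter values
#'
#' Projects parameter values given on an age grid onto B-spline bases by
#' least squares on the link scale.
#'
#' @param age_grid ages in years (dense grid recommended).
#' @param L,M,S parameter values on the grid (`M`, `S` positive).
#' @param df named vector/list with basis dimensions for `L`, `M`, `S`.
#' @param family `"BCCG"` or `"BCT"`; `tau` required for BCT.
#' @param tau constant df for BCT.
#' @param age_range supported age interval.
#' @return an `lms_curves` object.
#' @export
curves_from_values <- function(age_grid, L, M, S,
                               df = c(L = 2, M = 6, S = 2),
                               family = "BCCG", tau = NULL,
                               age_range = .AGE_RANGE) {
  stopifnot(all(M > 0), all(S > 0))
  bases <- list(L = lms_basis(df[["L"]], age_range),
                M = lms_basis(df[["M"]], age_range),
                S = lms_basis(df[["S"]], age_range))
  coef <- list(L = .project_curve(bases$L, age_grid, rep_len(L, length(age_grid))),
               M = .project_curve(bases$M, age_grid, log(rep_len(M, length(age_grid)))),
               S = .project_curve(bases$S, age_grid, log(rep_len(S, length(age_grid)))))
  lms_curves(family, bases, coef, tau = tau)
}
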