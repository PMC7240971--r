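# Age- and sex-dependent LMS reference curves by spline maximum likelihood.
# L(age), M(age), S(age) (and a constant tau for BCT) are expanded over
# B-spline bases and the joint log-likelihood sum(lms_logpdf) is maximized
# by quasi-Newton iteration. Smoothness (basis dimension per parameter) is
# chosen by BIC through a forward per-parameter search; BCT vs BCCG is
# likewise decided by BIC with ties going to the three-parameter family.

.DEFAULT_DF_GRID <- list(L = 1:2, M = 2:5, S = 1:3)

# soft barrier keeps the optimizer inside L in [-3,3], S in (0, 1.5]
.negloglik_factory <- function(age, y, family, bases) {
  BL <- eval_basis(bases$L, age)
  BM <- eval_basis(bases$M, age)
  BS <- eval_basis(bases$S, age)
  nL <- ncol(BL); nM <- ncol(BM); nS <- ncol(BS)
  bct <- family == "BCT"
  function(theta) {
    cL <- theta[seq_len(nL)]
    cM <- theta[nL + seq_len(nM)]
    cS <- theta[nL + nM + seq_len(nS)]
    L <- drop(BL %*% cL)
    etaS <- drop(BS %*% cS)
    etaM <- drop(BM %*% cM)
    viol <- sum(pmax(abs(L) - 3, 0)) + sum(pmax(etaS - log(1.5), 0)) +
      sum(pmax(-9 - etaS, 0)) + sum(pmax(abs(etaM) - 30, 0))
    if (viol > 0) return(1e8 * (1 + viol))
    M <- exp(etaM); S <- exp(etaS)
    tau <- if (bct) exp(theta[nL + nM + nS + 1L]) else NULL
    if (bct && (tau < 0.3 || tau > 1e6)) return(1e8 * (1 + abs(log(tau))))
    ll <- sum(lms_logpdf(y, lms_params(L, M, S, tau)))
    if (!is.finite(ll)) return(1e8)
    -ll
  }
}

.init_theta <- function(age, y, bases, family) {
  ord <- order(age)
  ly <- log(y)[ord]
  n <- length(y)
  win <- min(n, max(31L, 2L * (n %/% 20L) + 1L))
  if (win %% 2L == 0L) win <- win + 1L
  med <- stats::runmed(ly, k = win, endrule = "median")
  cM <- .project_curve(bases$M, age[ord], med)
  # guard ill-conditioned projections on sparse designs
  if (any(!is.finite(cM))) cM <- rep(mean(ly), bases$M$df)
  s0 <- stats::mad(ly - med)
  s0 <- min(max(s0, 0.02), 1)
  cS <- rep(log(s0), bases$S$df)
  cL <- rep(1, bases$L$df)
  c(cL, cM, cS, if (family == "BCT") log(10) else NULL)
}

.fit_lms_ml <- function(age, y, family, df, age_range = .AGE_RANGE,
                        max_restarts = 2) {
  bases <- list(L = lms_basis(df[["L"]], age_range),
                M = lms_basis(df[["M"]], age_range),
                S = lms_basis(df[["S"]], age_range))
  nll <- .negloglik_factory(age, y, family, bases)
  theta <- .init_theta(age, y, bases, family)
  init_ll <- -nll(theta)
  conv <- FALSE
  for (r in 0:max_restarts) {
    opt <- stats::optim(theta, nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    theta <- opt$par
    if (opt$convergence == 0) { conv <- TRUE; break }
  }
  nL <- bases$L$df; nM <- bases$M$df; nS <- bases$S$df
  tau <- if (family == "BCT") exp(theta[nL + nM + nS + 1L]) else NULL
  curves <- lms_curves(family, bases,
                       list(L = theta[seq_len(nL)],
                            M = theta[nL + seq_len(nM)],
                            S = theta[nL + nM + seq_len(nS)]),
                       tau = tau)
  loglik <- -opt$value
  df_total <- nL + nM + nS + as.integer(family == "BCT")
  n <- length(y)
  list(curves = curves, loglik = loglik, init_loglik = init_ll,
       df = c(L = nL, M = nM, S = nS), df_total = df_total,
       aic = -2 * loglik + 2 * df_total,
       bic = -2 * loglik + log(n) * df_total,
       n_obs = n, converged = conv)
}

.new_fitted_reference <- function(fit, family, metabolite = NA_character_,
                                  sex = NA_character_, extra = list()) {
  out <- c(list(metabolite = metabolite, sex = sex, family = family), fit,
           extra)
  class(out) <- "fitted_reference"
  out
}

#' Fit age-dependent LMS reference curves
#'
#' Maximizes the joint BCCG/BCT log-likelihood over spline coefficients for
#' L(age), M(age), S(age) (and constant tau under BCT). The basis dimension
#' of each parameter is selected by BIC via a forward search: M first
#' (L and S held at their smallest candidate), then S, then L.
#'
#' @param age ages in years, within the supported range.
#' @param value positive concentrations (same length).
#' @param family `"BCCG"` or `"BCT"`.
#' @param df_grid named list of candidate basis dimensions per parameter
#'   (default `list(L = 1:2, M = 2:5, S = 1:3)`).
#' @param age_range supported age interval.
#' @param metabolite,sex optional labels stored in the result.
#' @return object of class `fitted_reference`: curves, df per parameter,
#'   `loglik`, `aic`, `bic`, `n_obs`, `converged`, and the BIC trace of the
#'   df search.
#' @export
fit_reference <- function(age, value, family = c("BCCG", "BCT"),
                          df_grid = .DEFAULT_DF_GRID,
                          age_range = .AGE_RANGE,
                          metabolite = NA_character_, sex = NA_character_) {
  family <- match.arg(family)
  stopifnot(length(age) == length(value))
  if (length(value) < 50) stop("need at least 50 observations")
  if (any(!is.finite(value)) || any(value <= 0))
    stop("values must be finite and > 0 (apply QC first)")
  if (any(age < age_range[1] - 1e-8 | age > age_range[2] + 1e-8))
    stop("ages outside supported range")
  gl <- sort(unique(as.integer(df_grid$L)))
  gm <- sort(unique(as.integer(df_grid$M)))
  gs <- sort(unique(as.integer(df_grid$S)))
  trace <- list()
  fit_at <- function(dl, dm, ds)
    .fit_lms_ml(age, value, family, c(L = dl, M = dm, S = ds), age_range)
  pick <- function(cands) {
    bics <- vapply(cands, function(f) if (f$converged) f$bic else Inf,
                   numeric(1))
    cands[[which.min(bics)]]
  }
  fits_m <- lapply(gm, function(dm) fit_at(gl[1], dm, gs[1]))
  best <- pick(fits_m)
  trace$M <- data.frame(df = gm, bic = vapply(fits_m, `[[`, 0, "bic"))
  dm <- best$df[["M"]]
  if (length(gs) > 1) {
    fits_s <- c(list(best), lapply(gs[-1], function(ds) fit_at(gl[1], dm, ds)))
    best <- pick(fits_s)
    trace$S <- data.frame(df = gs, bic = vapply(fits_s, `[[`, 0, "bic"))
  }
  ds <- best$df[["S"]]
  if (length(gl) > 1) {
    fits_l <- c(list(best), lapply(gl[-1], function(dl) fit_at(dl, dm, ds)))
    best <- pick(fits_l)
    trace$L <- data.frame(df = gl, bic = vapply(fits_l, `[[`, 0, "bic"))
  }
  if (!best$converged)
    warning("fit did not converge after restarts; flagged in the result")
  .new_fitted_reference(best, family, metabolite, sex,
                        extra = list(bic_trace = trace))
}

#' Choose between BCCG and BCT by BIC
#'
#' Fits both families and returns BCT only when its BIC is strictly lower
#' (parsimony: ties keep the three-parameter BCCG).
#'
#' @inheritParams fit_reference
#' @return list with `family` (the selection), `bccg` and `bct` (both
#'   `fitted_reference` objects) and `fit` (the selected one).
#' @export
select_distribution <- function(age, value, df_grid = .DEFAULT_DF_GRID,
                                age_range = .AGE_RANGE,
                                metabolite = NA_character_,
                                sex = NA_character_) {
  f_bccg <- fit_reference(age, value, "BCCG", df_grid, age_range, metabolite, sex)
  f_bct <- fit_reference(age, value, "BCT", df_grid, age_range, metabolite, sex)
  if (!f_bccg$converged || !f_bct$converged)
    stop("distribution selection aborted: non-converged fit (BCCG converged: ",
         f_bccg$converged, ", BCT converged: ", f_bct$converged, ")")
  family <- if (f_bct$bic < f_bccg$bic) "BCT" else "BCCG"
  list(family = family, bccg = f_bccg, bct = f_bct,
       fit = if (family == "BCT") f_bct else f_bccg)
}

#' Family-resampled LMS reference fit
#'
#' Breaks sibling- and subject-level dependence: each iteration samples one
#' visit per family uniformly at random, refits the LMS model at the basis
#' dimensions selected once on the pooled data, and evaluates the parameter
#' curves on a fixed age grid. The final curves are the pointwise median
#' across iterations, projected back onto the spline basis. Iterations that
#' fail to converge are dropped and counted; more than 20 percent dropped
#' aborts the operation.
#'
#' @param table cohort table with `family_id`, `sex`, `age_years` and the
#'   metabolite column.
#' @param metabolite metabolite column name.
#' @param sex `"F"` or `"M"`.
#' @param family `"BCCG"` or `"BCT"`.
#' @param df_grid candidate basis dimensions (see [fit_reference()]).
#' @param n_iter number of resampling iterations (default 100).
#' @param seed integer seed.
#' @param age_range supported age interval.
#' @return `fitted_reference` with extra fields `n_iter_used` and
#'   `n_iter_dropped`; `loglik`/`aic`/`bic` are evaluated on the pooled data
#'   at the aggregated curves.
#' @export
fit_reference_resampled <- function(table, metabolite, sex,
                                    family = c("BCCG", "BCT"),
                                    df_grid = .DEFAULT_DF_GRID,
                                    n_iter = 100, seed = 1L,
                                    age_range = .AGE_RANGE) {
  family <- match.arg(family)
  stopifnot(n_iter >= 1)
  keep <- table$sex == sex & !is.na(table[[metabolite]]) &
    table[[metabolite]] > 0
  sub <- table[keep, , drop = FALSE]
  pooled <- fit_reference(sub$age_years, sub[[metabolite]], family, df_grid,
                          age_range, metabolite, sex)
  df_sel <- pooled$df
  fam_rows <- split(seq_len(nrow(sub)), sub$family_id)
  grid <- seq(age_range[1], age_range[2], length.out = 72)
  set.seed(as.integer(seed))
  evals <- vector("list", n_iter)
  dropped <- 0L
  for (it in seq_len(n_iter)) {
    idx <- vapply(fam_rows, function(r) r[sample.int(length(r), 1L)],
                  integer(1))
    fit <- .fit_lms_ml(sub$age_years[idx], sub[[metabolite]][idx], family,
                       df_sel, age_range)
    if (!fit$converged) { dropped <- dropped + 1L; next }
    ev <- eval_curves(fit$curves, grid)
    evals[[it]] <- cbind(L = ev$L, logM = log(ev$M), logS = log(ev$S),
                         ltau = if (family == "BCT") log(fit$curves$tau) else NA)
  }
  evals <- evals[!vapply(evals, is.null, logical(1))]
  if (dropped > 0.2 * n_iter)
    stop("resampled reference fit failed: ", dropped, " of ", n_iter,
         " iterations did not converge")
  arr <- simplify2array(evals)                       # grid x 4 x iter
  med <- apply(arr, c(1, 2), stats::median)
  bases <- pooled$curves$bases
  coef <- list(L = .project_curve(bases$L, grid, med[, "L"]),
               M = .project_curve(bases$M, grid, med[, "logM"]),
               S = .project_curve(bases$S, grid, med[, "logS"]))
  tau <- if (family == "BCT") exp(stats::median(med[, "ltau"])) else NULL
  curves <- lms_curves(family, bases, coef, tau = tau)
  pars <- curve_params(curves, sub$age_years)
  ll <- sum(lms_logpdf(sub[[metabolite]], pars))
  .new_fitted_reference(
    list(curves = curves, loglik = ll, init_loglik = pooled$loglik,
         df = df_sel, df_total = pooled$df_total,
         aic = -2 * ll + 2 * pooled$df_total,
         bic = -2 * ll + log(nrow(sub)) * pooled$df_total,
         n_obs = nrow(sub), converged = TRUE),
    family, metabolite, sex,
    extra = list(n_iter_used = length(evals), n_iter_dropped = dropped,
                 pooled_fit = pooled))
}

#' Percentile (centile) table from a fitted reference
#'
#' @param ref converged `fitted_reference`.
#' @param ages age grid in years.
#' @param levels percentile levels in percent, strictly inside (0, 100)
#'   (default the 2.5th, 10th, 50th, 90th and 97.5th).
#' @return long data.frame: `metabolite`, `sex`, `age`, `level`, `value`;
#'   values are strictly increasing across levels at every age.
#' @export
percentile_table <- function(ref, ages, levels = c(2.5, 10, 50, 90, 97.5)) {
  stopifnot(inherits(ref, "fitted_reference"))
  if (!isTRUE(ref$converged)) stop("reference fit did not converge")
  if (any(levels <= 0 | levels >= 100)) stop("levels must be inside (0, 100)")
  levels <- sort(levels)
  pars <- curve_params(ref$curves, ages)
  out <- do.call(rbind, lapply(levels, function(lv)
    data.frame(metabolite = ref$metabolite, sex = ref$sex, age = ages,
               level = lv, value = lms_quantile(lv / 100, pars))))
  rownames(out) <- NULL
  out
}

#' Standard deviation score (SDS) against a fitted reference
#'
#' Applies the Box-Cox z-transform at the subject's age. For BCT references
#' the t-distributed z is mapped to a normal-equivalent SDS through the
#' probability integral transform, so SDS is N(0,1) under the reference for
#' both families.
#'
#' @param value positive concentrations.
#' @param age ages in years; must lie within the fitted range (no
#'   extrapolation).
#' @param ref `fitted_reference` (or `lms_curves`).
#' @param sex optional label; checked against `ref$sex` when both are set.
#' @return numeric SDS vector.
#' @export
sds <- function(value, age, ref, sex = NULL) {
  curves <- if (inherits(ref, "fitted_reference")) ref$curves else ref
  stopifnot(inherits(curves, "lms_curves"))
  if (inherits(ref, "fitted_reference") && !is.null(sex) &&
      !is.na(ref$sex) && !identical(sex, ref$sex))
    stop("sex does not match the reference fit")
  rng <- curves$age_range
  if (any(age < rng[1] - 1e-8 | age > rng[2] + 1e-8))
    stop("age outside the fitted range; no extrapolation")
  pars <- curve_params(curves, age)
  z <- lms_z(value, lms_params(pars$L, pars$M, pars$S))
  if (!is.null(curves$tau))
    z <- stats::qnorm(stats::pt(z, df = curves$tau))
  z
}

#' Residual diagnostics for a fitted reference
#'
#' Summarizes the SDS residuals of observations under a reference: first
#' four moments, the maximum quantile-scale QQ deviation over a fixed
#' probability grid, and the Kolmogorov-Smirnov statistic against the
#' standard normal.
#'
#' @param ref converged `fitted_reference`.
#' @param age,value observations.
#' @return list: `n`, `mean`, `sd`, `skewness`, `excess_kurtosis`,
#'   `qq_deviation` (max |empirical - theoretical quantile| over
#'   probabilities 0.01..0.99), `ks_stat`, `reliable` (FALSE for n < 20).
#' @export
residual_diagnostics <- function(ref, age, value) {
  if (inherits(ref, "fitted_reference") && !isTRUE(ref$converged))
    stop("reference fit did not converge")
  z <- sds(value, age, ref)
  n <- length(z)
  m <- mean(z); s <- stats::sd(z)
  zc <- z - m
  skew <- mean(zc^3) / s^3
  exk <- mean(zc^4) / s^4 - 3
  probs <- seq(0.01, 0.99, by = 0.01)
  qq_dev <- max(abs(stats::quantile(z, probs, names = FALSE) -
                      stats::qnorm(probs)))
  zs <- sort(z)
  Fz <- stats::pnorm(zs)
  ks <- max(pmax(seq_len(n) / n - Fz, Fz - (seq_len(n) - 1) / n))
  list(n = n, mean = m, sd = s, skewness = skew, excess_kurtosis = exk,
       qq_deviation = qq_dev, ks_stat = ks, reliable = n >= 20)
}

# JSON serialization ------------------------------------------------------

.curves_to_list <- function(curves) {
  list(family = curves$family, tau = curves$tau,
       age_range = curves$age_range,
       params = lapply(stats::setNames(c("L", "M", "S"), c("L", "M", "S")),
                       function(pn) {
                         b <- curves$bases[[pn]]
                         list(df = b$df, degree = b$degree, knots = b$knots,
                              link = curves$links[[pn]],
                              coef = curves$coef[[pn]])
                       }))
}

.curves_from_list <- function(x) {
  bases <- lapply(x$params, function(p) lms_basis(p$df, unlist(x$age_range)))
  coef <- lapply(x$params, function(p) unlist(p$coef))
  lms_curves(x$family, bases, coef,
             tau = if (is.null(x$tau)) NULL else as.numeric(x$tau))
}

#' Serialize a fitted reference to JSON
#'
#' @param ref `fitted_reference`.
#' @param path output path.
#' @export
reference_to_json <- function(ref, path) {
  x <- list(metabolite = ref$metabolite, sex = ref$sex, family = ref$family,
            curves = .curves_to_list(ref$curves),
            df = as.list(ref$df), df_total = ref$df_total,
            loglik = ref$loglik, aic = ref$aic, bic = ref$bic,
            n_obs = ref$n_obs, converged = ref$converged)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a fitted reference from JSON
#'
#' @param path path written by [reference_to_json()].
#' @return `fitted_reference`.
#' @export
reference_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- .curves_from_list(x$curves)
  .new_fitted_reference(
    list(curves = curves, loglik = x$loglik, init_loglik = NA_real_,
         df = unlist(x$df), df_total = x$df_total, aic = x$aic, bic = x$bic,
         n_obs = x$n_obs, converged = x$converged),
    x$family, x$metabolite, x$sex)
}
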