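# Hierarchical association analyses. All tests share one engine: a Gaussian
# random-intercept (subject-level) model fitted by REML through lme4, with
# Wald z p-values on standardized coefficients, mirroring the standardized-
# coefficient + multiple-comparison workflow common in cohort studies.
# Multiple testing is controlled per analysis block by the Benjamini-
# Yekutieli step-up procedure (valid under arbitrary dependence).

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment valid under arbitrary dependence:
#' `p_adj(i) = min over j >= i of min(1, m * c(m) * p_(j) / j)` on the
#' sorted p-values, with `c(m) = sum(1/h, h = 1..m)`; order-preserving and
#' capped at 1.
#'
#' @param p p-values in (0, 1].
#' @return adjusted p-values in the original order.
#' @export
by_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q <- m * cm * p[o] / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(q))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# p-values may be NA for not-estimable tests; adjust over the estimable ones
.by_adjust_na <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  # Wald p can underflow to 0 for near-degenerate fits; clamp for adjustment
  if (any(ok)) out[ok] <- by_adjust(pmax(p[ok], 1e-300))
  out
}

#' Gaussian random-intercept regression with standardized coefficients
#'
#' Fits `y ~ X + (1 | group)` by REML (lme4), after z-scaling `y` and every
#' continuous column of `X` (columns with more than two distinct values);
#' binary/dummy columns and the intercept are left as is. p-values are Wald
#' normal. With a single group the model degenerates to ordinary least
#' squares and is fitted by `lm` with a warning flag in the result.
#'
#' @param y response vector.
#' @param X design matrix with column names; include an intercept column
#'   explicitly if wanted (a column named `"(Intercept)"` of ones is added
#'   when absent).
#' @param group grouping factor (subject ids).
#' @return list of class `ri_fit`: `coefficients` (data.frame with `term`,
#'   `estimate`, `se`, `z`, `p`), `var_subject`, `var_resid`, `n_obs`,
#'   `n_groups`, `ols_fallback`.
#' @export
fit_random_intercept <- function(y, X, group) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(y, X, group)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; group <- group[keep]
  if (!"(Intercept)" %in% colnames(X))
    X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  n_groups <- length(unique(group))
  sdy <- stats::sd(y)
  ys <- if (sdy > 0) (y - mean(y)) / sdy else y
  Xs <- X
  for (j in seq_len(ncol(X))) {
    cj <- X[, j]
    if (length(unique(cj)) > 2) {
      sj <- stats::sd(cj)
      if (sj > 0) Xs[, j] <- (cj - mean(cj)) / sj
    }
  }
  terms <- colnames(X)
  if (n_groups < 2) {
    fit <- stats::lm(ys ~ 0 + Xs)
    cf <- summary(fit)$coefficients
    coefs <- data.frame(term = terms, estimate = cf[, 1], se = cf[, 2],
                        z = cf[, 1] / cf[, 2],
                        p = 2 * stats::pnorm(-abs(cf[, 1] / cf[, 2])))
    rownames(coefs) <- NULL
    warning("single group: fell back to ordinary regression")
    return(structure(list(coefficients = coefs, var_subject = 0,
                          var_resid = summary(fit)$sigma^2,
                          n_obs = length(y), n_groups = n_groups,
                          ols_fallback = TRUE), class = "ri_fit"))
  }
  dd <- data.frame(.y = ys, .g = factor(group))
  dd$Xs <- Xs
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(.y ~ 0 + Xs + (1 | .g), data = dd, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  est <- lme4::fixef(fit)
  se <- suppressWarnings(tryCatch(sqrt(diag(as.matrix(stats::vcov(fit)))),
                                  error = function(e) rep(NA_real_, length(est))))
  z <- est / se
  vc <- lme4::VarCorr(fit)
  coefs <- data.frame(term = terms, estimate = unname(est), se = unname(se),
                      z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))))
  structure(list(coefficients = coefs,
                 var_subject = as.numeric(vc$.g[1]),
                 var_resid = attr(vc, "sc")^2,
                 n_obs = length(y), n_groups = n_groups,
                 ols_fallback = FALSE), class = "ri_fit")
}

.coef_row <- function(fit, term) {
  cf <- fit$coefficients
  cf[match(term, cf$term), , drop = FALSE]
}

#' Per-age-interval SDS trends
#'
#' Partitions age into half-open intervals `[a, b)` (the last interval is
#' closed at 18), and regresses metabolite SDS on age within each interval
#' and sex with a subject random intercept. Intervals with fewer than
#' `min_obs` observations are reported as not estimable. BY adjustment is
#' applied across all estimable slopes in the call.
#'
#' @param data data.frame with `subject_id`, `sex`, `age_years` and the SDS
#'   columns named in `value_cols`.
#' @param value_cols metabolite SDS column names.
#' @param cuts interior cut points partitioning `[0.25, 18]`
#'   (default `c(1, 5, 9, 13)`).
#' @param min_obs minimum observations per interval (default 30).
#' @return data.frame of class rows: `metabolite`, `covariate`, `stratum`,
#'   `interval`, `estimate`, `se`, `p_raw`, `p_adj`, `significant`, `n_obs`,
#'   `estimable`.
#' @export
interval_trends <- function(data, value_cols, cuts = c(1, 5, 9, 13),
                            min_obs = 30) {
  breaks <- unique(c(0.25, sort(cuts), 18))
  if (any(cuts <= 0.25) || any(cuts >= 18))
    stop("cuts must lie strictly inside (0.25, 18)")
  bin <- findInterval(data$age_years, breaks, rightmost.closed = TRUE)
  labs <- paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")")
  rows <- list()
  for (m in value_cols) for (sx in unique(data$sex)) for (b in seq_along(labs)) {
    idx <- data$sex == sx & bin == b & !is.na(data[[m]])
    n <- sum(idx)
    row <- data.frame(metabolite = m, covariate = "age_slope", stratum = sx,
                      interval = labs[b], estimate = NA_real_, se = NA_real_,
                      p_raw = NA_real_, n_obs = n, estimable = FALSE)
    if (n >= min_obs) {
      fit <- fit_random_intercept(data[[m]][idx],
                                  cbind(age = data$age_years[idx]),
                                  data$subject_id[idx])
      cr <- .coef_row(fit, "age")
      row$estimate <- cr$estimate; row$se <- cr$se; row$p_raw <- cr$p
      row$estimable <- TRUE
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  out$p_adj <- .by_adjust_na(out$p_raw)
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}

#' BMI-SDS associations with sex-interaction gating
#'
#' For each metabolite, fits SDS ~ BMI-SDS * sex with a subject random
#' intercept; the sex x BMI interaction p-values are BY-adjusted as one
#' family and, where an interaction is significant (adjusted p < `alpha`),
#' per-sex slopes are reported instead of the pooled (sex-adjusted) slope.
#' Reported slope p-values form a second BY family.
#'
#' @param data data.frame with `subject_id`, `sex`, `bmi_sds` and the SDS
#'   columns in `value_cols`.
#' @param value_cols metabolite SDS column names.
#' @param alpha significance level for the adjusted interaction p (0.05).
#' @return data.frame: `metabolite`, `covariate` (`"bmi_sds"`), `stratum`
#'   (`"pooled"`, `"F"` or `"M"`), `estimate`, `se`, `p_raw`, `p_adj`,
#'   `significant`, `p_interaction_adj`, `n_obs`.
#' @export
bmi_association <- function(data, value_cols, alpha = 0.05) {
  if (any(is.na(data$sex))) stop("missing sex codes")
  if (length(unique(stats::na.omit(data$bmi_sds))) < 2)
    stop("design matrix is rank deficient; collinear columns: bmi_sds")
  sexm <- as.numeric(data$sex == "M")
  inter <- lapply(value_cols, function(m) {
    X <- cbind(bmi_sds = data$bmi_sds, sexM = sexm,
               `bmi_sds:sexM` = data$bmi_sds * sexm)
    fit <- fit_random_intercept(data[[m]], X, data$subject_id)
    .coef_row(fit, "bmi_sds:sexM")$p
  })
  p_int <- unlist(inter)
  p_int_adj <- by_adjust(p_int)
  rows <- list()
  for (i in seq_along(value_cols)) {
    m <- value_cols[i]
    if (p_int_adj[i] < alpha) {
      for (sx in c("F", "M")) {
        idx <- data$sex == sx
        fit <- fit_random_intercept(data[[m]][idx],
                                    cbind(bmi_sds = data$bmi_sds[idx]),
                                    data$subject_id[idx])
        cr <- .coef_row(fit, "bmi_sds")
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite = m, covariate = "bmi_sds", stratum = sx,
          estimate = cr$estimate, se = cr$se, p_raw = cr$p,
          p_interaction_adj = p_int_adj[i], n_obs = fit$n_obs)
      }
    } else {
      fit <- fit_random_intercept(data[[m]],
                                  cbind(bmi_sds = data$bmi_sds, sexM = sexm),
                                  data$subject_id)
      cr <- .coef_row(fit, "bmi_sds")
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = m, covariate = "bmi_sds", stratum = "pooled",
        estimate = cr$estimate, se = cr$se, p_raw = cr$p,
        p_interaction_adj = p_int_adj[i], n_obs = fit$n_obs)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- .by_adjust_na(out$p_raw)
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}

#' Tanner-stage contrasts against the pre-pubertal reference
#'
#' Stratified by sex: metabolite (SDS or absolute) regressed on Tanner
#' stage as a categorical factor with stage 1 as reference, subject random
#' intercept; the four stage contrasts per metabolite and sex form one BY
#' family. Stages with no observations are reported not estimable.
#'
#' @param data data.frame with `subject_id`, `sex`, `tanner_stage` (1-5,
#'   NA allowed) and the columns in `value_cols`.
#' @param value_cols response column names.
#' @return data.frame: `metabolite`, `covariate` (`"tanner_2"`..
#'   `"tanner_5"`), `stratum` (sex), `estimate`, `se`, `p_raw`, `p_adj`,
#'   `significant`, `n_obs`, `estimable`.
#' @export
tanner_contrasts <- function(data, value_cols) {
  stopifnot(all(stats::na.omit(data$tanner_stage) %in% 1:5))
  rows <- list()
  for (sx in c("F", "M")) for (m in value_cols) {
    idx <- data$sex == sx & !is.na(data$tanner_stage) & !is.na(data[[m]])
    d <- data[idx, , drop = FALSE]
    stages_present <- sort(unique(d$tanner_stage))
    X <- NULL
    for (st in setdiff(stages_present, 1L))
      X <- cbind(X, as.numeric(d$tanner_stage == st))
    if (!is.null(X))
      colnames(X) <- paste0("tanner_", setdiff(stages_present, 1L))
    fit <- if (!is.null(X) && 1L %in% stages_present)
      fit_random_intercept(d[[m]], X, d$subject_id) else NULL
    for (st in 2:5) {
      term <- paste0("tanner_", st)
      est <- !is.null(fit) && term %in% fit$coefficients$term
      cr <- if (est) .coef_row(fit, term) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = m, covariate = term, stratum = sx,
        estimate = if (est) cr$estimate else NA_real_,
        se = if (est) cr$se else NA_real_,
        p_raw = if (est) cr$p else NA_real_,
        n_obs = sum(d$tanner_stage == st), estimable = est)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- .by_adjust_na(out$p_raw)
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}

#' Metabolite x lab-marker correlation matrix
#'
#' Each cell is the standardized coefficient from a subject-level
#' random-intercept regression of the metabolite on the marker (one marker
#' at a time), on absolute concentrations (`mode = "absolute"`) or on SDS
#' values of both sides (`mode = "sds"`, the age/sex-adjusted analysis).
#' Cell p-values are BY-adjusted over the whole matrix. Markers with zero
#' variance yield an all-NA column.
#'
#' @param metab_tab data.frame of metabolite values (rows = visits).
#' @param lab_tab data.frame of marker values (same rows).
#' @param subject subject ids (same rows).
#' @param mode `"absolute"` or `"sds"` (label recorded in the result).
#' @return list of class `correlation_matrix`: `estimate` and `p_adj`
#'   matrices (metabolites x markers), `mode`, `cluster_labels` (NULL until
#'   [cluster_correlation_profiles()] is applied).
#' @export
lab_correlations <- function(metab_tab, lab_tab, subject,
                             mode = c("absolute", "sds")) {
  mode <- match.arg(mode)
  stopifnot(nrow(metab_tab) == nrow(lab_tab),
            nrow(metab_tab) == length(subject))
  mets <- names(metab_tab); marks <- names(lab_tab)
  est <- praw <- matrix(NA_real_, length(mets), length(marks),
                        dimnames = list(mets, marks))
  for (k in marks) {
    v <- lab_tab[[k]]
    if (stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v))) next
    for (m in mets) {
      fit <- fit_random_intercept(metab_tab[[m]], cbind(marker = v), subject)
      cr <- .coef_row(fit, "marker")
      est[m, k] <- cr$estimate
      praw[m, k] <- cr$p
    }
  }
  padj <- praw
  padj[] <- .by_adjust_na(as.vector(praw))
  structure(list(estimate = est, p_adj = padj, mode = mode,
                 cluster_labels = NULL),
            class = "correlation_matrix")
}

#' Cluster metabolites by their marker-correlation profiles
#'
#' Agglomerative clustering (Euclidean distance between correlation-profile
#' rows, average linkage) of the metabolite rows into `k` groups.
#'
#' @param cm `correlation_matrix` from [lab_correlations()], or a numeric
#'   matrix of profiles.
#' @param k number of clusters (1 <= k <= number of rows).
#' @return named integer vector of cluster labels (and, when `cm` is a
#'   `correlation_matrix`, the updated object in attribute `"matrix"`).
#' @export
cluster_correlation_profiles <- function(cm, k = 5) {
  est <- if (inherits(cm, "correlation_matrix")) cm$estimate else as.matrix(cm)
  if (k < 1 || k > nrow(est)) stop("k must be between 1 and the row count")
  est0 <- est
  est0[is.na(est0)] <- 0
  hc <- stats::hclust(stats::dist(est0, method = "euclidean"),
                      method = "average")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(est)
  if (inherits(cm, "correlation_matrix")) {
    cm$cluster_labels <- labels
    attr(labels, "matrix") <- cm
  }
  labels
}
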