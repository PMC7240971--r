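# Pre-modelling quality control: limit-of-detection exclusion and the
# +/-5 SD log-scale outlier cutoff. Zeros encode non-detects throughout;
# they are never treated as biological outliers and never enter the log
# moments.

#' Limit-of-detection filter for one metabolite
#'
#' A metabolite is retained unless strictly more than 5 percent of its
#' values fall below the detection limit. Zeros (the non-detect sentinel)
#' always count as below the LOD.
#'
#' @param values concentrations (non-empty numeric vector).
#' @param lod detection limit (>= 0).
#' @param max_fraction exclusion threshold on the below-LOD fraction
#'   (default 0.05; the comparison is strict: retained iff fraction <=
#'   `max_fraction`).
#' @return list with `retained` (logical) and `report` (one-row data.frame:
#'   `n_total`, `n_below_lod`, `fraction_below_lod`, `retained`).
#' @export
lod_filter <- function(values, lod, max_fraction = 0.05) {
  if (length(values) == 0) stop("empty input")
  stopifnot(lod >= 0)
  below <- values < lod | values == 0
  frac <- mean(below)
  retained <- !(frac > max_fraction)
  list(retained = retained,
       report = data.frame(n_total = length(values),
                           n_below_lod = sum(below),
                           fraction_below_lod = frac,
                           retained = retained))
}

#' Log-scale outlier mask for one metabolite
#'
#' Flags values whose natural-log deviates from the mean of the logarithms
#' of the nonzero data by more than `cutoff` standard deviations (default
#' 5). Zeros are excluded from the log moments and are never flagged. The
#' mask is identical under any log base, since both the deviation and the
#' SD rescale by the same factor.
#'
#' @param values concentrations (>= 3 nonzero values required).
#' @param cutoff SD multiple (default 5).
#' @return list with `keep` (logical mask, TRUE = retain), `log_mean`,
#'   `log_sd`, `n_outliers`.
#' @export
outlier_mask <- function(values, cutoff = 5) {
  nz <- values != 0
  if (sum(nz) < 3) stop("need at least 3 nonzero values")
  if (any(values[nz] < 0)) stop("negative concentrations are invalid")
  lv <- log(values[nz])
  m <- mean(lv); s <- stats::sd(lv)
  keep <- rep(TRUE, length(values))
  keep[nz] <- abs(lv - m) <= cutoff * s
  list(keep = keep, log_mean = m, log_sd = s, n_outliers = sum(!keep))
}

#' Panel-wide QC: LOD exclusion then outlier removal
#'
#' Applies [lod_filter()] per metabolite; on retained metabolites, applies
#' [outlier_mask()] once and replaces flagged values with `NA`.
#'
#' @param table cohort table.
#' @param metabolites metabolite column names.
#' @param lod_map named numeric of detection limits.
#' @param max_fraction LOD exclusion threshold (default 0.05).
#' @param cutoff outlier SD cutoff (default 5).
#' @return list with `table` (outliers set to `NA`; excluded metabolite
#'   columns left untouched), `qc_report` (one row per metabolite),
#'   `retained` (character vector).
#' @export
qc_panel <- function(table, metabolites, lod_map, max_fraction = 0.05,
                     cutoff = 5) {
  stopifnot(all(metabolites %in% names(table)))
  rows <- vector("list", length(metabolites))
  retained <- character(0)
  for (i in seq_along(metabolites)) {
    m <- metabolites[i]
    v <- table[[m]]
    lf <- lod_filter(v[!is.na(v)], lod = lod_map[[m]], max_fraction = max_fraction)
    row <- cbind(data.frame(metabolite = m), lf$report,
                 n_outliers_removed = 0L,
                 log_mean = NA_real_, log_sd = NA_real_)
    if (lf$retained) {
      om <- outlier_mask(v[!is.na(v)], cutoff = cutoff)
      vv <- v
      vv[!is.na(v)][!om$keep] <- NA_real_
      table[[m]] <- vv
      row$n_outliers_removed <- om$n_outliers
      row$log_mean <- om$log_mean
      row$log_sd <- om$log_sd
      retained <- c(retained, m)
    }
    rows[[i]] <- row
  }
  list(table = table, qc_report = do.call(rbind, rows), retained = retained)
}
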