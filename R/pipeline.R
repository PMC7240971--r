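# Configuration-driven orchestration: simulate/load -> QC -> reference
# curves -> SDS -> associations, writing a complete plain-text output
# bundle. All randomness flows from explicit seeds so a rerun with the
# same configuration is byte-identical.

#' Pipeline configuration
#'
#' @param input path to a cohort TSV (as written by [write_cohort()]), or
#'   NULL to simulate from `cohort`.
#' @param cohort a [cohort_config()] used when `input` is NULL.
#' @param metabolites metabolite column names (default: the panel in
#'   `cohort`, or all panel metabolites present in the input).
#' @param lod_map named detection limits (default from `cohort`).
#' @param lod_fraction LOD exclusion threshold (default 0.05).
#' @param outlier_cutoff log-scale SD cutoff (default 5).
#' @param families named character `metabolite -> "BCCG"|"BCT"`, or the
#'   string `"select"` to let BIC decide per metabolite.
#' @param df_grid basis-dimension candidates (see [fit_reference()]).
#' @param n_iter resampling iterations per reference fit (default 100).
#' @param cuts age-interval cut points for trend analysis.
#' @param fdr_level FDR level (default 0.05).
#' @param cluster_k number of correlation-profile clusters (default 5).
#' @param lab_markers lab marker column names (default from
#'   [default_lab_spec()]); empty vector skips marker analyses.
#' @param seed master seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, cohort = cohort_config(),
                            metabolites = NULL, lod_map = NULL,
                            lod_fraction = 0.05, outlier_cutoff = 5,
                            families = NULL, df_grid = .DEFAULT_DF_GRID,
                            n_iter = 100, cuts = c(1, 5, 9, 13),
                            fdr_level = 0.05, cluster_k = 5,
                            lab_markers = names(default_lab_spec()),
                            seed = 1L) {
  stopifnot(lod_fraction >= 0, lod_fraction <= 1, outlier_cutoff > 0,
            n_iter >= 1, fdr_level > 0, fdr_level < 1, cluster_k >= 1)
  if (is.null(input)) stopifnot(inherits(cohort, "cohort_config"))
  if (is.null(metabolites))
    metabolites <- if (is.null(input)) cohort$panel$metabolite else NULL
  if (is.null(lod_map) && !is.null(cohort)) lod_map <- cohort$lod_map
  if (is.null(families) && !is.null(cohort))
    families <- stats::setNames(cohort$panel$family, cohort$panel$metabolite)
  structure(list(input = input, cohort = cohort, metabolites = metabolites,
                 lod_map = lod_map, lod_fraction = lod_fraction,
                 outlier_cutoff = outlier_cutoff, families = families,
                 df_grid = df_grid, n_iter = n_iter, cuts = cuts,
                 fdr_level = fdr_level, cluster_k = cluster_k,
                 lab_markers = lab_markers, seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages: acquire (simulate or read the cohort) -> validate -> QC (LOD
#' exclusion, log-scale outlier removal) -> family-resampled LMS reference
#' fitting per retained metabolite and sex -> percentile tables and SDS
#' scoring -> association analyses (BMI-SDS, Tanner contrasts, age-interval
#' trends, lab-marker correlation matrices with clustering). Writes
#' `qc_report.tsv`, `references/*.json`, `percentiles.tsv`,
#' `sds_table.tsv`, `associations_bmi.tsv`, `associations_tanner.tsv`,
#' `interval_trends.tsv`, `correlations_absolute.tsv`,
#' `correlations_sds.tsv`, `clusters.json` and `run_log.txt` into `outdir`.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(paste0("pedmetref ", as.character(utils::packageVersion("pedmetref"))),
                 paste0("seed: ", config$seed))

  tab <- .stage("acquire", {
    if (is.null(config$input)) {
      t0 <- simulate_cohort(config$cohort, seed = config$seed)
      degrade_panel(t0, config$cohort$lod_map, config$cohort$censor_rates,
                    config$cohort$outlier_rate, seed = config$seed + 1L)
    } else read_cohort(config$input)
  })

  mets <- config$metabolites
  if (is.null(mets))
    mets <- intersect(default_panel()$metabolite, names(tab))
  .stage("validate", {
    req <- c("subject_id", "family_id", "sex", "age_years")
    miss <- setdiff(c(req, mets), names(tab))
    if (nrow(tab) == 0) stop("input table is empty")
    if (length(miss) > 0)
      stop("missing required columns: ", paste(miss, collapse = ", "))
    if (!all(tab$sex %in% c("F", "M"))) stop("sex must be coded F/M")
  })

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "references"), showWarnings = FALSE)

  qc <- .stage("qc", qc_panel(tab, mets, config$lod_map,
                              max_fraction = config$lod_fraction,
                              cutoff = config$outlier_cutoff))
  .write_tsv(qc$qc_report, file.path(outdir, "qc_report.tsv"))
  log_lines <- c(log_lines,
                 paste0("qc: retained ", length(qc$retained), " of ",
                        length(mets), " metabolites"))
  tab <- qc$table

  refs <- .stage("references", {
    out <- list()
    for (m in qc$retained) for (sx in c("F", "M")) {
      fam <- if (identical(config$families, "select")) {
        keep <- tab$sex == sx & !is.na(tab[[m]]) & tab[[m]] > 0
        select_distribution(tab$age_years[keep], tab[[m]][keep],
                            config$df_grid, metabolite = m, sex = sx)$family
      } else unname(config$families[[m]])
      ref <- fit_reference_resampled(tab, m, sx, fam, config$df_grid,
                                     n_iter = config$n_iter,
                                     seed = config$seed + 1000L)
      reference_to_json(ref, file.path(outdir, "references",
                                       paste0(m, "_", sx, ".json")))
      out[[paste0(m, ".", sx)]] <- ref
    }
    out
  })

  perc <- .stage("percentiles", {
    ages <- seq(0.25, 18, by = 0.25)
    do.call(rbind, lapply(refs, percentile_table, ages = ages))
  })
  .write_tsv(perc, file.path(outdir, "percentiles.tsv"))

  sds_tab <- .stage("sds", {
    rows <- list()
    for (m in qc$retained) {
      sc <- rep(NA_real_, nrow(tab))
      for (sx in c("F", "M")) {
        idx <- which(tab$sex == sx & !is.na(tab[[m]]) & tab[[m]] > 0)
        if (length(idx))
          sc[idx] <- sds(tab[[m]][idx], tab$age_years[idx],
                         refs[[paste0(m, ".", sx)]])
      }
      rows[[m]] <- sc
    }
    out <- data.frame(subject_id = tab$subject_id, sex = tab$sex,
                      age_years = tab$age_years)
    for (m in qc$retained) out[[m]] <- rows[[m]]
    out
  })
  .write_tsv(sds_tab, file.path(outdir, "sds_table.tsv"))

  adat <- cbind(sds_tab, tab[c("bmi_sds", "tanner_stage")])
  assoc_bmi <- .stage("associations_bmi",
                      bmi_association(adat, qc$retained,
                                      alpha = config$fdr_level))
  .write_tsv(assoc_bmi, file.path(outdir, "associations_bmi.tsv"))

  assoc_tanner <- .stage("associations_tanner",
                         tanner_contrasts(adat, qc$retained))
  .write_tsv(assoc_tanner, file.path(outdir, "associations_tanner.tsv"))

  trends <- .stage("interval_trends",
                   interval_trends(adat, qc$retained, cuts = config$cuts))
  .write_tsv(trends, file.path(outdir, "interval_trends.tsv"))

  markers <- intersect(config$lab_markers, names(tab))
  cors <- NULL; clusters <- NULL
  if (length(markers) > 0) {
    cors <- .stage("correlations", {
      metab_abs <- tab[qc$retained]
      lab_abs <- tab[markers]
      cm_abs <- lab_correlations(metab_abs, lab_abs, tab$subject_id,
                                 mode = "absolute")
      # age/sex-adjusted side: marker SDS from internal LMS fits
      lab_sds <- as.data.frame(lapply(markers, function(k) {
        v <- tab[[k]]
        sc <- rep(NA_real_, nrow(tab))
        for (sx in c("F", "M")) {
          idx <- which(tab$sex == sx & !is.na(v) & v > 0)
          if (length(idx) < 50) next
          rf <- fit_reference(tab$age_years[idx], v[idx], "BCCG",
                              df_grid = list(L = 1, M = 2, S = 1),
                              metabolite = k, sex = sx)
          sc[idx] <- sds(v[idx], tab$age_years[idx], rf)
        }
        sc
      }))
      names(lab_sds) <- markers
      cm_sds <- lab_correlations(sds_tab[qc$retained], lab_sds,
                                 tab$subject_id, mode = "sds")
      list(absolute = cm_abs, sds = cm_sds)
    })
    .write_corr <- function(cm, path) {
      long <- expand.grid(metabolite = rownames(cm$estimate),
                          marker = colnames(cm$estimate),
                          stringsAsFactors = FALSE)
      long$estimate <- as.vector(cm$estimate)
      long$p_adj <- as.vector(cm$p_adj)
      .write_tsv(long, path)
    }
    .write_corr(cors$absolute, file.path(outdir, "correlations_absolute.tsv"))
    .write_corr(cors$sds, file.path(outdir, "correlations_sds.tsv"))
    clusters <- .stage("clusters", {
      k <- min(config$cluster_k, nrow(cors$sds$estimate))
      cluster_correlation_profiles(cors$sds, k = k)
    })
    jsonlite::write_json(
      list(k = length(unique(clusters)),
           rows = rownames(cors$sds$estimate),
           cols = colnames(cors$sds$estimate),
           labels = as.list(clusters)),
      file.path(outdir, "clusters.json"), auto_unbox = TRUE, digits = NA)
  }

  log_lines <- c(log_lines, paste0("rows: ", nrow(tab)),
                 paste0("references fitted: ", length(refs)),
                 if (length(markers) > 0 && is.null(config$input))
                   "lab marker SDS: internal LMS fit (no external reference tables)")
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(list(table = tab, qc = qc, references = refs,
                 percentiles = perc, sds = sds_tab, bmi = assoc_bmi,
                 tanner = assoc_tanner, trends = trends,
                 correlations = cors, clusters = clusters))
}
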