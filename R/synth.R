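# Synthetic pediatric cohort generator. Emulates the data structure the
# reference-curve and association machinery assumes: ~2000 subjects with
# repeated annual visits between 0.25 and 18 years, sibling clusters,
# four age-profile types for the metabolite medians, BCCG/BCT marginals,
# within-subject correlation, Tanner staging, BMI-SDS, lab markers with
# configurable correlation targets, LOD censoring and rare gross outliers.

#' Default 30-metabolite panel
#'
#' Amino acids (23, with leucine/isoleucine merged), six acylcarnitines and
#' free carnitine, each with an age-profile type (1 infancy-peak-then-dip,
#' 2 monotone increase, 3 rise-then-plateau, 4 flat), a distribution family
#' (BCT for the three kurtotic metabolites Asp, Met, Tau; BCCG otherwise)
#' and a plausible whole-blood base level in umol/L.
#'
#' @return data.frame with columns `metabolite`, `profile_type`, `family`,
#'   `base_level`.
#' @export
default_panel <- function() {
  p <- rbind(
    data.frame(metabolite = c("Ala", "Arg", "Glu", "LeuIle", "Orn", "Pro",
                              "Ser", "Thr", "Tyr", "C0", "C2", "C16", "C18.1"),
               profile_type = 1L,
               base_level = c(350, 60, 300, 150, 80, 180, 140, 120, 60,
                              30, 10, 1.5, 1.2)),
    data.frame(metabolite = c("Aba", "Asp", "Gly", "His", "OHProl", "MeHis",
                              "PiPA", "Phe", "Trp", "Val"),
               profile_type = 2L,
               base_level = c(15, 60, 250, 70, 20, 5, 2, 60, 50, 180)),
    data.frame(metabolite = c("Cit", "Sarc"), profile_type = 3L,
               base_level = c(25, 2)),
    data.frame(metabolite = c("Met", "Tau", "C3", "C18", "MMA"),
               profile_type = 4L,
               base_level = c(20, 150, 1.5, 0.8, 0.3))
  )
  p$family <- ifelse(p$metabolite %in% c("Asp", "Met", "Tau"), "BCT", "BCCG")
  p[order(p$metabolite), c("metabolite", "profile_type", "family", "base_level")]
}

#' Default lab-marker specification
#'
#' Each marker is a linear combination of target-metabolite z-scores plus an
#' optional age trend and noise, standardized so the correlation with each
#' individual target's SDS hits `rho`. Output scale is set by `mu`/`sd`
#' (conventional clinical units).
#'
#' @return named list of per-marker specs (`targets`, `rho`, `age_coef`,
#'   `mu`, `sd`).
#' @export
default_lab_spec <- function() {
  panel <- default_panel()$metabolite
  list(
    glucose      = list(targets = panel, rho = 0.25, age_coef = 0,   mu = 5.1,  sd = 0.6),
    hba1c        = list(targets = panel, rho = -0.3, age_coef = 0,   mu = 5.2,  sd = 0.3),
    triglycerides= list(targets = c("Ala", "LeuIle", "Val", "Tyr", "Pro"),
                        rho = 0.3,  age_coef = 0,   mu = 0.9,  sd = 0.4),
    chol_total   = list(targets = character(0), rho = 0, age_coef = 0, mu = 4.3, sd = 0.7),
    chol_ldl     = list(targets = character(0), rho = 0, age_coef = 0, mu = 2.4, sd = 0.6),
    chol_hdl     = list(targets = character(0), rho = 0, age_coef = 0, mu = 1.5, sd = 0.3),
    alt          = list(targets = character(0), rho = 0, age_coef = 0, mu = 20,  sd = 8),
    ast          = list(targets = character(0), rho = 0, age_coef = 0, mu = 28,  sd = 8),
    cysc         = list(targets = panel[1:10], rho = 0.5, age_coef = 0, mu = 0.85, sd = 0.12),
    creatinine   = list(targets = panel[1:10], rho = 0.3, age_coef = 0.5, mu = 55, sd = 15),
    tsh          = list(targets = character(0), rho = 0, age_coef = 0, mu = 2.5, sd = 1.0),
    ft3          = list(targets = character(0), rho = 0, age_coef = 0, mu = 6.2, sd = 0.8),
    ft4          = list(targets = character(0), rho = 0, age_coef = 0, mu = 15,  sd = 2)
  )
}

#' Cohort simulation configuration
#'
#' Defaults emulate the study design the package targets: 2191 subjects,
#' a mean of ~1.82 visits each (~3989 samples), ages 0.25-18 years, sibling
#' clusters, a 30-metabolite panel, within-subject intraclass correlation
#' 0.4 on the z-scale and a cross-metabolite shared factor of 0.3.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param sibling_fraction proportion of subjects sharing a family with at
#'   least one other subject.
#' @param visits_mean mean visits per subject (>= 1; counts are
#'   `1 + Poisson(visits_mean - 1)`).
#' @param age_range supported age interval (within `[0.25, 18]`).
#' @param sex_ratio proportion female.
#' @param panel metabolite panel as from [default_panel()].
#' @param icc intraclass (within-subject) correlation of the metabolite
#'   z-scores.
#' @param met_cor shared-factor correlation between metabolite z-scores.
#' @param lab_spec lab-marker specification as from [default_lab_spec()].
#' @param lod_map named numeric, metabolite -> detection limit (umol/L).
#' @param censor_rates named numeric, metabolite -> below-LOD injection rate.
#' @param outlier_rate proportion of values turned into gross outliers by
#'   [degrade_panel()].
#' @param bmi_effect named numeric `c(F=, M=)`, per-sex slope of metabolite
#'   z on BMI-SDS (0 = no association; used for power studies).
#' @param tanner_shift optional list(sex=, stages=, delta=, metabolites=)
#'   adding `delta` to z at the given Tanner stages (power studies).
#' @param seed integer seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 2191,
                          sibling_fraction = 0.15,
                          visits_mean = 1.82,
                          age_range = c(0.25, 18),
                          sex_ratio = 0.5,
                          panel = default_panel(),
                          icc = 0.4,
                          met_cor = 0.3,
                          lab_spec = default_lab_spec(),
                          lod_map = NULL,
                          censor_rates = NULL,
                          outlier_rate = 0.001,
                          bmi_effect = c(F = 0, M = 0),
                          tanner_shift = NULL,
                          seed = 1L) {
  stopifnot(n_subjects >= 1, visits_mean >= 1)
  if (sibling_fraction < 0 || sibling_fraction > 1) stop("sibling_fraction must be in [0,1]")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0,1]")
  if (icc < 0 || icc >= 1) stop("icc must be in [0,1)")
  if (met_cor < 0 || met_cor >= 1) stop("met_cor must be in [0,1)")
  if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate must be in [0,1]")
  if (age_range[1] < 0.25 - 1e-12 || age_range[2] > 18 + 1e-12 ||
      age_range[1] >= age_range[2])
    stop("age_range must be an increasing interval within [0.25, 18]")
  stopifnot(all(c("metabolite", "profile_type", "family", "base_level") %in%
                  names(panel)),
            all(panel$profile_type %in% 1:4),
            all(panel$family %in% c("BCCG", "BCT")),
            all(panel$base_level > 0))
  if (is.null(lod_map)) {
    lod_map <- stats::setNames(panel$base_level * 0.05, panel$metabolite)
  }
  if (is.null(censor_rates)) {
    censor_rates <- stats::setNames(rep(0.01, nrow(panel)), panel$metabolite)
  }
  if (any(censor_rates < 0 | censor_rates > 1)) stop("censor_rates must be in [0,1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 sibling_fraction = sibling_fraction,
                 visits_mean = visits_mean, age_range = age_range,
                 sex_ratio = sex_ratio, panel = panel, icc = icc,
                 met_cor = met_cor, lab_spec = lab_spec, lod_map = lod_map,
                 censor_rates = censor_rates, outlier_rate = outlier_rate,
                 bmi_effect = bmi_effect, tanner_shift = tanner_shift,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Ground-truth LMS curves for one metabolite
#'
#' Closed-form median shapes for the four age-profile types, projected onto
#' the package's spline basis so the truth object is the same `lms_curves`
#' type the fitter produces:
#' type 1 -- elevated in infancy, dip by 1-5 y, mild rise to 18 y;
#' type 2 -- strictly increasing from 0.25 to 18 y;
#' type 3 -- rise until ~5-9 y then plateau;
#' type 4 -- flat. Males get a 5 percent higher level.
#' S is 0.15 and L is 0.4 throughout (within the usual range for
#' right-skewed metabolite panels); BCT uses tau = 5.
#'
#' @param profile_type integer 1-4.
#' @param sex `"F"` or `"M"`.
#' @param base_level median scale (concentration units, > 0).
#' @param family `"BCCG"` or `"BCT"`.
#' @param age_range supported age interval.
#' @return an `lms_curves` object.
#' @export
make_true_curves <- function(profile_type, sex = c("F", "M"), base_level,
                             family = c("BCCG", "BCT"),
                             age_range = c(0.25, 18)) {
  sex <- match.arg(sex)
  family <- match.arg(family)
  if (!profile_type %in% 1:4)
    stop("unknown profile_type: must be 1, 2, 3 or 4")
  stopifnot(base_level > 0)
  b <- base_level * if (sex == "M") 1.05 else 1
  shape <- switch(profile_type,
    function(a) 1 + 0.40 * exp(-a / 0.8) + 0.15 * (a / 18),
    function(a) 0.70 + 0.60 * (a / 18)^0.7,
    function(a) 0.75 + 0.35 * (1 - exp(-a / 2.5)),
    function(a) rep(1, length(a)))
  grid <- seq(age_range[1], age_range[2], length.out = 200)
  curves_from_values(grid,
                     L = rep(0.4, length(grid)),
                     M = b * shape(grid),
                     S = rep(0.15, length(grid)),
                     df = c(L = 1, M = 6, S = 1),
                     family = family,
                     tau = if (family == "BCT") 5 else NULL,
                     age_range = age_range)
}

#' Ground-truth reference set for a panel
#'
#' @param panel as from [default_panel()].
#' @param age_range supported age interval.
#' @return nested list `truth[[metabolite]][[sex]]` of `lms_curves`, each
#'   with a `profile_type` attribute.
#' @export
make_true_reference <- function(panel = default_panel(),
                                age_range = c(0.25, 18)) {
  truth <- list()
  for (i in seq_len(nrow(panel))) {
    m <- panel$metabolite[i]
    truth[[m]] <- lapply(stats::setNames(c("F", "M"), c("F", "M")), function(sx) {
      cv <- make_true_curves(panel$profile_type[i], sx, panel$base_level[i],
                             panel$family[i], age_range)
      attr(cv, "profile_type") <- panel$profile_type[i]
      cv
    })
  }
  truth
}

# subject/family/visit scaffold ------------------------------------------

.simulate_design <- function(config) {
  n <- config$n_subjects
  subject_id <- sprintf("S%05d", seq_len(n))
  # sibling clusters: pair off the first round(frac * n) subjects
  n_sib <- 2L * (round(config$sibling_fraction * n) %/% 2L)
  family_id <- character(n)
  if (n_sib > 0) {
    fam_idx <- rep(seq_len(n_sib / 2L), each = 2L)
    family_id[seq_len(n_sib)] <- sprintf("F%05d", fam_idx)
  }
  if (n_sib < n)
    family_id[(n_sib + 1L):n] <- sprintf("F%05d", (n_sib %/% 2L) + seq_len(n - n_sib))
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
  n_visits <- 1L + stats::rpois(n, config$visits_mean - 1)
  lo <- config$age_range[1]; hi <- config$age_range[2]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_visits[i]
    gaps <- stats::runif(max(k - 1L, 0L), 0.8, 1.2)
    start_max <- max(lo, hi - sum(gaps))
    a0 <- stats::runif(1, lo, start_max)
    ages <- pmin(a0 + cumsum(c(0, gaps)), hi)
    rows[[i]] <- data.frame(subject_id = subject_id[i],
                            family_id = family_id[i], sex = sex[i],
                            age_years = ages)
  }
  do.call(rbind, rows)
}

.simulate_tanner <- function(age, sex) {
  onset <- ifelse(sex == "F", 10.5, 11.5)
  lat <- (age - onset) + stats::rlogis(length(age), 0, 0.8)
  stage <- 1L + findInterval(lat, c(-1.5, -0.5, 0.7, 2.0))
  stage[age < 7] <- 1L       # pre-pubertal by construction
  stage[age < 8] <- NA_integer_  # staging not assessed at young ages
  stage
}

#' Simulate a cohort table
#'
#' Draws the visit scaffold (subjects, families, sexes, ages), then per
#' metabolite a latent z with subject random shift (intraclass correlation
#' `icc`) and a cross-metabolite shared factor (`met_cor`), maps z through
#' a Gaussian copula to the metabolite's marginal (standard normal for
#' BCCG, Student t for BCT) and inverts the LMS transform at the subject's
#' age to obtain concentrations. Tanner stage follows an age- and
#' sex-dependent ordinal model (missing below age 8), BMI-SDS is standard
#' normal with within-subject correlation, and lab markers are linear
#' combinations of metabolite z-scores plus noise calibrated to the
#' configured correlation targets.
#'
#' @param config a [cohort_config()].
#' @param truth as from [make_true_reference()]; must cover every configured
#'   metabolite and both sexes.
#' @param seed optional override of `config$seed`.
#' @return data.frame (one row per visit) with design columns, metabolite
#'   concentrations and lab markers. The truth z-scores used for generation
#'   are attached as attribute `"z_norm"` (matrix) for calibration tests.
#' @export
simulate_cohort <- function(config, truth = NULL, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(truth)) truth <- make_true_reference(config$panel, config$age_range)
  mets <- config$panel$metabolite
  for (m in mets) {
    if (is.null(truth[[m]]) || is.null(truth[[m]][["F"]]) ||
        is.null(truth[[m]][["M"]]))
      stop("truth curves missing for metabolite ", m)
  }
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  tab <- .simulate_design(config)
  nr <- nrow(tab)
  subj <- match(tab$subject_id, unique(tab$subject_id))
  ns <- max(subj)
  icc <- config$icc; lam <- config$met_cor

  # shared factor with the same ICC structure as each metabolite's own part
  u0 <- stats::rnorm(ns)
  f_vis <- stats::rnorm(nr)
  common <- sqrt(icc) * u0[subj] + sqrt(1 - icc) * f_vis

  tab$tanner_stage <- .simulate_tanner(tab$age_years, tab$sex)
  b_subj <- stats::rnorm(ns)
  tab$bmi_sds <- sqrt(0.5) * b_subj[subj] + sqrt(0.5) * stats::rnorm(nr)

  zmat <- matrix(NA_real_, nr, length(mets), dimnames = list(NULL, mets))
  for (j in seq_along(mets)) {
    m <- mets[j]
    um <- stats::rnorm(ns)
    own <- sqrt(icc) * um[subj] + sqrt(1 - icc) * stats::rnorm(nr)
    z <- sqrt(lam) * common + sqrt(1 - lam) * own
    # optional injected effects (power studies); defaults are zero
    be <- config$bmi_effect
    if (any(be != 0))
      z <- z + ifelse(tab$sex == "F", be[["F"]], be[["M"]]) * tab$bmi_sds
    ts <- config$tanner_shift
    if (!is.null(ts) && m %in% ts$metabolites) {
      hit <- !is.na(tab$tanner_stage) & tab$tanner_stage %in% ts$stages &
        tab$sex == ts$sex
      z[hit] <- z[hit] + ts$delta
    }
    zmat[, j] <- z
    fam <- config$panel$family[j]
    vals <- numeric(nr)
    for (sx in c("F", "M")) {
      idx <- tab$sex == sx
      if (!any(idx)) next
      pars <- curve_params(truth[[m]][[sx]], tab$age_years[idx])
      zz <- z[idx]
      if (fam == "BCT") zz <- stats::qt(stats::pnorm(zz), df = pars$tau)
      # keep within the Box-Cox support (rare deep-left tail for L > 0)
      lb <- -0.999 / (pars$L * pars$S)
      zz <- pmax(zz, lb)
      arg <- 1 + pars$L * pars$S * zz
      vals[idx] <- pars$M * arg^(1 / pars$L)
    }
    tab[[m]] <- vals
  }

  for (k in names(config$lab_spec)) {
    sp <- config$lab_spec[[k]]
    tg <- intersect(sp$targets, mets)
    if (length(tg) == 0 || sp$rho == 0) {
      mz <- sp$age_coef * scale(tab$age_years)[, 1] +
        sqrt(max(0, 1 - sp$age_coef^2)) * stats::rnorm(nr)
    } else {
      m_n <- length(tg)
      # cor(mean of m equicorrelated z's, one z) under shared-factor lam
      cz <- (1 + (m_n - 1) * lam) / m_n
      vz <- (m_n + m_n * (m_n - 1) * lam) / m_n^2
      r_bar <- cz / sqrt(vz)
      rho_eff <- sp$rho / r_bar
      if (abs(rho_eff)^2 + sp$age_coef^2 > 1)
        stop("lab marker '", k, "': unattainable correlation target")
      zbar <- rowMeans(zmat[, tg, drop = FALSE]) / sqrt(vz)
      mz <- rho_eff * zbar + sp$age_coef * scale(tab$age_years)[, 1] +
        sqrt(max(0, 1 - rho_eff^2 - sp$age_coef^2)) * stats::rnorm(nr)
    }
    tab[[k]] <- sp$mu + sp$sd * mz
  }
  rownames(tab) <- NULL
  attr(tab, "z_norm") <- zmat
  tab
}

#' Inject LOD censoring and gross outliers
#'
#' For each metabolite, a `censor_rates[m]` fraction of values is replaced
#' by 0 (the below-LOD sentinel) and an `outlier_rate` fraction of the
#' remaining values is multiplied by `exp(7)` (beyond any +/-5 SD log-scale
#' band). Reproducible from `seed`.
#'
#' @param table cohort table from [simulate_cohort()].
#' @param lod_map named numeric of detection limits (metabolites to touch).
#' @param censor_rates named numeric in `[0,1]` (recycled from a scalar).
#' @param outlier_rate proportion in `[0,1]`.
#' @param seed integer seed.
#' @return the degraded table; injection bookkeeping in attributes
#'   `"censored"` and `"outliers"` (named counts).
#' @export
degrade_panel <- function(table, lod_map, censor_rates, outlier_rate = 0,
                          seed = 1L) {
  mets <- names(lod_map)
  stopifnot(all(mets %in% names(table)))
  if (length(censor_rates) == 1L && is.null(names(censor_rates)))
    censor_rates <- stats::setNames(rep(censor_rates, length(mets)), mets)
  if (any(censor_rates < 0 | censor_rates > 1) ||
      outlier_rate < 0 || outlier_rate > 1)
    stop("rates must be in [0, 1]")
  set.seed(as.integer(seed))
  n_cens <- n_out <- stats::setNames(integer(length(mets)), mets)
  for (m in mets) {
    v <- table[[m]]
    cr <- censor_rates[[m]]
    cens <- stats::runif(length(v)) < cr
    out <- stats::runif(length(v)) < outlier_rate & !cens
    v[cens] <- 0
    v[out] <- v[out] * exp(7)
    table[[m]] <- v
    n_cens[m] <- sum(cens); n_out[m] <- sum(out)
  }
  attr(table, "censored") <- n_cens
  attr(table, "outliers") <- n_out
  table
}

#' Write a cohort table with a JSON sidecar
#'
#' @param table cohort table.
#' @param path TSV output path; the sidecar is written next to it with
#'   extension `.json`.
#' @param config optional [cohort_config()] to record.
#' @param truth optional truth reference to record.
#' @export
write_cohort <- function(table, path, config = NULL, truth = NULL) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  meta <- list(
    n_rows = nrow(table),
    n_subjects = length(unique(table$subject_id)),
    config = if (is.null(config)) NULL else unclass(config[setdiff(names(config), "lab_spec")]),
    truth = if (is.null(truth)) NULL else lapply(truth, function(bysex)
      lapply(bysex, .curves_to_list))
  )
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
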