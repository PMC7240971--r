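# hierarchical association analyses and FDR control

sim_clustered <- function(n_subj, visits, icc, beta = 0, seed = 1) {
  set.seed(seed)
  subj <- rep(seq_len(n_subj), each = visits)
  n <- length(subj)
  u <- rnorm(n_subj)
  x <- rnorm(n)
  y <- beta * x + sqrt(icc) * u[subj] + sqrt(1 - icc) * rnorm(n)
  list(y = y, x = x, subj = subj)
}

test_that("by_adjust reproduces the step-up formula and its edge cases", {
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3))
  expect_equal(by_adjust(0.2), 0.2)         # c(1) = 1
  expect_equal(by_adjust(rep(1, 5)), rep(1, 5))
  set.seed(6)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))
    adj <- by_adjust(p)
    expect_equal(adj, oracle_by(p))
    expect_equal(adj, p.adjust(p, method = "BY"))
    expect_true(all(adj >= p))
    # order invariance: adjusted values follow their p-values
    perm <- sample(length(p))
    expect_equal(by_adjust(p[perm]), adj[perm])
  }
  expect_error(by_adjust(c(0.1, 0)), "in \\(0, 1\\]")
  expect_error(by_adjust(c(0.1, 1.2)), "in \\(0, 1\\]")
})

test_that("random-intercept fit matches OLS when group variance is zero", {
  set.seed(1)   # a draw whose REML subject variance sits at the zero boundary
  n <- 400
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 0.4 * X[, "a"] - 0.2 * X[, "b"] + rnorm(n)
  subj <- rep(1:200, each = 2)
  fit <- fit_random_intercept(y, X, subj)
  ols <- oracle_ols_standardized(y, X)
  got <- fit$coefficients$estimate[match(c("a", "b"), fit$coefficients$term)]
  expect_equal(got, unname(ols), tolerance = 1e-4)
})

test_that("random-intercept fit recovers an injected slope under clustering", {
  ests <- vapply(1:20, function(s) {
    d <- sim_clustered(300, 2, icc = 0.4, beta = 0.3, seed = s)
    fit <- fit_random_intercept(d$y, cbind(x = d$x), d$subj)
    # back to the raw scale: the generator's y has sd sqrt(1 + 0.09)
    fit$coefficients$estimate[fit$coefficients$term == "x"] * sd(d$y) / sd(d$x)
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.3), 0.05)
})

test_that("random-intercept fit handles degenerate designs explicitly", {
  set.seed(5)
  x <- rnorm(100)
  y <- x                                     # perfect fit
  fit <- fit_random_intercept(y, cbind(x = x), rep(1:50, each = 2))
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "x"], 1,
               tolerance = 1e-6)
  expect_lt(fit$var_resid, 1e-6)
  expect_error(fit_random_intercept(y, cbind(x = x, x2 = 2 * x),
                                    rep(1:50, each = 2)),
               "collinear columns: x2")
  expect_warning(f1 <- fit_random_intercept(y + rnorm(100), cbind(x = x),
                                            rep(1, 100)),
                 "single group")
  expect_true(f1$ols_fallback)
})

test_that("clustered null data keeps the Wald test near nominal level while
           ignoring clustering inflates it", {
  nrep <- 400
  rej_ri <- rej_ols <- logical(nrep)
  for (s in seq_len(nrep)) {
    set.seed(s)
    subj <- rep(1:100, each = 4)
    u <- rnorm(100)
    x_subj <- rnorm(100)                     # subject-level covariate
    x <- x_subj[subj]
    y <- sqrt(0.5) * u[subj] + sqrt(0.5) * rnorm(400)
    fit <- fit_random_intercept(y, cbind(x = x), subj)
    rej_ri[s] <- fit$coefficients$p[fit$coefficients$term == "x"] < 0.05
    ols <- summary(lm(y ~ x))$coefficients
    rej_ols[s] <- ols["x", 4] < 0.05
  }
  expect_gte(mean(rej_ri), 0.02)
  expect_lte(mean(rej_ri), 0.09)
  expect_gt(mean(rej_ols), 0.09)
})

test_that("interval trends use the half-open convention and find the
           injected slope", {
  # boundary ages land in the right-hand interval
  d0 <- data.frame(subject_id = sprintf("S%d", 1:200), sex = "F",
                   age_years = c(rep(5, 100), rep(4.99, 100)),
                   met = rnorm(200))
  tr0 <- interval_trends(d0, "met", cuts = c(1, 5, 9, 13), min_obs = 101)
  n_by_int <- tr0$n_obs[tr0$stratum == "F"]
  names(n_by_int) <- tr0$interval[tr0$stratum == "F"]
  expect_equal(unname(n_by_int["[5,9)"]), 100)
  expect_equal(unname(n_by_int["[1,5)"]), 100)
  # power: slope only in [5,13)
  hits_flat <- hits_rise <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    n_subj <- 600
    subj <- rep(sprintf("S%04d", 1:n_subj), each = 2)
    age <- runif(2 * n_subj, 1, 13)
    u <- rnorm(n_subj)
    slope <- ifelse(age >= 5, 0.1, 0)
    met <- slope * (age - 5) * (age >= 5) +
      sqrt(0.4) * u[match(subj, unique(subj))] + sqrt(0.6) * rnorm(2 * n_subj)
    d <- data.frame(subject_id = subj, sex = "F", age_years = age, met = met)
    tr <- interval_trends(d, "met", cuts = c(5, 13))
    sig <- tr$significant
    names(sig) <- tr$interval
    if (isTRUE(sig[["[5,13)"]])) hits_rise <- hits_rise + 1L
    if (isTRUE(sig[["[0.25,5)"]])) hits_flat <- hits_flat + 1L
  }
  expect_gte(hits_rise, 8)
  expect_lte(hits_flat, 2)
})

test_that("BMI association pools without interaction and splits with it", {
  mk <- function(bf, bm, seed) {
    set.seed(seed)
    n_subj <- 1000
    subj <- rep(sprintf("S%04d", 1:n_subj), each = 2)
    sex <- rep(sample(c("F", "M"), n_subj, TRUE), each = 2)
    bmi <- rnorm(2 * n_subj)
    u <- rnorm(n_subj)
    beta <- ifelse(sex == "F", bf, bm)
    met <- beta * bmi + sqrt(0.4) * u[match(subj, unique(subj))] +
      sqrt(0.6) * rnorm(2 * n_subj)
    data.frame(subject_id = subj, sex = sex, bmi_sds = bmi, met = met)
  }
  d <- mk(0.2, 0.2, 2)
  res <- bmi_association(d, "met")
  expect_equal(res$stratum, "pooled")
  raw <- res$estimate * sd(d$met) / sd(d$bmi_sds)
  expect_lt(abs(raw - 0.2), 0.05)
  # strong opposite slopes trigger per-sex reporting
  splits <- vapply(1:5, function(s) {
    r <- bmi_association(mk(-0.1, 0.3, 10 + s), "met")
    all(c("F", "M") %in% r$stratum)
  }, logical(1))
  expect_gte(sum(splits), 4)
  d_const <- d
  d_const$bmi_sds <- 0
  expect_error(bmi_association(d_const, "met"), "rank deficient")
  d_na <- d
  d_na$sex[1] <- NA
  expect_error(bmi_association(d_na, "met"), "missing sex")
})

test_that("Tanner contrasts are sex-stratified with stage 1 as reference", {
  mk <- function(delta_f, seed) {
    set.seed(seed)
    n_subj <- 800
    subj <- rep(sprintf("S%04d", 1:n_subj), each = 2)
    sex <- rep(sample(c("F", "M"), n_subj, TRUE), each = 2)
    stage <- sample(1:5, 2 * n_subj, TRUE)
    u <- rnorm(n_subj)
    met <- ifelse(sex == "F" & stage %in% 2:3, delta_f, 0) +
      sqrt(0.4) * u[match(subj, unique(subj))] + sqrt(0.6) * rnorm(2 * n_subj)
    data.frame(subject_id = subj, sex = sex, tanner_stage = stage, met = met)
  }
  # null: permuted labels stay overwhelmingly non-significant
  null_res <- tanner_contrasts(mk(0, 3), "met")
  expect_gte(mean(!null_res$significant), 0.95)
  # +0.5 SDS at stages 2-3 in girls only
  ok <- vapply(1:5, function(s) {
    r <- tanner_contrasts(mk(0.5, 20 + s), "met")
    f23 <- r$significant[r$stratum == "F" & r$covariate %in% c("tanner_2", "tanner_3")]
    m23 <- r$significant[r$stratum == "M" & r$covariate %in% c("tanner_2", "tanner_3")]
    all(f23) && !any(m23)
  }, logical(1))
  expect_gte(sum(ok), 4)
  # a stage with no observations is reported not estimable
  d <- mk(0, 4)
  d <- d[!(d$tanner_stage == 5), ]
  r5 <- tanner_contrasts(d, "met")
  expect_true(all(!r5$estimable[r5$covariate == "tanner_5"]))
  expect_true(all(is.na(r5$p_adj[r5$covariate == "tanner_5"])))
})

test_that("lab correlations recover planted structure and flag degeneracies", {
  set.seed(8)
  n_subj <- 1500
  subj <- rep(sprintf("S%04d", 1:n_subj), each = 2)
  n <- 2 * n_subj
  u1 <- rnorm(n_subj); u2 <- rnorm(n_subj)
  met1 <- sqrt(0.4) * u1[match(subj, unique(subj))] + sqrt(0.6) * rnorm(n)
  met2 <- sqrt(0.4) * u2[match(subj, unique(subj))] + sqrt(0.6) * rnorm(n)
  marker_null <- rnorm(n)
  marker_lin <- 2 * met1 + 3
  marker_half <- 0.5 * met2 + sqrt(0.75) * rnorm(n)
  cm <- lab_correlations(data.frame(met1 = met1, met2 = met2),
                         data.frame(null = marker_null, lin = marker_lin,
                                    half = marker_half, flat = rep(1, n)),
                         subj, mode = "absolute")
  expect_lt(abs(cm$estimate["met1", "null"]), 0.05)
  expect_equal(unname(cm$estimate["met1", "lin"]), 1, tolerance = 1e-6)
  expect_lt(abs(cm$estimate["met2", "half"] - 0.5), 0.07)
  expect_true(all(is.na(cm$estimate[, "flat"])))
  expect_true(all(abs(cm$estimate[!is.na(cm$estimate)]) <= 1 + 1e-8))
})

test_that("age confounding attenuates after SDS adjustment", {
  set.seed(15)
  n <- 3000
  subj <- sprintf("S%04d", rep(1:1500, each = 2))
  age <- runif(n, 0.25, 18)
  age_z <- scale(age)[, 1]
  met_z <- 0.6 * age_z + sqrt(1 - 0.36) * rnorm(n)   # age-driven metabolite
  marker <- 0.6 * age_z + sqrt(1 - 0.36) * rnorm(n)  # age-driven marker
  cm_abs <- lab_correlations(data.frame(met = met_z),
                             data.frame(mk = marker), subj, mode = "absolute")
  # SDS adjustment = remove the age trend from both sides
  cm_sds <- lab_correlations(data.frame(met = resid(lm(met_z ~ age_z))),
                             data.frame(mk = resid(lm(marker ~ age_z))),
                             subj, mode = "sds")
  expect_gt(cm_abs$estimate["met", "mk"], 0.25)
  expect_lt(abs(cm_sds$estimate["met", "mk"]),
            cm_abs$estimate["met", "mk"] - 0.2)
})

test_that("correlation-profile clustering recovers planted blocks", {
  set.seed(44)
  block1 <- matrix(rnorm(5 * 4, mean = 0.6, sd = 0.03), 5, 4)
  block2 <- matrix(rnorm(6 * 4, mean = -0.4, sd = 0.03), 6, 4)
  prof <- rbind(block1, block2)
  rownames(prof) <- paste0("m", 1:11)
  lab <- cluster_correlation_profiles(prof, k = 2)
  expect_equal(length(unique(lab[1:5])), 1)
  expect_equal(length(unique(lab[6:11])), 1)
  expect_false(lab[1] == lab[6])
  expect_true(all(cluster_correlation_profiles(prof, k = 1) == 1))
  perm <- sample(11)
  lab_p <- cluster_correlation_profiles(prof[perm, ], k = 2)
  expect_true(all((lab_p == lab_p[which(perm == 1)]) ==
                    (lab[perm] == lab[1])))
  expect_error(cluster_correlation_profiles(prof, k = 12), "k must be")
})
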