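# Cox models, Kaplan-Meier stratification, and the age-trend test.

sim_surv <- function(n, loghr = 0, x = NULL, censor_rate = 0.3,
                     base = 0.001) {
  if (is.null(x)) x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, base * exp(loghr * x))
  t_c <- rexp(n, base * censor_rate / (1 - censor_rate))
  data.frame(time = pmin(t_ev, t_c), status = as.integer(t_ev <= t_c),
             x = x)
}

test_that("null covariates are covered and planted effects recovered", {
  set.seed(31)
  d0 <- sim_surv(2000, loghr = 0)
  f0 <- fit_cox(d0, ~ x)
  expect_true(f0$terms$ci_low <= 1 && f0$terms$ci_high >= 1)
  expect_true(f0$converged)

  d1 <- sim_surv(1000, loghr = log(2))
  f1 <- fit_cox(d1, ~ x)
  expect_true(f1$terms$ci_low <= 2 && f1$terms$ci_high >= 2)
  expect_gt(f1$terms$hr, 1)

  # protective continuous covariate, true HR 0.5 per unit
  xc <- rnorm(1000)
  d2 <- sim_surv(1000, loghr = log(0.5), x = xc)
  f2 <- fit_cox(d2, ~ x)
  expect_lt(f2$terms$hr, 1)
  expect_lt(f2$terms$p, 0.05)
})

test_that("the score-test direction matches the group survival difference", {
  # two groups, no ties, no censoring: group B dies mostly earlier (with
  # overlap, so the partial likelihood has an interior maximum)
  d <- data.frame(time = c(5, 10, 20, 40, 1, 2, 3, 30),
                  status = 1, x = rep(c(0, 1), each = 4))
  f <- fit_cox(d, ~ x)
  expect_gt(f$terms$hr, 1)                       # B at higher hazard
})

test_that("interaction terms vanish when absent from the generator", {
  set.seed(37)
  n <- 2000
  g <- rbinom(n, 1, 0.5)
  z <- rnorm(n)
  t_ev <- rexp(n, 0.001 * exp(0.5 * g + 0.3 * z))
  d <- data.frame(time = t_ev, status = 1, g = g, z = z)
  f <- fit_cox(d, ~ g * z)
  it <- f$terms[f$terms$term == "g:z", ]
  expect_true(it$ci_low <= 1 && it$ci_high >= 1)
  # main effects near truth
  expect_equal(log(f$terms$hr[f$terms$term == "g"]), 0.5, tolerance = 0.2)
})

test_that("fit_cox validates input and flags separation", {
  d <- data.frame(time = c(1, 2, 3), status = c(1, 0, 1), x = c(0, 1, 1))
  expect_error(fit_cox(data.frame(time = c(0, 1), status = c(1, 1),
                                  x = 1:2), ~ x), "non-positive")
  expect_error(fit_cox(data.frame(time = c(1, 2), status = c(0, 0),
                                  x = 1:2), ~ x), "no events")
  # perfectly separated covariate
  set.seed(2)
  t_a <- runif(30, 10, 20); t_b <- runif(30, 1, 5)
  ds <- data.frame(time = c(t_a, t_b), status = 1,
                   x = rep(c(0, 1), each = 30))
  expect_error(fit_cox(ds, ~ x), "separation")
})

test_that("KM estimator matches the product-limit hand computation", {
  # classic 6-observation toy: deaths at 1, 3, 5; censored at 2, 4, 6
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                  status = c(1, 0, 1, 0, 1, 0))
  score <- c(0, 0, 0, 1, 1, 1)                   # low = first three
  km <- km_strata(d, score, split = 0.5)
  lo <- km$curves[km$curves$stratum == "low", ]
  # low stratum: death at 1 (3 at risk) then 3 (1 at risk after censor)
  expect_equal(lo$surv[lo$time == 1], 2 / 3)
  expect_equal(lo$surv[lo$time == 3], 2 / 3 * 0)
  # no censoring: steps drop 1/n per death
  d2 <- data.frame(time = 1:6, status = 1)
  km2 <- km_strata(d2, rep(c(0, 1), 3), split = 0.5)
  lo2 <- km2$curves[km2$curves$stratum == "low", ]
  expect_equal(lo2$surv, c(2 / 3, 1 / 3, 0))
  expect_error(km_strata(d2, rep(1, 6), split = "median"), "one side")
})

test_that("the log-rank test separates distinct hazards and respects the null", {
  set.seed(41)
  null_p <- vapply(1:20, function(i) {
    d <- sim_surv(500, loghr = 0)
    km_strata(d, d$x, split = 0.5)$logrank_p
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.8)
  d3 <- sim_surv(300, loghr = log(3))
  expect_lt(km_strata(d3, d3$x, split = 0.5)$logrank_p, 0.01)
})

test_that("age trend detects monotone decline and reduces to rank-sum for 2 groups", {
  set.seed(43)
  groups <- factor(rep(c("fetal", "child", "adult"), each = 30),
                   levels = c("fetal", "child", "adult"))
  vals <- c(rnorm(30, 0.9, 0.03), rnorm(30, 0.7, 0.03),
            rnorm(30, 0.5, 0.03))
  at <- age_trend(vals, groups)
  expect_lt(at$trend_rho, -0.8)
  expect_true(all(at$pairwise$adj_p < 0.05))
  # identical groups: trend near zero
  at0 <- age_trend(rnorm(90), groups)
  expect_lt(abs(at0$trend_rho), 0.25)
  # two groups reduce to a single rank-sum test
  g2 <- factor(rep(c("young", "old"), each = 20),
               levels = c("young", "old"))
  v2 <- c(rnorm(20, 1), rnorm(20, 0))
  at2 <- age_trend(v2, g2)
  expect_equal(nrow(at2$pairwise), 1)
  wt <- wilcox.test(v2[1:20], v2[21:40], exact = FALSE)
  expect_equal(at2$pairwise$p, wt$p.value)
  expect_error(age_trend(v2, as.character(g2)), "ordered factor")
  expect_error(age_trend(rnorm(4), factor(c("a", "a", "b", "b"))),
               ">= 3 values")
})

test_that("small histology levels collapse into one", {
  x <- c(rep("LGG", 10), rep("MB", 5), "RARE1", "RARE2", "RARE2")
  cc <- collapse_small_levels(x, min_n = 3)
  expect_setequal(levels(cc), c("LGG", "MB", "Collapsed"))
  expect_equal(sum(cc == "Collapsed"), 3)
})

test_that("the cohort generator's survival coefficients are recovered", {
  fits <- lapply(47:52, function(s) {
    cfg <- sim_config(n_samples = 1000, n_events = c(SE = 30),
                      n_clusters = 2, cluster_loghr = c(0, 0.7),
                      psi_loghr = -1.5, planted_frac = 0, seed = s)
    co <- simulate_cohort(cfg)
    mf <- co$manifest
    d <- data.frame(
      time = mf$OS_days, status = mf$OS_status,
      cluster = factor(co$truth$cluster[mf$sample]),
      resection = relevel(factor(mf$resection), ref = "gross/near total"),
      psi = co$truth$candidate_psi[mf$sample])
    fit_cox(d, ~ cluster + resection + psi)$terms
  })
  # cluster effect: tight and unbiased at this n
  b_cl <- vapply(fits, function(t) log(t$hr[t$term == "cluster2"]),
                 numeric(1))
  expect_equal(mean(b_cl), 0.7, tolerance = 0.15)
  # candidate-PSI effect: small covariate spread, so check CI coverage
  # across seeds plus an approximately unbiased mean
  covered <- vapply(fits, function(t) {
    r <- t[t$term == "psi", ]
    r$ci_low <= exp(-1.5) && r$ci_high >= exp(-1.5)
  }, logical(1))
  expect_gte(mean(covered), 4 / 6)
  b_psi <- vapply(fits, function(t) log(t$hr[t$term == "psi"]),
                  numeric(1))
  expect_equal(mean(b_psi), -1.5, tolerance = 0.8)
})
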