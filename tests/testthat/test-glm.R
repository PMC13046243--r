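test_that("fit_ols reproduces textbook slopes and agrees with lm", {
  X <- cbind(1, x = c(1, 2, 3, 4))
  fit <- fit_ols(X, c(1, 2, 2, 4))
  expect_equal(unname(fit$coef["x"]), 0.9, tolerance = 1e-12)
  # dual route: cross-check the full inference against stats::lm
  set.seed(1)
  n <- 40
  df <- data.frame(a = rnorm(n), b = runif(n))
  df$y <- 1 + 0.5 * df$a - 2 * df$b + rnorm(n)
  ours <- fit_ols(cbind("(Intercept)" = 1, a = df$a, b = df$b), df$y)
  ref <- summary(lm(y ~ a + b, df))
  expect_equal(unname(ours$coef), unname(ref$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(unname(ours$se), unname(ref$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(unname(ours$p), unname(ref$coefficients[, 4]), tolerance = 1e-10)
  expect_equal(ours$r2, ref$r.squared, tolerance = 1e-10)
  expect_equal(ours$aic, AIC(lm(y ~ a + b, df)), tolerance = 1e-8)
  # broom-style accessors
  td <- tidy(ours)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(glance(ours)$nobs, n)
})

test_that("degenerate responses follow the stated t conventions", {
  X <- cbind(1, x = 1:6)
  flat <- fit_ols(X, rep(2, 6))
  expect_equal(unname(flat$coef["x"]), 0, tolerance = 1e-10)
  expect_equal(unname(flat$t["x"]), 0)
  perfect <- fit_ols(X, 3 + 2 * (1:6))
  expect_equal(perfect$r2, 1, tolerance = 1e-12)
  expect_lt(perfect$rss, 1e-20)
})

test_that("rank-deficient designs raise a collinearity error naming columns", {
  X <- cbind("(Intercept)" = 1, a = 1:8, twice_a = 2 * (1:8))
  err <- expect_error(fit_ols(X, rnorm(8)), class = "neolaminar_collinearity_error")
  expect_match(conditionMessage(err), "twice_a")
  co <- simulate_cohort(20, seed = 1)
  expect_error(neolaminar:::build_design(co, c("pma", "ga", "pna")),
               class = "neolaminar_collinearity_error")
})

test_that("BH step-up reproduces the hand-worked example and q-value invariants", {
  p <- c(0.001, 0.008, 0.039, 0.041)
  expect_identical(bh_reject(p, alpha = 0.025), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bh_reject(p, alpha = 0.025), p.adjust(p, "BH") <= 0.025)
  set.seed(2)
  pr <- runif(66)
  expect_true(all(p.adjust(pr, "BH") >= pr))
  expect_identical(bh_reject(pr, 0.1), p.adjust(pr, "BH") <= 0.1)
})

test_that("parcelwise effects recover a planted deep GA slope with clean nulls", {
  study <- make_small_study(n = 50, seed = 9, n_parcels = 9, noise_sd = 0.05)
  moments <- study_moments(study)
  grp <- parcel_groups(study$geom, names(study$spec$groups))
  em <- parcelwise_effects(moments, study$cohort, c("ga", "pna", "sex"),
                           term = "ga", response = "mu1")
  em$group <- grp[as.integer(em$parcel_id)]
  expect_true(all(em$statistic[em$group == "deep_ga"] > 0))
  expect_true(all(em$significant[em$group == "deep_ga"]))
  expect_false(any(em$significant[em$group == "null"]))
  expect_true(all(em$q.value >= em$p.value - 1e-15))
})

test_that("misaligned or incomplete moment tables are rejected", {
  co <- simulate_cohort(10, seed = 1)
  mom <- tidyr::expand_grid(subject_id = co$subject_id, parcel_id = c("1", "2"))
  mom$mu1 <- rnorm(nrow(mom))
  bad <- mom
  bad$subject_id[1] <- "sub-9999"
  expect_error(parcelwise_effects(bad, co, c("ga", "sex"), term = "ga"),
               class = "neolaminar_contract_error")
  expect_error(parcelwise_effects(mom, co, c("ga", "sex"), term = "pna"),
               class = "neolaminar_parameter_error")
})

test_that("model comparison ranks the generative model and validates F-tests", {
  set.seed(3)
  wins <- 0L
  for (s in 1:30) {
    co <- simulate_cohort(80, seed = 100 + s)
    y <- 0.05 * co$ga_weeks + rnorm(80, sd = 0.1)
    cmp <- compare_models(y, co, list(c("sex"), c("ga", "sex")))
    if (cmp$models$AIC[2] < cmp$models$AIC[1]) wins <- wins + 1L
    if (s == 1) {
      expect_equal(nrow(cmp$f_tests), 1)
      expect_lt(cmp$f_tests$p.value, 1e-6)
    }
  }
  expect_gte(wins, 29L)
  # identical candidates give identical rows
  co <- simulate_cohort(40, seed = 5)
  y <- rnorm(40)
  cmp2 <- compare_models(y, co, list(c("ga", "sex"), c("ga", "sex")))
  expect_equal(cmp2$models$AIC[1], cmp2$models$AIC[2])
  # non-nested explicit F-test request fails
  expect_error(compare_models(y, co, list(c("ga", "sex"), c("pna", "sex")),
                              f_pairs = list(c(1, 2))),
               class = "neolaminar_contract_error")
})

test_that("null extra predictors give approximately uniform F-test p-values", {
  set.seed(4)
  ps <- vapply(1:200, function(s) {
    co <- simulate_cohort(60, seed = 4000 + s)
    y <- 0.04 * co$ga_weeks + rnorm(60, sd = 0.2)
    compare_models(y, co, list(c("ga", "sex"), c("ga", "pna", "sex")))$f_tests$p.value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("depth-wise age correlations flag undefined depths and match signs", {
  co <- simulate_cohort(30, seed = 6)
  prof <- matrix(5, 30, 12)
  prof[, 7] <- co$pma_weeks
  dc <- depthwise_age_correlation(prof, co$pma_weeks)
  expect_equal(dc$r[7], 1, tolerance = 1e-12)
  expect_true(all(dc$undefined[-7]))
  set.seed(6)
  prof2 <- matrix(rnorm(30 * 12), 30) + outer(co$pma_weeks, c(rep(0.3, 6), rep(-0.3, 6)))
  dc2 <- depthwise_age_correlation(prof2, co$pma_weeks)
  expect_true(all(dc2$r[1:6] > 0) && all(dc2$r[7:12] < 0))
  expect_error(depthwise_age_correlation(prof2[1:2, ], co$pma_weeks[1:2]),
               class = "neolaminar_contract_error")
})

test_that("depth-wise correlation p-values are calibrated under the null", {
  set.seed(7)
  age <- rnorm(40)
  ps <- replicate(500, depthwise_age_correlation(
    matrix(rnorm(40 * 2), 40), sample(age))$p.value)
  expect_gt(ks.test(as.vector(ps), "punif")$p.value, 0.01)
})

test_that("the GA x PNA interaction term is centered and shift-invariant", {
  study <- make_small_study(n = 40, seed = 13, n_parcels = 6)
  moments <- study_moments(study)
  em1 <- interaction_effects(moments, study$cohort, response = "mu1")
  shifted <- study$cohort
  shifted$ga_weeks <- shifted$ga_weeks + 3
  shifted$pma_weeks <- shifted$pma_weeks + 3
  em2 <- interaction_effects(moments, shifted, response = "mu1")
  expect_equal(em1$statistic, em2$statistic, tolerance = 1e-9)
  expect_equal(em1$p.value, em2$p.value, tolerance = 1e-9)
})

test_that("a planted positive interaction is detected and nulls stay quiet", {
  set.seed(8)
  co <- simulate_cohort(300, seed = 21)
  gac <- co$ga_weeks - mean(co$ga_weeks)
  pnac <- co$pna_weeks - mean(co$pna_weeks)
  mom <- dplyr::bind_rows(lapply(1:10, function(p) {
    mu <- if (p <= 5) 6.5 + 0.05 * gac * pnac else rep(6.5, 300)
    tibble::tibble(subject_id = co$subject_id, parcel_id = as.character(p),
                   mu1 = mu + rnorm(300, sd = 0.3), mu2 = 3)
  }))
  em <- interaction_effects(mom, co, response = "mu1")
  planted <- as.integer(em$parcel_id) <= 5
  expect_true(all(em$significant[planted] & em$statistic[planted] > 0))
  expect_false(any(em$significant[!planted]))
})
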