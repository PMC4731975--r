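test_that("a noise-free panel is fitted exactly, variances at the boundary", {
  cfg <- noise_free_config(n_baseline = 300, refreshment = c("3" = 50))
  panel <- build_panel(simulate_cohort(cfg, seed = 3))
  fit <- quiet_fit(panel, "female", "education")
  truth <- c(intercept = -0.100, age = -0.013, age2 = -4e-4, group = 0.106,
             group_age2 = -1e-4, height = 0.5, weight = 0.0015, wave = 0.005)
  expect_equal(coef(fit)[names(truth)], truth, tolerance = 1e-8)
  expect_lt(max(abs(fit$varcomp)), 1e-10)
  # men's slope form likewise
  fitm <- quiet_fit(panel, "male", "education")
  truth_m <- c(intercept = 0.143, age = -0.010, age2 = -4e-4, group = 0.131,
               group_age = -1e-4, height = 0.35, weight = 0.0015, wave = 0.005)
  expect_equal(coef(fitm)[names(truth_m)], truth_m, tolerance = 1e-8)
})

test_that("one large panel recovers the generating values within 3 SE", {
  cfg <- sim_config(n_baseline = 2000, refreshment = NULL, prop_female = 1,
                    fixed = list(female = women_truth(), male = men_truth()))
  panel <- build_panel(simulate_cohort(cfg, seed = 101))
  fit <- quiet_fit(panel, "female", "education")
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["group"]] - 0.106), 3 * fit$se[["group"]])
  # residual variance near its generating value (normal-theory SE)
  se_sigma2 <- fit$varcomp[["residual"]] * sqrt(2 / fit$n_obs)
  expect_lt(abs(fit$varcomp[["residual"]] - 0.023), 3 * se_sigma2)
  # AIC identity and bookkeeping
  expect_equal(fit$aic, 2 * fit$df - 2 * fit$loglik)
  expect_equal(fit$n_obs, nrow(as.data.frame(panel)))
})

test_that("the full model's ML log-likelihood dominates its nested models", {
  cfg <- sim_config(n_baseline = 400, prop_female = 1, refreshment = NULL)
  panel <- build_panel(simulate_cohort(cfg, seed = 55))
  base <- quiet_fit(panel, "female", "education", form = "none",
                    quadratic = FALSE, include_group = FALSE)
  quad <- quiet_fit(panel, "female", "education", form = "none",
                    quadratic = TRUE, include_group = FALSE)
  grp <- quiet_fit(panel, "female", "education", form = "none")
  full <- quiet_fit(panel, "female", "education", form = "acceleration")
  lls <- c(base$loglik, quad$loglik, grp$loglik, full$loglik)
  expect_true(all(diff(lls) > -1e-6))
})

test_that("likelihood-ratio tests behave and refuse non-nested comparisons", {
  cfg <- sim_config(n_baseline = 300, prop_female = 1, refreshment = NULL)
  panel <- build_panel(simulate_cohort(cfg, seed = 61))
  m0 <- quiet_fit(panel, "female", "education", form = "none")
  m1 <- quiet_fit(panel, "female", "education", form = "acceleration")
  lrt <- lrt_growth(m0, m1)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, 1, lower.tail = FALSE))
  # identical models: statistic 0, p 1
  self <- lrt_growth(m0, m0)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  # refusal paths
  expect_error(lrt_growth(m1, m0), "not nested")
  small <- build_panel(simulate_cohort(
    sim_config(n_baseline = 150, prop_female = 1, refreshment = NULL),
    seed = 62))
  m_small <- quiet_fit(small, "female", "education", form = "none")
  expect_error(lrt_growth(m_small, m1), "different numbers of observations")
})

test_that("the age-squared LRT statistic grows with the sample size", {
  stat_at <- function(n, seed) {
    cfg <- sim_config(n_baseline = n, prop_female = 1, refreshment = NULL)
    panel <- build_panel(simulate_cohort(cfg, seed = seed))
    lin <- quiet_fit(panel, "female", "education", form = "none",
                     quadratic = FALSE, include_group = FALSE)
    quad <- quiet_fit(panel, "female", "education", form = "none",
                      quadratic = TRUE, include_group = FALSE)
    lrt_growth(lin, quad)$statistic
  }
  expect_gt(stat_at(1600, 7), stat_at(400, 7))
})

test_that("population-average predictions follow the fixed-effect surface", {
  m <- growth_model(intercept = 0.9, age = -0.013, age2 = -4e-4,
                    group = 0.106, group_age2 = -1e-4, sex = "female")
  # intercept returned exactly at the origin of all predictors
  expect_identical(predict(m, group = 0, age = 70), 0.9)
  # group contrast at age 70 is the main effect, for both forms
  expect_equal(speed_gap(m, 70), 0.106)
  mm <- growth_model(intercept = 0.9, age = -0.010, age2 = -4e-4,
                     group = 0.131, group_age = -2e-3, sex = "male")
  expect_equal(speed_gap(mm, 70), 0.131)
  # covariates enter linearly
  expect_equal(predict(m, age = 70, height = 2, weight = 10, wave = 3), 0.9)
  m2 <- growth_model(intercept = 0.9, age = -0.013, height = 0.5,
                     weight = 0.001, wave = 0.01, sex = "female")
  expect_equal(predict(m2, age = 70, height = 1.6, weight = 70, wave = 2),
               0.9 + 0.5 * 1.6 + 0.001 * 70 + 0.01 * 2)
  # extrapolation guard
  expect_error(predict(m, age = 120), "force")
  expect_silent(predict(m, age = 120, force = TRUE))
})

test_that("fits are invariant to centring the age variable elsewhere", {
  cfg <- sim_config(n_baseline = 300, prop_female = 1, refreshment = NULL)
  panel <- build_panel(simulate_cohort(cfg, seed = 71))
  # equivariance requires the unstructured random-effect covariance: under a
  # diagonal structure the zero intercept-slope covariance is centring-specific
  f1 <- quiet_fit(panel, "female", "education", random = "unstructured")
  un <- as.data.frame(panel)
  un$age_c <- un$age - 60   # centred at 60 instead of 70
  f2 <- quiet_fit(un, "female", "education", random = "unstructured")
  # identical up to the optimiser's achieved precision on the poorly scaled
  # shifted problem (the quadratic term grows ~25-fold under this shift)
  expect_lt(abs(f1$loglik - f2$loglik), 0.1)
  expect_lt(max(abs(sort(fitted(f1$fit)) - sort(fitted(f2$fit)))), 0.005)
})

test_that("a single observation per person drives the slope to the boundary", {
  # everyone enters at nurse wave 4 and drops immediately: one record each
  cfg <- sim_config(n_baseline = 0, refreshment = c("4" = 400),
                    prop_female = 1, attrition = 1)
  panel <- build_panel(simulate_cohort(cfg, seed = 81))
  expect_true(all(table(panel$person_id) == 1))
  expect_warning(fit <- fit_growth(panel, "female", "education"), "boundary")
  expect_true(fit$boundary)
  expect_gte(min(fit$varcomp), 0)
})

test_that("stepwise selection recovers each sex's generating interaction form", {
  # women: acceleration (group x age^2), amplified for a decisive single run
  cfgw <- sim_config(n_baseline = 1500, prop_female = 1, refreshment = NULL,
                     fixed = list(female = women_truth(group_age2 = -6e-4),
                                  male = men_truth()))
  selw <- suppressWarnings(
    select_growth_model(build_panel(simulate_cohort(cfgw, seed = 14)),
                        "female", "education"))
  expect_equal(selw$form, "acceleration")
  expect_true(selw$quadratic)
  expect_true(all(c("step", "p_value", "decision") %in% names(selw$trail)))
  # men: slope (group x age)
  cfgm <- sim_config(n_baseline = 1500, prop_female = 0, refreshment = NULL,
                     fixed = list(female = women_truth(),
                                  male = men_truth(group_age = -6e-3)))
  selm <- suppressWarnings(
    select_growth_model(build_panel(simulate_cohort(cfgm, seed = 15)),
                        "male", "education"))
  expect_equal(selm$form, "slope")
  # null path: no curvature, no interaction -> linear base + group main effect
  lin <- true_fixed(intercept = -0.100, age = -0.013, age2 = 0, wave = 0.005,
                    group = 0.106, height = 0.5, weight = 0.0015)
  cfg0 <- sim_config(n_baseline = 800, prop_female = 1, refreshment = NULL,
                     fixed = list(female = lin, male = men_truth()))
  sel0 <- suppressWarnings(
    select_growth_model(build_panel(simulate_cohort(cfg0, seed = 16)),
                        "female", "education"))
  expect_equal(sel0$form, "none")
  expect_false(sel0$quadratic)
  expect_true("group" %in% names(coef(sel0$fit)))
})

test_that("fitted models serialise to JSON and back without losing predictions", {
  cfg <- sim_config(n_baseline = 250, prop_female = 1, refreshment = NULL)
  panel <- build_panel(simulate_cohort(cfg, seed = 91))
  fit <- quiet_fit(panel, "female", "education")
  tf <- withr::local_tempfile(fileext = ".json")
  write_growth_model(fit, tf)
  back <- read_growth_model(tf)
  expect_equal(coef(back), coef(fit))
  expect_equal(back$varcomp, fit$varcomp)
  expect_equal(back$loglik, fit$loglik)
  ages <- c(62, 70, 85)
  expect_equal(predict(back, group = 1, age = ages),
               predict(fit, group = 1, age = ages))
})

test_that("simulate() reproduces the model's variance structure", {
  m <- growth_model(intercept = 0.85, age = -0.013, age2 = -4e-4,
                    group = 0.106, group_age2 = -1e-4,
                    varcomp = c(intercept = 0.031, slope = 1e-4,
                                residual = 0.023), sex = "female")
  nd <- data.frame(person_id = rep(1:500, each = 3),
                   age = rep(c(65, 70, 75), 500), group = rep(0:1, 750))
  sims <- simulate(m, nsim = 2, seed = 1, newdata = nd)
  expect_equal(dim(sims), c(1500, 2))
  # marginal variance at age 70 ~ intercept + residual
  at70 <- nd$age == 70
  v <- var(sims$sim_1[at70])
  expect_lt(abs(v - 0.054), 0.012)
})
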