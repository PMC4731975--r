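# Shared fixtures: small generating configurations and an independent
# bisection oracle for the alpha-age closed form.

# the published women's / men's education-model generating values used as
# simulation truth throughout the tests
women_truth <- function(group_age2 = -1e-4) {
  true_fixed(intercept = -0.100, age = -0.013, age2 = -4e-4, wave = 0.005,
             group = 0.106, group_age2 = group_age2,
             height = 0.5, weight = 0.0015)
}
men_truth <- function(group_age = -1e-4) {
  true_fixed(intercept = 0.143, age = -0.010, age2 = -4e-4, wave = 0.005,
             group = 0.131, group_age = group_age,
             height = 0.35, weight = 0.0015)
}

quiet_fit <- function(...) suppressWarnings(fit_growth(...))

noise_free_config <- function(n_baseline = 300, refreshment = c("3" = 50),
                              fixed = list(female = women_truth(),
                                           male = men_truth()), ...) {
  zero <- true_variance(0, 0, 0, 0)
  sim_config(n_baseline = n_baseline, refreshment = refreshment,
             fixed = fixed, variance = list(female = zero, male = zero),
             trial_jitter_sd = 0, measure_sd = c(height = 0, weight = 0),
             ...)
}

# one raw person-wave record with valid defaults; override fields as needed
raw_row <- function(person_id = "x1", wave = 2L, survey_year = 2004L,
                    birth_year = 1934L, self_reported_age = 70L,
                    sex = "female", education_high = 1L,
                    occupation_nonmanual = 0L, region_wealthy = 1L,
                    height_m = 1.65, weight_kg = 70,
                    walk1_s = 3, walk2_s = 3, sample_weight = 1) {
  data.frame(person_id = person_id, wave = wave, survey_year = survey_year,
             birth_year = birth_year, self_reported_age = self_reported_age,
             sex = sex, education_high = education_high,
             occupation_nonmanual = occupation_nonmanual,
             region_wealthy = region_wealthy, height_m = height_m,
             weight_kg = weight_kg, walk1_s = walk1_s, walk2_s = walk2_s,
             sample_weight = sample_weight, stringsAsFactors = FALSE)
}

# expected latent trajectory for a cohort generated with zero variances,
# computed directly from the generating coefficients (independently of the
# generator's internals, but using its recorded covariates)
expected_clean_speed <- function(cohort, fixed, latent = "education_high") {
  g <- cohort[[latent]]
  a <- cohort$survey_year - cohort$birth_year - 70
  # person-level true height/weight: any nurse-wave record (no measurement noise)
  h <- stats::ave(cohort$height_m, cohort$person_id,
                  FUN = function(x) mean(x, na.rm = TRUE))
  w <- stats::ave(cohort$weight_kg, cohort$person_id,
                  FUN = function(x) mean(x, na.rm = TRUE))
  vapply(seq_len(nrow(cohort)), function(i) {
    b <- if (cohort$sex[i] == "female") fixed$female else fixed$male
    b$intercept + b$group * g[i] + b$height * h[i] + b$weight * w[i] +
      (b$age + b$group_age * g[i]) * a[i] +
      (b$age2 + b$group_age2 * g[i]) * a[i]^2 + b$wave * cohort$wave[i]
  }, numeric(1))
}

# independent oracle: bisection on the age-decreasing branch of the comparison
# trajectory, using only predict()
bisect_alpha <- function(model, t, reference = 0, comparison = 1,
                         lo = 50, hi = 110, tol = 1e-10) {
  k <- predict(model, group = reference, age = t)
  b <- coef(model)
  c2 <- unname(b["age2"] + ifelse("group_age2" %in% names(b),
                                  b["group_age2"], 0) * comparison)
  c1 <- unname(b["age"] + ifelse("group_age" %in% names(b),
                                 b["group_age"], 0) * comparison)
  if (abs(c2) > 1e-12) {
    vertex <- 70 - c1 / (2 * c2)
    if (c2 < 0) lo <- max(lo, vertex) else hi <- min(hi, vertex)
  }
  f <- function(age) predict(model, group = comparison, age = age,
                             force = TRUE) - k
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) return(NA_real_)   # not bracketed: unsolvable here
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# printed alpha-age table (reference ages 60..85 by 5)
published_alpha <- function() {
  rbind(women_education = c(70.8, 73.4, 76.5, 80.0, 83.7, 87.6),
        women_occupation = c(69.2, 72.4, 75.9, 79.6, 83.4, 87.2),
        women_region = c(64.1, 67.8, 72.1, 76.7, 81.4, 86.2),
        men_education = c(75.4, 76.7, 79.1, 82.3, 86.1, 90.1),
        men_occupation = c(73.1, 74.4, 76.8, 80.0, 83.7, 87.7),
        men_region = c(65.1, 68.0, 71.9, 76.2, 80.8, 85.5))
}
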