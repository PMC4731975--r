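# Published growth-curve estimates for English older adults (ELSA, waves
# 1-6, 2002-2012): sex-specific models of mean 2.4 m timed-walk speed with
# age centred at 70 years, controlling for height, weight and survey wave.
# The covariate and wave coefficients were not published; they cancel in
# group contrasts and alpha-age inversions, which is what these sets are for.

.ref_table <- list(
  women_education = list(sex = "female", factor = "education",
    intercept = -0.100, age = -0.013, age2 = -4e-4, group = 0.106,
    group_age = 0, group_age2 = -1e-4,
    se = c(intercept = 0.081, age = 0.000, age2 = 0.000, group = 0.007,
           group_age2 = 0.000),
    varcomp = c(intercept = 0.031, slope = 1e-4, residual = 0.023),
    aic = -6145.3, loglik = 3088.7),
  women_occupation = list(sex = "female", factor = "occupation",
    intercept = -0.074, age = -0.014, age2 = -3e-4, group = 0.099,
    group_age = 0, group_age2 = -2e-4,
    se = c(intercept = 0.077, age = 0.000, age2 = 0.000, group = 0.007,
           group_age2 = 0.000),
    varcomp = c(intercept = 0.031, slope = 7e-5, residual = 0.023),
    aic = -6823.3, loglik = 3427.6),
  women_region = list(sex = "female", factor = "region",
    intercept = -0.182, age = -0.014, age2 = -4e-4, group = 0.031,
    group_age = 0, group_age2 = 2e-5,
    se = c(intercept = 0.078, age = 0.000, age2 = 0.000, group = 0.007,
           group_age2 = 0.000),
    varcomp = c(intercept = 0.032, slope = 7e-5, residual = 0.023),
    aic = -6697.6, loglik = 3364.8),
  men_education = list(sex = "male", factor = "education",
    intercept = 0.143, age = -0.010, age2 = -4e-4, group = 0.131,
    group_age = -1e-4, group_age2 = 0,
    se = c(intercept = 0.091, age = 0.001, age2 = 0.000, group = 0.007,
           group_age = 0.001),
    varcomp = c(intercept = 0.032, slope = 1e-4, residual = 0.025),
    aic = -4620.1, loglik = 2326.1),
  men_occupation = list(sex = "male", factor = "occupation",
    intercept = 0.052, age = -0.010, age2 = -4e-4, group = 0.105,
    group_age = -2e-3, group_age2 = 0,
    se = c(intercept = 0.089, age = 0.001, age2 = 0.000, group = 0.007,
           group_age = 0.001),
    varcomp = c(intercept = 0.033, slope = 1e-4, residual = 0.025),
    aic = -4733.4, loglik = 2382.7),
  men_region = list(sex = "male", factor = "region",
    intercept = -0.073, age = -0.012, age2 = -4e-4, group = 0.025,
    group_age = -8e-4, group_age2 = 0,
    se = c(intercept = 0.091, age = 0.001, age2 = 0.000, group = 0.007,
           group_age = 0.001),
    varcomp = c(intercept = 0.035, slope = 1e-4, residual = 0.025),
    aic = -4504.1, loglik = 2268.0)
)

#' Published ELSA walking-speed growth models
#'
#' Coefficient-backed `"growth_fit"` objects for the six published
#' single-factor growth-curve models of walking speed in English older adults
#' (women and men by education, occupation and regional wealth; age centred at
#' 70 years). Height, weight and wave coefficients were not published and are
#' stored as 0; they cancel in the group contrasts, speed gaps and alpha-ages
#' these sets are intended for, so [predict()] output is only meaningful in
#' differences, not in absolute level.
#'
#' @return A named list of six `"growth_fit"` objects: `women_education`,
#'   `women_occupation`, `women_region`, `men_education`, `men_occupation`,
#'   `men_region`.
#' @examples
#' ref <- reference_models()
#' speed_gap(ref$women_education, age = 70)   # 0.106 m/s
#' alpha_age(ref$men_education, t = 60)
#' @export
reference_models <- function() {
  lapply(.ref_table, function(r) {
    se <- stats::setNames(rep(NA_real_, 9),
                          c("intercept", "age", "age2", "group", "group_age",
                            "group_age2", "height", "weight", "wave"))
    se[names(r$se)] <- r$se
    growth_model(intercept = r$intercept, age = r$age, age2 = r$age2,
                 group = r$group, group_age = r$group_age,
                 group_age2 = r$group_age2,
                 se = se, varcomp = r$varcomp,
                 sex = r$sex, group_factor = r$factor,
                 loglik = r$loglik, aic = r$aic)
  })
}
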