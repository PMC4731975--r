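# Synthetic ELSA-like cohort generator.
#
# The generating model is the sex-specific quadratic growth curve used throughout
# the package: for person i at wave t, with centred age a = age - 70,
#   speed_ti = pi0_i + pi1_i * a + pi2_i * a^2 + beta_wave * wave + e_ti
#   pi0_i = b0 + b_group*g_i + b_height*h_i + b_weight*w_i + r0_i
#   pi1_i = b_age  + b_group_age  * g_i + r1_i     (slope form, used for men)
#   pi2_i = b_age2 + b_group_age2 * g_i            (acceleration form, women)
# r0, r1 are person-level normal random effects, e_ti is iid normal residual.

#' Fixed effects of the generating growth curve
#'
#' Container for the population-level ("true") coefficients used by
#' [simulate_cohort()]. Units: m/s for the intercept and group main effect;
#' m/s per year (age, group x age), per year squared (age2, group x age2),
#' per wave, per metre and per kilogram for the covariate coefficients.
#' At most one of `group_age` and `group_age2` may be non-zero: the two
#' sex-specific model forms put the subpopulation interaction either on the
#' linear age slope (men) or on the age-squared acceleration (women).
#'
#' @param intercept Speed at centred age 0 for the reference group with
#'   height, weight and wave at 0 (m/s).
#' @param age Linear age slope (m/s per year of centred age).
#' @param age2 Age-squared (acceleration) coefficient.
#' @param wave Secular wave drift per survey round.
#' @param group Group main effect at centred age 0.
#' @param group_age Group x age interaction (slope form; default 0).
#' @param group_age2 Group x age-squared interaction (acceleration form;
#'   default 0).
#' @param height,weight Coefficients of person-level mean height (m) and
#'   weight (kg).
#' @return A named list of class `"true_fixed"`.
#' @export
true_fixed <- function(intercept, age, age2 = 0, wave = 0, group = 0,
                       group_age = 0, group_age2 = 0, height = 0, weight = 0) {
  if (group_age != 0 && group_age2 != 0)
    stop("at most one of 'group_age' and 'group_age2' may be non-zero ",
         "(slope form vs acceleration form)")
  out <- list(intercept = intercept, age = age, age2 = age2, wave = wave,
              group = group, group_age = group_age, group_age2 = group_age2,
              height = height, weight = weight)
  for (nm in names(out))
    if (!is.numeric(out[[nm]]) || length(out[[nm]]) != 1L || is.na(out[[nm]]))
      stop("'", nm, "' must be a single finite number")
  structure(out, class = "true_fixed")
}

#' Variance components of the generating growth curve
#'
#' @param intercept Variance of the person-level intercept deviation r0
#'   ((m/s)^2).
#' @param slope Variance of the person-level age-slope deviation r1.
#' @param cov Covariance of r0 and r1 (default 0; the published tables report
#'   no covariance term).
#' @param residual Residual variance sigma^2.
#' @return A named list of class `"true_variance"`.
#' @export
true_variance <- function(intercept = 0.031, slope = 1e-4, cov = 0,
                          residual = 0.023) {
  if (intercept < 0 || slope < 0 || residual < 0)
    stop("variances must be non-negative")
  if (cov^2 > intercept * slope + 1e-15)
    stop("random-effect covariance matrix is not positive semi-definite")
  structure(list(intercept = intercept, slope = slope, cov = cov,
                 residual = residual), class = "true_variance")
}

.default_fixed <- function() {
  list(
    # women's (acceleration) form; printed education-model estimates, with the
    # unprinted covariate/wave coefficients chosen to match the published
    # per-wave sample level (mean speed ~0.85-0.88 m/s, rising across waves)
    female = true_fixed(intercept = -0.100, age = -0.013, age2 = -4e-4,
                        wave = 0.005, group = 0.106, group_age2 = -1e-4,
                        height = 0.5, weight = 0.0015),
    # men's (slope) form
    male = true_fixed(intercept = 0.143, age = -0.010, age2 = -4e-4,
                      wave = 0.005, group = 0.131, group_age = -1e-4,
                      height = 0.35, weight = 0.0015)
  )
}

.default_variance <- function() {
  list(female = true_variance(0.031, 1e-4, 0, 0.023),
       male = true_variance(0.032, 1e-4, 0, 0.025))
}

#' Simulation configuration
#'
#' All generating parameters for [simulate_cohort()]. Defaults emulate the
#' English Longitudinal Study of Ageing: six biennial waves (2002-2012),
#' baseline sample aged 50+, refreshment samples entering at waves 3, 4 and 6,
#' nurse-measured anthropometrics at waves 2, 4 and 6 only, two timed 2.4 m
#' walks per person aged 60+, and per-wave attrition.
#'
#' @param n_baseline Number of wave-1 entrants.
#' @param refreshment Named integer vector of new entrants per refreshment
#'   wave, e.g. `c("3" = 400, "4" = 300, "6" = 300)`.
#' @param n_waves Number of waves (default 6).
#' @param wave_years Calendar year of each wave.
#' @param prop_female Probability that an entrant is female.
#' @param fixed,variance Lists with elements `female` and `male`: the
#'   generating [true_fixed()] and [true_variance()] sets.
#' @param latent_group Which binary indicator drives the generating group
#'   terms: `"education"`, `"occupation"` or `"region"`.
#' @param prevalence List with elements `education`, `occupation`, `region`;
#'   each a single probability or a vector of probabilities named by entry
#'   wave (baseline plus refreshment waves).
#' @param baseline_age Named vector `c(mean, sd, min, max)` of the truncated
#'   normal from which integer entry ages are drawn.
#' @param height,weight Lists with `female`/`male` elements `c(mean, sd)`,
#'   in metres and kilograms.
#' @param attrition Per-wave dropout probability (missing completely at
#'   random when `attrition_or_low_education` is 1).
#' @param attrition_or_low_education Odds ratio on the dropout probability for
#'   lower-educated persons (sensitivity knob; default 1 = MCAR).
#' @param contamination Named rates of injected implausible values:
#'   `speed_below_floor`, `height_low`, `weight_low` (per person), `age_error`,
#'   `missing_walk` (per record), `missing_group` (per person).
#' @param trial_jitter_sd SD of the per-trial speed jitter (m/s) from which
#'   the two recorded walk times are derived.
#' @param min_latent_speed Latent mean speeds below this floor (m/s) are
#'   treated as an incomplete walk test (trials recorded missing, logged).
#' @param measure_sd Named vector: measurement SD of nurse height (m) and
#'   weight (kg).
#' @param seed Optional integer seed stored with the configuration.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_baseline = 2000,
                       refreshment = c("3" = 400, "4" = 300, "6" = 300),
                       n_waves = 6,
                       wave_years = seq(2002, by = 2, length.out = n_waves),
                       prop_female = 0.55,
                       fixed = .default_fixed(),
                       variance = .default_variance(),
                       latent_group = c("education", "occupation", "region"),
                       prevalence = list(education = c("1" = 0.40, "3" = 0.52,
                                                       "4" = 0.55, "6" = 0.65),
                                         occupation = 0.52,
                                         region = 0.50),
                       baseline_age = c(mean = 62, sd = 10.5, min = 50, max = 89),
                       height = list(female = c(1.61, 0.07), male = c(1.74, 0.07)),
                       weight = list(female = c(72, 13), male = c(82, 13)),
                       attrition = 0.2,
                       attrition_or_low_education = 1,
                       contamination = c(speed_below_floor = 0, height_low = 0,
                                         weight_low = 0, age_error = 0,
                                         missing_walk = 0, missing_group = 0),
                       trial_jitter_sd = 0.02,
                       min_latent_speed = 0.05,
                       measure_sd = c(height = 0.004, weight = 0.5),
                       seed = NULL) {
  latent_group <- match.arg(latent_group)
  cfg <- list(n_baseline = n_baseline, refreshment = refreshment,
              n_waves = n_waves, wave_years = wave_years,
              prop_female = prop_female, fixed = fixed, variance = variance,
              latent_group = latent_group, prevalence = prevalence,
              baseline_age = baseline_age, height = height, weight = weight,
              attrition = attrition,
              attrition_or_low_education = attrition_or_low_education,
              contamination = .fill_contamination(contamination),
              trial_jitter_sd = trial_jitter_sd,
              min_latent_speed = min_latent_speed,
              measure_sd = measure_sd, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.contamination_types <- c("speed_below_floor", "height_low", "weight_low",
                          "age_error", "missing_walk", "missing_group")

.fill_contamination <- function(x) {
  out <- stats::setNames(numeric(length(.contamination_types)),
                         .contamination_types)
  if (length(x)) {
    if (is.null(names(x)) || !all(names(x) %in% .contamination_types))
      stop("contamination names must be among: ",
           paste(.contamination_types, collapse = ", "))
    out[names(x)] <- x
  }
  out
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, nm) {
    if (length(x) == 0) return(invisible())
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
        any(x != round(x)))
      stop("'", nm, "' must be a non-negative integer count")
  }
  chk_prob <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop("'", nm, "' must be a probability in [0, 1]")
  }
  chk_count(cfg$n_baseline, "n_baseline")
  chk_count(cfg$refreshment, "refreshment")
  if (!is.numeric(cfg$n_waves) || cfg$n_waves < 1)
    stop("'n_waves' must be >= 1")
  if (length(cfg$wave_years) != cfg$n_waves)
    stop("'wave_years' must have one entry per wave")
  if (length(cfg$refreshment)) {
    rw <- as.integer(names(cfg$refreshment))
    if (any(is.na(rw)) || any(rw < 2) || any(rw > cfg$n_waves))
      stop("'refreshment' must be named by waves in 2..n_waves")
  }
  chk_prob(cfg$prop_female, "prop_female")
  chk_prob(cfg$attrition, "attrition")
  for (nm in names(cfg$prevalence)) chk_prob(cfg$prevalence[[nm]],
                                             paste0("prevalence$", nm))
  chk_prob(cfg$contamination, "contamination")
  for (sx in c("female", "male")) {
    if (!inherits(cfg$fixed[[sx]], "true_fixed"))
      stop("fixed$", sx, " must be a true_fixed() object")
    if (!inherits(cfg$variance[[sx]], "true_variance"))
      stop("variance$", sx, " must be a true_variance() object")
  }
  ba <- cfg$baseline_age
  if (!all(c("mean", "sd", "min", "max") %in% names(ba)) ||
      ba["min"] < 0 || ba["max"] < ba["min"] || ba["sd"] < 0)
    stop("'baseline_age' must supply mean, sd >= 0 and min <= max")
  if (cfg$trial_jitter_sd < 0) stop("'trial_jitter_sd' must be >= 0")
  if (cfg$min_latent_speed <= 0) stop("'min_latent_speed' must be > 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  waves:", x$n_waves, "(", paste(range(x$wave_years), collapse = "-"),
      ")  baseline n:", x$n_baseline, "\n")
  if (length(x$refreshment))
    cat("  refreshment:", paste(sprintf("wave %s: %d", names(x$refreshment),
                                        x$refreshment), collapse = ", "), "\n")
  cat("  latent group factor:", x$latent_group,
      " attrition/wave:", x$attrition, "\n")
  ct <- x$contamination[x$contamination > 0]
  cat("  contamination:", if (length(ct))
    paste(names(ct), ct, sep = "=", collapse = ", ") else "none", "\n")
  invisible(x)
}

# integer ages from a truncated normal
.draw_entry_age <- function(n, ba) {
  lo <- stats::pnorm(ba["min"] - 0.5, ba["mean"], ba["sd"])
  hi <- stats::pnorm(ba["max"] + 0.5, ba["mean"], ba["sd"])
  a <- stats::qnorm(stats::runif(n, lo, hi), ba["mean"], ba["sd"])
  pmin(pmax(round(a), ba["min"]), ba["max"])
}

.nurse_waves <- c(2L, 4L, 6L)

#' Generate a synthetic person-wave cohort
#'
#' Draws a raw person-wave panel whose latent walking-speed structure follows
#' the configured growth-curve model exactly, then injects implausible values
#' at the configured contamination rates. Each injected defect is applied to a
#' record (or person, for anthropometrics and group flags) not already failing
#' an earlier cleaning rule, and at most one defect is applied per record, so
#' the generation log's expected exclusion counts are exact ground truth for
#' the preprocessing ledger.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; overrides `config$seed`. The same seed and
#'   configuration always yield an identical cohort.
#' @return A data frame of raw person-wave records (columns `person_id`,
#'   `wave`, `survey_year`, `birth_year`, `self_reported_age`, `sex`,
#'   `education_high`, `occupation_nonmanual`, `region_wealthy`, `height_m`,
#'   `weight_kg`, `walk1_s`, `walk2_s`, `sample_weight`) with the generation
#'   log attached as attribute `"generation_log"` (see [generation_log()]).
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)

  entry_waves <- c(1L, as.integer(names(config$refreshment)))
  entry_n <- c(config$n_baseline, unname(config$refreshment))
  n <- sum(entry_n)
  entry <- rep(entry_waves, entry_n)

  prev_at_entry <- function(p) {
    if (length(p) == 1L) return(rep(unname(p), length(entry_waves)))
    if (!is.null(names(p))) {
      idx <- match(as.character(entry_waves), names(p))
      if (anyNA(idx))
        stop("prevalence vector lacks entries for entry wave(s) ",
             paste(entry_waves[is.na(idx)], collapse = ", "))
      return(unname(p[idx]))
    }
    if (length(p) == length(entry_waves)) return(p)
    stop("prevalence vectors must have length 1, be named by entry wave, ",
         "or have one entry per entry wave")
  }
  ew_idx <- match(entry, entry_waves)

  persons <- data.frame(
    person_id = sprintf("p%05d", seq_len(n)),
    entry = entry,
    sex = ifelse(stats::runif(n) < config$prop_female, "female", "male"),
    stringsAsFactors = FALSE
  )
  persons$age0 <- .draw_entry_age(n, config$baseline_age)
  persons$birth_year <- config$wave_years[persons$entry] - persons$age0
  persons$education_high <-
    as.integer(stats::runif(n) < prev_at_entry(config$prevalence$education)[ew_idx])
  persons$occupation_nonmanual <-
    as.integer(stats::runif(n) < prev_at_entry(config$prevalence$occupation)[ew_idx])
  persons$region_wealthy <-
    as.integer(stats::runif(n) < prev_at_entry(config$prevalence$region)[ew_idx])

  persons$height <- NA_real_
  persons$weight <- NA_real_
  persons$r0 <- NA_real_
  persons$r1 <- NA_real_
  for (sx in c("female", "male")) {
    sel <- persons$sex == sx
    if (!any(sel)) next
    persons$height[sel] <- stats::rnorm(sum(sel), config$height[[sx]][1],
                                        config$height[[sx]][2])
    persons$weight[sel] <- stats::rnorm(sum(sel), config$weight[[sx]][1],
                                        config$weight[[sx]][2])
    vc <- config$variance[[sx]]
    S <- matrix(c(vc$intercept, vc$cov, vc$cov, vc$slope), 2)
    ev <- eigen(S, symmetric = TRUE)
    A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
    z <- matrix(stats::rnorm(2 * sum(sel)), ncol = 2) %*% A
    persons$r0[sel] <- z[, 1]
    persons$r1[sel] <- z[, 2]
  }

  # retention: consecutive waves from entry; optional education-dependent knob
  p_drop <- config$attrition
  if (config$attrition_or_low_education != 1) {
    odds <- p_drop / (1 - p_drop) *
      ifelse(persons$education_high == 1, 1, config$attrition_or_low_education)
    p_drop_i <- odds / (1 + odds)
  } else p_drop_i <- rep(p_drop, n)
  max_extra <- config$n_waves - persons$entry
  extra <- ifelse(max_extra > 0,
                  pmin(stats::rgeom(n, pmin(pmax(p_drop_i, 1e-12), 1)), max_extra),
                  0L)
  persons$n_obs <- 1L + extra

  id_row <- rep(seq_len(n), persons$n_obs)
  wave <- unlist(lapply(seq_len(n),
                        function(i) seq(persons$entry[i],
                                        length.out = persons$n_obs[i])),
                 use.names = FALSE)
  d <- data.frame(
    person_id = persons$person_id[id_row],
    wave = as.integer(wave),
    survey_year = as.integer(config$wave_years[wave]),
    birth_year = as.integer(persons$birth_year[id_row]),
    stringsAsFactors = FALSE
  )
  d$self_reported_age <- d$survey_year - d$birth_year
  d$sex <- persons$sex[id_row]
  d$education_high <- persons$education_high[id_row]
  d$occupation_nonmanual <- persons$occupation_nonmanual[id_row]
  d$region_wealthy <- persons$region_wealthy[id_row]

  # nurse anthropometrics at waves 2, 4, 6 only
  nurse <- d$wave %in% .nurse_waves
  d$height_m <- ifelse(nurse, persons$height[id_row] +
                         stats::rnorm(nrow(d), 0, config$measure_sd["height"]),
                       NA_real_)
  d$weight_kg <- ifelse(nurse, persons$weight[id_row] +
                          stats::rnorm(nrow(d), 0, config$measure_sd["weight"]),
                        NA_real_)

  # latent walking speed and the two timed walks (age 60+ only)
  age <- d$survey_year - d$birth_year
  a <- age - 70
  g <- d[[paste0(c(education = "education_high",
                   occupation = "occupation_nonmanual",
                   region = "region_wealthy")[config$latent_group])]]
  fx <- config$fixed
  sx <- d$sex
  pick <- function(fld) ifelse(sx == "female",
                               fx$female[[fld]], fx$male[[fld]])
  vr <- ifelse(sx == "female", config$variance$female$residual,
               config$variance$male$residual)
  mu <- pick("intercept") + pick("group") * g +
    pick("height") * persons$height[id_row] +
    pick("weight") * persons$weight[id_row] +
    persons$r0[id_row] +
    (pick("age") + pick("group_age") * g + persons$r1[id_row]) * a +
    (pick("age2") + pick("group_age2") * g) * a^2 +
    pick("wave") * d$wave
  latent <- mu + stats::rnorm(nrow(d), 0, sqrt(vr))

  eligible <- age >= 60
  incapable <- eligible & latent < config$min_latent_speed
  has_walk <- eligible & !incapable
  jitter_resampled <- 0L
  trial_speed <- function() {
    if (config$trial_jitter_sd == 0) return(latent)
    s <- latent + stats::rnorm(nrow(d), 0, config$trial_jitter_sd)
    bad <- has_walk & s <= 0.01
    while (any(bad)) {
      jitter_resampled <<- jitter_resampled + sum(bad)
      s[bad] <- latent[bad] + stats::rnorm(sum(bad), 0, config$trial_jitter_sd)
      bad <- has_walk & s <= 0.01
    }
    s
  }
  s1 <- trial_speed(); s2 <- trial_speed()
  d$walk1_s <- ifelse(has_walk, 2.4 / s1, NA_real_)
  d$walk2_s <- ifelse(has_walk, 2.4 / s2, NA_real_)

  # sampling weights: inverse retention propensity, normalised to mean 1 per wave
  p_stay <- 1 - p_drop_i[id_row]
  d$sample_weight <- 1 / pmax(p_stay^(d$wave - persons$entry[id_row]), 1e-8)
  for (w in unique(d$wave)) {
    sel <- d$wave == w
    d$sample_weight[sel] <- d$sample_weight[sel] / mean(d$sample_weight[sel])
  }

  cont <- .inject_contamination(d, config, has_walk)
  d <- cont$data

  log <- c(list(n_persons = n, n_rows = nrow(d),
                walk_incapable = sum(incapable),
                jitter_resampled = jitter_resampled),
           cont[c("injected", "eligible")])
  log$expected_exclusions <- .expected_exclusions(d)
  log$expected_kept <- nrow(d) - sum(log$expected_exclusions)
  attr(d, "generation_log") <- log
  class(d) <- c("walk_cohort", "data.frame")
  d
}

# inject at most one defect per record/person, only into records that would
# otherwise be kept, so injected counts map one-to-one onto exclusion counts
.inject_contamination <- function(d, config, has_walk) {
  rates <- config$contamination
  obs_speed <- rowMeans(cbind(2.4 / d$walk1_s, 2.4 / d$walk2_s))
  age <- d$survey_year - d$birth_year
  mean_h <- stats::ave(ifelse(!is.na(d$height_m) & d$height_m >= 1.29,
                              d$height_m, NA_real_), d$person_id,
                       FUN = function(x) mean(x, na.rm = TRUE))
  mean_w <- stats::ave(ifelse(!is.na(d$weight_kg) & d$weight_kg >= 29,
                              d$weight_kg, NA_real_), d$person_id,
                       FUN = function(x) mean(x, na.rm = TRUE))
  kept <- has_walk & !is.na(obs_speed) & obs_speed >= 0.09 &
    age >= 60 & age <= 89 & is.finite(mean_h) & is.finite(mean_w)

  injected <- stats::setNames(integer(length(.contamination_types)),
                              .contamination_types)
  eligible <- injected
  used_person <- character(0)

  draw_persons <- function(pool, rate) {
    pool <- setdiff(pool, used_person)
    k <- stats::rbinom(1, length(pool), rate)
    if (k > 0) sample(pool, k) else character(0)
  }
  person_pool <- unique(d$person_id[kept])

  # person-level: all nurse-wave heights (weights) made implausible
  ph <- draw_persons(person_pool, rates["height_low"])
  used_person <- c(used_person, ph)
  if (length(ph)) {
    sel <- d$person_id %in% ph & !is.na(d$height_m)
    d$height_m[sel] <- stats::runif(sum(sel), 1.00, 1.28)
  }
  pw <- draw_persons(person_pool, rates["weight_low"])
  used_person <- c(used_person, pw)
  if (length(pw)) {
    sel <- d$person_id %in% pw & !is.na(d$weight_kg)
    d$weight_kg[sel] <- stats::runif(sum(sel), 20, 28.5)
  }
  pg <- draw_persons(person_pool, rates["missing_group"])
  used_person <- c(used_person, pg)
  if (length(pg)) {
    flag <- sample(c("education_high", "occupation_nonmanual",
                     "region_wealthy"), length(pg), replace = TRUE)
    for (j in seq_along(pg))
      d[[flag[j]]][d$person_id == pg[j]] <- NA_integer_
  }
  injected["height_low"] <- length(ph)
  injected["weight_low"] <- length(pw)
  injected["missing_group"] <- length(pg)
  eligible["height_low"] <- eligible["weight_low"] <-
    eligible["missing_group"] <- length(person_pool)

  # record-level, drawn from rows still clean after person-level injections
  row_pool <- which(kept & !(d$person_id %in% used_person))
  draw_rows <- function(rate) {
    k <- stats::rbinom(1, length(row_pool), rate)
    rows <- if (k > 0) sample(row_pool, k) else integer(0)
    row_pool <<- setdiff(row_pool, rows)
    rows
  }
  n_row_pool <- length(row_pool)
  rs <- draw_rows(rates["speed_below_floor"])
  if (length(rs)) {
    slow <- stats::runif(length(rs), 0.02, 0.085)
    d$walk1_s[rs] <- 2.4 / slow
    d$walk2_s[rs] <- 2.4 / slow
  }
  rm_ <- draw_rows(rates["missing_walk"])
  if (length(rm_)) {
    d$walk1_s[rm_] <- NA_real_
    d$walk2_s[rm_] <- NA_real_
  }
  ra <- draw_rows(rates["age_error"])
  if (length(ra))
    d$self_reported_age[ra] <- d$self_reported_age[ra] +
      sample(c(-5:-3, 3:5), length(ra), replace = TRUE)
  injected["speed_below_floor"] <- length(rs)
  injected["missing_walk"] <- length(rm_)
  injected["age_error"] <- length(ra)
  eligible["speed_below_floor"] <- eligible["missing_walk"] <-
    eligible["age_error"] <- n_row_pool

  list(data = d, injected = injected, eligible = eligible)
}

# generator-side accounting of what the cleaning rules will exclude,
# first-failing-rule attribution in the fixed order
.expected_exclusions <- function(d) {
  rules <- c("no_walk_test", "speed_below_floor", "missing_birth_year",
             "age_out_of_range", "age_inconsistent", "missing_height",
             "missing_weight", "missing_group")
  obs_speed <- rowMeans(cbind(2.4 / d$walk1_s, 2.4 / d$walk2_s))
  age <- d$survey_year - d$birth_year
  mean_h <- stats::ave(ifelse(!is.na(d$height_m) & d$height_m >= 1.29,
                              d$height_m, NA_real_), d$person_id,
                       FUN = function(x) mean(x, na.rm = TRUE))
  mean_w <- stats::ave(ifelse(!is.na(d$weight_kg) & d$weight_kg >= 29,
                              d$weight_kg, NA_real_), d$person_id,
                       FUN = function(x) mean(x, na.rm = TRUE))
  fail <- cbind(
    no_walk_test = is.na(d$walk1_s) | is.na(d$walk2_s),
    speed_below_floor = !is.na(obs_speed) & obs_speed < 0.09,
    missing_birth_year = is.na(d$birth_year),
    age_out_of_range = !is.na(age) & (age < 60 | age > 89),
    age_inconsistent = !is.na(age) &
      abs(d$self_reported_age - age) > 2,
    missing_height = !is.finite(mean_h),
    missing_weight = !is.finite(mean_w),
    missing_group = is.na(d$education_high) | is.na(d$occupation_nonmanual) |
      is.na(d$region_wealthy)
  )
  first <- apply(fail, 1, function(z) if (any(z)) which(z)[1] else 0L)
  stats::setNames(tabulate(first, nbins = length(rules)), rules)
}

#' Retrieve the generation log of a synthetic cohort
#'
#' @param cohort A data frame returned by [simulate_cohort()].
#' @return A list with person/record counts, injected-contamination counts per
#'   rule, eligible pool sizes, and the generator's own expected exclusion
#'   counts per cleaning rule (ground truth for [exclusion_log()]).
#' @export
generation_log <- function(cohort) {
  log <- attr(cohort, "generation_log")
  if (is.null(log)) stop("no generation log attached; not a simulated cohort?")
  log
}

#' @export
print.walk_cohort <- function(x, ...) {
  cat("Synthetic person-wave cohort:", nrow(x), "records,",
      length(unique(x$person_id)), "persons, waves",
      paste(range(x$wave), collapse = "-"), "\n")
  log <- attr(x, "generation_log")
  if (!is.null(log)) {
    inj <- log$injected[log$injected > 0]
    cat("  injected contamination:", if (length(inj))
      paste(names(inj), inj, sep = "=", collapse = ", ") else "none", "\n")
  }
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("  ... (", nrow(x) - 6, " more records)\n", sep = "")
  invisible(x)
}

.cohort_columns <- c("person_id", "wave", "survey_year", "birth_year",
                     "self_reported_age", "sex", "education_high",
                     "occupation_nonmanual", "region_wealthy", "height_m",
                     "weight_kg", "walk1_s", "walk2_s", "sample_weight")
.cohort_numeric <- c("height_m", "weight_kg", "walk1_s", "walk2_s",
                     "sample_weight")
.cohort_integer <- c("wave", "survey_year", "birth_year", "self_reported_age",
                     "education_high", "occupation_nonmanual", "region_wealthy")

#' Write / read a cohort file
#'
#' Delimited-text (CSV) serialisation of raw person-wave records. Numeric
#' columns are written with 17 significant digits so that
#' `read_cohort(write_cohort(x))` reproduces `x` exactly; missing values are
#' empty fields.
#'
#' @param cohort Data frame with exactly the raw cohort columns.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  miss <- setdiff(.cohort_columns, names(cohort))
  if (length(miss)) stop("missing cohort columns: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(cohort), .cohort_columns)
  if (length(extra)) stop("unknown cohort columns: ",
                          paste(extra, collapse = ", "))
  out <- cohort[, .cohort_columns]
  for (nm in .cohort_numeric) {
    v <- out[[nm]]
    out[[nm]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  miss <- setdiff(.cohort_columns, names(d))
  if (length(miss)) stop("missing cohort columns: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(d), .cohort_columns)
  if (length(extra)) stop("unknown cohort columns: ",
                          paste(extra, collapse = ", "))
  d <- d[, .cohort_columns]
  to_na <- function(v) ifelse(v == "", NA, v)
  for (nm in .cohort_integer) d[[nm]] <- as.integer(to_na(d[[nm]]))
  for (nm in .cohort_numeric) d[[nm]] <- as.numeric(to_na(d[[nm]]))
  d$person_id <- as.character(d$person_id)
  d$sex <- as.character(d$sex)
  class(d) <- c("walk_cohort", "data.frame")
  d
}
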