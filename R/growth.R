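# Sex-specific growth-curve models for walking speed.
#
# Population model (centred age a = age - 70):
#   speed_ti = b0 + b_g*g_i + b_h*height_i + b_w*weight_i + r0_i
#              + (b_a + b_ga*g_i + r1_i) * a_ti
#              + (b_a2 + b_ga2*g_i) * a_ti^2
#              + b_wave * wave_ti + e_ti
# with the subpopulation interaction on the age slope (b_ga, men's form) or on
# the acceleration (b_ga2, women's form). Estimation is maximum likelihood
# (not REML) so nested fixed-effect models are comparable by likelihood-ratio
# tests; descriptive sampling weights are deliberately not used in the fits.

.group_vars <- c(education = "education_high", occupation = "occupation_nonmanual",
                 region = "region_wealthy")
.group_labels <- c(education = "higher education",
                   occupation = "higher occupation",
                   region = "wealthier region")

# canonical coefficient names <-> model-matrix terms for a given spec
.term_map <- function(spec) {
  terms <- c("(Intercept)" = "intercept", age_c = "age")
  if (spec$quadratic) terms["I(age_c^2)"] <- "age2"
  factors <- if (spec$group == "all") names(.group_vars) else spec$group
  for (f in factors) {
    v <- .group_vars[[f]]
    terms[v] <- if (spec$group == "all") paste0("group_", f) else "group"
  }
  if (spec$include_interaction && spec$form != "none") {
    for (f in factors) {
      v <- .group_vars[[f]]
      cn <- if (spec$group == "all") paste0("_", f) else ""
      if (spec$form == "slope")
        terms[paste0("age_c:", v)] <- paste0("group_age", cn)
      else
        terms[paste0("I(age_c^2):", v)] <- paste0("group_age2", cn)
    }
  }
  terms <- c(terms, mean_height = "height", mean_weight = "weight",
             wave = "wave")
  terms
}

#' Fit a walking-speed growth-curve model
#'
#' Fits the quadratic growth curve with person-level random intercept and age
#' slope by maximum likelihood (via \code{lme4::lmer}, \code{REML = FALSE}).
#' The subpopulation interaction enters on the age-squared term for women
#' ("acceleration" form) and on the linear age term for men ("slope" form);
#' `form = "auto"` selects by sex. Sampling weights are not used.
#'
#' @param panel A `"walk_panel"` (or plain data frame with the panel columns).
#' @param sex `"female"` or `"male"`; the panel is restricted to this sex.
#' @param group Group factor: `"education"`, `"occupation"`, `"region"`, or
#'   `"all"` (all three mains plus all three interactions).
#' @param form `"auto"`, `"acceleration"` (group x age^2), `"slope"`
#'   (group x age), or `"none"` (no interaction).
#' @param quadratic Include the age-squared fixed effect (default `TRUE`).
#' @param include_interaction Include the group-by-age interaction (default
#'   `TRUE`; ignored when `form = "none"`).
#' @param include_group Include the group main effect(s) (default `TRUE`).
#' @param random `"diagonal"` (independent random intercept and slope; the
#'   default, matching published variance tables that report no covariance) or
#'   `"unstructured"`.
#' @param keep_fit Keep the underlying `merMod` object (default `TRUE`).
#' @return An object of class `"growth_fit"`: canonical fixed-effect estimates
#'   and standard errors (`intercept`, `age`, `age2`, `group`, `group_age` or
#'   `group_age2`, `height`, `weight`, `wave`), variance components
#'   (`intercept`, `slope`, `cov`, `residual`), `loglik`, `aic`, `df`,
#'   `n_obs`, `n_persons`, and `converged`/`boundary` flags. Methods:
#'   `print`, `summary`, `coef`, `predict`, `logLik`, `residuals`, `simulate`,
#'   `plot`.
#' @seealso [growth_model()] to build the same object from known
#'   coefficients, [lrt_growth()], [select_growth_model()], [alpha_age()].
#' @export
fit_growth <- function(panel, sex = c("female", "male"),
                       group = c("education", "occupation", "region", "all"),
                       form = c("auto", "acceleration", "slope", "none"),
                       quadratic = TRUE, include_interaction = TRUE,
                       include_group = TRUE,
                       random = c("diagonal", "unstructured"),
                       keep_fit = TRUE) {
  sex <- match.arg(sex)
  group <- match.arg(group)
  form <- match.arg(form)
  random <- match.arg(random)
  if (form == "auto") form <- if (sex == "female") "acceleration" else "slope"
  if (form == "acceleration" && !quadratic)
    stop("acceleration form requires the quadratic age term")
  spec <- list(sex = sex, group = group, form = form, quadratic = quadratic,
               include_interaction = include_interaction && include_group,
               include_group = include_group, random = random)
  if (!include_group) spec$form <- "none"

  d <- as.data.frame(panel)
  d <- d[d$sex == sex, , drop = FALSE]
  if (!nrow(d)) stop("no observations for sex '", sex, "'")
  need <- c("speed", "age_c", "wave", "mean_height", "mean_weight",
            "person_id",
            if (spec$include_group) {
              unname(.group_vars[if (group == "all") names(.group_vars)
                                 else group])
            })
  missing_cov <- vapply(need, function(v) anyNA(d[[v]]), logical(1))
  if (any(missing_cov))
    stop("missing values in: ", paste(need[missing_cov], collapse = ", "),
         " (the panel must be complete-case)")

  tm <- .term_map(spec)
  if (!spec$include_group) tm <- tm[!grepl("group", tm)]
  rhs <- setdiff(names(tm), "(Intercept)")
  re <- if (random == "diagonal") "(1 + age_c || person_id)"
        else "(1 + age_c | person_id)"
  fml <- stats::as.formula(paste("speed ~", paste(c(rhs, re), collapse = " + ")))

  msgs <- character(0)
  slope_dropped <- FALSE
  # nobs-vs-levels checks relaxed so degenerate designs (e.g. one observation
  # per person) reach the variance boundary instead of erroring out
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  run_lmer <- function(f) withCallingHandlers(
    lme4::lmer(f, data = d, REML = FALSE, control = ctrl),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  fit <- tryCatch(run_lmer(fml), error = function(e) {
    if (!grepl("number of observations.*number of random effects",
               conditionMessage(e)))
      stop(e)
    # random slope inestimable (e.g. everyone observed once): refit with a
    # random intercept only and report the slope variance at its boundary 0
    slope_dropped <<- TRUE
    msgs <<- c(msgs, "random slope inestimable; variance fixed at boundary 0")
    run_lmer(stats::as.formula(paste("speed ~",
                                     paste(c(rhs, "(1 | person_id)"),
                                           collapse = " + "))))
  })

  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  canon <- unname(tm[names(fe)])
  if (anyNA(canon)) stop("internal: unmapped model terms")
  beta <- stats::setNames(as.numeric(fe), canon)
  beta_se <- stats::setNames(as.numeric(se), canon)

  vc <- as.data.frame(lme4::VarCorr(fit))
  pick_vc <- function(v1, v2 = NA) {
    sel <- !is.na(vc$var1) & vc$var1 == v1 &
      (if (is.na(v2)) is.na(vc$var2) else !is.na(vc$var2) & vc$var2 == v2)
    if (any(sel)) vc$vcov[sel][1] else 0
  }
  varcomp <- c(intercept = pick_vc("(Intercept)"),
               slope = pick_vc("age_c"),
               cov = if (random == "unstructured")
                 pick_vc("(Intercept)", "age_c") else 0,
               residual = vc$vcov[vc$grp == "Residual"][1])

  boundary <- lme4::isSingular(fit) || slope_dropped
  conv_ok <- !any(grepl("failed to converge|convergence code",
                        msgs, ignore.case = TRUE)) &&
    is.null(fit@optinfo$conv$lme4$code)
  if (boundary)
    msgs <- c(msgs, "variance component at boundary (reported as 0)")

  ll <- stats::logLik(fit)
  obj <- structure(list(
    spec = spec,
    coefficients = beta, se = beta_se, varcomp = varcomp,
    loglik = as.numeric(ll), df = attr(ll, "df"), aic = stats::AIC(fit),
    n_obs = nrow(d), n_persons = length(unique(d$person_id)),
    converged = conv_ok, boundary = boundary, messages = msgs,
    cov_means = c(height = mean(d$mean_height), weight = mean(d$mean_weight),
                  wave = mean(d$wave)),
    fitted = TRUE, fit = if (keep_fit) fit,
    call = match.call()), class = "growth_fit")
  if (!conv_ok)
    warning("growth model did not converge cleanly: ",
            paste(unique(msgs), collapse = "; "))
  if (boundary && !any(grepl("boundary", msgs[-length(msgs)])))
    warning("random-effect variance at boundary; reported as 0")
  obj
}

#' Construct a growth model from known coefficients
#'
#' Builds a `"growth_fit"` object directly from fixed-effect values (for
#' instance published estimates), so that [predict()], [speed_gap()] and
#' [alpha_age()] can be used without refitting. Coefficients not supplied are
#' 0. Exactly one of `group_age` / `group_age2` may be non-zero.
#'
#' @param intercept,age,age2,wave,group,group_age,group_age2,height,weight
#'   Fixed effects on the canonical scale (m/s, per year, per year^2, ...).
#' @param se Optional named vector of standard errors (canonical names).
#' @param varcomp Optional named vector `c(intercept, slope, cov, residual)`.
#' @param sex `"female"` or `"male"`.
#' @param group_factor `"education"`, `"occupation"` or `"region"`.
#' @param loglik,aic,n_obs,n_persons Optional fit statistics.
#' @return A `"growth_fit"` with `fitted = FALSE`.
#' @export
growth_model <- function(intercept, age, age2 = 0, wave = 0, group = 0,
                         group_age = 0, group_age2 = 0, height = 0, weight = 0,
                         se = NULL, varcomp = NULL,
                         sex = c("female", "male"),
                         group_factor = c("education", "occupation", "region"),
                         loglik = NA_real_, aic = NA_real_,
                         n_obs = NA_integer_, n_persons = NA_integer_) {
  sex <- match.arg(sex)
  group_factor <- match.arg(group_factor)
  if (group_age != 0 && group_age2 != 0)
    stop("at most one of 'group_age' and 'group_age2' may be non-zero")
  form <- if (group_age2 != 0) "acceleration"
          else if (group_age != 0) "slope" else "none"
  beta <- c(intercept = intercept, age = age, age2 = age2, group = group,
            group_age = group_age, group_age2 = group_age2,
            height = height, weight = weight, wave = wave)
  if (!is.null(varcomp)) {
    full <- c(intercept = 0, slope = 0, cov = 0, residual = 0)
    full[names(varcomp)] <- varcomp
    varcomp <- full
  }
  structure(list(
    spec = list(sex = sex, group = group_factor, form = form,
                quadratic = age2 != 0 || group_age2 != 0, include_group = TRUE,
                include_interaction = form != "none", random = "diagonal"),
    coefficients = beta,
    se = if (!is.null(se)) se else stats::setNames(rep(NA_real_, length(beta)),
                                                   names(beta)),
    varcomp = varcomp, loglik = loglik, df = NA_integer_, aic = aic,
    n_obs = n_obs, n_persons = n_persons,
    converged = TRUE, boundary = FALSE, messages = character(0),
    cov_means = c(height = 0, weight = 0, wave = 0),
    fitted = FALSE, fit = NULL, call = match.call()), class = "growth_fit")
}

.beta0 <- function(object, nm) {
  b <- object$coefficients
  if (nm %in% names(b)) unname(b[[nm]]) else 0
}

#' Population-average predicted walking speed
#'
#' Fixed-effects-only prediction (random effects at zero). Either supply
#' `newdata` (columns `group`, `age`, and optionally `height`, `weight`,
#' `wave`, which default to 0) or the individual vector arguments.
#'
#' @param object A `"growth_fit"`.
#' @param newdata Optional data frame.
#' @param group 0/1 subpopulation indicator (for `group = "all"` models,
#'   `newdata` must instead carry `education`, `occupation`, `region` columns).
#' @param age Chronological age in years.
#' @param height,weight,wave Shared covariates (default 0).
#' @param force Allow ages outside the supported range `[50, 110]`.
#' @param ... Unused.
#' @return Numeric vector of speeds (m/s).
#' @export
predict.growth_fit <- function(object, newdata = NULL, group = 0, age = 70,
                               height = 0, weight = 0, wave = 0,
                               force = FALSE, ...) {
  if (!is.null(newdata)) {
    age <- newdata$age
    if (is.null(age)) stop("'newdata' must contain an 'age' column")
    gcols <- intersect(names(.group_vars), names(newdata))
    if (object$spec$group == "all") {
      if (length(gcols) < 3)
        stop("'newdata' must contain education, occupation and region columns")
    } else {
      group <- if (!is.null(newdata$group)) newdata$group
               else if (object$spec$group %in% gcols)
                 newdata[[object$spec$group]]
               else 0
    }
    height <- if (!is.null(newdata$height)) newdata$height else 0
    weight <- if (!is.null(newdata$weight)) newdata$weight else 0
    wave <- if (!is.null(newdata$wave)) newdata$wave else 0
  }
  if (!force && any(age < 50 | age > 110, na.rm = TRUE))
    stop("age outside the supported range [50, 110]; use force = TRUE ",
         "to extrapolate")
  a <- age - 70
  out <- .beta0(object, "intercept") + .beta0(object, "height") * height +
    .beta0(object, "weight") * weight + .beta0(object, "wave") * wave
  if (object$spec$group == "all") {
    slope <- .beta0(object, "age")
    curv <- .beta0(object, "age2")
    for (f in names(.group_vars)) {
      gf <- newdata[[f]]
      out <- out + .beta0(object, paste0("group_", f)) * gf
      slope <- slope + .beta0(object, paste0("group_age_", f)) * gf
      curv <- curv + .beta0(object, paste0("group_age2_", f)) * gf
    }
    out + slope * a + curv * a^2
  } else {
    out + .beta0(object, "group") * group +
      (.beta0(object, "age") + .beta0(object, "group_age") * group) * a +
      (.beta0(object, "age2") + .beta0(object, "group_age2") * group) * a^2
  }
}

#' @rdname predict.growth_fit
#' @param model A `"growth_fit"`.
#' @export
predict_speed <- function(model, group = 0, age = 70, height = 0, weight = 0,
                          wave = 0, force = FALSE) {
  predict(model, group = group, age = age, height = height, weight = weight,
          wave = wave, force = force)
}

#' Model-implied speed gap between subpopulations
#'
#' Difference in population-average walking speed, comparison minus reference
#' group, at identical covariates (which therefore cancel).
#'
#' @param model A single-factor `"growth_fit"`.
#' @param age Age(s) in years.
#' @param reference,comparison Group codes (default 0 vs 1).
#' @return Numeric vector (m/s).
#' @export
speed_gap <- function(model, age, reference = 0, comparison = 1) {
  predict(model, group = comparison, age = age) -
    predict(model, group = reference, age = age)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
logLik.growth_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' @export
residuals.growth_fit <- function(object, ...) {
  if (!object$fitted || is.null(object$fit))
    stop("residuals are only available for models fitted to data ",
         "with keep_fit = TRUE")
  stats::residuals(object$fit, ...)
}

#' Simulate walking-speed observations from a growth model
#'
#' Draws person-level random effects and observation residuals from the
#' model's variance components and adds them to the fixed-effect trajectory.
#'
#' @param object A `"growth_fit"` with variance components.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param newdata Data frame with `person_id`, `age`, `group` (and optionally
#'   `height`, `weight`, `wave`) describing the design to simulate on;
#'   defaults to the fitting data for fitted models.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated speeds.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL,
                                newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) {
    if (!object$fitted || is.null(object$fit))
      stop("'newdata' is required for coefficient-only models")
    return(stats::simulate(object$fit, nsim = nsim))
  }
  if (is.null(object$varcomp)) stop("model carries no variance components")
  mu <- predict(object, newdata = newdata)
  ids <- factor(newdata$person_id)
  vc <- object$varcomp
  a <- newdata$age - 70
  out <- replicate(nsim, {
    r0 <- stats::rnorm(nlevels(ids), 0, sqrt(vc["intercept"]))
    r1 <- stats::rnorm(nlevels(ids), 0, sqrt(vc["slope"]))
    mu + r0[ids] + r1[ids] * a + stats::rnorm(length(mu), 0, sqrt(vc["residual"]))
  })
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

.coef_label <- function(nm, factor) {
  lab <- .group_labels
  base <- c(intercept = "Intercept", age = "Age", age2 = "Age^2",
            height = "Height", weight = "Weight", wave = "Wave")
  if (nm %in% names(base)) return(base[[nm]])
  if (nm == "group") return(lab[[factor]])
  if (nm == "group_age") return(paste("Age x", lab[[factor]]))
  if (nm == "group_age2") return(paste("Age^2 x", lab[[factor]]))
  for (f in names(lab)) {
    if (nm == paste0("group_", f)) return(lab[[f]])
    if (nm == paste0("group_age_", f)) return(paste("Age x", lab[[f]]))
    if (nm == paste0("group_age2_", f)) return(paste("Age^2 x", lab[[f]]))
  }
  nm
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat("Walking-speed growth-curve model (", x$spec$sex, ", ",
      if (x$spec$group == "all") "all three factors" else x$spec$group,
      if (x$fitted) ", ML fit" else ", from supplied coefficients",
      ")\n\n", sep = "")
  cat("Fixed Effects\n")
  est <- formatC(x$coefficients, digits = digits, format = "fg")
  se <- ifelse(is.na(x$se), "",
               paste0(" (", formatC(x$se, digits = 2, format = "fg"), ")"))
  labs <- vapply(names(x$coefficients), .coef_label, "",
                 factor = if (x$spec$group == "all") NULL else x$spec$group)
  for (i in seq_along(est))
    cat(sprintf("  %-28s %s%s\n", labs[i], est[i], se[i]))
  if (!is.null(x$varcomp)) {
    cat("Random Variance\n")
    vlabs <- c(intercept = "Intercept", slope = "Linear Slope",
               cov = "Covariance", residual = "Residual")
    for (nm in names(x$varcomp)) {
      if (nm == "cov" && x$varcomp[["cov"]] == 0 &&
          x$spec$random == "diagonal") next
      cat(sprintf("  %-28s %s (%s)\n", vlabs[[nm]],
                  formatC(x$varcomp[[nm]], digits = digits, format = "fg"),
                  formatC(sqrt(max(x$varcomp[[nm]], 0)), digits = 2,
                          format = "fg")))
    }
  }
  if (!is.na(x$aic)) cat("AIC:", formatC(x$aic, format = "f", digits = 1), " ")
  if (!is.na(x$loglik))
    cat("logLik:", formatC(x$loglik, format = "f", digits = 1))
  cat("\n")
  if (!is.na(x$n_obs))
    cat("n =", x$n_obs, "observations,", x$n_persons, "persons\n")
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  if (x$boundary) cat("Note: variance component(s) at boundary\n")
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  print(object, ...)
  if (length(object$messages)) {
    cat("\nFit messages:\n")
    for (m in unique(object$messages)) cat("  -", m, "\n")
  }
  invisible(object)
}

#' @export
plot.growth_fit <- function(x, ages = 60:89, covariates = NULL, ...) {
  if (is.null(covariates)) covariates <- x$cov_means
  p0 <- predict(x, group = 0, age = ages, height = covariates["height"],
                weight = covariates["weight"], wave = covariates["wave"])
  p1 <- predict(x, group = 1, age = ages, height = covariates["height"],
                weight = covariates["weight"], wave = covariates["wave"])
  lab <- if (x$spec$group == "all") "combined" else
    .group_labels[[x$spec$group]]
  graphics::matplot(ages, cbind(p0, p1), type = "l", lty = c(2, 1),
                    col = c("grey40", "black"), xlab = "age (years)",
                    ylab = "walking speed (m/s)",
                    main = paste0("Fitted trajectories (", x$spec$sex, ")"),
                    ...)
  graphics::legend("topright", legend = c(paste("not", lab), lab),
                   lty = c(2, 1), col = c("grey40", "black"), bty = "n")
  invisible(x)
}

#' Likelihood-ratio test between nested growth models
#'
#' @param nested,full Two `"growth_fit"` objects fitted by ML to the same
#'   observations, with the nested model's fixed terms a subset of the full
#'   model's.
#' @return A list of class `"growth_lrt"`: `statistic` (2 x log-likelihood
#'   difference), `df` (parameter-count difference) and `p_value` (upper-tail
#'   chi-square).
#' @export
lrt_growth <- function(nested, full) {
  stopifnot(inherits(nested, "growth_fit"), inherits(full, "growth_fit"))
  if (is.na(nested$loglik) || is.na(full$loglik))
    stop("both models need log-likelihoods (fit them to data)")
  if (!identical(nested$n_obs, full$n_obs))
    stop("models were fitted to different numbers of observations (",
         nested$n_obs, " vs ", full$n_obs, ")")
  if (!all(names(nested$coefficients) %in% names(full$coefficients)))
    stop("models are not nested: nested-model terms ",
         paste(setdiff(names(nested$coefficients),
                       names(full$coefficients)), collapse = ", "),
         " are absent from the full model")
  df <- full$df - nested$df
  if (df < 0) stop("models are not nested: full model has fewer parameters")
  stat <- 2 * (full$loglik - nested$loglik)
  if (stat < 0 && stat > -1e-6) stat <- 0
  p <- if (df == 0) as.numeric(stat <= 0)
       else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 loglik_nested = nested$loglik, loglik_full = full$loglik),
            class = "growth_lrt")
}

#' @export
print.growth_lrt <- function(x, ...) {
  cat("Likelihood-ratio test: chisq =",
      formatC(x$statistic, digits = 4, format = "g"),
      " df =", x$df, " p =", formatC(x$p_value, digits = 4, format = "g"),
      "\n")
  invisible(x)
}

#' Stepwise likelihood-ratio model building
#'
#' Reproduces the model-building narrative for one sex and group factor:
#' (1) linear base model (age, wave, height, weight; random intercept and
#' slope); (2) add the age-squared acceleration if its likelihood-ratio test
#' is significant; (3) add the group main effect; (4) test the group x age
#' (slope) and group x age^2 (acceleration) interactions and retain the
#' significant form — if both are significant, the one with the higher
#' log-likelihood.
#'
#' @param panel A `"walk_panel"`.
#' @param sex,group As in [fit_growth()] (single factor only).
#' @param alpha Significance level for each LRT (default 0.05).
#' @return A list of class `"growth_selection"`: `fit` (the final
#'   `"growth_fit"`), `form` (chosen interaction form or `"none"`),
#'   `quadratic`, and `trail` (a data frame logging every decision).
#' @export
select_growth_model <- function(panel, sex, group = "education",
                                alpha = 0.05) {
  trail <- data.frame(step = character(0), statistic = numeric(0),
                      df = integer(0), p_value = numeric(0),
                      decision = character(0), stringsAsFactors = FALSE)
  note <- function(step, lrt, decision) {
    trail[nrow(trail) + 1L, ] <<- list(step, lrt$statistic, lrt$df,
                                       lrt$p_value, decision)
  }
  base_lin <- fit_growth(panel, sex, group, form = "none", quadratic = FALSE,
                         include_group = FALSE, keep_fit = FALSE)
  base_quad <- fit_growth(panel, sex, group, form = "none", quadratic = TRUE,
                          include_group = FALSE, keep_fit = FALSE)
  t_quad <- lrt_growth(base_lin, base_quad)
  quadratic <- t_quad$p_value < alpha
  note("age^2", t_quad, if (quadratic) "keep" else "drop")

  m_group <- fit_growth(panel, sex, group, form = "none",
                        quadratic = quadratic, keep_fit = FALSE)
  trail[nrow(trail) + 1L, ] <- list("group main effect", NA, NA, NA, "add")

  m_slope <- fit_growth(panel, sex, group, form = "slope",
                        quadratic = quadratic, keep_fit = FALSE)
  t_slope <- lrt_growth(m_group, m_slope)
  note("group x age", t_slope,
       if (t_slope$p_value < alpha) "significant" else "not significant")

  t_acc <- NULL
  if (quadratic) {
    m_acc <- fit_growth(panel, sex, group, form = "acceleration",
                        quadratic = TRUE, keep_fit = FALSE)
    t_acc <- lrt_growth(m_group, m_acc)
    note("group x age^2", t_acc,
         if (t_acc$p_value < alpha) "significant" else "not significant")
  }

  sig_slope <- t_slope$p_value < alpha
  sig_acc <- !is.null(t_acc) && t_acc$p_value < alpha
  form <- if (sig_slope && sig_acc) {
    if (m_acc$loglik >= m_slope$loglik) "acceleration" else "slope"
  } else if (sig_acc) "acceleration"
    else if (sig_slope) "slope"
    else "none"
  trail[nrow(trail) + 1L, ] <- list("retained form", NA, NA, NA, form)

  final <- fit_growth(panel, sex, group, form = form, quadratic = quadratic,
                      include_interaction = form != "none")
  structure(list(fit = final, form = form, quadratic = quadratic,
                 trail = trail, alpha = alpha),
            class = "growth_selection")
}

#' @export
print.growth_selection <- function(x, ...) {
  cat("Stepwise growth-model selection (alpha =", x$alpha, ")\n")
  print(x$trail, row.names = FALSE)
  cat("\nFinal model:\n")
  print(x$fit)
  invisible(x)
}

#' Write / read a fitted growth model as JSON
#'
#' @param model A `"growth_fit"`.
#' @param path JSON file path.
#' @return `write_growth_model()` returns `path` invisibly;
#'   `read_growth_model()` returns a coefficient-backed `"growth_fit"`.
#' @export
write_growth_model <- function(model, path) {
  stopifnot(inherits(model, "growth_fit"))
  out <- model[c("spec", "coefficients", "se", "varcomp", "loglik", "aic",
                 "df", "n_obs", "n_persons", "converged", "boundary",
                 "cov_means")]
  # named vectors as JSON objects, so names survive the round trip
  for (nm in c("coefficients", "se", "varcomp", "cov_means"))
    if (!is.null(out[[nm]])) out[[nm]] <- as.list(out[[nm]])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_growth_model
#' @export
read_growth_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  null2na <- function(v, proto = NA_real_) if (is.null(v)) proto else v
  structure(list(
    spec = x$spec,
    coefficients = unlist(x$coefficients),
    se = unlist(x$se),
    varcomp = if (!is.null(x$varcomp)) unlist(x$varcomp),
    loglik = null2na(x$loglik), df = null2na(x$df), aic = null2na(x$aic),
    n_obs = null2na(x$n_obs), n_persons = null2na(x$n_persons),
    converged = isTRUE(x$converged), boundary = isTRUE(x$boundary),
    messages = character(0),
    cov_means = unlist(x$cov_means),
    fitted = FALSE, fit = NULL, call = NULL), class = "growth_fit")
}
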