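# Characteristic-based alpha-ages.
#
# The alpha-age alpha_{k,t} is the chronological age at which the comparison
# subpopulation attains the same walking speed k that the reference
# subpopulation has at age t. With quadratic fixed-effect trajectories and
# shared covariates (height, weight, wave) held equal across groups — so their
# terms cancel — the inversion is the closed-form root of
#   (b_age2 + b_ga2*g_c) a^2 + (b_age + b_ga*g_c) a + b_group*g_c = k*
# in centred age a, where k* is the reference group's trajectory value at t
# net of the shared terms.

# walking-speed trajectory net of shared covariate terms, centred age a
.traj <- function(model, a, g) {
  .beta0(model, "group") * g +
    (.beta0(model, "age") + .beta0(model, "group_age") * g) * a +
    (.beta0(model, "age2") + .beta0(model, "group_age2") * g) * a^2
}

#' Alpha-age: the comparison group's age at the reference group's speed
#'
#' Computes the chronological age at which the `comparison` subpopulation
#' walks as fast as the `reference` subpopulation does at age `t`, from the
#' fixed-effect trajectories of a single-factor growth model. Shared
#' covariates are held equal across the groups and cancel. The quadratic is
#' solved in closed form; among real roots mapped into the supported age range
#' the one on the age-decreasing branch of the comparison parabola is kept
#' (and of two such, the one nearer `t`).
#'
#' @param model A single-factor `"growth_fit"`.
#' @param t Reference age in years (within `support`).
#' @param reference,comparison Group codes, default 0 vs 1.
#' @param support Age interval treated as physically meaningful, default
#'   `c(50, 110)`; roots outside it are rejected.
#' @return An object of class `"alpha_age"`: `reference_age`, `alpha`,
#'   `matched_speed` (the trajectory value being matched, net of shared
#'   covariates), `gap_years` (`alpha - t`), `gap_speed_at_t` (comparison
#'   minus reference speed at `t`), and `root_diagnostics` (discriminant, all
#'   candidate roots, branch policy).
#' @examples
#' m <- reference_models()$women_education
#' alpha_age(m, 60)   # about 10 years of walking-age advantage
#' @export
alpha_age <- function(model, t, reference = 0, comparison = 1,
                      support = c(50, 110)) {
  stopifnot(inherits(model, "growth_fit"))
  if (isFALSE(model$converged))
    stop("refusing to invert a non-converged model")
  if (model$spec$group == "all")
    stop("alpha-ages are defined for single-factor models")
  if (t < support[1] || t > support[2])
    stop("reference age t must lie in [", support[1], ", ", support[2], "]")

  at <- t - 70
  k <- .traj(model, at, reference)
  gap_t <- .traj(model, at, comparison) - k

  same_traj <- comparison == reference ||
    (.beta0(model, "group") == 0 && .beta0(model, "group_age") == 0 &&
       .beta0(model, "group_age2") == 0)
  if (same_traj) {
    # identical trajectories: alpha is t exactly
    return(structure(list(reference_age = t, alpha = t, matched_speed = k,
                          gap_years = 0, gap_speed_at_t = gap_t,
                          root_diagnostics = list(identity = TRUE)),
                     class = "alpha_age"))
  }

  c2 <- .beta0(model, "age2") + .beta0(model, "group_age2") * comparison
  c1 <- .beta0(model, "age") + .beta0(model, "group_age") * comparison
  c0 <- .beta0(model, "group") * comparison - k

  diag <- list(identity = FALSE, c2 = c2, c1 = c1, c0 = c0)
  if (abs(c2) < 1e-12) {
    if (abs(c1) < 1e-12)
      stop("comparison trajectory is constant; speed never attained")
    roots <- -c0 / c1
    on_branch <- c1 < 0     # decreasing line
    diag$discriminant <- NA_real_
  } else {
    disc <- c1^2 - 4 * c2 * c0
    diag$discriminant <- disc
    if (disc < 0)
      stop("speed ", format(k), " is never attained by the comparison group ",
           "(negative discriminant)")
    roots <- (-c1 + c(1, -1) * sqrt(disc)) / (2 * c2)
    vertex <- -c1 / (2 * c2)
    on_branch <- if (c2 < 0) roots >= vertex - 1e-9 else roots <= vertex + 1e-9
  }
  diag$roots_age <- roots + 70
  cand <- roots[on_branch]
  cand <- cand[cand + 70 >= support[1] & cand + 70 <= support[2]]
  if (!length(cand))
    stop("all roots fall outside the supported age range [", support[1], ", ",
         support[2], "] (out of support)")
  a_star <- cand[which.min(abs(cand - at))]
  diag$chosen_age <- a_star + 70
  diag$n_candidates <- length(cand)

  structure(list(reference_age = t, alpha = a_star + 70,
                 matched_speed = k, gap_years = a_star + 70 - t,
                 gap_speed_at_t = gap_t, root_diagnostics = diag),
            class = "alpha_age")
}

#' @export
print.alpha_age <- function(x, ...) {
  cat(sprintf(
    "alpha-age: reference age %.1f -> alpha %.1f (gap %+.1f years, speed gap at t %+.3f m/s)\n",
    x$reference_age, x$alpha, x$gap_years, x$gap_speed_at_t))
  invisible(x)
}

# round half away from zero, matching the published table's presentation
.round_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Alpha-age table across reference ages and models
#'
#' Applies [alpha_age()] over a grid of reference ages for several fitted
#' models (one per sex-by-factor combination). Failed cells (speed not
#' attained, or out of the age support) are kept as `NA` with the error
#' recorded, never dropped silently.
#'
#' @param models Named list of single-factor `"growth_fit"` objects; names
#'   become columns.
#' @param ages Reference ages (default 60 to 85 by 5).
#' @param ... Passed to [alpha_age()].
#' @return A data frame of class `"alpha_age_table"`, first column `age`, one
#'   column of alpha-ages per model (full precision; the print method rounds
#'   to one decimal, half away from zero). Attributes: `"results"` (the
#'   `alpha_age` objects or error messages per cell).
#' @export
alpha_age_table <- function(models, ages = seq(60, 85, by = 5), ...) {
  stopifnot(is.list(models), length(models) > 0)
  if (is.null(names(models)) || any(names(models) == ""))
    stop("'models' must be a fully named list")
  out <- data.frame(age = ages)
  results <- list()
  for (nm in names(models)) {
    col <- rep(NA_real_, length(ages))
    res <- vector("list", length(ages))
    for (i in seq_along(ages)) {
      r <- tryCatch(alpha_age(models[[nm]], ages[i], ...),
                    error = function(e) conditionMessage(e))
      res[[i]] <- r
      if (inherits(r, "alpha_age")) col[i] <- r$alpha
    }
    out[[nm]] <- col
    results[[nm]] <- res
  }
  attr(out, "results") <- results
  class(out) <- c("alpha_age_table", "data.frame")
  out
}

#' @export
print.alpha_age_table <- function(x, ...) {
  cat("Alpha-ages by reference age (years)\n")
  disp <- as.data.frame(x)
  for (nm in names(disp)[-1])
    disp[[nm]] <- ifelse(is.na(disp[[nm]]), "--",
                         sprintf("%.1f", .round_away(disp[[nm]], 1)))
  print(disp, row.names = FALSE)
  res <- attr(x, "results")
  errs <- unlist(lapply(names(res), function(nm) {
    bad <- !vapply(res[[nm]], inherits, logical(1), "alpha_age")
    if (any(bad)) paste0(nm, " @ ", x$age[bad], ": ",
                         unlist(res[[nm]][bad]))
  }))
  if (length(errs)) {
    cat("Failed cells:\n")
    for (e in errs) cat("  ", e, "\n")
  }
  invisible(x)
}
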