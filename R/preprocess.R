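# Cleaning and derivation rules for raw person-wave cohorts.
#
# Rules, applied per record with first-failing-rule attribution, in this order:
#   1 no_walk_test        either timed walk missing
#   2 speed_below_floor   mean trial speed < 0.09 m/s (implausible, recoded missing)
#   3 missing_birth_year  age cannot be computed
#   4 age_out_of_range    computed age outside [60, 89]
#   5 age_inconsistent    |self-reported age - computed age| > 2 years
#   6 missing_height      person-level mean nurse height missing (< 1.29 m recoded)
#   7 missing_weight      person-level mean nurse weight missing (< 29 kg recoded)
#   8 missing_group       any of the three binary group indicators missing

.rule_order <- c("no_walk_test", "speed_below_floor", "missing_birth_year",
                 "age_out_of_range", "age_inconsistent", "missing_height",
                 "missing_weight", "missing_group")

#' Walking speed from two timed walks
#'
#' Mean of the two per-trial speeds over a fixed distance. Speeds below the
#' plausibility floor are recoded missing.
#'
#' @param walk1_s,walk2_s Trial times in seconds (`NA` allowed).
#' @param distance_m Walk distance, default 2.4 m (8 ft).
#' @param floor Plausibility floor in m/s; computed speeds below it become
#'   `NA` (default 0.09).
#' @param require_both If `TRUE` (default) both trials must be present;
#'   otherwise a single available trial is used.
#' @return Numeric vector of speeds in m/s, `NA` where unavailable.
#' @examples
#' derive_walk_speed(3, 2)       # mean(0.8, 1.2) = 1
#' derive_walk_speed(30, 30)     # 0.08 m/s -> NA (below floor)
#' @export
derive_walk_speed <- function(walk1_s, walk2_s, distance_m = 2.4,
                              floor = 0.09, require_both = TRUE) {
  if (any(c(walk1_s, walk2_s) <= 0, na.rm = TRUE))
    stop("walk times must be strictly positive")
  s1 <- distance_m / walk1_s
  s2 <- distance_m / walk2_s
  speed <- if (require_both) (s1 + s2) / 2
           else rowMeans(cbind(s1, s2), na.rm = TRUE)
  speed[is.nan(speed)] <- NA_real_
  speed[!is.na(speed) & speed < floor] <- NA_real_
  speed
}

#' Person-level mean anthropometrics
#'
#' Averages a person's nurse-wave height and weight measurements after
#' recoding implausible values (height < 1.29 m, weight < 29 kg) as missing.
#'
#' @param height_m,weight_kg Numeric vectors of one person's nurse-wave
#'   measurements.
#' @param min_height,min_weight Plausibility floors.
#' @return List with `mean_height` and `mean_weight` (either may be `NA`).
#' @examples
#' person_mean_anthro(c(1.20, 1.70), c(70, 71))  # 1.20 m dropped
#' @export
person_mean_anthro <- function(height_m, weight_kg,
                               min_height = 1.29, min_weight = 29) {
  h <- height_m[!is.na(height_m) & height_m >= min_height]
  w <- weight_kg[!is.na(weight_kg) & weight_kg >= min_weight]
  list(mean_height = if (length(h)) mean(h) else NA_real_,
       mean_weight = if (length(w)) mean(w) else NA_real_)
}

#' Age consistency between self-report and year of birth
#'
#' A record is kept when the self-assessed age and the age computed from
#' survey year and birth year differ by at most `max_diff` years (strictly
#' "more than two" is dropped, so a difference of exactly 2 is kept).
#'
#' @param self_reported_age,survey_year,birth_year Numeric vectors.
#' @param max_diff Tolerated absolute difference in years (default 2).
#' @return Logical vector: `TRUE` = keep. `NA` when the birth year is missing.
#' @export
age_consistent <- function(self_reported_age, survey_year, birth_year,
                           max_diff = 2) {
  computed <- survey_year - birth_year
  ifelse(is.na(birth_year) | is.na(survey_year), NA,
         abs(self_reported_age - computed) <= max_diff)
}

#' Build the analysis panel from a raw cohort
#'
#' Applies the full derivation and exclusion pipeline: walking speed as the
#' mean of two timed 2.4 m walks (plausibility floor 0.09 m/s), computed age
#' restricted to 60-89 and checked against the self-report, person-level mean
#' nurse height/weight with implausible values recoded missing, time-constant
#' group indicators, and age centred at 70 years. Every input record is either
#' kept or attributed to exactly one exclusion rule (first failing rule in the
#' fixed order), so the ledger is additive.
#'
#' @param raw Raw cohort data frame (see [write_cohort()] for the schema).
#' @param distance_m Walk distance in metres.
#' @param speed_floor Plausibility floor in m/s.
#' @param age_range Closed analysis age interval, default `c(60, 89)`.
#' @param max_age_diff Tolerated self-report/computed age difference.
#' @param require_both If `TRUE` (default) both walk trials are required.
#' @return A data frame of class `"walk_panel"` with columns `person_id`,
#'   `wave`, `age`, `age_c` (= age - 70), `speed`, `mean_height`,
#'   `mean_weight`, `sex`, `education_high`, `occupation_nonmanual`,
#'   `region_wealthy`, `sample_weight`; the exclusion ledger is attached as
#'   attribute `"exclusions"` (see [exclusion_log()]).
#' @export
build_panel <- function(raw, distance_m = 2.4, speed_floor = 0.09,
                        age_range = c(60, 89), max_age_diff = 2,
                        require_both = TRUE) {
  miss <- setdiff(.cohort_columns, names(raw))
  if (length(miss)) stop("missing cohort columns: ",
                         paste(miss, collapse = ", "))
  n_in <- nrow(raw)

  bad_time <- (!is.na(raw$walk1_s) & raw$walk1_s <= 0) |
    (!is.na(raw$walk2_s) & raw$walk2_s <= 0)
  if (any(bad_time)) {
    i <- which(bad_time)[1]
    stop("non-positive walk time for person ", raw$person_id[i],
         ", wave ", raw$wave[i])
  }

  s1 <- distance_m / raw$walk1_s
  s2 <- distance_m / raw$walk2_s
  speed_raw <- if (require_both) (s1 + s2) / 2
               else rowMeans(cbind(s1, s2), na.rm = TRUE)
  speed_raw[is.nan(speed_raw)] <- NA_real_

  age <- raw$survey_year - raw$birth_year

  # person-level mean anthropometrics (sub-floor values recoded first)
  h_ok <- ifelse(!is.na(raw$height_m) & raw$height_m >= 1.29,
                 raw$height_m, NA_real_)
  w_ok <- ifelse(!is.na(raw$weight_kg) & raw$weight_kg >= 29,
                 raw$weight_kg, NA_real_)
  nan2na <- function(x) ifelse(is.finite(x), x, NA_real_)
  mean_h <- nan2na(stats::ave(h_ok, raw$person_id,
                              FUN = function(x) mean(x, na.rm = TRUE)))
  mean_w <- nan2na(stats::ave(w_ok, raw$person_id,
                              FUN = function(x) mean(x, na.rm = TRUE)))

  # time-constant group flags: last observed (by wave) value wins
  resolve <- function(flag) {
    res <- vapply(split(seq_len(n_in), raw$person_id), function(idx) {
      v <- raw[[flag]][idx][order(raw$wave[idx])]
      v <- v[!is.na(v)]
      if (length(v)) v[length(v)] else NA_integer_
    }, integer(1))
    conflicts <- vapply(split(raw[[flag]], raw$person_id), function(v) {
      v <- unique(v[!is.na(v)]); length(v) > 1
    }, logical(1))
    list(value = res[raw$person_id], n_conflict = sum(conflicts))
  }
  edu <- resolve("education_high")
  occ <- resolve("occupation_nonmanual")
  reg <- resolve("region_wealthy")

  fail <- cbind(
    no_walk_test = if (require_both) is.na(raw$walk1_s) | is.na(raw$walk2_s)
                   else is.na(raw$walk1_s) & is.na(raw$walk2_s),
    speed_below_floor = !is.na(speed_raw) & speed_raw < speed_floor,
    missing_birth_year = is.na(raw$birth_year),
    age_out_of_range = !is.na(age) & (age < age_range[1] | age > age_range[2]),
    age_inconsistent = !is.na(age) &
      abs(raw$self_reported_age - age) > max_age_diff,
    missing_height = is.na(mean_h),
    missing_weight = is.na(mean_w),
    missing_group = is.na(edu$value) | is.na(occ$value) | is.na(reg$value)
  )
  first <- if (n_in) apply(fail, 1, function(z) if (any(z)) which(z)[1] else 0L)
           else integer(0)
  counts <- stats::setNames(tabulate(first, nbins = length(.rule_order)),
                            .rule_order)
  keep <- first == 0L

  panel <- data.frame(
    person_id = raw$person_id[keep],
    wave = raw$wave[keep],
    age = age[keep],
    age_c = age[keep] - 70,
    speed = speed_raw[keep],
    mean_height = mean_h[keep],
    mean_weight = mean_w[keep],
    sex = raw$sex[keep],
    education_high = edu$value[keep],
    occupation_nonmanual = occ$value[keep],
    region_wealthy = reg$value[keep],
    sample_weight = raw$sample_weight[keep],
    stringsAsFactors = FALSE
  )
  rownames(panel) <- NULL
  if (nrow(panel) == 0) warning("no records survive the exclusion rules")

  log <- list(input_rows = n_in, kept_rows = nrow(panel),
              counts = counts,
              group_conflicts = c(education = edu$n_conflict,
                                  occupation = occ$n_conflict,
                                  region = reg$n_conflict))
  stopifnot(log$input_rows == log$kept_rows + sum(log$counts))
  attr(panel, "exclusions") <- log
  class(panel) <- c("walk_panel", "data.frame")
  panel
}

#' Retrieve the exclusion ledger of a panel
#'
#' @param panel A `"walk_panel"` from [build_panel()].
#' @return List with `input_rows`, `kept_rows`, per-rule `counts`
#'   (first-failing-rule attribution; always
#'   `input_rows == kept_rows + sum(counts)`), and the number of persons whose
#'   group flags conflicted across waves.
#' @export
exclusion_log <- function(panel) {
  log <- attr(panel, "exclusions")
  if (is.null(log)) stop("no exclusion ledger attached; not a walk_panel?")
  log
}

#' @export
print.walk_panel <- function(x, ...) {
  cat("Analysis panel:", nrow(x), "observations,",
      length(unique(x$person_id)), "persons\n")
  log <- attr(x, "exclusions")
  if (!is.null(log)) {
    cat("  input rows:", log$input_rows, " kept:", log$kept_rows, "\n")
    ct <- log$counts[log$counts > 0]
    if (length(ct))
      cat("  excluded: ", paste(names(ct), ct, sep = "=", collapse = ", "),
          "\n", sep = "")
  }
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("  ... (", nrow(x) - 6, " more observations)\n", sep = "")
  invisible(x)
}

#' Write a panel and its exclusion ledger
#'
#' @param panel A `"walk_panel"`.
#' @param path CSV path for the panel.
#' @param log_path Optional JSON path for the exclusion ledger.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, log_path = NULL) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  if (!is.null(log_path)) {
    log <- attr(panel, "exclusions")
    jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
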