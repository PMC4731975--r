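test_that("walking speed is the mean of the two trial speeds with a floor", {
  expect_equal(derive_walk_speed(3.0, 2.0), 1.0)     # mean(0.8, 1.2)
  expect_equal(derive_walk_speed(2.4, 2.4), 1.0)
  expect_true(is.na(derive_walk_speed(30, 30)))      # 0.08 m/s, below floor
  expect_true(is.na(derive_walk_speed(NA, 2.0)))     # both trials required
  expect_equal(derive_walk_speed(NA, 2.4, require_both = FALSE), 1.0)
  expect_error(derive_walk_speed(-1, 2), "positive")
  expect_equal(derive_walk_speed(c(3, 2.4), c(2, 2.4)), c(1, 1))
})

test_that("person-level anthropometrics recode implausible values before averaging", {
  expect_equal(person_mean_anthro(c(1.70, 1.72), c(70, 72)),
               list(mean_height = 1.71, mean_weight = 71))
  expect_equal(person_mean_anthro(c(1.20, 1.70), 70)$mean_height, 1.70)
  expect_true(is.na(person_mean_anthro(1.7, c(28, 28))$mean_weight))
  expect_true(is.na(person_mean_anthro(NA_real_, NA_real_)$mean_height))
})

test_that("age consistency keeps differences of at most two years", {
  expect_true(age_consistent(70, 2002, 1932))
  expect_false(age_consistent(65, 2002, 1932))   # diff 5
  expect_true(age_consistent(68, 2002, 1932))    # diff exactly 2: kept
  expect_true(is.na(age_consistent(70, 2002, NA)))
})

test_that("exclusion ledger attributes each row to the first failing rule", {
  raw <- rbind(
    raw_row("a", 2, 2004, 1934, 70),                       # kept
    raw_row("b", 2, 2004, 1946, 58),                       # under 60: no walk
    raw_row("c", 2, 2004, 1913, 91),                       # over 89
    raw_row("d", 2, 2004, 1912, 92),                       # over 89
    raw_row("e", 2, 2004, 1934, 64),                       # inconsistent age
    raw_row("f", 2, 2004, 1934, 70, walk1_s = 30, walk2_s = 30), # below floor
    raw_row("g", 2, 2004, 1934, 70, height_m = 1.20),      # height recoded away
    raw_row("h", 2, 2004, 1934, 70, weight_kg = 25),       # weight recoded away
    raw_row("i", 2, 2004, 1934, 70, education_high = NA),  # group missing
    raw_row("j", 2, 2004, NA, 70)                          # no birth year
  )
  raw$walk1_s[raw$self_reported_age == 58] <- NA   # under-60: no trials taken
  raw$walk2_s[raw$self_reported_age == 58] <- NA
  panel <- build_panel(raw)
  log <- exclusion_log(panel)
  expect_equal(log$input_rows, 10)
  expect_equal(log$kept_rows, 1)
  expect_equal(log$counts[["no_walk_test"]], 1)
  expect_equal(log$counts[["speed_below_floor"]], 1)
  expect_equal(log$counts[["age_out_of_range"]], 2)
  expect_equal(log$counts[["age_inconsistent"]], 1)
  expect_equal(log$counts[["missing_height"]], 1)
  expect_equal(log$counts[["missing_weight"]], 1)
  expect_equal(log$counts[["missing_group"]], 1)
  expect_equal(log$counts[["missing_birth_year"]], 1)
  expect_equal(log$input_rows, log$kept_rows + sum(log$counts))
  # the kept row is fully derived
  expect_equal(panel$age, 70)
  expect_equal(panel$age_c, 0)
  expect_equal(panel$speed, 0.8)
})

test_that("an all-pass fixture is kept in full with zero exclusion counts", {
  raw <- do.call(rbind, lapply(1:6, function(i)
    raw_row(paste0("p", i), wave = 2L)))
  panel <- build_panel(raw)
  log <- exclusion_log(panel)
  expect_equal(log$kept_rows, 6)
  expect_true(all(log$counts == 0))
})

test_that("non-positive walk times are an error naming the record", {
  raw <- raw_row("weird", 3, 2006, 1936, 70, walk1_s = -2)
  expect_error(build_panel(raw), "weird.*wave 3")
})

test_that("exclusion counts equal the generator's injection accounting exactly", {
  cfg <- sim_config(n_baseline = 800, refreshment = c("3" = 150, "4" = 100,
                                                      "6" = 100),
                    contamination = c(speed_below_floor = 0.02,
                                      height_low = 0.01, weight_low = 0.01,
                                      age_error = 0.01, missing_walk = 0.06,
                                      missing_group = 0.01))
  coh <- simulate_cohort(cfg, seed = 23)
  log <- exclusion_log(build_panel(coh))
  gen <- generation_log(coh)
  expect_equal(log$counts[names(gen$expected_exclusions)],
               gen$expected_exclusions)
  expect_equal(log$kept_rows, gen$expected_kept)
  expect_equal(log$input_rows, log$kept_rows + sum(log$counts))
})

test_that("clean noise-free records aged 60-89 are kept in full", {
  # attrition 0 so every person reaches a nurse wave (otherwise wave-1-only
  # participants are legitimately excluded for missing anthropometrics)
  cfg <- noise_free_config(n_baseline = 300, attrition = 0)
  coh <- simulate_cohort(cfg, seed = 6)
  age <- coh$survey_year - coh$birth_year
  in_range <- sum(age >= 60 & age <= 89 & !is.na(coh$walk1_s))
  panel <- build_panel(coh)
  expect_equal(nrow(panel), in_range)
  log <- exclusion_log(panel)
  expect_equal(sum(log$counts[c("speed_below_floor", "age_inconsistent",
                                "missing_height", "missing_weight",
                                "missing_group")]), 0)
})

test_that("person-level means do not depend on record order", {
  cfg <- sim_config(n_baseline = 150, refreshment = c("3" = 30))
  coh <- as.data.frame(simulate_cohort(cfg, seed = 12))
  p1 <- build_panel(coh)
  set.seed(99)
  shuffled <- coh[sample(nrow(coh)), ]
  p2 <- build_panel(shuffled)
  key <- function(p) p[order(p$person_id, p$wave), ]
  expect_equal(key(as.data.frame(p1)), key(as.data.frame(p2)),
               ignore_attr = TRUE)
})

test_that("group flags are time-constant with the last observed value winning", {
  raw <- rbind(raw_row("a", 2, 2004, 1934, 70, education_high = 0L),
               raw_row("a", 4, 2008, 1934, 74, education_high = 1L),
               raw_row("a", 6, 2012, 1934, 78, education_high = NA))
  panel <- build_panel(raw)
  expect_true(all(panel$education_high == 1))
  expect_equal(exclusion_log(panel)$group_conflicts[["education"]], 1)
})
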