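make_panel <- function(...) {
  # minimal hand-built panel rows
  df <- data.frame(..., stringsAsFactors = FALSE)
  class(df) <- c("walk_panel", "data.frame")
  df
}

test_that("weighted descriptives reduce to unweighted ones under equal weights", {
  cfg <- sim_config(n_baseline = 200, refreshment = NULL)
  panel <- as.data.frame(build_panel(simulate_cohort(cfg, seed = 19)))
  panel$sample_weight <- 2.5
  desc <- descriptive_table(make_panel(panel))
  w1 <- panel[panel$wave == 1, ]
  expect_equal(desc[desc$variable == "walking speed", "wave 1"],
               mean(w1$speed))
  expect_equal(desc[desc$variable == "age", "wave 1"], mean(w1$age))
  expect_equal(desc[desc$variable == "females", "wave 1"],
               100 * mean(w1$sex == "female"))
  expect_equal(desc[desc$variable == "unweighted N", "wave 1"], nrow(w1))
  sds <- attr(desc, "sd")
  expect_equal(sds["walking speed", "wave 1"], sd(w1$speed))
})

test_that("weighted means follow the hand-computed example", {
  p <- make_panel(person_id = c("a", "b"), wave = 1L, age = c(65, 70),
                  age_c = c(-5, 0), speed = c(0.8, 1.0),
                  mean_height = 1.6, mean_weight = 70, sex = "female",
                  education_high = 1L, occupation_nonmanual = 0L,
                  region_wealthy = 1L, sample_weight = c(1, 3))
  desc <- descriptive_table(p)
  expect_equal(desc[desc$variable == "walking speed", "wave 1"], 0.95)
})

test_that("a wave with zero total weight is rejected by name", {
  p <- make_panel(person_id = c("a", "b"), wave = c(1L, 2L), age = 70,
                  age_c = 0, speed = 1, mean_height = 1.6, mean_weight = 70,
                  sex = "female", education_high = 1L,
                  occupation_nonmanual = 0L, region_wealthy = 1L,
                  sample_weight = c(1, 0))
  expect_error(descriptive_table(p), "wave 2")
})

test_that("weighted shares track the generating prevalences", {
  cfg <- sim_config(n_baseline = 3000, refreshment = NULL,
                    prevalence = list(education = 0.40, occupation = 0.52,
                                      region = 0.50))
  panel <- build_panel(simulate_cohort(cfg, seed = 29))
  desc <- descriptive_table(panel)
  n1 <- desc[desc$variable == "unweighted N", "wave 1"]
  tol <- 3 * 50 / sqrt(n1)   # 3 binomial SE in percentage points
  expect_lt(abs(desc[desc$variable == "higher educated", "wave 1"] - 40), tol)
  expect_lt(abs(desc[desc$variable == "non-manual occupation", "wave 1"] - 52),
            tol)
  expect_lt(abs(desc[desc$variable == "wealthier region", "wave 1"] - 50), tol)
})

test_that("noise-free trajectory summaries lie exactly on the generating quadratic", {
  fx <- list(female = true_fixed(intercept = 0.85, age = -0.013, age2 = -4e-4,
                                 wave = 0, group = 0.106, group_age2 = -1e-4),
             male = true_fixed(intercept = 0.95, age = -0.010, age2 = -4e-4,
                               wave = 0, group = 0.131, group_age = -1e-4))
  cfg <- noise_free_config(n_baseline = 500, refreshment = NULL, fixed = fx)
  panel <- build_panel(simulate_cohort(cfg, seed = 41))
  traj <- trajectory_summary(panel, "education", sex = "female",
                             bin_width = 1, min_n = 1)
  a <- traj$age_bin - 0.5 - 70   # integer ages, bin midpoint at +0.5
  g <- as.numeric(traj$group)
  truth <- 0.85 + 0.106 * g - 0.013 * a + (-4e-4 - 1e-4 * g) * a^2
  expect_equal(traj$mean_speed, truth, tolerance = 1e-12)
  # declining in age within every subgroup over the generated regime
  for (gr in unique(traj$group)) {
    tg <- traj[traj$group == gr, ]
    expect_true(all(diff(tg$mean_speed[order(tg$age_bin)]) < 0))
  }
})

test_that("sparse age bins are suppressed", {
  cfg <- sim_config(n_baseline = 150, refreshment = NULL)
  panel <- build_panel(simulate_cohort(cfg, seed = 43))
  traj <- trajectory_summary(panel, "education", bin_width = 5, min_n = 20)
  expect_true(all(traj$n >= 20))
})

test_that("the pipeline writes a complete, reproducible artifact bundle", {
  cfg <- sim_config(n_baseline = 300, refreshment = c("3" = 50),
                    contamination = c(missing_walk = 0.05))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res <- suppressWarnings(run_pipeline(cfg, out_dir = d1, seed = 7,
                                       verbose = FALSE))
  expect_s3_class(res$panel, "walk_panel")
  expect_length(res$models, 8)    # 2 sexes x 4 factor settings
  files <- c("cohort.csv", "panel.csv", "exclusions.json", "alpha_ages.csv",
             "descriptives.csv", "trajectories.csv", "manifest.json",
             "model_women_education.json", "model_men_all.txt")
  for (f in files) expect_true(file.exists(file.path(d1, f)), label = f)
  # manifest hashes match the files on disk
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE)
  for (f in names(man$files))
    expect_equal(unname(tools::md5sum(file.path(d1, f))), man$files[[f]],
                 label = f)
  # same seed: byte-identical tabular outputs
  suppressWarnings(run_pipeline(cfg, out_dir = d2, seed = 7, verbose = FALSE))
  for (f in c("cohort.csv", "panel.csv", "alpha_ages.csv", "descriptives.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("a missing cohort file fails before any computation", {
  expect_error(run_pipeline(out_dir = withr::local_tempdir(),
                            cohort_file = "/nonexistent/cohort.csv"),
               "not found")
})
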