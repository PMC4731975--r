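# Weighted descriptives, age-trajectory summaries, and the end-to-end pipeline.

.wmean <- function(x, w) sum(w * x) / sum(w)
# frequency-weight convention, weights normalised to mean 1 within the group
.wsd <- function(x, w) {
  w <- w / mean(w)
  m <- .wmean(x, w)
  sqrt(sum(w * (x - m)^2) / (sum(w) - 1))
}

#' Weighted descriptive overview by survey wave
#'
#' Sampling-weighted means (SD) of walking speed, age, height and weight and
#' weighted shares (%) of women, higher educated, non-manual occupation and
#' wealthier region, per wave, with the unweighted number of observations.
#' Weights are normalised to mean 1 within each wave; the SD uses the
#' frequency-weight convention.
#'
#' @param panel A `"walk_panel"`.
#' @return A data frame of class `"wave_descriptives"`: one row per variable,
#'   one column per wave. Means carry their SD in an attribute `"sd"`.
#' @export
descriptive_table <- function(panel) {
  d <- as.data.frame(panel)
  if (!nrow(d)) stop("empty panel")
  waves <- sort(unique(d$wave))
  mean_vars <- c(`walking speed` = "speed", age = "age",
                 height = "mean_height", weight = "mean_weight")
  share_vars <- c(females = "sex", `higher educated` = "education_high",
                  `non-manual occupation` = "occupation_nonmanual",
                  `wealthier region` = "region_wealthy")
  out <- matrix(NA_real_, nrow = length(mean_vars) + length(share_vars) + 1,
                ncol = length(waves),
                dimnames = list(c(names(mean_vars), names(share_vars),
                                  "unweighted N"),
                                paste("wave", waves)))
  sds <- matrix(NA_real_, nrow = length(mean_vars), ncol = length(waves),
                dimnames = list(names(mean_vars), paste("wave", waves)))
  for (j in seq_along(waves)) {
    dj <- d[d$wave == waves[j], ]
    w <- dj$sample_weight
    if (!sum(w) > 0) stop("zero total sampling weight in wave ", waves[j])
    w <- w / mean(w)
    for (i in seq_along(mean_vars)) {
      x <- dj[[mean_vars[i]]]
      out[i, j] <- .wmean(x, w)
      sds[i, j] <- .wsd(x, w)
    }
    for (i in seq_along(share_vars)) {
      v <- share_vars[i]
      x <- if (v == "sex") as.numeric(dj$sex == "female") else dj[[v]]
      out[length(mean_vars) + i, j] <- 100 * .wmean(x, w)
    }
    out[nrow(out), j] <- nrow(dj)
  }
  res <- as.data.frame(out)
  res <- cbind(variable = rownames(out), res)
  rownames(res) <- NULL
  attr(res, "sd") <- sds
  class(res) <- c("wave_descriptives", "data.frame")
  res
}

#' @export
print.wave_descriptives <- function(x, ...) {
  cat("Descriptive sample overview by survey wave (weighted)\n")
  disp <- as.data.frame(x)
  sds <- attr(x, "sd")
  for (j in 2:ncol(disp)) {
    v <- disp[[j]]
    txt <- ifelse(disp$variable == "unweighted N",
                  formatC(v, format = "d"),
                  formatC(v, format = "f", digits = 2))
    has_sd <- disp$variable %in% rownames(sds)
    txt[has_sd] <- paste0(txt[has_sd], " (",
                          formatC(sds[, j - 1], format = "f", digits = 2), ")")
    disp[[j]] <- txt
  }
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Mean walking speed by age bin and subpopulation
#'
#' Weighted mean speed per age bin and subgroup — the data behind age-profile
#' figures. Bins with fewer observations than `min_n` are suppressed.
#'
#' @param panel A `"walk_panel"`.
#' @param factor Grouping factor: `"education"`, `"occupation"`, `"region"`
#'   or `"sex"`.
#' @param sex Optional restriction to `"female"` or `"male"` (ignored when
#'   `factor = "sex"`).
#' @param bin_width Age bin width in years (default 1).
#' @param min_n Minimum observations per cell (default 5).
#' @return Data frame with `age_bin` (midpoint), `group`, `mean_speed`, `n`.
#' @export
trajectory_summary <- function(panel, factor = c("education", "occupation",
                                                 "region", "sex"),
                               sex = NULL, bin_width = 1, min_n = 5) {
  factor <- match.arg(factor)
  d <- as.data.frame(panel)
  if (!nrow(d)) stop("empty panel")
  if (!is.null(sex) && factor != "sex") d <- d[d$sex == sex, ]
  g <- if (factor == "sex") d$sex else d[[.group_vars[[factor]]]]
  bin <- floor(d$age / bin_width) * bin_width + bin_width / 2
  key <- split(seq_len(nrow(d)), paste(bin, g, sep = "|"))
  out <- do.call(rbind, lapply(names(key), function(k) {
    idx <- key[[k]]
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(age_bin = as.numeric(parts[1]),
               group = parts[2],
               mean_speed = .wmean(d$speed[idx], d$sample_weight[idx]),
               n = length(idx), stringsAsFactors = FALSE)
  }))
  out <- out[out$n >= min_n, ]
  out <- out[order(out$group, out$age_bin), ]
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort, cleans it, fits the growth models per sex
#' and group factor, computes the alpha-age table and the descriptive
#' summaries, and writes every artifact plus a manifest with content hashes.
#'
#' @param config A [sim_config()]; ignored when `cohort_file` is given.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the simulation.
#' @param cohort_file Optional path to an existing cohort CSV to analyse
#'   instead of simulating.
#' @param factors Group factors to fit (default all three plus the joint
#'   three-factor model).
#' @param ages Reference ages for the alpha-age table.
#' @param verbose Print stage-tagged progress messages (default `TRUE`).
#' @return Invisibly, a list with the panel, fitted models, alpha table,
#'   descriptives and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         cohort_file = NULL,
                         factors = c("education", "occupation", "region", "all"),
                         ages = seq(60, 85, by = 5), verbose = TRUE) {
  say <- function(stage, ...) if (verbose)
    message("[", stage, "] ", ...)
  stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(cohort_file) && !file.exists(cohort_file))
    stop("cohort file not found: ", cohort_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  keep <- function(p) { paths <<- c(paths, p); p }

  if (is.null(cohort_file)) {
    say("simulate", "generating cohort")
    cohort <- stage("simulate", simulate_cohort(config, seed = seed))
    write_cohort(cohort, keep(file.path(out_dir, "cohort.csv")))
    jsonlite::write_json(generation_log(cohort),
                         keep(file.path(out_dir, "generation_log.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    say("ingest", "reading ", cohort_file)
    cohort <- stage("ingest", read_cohort(cohort_file))
  }

  say("preprocess", "applying exclusion rules")
  panel <- stage("preprocess", build_panel(cohort))
  write_panel(panel, keep(file.path(out_dir, "panel.csv")),
              keep(file.path(out_dir, "exclusions.json")))

  say("fit", "fitting growth models")
  models <- list()
  for (sx in c("female", "male")) {
    for (f in factors) {
      nm <- paste(if (sx == "female") "women" else "men", f, sep = "_")
      models[[nm]] <- stage(paste0("fit:", nm),
                            fit_growth(panel, sex = sx, group = f,
                                       keep_fit = FALSE))
      write_growth_model(models[[nm]],
                         keep(file.path(out_dir, paste0("model_", nm, ".json"))))
      writeLines(utils::capture.output(print(models[[nm]])),
                 keep(file.path(out_dir, paste0("model_", nm, ".txt"))))
    }
  }

  say("alpha", "computing alpha-age table")
  single <- models[!grepl("_all$", names(models))]
  atab <- stage("alpha", alpha_age_table(single, ages = ages))
  utils::write.csv(as.data.frame(atab),
                   keep(file.path(out_dir, "alpha_ages.csv")),
                   row.names = FALSE)
  diag <- lapply(attr(atab, "results"), function(col)
    lapply(col, function(r) if (inherits(r, "alpha_age"))
      r[c("reference_age", "alpha", "gap_years", "gap_speed_at_t")]
      else list(error = r)))
  jsonlite::write_json(diag, keep(file.path(out_dir, "alpha_diagnostics.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("report", "descriptives and trajectories")
  desc <- stage("report", descriptive_table(panel))
  utils::write.csv(as.data.frame(desc),
                   keep(file.path(out_dir, "descriptives.csv")),
                   row.names = FALSE)
  traj <- do.call(rbind, lapply(c("education", "occupation", "region"),
                                function(f) {
    do.call(rbind, lapply(c("female", "male"), function(sx) {
      cbind(factor = f, sex = sx,
            trajectory_summary(panel, factor = f, sex = sx))
    }))
  }))
  utils::write.csv(traj, keep(file.path(out_dir, "trajectories.csv")),
                   row.names = FALSE)

  say("manifest", "writing run manifest")
  manifest <- list(
    package = as.character(utils::packageVersion("walkage")),
    r_version = R.version.string,
    seed = seed,
    config_hash = if (is.null(cohort_file))
      unname(.hash_object(config)) else NULL,
    cohort_file = cohort_file,
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done", length(paths) + 1, " artifacts in ", out_dir)
  invisible(list(panel = panel, models = models, alpha = atab,
                 descriptives = desc, trajectories = traj,
                 manifest = manifest))
}

.hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(x, file = tf)
  tools::md5sum(tf)
}
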