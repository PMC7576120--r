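# End-to-end in-silico experiment: generate a cohort, match controls,
# measure posterior-pole geometry, estimate the group mean foveo-BMO-center
# distance difference, reposition every SIOD scan circle nasally by that
# difference along the per-eye axis, and compare clock-hour sectors across
# the three conditions.

#' Experiment configuration
#'
#' @param seed mandatory integer seed; every random stage derives its stream
#'   from it.
#' @param params a [scene_params()] generator configuration.
#' @param n_siod_subjects,p_bilateral SIOD arm size (see [generate_cohort()]).
#' @param n_control_pool size of the control pool from which matches are
#'   drawn.
#' @param match_k,age_tol,al_tol matching parameters (see [match_controls()]).
#' @param grid,extent raster resolution and field size (see
#'   [render_thickness_map()]).
#' @param radius,n_samples scan-circle radius (mm) and profile sampling.
#' @param reposition_controls also reposition the control circles (the
#'   reverse-manipulation check; default FALSE).
#' @param shift_um forced shift in um; `NULL` (default) uses the estimated
#'   group mean difference.
#' @param shift_axis `"per_eye"` (each eye shifted along its own foveo-BMO
#'   axis) or `"group"` (all eyes shifted along the group mean axis).
#' @param shift_measure distance used for the estimated shift: `"center"`
#'   (foveo-BMO-center, default) or `"margin"`.
#' @return a validated list of class `experiment_config`.
#' @export
experiment_config <- function(seed,
                              params = scene_params(),
                              n_siod_subjects = 15,
                              p_bilateral = 7 / 15,
                              n_control_pool = 150,
                              match_k = 2,
                              age_tol = 10, al_tol = 0.5,
                              grid = 200, extent = 6,
                              radius = 1.73, n_samples = 720,
                              reposition_controls = FALSE,
                              shift_um = NULL,
                              shift_axis = c("per_eye", "group"),
                              shift_measure = c("center", "margin")) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    stop_config("a single integer seed is mandatory")
  }
  stopifnot(inherits(params, "scene_params"))
  structure(list(seed = as.integer(seed), params = params,
                 n_siod_subjects = n_siod_subjects,
                 p_bilateral = p_bilateral,
                 n_control_pool = n_control_pool,
                 match_k = match_k, age_tol = age_tol, al_tol = al_tol,
                 grid = grid, extent = extent, radius = radius,
                 n_samples = n_samples,
                 reposition_controls = reposition_controls,
                 shift_um = shift_um,
                 shift_axis = match.arg(shift_axis),
                 shift_measure = match.arg(shift_measure)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Every [experiment_config()] and [scene_params()] default can be overridden
#' in the file; the top-level `seed` is mandatory.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$params)) {
    raw$params <- do.call(scene_params, raw$params)
  }
  do.call(experiment_config, raw)
}

#' Run the full in-silico experiment
#'
#' Generates the cohort, matches two controls per SIOD eye on age and axial
#' length, measures every eye, compares the posterior-pole measurements
#' between groups with cluster-robust means, estimates the shift as the
#' control-minus-SIOD mean foveo-BMO-center distance difference, repositions
#' each SIOD scan circle nasally by that amount along the per-eye foveo-BMO
#' axis, and compares clock-hour sector thicknesses across the control,
#' SIOD, and repositioned-SIOD conditions. Fully reproducible from the
#' config seed.
#'
#' @param config an [experiment_config()], or a path readable by
#'   [read_experiment_config()].
#' @return an object of class `experiment_report`; see Details.
#' @details The report carries: `cohort_summary` (eye/subject counts and
#'   demographic comparisons, with the subject-level sex contingency test),
#'   `measurements` (per-eye rows), `comparisons` (per-measure
#'   `cohort_comparison` objects), `delta_hat_um` (the estimated shift),
#'   `sector_table` (the 12-hour condition comparison), `mean_profiles`
#'   (per-condition mean thickness by angle), `matches`, and the echoed
#'   `config`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  stage <- "generate"
  cohort <- generate_cohort(config$n_siod_subjects, config$p_bilateral,
                            config$n_control_pool, config$params,
                            rng_seed = derive_seed(config$seed, 1))

  stage <- "measure"
  meas <- measure_cohort(cohort)

  stage <- "match"
  cases <- meas[meas$group == "siod", ]
  pool <- meas[meas$group == "control", ]
  matches <- match_controls(cases, pool, age_tol = config$age_tol,
                            al_tol = config$al_tol, k = config$match_k,
                            rng_seed = derive_seed(config$seed, 2))
  analysis_ids <- c(cases$eye_id, matches$control_eye_id)
  ameas <- meas[meas$eye_id %in% analysis_ids, ]
  scenes <- cohort[analysis_ids]

  stage <- "compare"
  measures <- c("foveo_bmo_center_distance", "foveo_bmo_margin_distance",
                "foveo_bmo_axis_angle", "inter_arcade_distance", "bmo_area")
  comparisons <- lapply(measures, function(m) {
    clustered_group_difference(ameas, value = m, group = "group",
                               subject = "subject_id", measure = m)
  })
  names(comparisons) <- measures
  shift_name <- if (config$shift_measure == "center") {
    "foveo_bmo_center_distance"
  } else "foveo_bmo_margin_distance"
  delta_hat <- comparisons[[shift_name]]$difference
  shift <- config$shift_um %||% delta_hat

  stage <- "demographics"
  subj <- ameas[!duplicated(ameas$subject_id),
                c("subject_id", "group", "age", "axial_length", "sex")]
  sex_tab <- table(factor(subj$group, levels = c("siod", "control")),
                   factor(subj$sex, levels = c("male", "female")))
  sex_test <- tryCatch(chi_square_2x2(sex_tab),
                       error = function(e) list(statistic = NA_real_,
                                                p_value = NA_real_))
  cohort_summary <- list(
    n_eyes = table(ameas$group),
    n_subjects = table(subj$group),
    age = clustered_group_difference(ameas, "age", "group", "subject_id",
                                     measure = "age"),
    axial_length = clustered_group_difference(ameas, "axial_length", "group",
                                              "subject_id",
                                              measure = "axial_length"),
    sex_table = sex_tab, sex_test = sex_test)

  stage <- "scan"
  mean_axis <- mean(ameas$foveo_bmo_axis_angle)
  rows <- list(); prof_rows <- list()
  for (i in seq_along(scenes)) {
    sc <- canonical_scene(scenes[[i]])
    eid <- sc$eye_id
    res <- tryCatch({
      map <- render_thickness_map(sc, grid = config$grid,
                                  extent = config$extent,
                                  noise_seed = derive_seed(config$seed, 100 + i))
      axis <- foveo_bmo_axis_angle(sc$fovea, sc$bmo_center)
      orig <- resample_circle(map, sc$bmo_center, radius = config$radius,
                              n_samples = config$n_samples, axis_deg = axis)
      cond0 <- if (sc$group == "siod") "siod" else "control"
      out <- list(list(condition = cond0, profile = orig))
      do_shift <- sc$group == "siod" || config$reposition_controls
      if (do_shift) {
        new_center <- if (config$shift_axis == "per_eye") {
          reposition_center(sc$bmo_center, sc$fovea, shift)
        } else {
          dir <- c(cos(deg2rad(-mean_axis)), sin(deg2rad(-mean_axis)))
          sc$bmo_center + (shift / 1000) * dir
        }
        repo <- resample_circle(map, new_center, radius = config$radius,
                                n_samples = config$n_samples, axis_deg = axis)
        out <- c(out, list(list(condition = paste0(cond0, "_repositioned"),
                                profile = repo)))
      }
      out
    }, error = function(e) {
      stop(sprintf("stage scan failed for eye %s: %s", eid,
                   conditionMessage(e)), call. = FALSE)
    })
    for (r in res) {
      ch <- clock_hour_summary(r$profile, laterality = "right")
      rows[[length(rows) + 1L]] <- data.frame(
        eye_id = eid, subject_id = sc$subject_id, condition = r$condition,
        hour = as.integer(names(ch$sector_means)),
        thickness = as.numeric(ch$sector_means), stringsAsFactors = FALSE)
      prof_rows[[length(prof_rows) + 1L]] <- data.frame(
        eye_id = eid, condition = r$condition, angle_deg = r$profile$angles,
        thickness_um = r$profile$thickness, stringsAsFactors = FALSE)
    }
  }
  sectors_long <- do.call(rbind, rows)
  profiles_long <- do.call(rbind, prof_rows)

  stage <- "analyze"
  sector_table <- sector_comparison_table(sectors_long)
  mean_profiles <- stats::aggregate(
    thickness_um ~ condition + angle_deg, data = profiles_long, FUN = mean)

  structure(list(config = config, cohort_summary = cohort_summary,
                 measurements = meas, analysis_measurements = ameas,
                 matches = matches, comparisons = comparisons,
                 delta_hat_um = delta_hat, applied_shift_um = shift,
                 sectors_long = sectors_long, sector_table = sector_table,
                 mean_profiles = mean_profiles),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  eyes: %s siod / %s control; subjects: %s / %s\n",
              x$cohort_summary$n_eyes[["siod"]],
              x$cohort_summary$n_eyes[["control"]],
              x$cohort_summary$n_subjects[["siod"]],
              x$cohort_summary$n_subjects[["control"]]))
  cat(sprintf("  estimated shift (control - siod center distance): %.1f um (applied %.1f um)\n",
              x$delta_hat_um, x$applied_shift_um))
  ns <- sum(x$sector_table$sig_control_vs_siod)
  nr <- sum(x$sector_table$sig_control_vs_repositioned)
  cat(sprintf("  flagged sectors at p < %.4f: control vs siod %d/12, control vs repositioned %d/12\n",
              attr(x$sector_table, "bonferroni_threshold"), ns, nr))
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Emits measurement, match, sector and mean-profile CSVs plus a JSON
#' summary (counts, comparisons, shift, sector table) into `outdir`.
#'
#' @param report an `experiment_report`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_experiment_report <- function(report, outdir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$measurements, file.path(outdir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(report$matches, file.path(outdir, "matches.csv"),
                   row.names = FALSE)
  utils::write.csv(report$sectors_long, file.path(outdir, "sectors_long.csv"),
                   row.names = FALSE)
  st <- as.data.frame(report$sector_table)
  pcols <- grep("^p_", names(st))
  st[pcols] <- lapply(st[pcols], function(p) round(p, 4))
  utils::write.csv(st, file.path(outdir, "sector_table.csv"), row.names = FALSE)
  utils::write.csv(report$mean_profiles, file.path(outdir, "mean_profiles.csv"),
                   row.names = FALSE)
  summary <- list(
    seed = report$config$seed,
    n_eyes = as.list(report$cohort_summary$n_eyes),
    n_subjects = as.list(report$cohort_summary$n_subjects),
    delta_hat_um = report$delta_hat_um,
    applied_shift_um = report$applied_shift_um,
    comparisons = lapply(report$comparisons, function(cmp) {
      list(measure = cmp$measure, groups = cmp$groups,
           means = as.list(cmp$means), ses = as.list(cmp$ses),
           difference = cmp$difference, se_difference = cmp$se_difference,
           p_value = round(cmp$p_value, 4))
    }),
    sex_test = report$cohort_summary$sex_test,
    sector_table = st)
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
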