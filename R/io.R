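# Plain-text serialization: scenes as JSON (full parameter dump) and CSV
# (one row per eye), profiles and sector tables as CSV.

#' Write scenes as a JSON parameter dump
#'
#' @param scenes a list of `pp_scene` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenes_json <- function(scenes, path) {
  dump <- lapply(unname(scenes), function(s) {
    s <- unclass(s)
    s
  })
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read scenes written by [write_scenes_json()]
#'
#' @param path JSON file.
#' @return a `pp_cohort` list of `pp_scene` objects.
#' @export
read_scenes_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  scenes <- lapply(raw, function(s) {
    s$fovea <- as.numeric(s$fovea)
    s$arch_center <- as.numeric(s$arch_center)
    s$bmo_center <- as.numeric(s$bmo_center)
    s$bmo_semiaxes <- as.numeric(s$bmo_semiaxes)
    s$arcade_params$vertex <- as.numeric(s$arcade_params$vertex)
    structure(s, class = "pp_scene")
  })
  names(scenes) <- vapply(scenes, `[[`, "", "eye_id")
  structure(scenes, class = c("pp_cohort", "list"))
}

#' Write cohort metadata CSV
#'
#' @param scenes a list of `pp_scene` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(scenes, path) {
  utils::write.csv(scene_table(scenes), path, row.names = FALSE)
  invisible(path)
}

#' Convert profiles to a long data.frame
#'
#' @param profiles a list of `rnfl_profile` objects.
#' @param condition a single label or vector of labels per profile.
#' @return data.frame with eye_id, condition, angle_deg, thickness_um.
#' @export
profiles_long <- function(profiles, condition = "original") {
  condition <- rep_len(condition, length(profiles))
  out <- Map(function(p, cond) {
    data.frame(eye_id = p$eye_id %||% NA_character_, condition = cond,
               angle_deg = p$angles, thickness_um = p$thickness,
               stringsAsFactors = FALSE)
  }, profiles, condition)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
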