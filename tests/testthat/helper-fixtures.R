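# Shared fixture builders.

# Noiseless field: no pixel noise, no subject offset; geometry still random.
noiseless_params <- function(...) {
  scene_params(noise_sd = 0, subject_effect_sd = 0, ...)
}

# Fully deterministic geometry: every generator SD zeroed, so all eyes of a
# group are identical and the estimated shift equals the true displacement.
deterministic_params <- function(...) {
  scene_params(arch_distance_sd_between = 0, arch_distance_sd_within = 0,
               displacement_sd = 0, axis_angle_sd = 0, bmo_semiaxis_sd = 0,
               arcade_halfwidth_sd = 0, subject_effect_sd = 0, noise_sd = 0,
               age_sd = 0, axial_length_sd = 0, ...)
}

# A simple measurement frame for matching tests.
match_frame <- function(ids, subject_prefix, age, al) {
  data.frame(eye_id = ids,
             subject_id = paste0(subject_prefix, seq_along(ids)),
             age = age, axial_length = al, stringsAsFactors = FALSE)
}
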