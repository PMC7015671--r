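# YAML run configuration: one document holding the stage parameters of a
# pipeline run, with explicit seeds. Unknown keys are rejected so typos do
# not silently fall back to defaults.

run_config_known <- list(
  schema_version = 1L,
  lattice = c("n_pf", "start_number", "monomer_rise_A", "radius_A",
              "pf_skew_deg", "seam_index", "handedness"),
  density = c("voxel_size_A", "box_px", "motor_occupancy", "tail_occupancy",
              "motor_radius_offset_A", "tail_radius_offset_A"),
  simulate = c("n_filaments", "filament_len_A", "spacing_A", "snr",
               "tilt_jitter_deg", "shift_jitter_A", "seed"),
  refine = c("angular_step_deg", "shift_range_A", "n_iter",
             "twist_window_deg", "rise_window_A", "seed"),
  pf_refine = c("box_out", "soft_edge_deg", "ang_range_deg", "shift_range_A",
                "k_classes", "n_iter", "seed"),
  validate = c("fsc_threshold", "bfactor_A2", "locres_window_A",
               "locres_threshold"),
  paths = c("output_dir", "map", "stack", "alignments")
)

#' Read and validate a YAML run configuration
#'
#' Top-level sections and their keys are checked against the known schema;
#' unknown keys raise an error naming them, and every section that draws
#' random numbers must carry an explicit `seed`.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("schema_version", names(run_config_known)))
  if (length(unknown))
    abort(sprintf("unknown config section(s): %s",
                  paste(unknown, collapse = ", ")))
  for (sec in intersect(names(cfg), setdiff(names(run_config_known),
                                            "schema_version"))) {
    bad <- setdiff(names(cfg[[sec]]), run_config_known[[sec]])
    if (length(bad))
      abort(sprintf("unknown key(s) in config section '%s': %s", sec,
                    paste(bad, collapse = ", ")))
    if ("seed" %in% run_config_known[[sec]] &&
        is.null(cfg[[sec]][["seed"]]))
      abort(sprintf("config section '%s' must set an explicit seed", sec))
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration (with provenance) to YAML
#'
#' @param cfg A named list / `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
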