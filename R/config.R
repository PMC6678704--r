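# YAML-backed threshold registry for pipeline runs.

#' Read a pipeline threshold configuration from YAML
#'
#' Loads a named list of threshold overrides for [run_discovery()] /
#' [run_validation()] (keys as in the run manifest: `lrr_gain`, `lrr_loss`,
#' `min_patients_recurrent`, `alpha`, `os_horizon_years`, `nag_quartile`,
#' `fc_threshold`, `p_threshold`, `risk_score_quartile`,
#' `affinity_threshold_nm`). Unknown keys are an error, so typos cannot
#' silently fall back to defaults; omitted keys keep their defaults, which
#' equal the published analysis values.
#'
#' @param path YAML file.
#' @return named list suitable for the `thresholds` argument of the
#'   pipeline functions.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stopf("config must be a YAML mapping")
  unknown <- setdiff(names(cfg), names(default_thresholds()))
  if (length(unknown))
    stopf("unknown threshold key(s): %s", paste(unknown, collapse = ", "))
  cfg
}
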