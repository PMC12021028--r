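## run configuration: YAML file with a stage name, a mandatory seed for
## stochastic stages, input/output paths and stage parameters

config_schema <- list(
  simulate = c("kind", "size", "n_particles", "noise_sigma", "tilt_range",
               "increment", "n_repeats", "pairwise_identity", "coord_noise",
               "velocity_um_s", "duration_s", "n_cells"),
  `map-coat` = c("angular_step", "threshold", "refine_threshold",
                 "min_spacing", "d_in", "d_out", "overlap_threshold",
                 "bin", "highpass_sigma", "smoothing"),
  `analyze-repeats` = c("min_len", "max_len", "rmsd_cutoff", "keep_frac",
                        "disulfide_cutoff", "min_frequency"),
  `analyze-motility` = c("roi", "width", "threshold", "max_jump",
                         "min_frames"),
  `analyze-detachment` = c("foreground", "timepoints"))

stochastic_stages <- "simulate"

#' Read and validate a pipeline run configuration
#'
#' A YAML file with keys `stage`, `seed` (mandatory for stochastic
#' stages), `inputs`, `outputs` and `params`. Unknown top-level keys
#' and parameters not defined for the stage are rejected.
#'
#' @param path YAML file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list (as from [yaml::read_yaml]).
#' @export
validate_run_config <- function(cfg) {
  known_top <- c("stage", "seed", "inputs", "outputs", "params")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra))
    stop("run config: unknown key(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$stage) || !cfg$stage %in% names(config_schema))
    stop("run config: 'stage' must be one of ",
         paste(names(config_schema), collapse = ", "))
  if (cfg$stage %in% stochastic_stages && is.null(cfg$seed))
    stop("run config: stochastic stage '", cfg$stage,
         "' requires an explicit seed")
  if (!is.null(cfg$params)) {
    bad <- setdiff(names(cfg$params), config_schema[[cfg$stage]])
    if (length(bad))
      stop("run config: unknown parameter(s) for stage ", cfg$stage, ": ",
           paste(bad, collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}

## provenance logging: version, stage, seed, parameters, input hashes
log_stage <- function(stage, seed = NULL, params = list(), inputs = character()) {
  ver <- tryCatch(as.character(utils::packageVersion("ciliacoat")),
                  error = function(e) "dev")
  message(sprintf("[ciliacoat %s] stage=%s seed=%s", ver, stage,
                  if (is.null(seed)) "none" else seed))
  if (length(params))
    message("  params: ", paste(sprintf("%s=%s", names(params),
                                        vapply(params, function(p)
                                          paste(format(p), collapse = ","),
                                          character(1))),
                                collapse = " "))
  for (f in inputs) {
    if (file.exists(f))
      message(sprintf("  input %s md5=%s", f, unname(tools::md5sum(f))))
  }
  invisible(NULL)
}
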