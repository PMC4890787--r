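#' Read simulation configuration from YAML
#'
#' Recognised top-level sections: `cross` (fields of [cross_config()]),
#' `depth` ([depth_sim_config()]) and `pyro` ([pyro_sim_config()]); each is
#' passed to the matching constructor so invariants are checked at load time.
#' Unrecognised sections are returned as-is.
#'
#' @param path YAML file.
#' @return Named list of configuration objects.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  for (nm in names(raw)) {
    out[[nm]] <- switch(nm,
      cross = do.call(cross_config, raw[[nm]]),
      depth = do.call(depth_sim_config, raw[[nm]]),
      pyro = do.call(pyro_sim_config, raw[[nm]]),
      raw[[nm]]
    )
  }
  out
}
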