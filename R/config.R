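#' Read an analysis configuration file
#'
#' A plain-text YAML file holding the tunables shared by the command-line
#' workflow: the difficulty threshold in minutes, column alias map, Clavien
#' rank mapping, covariance mode, bootstrap replicate count and minimum
#' per-class resample size, and the stage-2 cross-validation band. Missing
#' keys fall back to the packaged defaults
#' (`system.file("extdata/default-config.yaml", package = "surgworkload")`).
#'
#' @param path optional YAML file; `NULL` for pure defaults.
#' @return Named list with elements `threshold`, `covariance`, `n_boot`,
#'   `min_group`, `cv_band`, `ridge`, `aliases`, `clavien_ranks`.
#' @export
read_workload_config <- function(path = NULL) {
  defaults <- yaml::read_yaml(system.file("extdata/default-config.yaml",
                                          package = "surgworkload"))
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  if (!cfg$covariance %in% c("pooled", "total"))
    stop("config covariance must be 'pooled' or 'total'", call. = FALSE)
  if (cfg$threshold <= 0) stop("config threshold must be > 0", call. = FALSE)
  cfg$aliases <- unlist(cfg$aliases)
  cfg
}
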