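run_config_defaults <- function() {
  list(
    G = c(0.05, 0.1, 0.3, 0.7, 1, 1.3, 1.7),
    hurst = c(0, 1),
    replicates = 30L,
    base_seed = NULL,
    R0 = 15, alpha = 3, K = 150, Eimmi = 2.5,
    tmax = 10000L, Ttrend = 0,
    width = 20L, height = 20L,
    out_dir = NULL,
    landscape_files = NULL
  )
}

#' Read and validate a run configuration
#'
#' Experiments are configured by a YAML file whose keys mirror
#' [sim_params()] plus the scenario grid: `G` and `hurst` (lists of
#' values to cross), `replicates`, `base_seed` (required), and optional
#' `out_dir` and `landscape_files`. Unknown keys are errors, guarding
#' against silently misconfigured scenario grids. Defaults reproduce
#' the full study design: `G` in {0.05, 0.1, 0.3, 0.7, 1, 1.3, 1.7}
#' crossed with `hurst` in {0, 1} (14 scenarios), 30 replicates of
#' 10,000 steps on 20 x 20 landscapes.
#'
#' @param path Path to a YAML configuration file.
#' @param config A configuration list (for programmatic use).
#' @return The validated configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[nm] <- defaults[nm]
  if (is.null(config$base_seed))
    stop("configuration is missing required key 'base_seed'", call. = FALSE)
  config$G <- as.numeric(unlist(config$G))
  config$hurst <- as.numeric(unlist(config$hurst))
  stopifnot(all(config$G >= 0), all(config$hurst >= 0 & config$hurst <= 1),
            config$replicates >= 1, config$tmax >= 1)
  if (!is.null(config$landscape_files)) {
    config$landscape_files <- as.character(unlist(config$landscape_files))
    if (length(config$landscape_files) < config$replicates)
      stop("need at least one landscape file per replicate", call. = FALSE)
    missing <- !file.exists(config$landscape_files)
    if (any(missing))
      stop("landscape files not found: ",
           paste(config$landscape_files[missing], collapse = ", "),
           call. = FALSE)
  }
  config
}
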