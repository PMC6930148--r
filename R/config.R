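#' Default run configuration
#'
#' Returns the pipeline defaults: per-group rarefaction depths (bacteria
#' 7987, fungi 1023, small eukaryotes 871, microfauna 700), the core-taxon
#' frequency cutoff of 12 plots, three latent variables, MCMC settings of
#' 40,000 iterations with burn-in 10,000 and thin 30, and a 95% credible
#' level for edge calling.
#'
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    rarefaction_depths = c(bacteria = 7987, fungi = 1023,
                           small_eukaryote = 871, microfauna = 700,
                           plant = 1),
    min_plots = 12,
    n_stages = 3,
    n_latent = 3,
    iterations = 40000,
    burn_in = 10000,
    thin = 30,
    level = 0.95,
    seed = 1,
    covariates = c("snow_depth", "pH", "moisture", "cv_snow"),
    n_covariates = 4,
    stage_variables = NULL,   # NULL = all metadata covariates enter the PCA
    orient_by = "plant_cover",
    n_perm = 999
  ), class = "run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' Keys present in the file override the defaults from
#' [default_run_config()]; all other keys keep their default values. The
#' result is validated.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) {
      v <- user[[k]]
      if (k == "rarefaction_depths") v <- unlist(v)
      cfg[[k]] <- v
    }
  }
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg a `run_config` list.
#' @return `cfg`, invisibly amended, or an error describing the violation.
#' @export
validate_run_config <- function(cfg) {
  if (any(cfg$rarefaction_depths <= 0)) stop("config error: rarefaction depths must be > 0")
  if (cfg$min_plots < 1) stop("config error: min_plots must be >= 1")
  if (cfg$n_latent < 0) stop("config error: n_latent must be >= 0")
  if (!(cfg$burn_in > 0 && cfg$burn_in < cfg$iterations)) {
    stop("config error: need 0 < burn_in < iterations")
  }
  if (cfg$thin < 1) stop("config error: thin must be >= 1")
  if (!(cfg$level > 0 && cfg$level < 1)) stop("config error: credible level must be in (0,1)")
  if (cfg$n_stages < 2) stop("config error: n_stages must be >= 2")
  invisible(cfg)
}
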