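# Run configuration: a nested list, readable from a YAML file, that
# names the inputs and parameters of every pipeline stage.

#' Default pipeline configuration
#'
#' Returns the configuration skeleton [run_pipeline()] consumes, with
#' every stage parameter at its default. Stages run only when their
#' inputs are configured. The defaults carry the package's standard
#' analysis constants: a 30% slope threshold and 72 / 129 minute
#' isochrones for catchments, MNI as the diversity basis, and a
#' 20000-iteration MCMC with 2000 burn-in.
#'
#' @param seed Integer seed used by every stochastic stage.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    specimens = NULL,           # path to specimens.csv
    template = NULL,            # path to template.csv
    units = NULL,               # unit labels to analyse (default: all)
    counts = NULL,              # counts-mode: pre-aggregated table
    counts_totals = NULL,
    diversity_basis = "MNI",
    bayes = list(taxon = NULL, unit = NULL, iterations = 20000,
                 burnin = 2000, thin = 1, beta_max = 12,
                 prop_sd_alpha = 0.1, prop_sd_beta = 0.4),
    catchment = list(dem = NULL, origin = NULL, times = c(72, 129),
                     slope_threshold = 30,
                     v0 = 6, k = 3.5, c0 = 0.05),
    npp = list(series = NULL, units = NULL, diversity = NULL)
  )
}

#' Read a pipeline configuration file
#'
#' YAML key-value file mirroring [default_config()]; unknown keys are
#' rejected, missing keys keep their defaults. A seed must be present
#' whenever any stochastic stage (Bayes) is configured.
#'
#' @param path Path to a YAML configuration file.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  merge_cfg <- function(base, user, prefix = "") {
    for (k in names(user)) {
      if (!(k %in% names(base))) {
        stop(sprintf("unknown configuration key '%s%s'", prefix, k), call. = FALSE)
      }
      if (is.list(base[[k]]) && is.list(user[[k]])) {
        base[[k]] <- merge_cfg(base[[k]], user[[k]], paste0(prefix, k, "."))
      } else {
        base[[k]] <- user[[k]]
      }
    }
    base
  }
  cfg <- merge_cfg(base, user)
  if (!is.null(cfg$bayes$taxon) && is.null(cfg$seed)) {
    stop("a seed is required when the Bayes stage is configured", call. = FALSE)
  }
  cfg
}
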