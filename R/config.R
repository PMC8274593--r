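# YAML scenario configuration: a thin, versioned key-value layer over the
# scenario drivers, so benchmark runs can be described in files and run
# from the command line.

#' Read a scenario configuration file
#'
#' YAML with a `scenario:` key (`swelling`, `drainage`, `fibre_swelling`,
#' `lv`) and any arguments of the corresponding driver
#' ([run_swelling()], [run_drainage()], [run_fibre_swelling()],
#' [run_lv()]).  Material parameters may be overridden under `params:`
#' (fields of [poro_params()]) and `law:` (fields of the skeleton law,
#' with `type: iso` or `type: ho`).
#'
#' @param path YAML file path.
#' @return a list with `scenario` and `args`, ready for [run_config()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenario)) stop("config must name a 'scenario'")
  if (!is.null(cfg$version) && cfg$version != 1) {
    stop("unsupported config schema version: ", cfg$version)
  }
  scenario <- cfg$scenario
  args <- cfg
  args$scenario <- NULL; args$version <- NULL
  if (!is.null(args$params)) {
    base <- switch(scenario,
                   swelling = , fibre_swelling = benchmark_params("swelling"),
                   drainage = benchmark_params("drainage"),
                   lv = benchmark_params("ventricle"))
    ov <- args$params
    if (!is.null(ov$K)) ov$K <- as.numeric(ov$K)
    fields <- modifyList(unclass(base)[c("Mb", "b", "kappa0", "phi0",
                                         "rho")], ov[names(ov) != "K"])
    args$params <- poro_params(Mb = fields$Mb, b = fields$b,
                               kappa0 = fields$kappa0, phi0 = fields$phi0,
                               rho = fields$rho,
                               K = if (is.null(ov$K)) base$K else ov$K)
  }
  if (!is.null(args$law)) {
    lw <- args$law
    type <- if (is.null(lw$type)) "iso" else lw$type
    lw$type <- NULL
    args$law <- if (type == "ho") do.call(ho_skeleton_law, lw)
                else do.call(iso_skeleton_law, lw)
  }
  if (!is.null(args$geometry)) {
    args$geometry <- do.call(lv_geometry_params, args$geometry)
  }
  list(scenario = scenario, args = args)
}

#' Run a scenario described by a configuration
#'
#' @param cfg result of [read_scenario_config()] (or a path to a YAML
#'   file).
#' @return the scenario's `probe_report`.
#' @export
run_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_scenario_config(cfg)
  fn <- switch(cfg$scenario,
               swelling = run_swelling,
               drainage = run_drainage,
               fibre_swelling = run_fibre_swelling,
               lv = run_lv,
               stop("unknown scenario '", cfg$scenario, "'"))
  do.call(fn, cfg$args)
}

#' Write a probe report as CSV
#'
#' @param report a `probe_report`.
#' @param path output file.
#' @export
write_probe_csv <- function(report, path) {
  utils::write.csv(report$series, path, row.names = FALSE)
  invisible(path)
}
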