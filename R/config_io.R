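# YAML config reading for the command-line interface.

#' Read an analysis configuration from YAML
#'
#' Keys mirror the [analysis_config()] arguments; `debris_gate` is a map
#' with `x_min`/`x_max`/`y_min`/`y_max`, `bins` a list of maps with
#' `label`/`low`/`high` (a missing or null `low` on the first bin means
#' "use the fitted GFP threshold"), and `split` a map of
#' [split_params()] arguments plus `transform`/`cofactor`.
#'
#' @param path YAML file.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("gfp_channel", "myhc_channel",
                                  "fsc_channel", "ssc_channel",
                                  "fsc_h_channel", "quantile_level",
                                  "singlet_gating", "singlet_tolerance",
                                  "qc_min_control_fraction"))]
  gfp <- if (!is.null(y$gfp_channel)) y$gfp_channel else "GRN-B-HLin"
  if (!is.null(y$debris_gate)) {
    g <- y$debris_gate
    args$debris_gate <- rect_gate(
      if (!is.null(y$fsc_channel)) y$fsc_channel else "FSC-HLin",
      if (!is.null(y$ssc_channel)) y$ssc_channel else "SSC-HLin",
      x_min = g$x_min %||% -Inf, x_max = g$x_max %||% Inf,
      y_min = g$y_min %||% -Inf, y_max = g$y_max %||% Inf)
  }
  if (!is.null(y$bins)) {
    args$bins <- lapply(y$bins, function(b)
      range_bin(b$label, gfp, b$low %||% NA_real_, b$high))
  }
  if (!is.null(y$split)) {
    s <- y$split
    tr <- transform_spec(s$transform %||% "biexponential",
                         cofactor = s$cofactor %||% 5,
                         floor = s$floor %||% 0.1)
    args$split <- split_params(
      transform = tr,
      min_events = s$min_events %||% 50L,
      prominence = s$prominence %||% 0.05,
      fallback_threshold = s$fallback_threshold %||% 10,
      grid_size = s$grid_size %||% 512L)
  }
  do.call(analysis_config, args)
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the [sim_config()] arguments (two-element channel
#' parameters as two-element sequences).
#'
#' @param path YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  do.call(sim_config, y[intersect(names(y), known)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
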