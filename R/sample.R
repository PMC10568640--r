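#' Construct a cytometry sample
#'
#' A `fcs_sample` bundles one acquisition: an event matrix (rows = events,
#' columns = channels, values in linear RFU), ordered channel metadata,
#' the FCS TEXT keywords, and — for simulated data only — a per-event
#' ground-truth table.
#'
#' @param events Numeric matrix, events x channels; all values finite.
#' @param channels Character vector of channel names, or a data frame with
#'   columns `name`, `range` and optionally `decades`, `offset` (the
#'   log-amplification keyword pair; `0,0` means linear).
#' @param sample_id Sample identifier.
#' @param well_id Optional plate well (e.g. `"A01"`).
#' @param keywords Named character vector of FCS TEXT keywords.
#' @param truth Optional data frame of per-event ground truth
#'   (simulator only); must have one row per event.
#' @return An object of class `fcs_sample`.
#' @export
fcs_sample <- function(events, channels, sample_id, well_id = NULL,
                       keywords = character(), truth = NULL) {
  if (!is.matrix(events)) events <- as.matrix(events)
  storage.mode(events) <- "double"
  if (length(channels) == 0L)
    md_stop("a sample needs at least one channel", "myodiff_invalid_sample")
  if (is.character(channels)) {
    channels <- data.frame(name = channels, range = 10000,
                           decades = 0, offset = 0,
                           stringsAsFactors = FALSE)
  }
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  if (is.null(channels$range)) channels$range <- 10000
  if (is.null(channels$decades)) channels$decades <- 0
  if (is.null(channels$offset)) channels$offset <- 0
  channels$index <- seq_len(nrow(channels))
  if (nrow(channels) == 0L)
    md_stop("a sample needs at least one channel", "myodiff_invalid_sample")
  if (anyDuplicated(channels$name))
    md_stop("channel names must be unique", "myodiff_invalid_sample")
  if (any(channels$range <= 0))
    md_stop("channel ranges must be positive", "myodiff_invalid_sample")
  if (ncol(events) != nrow(channels))
    md_stop("event matrix column count must equal channel count",
            "myodiff_invalid_sample")
  if (nrow(events) > 0 && any(!is.finite(events)))
    md_stop("event intensities must be finite", "myodiff_invalid_sample")
  if (!is.null(truth)) {
    truth <- as.data.frame(truth, stringsAsFactors = FALSE)
    if (nrow(truth) != nrow(events))
      md_stop("truth table must have one row per event",
              "myodiff_invalid_sample")
  }
  colnames(events) <- channels$name
  structure(list(sample_id = as.character(sample_id),
                 well_id = if (is.null(well_id)) NULL else as.character(well_id),
                 events = events, channels = channels,
                 keywords = keywords, truth = truth),
            class = "fcs_sample")
}

#' @export
print.fcs_sample <- function(x, ...) {
  cat(sprintf("<fcs_sample> %s%s: %d events x %d channels (%s)\n",
              x$sample_id,
              if (!is.null(x$well_id)) paste0(" [", x$well_id, "]") else "",
              nrow(x$events), nrow(x$channels),
              paste(x$channels$name, collapse = ", ")))
  invisible(x)
}

#' Number of events in a sample
#' @param sample A [fcs_sample()].
#' @return Integer event count.
#' @export
n_events <- function(sample) nrow(sample$events)

#' Assemble an experiment from samples and control-role assignments
#'
#' An experiment is the unit the pipeline analyzes: a set of acquisitions
#' plus a role map naming which sample is the double-negative control,
#' which the MyHC+ control, optionally a GFP+ control, and which are
#' target samples. Exactly one double-negative and one MyHC+ control are
#' required — they calibrate the GFP threshold.
#'
#' @param samples List of [fcs_sample()] objects.
#' @param roles Named list with elements `double_negative`, `myhc_positive`
#'   (each one sample_id), optionally `gfp_positive`, and `target`
#'   (character vector of sample_ids).
#' @return An object of class `fc_experiment`.
#' @export
fc_experiment <- function(samples, roles) {
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids))
    md_stop("sample ids must be unique within an experiment",
            "myodiff_config_error")
  names(samples) <- ids
  for (role in c("double_negative", "myhc_positive")) {
    if (length(roles[[role]]) != 1L || !(roles[[role]] %in% ids))
      md_stop(sprintf("role '%s' must name exactly one existing sample", role),
              "myodiff_config_error")
  }
  for (role in names(roles)) {
    missing <- setdiff(roles[[role]], ids)
    if (length(missing))
      md_stop(sprintf("role '%s' names unknown sample(s): %s", role,
                      paste(missing, collapse = ", ")),
              "myodiff_config_error")
  }
  structure(list(samples = samples, roles = roles), class = "fc_experiment")
}

#' @export
print.fc_experiment <- function(x, ...) {
  cat(sprintf("<fc_experiment> %d samples\n", length(x$samples)))
  for (role in names(x$roles))
    cat(sprintf("  %-16s %s\n", role, paste(x$roles[[role]], collapse = ", ")))
  invisible(x)
}

role_sample <- function(experiment, role) {
  experiment$samples[[experiment$roles[[role]][1]]]
}
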