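# End-to-end workflow: curate (debris gate + control-calibrated GFP
# threshold) -> GFP dose bins -> peak splitting -> population counts ->
# differentiation fractions -> QC -> export.

POP_ROOT <- "root"
POP_NONDEBRIS <- "/NonDebris"
POP_GFP <- "/NonDebris/GFP+"

#' Analysis configuration
#'
#' Defaults follow the assay's conventions: Guava-style channel names,
#' a fixed debris gate keeping FSC >= 100 and SSC >= 50 RFU, a 99%
#' quantile gate for the GFP threshold, up to three contiguous GFP
#' dose bins (the first bin's lower bound is always the fitted GFP
#' threshold), biexponential density space for peak splitting with a
#' 10 RFU fallback, and a 5% differentiation-control QC floor.
#'
#' @param gfp_channel,myhc_channel,fsc_channel,ssc_channel,fsc_h_channel
#'   Channel names; `.` and `-` separators are interchangeable when
#'   matching against file channel names.
#' @param debris_gate A [rect_gate()] on the scatter channels.
#' @param quantile_level Quantile for the control GFP threshold
#'   (default 0.99).
#' @param bins List of up to three [range_bin()]s, ordered, non-overlapping;
#'   the first bin's `low` may be `NA` — it is replaced by the fitted
#'   threshold.
#' @param split A [split_params()].
#' @param singlet_gating Apply [singlet_mask()] during curation
#'   (default `FALSE`; the assay assumes a single-cell suspension).
#' @param singlet_tolerance Tolerance passed to [singlet_mask()].
#' @param qc_min_control_fraction QC floor (percent) for the
#'   differentiation control (default 5).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(gfp_channel = "GRN-B-HLin",
                            myhc_channel = "RED-R-HLin",
                            fsc_channel = "FSC-HLin",
                            ssc_channel = "SSC-HLin",
                            fsc_h_channel = "FSC-H",
                            debris_gate = NULL,
                            quantile_level = 0.99,
                            bins = NULL,
                            split = split_params(),
                            singlet_gating = FALSE,
                            singlet_tolerance = 0.25,
                            qc_min_control_fraction = 5) {
  if (is.null(debris_gate))
    debris_gate <- rect_gate(fsc_channel, ssc_channel,
                             x_min = 100, y_min = 50)
  if (is.null(bins))
    bins <- list(range_bin("GFP-low", gfp_channel, NA, 100),
                 range_bin("GFP-medium", gfp_channel, 100, 1000),
                 range_bin("GFP-high", gfp_channel, 1000, 10000))
  if (quantile_level <= 0 || quantile_level >= 1)
    md_stop("quantile_level must lie in (0,1)", "myodiff_config_error")
  req <- c(gfp_channel, myhc_channel, fsc_channel, ssc_channel)
  if (anyDuplicated(normalize_channel_name(req)))
    md_stop("required channels must be distinct", "myodiff_config_error")
  structure(list(gfp_channel = gfp_channel, myhc_channel = myhc_channel,
                 fsc_channel = fsc_channel, ssc_channel = ssc_channel,
                 fsc_h_channel = fsc_h_channel, debris_gate = debris_gate,
                 quantile_level = quantile_level, bins = bins, split = split,
                 singlet_gating = isTRUE(singlet_gating),
                 singlet_tolerance = singlet_tolerance,
                 qc_min_control_fraction = qc_min_control_fraction),
            class = "analysis_config")
}

nondebris_mask <- function(sample, config) {
  mask <- apply_rect_gate(sample, config$debris_gate)
  if (config$singlet_gating)
    mask <- mask & singlet_mask(sample, config$singlet_tolerance,
                                config$fsc_channel, config$fsc_h_channel)
  mask
}

#' Fit the GFP threshold from the two calibration controls
#'
#' The threshold is the arithmetic mean of the `quantile_level` GFP
#' quantiles of the double-negative and MyHC+ controls, each computed on
#' the control's debris-gated (NonDebris) events. It separates GFP+
#' (transfected) from autofluorescent background cells and becomes the
#' lower bound of the first GFP bin.
#'
#' @param experiment A [fc_experiment()].
#' @param config An [analysis_config()].
#' @return Threshold in RFU.
#' @export
fit_gfp_threshold <- function(experiment, config = analysis_config()) {
  qs <- vapply(c("double_negative", "myhc_positive"), function(role) {
    if (is.null(experiment$roles[[role]]))
      md_stop(sprintf("experiment is missing the %s control", role),
              "myodiff_config_error")
    s <- role_sample(experiment, role)
    v <- channel_values(s, config$gfp_channel)[nondebris_mask(s, config)]
    if (length(v) < config$split$min_events)
      md_stop(sprintf(
        "control '%s' has only %d NonDebris events (need >= %d)",
        s$sample_id, length(v), config$split$min_events),
        "myodiff_insufficient_data")
    empirical_quantile(v, config$quantile_level)
  }, numeric(1))
  mean(qs)
}

new_tree <- function(sample_id) {
  structure(list(sample_id = sample_id, nodes = list(), splits = list(),
                 unbinned = NA_integer_), class = "gating_tree")
}

add_node <- function(tree, path, mask, parent) {
  if (!is.null(parent)) {
    pmask <- tree$nodes[[parent]]$mask
    if (any(mask & !pmask))
      md_stop(sprintf("node %s is not a subset of its parent %s", path, parent),
              "myodiff_internal_error")
  }
  tree$nodes[[path]] <- list(path = path, parent = parent, mask = mask,
                             count = sum(mask))
  tree
}

#' @export
print.gating_tree <- function(x, ...) {
  cat(sprintf("<gating_tree> %s\n", x$sample_id))
  for (nd in x$nodes)
    cat(sprintf("  %-45s %d\n", nd$path, nd$count))
  invisible(x)
}

#' Curate an experiment: debris gate and GFP threshold
#'
#' Builds, per sample, the top of the gating hierarchy: `root` (all
#' events), `/NonDebris` (debris-gate survivors, optionally singlet-gated),
#' and `/NonDebris/GFP+` (NonDebris events with GFP at or above the
#' control-fitted threshold).
#'
#' @param experiment A [fc_experiment()].
#' @param config An [analysis_config()].
#' @return An object of class `gating_tree_set`: one gating tree per
#'   sample plus the fitted `threshold` (RFU).
#' @export
curate <- function(experiment, config = analysis_config()) {
  threshold <- fit_gfp_threshold(experiment, config)
  trees <- lapply(experiment$samples, function(s) {
    tree <- new_tree(s$sample_id)
    root <- rep(TRUE, n_events(s))
    tree <- add_node(tree, POP_ROOT, root, NULL)
    nd <- nondebris_mask(s, config)
    tree <- add_node(tree, POP_NONDEBRIS, nd, POP_ROOT)
    gfp <- nd & channel_values(s, config$gfp_channel) >= threshold
    add_node(tree, POP_GFP, gfp, POP_NONDEBRIS)
  })
  structure(list(trees = trees, threshold = threshold, config = config,
                 experiment = experiment),
            class = "gating_tree_set")
}

resolved_bins <- function(config, threshold) {
  bins <- config$bins
  if (length(bins) < 1L)
    md_stop("at least one GFP bin must be configured", "myodiff_config_error")
  if (length(bins) > 3L)
    md_stop("at most three GFP bins are supported", "myodiff_config_error")
  bins[[1]]$low <- threshold
  lows <- vapply(bins, `[[`, numeric(1), "low")
  highs <- vapply(bins, `[[`, numeric(1), "high")
  if (any(lows >= highs) || is.unsorted(lows, strictly = TRUE) ||
      any(highs[-length(bins)] > lows[-1]))
    md_stop("bins must be ordered and non-overlapping", "myodiff_config_error")
  bins
}

#' Add GFP dose bins to a curated tree set
#'
#' Adds `/NonDebris/GFP+/<bin>` nodes. Bin masks are subsets of the GFP+
#' node; GFP+ events above the top bin or inside an inter-bin gap belong
#' to no bin — they are counted per sample in the `unbinned` field so
#' totals stay auditable.
#'
#' @param tree_set Output of [curate()].
#' @param config An [analysis_config()] (defaults to the one used for
#'   curation).
#' @return The tree set with bin nodes added and `bins` (resolved bounds,
#'   first lower bound = fitted threshold) attached.
#' @export
assign_bins <- function(tree_set, config = tree_set$config) {
  bins <- resolved_bins(config, tree_set$threshold)
  exp <- tree_set$experiment
  tree_set$trees <- lapply(tree_set$trees, function(tree) {
    s <- exp$samples[[tree$sample_id]]
    gfp_mask <- tree$nodes[[POP_GFP]]$mask
    binned <- rep(FALSE, n_events(s))
    for (b in bins) {
      m <- gfp_mask & apply_range_bin(s, b)
      tree <- add_node(tree, paste0(POP_GFP, "/", b$label), m, POP_GFP)
      binned <- binned | m
    }
    tree$unbinned <- sum(gfp_mask & !binned)
    tree
  })
  tree_set$bins <- bins
  tree_set
}

#' Split MyHC peaks within each GFP bin
#'
#' For every (sample, bin) with at least `min_events` members, runs
#' [mindensity_cutpoint()] on the bin's MyHC intensities and adds a
#' `/NonDebris/GFP+/<bin>/MyHC+` node holding events at or above the
#' cutpoint. Smaller bins are flagged not analyzable and get no MyHC+
#' node.
#'
#' @param tree_set Output of [assign_bins()].
#' @param config An [analysis_config()].
#' @return The tree set with MyHC+ nodes and per-(sample, bin)
#'   [split_result][mindensity_cutpoint()]s in each tree's `splits` field.
#' @export
split_peaks <- function(tree_set, config = tree_set$config) {
  if (is.null(tree_set$bins))
    md_stop("assign_bins() must run before split_peaks()",
            "myodiff_config_error")
  exp <- tree_set$experiment
  tree_set$trees <- lapply(tree_set$trees, function(tree) {
    s <- exp$samples[[tree$sample_id]]
    myhc <- channel_values(s, config$myhc_channel)
    for (b in tree_set$bins) {
      bin_path <- paste0(POP_GFP, "/", b$label)
      bmask <- tree$nodes[[bin_path]]$mask
      res <- mindensity_cutpoint(myhc[bmask], config$split)
      tree$splits[[b$label]] <- res
      if (res$analyzable) {
        tree <- add_node(tree, paste0(bin_path, "/MyHC+"),
                         bmask & myhc >= res$cutpoint, bin_path)
      }
    }
    tree
  })
  tree_set
}

#' Population statistics table
#'
#' One row per population node per sample, with the hierarchical
#' population paths of the assay's nomenclature (`root`, `/NonDebris`,
#' `/NonDebris/GFP+`, `/NonDebris/GFP+/<bin>`,
#' `/NonDebris/GFP+/<bin>/MyHC+`).
#'
#' @param tree_set A curated (and usually binned/split) tree set.
#' @return Data frame with columns `sample`, `pop`, `count`.
#' @export
population_stats <- function(tree_set) {
  rows <- lapply(tree_set$trees, function(tree) {
    data.frame(sample = tree$sample_id,
               pop = vapply(tree$nodes, `[[`, character(1), "path"),
               count = vapply(tree$nodes, function(nd) as.integer(nd$count),
                              integer(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differentiation fractions per sample and GFP bin
#'
#' The assay's readout: the percentage of differentiated (MyHC+) cells
#' among the cells of each GFP bin,
#' `100 * count(<bin>/MyHC+) / count(<bin>)`. Bins with zero members or
#' too few events for peak splitting are reported not analyzable with no
#' fraction.
#'
#' @param x A `gating_tree_set` (after [split_peaks()]) or a population
#'   statistics data frame from [population_stats()].
#' @param ... Unused.
#' @return Data frame with columns `sample`, `bin`, `myhc_pos`,
#'   `bin_total`, `fraction_percent`, `method`, `analyzable`.
#' @export
differentiation_fractions <- function(x, ...) UseMethod("differentiation_fractions")

#' @export
differentiation_fractions.gating_tree_set <- function(x, ...) {
  rows <- lapply(x$trees, function(tree) {
    do.call(rbind, lapply(x$bins, function(b) {
      bin_path <- paste0(POP_GFP, "/", b$label)
      total <- tree$nodes[[bin_path]]$count
      res <- tree$splits[[b$label]]
      analyzable <- !is.null(res) && res$analyzable && total > 0
      pos <- if (analyzable) tree$nodes[[paste0(bin_path, "/MyHC+")]]$count
             else NA_integer_
      data.frame(sample = tree$sample_id, bin = b$label,
                 myhc_pos = pos, bin_total = total,
                 fraction_percent = if (analyzable) 100 * pos / total else NA_real_,
                 method = if (is.null(res)) NA_character_ else res$method,
                 analyzable = analyzable, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
differentiation_fractions.data.frame <- function(x, ...) {
  bins <- x[grepl("^/NonDebris/GFP\\+/[^/]+$", x$pop), ]
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    b <- bins[i, ]
    label <- sub("^/NonDebris/GFP\\+/", "", b$pop)
    pos_row <- x[x$sample == b$sample & x$pop == paste0(b$pop, "/MyHC+"), ]
    analyzable <- nrow(pos_row) == 1L && b$count > 0
    pos <- if (analyzable) pos_row$count else NA_integer_
    data.frame(sample = b$sample, bin = label, myhc_pos = pos,
               bin_total = b$count,
               fraction_percent = if (analyzable) 100 * pos / b$count else NA_real_,
               method = NA_character_, analyzable = analyzable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' QC flag for the differentiation control
#'
#' A differentiation control incubated in low-serum medium should exceed
#' the configured floor of MyHC+ cells; a fraction strictly below it
#' indicates poor differentiation of the culture (flag
#' `"poor_differentiation"`).
#'
#' @param result A row (or data frame of rows) from
#'   [differentiation_fractions()].
#' @param min_fraction QC floor in percent (default 5).
#' @return Character vector: `"poor_differentiation"` or `"ok"` per row
#'   (`NA` where the bin was not analyzable).
#' @export
qc_differentiation_control <- function(result, min_fraction = 5) {
  ifelse(!result$analyzable, NA_character_,
         ifelse(result$fraction_percent < min_fraction,
                "poor_differentiation", "ok"))
}

#' Quadrant-marker differentiation analysis
#'
#' The manual-analysis surrogate: fixed thresholds on both axes (classically
#' ~10 RFU, where the double-negative cluster is bounded) instead of the
#' control-calibrated threshold and density splitting. Within each GFP bin,
#' an event is MyHC+ iff its MyHC intensity is at or above the quadrant's
#' y threshold. The manual workflow's basic gates exclude both debris and
#' doublets, so the scatter-ratio singlet gate is applied here by default
#' (unlike the automated pipeline, which assumes a single-cell suspension).
#' Used to check that the automated pipeline and the manual quadrant
#' counting agree.
#'
#' @param experiment A [fc_experiment()].
#' @param scheme A [quadrant_scheme()] (default thresholds 10/10 RFU).
#' @param bins List of [range_bin()]s with literal bounds.
#' @param config An [analysis_config()] (debris gate and channels).
#' @param singlet Apply [singlet_mask()] as part of the basic gates
#'   (default `TRUE`).
#' @return Data frame with columns `sample`, `bin`, `myhc_pos`,
#'   `bin_total`, `fraction_percent`.
#' @export
quadrant_analysis <- function(experiment, scheme = quadrant_scheme(10, 10),
                              bins, config = analysis_config(),
                              singlet = TRUE) {
  rows <- lapply(experiment$samples, function(s) {
    nd <- nondebris_mask(s, config)
    if (singlet)
      nd <- nd & singlet_mask(s, config$singlet_tolerance,
                              config$fsc_channel, config$fsc_h_channel)
    g <- channel_values(s, config$gfp_channel)
    m <- channel_values(s, config$myhc_channel)
    do.call(rbind, lapply(bins, function(b) {
      inb <- nd & g >= scheme$x_threshold & apply_range_bin(s, b)
      pos <- sum(inb & m >= scheme$y_threshold)
      data.frame(sample = s$sample_id, bin = b$label, myhc_pos = pos,
                 bin_total = sum(inb),
                 fraction_percent = if (sum(inb) > 0) 100 * pos / sum(inb)
                                    else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Import -> curate -> bin -> split peaks -> count -> fractions -> QC ->
#' export. Deterministic: re-running on the same inputs produces
#' byte-identical CSVs.
#'
#' @param input A [fc_experiment()], a directory of `.fcs` files containing
#'   a `manifest.csv` (columns `file`, `sample_id`, `role`), or a single
#'   merged `.fcs` file (then `roles` is required).
#' @param config An [analysis_config()].
#' @param out_dir Output directory; receives `population_stats.csv`
#'   (header `sample,pop,count`), `differentiation.csv` and `run_log.txt`.
#' @param roles Role map as in [fc_experiment()] (required when `input` is
#'   a merged file or a directory without a manifest); entries may name
#'   sample ids or well ids.
#' @return Invisibly, a list with `stats`, `fractions`, `tree_set`,
#'   `threshold` and `qc`.
#' @export
run_pipeline <- function(input, config = analysis_config(), out_dir,
                         roles = NULL) {
  experiment <- load_experiment(input, roles)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("myodiff %s", as.character(utils::packageVersion("myodiff")))
  note("samples: %s", paste(names(experiment$samples), collapse = ", "))
  note("debris gate: %s >= %g, %s >= %g RFU", config$fsc_channel,
       config$debris_gate$x_min, config$ssc_channel, config$debris_gate$y_min)
  note("quantile level: %g; singlet gating: %s", config$quantile_level,
       config$singlet_gating)
  note("split: transform=%s (cofactor %g RFU), min_events=%d, prominence=%g, fallback=%g RFU",
       config$split$transform$kind, config$split$transform$cofactor,
       config$split$min_events, config$split$prominence,
       config$split$fallback_threshold)

  tree_set <- withCallingHandlers(
    split_peaks(assign_bins(curate(experiment, config))),
    warning = function(w) {
      note("warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  note("fitted GFP threshold: %.6g RFU", tree_set$threshold)
  for (b in tree_set$bins)
    note("bin %s: [%.6g, %.6g) RFU", b$label, b$low, b$high)
  for (tree in tree_set$trees)
    note("sample %s: %d GFP+ events outside all bins", tree$sample_id,
         tree$unbinned)

  stats <- population_stats(tree_set)
  fr <- differentiation_fractions(tree_set)
  myhc_ctrl <- experiment$roles$myhc_positive
  qc <- qc_differentiation_control(
    fr[fr$sample == myhc_ctrl & fr$bin == tree_set$bins[[1]]$label, ],
    config$qc_min_control_fraction)
  note("differentiation-control QC (%s, %s): %s", myhc_ctrl,
       tree_set$bins[[1]]$label,
       if (length(qc) && !is.na(qc)) qc else "not analyzable")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  export_population_stats(stats, file.path(out_dir, "population_stats.csv"))
  fr_out <- fr
  fr_out$fraction_percent <- ifelse(is.na(fr$fraction_percent), "",
                                    format(fr$fraction_percent, digits = 15))
  utils::write.table(fr_out, file.path(out_dir, "differentiation.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(list(stats = stats, fractions = fr, tree_set = tree_set,
                 threshold = tree_set$threshold, qc = qc))
}

load_experiment <- function(input, roles = NULL) {
  if (inherits(input, "fc_experiment")) return(input)
  if (dir.exists(input)) {
    manifest_path <- file.path(input, "manifest.csv")
    files <- list.files(input, pattern = "\\.fcs$", ignore.case = TRUE,
                        full.names = TRUE)
    samples <- unlist(lapply(sort(files), read_fcs), recursive = FALSE)
    if (is.null(roles) && file.exists(manifest_path)) {
      man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
      roles <- split(man$sample_id, man$role)
    }
  } else {
    samples <- read_fcs(input)
  }
  if (is.null(roles))
    md_stop("role assignments are required (roles argument or manifest.csv)",
            "myodiff_config_error")
  # allow role entries to reference wells instead of sample ids
  wells <- vapply(samples, function(s)
    if (is.null(s$well_id)) NA_character_ else s$well_id, character(1))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  roles <- lapply(roles, function(v)
    vapply(v, function(x) if (x %in% ids) x else ids[match(x, wells)],
           character(1), USE.NAMES = FALSE))
  fc_experiment(samples, roles)
}
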