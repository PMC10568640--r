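# Synthetic-experiment generator: emulates a 4-channel (plus FSC height)
# acquisition of a myoblast differentiation assay — debris, doublets,
# autofluorescent background, a transfected GFP+ subpopulation spanning
# ~10^1-10^4 RFU, and a bimodal MyHC channel — with per-event ground truth.

SIM_CHANNELS <- c("FSC-HLin", "SSC-HLin", "GRN-B-HLin", "RED-R-HLin", "FSC-H")

#' Simulation configuration
#'
#' Population intensities are lognormal; locations and scales are given in
#' log10 RFU. Defaults place the double-negative fluorescence cluster
#' around 5 RFU (below the ~10 RFU manual quadrant marker), differentiated
#' MyHC around 300 RFU, cells at FSC ~500 / SSC ~250, and debris scatter at
#' 20% of the cell locations, so the default debris gate
#' (FSC >= 100, SSC >= 50) behaves as intended.
#'
#' Differentiation is assigned per cell before intensities are drawn, via
#' the dose-response law [dose_response()]: untransfected cells (GFP dose
#' 0) differentiate with baseline probability `p0`; the expressed construct
#' suppresses differentiation with half-effect at `K` RFU, and a drug
#' effect `drug_effect` in \[0, 1\] rescues it (1 = full rescue).
#'
#' @param n_events Events per sample (default 30000, the standard
#'   acquisition depth of the assay).
#' @param debris_fraction,doublet_fraction,transfection_fraction Fractions
#'   in \[0, 1\] (doublets at most 0.5).
#' @param gfp_dose_meanlog10,gfp_dose_sdlog10 Lognormal (log10) parameters
#'   of the expression dose of transfected cells; defaults span
#'   ~10^1-10^4 RFU.
#' @param p0 Baseline differentiation probability.
#' @param K,hill Dose-response midpoint (RFU) and Hill exponent.
#' @param drug_effect Rescue strength E in \[0, 1\] for target samples.
#' @param e_vehicle,e_drug Rescue strengths of the two target samples
#'   emitted by [simulate_experiment()].
#' @param fsc_cell,ssc_cell,fsc_debris,ssc_debris,gfp_bg,myhc_bg,myhc_pos,debris_fluor
#'   Two-element `c(location, scale)` vectors in log10 RFU.
#' @param fsc_h_noise Log10-scale of the singlet area/height ratio noise.
#' @param seed Optional integer seed; given the same config the simulator
#'   is bit-reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_events = 30000L,
                       debris_fraction = 0.05,
                       doublet_fraction = 0.02,
                       transfection_fraction = 0.5,
                       gfp_dose_meanlog10 = 2.5,
                       gfp_dose_sdlog10 = 0.75,
                       p0 = 0.4, K = 150, hill = 1.5,
                       drug_effect = 0,
                       e_vehicle = 0, e_drug = 0.9,
                       fsc_cell = c(log10(500), 0.12),
                       ssc_cell = c(log10(250), 0.15),
                       fsc_debris = c(log10(100), 0.15),
                       ssc_debris = c(log10(50), 0.15),
                       gfp_bg = c(log10(5), 0.15),
                       myhc_bg = c(log10(5), 0.15),
                       myhc_pos = c(log10(300), 0.2),
                       debris_fluor = c(log10(2), 0.2),
                       fsc_h_noise = 0.03,
                       seed = NULL) {
  cfg <- as.list(environment())
  for (f in c("debris_fraction", "doublet_fraction", "transfection_fraction",
              "drug_effect", "e_vehicle", "e_drug", "p0")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      md_stop(sprintf("%s must lie in [0,1]", f), "myodiff_config_error")
  }
  if (cfg$doublet_fraction > 0.5)
    md_stop("doublet_fraction must be at most 0.5", "myodiff_config_error")
  if (n_events <= 0)
    md_stop("n_events must be positive", "myodiff_config_error")
  if (K <= 0) md_stop("K must be positive", "myodiff_config_error")
  cfg$n_events <- as.integer(n_events)
  structure(cfg, class = "sim_config")
}

#' Dose-dependent differentiation probability
#'
#' `p(g) = p0 * (1 - (1 - E) * g^h / (g^h + K^h))`: at dose 0 the baseline
#' `p0`; increasing construct dose suppresses differentiation down to
#' `p0 * E` at saturation; a drug effect `E = 1` is a full rescue
#' (`p(g) = p0` for every dose).
#'
#' @param gfp Expression dose in RFU (vectorized, `>= 0`).
#' @param p0 Baseline probability.
#' @param K Half-effect dose, RFU.
#' @param hill Hill exponent.
#' @param drug_effect Rescue strength E in \[0, 1\].
#' @return Probabilities, same length as `gfp`.
#' @export
dose_response <- function(gfp, p0 = 0.4, K = 150, hill = 1.5,
                          drug_effect = 0) {
  occ <- ifelse(gfp <= 0, 0, gfp^hill / (gfp^hill + K^hill))
  p0 * (1 - (1 - drug_effect) * occ)
}

rlnorm10 <- function(n, par) 10^stats::rnorm(n, par[1], par[2])

#' Simulate one acquisition
#'
#' @param config A [sim_config()].
#' @param role One of `"double_negative"`, `"gfp_positive"`,
#'   `"myhc_positive"`, `"target"`. Controls are constructed per their
#'   definition: the double-negative control has neither transfected nor
#'   differentiated cells, the GFP+ control has transfected but no
#'   differentiated cells, the MyHC+ control differentiated but no
#'   transfected cells; targets have both, with dose-dependent
#'   differentiation.
#' @param sample_id,well_id Identifiers for the emitted sample.
#' @return A [fcs_sample()] carrying a `truth` data frame (columns `label`,
#'   `is_doublet`, `gfp_true`, `differentiated`).
#' @export
simulate_sample <- function(config, role, sample_id = role, well_id = NULL) {
  roles <- c("double_negative", "gfp_positive", "myhc_positive", "target")
  if (!role %in% roles)
    md_stop(sprintf("unknown role '%s' (expected one of %s)", role,
                    paste(roles, collapse = ", ")), "myodiff_config_error")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_events

  is_debris <- stats::runif(n) < config$debris_fraction
  transfected <- !is_debris &
    (role %in% c("gfp_positive", "target")) &
    stats::runif(n) < config$transfection_fraction
  gfp_true <- numeric(n)
  gfp_true[transfected] <- rlnorm10(sum(transfected),
                                    c(config$gfp_dose_meanlog10,
                                      config$gfp_dose_sdlog10))
  p_diff <- switch(role,
    double_negative = ,
    gfp_positive = rep(0, n),
    myhc_positive = rep(config$p0, n),
    target = dose_response(gfp_true, config$p0, config$K, config$hill,
                           config$drug_effect))
  differentiated <- !is_debris & stats::runif(n) < p_diff

  draw_events <- function(is_debris, gfp_true, differentiated) {
    n <- length(is_debris)
    fsc <- ifelse(is_debris, rlnorm10(n, config$fsc_debris),
                  rlnorm10(n, config$fsc_cell))
    ssc <- ifelse(is_debris, rlnorm10(n, config$ssc_debris),
                  rlnorm10(n, config$ssc_cell))
    gfp <- gfp_true + ifelse(is_debris, rlnorm10(n, config$debris_fluor),
                             rlnorm10(n, config$gfp_bg))
    myhc <- ifelse(is_debris, rlnorm10(n, config$debris_fluor),
                   ifelse(differentiated, rlnorm10(n, config$myhc_pos),
                          rlnorm10(n, config$myhc_bg)))
    fsc_h <- fsc / 10^stats::rnorm(n, 0, config$fsc_h_noise)
    cbind(fsc, ssc, gfp, myhc, fsc_h)
  }
  events <- draw_events(is_debris, gfp_true, differentiated)
  colnames(events) <- SIM_CHANNELS

  truth <- data.frame(
    label = truth_label(is_debris, transfected, differentiated),
    is_doublet = FALSE, gfp_true = gfp_true,
    differentiated = differentiated, stringsAsFactors = FALSE)

  s <- fcs_sample(events, channels = SIM_CHANNELS, sample_id = sample_id,
                  well_id = well_id, truth = truth)
  if (config$doublet_fraction > 0)
    s <- inject_doublets(s, config$doublet_fraction, config)
  s
}

truth_label <- function(is_debris, transfected, differentiated) {
  ifelse(is_debris, "debris",
    ifelse(transfected & differentiated, "double_pos",
      ifelse(transfected, "gfp_only",
        ifelse(differentiated, "myhc_only", "neg"))))
}

#' Inject doublets into a simulated sample
#'
#' Each event is independently flagged a doublet with probability
#' `fraction`; a flagged event is merged with a random partner event: area
#' channels (scatter and fluorescence) are summed, the height channel takes
#' the maximum of the pair, so the doublet's area/height ratio is about
#' twice the singlet ratio. Ground truth is merged at the event level
#' (`differentiated` is the OR of the pair, `gfp_true` the sum, `debris`
#' only if both constituents are debris).
#'
#' @param sample A simulated [fcs_sample()] with a truth table.
#' @param fraction Doublet fraction in \[0, 0.5\].
#' @param config A [sim_config()] (unused beyond validation hooks; kept for
#'   symmetry).
#' @return The sample with merged doublet events and updated truth.
#' @export
inject_doublets <- function(sample, fraction, config = NULL) {
  if (fraction < 0 || fraction > 0.5)
    md_stop("doublet fraction must lie in [0, 0.5]", "myodiff_config_error")
  n <- n_events(sample)
  if (fraction == 0 || n < 2L) return(sample)
  flag <- stats::runif(n) < fraction
  idx <- which(flag)
  if (length(idx) == 0L) return(sample)
  partner <- vapply(idx, function(i) sample.int(n, 1), integer(1))
  same <- partner == idx
  partner[same] <- (idx[same] %% n) + 1L

  ev <- sample$events
  area_cols <- match(c("FSC-HLin", "SSC-HLin", "GRN-B-HLin", "RED-R-HLin"),
                     colnames(ev))
  h_col <- match("FSC-H", colnames(ev))
  ev[idx, area_cols] <- ev[idx, area_cols] + ev[partner, area_cols]
  ev[idx, h_col] <- pmax(ev[idx, h_col], ev[partner, h_col])

  tr <- sample$truth
  deb <- tr$label == "debris"
  merged_debris <- deb[idx] & deb[partner]
  merged_transfected <- (tr$gfp_true[idx] + tr$gfp_true[partner]) > 0
  merged_diff <- tr$differentiated[idx] | tr$differentiated[partner]
  tr$gfp_true[idx] <- tr$gfp_true[idx] + tr$gfp_true[partner]
  tr$differentiated[idx] <- merged_diff & !merged_debris
  tr$label[idx] <- truth_label(merged_debris, merged_transfected,
                               tr$differentiated[idx])
  tr$is_doublet[idx] <- TRUE

  fcs_sample(ev, channels = sample$channels, sample_id = sample$sample_id,
             well_id = sample$well_id, keywords = sample$keywords,
             truth = tr)
}

#' Ground-truth differentiation fraction per GFP bin
#'
#' Recomputes, from the per-event truth table, the fraction of
#' differentiated events among the events whose measured GFP intensity
#' falls in each bin (optionally restricted by a mask, e.g. a gating-tree
#' bin membership).
#'
#' @param sample A simulated [fcs_sample()].
#' @param bins List of [range_bin()] objects.
#' @param mask Optional logical mask restricting the events considered.
#' @return Data frame with columns `bin`, `n`, `n_differentiated`,
#'   `fraction_percent`.
#' @export
true_bin_fractions <- function(sample, bins, mask = NULL) {
  if (is.null(sample$truth))
    md_stop("sample carries no ground truth", "myodiff_input_error")
  if (is.null(mask)) mask <- rep(TRUE, n_events(sample))
  rows <- lapply(bins, function(b) {
    inb <- mask & apply_range_bin(sample, b)
    nd <- sum(sample$truth$differentiated[inb])
    data.frame(bin = b$label, n = sum(inb), n_differentiated = nd,
               fraction_percent = if (sum(inb) > 0) 100 * nd / sum(inb) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a complete experiment
#'
#' Emits the standard five acquisitions of the assay: a double-negative
#' control, a GFP+ control, a MyHC+ control, and two target samples —
#' oncogene + vehicle (`drug_effect = e_vehicle`) and oncogene + drug
#' (`drug_effect = e_drug`, a stronger rescue, so its true differentiation
#' exceeds the vehicle's by construction). Optionally writes each sample as
#' an FCS 3.0 file with a truth-sidecar CSV and a manifest mapping
#' filenames to roles.
#'
#' @param config A [sim_config()]; its `seed` makes the whole experiment
#'   reproducible (per-sample seeds are derived as `seed + 1 .. seed + 5`).
#' @param out_dir Optional directory to write FCS files, truth sidecars and
#'   `manifest.csv` into.
#' @return A [fc_experiment()]; if `out_dir` is given, the manifest data
#'   frame is attached as attribute `"manifest"`.
#' @export
simulate_experiment <- function(config = sim_config(), out_dir = NULL) {
  spec <- list(
    list(id = "01_double_negative", well = "A01", role = "double_negative",
         cfg = config),
    list(id = "02_gfp_control", well = "A02", role = "gfp_positive",
         cfg = config),
    list(id = "03_myhc_control", well = "A03", role = "myhc_positive",
         cfg = config),
    list(id = "04_target_vehicle", well = "A04", role = "target",
         cfg = modify_config(config, drug_effect = config$e_vehicle)),
    list(id = "05_target_drug", well = "A05", role = "target",
         cfg = modify_config(config, drug_effect = config$e_drug))
  )
  samples <- vector("list", length(spec))
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    cfg <- s$cfg
    if (!is.null(config$seed)) cfg$seed <- config$seed + i
    samples[[i]] <- simulate_sample(cfg, s$role, sample_id = s$id,
                                    well_id = s$well)
  }
  roles <- list(
    double_negative = "01_double_negative",
    gfp_positive = "02_gfp_control",
    myhc_positive = "03_myhc_control",
    target = c("04_target_vehicle", "05_target_drug"))
  exp <- fc_experiment(samples, roles)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- do.call(rbind, lapply(seq_along(spec), function(i) {
      s <- spec[[i]]
      fn <- paste0(s$id, ".fcs")
      write_fcs(samples[[i]], file.path(out_dir, fn))
      utils::write.csv(samples[[i]]$truth,
                       file.path(out_dir, paste0(s$id, "_truth.csv")),
                       row.names = FALSE)
      data.frame(file = fn, sample_id = s$id, well = s$well, role = s$role,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    attr(exp, "manifest") <- manifest
  }
  exp
}

modify_config <- function(config, ...) {
  new <- config
  repl <- list(...)
  new[names(repl)] <- repl
  new
}
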