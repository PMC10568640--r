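# Primitive gates and the density machinery behind peak splitting.

#' Type-7 sample quantile
#'
#' The quantile gate places a threshold at a stated sample quantile of a
#' control population (here, the level below which 99% of control cells
#' are found). Uses the linear-interpolation (type-7) estimator: with
#' sorted values x1..xn and h = (n-1)q, the result is
#' x[floor(h)+1] + (h - floor(h)) * (x[floor(h)+2] - x[floor(h)+1]).
#'
#' @param values Numeric vector with at least one finite value.
#' @param q Quantile level in (0, 1).
#' @return The quantile, in the units of `values`.
#' @examples
#' empirical_quantile(1:100, 0.99)  # 99.01
#' @export
empirical_quantile <- function(values, q) {
  values <- values[is.finite(values)]
  if (length(values) == 0L)
    md_stop("no finite values to take a quantile of",
            "myodiff_insufficient_data")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    md_stop("q must be a single fraction in (0,1)", "myodiff_config_error")
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

#' Rectangular gate
#'
#' @param channel_x,channel_y Channel names.
#' @param x_min,x_max,y_min,y_max Bounds in RFU; `Inf` leaves an axis
#'   unbounded above. Membership is half-open: `min <= v < max`.
#' @return An object of class `rect_gate`.
#' @export
rect_gate <- function(channel_x, channel_y, x_min = -Inf, x_max = Inf,
                      y_min = -Inf, y_max = Inf) {
  if (x_min >= x_max || y_min >= y_max)
    md_stop("gate bounds must satisfy min < max", "myodiff_config_error")
  structure(list(channel_x = channel_x, channel_y = channel_y,
                 x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "rect_gate")
}

#' Apply a rectangular gate
#'
#' @param sample A [fcs_sample()].
#' @param gate A [rect_gate()].
#' @return Logical membership mask, one entry per event.
#' @export
apply_rect_gate <- function(sample, gate) {
  x <- channel_values(sample, gate$channel_x)
  y <- channel_values(sample, gate$channel_y)
  x >= gate$x_min & x < gate$x_max & y >= gate$y_min & y < gate$y_max
}

#' One-dimensional intensity bin
#'
#' GFP gene-dose bins stratify transfected cells by construct expression
#' level. Membership is half-open, `low <= v < high`, so contiguous bins
#' sharing a boundary classify every event exactly once.
#'
#' @param label Bin label (e.g. `"GFP-low"`).
#' @param channel Channel name.
#' @param low,high Bounds in RFU, `low < high`.
#' @return An object of class `range_bin`.
#' @export
range_bin <- function(label, channel, low, high) {
  if (!is.na(low) && low >= high)
    md_stop("bin bounds must satisfy low < high", "myodiff_config_error")
  structure(list(label = label, channel = channel, low = low, high = high),
            class = "range_bin")
}

#' Apply a one-dimensional bin
#'
#' @param sample A [fcs_sample()].
#' @param bin A [range_bin()].
#' @return Logical membership mask.
#' @export
apply_range_bin <- function(sample, bin) {
  v <- channel_values(sample, bin$channel)
  v >= bin$low & v < bin$high
}

#' Quadrant thresholds for a GFP x MyHC dot plot
#'
#' @param x_threshold GFP (x-axis) threshold, RFU.
#' @param y_threshold MyHC (y-axis) threshold, RFU.
#' @return An object of class `quadrant_scheme`.
#' @export
quadrant_scheme <- function(x_threshold, y_threshold) {
  if (x_threshold <= 0 || y_threshold <= 0)
    md_stop("quadrant thresholds must be positive", "myodiff_config_error")
  structure(list(x_threshold = x_threshold, y_threshold = y_threshold),
            class = "quadrant_scheme")
}

#' Count events per quadrant
#'
#' Quadrant placement follows the standard dot-plot convention of the
#' assay: Q1 MyHC+ only (top left), Q2 double-positive (top right),
#' Q3 double-negative (bottom left), Q4 GFP+ only (bottom right). The four
#' counts always partition the base mask.
#'
#' @param sample A [fcs_sample()].
#' @param scheme A [quadrant_scheme()].
#' @param gfp_channel,myhc_channel Channel names for the two axes.
#' @param base_mask Logical mask restricting which events are counted
#'   (default: all).
#' @return Named integer vector `c(Q1=, Q2=, Q3=, Q4=)`.
#' @export
quadrant_counts <- function(sample, scheme,
                            gfp_channel = "GRN-B-HLin",
                            myhc_channel = "RED-R-HLin",
                            base_mask = NULL) {
  g <- channel_values(sample, gfp_channel)
  m <- channel_values(sample, myhc_channel)
  if (is.null(base_mask)) base_mask <- rep(TRUE, length(g))
  if (length(base_mask) != length(g))
    md_stop("base_mask length must equal the event count",
            "myodiff_input_error")
  gp <- g >= scheme$x_threshold
  mp <- m >= scheme$y_threshold
  c(Q1 = sum(base_mask & !gp & mp),
    Q2 = sum(base_mask & gp & mp),
    Q3 = sum(base_mask & !gp & !mp),
    Q4 = sum(base_mask & gp & !mp))
}

#' Gaussian kernel density of transformed intensities
#'
#' Bandwidth is Silverman's rule of thumb,
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, and the grid spans the
#' transformed data range extended by three bandwidths on each side.
#'
#' @param values Intensity vector, RFU.
#' @param transform A [transform_spec()] (default linear).
#' @param grid_size Number of grid points (default 512).
#' @param bw Optional bandwidth override (transformed units); by default
#'   computed from the data by the rule above.
#' @return List with `grid`, `density` (both length `grid_size`) and `bw`,
#'   all in transformed units.
#' @export
kde_density <- function(values, transform = transform_spec("linear"),
                        grid_size = 512L, bw = NULL) {
  t <- apply_transform(values, transform)
  if (length(unique(t)) < 2L)
    md_stop("density estimation needs at least 2 distinct values",
            "myodiff_degenerate_distribution")
  if (is.null(bw)) bw <- stats::bw.nrd0(t)
  d <- stats::density(t, bw = bw, kernel = "gaussian", n = grid_size,
                      from = min(t) - 3 * bw, to = max(t) + 3 * bw)
  list(grid = d$x, density = d$y, bw = bw)
}

#' Locate density peaks by prominence
#'
#' Finds local maxima of a density curve and keeps those whose topographic
#' prominence (height above the higher of the two flanking key saddles) is
#' at least `min_prominence_fraction` of the curve maximum; this suppresses
#' shot-noise wiggles that would fake bimodality.
#'
#' @param grid,density Output of [kde_density()].
#' @param min_prominence_fraction Fraction of the maximum density
#'   (default 0.05).
#' @return Numeric vector of peak positions (transformed units), sorted by
#'   peak height, tallest first. May be empty.
#' @export
find_density_peaks <- function(grid, density, min_prominence_fraction = 0.05) {
  n <- length(density)
  if (n < 3L || max(density) <= 0) return(numeric(0))
  i <- 2:(n - 1)
  peak_idx <- i[density[i] > density[i - 1] & density[i] > density[i + 1]]
  if (length(peak_idx) == 0L) return(numeric(0))
  prominence <- vapply(peak_idx, function(j) {
    h <- density[j]
    left <- density[1:(j - 1)]
    higher_l <- which(left > h)
    left_min <- min(left[if (length(higher_l)) (max(higher_l) + 1):(j - 1) else 1:(j - 1)])
    right <- density[(j + 1):n]
    higher_r <- which(right > h)
    right_min <- min(right[if (length(higher_r)) 1:(min(higher_r) - 1) else seq_along(right)])
    h - max(left_min, right_min)
  }, numeric(1))
  keep <- prominence >= min_prominence_fraction * max(density)
  peak_idx <- peak_idx[keep]
  if (length(peak_idx) == 0L) return(numeric(0))
  ord <- order(density[peak_idx], decreasing = TRUE)
  grid[peak_idx[ord]]
}

#' Parameters for peak splitting
#'
#' @param transform A [transform_spec()]; density estimation runs in this
#'   space (default biexponential, cofactor 5 RFU, because RFU span ~4
#'   decades).
#' @param min_events Minimum events needed to attempt a split (default 50).
#' @param prominence Peak prominence threshold as a fraction of the density
#'   maximum (default 0.05).
#' @param fallback_threshold RFU threshold used when the distribution is
#'   not bimodal (default 10 RFU, the level at which the double-negative
#'   cluster is bounded on a correctly gained instrument).
#' @param grid_size KDE grid size (default 512).
#' @return An object of class `split_params`.
#' @export
split_params <- function(transform = transform_spec("biexponential"),
                         min_events = 50L, prominence = 0.05,
                         fallback_threshold = 10, grid_size = 512L) {
  structure(list(transform = transform, min_events = as.integer(min_events),
                 prominence = prominence,
                 fallback_threshold = fallback_threshold,
                 grid_size = as.integer(grid_size)),
            class = "split_params")
}

#' Density-valley cutpoint between two population peaks
#'
#' The peak-splitting step of the pipeline: estimate the kernel density of
#' the (transformed) intensities, take the two most prominent peaks, and
#' place the cutpoint at the global density minimum strictly between them
#' (leftmost grid point on ties), mapped back to RFU. Events at or above
#' the cutpoint are the positive population. If fewer than two peaks are
#' found the configured fallback threshold is used instead and the result
#' is flagged, with a warning.
#'
#' @param values Intensity vector, RFU.
#' @param config A [split_params()].
#' @return An object of class `split_result` with fields `cutpoint` (RFU),
#'   `method` (`"density_valley"`, `"fallback_threshold"` or
#'   `"insufficient_events"`), `n_events`, `peak_positions` (RFU),
#'   and `analyzable`.
#' @export
mindensity_cutpoint <- function(values, config = split_params()) {
  n <- length(values)
  if (n < config$min_events) {
    return(structure(list(cutpoint = NA_real_, method = "insufficient_events",
                          n_events = n, peak_positions = numeric(0),
                          analyzable = FALSE),
                     class = "split_result"))
  }
  t_vals <- apply_transform(values, config$transform)
  if (length(unique(t_vals)) < 2L) {
    # a point mass is unimodal: use the fallback threshold
    kde <- NULL
    peaks_t <- numeric(0)
  } else {
    kde <- kde_density(values, config$transform, config$grid_size)
    peaks_t <- find_density_peaks(kde$grid, kde$density, config$prominence)
  }
  if (length(peaks_t) >= 2L) {
    two <- sort(peaks_t[1:2])
    between <- which(kde$grid > two[1] & kde$grid < two[2])
    valley <- between[which.min(kde$density[between])]  # leftmost on ties
    cut_t <- kde$grid[valley]
    cutpoint <- invert_transform(cut_t, config$transform)
    method <- "density_valley"
  } else {
    cutpoint <- config$fallback_threshold
    method <- "fallback_threshold"
    warning(sprintf(
      "no bimodal structure detected (n=%d); using fallback threshold %g RFU",
      n, cutpoint), call. = FALSE)
  }
  structure(list(cutpoint = cutpoint, method = method, n_events = n,
                 peak_positions = invert_transform(peaks_t, config$transform),
                 analyzable = TRUE),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> cutpoint=%s RFU, method=%s, n=%d\n",
              format(x$cutpoint), x$method, x$n_events))
  invisible(x)
}

#' Singlet mask from scatter area/height ratio
#'
#' Doublets read roughly twice the forward-scatter area per unit height.
#' Events whose area/height ratio deviates from the sample median ratio by
#' more than `tolerance` (relative) are dropped. Optional; disabled in the
#' default pipeline, which assumes a single-cell suspension.
#'
#' @param sample A [fcs_sample()].
#' @param tolerance Relative deviation kept (default 0.25).
#' @param area_channel,height_channel Scatter channel names.
#' @return Logical mask. If the height channel is missing, returns an
#'   all-`TRUE` mask with attribute `available = FALSE` and a warning, so
#'   the analysis can proceed without doublet discrimination.
#' @export
singlet_mask <- function(sample, tolerance = 0.25,
                         area_channel = "FSC-HLin",
                         height_channel = "FSC-H") {
  if (!has_channel(sample, height_channel) ||
      !has_channel(sample, area_channel)) {
    warning("FSC height/area channel missing; singlet gating unavailable, keeping all events",
            call. = FALSE)
    return(structure(rep(TRUE, n_events(sample)), available = FALSE))
  }
  a <- channel_values(sample, area_channel)
  h <- channel_values(sample, height_channel)
  if (length(a) == 0L) return(structure(logical(0), available = TRUE))
  ratio <- a / h
  med <- stats::median(ratio)
  structure(abs(ratio / med - 1) <= tolerance, available = TRUE)
}
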