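# Gates, quantiles, KDE, peak finding and the density-valley cutpoint.

test_that("type-7 quantile matches hand evaluation and handles edge input", {
  expect_equal(empirical_quantile(rep(7, 50), 0.99), 7)
  # sorted 1..100: h = 99 * 0.99 = 98.01 -> x[99] + 0.01 * (x[100] - x[99])
  expect_equal(empirical_quantile(1:100, 0.99), 99.01)
  expect_equal(empirical_quantile(sample(1:100), 0.5), 50.5)
  expect_error_class(empirical_quantile(numeric(0), 0.99),
                     "myodiff_insufficient_data")
})

test_that("quantile is monotone in q and affine-equivariant", {
  set.seed(3)
  v <- rlnorm(500, 1, 1)
  qs <- seq(0.05, 0.95, by = 0.05)
  res <- vapply(qs, function(q) empirical_quantile(v, q), numeric(1))
  expect_true(all(diff(res) >= 0))
  for (q in c(0.25, 0.99)) {
    expect_equal(empirical_quantile(3 * v + 2, q),
                 3 * empirical_quantile(v, q) + 2)
  }
  # fraction of values at or below the 99% threshold is 99% within 1/n
  thr <- empirical_quantile(v, 0.99)
  expect_lte(abs(mean(v <= thr) - 0.99), 1 / length(v))
})

test_that("rectangular gates match per-event brute force", {
  s <- random_sample(1000, seed = 5)
  g <- rect_gate("FSC-HLin", "SSC-HLin", x_min = 100, x_max = 2000,
                 y_min = 50, y_max = Inf)
  mask <- apply_rect_gate(s, g)
  brute <- vapply(seq_len(1000), function(i) {
    x <- s$events[i, "FSC-HLin"]; y <- s$events[i, "SSC-HLin"]
    x >= 100 && x < 2000 && y >= 50
  }, logical(1))
  expect_identical(mask, brute)

  expect_true(all(apply_rect_gate(s, rect_gate("FSC-HLin", "SSC-HLin"))))
  expect_identical(apply_rect_gate(make_sample(0), g), logical(0))
  expect_error_class(apply_rect_gate(s, rect_gate("nope", "SSC-HLin")),
                     "myodiff_channel_error")
})

test_that("range bins are half-open [low, high) and match brute force", {
  s <- make_sample(3, gfp = c(10, 55, 100))
  b <- range_bin("GFP-low", "GRN-B-HLin", 10, 100)
  expect_identical(apply_range_bin(s, b), c(TRUE, TRUE, FALSE))
  expect_false(any(apply_range_bin(make_sample(4, gfp = 5), b)))

  r <- random_sample(2000, seed = 9)
  brute <- vapply(r$events[, "GRN-B-HLin"],
                  function(v) v >= 10 && v < 100, logical(1))
  expect_identical(apply_range_bin(r, b), unname(brute))
})

test_that("quadrant counts partition the base mask and match brute force", {
  sch <- quadrant_scheme(10, 10)
  dn <- make_sample(50, gfp = 3, myhc = 4)
  expect_identical(quadrant_counts(dn, sch),
                   c(Q1 = 0L, Q2 = 0L, Q3 = 50L, Q4 = 0L))
  dp <- make_sample(1, gfp = 100, myhc = 100)
  expect_identical(quadrant_counts(dp, sch)[["Q2"]], 1L)

  s <- random_sample(5000, seed = 13)
  base <- s$events[, "FSC-HLin"] >= 100
  counts <- quadrant_counts(s, sch, base_mask = base)
  g <- s$events[, "GRN-B-HLin"]; m <- s$events[, "RED-R-HLin"]
  brute <- c(Q1 = sum(base & g < 10 & m >= 10),
             Q2 = sum(base & g >= 10 & m >= 10),
             Q3 = sum(base & g < 10 & m < 10),
             Q4 = sum(base & g >= 10 & m < 10))
  expect_identical(counts, brute)
  expect_identical(sum(counts), sum(base))
})

test_that("kernel density recovers the standard normal and normalizes", {
  set.seed(21)
  v <- rnorm(10000)
  kde <- kde_density(v, transform_spec("linear"))
  at0 <- kde$density[which.min(abs(kde$grid))]
  expect_lt(abs(at0 - 1 / sqrt(2 * pi)) / (1 / sqrt(2 * pi)), 0.15)
  integral <- sum(diff(kde$grid) * (head(kde$density, -1) + tail(kde$density, -1)) / 2)
  expect_lt(abs(integral - 1), 0.01)
  expect_error_class(kde_density(rep(3, 10)), "myodiff_degenerate_distribution")
})

test_that("density curve is unchanged by sample duplication at fixed bandwidth", {
  set.seed(22)
  v <- rnorm(2000, 5, 2)
  bw <- stats::bw.nrd0(v)
  k1 <- kde_density(v, grid_size = 256, bw = bw)
  k2 <- kde_density(c(v, v), grid_size = 256, bw = bw)
  expect_equal(k1$grid, k2$grid)
  expect_equal(k1$density, k2$density, tolerance = 1e-12)
})

test_that("peak finding returns modes by prominence, deterministically", {
  set.seed(31)
  uni <- kde_density(rnorm(5000), transform_spec("linear"))
  expect_length(find_density_peaks(uni$grid, uni$density), 1L)

  # two equal, well-separated Gaussian bumps: peaks near the means
  v <- c(rnorm(5000, 0, 0.5), rnorm(5000, 6, 0.5))
  kde <- kde_density(v, transform_spec("linear"))
  peaks <- find_density_peaks(kde$grid, kde$density)
  expect_length(peaks, 2L)
  expect_true(all(abs(sort(peaks) - c(0, 6)) < 2 * kde$bw))

  expect_length(find_density_peaks(seq(0, 1, length = 100), rep(0, 100)), 0L)
})

test_that("mindensity cutpoint sits at the analytic mixture-density minimum", {
  sp <- transform_spec("biexponential", cofactor = 5)
  set.seed(41)
  t_vals <- c(rnorm(10000, 0.7, 0.15), rnorm(10000, 2.5, 0.15))
  values <- invert_transform(t_vals, sp)
  res <- mindensity_cutpoint(values, split_params(transform = sp))
  expect_identical(res$method, "density_valley")
  cut_t <- apply_transform(res$cutpoint, sp)
  expect_lt(abs(cut_t - mixture_cutpoint_oracle()), 0.15)
  # equal symmetric mixture: cutpoint near the midpoint of the two peaks
  peaks_t <- apply_transform(sort(res$peak_positions)[1:2], sp)
  expect_lt(abs(cut_t - mean(peaks_t)), 0.1)
})

test_that("unimodal input falls back to the 10 RFU threshold with a warning", {
  set.seed(43)
  values <- 10^rnorm(5000, 0.7, 0.15)  # background only
  expect_warning(res <- mindensity_cutpoint(values), "fallback")
  expect_identical(res$method, "fallback_threshold")
  expect_equal(res$cutpoint, 10)
})

test_that("too few events yield a not-analyzable split, not an error", {
  res <- mindensity_cutpoint(rnorm(10, 100, 5))
  expect_false(res$analyzable)
  expect_identical(res$method, "insufficient_events")
})

test_that("cutpoint is invariant under sample duplication to one grid step", {
  sp <- split_params()
  set.seed(47)
  values <- invert_transform(c(rnorm(3000, 0.7, 0.15), rnorm(3000, 2.5, 0.15)),
                             sp$transform)
  r1 <- mindensity_cutpoint(values, sp)
  r2 <- mindensity_cutpoint(c(values, values), sp)
  t1 <- apply_transform(r1$cutpoint, sp$transform)
  t2 <- apply_transform(r2$cutpoint, sp$transform)
  kde <- kde_density(values, sp$transform, sp$grid_size)
  step <- diff(kde$grid[1:2])
  # duplication changes only n in the bandwidth rule (factor 2^(-1/5));
  # the valley of a well-separated mixture moves by at most a grid step
  expect_lt(abs(t1 - t2), 2 * step)
})

test_that("singlet mask keeps unit-ratio events and removes simulated doublets", {
  s <- make_sample(100, fsc = 500, fsc_h = 500)
  expect_true(all(singlet_mask(s)))
  expect_length(singlet_mask(make_sample(0)), 0L)

  set.seed(53)
  sim <- simulate_sample(small_sim_config(n_events = 10000,
                                          debris_fraction = 0,
                                          doublet_fraction = 0.1),
                         "target")
  mask <- singlet_mask(sim, tolerance = 0.25)
  doublets <- sim$truth$is_doublet
  expect_gte(mean(!mask[doublets]), 0.99)
  # and nearly all true singlets are kept
  expect_gte(mean(mask[!doublets]), 0.99)

  no_h <- fcs_sample(s$events[, 1:4], s$channels$name[1:4], "x")
  expect_warning(m <- singlet_mask(no_h), "unavailable")
  expect_true(all(m))
  expect_false(attr(m, "available"))
})
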