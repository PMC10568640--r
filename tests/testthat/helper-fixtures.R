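# Shared fixture builders. Everything is generated in code at test time.

# A sample with explicitly chosen per-channel values (recycled to n rows),
# defaulting to scatter values well inside the debris gate.
make_sample <- function(n, gfp = 5, myhc = 5, fsc = 500, ssc = 250,
                        fsc_h = NULL, sample_id = "s1", well_id = NULL,
                        truth = NULL) {
  if (is.null(fsc_h)) fsc_h <- fsc
  ev <- cbind("FSC-HLin" = rep_len(fsc, n), "SSC-HLin" = rep_len(ssc, n),
              "GRN-B-HLin" = rep_len(gfp, n), "RED-R-HLin" = rep_len(myhc, n),
              "FSC-H" = rep_len(fsc_h, n))
  fcs_sample(ev, channels = colnames(ev), sample_id = sample_id,
             well_id = well_id, truth = truth)
}

# Random events for brute-force gate comparisons.
random_sample <- function(n, seed = 1) {
  set.seed(seed)
  make_sample(n,
              gfp = 10^runif(n, -1, 4), myhc = 10^runif(n, -1, 4),
              fsc = 10^runif(n, 0, 3.5), ssc = 10^runif(n, 0, 3.5))
}

# Scaled-down simulation for fast unit tests.
small_sim_config <- function(n_events = 4000, ...) {
  sim_config(n_events = n_events, ...)
}

# Two engineered calibration controls whose GFP 99% quantiles are forced
# (constant GFP columns), scatter inside the debris gate.
engineered_controls <- function(q_dn = 20, q_myhc = 28, n = 200) {
  fc_experiment(
    list(make_sample(n, gfp = q_dn, sample_id = "dn"),
         make_sample(n, gfp = q_myhc, sample_id = "mp")),
    roles = list(double_negative = "dn", myhc_positive = "mp"))
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}

# Analytic oracle for peak splitting: equal mixture of two lognormals whose
# biexponential images are N(m1, s) and N(m2, s); the true density minimum
# is located by a dense numerical scan of the closed-form mixture density.
mixture_cutpoint_oracle <- function(m1 = 0.7, m2 = 2.5, s = 0.15) {
  grid <- seq(m1, m2, by = 1e-4)
  dens <- 0.5 * dnorm(grid, m1, s) + 0.5 * dnorm(grid, m2, s)
  grid[which.min(dens)]
}
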