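test_that("rate constant k is the stimulus fraction of total counts", {
  expect_equal(as.numeric(compute_k(900, 0)), 1.0)
  expect_equal(as.numeric(compute_k(100, 900)), 0.1)
  expect_error(compute_k(0, 0), "both zero")
  expect_error(compute_k(-1, 5))
  k0 <- compute_k(0, 500)
  expect_equal(as.numeric(k0), 0)
  expect_true(attr(k0, "below_detection"))
  # vectorized over a trace's counts with fixed discharge
  expect_equal(as.numeric(compute_k(c(100, 300), 900)),
               c(100 / 1000, 300 / 1200))
})

test_that("pCa calibration reproduces the published constants", {
  expect_identical(k_to_pca(1), 5.5593)        # intercept: -log term vanishes
  expect_equal(k_to_pca(0.1), 0.332588 + 5.5593)
  expect_equal(k_to_pca(0.01), 2 * 0.332588 + 5.5593)
  expect_error(k_to_pca(0), "\\(0, 1\\]")
  expect_error(k_to_pca(1.01), "\\(0, 1\\]")
  # custom parameters and log base
  p2 <- calibration_params(slope = 1, intercept = 2, log_base = exp(1))
  expect_equal(k_to_pca(exp(-1), p2), 3)
  expect_error(calibration_params(slope = -1), "slope")
})

test_that("pCa <-> concentration conversions invert each other", {
  expect_equal(pca_to_concentration(6), 1e-6)
  expect_equal(pca_to_concentration(5.5593), 10^(-5.5593))
  pca <- runif(100, 4, 9)
  expect_equal(concentration_to_pca(pca_to_concentration(pca)), pca,
               tolerance = 1e-12)
  conc <- 10^runif(100, -9, -4)
  expect_equal(pca_to_concentration(concentration_to_pca(conc)), conc,
               tolerance = 1e-12)
})

test_that("calibrated concentration is strictly increasing in k", {
  k <- seq(1e-6, 1, length.out = 1000)
  conc <- pca_to_concentration(k_to_pca(k))
  expect_true(all(diff(conc) > 0))
})

test_that("a constant trace calibrates to a flat curve at resting level", {
  tr <- luminescence_trace(0:120, rep(50, 121), discharge_counts = 1e6,
                           stimulus_time = 60)
  for (mode in c("aggregate", "pointwise")) {
    ca <- calibrate_trace(tr, mode = mode)
    if (mode == "aggregate")
      expect_equal(ca$concentration, rep(ca$resting_level, 121))
    sig <- extract_signature(ca)
    if (mode == "aggregate") {
      expect_equal(sig$amplitude, 0)
      expect_equal(sig$curve_area, 0)
      expect_true(is.na(sig$peak_time))
    }
  }
})

test_that("aggregate-mode calibration is invariant to joint count rescaling", {
  set.seed(7)
  counts <- rpois(121, lambda = c(rep(40, 60), 400 * exp(-(0:60) / 15)) + 40)
  tr <- luminescence_trace(0:120, counts, 5e5, stimulus_time = 60)
  ca <- calibrate_trace(tr, mode = "aggregate")
  for (c_scale in c(0.25, 7, 1000)) {
    tr2 <- luminescence_trace(0:120, counts * c_scale, 5e5 * c_scale,
                              stimulus_time = 60)
    ca2 <- calibrate_trace(tr2, mode = "aggregate",
                           count_floor = 0.5 * c_scale)
    expect_equal(ca2$concentration, ca$concentration, tolerance = 1e-12)
  }
})

test_that("pointwise denominator is the non-increasing remaining pool", {
  set.seed(11)
  counts <- rpois(100, 80)
  tr <- luminescence_trace(seq_len(100), counts, 2e4, stimulus_time = 50)
  ca <- calibrate_trace(tr, mode = "pointwise", count_floor = 0.5)
  den <- attr(ca, "denominator")
  expect_true(all(diff(den) <= 0))
  # after the last interval's emission, exactly the discharge pool remains
  expect_equal(den[length(den)] - pmax(counts, 0.5)[100], 2e4)
  expect_equal(den[1], 2e4 + sum(pmax(counts, 0.5)))
  expect_error(calibrate_trace(
    luminescence_trace(1:10, rep(1, 10), 0, 5), mode = "pointwise"),
    "discharge")
})

test_that("empty pre-stimulus window is an error", {
  tr <- luminescence_trace(0:50, rep(10, 51), 1e5, stimulus_time = 0)
  expect_error(calibrate_trace(tr), "pre-stimulus")
})

test_that("signature of a triangular pulse matches hand-computed values", {
  # rest 0.1 uM; linear rise to +0.5 uM at 10 s post-stimulus, back at 20 s
  times <- 0:40
  rest <- 1e-7
  stim <- 10
  excess <- approx(c(0, 10, 20, 30), c(0, 5e-7, 0, 0),
                   xout = pmax(times - stim, 0))$y
  ca <- make_calcium_trace(times, rest + excess, rest, stim)
  sig <- extract_signature(ca)
  expect_equal(sig$amplitude, 5e-7)
  expect_equal(sig$peak_time, 10)
  expect_equal(sig$curve_area, 0.5 * 20 * 5e-7)  # triangle area
  if (requireNamespace("pracma", quietly = TRUE)) {
    post <- times >= stim
    expect_equal(sig$curve_area, pracma::trapz(times[post], excess[post]))
  }
})

test_that("peak search is post-stimulus only and ties break earliest", {
  rest <- 1e-7
  conc <- rep(rest, 41)
  conc[5] <- 10e-7          # pre-stimulus spike must be ignored
  conc[c(25, 30)] <- 3e-7   # tied post-stimulus peaks
  ca <- make_calcium_trace(0:40, conc, rest, 20)
  sig <- extract_signature(ca)
  expect_equal(sig$peak_time, 4)  # t = 24, the earliest of the tie
  expect_equal(sig$amplitude, 2e-7)
  expect_error(extract_signature(make_calcium_trace(0:40, conc, rest, 40)),
               "post-stimulus")
})

test_that("group summary gives field-wise mean and SEM", {
  sig <- function(a) structure(list(amplitude = a, curve_area = 2 * a,
                                    peak_time = 10, resting_level = 1e-7),
                               class = "ca_signature")
  s <- summarize_group(list(sig(1), sig(2), sig(3)))
  amp <- s[s$field == "amplitude", ]
  expect_equal(amp$mean, 2)
  expect_equal(amp$sem, 1 / sqrt(3), tolerance = 1e-4)  # 0.5774
  expect_equal(amp$n, 3)
  # identical signatures: SEM 0
  s0 <- summarize_group(list(sig(2), sig(2)))
  expect_equal(s0$sem[s0$field == "amplitude"], 0)
  # permutation symmetry
  expect_equal(summarize_group(list(sig(3), sig(1), sig(2))), s)
  expect_error(summarize_group(list()), "empty")
  expect_error(summarize_group(list(sig(1))), "at least two")
})
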