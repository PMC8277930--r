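test_that("motion energy counts exactly the suprathreshold ROI pixels", {
  # two frames differing by +40 grey levels in exactly 37 ROI pixels
  f <- array(50, dim = c(20, 20, 2))
  m <- f[, , 2]
  m[1:37] <- 90                        # +40 grey levels in 37 pixels
  f[, , 2] <- m
  r <- roi(matrix(TRUE, 20, 20))
  me <- motion_energy(frame_stack(f, 10), r, pixel_threshold = 12)
  expect_equal(me$values, 37)
  expect_equal(me$rate, 10)

  # identical frames -> all-zero series
  g <- array(120, dim = c(8, 8, 5))
  expect_equal(motion_energy(frame_stack(g, 25), roi(matrix(TRUE, 8, 8)))$values,
               rep(0, 4))
})

test_that("a difference equal to the threshold does not count (strict inequality)", {
  f <- array(100, dim = c(5, 5, 2))
  f[2, 2, 2] <- 112    # diff exactly 12
  f[3, 3, 2] <- 113    # diff 13, strictly above
  me <- motion_energy(frame_stack(f, 10), roi(matrix(TRUE, 5, 5)), 12)
  expect_equal(me$values, 1)
})

test_that("motion energy ignores pixels outside the ROI and is mask-shape only", {
  f <- array(0, dim = c(10, 10, 2))
  f[, , 2] <- 100                       # everything changes
  inside <- roi_rect(c(10, 10), 2, 2, 3, 3)
  expect_equal(motion_energy(frame_stack(f, 10), inside)$values, 9)
})

test_that("motion energy validates inputs", {
  f <- array(0, dim = c(5, 5, 1))
  expect_error(motion_energy(frame_stack(f, 10), roi(matrix(TRUE, 5, 5))),
               "at least 2")
  f2 <- array(0, dim = c(5, 5, 3))
  expect_error(motion_energy(frame_stack(f2, 10), roi(matrix(TRUE, 4, 4))),
               "dimensions")
})

test_that("ROI standardization is a pure scaling", {
  s <- mea_series(c(37, 0, 74), 10, roi_area = 3700)
  z <- standardize_roi(s, scale = 100)
  expect_equal(z$values, c(1, 0, 2))
  # doubling the area halves every value
  z2 <- standardize_roi(s, roi_area = 7400, scale = 100)
  expect_equal(z2$values, z$values / 2)
  zz <- standardize_roi(mea_series(rep(0, 4), 10, roi_area = 10))
  expect_equal(zz$values, rep(0, 4))
})

test_that("despiking replaces extreme values by carry-forward", {
  s <- mea_series(c(1, 1, 1, 1000, 1), 10)
  expect_equal(despike(s, 1)$values, c(1, 1, 1, 1, 1))
  # below-cutoff series is untouched
  s2 <- mea_series(c(1, 2, 3, 2, 1), 10)
  expect_equal(despike(s2, 10)$values, s2$values)
  # zero-variance series returned unchanged
  s3 <- mea_series(rep(5, 6), 10)
  expect_equal(despike(s3, 10)$values, rep(5, 6))
})

test_that("despike matches a scalar reference loop, including a leading spike", {
  locf_oracle <- function(v, bad) {
    out <- v
    last <- 0
    for (i in seq_along(v)) {
      if (bad[i]) out[i] <- last else last <- v[i]
    }
    out
  }
  set.seed(42)
  for (rep in 1:20) {
    v <- round(rexp(50, 0.2), 2)
    v[1] <- max(v) * 50          # spike at the first sample
    v[sample(2:50, 3)] <- max(v) * 40
    cutoff <- 2
    bad <- v >= cutoff * sd(v)
    got <- despike(mea_series(v, 10), cutoff)$values
    expect_equal(got, locf_oracle(v, bad))
  }
  # despiking its own output is a no-op when the original SD is retained
  v <- c(2, 2, 2, 500, 2, 2)
  once <- despike(mea_series(v, 10), 2)$values
  twice <- despike(mea_series(once, 10), 2)$values
  expect_equal(twice, once)
})

test_that("control filtering carries the last clean value forward", {
  person <- mea_series(as.numeric(1:20), 10)
  control <- mea_series(rep(0, 20), 10)
  expect_equal(control_filter(person, control, 5)$values, as.numeric(1:20))

  control$values[11:13] <- 6
  got <- control_filter(person, control, 5)$values
  want <- as.numeric(1:20); want[11:13] <- 10
  expect_equal(got, want)

  # fully contaminated control -> carried leading zero everywhere
  allbad <- mea_series(rep(9, 20), 10)
  expect_equal(control_filter(person, allbad, 5)$values, rep(0, 20))

  expect_error(control_filter(person, mea_series(rep(0, 5), 10), 5),
               "equal length")
})

test_that("Butterworth smoothing has unit DC gain and attenuates high frequencies", {
  s <- mea_series(rep(3.7, 200), 50)
  expect_equal(smooth_series(s, 2, 2)$values, rep(3.7, 200), tolerance = 1e-6)

  # 10 Hz sinusoid vs 2 Hz cutoff: zero-phase (two-pass) gain must be at
  # most the analog squared magnitude 1/(1 + (f/fc)^(2*order))
  t <- seq(0, 8, by = 1 / 50)
  s2 <- mea_series(2 + sin(2 * pi * 10 * t), 50)
  out <- smooth_series(s2, 2, 2)$values
  core <- 51:350                         # avoid filter edge transients
  gain <- sd(out[core] - mean(out[core])) / sd(s2$values[core] - 2)
  h2 <- 1 / (1 + (10 / 2)^4)
  expect_lt(gain, h2)

  # white noise loses variance under any low-pass
  set.seed(8)
  s3 <- mea_series(abs(rnorm(500)) + 1, 50)
  expect_lt(var(smooth_series(s3, 2, 2)$values), var(s3$values))

  expect_error(smooth_series(mea_series(1:10, 10), 2, 5), "Nyquist")
})

test_that("block-average resampling matches hand-computed block means", {
  ramp <- mea_series(as.numeric(1:50), 50)
  out <- resample_series(ramp, 10)
  expect_equal(out$rate, 10)
  expect_equal(out$values, colMeans(matrix(1:50, nrow = 5)))

  same <- resample_series(mea_series(1:7, 10), 10)
  expect_equal(same$values, as.numeric(1:7))
  expect_equal(same$rate, 10)

  const <- resample_series(mea_series(rep(2.5, 30), 30), 10)
  expect_equal(const$values, rep(2.5, 10))

  # trailing partial block is dropped
  out2 <- resample_series(mea_series(as.numeric(1:52), 50), 10)
  expect_length(out2$values, 10)
  expect_error(resample_series(mea_series(1:5, 10), 20), "exceed")
})

test_that("the full preprocessing pipeline composes the stages in order", {
  # blob moves horizontally through the middle rows; the person ROI is a
  # row band containing it and the control ROI a disjoint bottom band
  dx <- rep(c(1, 2, 0, 3, 1, 2), 20)
  fs <- toy_stack(dx, dims = c(32, 64), blob = 6, rate = 10)
  person <- roi_rect(c(32, 64), 1, 1, 24, 64)
  control <- roi_rect(c(32, 64), 28, 1, 5, 64, kind = "control")
  out <- mea_preprocess(fs, person, control)
  expect_identical(provenance_steps(out),
                   c("motion_energy", "standardize_roi", "despike",
                     "control_filter", "smooth", "resample"))
  expect_true(all(out$values >= 0))

  # zero-movement stack -> zero series end to end
  fs0 <- toy_stack(rep(0, 120), dims = c(32, 64), blob = 6, rate = 10)
  out0 <- mea_preprocess(fs0, person, control)
  expect_equal(out0$values, rep(0, length(out0$values)))

  # overlapping ROIs are rejected
  expect_error(mea_preprocess(fs, person, roi_rect(c(32, 64), 20, 1, 8, 10,
                                                   kind = "control")),
               "disjoint")
})

test_that("preprocessed motion energy tracks the planted movement closely", {
  set.seed(31)
  planted <- pmin(6, rpois(240, 2))
  fs <- toy_stack(planted, dims = c(40, 80), blob = 6, rate = 10,
                  noise_amp = 10, seed = 13)
  person <- roi_rect(c(40, 80), 1, 1, 28, 80)     # blob rows 18-23
  control <- roi_rect(c(40, 80), 33, 1, 6, 80, kind = "control")
  out <- mea_preprocess(fs, person, control,
                        mea_config(butterworth_cutoff = 4))
  # smooth the planted series with the same filter for a fair comparison
  ref <- smooth_series(mea_series(2 * 6 * planted, 10), 2, 4)
  expect_gt(cor(out$values, ref$values), 0.95)
})
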