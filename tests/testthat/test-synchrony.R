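test_that("lag grids enumerate the requested steps symmetrically", {
  g <- make_lag_grid(5, 0.1)
  expect_length(g$lags, 101)
  expect_equal(sum(g$lags > 0), 50)
  expect_equal(sum(g$lags < 0), 50)
  expect_equal(g$n_positive, 50)
  expect_true(0 %in% g$lags)

  expect_equal(make_lag_grid(0, 0.1)$lags, 0)
  expect_equal(make_lag_grid(1, 0.5)$lags, c(-1, -0.5, 0, 0.5, 1))
  expect_error(make_lag_grid(1, 0.3), "divide")
})

test_that("identical partners give lag-0 correlations of exactly 1", {
  set.seed(1)
  x <- abs(rnorm(1200)) + 0.1
  d <- toy_dyad(x, x)
  cc <- windowed_ccf(d, make_lag_grid(2, 0.1))
  lag0 <- unclass(cc)[, attr(cc, "lags_s") == 0]
  expect_true(all(abs(lag0 - 1) < 1e-12))
})

test_that("a time-shifted copy peaks at the planted lag", {
  t <- seq(0, 180 - 0.1, by = 0.1)
  base <- sin(2 * pi * 0.2 * t) + 2
  shift <- 5L                           # 0.5 s at 10 Hz
  p <- base[1:(length(base) - shift)]
  y <- base[(1 + shift):length(base)]   # therapist runs ahead by 0.5 s
  cc <- windowed_ccf(toy_dyad(p, y), make_lag_grid(2, 0.1))
  lags <- attr(cc, "lags_s")
  for (w in seq_len(nrow(cc))) {
    expect_equal(lags[which.max(unclass(cc)[w, ])], -0.5)
  }
  # swapping the partners mirrors the lag axis
  cc_sw <- windowed_ccf(toy_dyad(y, p), make_lag_grid(2, 0.1))
  expect_equal(unclass(cc_sw)[, rev(seq_along(lags))], unclass(cc),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fast kernel and naive triple-loop oracle agree to 1e-12", {
  d <- quick_session(101, coupling = 0.4, minutes = 2)
  fast <- windowed_ccf(d, make_lag_grid(3, 0.1), window_s = 30)
  slow <- windowed_ccf_naive(d, make_lag_grid(3, 0.1), window_s = 30)
  expect_equal(unclass(fast), slow, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("white-noise windows scatter around the analytic null level", {
  # E|r| under independence is ~ sqrt(2 / (pi * n)) for n = 600 samples
  set.seed(99)
  d <- toy_dyad(rnorm(18000), rnorm(18000))
  cc <- windowed_ccf(d, make_lag_grid(5, 0.1))
  got <- mean(abs(unclass(cc)), na.rm = TRUE)
  expect_lt(abs(got - sqrt(2 / (pi * 600))) / sqrt(2 / (pi * 600)), 0.15)
})

test_that("zero-variance windows yield missing cells, not distorted means", {
  set.seed(5)
  p <- abs(rnorm(1800)) + 0.5
  y <- abs(rnorm(1800)) + 0.5
  p[601:1200] <- 1                      # second window flat
  cc <- windowed_ccf(toy_dyad(p, y), make_lag_grid(1, 0.1))
  expect_true(all(is.na(unclass(cc)[2, ])))
  expect_false(anyNA(unclass(cc)[c(1, 3), ]))
  full <- windowed_ccf(toy_dyad(p[c(1:600, 1201:1800)],
                                y[c(1:600, 1201:1800)]),
                       make_lag_grid(1, 0.1))
  expect_equal(grand_average(cc)$value, grand_average(full)$value,
               tolerance = 1e-12)
  expect_equal(grand_average(cc)$n_valid, attr(cc, "n_valid"))
})

test_that("too-short series are rejected", {
  expect_error(windowed_ccf(toy_dyad(1:30, 1:30), make_lag_grid(1, 0.1)),
               "shorter than one window")
})

test_that("grand averaging applies the documented transforms", {
  d <- quick_session(7, coupling = 0.3)
  cc <- windowed_ccf(d, make_lag_grid(1, 0.1))

  fake <- cc
  fake[] <- 0
  expect_equal(grand_average(fake)$value, 0)

  one <- cc[1, , drop = FALSE]
  attr_names <- names(attributes(cc))
  for (a in setdiff(attr_names, c("dim", "dimnames"))) {
    attr(one, a) <- attr(cc, a)
  }
  one[] <- NA_real_
  one[1, 1] <- 0.5
  expect_equal(grand_average(one)$value, atanh(0.5), tolerance = 1e-12)

  # Jensen-type orderings on a fixed matrix
  zabs <- grand_average(cc, use_abs = TRUE, use_fisher_z = TRUE)$value
  rabs <- grand_average(cc, use_abs = TRUE, use_fisher_z = FALSE)$value
  rraw <- grand_average(cc, use_abs = FALSE, use_fisher_z = FALSE)$value
  expect_gte(zabs, rabs)            # atanh(|r|) >= |r|
  expect_gte(rabs, abs(rraw))       # triangle inequality on means
})

test_that("grand average with the default transforms is partner-symmetric", {
  d <- quick_session(55, coupling = 0.5)
  sw <- dyad_series(d$therapist, d$patient, d$dyad_id, d$session_id)
  g1 <- grand_average(windowed_ccf(d, make_lag_grid(1, 0.1)))$value
  g2 <- grand_average(windowed_ccf(sw, make_lag_grid(1, 0.1)))$value
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("dyad trait synchrony is the median of the session indices", {
  expect_equal(dyad_trait(3.2), 3.2)
  expect_equal(dyad_trait(c(1, 2, 100)), 2)
  set.seed(2)
  v <- rnorm(10)
  expect_equal(dyad_trait(v), mean(sort(v)[5:6]))
})
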