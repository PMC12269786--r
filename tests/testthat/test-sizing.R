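# Length conversion, classing, IPI measurement and per-individual summaries.

test_that("the piecewise conversion reproduces the printed values", {
  expect_equal(round(size_from_ipi(1.90), 1), 7.6)
  expect_equal(round(size_from_ipi(2.9)), 9)
  expect_equal(round(size_from_ipi(5.0)), 12)
  expect_equal(size_from_ipi(3.85), 4.833 + 1.453 * 3.85 - 0.001 * 3.85^2)
  expect_equal(round(size_from_ipi(3.85), 2), 10.41)
  expect_error(size_from_ipi(-1), "positive")
})

test_that("the conversion is strictly increasing with near-continuity at the switch", {
  ipi <- seq(0.1, 10, by = 0.01)
  expect_true(all(diff(size_from_ipi(ipi)) > 0))
  # both equations sit at ~11 m over their overlap; gap below 0.11 m
  ov <- seq(4.184, 4.250, by = 0.001)
  gap <- abs(size_from_ipi(ov, "quadratic") - size_from_ipi(ov, "linear"))
  expect_lt(max(gap), 0.11)
  expect_true(all(round(size_from_ipi(ov, "quadratic")) == 11))
  expect_true(all(round(size_from_ipi(ov, "linear")) == 11))
})

test_that("the inverse conversion matches its hand-derived roots", {
  # quadratic formula on the sub-11 m equation
  expect_equal(round(ipi_from_size(9.0), 3), 2.874)
  # linear inverse
  expect_equal(round(ipi_from_size(12.0), 3), 4.979)
  expect_equal(size_from_ipi(ipi_from_size(10.0)), 10.0, tolerance = 1e-9)
  # round trip over attainable lengths
  L <- c(seq(6, 10.98, by = 0.01), seq(11.09, 18, by = 0.01))
  expect_equal(size_from_ipi(ipi_from_size(L)), L, tolerance = 1e-9)
  expect_error(ipi_from_size(3), "range")
})

test_that("class thresholds map through the conversion to about 9 and 12 m", {
  expect_identical(classify_individual(2.5), "immature")
  expect_identical(classify_individual(3.85), "female_or_juvenile_male")
  expect_identical(classify_individual(7.8), "adult_male")
  # boundary resolution: 2.9 and 5.0 fall in the middle class
  expect_identical(classify_individual(c(2.9, 5.0)),
                   rep("female_or_juvenile_male", 2))
  expect_equal(size_from_ipi(2.9), 9, tolerance = 0.05)
  expect_equal(size_from_ipi(5.0), 12, tolerance = 0.05)
})

test_that("envelope and cepstrum agree on clean clicks across the IPI range", {
  for (ipi in seq(2.0, 7.5, by = 0.5)) {
    ck <- clean_click(ipi, seed = round(ipi * 10), t0 = 0.02, duration_s = 0.07)
    t1 <- attr(ck, "truth")$p1_time
    env <- estimate_ipi_envelope(ck, t1)
    cep <- estimate_ipi_cepstrum(ck, t1)
    expect_equal(env$ipi_ms, ipi, tolerance = 0.0104)  # one sample period
    expect_equal(cep$ipi_ms, ipi, tolerance = 0.05)
    expect_lt(abs(env$ipi_ms - cep$ipi_ms), 0.1)
  }
})

test_that("a noisy 4 ms click is still measured to within 0.05 ms", {
  ck <- synth_click(click_spec(ipi_ms = 4.00, snr_db = 20), t0 = 0.01,
                    seed = 11, duration_s = 0.05)
  m <- estimate_ipi_envelope(highpass(ck), attr(ck, "truth")$p1_time)
  expect_equal(m$ipi_ms, 4.00, tolerance = 0.05)
  # cepstral cross-check on a clean 5.5 ms click
  ck2 <- clean_click(5.5, seed = 12, t0 = 0.02, duration_s = 0.07)
  m2 <- estimate_ipi_cepstrum(ck2, attr(ck2, "truth")$p1_time)
  expect_equal(m2$ipi_ms, 5.5, tolerance = 0.05)
})

test_that("pure noise yields no cepstral IPI", {
  noise <- audio_segment(withr::with_seed(9, rnorm(9600, 0, 0.3)), 96000)
  m <- estimate_ipi_cepstrum(noise, 0.05)
  expect_true(is.na(m$ipi_ms))
})

test_that("sub-floor IPIs are measurable but flagged for the summary stage", {
  ck <- clean_click(1.7, seed = 13, t0 = 0.02, duration_s = 0.06)
  m <- estimate_ipi_envelope(ck, attr(ck, "truth")$p1_time)
  expect_equal(m$ipi_ms, 1.7, tolerance = 0.05)
  est <- summarize_individual(rep(m$ipi_ms, 10))
  expect_false(est$accepted)
  expect_true("below_ipi_floor" %in% est$flags)
})

test_that("individual summaries apply the floor, calf override and flags", {
  vals <- withr::with_seed(3, rnorm(10, 3.85, 0.05))
  est <- summarize_individual(vals)
  expect_true(est$accepted)
  expect_equal(est$ipi_mean_ms, 3.85, tolerance = 0.1)
  expect_length(est$flags, 0L)
  # the 1.90 ms calf: rejected without visual confirmation, accepted with it
  rej <- summarize_individual(rep(1.90, 10))
  expect_false(rej$accepted)
  expect_true(is.na(rej$length_m))
  calf <- summarize_individual(rep(1.90, 10), calf_confirmed = TRUE)
  expect_true(calf$accepted)
  expect_equal(round(calf$length_m, 1), 7.6)
  expect_identical(calf$class_label, "immature")
  # warning flags
  expect_true("low_n" %in% summarize_individual(c(3, 3.1))$flags)
  expect_true("high_sd" %in% summarize_individual(withr::with_seed(4, rnorm(10, 4, 0.5)))$flags)
  expect_error(summarize_individual(numeric(0)), "no valid")
})

test_that("IPI clustering counts vocal individuals by single linkage", {
  two <- c(withr::with_seed(5, rnorm(10, 3.0, 0.03)),
           withr::with_seed(6, rnorm(10, 5.5, 0.03)))
  groups <- cluster_individuals(two)
  expect_length(groups, 2L)
  expect_setequal(groups[[1]], 1:10)
  expect_length(cluster_individuals(numeric(0)), 0L)
  # chaining: steps of 0.1 ms link into one group at tol 0.15
  expect_length(cluster_individuals(seq(3.0, 3.5, by = 0.1)), 1L)
})

test_that("50 synthetic individuals are recovered to 0.15 m and classed correctly", {
  set.seed(77)
  L_true <- runif(50, 7.6, 15.6)
  ipi_true <- ipi_from_size(L_true)
  L_attain <- size_from_ipi(ipi_true)
  err <- numeric(50); cls_ok <- logical(50)
  for (i in 1:50) {
    snr <- runif(1, 10, 25)
    # the protocol averages ten *clear* measurements: keep measuring clicks
    # until ten pass the quality gates
    meas <- numeric(0)
    for (j in 1:40) {
      if (sum(is.finite(meas)) >= 10) break
      ck <- synth_click(click_spec(ipi_ms = ipi_true[i], snr_db = snr),
                        t0 = 0.01, seed = i * 100 + j, duration_s = 0.05)
      m <- estimate_ipi_envelope(highpass(ck), attr(ck, "truth")$p1_time)
      meas <- c(meas, m$ipi_ms)
    }
    est <- summarize_individual(meas[is.finite(meas)], calf_confirmed = TRUE)
    err[i] <- abs(est$length_m - L_attain[i])
    cls_ok[i] <- identical(est$class_label, classify_individual(ipi_true[i]))
  }
  expect_lte(mean(err), 0.15)
  # class exact for animals at least 0.2 m from the 9 / 12 m boundaries
  away <- abs(L_attain - 9) > 0.2 & abs(L_attain - 12) > 0.2
  expect_true(all(cls_ok[away]))
})
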