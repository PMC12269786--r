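# Synthetic generators: clicks, trains, bathymetry, scenes, WAV round trips.

test_that("synthetic clicks carry the specified multipulse structure", {
  sp <- click_spec(ipi_ms = 4.00, snr_db = Inf)
  ck <- synth_click(sp, t0 = 0.005, seed = 1, duration_s = 0.05)
  truth <- attr(ck, "truth")
  expect_equal(truth$p1_time, 0.005 + 0.004)
  # oracle: noiseless envelope argmax peak times sit at the pulse centres
  pk <- noiseless_peak_times(ck)
  expect_equal(length(pk), 4L)
  # grid argmax sits within two sample periods of the true pulse centres
  expect_lt(max(abs(pk - truth$pulse_times)), 2.1e-5)
  # pulse-pair measurement recovers the spec IPI
  m <- estimate_ipi_envelope(ck, truth$p1_time)
  expect_equal(m$ipi_ms, 4.00, tolerance = 0.05)
})

test_that("a single-pulse click yields one envelope peak and no IPI", {
  sp <- click_spec(ipi_ms = 4, pulse_amplitudes = c(0, 1, 0, 0), snr_db = Inf)
  ck <- synth_click(sp, t0 = 0.005, seed = 1, duration_s = 0.03)
  expect_equal(length(noiseless_peak_times(ck)), 1L)
  m <- estimate_ipi_envelope(ck, attr(ck, "truth")$p1_time)
  expect_true(is.na(m$ipi_ms))
})

test_that("click generation is deterministic for a fixed seed", {
  sp <- click_spec(ipi_ms = 3.3, snr_db = 12)
  a <- synth_click(sp, t0 = 0.002, seed = 99)
  b <- synth_click(sp, t0 = 0.002, seed = 99)
  expect_identical(a$samples, b$samples)
  c <- synth_click(sp, t0 = 0.002, seed = 100)
  expect_false(identical(a$samples, c$samples))
})

test_that("click specs are validated", {
  expect_error(click_spec(ipi_ms = -1), "ipi_ms")
  expect_error(click_spec(pulse_amplitudes = c(1, 0.5, 0.2, 0.1)), "p1")
  expect_error(click_spec(sample_rate = 10000), "Nyquist")
})

test_that("train specs enforce the ICI regimes", {
  expect_error(train_spec("regular", 10, ici_s = c(0.1, 1)), "0.5")
  expect_error(train_spec("buzz", 10, ici_s = 0.5), "0.2")
  expect_error(train_spec("coda", 50, duration_s = 1), "3 to 20")
  expect_error(train_spec("coda", 8, duration_s = 5), "duration")
  expect_silent(train_spec("coda", 8, duration_s = 1))
})

test_that("synth_train truth matches its spec", {
  st <- synth_train(train_spec("regular", 10, ici_s = c(0.8, 1.2)),
                    click_spec(ipi_ms = 4), seed = 5, render_audio = FALSE)
  expect_equal(nrow(st$truth$clicks), 10L)
  expect_true(all(st$icis_s >= 0.8 & st$icis_s <= 1.2))
  expect_identical(st$truth$kind, "regular")
  # fixed-ICI buzz: duration is (n - 1) * ici
  sb <- synth_train(train_spec("buzz", 40, ici_s = 0.05),
                    click_spec(ipi_ms = 4), seed = 5, render_audio = FALSE)
  expect_equal(diff(range(sb$truth$clicks$time_s)), 39 * 0.05)
  expect_equal(nrow(sb$truth$clicks), 40L)
})

test_that("a coda round-trips through detection and classification", {
  st <- synth_train(train_spec("coda", 8, duration_s = 1.0),
                    click_spec(ipi_ms = 3, snr_db = Inf), seed = 7)
  det <- detect_clicks(highpass(st$audio))
  trains <- segment_trains(det)
  expect_length(trains, 1L)
  expect_identical(trains[[1]]$kind, "coda")
})

test_that("WAV files round-trip at 16 and 24 bit, mono and stereo", {
  x <- sin(2 * pi * 3000 * seq(0, 0.05, by = 1 / 48000)) * 0.7
  mono <- audio_segment(x, 48000)
  for (bits in c(16, 24)) {
    p <- tempfile(fileext = ".wav")
    write_wav(mono, p, bit_depth = bits)
    back <- read_wav(p)
    expect_equal(back$sample_rate, 48000)
    expect_equal(back$samples, x, tolerance = if (bits == 16) 1e-4 else 1e-6)
  }
  stereo <- audio_segment(cbind(x, -x / 2), 48000)
  p <- tempfile(fileext = ".wav")
  write_wav(stereo, p)
  back <- read_wav(p)
  expect_equal(n_channels(back), 2L)
  expect_equal(back$samples, unname(stereo$samples), tolerance = 1e-6)
})

test_that("synthetic bathymetry is monotone offshore with a coastline", {
  bb <- synth_bathymetry(40, 60, cell_m = 250,
                         profile = list(canyon = list(row_frac = 0.5)))
  expect_true(all(apply(bb$grid$depths, 1, function(r) all(diff(r) >= 0))))
  expect_equal(nrow(bb$coastline), 40L)
  expect_true(all(bb$coastline$lon == bb$grid$lon[1]))
  # determinism
  bb2 <- synth_bathymetry(40, 60, cell_m = 250,
                          profile = list(canyon = list(row_frac = 0.5)))
  expect_identical(bb$grid$depths, bb2$grid$depths)
  expect_error(synth_bathymetry(0, 10), "positive")
})

test_that("a linear ramp has the slope implied by its profile", {
  # 0 -> 2,500 m over 12.5 km is a 20 percent grade
  bb <- synth_bathymetry(20, 60, cell_m = 250,
                         profile = list(shelf_width_m = 1, shelf_depth_m = 0,
                                        ramp_width_m = 12500, max_depth_m = 2500))
  g <- bb$grid
  sl <- slope_at(g, g$lat[10], g$lon[30])
  expect_equal(sl$slope_pct, 20, tolerance = 0.005)
  expect_identical(sl$slope_class, "steep")
  # flat profile: zero slope, class light
  fl <- synth_bathymetry(20, 20, cell_m = 250, profile = list(flat_depth_m = 1500))
  sf <- slope_at(fl$grid, fl$grid$lat[10], fl$grid$lon[10])
  expect_equal(sf$slope_pct, 0)
  expect_identical(sf$slope_class, "light")
})

test_that("survey scenes honour their composition rules and truth invariants", {
  rules <- survey_composition(
    class_counts = c(adult_male = 4, female_or_juvenile_male = 5, immature = 3),
    sizes = c(2, 3, 3, 4), n_clicks = 10, ici_s = c(0.5, 0.7))
  scene <- synth_survey(4, rules, seed = 21, out_dir = tempfile("sc"),
                        render_audio = FALSE)
  ind <- scene$individuals
  expect_equal(nrow(ind), 12L)
  expect_equal(as.vector(table(ind$class_label)[c("adult_male", "female_or_juvenile_male", "immature")]),
               c(4L, 5L, 3L))
  # every true IPI within the study range and consistent with its class
  expect_true(all(ind$true_ipi_ms >= 1.9 & ind$true_ipi_ms <= 7.8))
  expect_identical(classify_individual(ind$true_ipi_ms), ind$class_label)
  # positions between the configured isobaths
  depths <- mapply(function(la, lo) depth_at(scene$grid, la, lo),
                   scene$aggregations$lat, scene$aggregations$lon)
  expect_true(all(depths >= 999 & depths <= 2001))
  # determinism of the whole scene
  scene2 <- synth_survey(4, rules, seed = 21, out_dir = tempfile("sc"),
                         render_audio = FALSE)
  expect_identical(scene$individuals, scene2$individuals)
  expect_equal(scene$aggregations[, setdiff(names(scene$aggregations), "wav")],
               scene2$aggregations[, setdiff(names(scene2$aggregations), "wav")])
})

test_that("an empty survey yields empty manifests", {
  scene <- synth_survey(0, survey_composition(), seed = 1, out_dir = tempfile("sc"))
  expect_equal(nrow(scene$individuals), 0L)
  expect_equal(nrow(scene$audio_manifest), 0L)
})

test_that("sightings placed apart resolve into separate aggregations", {
  # two individuals 1,500 m apart on one day: the 1 km rule keeps them apart
  s <- data.frame(date = "2024-02-01",
                  lat = c(14.5, 14.5 + 1500 / (pi / 180 * 6371000)),
                  lon = c(-61.2, -61.2))
  cl <- cluster_aggregations(s)
  expect_equal(length(unique(cl$aggregation_id)), 2L)
})
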