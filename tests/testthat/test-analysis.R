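# build a recordings object from a synthetic spike table (analysis-layer tests)
synthetic_recordings <- function(spikes, pop_sizes, duration_ms) {
  structure(list(
    spikes = spikes,
    epochs = tibble::tibble(epoch = "control", start_ms = 0,
                            end_ms = duration_ms, gAr = 0, gCh = 0,
                            target = "both"),
    traces = NULL, pop_sizes = pop_sizes,
    meta = list(dt = 0.1, settle_s = 0, threshold = -10, run_seed = 0,
                build_seed = 0, variant = "drug", topology = "intact",
                alpha = 0, d = 0, scale = 1)),
    class = "cpg_recordings")
}

test_that("histogram rates follow the spikes/(N x s) convention and conserve spikes", {
  sp <- tibble::tibble(neuron = 1L, population = "F", side = "left",
                       time_ms = seq(10, 100, by = 10), epoch = "control")
  rec <- synthetic_recordings(sp, tibble::tibble(population = "F",
                                                 side = "left", N = 100), 1000)
  h <- population_histogram(rec, "F", "left", bin_ms = 100)
  # 10 spikes in the first 100 ms bin, N = 100 -> 1.0 spikes/(N s)
  expect_equal(h$rate[1], 1.0)
  expect_equal(h$rate[-1], rep(0, 9))
  # conservation: sum(rate * N * bin_s) equals the raw count
  expect_equal(sum(h$rate * attr(h, "N") * 0.1), nrow(sp))
  # silent population
  rec2 <- synthetic_recordings(sp[0, ], tibble::tibble(population = "F",
                                                       side = "left", N = 10), 1000)
  expect_true(all(population_histogram(rec2, "F", "left")$rate == 0))
  expect_error(population_histogram(rec, "E", "left"),
               class = "spinalcpg_config_error")
})

test_that("histogram conservation holds on a simulated raster", {
  rec <- quarter_run("intact", 0.17)
  h <- population_histogram(rec, "F", "left")
  n_raw <- sum(rec$spikes$population == "F" & rec$spikes$side == "left")
  expect_equal(sum(h$rate * attr(h, "N") * 0.1), n_raw)
})

test_that("burst segmentation recovers square-wave ground truth", {
  # 1 Hz, 50% duty square wave rate series, 100 ms bins, 30 s
  bins <- seq(0, 29900, by = 100)
  rate <- ifelse((bins %% 1000) < 500, 10, 0)
  h <- structure(tibble::tibble(population = "F", side = "left",
                                bin_start = bins, bin_mid = bins + 50,
                                rate = rate),
                 N = 10, bin_ms = 100, class = c("cpg_histogram", "tbl_df",
                                                 "tbl", "data.frame"))
  b <- detect_bursts(h)
  expect_equal(nrow(b), 30)
  truth <- seq(0, 29000, by = 1000)
  expect_true(all(abs(b$onset - truth) <= 100))
  # invariance under rate rescaling (relative threshold)
  h10 <- h; h10$rate <- h10$rate * 10
  expect_equal(detect_bursts(h10)$onset, b$onset)
  # constant series: at most one run spanning the window
  hc <- h; hc$rate <- 5
  expect_lte(nrow(detect_bursts(hc)), 1)
})

test_that("short bursts are dropped and short gaps merged", {
  bins <- seq(0, 9900, by = 100)
  rate <- numeric(100)
  rate[11:12] <- 10              # 200 ms run: below min burst, dropped
  rate[41:50] <- 10              # 1 s burst
  rate[52:60] <- 10              # 100 ms gap: merged with previous
  h <- structure(tibble::tibble(population = "F", side = "left",
                                bin_start = bins, bin_mid = bins + 50,
                                rate = rate),
                 N = 10, bin_ms = 100, class = c("cpg_histogram", "tbl_df",
                                                 "tbl", "data.frame"))
  b <- detect_bursts(h, threshold_frac = 0.3, min_burst_ms = 300,
                     min_gap_ms = 200)
  expect_equal(nrow(b), 1)
  expect_equal(b$onset, 4000)
  expect_equal(b$offset, 6000)
})

test_that("oscillation frequency is bursts per window with a 3-burst flag", {
  b15 <- tibble::tibble(onset = seq(0, by = 20000, length.out = 15),
                        offset = seq(5000, by = 20000, length.out = 15),
                        peak_rate = 1)
  f <- oscillation_frequency(b15, 300)
  expect_equal(f$frequency_hz, 0.05)
  expect_true(f$oscillatory)
  f0 <- oscillation_frequency(b15[0, ], 300)
  expect_equal(f0$frequency_hz, 0)
  expect_false(f0$oscillatory)
  expect_false(oscillation_frequency(b15[1:2, ], 300)$oscillatory)
})

test_that("count-based frequency agrees with inter-onset intervals on regular trains", {
  for (f_true in c(0.02, 0.1, 0.5, 1)) {
    period <- 1000 / f_true
    window <- max(60000, 10 * period)
    onsets <- seq(0, window - period, by = period)
    b <- tibble::tibble(onset = onsets, offset = onsets + period / 4,
                        peak_rate = 1)
    f_count <- oscillation_frequency(b, window / 1000)$frequency_hz
    f_ioi <- 1000 / mean(diff(onsets))
    expect_equal(f_count, f_ioi, tolerance = 0.1)
  }
})

test_that("phase difference identifies synchrony, alternation and noise", {
  tr <- make_fixture("square_wave_trains", freq_hz = 1, duration_s = 30)
  # identical trains -> 0 / synchronous
  pd0 <- phase_difference(tr$a, tr$a)
  expect_equal(pd0$phase, 0)
  expect_equal(pd0$label, "synchronous")
  # half-period shift -> 0.5 / alternating
  pd5 <- phase_difference(tr$a, tr$b)
  expect_equal(pd5$phase, 0.5, tolerance = 1e-8)
  expect_equal(pd5$label, "alternating")
  # uniform random onsets -> high circular variance -> irregular
  set.seed(42)
  rnd <- tibble::tibble(onset = sort(runif(40, 0, 30000)))
  rnd$offset <- rnd$onset + 100; rnd$peak_rate <- 1
  expect_equal(phase_difference(tr$a, rnd)$label, "irregular")
  # undefined below 3 bursts
  expect_equal(phase_difference(tr$a[1:2, ], tr$b)$label, "undefined")
})

test_that("frequency normalization is a positive rescaling", {
  expect_equal(normalize_frequency(c(0.05, 0.10), 0.05), c(1, 2))
  expect_equal(normalize_frequency(0.05, 0.05), 1)
  x <- c(0.02, 0.08, 0.05)
  expect_equal(order(normalize_frequency(x, 0.04)), order(x))
  expect_error(normalize_frequency(1, 0), class = "spinalcpg_config_error")
})
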