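test_that("PSTH counts offsets per stimulus and handles edge cases", {
  stims <- seq(100, 2000, by = 100)
  # spikes exactly 2 ms after every stimulus: single bin at height 1
  psth <- compute_psth(stims + 2, stims, window_ms = c(-20, 20), bin_ms = 0.5)
  hit <- psth$rate[psth$bin_start == 1.5]
  expect_equal(hit, 1.0)
  expect_equal(sum(psth$rate), 1.0)

  # empty spike train: all-zero histogram
  expect_true(all(compute_psth(numeric(), stims, 20, 0.5)$rate == 0))

  expect_error(compute_psth(1:10, numeric(), 20, 0.5), "no stimuli")
  expect_error(compute_psth(1:10, stims, 20, 0.3), "divide")

  # homogeneous random spikes: flat PSTH within sampling error
  set.seed(2)
  spikes <- sort(runif(20000, 0, 200000))
  stims <- seq(500, 199500, by = 200)
  psth <- compute_psth(spikes, stims, c(-20, 20), 1)
  expect_lt(max(abs(psth$rate - mean(psth$rate))) / mean(psth$rate), 0.5)
})

test_that("evoked-window detector finds the earliest super-threshold run", {
  stims <- seq(100, 50000, by = 50)
  set.seed(3)
  base <- sort(runif(5000, 0, 50100))          # background at ~100 Hz
  evoked <- stims + runif(length(stims), 1.8, 2.4)
  psth <- compute_psth(c(base, evoked), stims, c(-20, 20), 0.5)
  win <- detect_evoked_window(psth)
  expect_gte(win[["start_ms"]], 1.0)
  expect_lte(win[["end_ms"]], 3.0)

  # flat PSTH: non-responsive flag
  psth_flat <- compute_psth(base, stims, c(-20, 20), 0.5)
  expect_warning(win_flat <- detect_evoked_window(psth_flat),
                 "non-responsive")
  expect_null(win_flat)

  expect_error(detect_evoked_window(compute_psth(base, stims, c(-20, 20), 1)),
               "0.5 ms")
})

test_that("doublets within 3 ms of the first evoked spike join the evoked response", {
  # one stimulus at 100; evoked spike at 102, doublet at 104.5, rebound at 140
  ann <- hybridloop:::annotate_stimuli(
    spike_times = c(50, 102, 104.5, 140),
    stim_times = 100, evoked_window = c(1, 3))
  expect_equal(ann$evoked_off, 2)
  expect_equal(ann$rebound_off, 40)   # 104.5 is a doublet, not the rebound
  expect_equal(ann$dt_prev, 50L)
})

test_that("evoked-probability smoothing behaves like a 10 ms boxcar", {
  win <- c(1, 3)
  # constant raw curve: smoothing is the identity
  spikes <- numeric(); stims <- numeric()
  for (d in seq(5, 95, by = 2)) {
    s <- 1000 * d + 500
    spikes <- c(spikes, s - d, s + 2)   # previous spike d ms before, evoked
    stims <- c(stims, s)
  }
  pe <- suppressWarnings(
    estimate_evoke_probability(sort(spikes), sort(stims), win))
  expect_true(all(abs(pe$p[5:95] - 1) < 1e-9))

  # two raw bins inside one boxcar window average together: stim at 500
  # (dt_prev 50) evokes, stim at 1450 (dt_prev 47) does not
  pe <- suppressWarnings(estimate_evoke_probability(
    c(450, 502, 1403, 1520), c(500, 1450), win))
  expect_equal(pe$p[50], 0.5)
  # empty bins far from any observation are imputed with the plateau
  expect_equal(pe$plateau, 0.5)
  expect_equal(pe$p[90], 0.5)
})

test_that("rebound oversampling respects noise bounds and the evoked window", {
  win <- c(1, 4)
  stims <- seq(100, 10100, by = 100)
  spikes <- c(stims - 30, stims + 40)   # rebound exactly 40 ms post-stimulus
  set.seed(4)
  reb <- extract_rebound_distribution(sort(spikes), stims, win)
  expect_true(all(reb > 30 - 1e-9 & reb < 50 + 1e-9))
  expect_false(any(reb >= win[1] & reb <= win[2]))
  # symmetric noise: oversampled mean close to the raw mean
  expect_lt(abs(mean(reb) - 40), 0.5)

  # samples jittered into the evoked window are discarded
  spikes2 <- c(stims - 30, stims + 6)   # raw rebound at 6 ms, noise spans (-4, 16)
  set.seed(5)
  reb2 <- extract_rebound_distribution(sort(spikes2), stims, win)
  expect_false(any(reb2 >= win[1] & reb2 <= win[2]))
  expect_true(all(reb2 > 0))

  # Gaussian supplement extends support beyond the jitter bounds
  set.seed(6)
  reb3 <- extract_rebound_distribution(
    sort(spikes), stims, win,
    gaussian_supplement = list(n = 5000, sd = 15))
  expect_gt(length(reb3), length(reb) * 0.9)
  expect_gt(max(reb3), 50)
})

test_that("library construction recovers a known generating model", {
  set.seed(11)
  truth <- make_synthetic_library(p_max = 0.7, recovery_tau_ms = 25,
                                  latency_mean = 2.5, latency_sd = 0.3,
                                  rebound_mean = 45, rebound_sd = 10)
  ol <- make_synthetic_ol_log(rate_hz = 12, stim_rate_hz = 5,
                              duration_ms = 300000, lib = truth)
  lib <- build_response_library(ol$spikes, ol$stims)
  expect_s3_class(lib, "response_library")
  # detected window covers the true latency mass
  expect_lt(lib$evoked_window[1], 2.5)
  expect_gt(lib$evoked_window[2], 2.5)
  # recovered curve tracks the generating curve where sampling is dense
  expect_lt(abs(mean(lib$p_evoke[60:100]) - mean(truth$p_evoke[60:100])), 0.1)
  # recovery: probability rises from short to long dt_prev
  expect_gt(mean(lib$p_evoke[60:100]), mean(lib$p_evoke[1:15]))
  # the plateau is the overall average evoked probability, which sits
  # between the short-interval and asymptotic probabilities
  expect_gt(lib$plateau, mean(lib$p_evoke[1:15]))
  expect_lt(lib$plateau, 0.7)
  # rebound distribution centred near the truth
  expect_lt(abs(mean(lib$rebound_samples) - 45), 6)
})
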