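test_that("zero weights recover the open-loop Markov generator", {
  src <- make_synthetic_sn(18, 300000, isi_shape = 2)
  tab <- build_transition_table(src)
  spec <- network_spec(W = matrix(0, 1, 1), stim_delay_ms = 5, stim_target = 1)
  cfg <- sim_config(duration_ms = 60000)

  set.seed(21)
  log <- run_closed_loop(spec, list(tab), list(det_library()), cfg)
  expect_equal(nrow(log$stims), 0L)
  expect_equal(nrow(log$ifu_spikes), 0L)
  expect_true(all(log$spikes$label == "spontaneous"))

  # per-SN ISI distribution indistinguishable from sample_train
  set.seed(22)
  ref <- diff(sample_train(tab, 60000))
  isi <- diff(log$spikes$time_ms)
  p <- suppressWarnings(stats::ks.test(isi, ref)$p.value)
  expect_gt(p, 0.01)
})

test_that("suprathreshold chain: every visible spike triggers one stimulus and a 50 ms rebound", {
  spec <- network_spec(W = matrix(1.05, 1, 1), stim_delay_ms = 5,
                       stim_target = 1)
  lib <- det_library(p = 0, latency = 2, rebound = 50)
  cfg <- sim_config(duration_ms = 20000, artifacts_enabled = FALSE)
  set.seed(31)
  log <- run_closed_loop(spec, list(const_table(80)), list(lib), cfg)

  expect_gt(nrow(log$stims), 10)
  # no evoked spikes (p = 0); every spike triggers a stimulus (the final
  # spike's stimulus may fall beyond the simulated horizon)
  expect_false(any(log$spikes$label == "evoked"))
  expect_true(nrow(log$stims) %in% (nrow(log$spikes) - c(0L, 1L)))
  # each stimulus is delivered t_stim after its IFU spike, and the
  # post-stimulus interval equals the rebound latency exactly
  expect_true(all(log$stims$delayed_by_ms == 0))
  post_isi <- round(diff(log$spikes$time_ms), 6)
  # steady state: spike -> (conduction 0.1 + kernel rise to threshold)
  # + 5 ms delay + 50 ms rebound; all intervals identical after the first
  expect_equal(length(unique(post_isi[-1])), 1L)
  expect_gt(unique(post_isi[-1])[1], 55)
  expect_true(all(log$spikes$label[-1] == "rebound"))
})

test_that("deliver_stimulus honours the probability curve and rebound independence", {
  lib <- make_synthetic_library(p_max = 0.8, recovery_tau_ms = 30)
  set.seed(41)
  n <- 20000
  hits <- vapply(seq_len(n), function(i)
    deliver_stimulus(lib, dt_prev = 20)$evoked, logical(1))
  p_true <- lib$p_evoke[20]
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(hits) - p_true), 3 * se)

  r <- deliver_stimulus(lib, dt_prev = 150)   # plateau region
  expect_true(r$rebound_ms %in% lib$rebound_samples)
  zero <- det_library(p = 0)
  expect_false(deliver_stimulus(zero, 10)$evoked)
  one <- det_library(p = 1, latency = 2)
  r1 <- deliver_stimulus(one, 10)
  expect_true(r1$evoked)
  expect_true(r1$latency_ms %in% one$latency_samples)
})

test_that("artifact staggering and obstruction follow the 1 ms rule", {
  pol <- apply_artifact_policy(c(100.0, 100.4))
  expect_equal(pol$delivered_ms, c(100.0, 101.0))
  expect_equal(pol$delayed_by_ms, c(0, 0.6))
  # cascade: three stimuli in the same ms
  pol3 <- apply_artifact_policy(c(50.0, 50.2, 50.4))
  expect_equal(pol3$delivered_ms, c(50, 51, 52))

  expect_equal(mark_obstructed(c(100.5, 101.2), 100), c(TRUE, FALSE))
  expect_equal(mark_obstructed(100, numeric()), FALSE)

  # in the engine: delivered stimuli are never within 1 ms of each other,
  # and obstructed spikes always fall within 1 ms after some stimulus
  spec <- make_fixture_network("recurrent3")
  pool <- local({
    set.seed(51)
    make_sn_pool(c(25, 30, 35), duration_ms = 120000)
  })
  set.seed(52)
  log <- run_closed_loop(spec, pool$tables, pool$libs,
                         sim_config(duration_ms = 20000))
  if (nrow(log$stims) > 1)
    expect_gte(min(diff(sort(log$stims$time_ms))), 1)
  obs <- log$spikes[log$spikes$obstructed, ]
  if (nrow(obs)) {
    gap <- vapply(obs$time_ms, function(t) {
      d <- t - log$stims$time_ms
      min(d[d >= 0])
    }, numeric(1))
    expect_true(all(gap < 1))
  }
})

test_that("engine runs are causal and byte-for-byte reproducible", {
  spec <- make_fixture_network("recurrent4")
  set.seed(61)
  pool <- make_sn_pool(c(15, 20, 25, 30), duration_ms = 120000,
                       library_args = list(p_max = 0.9))
  cfg <- sim_config(duration_ms = 15000)

  set.seed(62)
  a <- run_closed_loop(spec, pool$tables, pool$libs, cfg)
  set.seed(62)
  b <- run_closed_loop(spec, pool$tables, pool$libs, cfg)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$stims, b$stims)
  expect_identical(a$ifu_spikes, b$ifu_spikes)

  # causality: every evoked spike follows its stimulus by a library latency
  ev <- a$spikes[a$spikes$label == "evoked", ]
  lat <- ev$time_ms - a$stims$time_ms[ev$stim_id]
  expect_true(all(lat >= 0))
  expect_true(all(lat <= max(pool$libs[[1]]$evoked_window[2] + 0.1)))
  # at most one evoked response per stimulus per SN
  expect_false(any(duplicated(ev$stim_id)))
  # every stimulus traces back to an IFU spike t_stim earlier
  d <- a$stims$scheduled_ms - a$ifu_spikes$time_ms[a$stims$ifu_spike_id]
  expect_true(all(abs(d - spec$stim_delay_ms[a$stims$source_ifu]) < 1e-9))
})

test_that("cross-excitation with certain evocation sustains feedback loops", {
  # two SNs and two IFUs, each IFU pooling both SNs; p_evoke = 1 with short
  # latency keeps evoked spikes coincident, so loops self-sustain
  spec <- network_spec(W = matrix(0.75, 2, 2), stim_delay_ms = c(5, 10),
                       stim_target = c(1, 2))
  lib <- det_library(p = 1, latency = 2, rebound = 120)
  set.seed(71)
  tabs <- lapply(c(12, 14), function(r)
    build_transition_table(make_synthetic_sn(r, 200000)))
  set.seed(72)
  log <- run_closed_loop(spec, tabs, list(lib, lib),
                         sim_config(duration_ms = 30000))
  loops <- merge_feedback_loops(find_elementary_patterns(log))
  expect_gt(nrow(loops), 0)
  expect_gt(max(loops$size), 3)
})

test_that("hidden layers gate output activation to multi-SN coincidence", {
  spec <- make_fixture_network("hidden")
  lib <- det_library(p = 0, latency = 2, rebound = 60)
  # three SNs firing in close succession drive the output IFUs; a periodic
  # low-rate train per SN with staggered phases makes this deterministic
  tabs <- lapply(c(100, 101, 102), const_table)
  set.seed(81)
  log <- run_closed_loop(spec, tabs, list(lib, NULL, lib),
                         sim_config(duration_ms = 30000,
                                    inhibit_enabled = FALSE))
  # hidden IFUs (1-3) spike; output IFUs (4-5) spike only after them
  expect_true(any(log$ifu_spikes$ifu <= 3))
  out_spikes <- log$ifu_spikes[log$ifu_spikes$ifu >= 4, ]
  if (nrow(out_spikes)) {
    expect_true(all(out_spikes$trig1_kind == "ifu" |
                    out_spikes$trig2_kind == "ifu"))
    # indirect patterns are flagged
    pats <- find_elementary_patterns(log)
    if (length(pats))
      expect_true(all(vapply(pats, `[[`, logical(1), "indirect")))
  }
})
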