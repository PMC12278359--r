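test_that("elementary patterns group an evoked spike with its two triggers", {
  log <- build_pattern_log(list(c(1, 2)))
  pats <- find_elementary_patterns(log)
  expect_length(pats, 1)
  expect_length(pats[[1]]$spike_ids, 3)
  expect_setequal(pats[[1]]$trigger_ids, c(1, 2))
  expect_false(pats[[1]]$indirect)

  # no evoked spikes: empty list
  empty <- build_pattern_log(list(c(1, 2)))
  empty$spikes$label[empty$spikes$label == "evoked"] <- "spontaneous"
  empty$spikes$stim_id <- NA_integer_
  expect_length(find_elementary_patterns(empty), 0)

  # untraceable triggers (single suprathreshold EPSP): no pattern, flagged
  solo <- build_pattern_log(list(c(1, 2)))
  solo$ifu_spikes$trig1_id <- NA_integer_
  solo$ifu_spikes$trig1_kind <- NA_character_
  pats <- find_elementary_patterns(solo)
  expect_length(pats, 0)
  expect_equal(attr(pats, "n_untraceable"), 1L)

  # two evoked spikes sharing one trigger: two patterns share one spike
  shared <- build_pattern_log(list(c(1, 2), c(2, 3)))
  pats <- find_elementary_patterns(shared)
  expect_length(pats, 2)
  expect_equal(length(intersect(pats[[1]]$spike_ids, pats[[2]]$spike_ids)), 1L)
})

test_that("feedback-loop merging matches the worked example and the oracle", {
  # two patterns sharing exactly one spike merge into one loop of 5 spikes
  p <- list(list(spike_ids = c(1, 2, 10)), list(spike_ids = c(2, 3, 11)))
  loops <- merge_feedback_loops(p)
  expect_equal(nrow(loops), 1L)
  expect_equal(loops$size, 5L)
  expect_equal(loops$n_patterns, 2L)

  # disjoint patterns stay separate
  q <- list(list(spike_ids = 1:3), list(spike_ids = 4:6))
  expect_equal(sort(merge_feedback_loops(q)$size), c(3L, 3L))

  # chain of k patterns sharing one spike with the next: size 2k + 1
  for (k in c(2, 5, 10)) {
    chain <- lapply(seq_len(k), function(i)
      list(spike_ids = c(2 * i - 1, 2 * i, 2 * i + 1)))
    loops <- merge_feedback_loops(chain)
    expect_equal(nrow(loops), 1L)
    expect_equal(loops$size, 2L * k + 1L)
  }

  # partition property and order invariance on random instances
  set.seed(91)
  for (rep_i in 1:25) {
    pats <- random_patterns(sample(1:40, 1))
    loops <- merge_feedback_loops(pats)
    expect_equal(sum(loops$n_patterns), length(pats))
    expect_true(all(loops$size >= 3))
    perm <- sample(length(pats))
    loops_p <- merge_feedback_loops(pats[perm])
    expect_equal(sort(loops_p$size), sort(loops$size))
    # brute-force transitive-closure oracle agrees (up to relabeling both
    # memberships are put in first-appearance canonical form)
    mem <- attr(loops, "membership")
    oracle <- oracle_merge(pats)
    expect_equal(match(mem, unique(mem)), match(oracle, unique(oracle)))
  }
})

test_that("correlograms count lagged coincidences per reference spike", {
  # periodic 10 ms autocorrelogram: 1 at multiples of 10, 0 at lag 0
  tr <- seq(0, 5000, by = 10)
  cg <- correlogram(tr)
  expect_equal(cg$value[cg$lag_ms == 0], 0)
  on_peak <- cg$lag_ms != 0 & cg$lag_ms %% 10 == 0
  expect_true(all(cg$value[on_peak] > 0.99))
  expect_true(all(cg$value[!on_peak & cg$lag_ms != 0] == 0))

  # symmetry: value(l) of (a, b) equals value(-l) of (b, a)
  set.seed(92)
  a <- sort(runif(400, 0, 20000))
  b <- sort(runif(300, 0, 20000))
  cab <- correlogram(a, b)
  cba <- correlogram(b, a)
  na <- length(unique(round(a)))
  nb <- length(unique(round(b)))
  expect_equal(cab$value * na, rev(cba$value) * nb, tolerance = 1e-12)

  # mass conservation: sum over lags = mean count of b-spikes near a-spike
  direct <- mean(vapply(unique(round(a)), function(t)
    sum(abs(unique(round(b)) - t) <= 50), numeric(1)))
  expect_equal(sum(cab$value), direct, tolerance = 1e-12)

  # independent sparse trains: flat around rate_b per ms
  lam <- length(unique(round(b))) / 20000
  expect_lt(max(abs(cab$value - lam)), 6 * sqrt(lam / length(a)) + lam)

  expect_error(correlogram(numeric(), 1:10), "empty")
})

test_that("correlogram similarity is Pearson r with central-bin exclusion", {
  set.seed(93)
  a <- sort(runif(500, 0, 30000))
  c1 <- correlogram(a)
  expect_equal(correlogram_similarity(c1, c1)$r, 1)

  c2 <- c1
  c2$value <- -c1$value + 0.3
  attr(c2, "is_auto") <- FALSE
  # affine rescaling leaves |r| = 1
  expect_equal(correlogram_similarity(c1, c2)$r, -1)
  c3 <- c1
  c3$value <- 2 * c1$value + 1
  expect_equal(correlogram_similarity(c1, c3)$r, 1)

  flat <- c1
  flat$value <- rep(0.1, nrow(flat))
  attr(flat, "is_auto") <- FALSE
  expect_warning(r0 <- correlogram_similarity(c1, flat), "zero variance")
  expect_true(is.na(r0$r))
})

test_that("smoothing is a mass-preserving moving average away from edges", {
  set.seed(94)
  cg <- correlogram(sort(runif(300, 0, 10000)))
  sm <- smooth_correlogram(cg, 3)
  i <- 10:90
  manual <- vapply(i, function(j) mean(cg$value[(j - 1):(j + 1)]), numeric(1))
  expect_equal(sm$value[i], manual)
})

test_that("stimulation efficiency is stimuli per spike", {
  log <- toy_event_log(
    spikes = data.frame(id = 1:400, time_ms = sort(runif(400, 0, 1000)),
                        sn = 1L, label = "spontaneous", obstructed = FALSE,
                        stim_id = NA_integer_),
    stims = data.frame(id = 1:100, time_ms = sort(runif(100, 0, 1000))),
    ifu_spikes = data.frame())
  expect_equal(stimulation_efficiency(log), 0.25)
  log$stims <- log$stims[0, , drop = FALSE]
  expect_equal(stimulation_efficiency(log), 0)
  log$spikes <- log$spikes[0, , drop = FALSE]
  expect_warning(v <- stimulation_efficiency(log), "undefined")
  expect_true(is.na(v))
})
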