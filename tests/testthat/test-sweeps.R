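test_that("linear model wrapper reports fits and flags degenerate designs", {
  set.seed(101)
  X <- data.frame(x1 = runif(60), x2 = runif(60))
  y <- 2 + 3 * X$x1 - X$x2
  m <- suppressWarnings(fit_linear_model(y, X))  # exact fit warns in summary.lm
  expect_equal(m$r_squared, 1)
  expect_equal(m$coefficients$beta[m$coefficients$term == "x1"], 3)

  # duplicated predictor: rank deficiency is an error
  X2 <- data.frame(x1 = X$x1, x1b = X$x1)
  expect_error(fit_linear_model(y, X2), "collinear")

  # permuted response carries no signal
  m0 <- fit_linear_model(sample(y), X)
  expect_lt(m0$r_squared, 0.15)

  expect_error(fit_linear_model(y[1:2], X[1:2, ]), "more observations")
})

test_that("artifact sweep builds valid random networks and obstruction metrics", {
  set.seed(102)
  pool <- make_sn_pool(rates_hz = c(5, 10, 15, 20, 30, 40),
                       duration_ms = 60000)
  set.seed(103)
  sw <- artifact_sweep(pool, sizes = c(4, 6), weights = c(0.5, 0.875),
                       replicates = 2, duration_ms = 5000,
                       evoked_responses = FALSE)
  expect_equal(nrow(sw$results), 8)
  expect_true(all(sw$results$missed_frac >= 0 & sw$results$missed_frac <= 1))
  expect_true(all(sw$results$n_missed <= sw$results$n_spikes))
  # no evoked responses: every obstructed spike is spontaneous
  expect_true(all(is.na(sw$results$evoked_missed_ratio) |
                  sw$results$evoked_missed_ratio == 0))
  expect_s3_class(sw$model, "regression_result")
  expect_equal(nrow(sw$per_sn), sum(sw$results$size))

  # pool smaller than the largest network size is a configuration error
  expect_error(artifact_sweep(pool, sizes = 8), "smaller")

  # per-SN aggregation feeds the rate regression
  mr <- missed_rate_regression(sw$per_sn)
  expect_equal(nrow(mr$data), length(unique(sw$per_sn$pool_sn)))
  expect_s3_class(mr$model, "regression_result")
})

test_that("delay sweep uses common random numbers across conditions", {
  spec <- make_fixture_network("recurrent3")
  set.seed(104)
  pool <- make_sn_pool(c(20, 25, 30), duration_ms = 60000,
                       library_args = list(p_max = 0.9, recovery_tau_ms = 20))
  set.seed(105)
  sw <- delay_sweep(spec, pool$tables, pool$libs,
                    delay_sets = list(c(5, 10, 15), c(5, 10, 15)),
                    duration_ms = 8000, replicates = 2)
  # identical delay sets with shared seeds: identical loop-size distributions
  a <- sw$loop_sizes$size[sw$loop_sizes$condition == "set1: 5/10/15"]
  b <- sw$loop_sizes$size[sw$loop_sizes$condition == "set2: 5/10/15"]
  expect_identical(a, b)
  expect_equal(sw$kruskal$p.value, 1, tolerance = 1e-6)

  expect_error(delay_sweep(spec, pool$tables, pool$libs,
                           delay_sets = list(c(5, 10, 15))), "at least 2")
  expect_error(delay_sweep(spec, pool$tables, pool$libs,
                           delay_sets = list(c(5, 10), c(5, 10))),
               "one delay per output IFU")
})

test_that("inhibition sweep rescales IPSPs jointly and fits both factors", {
  spec <- make_fixture_network("recurrent4")
  set.seed(106)
  pool <- make_sn_pool(c(18, 22, 26, 30), duration_ms = 60000,
                       library_args = list(p_max = 0.9, recovery_tau_ms = 15))
  set.seed(107)
  sw <- inhibition_sweep(spec, pool$tables, pool$libs,
                         magnitudes = c(0, 1), decays_ms = c(4, 16),
                         duration_ms = 8000)
  expect_equal(nrow(sw$results), 4)
  expect_true(all(c("magnitude_pct", "decay_ms", "mean_loop_size", "seed")
                  %in% names(sw$results)))
  expect_s3_class(sw$model, "regression_result")
  expect_equal(nrow(sw$model$coefficients), 3)

  # a network without inhibitory connections cannot be swept
  pure <- network_spec(matrix(0.75, 2, 2), c(5, 10), c(1, 2))
  expect_error(inhibition_sweep(pure, pool$tables[1:2], pool$libs[1:2]),
               "no inhibitory connection")
  # grid outside the calibrated ranges warns but runs
  expect_warning(
    inhibition_sweep(spec, pool$tables, pool$libs, magnitudes = c(0, 2.5),
                     decays_ms = c(4, 16), duration_ms = 1000),
    "calibrated ranges")
})

test_that("ANCOVA wrapper fits rate-by-condition interaction models", {
  set.seed(108)
  mk <- function(cond, icpt) data.frame(
    pool_sn = 1:20, rate_hz = seq(2, 40, length.out = 20),
    realized_rate_hz = seq(2, 40, length.out = 20),
    n_spikes = 1000L,
    n_missed = round(icpt + 2 * seq(2, 40, length.out = 20) + rnorm(20, 0, 1)))
  m <- artifact_ancova(mk("baseline", 5), mk("evoked", 25))
  terms <- m$coefficients$term
  expect_true(any(grepl("rate_hz$", terms)))
  expect_true(any(grepl("conditionevoked$", terms)))
  expect_true(any(grepl(":", terms)))
  # the built-in intercept difference is detected
  expect_lt(m$coefficients$p_value[terms == "conditionevoked"], 0.01)
})
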