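#' Ordinary least squares with coefficient tests
#'
#' Thin wrapper around [stats::lm()] returning the coefficient table and
#' coefficient of determination, with explicit rank-deficiency detection
#' (duplicated or collinear predictors are an error, not a silent drop).
#'
#' @param y Response vector.
#' @param X data.frame of predictors.
#' @param interaction Include all pairwise interaction terms. Default FALSE.
#' @return An object of class `regression_result`: list with `coefficients`
#'   (data.frame `term`, `beta`, `p_value`), `r_squared`, and `fit` (the
#'   `lm` object).
#' @export
fit_linear_model <- function(y, X, interaction = FALSE) {
  stopifnot(is.data.frame(X), length(y) == nrow(X))
  if (nrow(X) <= ncol(X) + 1L)
    stop("need more observations than predictors")
  dat <- cbind(.y = y, X)
  form <- if (interaction) .y ~ .^2 else .y ~ .
  fit <- lm(form, data = dat)
  if (anyNA(coef(fit)))
    stop("rank-deficient design: predictors ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         " are collinear")
  sm <- summary(fit)
  structure(
    list(coefficients = data.frame(
           term = rownames(sm$coefficients),
           beta = sm$coefficients[, "Estimate"],
           p_value = sm$coefficients[, "Pr(>|t|)"],
           row.names = NULL),
         r_squared = sm$r.squared,
         fit = fit),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Linear model: R^2 = %.3f\n", x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

## derive per-condition seeds from the current RNG stream and record them
draw_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

## summary metrics shared by the sweeps
loop_sizes_of <- function(log) {
  merge_feedback_loops(find_elementary_patterns(log))$size
}

#' Inhibition sweep: IPSP magnitude and decay versus feedback-loop size
#'
#' Simulates the closed loop over a grid of IPSP magnitudes (fraction of the
#' IFU activation threshold; all inhibitory connections are set jointly) and
#' IPSP decay time constants, holding the excitatory weights at their base
#' values, and regresses the average feedback-loop size on both factors.
#' The default grid is the 9 x 9 grid over 0-200% of threshold and
#' 4-20 ms (81 conditions).
#'
#' @param spec Base [network_spec()] with at least one inhibitory connection.
#' @param tables,libs Per-SN models as in [run_closed_loop()].
#' @param magnitudes IPSP magnitudes as fractions of threshold.
#'   Default `seq(0, 2, length.out = 9)`.
#' @param decays_ms IPSP decay time constants in ms.
#'   Default `seq(4, 20, length.out = 9)`.
#' @param duration_ms Simulated duration per condition. Default 300000
#'   (5 min).
#' @param cfg_args Further arguments to [sim_config()].
#' @return A list with `results` (one row per condition: `magnitude`,
#'   `magnitude_pct`, `decay_ms`, `seed`, `n_loops`, `mean_loop_size`) and
#'   `model` (average loop size regressed on magnitude in percent and decay
#'   in ms).
#' @export
inhibition_sweep <- function(spec, tables, libs,
                             magnitudes = seq(0, 2, length.out = 9),
                             decays_ms = seq(4, 20, length.out = 9),
                             duration_ms = 300000, cfg_args = list()) {
  stopifnot(inherits(spec, "network_spec"))
  if (!any(spec$W < 0))
    stop("base network has no inhibitory connection to rescale")
  if (any(magnitudes < 0 | magnitudes > 2) || any(decays_ms < 4 | decays_ms > 20))
    warning("grid extends beyond the calibrated ranges (0-200% and 4-20 ms)")
  grid <- expand.grid(magnitude = magnitudes, decay_ms = decays_ms)
  grid$seed <- draw_seeds(nrow(grid))
  cfg <- do.call(sim_config, c(list(duration_ms = duration_ms), cfg_args))

  res <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- spec
    sp$W[spec$W < 0] <- -grid$magnitude[i]
    sp$inh_kernel <- calibrate_kernel(
      tau_rise_ms = spec$kernel$tau_rise_ms,
      tau_decay_ms = grid$decay_ms[i],
      tick_ms = spec$kernel$tick_ms)
    set.seed(grid$seed[i])
    sizes <- loop_sizes_of(run_closed_loop(sp, tables, libs, cfg))
    data.frame(n_loops = length(sizes),
               mean_loop_size = if (length(sizes)) mean(sizes) else NA_real_)
  })
  results <- cbind(grid, do.call(rbind, res))
  results$magnitude_pct <- 100 * results$magnitude

  ok <- !is.na(results$mean_loop_size)
  model <- fit_linear_model(
    results$mean_loop_size[ok],
    results[ok, c("magnitude_pct", "decay_ms")])
  list(results = results, model = model)
}

#' Stimulation-delay sweep: loop-size distributions across delay sets
#'
#' Simulates the closed loop for each assignment of per-output-IFU
#' stimulation delays, pools the feedback-loop sizes per delay set, and
#' compares the distributions with a Kruskal-Wallis test followed by
#' pairwise Wilcoxon rank-sum post-hoc tests.
#'
#' @param spec Base [network_spec()].
#' @param tables,libs Per-SN models.
#' @param delay_sets List of numeric vectors, each giving the stimulation
#'   delays (ms) of the output IFUs in order.
#' @param duration_ms Duration per run. Default 300000 (5 min).
#' @param replicates Runs per delay set. Default 1.
#' @param cfg_args Further arguments to [sim_config()].
#' @return A list with `loop_sizes` (data.frame `condition`, `replicate`,
#'   `seed`, `size`), `summary` (per condition), `kruskal` (htest), and
#'   `pairwise` (data.frame of Wilcoxon comparisons).
#' @export
delay_sweep <- function(spec, tables, libs, delay_sets, duration_ms = 300000,
                        replicates = 1, cfg_args = list()) {
  stopifnot(inherits(spec, "network_spec"))
  if (length(delay_sets) < 2L) stop("need at least 2 delay sets to compare")
  out_idx <- which(!is.na(spec$stim_delay_ms))
  cfg <- do.call(sim_config, c(list(duration_ms = duration_ms), cfg_args))
  conds <- sprintf("set%d: %s", seq_along(delay_sets),
                   vapply(delay_sets, function(d) paste(d, collapse = "/"),
                          character(1)))
  ## common random numbers: replicate r uses the same seed in every
  ## condition, so identical delay sets yield identical distributions
  rep_seeds <- draw_seeds(replicates)

  rows <- list()
  for (ci in seq_along(delay_sets)) {
    d <- delay_sets[[ci]]
    if (length(d) != length(out_idx))
      stop("delay set ", ci, " must give one delay per output IFU")
    sp <- spec
    sp$stim_delay_ms[out_idx] <- d
    sp <- do.call(network_spec, sp[c("W", "stim_delay_ms", "stim_target",
                                     "thresholds", "ifu_to_ifu_W", "kernel",
                                     "inh_kernel")])
    for (rep_i in seq_len(replicates)) {
      set.seed(rep_seeds[rep_i])
      sizes <- loop_sizes_of(run_closed_loop(sp, tables, libs, cfg))
      if (length(sizes))
        rows[[length(rows) + 1L]] <- data.frame(
          condition = conds[ci], replicate = rep_i,
          seed = rep_seeds[rep_i], size = sizes)
    }
  }
  loop_sizes <- do.call(rbind, rows)
  summary_df <- do.call(rbind, lapply(split(loop_sizes, loop_sizes$condition),
    function(d) data.frame(condition = d$condition[1], n_loops = nrow(d),
                           mean_size = mean(d$size))))
  kr <- kruskal.test(loop_sizes$size, factor(loop_sizes$condition))
  pairs <- utils::combn(conds, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(q) {
    a <- loop_sizes$size[loop_sizes$condition == pairs[1, q]]
    b <- loop_sizes$size[loop_sizes$condition == pairs[2, q]]
    data.frame(a = pairs[1, q], b = pairs[2, q],
               p_value = wilcox.test(a, b)$p.value)
  }))
  list(loop_sizes = loop_sizes, summary = summary_df, kruskal = kr,
       pairwise = pw)
}

#' Artifact-obstruction sweep over network size and connection strength
#'
#' Builds random purely excitatory networks of `size` SNs and `size` IFUs
#' from a pool of SN models (each IFU receives `presyn_per_ifu` random
#' presynaptic connections and targets its own SN with a random delay of
#' `n * 4` ms, `n` drawn without replacement from 1..10 so delays stay at
#' least 4 ms apart), simulates each condition `replicates` times, and
#' measures the fraction of spikes obstructed by stimulation artifacts.
#' With `evoked_responses = FALSE` the stimuli evoke and inhibit nothing and
#' only obstruct detection (baseline condition); with `TRUE` the full
#' stimulation-response model is active.
#'
#' @param pool SN model pool from [make_sn_pool()].
#' @param sizes Network sizes. Default `c(4, 6, 8, 10)`.
#' @param weights EPSP magnitudes as fractions of threshold.
#'   Default `c(0.5, 0.625, 0.75, 0.875)`.
#' @param presyn_per_ifu Presynaptic connections per IFU. Default 4.
#' @param replicates Random replicates per condition. Default 10.
#' @param duration_ms Duration per simulation in ms. Default 60000.
#' @param evoked_responses Enable evoked spikes and inhibition. Default
#'   FALSE.
#' @param kernel Kernel parameters. Default [calibrate_kernel()].
#' @return A list with `results` (one row per condition x replicate:
#'   `size`, `weight_pct`, `replicate`, `seed`, `n_spikes`, `n_stims`,
#'   `n_missed`, `missed_frac`, `evoked_missed_ratio`), `per_sn` (one row
#'   per SN appearance: `pool_sn`, `rate_hz`, `n_spikes`, `n_missed`,
#'   condition columns), and `model` (missed fraction regressed on weight
#'   percent and network size over condition means).
#' @export
artifact_sweep <- function(pool, sizes = c(4, 6, 8, 10),
                           weights = c(0.5, 0.625, 0.75, 0.875),
                           presyn_per_ifu = 4, replicates = 10,
                           duration_ms = 60000, evoked_responses = FALSE,
                           kernel = calibrate_kernel()) {
  n_pool <- length(pool$tables)
  if (n_pool < max(sizes))
    stop("SN pool (", n_pool, ") smaller than the largest network size")
  grid <- expand.grid(size = sizes, weight = weights,
                      replicate = seq_len(replicates))
  grid$seed <- draw_seeds(nrow(grid))
  cfg <- sim_config(duration_ms = duration_ms,
                    evoke_enabled = evoked_responses,
                    inhibit_enabled = evoked_responses,
                    artifacts_enabled = TRUE)

  res_rows <- vector("list", nrow(grid))
  sn_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    set.seed(grid$seed[i])
    s <- grid$size[i]
    w <- grid$weight[i]
    members <- sample.int(n_pool, s)
    W <- matrix(0, s, s)
    for (j in seq_len(s)) W[sample.int(s, presyn_per_ifu), j] <- w
    delays <- 4 * sample.int(10L, s)
    spec <- network_spec(W = W, stim_delay_ms = delays, stim_target = seq_len(s),
                         kernel = kernel)
    log <- run_closed_loop(spec, pool$tables[members], pool$libs[members], cfg)
    spk <- log$spikes
    n_missed <- sum(spk$obstructed)
    res_rows[[i]] <- data.frame(
      size = s, weight_pct = 100 * w, replicate = grid$replicate[i],
      seed = grid$seed[i], n_spikes = nrow(spk), n_stims = nrow(log$stims),
      n_missed = n_missed,
      missed_frac = if (nrow(spk)) n_missed / nrow(spk) else 0,
      evoked_missed_ratio = if (n_missed)
        sum(spk$obstructed & spk$label == "evoked") / n_missed else NA_real_)
    per <- do.call(rbind, lapply(seq_len(s), function(k) {
      sk <- spk[spk$sn == k, ]
      data.frame(pool_sn = members[k], rate_hz = pool$rates_hz[members[k]],
                 realized_rate_hz = 1000 * nrow(sk) / duration_ms,
                 n_spikes = nrow(sk), n_missed = sum(sk$obstructed))
    }))
    per$size <- s
    per$weight_pct <- 100 * w
    per$replicate <- grid$replicate[i]
    sn_rows[[i]] <- per
  }
  results <- do.call(rbind, res_rows)
  per_sn <- do.call(rbind, sn_rows)

  ## condition means over replicates, then OLS on (weight, size)
  agg <- stats::aggregate(missed_frac ~ size + weight_pct, data = results,
                          FUN = mean)
  model <- fit_linear_model(agg$missed_frac, agg[, c("weight_pct", "size")])
  list(results = results, per_sn = per_sn, model = model,
       evoked_responses = evoked_responses)
}

#' Regression of per-SN obstructed-spike counts on firing rate
#'
#' Aggregates an [artifact_sweep()] per-SN table over all conditions and
#' replicates (mean obstructed count per appearance) and regresses the
#' aggregate on the SN's firing rate. With evoked responses disabled the
#' obstructed count is proportional to the product of firing rate and total
#' artifact time, so the relationship is almost perfectly linear.
#'
#' @param per_sn The `per_sn` table of an [artifact_sweep()].
#' @param use_realized_rate Regress on the realized simulation rate (TRUE,
#'   default) or the pool's nominal baseline rate.
#' @return A list with `data` (per-SN aggregates) and `model`
#'   (a [fit_linear_model()] result).
#' @export
missed_rate_regression <- function(per_sn, use_realized_rate = TRUE) {
  agg <- do.call(rbind, lapply(split(per_sn, per_sn$pool_sn), function(d) {
    data.frame(pool_sn = d$pool_sn[1],
               rate_hz = if (use_realized_rate) mean(d$realized_rate_hz)
                         else d$rate_hz[1],
               mean_missed = mean(d$n_missed),
               n_appearances = nrow(d))
  }))
  model <- fit_linear_model(agg$mean_missed, agg[, "rate_hz", drop = FALSE])
  list(data = agg, model = model)
}

#' ANCOVA-style comparison of spike loss with and without evoked responses
#'
#' Fits `missed percentage ~ firing rate * condition` over the per-SN tables
#' of two artifact sweeps (evoked responses disabled vs. enabled), testing
#' whether evoked spikes raise the baseline missed-spike rate (condition
#' main effect) and whether they change the slope relating firing rate to
#' spike loss (interaction term).
#'
#' @param per_sn_baseline `per_sn` table from the sweep without evoked
#'   responses.
#' @param per_sn_evoked `per_sn` table from the sweep with evoked responses.
#' @return A [fit_linear_model()] result with terms `rate_hz`,
#'   `conditionevoked`, and their interaction.
#' @export
artifact_ancova <- function(per_sn_baseline, per_sn_evoked) {
  mk <- function(d, cond) data.frame(
    missed_pct = 100 * d$n_missed / pmax(1L, d$n_spikes),
    rate_hz = d$realized_rate_hz, condition = cond)
  dat <- rbind(mk(per_sn_baseline, "baseline"), mk(per_sn_evoked, "evoked"))
  dat$condition <- factor(dat$condition, levels = c("baseline", "evoked"))
  fit_linear_model(dat$missed_pct, dat[, c("rate_hz", "condition")],
                   interaction = TRUE)
}
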