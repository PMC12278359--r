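#' Closed-loop simulation configuration
#'
#' @param duration_ms Simulated duration in ms.
#' @param tick_ms Tick duration in ms. Default 0.1 (10 kHz).
#' @param artifact_ms Stimulation-artifact duration in ms; every spike within
#'   this interval after a delivered stimulus is obstructed (undetectable by
#'   the decoder), and a stimulus scheduled within it is delayed to its end.
#'   Default 1.
#' @param evoke_enabled Stimuli may evoke spikes. Default TRUE.
#' @param inhibit_enabled Stimuli inhibit: the target SN's pending
#'   spontaneous spike is cancelled and replaced by a rebound spike drawn
#'   from the library. Default TRUE.
#' @param artifacts_enabled Artifact obstruction and staggering. Default TRUE.
#' @param obstructed_resets_dtprev Obstructed spikes still reset the time
#'   since the previous spike (the neuron truly fired; the artifact only
#'   hides it from the decoder). Default TRUE.
#' @param evoked_exempt The target SN's own evoked spike is exempt from
#'   obstruction by its causal stimulus. Default TRUE.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration_ms, tick_ms = 0.1, artifact_ms = 1,
                       evoke_enabled = TRUE, inhibit_enabled = TRUE,
                       artifacts_enabled = TRUE,
                       obstructed_resets_dtprev = TRUE,
                       evoked_exempt = TRUE) {
  stopifnot(duration_ms > 0, tick_ms > 0, artifact_ms >= 0)
  structure(list(duration_ms = duration_ms, tick_ms = tick_ms,
                 artifact_ms = artifact_ms, evoke_enabled = evoke_enabled,
                 inhibit_enabled = inhibit_enabled,
                 artifacts_enabled = artifacts_enabled,
                 obstructed_resets_dtprev = obstructed_resets_dtprev,
                 evoked_exempt = evoked_exempt),
            class = "sim_config")
}

## flatten a response_library for the engine
lib_for_engine <- function(lib) {
  if (is.null(lib)) return(NULL)
  list(p = lib$p_evoke, plateau = lib$plateau,
       latency = lib$latency_samples, rebound = lib$rebound_samples)
}

## flatten an isi_table for the engine (concatenated successor pools)
table_for_engine <- function(tab) {
  lens <- lengths(tab$succ)
  list(keys = as.integer(tab$keys),
       off = as.integer(c(0L, cumsum(lens))),
       succ = as.integer(unlist(tab$succ, use.names = FALSE)),
       obs = as.integer(tab$isi1_obs))
}

#' Run the closed-loop simulation
#'
#' Couples per-SN Markov spike generators and stimulation-response libraries
#' to the IFU network and simulates the closed loop tick by tick: SN spikes
#' (after a one-tick conduction delay) drive IFU PSPs; IFUs crossing
#' threshold spike, reset, and (if output IFUs) trigger a stimulus on their
#' target SN after their stimulation delay; each delivered stimulus evokes a
#' spike with probability `p_evoke(dt_prev)` at a sampled latency, replaces
#' the target's next spontaneous spike with a sampled rebound spike, and
#' creates a 1 ms artifact that obstructs spike detection and staggers any
#' concurrent stimulus.
#'
#' Randomness is consumed from R's RNG stream: call `set.seed()` before this
#' function for reproducible runs.
#'
#' @param spec A [network_spec()].
#' @param tables List of `n_sn` [isi_table][build_transition_table]s.
#' @param libs List of `n_sn` [response_library()]s (entries for SNs that no
#'   output IFU targets may be `NULL`).
#' @param cfg A [sim_config()].
#' @return An object of class `event_log`: list of data.frames `spikes`
#'   (`time_ms`, `sn`, `label` in spontaneous/evoked/rebound, `obstructed`,
#'   `id`, `stim_id`), `stims` (`id`, `time_ms`, `scheduled_ms`,
#'   `delayed_by_ms`, `target_sn`, `source_ifu`, `ifu_spike_id`), and
#'   `ifu_spikes` (`id`, `time_ms`, `ifu`, trigger provenance columns),
#'   plus the `spec` and `cfg` used.
#' @export
run_closed_loop <- function(spec, tables, libs, cfg) {
  stopifnot(inherits(spec, "network_spec"), inherits(cfg, "sim_config"))
  if (length(tables) != spec$n_sn)
    stop("need one ISI transition table per SN (", spec$n_sn, ")")
  for (k in seq_len(spec$n_sn))
    if (!inherits(tables[[k]], "isi_table"))
      stop("tables[[", k, "]] is not an isi_table")
  if (length(libs) != spec$n_sn)
    stop("need a response-library slot per SN (", spec$n_sn, ")")
  targets <- unique(spec$stim_target[!is.na(spec$stim_target)])
  for (k in targets) {
    if (is.null(libs[[k]]))
      stop("missing response library for stimulated SN ", k)
    if (!inherits(libs[[k]], "response_library"))
      stop("libs[[", k, "]] is not a response_library")
  }
  if (abs(cfg$tick_ms - spec$kernel$tick_ms) > 1e-12)
    stop("cfg$tick_ms must match the network kernel tick")

  ke <- spec$kernel
  ki <- if (is.null(spec$inh_kernel)) ke else spec$inh_kernel
  delay_ticks <- ifelse(is.na(spec$stim_delay_ms), -1L,
                        as.integer(round(spec$stim_delay_ms / cfg$tick_ms)))
  net <- list(n_sn = spec$n_sn, n_ifu = spec$n_ifu, W = spec$W,
              Wh = spec$ifu_to_ifu_W, thresholds = spec$thresholds,
              stim_delay_ticks = delay_ticks,
              stim_target = ifelse(is.na(spec$stim_target), -1L,
                                   spec$stim_target - 1L),
              kern_exc = c(ke$c_slow, ke$c_fast, ke$peak_gain),
              kern_inh = c(ki$c_slow, ki$c_fast, ki$peak_gain))
  ccfg <- list(duration_ms = cfg$duration_ms, tick_ms = cfg$tick_ms,
               artifact_ticks = as.integer(round(cfg$artifact_ms / cfg$tick_ms)),
               evoke_enabled = cfg$evoke_enabled,
               inhibit_enabled = cfg$inhibit_enabled,
               artifacts_enabled = cfg$artifacts_enabled,
               obstructed_resets_dtprev = cfg$obstructed_resets_dtprev,
               evoked_exempt = cfg$evoked_exempt)

  raw <- .cl_engine(net, lapply(tables, table_for_engine),
                    lapply(libs, lib_for_engine), ccfg)

  labels <- c("spontaneous", "evoked", "rebound")
  spikes <- data.frame(
    id = seq_along(raw$spikes$time_ms),
    time_ms = raw$spikes$time_ms, sn = raw$spikes$sn,
    label = labels[raw$spikes$label + 1L],
    obstructed = as.logical(raw$spikes$obstructed),
    stim_id = raw$spikes$stim_id)
  stims <- data.frame(
    id = seq_along(raw$stims$time_ms),
    time_ms = raw$stims$time_ms, scheduled_ms = raw$stims$scheduled_ms,
    delayed_by_ms = raw$stims$time_ms - raw$stims$scheduled_ms,
    target_sn = raw$stims$target_sn, source_ifu = raw$stims$source_ifu,
    ifu_spike_id = raw$stims$ifu_spike_id)
  kinds <- c("sn", "ifu")
  ifu_spikes <- data.frame(
    id = seq_along(raw$ifu_spikes$time_ms),
    time_ms = raw$ifu_spikes$time_ms, ifu = raw$ifu_spikes$ifu,
    trig1_id = raw$ifu_spikes$trig1_id,
    trig1_kind = kinds[raw$ifu_spikes$trig1_kind + 1L],
    trig2_id = raw$ifu_spikes$trig2_id,
    trig2_kind = kinds[raw$ifu_spikes$trig2_kind + 1L])
  structure(list(spikes = spikes, stims = stims, ifu_spikes = ifu_spikes,
                 spec = spec, cfg = cfg),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf(
    paste0("Closed-loop event log: %.1f s simulated, %d SN spikes ",
           "(%d evoked, %d rebound, %d obstructed), %d stimuli, %d IFU spikes\n"),
    x$cfg$duration_ms / 1000, nrow(x$spikes),
    sum(x$spikes$label == "evoked"), sum(x$spikes$label == "rebound"),
    sum(x$spikes$obstructed), nrow(x$stims), nrow(x$ifu_spikes)))
  invisible(x)
}

#' Sample one stimulus response from a library
#'
#' Draws the response of an SN to a single stimulation pulse: a Bernoulli
#' evoked-spike draw with probability `p_evoke(dt_prev)` (the plateau value
#' beyond 100 ms) and, independently of the evoked outcome, a rebound
#' latency drawn from the rebound distribution.
#'
#' @param lib A [response_library()].
#' @param dt_prev Time since the SN's previous spike in ms (rounded to the
#'   nearest ms; `Inf` or values > 100 use the plateau).
#' @return A list with `evoked` (logical), `latency_ms` (evoked latency, or
#'   `NA` if not evoked), and `rebound_ms`.
#' @export
deliver_stimulus <- function(lib, dt_prev) {
  stopifnot(inherits(lib, "response_library"), dt_prev >= 0)
  dt <- round(dt_prev)
  p <- if (dt > 100) lib$plateau else lib$p_evoke[max(1, dt)]
  evoked <- runif(1) < p
  draw1 <- function(x) x[sample.int(length(x), 1L)]
  list(evoked = evoked,
       latency_ms = if (evoked) draw1(lib$latency_samples) else NA_real_,
       rebound_ms = draw1(lib$rebound_samples))
}

#' Stagger stimuli around stimulation artifacts
#'
#' A stimulus scheduled within `artifact_ms` after another delivered
#' stimulus is postponed to the end of that artifact (postponements cascade
#' in scheduling order).
#'
#' @param scheduled_ms Scheduled stimulation times in ms.
#' @param artifact_ms Artifact duration in ms. Default 1.
#' @return A data.frame with `scheduled_ms`, `delivered_ms`, and
#'   `delayed_by_ms`, in order of delivery.
#' @examples
#' apply_artifact_policy(c(100.0, 100.4))  # delivered at 100.0 and 101.0
#' @export
apply_artifact_policy <- function(scheduled_ms, artifact_ms = 1) {
  s <- sort(as.numeric(scheduled_ms))
  delivered <- numeric(length(s))
  last <- -Inf
  for (i in seq_along(s)) {
    d <- if (s[i] - last < artifact_ms) last + artifact_ms else s[i]
    delivered[i] <- d
    last <- d
  }
  data.frame(scheduled_ms = s, delivered_ms = delivered,
             delayed_by_ms = delivered - s)
}

#' Mark spikes obstructed by stimulation artifacts
#'
#' @param spike_times Spike times in ms.
#' @param stim_times Delivered stimulation times in ms.
#' @param artifact_ms Artifact duration in ms. Default 1.
#' @return Logical vector: `TRUE` where the spike falls within
#'   `[stim, stim + artifact_ms)` of any stimulus.
#' @export
mark_obstructed <- function(spike_times, stim_times, artifact_ms = 1) {
  if (!length(stim_times)) return(rep(FALSE, length(spike_times)))
  stim_times <- sort(as.numeric(stim_times))
  idx <- findInterval(spike_times, stim_times)
  out <- rep(FALSE, length(spike_times))
  has <- idx >= 1L
  out[has] <- spike_times[has] - stim_times[idx[has]] < artifact_ms
  out
}
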