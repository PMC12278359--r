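#' Initialize IFU network state
#'
#' Creates the per-synapse slow/fast trace matrices for a reference
#' (pure-R) implementation of the IFU update. This mirrors the compiled
#' closed-loop engine tick-for-tick and is intended for small-scale
#' verification and exploration; the engine is used for full simulations.
#'
#' @param spec A [network_spec()].
#' @return An object of class `ifu_state`: trace matrices `S`, `F`
#'   (SN-to-IFU), optional `SH`, `FH` (IFU-to-IFU), membrane potentials `v`,
#'   and `last_spike_tick` per IFU.
#' @export
ifu_state <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  z <- matrix(0, spec$n_sn, spec$n_ifu)
  st <- list(S = z, F = z, v = numeric(spec$n_ifu),
             last_spike_tick = rep(NA_integer_, spec$n_ifu))
  if (!is.null(spec$ifu_to_ifu_W)) {
    zh <- matrix(0, spec$n_ifu, spec$n_ifu)
    st$SH <- zh
    st$FH <- zh
  }
  structure(st, class = "ifu_state")
}

## per-synapse decay multipliers and increment scale; inhibitory synapses
## may carry their own kernel (inhibition sweep varies the IPSP decay)
synapse_constants <- function(spec) {
  ke <- spec$kernel
  ki <- if (is.null(spec$inh_kernel)) ke else spec$inh_kernel
  pick <- function(W) {
    inh <- W < 0
    list(c_slow = ifelse(inh, ki$c_slow, ke$c_slow),
         c_fast = ifelse(inh, ki$c_fast, ke$c_fast),
         gain   = ifelse(inh, ki$peak_gain, ke$peak_gain))
  }
  out <- list(sn = pick(spec$W))
  if (!is.null(spec$ifu_to_ifu_W)) out$ifu <- pick(spec$ifu_to_ifu_W)
  out
}

#' Advance PSP traces by one tick
#'
#' Applies the per-tick exponential decay to every synaptic trace, then adds
#' the increments for spikes arriving this tick (already delayed by the
#' conduction delay). Increments are scaled by `threshold / peak_gain` so
#' the realized PSP peak of a lone arrival equals `weight * threshold`.
#'
#' @param state An [ifu_state()].
#' @param spec The [network_spec()].
#' @param sn_arrivals Integer vector of SN indices whose spikes arrive this
#'   tick (a repeated index adds twice).
#' @param ifu_arrivals Integer vector of presynaptic IFU indices arriving
#'   this tick (hidden-layer networks only).
#' @return The updated `ifu_state` with recomputed membrane potentials `v`.
#' @export
psp_step <- function(state, spec, sn_arrivals = integer(), ifu_arrivals = integer()) {
  stopifnot(inherits(state, "ifu_state"), inherits(spec, "network_spec"))
  ct <- synapse_constants(spec)
  state$S <- state$S * ct$sn$c_slow
  state$F <- state$F * ct$sn$c_fast
  for (i in sn_arrivals) {
    inc <- spec$W[i, ] * spec$thresholds / ct$sn$gain[i, ]
    state$S[i, ] <- state$S[i, ] + inc
    state$F[i, ] <- state$F[i, ] + inc
  }
  state$v <- colSums(state$S - state$F)
  if (!is.null(state$SH)) {
    state$SH <- state$SH * ct$ifu$c_slow
    state$FH <- state$FH * ct$ifu$c_fast
    for (m in ifu_arrivals) {
      inc <- spec$ifu_to_ifu_W[m, ] * spec$thresholds / ct$ifu$gain[m, ]
      state$SH[m, ] <- state$SH[m, ] + inc
      state$FH[m, ] <- state$FH[m, ] + inc
    }
    state$v <- state$v + colSums(state$SH - state$FH)
  }
  state
}

#' Threshold test, reset, and stimulus scheduling for one tick
#'
#' Every IFU whose membrane potential has reached its threshold emits a
#' spike; its input traces are zeroed (so its potential is exactly 0 on the
#' same tick's output state), and if it is an output IFU a stimulus is
#' scheduled `stim_delay_ms` later on its target SN. The refractory period
#' is 0 ms: an IFU may spike on consecutive ticks.
#'
#' @param state An [ifu_state()] already advanced by [psp_step()] this tick.
#' @param spec The [network_spec()].
#' @param tick Integer tick index (time = `tick * tick_ms`).
#' @return A list with `state` (reset applied), `ifu_spikes` (integer vector
#'   of IFUs that fired), and `scheduled_stims` (data.frame with
#'   `deliver_tick`, `target_sn`, `source_ifu`).
#' @export
ifu_step <- function(state, spec, tick) {
  stopifnot(inherits(state, "ifu_state"))
  fired <- which(state$v >= spec$thresholds)
  for (j in fired) {
    state$S[, j] <- 0
    state$F[, j] <- 0
    if (!is.null(state$SH)) {
      state$SH[, j] <- 0
      state$FH[, j] <- 0
    }
    state$v[j] <- 0
    state$last_spike_tick[j] <- tick
  }
  out <- fired[!is.na(spec$stim_delay_ms[fired])]
  stims <- data.frame(
    deliver_tick = tick + as.integer(round(
      spec$stim_delay_ms[out] / spec$kernel$tick_ms)),
    target_sn = spec$stim_target[out],
    source_ifu = out)
  list(state = state, ifu_spikes = fired, scheduled_stims = stims)
}
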