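#' Generate a ground-truth spontaneous spike train
#'
#' Produces a gamma-renewal spike train with an absolute refractory period.
#' The gamma-renewal process is deliberately *not* the first-order Markov
#' ISI model, so it can serve as an independent ground truth when testing
#' the Markov generator. The shape parameter controls ISI regularity
#' (shape = 1 gives exponential ISIs, i.e. a Poisson process with
#' refractory; larger shapes give more regular trains).
#'
#' @param target_rate_hz Target mean firing rate in Hz. The recorded
#'   baseline trains being emulated span roughly 1.4-51.4 Hz.
#' @param duration_ms Train duration in ms.
#' @param isi_shape Gamma shape parameter. Default 2.
#' @param refractory_ms Absolute refractory period in ms. Default 1.
#' @return Numeric vector of spike times in ms (0, duration].
#' @export
make_synthetic_sn <- function(target_rate_hz, duration_ms, isi_shape = 2,
                              refractory_ms = 1) {
  stopifnot(target_rate_hz > 0, duration_ms > 0, isi_shape > 0,
            refractory_ms >= 0)
  mean_isi <- 1000 / target_rate_hz
  if (mean_isi <= refractory_ms)
    stop("target rate incompatible with the refractory period")
  ## gamma ISIs with mean (mean_isi - refractory) on top of the refractory
  scale <- (mean_isi - refractory_ms) / isi_shape
  n_guess <- ceiling(duration_ms / mean_isi * 1.5) + 20L
  times <- numeric(0)
  t_cur <- 0
  repeat {
    isi <- refractory_ms + rgamma(n_guess, shape = isi_shape, scale = scale)
    tt <- t_cur + cumsum(isi)
    times <- c(times, tt)
    t_cur <- tt[length(tt)]
    if (t_cur > duration_ms) break
  }
  times[times <= duration_ms]
}

#' Generate a parametric stimulation-response library
#'
#' Builds a [response_library()] from interpretable parameters, emulating
#' the empirically observed shapes: an evoked-spike probability that rises
#' with time since the previous spike and plateaus (recovery curve
#' `p_max * (1 - exp(-dt / recovery_tau_ms))`), short Gaussian evoked
#' latencies truncated to the evoked window, and Gaussian rebound latencies
#' tens of ms post-stimulus truncated positive and outside the evoked
#' window.
#'
#' @param p_max Plateau evoked probability (the experiments span roughly
#'   0.25-0.95 across SNs). Default 0.8.
#' @param recovery_tau_ms Time constant of the probability recovery. Use 0
#'   for a flat curve at `p_max`. Default 30.
#' @param latency_mean,latency_sd Evoked-latency parameters in ms.
#'   Defaults 2.5 and 0.4.
#' @param rebound_mean,rebound_sd Rebound-latency parameters in ms.
#'   Defaults 40 and 12.
#' @param n_samples Latency/rebound sample count. Default 2000.
#' @return A [response_library()].
#' @export
make_synthetic_library <- function(p_max = 0.8, recovery_tau_ms = 30,
                                   latency_mean = 2.5, latency_sd = 0.4,
                                   rebound_mean = 40, rebound_sd = 12,
                                   n_samples = 2000) {
  stopifnot(p_max >= 0, p_max <= 1, recovery_tau_ms >= 0)
  dt <- 1:100
  p <- if (recovery_tau_ms == 0) rep(p_max, 100)
       else p_max * (1 - exp(-dt / recovery_tau_ms))
  win <- c(max(0.5, latency_mean - 3 * latency_sd),
           latency_mean + 3 * latency_sd)
  lat <- rnorm(n_samples, latency_mean, latency_sd)
  lat <- pmin(pmax(lat, win[1]), win[2])
  reb <- rnorm(4 * n_samples, rebound_mean, rebound_sd)
  reb <- reb[reb > win[2] + 0.5]  # positive and clear of the evoked window
  if (length(reb) < n_samples)
    stop("rebound parameters leave too little mass outside the evoked window")
  reb <- reb[seq_len(n_samples)]
  response_library(evoked_window = win, p_evoke = p, plateau = p_max,
                   latency_samples = lat, rebound_samples = reb)
}

#' Fixture network topologies
#'
#' Reference SN-IFU architectures mirroring the four closed-loop
#' configurations studied experimentally: `"recurrent3"` (3 SNs / 3 IFUs,
#' mixed excitation and inhibition), `"recurrent4"` (4 SNs / 4 IFUs, each SN
#' with three excitatory and one inhibitory connection), `"balanced4"`
#' (4 SNs / 4 IFUs, two excitatory and two inhibitory connections per SN),
#' and `"hidden"` (3 SNs, 3 hidden IFUs, 2 output IFUs, purely excitatory).
#' Exact per-connection weights were not published; fixtures default to the
#' midpoint of the calibrated excitatory envelope (52.5-97.5\% of threshold,
#' midpoint 75\%) with inhibitory magnitudes at half the excitatory value.
#'
#' @param name One of `"recurrent3"`, `"recurrent4"`, `"balanced4"`,
#'   `"hidden"`.
#' @param exc Excitatory weight (fraction of threshold). Default 0.75.
#' @param inh Inhibitory magnitude (fraction of threshold). Default 0.375.
#' @param kernel Kernel parameters. Default [calibrate_kernel()].
#' @return A [network_spec()].
#' @export
make_fixture_network <- function(name = c("recurrent3", "recurrent4",
                                          "balanced4", "hidden"),
                                 exc = 0.75, inh = 0.375,
                                 kernel = calibrate_kernel()) {
  name <- match.arg(name)
  e <- exc
  i <- -inh
  switch(name,
    recurrent3 = network_spec(
      ## columns are IFUs: IFU1 exc from SN1+SN2, IFU2 exc from SN2+SN3,
      ## IFU3 exc from SN1+SN3 with inhibition from SN2
      W = rbind(c(e, 0, e),
                c(e, e, i),
                c(0, e, e)),
      stim_delay_ms = c(5, 10, 15), stim_target = c(1, 2, 3),
      kernel = kernel),
    recurrent4 = network_spec(
      ## each SN: three excitatory connections and one inhibitory
      W = {
        W <- matrix(e, 4, 4)
        for (s in 1:4) W[s, (s %% 4) + 1L] <- i
        W
      },
      stim_delay_ms = c(15, 10, 5, 21), stim_target = 1:4,
      kernel = kernel),
    balanced4 = network_spec(
      ## each SN: two excitatory and two inhibitory connections
      W = {
        W <- matrix(i, 4, 4)
        for (s in 1:4) W[s, c(s, (s %% 4) + 1L)] <- e
        W
      },
      stim_delay_ms = c(15, 10, 5, 21), stim_target = 1:4,
      kernel = kernel),
    hidden = {
      ## hidden IFUs pool pairs of SNs; output IFUs need two coincident
      ## hidden spikes, so two different SNs firing once each cannot drive
      ## an output, but one SN firing twice (or all three SNs together) can
      Wh <- matrix(0, 5, 5)
      Wh[1, 4:5] <- e
      Wh[2, 4:5] <- e
      Wh[3, 4:5] <- e
      network_spec(
        W = rbind(c(e, 0, e, 0, 0),   # SN1 -> hidden 1, 3
                  c(e, e, 0, 0, 0),   # SN2 -> hidden 1, 2
                  c(0, e, e, 0, 0)),  # SN3 -> hidden 2, 3
        stim_delay_ms = c(NA, NA, NA, 5, 20),
        stim_target = c(NA, NA, NA, 1, 3),
        ifu_to_ifu_W = Wh, kernel = kernel)
    })
}

#' Baseline firing rates of the recorded SN cohort
#'
#' The 13 baseline (pre-stimulation) firing rates, in Hz, of the recorded
#' single neurons used in the artifact-obstruction simulations (one unit
#' with highly variable evoked latency was excluded from that analysis).
#' Used as the default rate set for synthetic SN pools so simulated cohorts
#' span the observed 1.4-51.4 Hz envelope.
#'
#' @return Numeric vector of 13 firing rates in Hz.
#' @export
reference_sn_rates <- function() {
  c(13.5, 21.9, 17.6,        # experiment 1
    20.5, 24.4, 18.1, 1.4,   # experiment 2
    51.4, 18.6, 8.7, 25.5,   # experiment 3
    11.5, 16.5)              # experiment 4 (excluded unit omitted)
}

#' Generate a pool of synthetic SN models
#'
#' For each requested rate, generates a baseline gamma-renewal train, builds
#' its ISI transition table, and attaches a synthetic response library. The
#' result is the input expected by [artifact_sweep()] and by the closed-loop
#' engine's per-SN model arguments.
#'
#' @param rates_hz Firing rates in Hz; defaults to [reference_sn_rates()].
#' @param duration_ms Baseline train length used to build each transition
#'   table. Default 300000 (5 min).
#' @param isi_shape Gamma shape for the ground-truth trains. Default 2.
#' @param library_args List of arguments passed to
#'   [make_synthetic_library()] (recycled across SNs).
#' @return A list with elements `tables` (list of [isi_table]s), `libs`
#'   (list of [response_library]s), and `rates_hz`.
#' @export
make_sn_pool <- function(rates_hz = reference_sn_rates(),
                         duration_ms = 300000, isi_shape = 2,
                         library_args = list()) {
  n <- length(rates_hz)
  tables <- vector("list", n)
  libs <- vector("list", n)
  for (k in seq_len(n)) {
    train <- make_synthetic_sn(rates_hz[k], duration_ms, isi_shape = isi_shape)
    tables[[k]] <- build_transition_table(train)
    libs[[k]] <- do.call(make_synthetic_library, library_args)
  }
  list(tables = tables, libs = libs, rates_hz = rates_hz)
}

#' Simulate an open-loop stimulation epoch for one SN
#'
#' Generates a ground-truth spontaneous train, Poisson-distributed
#' stimulation, and the SN's responses under a known stimulation-response
#' model (evoked spikes with probability `p(dt_prev)`, Gaussian latency;
#' the spontaneous spike following each stimulus is replaced by a rebound
#' spike drawn from the true rebound distribution). Used to validate that
#' [build_response_library()] recovers the generating model.
#'
#' @param rate_hz Spontaneous rate in Hz.
#' @param stim_rate_hz Open-loop stimulation rate in Hz (2-7 Hz in the
#'   emulated experiments).
#' @param duration_ms Epoch length in ms.
#' @param lib A [response_library()] acting as the ground truth.
#' @param isi_shape Gamma shape of the spontaneous train. Default 2.
#' @return A list with `spikes`, `stims` (times in ms), and `truth_lib`.
#' @export
make_synthetic_ol_log <- function(rate_hz, stim_rate_hz, duration_ms, lib,
                                  isi_shape = 2) {
  stopifnot(inherits(lib, "response_library"))
  spont <- make_synthetic_sn(rate_hz, duration_ms, isi_shape = isi_shape)
  n_stim <- max(1L, round(stim_rate_hz * duration_ms / 1000))
  stims <- sort(runif(n_stim, 0, duration_ms))

  spikes <- spont
  for (s in stims) {
    prev <- spikes[spikes < s]
    dt_prev <- if (length(prev)) round(s - max(prev)) else Inf
    p <- if (dt_prev > 100) lib$plateau else lib$p_evoke[max(1, dt_prev)]
    draw1 <- function(x) x[sample.int(length(x), 1L)]
    if (runif(1) < p) {
      lat <- draw1(lib$latency_samples)
      spikes <- c(spikes, s + lat)
    }
    ## inhibition: cancel spontaneous spikes up to the rebound time
    reb <- draw1(lib$rebound_samples)
    drop <- spikes > s + lib$evoked_window[2] & spikes < s + reb &
      spikes %in% spont
    spikes <- c(spikes[!drop], s + reb)
  }
  list(spikes = sort(spikes[spikes <= duration_ms]), stims = stims,
       truth_lib = lib)
}
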