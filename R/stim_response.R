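#' Peristimulus time histogram
#'
#' Counts spike offsets relative to each stimulus in fixed-width bins,
#' normalized per stimulus (a value of 1 means one spike per stimulus in
#' that bin on average).
#'
#' @param spike_times Numeric vector of spike times in ms.
#' @param stim_times Numeric vector of stimulation times in ms (non-empty).
#' @param window_ms Either a single positive number (window `(0, window]`
#'   post-stimulus) or a length-2 vector `c(start, end)` with `start < end`
#'   (negative start includes pre-stimulus baseline bins).
#' @param bin_ms Bin width in ms; must divide the window length.
#' @return An object of class `psth`: data.frame with `bin_start`,
#'   `bin_mid`, `bin_end` (ms relative to stimulus) and `rate` (spikes per
#'   stimulus per bin), with attributes `n_stim` and `bin_ms`.
#' @export
compute_psth <- function(spike_times, stim_times, window_ms = c(-20, 20),
                         bin_ms = 0.5) {
  if (length(stim_times) == 0L) stop("no stimuli: PSTH undefined")
  if (length(window_ms) == 1L) window_ms <- c(0, window_ms)
  stopifnot(length(window_ms) == 2L, window_ms[1] < window_ms[2], bin_ms > 0)
  span <- window_ms[2] - window_ms[1]
  n_bin <- span / bin_ms
  if (abs(n_bin - round(n_bin)) > 1e-9)
    stop("bin_ms must divide the window length")
  n_bin <- as.integer(round(n_bin))
  edges <- window_ms[1] + bin_ms * (0:n_bin)

  counts <- integer(n_bin)
  spike_times <- sort(as.numeric(spike_times))
  for (s in stim_times) {
    off <- spike_times[spike_times > s + window_ms[1] &
                       spike_times <= s + window_ms[2]] - s
    if (length(off))
      counts <- counts + tabulate(
        pmin(n_bin, ceiling((off - window_ms[1]) / bin_ms)), nbins = n_bin)
  }
  out <- data.frame(bin_start = edges[-length(edges)],
                    bin_mid = edges[-length(edges)] + bin_ms / 2,
                    bin_end = edges[-1L],
                    rate = counts / length(stim_times))
  attr(out, "n_stim") <- length(stim_times)
  attr(out, "bin_ms") <- bin_ms
  class(out) <- c("psth", "data.frame")
  out
}

#' Detect the evoked-spike window in a PSTH
#'
#' Finds the earliest post-stimulus peak exceeding the pre-stimulus baseline
#' and returns the maximal contiguous super-threshold bin run containing it.
#' The criterion is `baseline mean + k * baseline SD`, with the baseline
#' taken from the pre-stimulus bins (bin centers < 0). Any spike falling in
#' this window is counted as evoked; downstream, a second spike within 3 ms
#' of the first evoked spike is counted as part of the evoked response
#' (doublet).
#'
#' @param psth A [psth][compute_psth] computed over a window that includes
#'   pre-stimulus baseline bins and at least 10 ms post-stimulus, at bins of
#'   at most 0.5 ms.
#' @param k Baseline SD multiplier. Default 3.
#' @return Numeric `c(start_ms, end_ms)` of the evoked window, or `NULL`
#'   (with a warning) if no post-stimulus bin exceeds the criterion
#'   (non-responsive SN).
#' @export
detect_evoked_window <- function(psth, k = 3) {
  stopifnot(inherits(psth, "psth"))
  if (attr(psth, "bin_ms") > 0.5 + 1e-9)
    stop("evoked-window detection requires bins of at most 0.5 ms")
  if (max(psth$bin_end) < 10)
    stop("PSTH must extend at least 10 ms post-stimulus")
  base <- psth$rate[psth$bin_mid < 0]
  if (!length(base))
    stop("PSTH must include pre-stimulus baseline bins (window start < 0)")
  thr <- mean(base) + k * sd(base)
  if (!is.finite(thr)) thr <- mean(base)
  super <- psth$bin_mid > 0 & psth$rate > thr
  if (!any(super)) {
    warning("no post-stimulus bin exceeds the baseline criterion; ",
            "SN flagged non-responsive")
    return(NULL)
  }
  ## maximal contiguous run containing the earliest super-threshold bin
  first <- which(super)[1L]
  last <- first
  while (last < nrow(psth) && super[last + 1L]) last <- last + 1L
  c(start_ms = psth$bin_start[first], end_ms = psth$bin_end[last])
}

## stimulus annotations shared by the probability and rebound extractors:
## time since the target SN's previous spike, and the offsets of the evoked
## spike / first non-evoked (rebound) spike after each stimulus
annotate_stimuli <- function(spike_times, stim_times, evoked_window,
                             doublet_window_ms = 3) {
  spike_times <- sort(as.numeric(spike_times))
  stim_times <- sort(as.numeric(stim_times))
  n <- length(stim_times)
  dt_prev <- rep(NA_integer_, n)
  evoked_off <- rep(NA_real_, n)
  rebound_off <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- stim_times[i]
    prev <- spike_times[spike_times < s]
    if (length(prev)) dt_prev[i] <- as.integer(round(s - prev[length(prev)]))
    post <- spike_times[spike_times > s] - s
    if (!length(post)) next
    in_win <- post >= evoked_window[1] & post <= evoked_window[2]
    if (any(in_win)) {
      evoked_off[i] <- post[in_win][1L]
      ## doublet: a second spike within 3 ms of the first evoked spike is
      ## part of the evoked response, not a rebound
      not_evoked <- post[!in_win & post > evoked_off[i] + doublet_window_ms]
    } else {
      not_evoked <- post[!in_win]
    }
    if (length(not_evoked)) rebound_off[i] <- not_evoked[1L]
  }
  data.frame(stim_time = stim_times, dt_prev = dt_prev,
             evoked_off = evoked_off, rebound_off = rebound_off)
}

#' Evoked-spike probability as a function of time since the previous spike
#'
#' For each stimulus, the interval `dt_prev` between the SN's most recent
#' spike and stimulation onset is rounded to the nearest ms, and the raw
#' per-ms probability of evoking a spike (a spike inside the evoked window)
#' is computed over `dt_prev = 1..100` ms. The raw curve is smoothed with a
#' 10 ms boxcar moving average (window shrunk symmetrically at the edges;
#' empty bins are imputed by the smoothing pass). For `dt_prev > 100` ms the
#' probability is the SN's overall average evoked probability (plateau).
#' Stimuli delivered before any recorded spike of the SN are treated as
#' plateau observations.
#'
#' @param spike_times,stim_times Event times in ms.
#' @param evoked_window Length-2 evoked window from [detect_evoked_window()].
#' @param smooth_ms Boxcar width in ms. Default 10.
#' @param max_dt_ms Domain end of the curve. Default 100.
#' @param min_stimuli Warn if fewer stimuli than this. Default 50.
#' @return A list with `p` (numeric vector indexed by `dt_prev = 1..100`),
#'   `p_raw`, `n_raw` (trials per bin), and `plateau`.
#' @export
estimate_evoke_probability <- function(spike_times, stim_times, evoked_window,
                                       smooth_ms = 10, max_dt_ms = 100,
                                       min_stimuli = 50) {
  ann <- annotate_stimuli(spike_times, stim_times, evoked_window)
  if (nrow(ann) < min_stimuli)
    warning("only ", nrow(ann), " stimuli: evoked-probability curve may be noisy")
  evoked <- !is.na(ann$evoked_off)
  plateau_obs <- is.na(ann$dt_prev) | ann$dt_prev > max_dt_ms
  plateau <- mean(evoked)

  n_raw <- p_raw <- rep(NA_real_, max_dt_ms)
  in_dom <- !plateau_obs & ann$dt_prev >= 1L
  if (any(in_dom)) {
    tb <- tapply(evoked[in_dom], factor(ann$dt_prev[in_dom], levels = 1:max_dt_ms),
                 function(z) c(mean(z), length(z)))
    for (d in which(!vapply(tb, is.null, logical(1)))) {
      p_raw[d] <- tb[[d]][1]
      n_raw[d] <- tb[[d]][2]
    }
  }
  n_raw[is.na(n_raw)] <- 0

  half <- smooth_ms / 2
  p <- numeric(max_dt_ms)
  for (d in seq_len(max_dt_ms)) {
    ## symmetric shrink at the 1 ms and 100 ms edges
    h <- min(half, d - 1 + 0.5, max_dt_ms - d + 0.5)
    idx <- seq(ceiling(d - h), floor(d + h - 1e-9))
    idx <- idx[idx >= 1 & idx <= max_dt_ms]
    vals <- p_raw[idx]
    p[d] <- if (all(is.na(vals))) plateau else mean(vals, na.rm = TRUE)
  }
  p <- pmin(1, pmax(0, p))
  list(p = p, p_raw = p_raw, n_raw = n_raw, plateau = plateau)
}

#' Rebound-spike (post-stimulus inhibition) distribution with oversampling
#'
#' The rebound spike is the first non-evoked spike after each stimulus; the
#' distribution of its post-stimulus latency models stimulation-induced
#' inhibition. To compensate for short open-loop epochs the raw samples are
#' oversampled: `n_oversample` draws with replacement, each jittered by
#' uniform noise on (-10, 10) ms, are combined with the originals; samples
#' landing inside the evoked window (or at non-positive latency) are
#' discarded. An optional Gaussian supplement extends the support for SNs
#' whose next stimulus frequently precedes the rebound spike.
#'
#' @param spike_times,stim_times Event times in ms.
#' @param evoked_window Length-2 evoked window.
#' @param n_oversample Number of oversampling draws. Default 10000.
#' @param noise_ms Half-width of the jitter noise in ms. Default 10.
#' @param gaussian_supplement `NULL`, or a list with `n`, and optionally
#'   `mean` and `sd` (defaults: raw rebound mean and SD).
#' @param min_raw Warn (and recommend a Gaussian supplement) below this many
#'   raw observations. Default 10.
#' @return Numeric vector of rebound latencies in ms (raw + oversampled
#'   + supplement).
#' @export
extract_rebound_distribution <- function(spike_times, stim_times, evoked_window,
                                         n_oversample = 10000, noise_ms = 10,
                                         gaussian_supplement = NULL,
                                         min_raw = 10) {
  ann <- annotate_stimuli(spike_times, stim_times, evoked_window)
  raw <- ann$rebound_off[!is.na(ann$rebound_off)]
  if (length(raw) < min_raw)
    warning("only ", length(raw), " raw rebound observations; ",
            "a Gaussian supplement is recommended")
  if (!length(raw)) return(numeric())

  over <- raw[sample.int(length(raw), n_oversample, replace = TRUE)] +
    runif(n_oversample, -noise_ms, noise_ms)
  samples <- c(raw, over)
  if (!is.null(gaussian_supplement)) {
    gs <- gaussian_supplement
    m <- if (is.null(gs$mean)) mean(raw) else gs$mean
    s <- if (is.null(gs$sd)) sd(raw) else gs$sd
    samples <- c(samples, rnorm(gs$n, m, s))
  }
  keep <- samples > 0 &
    !(samples >= evoked_window[1] & samples <= evoked_window[2])
  samples[keep]
}

#' Construct a stimulation-response library
#'
#' Bundles the per-SN responses to single-pulse microstimulation: the evoked
#' window, the evoked-spike probability curve over `dt_prev = 1..100` ms with
#' its plateau, the evoked-latency samples, and the rebound-spike samples.
#'
#' @param evoked_window Length-2 numeric, ms post-stimulus.
#' @param p_evoke Numeric vector of length 100 (probability at
#'   `dt_prev = 1..100` ms).
#' @param plateau Probability used for `dt_prev > 100` ms.
#' @param latency_samples Evoked-latency samples (ms), all inside the evoked
#'   window.
#' @param rebound_samples Rebound-latency samples (ms), all outside the
#'   evoked window and positive.
#' @param doublet_window_ms Doublet window (second evoked spike within this
#'   many ms of the first). Default 3.
#' @return An object of class `response_library`.
#' @export
response_library <- function(evoked_window, p_evoke, plateau, latency_samples,
                             rebound_samples, doublet_window_ms = 3) {
  evoked_window <- as.numeric(evoked_window)
  stopifnot(length(evoked_window) == 2L, evoked_window[1] < evoked_window[2],
            length(p_evoke) == 100L)
  if (any(p_evoke < 0 | p_evoke > 1) || plateau < 0 || plateau > 1)
    stop("evoked probabilities must lie in [0, 1]")
  latency_samples <- as.numeric(latency_samples)
  rebound_samples <- as.numeric(rebound_samples)
  if (!length(latency_samples)) stop("latency_samples must be non-empty")
  if (!length(rebound_samples)) stop("rebound_samples must be non-empty")
  if (any(latency_samples < evoked_window[1] - 1e-9 |
          latency_samples > evoked_window[2] + 1e-9))
    stop("latency samples must lie inside the evoked window")
  if (any(rebound_samples >= evoked_window[1] &
          rebound_samples <= evoked_window[2]) || any(rebound_samples <= 0))
    stop("rebound samples must be positive and outside the evoked window")
  structure(
    list(evoked_window = evoked_window, p_evoke = as.numeric(p_evoke),
         plateau = plateau, latency_samples = latency_samples,
         rebound_samples = rebound_samples,
         doublet_window_ms = doublet_window_ms),
    class = "response_library")
}

#' @export
print.response_library <- function(x, ...) {
  cat(sprintf(
    paste0("Stimulation-response library: evoked window (%.1f, %.1f) ms, ",
           "plateau p = %.2f\n  latency %.1f +/- %.1f ms (n = %d), ",
           "rebound %.1f +/- %.1f ms (n = %d)\n"),
    x$evoked_window[1], x$evoked_window[2], x$plateau,
    mean(x$latency_samples), sd(x$latency_samples), length(x$latency_samples),
    mean(x$rebound_samples), sd(x$rebound_samples), length(x$rebound_samples)))
  invisible(x)
}

#' Build a response library from an open-loop stimulation log
#'
#' Runs the full open-loop pipeline for one SN: PSTH, evoked-window
#' detection, evoked-probability estimation, evoked-latency collection, and
#' rebound-distribution extraction with oversampling.
#'
#' @param spike_times,stim_times Event times in ms from the open-loop epoch.
#' @param psth_window,psth_bin_ms PSTH parameters (window must include
#'   pre-stimulus baseline); defaults `c(-20, 20)` ms at 0.5 ms bins.
#' @param gaussian_supplement Passed to [extract_rebound_distribution()].
#' @param ... Further arguments to [estimate_evoke_probability()].
#' @return A [response_library()], or `NULL` if the SN is non-responsive.
#' @export
build_response_library <- function(spike_times, stim_times,
                                   psth_window = c(-20, 20), psth_bin_ms = 0.5,
                                   gaussian_supplement = NULL, ...) {
  psth <- compute_psth(spike_times, stim_times, psth_window, psth_bin_ms)
  win <- detect_evoked_window(psth)
  if (is.null(win)) return(NULL)
  pe <- estimate_evoke_probability(spike_times, stim_times, win, ...)
  ann <- annotate_stimuli(spike_times, stim_times, win)
  lat <- ann$evoked_off[!is.na(ann$evoked_off)]
  reb <- extract_rebound_distribution(spike_times, stim_times, win,
                                      gaussian_supplement = gaussian_supplement)
  response_library(evoked_window = unname(win), p_evoke = pe$p,
                   plateau = pe$plateau, latency_samples = lat,
                   rebound_samples = reb)
}
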