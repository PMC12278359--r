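#' Define an SN-IFU network
#'
#' A network couples `n_sn` recorded single neurons (SNs) to `n_ifu`
#' integrate-and-fire units (IFUs). Weights are signed and expressed as the
#' fraction of the realized PSP peak amplitude to the IFU activation
#' threshold (so `W[i, j] = 0.75` means a spike of SN `i` produces an EPSP
#' in IFU `j` peaking at 75\% of threshold). Output IFUs trigger a single
#' stimulation pulse on their target SN `stim_delay_ms` after they spike;
#' hidden IFUs (with `NA` delay/target) project to other IFUs through
#' `ifu_to_ifu_W` instead.
#'
#' @param W Numeric `n_sn x n_ifu` signed weight matrix (fractions of
#'   threshold).
#' @param stim_delay_ms Per-IFU stimulation delay in ms (`NA` for hidden
#'   IFUs). Delays of any two output IFUs must differ by at least 4 ms and
#'   must be multiples of the tick.
#' @param stim_target Per-IFU target SN index in `1..n_sn` (`NA` for hidden
#'   IFUs).
#' @param thresholds Per-IFU activation threshold, positive. Default 1.
#' @param ifu_to_ifu_W Optional `n_ifu x n_ifu` weight matrix for
#'   hidden-layer projections (row = presynaptic IFU). Default none.
#' @param kernel PSP kernel parameters ([calibrate_kernel()]); shared by all
#'   excitatory synapses (and by inhibitory ones unless `inh_kernel` is
#'   given).
#' @param inh_kernel Optional separate kernel for inhibitory synapses (used
#'   by the inhibition sweep, which varies the IPSP decay time constant).
#' @param conduction_delay_ms Synaptic conduction delay in ms; fixed at one
#'   tick (0.1 ms) by the recording hardware being modelled.
#' @param min_delay_sep_ms Minimum separation required between output-IFU
#'   stimulation delays. Default 4 ms.
#' @return An object of class `network_spec`.
#' @examples
#' spec <- network_spec(
#'   W = matrix(c(0.75, 0.75), nrow = 2),
#'   stim_delay_ms = 10, stim_target = 1)
#' @export
network_spec <- function(W, stim_delay_ms, stim_target, thresholds = 1,
                         ifu_to_ifu_W = NULL, kernel = calibrate_kernel(),
                         inh_kernel = NULL, conduction_delay_ms = 0.1,
                         min_delay_sep_ms = 4) {
  W <- as.matrix(W)
  n_sn <- nrow(W)
  n_ifu <- ncol(W)
  if (n_sn < 1L || n_ifu < 1L) stop("W must have at least one SN and one IFU")
  if (!is.numeric(W) || anyNA(W)) stop("W must be numeric with no missing values")

  thresholds <- rep_len(as.numeric(thresholds), n_ifu)
  if (any(thresholds <= 0)) stop("thresholds must be positive")

  stim_delay_ms <- rep_len(as.numeric(stim_delay_ms), n_ifu)
  stim_target <- rep_len(as.integer(stim_target), n_ifu)

  out <- !is.na(stim_delay_ms)
  if (any(out != !is.na(stim_target)))
    stop("stim_delay_ms and stim_target must be NA for the same (hidden) IFUs")
  if (!any(out)) stop("at least one output IFU (non-NA stim delay) is required")
  if (any(stim_target[out] < 1L | stim_target[out] > n_sn))
    stop("stim_target out of range: every output IFU needs one target SN")

  tick <- kernel$tick_ms
  d <- stim_delay_ms[out]
  if (any(abs(d / tick - round(d / tick)) > 1e-9))
    stop("stim_delay_ms must be multiples of the tick (", tick, " ms)")
  if (any(d < 0)) stop("stim_delay_ms must be non-negative")
  if (sum(out) > 1L) {
    sep <- min(diff(sort(d)))
    if (sep < min_delay_sep_ms)
      stop(sprintf(
        "output-IFU stimulation delays must be >= %g ms apart (found %g ms)",
        min_delay_sep_ms, sep))
  }

  if (!is.null(ifu_to_ifu_W)) {
    ifu_to_ifu_W <- as.matrix(ifu_to_ifu_W)
    if (!all(dim(ifu_to_ifu_W) == c(n_ifu, n_ifu)))
      stop("ifu_to_ifu_W must be n_ifu x n_ifu")
    if (anyNA(ifu_to_ifu_W)) stop("ifu_to_ifu_W must have no missing values")
  }
  if (!is.null(inh_kernel)) stopifnot(inherits(inh_kernel, "kernel_params"))
  stopifnot(inherits(kernel, "kernel_params"))
  if (abs(conduction_delay_ms - tick) > 1e-9)
    stop("conduction_delay_ms must equal one tick (", tick, " ms)")

  structure(
    list(n_sn = n_sn, n_ifu = n_ifu, W = W, thresholds = thresholds,
         stim_delay_ms = stim_delay_ms, stim_target = stim_target,
         ifu_to_ifu_W = ifu_to_ifu_W, kernel = kernel,
         inh_kernel = inh_kernel, conduction_delay_ms = conduction_delay_ms,
         min_delay_sep_ms = min_delay_sep_ms),
    class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  out <- !is.na(x$stim_delay_ms)
  cat(sprintf("SN-IFU network: %d SNs, %d IFUs (%d output, %d hidden)\n",
              x$n_sn, x$n_ifu, sum(out), sum(!out)))
  cat(sprintf("  excitatory weights: %d, inhibitory: %d\n",
              sum(x$W > 0), sum(x$W < 0)))
  if (any(out))
    cat("  stim delays (ms):",
        paste(sprintf("IFU%d->SN%d @%g", which(out), x$stim_target[out],
                      x$stim_delay_ms[out]), collapse = ", "), "\n")
  if (!is.null(x$ifu_to_ifu_W))
    cat(sprintf("  hidden-layer connections: %d\n", sum(x$ifu_to_ifu_W != 0)))
  invisible(x)
}

#' Read or write a network specification as JSON
#'
#' The on-disk format is a JSON object with keys `n_sn`, `n_ifu`, `weights`
#' (row-major SN-by-IFU), `thresholds`, `stim_delay_ms`, `stim_target`
#' (1-based, `null` for hidden IFUs), optional `hidden_weights`, and
#' `kernel{tau_rise_ms, tau_decay_ms, tick_ms}`.
#'
#' @param path File path.
#' @return `read_network_spec()` returns a validated [network_spec()];
#'   `write_network_spec()` returns `path` invisibly.
#' @export
read_network_spec <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("weights", "stim_delay_ms", "stim_target")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("network config ", path, " is missing keys: ",
         paste(miss, collapse = ", "))
  kern <- if (!is.null(cfg$kernel)) {
    calibrate_kernel(tau_rise_ms = cfg$kernel$tau_rise_ms,
                     tau_decay_ms = cfg$kernel$tau_decay_ms,
                     tick_ms = cfg$kernel$tick_ms)
  } else calibrate_kernel()
  W <- as.matrix(cfg$weights)
  if (!is.null(cfg$n_sn) && nrow(W) != cfg$n_sn)
    stop("weights have ", nrow(W), " rows but n_sn = ", cfg$n_sn)
  if (!is.null(cfg$n_ifu) && ncol(W) != cfg$n_ifu)
    stop("weights have ", ncol(W), " columns but n_ifu = ", cfg$n_ifu)
  delay <- as.numeric(cfg$stim_delay_ms)
  target <- suppressWarnings(as.integer(cfg$stim_target))
  network_spec(
    W = W, stim_delay_ms = delay, stim_target = target,
    thresholds = if (is.null(cfg$thresholds)) 1 else cfg$thresholds,
    ifu_to_ifu_W = if (is.null(cfg$hidden_weights)) NULL
                   else as.matrix(cfg$hidden_weights),
    kernel = kern)
}

#' @rdname read_network_spec
#' @param spec A [network_spec()] object to serialize.
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  obj <- list(
    n_sn = spec$n_sn, n_ifu = spec$n_ifu,
    weights = spec$W, thresholds = spec$thresholds,
    stim_delay_ms = spec$stim_delay_ms, stim_target = spec$stim_target,
    hidden_weights = spec$ifu_to_ifu_W,
    kernel = list(tau_rise_ms = spec$kernel$tau_rise_ms,
                  tau_decay_ms = spec$kernel$tau_decay_ms,
                  tick_ms = spec$kernel$tick_ms))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", matrix = "rowmajor")
  invisible(path)
}
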