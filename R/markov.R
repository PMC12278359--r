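#' Build a first-order ISI transition table from a spike train
#'
#' Interspike intervals (ISIs) are computed, rounded to the nearest
#' millisecond (sub-millisecond intervals are clamped to 1 ms), and for each
#' consecutive pair (ISI1, ISI2) the successor ISI2 is stored in the
#' multiset of its predecessor. Sampling from the table reproduces the
#' empirical conditional distribution P(ISI2 | ISI1) exactly in expectation.
#'
#' @param times Numeric vector of spike times in ms (at least 3 spikes),
#'   nondecreasing.
#' @return An object of class `isi_table`: a list with `keys` (sorted unique
#'   ISI1 values, integer ms), `succ` (list of integer successor multisets,
#'   one per key), and `isi1_obs` (all ISI1 observations, used to seed
#'   generation).
#' @examples
#' tab <- build_transition_table(c(0, 5, 20, 25, 40))
#' tab$keys          # 5 15
#' tab$succ          # list(c(15, 15), 5) up to ordering
#' @export
build_transition_table <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 3L)
    stop("need at least 3 spikes to build a transition table (got ",
         length(times), ")")
  if (is.unsorted(times)) stop("spike times must be nondecreasing")
  isi <- pmax(1L, as.integer(round(diff(times))))
  n <- length(isi)
  isi1 <- isi[-n]
  isi2 <- isi[-1L]
  keys <- sort(unique(isi1))
  succ <- split(isi2, factor(isi1, levels = keys))
  names(succ) <- NULL
  structure(list(keys = keys, succ = succ, isi1_obs = isi1),
            class = "isi_table")
}

#' @export
print.isi_table <- function(x, ...) {
  cat(sprintf(
    "ISI transition table: %d keys (%d-%d ms), %d transitions, mean ISI %.1f ms\n",
    length(x$keys), min(x$keys), max(x$keys), length(x$isi1_obs),
    mean(x$isi1_obs)))
  invisible(x)
}

#' Convert an ISI transition table to a two-column data.frame
#'
#' @param x An [isi_table][build_transition_table].
#' @param ... Unused.
#' @return A data.frame with columns `isi1` and `isi2`, one row per stored
#'   transition.
#' @export
as.data.frame.isi_table <- function(x, ...) {
  data.frame(isi1 = rep.int(x$keys, lengths(x$succ)),
             isi2 = unlist(x$succ, use.names = FALSE))
}

## nearest stored key for a context never observed as ISI1
## (ties broken toward the smaller key)
nearest_key_index <- function(keys, value) {
  d <- abs(keys - value)
  which.min(d) # which.min takes the first (smaller key) on ties
}

#' Generate a surrogate spike train from an ISI transition table
#'
#' The seed ISI1 is drawn uniformly from all stored ISI1 observations
#' (i.e. weighted by multiplicity); successive intervals are drawn uniformly
#' from the successor multiset of the current interval, approximating a
#' first-order Markov chain on ISIs. A context never observed as an ISI1
#' key falls back to the nearest stored key in absolute distance (ties
#' toward the smaller key).
#'
#' @param table An [isi_table][build_transition_table].
#' @param duration_ms Target train length in ms; generation stops once the
#'   cumulative time would exceed it.
#' @return Numeric vector of spike times in ms; the first spike falls at the
#'   seed interval.
#' @export
sample_train <- function(table, duration_ms) {
  stopifnot(inherits(table, "isi_table"), duration_ms > 0)
  keys <- table$keys
  succ <- table$succ
  cur <- table$isi1_obs[sample.int(length(table$isi1_obs), 1L)]
  t_cur <- 0
  out <- numeric(max(16L, ceiling(duration_ms / mean(table$isi1_obs)) + 16L))
  n <- 0L
  isi <- cur
  repeat {
    t_cur <- t_cur + isi
    if (t_cur > duration_ms) break
    n <- n + 1L
    if (n > length(out)) out <- c(out, numeric(length(out)))
    out[n] <- t_cur
    pool <- succ[[nearest_key_index(keys, isi)]]
    isi <- pool[sample.int(length(pool), 1L)]
  }
  out[seq_len(n)]
}
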