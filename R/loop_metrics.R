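#' Extract elementary patterns from a closed-loop event log
#'
#' An elementary pattern groups an evoked spike with the two SN spikes whose
#' EPSPs drove the IFU that triggered the stimulation (the networks are
#' calibrated so two coincident EPSPs are required and sufficient). For
#' hidden-layer networks the output IFU's triggers are hidden-IFU spikes;
#' these are resolved to the hidden units' own SN trigger spikes and the
#' pattern is flagged `indirect`. Evoked spikes whose triggers cannot be
#' traced to at least two distinct SN spikes (e.g. a suprathreshold single
#' EPSP) do not form a pattern and are counted in the `n_untraceable`
#' attribute.
#'
#' @param log An [event_log][run_closed_loop].
#' @return An object of class `elementary_patterns`: a list of patterns,
#'   each with `trigger_ids` (SN spike ids), `evoked_id`, `spike_ids`
#'   (triggers plus evoked spike), `ifu`, `stim_time_ms`, and `indirect`;
#'   with attribute `n_untraceable`.
#' @export
find_elementary_patterns <- function(log) {
  stopifnot(inherits(log, "event_log"))
  ifu <- log$ifu_spikes
  resolve_sn_triggers <- function(ifu_spike_id, depth = 0L) {
    ## returns list(ids = SN spike ids, indirect = flag)
    if (is.na(ifu_spike_id) || depth > 4L)
      return(list(ids = integer(), indirect = depth > 0L))
    row <- ifu[ifu_spike_id, ]
    ids <- integer()
    indirect <- FALSE
    for (h in 1:2) {
      tid <- row[[paste0("trig", h, "_id")]]
      tkind <- row[[paste0("trig", h, "_kind")]]
      if (is.na(tid)) next
      if (identical(tkind, "sn")) {
        ids <- c(ids, tid)
      } else {
        sub <- resolve_sn_triggers(tid, depth + 1L)
        ids <- c(ids, sub$ids)
        indirect <- TRUE
      }
    }
    list(ids = unique(ids), indirect = indirect)
  }

  evoked <- log$spikes[log$spikes$label == "evoked" & !is.na(log$spikes$stim_id), ]
  patterns <- list()
  n_untraceable <- 0L
  for (r in seq_len(nrow(evoked))) {
    stim <- log$stims[evoked$stim_id[r], ]
    trig <- resolve_sn_triggers(stim$ifu_spike_id)
    if (length(trig$ids) < 2L) {
      n_untraceable <- n_untraceable + 1L
      next
    }
    patterns[[length(patterns) + 1L]] <- list(
      trigger_ids = trig$ids,
      evoked_id = evoked$id[r],
      spike_ids = unique(c(trig$ids, evoked$id[r])),
      ifu = stim$source_ifu,
      stim_time_ms = stim$time_ms,
      indirect = trig$indirect)
  }
  structure(patterns, class = "elementary_patterns",
            n_untraceable = n_untraceable)
}

#' Merge elementary patterns into feedback loops
#'
#' Feedback loops are the connected components of the "shares at least one
#' spike" relation on elementary patterns, computed with union-find. The
#' size of a loop is the number of distinct spikes in the union of its
#' member patterns; loops partition the set of patterns.
#'
#' @param patterns An [elementary_patterns][find_elementary_patterns]
#'   object, or a plain list whose elements contain a `spike_ids` vector.
#' @return An object of class `feedback_loops`: a data.frame with one row
#'   per loop (`loop`, `size`, `n_patterns`) and attribute `membership`
#'   (loop index per pattern).
#' @examples
#' p <- list(list(spike_ids = c(1, 2, 3)), list(spike_ids = c(3, 4, 5)))
#' merge_feedback_loops(p)  # one loop of size 5
#' @export
merge_feedback_loops <- function(patterns) {
  n <- length(patterns)
  if (n == 0L) {
    out <- data.frame(loop = integer(), size = integer(),
                      n_patterns = integer())
    attr(out, "membership") <- integer()
    class(out) <- c("feedback_loops", "data.frame")
    return(out)
  }
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (p in seq_len(n)) {
    for (sid in as.character(patterns[[p]]$spike_ids)) {
      q <- seen[[sid]]
      if (is.null(q)) {
        seen[[sid]] <- p
      } else {
        rp <- find(p); rq <- find(q)
        if (rp != rq) parent[rp] <- rq
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  loop_id <- match(roots, unique(roots))
  sizes <- vapply(split(seq_len(n), loop_id), function(members) {
    length(unique(unlist(lapply(patterns[members],
                                function(p) p$spike_ids))))
  }, integer(1))
  out <- data.frame(loop = seq_along(sizes), size = as.integer(sizes),
                    n_patterns = as.integer(table(loop_id)))
  attr(out, "membership") <- loop_id
  class(out) <- c("feedback_loops", "data.frame")
  out
}

#' Spike-train correlogram
#'
#' Spike times are rounded to the nearest millisecond and binarized; the
#' correlogram value at lag `l` is the probability of observing a spike of
#' train `b` at offset `l` ms from a reference spike of train `a`
#' (pair count at lag `l` divided by the number of reference spikes). For
#' autocorrelograms the central (lag 0) bin is zeroed.
#'
#' @param a,b Spike time vectors in ms; omit `b` for an autocorrelogram.
#' @param max_lag_ms Maximum lag. Default 50.
#' @return An object of class `correlogram`: data.frame with `lag_ms`
#'   (-max_lag..max_lag) and `value`, with attributes `is_auto` and `n_ref`.
#' @export
correlogram <- function(a, b = NULL, max_lag_ms = 50) {
  is_auto <- is.null(b)
  if (is_auto) b <- a
  if (!length(a) || !length(b)) stop("empty spike train: correlogram undefined")
  ## binarize at 1 ms (binary vectors: repeated spikes in one bin count once)
  pa <- unique(round(a))
  pb <- unique(round(b))
  t_max <- max(pa, pb)
  t_min <- min(pa, pb)
  bv <- logical(t_max - t_min + 1L)
  bv[pb - t_min + 1L] <- TRUE
  lags <- -max_lag_ms:max_lag_ms
  value <- vapply(lags, function(l) {
    idx <- pa + l - t_min + 1L
    ok <- idx >= 1L & idx <= length(bv)
    sum(bv[idx[ok]]) / length(pa)
  }, numeric(1))
  if (is_auto) value[lags == 0L] <- 0
  out <- data.frame(lag_ms = lags, value = value)
  attr(out, "is_auto") <- is_auto
  attr(out, "n_ref") <- length(pa)
  class(out) <- c("correlogram", "data.frame")
  out
}

#' Smooth a correlogram with a moving average (display aid)
#'
#' @param cg A [correlogram()].
#' @param window_ms Moving-average window in ms. Default 3.
#' @return A `correlogram` with smoothed values (window shrunk at the edges).
#' @export
smooth_correlogram <- function(cg, window_ms = 3) {
  stopifnot(inherits(cg, "correlogram"))
  half <- (window_ms - 1) / 2
  v <- cg$value
  n <- length(v)
  sm <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - floor(half)):min(n, i + ceiling(half - 1e-9))
    mean(v[idx])
  }, numeric(1))
  out <- cg
  out$value <- sm
  out
}

#' Pearson similarity between two correlograms
#'
#' Computes the Pearson correlation over paired lag bins with a two-sided
#' test. If either input is an autocorrelogram, the zeroed central bin is
#' excluded from both.
#'
#' @param c1,c2 [correlogram()]s on the same lag grid.
#' @return A list with `r` and `p_value`.
#' @export
correlogram_similarity <- function(c1, c2) {
  stopifnot(inherits(c1, "correlogram"), inherits(c2, "correlogram"))
  if (!identical(c1$lag_ms, c2$lag_ms))
    stop("correlograms must share the same lag grid")
  keep <- rep(TRUE, nrow(c1))
  if (isTRUE(attr(c1, "is_auto")) || isTRUE(attr(c2, "is_auto")))
    keep[c1$lag_ms == 0L] <- FALSE
  x <- c1$value[keep]
  y <- c2$value[keep]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in a correlogram: Pearson r undefined")
    return(list(r = NA_real_, p_value = NA_real_))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Stimulation efficiency ratio
#'
#' Total number of stimulation events divided by the total number of SN
#' spikes (all labels, including obstructed spikes) over the epoch. A higher
#' ratio means a greater proportion of spikes led to stimulation.
#'
#' @param log An [event_log][run_closed_loop], or a list with `spikes` and
#'   `stims` data.frames.
#' @return The ratio (0 if there are no stimuli); `NA` with a warning if the
#'   log contains no spikes.
#' @export
stimulation_efficiency <- function(log) {
  n_spk <- nrow(log$spikes)
  n_stim <- nrow(log$stims)
  if (n_spk == 0L) {
    warning("no SN spikes: stimulation efficiency undefined")
    return(NA_real_)
  }
  n_stim / n_spk
}
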