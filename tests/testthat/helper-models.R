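# deterministic fixtures used across tests (built in code, no files)

# response library with a flat evoked-probability curve and point-mass
# latency/rebound distributions: makes engine behaviour hand-checkable
det_library <- function(p = 0, latency = 2, rebound = 50,
                        window = c(1, 4)) {
  response_library(evoked_window = window, p_evoke = rep(p, 100),
                   plateau = p, latency_samples = latency,
                   rebound_samples = rebound)
}

# transition table of a strictly periodic train (single-support chain)
const_table <- function(isi_ms, n = 50) {
  build_transition_table(seq(0, by = isi_ms, length.out = n))
}

# minimal hand-built event log (direct network provenance), for the loop
# analysis layer: spikes/stims/ifu_spikes with consistent ids
toy_event_log <- function(spikes, stims, ifu_spikes,
                          duration_ms = max(spikes$time_ms) + 1) {
  structure(list(spikes = spikes, stims = stims, ifu_spikes = ifu_spikes,
                 spec = NULL, cfg = sim_config(duration_ms)),
            class = "event_log")
}

# log with n_evoked evoked spikes; triggers given as a list of length-2
# id vectors referring to spontaneous spikes
build_pattern_log <- function(trigger_pairs, evoked_times = NULL) {
  n_trig <- max(unlist(trigger_pairs))
  n_ev <- length(trigger_pairs)
  if (is.null(evoked_times)) evoked_times <- 100 + 10 * seq_len(n_ev)
  spikes <- data.frame(
    id = seq_len(n_trig + n_ev),
    time_ms = c(seq_len(n_trig), evoked_times),
    sn = 1L,
    label = c(rep("spontaneous", n_trig), rep("evoked", n_ev)),
    obstructed = FALSE,
    stim_id = c(rep(NA_integer_, n_trig), seq_len(n_ev)))
  stims <- data.frame(
    id = seq_len(n_ev), time_ms = evoked_times - 2,
    scheduled_ms = evoked_times - 2, delayed_by_ms = 0,
    target_sn = 1L, source_ifu = 1L, ifu_spike_id = seq_len(n_ev))
  ifu_spikes <- data.frame(
    id = seq_len(n_ev), time_ms = evoked_times - 4, ifu = 1L,
    trig1_id = vapply(trigger_pairs, `[`, numeric(1), 1),
    trig1_kind = "sn",
    trig2_id = vapply(trigger_pairs, `[`, numeric(1), 2),
    trig2_kind = "sn")
  toy_event_log(spikes, stims, ifu_spikes)
}

# brute-force transitive-closure oracle for feedback-loop merging:
# full pairwise shared-spike adjacency (pattern x spike incidence), then
# BFS connected components -- an independent route from the union-find
oracle_merge <- function(patterns) {
  n <- length(patterns)
  if (n == 0) return(integer())
  ids <- sort(unique(unlist(lapply(patterns, `[[`, "spike_ids"))))
  M <- matrix(0L, n, length(ids))
  for (i in seq_len(n)) M[i, match(patterns[[i]]$spike_ids, ids)] <- 1L
  adj <- tcrossprod(M) > 0   # shares >= 1 spike (diagonal trivially TRUE)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    frontier <- s
    while (length(frontier)) {
      comp[frontier] <- cid
      nxt <- unique(unlist(lapply(frontier, function(i) which(adj[i, ]))))
      frontier <- nxt[is.na(comp[nxt])]
    }
  }
  comp
}

# random pattern set over a shared spike-id pool
random_patterns <- function(n_patterns, pool_size = 3 * n_patterns) {
  lapply(seq_len(n_patterns), function(i)
    list(spike_ids = sample.int(pool_size, 3)))
}
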