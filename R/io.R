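#' Flatten an event log to a single event table
#'
#' Produces one delimited-text-friendly table with the columns `time_ms`,
#' `stream` (`sn`, `ifu`, or `stim`), `channel`, `label`, `obstructed`, and
#' `source` (causal stimulus id for SN spikes; source IFU for stimuli), plus
#' provenance id columns so the table round-trips losslessly.
#'
#' @param log An [event_log][run_closed_loop].
#' @return A data.frame sorted by time (ties: sn, ifu, stim).
#' @export
as_event_table <- function(log) {
  stopifnot(inherits(log, "event_log"))
  na_prov <- function(n) data.frame(
    ref_id = rep(NA_integer_, n), trig1_id = NA_integer_,
    trig1_kind = NA_character_, trig2_id = NA_integer_,
    trig2_kind = NA_character_)
  sn <- cbind(
    data.frame(time_ms = log$spikes$time_ms, stream = "sn",
               channel = log$spikes$sn, label = log$spikes$label,
               obstructed = log$spikes$obstructed,
               source = log$spikes$stim_id, id = log$spikes$id),
    na_prov(nrow(log$spikes)))
  ifu <- data.frame(time_ms = log$ifu_spikes$time_ms, stream = "ifu",
                    channel = log$ifu_spikes$ifu, label = NA_character_,
                    obstructed = NA, source = NA_integer_,
                    id = log$ifu_spikes$id, ref_id = NA_integer_,
                    trig1_id = log$ifu_spikes$trig1_id,
                    trig1_kind = log$ifu_spikes$trig1_kind,
                    trig2_id = log$ifu_spikes$trig2_id,
                    trig2_kind = log$ifu_spikes$trig2_kind)
  st <- cbind(
    data.frame(time_ms = log$stims$time_ms, stream = "stim",
               channel = log$stims$target_sn, label = NA_character_,
               obstructed = NA, source = log$stims$source_ifu,
               id = log$stims$id),
    na_prov(nrow(log$stims)))
  st$ref_id <- log$stims$ifu_spike_id   # IFU spike that scheduled the stim
  out <- rbind(sn, ifu, st)
  out[order(out$time_ms, match(out$stream, c("sn", "ifu", "stim")), out$channel), ,
      drop = FALSE]
}

#' Reconstruct an event log from a flat event table
#'
#' Inverse of [as_event_table()]: rebuilds the `spikes`, `stims`, and
#' `ifu_spikes` data.frames (including trigger provenance, when the
#' provenance columns are present) so that the loop and correlogram
#' analyses can run on event tables read from disk.
#'
#' @param tab A data.frame as returned by [read_event_table()].
#' @return An [event_log][run_closed_loop] object.
#' @export
as_event_log <- function(tab) {
  stopifnot(all(c("time_ms", "stream", "channel") %in% names(tab)))
  col <- function(d, nm, default) if (nm %in% names(d)) d[[nm]] else default
  sn <- tab[tab$stream == "sn", , drop = FALSE]
  st <- tab[tab$stream == "stim", , drop = FALSE]
  ifu <- tab[tab$stream == "ifu", , drop = FALSE]
  spikes <- data.frame(
    id = col(sn, "id", seq_len(nrow(sn))), time_ms = sn$time_ms,
    sn = sn$channel, label = col(sn, "label", "spontaneous"),
    obstructed = as.logical(col(sn, "obstructed", FALSE)),
    stim_id = col(sn, "source", NA_integer_))
  stims <- data.frame(
    id = col(st, "id", seq_len(nrow(st))), time_ms = st$time_ms,
    scheduled_ms = col(st, "scheduled_ms", st$time_ms),
    delayed_by_ms = st$time_ms - col(st, "scheduled_ms", st$time_ms),
    target_sn = st$channel, source_ifu = col(st, "source", NA_integer_),
    ifu_spike_id = col(st, "ref_id", NA_integer_))
  ifu_spikes <- data.frame(
    id = col(ifu, "id", seq_len(nrow(ifu))), time_ms = ifu$time_ms,
    ifu = ifu$channel,
    trig1_id = col(ifu, "trig1_id", NA_integer_),
    trig1_kind = col(ifu, "trig1_kind", NA_character_),
    trig2_id = col(ifu, "trig2_id", NA_integer_),
    trig2_kind = col(ifu, "trig2_kind", NA_character_))
  ## provenance ids index rows: restore row order by id
  if (nrow(spikes)) spikes <- spikes[order(spikes$id), , drop = FALSE]
  if (nrow(stims)) stims <- stims[order(stims$id), , drop = FALSE]
  if (nrow(ifu_spikes))
    ifu_spikes <- ifu_spikes[order(ifu_spikes$id), , drop = FALSE]
  rownames(spikes) <- rownames(stims) <- rownames(ifu_spikes) <- NULL
  structure(list(spikes = spikes, stims = stims, ifu_spikes = ifu_spikes,
                 spec = NULL,
                 cfg = sim_config(max(tab$time_ms, 1) + 1)),
            class = "event_log")
}

#' Write an event table as delimited text
#'
#' Times are written in ms with one decimal (0.1 ms tick resolution), UTF-8,
#' `.` decimal separator.
#'
#' @param table A data.frame with at least `time_ms`, `stream`, `channel`
#'   (e.g. from [as_event_table()]), or an [event_log][run_closed_loop].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(table, path) {
  if (inherits(table, "event_log")) table <- as_event_table(table)
  stopifnot(all(c("time_ms", "stream", "channel") %in% names(table)))
  table$time_ms <- sprintf("%.1f", table$time_ms)
  write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate an event table
#'
#' Requires the header columns `time_ms`, `stream`, and `channel`; checks
#' that times parse, are non-negative, and are nondecreasing within each
#' (stream, channel); unknown columns are preserved. Violations are reported
#' with row numbers rather than silently repaired.
#'
#' @param path Input file path.
#' @return A validated data.frame.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ms", "stream", "channel")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("event table ", path, " is missing required columns: ",
         paste(miss, collapse = ", "))
  t_num <- suppressWarnings(as.numeric(tab$time_ms))
  bad <- which(is.na(t_num) & !is.na(tab$time_ms))
  if (length(bad))
    stop("unparseable time_ms at rows: ", paste(head(bad, 5), collapse = ", "))
  neg <- which(t_num < 0)
  if (length(neg))
    stop("negative time_ms at rows: ", paste(head(neg, 5), collapse = ", "))
  tab$time_ms <- t_num
  key <- paste(tab$stream, tab$channel)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (is.unsorted(tab$time_ms[idx]))
      stop("times not nondecreasing for ", k, " starting at row ",
           idx[which(diff(tab$time_ms[idx]) < 0)[1] + 1L])
  }
  tab
}

#' Serialize a response library to JSON
#'
#' @param lib A [response_library()] (or a named list of them, one per SN).
#' @param path Output path.
#' @return `path` invisibly; `read_response_library()` returns the
#'   [response_library()] (or named list).
#' @export
write_response_library <- function(lib, path) {
  enc <- function(l) list(
    evoked_window = l$evoked_window, p_evoke = l$p_evoke,
    plateau = l$plateau, latency_samples = l$latency_samples,
    rebound_samples = l$rebound_samples,
    doublet_window_ms = l$doublet_window_ms)
  obj <- if (inherits(lib, "response_library")) enc(lib) else lapply(lib, enc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_response_library
#' @export
read_response_library <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dec <- function(l) response_library(
    evoked_window = l$evoked_window, p_evoke = l$p_evoke,
    plateau = l$plateau, latency_samples = l$latency_samples,
    rebound_samples = l$rebound_samples,
    doublet_window_ms = l$doublet_window_ms)
  if (!is.null(obj$evoked_window)) dec(obj) else lapply(obj, dec)
}

#' Run a synth -> simulate -> analyze pipeline from a config
#'
#' Minimal reproducible pipeline driver: generates a synthetic SN pool,
#' simulates the closed loop for a fixture (or user-supplied) network, and
#' writes the event table, loop metrics, and a manifest (seed, config, and
#' package version) sufficient to reproduce the outputs byte-for-byte.
#'
#' @param config A list (or path to a JSON file) with entries `seed`,
#'   `network` (fixture name for [make_fixture_network()] or a path to a
#'   network JSON), `rates_hz`, `duration_ms`, and optionally
#'   `library_args`, `pre_duration_ms`, and flags `evoke`, `inhibit`,
#'   `artifacts`.
#' @param out_dir Output directory (created if needed).
#' @param dry_run List the planned stages without writing. Default FALSE.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, dry_run = FALSE) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  need <- c("seed", "network", "rates_hz", "duration_ms")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("pipeline config missing entries: ", paste(miss, collapse = ", "))
  stages <- c("synth: SN pool", "simulate: closed loop",
              "analyze: loops, correlograms, efficiency")
  if (dry_run) {
    message("planned stages (dry run):\n  ", paste(stages, collapse = "\n  "))
    return(invisible(NULL))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  message("[synth] generating ", length(config$rates_hz), " SN models")
  pool <- make_sn_pool(
    rates_hz = config$rates_hz,
    duration_ms = config$pre_duration_ms %||% 300000,
    library_args = config$library_args %||% list())

  spec <- if (file.exists(config$network)) read_network_spec(config$network)
          else make_fixture_network(config$network)
  if (spec$n_sn > length(pool$tables))
    stop("configuration error: network needs ", spec$n_sn,
         " SNs but the pool has ", length(pool$tables))
  cfg <- sim_config(duration_ms = config$duration_ms,
                    evoke_enabled = config$evoke %||% TRUE,
                    inhibit_enabled = config$inhibit %||% TRUE,
                    artifacts_enabled = config$artifacts %||% TRUE)
  message("[simulate] ", config$duration_ms / 1000, " s of closed loop")
  log <- run_closed_loop(spec, pool$tables[seq_len(spec$n_sn)],
                         pool$libs[seq_len(spec$n_sn)], cfg)
  write_event_table(log, file.path(out_dir, "events.csv"))

  message("[analyze] feedback loops and efficiency")
  loops <- merge_feedback_loops(find_elementary_patterns(log))
  write.csv(loops, file.path(out_dir, "loops.csv"), row.names = FALSE)
  metrics <- list(
    n_spikes = nrow(log$spikes), n_stims = nrow(log$stims),
    stimulation_efficiency = stimulation_efficiency(log),
    n_loops = nrow(loops),
    mean_loop_size = if (nrow(loops)) mean(loops$size) else NA)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  manifest <- list(
    package = "hybridloop",
    version = as.character(utils::packageVersion("hybridloop")),
    seed = config$seed, config = config,
    outputs = c("events.csv", "loops.csv", "metrics.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
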