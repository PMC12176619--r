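#' Session event log
#'
#' Typed timeline of one behavioural session: cue onsets, reward deliveries,
#' port entries, stimulation bouts, an optional injection time, and named
#' epochs. Validated on construction: times non-decreasing within streams,
#' epochs ordered consumption < delay < stimulation/malaise and
#' non-overlapping, every reward inside the consumption epoch, every bout
#' inside the stimulation epoch.
#'
#' @param cues data.frame with `time`, `port`.
#' @param rewards data.frame with `time`, `port` (`"flavour"` or `"water"`).
#' @param entries data.frame with `time`, `port` (may be empty).
#' @param bouts data.frame with `onset`, `offset` (may be empty).
#' @param injection_time numeric scalar or `NA`.
#' @param epochs named list of [epoch()] objects; must contain
#'   `consumption` and `delay`, plus `stim` and/or `malaise`.
#' @return an `event_log` object.
#' @export
event_log <- function(cues, rewards, entries = NULL, bouts = NULL,
                      injection_time = NA_real_, epochs) {
  empty_tp <- data.frame(time = numeric(0), port = character(0),
                         stringsAsFactors = FALSE)
  if (is.null(entries)) entries <- empty_tp
  if (is.null(bouts)) bouts <- data.frame(onset = numeric(0), offset = numeric(0))
  x <- structure(list(cues = cues, rewards = rewards, entries = entries,
                      bouts = bouts, injection_time = injection_time,
                      epochs = epochs),
                 class = "event_log")
  validate_event_log(x)
  x
}

#' Validate an event log
#'
#' @param x an `event_log`.
#' @return `x` invisibly; errors describe the first violated invariant.
#' @export
validate_event_log <- function(x) {
  stopifnot(inherits(x, "event_log"))
  for (nm in c("cues", "rewards", "entries")) {
    tt <- x[[nm]]$time
    if (is.unsorted(tt)) .invalid_input(sprintf("%s times must be non-decreasing", nm))
  }
  if (nrow(x$bouts) > 0) {
    if (is.unsorted(x$bouts$onset)) .invalid_input("bout onsets must be non-decreasing")
    if (any(x$bouts$offset <= x$bouts$onset)) {
      .invalid_input("bout offsets must follow onsets")
    }
  }
  eps <- x$epochs
  if (!all(c("consumption", "delay") %in% names(eps))) {
    .invalid_input("epochs must include 'consumption' and 'delay'")
  }
  post <- intersect(c("stim", "malaise"), names(eps))
  ord <- c("consumption", "delay", post)
  for (i in seq_along(ord)[-1]) {
    a <- eps[[ord[i - 1]]]; b <- eps[[ord[i]]]
    if (a$end > b$start + 1e-9) {
      .invalid_input(sprintf("epochs '%s' and '%s' overlap or are out of order",
                             ord[i - 1], ord[i]))
    }
  }
  cons <- eps$consumption
  if (nrow(x$rewards) > 0 &&
      (any(x$rewards$time < cons$start - 1e-9) ||
       any(x$rewards$time > cons$end + 1e-9))) {
    .invalid_input("every reward delivery must lie inside the consumption epoch")
  }
  if (nrow(x$bouts) > 0) {
    if (!"stim" %in% names(eps)) .invalid_input("bouts present but no stim epoch")
    se <- eps$stim
    if (any(x$bouts$onset < se$start - 1e-9) ||
        any(x$bouts$offset > se$end + 1e-9)) {
      .invalid_input("every stim bout must lie inside the stim epoch")
    }
  }
  if (!all(x$rewards$port %in% c("flavour", "water"))) {
    .invalid_input("reward ports must be 'flavour' or 'water'")
  }
  invisible(x)
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d cues, %d rewards (%d flavour / %d water), %d bouts%s\n",
              nrow(x$cues), nrow(x$rewards),
              sum(x$rewards$port == "flavour"), sum(x$rewards$port == "water"),
              nrow(x$bouts),
              if (is.finite(x$injection_time))
                sprintf(", injection at %.0f s", x$injection_time) else ""))
  for (ep in x$epochs) print(ep)
  invisible(x)
}

#' Read spike times from long-format CSV
#'
#' @param path CSV with columns `unit_id`, `time_s`.
#' @return named list of sorted spike-time vectors, one per unit, ordered by
#'   first appearance of the unit id.
#' @export
read_spikes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(df))) {
    .invalid_input("spike CSV must have columns unit_id,time_s")
  }
  ids <- unique(df$unit_id)
  out <- lapply(ids, function(id) sort(df$time_s[df$unit_id == id]))
  names(out) <- as.character(ids)
  out
}

#' Write spike times to long-format CSV
#' @param spikes named list of spike-time vectors.
#' @param path output path.
#' @export
write_spikes_csv <- function(spikes, path) {
  df <- data.frame(
    unit_id = rep(names(spikes), lengths(spikes)),
    time_s = unlist(spikes, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an event log from CSV + JSON epochs sidecar
#'
#' The CSV has columns `stream` (`cue|reward|entry|bout_on|bout_off|injection`),
#' `time_s` and `port`; epochs come from a JSON file mapping epoch labels to
#' `[start, end]` pairs.
#'
#' @param csv_path events CSV path.
#' @param epochs_path JSON epochs path.
#' @return an [event_log()].
#' @export
read_events_csv <- function(csv_path, epochs_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  eps <- jsonlite::read_json(epochs_path, simplifyVector = TRUE)
  epochs <- lapply(names(eps), function(nm) epoch(nm, eps[[nm]][1], eps[[nm]][2]))
  names(epochs) <- names(eps)
  pick <- function(s) df[df$stream == s, , drop = FALSE]
  bouts_on <- pick("bout_on"); bouts_off <- pick("bout_off")
  inj <- pick("injection")
  event_log(
    cues = data.frame(time = pick("cue")$time_s, port = pick("cue")$port,
                      stringsAsFactors = FALSE),
    rewards = data.frame(time = pick("reward")$time_s, port = pick("reward")$port,
                         stringsAsFactors = FALSE),
    entries = data.frame(time = pick("entry")$time_s, port = pick("entry")$port,
                         stringsAsFactors = FALSE),
    bouts = data.frame(onset = bouts_on$time_s, offset = bouts_off$time_s),
    injection_time = if (nrow(inj) > 0) inj$time_s[1] else NA_real_,
    epochs = epochs)
}

#' Write an event log to CSV + JSON epochs sidecar
#' @param events an [event_log()].
#' @param csv_path,epochs_path output paths.
#' @export
write_events_csv <- function(events, csv_path, epochs_path) {
  block <- function(stream, time_s, port = rep("", length(time_s))) {
    if (length(time_s) == 0L) return(NULL)
    data.frame(stream = stream, time_s = time_s, port = port,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    block("cue", events$cues$time, events$cues$port),
    block("reward", events$rewards$time, events$rewards$port),
    block("entry", events$entries$time, events$entries$port),
    block("bout_on", events$bouts$onset),
    block("bout_off", events$bouts$offset),
    if (is.finite(events$injection_time))
      block("injection", events$injection_time))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  eps <- lapply(events$epochs, function(e) c(e$start, e$end))
  jsonlite::write_json(eps, epochs_path, auto_unbox = FALSE, digits = NA)
  invisible(csv_path)
}
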