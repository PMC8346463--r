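#' @title False-positive detection filter cascade
#'
#' @description
#' Filters raw CRC-validated decodes into clean detection events. The
#' cascade order is fixed: for cabled arrays, multipath filter (per
#' hydrophone), grouping of decodes into messages across hydrophones,
#' single-detection filter, then the message ping-rate-interval (PRI)
#' filter which also builds detection events; for autonomous receivers,
#' multipath filter then a single-node PRI filter (each receiver is
#' processed entirely by itself and the single-detection filter is not
#' used). A mimic filter runs last, and a chronology filter cross-checks
#' each tag's event history along the river.
#'
#' Every filter satisfies: output is a subset of its input (no filter
#' invents decodes) and a second application changes nothing.
#'
#' @name detection_filters
NULL

#' Multipath filter
#'
#' Removes suspected multipath reflections: within each (receiver, tag)
#' stream, any decode arriving strictly less than `window` seconds after
#' the last kept decode of the same tag is dropped (greedy
#' left-to-right; the earliest decode of a burst is assumed to be the
#' direct path). A decode exactly at `window` after the kept decode is
#' kept.
#'
#' @param decodes data.frame with columns receiver, tag_id, time
#' @param window multipath window, s (default 0.3)
#' @return the filtered decode data.frame, original order of surviving
#'   rows preserved
#' @export
multipath_filter <- function(decodes, window = 0.3) {
  stopifnot(window > 0)
  if (nrow(decodes) == 0L) return(decodes)
  keep <- logical(nrow(decodes))
  key <- paste(decodes$receiver, decodes$tag_id, sep = "\r")
  for (k in unique(key)) {
    ix <- which(key == k)
    ix <- ix[order(decodes$time[ix])]
    last_kept <- -Inf
    for (i in ix) {
      if (decodes$time[i] - last_kept >= window || !is.finite(last_kept)) {
        keep[i] <- TRUE
        last_kept <- decodes$time[i]
      }
    }
  }
  out <- decodes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group decodes into messages
#'
#' Groups same-tag decodes across hydrophones into "messages" suspected
#' to originate from the same tag transmission: per tag, single-linkage
#' clustering in time (clusters break where the gap between consecutive
#' decodes exceeds `window`). When a cluster contains more than one
#' decode from the same receiver, the earliest is kept. The message time
#' is its earliest member decode.
#'
#' @param decodes data.frame with columns receiver, tag_id, time
#' @param window grouping window, s; sensible default is the maximum
#'   pairwise hydrophone distance over the sound speed plus timing
#'   slack (see [grouping_window()])
#' @return list with `messages` (tag_id, message_id, time, n_receivers)
#'   and `decodes` (input rows that survived de-duplication, with a
#'   `message_id` column)
#' @export
group_messages <- function(decodes, window) {
  stopifnot(window > 0)
  if (nrow(decodes) == 0L)
    return(list(messages = data.frame(tag_id = integer(),
                                      message_id = integer(),
                                      time = numeric(),
                                      n_receivers = integer()),
                decodes = cbind(decodes, message_id = integer(0))))
  decodes <- decodes[order(decodes$tag_id, decodes$time), , drop = FALSE]
  msg_id <- integer(nrow(decodes))
  next_id <- 0L
  for (tg in unique(decodes$tag_id)) {
    ix <- which(decodes$tag_id == tg)
    gaps <- c(Inf, diff(decodes$time[ix]))
    cl <- cumsum(gaps > window)
    msg_id[ix] <- next_id + cl
    next_id <- next_id + max(cl)
  }
  decodes$message_id <- msg_id
  # within a message keep the earliest decode per receiver
  ord <- order(decodes$message_id, decodes$time)
  decodes <- decodes[ord, , drop = FALSE]
  dup <- duplicated(paste(decodes$message_id, decodes$receiver, sep = "\r"))
  decodes <- decodes[!dup, , drop = FALSE]
  agg_t <- tapply(decodes$time, decodes$message_id, min)
  agg_n <- tapply(decodes$receiver, decodes$message_id,
                  function(r) length(unique(r)))
  agg_tag <- tapply(decodes$tag_id, decodes$message_id, `[`, 1L)
  ids <- as.integer(names(agg_t))
  messages <- data.frame(tag_id = as.vector(agg_tag), message_id = ids,
                         time = as.vector(agg_t),
                         n_receivers = as.vector(agg_n))
  messages <- messages[order(messages$time), , drop = FALSE]
  rownames(messages) <- rownames(decodes) <- NULL
  list(messages = messages, decodes = decodes)
}

#' Default message-grouping window for an array
#'
#' Maximum pairwise hydrophone distance divided by the sound speed, plus
#' three standard deviations of the timing noise.
#'
#' @param phones hydrophone table with x, y, z columns
#' @param c_sound sound speed, m/s
#' @param sigma_t timing noise sd, s
#' @return window in seconds
#' @export
grouping_window <- function(phones, c_sound = sound_speed(15),
                            sigma_t = 1e-5) {
  max(stats::dist(phones[, c("x", "y", "z")])) / c_sound + 3 * sigma_t
}

#' Single-detection filter
#'
#' Removes messages detected by only one hydrophone: real transmissions
#' within range of a cabled array should reach multiple hydrophones.
#' Not applicable to autonomous receivers, which are processed one at a
#' time.
#'
#' @param messages message data.frame from [group_messages()]
#' @param source "cabled" (the only valid value; "autonomous" is
#'   rejected)
#' @return messages with `n_receivers >= 2`
#' @export
single_detection_filter <- function(messages, source = "cabled") {
  if (!identical(source, "cabled"))
    stop("the single-detection filter applies only to cabled-array data")
  out <- messages[messages$n_receivers >= 2L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# does dt sit on the PRI lattice within tolerance?
.on_lattice <- function(dt, pri, tol, k_max) {
  k <- round(dt / pri)
  k >= 1L & k <= k_max & abs(dt - k * pri) <= tol
}

#' Ping-rate-interval (PRI) filter and event builder
#'
#' Keeps messages whose timing follows the tag's transmission pattern: a
#' message is accepted when its interval to some other accepted message
#' is within `tolerance` of an integer multiple (1..`k_max`) of the
#' nominal PRI. Acceptance is computed as connected components of the
#' lattice-consistency graph over the message times. Components are then
#' split into events wherever the gap between consecutive accepted
#' messages exceeds `gap_close`, and events with fewer than
#' `min_messages` messages are discarded entirely.
#'
#' @param times numeric message (or decode) times of one tag at one
#'   array or receiver, seconds
#' @param pri_nominal nominal PRI, s
#' @param tolerance lattice tolerance, s (must be < pri_nominal / 2)
#' @param min_messages minimum messages per event
#' @param k_max largest PRI multiple bridged by a single link
#' @param gap_close event-closure gap, s (default 30 * pri_nominal)
#' @return list with `accepted` (logical per input time) and `events`
#'   (data.frame event_id, first, last, n_messages) and `event_of`
#'   (integer event id per input time, NA if rejected)
#' @export
pri_filter <- function(times, pri_nominal, tolerance = 0.2,
                       min_messages = 4L, k_max = 12L,
                       gap_close = 30 * pri_nominal) {
  stopifnot(pri_nominal > 0, tolerance < pri_nominal / 2)
  n <- length(times)
  if (n == 0L)
    return(list(accepted = logical(0),
                events = data.frame(event_id = integer(), first = numeric(),
                                    last = numeric(), n_messages = integer()),
                event_of = integer(0)))
  ord <- order(times)
  ts <- times[ord]
  comp <- seq_len(n)          # union-find over sorted indices
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  reach <- k_max * pri_nominal + tolerance
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && ts[j] - ts[i] <= reach) {
      if (.on_lattice(ts[j] - ts[i], pri_nominal, tolerance, k_max)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[ri] <- rj
      }
      j <- j + 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  sizes <- table(roots)
  # singleton components are off-lattice messages
  member <- sizes[as.character(roots)] >= 2L
  event_sorted <- rep(NA_integer_, n)
  eid <- 0L
  for (r in names(sizes)[sizes >= 2L]) {
    ix <- which(roots == as.integer(r) & member)
    # split at gaps > gap_close within the component
    gaps <- c(Inf, diff(ts[ix]))
    sub <- cumsum(gaps > gap_close)
    for (s in unique(sub)) {
      six <- ix[sub == s]
      if (length(six) >= min_messages) {
        eid <- eid + 1L
        event_sorted[six] <- eid
      }
    }
  }
  event_of <- integer(n)
  event_of[ord] <- event_sorted
  accepted <- !is.na(event_of)
  ev <- if (eid > 0L) {
    first <- tapply(times[accepted], event_of[accepted], min)
    last <- tapply(times[accepted], event_of[accepted], max)
    nm <- tapply(times[accepted], event_of[accepted], length)
    data.frame(event_id = as.integer(names(first)),
               first = as.vector(first), last = as.vector(last),
               n_messages = as.vector(as.integer(nm)))
  } else data.frame(event_id = integer(), first = numeric(),
                    last = numeric(), n_messages = integer())
  ev <- ev[order(ev$first), , drop = FALSE]
  # renumber events in first-time order
  if (nrow(ev)) {
    remap <- stats::setNames(seq_len(nrow(ev)), ev$event_id)
    event_of[accepted] <- remap[as.character(event_of[accepted])]
    ev$event_id <- seq_len(nrow(ev))
  }
  rownames(ev) <- NULL
  list(accepted = accepted, events = ev, event_of = event_of)
}

#' Message PRI filter over a cabled-array message table
#'
#' Applies [pri_filter()] per tag to the message times of a cabled
#' array and attaches event ids.
#'
#' @param messages message data.frame (tag_id, message_id, time, ...)
#' @param pri_by_tag named numeric vector or single number: nominal PRI
#'   per tag id
#' @param ... further arguments to [pri_filter()]
#' @return list with `messages` (accepted rows + `event_id`) and
#'   `events` (tag_id, event_id, first, last, n_messages)
#' @export
message_pri_filter <- function(messages, pri_by_tag, ...) {
  out_m <- list(); out_e <- list()
  for (tg in unique(messages$tag_id)) {
    ix <- which(messages$tag_id == tg)
    pri <- if (length(pri_by_tag) == 1L && is.null(names(pri_by_tag)))
      pri_by_tag else unname(pri_by_tag[as.character(tg)])
    if (is.na(pri)) next   # unknown tag: no PRI model, all removed
    pf <- pri_filter(messages$time[ix], pri, ...)
    if (any(pf$accepted)) {
      m <- messages[ix[pf$accepted], , drop = FALSE]
      m$event_id <- pf$event_of[pf$accepted]
      out_m[[length(out_m) + 1L]] <- m
      e <- pf$events
      e <- cbind(tag_id = tg, e)
      out_e[[length(out_e) + 1L]] <- e
    }
  }
  msgs <- if (length(out_m)) do.call(rbind, out_m) else
    cbind(messages[0, , drop = FALSE], event_id = integer(0))
  evs <- if (length(out_e)) do.call(rbind, out_e) else
    data.frame(tag_id = integer(), event_id = integer(), first = numeric(),
               last = numeric(), n_messages = integer())
  rownames(msgs) <- rownames(evs) <- NULL
  list(messages = msgs, events = evs)
}

#' Single-node PRI filter for autonomous receivers
#'
#' Autonomous receivers are not time-synchronised with each other, so
#' each receiver's decode stream is filtered entirely by itself using
#' the same PRI-lattice logic as the message PRI filter; one event
#' stream per (receiver, tag).
#'
#' @param decodes multipath-filtered decode data.frame (receiver,
#'   tag_id, time)
#' @param pri_by_tag nominal PRI per tag (see [message_pri_filter()])
#' @param ... further arguments to [pri_filter()]
#' @return list with `decodes` (accepted rows + event_id) and `events`
#'   (receiver, tag_id, event_id, first, last, n_messages)
#' @export
single_node_pri_filter <- function(decodes, pri_by_tag, ...) {
  out_d <- list(); out_e <- list()
  for (rec in unique(decodes$receiver)) {
    rix <- which(decodes$receiver == rec)
    sub <- decodes[rix, , drop = FALSE]
    res <- message_pri_filter(
      data.frame(tag_id = sub$tag_id, message_id = seq_len(nrow(sub)),
                 time = sub$time),
      pri_by_tag, ...)
    if (nrow(res$messages)) {
      d <- sub[res$messages$message_id, , drop = FALSE]
      d$event_id <- res$messages$event_id
      out_d[[length(out_d) + 1L]] <- d
      out_e[[length(out_e) + 1L]] <- cbind(receiver = rec, res$events)
    }
  }
  dec <- if (length(out_d)) do.call(rbind, out_d) else
    cbind(decodes[0, , drop = FALSE], event_id = integer(0))
  evs <- if (length(out_e)) do.call(rbind, out_e) else
    data.frame(receiver = character(), tag_id = integer(),
               event_id = integer(), first = numeric(), last = numeric(),
               n_messages = integer())
  rownames(dec) <- rownames(evs) <- NULL
  list(decodes = dec, events = evs)
}

#' Mimic filter over detection events
#'
#' Removes events attributable to mimic tag codes. For each pair of
#' events whose tags are in the mimic relation and whose time spans
#' overlap, the event with fewer messages is the suspected mimic; it is
#' removed when (a) at least `min_match_frac` of its message times fall
#' within `concurrency_tol` of a message of the other event and (b) if
#' 3-D tracks for both tags are supplied, the median 3-D separation
#' between the paired track points is below `coloc_threshold`. Ties in
#' message count are broken by keeping the tag present in the
#' tagged-fish release list.
#'
#' @param events event data.frame (tag_id, event_id, first, last,
#'   n_messages)
#' @param messages message data.frame with tag_id, event_id, time
#' @param mimics mimic table ([mimic_table()])
#' @param concurrency_tol per-message time-match tolerance, s
#' @param min_match_frac minimum fraction of matched messages
#' @param coloc_threshold colocation threshold on median 3-D
#'   separation, m
#' @param tracks optional track data.frame (tag_id, time, x, y, z)
#' @param fish_ids optional integer vector of released tag ids (for
#'   tie-breaking)
#' @return list with `events` (surviving), `removed` (removed events
#'   plus `mimic_of` column)
#' @export
mimic_event_filter <- function(events, messages, mimics,
                               concurrency_tol = 0.025,
                               min_match_frac = 0.5,
                               coloc_threshold = 10,
                               tracks = NULL, fish_ids = NULL) {
  if (nrow(events) == 0L)
    return(list(events = events, removed = cbind(events, mimic_of = integer(0))))
  drop <- logical(nrow(events))
  mimic_of <- rep(NA_integer_, nrow(events))
  pairs <- unique(mimics[, c("source_id", "mimic_id")])
  for (i in seq_len(nrow(events))) {
    if (drop[i]) next
    partners <- pairs$mimic_id[pairs$source_id == events$tag_id[i]]
    if (!length(partners)) next
    for (j in which(events$tag_id %in% partners & !drop)) {
      if (events$first[i] > events$last[j] ||
          events$first[j] > events$last[i]) next  # no temporal overlap
      # suspected mimic = fewer messages; tie -> the one not in fish_ids
      ij <- c(i, j)
      nm <- events$n_messages[ij]
      victim <- if (nm[1] != nm[2]) ij[which.min(nm)] else {
        in_fish <- events$tag_id[ij] %in% fish_ids
        if (xor(in_fish[1], in_fish[2])) ij[!in_fish][1] else ij[2]
      }
      keeper <- setdiff(ij, victim)
      tv <- messages$time[messages$tag_id == events$tag_id[victim] &
                            messages$event_id == events$event_id[victim]]
      tk <- messages$time[messages$tag_id == events$tag_id[keeper] &
                            messages$event_id == events$event_id[keeper]]
      if (!length(tv) || !length(tk)) next
      matched <- vapply(tv, function(tm) min(abs(tk - tm)) <= concurrency_tol,
                        logical(1L))
      if (mean(matched) < min_match_frac) next
      if (!is.null(tracks)) {
        sep <- .track_separation(tracks, events$tag_id[victim],
                                 events$tag_id[keeper])
        if (!is.na(sep) && sep >= coloc_threshold) next  # spatially distinct
      }
      drop[victim] <- TRUE
      mimic_of[victim] <- events$tag_id[keeper]
      if (victim == i) break
    }
  }
  removed <- events[drop, , drop = FALSE]
  removed$mimic_of <- mimic_of[drop]
  out <- events[!drop, , drop = FALSE]
  rownames(out) <- rownames(removed) <- NULL
  list(events = out, removed = removed)
}

# median 3-D separation between two tags' tracks at matched times
.track_separation <- function(tracks, tag_a, tag_b) {
  a <- tracks[tracks$tag_id == tag_a, , drop = FALSE]
  b <- tracks[tracks$tag_id == tag_b, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) return(NA_real_)
  seps <- vapply(seq_len(nrow(a)), function(i) {
    j <- which.min(abs(b$time - a$time[i]))
    sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
  }, numeric(1L))
  stats::median(seps)
}

#' Chronology filter over a tag's event history
#'
#' Cross-checks the sequence of detection events of one tag along the
#' river. Migration runs downstream (decreasing river kilometre), so an
#' event at an array upstream of one already passed, an event before the
#' tag's release time, or an implausibly long stationary event at a
#' single array (a transmitter dropped near a receiver after predation)
#' is flagged anomalous and excluded from the exported history.
#'
#' @param events event data.frame with tag_id, array, first, last
#' @param array_rkm named numeric: river kilometre per array name
#' @param release_time release time of the tag, s (optional)
#' @param rkm_slack river-km slack before movement counts as upstream
#' @param dropped_hours duration threshold for the dropped-tag flag
#' @return list with `events` (clean) and `flagged` (with a `reason`
#'   column: before_release, upstream_movement, dropped_tag)
#' @export
chronology_filter <- function(events, array_rkm, release_time = NULL,
                              rkm_slack = 0, dropped_hours = 24) {
  if (nrow(events) == 0L)
    return(list(events = events, flagged = cbind(events, reason = character(0))))
  events <- events[order(events$first), , drop = FALSE]
  rkm <- array_rkm[as.character(events$array)]
  reason <- rep(NA_character_, nrow(events))
  if (!is.null(release_time))
    reason[events$first < release_time] <- "before_release"
  min_rkm <- Inf
  for (i in seq_len(nrow(events))) {
    if (!is.na(reason[i])) next
    if (is.na(rkm[i])) next
    if (rkm[i] > min_rkm + rkm_slack) {
      reason[i] <- "upstream_movement"
    } else {
      min_rkm <- min(min_rkm, rkm[i])
    }
  }
  dur <- events$last - events$first
  stale <- is.na(reason) & dur > dropped_hours * 3600
  reason[stale] <- "dropped_tag"
  flagged <- events[!is.na(reason), , drop = FALSE]
  flagged$reason <- reason[!is.na(reason)]
  out <- events[is.na(reason), , drop = FALSE]
  rownames(out) <- rownames(flagged) <- NULL
  list(events = out, flagged = flagged)
}
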