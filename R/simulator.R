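#' @title Synthetic telemetry data generator
#'
#' @description
#' Generates the synthetic inputs every pipeline stage needs: hydrophone
#' arrays on dam piers, correlated-random-walk fish tracks, tag
#' transmission schedules with ping-rate-interval jitter, propagation of
#' transmissions to time-stamped decodes (range-dependent detection,
#' timing noise, multipath echoes), injected false positives and mimic
#' corruption, and an unmanned-surface-vessel (USV) style GPS-referenced
#' survey. All generators are deterministic given their seed, and each
#' decode is paired with a ground-truth record so filter and localization
#' performance can be scored exactly.
#'
#' @name simulator
NULL

#' Propagation and receiver model
#'
#' @param c_sound sound speed, m/s
#' @param sigma_t per-decode timing noise standard deviation, s
#' @param detect_prob function of range (m) returning detection
#'   probability; must be non-increasing with p(0) <= 1
#' @param p_multipath probability that a detected transmission also
#'   produces one multipath echo on the same hydrophone
#' @param multipath_lag length-2 range (s) of the uniform echo-lag
#'   distribution; strictly positive, below the multipath-filter window
#' @param fp_rate false-positive decode rate, decodes per second per
#'   hydrophone
#' @param p_mimic probability that a true decode's identifier is replaced
#'   by one of its mimic codes
#' @return object of class `propagation_model`
#' @export
propagation_model <- function(c_sound = sound_speed(15),
                              sigma_t = 1e-5,
                              detect_prob = detection_prob_logistic,
                              p_multipath = 0.2,
                              multipath_lag = c(0.01, 0.3),
                              fp_rate = 0,
                              p_mimic = 0) {
  stopifnot(c_sound > 0, sigma_t >= 0, p_multipath >= 0, p_multipath <= 1,
            all(multipath_lag > 0), multipath_lag[1] < multipath_lag[2],
            fp_rate >= 0, p_mimic >= 0, p_mimic <= 1)
  structure(list(c_sound = c_sound, sigma_t = sigma_t,
                 detect_prob = detect_prob, p_multipath = p_multipath,
                 multipath_lag = multipath_lag, fp_rate = fp_rate,
                 p_mimic = p_mimic),
            class = "propagation_model")
}

#' Default range-dependent detection probability
#'
#' Logistic decay with range, near 1 close to the array and ~0.99 at
#' 140 m, mirroring the scale of field detection efficiencies for
#' dam-face arrays; purely a stand-in, not an estimate of any deployed
#' system.
#'
#' @param range_m range, m
#' @param r50 range at which probability is 0.5
#' @param width logistic width parameter, m
#' @return detection probability in \[0, 1\]
#' @export
detection_prob_logistic <- function(range_m, r50 = 450, width = 65) {
  stats::plogis((r50 - range_m) / width)
}

#' Simulate a correlated-random-walk fish track
#'
#' Horizontal correlated random walk with heading persistence plus a
#' small vertical random walk, time-stepped at `timestep`. Persistence 1
#' with zero heading noise yields a straight line; mean speed 0 yields a
#' stationary track.
#'
#' @param seed integer RNG seed
#' @param start numeric length 3 starting position (dam-local m)
#' @param mean_speed mean horizontal speed, m/s
#' @param persistence heading autocorrelation in \[0, 1\]
#' @param heading_sd innovation sd of the heading, radians
#' @param duration track duration, s (> 0)
#' @param timestep step, s (> 0)
#' @param heading0 initial heading, radians
#' @param z_sd vertical random-walk innovation sd per step, m
#' @return data.frame with columns time, x, y, z
#' @export
simulate_fish_track <- function(seed, start = c(100, 100, -5),
                                mean_speed = 0.3, persistence = 0.95,
                                heading_sd = 0.3, duration = 600,
                                timestep = 1, heading0 = pi,
                                z_sd = 0.05) {
  if (duration <= 0) stop("duration must be positive")
  if (timestep <= 0) stop("timestep must be positive")
  set.seed(seed)
  n <- floor(duration / timestep) + 1L
  t <- (seq_len(n) - 1L) * timestep
  heading <- numeric(n); heading[1] <- heading0
  if (n > 1) for (i in 2:n)
    heading[i] <- persistence * heading[i - 1] +
      (1 - persistence) * heading0 + heading_sd * sqrt(1 - persistence^2) *
      stats::rnorm(1)
  step <- mean_speed * timestep
  x <- start[1] + c(0, cumsum(step * cos(heading[-n])))
  y <- start[2] + c(0, cumsum(step * sin(heading[-n])))
  z <- start[3] + c(0, cumsum(stats::rnorm(n - 1L, 0, z_sd)))
  data.frame(time = t, x = x, y = y, z = z)
}

#' Simulate tag transmission times
#'
#' Successive emissions separated by the nominal ping-rate interval (PRI)
#' plus Gaussian jitter. Study tags transmit nominally every 4.2 s; the
#' USV reference tag every 3 s.
#'
#' @param pri_nominal nominal PRI, s (> 0)
#' @param jitter_sd interval jitter sd, s; must be < pri_nominal / 2
#' @param duration total duration, s
#' @param t0 time of the first emission, s
#' @param seed optional RNG seed
#' @return numeric vector of emission times
#' @export
simulate_transmissions <- function(pri_nominal = 4.2, jitter_sd = 0,
                                   duration = 600, t0 = 0, seed = NULL) {
  if (pri_nominal <= 0) stop("pri_nominal must be positive")
  if (jitter_sd >= pri_nominal / 2)
    stop("jitter_sd >= pri_nominal/2 would destroy the PRI structure")
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / pri_nominal)
  iv <- rep(pri_nominal, n)
  if (jitter_sd > 0) iv <- iv + stats::rnorm(n, 0, jitter_sd)
  times <- t0 + c(0, cumsum(iv))
  times[times <= t0 + duration]
}

# interpolate a track at arbitrary times (linear per axis)
.track_at <- function(track, times) {
  cbind(x = stats::approx(track$time, track$x, times, rule = 2)$y,
        y = stats::approx(track$time, track$y, times, rule = 2)$y,
        z = stats::approx(track$time, track$z, times, rule = 2)$y)
}

#' Propagate transmissions to per-hydrophone decodes
#'
#' For each emission, computes the true arrival time at every hydrophone
#' (emission time + range / sound speed), applies Bernoulli detection
#' with the model's range-dependent probability, adds Gaussian timing
#' noise, and (with probability `p_multipath`) appends one multipath echo
#' at a positive lag. Every decode carries the tag's valid codeword
#' identifier and is paired with a ground-truth record.
#'
#' @param track data.frame time/x/y/z true trajectory
#' @param emissions numeric emission times
#' @param phones data.frame with columns receiver, x, y, z
#' @param model a [propagation_model()]
#' @param tag_id integer tag identifier
#' @param seed RNG seed
#' @return list with `decodes` (data.frame receiver, tag_id, time,
#'   emission_id, origin) and `truth` (per emission: emission_id, time,
#'   x, y, z, n_detected)
#' @export
propagate_to_decodes <- function(track, emissions, phones, model, tag_id,
                                 seed = 1L) {
  if (nrow(phones) == 0L) stop("hydrophone set must be non-empty")
  set.seed(seed)
  pos <- .track_at(track, emissions)
  ph <- as.matrix(phones[, c("x", "y", "z")])
  out <- vector("list", length(emissions))
  n_det <- integer(length(emissions))
  for (i in seq_along(emissions)) {
    rng <- sqrt(colSums((t(ph) - pos[i, ])^2))
    p <- model$detect_prob(rng)
    det <- stats::runif(nrow(ph)) < p
    n_det[i] <- sum(det)
    if (!any(det)) next
    t_arr <- emissions[i] + rng[det] / model$c_sound +
      stats::rnorm(sum(det), 0, model$sigma_t)
    d <- data.frame(receiver = phones$receiver[det], tag_id = tag_id,
                    time = t_arr, emission_id = i, origin = "direct",
                    stringsAsFactors = FALSE)
    mp <- stats::runif(sum(det)) < model$p_multipath
    if (any(mp)) {
      lag <- stats::runif(sum(mp), model$multipath_lag[1],
                          model$multipath_lag[2])
      d <- rbind(d, data.frame(receiver = phones$receiver[det][mp],
                               tag_id = tag_id, time = t_arr[mp] + lag,
                               emission_id = i, origin = "multipath",
                               stringsAsFactors = FALSE))
    }
    out[[i]] <- d
  }
  decodes <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(decodes))
    decodes <- data.frame(receiver = character(), tag_id = integer(),
                          time = numeric(), emission_id = integer(),
                          origin = character(), stringsAsFactors = FALSE)
  decodes <- decodes[order(decodes$time), , drop = FALSE]
  rownames(decodes) <- NULL
  truth <- data.frame(emission_id = seq_along(emissions), time = emissions,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      n_detected = n_det)
  list(decodes = decodes, truth = truth)
}

#' Inject false positives and mimic corruption into a decode table
#'
#' False positives are added per hydrophone as a Poisson process of rate
#' `fp_rate` over the observation span, with identifiers drawn by
#' rejection from uniformly random 31-bit words that pass CRC validation
#' (so, by construction, all false positives carry valid codes). With
#' probability `p_mimic` a true decode's identifier is replaced by one of
#' its mimic codes from `mimics`.
#'
#' @param decodes decode data.frame (receiver, tag_id, time, ...)
#' @param model a [propagation_model()] (uses fp_rate, p_mimic)
#' @param span length-2 observation window, s; defaults to the decode
#'   time range
#' @param mimics mimic table from [mimic_table()] (required if p_mimic > 0)
#' @param seed RNG seed
#' @return decode data.frame with extra rows `origin = "false_positive"`
#'   and altered rows `origin = "mimic"`, time-sorted
#' @export
inject_noise <- function(decodes, model, span = NULL, mimics = NULL,
                         seed = 1L) {
  set.seed(seed)
  if (is.null(span))
    span <- if (nrow(decodes)) range(decodes$time) else c(0, 0)
  out <- decodes
  if (model$p_mimic > 0 && nrow(out)) {
    if (is.null(mimics)) stop("mimic table required when p_mimic > 0")
    hit <- which(stats::runif(nrow(out)) < model$p_mimic &
                   out$origin == "direct")
    for (i in hit) {
      cand <- mimics$mimic_id[mimics$source_id == out$tag_id[i]]
      if (length(cand)) {
        out$tag_id[i] <- sample(cand, 1L)
        out$origin[i] <- "mimic"
      }
    }
  }
  T_obs <- diff(span)
  if (model$fp_rate > 0 && T_obs > 0) {
    for (rec in unique(decodes$receiver)) {
      k <- stats::rpois(1L, model$fp_rate * T_obs)
      if (k == 0L) next
      ids <- .random_valid_ids(k)
      out <- rbind(out, data.frame(
        receiver = rec, tag_id = ids,
        time = stats::runif(k, span[1], span[2]),
        emission_id = NA_integer_, origin = "false_positive",
        stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ids of uniformly random 31-bit words that happen to validate
.random_valid_ids <- function(k, layout = .default_layout) {
  ids <- integer(0)
  while (length(ids) < k) {
    w <- floor(stats::runif(max(1000L, 300L * k)) * 2^31)
    ok <- validate_words(w, layout)
    ids <- c(ids, as.integer((w[ok] %/% 2^layout$crc_bits) %%
                               2^layout$id_bits))
  }
  ids[seq_len(k)]
}

#' Build a pier-mounted dam-face hydrophone array
#'
#' Hydrophones at two depths on each pier nose along the dam face
#' (X = 0), mirroring the cabled-array geometry at a dam: nearly
#' coplanar in the dam plane, which is why depth accuracy degrades with
#' range in validation.
#'
#' @param n_piers number of piers
#' @param pier_spacing pier spacing along Y, m
#' @param depths hydrophone depths (negative Z), m
#' @param y0 Y of the first pier, m
#' @param x_offset small X stagger of alternate piers, m
#' @return data.frame: receiver, pier_id, x, y, z
#' @export
make_pier_array <- function(n_piers = 8L, pier_spacing = 30,
                            depths = c(-2, -12), y0 = 0, x_offset = 0.5) {
  pier <- rep(seq_len(n_piers), each = length(depths))
  y <- y0 + (pier - 1L) * pier_spacing
  z <- rep(depths, times = n_piers)
  x <- ifelse(pier %% 2L == 0L, x_offset, 0)
  data.frame(receiver = sprintf("P%02d%s", pier,
                                rep(c("S", "D")[seq_along(depths)],
                                    times = n_piers)),
             pier_id = pier, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

#' Simulate a USV-style GPS-referenced accuracy survey
#'
#' Drives a surface vessel towing a reference tag out from the dam face
#' to `max_range` and back along one or more transect lines (one per
#' surveyed bay), at constant speed, with the tag pinging at a fixed PRI.
#' A GPS reference track is sampled at `gps_rate` with optional Gaussian
#' position noise; decodes are generated through
#' [propagate_to_decodes()].
#'
#' @param phones hydrophone table (see [make_pier_array()])
#' @param bay_y numeric Y coordinates of the surveyed transect lines, m
#' @param max_range outbound extent of each transect, m (field protocol:
#'   ~150 m from the dam face)
#' @param speed vessel speed, m/s (field protocol: 0.28 m/s)
#' @param pri reference-tag PRI, s (field protocol: 3 s)
#' @param tag_depth towed-tag depth, m (negative)
#' @param gps_rate GPS sampling interval, s
#' @param gps_noise_sd GPS position noise sd per axis, m
#' @param model a [propagation_model()]
#' @param tag_id reference tag identifier
#' @param seed RNG seed
#' @return list with `truth` (tag track), `gps` (noisy GPS reference
#'   track), `decodes`, `emissions` (emission times), `transects`
#'   (per-emission transect index)
#' @export
simulate_usv_survey <- function(phones, bay_y = c(45, 105, 165),
                                max_range = 150, speed = 0.28, pri = 3,
                                tag_depth = -1.5, gps_rate = 1,
                                gps_noise_sd = 0.03,
                                model = propagation_model(),
                                tag_id = 4660L, seed = 1L) {
  if (nrow(phones) == 0L) stop("array must be non-empty")
  set.seed(seed)
  leg <- max_range / speed           # one-way duration per leg, s
  rows <- list(); t0 <- 0
  for (yb in bay_y) {
    tt <- seq(0, 2 * leg, by = gps_rate)
    xx <- ifelse(tt <= leg, speed * tt, speed * (2 * leg - tt))
    rows[[length(rows) + 1L]] <- data.frame(
      time = t0 + tt, x = xx, y = yb, z = tag_depth,
      transect = length(rows) + 1L)
    t0 <- t0 + 2 * leg + 10 * pri    # gap while repositioning
  }
  truth <- do.call(rbind, rows)
  emissions <- simulate_transmissions(pri_nominal = pri, jitter_sd = 0,
                                      duration = max(truth$time))
  # keep emissions inside transect occupancy (drop repositioning gaps)
  on_line <- vapply(emissions, function(tm)
    any(abs(truth$time - tm) <= gps_rate), logical(1L))
  emissions <- emissions[on_line]
  pd <- propagate_to_decodes(truth, emissions, phones, model, tag_id,
                             seed = seed + 1L)
  gps <- truth
  if (gps_noise_sd > 0) {
    gps$x <- gps$x + stats::rnorm(nrow(gps), 0, gps_noise_sd)
    gps$y <- gps$y + stats::rnorm(nrow(gps), 0, gps_noise_sd)
    gps$z <- gps$z + stats::rnorm(nrow(gps), 0, gps_noise_sd)
  }
  tr_ix <- vapply(emissions, function(tm)
    truth$transect[which.min(abs(truth$time - tm))], integer(1L))
  list(truth = truth, gps = gps, decodes = pd$decodes,
       emission_truth = pd$truth, emissions = emissions, transects = tr_ix)
}
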