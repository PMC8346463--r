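#' @title GPS-referenced accuracy and efficiency validation
#'
#' @description
#' Scores 3-D tracked positions against a GPS reference track from a
#' controlled survey: per-axis absolute differences (with the reference
#' linearly interpolated at each tracked time), their medians and
#' root-mean-square values, detection and tracking efficiencies, and a
#' distance-binned summary table (10 m bins out from the dam face).
#'
#' @name validation
NULL

#' Per-axis tracking errors against a GPS reference
#'
#' The GPS reference position at each tracked time is obtained by
#' linear interpolation of the (strictly time-ordered) GPS track;
#' tracked points outside the GPS time span are excluded with a
#' warning. Errors are absolute per-axis differences; summary
#' statistics are the per-axis median (even-count median = mean of the
#' middle two) and RMS (square root of the mean squared difference).
#'
#' @param tracked data.frame with time, x, y, z (tracked positions)
#' @param gps data.frame with time, x, y, z (reference track)
#' @return list with `points` (per-point data.frame: time, dx, dy, dz,
#'   ref_x, ref_y, ref_z), `median` (named dx/dy/dz), `rms` (named
#'   dx/dy/dz)
#' @export
error_stats <- function(tracked, gps) {
  if (is.unsorted(gps$time, strictly = TRUE))
    stop("GPS track must be strictly time-ordered")
  inside <- tracked$time >= min(gps$time) & tracked$time <= max(gps$time)
  if (any(!inside))
    warning(sum(!inside), " tracked points outside the GPS time span excluded")
  tr <- tracked[inside, , drop = FALSE]
  rx <- stats::approx(gps$time, gps$x, tr$time)$y
  ry <- stats::approx(gps$time, gps$y, tr$time)$y
  rz <- stats::approx(gps$time, gps$z, tr$time)$y
  pts <- data.frame(time = tr$time,
                    dx = abs(tr$x - rx), dy = abs(tr$y - ry),
                    dz = abs(tr$z - rz),
                    ref_x = rx, ref_y = ry, ref_z = rz)
  list(points = pts,
       median = c(dx = stats::median(pts$dx), dy = stats::median(pts$dy),
                  dz = stats::median(pts$dz)),
       rms = c(dx = sqrt(mean(pts$dx^2)), dy = sqrt(mean(pts$dy^2)),
               dz = sqrt(mean(pts$dz^2))))
}

#' Detection and tracking efficiency
#'
#' Detection efficiency is the number of valid detections (messages)
#' divided by the number of transmissions; tracking efficiency is the
#' number of successful 3-D-tracked locations divided by the number of
#' transmissions.
#'
#' @param n_transmissions number of transmissions (> 0)
#' @param n_detected number of validly detected transmissions
#' @param n_tracked number of successfully tracked locations
#' @return named numeric: detection, tracking
#' @export
efficiencies <- function(n_transmissions, n_detected, n_tracked) {
  if (n_transmissions <= 0) stop("transmission count must be positive")
  c(detection = n_detected / n_transmissions,
    tracking = n_tracked / n_transmissions)
}

#' Distance-binned accuracy and efficiency table
#'
#' Splits validation points into half-open bins of the reference
#' distance from the dam face (the X coordinate of the interpolated
#' GPS position), [0,10), [10,20), ...; the bin label is the upper
#' edge. Per bin: detection and tracking efficiency (against the
#' per-bin transmission count) and per-axis median and RMS errors.
#'
#' Efficiencies are computed on a single binning basis -- the true
#' distance of each transmission -- so each bin's detected and tracked
#' counts are subsets of its transmission count and the ratios stay in
#' \[0, 1\]. Error statistics are binned by the reference distance of
#' each validation point.
#'
#' @param val_points per-point data.frame from [error_stats()]
#' @param tx_dist reference distances of all transmissions, m (one per
#'   transmission, used for per-bin efficiency denominators)
#' @param det_dist reference distances of validly detected
#'   transmissions, m
#' @param trk_dist reference distances of successfully tracked
#'   transmissions, m; when NULL the tracking column falls back to
#'   counting validation points per bin
#' @param bin_width bin width, m (default 10)
#' @return data.frame: distance (upper edge), n_transmissions,
#'   detection_eff, tracking_eff, median_dx/dy/dz, rms_dx/dy/dz, n
#' @export
distance_binned_table <- function(val_points, tx_dist, det_dist = NULL,
                                  trk_dist = NULL, bin_width = 10) {
  bin_of <- function(d) floor(d / bin_width)
  all_bins <- sort(unique(bin_of(tx_dist)))
  rows <- lapply(all_bins, function(b) {
    in_tx <- bin_of(tx_dist) == b
    in_det <- if (is.null(det_dist)) NA else sum(bin_of(det_dist) == b)
    in_val <- bin_of(val_points$ref_x) == b
    v <- val_points[in_val, , drop = FALSE]
    n_tx <- sum(in_tx)
    n_trk <- if (is.null(trk_dist)) nrow(v) else sum(bin_of(trk_dist) == b)
    data.frame(distance = (b + 1) * bin_width,
               n_transmissions = n_tx,
               detection_eff = if (is.null(det_dist)) NA_real_
               else in_det / n_tx,
               tracking_eff = n_trk / n_tx,
               median_dx = stats::median(v$dx), median_dy = stats::median(v$dy),
               median_dz = stats::median(v$dz),
               rms_dx = sqrt(mean(v$dx^2)), rms_dy = sqrt(mean(v$dy^2)),
               rms_dz = sqrt(mean(v$dz^2)),
               n = nrow(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
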