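#' @title 3-D trajectory cleaning and quality-assurance trimming
#'
#' @description
#' Post-localization outlier removal for 3-D tracks: points too far
#' spatially from their surviving temporal neighbours (> 45 m), track
#' splits at temporal gaps (> 10 min), and points implying unrealistic
#' swimming speeds (~2 m/s for juvenile salmonids) are removed,
#' iterating to a fixed point. Quality-assurance trimming then removes
#' points before the tag's release and after the first independent
#' evidence the fish has moved downstream (a PIT detection or an
#' autonomous-array event).
#'
#' @name trajectory
NULL

#' Trajectory cleaning configuration
#'
#' @param max_jump maximum spatial distance to surviving neighbours, m
#' @param max_gap maximum temporal gap before the track is split, s
#' @param max_speed maximum plausible speed, m/s
#' @param min_fragment minimum points a split fragment must keep
#' @return object of class `cleaning_config`
#' @export
cleaning_config <- function(max_jump = 45, max_gap = 600, max_speed = 2,
                            min_fragment = 3L) {
  stopifnot(max_jump > 0, max_gap > 0, max_speed > 0, min_fragment >= 1)
  structure(list(max_jump = max_jump, max_gap = max_gap,
                 max_speed = max_speed,
                 min_fragment = as.integer(min_fragment)),
            class = "cleaning_config")
}

.dist3 <- function(p, q) sqrt(sum((p - q)^2))

#' Clean a 3-D trajectory
#'
#' Iterates three rules to a fixed point over the time-ordered points:
#' \itemize{
#'   \item spatial rule: a point farther than `max_jump` from every
#'     surviving temporal neighbour is removed (interior points must
#'     violate against both neighbours; endpoints against their single
#'     neighbour);
#'   \item speed rule: a point implying a speed above `max_speed` to
#'     every surviving neighbour is removed (requiring violation on
#'     both sides avoids deleting the innocent neighbour of a bad
#'     point);
#'   \item gap rule: the track is split where consecutive surviving
#'     points are more than `max_gap` apart; fragments with fewer than
#'     `min_fragment` points are dropped.
#' }
#' Iteration to a fixed point makes the result independent of scan
#' order; a second application changes nothing.
#'
#' @param points data.frame with columns time, x, y, z (time-ordered)
#' @param config a [cleaning_config()]
#' @return list with `points` (cleaned, with a `fragment` column) and
#'   `removed` (dropped rows with a `rule` column: spatial, speed,
#'   fragment)
#' @export
clean_trajectory <- function(points, config = cleaning_config()) {
  if (is.unsorted(points$time)) stop("points must be time-ordered")
  n <- nrow(points)
  alive <- rep(TRUE, n)
  rule <- rep(NA_character_, n)
  P <- as.matrix(points[, c("x", "y", "z")])
  tms <- points$time
  repeat {
    changed <- FALSE
    ix <- which(alive)
    m <- length(ix)
    if (m == 0L) break
    # spatial and speed rules against surviving neighbours; after any
    # removal the scan restarts so later points are never judged against
    # an already-removed neighbour
    for (k in seq_len(m)) {
      i <- ix[k]
      nb <- c(if (k > 1L) ix[k - 1L], if (k < m) ix[k + 1L])
      if (!length(nb)) next
      dists <- vapply(nb, function(j) .dist3(P[i, ], P[j, ]), numeric(1L))
      if (all(dists > config$max_jump)) {
        alive[i] <- FALSE; rule[i] <- "spatial"; changed <- TRUE; break
      }
      speeds <- dists / abs(tms[nb] - tms[i])
      if (all(is.finite(speeds)) && all(speeds > config$max_speed)) {
        alive[i] <- FALSE; rule[i] <- "speed"; changed <- TRUE; break
      }
    }
    if (!changed) break
  }
  # gap splitting on the survivors
  ix <- which(alive)
  frag <- integer(n)
  if (length(ix)) {
    gaps <- c(Inf, diff(tms[ix]))
    fr <- cumsum(gaps > config$max_gap)
    frag[ix] <- fr
    for (f in unique(fr)) {
      fx <- ix[fr == f]
      if (length(fx) < config$min_fragment) {
        alive[fx] <- FALSE
        rule[fx] <- "fragment"
      }
    }
  }
  out <- points[alive, , drop = FALSE]
  out$fragment <- frag[alive]
  removed <- points[!alive & !is.na(rule), , drop = FALSE]
  removed$rule <- rule[!alive & !is.na(rule)]
  rownames(out) <- rownames(removed) <- NULL
  list(points = out, removed = removed)
}

#' Quality-assurance trim of a trajectory
#'
#' Removes track points outside the interval from the tag's release to
#' the earliest independent downstream evidence (PIT detection within a
#' bypass, or an event at a downstream autonomous array). Without
#' downstream evidence only the lower bound applies. A missing release
#' time is an error: silently keeping unverifiable points would
#' contaminate passage analyses.
#'
#' @param points track data.frame with a `time` column
#' @param release_time tag release time, s (required)
#' @param downstream_times numeric times of downstream evidence, s (may
#'   be empty)
#' @return trimmed data.frame
#' @export
qa_trim <- function(points, release_time, downstream_times = numeric(0)) {
  if (is.null(release_time) || is.na(release_time))
    stop("release time is required for QA trimming")
  hi <- if (length(downstream_times)) min(downstream_times) else Inf
  out <- points[points$time >= release_time & points$time <= hi, ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}
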