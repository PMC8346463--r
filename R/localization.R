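#' @title TDOA-based 3-D localization
#'
#' @description
#' Converts per-hydrophone arrival times of a tag transmission into
#' time-differences of arrival (TDOA), and solves for the 3-D source
#' position in the dam-local Cartesian frame by nonlinear least squares
#' on the hyperbolic TDOA residuals: multi-start coarse grid followed by
#' damped Gauss-Newton (Levenberg-Marquardt) refinement. Sound speed is
#' computed from water temperature with a published fifth-order freshwater
#' polynomial. An exhaustive grid-search oracle over the same objective is
#' provided for independent verification in tests.
#'
#' @name localization
NULL

# Marczak (1997) freshwater sound-speed polynomial coefficients, m/s,
# valid 0-95 degC; monotone increasing on [0, 40].
.MARCZAK <- c(1.402385e3, 5.038813, -5.799136e-2, 3.287156e-4,
              -1.398845e-6, 2.787860e-9)

#' Sound speed in fresh water from temperature
#'
#' Fifth-order polynomial fit to the speed of sound in pure water at
#' atmospheric pressure (Marczak-type). Restricted here to 0-40 degC, the
#' range relevant to river forebays, over which the curve is monotone
#' increasing.
#'
#' @param temp_c water temperature, degrees Celsius, in \[0, 40\]
#' @return sound speed in m/s
#' @examples
#' sound_speed(0)   # 1402.385
#' sound_speed(20)  # ~1482.4
#' @export
sound_speed <- function(temp_c) {
  if (any(is.na(temp_c)) || any(temp_c < 0 | temp_c > 40))
    stop("temperature must lie in [0, 40] degC")
  p <- outer(temp_c, 0:5, `^`)
  as.numeric(p %*% .MARCZAK)
}

#' Dam-local coordinate frame
#'
#' Rigid transform between the projected geographic frame
#' (easting, northing, elevation) and the dam-local frame in which the
#' X-axis extends upstream into the forebay normal to the dam face, the
#' Y-axis runs parallel to the dam, and the Z-axis is normal to the water
#' surface. The transform is a rotation by `theta` about the vertical
#' axis followed by a translation; elevations shift by a constant.
#'
#' @param origin numeric length 3: easting, northing, elevation of the
#'   dam-local origin
#' @param theta rotation angle (radians) from the easting axis to the
#'   dam-local X axis, measured counter-clockwise
#' @return object of class `dam_frame`
#' @export
dam_frame <- function(origin, theta) {
  stopifnot(length(origin) == 3, is.finite(origin), is.finite(theta))
  structure(list(origin = as.numeric(origin), theta = as.numeric(theta)),
            class = "dam_frame")
}

#' Transform points between geographic-projected and dam-local frames
#'
#' @param points matrix or data.frame with 3 columns (easting, northing,
#'   elevation for direction "to_local"; x, y, z for "to_geo")
#' @param frame a [dam_frame()]
#' @param direction "to_local" or "to_geo"
#' @return matrix of transformed coordinates, same number of rows
#' @export
dam_transform <- function(points, frame, direction = c("to_local", "to_geo")) {
  direction <- match.arg(direction)
  p <- as.matrix(points)
  if (ncol(p) != 3) stop("points must have 3 columns")
  ct <- cos(frame$theta); st <- sin(frame$theta)
  R <- matrix(c(ct, -st, st, ct), 2L, 2L, byrow = TRUE)  # geo -> local
  if (direction == "to_local") {
    d <- sweep(p, 2L, frame$origin)
    cbind(d[, 1:2, drop = FALSE] %*% t(R), d[, 3])
  } else {
    xy <- p[, 1:2, drop = FALSE] %*% R   # R^-1 = t(R); (xy %*% R) = xy %*% t(t(R))
    sweep(cbind(xy, p[, 3]), 2L, frame$origin, `+`)
  }
}

#' Fit a dam-local frame from dual hydrophone coordinates
#'
#' Hydrophone configuration tables carry both projected geographic
#' (easting, northing, elevation) and dam-local (x, y, z) coordinates.
#' This recovers the rigid rotation + translation between them by a 2-D
#' orthogonal Procrustes fit in the horizontal plane and a constant
#' vertical offset.
#'
#' @param geo matrix/data.frame, columns easting, northing, elevation
#' @param local matrix/data.frame, columns x, y, z
#' @return a [dam_frame()]
#' @export
fit_dam_frame <- function(geo, local) {
  g <- as.matrix(geo); l <- as.matrix(local)
  stopifnot(nrow(g) == nrow(l), nrow(g) >= 2)
  gc <- colMeans(g[, 1:2, drop = FALSE]); lc <- colMeans(l[, 1:2, drop = FALSE])
  A <- sweep(g[, 1:2, drop = FALSE], 2L, gc)
  B <- sweep(l[, 1:2, drop = FALSE], 2L, lc)
  # rotation angle such that B = (A rotated by theta)
  num <- sum(A[, 1] * B[, 2] - A[, 2] * B[, 1])
  den <- sum(A[, 1] * B[, 1] + A[, 2] * B[, 2])
  theta <- atan2(num, den)
  ct <- cos(theta); st <- sin(theta)
  R <- matrix(c(ct, -st, st, ct), 2L, 2L, byrow = TRUE)
  # solve: local = R (geo - o)  =>  o = gc - R^-1 lc
  origin_xy <- gc - as.numeric(t(R) %*% lc)
  z0 <- mean(g[, 3] - l[, 3])
  dam_frame(c(origin_xy, z0), theta)
}

#' Time differences of arrival for one message
#'
#' The reference receiver is the earliest arrival (minimising the
#' magnitudes of the differences); each receiver's TDOA is its arrival
#' time minus the reference arrival time. TDOAs whose magnitude exceeds
#' the array aperture divided by the sound speed are geometrically
#' infeasible and flagged.
#'
#' @param times numeric arrival times (s), one per receiver
#' @param positions matrix of receiver dam-local coordinates, rows
#'   matching `times`
#' @param c_sound sound speed, m/s
#' @return object of class `tdoa_set`: list with `ref` (row index of the
#'   reference receiver), `dt` (TDOA vector, zero at the reference),
#'   `positions`, `c_sound`, `feasible` (logical per receiver)
#' @export
message_tdoas <- function(times, positions, c_sound) {
  positions <- as.matrix(positions)
  n <- length(times)
  if (n < 4L)
    stop("localization needs >= 4 receivers, got ", n)
  if (nrow(positions) != n) stop("positions must match times")
  ref <- which.min(times)
  dt <- times - times[ref]
  aperture <- max(stats::dist(positions))
  structure(list(ref = ref, dt = dt, positions = positions,
                 c_sound = c_sound,
                 feasible = abs(dt) <= aperture / c_sound + 1e-9),
            class = "tdoa_set")
}

# TDOA residuals at a candidate position p (length-3).
.tdoa_residuals <- function(p, tdoas) {
  d <- sqrt(colSums((t(tdoas$positions) - p)^2))
  tdoas$dt - (d - d[tdoas$ref]) / tdoas$c_sound
}

#' Solver configuration for 3-D localization
#'
#' @param c_sound sound speed m/s (overrides `temp_c` when given)
#' @param temp_c water temperature, used via [sound_speed()] when
#'   `c_sound` is NULL
#' @param bounds 3x2 matrix of lower/upper box bounds (dam-local m)
#'   constraining the solution; the default keeps sources in the
#'   forebay (X >= 0, the dam face)
#' @param grid_n points per axis of the multi-start grid
#' @param n_starts number of best grid points used as refinement starts
#' @param max_iter maximum Gauss-Newton iterations
#' @param tol convergence tolerance on the residual norm change
#' @return object of class `loc_config`
#' @export
loc_config <- function(c_sound = NULL, temp_c = 15,
                       bounds = rbind(x = c(0, 200), y = c(-50, 350),
                                      z = c(-30, 2)),
                       grid_n = 6L, n_starts = 4L, max_iter = 50L,
                       tol = 1e-12) {
  if (is.null(c_sound)) c_sound <- sound_speed(temp_c)
  stopifnot(c_sound > 0, all(bounds[, 2] > bounds[, 1]))
  structure(list(c_sound = c_sound, bounds = bounds,
                 grid_n = as.integer(grid_n),
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter),
                 tol = tol),
            class = "loc_config")
}

#' Solve one TDOA set for source position
#'
#' Minimises the sum of squared TDOA residuals
#' sum_i (dt_i - (|p - h_i| - |p - h_ref|)/c)^2 over candidate positions
#' p, starting damped Gauss-Newton (Levenberg-Marquardt via
#' \pkg{minpack.lm}) from the best point of a coarse multi-start grid
#' spanning the configured bounds box. Deterministic given its inputs.
#' Near-coplanar receiver geometry is detected (smallest principal extent
#' below 0.5 m) and reported in the diagnostics: depth is then weakly
#' constrained.
#'
#' @param tdoas a `tdoa_set` from [message_tdoas()]
#' @param config a [loc_config()]
#' @return list with `position` (length 3), `residual_rms` (s),
#'   `n_receivers`, `converged`, `clipped`, `near_coplanar`
#' @export
solve_position <- function(tdoas, config = loc_config()) {
  tdoas$c_sound <- config$c_sound
  b <- config$bounds
  # coplanarity diagnostic
  sv <- svd(sweep(tdoas$positions, 2L, colMeans(tdoas$positions)))$d
  near_coplanar <- sv[3] < 0.5
  # multi-start grid
  gr <- lapply(1:3, function(k) seq(b[k, 1], b[k, 2], length.out = config$grid_n))
  grid <- as.matrix(expand.grid(gr[[1]], gr[[2]], gr[[3]]))
  obj <- apply(grid, 1L, function(p) sum(.tdoa_residuals(p, tdoas)^2))
  starts <- grid[order(obj)[seq_len(min(config$n_starts, nrow(grid)))], ,
                 drop = FALSE]
  refine <- function(p0) suppressWarnings(minpack.lm::nls.lm(
    par = p0, fn = .tdoa_residuals, tdoas = tdoas,
    control = minpack.lm::nls.lm.control(maxiter = config$max_iter,
                                         ftol = config$tol,
                                         ptol = config$tol)))
  in_box <- function(p) all(p >= b[, 1] & p <= b[, 2])
  best_in <- NULL; best_in_obj <- Inf     # best converged in-box solution
  best_any <- NULL; best_any_obj <- Inf
  queue <- split(starts, row(starts))
  tried_reflect <- FALSE
  while (length(queue)) {
    fit <- refine(as.numeric(queue[[1L]])); queue[[1L]] <- NULL
    if (!fit$info %in% 1:4) next
    p <- as.numeric(fit$par); o <- sum(fit$fvec^2)
    if (o < best_any_obj) { best_any <- p; best_any_obj <- o }
    if (in_box(p) && o < best_in_obj) { best_in <- p; best_in_obj <- o }
    # an out-of-box optimum is typically the mirror solution of a
    # near-planar array: restart once from its reflection into the box
    if (!in_box(p) && !tried_reflect) {
      refl <- ifelse(p < b[, 1], 2 * b[, 1] - p,
                     ifelse(p > b[, 2], 2 * b[, 2] - p, p))
      queue[[length(queue) + 1L]] <- pmin(pmax(refl, b[, 1]), b[, 2])
      tried_reflect <- TRUE
    }
  }
  converged <- !is.null(best_any)
  clipped <- FALSE
  if (!is.null(best_in)) {
    p <- best_in
  } else if (converged) {
    p <- pmin(pmax(best_any, b[, 1]), b[, 2])
    clipped <- TRUE
  } else {
    p <- as.numeric(starts[1L, ])
    clipped <- TRUE
  }
  res <- .tdoa_residuals(p, tdoas)
  list(position = p,
       residual_rms = sqrt(mean(res^2)),
       n_receivers = length(tdoas$dt),
       converged = converged,
       clipped = clipped,
       near_coplanar = near_coplanar)
}

#' Exhaustive grid oracle for the TDOA objective
#'
#' Minimises the identical objective as [solve_position()] by brute-force
#' evaluation over a regular lattice in the bounds box. Intended as an
#' independent verification oracle in tests, not for production tracking.
#'
#' @param tdoas a `tdoa_set`
#' @param config a [loc_config()]
#' @param resolution lattice spacing, m
#' @return list with `position` (lattice point of minimum objective) and
#'   `objective`
#' @export
grid_oracle <- function(tdoas, config = loc_config(), resolution = 1) {
  stopifnot(resolution > 0)
  tdoas$c_sound <- config$c_sound
  b <- config$bounds
  ax <- lapply(1:3, function(k) seq(b[k, 1], b[k, 2], by = resolution))
  best <- NULL; best_obj <- Inf
  for (z in ax[[3]]) {
    g <- as.matrix(expand.grid(ax[[1]], ax[[2]]))
    pts <- cbind(g, z)
    o <- apply(pts, 1L, function(p) sum(.tdoa_residuals(p, tdoas)^2))
    k <- which.min(o)
    if (o[k] < best_obj) { best_obj <- o[k]; best <- pts[k, ] }
  }
  list(position = as.numeric(best), objective = best_obj)
}

#' Localize every multi-receiver message of one tag
#'
#' Attempts one localization per message detected on at least four
#' receivers with known positions; messages with fewer receivers and
#' non-converged solutions are counted for tracking-efficiency
#' accounting. Output rows are time-ordered.
#'
#' @param messages a message data.frame (see [group_messages()]) with
#'   columns `tag_id`, `time`, `message_id`
#' @param decodes the decode table the messages were built from, columns
#'   `receiver`, `tag_id`, `time`, `message_id`
#' @param phones data.frame with columns `receiver`, `x`, `y`, `z`
#' @param config a [loc_config()]
#' @return list with `points` (data.frame: tag_id, message_id, time
#'   (estimated emission time), x, y, z, residual_rms, n_receivers) and
#'   `stats` (attempted, localized, skipped_few_receivers, failed)
#' @export
track_tag <- function(messages, decodes, phones, config = loc_config()) {
  messages <- messages[order(messages$time), , drop = FALSE]
  pos_lookup <- phones[match(decodes$receiver, phones$receiver),
                       c("x", "y", "z")]
  rows <- vector("list", nrow(messages))
  skipped <- 0L; failed <- 0L
  for (i in seq_len(nrow(messages))) {
    sel <- which(decodes$message_id == messages$message_id[i])
    if (length(sel) < 4L || anyNA(pos_lookup[sel, 1])) { skipped <- skipped + 1L; next }
    td <- message_tdoas(decodes$time[sel], pos_lookup[sel, , drop = FALSE],
                        config$c_sound)
    sol <- solve_position(td, config)
    if (!sol$converged) { failed <- failed + 1L; next }
    # timestamp at the estimated emission time: the solved position is
    # where the tag transmitted, not where it was at first arrival
    r_ref <- sqrt(sum((sol$position -
                         unlist(pos_lookup[sel, ][td$ref, ]))^2))
    t_emit <- min(decodes$time[sel]) - r_ref / config$c_sound
    rows[[i]] <- data.frame(
      tag_id = messages$tag_id[i], message_id = messages$message_id[i],
      time = t_emit,
      x = sol$position[1], y = sol$position[2], z = sol$position[3],
      residual_rms = sol$residual_rms, n_receivers = sol$n_receivers)
  }
  pts <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(pts))
    pts <- data.frame(tag_id = character(), message_id = integer(),
                      time = numeric(), x = numeric(),
                      y = numeric(), z = numeric(), residual_rms = numeric(),
                      n_receivers = integer())
  list(points = pts,
       stats = c(attempted = nrow(messages),
                 localized = nrow(pts),
                 skipped_few_receivers = skipped,
                 failed = failed))
}
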