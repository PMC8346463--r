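#' @title Dam passage-route assignment
#'
#' @description
#' Assigns the passage route of each tagged fish through a dam at three
#' levels: main route (powerhouse, spillway, or the generic "dam"),
#' subroute (turbine / JBS for the powerhouse; regular spillbay /
#' surface spill weir for the spillway), and the specific passage hole
#' (turbine intake or spillbay). Two independent methods are
#' implemented -- the last 3-D tracked position within a box at the dam
#' face, and pier-averaging of the last multi-hydrophone detection --
#' together with their reconciliation, PIT-based juvenile-bypass-system
#' (JBS) subroute assignment, and a dam-operations cross-check.
#'
#' @name routing
NULL

#' Dam passage geometry
#'
#' Describes a dam's bays in dam-local coordinates. Bays are held in a
#' single south-to-north physical order along the Y axis; `hole` labels
#' follow each dam's published numbering direction (e.g. at LGS both
#' turbines and spillbays are numbered south to north, at LMN turbines
#' are numbered north to south). Bay `b` is flanked by piers `b` and
#' `b + 1`; hydrophone `pier_id`s refer to this pier numbering.
#'
#' @param dam dam name ("LGS", "LMN", or any label for synthetic
#'   geometries)
#' @param holes character vector of hole labels in physical
#'   south-to-north order (prefix T = turbine, B = spillbay)
#' @param bay_width bay width along Y, m (single number or per bay)
#' @param y0 Y coordinate of the southern edge of the first bay, m
#' @param weir_bays hole labels operated as surface spill weirs
#' @return object of class `dam_geometry` with `bays` data.frame
#'   (index, hole, y_lo, y_hi, class) and `piers` data.frame (pier_id,
#'   y)
#' @export
dam_geometry <- function(dam, holes, bay_width = 30, y0 = 0,
                         weir_bays = character(0)) {
  n <- length(holes)
  w <- rep(bay_width, length.out = n)
  edges <- y0 + c(0, cumsum(w))
  bays <- data.frame(index = seq_len(n), hole = holes,
                     y_lo = edges[-(n + 1L)], y_hi = edges[-1L],
                     class = ifelse(startsWith(holes, "T"), "powerhouse",
                                    "spillway"),
                     stringsAsFactors = FALSE)
  piers <- data.frame(pier_id = seq_len(n + 1L), y = edges)
  structure(list(dam = dam, bays = bays, piers = piers,
                 weir_bays = weir_bays),
            class = "dam_geometry")
}

#' Built-in geometries for the two instrumented dams
#'
#' Little Goose (LGS): six turbine intakes T01-T06 numbered south to
#' north followed by seven spillbays B01-B07 numbered south to north,
#' with the surface spill weir in B01. Lower Monumental (LMN): the same
#' physical arrangement but turbines numbered north to south and the
#' weir in B08 (the spillbay sequence carries eight labels with B08 the
#' weir bay). Bay widths are nominal; real analyses fit geometry from
#' the hydrophone configuration.
#'
#' @param dam "LGS" or "LMN"
#' @param bay_width nominal bay width, m
#' @return a [dam_geometry()]
#' @export
standard_dam_geometry <- function(dam = c("LGS", "LMN"), bay_width = 30) {
  dam <- match.arg(dam)
  if (dam == "LGS") {
    holes <- c(sprintf("T%02d", 1:6), sprintf("B%02d", 1:7))
    weir <- "B01"
  } else {
    holes <- c(sprintf("T%02d", 6:1), sprintf("B%02d", 1:8))
    weir <- "B08"
  }
  dam_geometry(dam, holes, bay_width = bay_width, weir_bays = weir)
}

# assemble a route assignment row, deriving main route and subroute
.route_row <- function(tag_id, method, geometry, bay_index,
                       review = FALSE, reason = NA_character_) {
  if (is.na(bay_index))
    return(data.frame(tag_id = tag_id, method = method, route = "dam",
                      subroute = "N/A", hole = "N/A",
                      bay_index = NA_integer_, review = review,
                      reason = reason, stringsAsFactors = FALSE))
  b <- geometry$bays[bay_index, ]
  sub <- if (b$class == "powerhouse") "turbine"
  else if (b$hole %in% geometry$weir_bays) "spillway_weir"
  else "regular_spillway"
  data.frame(tag_id = tag_id, method = method, route = b$class,
             subroute = sub, hole = b$hole, bay_index = b$index,
             review = review, reason = reason, stringsAsFactors = FALSE)
}

#' Route assignment from the last 3-D tracked position
#'
#' Tests whether the last cleaned, QA-trimmed track point lies within
#' the assignment box: the full dam width plus `margin_side` on each
#' side in Y, from the dam face (X = 0) to `depth_upstream` into the
#' forebay. Inside the box, the hole is the bay whose Y interval
#' contains the point; a point beyond the outermost piers (but within
#' the side margin) is assigned to the nearest bay. Outside the box, no
#' assignment is made.
#'
#' @param trajectory cleaned track data.frame (time, x, y, z),
#'   time-ordered
#' @param geometry a [dam_geometry()]
#' @param tag_id tag identifier for the output row
#' @param margin_side side margin beyond the outer piers, m
#' @param depth_upstream upstream extent of the box, m
#' @return one-row route data.frame, or NULL when no assignment can be
#'   made
#' @export
route_from_track <- function(trajectory, geometry, tag_id = NA_integer_,
                             margin_side = 25, depth_upstream = 30) {
  if (is.null(trajectory) || nrow(trajectory) == 0L) return(NULL)
  last <- trajectory[nrow(trajectory), ]
  y_min <- min(geometry$piers$y) - margin_side
  y_max <- max(geometry$piers$y) + margin_side
  if (last$x < 0 || last$x > depth_upstream ||
      last$y < y_min || last$y > y_max) return(NULL)
  bay <- which(geometry$bays$y_lo <= last$y & last$y < geometry$bays$y_hi)
  if (!length(bay)) {   # outside the piers but within the margin
    mid <- (geometry$bays$y_lo + geometry$bays$y_hi) / 2
    bay <- which.min(abs(mid - last$y))
  }
  .route_row(tag_id, "track3d", geometry, bay[1L])
}

#' Route assignment from the last multi-pier detection
#'
#' Uses the last message detected by hydrophones on at least two
#' distinct piers. Its decodes are sorted by time and the pier numbers
#' of the first two hydrophones on different piers are averaged. Bay
#' `b` lies between piers `b` and `b + 1`, so a half-integer average
#' pier maps uniquely to the bay it flanks; an integer average (the
#' transmission straddled a bay symmetrically) is tie-broken to the
#' lower-indexed bay.
#'
#' @param decodes decode data.frame of one tag with columns receiver,
#'   time, message_id
#' @param phones hydrophone table with receiver and pier_id columns
#' @param geometry a [dam_geometry()]
#' @param tag_id tag identifier
#' @return one-row route data.frame, or NULL when no message spans two
#'   piers
#' @export
route_from_last_detection <- function(decodes, phones, geometry,
                                      tag_id = NA_integer_) {
  if (is.null(decodes) || nrow(decodes) == 0L) return(NULL)
  decodes$pier_id <- phones$pier_id[match(decodes$receiver, phones$receiver)]
  multi <- tapply(decodes$pier_id, decodes$message_id,
                  function(p) length(unique(p)) >= 2L)
  cand <- names(multi)[multi]
  if (!length(cand)) return(NULL)
  last_t <- vapply(cand, function(m)
    min(decodes$time[decodes$message_id == m]), numeric(1L))
  mid <- cand[which.max(last_t)]
  d <- decodes[decodes$message_id == mid, , drop = FALSE]
  d <- d[order(d$time), ]
  first_two <- d[!duplicated(d$pier_id), ][1:2, ]
  avg <- mean(first_two$pier_id)
  bay <- if (avg %% 1 == 0) avg - 1L else floor(avg)
  bay <- max(1L, min(nrow(geometry$bays), as.integer(bay)))
  .route_row(tag_id, "last_detection", geometry, bay)
}

#' Reconcile the two route-assignment methods
#'
#' The 3-D tracked assignment is the default. A review flag is raised
#' when the two methods disagree on the main route, on the subroute, or
#' assign holes more than two bays apart; flagged cases still carry the
#' default assignment with the disagreement recorded (resolution is a
#' manual step outside this pipeline).
#'
#' @param r_track route row from [route_from_track()] (or NULL)
#' @param r_last route row from [route_from_last_detection()] (or NULL)
#' @param geometry a [dam_geometry()]
#' @return one-row route data.frame with method "reconciled"; error if
#'   both inputs are NULL
#' @export
reconcile_routes <- function(r_track, r_last, geometry) {
  if (is.null(r_track) && is.null(r_last))
    stop("no method produced an assignment")
  base <- if (!is.null(r_track)) r_track else r_last
  out <- base
  out$method <- "reconciled"
  if (!is.null(r_track) && !is.null(r_last)) {
    reasons <- character(0)
    if (r_track$route != r_last$route) reasons <- c(reasons, "main_route")
    if (r_track$subroute != r_last$subroute) reasons <- c(reasons, "subroute")
    if (!is.na(r_track$bay_index) && !is.na(r_last$bay_index) &&
        abs(r_track$bay_index - r_last$bay_index) > 2L)
      reasons <- c(reasons, "hole_distance")
    if (length(reasons)) {
      out$review <- TRUE
      out$reason <- paste(reasons, collapse = ";")
    }
  }
  out
}

#' PIT-based JBS subroute assignment
#'
#' A powerhouse-assigned fish whose PIT tag was read inside the dam's
#' juvenile bypass system is reassigned the JBS subroute; a powerhouse
#' fish without such a detection keeps (or receives) the turbine
#' subroute. Spillway assignments are untouched.
#'
#' @param assignments route data.frame (one row per tag) with route and
#'   subroute columns
#' @param pit data.frame of PIT detections with tag_id and site columns
#' @param jbs_sites character vector: PIT site labels that are this
#'   dam's JBS detectors
#' @return updated assignments
#' @export
apply_pit_jbs <- function(assignments, pit, jbs_sites) {
  ph <- assignments$route == "powerhouse"
  jbs_tags <- unique(pit$tag_id[pit$site %in% jbs_sites])
  assignments$subroute[ph] <-
    ifelse(assignments$tag_id[ph] %in% jbs_tags, "JBS", "turbine")
  assignments
}

#' Dam-operations quality-assurance check
#'
#' Compares each assignment with the dam-operations record. Assignment
#' to a bay closed at passage time is flagged, with the nearest open
#' bay suggested; nothing is silently reassigned. Times not covered by
#' the operations table produce a coverage warning.
#'
#' @param assignments route data.frame with hole, bay_index and
#'   `passage_time` columns
#' @param operations data.frame with hole, open_from, open_to (s)
#' @param geometry a [dam_geometry()]
#' @return assignments with `ops_flag` and `suggested_hole` columns
#' @export
operations_qa <- function(assignments, operations, geometry) {
  assignments$ops_flag <- NA_character_
  assignments$suggested_hole <- NA_character_
  for (i in seq_len(nrow(assignments))) {
    h <- assignments$hole[i]; tm <- assignments$passage_time[i]
    if (is.na(h) || h == "N/A" || is.na(tm)) next
    rows <- operations[operations$hole == h, , drop = FALSE]
    covered <- rows[rows$open_from <= tm & tm <= rows$open_to, ,
                    drop = FALSE]
    any_cover <- any(operations$open_from <= tm & tm <= operations$open_to)
    if (!any_cover) {
      assignments$ops_flag[i] <- "no_operations_coverage"
      next
    }
    open <- nrow(covered) > 0L && any(covered$open)
    if (!open) {
      assignments$ops_flag[i] <- "assigned_to_closed_bay"
      open_now <- operations$hole[operations$open &
                                    operations$open_from <= tm &
                                    tm <= operations$open_to]
      if (length(open_now)) {
        bi <- assignments$bay_index[i]
        cand <- geometry$bays[geometry$bays$hole %in% open_now, ]
        assignments$suggested_hole[i] <-
          cand$hole[which.min(abs(cand$index - bi))]
      }
    }
  }
  assignments
}

#' Validate a route/subroute/hole triple against a dam's taxonomy
#'
#' @param route main route
#' @param subroute subroute
#' @param hole hole label
#' @param geometry a [dam_geometry()]
#' @return TRUE or a character message describing the violation
#' @export
validate_route <- function(route, subroute, hole, geometry) {
  if (route == "dam")
    return(if (subroute == "N/A" && hole == "N/A") TRUE
           else "main route 'dam' carries N/A subroute and hole")
  b <- geometry$bays[geometry$bays$hole == hole, ]
  if (nrow(b) == 0L)
    return(paste0("hole ", hole, " not in the ", geometry$dam, " taxonomy"))
  if (b$class != route)
    return(paste0("hole ", hole, " is not a ", route, " hole"))
  # a surface weir resides within one of the spillbays, so its bay label
  # admits both spillway subroutes
  ok_sub <- if (route == "powerhouse") c("turbine", "JBS")
  else if (hole %in% geometry$weir_bays) c("regular_spillway",
                                           "spillway_weir")
  else "regular_spillway"
  if (!subroute %in% ok_sub)
    return(paste0("subroute ", subroute, " invalid for hole ", hole))
  TRUE
}
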