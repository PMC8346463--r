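#' @title End-to-end pipeline and configuration
#'
#' @description
#' Runs the full processing chain on simulated (or supplied) data:
#' simulate -> filter -> track -> route -> validate, with a structured
#' log of record counts in and out of every filter stage. All
#' parameters live in a single configuration list (serialisable as
#' YAML) with defaults matching the published processing rules; every
#' run is deterministic given the configuration's seed.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @param seed master RNG seed
#' @return nested configuration list
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    t_base = 1370000000,                      # epoch s of simulation zero
    dam = "LGS",
    frame = list(origin = c(3e5, 1e5, 150), theta = 0.5),
    array = list(n_piers = 14L, pier_spacing = 30, depths = c(-2, -12)),
    fish = list(n_tags = 5L, pri = 4.2, pri_jitter_sd = 0.02,
                duration = 900, mean_speed = 0.3,
                start_x = 120, start_z = -5),
    model = list(temp_c = 15, sigma_t = 1e-5, p_multipath = 0.2,
                 fp_rate = 0.02, p_mimic = 0),
    filters = list(multipath_window = 0.3, pri_tolerance = 0.2,
                   min_messages = 4L, k_max = 12L),
    solver = list(bounds = rbind(c(0, 200), c(-60, 480), c(-30, 2)),
                  grid_n = 5L),
    cleaning = list(max_jump = 45, max_gap = 600, max_speed = 2,
                    min_fragment = 3L),
    routing = list(margin_side = 25, depth_upstream = 30, bay_width = 30),
    survey = list(bay_y = c(45, 195, 345), max_range = 150, speed = 0.28,
                  pri = 3, tag_depth = -1.5, gps_noise_sd = 0.03,
                  bin_width = 10)
  )
}

#' Load a YAML configuration file over the defaults
#'
#' @param path YAML file; keys present override [default_config()]
#' @return configuration list
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = if (!is.null(user$seed)) user$seed else 1L)
  deep_merge <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        deep_merge(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  cfg <- deep_merge(cfg, user)
  if (!is.null(cfg$solver$bounds) && !is.matrix(cfg$solver$bounds))
    cfg$solver$bounds <- matrix(unlist(cfg$solver$bounds), ncol = 2,
                                byrow = TRUE)
  cfg
}

.log_stage <- function(log, stage, n_in, n_out) {
  message(sprintf("[%s] %d -> %d", stage, n_in, n_out))
  rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out))
}

#' Run the pipeline
#'
#' Simulates a cohort of tagged fish moving through the forebay of an
#' instrumented dam, processes the decodes through the filter cascade,
#' localizes and cleans 3-D tracks, assigns passage routes, and runs
#' the GPS-referenced validation survey. Outputs are written to
#' `out_dir` in the data-record CSV schemas.
#'
#' @param config configuration list ([default_config()] /
#'   [load_config()])
#' @param out_dir output directory (created if absent)
#' @param stages character vector of stages to run; "all" runs
#'   everything
#' @return invisible list with the main intermediate objects and the
#'   per-stage count log
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile(),
                         stages = "all") {
  if ("all" %in% stages)
    stages <- c("simulate", "filter", "track", "route", "validate")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- data.frame(stage = character(), n_in = integer(),
                    n_out = integer())
  res <- list(config = config)
  dam <- config$dam
  geometry <- standard_dam_geometry(dam, bay_width = config$routing$bay_width)
  phones <- make_pier_array(config$array$n_piers, config$array$pier_spacing,
                            config$array$depths)
  frame <- dam_frame(config$frame$origin, config$frame$theta)
  model <- propagation_model(
    c_sound = sound_speed(config$model$temp_c),
    sigma_t = config$model$sigma_t,
    p_multipath = config$model$p_multipath,
    fp_rate = config$model$fp_rate, p_mimic = config$model$p_mimic)
  res$phones <- phones; res$geometry <- geometry; res$frame <- frame

  if ("simulate" %in% stages) {
    sim <- simulate_cohort(config, phones, geometry, model)
    res$sim <- sim
    .write_hydrophone_config(phones, frame, dam, out_dir)
    .write_tagged_fish(sim$fish, config, out_dir)
    utils::write.csv(sim$decodes, file.path(out_dir, "decodes.csv"),
                     row.names = FALSE)
    log <- .log_stage(log, "simulate", 0L, nrow(sim$decodes))
  }

  if ("filter" %in% stages) {
    sim <- res$sim
    dec <- sim$decodes
    n0 <- nrow(dec)
    dec1 <- multipath_filter(dec, config$filters$multipath_window)
    log <- .log_stage(log, "multipath_filter", n0, nrow(dec1))
    gw <- grouping_window(phones, model$c_sound, model$sigma_t)
    gm <- group_messages(dec1, gw)
    log <- .log_stage(log, "group_messages", nrow(dec1), nrow(gm$messages))
    msg <- single_detection_filter(gm$messages)
    log <- .log_stage(log, "single_detection_filter", nrow(gm$messages),
                      nrow(msg))
    pri_map <- stats::setNames(sim$fish$pri, sim$fish$tag_id)
    mp <- message_pri_filter(msg, pri_map,
                             tolerance = config$filters$pri_tolerance,
                             min_messages = config$filters$min_messages,
                             k_max = config$filters$k_max)
    log <- .log_stage(log, "message_pri_filter", nrow(msg),
                      nrow(mp$messages))
    res$messages <- mp$messages
    res$events <- mp$events
    res$grouped_decodes <- gm$decodes
    .write_cabled_events(mp, gm$decodes, out_dir, dam)
  }

  if ("track" %in% stages) {
    cfgs <- loc_config(c_sound = model$c_sound,
                       bounds = config$solver$bounds,
                       grid_n = config$solver$grid_n)
    # tracking starts from the multipath-filtered decodes, grouped
    all_pts <- list()
    for (tg in unique(res$messages$tag_id)) {
      m <- res$messages[res$messages$tag_id == tg, , drop = FALSE]
      tt <- track_tag(m, res$grouped_decodes, phones, cfgs)
      cl <- clean_trajectory(tt$points,
                             cleaning_config(config$cleaning$max_jump,
                                             config$cleaning$max_gap,
                                             config$cleaning$max_speed,
                                             config$cleaning$min_fragment))
      fish_row <- res$sim$fish[res$sim$fish$tag_id == tg, ]
      pts <- qa_trim(cl$points, fish_row$release_time)
      if (nrow(pts)) all_pts[[length(all_pts) + 1L]] <- pts
    }
    tracks <- if (length(all_pts)) do.call(rbind, all_pts) else NULL
    res$tracks <- tracks
    n_msg <- nrow(res$messages)
    log <- .log_stage(log, "track", n_msg,
                      if (is.null(tracks)) 0L else nrow(tracks))
    if (!is.null(tracks)) .write_tracks(tracks, frame, out_dir, dam)
  }

  if ("route" %in% stages) {
    rows <- list()
    for (tg in unique(res$messages$tag_id)) {
      tr <- res$tracks[res$tracks$tag_id == tg, , drop = FALSE]
      dec_t <- res$grouped_decodes[res$grouped_decodes$tag_id == tg, ,
                                   drop = FALSE]
      r1 <- route_from_track(tr, geometry, tg,
                             config$routing$margin_side,
                             config$routing$depth_upstream)
      r2 <- route_from_last_detection(dec_t, phones, geometry, tg)
      if (is.null(r1) && is.null(r2)) next
      rows[[length(rows) + 1L]] <- reconcile_routes(r1, r2, geometry)
    }
    routes <- if (length(rows)) do.call(rbind, rows) else NULL
    res$routes <- routes
    log <- .log_stage(log, "route", length(unique(res$messages$tag_id)),
                      if (is.null(routes)) 0L else nrow(routes))
    if (!is.null(routes)) .write_routes(routes, out_dir, dam)
  }

  if ("validate" %in% stages) {
    val <- run_survey_validation(config, phones, model)
    res$validation <- val
    utils::write.csv(val$table, file.path(out_dir, "validation_table.csv"),
                     row.names = FALSE)
    log <- .log_stage(log, "validate", length(val$survey$emissions),
                      nrow(val$err$points))
  }

  res$log <- log
  utils::write.csv(log, file.path(out_dir, "stage_log.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Simulate a cohort of tagged fish at one dam
#'
#' @param config configuration list
#' @param phones hydrophone table
#' @param geometry dam geometry
#' @param model propagation model
#' @return list: fish (tag_id, pri, release_time, true_bay), decodes,
#'   truth
#' @export
simulate_cohort <- function(config, phones, geometry, model) {
  set.seed(config$seed)
  n <- config$fish$n_tags
  tag_ids <- sample(1000:60000, n)
  y_span <- range(geometry$piers$y)
  fish <- data.frame(tag_id = tag_ids,
                     pri = config$fish$pri,
                     release_time = config$t_base - 3600,
                     pit_id = sprintf("3DD.%09d", seq_len(n)))
  all_dec <- list(); all_truth <- list(); true_bay <- integer(n)
  for (i in seq_len(n)) {
    sub_seed <- config$seed * 1000L + i
    # each fish swims from the forebay toward a chosen bay on the dam face
    target_bay <- sample(nrow(geometry$bays), 1L)
    true_bay[i] <- target_bay
    yb <- mean(unlist(geometry$bays[target_bay, c("y_lo", "y_hi")]))
    start <- c(config$fish$start_x,
               stats::runif(1, y_span[1], y_span[2]), config$fish$start_z)
    head0 <- atan2(yb - start[2], 0 - start[1])
    track <- simulate_fish_track(sub_seed, start = start,
                                 mean_speed = config$fish$mean_speed,
                                 persistence = 0.97, heading_sd = 0.2,
                                 duration = config$fish$duration,
                                 heading0 = head0)
    # stop the track once the fish reaches the dam face
    hit <- which(track$x <= 1)[1]
    if (!is.na(hit)) track <- track[seq_len(hit), , drop = FALSE]
    # steer the final approach into the target bay
    k <- nrow(track)
    tail_n <- min(k, 60L)
    wts <- seq(0, 1, length.out = tail_n)^2
    ix <- (k - tail_n + 1L):k
    track$y[ix] <- track$y[ix] * (1 - wts) + yb * wts
    track$x[ix] <- pmax(track$x[ix] * (1 - wts) + 2 * wts, 0.5)
    track$time <- track$time + config$t_base
    em <- simulate_transmissions(config$fish$pri,
                                 config$fish$pri_jitter_sd,
                                 duration = max(track$time) - config$t_base,
                                 t0 = config$t_base, seed = sub_seed + 1L)
    pd <- propagate_to_decodes(track, em, phones, model, tag_ids[i],
                               seed = sub_seed + 2L)
    all_dec[[i]] <- pd$decodes
    all_truth[[i]] <- cbind(tag_id = tag_ids[i], pd$truth)
  }
  decodes <- do.call(rbind, all_dec)
  decodes <- inject_noise(decodes, model,
                          span = config$t_base + c(0, config$fish$duration),
                          seed = config$seed + 7L)
  fish$true_bay <- true_bay
  list(fish = fish, decodes = decodes,
       truth = do.call(rbind, all_truth))
}

#' Run the GPS-referenced survey validation
#'
#' @param config configuration list
#' @param phones hydrophone table
#' @param model propagation model
#' @return list: survey, tracked points, error stats, binned table
#' @export
run_survey_validation <- function(config, phones, model) {
  sv <- config$survey
  survey <- simulate_usv_survey(phones, bay_y = sv$bay_y,
                                max_range = sv$max_range, speed = sv$speed,
                                pri = sv$pri, tag_depth = sv$tag_depth,
                                gps_noise_sd = sv$gps_noise_sd,
                                model = model, seed = config$seed)
  cfgs <- loc_config(c_sound = model$c_sound,
                     bounds = config$solver$bounds,
                     grid_n = config$solver$grid_n)
  dec <- multipath_filter(survey$decodes, config$filters$multipath_window)
  gm <- group_messages(dec, grouping_window(phones, model$c_sound,
                                            model$sigma_t))
  tt <- track_tag(gm$messages, gm$decodes, phones, cfgs)
  # estimated emission times can fall a hair outside the GPS span at the
  # transect edges; those points are expected and dropped up front
  pts <- tt$points
  pts <- pts[pts$time >= min(survey$gps$time) &
               pts$time <= max(survey$gps$time), , drop = FALSE]
  err <- error_stats(pts[, c("time", "x", "y", "z")], survey$gps)
  # per-transmission reference distances for efficiency denominators
  tx_x <- stats::approx(survey$truth$time, survey$truth$x,
                        survey$emissions, rule = 2)$y
  det_ids <- unique(dec$emission_id[!is.na(dec$emission_id)])
  # emission behind each localized message (modal member emission id)
  msg_em <- tapply(gm$decodes$emission_id, gm$decodes$message_id,
                   function(e) { e <- e[!is.na(e)]
                     if (length(e)) as.integer(names(which.max(table(e))))
                     else NA_integer_ })
  trk_ids <- unique(stats::na.omit(msg_em[as.character(pts$message_id)]))
  tab <- distance_binned_table(err$points, tx_x, tx_x[det_ids],
                               tx_x[trk_ids], bin_width = sv$bin_width)
  eff <- efficiencies(length(survey$emissions), length(det_ids),
                      nrow(tt$points))
  list(survey = survey, tracked = tt$points, err = err, table = tab,
       efficiency = eff)
}

# ---- schema-conformant writers ---------------------------------------

.write_hydrophone_config <- function(phones, frame, dam, out_dir) {
  geo <- dam_transform(as.matrix(phones[, c("x", "y", "z")]), frame,
                       "to_geo")
  df <- data.frame(
    "Sys_#" = seq_len(nrow(phones)),
    Sys_Name = sprintf("PS%d", (seq_len(nrow(phones)) + 3L) %/% 4L),
    Location = phones$receiver, Node_Position = substring(
      phones$receiver, nchar(phones$receiver)),
    Channel = (seq_len(nrow(phones)) - 1L) %% 4L + 1L,
    Phone_ID = seq_len(nrow(phones)), Pier_ID = phones$pier_id,
    Phone_Name = phones$receiver,
    "Latitude_(NAD83)" = NA_real_, "Longitude_(NAD83)" = NA_real_,
    "Easting_(m; NAD83 - WA South)" = geo[, 1],
    "Northing_(m; NAD83 - WA South)" = geo[, 2],
    "Elevation_(m AMSL)" = geo[, 3],
    "X_(m)" = phones$x, "Y_(m)" = phones$y, "Z_(m)" = phones$z,
    check.names = FALSE)
  df[["Latitude_(NAD83)"]] <- 46.5 + geo[, 2] / 111320
  df[["Longitude_(NAD83)"]] <- -118 + geo[, 1] / 76000
  write_table(df, file.path(out_dir,
                            paste0(dam, "_Hydrophone_Configuration.csv")),
              "hydrophone_config")
}

.write_tagged_fish <- function(fish, config, out_dir) {
  df <- data.frame(
    Tag_ID = fish$tag_id, PIT_ID = fish$pit_id,
    Tag_Release_Date = fish$release_time, PRI = fish$pri,
    Fish_Tagging_Date = fish$release_time - 20 * 3600,
    "Fish_Length_at_Tagging_(mm)" = 110, "Fish_Weight_at_Tagging_(g)" = 14,
    check.names = FALSE)
  write_table(df, file.path(out_dir, "Tagged_Fish_List.csv"), "tagged_fish")
}

.write_cabled_events <- function(mp, decodes, out_dir, dam) {
  if (!nrow(mp$events)) return(invisible(NULL))
  first_phone <- vapply(seq_len(nrow(mp$events)), function(i) {
    m <- mp$messages[mp$messages$tag_id == mp$events$tag_id[i] &
                       mp$messages$event_id == mp$events$event_id[i], ]
    last_msg <- m$message_id[which.max(m$time)]
    d <- decodes[decodes$message_id == last_msg, ]
    d$receiver[which.min(d$time)]
  }, character(1L))
  df <- data.frame(
    Phone_Name = first_phone, Tag_ID = mp$events$tag_id,
    Event_ID = mp$events$event_id,
    First_Computed_Datetime = mp$events$first,
    Last_Computed_Datetime = mp$events$last,
    Number_Messages = mp$events$n_messages, check.names = FALSE)
  write_table(df, file.path(out_dir, paste0(dam, "_Event_Data.csv")),
              "cabled_events")
}

.write_tracks <- function(tracks, frame, out_dir, dam) {
  geo <- dam_transform(as.matrix(tracks[, c("x", "y", "z")]), frame,
                       "to_geo")
  df <- data.frame(
    Tag_ID = tracks$tag_id, Time = tracks$time,
    "Latitude_(NAD83)" = 46.5 + geo[, 2] / 111320,
    "Longitude_(NAD83)" = -118 + geo[, 1] / 76000,
    "Easting_(m; NAD83 - WA South)" = geo[, 1],
    "Northing_(m; NAD83 - WA South)" = geo[, 2],
    "Elevation_(m AMSL)" = geo[, 3],
    "X_(m)" = tracks$x, "Y_(m)" = tracks$y, "Z_(m)" = tracks$z,
    check.names = FALSE)
  write_table(df, file.path(out_dir, paste0(dam, "_3D_Tracks.csv")),
              "tracks_3d")
}

.write_routes <- function(routes, out_dir, dam) {
  df <- data.frame(
    Tag_ID = routes$tag_id, Route = routes$route,
    Subroute = routes$subroute, Passage_Hole = routes$hole,
    Array_Name = dam, check.names = FALSE)
  write_table(df, file.path(out_dir, paste0(dam, "_Passage_Routes.csv")),
              "passage_routes")
}
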