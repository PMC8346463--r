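#' @title Typed CSV readers and writers for the data-record schemas
#'
#' @description
#' The pipeline's external interface is a set of CSV tables: hydrophone
#' configuration, autonomous receiver deployments, the tagged-fish
#' list, PIT detections, cabled and autonomous event data, 3-D tracks
#' and passage routes. Each schema is registered with its printed
#' column names and column types; readers validate the header and every
#' cell, writers enforce record invariants and guarantee a
#' field-for-field round trip.
#'
#' Datetimes travel as ISO-8601 text (a small set of common variants is
#' accepted on read and the variant used is recorded) and are held
#' internally as numeric seconds since the epoch, UTC. The deposited
#' files do not state a timezone; UTC is assumed and the input offset
#' is configurable via `tz`.
#'
#' @name core_io
NULL

.DT_FORMATS <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                 "%m/%d/%Y %H:%M:%OS", "%Y/%m/%d %H:%M:%OS", "%Y-%m-%d")

#' Parse datetime text to epoch seconds
#'
#' @param x character vector
#' @param tz timezone of the text (default UTC)
#' @return numeric epoch seconds, with attribute `format` naming the
#'   accepted variant
#' @export
parse_datetime_s <- function(x, tz = "UTC") {
  for (fmt in .DT_FORMATS) {
    p <- as.POSIXct(x, format = fmt, tz = tz)
    if (!anyNA(p[!is.na(x) & nzchar(x)])) {
      out <- as.numeric(p)
      attr(out, "format") <- fmt
      return(out)
    }
  }
  stop("unparseable datetime values, e.g. ", x[which(is.na(
    as.POSIXct(x, format = .DT_FORMATS[1], tz = tz)))[1]])
}

#' Format epoch seconds as ISO-8601 text
#'
#' @param s numeric epoch seconds
#' @param tz timezone for rendering (default UTC)
#' @param digits fractional-second digits
#' @return character vector
#' @export
format_datetime_s <- function(s, tz = "UTC", digits = 3) {
  format(as.POSIXct(s, origin = "1970-01-01", tz = tz),
         format = paste0("%Y-%m-%d %H:%M:%OS", digits), tz = tz)
}

# ---- schema registry --------------------------------------------------

# type codes: c character, i integer, d double, t datetime, x hex tag id
.SCHEMAS <- list(
  hydrophone_config = list(
    columns = c("Sys_#" = "i", "Sys_Name" = "c", "Location" = "c",
                "Node_Position" = "c", "Channel" = "i", "Phone_ID" = "i",
                "Pier_ID" = "i", "Phone_Name" = "c",
                "Latitude_(NAD83)" = "d", "Longitude_(NAD83)" = "d",
                "Easting_(m; NAD83 - WA South)" = "d",
                "Northing_(m; NAD83 - WA South)" = "d",
                "Elevation_(m AMSL)" = "d",
                "X_(m)" = "d", "Y_(m)" = "d", "Z_(m)" = "d"),
    key = "Phone_Name"),
  autonomous_deployment = list(
    columns = c("Node_ID" = "c", "Node_SN" = "c", "Latitude_(NAD83)" = "d",
                "Longitude_(NAD83)" = "d", "River Kilometer" = "d",
                "Depth_(m)" = "d", "Deploy_Date" = "t",
                "Recovery_Date" = "t", "Location_ID" = "c",
                "Start_Sample" = "t", "End_Sample" = "t", "Comments" = "c"),
    key = "Node_ID"),
  tagged_fish = list(
    columns = c("Tag_ID" = "x", "PIT_ID" = "c", "Tag_Release_Date" = "t",
                "PRI" = "d", "Fish_Tagging_Date" = "t",
                "Fish_Length_at_Tagging_(mm)" = "d",
                "Fish_Weight_at_Tagging_(g)" = "d"),
    key = "Tag_ID"),
  pit_detections = list(
    columns = c("Tag_ID" = "x", "PIT_ID" = "c", "First_PIT_Datetime" = "t",
                "Last_PIT_Datetime" = "t", "PIT_Site" = "c",
                "PIT_Site_Description" = "c", "PIT_Site_Basin" = "c",
                "PIT_Site_Subbasin" = "c", "PIT_Site_Type" = "c",
                "PIT_Site_Latitude_(NAD83)" = "d",
                "PIT_Site_Longitude_(NAD83)" = "d", "PIT_Site_RKM" = "d",
                "Fish_Characteristics_at_Tagging" = "c",
                "PIT_Tagging_Date" = "t",
                "Fish_Length_at_Tagging_(mm)" = "d",
                "Fish_Weight_at_Tagging_(g)" = "d"),
    key = NULL),
  cabled_events = list(
    columns = c("Phone_Name" = "c", "Tag_ID" = "x", "Event_ID" = "i",
                "First_Computed_Datetime" = "t",
                "Last_Computed_Datetime" = "t", "Number_Messages" = "i"),
    key = NULL),
  autonomous_events = list(
    columns = c("Node_ID" = "c", "Tag_ID" = "x",
                "First_Computed_Datetime" = "t",
                "Last_Computed_Datetime" = "t", "Number_Messages" = "i"),
    key = NULL),
  tracks_3d = list(
    columns = c("Tag_ID" = "x", "Time" = "t", "Latitude_(NAD83)" = "d",
                "Longitude_(NAD83)" = "d",
                "Easting_(m; NAD83 - WA South)" = "d",
                "Northing_(m; NAD83 - WA South)" = "d",
                "Elevation_(m AMSL)" = "d",
                "X_(m)" = "d", "Y_(m)" = "d", "Z_(m)" = "d"),
    key = NULL),
  passage_routes = list(
    columns = c("Tag_ID" = "x", "Route" = "c", "Subroute" = "c",
                "Passage_Hole" = "c", "Array_Name" = "c"),
    key = NULL)
)

# deposited file name -> schema
.FILE_SCHEMA <- c(
  "Autonomous_Receiver_Deployment_Data.csv" = "autonomous_deployment",
  "LGS_Hydrophone_Configuration.csv" = "hydrophone_config",
  "LMN_Hydrophone_Configuration.csv" = "hydrophone_config",
  "Tagged_Fish_List.csv" = "tagged_fish",
  "PIT_Detection_Data.csv" = "pit_detections",
  "LGS_Event_Data.csv" = "cabled_events",
  "LMN_Event_Data.csv" = "cabled_events",
  "Autonomous_Receiver_Event_Data.csv" = "autonomous_events",
  "LGS_3D_Tracks.csv" = "tracks_3d",
  "LMN_3D_Tracks.csv" = "tracks_3d",
  "LGS_Passage_Routes.csv" = "passage_routes",
  "LMN_Passage_Routes.csv" = "passage_routes")

#' List registered schemas or resolve one
#'
#' @param name schema name, or a deposited file name (with or without
#'   path); NULL lists all schema names
#' @return schema definition (list with `columns`, `key`), or character
#'   vector of names
#' @export
schema <- function(name = NULL) {
  if (is.null(name)) return(names(.SCHEMAS))
  if (name %in% names(.SCHEMAS)) return(.SCHEMAS[[name]])
  fn <- basename(name)
  if (fn %in% names(.FILE_SCHEMA)) return(.SCHEMAS[[.FILE_SCHEMA[[fn]]]])
  stop("unknown schema or file name: ", name)
}

#' @rdname schema
#' @export
schema_for_file <- function(name) {
  fn <- basename(name)
  if (!fn %in% names(.FILE_SCHEMA)) stop("no schema registered for ", fn)
  .FILE_SCHEMA[[fn]]
}

# header names normalised for comparison (whitespace/underscore variants)
.norm_col <- function(x) {
  x <- gsub("–|—", "-", x)   # en/em dash variants of the hyphen
  gsub("[ _]+", "_", trimws(x))
}

#' Read a typed data-record CSV
#'
#' Validates the header against the registered schema (column-name
#' whitespace/underscore variants are tolerated), parses each column to
#' its registered type (datetimes to epoch seconds UTC, tag ids from
#' 4-hex-digit text to integers), and reports unparseable cells with
#' their line numbers.
#'
#' @param path file path
#' @param schema_name schema name; inferred from the file name when
#'   omitted
#' @param tz timezone of datetime text
#' @return data.frame with internal column names equal to the printed
#'   headers; attribute `schema` names the schema used
#' @export
read_table <- function(path, schema_name = NULL, tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(schema_name)) schema_name <- schema_for_file(path)
  sc <- schema(schema_name)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = character(0))
  want <- names(sc$columns)
  have_norm <- .norm_col(names(raw)); want_norm <- .norm_col(want)
  missing <- want[!want_norm %in% have_norm]
  extra <- names(raw)[!have_norm %in% want_norm]
  if (length(missing))
    stop("schema '", schema_name, "': missing column(s) ",
         paste(missing, collapse = ", "))
  if (length(extra))
    stop("schema '", schema_name, "': unexpected column(s) ",
         paste(extra, collapse = ", "))
  out <- raw[match(want_norm, have_norm)]
  names(out) <- want
  for (j in seq_along(want)) {
    ty <- sc$columns[[j]]
    v <- out[[j]]
    out[[j]] <- switch(
      ty,
      c = v,
      i = {
        r <- suppressWarnings(as.integer(v))
        bad <- which(is.na(r) & nzchar(v))
        if (length(bad)) stop("column '", want[j], "', line ", bad[1] + 1L,
                              ": cannot parse '", v[bad[1]], "' as integer")
        r
      },
      d = {
        r <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(r) & nzchar(v))
        if (length(bad)) stop("column '", want[j], "', line ", bad[1] + 1L,
                              ": cannot parse '", v[bad[1]], "' as numeric")
        r
      },
      t = if (length(v)) as.numeric(parse_datetime_s(v, tz)) else numeric(0),
      x = {
        r <- suppressWarnings(parse_tag_id(v))
        bad <- which(is.na(r) & nzchar(v))
        if (length(bad)) stop("column '", want[j], "', line ", bad[1] + 1L,
                              ": cannot parse '", v[bad[1]], "' as tag id")
        r
      })
  }
  attr(out, "schema") <- schema_name
  out
}

# ---- record invariants per schema ------------------------------------

.check_records <- function(records, schema_name) {
  bad <- function(i, msg) stop("record ", i, ": ", msg)
  n <- nrow(records)
  if (schema_name == "hydrophone_config") {
    if (anyDuplicated(records[["Phone_Name"]]))
      stop("duplicate Phone_Name values")
    for (i in seq_len(n)) {
      if (records[["Pier_ID"]][i] < 0) bad(i, "Pier_ID must be >= 0")
      if (!all(is.finite(unlist(records[i, c("X_(m)", "Y_(m)", "Z_(m)")]))))
        bad(i, "dam-local coordinates must be finite")
    }
  } else if (schema_name == "autonomous_deployment") {
    for (i in seq_len(n)) {
      if (records[["Deploy_Date"]][i] >= records[["Recovery_Date"]][i])
        bad(i, "deploy must precede recovery")
      if (records[["Start_Sample"]][i] < records[["Deploy_Date"]][i])
        bad(i, "sampling cannot start before deployment")
    }
  } else if (schema_name == "tagged_fish") {
    for (i in seq_len(n)) {
      if (records[["PRI"]][i] <= 0) bad(i, "PRI must be positive")
      if (records[["Fish_Tagging_Date"]][i] > records[["Tag_Release_Date"]][i])
        bad(i, "tagging must not follow release")
    }
  } else if (schema_name %in% c("cabled_events", "autonomous_events")) {
    for (i in seq_len(n)) {
      if (records[["First_Computed_Datetime"]][i] >
          records[["Last_Computed_Datetime"]][i])
        bad(i, "event first datetime after last")
      if (records[["Number_Messages"]][i] < 1L)
        bad(i, "event must contain at least one message")
    }
  } else if (schema_name == "passage_routes") {
    for (i in seq_len(n)) {
      dam <- records[["Array_Name"]][i]
      if (dam %in% c("LGS", "LMN")) {
        ok <- validate_route(records[["Route"]][i], records[["Subroute"]][i],
                             records[["Passage_Hole"]][i],
                             standard_dam_geometry(dam))
        if (!isTRUE(ok)) bad(i, ok)
      }
    }
  }
  invisible(TRUE)
}

#' Write a typed data-record CSV
#'
#' Checks the schema invariants of `records` (rejecting with the
#' offending record index), then writes RFC-4180 CSV, UTF-8, with the
#' printed column headers; datetimes are rendered as ISO-8601 with
#' millisecond precision and tag ids as 4-hex-digit uppercase.
#' `read_table(write_table(r))` reproduces `r` field for field (with
#' datetimes at the rendered precision).
#'
#' @param records data.frame in internal representation (as produced by
#'   [read_table()] or the pipeline)
#' @param path output path
#' @param schema_name schema name; inferred from the file name when
#'   omitted
#' @return `path`, invisibly
#' @export
write_table <- function(records, path, schema_name = NULL) {
  if (is.null(schema_name)) schema_name <- schema_for_file(path)
  sc <- schema(schema_name)
  want <- names(sc$columns)
  if (!all(.norm_col(want) %in% .norm_col(names(records))))
    stop("records lack required columns for schema '", schema_name, "'")
  records <- records[match(.norm_col(want), .norm_col(names(records)))]
  names(records) <- want
  .check_records(records, schema_name)
  out <- records
  for (j in seq_along(want)) {
    ty <- sc$columns[[j]]
    if (ty == "t") out[[j]] <- format_datetime_s(out[[j]])
    if (ty == "x") out[[j]] <- format_tag_id(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
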