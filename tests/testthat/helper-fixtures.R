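# Shared fixtures and independent oracles for the test suite.

# Independent CRC-8 oracle: polynomial long division over GF(2) on the
# message polynomial times x^8, written without any of the package's
# bit helpers.
oracle_crc8 <- function(bits, poly_bits = c(1, 0, 0, 0, 0, 0, 1, 1, 1)) {
  reg <- c(as.integer(bits), integer(8))
  for (i in seq_len(length(reg) - 8L)) {
    if (reg[i] == 1L)
      reg[i:(i + 8L)] <- xor(reg[i:(i + 8L)], poly_bits) * 1L
  }
  sum(reg[(length(reg) - 7L):length(reg)] * 2^(7:0))
}

int_to_bits <- function(x, width)
  as.integer(rev(as.integer(intToBits(x))[seq_len(width)]))

# Small 3-D receiver cluster with genuine spatial extent in every axis
# (well-conditioned localization test geometry).
cube_array <- function() {
  data.frame(
    receiver = sprintf("H%d", 1:8),
    pier_id = rep(1:4, each = 2),
    x = c(0, 0, 0, 0, 20, 20, 20, 20),
    y = c(0, 60, 120, 30, 0, 60, 120, 90),
    z = c(-2, -12, -2, -12, -3, -11, -2, -12))
}

# Pier-line array matching the cabled dam-face deployment geometry.
pier_array <- function(n_piers = 8L) make_pier_array(n_piers = n_piers)

# Noiseless TDOA set from a known source.
noiseless_tdoas <- function(src, phones, c_sound = 1482) {
  ph <- as.matrix(phones[, c("x", "y", "z")])
  d <- sqrt(colSums((t(ph) - src)^2))
  message_tdoas(d / c_sound, ph, c_sound)
}

# Synthetic valid records for each writable schema (round-trip tests).
fixture_records <- function(schema_name, t0 = 1370000000) {
  switch(
    schema_name,
    tracks_3d = data.frame(
      Tag_ID = c(4660L, 4660L, 301L),
      Time = t0 + c(0, 4.2, 8.4),
      "Latitude_(NAD83)" = c(46.58, 46.581, 46.582),
      "Longitude_(NAD83)" = c(-118.02, -118.021, -118.022),
      "Easting_(m; NAD83 - WA South)" = c(3e5, 3e5 + 1, 3e5 + 2),
      "Northing_(m; NAD83 - WA South)" = c(1e5, 1e5 + 1, 1e5 + 2),
      "Elevation_(m AMSL)" = c(150, 150.5, 151),
      "X_(m)" = c(10, 11, 12), "Y_(m)" = c(50, 51, 52),
      "Z_(m)" = c(-5, -5.5, -6), check.names = FALSE),
    cabled_events = data.frame(
      Phone_Name = c("P01D", "S03S"), Tag_ID = c(4660L, 301L),
      Event_ID = 1:2, First_Computed_Datetime = t0 + c(0, 100),
      Last_Computed_Datetime = t0 + c(50, 160),
      Number_Messages = c(12L, 5L), check.names = FALSE),
    passage_routes = data.frame(
      Tag_ID = c(4660L, 301L), Route = c("spillway", "powerhouse"),
      Subroute = c("regular_spillway", "turbine"),
      Passage_Hole = c("B03", "T02"), Array_Name = c("LGS", "LGS"),
      check.names = FALSE),
    tagged_fish = data.frame(
      Tag_ID = c(4660L, 301L), PIT_ID = c("3DD.000001", "3DD.000002"),
      Tag_Release_Date = t0 + c(0, 10), PRI = c(4.2, 4.2),
      Fish_Tagging_Date = t0 - 72000 + c(0, 10),
      "Fish_Length_at_Tagging_(mm)" = c(104, 121),
      "Fish_Weight_at_Tagging_(g)" = c(10.2, 15.8), check.names = FALSE),
    stop("no fixture for schema ", schema_name))
}
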