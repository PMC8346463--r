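test_that("standard geometries carry the published hole taxonomy", {
  lgs <- standard_dam_geometry("LGS")
  expect_identical(lgs$bays$hole,
                   c(sprintf("T%02d", 1:6), sprintf("B%02d", 1:7)))
  expect_identical(lgs$weir_bays, "B01")
  lmn <- standard_dam_geometry("LMN")
  expect_identical(lmn$bays$hole[1:6], sprintf("T%02d", 6:1))
  expect_identical(lmn$weir_bays, "B08")
  expect_identical(nrow(lmn$bays), 14L)
  # bays tile the dam face without gaps; piers sit on bay edges
  expect_equal(lgs$bays$y_lo[-1], lgs$bays$y_hi[-13])
  expect_identical(nrow(lgs$piers), 14L)
  expect_equal(lgs$piers$y[3], lgs$bays$y_lo[3])
})

test_that("track assignment uses the box and the containing bay", {
  g <- standard_dam_geometry("LGS")
  # LGS spillbay B03 spans y in [240, 270); a last point inside it
  tr <- data.frame(time = 1:3, x = c(40, 20, 10), y = c(250, 252, 255),
                   z = -6)
  r <- route_from_track(tr, g, tag_id = 7L)
  expect_identical(r$hole, "B03")
  expect_identical(r$route, "spillway")
  expect_identical(r$subroute, "regular_spillway")
  expect_false(r$review)

  # last point 40 m upstream: outside the 30 m box, no assignment
  tr2 <- tr[c(2, 3, 1), ]; tr2$time <- 1:3
  expect_null(route_from_track(tr2, g))
  # behind the dam face (x < 0) is also outside
  tr3 <- tr; tr3$x[3] <- -1
  expect_null(route_from_track(tr3, g))

  # a point within the 25 m side margin snaps to the nearest bay
  trs <- data.frame(time = 1, x = 5, y = max(g$piers$y) + 10, z = -4)
  expect_identical(route_from_track(trs, g)$hole, "B07")
  trs$y <- max(g$piers$y) + 30     # beyond the margin
  expect_null(route_from_track(trs, g))

  # a weir-bay landing carries the weir subroute
  trw <- data.frame(time = 1, x = 4, y = g$bays$y_lo[7] + 5, z = -2)
  rw <- route_from_track(trw, g)
  expect_identical(rw$hole, "B01")
  expect_identical(rw$subroute, "spillway_weir")
})

test_that("pier averaging maps detections to flanked bays", {
  g <- standard_dam_geometry("LGS")
  phones <- data.frame(receiver = sprintf("P%02d", 1:14), pier_id = 1:14)
  mk <- function(piers, times) {
    data.frame(receiver = sprintf("P%02d", piers), time = times,
               message_id = 1L)
  }
  # piers 3 and 4 first: average 3.5 -> bay 3 (between piers 3 and 4)
  r <- route_from_last_detection(mk(c(3, 4, 7), c(0, 0.01, 0.02)),
                                 phones, g, 9L)
  expect_identical(r$bay_index, 3L)
  expect_identical(r$hole, "T03")

  # integer average (piers 2 and 4 -> 3) tie-breaks to the lower bay 2
  r2 <- route_from_last_detection(mk(c(2, 4), c(0, 0.01)), phones, g)
  expect_identical(r2$bay_index, 2L)

  # the LAST multi-pier message wins, not the first
  d <- rbind(mk(c(2, 3), c(0, 0.01)), mk(c(9, 10), c(100, 100.01)))
  d$message_id <- c(1L, 1L, 2L, 2L)
  r3 <- route_from_last_detection(d, phones, g)
  expect_identical(r3$bay_index, 9L)
  expect_identical(r3$hole, "B03")

  # single-pier-only detections give no assignment
  one <- mk(c(5, 5), c(0, 0.01))
  expect_null(route_from_last_detection(one, phones, g))
  expect_null(route_from_last_detection(one[0, ], phones, g))
})

test_that("reconciliation flags main-route, subroute and distance splits", {
  g <- standard_dam_geometry("LGS")
  row_at <- function(bay, method = "track3d")
    damtel:::.route_row(1L, method, g, bay)
  # B02 vs B04: same route/subroute, two bays apart -> no flag
  rec <- reconcile_routes(row_at(8L), row_at(10L, "last_detection"), g)
  expect_false(rec$review)
  expect_identical(rec$hole, "B02")           # track method is the default
  expect_identical(rec$method, "reconciled")
  # B02 vs B05: three bays apart -> flagged
  rec2 <- reconcile_routes(row_at(8L), row_at(11L, "last_detection"), g)
  expect_true(rec2$review)
  expect_identical(rec2$reason, "hole_distance")
  # powerhouse vs spillway: main route disagreement
  rec3 <- reconcile_routes(row_at(5L), row_at(8L, "last_detection"), g)
  expect_true(rec3$review)
  expect_match(rec3$reason, "main_route")
  # weir bay vs adjacent regular bay: subroute disagreement only
  rec4 <- reconcile_routes(row_at(7L), row_at(8L, "last_detection"), g)
  expect_identical(rec4$reason, "subroute")
  # one method missing: the other is adopted unflagged
  rec5 <- reconcile_routes(NULL, row_at(9L, "last_detection"), g)
  expect_identical(rec5$hole, "B03")
  expect_false(rec5$review)
  expect_error(reconcile_routes(NULL, NULL, g), "no method")
})

test_that("PIT detections reassign powerhouse fish to the bypass", {
  g <- standard_dam_geometry("LGS")
  asg <- rbind(damtel:::.route_row(1L, "reconciled", g, 3L),
               damtel:::.route_row(2L, "reconciled", g, 4L),
               damtel:::.route_row(3L, "reconciled", g, 9L))
  pit <- data.frame(tag_id = c(1L, 3L), site = c("LGS_JBS", "LGS_JBS"))
  out <- apply_pit_jbs(asg, pit, "LGS_JBS")
  expect_identical(out$subroute, c("JBS", "turbine", "regular_spillway"))
  # a PIT read at another site does not count
  out2 <- apply_pit_jbs(asg, data.frame(tag_id = 1L, site = "GOA"),
                        "LGS_JBS")
  expect_identical(out2$subroute[1], "turbine")
})

test_that("operations QA flags closed bays but never reassigns", {
  g <- standard_dam_geometry("LGS")
  asg <- damtel:::.route_row(1L, "reconciled", g, 9L)   # B03
  asg$passage_time <- 500
  ops <- data.frame(hole = c("B03", "B04", "B02"),
                    open = c(FALSE, TRUE, FALSE),
                    open_from = 0, open_to = 1000)
  out <- operations_qa(asg, ops, g)
  expect_identical(out$ops_flag, "assigned_to_closed_bay")
  expect_identical(out$suggested_hole, "B04")
  expect_identical(out$hole, "B03")           # assignment untouched
  # open bay: no flag
  ops2 <- ops; ops2$open[1] <- TRUE
  expect_true(is.na(operations_qa(asg, ops2, g)$ops_flag))
  # passage outside the operations record: coverage warning
  asg2 <- asg; asg2$passage_time <- 5000
  expect_identical(operations_qa(asg2, ops, g)$ops_flag,
                   "no_operations_coverage")
})

test_that("route validation enforces each dam's taxonomy", {
  lgs <- standard_dam_geometry("LGS")
  lmn <- standard_dam_geometry("LMN")
  expect_true(validate_route("powerhouse", "turbine", "T05", lgs))
  expect_true(validate_route("powerhouse", "JBS", "T02", lgs))
  expect_true(validate_route("spillway", "spillway_weir", "B01", lgs))
  expect_true(validate_route("spillway", "regular_spillway", "B01", lgs))
  expect_true(validate_route("dam", "N/A", "N/A", lgs))
  expect_match(validate_route("spillway", "spillway_weir", "B03", lgs),
               "invalid")
  expect_match(validate_route("powerhouse", "turbine", "B03", lgs), "not a")
  expect_match(validate_route("spillway", "regular_spillway", "B08", lgs),
               "not in")
  expect_true(validate_route("spillway", "spillway_weir", "B08", lmn))
  expect_match(validate_route("dam", "turbine", "N/A", lgs), "N/A")
})
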