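test_that("multipath filter keeps the first decode of each burst", {
  d <- data.frame(receiver = "A", tag_id = 1L,
                  time = c(0, 0.10, 0.25, 5.0))
  expect_equal(multipath_filter(d)$time, c(0, 5.0))

  # boundary: exactly window after the kept decode is retained
  d2 <- data.frame(receiver = "A", tag_id = 1L, time = c(0, 0.3))
  expect_equal(multipath_filter(d2)$time, c(0, 0.3))
  d3 <- data.frame(receiver = "A", tag_id = 1L, time = c(0, 0.2999))
  expect_equal(multipath_filter(d3)$time, 0)

  # per-tag and per-receiver independence
  d4 <- data.frame(receiver = "A", tag_id = c(1L, 2L), time = c(0, 0.05))
  expect_identical(nrow(multipath_filter(d4)), 2L)
  d5 <- data.frame(receiver = c("A", "B"), tag_id = 1L, time = c(0, 0.05))
  expect_identical(nrow(multipath_filter(d5)), 2L)

  # idempotent, output subset of input
  once <- multipath_filter(d)
  expect_identical(multipath_filter(once), once)
})

test_that("message grouping clusters one transmission across hydrophones", {
  d <- data.frame(receiver = c("A", "B", "C", "A"), tag_id = 1L,
                  time = c(0, 0.012, 0.030, 4.2))
  g <- group_messages(d, 0.1)
  expect_identical(nrow(g$messages), 2L)
  expect_identical(g$messages$n_receivers, c(3L, 1L))
  expect_equal(g$messages$time, c(0, 4.2))

  # duplicate receiver in one cluster keeps the earliest decode
  d2 <- data.frame(receiver = c("A", "A", "B"), tag_id = 1L,
                   time = c(0, 0.02, 0.05))
  g2 <- group_messages(d2, 0.1)
  expect_identical(nrow(g2$decodes), 2L)
  expect_equal(sort(g2$decodes$time), c(0, 0.05))

  g3 <- group_messages(d[0, ], 0.1)
  expect_identical(nrow(g3$messages), 0L)
})

test_that("single-detection filter requires two hydrophones and cabled data", {
  g <- group_messages(data.frame(receiver = c("A", "B", "C"), tag_id = 1L,
                                 time = c(0, 0.01, 4.2)), 0.1)
  kept <- single_detection_filter(g$messages)
  expect_identical(kept$n_receivers, 2L)
  expect_identical(nrow(single_detection_filter(g$messages[0, ])), 0L)
  expect_error(single_detection_filter(g$messages, source = "autonomous"),
               "cabled")
})

test_that("PRI filter keeps lattice-consistent messages and builds events", {
  pf <- pri_filter(c(0, 4.2, 8.4, 12.6), 4.2, 0.2, min_messages = 4L)
  expect_true(all(pf$accepted))
  expect_identical(nrow(pf$events), 1L)
  expect_identical(pf$events$n_messages, 4L)

  # off-lattice intruder removed, event retains its four members
  pf2 <- pri_filter(c(0, 4.2, 6.1, 8.4, 12.6), 4.2, 0.2, min_messages = 4L)
  expect_identical(pf2$accepted, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_identical(pf2$events$n_messages, 4L)

  # below min_messages: no event at all
  pf3 <- pri_filter(c(0, 4.2), 4.2, 0.2, min_messages = 4L)
  expect_identical(nrow(pf3$events), 0L)
  expect_false(any(pf3$accepted))

  # long gap splits into two events
  tms <- c(0, 4.2, 8.4, 12.6, 1000, 1004.2, 1008.4, 1012.6)
  pf4 <- pri_filter(tms, 4.2, 0.2, min_messages = 4L)
  expect_identical(nrow(pf4$events), 2L)
  expect_equal(pf4$events$first, c(0, 1000))

  expect_identical(nrow(pri_filter(numeric(0), 4.2)$events), 0L)
  expect_error(pri_filter(1, 4.2, tolerance = 3), "tolerance")
})

test_that("single-node PRI filter cleans unstructured noise per receiver", {
  # structured: 5 decodes at exact PRI on one node
  d <- data.frame(receiver = "N1", tag_id = 3L,
                  time = seq(0, 16.8, by = 4.2))
  res <- single_node_pri_filter(d, 4.2, min_messages = 4L)
  expect_identical(nrow(res$events), 1L)
  expect_identical(res$events$n_messages, 5L)

  # pure false-positive stream: ids uniform over the code space, so PRI
  # structure is absent and >= 99% of decodes must be removed
  removed_frac <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 40L
    fp <- data.frame(receiver = "N1",
                     tag_id = sample(0:65535, n, replace = TRUE),
                     time = sort(runif(n, 0, 2000)))
    out <- single_node_pri_filter(fp, rep(4.2, 65536) |>
                                    stats::setNames(0:65535),
                                  min_messages = 4L)
    1 - nrow(out$decodes) / n
  }, numeric(1))
  expect_gte(mean(removed_frac), 0.99)

  empty <- single_node_pri_filter(d[0, ], 4.2)
  expect_identical(nrow(empty$events), 0L)
})

test_that("filters never invent decodes and the cascade is monotone", {
  set.seed(77)
  phones <- cube_array()
  model <- propagation_model(sigma_t = 1e-5, p_multipath = 0.3,
                             fp_rate = 0.05)
  track <- simulate_fish_track(8, start = c(40, 60, -5), duration = 400)
  em <- simulate_transmissions(4.2, 0.02, 400, seed = 9)
  pd <- propagate_to_decodes(track, em, phones, model, 55L, seed = 10)
  dec <- inject_noise(pd$decodes, model, seed = 11)

  n0 <- nrow(dec)
  d1 <- multipath_filter(dec)
  expect_lte(nrow(d1), n0)
  gm <- group_messages(d1, grouping_window(phones))
  m1 <- single_detection_filter(gm$messages)
  expect_lte(nrow(m1), nrow(gm$messages))
  mp <- message_pri_filter(m1, c("55" = 4.2))
  expect_lte(nrow(mp$messages), nrow(m1))
  # no filter invents rows: surviving decode times all existed originally
  expect_true(all(d1$time %in% dec$time))
  expect_true(all(mp$messages$time %in% gm$messages$time))
})

test_that("mimic filter removes co-located concurrent mimic events", {
  mt <- data.frame(source_id = 5L, mimic_id = 1029L, weight = 4L,
                   error_pattern = "x")
  msgs <- rbind(
    data.frame(tag_id = 5L, event_id = 1L, time = seq(0, 42, 4.2)),
    data.frame(tag_id = 1029L, event_id = 1L,
               time = seq(0, 42, 4.2)[1:5] + 0.003))
  ev <- data.frame(tag_id = c(5L, 1029L), event_id = 1L,
                   first = c(0, 0.003), last = c(42, 16.8 + 0.003),
                   n_messages = c(11L, 5L))
  res <- mimic_event_filter(ev, msgs, mt, fish_ids = 5L)
  expect_identical(res$events$tag_id, 5L)
  expect_identical(res$removed$tag_id, 1029L)
  expect_identical(res$removed$mimic_of, 5L)

  # spatially distinct events both survive when tracks are supplied
  tracks <- rbind(
    data.frame(tag_id = 5L, time = seq(0, 42, 4.2), x = 10, y = 50, z = -5),
    data.frame(tag_id = 1029L, time = seq(0, 16.8, 4.2), x = 10, y = 250,
               z = -5))
  res2 <- mimic_event_filter(ev, msgs, mt, tracks = tracks, fish_ids = 5L)
  expect_identical(nrow(res2$events), 2L)

  # co-located tracks: mimic removed again
  tracks$y <- 50
  res3 <- mimic_event_filter(ev, msgs, mt, tracks = tracks, fish_ids = 5L)
  expect_identical(res3$removed$tag_id, 1029L)

  # unrelated tags untouched
  ev4 <- data.frame(tag_id = c(7L, 8L), event_id = 1L, first = c(0, 0),
                    last = c(42, 42), n_messages = c(5L, 5L))
  res4 <- mimic_event_filter(ev4, msgs, mt)
  expect_identical(nrow(res4$events), 2L)

  # non-overlapping events of a mimic pair are both kept
  ev5 <- ev; ev5$first[2] <- 100; ev5$last[2] <- 120
  res5 <- mimic_event_filter(ev5, msgs, mt)
  expect_identical(nrow(res5$events), 2L)
})

test_that("chronology filter flags upstream and pre-release anomalies", {
  rkm <- c("LGS Forebay" = 636, "LMN Dam" = 589, "LGS Dam" = 635,
           "Ice Harbor Dam" = 538)
  ev <- data.frame(tag_id = 1L,
                   array = c("LGS Forebay", "LMN Dam", "LGS Dam"),
                   first = c(0, 1e5, 2e5), last = c(10, 1e5 + 10, 2e5 + 10))
  res <- chronology_filter(ev, rkm)
  expect_identical(res$flagged$array, "LGS Dam")
  expect_identical(res$flagged$reason, "upstream_movement")

  # monotone downstream: nothing flagged
  ok <- data.frame(tag_id = 1L,
                   array = c("LGS Forebay", "LMN Dam", "Ice Harbor Dam"),
                   first = c(0, 1e5, 2e5), last = c(10, 1e5 + 10, 2e5 + 10))
  expect_identical(nrow(chronology_filter(ok, rkm)$flagged), 0L)

  # pre-release events excluded
  res2 <- chronology_filter(ok, rkm, release_time = 5e4)
  expect_identical(res2$flagged$reason, "before_release")

  # a 48 h stationary event reads as a dropped transmitter
  drop <- data.frame(tag_id = 1L, array = "LMN Dam", first = 0,
                     last = 48 * 3600)
  expect_identical(chronology_filter(drop, rkm)$flagged$reason,
                   "dropped_tag")
})
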