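test_that("freshwater sound speed matches the published polynomial", {
  expect_equal(sound_speed(0), 1402.385, tolerance = 1e-6)
  # independent arithmetic at 20 degC
  coef <- c(1.402385e3, 5.038813, -5.799136e-2, 3.287156e-4,
            -1.398845e-6, 2.787860e-9)
  byhand <- sum(coef * 20^(0:5))
  expect_equal(sound_speed(20), byhand, tolerance = 1e-9)
  expect_equal(byhand, 1482.38, tolerance = 0.01)
  expect_gt(sound_speed(25), sound_speed(15))   # monotone in range
  expect_error(sound_speed(-1), "temperature")
  expect_error(sound_speed(45), "temperature")
})

test_that("dam frame transforms are rigid and invertible", {
  f <- dam_frame(c(3e5, 1e5, 150), 0.62)
  set.seed(12)
  p <- matrix(rnorm(60, 0, 100), 20, 3)
  l <- dam_transform(p, f, "to_local")
  expect_equal(dam_transform(l, f, "to_geo"), unname(p), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(as.numeric(dist(p[, 1:2])), as.numeric(dist(l[, 1:2])),
               tolerance = 1e-9)
  # origin maps to the local origin; theta = 0 is pure translation
  expect_equal(as.numeric(dam_transform(rbind(c(3e5, 1e5, 150)), f,
                                        "to_local")), c(0, 0, 0),
               tolerance = 1e-9)
  f0 <- dam_frame(c(10, 20, 30), 0)
  expect_equal(as.numeric(dam_transform(rbind(c(11, 22, 33)), f0,
                                        "to_local")), c(1, 2, 3))
})

test_that("frames are recoverable from dual coordinates", {
  f <- dam_frame(c(341200.5, 120040.25, 147.3), -1.13)
  set.seed(13)
  geo <- matrix(rnorm(45, 0, 50), 15, 3) + matrix(rep(f$origin, each = 15), 15)
  loc <- dam_transform(geo, f, "to_local")
  fit <- fit_dam_frame(geo, loc)
  expect_equal(fit$theta, f$theta, tolerance = 1e-9)
  expect_equal(fit$origin, f$origin, tolerance = 1e-6)
})

test_that("TDOAs reference the earliest arrival and flag infeasibility", {
  phones <- cube_array()
  td <- noiseless_tdoas(c(10, 50, -5), phones)
  expect_identical(td$dt[td$ref], 0)
  expect_true(all(td$dt >= 0))
  expect_true(all(td$feasible))

  # equal times: all differences zero
  ph <- as.matrix(phones[, c("x", "y", "z")])
  td0 <- message_tdoas(rep(1.5, 8), ph, 1480)
  expect_true(all(td0$dt == 0))

  # a TDOA beyond aperture / c is geometrically impossible
  tms <- sqrt(colSums((t(ph) - c(10, 50, -5))^2)) / 1480
  tms[3] <- tms[3] + 1
  tdb <- message_tdoas(tms, ph, 1480)
  expect_false(all(tdb$feasible))

  expect_error(message_tdoas(1:3, ph[1:3, ], 1480), "4 receivers")
})

test_that("noiseless TDOA sets are inverted to the source within 1 mm", {
  phones <- cube_array()
  cfg <- loc_config(c_sound = 1482,
                    bounds = rbind(c(0, 150), c(-20, 160), c(-25, 1)))
  for (src in list(c(10, 50, -5), c(40, 100, -12), c(80, 20, -3))) {
    td <- noiseless_tdoas(src, phones, 1482)
    sol <- solve_position(td, cfg)
    expect_true(sol$converged)
    expect_lt(sqrt(sum((sol$position - src)^2)), 1e-3)
    expect_lt(sol$residual_rms, 1e-9)
  }
})

test_that("solver and exhaustive grid oracle agree on random cases", {
  # an array with genuine aperture on every axis, so the objective is
  # comparably sensitive in x, y and z and the lattice minimum is spatially
  # close to the continuous one
  set.seed(14)
  phones <- data.frame(
    receiver = sprintf("H%d", 1:8),
    x = c(0, 0, 0, 0, 40, 40, 40, 40),
    y = c(0, 0, 60, 60, 0, 0, 60, 60),
    z = c(-2, -30, -2, -30, -30, -2, -30, -2))
  bounds <- rbind(c(5, 35), c(5, 55), c(-28, -4))
  cfg <- loc_config(c_sound = 1482, bounds = bounds)
  res <- 1
  for (k in 1:20) {
    src <- c(runif(1, 8, 32), runif(1, 8, 52), runif(1, -26, -6))
    td <- noiseless_tdoas(src, phones, 1482)
    sol <- solve_position(td, cfg)
    orc <- grid_oracle(td, cfg, resolution = res)
    expect_lte(max(abs(sol$position - orc$position)), res)
    # the refined solution is never worse than the exhaustive search
    expect_lte(sol$residual_rms^2, orc$objective + 1e-12)
  }
})

test_that("grid oracle refines toward the truth as resolution shrinks", {
  phones <- cube_array()
  src <- c(23.3, 61.7, -7.9)
  td <- noiseless_tdoas(src, phones, 1482)
  cfg <- loc_config(c_sound = 1482,
                    bounds = rbind(c(20, 28), c(58, 66), c(-12, -4)))
  e <- vapply(c(2, 1, 0.5), function(r)
    max(abs(grid_oracle(td, cfg, r)$position - src)), numeric(1))
  expect_true(all(diff(e) <= 0))
  expect_lt(e[3], 0.5)
})

test_that("a symmetric source with all-zero TDOAs sits at the symmetry point", {
  # receivers at the corners of a square, source on the axis
  ph <- data.frame(receiver = sprintf("H%d", 1:4),
                   x = c(0, 0, 0, 30), y = c(0, 60, 30, 30),
                   z = c(-20, -20, 0, -10))
  ph2 <- rbind(ph, data.frame(receiver = "H5", x = 15, y = 30, z = -30))
  src <- c(10, 30, -10)
  td <- noiseless_tdoas(src, ph2, 1482)
  cfg <- loc_config(c_sound = 1482,
                    bounds = rbind(c(0, 40), c(0, 60), c(-30, 0)))
  sol <- solve_position(td, cfg)
  expect_lt(sqrt(sum((sol$position - src)^2)), 1e-3)
})

test_that("timing noise of 10 us keeps horizontal errors submeter at 50 m", {
  set.seed(15)
  phones <- pier_array()
  cfg <- loc_config(c_sound = 1482,
                    bounds = rbind(c(0, 200), c(-30, 250), c(-25, 1)))
  errs <- matrix(NA_real_, 100, 2)
  src <- c(50, 105, -5)
  ph <- as.matrix(phones[, c("x", "y", "z")])
  d <- sqrt(colSums((t(ph) - src)^2))
  for (k in 1:100) {
    td <- message_tdoas(d / 1482 + rnorm(length(d), 0, 1e-5), ph, 1482)
    sol <- solve_position(td, cfg)
    errs[k, ] <- abs(sol$position[1:2] - src[1:2])
  }
  expect_lt(sqrt(mean(errs[, 1]^2)), 1)
  expect_lt(sqrt(mean(errs[, 2]^2)), 1)
})

test_that("near-coplanar pier geometry degrades depth more than position", {
  set.seed(16)
  phones <- pier_array()
  cfg <- loc_config(c_sound = 1482,
                    bounds = rbind(c(0, 250), c(-30, 250), c(-40, 2)))
  ph <- as.matrix(phones[, c("x", "y", "z")])
  rng_err <- function(range_x) {
    src <- c(range_x, 105, -5)
    d <- sqrt(colSums((t(ph) - src)^2))
    e <- vapply(1:40, function(k) {
      td <- message_tdoas(d / 1482 + rnorm(length(d), 0, 1e-5), ph, 1482)
      abs(solve_position(td, cfg)$position - src)
    }, numeric(3))
    rowMeans(e)
  }
  near <- rng_err(20); far <- rng_err(120)
  expect_gt(far[3], near[3])          # Z error grows with range
  expect_gt(far[3], far[1])           # and exceeds X error at long range
})

test_that("sound-speed mis-specification inflates localization error", {
  phones <- cube_array()
  src <- c(30, 70, -8)
  cfg0 <- loc_config(c_sound = 1482,
                     bounds = rbind(c(0, 100), c(0, 140), c(-20, 0)))
  err_at <- function(dc) {
    td <- noiseless_tdoas(src, phones, 1482)
    cfg <- loc_config(c_sound = 1482 + dc, bounds = cfg0$bounds)
    sqrt(sum((solve_position(td, cfg)$position - src)^2))
  }
  e <- vapply(c(0, 5, 15, 30), err_at, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("track_tag accounts for unlocalizable and failed messages", {
  phones <- cube_array()
  model <- propagation_model(c_sound = 1482, sigma_t = 0, p_multipath = 0,
                             detect_prob = function(r) rep(1, length(r)))
  track <- data.frame(time = c(0, 100), x = 30, y = 60, z = -6)
  em <- seq(0, 42, 4.2)
  pd <- propagate_to_decodes(track, em, phones, model, 5L)
  gm <- group_messages(pd$decodes, grouping_window(phones, 1482, 0))
  cfg <- loc_config(c_sound = 1482,
                    bounds = rbind(c(0, 100), c(0, 140), c(-20, 0)))
  tt <- track_tag(gm$messages, gm$decodes, phones, cfg)
  expect_identical(unname(tt$stats["attempted"]), length(em))
  expect_identical(nrow(tt$points), length(em))
  expect_true(all(diff(tt$points$time) > 0))
  expect_true(all(tt$points$n_receivers >= 4L))
  # degrade three messages to 2 receivers: they are skipped, not solved
  thin <- gm$decodes[!(gm$decodes$message_id %in% 1:3 &
                         !gm$decodes$receiver %in% c("H1", "H2")), ]
  tt2 <- track_tag(gm$messages, thin, phones, cfg)
  expect_identical(unname(tt2$stats["skipped_few_receivers"]), 3L)
  expect_identical(nrow(tt2$points), length(em) - 3L)
})
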