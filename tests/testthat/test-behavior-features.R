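test_that("step_turning returns the smaller arc and is symmetric", {
  expect_equal(step_turning(0, 350), 10)
  expect_equal(step_turning(90, 90), 0)
  expect_equal(step_turning(10, 200), 170)
  set.seed(7)
  a <- runif(500, 0, 360); b <- runif(500, 0, 360)
  expect_true(all(step_turning(a, b) >= 0 & step_turning(a, b) <= 180))
  expect_equal(step_turning(a, b), step_turning(b, a))
  expect_equal(step_turning(a, b),
               mapply(oracle_smaller_angle, a, b))
})

.w <- function(a, b) data.frame(label = "custom", cycle = 1,
                                start_s = a, end_s = b)

test_that("relative turning sums heading changes per unit distance", {
  tr <- track("f", t = 0:4, x = c(0, 1, 2, 3, 4), y = rep(0, 5),
              heading = c(0, 30, 30, 300, 310),
              step_dist = c(0, 1, 1, 1, 1), frame_rate = 1)
  expect_equal(relative_turning(tr, .w(0, 5)), (30 + 0 + 90 + 10) / 4)
  # straight path has zero turning
  tr2 <- track("f", t = 0:4, x = 0:4, y = rep(0, 5), heading = rep(0, 5),
               frame_rate = 1)
  expect_equal(relative_turning(tr2, .w(0, 5)), 0)
  # stationary fish: 0/0, flagged missing
  tr3 <- track("f", t = 0:4, x = rep(1, 5), y = rep(1, 5),
               heading = rep(0, 5), frame_rate = 1)
  expect_true(is.na(relative_turning(tr3, .w(0, 5))))
})

test_that("pause time counts frames at or below the movement threshold", {
  tr <- track("f", t = 0:4, x = rep(0, 5), y = rep(0, 5), heading = rep(0, 5),
              step_dist = c(0, 1, 0, 0, 2), frame_rate = 1)
  expect_equal(pause_time(tr, .w(0, 5)), 3)
  tr2 <- track("f", t = 0:2, x = 0:2, y = rep(0, 3), heading = rep(0, 3),
               step_dist = c(0, 0.01, 0.2), frame_rate = 1)
  # step_dist[1] is 0 by definition, so eps applies to the rest
  expect_equal(pause_time(tr2, .w(0, 3), eps = 0.05), 2)
})

test_that("spurt velocity averages per-bout maxima", {
  tr <- track("f", t = 0:5, x = rep(0, 6), y = rep(0, 6), heading = rep(0, 6),
              step_dist = c(0, 2, 4, 0, 6, 0), frame_rate = 1)
  expect_equal(spurt_velocity(tr, .w(0, 6)), 5)        # bouts {2,4}, {6}
  tr1 <- track("f", t = 0:3, x = rep(0, 4), y = rep(0, 4), heading = rep(0, 4),
               step_dist = c(0, 1, 2, 3), frame_rate = 1)
  expect_equal(spurt_velocity(tr1, .w(0, 4)), 3)       # single bout: its max
  tr2 <- track("f", t = 0:3, x = rep(0, 4), y = rep(0, 4), heading = rep(0, 4),
               step_dist = rep(0, 4), frame_rate = 1)
  expect_true(is.na(spurt_velocity(tr2, .w(0, 4))))    # fully paused
})

test_that("thigmotaxis classifies frames against the centered inner zone", {
  g <- well_geometry(0, 10, 0, 10, inner_fraction = 0.4)
  fixed <- function(x, y) track("f", t = 0:9, x = rep(x, 10), y = rep(y, 10),
                                heading = rep(0, 10), frame_rate = 1)
  expect_equal(thigmotaxis(fixed(5, 5), .w(0, 10), g)$time_ratio, 0)
  expect_equal(thigmotaxis(fixed(1, 1), .w(0, 10), g)$time_ratio, 1)
  # 4 frames inside the [3,7]^2 inner zone, 6 outside, equal steps
  tr <- track("f", t = 0:9, x = c(5, 5, 5, 5, 1, 1, 1, 9, 9, 9),
              y = rep(5, 10), heading = rep(0, 10),
              step_dist = c(0, rep(1, 9)), frame_rate = 1)
  th <- thigmotaxis(tr, .w(0, 10), g)
  expect_equal(th$time_ratio, 0.6)
  expect_equal(th$dist_ratio, 6 / 9)
  # stationary fish: distance ratio undefined
  expect_true(is.na(thigmotaxis(fixed(5, 5), .w(0, 10), g)$dist_ratio))
})

test_that("stationary fish yields the degenerate feature vector", {
  g <- well_geometry(0, 10, 0, 10)
  tr <- track("f", t = 0:9, x = rep(5, 10), y = rep(5, 10),
              heading = rep(0, 10), frame_rate = 1)
  fv <- extract_features(tr, .w(0, 10), g)
  expect_equal(fv$distance_mm, 0)
  expect_equal(fv$pause_s, 10)
  expect_true(is.na(fv$turning_rel))
  expect_true(is.na(fv$spurt_mms))
  expect_true(is.na(fv$thigmo_dist))
  expect_error(extract_features(tr, .w(0, 100), g), "outside track span")
})

test_that("feature extraction matches the brute-force oracle", {
  set.seed(11)
  g <- well_geometry(0, 10, 0, 10)
  for (i in 1:25) {
    tr <- random_track(150, frame_rate = 5, geom = g)
    win <- .w(2, 25)
    fv <- extract_features(tr, win, g, eps = 0)
    or <- oracle_features(tr, win, g, eps = 0)
    for (f in names(or)) {
      if (is.na(or[[f]])) expect_true(is.na(fv[[f]]))
      else expect_equal(fv[[f]], or[[f]], tolerance = 1e-9)
    }
  }
})

test_that("pause time plus bout time tiles the window", {
  set.seed(3)
  g <- well_geometry(0, 10, 0, 10)
  for (i in 1:10) {
    tr <- random_track(100, frame_rate = 5, geom = g)
    win <- .w(0, 20)
    i0 <- which(tr$t >= win$start_s & tr$t < win$end_s)
    moving <- tr$step_dist[i0] > 0
    expect_equal(pause_time(tr, win) + sum(moving) / tr$frame_rate,
                 length(i0) / tr$frame_rate)
  }
})

test_that("normalization is percent change against same-plate control means", {
  base <- expand.grid(fish_id = paste0("f", 1:6), plate_id = c("p1", "p2"),
                      label = "SRB", cycle = 1, stringsAsFactors = FALSE)
  base$fish_id <- paste(base$plate_id, base$fish_id, sep = "_")
  base$treatment <- rep(c("control", "control", "drug", "drug", "drug", "drug"),
                        2)
  base$dose_level <- rep(c(0, 0, 1, 1, 2, 2), 2)
  set.seed(5)
  for (f in phenoscreen:::.feature_cols) base[[f]] <- runif(12, 50, 150)
  # plant known control means on each plate
  base$distance_mm[base$plate_id == "p1" & base$dose_level == 0] <- c(90, 110)
  base$distance_mm[base$plate_id == "p2" & base$dose_level == 0] <- c(190, 210)
  norm <- normalize_to_controls(base)
  i1 <- base$plate_id == "p1" & base$dose_level > 0
  expect_equal(norm$distance_mm[i1],
               100 * (base$distance_mm[i1] - 100) / 100)
  i2 <- base$plate_id == "p2" & base$dose_level > 0
  expect_equal(norm$distance_mm[i2],
               100 * (base$distance_mm[i2] - 200) / 200)
  # pooled controls centre at 0% per plate
  for (p in c("p1", "p2"))
    expect_equal(mean(norm$distance_mm[norm$plate_id == p &
                                         norm$dose_level == 0]), 0)
  # a plate without controls is an error naming the plate
  nob <- base[!(base$plate_id == "p2" & base$dose_level == 0), ]
  expect_error(normalize_to_controls(nob), "p2")
})
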