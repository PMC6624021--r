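test_that("uniform translation is recovered in every interior subregion", {
  mv <- make_invitro_movie(13, 96, empty_spots,
                           actin_flow = list(type = "uniform", vx = 1, vy = 0),
                           noise_sd = 0, seed = 2)
  vf <- stics_field(mv$actin, shift_frames = 3)
  int <- vf$cx >= 24 & vf$cx <= 72 & vf$cy >= 24 & vf$cy <= 72
  v <- vf[int, ]
  expect_true(all(v$valid))
  # displacement (3, 0) at shift 3; speed error < 0.1 px/frame
  expect_lt(max(abs(v$speed_px_frame - 1)), 0.1)
  expect_lt(max(abs(v$dy)) / 3, 0.1)
  expect_lt(stats::median(abs(v$dx - 3)), 0.1)
  # physical units: 1 px/frame = pixel_size / frame_interval um/s
  expect_equal(stats::median(v$speed_um_s), 0.16 / 15, tolerance = 0.05)
})

test_that("a static movie yields no valid vectors", {
  mv <- make_invitro_movie(13, 96, empty_spots, actin_flow = NULL,
                           noise_sd = 8, seed = 2)
  vf <- stics_field(mv$actin, shift_frames = 3)
  expect_lt(mean(vf$valid), 0.15)
})

test_that("STICS is equivariant under 90-degree rotation", {
  mv <- make_invitro_movie(13, 96, empty_spots,
                           actin_flow = list(type = "uniform", vx = 1, vy = 0),
                           noise_sd = 0, seed = 6)
  vf <- stics_field(mv$actin, shift_frames = 3)
  vr <- stics_field(rot90_stack(mv$actin), shift_frames = 3)
  # the rotation maps position (x, y) -> (W-1-y, x), vector (dx, dy) ->
  # (-dy, dx)
  w <- 96
  key <- function(cx, cy) paste(round(cx, 3), round(cy, 3))
  map <- match(key(w - 1 - vf$cy, vf$cx), key(vr$cx, vr$cy))
  ok <- vf$valid & !is.na(map) & vr$valid[map]
  expect_gt(sum(ok), 50)
  expect_equal(vr$dx[map[ok]], -vf$dy[ok], tolerance = 1e-9)
  expect_equal(vr$dy[map[ok]], vf$dx[ok], tolerance = 1e-9)
})

test_that("radial contraction points vectors at the aster center", {
  mv <- make_invitro_movie(13, 128, empty_spots,
                           actin_flow = list(type = "radial",
                                             center = c(63.5, 63.5),
                                             rate = 0.015),
                           noise_sd = 0, seed = 4)
  vf <- stics_field(mv$actin, shift_frames = 3)
  v <- vf[vf$valid, ]
  rx <- 63.5 - v$cx; ry <- 63.5 - v$cy
  rad <- sqrt(rx^2 + ry^2)
  ang <- acos(pmin(pmax((v$dx * rx + v$dy * ry) /
                          (sqrt(v$dx^2 + v$dy^2) * rad), -1), 1)) * 180 / pi
  sel <- rad > 16  # more than one window from the center
  expect_gt(sum(sel), 100)
  expect_lt(stats::quantile(ang[sel], 0.95), 10)
})

test_that("co-movement pairs speeds and angles per subregion", {
  vf <- data.frame(cx = c(8, 16, 24), cy = 8, dx = c(3, 0, -1),
                   dy = c(0, 3, 0), speed_px_frame = c(1, 1, 1 / 3),
                   speed_um_s = 1, angle_deg = 0,
                   peak = 1, valid = TRUE)
  self <- comovement(vf, vf)
  expect_equal(self$angle_deg, rep(0, 3))
  expect_equal(self$speed_a, self$speed_b)

  rot <- vf; rot$dx <- -vf$dy; rot$dy <- vf$dx
  expect_equal(comovement(vf, rot)$angle_deg, rep(90, 3))
  opp <- vf; opp$dx <- -vf$dx; opp$dy <- -vf$dy
  expect_equal(comovement(vf, opp)$angle_deg, rep(180, 3))
  # symmetry in arguments
  expect_equal(comovement(vf, rot)$angle_deg, comovement(rot, vf)$angle_deg)
  # only co-valid subregions pair
  vhalf <- vf; vhalf$valid <- c(TRUE, FALSE, TRUE)
  expect_equal(nrow(comovement(vhalf, vf)), 2L)
  bad <- vf; bad$cx <- bad$cx + 1
  expect_error(comovement(vf, bad), "grid")

  h <- speed_hist2d(self, breaks = seq(0, 2, 0.5))
  expect_equal(sum(h), 1)
})

test_that("randomized control permutes reproducibly", {
  vf <- data.frame(cx = seq(8, 48, 8), cy = 8,
                   dx = c(1, 2, 3, 4, 5, 6), dy = 0,
                   speed_px_frame = 1:6 / 3, speed_um_s = 1,
                   angle_deg = 0, peak = 1, valid = TRUE)
  a <- randomize_control(vf, vf, seed = 4)
  b <- randomize_control(vf, vf, seed = 4)
  expect_identical(a, b)
  expect_false(identical(randomize_control(vf, vf, seed = 5), a))

  one <- vf[1, ]
  expect_equal(randomize_control(one, one, seed = 1)$angle_deg, 0)

  # two valid subregions: identity or swap are the only outcomes
  two <- vf[1:2, ]
  two$dy <- c(0, 2)
  swapped <- two[2:1, ]
  swapped$cx <- two$cx; swapped$cy <- two$cy
  allowed <- c(comovement(two, two)$angle_deg,
               comovement(swapped, two)$angle_deg)
  r <- randomize_control(two, two, seed = 3)
  expect_true(all(round(r$angle_deg, 6) %in% round(allowed, 6)))
})

test_that("subsampled tests trigger on large samples and agree when small", {
  set.seed(2)
  a <- rnorm(100); b <- rnorm(100, 0.2)
  expect_equal(subsampled_test(a, b, "ks"),
               suppressWarnings(stats::ks.test(a, b))$p.value)
  expect_equal(subsampled_test(a, b, "ranksum"),
               suppressWarnings(stats::wilcox.test(a, b,
                                                   exact = FALSE))$p.value)

  big_a <- rnorm(3000); big_b <- rnorm(3000)
  p_same <- subsampled_test(big_a, big_b, "ks", seed = 1)
  expect_gt(p_same, 0.3)
  expect_identical(p_same, subsampled_test(big_a, big_b, "ks", seed = 1))

  disj <- subsampled_test(rnorm(2000), rnorm(2000) + 100, "ks", seed = 1)
  expect_lt(disj, 1e-6)

  expect_error(subsampled_test(a, b, "chisq"))
})
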