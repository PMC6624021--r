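test_that("drift correction inverts imposed stage drift exactly", {
  sp <- make_spot_layout(4, 15, 48, 6, c(200, 150, 180, 120), seed = 2)
  # no drift: all shifts zero
  mv0 <- make_invitro_movie(4, 64, sp, noise_sd = 0, seed = 3)
  dc0 <- correct_drift(mv0$condensate)
  expect_true(all(dc0$drift$dy == 0) && all(dc0$drift$dx == 0))

  drift <- rbind(c(0, 0), matrix(rep(c(3, -2), 4), 4, 2, byrow = TRUE))
  mv <- make_invitro_movie(5, 64, sp, drift = drift, noise_sd = 0, seed = 3)
  dc <- correct_drift(mv$condensate, max_shift_px = 10)
  expect_identical(dc$drift$dy, as.integer(-3 * (0:4)))
  expect_identical(dc$drift$dx, as.integer(2 * (0:4)))
  # corrected interior equals the undrifted movie's interior
  ref <- make_invitro_movie(5, 64, sp, noise_sd = 0, seed = 3)
  expect_equal(get_frame(dc$stack, 5)[20:50, 20:50],
               get_frame(ref$condensate, 5)[20:50, 20:50], tolerance = 1e-9)
  # companion channel gets identical shifts
  comp <- apply_drift(mv$actin, dc$drift)
  expect_equal(get_frame(comp, 5)[20:50, 20:50],
               get_frame(ref$actin, 5)[20:50, 20:50], tolerance = 1e-9)

  # drift beyond the search window is flagged
  big <- rbind(c(0, 0), c(12, 0))
  mvb <- make_invitro_movie(2, 64, sp, drift = big, noise_sd = 0, seed = 3)
  dcb <- correct_drift(mvb$condensate, max_shift_px = 5)
  expect_true(dcb$drift$at_limit[2])
  expect_lte(abs(dcb$drift$dy[2]), 5)

  expect_error(correct_drift(image_stack(array(1, c(1, 8, 8)))), "2 frames")
  expect_warning(correct_drift(image_stack(array(1, c(2, 8, 8)))),
                 "constant")
})

test_that("single-frame detection localizes spots and handles blanks", {
  # blank and constant frames give no detections
  expect_equal(nrow(detect_frame(matrix(0, 32, 32))$detections), 0L)
  expect_equal(nrow(detect_frame(matrix(5, 32, 32))$detections), 0L)

  # one spot at 10x noise SD: center within 0.5 px
  sp <- data.frame(x = 20.3, y = 31.7, amplitude = 50, sigma = 1)
  mv <- make_invitro_movie(1, 64, sp, noise_sd = 5, seed = 7)
  d <- detect_frame(get_frame(mv$condensate, 1))$detections
  expect_gte(nrow(d), 1L)
  i <- which.min((d$x - 20.3)^2 + (d$y - 31.7)^2)
  expect_lt(sqrt((d$x[i] - 20.3)^2 + (d$y[i] - 31.7)^2), 0.5)

  # two well-separated bright extended condensates segment individually
  sp2 <- data.frame(x = c(20, 42), y = c(30, 30), amplitude = 300,
                    sigma = NA, radius = 3)
  mv2 <- make_invitro_movie(1, 64, sp2, noise_sd = 2, seed = 8)
  d2 <- detect_frame(get_frame(mv2$condensate, 1))$detections
  expect_equal(sum(d2$scenario == "segmented-single"), 2L)

  # peak >= mean for every condensate; labels contiguous
  full <- detect_frame(get_frame(mv2$condensate, 1))
  expect_true(all(full$detections$peak_intensity >=
                  full$detections$mean_intensity))
  labs <- sort(unique(full$labels[full$labels > 0]))
  expect_identical(labs, seq_along(labs))
})

test_that("detection is equivariant to whole-pixel translations", {
  sp <- make_spot_layout(5, 18, 42, 6, 200, seed = 5)
  mv0 <- make_invitro_movie(1, 64, sp, noise_sd = 0,
                            background_relief = 0, seed = 5)
  sp1 <- sp; sp1$x <- sp$x + 3; sp1$y <- sp$y + 2
  mv1 <- make_invitro_movie(1, 64, sp1, noise_sd = 0,
                            background_relief = 0, seed = 5)
  d0 <- detect_frame(get_frame(mv0$condensate, 1))$detections
  d1 <- detect_frame(get_frame(mv1$condensate, 1))$detections
  d0 <- d0[order(d0$x), ]; d1 <- d1[order(d1$x), ]
  expect_equal(nrow(d1), nrow(d0))
  expect_equal(d1$x, d0$x + 3, tolerance = 1e-6)
  expect_equal(d1$y, d0$y + 2, tolerance = 1e-6)
})

test_that("isolated-condensate ratio threshold follows the 1st percentile", {
  # order-statistic oracle: equally spaced ratios on [2, 4]
  ratios <- seq(2, 4, length.out = 100)
  iso <- data.frame(peak = ratios, edge_min = 1)
  got <- ratio_threshold(iso, min_isolated = 20)
  v <- sort(ratios)
  h <- (100 - 1) * 0.01 + 1  # type-7 position
  oracle <- v[1] + (h - 1) * (v[2] - v[1])
  expect_equal(got, oracle)
  expect_equal(got, 2.02, tolerance = 1e-12)

  expect_equal(ratio_threshold(data.frame(peak = rep(3, 30), edge_min = 1)),
               3)
  expect_error(ratio_threshold(data.frame(peak = 1:5, edge_min = 1)),
               "fallback")
})

test_that("multi-maximum regions split or merge by the valley ratio", {
  # two Gaussians with a deep valley between them
  xs <- 0:40
  deep <- outer(exp(-(xs - 20)^2 / 18),
                exp(-(xs - 12)^2 / 8) + exp(-(xs - 28)^2 / 8)) * 100
  mask <- deep > 5
  mx <- data.frame(x = c(12, 28), y = c(20, 20),
                   value = deep[cbind(21, c(13, 29))])
  parts <- resolve_multimax(deep, mask, mx, threshold = 2)
  expect_length(parts, 2L)
  expect_true(all(vapply(parts, function(p) p$split, TRUE)))
  # partition: parts tile the region exactly
  un <- parts[[1]]$mask | parts[[2]]$mask
  expect_identical(un, mask)
  expect_false(any(parts[[1]]$mask & parts[[2]]$mask))

  # shallow valley (ratio below threshold): dimmer maximum discarded
  shallow <- outer(exp(-(xs - 20)^2 / 200),
                   exp(-(xs - 16)^2 / 60) + 0.9 * exp(-(xs - 24)^2 / 60)) * 100
  mask2 <- shallow > 30
  mx2 <- data.frame(x = c(16, 24), y = c(20, 20),
                    value = shallow[cbind(21, c(17, 25))])
  parts2 <- resolve_multimax(shallow, mask2, mx2, threshold = 3)
  expect_length(parts2, 1L)
  expect_false(parts2[[1]]$split)

  # single maximum: identity
  one <- resolve_multimax(deep, mask, mx[1, ], threshold = 2)
  expect_length(one, 1L)
  expect_identical(one[[1]]$mask, mask)
})

test_that("detection achieves high recall and precision at SNR 5", {
  noise_sd <- 5
  sp <- make_spot_layout(30, 5, 122, 4, 5 * noise_sd, seed = 7)
  mv <- make_invitro_movie(3, 128, sp, noise_sd = noise_sd, seed = 11)
  ds <- detect_stack(mv$condensate)
  prs <- t(vapply(1:3, function(t)
    match_detections(ds$detections[ds$detections$frame == t, ], sp), c(0, 0)))
  expect_gte(mean(prs[, "recall"]), 0.95)
  expect_gte(mean(prs[, "precision"]), 0.95)
})
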