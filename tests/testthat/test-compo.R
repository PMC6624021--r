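test_that("condensate content subtracts the aggregate-ring background", {
  fr <- matrix(10, 40, 40)
  lab <- matrix(0L, 40, 40)
  lab[10:12, 10:12] <- 1L
  fr[lab == 1L] <- 100
  cc <- condensate_content(fr, lab, perimeter_px = 2)
  expect_equal(cc$content, 90)
  expect_equal(cc$bg_mean, 10)
  expect_equal(cc$bg_sd, 0)

  # uniform frame: zero content
  cc0 <- condensate_content(matrix(5, 40, 40), lab)
  expect_equal(cc0$content, 0)

  # two condensates 3 px apart with 2-px perimeter share one aggregate
  lab2 <- matrix(0L, 40, 40)
  lab2[10:11, 10:11] <- 1L
  lab2[10:11, 15:16] <- 2L  # 3 px gap in x
  lab2[30:31, 30:31] <- 3L  # far away
  cc2 <- condensate_content(matrix(10, 40, 40), lab2)
  expect_equal(cc2$aggregate[1], cc2$aggregate[2])
  expect_false(cc2$aggregate[3] == cc2$aggregate[1])
  expect_equal(cc2$bg_mean[1], cc2$bg_mean[2])

  # oracle for the shared ring: dilation minus condensate pixels
  set.seed(3)
  frr <- matrix(runif(1600, 0, 50), 40, 40)
  ccr <- condensate_content(frr, lab2)
  dil <- EBImage::dilate((lab2 == 1L | lab2 == 2L) * 1,
                         EBImage::makeBrush(5, "disc")) > 0
  ring <- dil & lab2 == 0L
  expect_equal(ccr$bg_mean[1], mean(frr[ring]), tolerance = 1e-12)
  expect_equal(ccr$content[1], mean(frr[lab2 == 1L]) - mean(frr[ring]),
               tolerance = 1e-12)

  # an aggregate with no ring pixels is flagged missing
  lab3 <- matrix(1L, 5, 5)
  cc3 <- condensate_content(matrix(1, 5, 5), lab3)
  expect_true(cc3$missing)
  expect_true(is.na(cc3$content))
})

test_that("the four selection filters reject in order", {
  geom <- make_circle_geometry(220, n_frames = 12, synapse_radius_px = 100,
                               csmac_radius_px = 20)
  ctr <- geom$frames[[1]]$center
  mk <- function(r_start, r_end, n, wob = 0) {
    rr <- seq(r_start, r_end, length.out = n)
    ang <- 0.3 + wob * sin(seq(0, 6 * pi, length.out = n))
    data.frame(frame = seq_len(n),
               x = ctr[1] + 100 * rr * cos(ang),
               y = ctr[2] + 100 * rr * sin(ang),
               det_id = seq_len(n), is_gap = FALSE)
  }
  tracks <- list(
    ok = mk(0.95, 0.3, 10),
    short = mk(0.95, 0.3, 4),
    wiggly = mk(0.95, 0.9, 10, wob = 2),      # low anisotropy
    starts_low = mk(0.55, 0.2, 10),           # starts inside threshold
    dim = mk(0.95, 0.3, 10))
  contents <- do.call(rbind, lapply(seq_along(tracks), function(k)
    data.frame(track_id = k, frame = tracks[[k]]$frame,
               content = if (k == 5) 0.5 else 50, bg_sd = 2)))
  sel <- select_tracks(tracks, geom, contents, min_frames = 5,
                       min_anisotropy = 3, position_threshold = 0.6)
  expect_identical(sel$selected, 1L)
  expect_identical(unname(sel$rejections),
                   c(1L, 1L, 1L, 1L))
})

test_that("composition profile recovers a known decay and flags the step", {
  # analytic fixture: fabricate tracks, radii, and contents directly
  geom <- make_circle_geometry(220, n_frames = 30, synapse_radius_px = 100,
                               csmac_radius_px = 20)
  ctr <- geom$frames[[1]]$center
  g_step <- function(r) ifelse(r > 0.6, 1, 0.5)
  set.seed(12)
  tracks <- list(); mrows <- list(); srows <- list()
  for (k in 1:30) {
    n <- 26
    rr <- seq(0.97, 0.22, length.out = n) + rnorm(n, 0, 0.005)
    ang <- runif(1, 0, 2 * pi)
    tracks[[k]] <- data.frame(frame = seq_len(n),
                              x = ctr[1] + 100 * rr * cos(ang),
                              y = ctr[2] + 100 * rr * sin(ang),
                              det_id = seq_len(n), is_gap = FALSE)
    master <- 60 * exp(rnorm(n, 0, 0.03))
    slave <- 40 * vapply(rr, g_step, 0) * exp(rnorm(n, 0, 0.03))
    mrows[[k]] <- data.frame(track_id = k, frame = seq_len(n),
                             content = master, bg_sd = 1)
    srows[[k]] <- data.frame(track_id = k, frame = seq_len(n),
                             content = slave, bg_sd = 1)
  }
  mc <- do.call(rbind, mrows); sc <- do.call(rbind, srows)
  sel <- select_tracks(tracks, geom, sc)
  expect_gte(length(sel$selected), 27)  # >= 90% of designed tracks pass
  prof <- composition_profile(tracks, sel, mc, sc, geom,
                              reference_bin = 0.9)
  # medians follow g (start-normalized, so ratio approximates g(r)/g(start))
  above <- prof$bin_lo >= 0.6 & !is.na(prof$median)
  below <- prof$bin_hi <= 0.6 & !is.na(prof$median)
  expect_true(all(abs(prof$median[above] - 1) < 0.1))
  expect_true(all(abs(prof$median[below] - 0.5) < 0.1 * 0.5))
  # significance appears exactly below the step
  expect_true(all(prof$significant[below]))
  expect_false(any(prof$significant[above & prof$bin_lo != 0.9],
                   na.rm = TRUE))

  # flat profile: medians near 1, nothing significant
  sc1 <- sc; sc1$content <- 40 * exp(rnorm(nrow(sc), 0, 0.03))
  sel1 <- select_tracks(tracks, geom, sc1)
  prof1 <- composition_profile(tracks, sel1, mc, sc1, geom,
                               reference_bin = 0.9)
  expect_true(all(abs(prof1$median - 1) < 0.1, na.rm = TRUE))
  expect_false(any(prof1$significant, na.rm = TRUE))

  # per-track gain invariance: scaling one track's slave contents by c > 0
  # leaves its normalized contribution unchanged
  sc2 <- sc
  sc2$content[sc2$track_id == 1] <- sc2$content[sc2$track_id == 1] * 7.3
  prof2 <- composition_profile(tracks, sel, mc, sc2, geom,
                               reference_bin = 0.9)
  expect_equal(prof2$median, prof$median, tolerance = 1e-12)

  # notch CI brackets the median and narrows with n
  rep_bins <- !is.na(prof$median)
  expect_true(all(prof$ci_lo[rep_bins] <= prof$median[rep_bins]))
  expect_true(all(prof$ci_hi[rep_bins] >= prof$median[rep_bins]))
  expect_equal(attr(prof, "threshold"), 0.05 / attr(prof, "m"))
})

test_that("sparse bins are suppressed and a lost reference bin errors", {
  geom <- make_circle_geometry(220, n_frames = 10, synapse_radius_px = 100,
                               csmac_radius_px = 20)
  ctr <- geom$frames[[1]]$center
  tracks <- list()
  mrows <- srows <- list()
  for (k in 1:12) {
    n <- 8
    rr <- seq(0.75, 0.3, length.out = n)  # never visits the 0.9-1 bin
    tracks[[k]] <- data.frame(frame = seq_len(n),
                              x = ctr[1] + 100 * rr,
                              y = ctr[2] + 0.1 * k,
                              det_id = seq_len(n), is_gap = FALSE)
    mrows[[k]] <- data.frame(track_id = k, frame = seq_len(n), content = 50,
                             bg_sd = 1)
    srows[[k]] <- mrows[[k]]
  }
  sel <- list(selected = 1:12, rejections = c(0, 0, 0, 0),
              radii = vector("list", 12))
  expect_error(composition_profile(tracks, sel, do.call(rbind, mrows),
                                   do.call(rbind, srows), geom,
                                   reference_bin = 0.9),
               "reference bin")
})

test_that("photobleach control matches the closed-form decay", {
  spec0 <- data.frame(birth_frame = integer(0), birth_r = numeric(0),
                      angle_deg = numeric(0), radial_speed = numeric(0),
                      wobble_deg = numeric(0))
  mv <- make_synapse_movie(8, size_px = 120, synapse_radius_px = 50,
                           csmac_radius_px = 10, tracks = spec0,
                           bleach_k = 0.01, noise_sd = 0.5, seed = 4)
  geom <- make_circle_geometry(120, n_frames = 8, synapse_radius_px = 50,
                               csmac_radius_px = 10)
  pb <- photobleach_control(mv$slave, geom)
  expect_equal(pb$normalized, exp(-0.01 * (0:7)), tolerance = 0.01)

  mv0 <- make_synapse_movie(8, size_px = 120, synapse_radius_px = 50,
                            csmac_radius_px = 10, tracks = spec0,
                            bleach_k = 0, noise_sd = 0.5, seed = 4)
  pb0 <- photobleach_control(mv0$slave, geom)
  expect_true(all(abs(pb0$normalized - 1) < 0.01))

  dark <- image_stack(array(0, c(3, 120, 120)))
  expect_error(photobleach_control(dark, geom), "zero")
})
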