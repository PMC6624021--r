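test_that("synapse and cSMAC segmentation recovers a synthetic disc", {
  mv <- make_synapse_movie(3, synapse_radius_px = 100, csmac_radius_px = 20,
                           tracks = make_inward_spec(5, seed = 1),
                           noise_sd = 2, seed = 2)
  geom <- segment_geometry(mv$master)
  truth <- make_circle_geometry(dim(mv$master$frames)[2],
                                synapse_radius_px = 100,
                                csmac_radius_px = 20)$frames[[1]]
  iou <- function(a, b) sum(a & b) / sum(a | b)
  for (g in geom$frames) {
    expect_gte(iou(g$synapse, truth$synapse), 0.95)
    expect_gte(iou(g$csmac, truth$csmac), 0.9)
    expect_lt(max(abs(g$center - truth$center)), 2)
    expect_true(all(g$synapse[g$csmac]))  # cSMAC inside synapse
  }

  expect_error(segment_geometry(image_stack(array(5, c(1, 32, 32)))),
               "constant|no object")

  # near-idempotence: segmenting the geometry rendered as a tiered image
  # reproduces the masks up to the smoothing kernel's boundary blur
  g1 <- geom$frames[[1]]
  tier <- matrix(0, nrow(g1$synapse), ncol(g1$synapse))
  tier[g1$synapse] <- 1
  tier[g1$csmac] <- 2
  geom2 <- segment_geometry(image_stack(list(tier)))
  expect_gte(iou(geom2$frames[[1]]$synapse, g1$synapse), 0.99)
  expect_gte(iou(geom2$frames[[1]]$csmac, g1$csmac), 0.99)
})

test_that("frames before cSMAC formation fall back to the averaged center", {
  # synapse disc with faint puncta early; bright center appears at frame 4
  size <- 120
  g <- make_circle_geometry(size, synapse_radius_px = 50, csmac_radius_px = 12)
  base <- matrix(0, size, size)
  base[g$frames[[1]]$synapse] <- 40
  spots <- render_spots(size, size,
                        data.frame(x = c(30, 85), y = c(40, 80),
                                   amplitude = 30, sigma = 1))
  cs <- matrix(0, size, size)
  cs[g$frames[[1]]$csmac] <- 60
  set.seed(5)
  frames <- lapply(1:6, function(t) {
    fr <- base + spots + if (t >= 4) cs else 0
    pmax(fr + matrix(rnorm(size^2, 0, 1), size, size), 0)
  })
  geom <- segment_geometry(image_stack(frames))
  formed <- vapply(geom$frames, function(f) f$csmac_formed, TRUE)
  expect_false(any(formed[1:3]))
  expect_true(all(formed[4:6]))
  expect_true(all(vapply(geom$frames[1:3], function(f)
    f$csmac_area_px, 0) == 0))
  # early-frame centers come from the time average: near the true center
  for (t in 1:3)
    expect_lt(max(abs(geom$frames[[t]]$center - g$frames[[1]]$center)), 3)
})

test_that("normalized radial position follows the ray geometry", {
  geom <- make_circle_geometry(220, synapse_radius_px = 100,
                               csmac_radius_px = 20)
  ctr <- geom$frames[[1]]$center
  expect_equal(normalized_radial_position(ctr, geom)$r, 0)
  p60 <- normalized_radial_position(ctr + c(60, 0), geom)
  expect_equal(p60$r, 0.6, tolerance = 0.01)
  # boundary point
  pb <- normalized_radial_position(ctr + c(0, 99.5), geom)
  expect_gte(pb$r, 0.98)
  # off-axis ray: similar triangles hold in any direction
  d <- 45 / sqrt(2)
  expect_equal(normalized_radial_position(ctr + c(d, d), geom)$r, 0.45,
               tolerance = 0.01)
  # scale invariance
  half <- make_circle_geometry(110, synapse_radius_px = 50,
                               csmac_radius_px = 10)
  expect_equal(normalized_radial_position(half$frames[[1]]$center + c(30, 0),
                                          half)$r,
               0.6, tolerance = 0.015)
  # outside points clamp to 1 and flag
  out <- normalized_radial_position(ctr + c(108, 0), geom)
  expect_identical(out$r, 1)
  expect_true(out$flagged)
  # circular identity: ray-cast r equals |p - c| / R
  set.seed(8)
  for (i in 1:10) {
    ang <- runif(1, 0, 2 * pi); rad <- runif(1, 5, 95)
    p <- ctr + rad * c(cos(ang), sin(ang))
    expect_equal(normalized_radial_position(p, geom)$r, rad / 100,
                 tolerance = 0.012)
  }
})

test_that("radial profiles find the actin peak position", {
  size <- 220
  geom <- make_circle_geometry(size, synapse_radius_px = 100,
                               csmac_radius_px = 20)
  ctr <- geom$frames[[1]]$center
  xs <- matrix(rep(0:(size - 1), each = size), size)
  ys <- matrix(rep(0:(size - 1), size), size)
  rr <- sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2) / 100
  annulus <- 100 * exp(-(rr - 0.6)^2 / (2 * 0.08^2))
  rp <- radial_profiles(annulus, geom)
  expect_equal(rp$median_peak_r, 0.6, tolerance = 0.02)
  expect_true(all(abs(rp$peaks$peak_r - 0.6) < 0.05))

  ramp <- rr * 50
  rp2 <- radial_profiles(ramp, geom)
  expect_true(all(rp2$peaks$peak_r > 0.95))

  flat <- matrix(7, size, size)
  rp3 <- radial_profiles(flat, geom)
  expect_true(all(rp3$peaks$flat))
  expect_true(is.na(rp3$median_peak_r))
})

test_that("speckle orientation fractions recover a radial step rule", {
  geom <- make_circle_geometry(220, synapse_radius_px = 100,
                               csmac_radius_px = 20)
  rule <- function(r) if (r > 0.6) 90 else 0
  sp <- make_speckles(4000, geom, rule, seed = 9)
  fr <- speckle_orientation_fractions(sp, geom, bin_width = 0.1)
  hi <- fr$bin_lo >= 0.65
  lo <- fr$bin_hi <= 0.55 & fr$n > 0
  expect_true(all(fr$fraction_perpendicular[hi] > 0.9))
  expect_true(all(fr$fraction_perpendicular[lo] < 0.1))

  # dipole input is rotated by 90 degrees
  fd <- speckle_orientation_fractions(sp, geom, input = "dipole")
  expect_true(all(fd$fraction_perpendicular[hi] < 0.1))
})
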