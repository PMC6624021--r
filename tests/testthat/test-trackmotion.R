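test_that("assignment solver matches brute-force enumeration", {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n, n)
    a <- condensr:::solve_lap(C)
    expect_identical(sort(a), 1:n)
    best <- min(vapply(perms(1:n), function(p)
      sum(C[cbind(1:n, p)]), 0))
    expect_equal(sum(C[cbind(1:n, a)]), best, tolerance = 1e-12)
  }
})

test_that("frame-to-frame linking respects the search radius", {
  # two stationary spots 20 px apart: two full-length tracks
  dets <- do.call(rbind, lapply(1:10, function(f)
    data.frame(frame = f, id = 1:2, x = c(10, 30), y = c(10, 10))))
  tr <- link_tracks(dets, search_radius_px = 5, gap_window = 3)
  expect_length(tr, 2L)
  expect_true(all(vapply(tr, nrow, 0L) == 10))

  # a 6 px jump exceeds the radius: track terminates, new one starts
  dets2 <- data.frame(frame = 1:6, id = 1,
                      x = c(10, 10, 10, 16, 16, 16), y = 5)
  tr2 <- link_tracks(dets2, search_radius_px = 5, gap_window = 0)
  expect_length(tr2, 2L)

  # empty detections give an empty track list
  expect_length(link_tracks(dets2[0, ]), 0L)
})

test_that("gap closing bridges short detection dropouts", {
  dets <- data.frame(frame = c(1:4, 6:10), id = 1,
                     x = (c(1:4, 6:10)) * 0.5, y = 3)
  tr <- link_tracks(dets, search_radius_px = 5, gap_window = 3)
  expect_length(tr, 1L)
  t1 <- tr[[1]]
  expect_identical(t1$frame, 1:10)
  expect_true(t1$is_gap[t1$frame == 5])
  expect_equal(t1$x[t1$frame == 5], 2.5)  # interpolated
  # gap longer than the window is not closed
  dets2 <- data.frame(frame = c(1:3, 8:10), id = 1, x = 1, y = 1)
  expect_length(link_tracks(dets2, 5, 3), 2L)
})

test_that("linking is invariant to detection order within frames", {
  set.seed(9)
  dets <- do.call(rbind, lapply(1:6, function(f)
    data.frame(frame = f, id = 1:5,
               x = c(5, 20, 35, 50, 65) + rnorm(5, 0, 0.8),
               y = 10 + rnorm(5, 0, 0.8))))
  shuf <- do.call(rbind, lapply(split(dets, dets$frame), function(d)
    d[sample(nrow(d)), ]))
  a <- tracks_to_df(link_tracks(dets, 5, 3))
  b <- tracks_to_df(link_tracks(shuf, 5, 3))
  a <- a[order(a$frame, a$x), c("frame", "x", "y")]
  b <- b[order(b$frame, b$x), c("frame", "x", "y")]
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("merge events are annotated without altering tracks", {
  dets <- rbind(
    do.call(rbind, lapply(1:10, function(f)
      data.frame(frame = f, id = 1, x = 10, y = 10))),
    do.call(rbind, lapply(1:5, function(f)
      data.frame(frame = f, id = 2, x = 10 + (5 - f) * 2 + 3, y = 10))))
  tr <- link_tracks(dets, search_radius_px = 5, gap_window = 0,
                    allow_merge_split = TRUE)
  ev <- attr(tr, "events")
  expect_true(any(ev$type == "merge"))
})

test_that("MSS classifies directed, immobile, and Brownian motion", {
  dr <- make_tracks(1, 40, "directed", D = 0, v = 0.1,
                    frame_interval_s = 15, seed = 2)$tracks
  m <- mss(data.frame(frame = dr$frame, x = dr$x_um, y = dr$y_um), 15)
  expect_equal(unname(m$gamma["2"]), 2, tolerance = 0.01)
  expect_equal(m$S, 1, tolerance = 0.02)

  im <- data.frame(frame = 1:10, x = 2, y = 3)
  mi <- mss(im, 15)
  expect_identical(mi$D2, 0)
  expect_identical(mi$S, 0)

  expect_error(mss(im[1:4, ], 15), "5 frames")

  set.seed(1)
  br <- make_tracks(150, 60, "brownian", D = 1e-4,
                    frame_interval_s = 15, seed = 5)$tracks
  me <- mss_ensemble(data.frame(track_id = br$track_id, frame = br$frame,
                                x = br$x_um, y = br$y_um), 15)
  expect_equal(attr(me, "median_D2"), 1e-4, tolerance = 0.1)
  expect_gt(attr(me, "median_S"), 0.42)
  expect_lt(attr(me, "median_S"), 0.58)
})

test_that("MSS is invariant to time reversal", {
  br <- make_tracks(1, 30, "brownian", D = 1e-3, frame_interval_s = 5,
                    seed = 7)$tracks
  tr <- data.frame(frame = br$frame, x = br$x_um, y = br$y_um)
  rev_tr <- data.frame(frame = tr$frame, x = rev(tr$x), y = rev(tr$y))
  a <- mss(tr, 5); b <- mss(rev_tr, 5)
  expect_equal(a$gamma, b$gamma)
  expect_equal(a$D2, b$D2)
})

test_that("median D2 orders immobile < Brownian < actomyosin-like directed", {
  d2_of <- function(model, D, v) {
    tk <- make_tracks(60, 40, model, D = D, v = v, frame_interval_s = 15,
                      seed = 11)$tracks
    attr(mss_ensemble(data.frame(track_id = tk$track_id, frame = tk$frame,
                                 x = tk$x_um, y = tk$y_um), 15), "median_D2")
  }
  d_imm <- d2_of("immobile", 0, 0)
  d_br <- d2_of("brownian", 1e-4, 0)
  d_dir <- d2_of("directed", 1e-4, 0.05)
  expect_lt(d_imm, d_br)
  expect_lt(d_br, d_dir)
})

test_that("track anisotropy reflects scatter shape", {
  th <- seq(0, 2 * pi, length.out = 60)
  circ <- data.frame(x = cos(th), y = sin(th))
  expect_equal(track_anisotropy(circ), 1, tolerance = 0.05)

  set.seed(3)
  cloud <- data.frame(x = rnorm(4000, 0, 10), y = rnorm(4000, 0, 1))
  expect_equal(track_anisotropy(cloud), 10, tolerance = 0.08)

  lin <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  expect_identical(track_anisotropy(lin), Inf)
  expect_error(track_anisotropy(data.frame(x = c(1, 2), y = c(1, 2))),
               "3 distinct")
})
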