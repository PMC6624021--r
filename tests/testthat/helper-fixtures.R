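# shared fixture builders

empty_spots <- data.frame(x = numeric(0), y = numeric(0),
                          amplitude = numeric(0), sigma = numeric(0))

# spot layout with guaranteed pairwise separation
make_spot_layout <- function(n, lo, hi, min_sep, amplitude, sigma = 1,
                             seed = 1) {
  set.seed(seed)
  repeat {
    xs <- runif(n, lo, hi); ys <- runif(n, lo, hi)
    d <- as.matrix(dist(cbind(xs, ys)))
    diag(d) <- Inf
    if (min(d) >= min_sep) break
  }
  data.frame(x = xs, y = ys, amplitude = amplitude, sigma = sigma)
}

# inward-track spec for synapse movies (approximately linear tracks that
# end before the cSMAC-adjacent background-contamination zone)
make_inward_spec <- function(n_tracks, seed = 1, radial_speed = 0.02,
                             wobble_deg = 1) {
  set.seed(seed)
  data.frame(birth_frame = sample(1:6, n_tracks, TRUE),
             birth_r = runif(n_tracks, 0.90, 0.95),
             angle_deg = runif(n_tracks, 0, 360),
             radial_speed = radial_speed,
             wobble_deg = wobble_deg)
}

# precision/recall of detections against true spot centers
match_detections <- function(dets, truth, radius = 2) {
  if (nrow(dets) == 0L) return(c(recall = 0, precision = NA))
  d <- sqrt(outer(dets$x, truth$x, "-")^2 + outer(dets$y, truth$y, "-")^2)
  c(recall = mean(apply(d, 2, min) <= radius),
    precision = mean(apply(d, 1, min) <= radius))
}

rot90_stack <- function(stack) {
  d <- dim(stack$frames)
  out <- array(0, c(d[1], d[3], d[2]))
  for (t in seq_len(d[1])) {
    m <- stack$frames[t, , ]
    # counter-clockwise rotation: new[y, x] = old[x, H - y + 1]
    out[t, , ] <- t(m)[, rev(seq_len(d[2]))]
  }
  image_stack(lapply(seq_len(d[1]), function(t) out[t, , ]),
              stack$pixel_size_um, stack$frame_interval_s,
              stack$channel_name)
}
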