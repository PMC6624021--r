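# Synthetic-data generators. Every generator returns (data, ground_truth)
# where the ground truth suffices to compute the expected output of the
# corresponding analysis stage in closed form or by brute force. With
# noise_sd = 0 the output is an exact deterministic function of its spec;
# identical seeds reproduce bit-identical output.

#' Render diffraction-limited spots and extended blobs into a frame
#'
#' Diffraction-limited spots are integrated 2-D Gaussians (error-function
#' integration over each pixel, normalized so an on-grid center pixel equals
#' the amplitude). Extended blobs are discs with a PSF-smoothed edge.
#'
#' @param h,w frame size in pixels.
#' @param spots data.frame with columns `x`, `y` (0-based centers),
#'   `amplitude`, and either `sigma` (Gaussian spot) or `radius` (extended
#'   blob); exactly one of the two per row, the other NA.
#' @param psf_sigma_px PSF sigma used to smooth blob edges.
#' @return intensity matrix `[y, x]`.
#' @export
render_spots <- function(h, w, spots, psf_sigma_px = 0.46) {
  img <- matrix(0, h, w)
  if (nrow(spots) == 0L) return(img)
  for (i in seq_len(nrow(spots))) {
    cx <- spots$x[i]; cy <- spots$y[i]; A <- spots$amplitude[i]
    if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1)
      stop("spot center outside frame: (", cx, ", ", cy, ")")
    if (!is.null(spots$sigma) && is.finite(spots$sigma[i])) {
      s <- spots$sigma[i]
      ext <- ceiling(5 * s) + 1L
      xs <- max(0, floor(cx) - ext):min(w - 1, ceiling(cx) + ext)
      ys <- max(0, floor(cy) - ext):min(h - 1, ceiling(cy) + ext)
      norm1 <- stats::pnorm(0.5 / s) - stats::pnorm(-0.5 / s)
      ex <- (stats::pnorm((xs - cx + 0.5) / s) -
             stats::pnorm((xs - cx - 0.5) / s)) / norm1
      ey <- (stats::pnorm((ys - cy + 0.5) / s) -
             stats::pnorm((ys - cy - 0.5) / s)) / norm1
      img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + A * outer(ey, ex)
    } else {
      R <- spots$radius[i]
      ext <- ceiling(R + 5 * psf_sigma_px) + 1L
      xs <- max(0, floor(cx) - ext):min(w - 1, ceiling(cx) + ext)
      ys <- max(0, floor(cy) - ext):min(h - 1, ceiling(cy) + ext)
      d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
      img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] +
        A * stats::pnorm((R - d) / max(psf_sigma_px, 1e-6))
    }
  }
  img
}

#' Render anti-aliased filament segments
#'
#' Each segment is a line with a Gaussian cross-section, evaluated from the
#' exact point-to-segment distance, giving a filamentous texture whose
#' advection under a known velocity field is exact (segments are moved in
#' continuous coordinates and re-rendered per frame).
#'
#' @param h,w frame size.
#' @param segs data.frame with `x0`, `y0`, `x1`, `y1` (0-based endpoints),
#'   `amplitude`, `width` (Gaussian half-width in px).
#' @return intensity matrix.
#' @export
render_segments <- function(h, w, segs) {
  img <- matrix(0, h, w)
  if (nrow(segs) == 0L) return(img)
  for (i in seq_len(nrow(segs))) {
    x0 <- segs$x0[i]; y0 <- segs$y0[i]; x1 <- segs$x1[i]; y1 <- segs$y1[i]
    A <- segs$amplitude[i]; wd <- segs$width[i]
    ext <- ceiling(4 * wd) + 1L
    xlo <- max(0, floor(min(x0, x1)) - ext)
    xhi <- min(w - 1, ceiling(max(x0, x1)) + ext)
    ylo <- max(0, floor(min(y0, y1)) - ext)
    yhi <- min(h - 1, ceiling(max(y0, y1)) + ext)
    if (xlo > xhi || ylo > yhi) next  # segment outside the frame
    xs <- xlo:xhi; ys <- ylo:yhi
    px <- matrix(rep(xs, each = length(ys)), length(ys))
    py <- matrix(rep(ys, length(xs)), length(ys))
    dx <- x1 - x0; dy <- y1 - y0
    len2 <- dx^2 + dy^2
    tt <- if (len2 == 0) matrix(0, nrow(px), ncol(px)) else
      pmin(pmax(((px - x0) * dx + (py - y0) * dy) / len2, 0), 1)
    d2 <- (px - (x0 + tt * dx))^2 + (py - (y0 + tt * dy))^2
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + A * exp(-d2 / (2 * wd^2))
  }
  img
}

#' Smooth inhomogeneous background field
#'
#' Deterministic low-frequency cosine mixture; used to emulate uneven
#' illumination in in-vitro movies.
#' @param h,w frame size.
#' @param level mean background level.
#' @param relief peak-to-trough relief as a fraction of `level`.
#' @param seed integer seed fixing the phases.
#' @return matrix with mean approximately `level`.
#' @export
render_background <- function(h, w, level = 50, relief = 0.4, seed = 1) {
  set.seed(seed)
  ph <- stats::runif(4, 0, 2 * pi)
  xs <- (0:(w - 1)) / w; ys <- (0:(h - 1)) / h
  f <- outer(cos(2 * pi * ys + ph[1]), cos(2 * pi * xs + ph[2])) +
    0.5 * outer(sin(2 * pi * 2 * ys + ph[3]), sin(2 * pi * 2 * xs + ph[4]))
  level * (1 + relief * f / max(abs(f)))
}

# advance segment endpoints by t frames of the specified flow
.advect <- function(pts, flow, t) {
  if (is.null(flow) || flow$type == "none" || t == 0) return(pts)
  if (flow$type == "uniform") {
    pts[, 1] <- pts[, 1] + flow$vx * t
    pts[, 2] <- pts[, 2] + flow$vy * t
    return(pts)
  }
  if (flow$type == "radial") {
    fac <- (1 - flow$rate)^t
    pts[, 1] <- flow$center[1] + (pts[, 1] - flow$center[1]) * fac
    pts[, 2] <- flow$center[2] + (pts[, 2] - flow$center[2]) * fac
    return(pts)
  }
  stop("unknown flow type: ", flow$type)
}

#' Synthetic in-vitro TIRF movie
#'
#' Two-channel movie: a condensate channel (spots over a smooth
#' inhomogeneous background) and an actin channel (filament texture advected
#' exactly by a known velocity field). Both channels receive the same
#' per-frame integer stage drift and additive Gaussian noise.
#'
#' @param n_frames number of frames.
#' @param size_px square frame side.
#' @param condensates spot spec data.frame (see [render_spots()]).
#' @param actin_flow `NULL`, or `list(type = "uniform", vx =, vy =)` in
#'   px/frame, or `list(type = "radial", center = c(x, y), rate =)` with
#'   `rate` the per-frame fractional contraction toward the aster center.
#' @param drift `NULL` or an `n_frames x 2` matrix of per-frame incremental
#'   integer shifts `(dy, dx)`; row 1 should be zero.
#' @param noise_sd additive Gaussian noise SD (both channels).
#' @param n_filaments,filament_length_px,filament_width_px,filament_amp
#'   actin-texture parameters.
#' @param background_level,background_relief condensate-channel background.
#' @param pixel_size_um,frame_interval_s calibration (defaults 0.16 um/px;
#'   15 s for steady-state movies, pass 5 for contraction movies).
#' @param seed integer seed.
#' @return `list(condensate = ImageStack, actin = ImageStack,
#'   ground_truth = list)`; the ground truth records spot positions per
#'   frame, cumulative drift, the flow, and all parameters.
#' @export
make_invitro_movie <- function(n_frames, size_px, condensates,
                               actin_flow = NULL, drift = NULL,
                               noise_sd = 0,
                               n_filaments = NULL, filament_length_px = 15,
                               filament_width_px = 1, filament_amp = 60,
                               background_level = 50, background_relief = 0.4,
                               pixel_size_um = 0.16, frame_interval_s = 15,
                               seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  h <- w <- size_px
  # default filament density approximates a cortical meshwork: texture
  # correlation length below the STICS window size
  if (is.null(n_filaments)) n_filaments <- round(0.015 * size_px^2)
  if (is.null(drift)) drift <- matrix(0L, n_frames, 2)
  drift <- matrix(as.integer(drift), n_frames, 2)
  drift_cum <- apply(drift, 2, cumsum)
  drift_cum <- matrix(drift_cum, n_frames, 2)
  set.seed(seed)
  segs <- data.frame(
    x0 = stats::runif(n_filaments, 0, w - 1),
    y0 = stats::runif(n_filaments, 0, h - 1))
  ang <- stats::runif(n_filaments, 0, 2 * pi)
  segs$x1 <- segs$x0 + filament_length_px * cos(ang)
  segs$y1 <- segs$y0 + filament_length_px * sin(ang)
  segs$amplitude <- filament_amp * stats::runif(n_filaments, 0.5, 1)
  segs$width <- filament_width_px
  bg <- render_background(h, w, background_level, background_relief, seed)
  cond_frames <- vector("list", n_frames)
  actin_frames <- vector("list", n_frames)
  spot_positions <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    sp <- condensates
    spot_positions[[t]] <- sp
    base_c <- render_spots(h, w, sp) + bg
    p0 <- .advect(as.matrix(segs[, c("x0", "y0")]), actin_flow, t - 1)
    p1 <- .advect(as.matrix(segs[, c("x1", "y1")]), actin_flow, t - 1)
    st <- data.frame(x0 = p0[, 1], y0 = p0[, 2], x1 = p1[, 1], y1 = p1[, 2],
                     amplitude = segs$amplitude, width = segs$width)
    base_a <- render_segments(h, w, st)
    base_c <- shift_frame(base_c, drift_cum[t, 1], drift_cum[t, 2])
    base_a <- shift_frame(base_a, drift_cum[t, 1], drift_cum[t, 2])
    if (noise_sd > 0) {
      base_c <- pmax(base_c + matrix(stats::rnorm(h * w, 0, noise_sd), h, w), 0)
      base_a <- pmax(base_a + matrix(stats::rnorm(h * w, 0, noise_sd), h, w), 0)
    }
    cond_frames[[t]] <- base_c
    actin_frames[[t]] <- base_a
  }
  list(
    condensate = image_stack(cond_frames, pixel_size_um, frame_interval_s,
                             "condensate"),
    actin = image_stack(actin_frames, pixel_size_um, frame_interval_s,
                        "actin"),
    ground_truth = list(condensates = condensates,
                        spot_positions = spot_positions,
                        drift_incr = drift, drift_cum = drift_cum,
                        flow = actin_flow, noise_sd = noise_sd,
                        segments = segs, seed = seed))
}

#' Synthetic particle tracks with known motion model
#'
#' @param n_tracks number of tracks.
#' @param n_frames frames per track.
#' @param model one of `"brownian"`, `"confined"`, `"directed"`,
#'   `"immobile"`.
#' @param D diffusion coefficient in um^2/s (per-axis step variance
#'   `2 * D * dt` for Brownian motion).
#' @param v speed in um/s for the directed model.
#' @param frame_interval_s frame interval dt in seconds.
#' @param confine_radius_um reflecting circular boundary radius (confined).
#' @param box_um side of the box over which starting points are spread.
#' @param seed integer seed.
#' @return `list(tracks = data.frame(track_id, frame, x_um, y_um),
#'   ground_truth = list)`.
#' @export
make_tracks <- function(n_tracks, n_frames, model = "brownian",
                        D = 1e-4, v = 0, frame_interval_s = 15,
                        confine_radius_um = 0.5, box_um = 20, seed = 1) {
  model <- match.arg(model, c("brownian", "confined", "directed", "immobile"))
  stopifnot(D >= 0, n_frames >= 2)
  set.seed(seed)
  dt <- frame_interval_s
  sd_step <- sqrt(2 * D * dt)
  out <- vector("list", n_tracks)
  dirs <- stats::runif(n_tracks, 0, 2 * pi)
  for (k in seq_len(n_tracks)) {
    x <- numeric(n_frames); y <- numeric(n_frames)
    x[1] <- stats::runif(1, 0, box_um); y[1] <- stats::runif(1, 0, box_um)
    if (model == "immobile" || (model == "brownian" && D == 0)) {
      x[] <- x[1]; y[] <- y[1]
    } else {
      cx <- x[1]; cy <- y[1]
      for (t in 2:n_frames) {
        dx <- stats::rnorm(1, 0, sd_step); dy <- stats::rnorm(1, 0, sd_step)
        if (model == "directed") {
          dx <- dx + v * dt * cos(dirs[k]); dy <- dy + v * dt * sin(dirs[k])
        }
        nx <- x[t - 1] + dx; ny <- y[t - 1] + dy
        if (model == "confined") {
          # reflect at the circular boundary (radial fold-back)
          r <- sqrt((nx - cx)^2 + (ny - cy)^2)
          if (r > confine_radius_um) {
            f <- (2 * confine_radius_um - r) / r
            f <- max(f, 0)
            nx <- cx + (nx - cx) * f; ny <- cy + (ny - cy) * f
          }
        }
        x[t] <- nx; y[t] <- ny
      }
    }
    out[[k]] <- data.frame(track_id = k, frame = seq_len(n_frames),
                           x_um = x, y_um = y)
  }
  list(tracks = do.call(rbind, out),
       ground_truth = list(model = model, D = D, v = v,
                           frame_interval_s = dt,
                           confine_radius_um = confine_radius_um,
                           directions = dirs, seed = seed))
}

#' Circular synapse geometry constructed from parameters
#'
#' Builds the `SynapseGeometry` of an ideal circular synapse with a centered
#' circular cSMAC; used by generators and as ground truth in tests.
#' @param size_px square frame side.
#' @param n_frames number of frames (geometry repeated per frame).
#' @param center 0-based `(x, y)` center; default frame center.
#' @param synapse_radius_px,csmac_radius_px disc radii.
#' @return a `SynapseGeometry` object.
#' @export
make_circle_geometry <- function(size_px, n_frames = 1, center = NULL,
                                 synapse_radius_px, csmac_radius_px) {
  stopifnot(csmac_radius_px < synapse_radius_px)
  if (is.null(center)) center <- c((size_px - 1) / 2, (size_px - 1) / 2)
  syn <- disc_mask(size_px, size_px, center[1], center[2], synapse_radius_px)
  cs <- disc_mask(size_px, size_px, center[1], center[2], csmac_radius_px)
  contour <- mask_contour(syn)
  fr <- list(synapse = syn, csmac = cs, center = center,
             contour = contour, csmac_formed = TRUE,
             csmac_area_px = sum(cs))
  structure(list(frames = rep(list(fr), n_frames),
                 dim = c(size_px, size_px)),
            class = "SynapseGeometry")
}

#' Synthetic live-cell synapse movie
#'
#' Master channel: synapse disc + bright central cSMAC + condensate spots
#' moving inward from the periphery. Slave channel: the same spots with
#' amplitude scaled by a known content-decay function `g(r)` of the
#' normalized radial position and by global multiplicative photobleaching
#' `exp(-bleach_k * (t - 1))`.
#'
#' @param n_frames number of frames.
#' @param size_px frame side; default sized to fit the synapse.
#' @param synapse_radius_px,csmac_radius_px geometry radii.
#' @param tracks inward-track spec data.frame with columns `birth_frame`,
#'   `birth_r` (normalized radius in (csmac, 1]), `angle_deg`,
#'   `radial_speed` (normalized r units per frame, positive = inward),
#'   `wobble_deg` (SD of per-frame angular jitter), `amplitude`.
#' @param decay_g function mapping normalized radial position r in `[0, 1]`
#'   to relative slave content in `[0, 1]`.
#' @param bleach_k photobleach rate per frame (slave channel).
#' @param noise_sd additive Gaussian noise SD (both channels).
#' @param synapse_level,csmac_level,spot_sigma_px rendering parameters.
#' @param pixel_size_um,frame_interval_s calibration (5 s default for cells).
#' @param seed integer seed.
#' @return `list(master = ImageStack, slave = ImageStack, geometry =
#'   SynapseGeometry, ground_truth = list)`; ground truth holds per-frame
#'   true positions and r of every condensate, `decay_g`, and `bleach_k`.
#' @export
make_synapse_movie <- function(n_frames, size_px = NULL,
                               synapse_radius_px = 100, csmac_radius_px = 20,
                               tracks, decay_g = function(r) 1,
                               bleach_k = 0, noise_sd = 0,
                               synapse_level = 40, csmac_level = 100,
                               spot_amp_master = 150, spot_sigma_px = 1.0,
                               pixel_size_um = 0.16, frame_interval_s = 5,
                               seed = 1) {
  if (is.null(size_px)) size_px <- ceiling(2.4 * synapse_radius_px)
  stopifnot(csmac_radius_px < synapse_radius_px)
  if (any(tracks$birth_r > 1 | tracks$birth_r <= 0))
    stop("track birth radius outside synapse (birth_r must be in (0, 1])")
  geom <- make_circle_geometry(size_px, n_frames,
                               synapse_radius_px = synapse_radius_px,
                               csmac_radius_px = csmac_radius_px)
  center <- geom$frames[[1]]$center
  set.seed(seed)
  n_tr <- nrow(tracks)
  truth <- vector("list", n_frames)
  master_frames <- vector("list", n_frames)
  slave_frames <- vector("list", n_frames)
  # precompute per-track per-frame positions
  pos <- vector("list", n_tr)
  for (k in seq_len(n_tr)) {
    bf <- tracks$birth_frame[k]
    live <- bf:n_frames
    nf <- length(live)
    r <- pmax(tracks$birth_r[k] - tracks$radial_speed[k] * (seq_len(nf) - 1), 0)
    ang <- tracks$angle_deg[k] * pi / 180 +
      cumsum(c(0, stats::rnorm(nf - 1, 0, tracks$wobble_deg[k] * pi / 180)))
    pos[[k]] <- data.frame(
      frame = live, r = r,
      x = center[1] + r * synapse_radius_px * cos(ang),
      y = center[2] + r * synapse_radius_px * sin(ang))
  }
  for (t in seq_len(n_frames)) {
    base <- matrix(0, size_px, size_px)
    base[geom$frames[[1]]$synapse] <- synapse_level
    base[geom$frames[[1]]$csmac] <- csmac_level
    rows <- do.call(rbind, lapply(seq_len(n_tr), function(k) {
      p <- pos[[k]][pos[[k]]$frame == t, ]
      if (nrow(p) == 0L) return(NULL)
      cbind(track_id = k, p)
    }))
    mspots <- sspots <- data.frame(x = numeric(0), y = numeric(0),
                                   amplitude = numeric(0), sigma = numeric(0))
    if (!is.null(rows) && nrow(rows) > 0L) {
      mspots <- data.frame(x = rows$x, y = rows$y,
                           amplitude = spot_amp_master,
                           sigma = spot_sigma_px)
      sspots <- data.frame(x = rows$x, y = rows$y,
                           amplitude = spot_amp_master *
                             vapply(rows$r, decay_g, 0) *
                             exp(-bleach_k * (t - 1)),
                           sigma = spot_sigma_px)
    }
    m <- base + render_spots(size_px, size_px, mspots)
    s <- 0.5 * base * exp(-bleach_k * (t - 1)) +
      render_spots(size_px, size_px, sspots)
    if (noise_sd > 0) {
      m <- pmax(m + matrix(stats::rnorm(size_px^2, 0, noise_sd),
                           size_px, size_px), 0)
      s <- pmax(s + matrix(stats::rnorm(size_px^2, 0, noise_sd),
                           size_px, size_px), 0)
    }
    master_frames[[t]] <- m
    slave_frames[[t]] <- s
    truth[[t]] <- rows
  }
  list(master = image_stack(master_frames, pixel_size_um, frame_interval_s,
                            "master"),
       slave = image_stack(slave_frames, pixel_size_um, frame_interval_s,
                           "slave"),
       geometry = geom,
       ground_truth = list(positions = truth, decay_g = decay_g,
                           bleach_k = bleach_k, tracks = tracks,
                           synapse_radius_px = synapse_radius_px,
                           csmac_radius_px = csmac_radius_px,
                           center = center, noise_sd = noise_sd,
                           spot_amp_master = spot_amp_master, seed = seed))
}

#' Simulated composition study: movies, pipeline, pooled profile
#'
#' Emulates a live-cell composition experiment at the study's scale —
#' several cells, each contributing a handful of inward-moving condensates
#' — and runs the full pipeline on it: synapse/cSMAC segmentation,
#' local-maxima detection, tracking with gap closing, master/slave content
#' measurement, the four-filter track selection, and the pooled radial
#' composition profile with rank-sum tests.
#'
#' @param decay_g slave content decay function of normalized radius.
#' @param seed integer seed.
#' @param n_movies number of cells (movies) pooled.
#' @param tracks_per_movie inward tracks per cell (the study pools roughly
#'   5-10 condensates per cell).
#' @param n_frames frames per movie.
#' @param noise_sd additive noise SD.
#' @param reference_bin,min_bin_n passed to [composition_profile()]. The
#'   default reference is the 0.8-0.9 bin: the outermost bin holds each
#'   track's own first-three-frame normalization anchor — a degenerate,
#'   near-constant sample — and is not a fair rank-sum reference for
#'   ordinary measurement bins.
#' @return the pooled `composition_profile()` data.frame.
#' @export
simulate_composition_study <- function(decay_g, seed = 1, n_movies = 3,
                                       tracks_per_movie = 10,
                                       n_frames = 32, noise_sd = 2,
                                       reference_bin = 0.8, min_bin_n = 10) {
  all_tracks <- list(); mc_all <- list(); sc_all <- list()
  geom_ref <- NULL
  offset <- 0L
  for (mvi in seq_len(n_movies)) {
    s <- (as.numeric(seed) + 1000 * mvi) %% 2147483647
    set.seed(s)
    spec <- data.frame(birth_frame = sample(1:6, tracks_per_movie, TRUE),
                       birth_r = stats::runif(tracks_per_movie, 0.90, 0.95),
                       angle_deg = stats::runif(tracks_per_movie, 0, 360),
                       radial_speed = 0.02, wobble_deg = 1)
    smv <- make_synapse_movie(n_frames, synapse_radius_px = 100,
                              csmac_radius_px = 20, tracks = spec,
                              decay_g = decay_g, noise_sd = noise_sd,
                              seed = s + 1L)
    geom <- segment_geometry(smv$master)
    det <- detect_stack(smv$master, segmentation = "off")
    trk <- link_tracks(det$detections, search_radius_px = 5,
                       gap_window = 3)
    mc <- measure_track_contents(smv$master, det$labels, trk)
    sc <- measure_track_contents(smv$slave, det$labels, trk)
    sel <- select_tracks(trk, geom, sc)
    # keep only selected tracks, re-indexed into the pooled set; radii are
    # frozen per movie since each movie has its own geometry
    for (k in sel$selected) {
      offset <- offset + 1L
      tr <- trk[[k]]
      all_tracks[[offset]] <- tr
      r <- sel$radii[[k]]
      if (is.null(r)) r <- .track_radii(tr, geom)
      attr(all_tracks[[offset]], "radii") <- r
      mk <- mc[mc$track_id == k, ]; mk$track_id <- offset
      sk <- sc[sc$track_id == k, ]; sk$track_id <- offset
      mc_all[[offset]] <- mk; sc_all[[offset]] <- sk
    }
    if (is.null(geom_ref)) geom_ref <- geom
  }
  sel_pooled <- list(selected = seq_len(offset),
                     rejections = c(duration = 0L, anisotropy = 0L,
                                    position = 0L, content = 0L),
                     radii = lapply(all_tracks, attr, "radii"))
  composition_profile(all_tracks, sel_pooled, do.call(rbind, mc_all),
                      do.call(rbind, sc_all), geom_ref,
                      reference_bin = reference_bin, min_bin_n = min_bin_n)
}

#' Synthetic Hill-shaped binding curve
#'
#' Intensity follows `I = I_max * c^n / (K_D^n + c^n)` plus additive
#' Gaussian noise.
#' @param K_D dissociation constant (same units as `conc_grid`).
#' @param n Hill coefficient.
#' @param I_max saturation intensity.
#' @param conc_grid concentrations (>= 0).
#' @param noise_sd additive noise SD.
#' @param seed integer seed.
#' @return data.frame with `concentration` and `intensity`.
#' @export
make_binding_curve <- function(K_D, n, I_max, conc_grid, noise_sd = 0,
                               seed = 1) {
  stopifnot(K_D > 0, n > 0, all(conc_grid >= 0))
  set.seed(seed)
  mu <- I_max * conc_grid^n / (K_D^n + conc_grid^n)
  data.frame(concentration = conc_grid,
             intensity = mu + stats::rnorm(length(conc_grid), 0, noise_sd))
}

#' Synthetic filament-orientation speckles
#'
#' Positions are sampled uniformly inside the synapse mask; each speckle's
#' filament orientation is drawn from `orientation_rule` evaluated at its
#' normalized radial position.
#'
#' @param n number of speckles.
#' @param geom a `SynapseGeometry`.
#' @param orientation_rule function `r -> angle` giving the filament angle
#'   relative to the local synapse-edge tangent, in degrees (90 =
#'   perpendicular to the edge, 0 = parallel). May be stochastic.
#' @param frame geometry frame to use.
#' @param seed integer seed.
#' @return data.frame with `x`, `y` (0-based), `r`, and `orientation_deg`
#'   (absolute filament angle in the image frame, degrees).
#' @export
make_speckles <- function(n, geom, orientation_rule, frame = 1, seed = 1) {
  g <- geom$frames[[frame]]
  idx <- which(g$synapse)
  if (length(idx) == 0L) stop("empty synapse mask")
  set.seed(seed)
  pick <- sample(idx, n, replace = TRUE)
  h <- geom$dim[1]
  y <- (pick - 1) %% h          # 0-based row
  x <- (pick - 1) %/% h         # 0-based col
  # jitter within the pixel, then recompute r from geometry
  x <- x + stats::runif(n, -0.45, 0.45)
  y <- y + stats::runif(n, -0.45, 0.45)
  r <- vapply(seq_len(n), function(i)
    normalized_radial_position(c(x[i], y[i]), geom, frame)$r, 0)
  # local edge tangent: perpendicular to the ray from center (exact for the
  # circular geometries these are generated on)
  ray <- atan2(y - g$center[2], x - g$center[1]) * 180 / pi
  tangent <- ray + 90
  rel <- vapply(r, orientation_rule, 0)
  data.frame(x = x, y = y, r = r,
             orientation_deg = (tangent + rel) %% 180)
}
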