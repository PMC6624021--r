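# Tracking of detected condensates (frame-to-frame optimal assignment with
# gap closing and merge/split annotation) and mobility quantification by
# moment-scaling-spectrum (MSS) analysis.

.LAP_BIG <- 1e9

#' Link detections into tracks
#'
#' Frame-to-frame links minimize total squared displacement over a
#' one-to-one assignment (optimal, not greedy); links beyond
#' `search_radius_px` are forbidden, with the alternative (birth/death)
#' cost set just above the maximum allowed link cost. Track ends are then
#' re-joined to later track starts within the search radius and at most
#' `gap_window` missing frames apart, again by optimal assignment. Gap
#' frames are filled with linearly interpolated positions and flagged.
#'
#' @param dets detection data.frame with columns `frame`, `id`, `x`, `y`
#'   (as from [detect_stack()]; coordinates in pixels, 0-based).
#' @param search_radius_px maximum frame-to-frame displacement (default 5).
#' @param gap_window maximum number of missing frames a closed gap may span
#'   (default 3).
#' @param allow_merge_split annotate merge/split events (annotation only;
#'   tracks are not altered).
#' @param max_intensity_ratio when detections carry a `peak_intensity`
#'   column, links (direct or gap-closing) between detections whose peak
#'   intensities differ by more than this factor are forbidden (default 3)
#'   — a minimal amplitude-aware cost in the spirit of full particle
#'   trackers, preventing dim noise detections from stitching onto bright
#'   condensate tracks. Set to `Inf` to disable.
#' @return list of tracks, each a data.frame `(frame, x, y, det_id,
#'   is_gap)`; the list carries an `events` attribute with merge/split
#'   annotations `(type, track, other_track, frame)`.
#' @export
link_tracks <- function(dets, search_radius_px = 5, gap_window = 3,
                        allow_merge_split = TRUE, max_intensity_ratio = 3) {
  if (is.null(dets) || nrow(dets) == 0L) return(list())
  r2 <- search_radius_px^2
  has_peak <- "peak_intensity" %in% names(dets) &&
    is.finite(max_intensity_ratio)
  frames <- sort(unique(dets$frame))
  # segment bookkeeping: each segment is a list of row indices into dets
  dets$.row <- seq_len(nrow(dets))
  by_frame <- split(dets, dets$frame)
  segs <- lapply(by_frame[[as.character(frames[1])]]$.row, function(i) i)
  open_seg <- seq_along(segs)  # segments whose head is in the current frame
  for (fi in seq_len(length(frames) - 1L)) {
    f0 <- frames[fi]; f1 <- frames[fi + 1L]
    d1 <- by_frame[[as.character(f1)]]
    if (f1 != f0 + 1L || is.null(d1)) { open_seg <- integer(0) }
    if (is.null(d1)) next
    if (f1 != f0 + 1L) {
      # non-adjacent frames: all current detections start new segments
      for (i in d1$.row) { segs[[length(segs) + 1L]] <- i }
      open_seg <- seq.int(length(segs) - nrow(d1) + 1L, length(segs))
      next
    }
    heads <- vapply(open_seg, function(s) utils::tail(segs[[s]], 1L), 0L)
    n1 <- length(heads); n2 <- nrow(d1)
    if (n1 == 0L) {
      for (i in d1$.row) segs[[length(segs) + 1L]] <- i
      open_seg <- seq.int(length(segs) - n2 + 1L, length(segs))
      next
    }
    hx <- dets$x[heads]; hy <- dets$y[heads]
    d2mat <- outer(hx, d1$x, "-")^2 + outer(hy, d1$y, "-")^2
    if (has_peak) {
      pr <- outer(dets$peak_intensity[heads], d1$peak_intensity,
                  function(a, b) pmax(a, b) / pmin(a, b))
      d2mat[pr > max_intensity_ratio] <- Inf
    }
    ok <- which(d2mat <= r2, arr.ind = TRUE)
    edges <- data.frame(i = ok[, 1], j = ok[, 2],
                        cost = d2mat[ok])
    m <- sparse_assign(n1, n2, edges, alt = r2 * 1.05)
    new_open <- integer(0)
    linked2 <- logical(n2)
    for (k in seq_len(n1)) {
      j <- m[k]
      if (!is.na(j)) {
        s <- open_seg[k]
        segs[[s]] <- c(segs[[s]], d1$.row[j])
        new_open <- c(new_open, s)
        linked2[j] <- TRUE
      }
    }
    for (j in which(!linked2)) {
      segs[[length(segs) + 1L]] <- d1$.row[j]
      new_open <- c(new_open, length(segs))
    }
    open_seg <- new_open
  }
  # gap closing: join segment ends to later segment starts
  seg_start <- vapply(segs, function(s) dets$frame[s[1]], 0)
  seg_end <- vapply(segs, function(s) dets$frame[utils::tail(s, 1L)], 0)
  if (gap_window >= 1 && length(segs) > 1L) {
    ns_seg <- length(segs)
    ie <- vapply(segs, function(s) utils::tail(s, 1L), 0L)
    is_ <- vapply(segs, function(s) s[1], 0L)
    ex <- dets$x[ie]; ey <- dets$y[ie]
    sx <- dets$x[is_]; sy <- dets$y[is_]
    edges <- list()
    for (e in seq_len(ns_seg)) {
      miss <- seg_start - seg_end[e] - 1L
      cand <- which(miss >= 1L & miss <= gap_window)
      cand <- cand[cand != e]
      if (length(cand) == 0L) next
      dd <- (ex[e] - sx[cand])^2 + (ey[e] - sy[cand])^2
      okc <- dd <= r2
      if (has_peak) {
        pe <- dets$peak_intensity[ie[e]]
        ps <- dets$peak_intensity[is_[cand]]
        okc <- okc & pmax(pe, ps) / pmin(pe, ps) <= max_intensity_ratio
      }
      if (any(okc))
        edges[[length(edges) + 1L]] <- data.frame(
          i = e, j = cand[okc], cost = dd[okc])
    }
    edges <- if (length(edges)) do.call(rbind, edges) else NULL
    if (!is.null(edges)) {
      succ <- sparse_assign(ns_seg, ns_seg, edges, alt = r2 * 1.05)
      # stitch chains
      has_pred <- rep(FALSE, length(segs))
      has_pred[stats::na.omit(succ)] <- TRUE
      keep <- logical(length(segs))
      chains <- list()
      for (s in seq_along(segs)) {
        if (has_pred[s]) next
        chain <- s
        while (!is.na(succ[utils::tail(chain, 1L)]))
          chain <- c(chain, succ[utils::tail(chain, 1L)])
        chains[[length(chains) + 1L]] <- chain
      }
      segs <- lapply(chains, function(ch) unlist(segs[ch]))
    }
  }
  # build track data.frames with interpolated gap rows
  tracks <- lapply(segs, function(s) {
    fr <- dets$frame[s]
    df <- data.frame(frame = fr, x = dets$x[s], y = dets$y[s],
                     det_id = dets$id[s], is_gap = FALSE)
    full <- seq(min(fr), max(fr))
    if (length(full) > nrow(df)) {
      gaps <- setdiff(full, fr)
      gx <- stats::approx(fr, df$x, xout = gaps)$y
      gy <- stats::approx(fr, df$y, xout = gaps)$y
      df <- rbind(df, data.frame(frame = gaps, x = gx, y = gy,
                                 det_id = NA_integer_, is_gap = TRUE))
      df <- df[order(df$frame), ]
      rownames(df) <- NULL
    }
    df
  })
  ord <- order(vapply(tracks, function(tr) tr$frame[1], 0),
               vapply(tracks, function(tr) tr$x[1], 0))
  tracks <- tracks[ord]
  events <- data.frame(type = character(0), track = integer(0),
                       other_track = integer(0), frame = integer(0))
  if (allow_merge_split && length(tracks) > 1L) {
    all_pts <- do.call(rbind, lapply(seq_along(tracks), function(i) {
      tr <- tracks[[i]]
      data.frame(track = i, frame = tr$frame, x = tr$x, y = tr$y,
                 first = tr$frame[1], last = tr$frame[nrow(tr)])
    }))
    last_frame <- max(dets$frame); first_frame <- min(dets$frame)
    ev <- list()
    for (i in seq_along(tracks)) {
      tri <- tracks[[i]]
      n <- nrow(tri)
      fe <- tri$frame[n]
      if (fe < last_frame) {
        cand <- all_pts[all_pts$frame == fe + 1L & all_pts$track != i &
                          all_pts$first <= fe, , drop = FALSE]
        hit <- cand[(cand$x - tri$x[n])^2 + (cand$y - tri$y[n])^2 <= r2, ]
        for (j in unique(hit$track))
          ev[[length(ev) + 1L]] <- data.frame(
            type = "merge", track = i, other_track = j, frame = fe)
      }
      fs <- tri$frame[1]
      if (fs > first_frame) {
        cand <- all_pts[all_pts$frame == fs - 1L & all_pts$track != i &
                          all_pts$last >= fs, , drop = FALSE]
        hit <- cand[(cand$x - tri$x[1])^2 + (cand$y - tri$y[1])^2 <= r2, ]
        for (j in unique(hit$track))
          ev[[length(ev) + 1L]] <- data.frame(
            type = "split", track = i, other_track = j, frame = fs)
      }
    }
    if (length(ev) > 0L) events <- do.call(rbind, ev)
  }
  attr(tracks, "events") <- events
  tracks
}

#' Flatten a track list into one data.frame
#' @param tracks list of track data.frames from [link_tracks()].
#' @return data.frame with a `track_id` column.
#' @export
tracks_to_df <- function(tracks) {
  if (length(tracks) == 0L)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0)))
  do.call(rbind, lapply(seq_along(tracks), function(i)
    cbind(track_id = i, tracks[[i]])))
}

#' Moment scaling spectrum analysis of one track
#'
#' For each lag tau up to `max_lag_fraction * duration`, the nu-th moment
#' is the time average of `|displacement over tau|^nu` for nu = 0..6. The
#' scaling exponent gamma_nu is the slope of `log mu_nu` vs `log tau`
#' (ordinary least squares, equal lag weights; lags with fewer than 5
#' displacement samples are excluded, relaxed to 2 when nothing remains).
#' The MSS slope S is the least-squares slope of gamma_nu vs nu over
#' nu = 1..6: 0.5 for Brownian motion, 1 in the ballistic limit, below 0.5
#' for confined motion. The effective diffusion coefficient D2 is
#' `exp(intercept of the nu = 2 fit) / 4` with lags in seconds, in um^2/s
#' when positions are in micrometres.
#'
#' @param track data.frame with `frame`, `x`, `y` (positions in um for
#'   physical units; use `pixel_size_um` to convert pixel tracks).
#' @param frame_interval_s frame interval in seconds.
#' @param max_lag_fraction largest lag as a fraction of track duration.
#' @param pixel_size_um optional scale applied to `x`, `y` before analysis.
#' @return list with `gamma` (named vector, nu = 0..6), `S`, `D2`,
#'   `n_lags`.
#' @export
mss <- function(track, frame_interval_s, max_lag_fraction = 0.1,
                pixel_size_um = 1) {
  n <- nrow(track)
  if (n < 5) stop("MSS requires tracks lasting a minimum of 5 frames")
  x <- track$x * pixel_size_um
  y <- track$y * pixel_size_um
  nu <- 0:6
  max_lag <- max(2L, floor(max_lag_fraction * n))
  lags <- seq_len(min(max_lag, n - 1L))
  enough <- (n - lags) >= 5L
  if (sum(enough) < 2L) enough <- (n - lags) >= 2L
  lags <- lags[enough]
  if (length(lags) < 2L) stop("track too short for MSS lag fit")
  mom <- matrix(0, length(lags), length(nu))
  for (li in seq_along(lags)) {
    tau <- lags[li]
    disp <- sqrt((x[(1 + tau):n] - x[1:(n - tau)])^2 +
                 (y[(1 + tau):n] - y[1:(n - tau)])^2)
    mom[li, ] <- vapply(nu, function(v) mean(disp^v), 0)
  }
  if (all(mom[, 3] == 0)) {  # immobile: all displacements zero
    gamma <- stats::setNames(rep(0, length(nu)), nu)
    return(list(gamma = gamma, S = 0, D2 = 0, n_lags = length(lags)))
  }
  lt <- log(lags * frame_interval_s)
  gamma <- numeric(length(nu))
  d2 <- 0
  for (vi in seq_along(nu)) {
    if (nu[vi] == 0) { gamma[vi] <- 0; next }
    lm_ok <- mom[, vi] > 0
    if (sum(lm_ok) < 2L) { gamma[vi] <- NA_real_; next }
    fit <- stats::lm.fit(cbind(1, lt[lm_ok]), log(mom[lm_ok, vi]))
    gamma[vi] <- fit$coefficients[2]
    if (nu[vi] == 2) d2 <- exp(fit$coefficients[1]) / 4
  }
  use <- nu >= 1 & is.finite(gamma)
  S <- if (sum(use) >= 2L)
    unname(stats::lm.fit(cbind(1, nu[use]), gamma[use])$coefficients[2])
  else NA_real_
  list(gamma = stats::setNames(gamma, nu), S = S, D2 = d2,
       n_lags = length(lags))
}

#' MSS analysis of a track ensemble
#' @param tracks list of track data.frames (or a data.frame with
#'   `track_id`).
#' @inheritParams mss
#' @param min_frames minimum track duration (frames) to analyze.
#' @return data.frame `(track_id, D2, S, n_frames, n_lags)` plus
#'   `median_D2`, `median_S` attributes.
#' @export
mss_ensemble <- function(tracks, frame_interval_s, max_lag_fraction = 0.1,
                         pixel_size_um = 1, min_frames = 5) {
  if (is.data.frame(tracks)) tracks <- split(tracks, tracks$track_id)
  rows <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    if (nrow(tr) < min_frames) return(NULL)
    m <- mss(tr, frame_interval_s, max_lag_fraction, pixel_size_um)
    data.frame(track_id = i, D2 = m$D2, S = m$S, n_frames = nrow(tr),
               n_lags = m$n_lags)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(track_id = integer(0), D2 = numeric(0),
                      S = numeric(0), n_frames = integer(0),
                      n_lags = integer(0))
  attr(out, "median_D2") <- stats::median(out$D2)
  attr(out, "median_S") <- stats::median(out$S, na.rm = TRUE)
  out
}

#' Anisotropy of the scatter of track positions
#'
#' Square root of the ratio of the larger to the smaller eigenvalue of the
#' 2x2 position-scatter (covariance) matrix. Approximately 1 for isotropic
#' scatter, large for linear tracks; collinear tracks (zero smaller
#' eigenvalue) return `Inf`.
#'
#' @param track data.frame with `x`, `y` (at least 3 distinct positions).
#' @return scalar >= 1 (possibly `Inf`).
#' @export
track_anisotropy <- function(track) {
  pts <- unique(track[, c("x", "y")])
  if (nrow(pts) < 3L)
    stop("track anisotropy requires at least 3 distinct positions")
  cv <- stats::cov(cbind(pts$x, pts$y))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev)
  if (ev[1] <= .Machine$double.eps * max(ev[2], 1)) return(Inf)
  sqrt(ev[2] / ev[1])
}
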