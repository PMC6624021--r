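# Trajectory-shape statistics: transition-point detection (edge-travel vs
# inward movement), track trimming at the cSMAC, and endpoint-zeroed
# deviation from a straight path.

#' Find the transition from edge travel to inward movement
#'
#' At every interior time point the ratio R of the frame-to-frame change in
#' distance to the cSMAC center to the absolute turn angle between
#' consecutive displacements (floored at `angle_floor_rad`) is computed.
#' Before a condensate turns inward the distance change is low and the turn
#' angle high; after, the reverse. The transition is the first time point
#' with R at or above the 90th percentile of the within-track R values; if
#' the position there is already inside the actin position threshold
#' (`r < position_threshold`), the 75th percentile is used instead. The
#' returned point's r is reported for audit rather than enforced.
#'
#' @param track data.frame `(frame, x, y)` with at least 5 rows.
#' @param geom a `SynapseGeometry`.
#' @param position_threshold actin position threshold (default 0.6).
#' @param angle_floor_rad floor for the turn angle (default 1e-3 rad).
#' @return `list(index` (row index in `track`), `frame`, `r`,
#'   `percentile_used)`.
#' @export
find_transition <- function(track, geom, position_threshold = 0.6,
                            angle_floor_rad = 1e-3) {
  n <- nrow(track)
  if (n < 5) stop("transition detection requires at least 5 track points")
  fr1 <- min(track$frame[1], length(geom$frames))
  ctr <- geom$frames[[fr1]]$center
  d <- sqrt((track$x - ctr[1])^2 + (track$y - ctr[2])^2)
  vx <- diff(track$x); vy <- diff(track$y)
  # interior time points t = 2..n-1 have both a distance change and a turn
  # angle defined
  idx <- 2:(n - 1)
  ddist <- abs(d[idx + 1] - d[idx])
  dot <- vx[idx - 1] * vx[idx] + vy[idx - 1] * vy[idx]
  nrm <- sqrt(vx[idx - 1]^2 + vy[idx - 1]^2) * sqrt(vx[idx]^2 + vy[idx]^2)
  ang <- ifelse(nrm > 0, acos(pmin(pmax(dot / nrm, -1), 1)), 0)
  ang <- pmax(ang, angle_floor_rad)
  R <- ddist / ang
  if (length(R) < 3) stop("fewer than 3 displacement ratios available")
  pick <- function(p) {
    thr <- percentile_linear(R, p)
    # relative tolerance so exact ties (e.g. perfectly straight tracks,
    # where all ratios are equal up to rounding) resolve to the first point
    idx[which(R >= thr - 1e-9 * max(thr, 1))[1]]
  }
  t90 <- pick(0.90)
  r90 <- normalized_radial_position(c(track$x[t90], track$y[t90]), geom,
                                    min(track$frame[t90],
                                        length(geom$frames)))$r
  if (r90 >= position_threshold)
    return(list(index = t90, frame = track$frame[t90], r = r90,
                percentile_used = 0.90))
  t75 <- pick(0.75)
  r75 <- normalized_radial_position(c(track$x[t75], track$y[t75]), geom,
                                    min(track$frame[t75],
                                        length(geom$frames)))$r
  list(index = t75, frame = track$frame[t75], r = r75,
       percentile_used = 0.75)
}

#' Trim a track to its inward-travel segment
#'
#' Returns the segment from the transition point to the last time point
#' before the condensate's position first falls inside the cSMAC mask.
#'
#' @param track data.frame `(frame, x, y)`.
#' @param geom a `SynapseGeometry`.
#' @param transition row index of the transition point (from
#'   [find_transition()]).
#' @return the trimmed track data.frame.
#' @export
trim_track <- function(track, geom, transition) {
  n <- nrow(track)
  stopifnot(transition >= 1, transition <= n)
  in_csmac <- vapply(seq_len(n), function(i) {
    g <- geom$frames[[min(track$frame[i], length(geom$frames))]]
    x <- round(track$x[i]) + 1; y <- round(track$y[i]) + 1
    x >= 1 && x <= ncol(g$csmac) && y >= 1 && y <= nrow(g$csmac) &&
      g$csmac[y, x]
  }, TRUE)
  entry <- which(in_csmac)[1]
  last <- if (is.na(entry)) n else entry - 1L
  if (transition > last)
    stop("transition point lies at or beyond cSMAC entry; empty segment")
  track[transition:last, , drop = FALSE]
}

#' Signed deviations from a straight path
#'
#' The segment is rigidly rotated and translated so that its first and
#' last points lie on the x-axis (y = 0); the deviation at each time point
#' is then its y-coordinate. The sign is flipped, if necessary, so that the
#' count of positive deviations is at least the count of negative ones
#' (ties broken toward the orientation with the larger positive sum).
#'
#' @param segment data.frame `(x, y)` with at least 3 points and distinct
#'   endpoints.
#' @return numeric vector of signed deviations (same length units as the
#'   input coordinates).
#' @export
straight_path_deviation <- function(segment) {
  n <- nrow(segment)
  if (n < 3) stop("segment must have at least 3 points")
  dx <- segment$x[n] - segment$x[1]
  dy <- segment$y[n] - segment$y[1]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("segment endpoints coincide")
  ux <- dx / len; uy <- dy / len
  relx <- segment$x - segment$x[1]
  rely <- segment$y - segment$y[1]
  dev <- -uy * relx + ux * rely  # perpendicular component
  eps <- 1e-9 * max(abs(dev), 1)  # endpoints are zero only up to rounding
  npos <- sum(dev > eps); nneg <- sum(dev < -eps)
  flip <- npos < nneg ||
    (npos == nneg && sum(dev[dev > 0]) < sum(-dev[dev < 0]))
  if (flip) dev <- -dev
  dev
}

#' Pooled deviation distribution for a track ensemble
#'
#' Convenience wrapper: per track, finds the transition point, trims at the
#' cSMAC, and pools the signed deviations of all time points of all tracks.
#' Tracks that fail (too short, degenerate segment) are skipped with a
#' count.
#'
#' @param tracks track list.
#' @param geom a `SynapseGeometry`.
#' @param position_threshold actin position threshold (default 0.6).
#' @return `list(deviations = numeric vector, n_tracks_used, n_skipped)`.
#' @export
deviation_distribution <- function(tracks, geom, position_threshold = 0.6) {
  devs <- numeric(0); used <- 0L; skipped <- 0L
  for (tr in tracks) {
    d <- tryCatch({
      trans <- find_transition(tr, geom, position_threshold)
      seg <- trim_track(tr, geom, trans$index)
      straight_path_deviation(seg)
    }, error = function(e) NULL)
    if (is.null(d)) { skipped <- skipped + 1L } else {
      devs <- c(devs, d); used <- used + 1L
    }
  }
  list(deviations = devs, n_tracks_used = used, n_skipped = skipped)
}
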