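# Immunological-synapse geometry: synapse / cSMAC segmentation, the
# normalized radial coordinate r (0 at the cSMAC center, 1 at the synapse
# edge), radial actin profiles, and filament-orientation classification.

#' Ordered boundary contour of a mask
#'
#' Boundary pixels (mask pixels with a 4-neighbor outside) ordered by angle
#' around the mask centroid; adequate for the star-convex synapse shapes
#' this package segments.
#' @param mask logical matrix.
#' @return matrix with columns `x`, `y` (0-based), ordered by angle.
#' @export
mask_contour <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  edge <- which(mask & !interior)
  if (length(edge) == 0L) stop("degenerate contour: empty mask boundary")
  y <- (edge - 1) %% h
  x <- (edge - 1) %/% h
  cx <- mean(x); cy <- mean(y)
  ord <- order(atan2(y - cy, x - cx))
  cbind(x = x[ord], y = y[ord])
}

# segment one frame into synapse mask (largest/central 2-level object)
.segment_synapse_frame <- function(img, smooth_sigma_px) {
  sm <- gaussian_blur(img, smooth_sigma_px)
  thr <- otsu_thresholds(sm, 1)
  lab <- label_components(sm > thr)
  if (max(lab) == 0L) stop("no object found in frame")
  h <- nrow(img); w <- ncol(img)
  ctr_lab <- lab[round(h / 2), round(w / 2)]
  if (ctr_lab > 0L) return(lab == ctr_lab)
  # nearest component to the frame center; ties to the larger one
  cands <- seq_len(max(lab))
  dmin <- vapply(cands, function(l) {
    idx <- which(lab == l)
    yy <- (idx - 1) %% h + 1; xx <- (idx - 1) %/% h + 1
    min((yy - h / 2)^2 + (xx - w / 2)^2)
  }, 0)
  area <- tabulate(lab[lab > 0], max(lab))
  best <- cands[order(dmin, -area)][1]
  lab == best
}

# cSMAC from the master (LAT) channel: largest highest-tier 3-level region
# inside the synapse
.segment_csmac_frame <- function(img, synapse, smooth_sigma_px,
                                 min_csmac_area_px) {
  sm <- gaussian_blur(img, smooth_sigma_px)
  thr <- tryCatch(otsu_thresholds(sm, 2), error = function(e) NULL)
  if (is.null(thr)) return(NULL)
  top <- (sm > thr[2]) & synapse
  lab <- label_components(top)
  if (max(lab) == 0L) return(NULL)
  area <- tabulate(lab[lab > 0], max(lab))
  best <- which.max(area)
  # a credible cSMAC is neither tiny nor most of the synapse (a top tier
  # spanning the synapse means the image is still bimodal: not formed yet)
  if (area[best] < min_csmac_area_px ||
      area[best] > 0.5 * sum(synapse)) return(NULL)
  m <- lab == best
  h <- nrow(img)
  idx <- which(m)
  list(mask = m,
       center = c(mean((idx - 1) %/% h), mean((idx - 1) %% h)))
}

#' Segment synapse and cSMAC geometry
#'
#' Per frame: the synapse is the central object of a two-level Otsu
#' threshold of the Gaussian-smoothed actin channel (or the master channel
#' when no actin channel is available); the cSMAC is the largest
#' highest-intensity-tier region of a three-level threshold of the master
#' channel inside the synapse. Frames before cSMAC formation (top-tier area
#' below `min_csmac_area_px`) receive the cSMAC center segmented from the
#' time-averaged master image, with area 0.
#'
#' @param master master-channel (LAT) `ImageStack`; always used for the
#'   cSMAC.
#' @param actin optional actin-channel `ImageStack` used for the synapse
#'   outline.
#' @param smooth_sigma_px smoothing kernel sigma (default 2).
#' @param min_csmac_area_px minimum top-tier area for a formed cSMAC.
#' @return a `SynapseGeometry`: list with `frames` (per frame: `synapse`
#'   mask, `csmac` mask, `center` `(x, y)` 0-based, `contour`,
#'   `csmac_formed`, `csmac_area_px`) and `dim`.
#' @export
segment_geometry <- function(master, actin = NULL, smooth_sigma_px = 2,
                             min_csmac_area_px = 20) {
  nt <- n_frames(master)
  syn_src <- if (is.null(actin)) master else actin
  frames <- vector("list", nt)
  missing_cs <- integer(0)
  for (t in seq_len(nt)) {
    syn <- .segment_synapse_frame(get_frame(syn_src, t), smooth_sigma_px)
    cs <- .segment_csmac_frame(get_frame(master, t), syn, smooth_sigma_px,
                               min_csmac_area_px)
    frames[[t]] <- list(
      synapse = syn,
      csmac = if (is.null(cs)) syn & FALSE else cs$mask,
      center = if (is.null(cs)) c(NA_real_, NA_real_) else cs$center,
      contour = mask_contour(syn),
      csmac_formed = !is.null(cs),
      csmac_area_px = if (is.null(cs)) 0 else sum(cs$mask))
    if (is.null(cs)) missing_cs <- c(missing_cs, t)
  }
  if (length(missing_cs) > 0L) {
    avg <- apply(master$frames, c(2, 3), mean)
    syn_avg <- .segment_synapse_frame(
      if (is.null(actin)) avg else apply(actin$frames, c(2, 3), mean),
      smooth_sigma_px)
    cs_avg <- .segment_csmac_frame(avg, syn_avg, smooth_sigma_px,
                                   min_csmac_area_px)
    if (is.null(cs_avg))
      stop("cSMAC not found in any frame nor in the time-averaged image")
    for (t in missing_cs) frames[[t]]$center <- cs_avg$center
  }
  structure(list(frames = frames, dim = dim(master$frames)[2:3]),
            class = "SynapseGeometry")
}

#' @export
print.SynapseGeometry <- function(x, ...) {
  cat(sprintf("SynapseGeometry: %d frame(s), %d x %d px\n",
              length(x$frames), x$dim[1], x$dim[2]))
  invisible(x)
}

#' Normalized radial position within the synapse
#'
#' A straight ray is cast from the cSMAC center through the point and
#' marched outward in 0.25-px steps until it exits the synapse mask; the
#' last inside position is the edge point. The normalized radial position
#' is the ratio of the point's distance from the center to the full
#' center-to-edge distance: 0 at the center, 1 at the edge. Points outside
#' the synapse mask are clamped to r = 1 and flagged.
#'
#' @param point `(x, y)` 0-based coordinates.
#' @param geom a `SynapseGeometry`.
#' @param frame frame index.
#' @return `list(r, edge = c(x, y), flagged)`.
#' @export
normalized_radial_position <- function(point, geom, frame = 1) {
  g <- geom$frames[[frame]]
  ctr <- g$center
  if (any(is.na(ctr))) stop("geometry has no cSMAC center for this frame")
  dx <- point[1] - ctr[1]; dy <- point[2] - ctr[2]
  dist <- sqrt(dx^2 + dy^2)
  if (dist == 0) return(list(r = 0, edge = ctr, flagged = FALSE))
  ux <- dx / dist; uy <- dy / dist
  h <- geom$dim[1]; w <- geom$dim[2]
  max_len <- sqrt(h^2 + w^2)
  steps <- seq(0, max_len, by = 0.25)
  px <- ctr[1] + steps * ux; py <- ctr[2] + steps * uy
  ok <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
  inside <- rep(FALSE, length(steps))
  inside[ok] <- g$synapse[cbind(round(py[ok]) + 1, round(px[ok]) + 1)]
  exit <- which(!inside)
  exit <- exit[exit > 1]
  last_in <- if (length(exit) == 0L) length(steps) else exit[1] - 1L
  if (last_in < 1L) stop("ray fails to intersect the synapse contour")
  edge_len <- steps[last_in]
  if (edge_len == 0) stop("ray fails to intersect the synapse contour")
  r <- dist / edge_len
  flagged <- r > 1
  list(r = min(r, 1), edge = c(px[last_in], py[last_in]), flagged = flagged)
}

#' Radial intensity profiles and the actin peak position
#'
#' Takes `n_lines` straight intensity profiles from the synapse edge to the
#' cSMAC center at equal angular spacing (45 degrees for the default 8),
#' bilinearly interpolated, and reports each line's intensity-peak
#' normalized radial position. The pooled median peak position over lines
#' (and, pooled by the caller, frames and cells) is the position threshold
#' used to select inward-moving tracks.
#'
#' @param actin_frame 2-D actin intensity matrix.
#' @param geom a `SynapseGeometry`.
#' @param frame frame index.
#' @param n_lines number of radial lines (default 8).
#' @param n_samples samples per line.
#' @param flat_tol lines whose intensity range is below this fraction of
#'   the frame's range are flagged and excluded from the peak pool.
#' @return `list(profiles, peaks, median_peak_r)`; `profiles` has columns
#'   `(line, r, intensity)`, `peaks` has `(line, peak_r, flat)`.
#' @export
radial_profiles <- function(actin_frame, geom, frame = 1, n_lines = 8,
                            n_samples = 200, flat_tol = 1e-6) {
  g <- geom$frames[[frame]]
  ctr <- g$center
  if (any(is.na(ctr))) stop("geometry has no cSMAC center for this frame")
  angles <- (seq_len(n_lines) - 1) * 2 * pi / n_lines
  rng <- diff(range(actin_frame))
  profs <- list(); peaks <- list()
  for (li in seq_len(n_lines)) {
    probe <- c(ctr[1] + cos(angles[li]), ctr[2] + sin(angles[li]))
    edge <- normalized_radial_position(probe, geom, frame)$edge
    rr <- seq(0, 1, length.out = n_samples)
    xs <- ctr[1] + rr * (edge[1] - ctr[1])
    ys <- ctr[2] + rr * (edge[2] - ctr[2])
    iv <- interp_bilinear(actin_frame, xs, ys)
    flat <- diff(range(iv)) <= max(flat_tol * rng,
                                   1e-9 * max(abs(iv)),
                                   .Machine$double.eps)
    profs[[li]] <- data.frame(line = li, r = rr, intensity = iv)
    peaks[[li]] <- data.frame(line = li,
                              peak_r = if (flat) NA_real_ else
                                rr[which.max(iv)],
                              flat = flat)
  }
  peaks <- do.call(rbind, peaks)
  list(profiles = do.call(rbind, profs), peaks = peaks,
       median_peak_r = stats::median(peaks$peak_r[!peaks$flat]))
}

#' Fraction of filaments perpendicular to the synapse edge, by radial bin
#'
#' Each speckle's filament orientation is compared with the local synapse
#' edge tangent (estimated from a 5-point window of the boundary contour at
#' the speckle's ray-edge intersection). A filament is "perpendicular" when
#' the acute angle between filament and tangent is within 45 degrees of 90
#' (inclusive). Speckle inputs may be filament orientations or fluorophore
#' dipole orientations; dipoles are rotated by 90 degrees since the dye's
#' dipole lies orthogonal to the underlying filament.
#'
#' @param speckles data.frame with `x`, `y`, `orientation_deg` (and
#'   optionally precomputed `r`).
#' @param geom a `SynapseGeometry`.
#' @param frame frame index.
#' @param bin_width radial bin width (default 0.1).
#' @param input `"filament"` or `"dipole"`.
#' @return data.frame `(bin_lo, bin_hi, n, fraction_perpendicular)`; empty
#'   bins carry `NA`.
#' @export
speckle_orientation_fractions <- function(speckles, geom, frame = 1,
                                          bin_width = 0.1,
                                          input = c("filament", "dipole")) {
  input <- match.arg(input)
  g <- geom$frames[[frame]]
  contour <- g$contour
  nC <- nrow(contour)
  n <- nrow(speckles)
  ori <- speckles$orientation_deg
  if (input == "dipole") ori <- ori + 90
  perp <- logical(n); rs <- numeric(n)
  for (i in seq_len(n)) {
    p <- c(speckles$x[i], speckles$y[i])
    np <- normalized_radial_position(p, geom, frame)
    rs[i] <- if (!is.null(speckles$r)) speckles$r[i] else np$r
    # nearest contour point to the ray-edge intersection
    d2 <- (contour[, 1] - np$edge[1])^2 + (contour[, 2] - np$edge[2])^2
    ci <- which.min(d2)
    lo <- ((ci - 3) %% nC) + 1L
    hi <- ((ci + 1) %% nC) + 1L
    tangent <- atan2(contour[hi, 2] - contour[lo, 2],
                     contour[hi, 1] - contour[lo, 1]) * 180 / pi
    d <- abs((ori[i] - tangent) %% 180)
    if (d > 90) d <- 180 - d
    perp[i] <- d >= 45
  }
  edges <- seq(0, 1, by = bin_width)
  bin <- findInterval(rs, edges, rightmost.closed = TRUE)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1])
  out$n <- vapply(seq_len(nrow(out)), function(b) sum(bin == b), 0L)
  out$fraction_perpendicular <- vapply(seq_len(nrow(out)), function(b)
    if (out$n[b] == 0L) NA_real_ else mean(perp[bin == b]), 0)
  out
}
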