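# Condensate detection: stage-drift correction, per-frame detection by
# local maxima + Otsu segmentation, the isolated-condensate peak/valley
# ratio threshold, and seeded-watershed splitting of multi-maximum regions.

#' Correct stage drift by adjacent-frame cross-correlation
#'
#' Each frame t > 1 is shifted by the integer offset that maximizes the
#' normalized (Pearson) cross-correlation of its overlap with frame t - 1,
#' searched over offsets within `max_shift_px`; shifts accumulate along the
#' movie. Ties are broken toward the smaller-magnitude shift. Use
#' [apply_drift()] to apply the identical shifts to companion channels.
#'
#' @param stack an `ImageStack` with at least 2 frames.
#' @param max_shift_px search window half-width (default 10).
#' @return `list(stack = corrected ImageStack, drift = data.frame(frame,
#'   dy, dx, at_limit))` with cumulative shifts applied per frame (frame 1
#'   is (0, 0)); `at_limit` flags best-in-window shifts on the search
#'   boundary.
#' @export
correct_drift <- function(stack, max_shift_px = 10) {
  stopifnot(max_shift_px >= 1)
  nt <- n_frames(stack)
  if (nt < 2) stop("drift correction needs at least 2 frames")
  offs <- expand.grid(dy = -max_shift_px:max_shift_px,
                      dx = -max_shift_px:max_shift_px)
  offs <- offs[order(offs$dy^2 + offs$dx^2, abs(offs$dy), abs(offs$dx)), ]
  cum <- matrix(0L, nt, 2)
  at_limit <- logical(nt)
  for (t in 2:nt) {
    a <- get_frame(stack, t - 1)
    b <- get_frame(stack, t)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant frame at t=", t, "; correlation undefined, shift 0")
      cum[t, ] <- cum[t - 1, ]
      next
    }
    best <- -Inf; bdy <- 0L; bdx <- 0L
    h <- nrow(a); w <- ncol(a)
    for (i in seq_len(nrow(offs))) {
      dy <- offs$dy[i]; dx <- offs$dx[i]
      # shifting b by (dy, dx): b[y - dy, x - dx] overlaps a[y, x]
      ya <- max(1, 1 + dy):min(h, h + dy)
      xa <- max(1, 1 + dx):min(w, w + dx)
      sub_a <- a[ya, xa]
      sub_b <- b[ya - dy, xa - dx]
      if (stats::sd(sub_a) == 0 || stats::sd(sub_b) == 0) next
      cc <- stats::cor(as.numeric(sub_a), as.numeric(sub_b))
      if (cc > best + 1e-12) { best <- cc; bdy <- dy; bdx <- dx }
    }
    cum[t, ] <- cum[t - 1, ] + c(bdy, bdx)
    at_limit[t] <- abs(bdy) == max_shift_px || abs(bdx) == max_shift_px
  }
  frames <- lapply(seq_len(nt), function(t)
    shift_frame(get_frame(stack, t), cum[t, 1], cum[t, 2]))
  out <- image_stack(frames, stack$pixel_size_um, stack$frame_interval_s,
                     stack$channel_name)
  list(stack = out,
       drift = data.frame(frame = seq_len(nt), dy = cum[, 1], dx = cum[, 2],
                          at_limit = at_limit))
}

#' Apply a drift series to a companion channel
#' @param stack an `ImageStack`.
#' @param drift the `drift` data.frame from [correct_drift()].
#' @return the shifted `ImageStack`.
#' @export
apply_drift <- function(stack, drift) {
  nt <- n_frames(stack)
  stopifnot(nrow(drift) == nt)
  frames <- lapply(seq_len(nt), function(t)
    shift_frame(get_frame(stack, t), drift$dy[t], drift$dx[t]))
  image_stack(frames, stack$pixel_size_um, stack$frame_interval_s,
              stack$channel_name)
}

# Fixed-sigma 2-D Gaussian least-squares fit (amplitude, offset, center)
# on a small patch around a maximum, by Gauss-Newton with analytic
# Jacobian; returns the sub-pixel center (0-based). Falls back to the
# input position if the fit diverges.
.gauss_fit_center <- function(img, x0, y0, sigma, half = 3L) {
  h <- nrow(img); w <- ncol(img)
  xs <- max(0, x0 - half):min(w - 1, x0 + half)
  ys <- max(0, y0 - half):min(h - 1, y0 + half)
  px <- rep(xs, each = length(ys)); py <- rep(ys, length(xs))
  z <- as.numeric(img[ys + 1, xs + 1])
  p <- c(x0, y0, max(z) - min(z), min(z))  # (cx, cy, A, offset)
  s2 <- sigma^2
  for (it in 1:25) {
    g <- exp(-((px - p[1])^2 + (py - p[2])^2) / (2 * s2))
    mu <- p[4] + p[3] * g
    r <- z - mu
    J <- cbind(p[3] * g * (px - p[1]) / s2,
               p[3] * g * (py - p[2]) / s2,
               g, 1)
    step <- tryCatch(solve(crossprod(J) + diag(1e-9, 4), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    p <- p + as.numeric(step)
    if (max(abs(step[1:2])) < 1e-4) break
  }
  if (!is.finite(p[1]) || !is.finite(p[2]) ||
      abs(p[1] - x0) > half || abs(p[2] - y0) > half) return(c(x0, y0))
  c(p[1], p[2])
}

#' Detect condensates in one frame
#'
#' Pipeline: (i) estimate the inhomogeneous background by blurring with a
#' large Gaussian kernel (sigma `bg_sigma_px`, default 10), subtract, clamp
#' at 0; (ii) suppress noise with a small Gaussian kernel (sigma
#' `noise_sigma_px`, default 1); (iii) segment the filtered image with a
#' two-class Otsu threshold and find significant strict 8-neighborhood
#' local maxima (see below). Three scenarios result: a segmented region
#' with one maximum
#' (`"segmented-single"`), a maximum outside any region
#' (`"diffraction-limited"`, assigned a disc of radius `3 * psf_sigma_px`),
#' and a segmented region with several maxima, which is split by
#' [resolve_multimax()] (`"watershed-split"`) using `ratio_thresh`.
#'
#' The significance of a local maximum is judged against the local
#' background of the filtered image: the filtered value must exceed the
#' local background mean (a second large-kernel Gaussian estimate on the
#' filtered image) by `maxima_threshold_k` times the robust noise SD (MAD
#' of the unclamped filtered residual). Otsu segmentation is honored only
#' when its threshold itself clears this significance cut over the
#' background median; otherwise the frame is treated as containing only
#' diffraction-limited condensates, as appropriate for dim low-SNR data.
#'
#' @param frame 2-D intensity matrix (finite, non-negative).
#' @param psf_sigma_px PSF sigma in pixels (default 0.46; disc radius is
#'   `3 * 0.46 = 1.4` px, i.e. 222 nm at 0.16 um/px).
#' @param bg_sigma_px,noise_sigma_px pipeline kernel sigmas.
#' @param maxima_threshold_k significance multiplier k (default 3.5, which
#'   keeps the expected count of noise maxima passing the cut well below
#'   one per 128 x 128 frame; a 3-sigma cut admits several per frame).
#' @param ratio_thresh peak/valley ratio threshold for multi-maximum
#'   regions, from [ratio_threshold()]; if `NULL`, computed from this
#'   frame's isolated condensates, falling back to
#'   `fallback_ratio_threshold` if there are too few.
#' @param min_isolated minimum number of isolated condensates required to
#'   estimate the ratio threshold.
#' @param fallback_ratio_threshold threshold used when too few isolated
#'   condensates are available.
#' @param segmentation `"auto"` (honor Otsu segmentation only when its
#'   threshold is significantly bright, see above), `"on"`, or `"off"`
#'   (local maxima only, as used for dim cellular movies).
#' @return `list(detections = data.frame(id, x, y, area_px, peak_intensity,
#'   mean_intensity, scenario), labels = integer label matrix, maxima =
#'   data.frame(x, y, value, region), filtered = matrix, ratio_thresh)`.
#'   Coordinates are 0-based; labels are contiguous positive integers.
#' @export
detect_frame <- function(frame, psf_sigma_px = 0.46, bg_sigma_px = 10,
                         noise_sigma_px = 1, maxima_threshold_k = 3.5,
                         ratio_thresh = NULL, min_isolated = 20,
                         fallback_ratio_threshold = 2,
                         segmentation = c("auto", "on", "off")) {
  segmentation <- match.arg(segmentation)
  stopifnot(all(is.finite(frame)), all(frame >= 0))
  empty <- list(
    detections = data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                            area_px = numeric(0), peak_intensity = numeric(0),
                            mean_intensity = numeric(0),
                            scenario = character(0)),
    labels = matrix(0L, nrow(frame), ncol(frame)),
    maxima = data.frame(x = integer(0), y = integer(0), value = numeric(0),
                        region = integer(0)),
    filtered = frame * 0, ratio_thresh = NA_real_)
  if (stats::sd(frame) == 0) return(empty)
  bg <- gaussian_blur(frame, bg_sigma_px)
  sub_un <- frame - bg
  f <- gaussian_blur(pmax(sub_un, 0), noise_sigma_px)
  if (stats::sd(f) == 0) return(empty)
  # maxima significance is judged on the unclamped filtered image, whose
  # local mean and robust noise SD are unbiased (clamping at 0 censors the
  # lower noise tail and lifts the background estimate in dark areas); the
  # clamped image f is used for segmentation, intensities, and centroids
  f_un <- gaussian_blur(sub_un, noise_sigma_px)
  loc_mean <- gaussian_blur(f_un, bg_sigma_px)
  sigma_n <- stats::mad(f_un - loc_mean)
  thr <- otsu_thresholds(f, 1)
  use_seg <- switch(segmentation,
    on = TRUE, off = FALSE,
    auto = thr > stats::median(f) + maxima_threshold_k * sigma_n)
  segmask <- if (use_seg) f > thr else matrix(FALSE, nrow(f), ncol(f))
  seg <- label_components(segmask)
  mx <- local_maxima_8(f_un)
  mx <- mx & (f_un > loc_mean + maxima_threshold_k * sigma_n)
  midx <- which(mx)
  h <- nrow(frame)
  maxima <- data.frame(
    y = as.integer((midx - 1) %% h),
    x = as.integer((midx - 1) %/% h),
    value = f[midx],
    region = seg[midx])
  maxima <- maxima[, c("x", "y", "value", "region")]
  labels <- matrix(0L, nrow(frame), ncol(frame))
  dets <- list()
  next_id <- 1L

  add_det <- function(mask, scenario, cx, cy) {
    mask <- mask & labels == 0L  # never overwrite an earlier condensate
    if (!any(mask)) return(invisible(NULL))
    id <- next_id
    labels[mask] <<- id
    vals <- f[mask]
    dets[[id]] <<- data.frame(
      id = id, x = cx, y = cy, area_px = sum(mask),
      peak_intensity = max(vals), mean_intensity = mean(vals),
      scenario = scenario)
    next_id <<- next_id + 1L
  }

  # scenario 2: maxima outside any segmented region -> diffraction-limited
  iso_max <- maxima[maxima$region == 0L, , drop = FALSE]
  for (i in seq_len(nrow(iso_max))) {
    ctr <- .gauss_fit_center(f, iso_max$x[i], iso_max$y[i], psf_sigma_px)
    m <- disc_mask(nrow(frame), ncol(frame), ctr[1], ctr[2],
                   3 * psf_sigma_px)
    add_det(m, "diffraction-limited", ctr[1], ctr[2])
  }

  # scenarios 1 and 3: segmented regions by maxima count
  region_ids <- sort(unique(seg[seg > 0]))
  pending_multi <- list()
  iso_records <- list()
  for (rid in region_ids) {
    rmask <- seg == rid
    rmax <- maxima[maxima$region == rid, , drop = FALSE]
    if (nrow(rmax) == 0L) next  # region without a significant maximum
    if (nrow(rmax) == 1L) {
      vals <- f[rmask]
      cx <- sum((col(frame)[rmask] - 1) * vals) / sum(vals)
      cy <- sum((row(frame)[rmask] - 1) * vals) / sum(vals)
      add_det(rmask, "segmented-single", cx, cy)
      iso_records[[length(iso_records) + 1L]] <- data.frame(
        peak = max(vals), edge_min = region_edge_min(f, rmask))
    } else {
      pending_multi[[length(pending_multi) + 1L]] <-
        list(mask = rmask, maxima = rmax)
    }
  }
  if (length(pending_multi) > 0L) {
    if (is.null(ratio_thresh)) {
      iso <- do.call(rbind, iso_records)
      ratio_thresh <- tryCatch(
        ratio_threshold(iso, min_isolated = min_isolated),
        error = function(e) fallback_ratio_threshold)
    }
    for (pm in pending_multi) {
      parts <- resolve_multimax(f, pm$mask, pm$maxima, ratio_thresh)
      for (p in parts) {
        vals <- f[p$mask]
        cx <- sum((col(frame)[p$mask] - 1) * vals) / sum(vals)
        cy <- sum((row(frame)[p$mask] - 1) * vals) / sum(vals)
        add_det(p$mask, if (p$split) "watershed-split" else
          "segmented-single", cx, cy)
      }
    }
  }
  if (length(dets) == 0L) {
    out <- empty; out$filtered <- f
    out$maxima <- maxima
    return(out)
  }
  list(detections = do.call(rbind, dets), labels = labels, maxima = maxima,
       filtered = f,
       ratio_thresh = if (is.null(ratio_thresh)) NA_real_ else ratio_thresh)
}

# minimum filtered intensity on the region boundary (pixels of the region
# with a 4-neighbor outside it)
region_edge_min <- function(f, rmask) {
  h <- nrow(rmask); w <- ncol(rmask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- rmask
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  edge <- rmask & !interior
  min(f[edge])
}

#' Peak/valley ratio threshold from isolated condensates
#'
#' For isolated (single-maximum) condensates the ratio of peak intensity to
#' the minimum filtered intensity on the region edge forms a reference
#' distribution for truly separate condensates; its 1st percentile (linear
#' interpolation between order statistics) is the splitting threshold used
#' by [resolve_multimax()].
#'
#' @param isolated data.frame with columns `peak` and `edge_min`.
#' @param min_isolated minimum number of condensates required (default 20).
#' @param probs percentile to take (default 0.01).
#' @return the threshold ratio.
#' @export
ratio_threshold <- function(isolated, min_isolated = 20, probs = 0.01) {
  if (is.null(isolated) || nrow(isolated) < min_isolated)
    stop("fewer than ", min_isolated, " isolated condensates; ",
         "use the fallback ratio threshold from the run configuration")
  ratios <- isolated$peak / isolated$edge_min
  percentile_linear(ratios, probs)
}

#' Split or merge multiple maxima within one segmented region
#'
#' For every pair of maxima, the mean of their peak intensities is divided
#' by the minimum bilinearly-interpolated intensity along the straight line
#' between them. Pairs whose ratio falls below `threshold` belong to the
#' same condensate: processing pairs in ascending ratio, the dimmer maximum
#' of each sub-threshold pair is discarded and pairs are recomputed among
#' survivors until stable. The surviving maxima then seed a watershed
#' restricted to the region.
#'
#' @param f filtered intensity matrix.
#' @param rmask logical region mask.
#' @param rmax data.frame of the region's maxima (`x`, `y`, `value`).
#' @param threshold ratio threshold from [ratio_threshold()].
#' @return list of parts, each `list(mask, split)`; `split` is TRUE when
#'   the region was divided among several maxima.
#' @export
resolve_multimax <- function(f, rmask, rmax, threshold) {
  keep <- rmax
  n <- nrow(keep)
  if (n > 1L) {
    # pairwise ratios are fixed by the image, so they are computed once;
    # pairs are then processed in ascending ratio, discarding the dimmer
    # endpoint of each sub-threshold pair whose endpoints both survive
    pr <- utils::combn(n, 2)
    ratios <- apply(pr, 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      ns <- max(2L, ceiling(4 * sqrt((keep$x[i] - keep$x[j])^2 +
                                     (keep$y[i] - keep$y[j])^2)))
      tt <- seq(0, 1, length.out = ns)
      line <- interp_bilinear(f, keep$x[i] + tt * (keep$x[j] - keep$x[i]),
                              keep$y[i] + tt * (keep$y[j] - keep$y[i]))
      mean(c(keep$value[i], keep$value[j])) / min(line)
    })
    alive <- rep(TRUE, n)
    for (k in order(ratios)) {
      if (ratios[k] >= threshold) break
      i <- pr[1, k]; j <- pr[2, k]
      if (!alive[i] || !alive[j]) next
      drop <- if (keep$value[i] <= keep$value[j]) i else j
      alive[drop] <- FALSE
    }
    keep <- keep[alive, , drop = FALSE]
  }
  if (nrow(keep) == 1L)
    return(list(list(mask = rmask, split = FALSE)))
  seeds <- matrix(0L, nrow(f), ncol(f))
  for (i in seq_len(nrow(keep)))
    seeds[keep$y[i] + 1, keep$x[i] + 1] <- i
  lab <- seeded_watershed(f, seeds, rmask)
  lapply(seq_len(nrow(keep)), function(i)
    list(mask = lab == i, split = TRUE))
}

#' Detect condensates across a whole stack
#'
#' Runs [detect_frame()] on every frame. The ratio threshold is estimated
#' once from the pooled isolated condensates of all frames (first pass),
#' then applied in a second pass, mirroring a per-movie reference
#' distribution.
#'
#' @param stack an `ImageStack`.
#' @inheritParams detect_frame
#' @return `list(detections = data.frame with a `frame` column, labels =
#'   list of label matrices, ratio_thresh)`.
#' @export
detect_stack <- function(stack, psf_sigma_px = 0.46, bg_sigma_px = 10,
                         noise_sigma_px = 1, maxima_threshold_k = 3.5,
                         min_isolated = 20, fallback_ratio_threshold = 2,
                         segmentation = c("auto", "on", "off")) {
  segmentation <- match.arg(segmentation)
  nt <- n_frames(stack)
  if (segmentation == "off") {
    thr <- fallback_ratio_threshold  # unused: no segmented regions
  } else {
    # first pass: collect isolated-condensate ratios
    pre <- lapply(seq_len(nt), function(t)
      detect_frame(get_frame(stack, t), psf_sigma_px, bg_sigma_px,
                   noise_sigma_px, maxima_threshold_k,
                   ratio_thresh = fallback_ratio_threshold,
                   min_isolated = min_isolated, segmentation = segmentation))
    iso <- do.call(rbind, lapply(pre, function(d) {
      di <- d$detections
      di <- di[di$scenario == "segmented-single", , drop = FALSE]
      if (nrow(di) == 0L) return(NULL)
      data.frame(peak = di$peak_intensity,
                 edge_min = vapply(di$id, function(id)
                   region_edge_min(d$filtered, d$labels == id), 0))
    }))
    thr <- tryCatch(ratio_threshold(iso, min_isolated = min_isolated),
                    error = function(e) fallback_ratio_threshold)
  }
  res <- lapply(seq_len(nt), function(t)
    detect_frame(get_frame(stack, t), psf_sigma_px, bg_sigma_px,
                 noise_sigma_px, maxima_threshold_k, ratio_thresh = thr,
                 min_isolated = min_isolated, segmentation = segmentation))
  dets <- do.call(rbind, lapply(seq_len(nt), function(t) {
    d <- res[[t]]$detections
    if (nrow(d) == 0L) return(NULL)
    cbind(frame = t, d)
  }))
  if (is.null(dets))
    dets <- data.frame(frame = integer(0), id = integer(0), x = numeric(0),
                       y = numeric(0), area_px = numeric(0),
                       peak_intensity = numeric(0),
                       mean_intensity = numeric(0), scenario = character(0))
  list(detections = dets, labels = lapply(res, `[[`, "labels"),
       ratio_thresh = thr)
}
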