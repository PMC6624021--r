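# Spatio-temporal image correlation spectroscopy (STICS): per-subregion
# velocity vectors from windowed space-time cross-correlation, plus the
# two-channel co-movement statistics and the subsampled two-sample tests.

# Cross-spectra for the linear (zero-padded) normalized cross-correlation
# of two n x n patches: product spectrum plus the two overlap-energy
# spectra, from which the NCC surface can be evaluated at integer or
# fractional displacements. At each displacement the raw product sum over
# the overlap region is divided by the geometric mean of the two patches'
# energies over that same overlap, cancelling texture-energy inhomogeneity
# so the peak position is unbiased.
.xcorr_spectra <- function(A, B, f1) {
  n <- nrow(A)
  m <- 2L * n
  pad <- function(x) { p <- matrix(0, m, m); p[1:n, 1:n] <- x; p }
  fA <- stats::fft(pad(A)); fB <- stats::fft(pad(B))
  fA2 <- stats::fft(pad(A^2)); fB2 <- stats::fft(pad(B^2))
  list(num = Conj(fA) * fB,    # -> sum A(x) B(x + k) over the overlap
       eA = Conj(fA2) * f1,    # -> sum A(x)^2 over the overlap at k
       eB = Conj(f1) * fB2)    # -> sum B(x + k)^2 over the overlap
}

# evaluate an inverse-DFT surface at the integer displacements in
# [-max_d, max_d]^2 (delta = 0 at the center)
.spec_surface <- function(spec, max_d) {
  m <- nrow(spec)
  cc <- Re(stats::fft(spec, inverse = TRUE)) / (m * m)
  ix <- c((m - max_d + 1):m, 1:(max_d + 1))
  cc[ix, ix]
}

.ncc_from_spectra <- function(sp, max_d) {
  num <- .spec_surface(sp$num, max_d)
  eA <- .spec_surface(sp$eA, max_d)
  eB <- .spec_surface(sp$eB, max_d)
  num / pmax(sqrt(pmax(eA, 0) * pmax(eB, 0)), .Machine$double.eps)
}

# Evaluate the NCC surface on a fine fractional-displacement grid around
# (dy0, dx0) by local matrix-multiply inverse DFT of the three spectra;
# returns the sub-pixel displacement of the maximum.
.ncc_upsample_peak <- function(sp, dy0, dx0, half_px = 1, upsample = 40) {
  m <- nrow(sp$num)
  kk <- c(0:(m / 2 - 1), -(m / 2):-1)  # signed DFT frequencies
  ds <- seq(-half_px, half_px, length.out = 2 * half_px * upsample + 1)
  Wy <- exp(2i * pi * outer(kk, dy0 + ds) / m)
  Wx <- exp(2i * pi * outer(kk, dx0 + ds) / m)
  ev <- function(spec) Re(t(Wy) %*% spec %*% Wx) / (m * m)
  num <- ev(sp$num)
  den <- sqrt(pmax(ev(sp$eA), 0) * pmax(ev(sp$eB), 0))
  ncc <- num / pmax(den, .Machine$double.eps)
  pk <- which(ncc == max(ncc), arr.ind = TRUE)[1, ]
  c(dy = dy0 + ds[pk[1]], dx = dx0 + ds[pk[2]], peak = max(ncc))
}

#' STICS velocity field of one channel
#'
#' The movie (restricted to `t_range`) is divided into square subregions of
#' `window_px` pixels every `step_px` pixels. The per-pixel immobile
#' component over the analysis interval (temporal mean by default; a
#' temporal median is available, see `remove_immobile`) is subtracted; for
#' every frame pair `(t, t + shift)`
#' the mean-subtracted patches are cross-correlated by zero-padded (linear)
#' frequency-domain products with overlap-energy normalization, correlation
#' surfaces are pooled over pairs, and the displacement is located to
#' sub-pixel precision by a second correlation pass against the window
#' displaced by the integer peak, with the residual fractional peak read
#' off an upsampled (frequency-domain) normalized correlation surface.
#' Displacements are restricted to at most `window_px / 4`. A subregion's vector is valid when the peak rises
#' above `noise_floor_k` robust SDs of the correlation surface and the
#' speed exceeds `min_speed_px_frame`.
#'
#' @param stack an `ImageStack`.
#' @param t_range integer vector of frames to analyze (default: all); the
#'   contraction interval of a movie is typically 10-15 frames.
#' @param window_px subregion size (default 16, i.e. 2.56 um at 0.16
#'   um/px).
#' @param step_px grid step (default 8).
#' @param shift_frames temporal correlation shift (default 3 frames).
#' @param noise_floor_k peak significance multiplier (default 5).
#' @param min_speed_px_frame minimum speed for a valid vector (default
#'   0.01 px/frame).
#' @return data.frame `(cx, cy, dx, dy, speed_px_frame, speed_um_s,
#'   angle_deg, peak, valid)`, one row per subregion; `(cx, cy)` are
#'   0-based subregion centers, `(dx, dy)` the displacement in px per
#'   `shift_frames` frames, angle in degrees with y increasing downward.
#'   Grid geometry is carried in attributes.
#' @export
stics_field <- function(stack, t_range = NULL, window_px = 16, step_px = 8,
                        shift_frames = 3, noise_floor_k = 5,
                        min_speed_px_frame = 0.01,
                        remove_immobile = c("mean", "median", "none")) {
  if (is.logical(remove_immobile))
    remove_immobile <- if (remove_immobile) "mean" else "none"
  remove_immobile <- match.arg(remove_immobile)
  d <- dim(stack$frames)
  if (is.null(t_range)) t_range <- seq_len(d[1])
  if (length(t_range) < shift_frames + 1L)
    stop("t_range must span at least shift_frames + 1 frames")
  h <- d[2]; w <- d[3]
  if (window_px > h || window_px > w)
    stop("window larger than frame")
  sub <- stack$frames[t_range, , , drop = FALSE]
  if (remove_immobile != "none") {
    # the temporal median estimates the immobile component robustly: a
    # moving texture leaves almost no footprint in it, whereas the mean
    # carries a ghost of the moving component that biases sub-pixel peaks
    imm <- apply(sub, c(2, 3),
                 if (remove_immobile == "median") stats::median else mean)
    for (t in seq_len(dim(sub)[1])) sub[t, , ] <- sub[t, , ] - imm
  }
  x0s <- seq(0, w - window_px, by = step_px)
  y0s <- seq(0, h - window_px, by = step_px)
  nt <- dim(sub)[1]
  pairs <- seq_len(nt - shift_frames)
  max_d <- floor(window_px / 4)
  max_d_full <- max(max_d + 2L, window_px %/% 2 - 1L)
  dd <- -max_d_full:max_d_full
  outer_ring <- outer(abs(dd), abs(dd), pmax) > max_d
  inner <- which(abs(dd) <= max_d)
  np <- length(pairs)
  f1 <- stats::fft(rbind(cbind(matrix(1, window_px, window_px),
                               matrix(0, window_px, window_px)),
                         matrix(0, window_px, 2 * window_px)))
  rows <- list()
  for (y0 in y0s) for (x0 in x0s) {
    spsum <- NULL
    acc <- matrix(0, 2 * max_d_full + 1, 2 * max_d_full + 1)
    acc2 <- acc
    for (t in pairs) {
      A <- sub[t, y0 + seq_len(window_px), x0 + seq_len(window_px)]
      B <- sub[t + shift_frames, y0 + seq_len(window_px),
               x0 + seq_len(window_px)]
      sp <- .xcorr_spectra(A - mean(A), B - mean(B), f1)
      cc <- .ncc_from_spectra(sp, max_d_full)
      acc <- acc + cc
      acc2 <- acc2 + cc^2
      if (is.null(spsum)) spsum <- sp else {
        spsum$num <- spsum$num + sp$num
        spsum$eA <- spsum$eA + sp$eA
        spsum$eB <- spsum$eB + sp$eB
      }
    }
    acc <- acc / np
    # standard error of the pair-averaged correlation at each displacement
    se <- if (np > 1) sqrt(pmax(acc2 / np - acc^2, 0) / (np - 1)) else
      acc * 0 + Inf
    win <- acc[inner, inner]
    pk <- which(win == max(win), arr.ind = TRUE)[1, ]
    py <- unname(pk[1]); px <- unname(pk[2])
    dyi <- py - (max_d + 1); dxi <- px - (max_d + 1)
    # second pass (window-offset refinement): re-correlate against the
    # search window displaced by the integer peak so matching content
    # aligns and the residual fractional peak is symmetric around zero
    yb <- y0 + dyi; xb <- x0 + dxi
    if (yb >= 0 && xb >= 0 && yb + window_px <= h && xb + window_px <= w) {
      sp2 <- NULL
      for (t in pairs) {
        A <- sub[t, y0 + seq_len(window_px), x0 + seq_len(window_px)]
        B <- sub[t + shift_frames, yb + seq_len(window_px),
                 xb + seq_len(window_px)]
        sp <- .xcorr_spectra(A - mean(A), B - mean(B), f1)
        if (is.null(sp2)) sp2 <- sp else {
          sp2$num <- sp2$num + sp$num
          sp2$eA <- sp2$eA + sp$eA
          sp2$eB <- sp2$eB + sp$eB
        }
      }
      up <- .ncc_upsample_peak(sp2, 0, 0)
      dy <- dyi + unname(up["dy"]); dx <- dxi + unname(up["dx"])
    } else {
      # offset window would leave the frame: refine on the first pass
      up <- .ncc_upsample_peak(spsum, dyi, dxi)
      dy <- unname(up["dy"]); dx <- unname(up["dx"])
    }
    # clamp to the search range
    dy <- min(max(dy, -max_d), max_d)
    dx <- min(max(dx, -max_d), max_d)
    peak <- max(win)
    # robust noise level: reproducibility of the surface across frame
    # pairs (sampling SE), with the outer annulus as a floor
    noise <- max(stats::median(se[inner, inner][win >= peak]),
                 stats::mad(acc[outer_ring]) / sqrt(np), 1e-12)
    base <- stats::median(acc[outer_ring])
    speed <- sqrt(dx^2 + dy^2) / shift_frames
    valid <- is.finite(peak) && peak > 0 &&
      peak - base > noise_floor_k * noise &&
      speed > min_speed_px_frame
    rows[[length(rows) + 1L]] <- data.frame(
      cx = x0 + (window_px - 1) / 2, cy = y0 + (window_px - 1) / 2,
      dx = dx, dy = dy, speed_px_frame = speed,
      speed_um_s = speed * stack$pixel_size_um / stack$frame_interval_s,
      angle_deg = atan2(dy, dx) * 180 / pi,
      peak = peak, valid = valid)
  }
  out <- do.call(rbind, rows)
  attr(out, "window_px") <- window_px
  attr(out, "step_px") <- step_px
  attr(out, "shift_frames") <- shift_frames
  out
}

#' Two-channel co-movement statistics
#'
#' Pairs the velocity vectors of two channels at each subregion where both
#' are valid and reports both speeds and the angle between the vectors
#' (degrees, in `[0, 180]`). Pool rows across movies before plotting or
#' testing.
#'
#' @param vfA,vfB vector fields from [stics_field()] on the same grid.
#' @return data.frame `(cx, cy, speed_a, speed_b, angle_deg)`.
#' @export
comovement <- function(vfA, vfB) {
  if (nrow(vfA) != nrow(vfB) ||
      any(vfA$cx != vfB$cx) || any(vfA$cy != vfB$cy))
    stop("vector fields have mismatched subregion grids")
  ok <- vfA$valid & vfB$valid
  a <- vfA[ok, ]; b <- vfB[ok, ]
  dot <- a$dx * b$dx + a$dy * b$dy
  na <- sqrt(a$dx^2 + a$dy^2); nb <- sqrt(b$dx^2 + b$dy^2)
  cosang <- pmin(pmax(dot / (na * nb), -1), 1)
  data.frame(cx = a$cx, cy = a$cy,
             speed_a = a$speed_px_frame, speed_b = b$speed_px_frame,
             angle_deg = acos(cosang) * 180 / pi)
}

#' Normalized 2-D speed-frequency histogram
#' @param pairs co-movement pairs from [comovement()].
#' @param breaks bin edges applied to both speed axes.
#' @return matrix of frequencies (counts normalized by total count); rows =
#'   channel-A speed bins, columns = channel-B speed bins.
#' @export
speed_hist2d <- function(pairs, breaks = seq(0, 1, by = 0.05)) {
  ia <- cut(pairs$speed_a, breaks, include.lowest = TRUE)
  ib <- cut(pairs$speed_b, breaks, include.lowest = TRUE)
  tab <- table(ia, ib)
  tab / max(sum(tab), 1)
}

#' Randomized-pairing control for co-movement
#'
#' Channel-A vectors are randomly permuted across the valid channel-A
#' subregion positions before pairing with channel B, destroying the
#' spatial correspondence while preserving both marginal vector
#' distributions. Seed-deterministic.
#'
#' @inheritParams comovement
#' @param seed integer seed for the permutation.
#' @return co-movement data.frame as from [comovement()].
#' @export
randomize_control <- function(vfA, vfB, seed = 1) {
  if (nrow(vfA) != nrow(vfB) ||
      any(vfA$cx != vfB$cx) || any(vfA$cy != vfB$cy))
    stop("vector fields have mismatched subregion grids")
  set.seed(seed)
  va <- which(vfA$valid)
  perm <- if (length(va) > 1L) sample(va) else va
  vfA2 <- vfA
  vfA2[va, c("dx", "dy", "speed_px_frame", "speed_um_s", "angle_deg",
             "peak")] <-
    vfA[perm, c("dx", "dy", "speed_px_frame", "speed_um_s", "angle_deg",
                "peak")]
  comovement(vfA2, vfB)
}

#' Subsampled two-sample test for large samples
#'
#' Two-sample tests become hypersensitive when samples hold more than about
#' a thousand points. When either sample exceeds `trigger_n`, the test is
#' run on `reps` random subsample pairs of `n_sub` points each (without
#' replacement) and the arithmetic mean p-value is reported; otherwise the
#' plain test is run once.
#'
#' @param sampleA,sampleB numeric vectors.
#' @param statistic `"ks"` (Kolmogorov-Smirnov) or `"ranksum"` (Wilcoxon
#'   rank-sum).
#' @param n_sub subsample size (default 500).
#' @param reps number of repeats (default 100).
#' @param trigger_n sample size above which subsampling engages (default
#'   1000).
#' @param seed integer seed.
#' @return the (mean) p-value.
#' @export
subsampled_test <- function(sampleA, sampleB, statistic = c("ks", "ranksum"),
                            n_sub = 500, reps = 100, trigger_n = 1000,
                            seed = 1) {
  statistic <- match.arg(statistic)
  stopifnot(length(sampleA) > 0, length(sampleB) > 0)
  run1 <- function(a, b) {
    if (statistic == "ks")
      suppressWarnings(stats::ks.test(a, b))$p.value
    else
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))$p.value
  }
  if (length(sampleA) <= trigger_n && length(sampleB) <= trigger_n)
    return(run1(sampleA, sampleB))
  set.seed(seed)
  ps <- vapply(seq_len(reps), function(i) {
    a <- sample(sampleA, min(n_sub, length(sampleA)))
    b <- sample(sampleB, min(n_sub, length(sampleB)))
    run1(a, b)
  }, 0)
  mean(ps)
}
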