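# Shared low-level image primitives. Matrices are [y, x]; user-facing
# coordinates are 0-based with pixel centers at integers, so matrix element
# [i, j] sits at (x, y) = (j - 1, i - 1).

#' Gaussian blur with replicated borders
#' @param img matrix `[y, x]`.
#' @param sigma kernel standard deviation in pixels.
#' @return blurred matrix of the same size.
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  EBImage::gblur(img, sigma = sigma, boundary = "replicate")
}

#' Bilinear interpolation at sub-pixel positions
#' @param img matrix `[y, x]`.
#' @param x,y 0-based coordinates (vectors). Positions outside the frame are
#'   clamped to the border.
#' @return interpolated intensities.
#' @keywords internal
interp_bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), h - 2); y1 <- y0 + 1
  if (w == 1) { x0 <- x1 <- 0 }
  if (h == 1) { y0 <- y1 <- 0 }
  fx <- x - x0; fy <- y - y0
  v00 <- img[cbind(y0 + 1, x0 + 1)]; v01 <- img[cbind(y0 + 1, x1 + 1)]
  v10 <- img[cbind(y1 + 1, x0 + 1)]; v11 <- img[cbind(y1 + 1, x1 + 1)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Percentile with linear interpolation between order statistics
#'
#' Pins the percentile convention used for the detection ratio threshold and
#' the trajectory transition rule (R's type-7 inclusive interpolation).
#' @param x numeric vector.
#' @param p probability in `[0, 1]`.
#' @keywords internal
percentile_linear <- function(x, p) {
  unname(stats::quantile(x, p, type = 7, names = FALSE))
}

#' Strict 8-neighborhood local maxima
#' @param img matrix.
#' @return logical matrix, TRUE where a pixel strictly exceeds all 8
#'   neighbors. Border pixels are never maxima.
#' @keywords internal
local_maxima_8 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(FALSE, h, w)
  if (h < 3 || w < 3) return(out)
  c0 <- img[2:(h - 1), 2:(w - 1)]
  ok <- matrix(TRUE, h - 2, w - 2)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ok <- ok & (c0 > img[(2 + dy):(h - 1 + dy), (2 + dx):(w - 1 + dx)])
  }
  out[2:(h - 1), 2:(w - 1)] <- ok
  out
}

#' Multi-level Otsu thresholds
#'
#' Exhaustive inter-class-variance maximization over a 256-bin histogram,
#' generalizing Otsu's method to one or two thresholds (the behavior of
#' MATLAB's multithresh).
#' @param img numeric matrix or vector.
#' @param n_thresh 1 (two classes) or 2 (three classes).
#' @return threshold value(s) on the intensity scale of `img`.
#' @keywords internal
otsu_thresholds <- function(img, n_thresh = 1) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant image: no threshold exists")
  nb <- 256L
  br <- seq(lo, hi, length.out = nb + 1L)
  cnt <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), nb), nb)
  p <- cnt / sum(cnt)
  mids <- (br[-1] + br[-(nb + 1L)]) / 2
  cw <- cumsum(p); cm <- cumsum(p * mids)
  tot_m <- cm[nb]
  if (n_thresh == 1L) {
    w0 <- cw[-nb]; m0 <- cm[-nb]
    w1 <- 1 - w0; m1 <- tot_m - m0
    valid <- w0 > 0 & w1 > 0
    bcv <- rep(-Inf, nb - 1L)
    bcv[valid] <- (m0[valid] / w0[valid] - m1[valid] / w1[valid])^2 *
      w0[valid] * w1[valid]
    k <- which.max(bcv)
    return(br[k + 1L])
  }
  # two thresholds: exhaustive over ordered bin pairs
  best <- -Inf; bi <- c(1L, 2L)
  for (k1 in 1:(nb - 2L)) {
    w0 <- cw[k1]; if (w0 <= 0) next
    m0 <- cm[k1] / w0
    for (k2 in (k1 + 1L):(nb - 1L)) {
      w1 <- cw[k2] - cw[k1]; w2 <- 1 - cw[k2]
      if (w1 <= 0 || w2 <= 0) next
      m1 <- (cm[k2] - cm[k1]) / w1
      m2 <- (tot_m - cm[k2]) / w2
      mu <- tot_m
      bcv <- w0 * (m0 - mu)^2 + w1 * (m1 - mu)^2 + w2 * (m2 - mu)^2
      if (bcv > best) { best <- bcv; bi <- c(k1, k2) }
    }
  }
  c(br[bi[1] + 1L], br[bi[2] + 1L])
}

#' Connected-component labels (8-connectivity)
#' @param mask logical matrix.
#' @return integer matrix of labels, 0 = background.
#' @keywords internal
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
}

#' Binary dilation by a disc
#' @param mask logical matrix.
#' @param radius_px disc radius in pixels.
#' @keywords internal
dilate_disc <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  EBImage::dilate(mask * 1, brush) > 0
}

#' Seeded watershed by descending-intensity flood
#'
#' Partitions `mask` among the seed labels: pixels are visited in order of
#' decreasing intensity and each unlabeled pixel adjacent (8-connectivity)
#' to a labeled one inherits that label. Deterministic; ties broken by
#' visiting order (row-major within equal intensity).
#' @param intensity matrix.
#' @param seeds integer matrix, positive labels at seed pixels.
#' @param mask logical matrix restricting the flood.
#' @return integer label matrix partitioning `mask` (labels from `seeds`).
#' @keywords internal
seeded_watershed <- function(intensity, seeds, mask) {
  h <- nrow(intensity); w <- ncol(intensity)
  lab <- ifelse(mask, seeds, 0L)
  idx <- which(mask & seeds == 0L)
  if (length(idx) == 0L) return(lab)
  ord <- idx[order(-intensity[idx])]
  pend <- ord
  repeat {
    assigned_any <- FALSE
    still <- integer(0)
    for (i in pend) {
      yy <- (i - 1L) %% h + 1L; xx <- (i - 1L) %/% h + 1L
      nb <- 0L; best_int <- -Inf
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0L && dx == 0L) next
        y2 <- yy + dy; x2 <- xx + dx
        if (y2 < 1L || y2 > h || x2 < 1L || x2 > w) next
        l2 <- lab[y2, x2]
        if (l2 > 0L && intensity[y2, x2] > best_int) {
          best_int <- intensity[y2, x2]; nb <- l2
        }
      }
      if (nb > 0L) { lab[yy, xx] <- nb; assigned_any <- TRUE }
      else still <- c(still, i)
    }
    if (length(still) == 0L || !assigned_any) break
    pend <- still[order(-intensity[still])]
  }
  lab
}

#' Disc pixel mask around a sub-pixel center
#' @param h,w frame size.
#' @param cx,cy 0-based center.
#' @param radius_px radius; pixels whose centers lie within it are included.
#' @return logical matrix.
#' @keywords internal
disc_mask <- function(h, w, cx, cy, radius_px) {
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= radius_px^2
}

#' Shift a frame by whole pixels, zero-filling exposed borders
#' @param img matrix.
#' @param dy,dx shift in rows/columns (positive moves content down/right).
#' @keywords internal
shift_frame <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  ys <- seq_len(h) - dy; xs <- seq_len(w) - dx
  oky <- ys >= 1 & ys <= h; okx <- xs >= 1 & xs <= w
  out[which(oky), which(okx)] <- img[ys[oky], xs[okx]]
  out
}
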