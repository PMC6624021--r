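# Condensate composition analysis: aggregate-perimeter local background,
# the four track-selection filters, first-three-frame normalization, radial
# binning with median and notch 95% CI, rank-sum tests with Bonferroni
# correction, and the photobleaching control.

#' Background-subtracted condensate content in one frame
#'
#' Condensates whose masks come within `perimeter_px` of one another form
#' "condensate aggregates" that share one local background, estimated as
#' the mean and SD of intensity in a `perimeter_px`-thick ring around each
#' aggregate (the ring excludes all condensate pixels). A condensate's
#' content is the mean of (inside intensity - background mean); negative
#' values are allowed and flagged.
#'
#' @param frame 2-D intensity matrix.
#' @param labels condensate label matrix for the same frame.
#' @param perimeter_px ring thickness and proximity radius (default 2).
#' @return data.frame `(id, aggregate, content, bg_mean, bg_sd, negative,
#'   missing)`; `missing` is TRUE when the aggregate's ring is empty.
#' @export
condensate_content <- function(frame, labels, perimeter_px = 2) {
  stopifnot(all(dim(frame) == dim(labels)))
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L)
    return(data.frame(id = integer(0), aggregate = integer(0),
                      content = numeric(0), bg_mean = numeric(0),
                      bg_sd = numeric(0), negative = logical(0),
                      missing = logical(0)))
  any_cond <- labels > 0
  dil <- dilate_disc(any_cond, perimeter_px)
  agg_lab <- label_components(dil)
  # every ring pixel lies inside the dilated mask, so it already carries
  # its aggregate's label; one grouped pass gives all backgrounds
  first_px <- match(ids, labels)
  agg_of <- agg_lab[first_px]
  ring <- dil & !any_cond
  ring_lab <- agg_lab[ring]
  ring_val <- frame[ring]
  bg_mean <- tapply(ring_val, ring_lab, mean)
  bg_sd <- tapply(ring_val, ring_lab, stats::sd)
  inside_mean <- tapply(frame[any_cond], labels[any_cond], mean)
  out <- data.frame(id = ids, aggregate = agg_of)
  out$bg_mean <- unname(bg_mean[as.character(agg_of)])
  out$bg_sd <- unname(bg_sd[as.character(agg_of)])
  out$missing <- is.na(out$bg_mean)
  out$content <- unname(inside_mean[as.character(ids)]) - out$bg_mean
  out$negative <- !is.na(out$content) & out$content < 0
  out[, c("id", "aggregate", "content", "bg_mean", "bg_sd",
          "negative", "missing")]
}

#' Per-track protein contents along a movie
#'
#' Reads a channel's background-subtracted condensate content at the master
#' channel's condensate masks for every non-gap time point of every track
#' (master/slave analysis: the slave channel is never re-detected).
#'
#' @param stack channel `ImageStack` to measure.
#' @param labels list of per-frame label matrices (from [detect_stack()]).
#' @param tracks track list from [link_tracks()].
#' @param perimeter_px aggregate/ring radius (default 2).
#' @return data.frame `(track_id, frame, det_id, content, bg_sd)`.
#' @export
measure_track_contents <- function(stack, labels, tracks, perimeter_px = 2) {
  nt <- n_frames(stack)
  per_frame <- lapply(seq_len(nt), function(t)
    condensate_content(get_frame(stack, t), labels[[t]], perimeter_px))
  rows <- list()
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    for (i in seq_len(nrow(tr))) {
      if (isTRUE(tr$is_gap[i])) next
      cc <- per_frame[[tr$frame[i]]]
      row <- cc[cc$id == tr$det_id[i], ]
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = k, frame = tr$frame[i], det_id = tr$det_id[i],
        content = if (nrow(row) == 1L) row$content else NA_real_,
        bg_sd = if (nrow(row) == 1L) row$bg_sd else NA_real_)
    }
  }
  do.call(rbind, rows)
}

# normalized radial position of every non-gap point of a track
.track_radii <- function(track, geom) {
  vapply(seq_len(nrow(track)), function(i) {
    fr <- min(track$frame[i], length(geom$frames))
    normalized_radial_position(c(track$x[i], track$y[i]), geom, fr)$r
  }, 0)
}

#' Select tracks for composition analysis
#'
#' Applies the four selection filters in order: (1) duration of at least
#' `min_frames` frames; (2) approximately linear geometry, i.e.
#' [track_anisotropy()] at least `min_anisotropy`; (3) the track starts
#' between the synapse edge and the actin position threshold
#' (`r > position_threshold`) and ends between the threshold and the cSMAC
#' center (`r < position_threshold`); (4) the mean slave content over the
#' first three time points exceeds the mean background SD over the first
#' three time points.
#'
#' @param tracks track list from [link_tracks()].
#' @param geom a `SynapseGeometry`.
#' @param slave_contents data.frame from [measure_track_contents()] for the
#'   slave channel.
#' @param min_frames,min_anisotropy,position_threshold filter parameters
#'   (defaults 5, 3, 0.6).
#' @return `list(selected = integer track ids, rejections = named counts
#'   per filter in application order, radii = list of per-track r series)`.
#' @export
select_tracks <- function(tracks, geom, slave_contents, min_frames = 5,
                          min_anisotropy = 3, position_threshold = 0.6) {
  rej <- c(duration = 0L, anisotropy = 0L, position = 0L, content = 0L)
  selected <- integer(0)
  radii <- vector("list", length(tracks))
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    if (nrow(tr) < min_frames) { rej["duration"] <- rej["duration"] + 1L; next }
    an <- track_anisotropy(tr)
    if (an < min_anisotropy) { rej["anisotropy"] <- rej["anisotropy"] + 1L; next }
    r <- .track_radii(tr, geom)
    radii[[k]] <- r
    if (!(r[1] > position_threshold && r[1] <= 1 &&
          r[length(r)] >= 0 && r[length(r)] < position_threshold)) {
      rej["position"] <- rej["position"] + 1L; next
    }
    sc <- slave_contents[slave_contents$track_id == k, ]
    if (nrow(sc) == 0L) stop("missing content rows for track ", k)
    sc <- sc[order(sc$frame), ]
    first3 <- seq_len(min(3L, nrow(sc)))
    if (!isTRUE(mean(sc$content[first3]) > mean(sc$bg_sd[first3]))) {
      rej["content"] <- rej["content"] + 1L; next
    }
    selected <- c(selected, k)
  }
  list(selected = selected, rejections = rej, radii = radii)
}

#' Radial composition profile with rank-sum tests
#'
#' For every time point of every selected track the slave and master
#' contents are each normalized by their own track's mean over its first
#' three time points, and their ratio is pooled into the radial bin of that
#' frame's normalized radial position (bins of width `bin_width`, half-open
#' `[lo, hi)` with the outermost bin closed at 1). Each bin reports the
#' pooled median, the boxplot-notch 95% CI `median +/- 1.57 * IQR /
#' sqrt(n)`, `n`, and a two-sided Wilcoxon rank-sum p-value against the
#' reference bin; significance uses the Bonferroni threshold
#' `alpha_total / m` with `m` the number of comparisons performed. Bins
#' with fewer than `min_bin_n` points are suppressed.
#'
#' @param tracks track list.
#' @param selection result of [select_tracks()] (its `selected` ids and
#'   cached radii are used).
#' @param master_contents,slave_contents content tables from
#'   [measure_track_contents()].
#' @param geom a `SynapseGeometry`.
#' @param reference_bin lower edge of the reference bin (e.g. 0.9 for the
#'   bin closest to the synapse edge).
#' @param alpha_total total type-I error (default 0.05).
#' @param bin_width,r_min bin geometry: bins cover `[r_min, 1]` (defaults
#'   0.1 and 0.1, giving nine bins and eight comparisons).
#' @param min_bin_n minimum pooled points per reported bin (default 10).
#' @return data.frame `(bin_lo, bin_hi, n, median, ci_lo, ci_hi, p,
#'   significant)` with attributes `threshold` (per-pair significance
#'   threshold) and `m` (number of comparisons).
#' @export
composition_profile <- function(tracks, selection, master_contents,
                                slave_contents, geom, reference_bin = 0.9,
                                alpha_total = 0.05, bin_width = 0.1,
                                r_min = 0.1, min_bin_n = 10) {
  vals <- numeric(0); rpos <- numeric(0)
  for (k in selection$selected) {
    tr <- tracks[[k]]
    mc <- master_contents[master_contents$track_id == k, ]
    sc <- slave_contents[slave_contents$track_id == k, ]
    mc <- mc[order(mc$frame), ]; sc <- sc[order(sc$frame), ]
    if (nrow(mc) < 3L || nrow(sc) < 3L)
      stop("track ", k, " lacks three leading content values")
    nm <- mc$content / mean(mc$content[1:3])
    ns <- sc$content / mean(sc$content[1:3])
    common <- intersect(mc$frame, sc$frame)
    nm <- nm[match(common, mc$frame)]
    ns <- ns[match(common, sc$frame)]
    r <- selection$radii[[k]]
    if (is.null(r)) r <- .track_radii(tr, geom)
    r <- r[match(common, tr$frame)]
    ok <- is.finite(nm) & is.finite(ns) & nm != 0
    vals <- c(vals, (ns / nm)[ok])
    rpos <- c(rpos, r[ok])
  }
  edges <- seq(r_min, 1, by = bin_width)
  nb <- length(edges) - 1L
  bin_of <- findInterval(rpos, edges, rightmost.closed = TRUE)
  out <- data.frame(bin_lo = edges[-(nb + 1L)], bin_hi = edges[-1])
  pooled <- lapply(seq_len(nb), function(b) vals[bin_of == b])
  out$n <- vapply(pooled, length, 0L)
  suppressed <- out$n < min_bin_n
  out$median <- ifelse(suppressed, NA_real_,
                       vapply(pooled, function(v)
                         if (length(v)) stats::median(v) else NA_real_, 0))
  iqr <- vapply(pooled, function(v)
    if (length(v)) stats::IQR(v) else NA_real_, 0)
  notch <- 1.57 * iqr / sqrt(pmax(out$n, 1))
  out$ci_lo <- out$median - notch
  out$ci_hi <- out$median + notch
  ref <- which(abs(out$bin_lo - reference_bin) < 1e-9)
  if (length(ref) != 1L || suppressed[ref])
    stop("reference bin is missing or suppressed (n < ", min_bin_n, ")")
  comp <- which(!suppressed & seq_len(nb) != ref)
  m <- length(comp)
  out$p <- NA_real_
  for (b in comp)
    out$p[b] <- suppressWarnings(
      stats::wilcox.test(pooled[[b]], pooled[[ref]], exact = FALSE))$p.value
  threshold <- if (m > 0) alpha_total / m else NA_real_
  out$significant <- !is.na(out$p) & out$p < threshold
  attr(out, "threshold") <- threshold
  attr(out, "m") <- m
  attr(out, "reference_bin") <- reference_bin
  out
}

#' Photobleaching control series
#'
#' Mean intensity within the segmented synapse but outside the segmented
#' cSMAC and all detected condensate areas, per frame, normalized by the
#' first frame.
#'
#' @param stack channel `ImageStack`.
#' @param geom a `SynapseGeometry`.
#' @param labels list of per-frame condensate label matrices (or `NULL`
#'   for none).
#' @return data.frame `(frame, background_mean, normalized)`; frames with
#'   an empty measurement region carry `NA`.
#' @export
photobleach_control <- function(stack, geom, labels = NULL) {
  nt <- n_frames(stack)
  means <- vapply(seq_len(nt), function(t) {
    g <- geom$frames[[min(t, length(geom$frames))]]
    region <- g$synapse & !g$csmac
    if (!is.null(labels)) region <- region & !(labels[[t]] > 0)
    if (!any(region)) return(NA_real_)
    mean(get_frame(stack, t)[region])
  }, 0)
  if (is.na(means[1]) || means[1] == 0)
    stop("first-frame background is zero or missing; cannot normalize")
  data.frame(frame = seq_len(nt), background_mean = means,
             normalized = means / means[1])
}
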