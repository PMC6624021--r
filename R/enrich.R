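# Actin enrichment at condensates: point-to-continuum colocalization
# summarized as an inside/outside intensity ratio.

#' Actin enrichment at condensates
#'
#' For each condensate the ratio of the mean actin intensity inside its
#' mask to the mean actin intensity over all non-condensate pixels of the
#' frame is computed; the movie-level enrichment is the average of these
#' ratios over condensates, taken by default at the last frame of the
#' movie. Intensities are assumed camera-background subtracted (done on
#' `ImageStack` construction).
#'
#' @param actin actin-channel `ImageStack`.
#' @param labels condensate label matrix for the analyzed frame (or list of
#'   matrices from [detect_stack()]).
#' @param frame_index frame to analyze (default: last frame).
#' @param exclude_dilation_px optional guard zone: condensate masks are
#'   dilated by this radius when defining "outside" (default 0, i.e.
#'   outside = every non-condensate pixel).
#' @return the enrichment ratio (scalar).
#' @export
actin_enrichment <- function(actin, labels, frame_index = NULL,
                             exclude_dilation_px = 0) {
  if (is.null(frame_index)) frame_index <- n_frames(actin)
  a <- get_frame(actin, frame_index)
  lab <- if (is.list(labels)) labels[[frame_index]] else labels
  stopifnot(all(dim(a) == dim(lab)))
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0L) stop("no condensates in frame ", frame_index)
  inside_any <- lab > 0
  outside <- !if (exclude_dilation_px > 0)
    dilate_disc(inside_any, exclude_dilation_px) else inside_any
  out_mean <- mean(a[outside])
  if (out_mean == 0) stop("outside mean intensity is zero; ",
                          "enrichment ratio undefined")
  ratios <- vapply(ids, function(id) mean(a[lab == id]) / out_mean, 0)
  mean(ratios)
}
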