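#' Image stack container
#'
#' An `ImageStack` holds a time-ordered set of single-channel 2-D frames
#' together with the physical calibration needed to convert pixel
#' measurements into micrometres and seconds. All positions elsewhere in the
#' package use the convention x = column, y = row, 0-based, with pixel
#' centers at integer coordinates.
#'
#' @param frames numeric 3-D array `[time, y, x]`, or a list of matrices of
#'   identical dimension. Values must be finite and non-negative after
#'   camera-background subtraction.
#' @param pixel_size_um pixel size in micrometres per pixel (default 0.16,
#'   i.e. 16 px = 2.56 um).
#' @param frame_interval_s time between frames in seconds.
#' @param channel_name label for the channel (e.g. "LAT", "actin").
#' @param camera_background scalar camera offset subtracted from every pixel
#'   on construction; the result is clamped at 0.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(frames, pixel_size_um = 0.16, frame_interval_s = 15,
                        channel_name = "", camera_background = 0) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must share the same (height, width)")
    arr <- array(0, c(length(frames), dims[[1]][1], dims[[1]][2]))
    for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
    frames <- arr
  }
  if (length(dim(frames)) != 3L)
    stop("frames must be a 3-D array [time, y, x]")
  if (!all(is.finite(frames)))
    stop("frame intensities must be finite")
  stopifnot(pixel_size_um > 0, frame_interval_s > 0)
  if (camera_background != 0)
    frames <- pmax(frames - camera_background, 0)
  if (min(frames) < 0)
    stop("frame intensities must be >= 0")
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s, channel_name = channel_name),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("ImageStack '%s': %d frame(s) of %d x %d px, %.3g um/px, %.3g s/frame\n",
              x$channel_name, d[1], d[2], d[3],
              x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Number of frames / frame accessor
#' @param stack an `ImageStack`.
#' @return `n_frames`: integer count. `get_frame`: a `[y, x]` matrix.
#' @export
n_frames <- function(stack) dim(stack$frames)[1]

#' @rdname n_frames
#' @param t frame index, 1-based.
#' @export
get_frame <- function(stack, t) stack$frames[t, , ]

#' Convert a length in pixels to micrometres
#' @param px length in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @return length in micrometres (`px * pixel_size_um`, exact).
#' @export
px_to_um <- function(px, pixel_size_um = 0.16) px * pixel_size_um

#' Read a multi-page TIFF as an ImageStack
#'
#' Pages are read in file order, one frame per page. 16-bit integer files
#' written by [write_stack()] round-trip bit-identically.
#'
#' @param path path to a multi-page TIFF.
#' @inheritParams image_stack
#' @return an `ImageStack`.
#' @export
read_stack <- function(path, pixel_size_um = 0.16, frame_interval_s = 15,
                       channel_name = "", camera_background = 0) {
  if (!file.exists(path))
    stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate grey stored as RGB
    round(p * 65535)
  })
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("inconsistent page shapes in ", path)
  image_stack(pages, pixel_size_um, frame_interval_s, channel_name,
              camera_background)
}

#' Write an ImageStack as a multi-page TIFF
#'
#' Frames are stored as 16-bit unsigned integers (range 0..65535), which is
#' lossless for integer-valued stacks. Non-integer intensities are rounded
#' with a warning.
#'
#' @param stack an `ImageStack`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  fr <- stack$frames
  if (max(fr) > 65535)
    stop("intensities exceed the 16-bit range; rescale before writing")
  if (any(fr != round(fr))) {
    warning("non-integer intensities rounded for 16-bit TIFF storage")
    fr <- round(fr)
  }
  pages <- lapply(seq_len(dim(fr)[1]), function(t) fr[t, , ] / 65535)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16,
                                 compression = "none"),
                 error = function(e) stop("cannot write TIFF: ", path,
                                          " (", conditionMessage(e), ")"))
  invisible(path)
}

#' Write / read a results table
#'
#' Tables are UTF-8 comma-delimited with a header row; numeric columns are
#' written with full double precision so that a read-back reproduces values
#' exactly.
#'
#' @param records a data.frame (or list of uniform named lists/rows).
#' @param path destination path.
#' @return `path` invisibly (`write_table`); a data.frame (`read_table`).
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) {
    if (length(records) == 0L) {
      stop("empty record list without column information; pass a data.frame")
    }
    keys <- lapply(records, names)
    if (length(unique(keys)) != 1L)
      stop("records do not share identical keys")
    records <- do.call(rbind, lapply(records, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  df <- records
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Default run configuration
#'
#' One named list holding every tunable parameter of the pipeline, each with
#' its default. The configuration serializes to YAML and back without loss,
#' and every random operation in the package takes its seed from here when
#' driven through the high-level wrappers.
#'
#' @return a named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    pixel_size_um = 0.16,
    frame_interval_steady_s = 15,
    frame_interval_contract_s = 5,
    frame_interval_cell_s = 5,
    camera_background = 0,
    # detection
    psf_sigma_nm = 74,     # physical PSF sigma; 74/160 ~ 0.46 px
    psf_sigma_px = 0.46,
    bg_sigma_px = 10,
    noise_sigma_px = 1,
    maxima_threshold_k = 3.5,
    min_isolated_for_ratio = 20L,
    fallback_ratio_threshold = 2,
    drift_max_shift_px = 10L,
    # tracking / motion
    search_radius_px = 5,
    gap_window_frames = 3L,
    min_track_frames = 5L,
    mss_max_lag_fraction = 0.1,
    # STICS
    stics_window_px = 16L,
    stics_step_px = 8L,
    stics_shift_frames = 3L,
    # synapse / composition
    smooth_sigma_px = 2,
    n_radial_lines = 8L,
    position_threshold = 0.6,
    min_anisotropy = 3,
    aggregate_perimeter_px = 2L,
    min_bin_n = 10L,
    alpha_total = 0.05,
    # subsampled tests
    subsample_n = 500L,
    subsample_reps = 100L,
    subsample_trigger_n = 1000L
  )
}

#' Write / read a run configuration
#' @param config named list as from [default_config()].
#' @param path YAML file path.
#' @return `path` invisibly / the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml drops integer typing on some platforms; coerce known integer params
  ints <- c("seed", "min_isolated_for_ratio", "drift_max_shift_px",
            "gap_window_frames", "min_track_frames", "stics_window_px",
            "stics_step_px", "stics_shift_frames", "n_radial_lines",
            "aggregate_perimeter_px", "min_bin_n", "subsample_n",
            "subsample_reps", "subsample_trigger_n")
  for (k in intersect(ints, names(cfg))) cfg[[k]] <- as.integer(cfg[[k]])
  cfg
}

#' Stage logging
#'
#' Emits one log line per pipeline stage with its name, parameters and seed.
#' @param stage stage name.
#' @param ... named parameters to report.
#' @return the log line, invisibly.
#' @export
log_stage <- function(stage, ...) {
  p <- list(...)
  msg <- sprintf("[%s] %s", stage,
                 paste(names(p), vapply(p, function(x)
                   paste(format(x), collapse = ","), ""),
                   sep = "=", collapse = " "))
  message(msg)
  invisible(msg)
}
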