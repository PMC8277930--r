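#' Frame stack container
#'
#' An ordered sequence of 8-bit grayscale frames with a frame rate, the raw
#' observable for motion energy analysis. Frames are stored as an
#' `height x width x n_frames` array of integers in `[0, 255]`.
#'
#' @param frames 3-D numeric array, `height x width x n_frames`.
#' @param rate frame rate in frames per second.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, rate) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L, rate > 0)
  if (min(frames) < 0 || max(frames) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  structure(list(frames = frames, rate = as.numeric(rate),
                 dims = dim(frames)[1:2]), class = "frame_stack")
}

#' @exportS3Method base::print
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames of %dx%d px @ %g fps\n",
              dim(x$frames)[3], x$dims[1], x$dims[2], x$rate))
  invisible(x)
}

#' Region of interest
#'
#' A fixed boolean pixel mask covering one person's movement range
#' (`kind = "person"`) or a region where no genuine movement is expected
#' (`kind = "control"`), used to flag recording artifacts.
#'
#' @param mask logical matrix, same dims as the frames it will be applied to.
#' @param kind `"person"` or `"control"`.
#' @return An object of class `roi` with fields `mask`, `area`, `kind`.
#' @export
roi <- function(mask, kind = c("person", "control")) {
  kind <- match.arg(kind)
  stopifnot(is.logical(mask), is.matrix(mask))
  area <- sum(mask)
  if (area == 0) stop("ROI must contain at least one pixel")
  structure(list(mask = mask, area = area, kind = kind), class = "roi")
}

#' Rectangular region of interest
#'
#' @param dims `(height, width)` of the frames.
#' @param row0,col0 top-left corner (1-based).
#' @param height,width extent in pixels.
#' @inheritParams roi
#' @return An [roi()] object.
#' @export
roi_rect <- function(dims, row0, col0, height, width,
                     kind = c("person", "control")) {
  stopifnot(row0 >= 1, col0 >= 1,
            row0 + height - 1 <= dims[1], col0 + width - 1 <= dims[2])
  m <- matrix(FALSE, dims[1], dims[2])
  m[row0:(row0 + height - 1), col0:(col0 + width - 1)] <- TRUE
  roi(m, match.arg(kind))
}

#' Motion energy analysis configuration
#'
#' Defaults follow a conservative frame-differencing setup: a pixel
#' grey-level threshold of 12, despiking at 10 SD with
#' last-observation-carried-forward, control-region replacement at a
#' standardized energy of 5, and a zero-phase order-2 Butterworth low-pass
#' at 2 Hz, followed by block-average resampling to 10 samples/s so that a
#' 0.1 s cross-correlation lag step equals exactly one sample.
#'
#' @param pixel_threshold grey levels; a pixel counts as changed when its
#'   absolute frame-to-frame difference strictly exceeds this.
#' @param despike_sd multiplier; values at or above `despike_sd * sd(series)`
#'   are treated as video errors.
#' @param control_threshold standardized energy at or above which the
#'   control ROI flags an artifact.
#' @param butterworth_order,butterworth_cutoff smoothing filter order and
#'   cutoff frequency (Hz).
#' @param target_rate output sampling rate (samples/s).
#' @param standardize_scale scale for ROI-size standardization (100 gives
#'   percent-of-ROI-active units).
#' @param method `"count"` counts suprathreshold pixels; `"sad"` sums
#'   absolute suprathreshold differences.
#' @return An object of class `mea_config`.
#' @export
mea_config <- function(pixel_threshold = 12, despike_sd = 10,
                       control_threshold = 5, butterworth_order = 2,
                       butterworth_cutoff = 2, target_rate = 10,
                       standardize_scale = 100,
                       method = c("count", "sad")) {
  method <- match.arg(method)
  cfg <- list(pixel_threshold = pixel_threshold, despike_sd = despike_sd,
              control_threshold = control_threshold,
              butterworth_order = butterworth_order,
              butterworth_cutoff = butterworth_cutoff,
              target_rate = target_rate,
              standardize_scale = standardize_scale, method = method)
  num <- cfg[setdiff(names(cfg), "method")]
  if (any(vapply(num, function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    stop("all mea_config thresholds and rates must be positive numbers")
  }
  structure(cfg, class = "mea_config")
}

#' Raw motion energy by frame differencing
#'
#' For each consecutive frame pair, counts the ROI pixels whose absolute
#' grayscale difference strictly exceeds `pixel_threshold` (a difference
#' exactly equal to the threshold does not count). The output has
#' `n_frames - 1` samples at the frame rate.
#'
#' @param stack a [frame_stack()].
#' @param roi an [roi()] whose mask matches the frame dims.
#' @param pixel_threshold grey-level threshold (default 12).
#' @param method `"count"` (changed-pixel count, the default) or `"sad"`
#'   (sum of absolute differences over suprathreshold pixels).
#' @return An [mea_series()].
#' @export
motion_energy <- function(stack, roi, pixel_threshold = 12,
                          method = c("count", "sad")) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "frame_stack"), inherits(roi, "roi"))
  if (!all(dim(roi$mask) == stack$dims)) {
    stop("ROI dimensions do not match the frame dimensions")
  }
  n <- dim(stack$frames)[3]
  if (n < 2) stop("frame stack must contain at least 2 frames")
  d <- abs(stack$frames[, , -1, drop = FALSE] -
             stack$frames[, , -n, drop = FALSE])
  dim(d) <- c(prod(stack$dims), n - 1L)
  d <- d[as.vector(roi$mask), , drop = FALSE]
  hit <- d > pixel_threshold
  vals <- if (method == "count") colSums(hit) else colSums(d * hit)
  out <- mea_series(vals, rate = stack$rate, roi_area = roi$area)
  add_provenance(out, "motion_energy",
                 list(pixel_threshold = pixel_threshold, method = method,
                      roi_kind = roi$kind, roi_area = roi$area))
}

#' Standardize a motion-energy series for ROI size
#'
#' Multiplies every value by `scale / roi_area`; with the default scale of
#' 100 the result is the percentage of ROI pixels active per frame, which
#' makes series from differently sized regions comparable.
#'
#' @param series an [mea_series()].
#' @param roi_area pixel area; defaults to the area recorded on the series.
#' @param scale output scale (default 100).
#' @return An [mea_series()].
#' @export
standardize_roi <- function(series, roi_area = series$roi_area, scale = 100) {
  stopifnot(inherits(series, "mea_series"))
  if (!is.finite(roi_area) || roi_area <= 0) {
    stop("roi_area must be a positive number")
  }
  series$values <- series$values * scale / roi_area
  add_provenance(series, "standardize_roi",
                 list(roi_area = roi_area, scale = scale))
}

# Replace flagged values by the most recent retained value (0 before the
# first retained sample).
locf_replace <- function(values, bad) {
  keep <- !bad
  c(0, values[keep])[cumsum(keep) + 1L]
}

#' Remove video-error spikes from a motion-energy series
#'
#' Values at or above `despike_sd` times the standard deviation of the raw
#' input series (computed once, not recursively) are treated as recording
#' errors and replaced by carrying the last retained value forward; a spike
#' at the first sample becomes 0. A zero-variance series is returned
#' unchanged.
#'
#' @param series an [mea_series()] of length >= 2.
#' @param despike_sd SD multiplier (default 10).
#' @return An [mea_series()].
#' @export
despike <- function(series, despike_sd = 10) {
  stopifnot(inherits(series, "mea_series"))
  v <- series$values
  if (length(v) < 2) stop("despike needs at least 2 samples")
  s <- stats::sd(v)
  n_rep <- 0L
  if (s > 0) {
    bad <- v >= despike_sd * s
    n_rep <- sum(bad)
    series$values <- locf_replace(v, bad)
  }
  add_provenance(series, "despike",
                 list(despike_sd = despike_sd, sd = s, n_replaced = n_rep))
}

#' Replace values flagged by a control region
#'
#' Wherever the (standardized) motion energy of a control ROI — a region
#' where no genuine movement is expected — reaches `control_threshold`, the
#' person's value is considered a recording artifact and replaced by
#' last-observation-carried-forward (0 before the first clean sample).
#'
#' @param series person [mea_series()].
#' @param control_series control-ROI [mea_series()], standardized, equal
#'   length.
#' @param control_threshold standardized energy threshold (default 5);
#'   control values `>=` this trigger replacement.
#' @return An [mea_series()].
#' @export
control_filter <- function(series, control_series, control_threshold = 5) {
  stopifnot(inherits(series, "mea_series"))
  cv <- if (inherits(control_series, "mea_series")) control_series$values
        else as.numeric(control_series)
  if (length(cv) != length(series$values)) {
    stop("person and control series must have equal length")
  }
  bad <- cv >= control_threshold
  series$values <- locf_replace(series$values, bad)
  add_provenance(series, "control_filter",
                 list(control_threshold = control_threshold,
                      n_replaced = sum(bad)))
}

#' Smooth a motion-energy series with a zero-phase Butterworth filter
#'
#' Applies a low-pass Butterworth filter forward and backward
#' (zero phase), preserving length and clipping negative filter output to
#' 0 so the series stays a nonnegative energy.
#'
#' @param series an [mea_series()].
#' @param order filter order (default 2).
#' @param cutoff_hz cutoff frequency; must be below the Nyquist frequency.
#' @return An [mea_series()].
#' @export
smooth_series <- function(series, order = 2, cutoff_hz = 2) {
  stopifnot(inherits(series, "mea_series"))
  nyquist <- series$rate / 2
  if (cutoff_hz >= nyquist) {
    stop("cutoff_hz must be below the Nyquist frequency (rate/2)")
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass; trimmed off afterwards
  v <- series$values
  n <- length(v)
  pad <- min(n - 1, max(12, 3 * ceiling(series$rate / cutoff_hz)))
  if (pad > 0) {
    head_pad <- 2 * v[1] - v[(pad + 1):2]
    tail_pad <- 2 * v[n] - v[(n - 1):(n - pad)]
    out <- signal::filtfilt(bf, c(head_pad, v, tail_pad))
    out <- out[(pad + 1):(pad + n)]
  } else {
    out <- signal::filtfilt(bf, v)
  }
  series$values <- pmax(out, 0)
  add_provenance(series, "smooth",
                 list(order = order, cutoff_hz = cutoff_hz,
                      zero_phase = TRUE))
}

#' Resample a motion-energy series by block averaging
#'
#' Averages consecutive blocks of `rate / target_rate` samples. When the
#' ratio is not an integer the nearest integer block size is used (and the
#' achieved rate recorded); a trailing partial block is dropped.
#'
#' @param series an [mea_series()].
#' @param target_rate desired sampling rate, `<=` the current rate.
#' @return An [mea_series()] at the achieved rate.
#' @export
resample_series <- function(series, target_rate = 10) {
  stopifnot(inherits(series, "mea_series"))
  if (target_rate > series$rate) {
    stop("target_rate must not exceed the current rate")
  }
  block <- max(1L, as.integer(round(series$rate / target_rate)))
  new_rate <- series$rate / block
  if (block > 1L) {
    nb <- length(series$values) %/% block
    if (nb == 0) stop("series shorter than one resampling block")
    v <- series$values[seq_len(nb * block)]
    series$values <- colMeans(matrix(v, nrow = block))
  }
  series$rate <- new_rate
  add_provenance(series, "resample",
                 list(target_rate = target_rate, block = block,
                      achieved_rate = new_rate))
}

#' Full motion energy preprocessing pipeline
#'
#' Composes, in order: raw frame differencing, ROI-size standardization,
#' despiking, control-ROI artifact filtering, zero-phase Butterworth
#' smoothing, and block-average resampling. Provenance records every stage
#' with its parameters.
#'
#' @param stack a [frame_stack()].
#' @param roi_person person [roi()].
#' @param roi_control control [roi()]; must be disjoint from the person ROI.
#' @param config an [mea_config()].
#' @return A preprocessed [mea_series()].
#' @export
mea_preprocess <- function(stack, roi_person, roi_control,
                           config = mea_config()) {
  stopifnot(inherits(config, "mea_config"),
            inherits(roi_person, "roi"), inherits(roi_control, "roi"))
  if (any(roi_person$mask & roi_control$mask)) {
    stop("person and control ROIs must be disjoint")
  }
  person <- motion_energy(stack, roi_person, config$pixel_threshold,
                          method = config$method)
  person <- standardize_roi(person, scale = config$standardize_scale)
  person <- despike(person, config$despike_sd)
  control <- standardize_roi(
    motion_energy(stack, roi_control, config$pixel_threshold,
                  method = config$method),
    scale = config$standardize_scale)
  person <- control_filter(person, control, config$control_threshold)
  person <- smooth_series(person, config$butterworth_order,
                          config$butterworth_cutoff)
  resample_series(person, config$target_rate)
}
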