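#' Write a motion-energy series as two-column delimited text
#'
#' Writes `time_s, energy` CSV rows plus (optionally) a JSON provenance
#' sidecar (`<path>.prov.json`) recording rate, ROI area and every
#' preprocessing step.
#'
#' @param series an [mea_series()].
#' @param path output CSV path.
#' @param sidecar write the provenance sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, sidecar = TRUE) {
  stopifnot(inherits(series, "mea_series"))
  n <- length(series$values)
  df <- data.frame(time_s = (seq_len(n) - 1) / series$rate,
                   energy = series$values)
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(rate = series$rate,
           roi_area = if (is.finite(series$roi_area)) series$roi_area,
           n_samples = n, provenance = series$provenance),
      paste0(path, ".prov.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(path)
}

#' Read a motion-energy series written by [write_series()]
#'
#' The sampling rate is taken from the provenance sidecar when present,
#' otherwise inferred from the time column.
#'
#' @param path CSV path with `time_s, energy` columns.
#' @return An [mea_series()].
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "energy") %in% names(df)))
  side <- paste0(path, ".prov.json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = FALSE)
    mea_series(df$energy, rate = meta$rate,
               roi_area = if (is.null(meta$roi_area)) NA_real_
                          else as.numeric(meta$roi_area),
               provenance = meta$provenance)
  } else {
    dt <- stats::median(diff(df$time_s))
    mea_series(df$energy, rate = 1 / dt)
  }
}

#' Write study tables to a directory
#'
#' Writes `sessions.csv` (dyad_id, session_no, sync_true,
#' seq_goodness_pat, seq_goodness_ther) and `dyads.csv` (dyad_id,
#' lopf_base, lopf_fu, cgas_base, cgas_fu, wai_sr).
#'
#' @param study a [gen_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_tables <- function(study, dir) {
  stopifnot(inherits(study, "study_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$sessions, file.path(dir, "sessions.csv"),
                   row.names = FALSE)
  utils::write.csv(study$dyads, file.path(dir, "dyads.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read study tables written by [write_study_tables()]
#'
#' @param dir directory containing `sessions.csv` and `dyads.csv`.
#' @return A `study_tables` list (without ground-truth attributes).
#' @export
read_study_tables <- function(dir) {
  structure(
    list(sessions = utils::read.csv(file.path(dir, "sessions.csv")),
         dyads = utils::read.csv(file.path(dir, "dyads.csv"))),
    class = "study_tables"
  )
}

#' Write a frame stack as a directory of PNG frames
#'
#' Frames are written as numerically ordered 8-bit grayscale PNGs
#' (`frame_000001.png`, ...) with a small JSON metadata file recording the
#' frame rate.
#'
#' @param stack a [frame_stack()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_frame_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(stack$frames)[3]
  for (t in seq_len(n)) {
    png::writePNG(stack$frames[, , t] / 255,
                  file.path(dir, sprintf("frame_%06d.png", t)))
  }
  jsonlite::write_json(list(rate = stack$rate, n_frames = n),
                       file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a frame stack from a directory of PNG frames
#'
#' @param dir directory of numerically ordered grayscale PNGs; the frame
#'   rate is read from `stack.json` or given explicitly.
#' @param rate frame rate override (frames/s).
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(dir, rate = NULL) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames in ", dir)
  if (is.null(rate)) {
    meta_path <- file.path(dir, "stack.json")
    if (!file.exists(meta_path)) stop("no stack.json and no rate given")
    rate <- jsonlite::read_json(meta_path)$rate
  }
  imgs <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    round(img * 255)
  })
  frames <- array(unlist(imgs), dim = c(dim(imgs[[1]]), length(imgs)))
  frame_stack(frames, rate = rate)
}

#' Read / write a session manifest
#'
#' A manifest lists every administered session with its recording paths
#' and status (`analyzable`, `consent_withdrawn`, `technical_failure`).
#'
#' @param manifest data frame (see [simulate_manifest()]).
#' @param path CSV path.
#' @return The manifest data frame (read) or `path` invisibly (write).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path)
  stopifnot(all(c("dyad_id", "session_no", "status") %in% names(m)))
  m
}

#' Session data accounting
#'
#' Totals administered sessions by status and derives the analyzable
#' count (administered minus excluded). Duplicate session keys are an
#' error.
#'
#' @param manifest data frame with `dyad_id`, `session_no`, `status`.
#' @return List with `administered`, `by_status` (named integer vector)
#'   and `analyzable`.
#' @export
account_sessions <- function(manifest) {
  stopifnot(is.data.frame(manifest),
            all(c("dyad_id", "session_no", "status") %in% names(manifest)))
  if (anyDuplicated(paste(manifest$dyad_id, manifest$session_no,
                          sep = "\r"))) {
    stop("duplicate (dyad_id, session_no) keys in manifest")
  }
  n <- nrow(manifest)
  by_status <- if (n > 0) {
    tab <- table(manifest$status)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  excluded <- sum(by_status[names(by_status) != "analyzable"])
  list(administered = n, by_status = by_status,
       analyzable = n - excluded)
}
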