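# VideoStack container and TIFF + sidecar-metadata I/O.

#' Video stack container
#'
#' Ordered grayscale frames with acquisition metadata. Frames are numeric
#' matrices `[y, x]` with intensities in `[0, 1]`.
#'
#' @param frames list of numeric matrices, all the same dimensions.
#' @param fps frame rate (Hz).
#' @param um_per_px pixel calibration (µm/px).
#' @param event_frames optional strictly increasing 1-based frame indices;
#'   each marks the first post-flash frame.
#' @return an object of class `video_stack`.
#' @export
video_stack <- function(frames, fps, um_per_px, event_frames = NULL) {
  stopifnot(length(frames) >= 1, fps > 0, um_per_px > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same dimensions")
  if (!is.null(event_frames)) {
    event_frames <- as.integer(event_frames)
    if (any(diff(event_frames) <= 0) || any(event_frames < 1) ||
        any(event_frames > length(frames)))
      stop("event_frames must be strictly increasing and within range")
  }
  structure(list(frames = frames, fps = fps, um_per_px = um_per_px,
                 event_frames = event_frames), class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("Video stack: ", length(x$frames), " frames of ", d[2], "x", d[1],
      " px at ", x$fps, " fps (", x$um_per_px, " um/px)\n", sep = "")
  if (!is.null(x$event_frames))
    cat("  event frames:", paste(x$event_frames, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.video_stack <- function(x) length(x$frames)

#' Write a video stack as multi-page TIFF plus sidecar metadata
#'
#' @param video a [video_stack()].
#' @param tiff_path output TIFF path.
#' @param meta_path sidecar YAML path; defaults to the TIFF path with a
#'   `.yaml` extension.
#' @return invisibly, the two paths.
#' @export
write_video <- function(video, tiff_path,
                        meta_path = sub("\\.tiff?$", ".yaml", tiff_path)) {
  tiff::writeTIFF(video$frames, tiff_path, bits.per.sample = 16L)
  meta <- list(fps = video$fps, um_per_px = video$um_per_px,
               n_frames = length(video$frames))
  if (!is.null(video$event_frames))
    meta$event_frames <- as.integer(video$event_frames)
  yaml::write_yaml(meta, meta_path)
  invisible(c(tiff = tiff_path, meta = meta_path))
}

#' Read a video stack from multi-page TIFF plus sidecar metadata
#'
#' @param tiff_path TIFF path.
#' @param meta_path sidecar YAML path with `fps`, `um_per_px` and optional
#'   `event_frames`.
#' @return a [video_stack()].
#' @export
read_video <- function(tiff_path,
                       meta_path = sub("\\.tiff?$", ".yaml", tiff_path)) {
  frames <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]
    f
  })
  meta <- yaml::read_yaml(meta_path)
  video_stack(frames, fps = meta$fps, um_per_px = meta$um_per_px,
              event_frames = meta$event_frames)
}

#' Write ground truth as CSV and JSON
#'
#' The per-frame table goes to CSV; scalar metadata (event frame) and the
#' per-frame table to JSON.
#'
#' @param truth the `truth` element of [generate_video()].
#' @param csv_path,json_path output paths.
#' @return invisibly, the paths.
#' @export
write_ground_truth <- function(truth, csv_path, json_path = NULL) {
  utils::write.csv(truth$per_frame, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(event_frame = truth$event_frame,
                              per_frame = truth$per_frame),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
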