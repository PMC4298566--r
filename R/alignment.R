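# Head registration, annulus-based neck azimuth, and rotational alignment of
# frames into a "stop-motion" waveform envelope.

#' Annulus mask geometry
#'
#' Ring centred on the sperm head used to isolate the first pixels of the
#' neck: the default internal diameter of 16 µm covers the head, and the
#' external diameter is 4 µm longer.
#'
#' @param inner_diameter_um internal diameter (µm).
#' @param outer_diameter_um external diameter (µm).
#' @return an object of class `annulus`.
#' @export
annulus <- function(inner_diameter_um = 16, outer_diameter_um = 20) {
  stopifnot(outer_diameter_um > inner_diameter_um, inner_diameter_um > 0)
  structure(list(inner_diameter_um = inner_diameter_um,
                 outer_diameter_um = outer_diameter_um), class = "annulus")
}

# Extract an (2r+1)^2 patch around integer center, NA-padded at borders.
extract_patch <- function(img, cx, cy, r) {
  h <- nrow(img); w <- ncol(img)
  xs <- (cx - r):(cx + r); ys <- (cy - r):(cy + r)
  ok_x <- xs >= 1 & xs <= w; ok_y <- ys >= 1 & ys <= h
  out <- matrix(NA_real_, 2 * r + 1, 2 * r + 1)
  out[which(ok_y), which(ok_x)] <- img[ys[ok_y], xs[ok_x]]
  out
}

ncc <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# Parabolic sub-pixel refinement from three samples around a peak.
parabolic_offset <- function(l, m, r) {
  den <- l - 2 * m + r
  if (den >= 0) return(0)  # not a maximum
  off <- 0.5 * (l - r) / den
  max(-0.5, min(0.5, off))
}

#' Register the head across frames
#'
#' Matches a fixed head template (taken from the first frame inside the
#' user-defined region of interest) against each frame by normalized
#' cross-correlation over integer shifts, with parabolic sub-pixel
#' refinement; the search window follows the previous frame's estimate.
#'
#' @param video a [video_stack()].
#' @param roi list with `center` `(x, y)` and `radius` (px) containing the
#'   head in frame 1.
#' @param search_px integer search half-range around the previous estimate.
#' @param min_confidence matches scoring below this NCC are tracking losses.
#' @return data frame of class `head_track` with `frame`, `x`, `y`,
#'   `confidence`.
#' @export
register_head <- function(video, roi, search_px = 6, min_confidence = 0.5) {
  f1 <- video$frames[[1]]
  bin1 <- binarize(f1, frame_index = 1)
  pose1 <- tryCatch(
    locate_head(bin1, intensity = f1, prior = roi$center,
                prior_radius_px = roi$radius, frame_index = 1),
    error = function(e)
      stop("ROI does not contain the head in frame 1: ", conditionMessage(e)))
  r <- ceiling(roi$radius)
  c0 <- round(pose1$center)
  template <- extract_patch(f1, c0[1], c0[2], r)
  n <- length(video$frames)
  out <- data.frame(frame = seq_len(n), x = NA_real_, y = NA_real_,
                    confidence = NA_real_)
  prev <- pose1$center
  for (k in seq_len(n)) {
    fk <- video$frames[[k]]
    pc <- round(prev)
    shifts <- expand.grid(dx = -search_px:search_px, dy = -search_px:search_px)
    scores <- matrix(NA_real_, 2 * search_px + 1, 2 * search_px + 1)
    for (i in seq_len(nrow(shifts))) {
      patch <- extract_patch(fk, pc[1] + shifts$dx[i], pc[2] + shifts$dy[i], r)
      scores[shifts$dy[i] + search_px + 1, shifts$dx[i] + search_px + 1] <-
        ncc(template, patch)
    }
    best <- which(scores == max(scores), arr.ind = TRUE)[1, ]
    conf <- max(scores)
    if (conf < min_confidence)
      stop("tracking lost at frame ", k, ": best match score ",
           sprintf("%.3f", conf), " below ", min_confidence)
    iy <- best[1]; ix <- best[2]
    sx <- if (ix > 1 && ix < ncol(scores))
      parabolic_offset(scores[iy, ix - 1], scores[iy, ix], scores[iy, ix + 1])
      else 0
    sy <- if (iy > 1 && iy < nrow(scores))
      parabolic_offset(scores[iy - 1, ix], scores[iy, ix], scores[iy + 1, ix])
      else 0
    x <- pc[1] + (ix - search_px - 1) + sx
    y <- pc[2] + (iy - search_px - 1) + sy
    out$x[k] <- x; out$y[k] <- y; out$confidence[k] <- conf
    prev <- c(x, y)
  }
  structure(out, class = c("head_track", "data.frame"),
            template_center = pose1$center)
}

#' Neck azimuth within an annulus mask
#'
#' Direction (y-up) of the centroid of the foreground pixels that fall
#' inside the annulus, relative to the head center. The annulus covers the
#' head and resolves the first pixels of the neck. When the raw frame is
#' supplied the centroid is intensity-weighted, which suppresses the
#' contribution of dim rim pixels that flicker across the threshold and
#' roughly halves the angular noise.
#'
#' @param binary logical matrix from [binarize()].
#' @param head_center `(x, y)` head position (px).
#' @param ann an [annulus()].
#' @param um_per_px pixel calibration (µm/px).
#' @param intensity optional raw frame for intensity weighting.
#' @param frame_index optional index used in error messages.
#' @return azimuth in radians, (-pi, pi].
#' @export
neck_azimuth <- function(binary, head_center, ann = annulus(), um_per_px,
                         intensity = NULL, frame_index = NULL) {
  tag <- if (is.null(frame_index)) "" else paste0(" (frame ", frame_index, ")")
  r_in <- ann$inner_diameter_um / 2 / um_per_px
  r_out <- ann$outer_diameter_um / 2 / um_per_px
  h <- nrow(binary); w <- ncol(binary)
  if (head_center[1] - r_out < 1 || head_center[1] + r_out > w ||
      head_center[2] - r_out < 1 || head_center[2] + r_out > h)
    stop("annulus extends beyond the image", tag)
  xs <- floor(head_center[1] - r_out):ceiling(head_center[1] + r_out)
  ys <- floor(head_center[2] - r_out):ceiling(head_center[2] + r_out)
  d <- sqrt(outer((ys - head_center[2])^2, (xs - head_center[1])^2, `+`))
  ring <- d > r_in & d <= r_out & binary[ys, xs, drop = FALSE]
  if (!any(ring))
    stop("no-neck error: annulus contains no foreground", tag)
  sel <- which(ring, arr.ind = TRUE)
  dx <- xs[sel[, 2]] - head_center[1]
  dy <- ys[sel[, 1]] - head_center[2]
  ang <- atan2(-dy, dx)
  # two opposite sectors (e.g. a flagellar loop re-entering the annulus)
  resultant <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  if (resultant < 0.5)
    stop("ambiguous-neck error: foreground in opposite annulus sectors", tag)
  w <- if (is.null(intensity)) rep(1, nrow(sel)) else
    intensity[ys, xs, drop = FALSE][ring]
  atan2(sum(-dy * w) / sum(w), sum(dx * w) / sum(w))
}

# Rigid resampling: translate so the head lands on `center_out`, then rotate
# by `delta` (CCW, y-up) about it. Bilinear interpolation; `fill` outside.
align_one_frame <- function(frame, head_center, delta, center_out, fill) {
  h <- nrow(frame); w <- ncol(frame)
  xo <- rep(seq_len(w), each = h) - center_out[1]
  yo <- rep(seq_len(h), times = w) - center_out[2]
  # inverse map: rotate output offsets by -delta (in storage coords a CCW
  # y-up rotation by a is x' = cos(a) x + sin(a) y, y' = -sin(a) x + cos(a) y)
  ca <- cos(-delta); sa <- sin(-delta)
  xi <- ca * xo + sa * yo + head_center[1]
  yi <- -sa * xo + ca * yo + head_center[2]
  matrix(bilinear_sample(frame, xi, yi, fill = fill), nrow = h, ncol = w)
}

#' Rotationally align frames to a common neck azimuth
#'
#' Each frame is translated so its head sits at the reference center and
#' rotated by `reference_azimuth - azimuth_k` with bilinear interpolation.
#'
#' @param video a [video_stack()].
#' @param heads per-frame head centers: a `head_track` or a 2-column matrix.
#' @param azimuths per-frame neck azimuths (radians); NAs are gaps.
#' @param reference_azimuth target azimuth; defaults to the first non-gap
#'   frame's azimuth.
#' @param center_out reference center; defaults to the image center.
#' @return list with `frames` (aligned, gaps dropped), `used` (frame
#'   indices), `reference_azimuth`, `center`.
#' @export
align_frames <- function(video, heads, azimuths, reference_azimuth = NULL,
                         center_out = NULL) {
  if (is.data.frame(heads)) heads <- cbind(heads$x, heads$y)
  n <- length(video$frames)
  stopifnot(nrow(heads) == n, length(azimuths) == n)
  good <- !is.na(azimuths) & !is.na(heads[, 1])
  if (!any(good)) stop("all frames are gapped; nothing to align")
  if (is.null(reference_azimuth)) reference_azimuth <- azimuths[which(good)[1]]
  d <- dim(video$frames[[1]])
  if (is.null(center_out)) center_out <- c((d[2] + 1) / 2, (d[1] + 1) / 2)
  fill <- stats::median(video$frames[[which(good)[1]]])
  frames <- lapply(which(good), function(k)
    align_one_frame(video$frames[[k]], heads[k, ],
                    wrap_angle(reference_azimuth - azimuths[k]),
                    center_out, fill))
  list(frames = frames, used = which(good),
       reference_azimuth = reference_azimuth, center = center_out)
}

#' Superimpose aligned frames into a stop-motion envelope
#'
#' @inheritParams align_frames
#' @param projection `"max"` (default; bright dark-field structures
#'   superimpose naturally) or `"mean"`.
#' @return an object of class `envelope_image` with `image`,
#'   `n_frames_used`, `reference_azimuth`, `projection`, `center`.
#' @export
align_and_superimpose <- function(video, heads, azimuths,
                                  projection = c("max", "mean"),
                                  reference_azimuth = NULL,
                                  center_out = NULL) {
  projection <- match.arg(projection)
  al <- align_frames(video, heads, azimuths, reference_azimuth, center_out)
  img <- switch(projection,
    max = Reduce(pmax, al$frames),
    mean = Reduce(`+`, al$frames) / length(al$frames))
  structure(list(image = img, n_frames_used = length(al$frames),
                 reference_azimuth = al$reference_azimuth,
                 projection = projection, center = al$center),
            class = "envelope_image")
}

#' @export
print.envelope_image <- function(x, ...) {
  cat(sprintf(
    "Stop-motion envelope: %d frames, %s projection, reference azimuth %.3f rad\n",
    x$n_frames_used, x$projection, x$reference_azimuth))
  invisible(x)
}
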