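# Synthetic dark-field video and fluorescence-trace generation with full
# ground truth. The flagellum is modelled as a traveling wave of the tangent
# angle psi(s, t) = base_orientation + amplitude * sin(phi(t) - 2*pi*s/lambda)
# with beat phase phi(t) = 2*pi * integral of the frequency time course; the
# curve is obtained by integrating the tangent from the head attachment point
# along arc length. Coordinates delivered by flagellum_curve() are µm in a
# y-up mathematical frame relative to the head attachment point.

#' Flagellum centreline at a given time
#'
#' Integrates the tangent-angle traveling wave from the head attachment point
#' using midpoint-rule steps of 0.25 µm, so consecutive point spacing is
#' exactly the step and total arc length is exact.
#'
#' @param protocol a [beat_protocol()].
#' @param t time (s) within `[0, duration_s]`.
#' @param ds_um arc-length step (µm), at most 0.5.
#' @return matrix with columns `x`, `y` (µm, y-up, relative to the head
#'   attachment point); the first row is the attachment point itself.
#' @export
flagellum_curve <- function(protocol, t, ds_um = 0.25) {
  if (t < 0 || t > protocol$duration_s)
    stop("t = ", t, " outside the protocol duration [0, ",
         protocol$duration_s, "]")
  stopifnot(ds_um > 0, ds_um <= 0.5)
  L <- protocol$flagellum_length_um
  n <- ceiling(L / ds_um)
  ds <- L / n
  smid <- (seq_len(n) - 0.5) * ds
  phi <- beat_phase(protocol, t)
  psi <- protocol$base_orientation_rad +
    protocol$amplitude_rad * sin(phi - 2 * pi * smid / protocol$wavelength_um)
  x <- c(0, cumsum(ds * cos(psi)))
  y <- c(0, cumsum(ds * sin(psi)))
  cbind(x = x, y = y)
}

# Map a curve in µm (y-up, relative to head) into storage pixel coordinates.
curve_to_px <- function(curve_um, head_center_px, um_per_px) {
  cbind(x = head_center_px[1] + curve_um[, 1] / um_per_px,
        y = head_center_px[2] - curve_um[, 2] / um_per_px)
}

# Splat a value patch around dense polyline samples, combining by max.
# Returns the updated image.
splat_curve <- function(img, pts_px, sigma, peak) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(3 * sigma)
  for (i in seq_len(nrow(pts_px))) {
    px <- pts_px[i, 1]; py <- pts_px[i, 2]
    xs <- max(1, floor(px) - r):min(w, ceiling(px) + r)
    ys <- max(1, floor(py) - r):min(h, ceiling(py) + r)
    d2 <- outer((ys - py)^2, (xs - px)^2, `+`)
    img[ys, xs] <- pmax(img[ys, xs], peak * exp(-d2 / (2 * sigma^2)))
  }
  img
}

#' Render one dark-field frame
#'
#' The flagellum appears as a Gaussian-profile ridge of width
#' `line_sigma_px`; the head as a filled disk of radius `head_radius_um`
#' with a 1-px antialiased rim. Additive Gaussian noise (if any) is clipped
#' to `[0, 1]`.
#'
#' @param curve_um flagellum centreline from [flagellum_curve()] (µm, y-up,
#'   relative to the head attachment point).
#' @param head_center_px head attachment point `(x, y)` in pixels.
#' @param render a [render_params()].
#' @param frame_index optional index used in error messages.
#' @param seed if not `NULL`, seeds the noise draw (defaults to the
#'   `render_params` seed); pass `NA` to use the current RNG stream.
#' @return numeric matrix `[y, x]` with intensities in `[0, 1]`.
#' @export
render_frame <- function(curve_um, head_center_px, render,
                         frame_index = NULL, seed = render$seed) {
  stopifnot(nrow(curve_um) >= 1)
  w <- render$image_size_px[1]; h <- render$image_size_px[2]
  pts <- curve_to_px(curve_um, head_center_px, render$um_per_px)
  if (any(pts[, 1] < 1 | pts[, 1] > w | pts[, 2] < 1 | pts[, 2] > h))
    stop("flagellum leaves the field of view",
         if (!is.null(frame_index)) paste0(" at frame ", frame_index) else "")
  dense <- densify_polyline(pts, by = 0.1)
  img <- matrix(0, nrow = h, ncol = w)
  img <- splat_curve(img, dense, render$line_sigma_px, render$flagellum_peak)
  # head disk, antialiased rim
  r_px <- render$head_radius_um / render$um_per_px
  rr <- ceiling(r_px) + 1
  xs <- max(1, floor(head_center_px[1]) - rr):min(w, ceiling(head_center_px[1]) + rr)
  ys <- max(1, floor(head_center_px[2]) - rr):min(h, ceiling(head_center_px[2]) + rr)
  d <- sqrt(outer((ys - head_center_px[2])^2, (xs - head_center_px[1])^2, `+`))
  img[ys, xs] <- pmax(img[ys, xs],
                      render$flagellum_peak * clip01(r_px + 0.5 - d))
  frame <- render$background_level + img
  if (render$noise_sigma > 0) {
    if (!is.null(seed) && !is.na(seed)) set.seed(seed)
    frame <- frame + stats::rnorm(length(frame), 0, render$noise_sigma)
  }
  clip01(matrix(frame, nrow = h, ncol = w))
}

#' Ground-truth foreground mask for a rendered frame
#'
#' Pixels within `2 * line_sigma_px` of the curve, plus the head disk.
#'
#' @inheritParams render_frame
#' @return logical matrix `[y, x]`.
#' @export
curve_mask <- function(curve_um, head_center_px, render) {
  w <- render$image_size_px[1]; h <- render$image_size_px[2]
  pts <- curve_to_px(curve_um, head_center_px, render$um_per_px)
  dense <- densify_polyline(pts, by = 0.1)
  lim <- 2 * render$line_sigma_px
  mind <- matrix(Inf, nrow = h, ncol = w)
  r <- ceiling(lim) + 1
  for (i in seq_len(nrow(dense))) {
    px <- dense[i, 1]; py <- dense[i, 2]
    xs <- max(1, floor(px) - r):min(w, ceiling(px) + r)
    ys <- max(1, floor(py) - r):min(h, ceiling(py) + r)
    d <- sqrt(outer((ys - py)^2, (xs - px)^2, `+`))
    mind[ys, xs] <- pmin(mind[ys, xs], d)
  }
  mask <- mind <= lim
  r_px <- render$head_radius_um / render$um_per_px
  rr <- ceiling(r_px) + 1
  xs <- max(1, floor(head_center_px[1]) - rr):min(w, ceiling(head_center_px[1]) + rr)
  ys <- max(1, floor(head_center_px[2]) - rr):min(h, ceiling(head_center_px[2]) + rr)
  d <- sqrt(outer((ys - head_center_px[2])^2, (xs - head_center_px[1])^2, `+`))
  mask[ys, xs] <- mask[ys, xs] | d <= r_px
  mask
}

#' Generate a synthetic tethered-sperm video with ground truth
#'
#' Renders `round(duration_s * fps)` frames. The head moves only by the
#' explicit drift; the whole cell may rigidly rotate about the head. Geometry
#' is validated for every frame before any frame is rendered.
#'
#' @param protocol a [beat_protocol()].
#' @param render a [render_params()].
#' @return a list of class `synthetic_video` with elements
#'   \describe{
#'     \item{video}{a [video_stack()] carrying fps, µm/px and event frames}
#'     \item{truth}{a `ground_truth` list: `per_frame` data frame (head
#'       center px, neck azimuth, midpoint angle relative to the symmetry
#'       axis, chord direction, instantaneous frequency), `curves` (per-frame
#'       µm coordinates) and `event_frame`}
#'   }
#' @export
generate_video <- function(protocol, render = render_params()) {
  n <- round(protocol$duration_s * protocol$fps)
  tk <- (seq_len(n) - 1) / protocol$fps
  event_frame <- if (is.null(protocol$event_time_s)) NULL else
    which(tk >= protocol$event_time_s)[1]
  centers <- cbind(
    protocol$head_center_px[1] + (seq_len(n) - 1) * protocol$drift_px_per_frame[1],
    protocol$head_center_px[2] + (seq_len(n) - 1) * protocol$drift_px_per_frame[2])
  # per-frame kinematics first; fail before rendering if geometry is bad
  curves <- vector("list", n)
  w <- render$image_size_px[1]; h <- render$image_size_px[2]
  for (k in seq_len(n)) {
    pk <- protocol
    pk$base_orientation_rad <- protocol$base_orientation_rad +
      (k - 1) * protocol$rotation_rad_per_frame
    curves[[k]] <- flagellum_curve(pk, tk[k])
    pts <- curve_to_px(curves[[k]], centers[k, ], render$um_per_px)
    if (any(pts[, 1] < 1 | pts[, 1] > w | pts[, 2] < 1 | pts[, 2] > h))
      stop("geometry inconsistent: cell leaves the field of view at frame ", k)
  }
  set.seed(protocol$seed + render$seed)
  frames <- vector("list", n)
  for (k in seq_len(n))
    frames[[k]] <- render_frame(curves[[k]], centers[k, ], render,
                                frame_index = k, seed = NA)
  L <- protocol$flagellum_length_um
  axis_k <- protocol$base_orientation_rad +
    (seq_len(n) - 1) * protocol$rotation_rad_per_frame
  gt <- data.frame(frame = seq_len(n), time_s = tk,
                   head_x_px = centers[, 1], head_y_px = centers[, 2],
                   axis_rad = wrap_angle(axis_k))
  gt$neck_azimuth_rad <- vapply(seq_len(n), function(k)
    curve_point_direction(curves[[k]], s = 9), numeric(1))
  gt$midpoint_dir_rad <- vapply(seq_len(n), function(k)
    curve_point_direction(curves[[k]], s = L / 2), numeric(1))
  gt$midpoint_angle_rad <- wrap_angle(gt$midpoint_dir_rad - axis_k)
  gt$frequency_hz <- frequency_at(protocol, tk)
  truth <- structure(list(per_frame = gt, curves = curves,
                          event_frame = event_frame),
                     class = "ground_truth")
  video <- video_stack(frames, fps = protocol$fps,
                       um_per_px = render$um_per_px,
                       event_frames = event_frame)
  structure(list(video = video, truth = truth), class = "synthetic_video")
}

# Direction (y-up) from the head attachment point to the curve point at arc
# length s (µm); the curve has uniform spacing so index = s / ds.
curve_point_direction <- function(curve_um, s) {
  d <- sqrt(diff(curve_um[, 1])^2 + diff(curve_um[, 2])^2)
  cs <- c(0, cumsum(d))
  x <- stats::approx(cs, curve_um[, 1], xout = s)$y
  y <- stats::approx(cs, curve_um[, 2], xout = s)$y
  atan2(y, x)
}

#' Generate a synthetic fluorescence trace
#'
#' Samples before `event_index` follow the baseline plus noise; from
#' `event_index` on, the response (step or saturating exponential) is added.
#'
#' @param protocol a [trace_protocol()].
#' @param instrument instrument tag stored on the trace.
#' @return a [fluorescence_trace()].
#' @export
generate_trace <- function(protocol,
                           instrument = c("plate_reader", "stopped_flow")) {
  instrument <- match.arg(instrument)
  n <- protocol$n_samples
  tt <- (seq_len(n) - 1) * protocol$sample_interval_s
  v <- rep(protocol$baseline_level, n)
  e <- protocol$event_index
  if (protocol$response != "none") {
    post <- seq(e, n)
    dt <- (post - e) * protocol$sample_interval_s
    resp <- switch(protocol$response,
      step = rep(protocol$response_amplitude, length(post)),
      exp  = protocol$response_amplitude *
        (1 - exp(-dt / protocol$response_tau_s)))
    v[post] <- v[post] + resp
  }
  if (protocol$noise_sigma > 0) {
    set.seed(protocol$seed)
    v <- v + stats::rnorm(n, 0, protocol$noise_sigma)
  }
  fluorescence_trace(times = tt, values = v, event_index = e,
                     instrument = instrument)
}
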