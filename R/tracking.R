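# Per-frame segmentation, flagellum tracing and angle measurement.

# Triangle threshold (Zack et al. 1977) on a 256-bin histogram of [0, 1]
# intensities: the bin between the histogram peak and the far tail that is
# farthest from the line joining them.
threshold_triangle <- function(x, nbins = 256) {
  h <- graphics::hist(x, breaks = seq(0, 1, length.out = nbins + 1),
                      plot = FALSE)
  cnt <- h$counts; mids <- h$mids
  pk <- which.max(cnt)
  nz <- which(cnt > 0)
  far <- max(nz)
  if (far == pk) far <- min(nz)
  i <- if (far > pk) pk:far else far:pk
  # unnormalized point-line distance; the line joins (pk, cnt[pk]) and
  # (far, cnt[far])
  d <- abs((cnt[far] - cnt[pk]) * (i - pk) - (far - pk) * (cnt[i] - cnt[pk]))
  mids[i[which.max(d)]]
}

#' Binarize a dark-field frame
#'
#' Global automatic threshold, restricted to the largest connected
#' foreground component. The default criterion is the triangle method (Zack
#' et al. 1977), the standard parameter-free choice for dark-field and
#' fluorescence histograms where a dominant background peak carries a long,
#' sparse bright tail; Otsu's between-class-variance criterion is available
#' but places the threshold too high on such extremely class-imbalanced
#' histograms, clipping the dim flanks of the flagellar ridge.
#'
#' @param frame numeric matrix `[y, x]` with intensities in `[0, 1]`.
#' @param frame_index optional index used in error messages.
#' @param min_foreground_px minimum admissible component size.
#' @param method threshold criterion, `"triangle"` (default) or `"otsu"`.
#' @return logical matrix (the largest component), with the threshold in
#'   `attr(, "threshold")`.
#' @export
binarize <- function(frame, frame_index = NULL, min_foreground_px = 20,
                     method = c("triangle", "otsu")) {
  method <- match.arg(method)
  tag <- if (is.null(frame_index)) "" else paste0(" (frame ", frame_index, ")")
  if (stats::var(as.vector(frame)) == 0)
    stop("segmentation error: zero-variance frame", tag)
  thr <- if (method == "otsu")
    EBImage::otsu(EBImage::Image(frame), range = c(0, 1), levels = 256)
  else
    threshold_triangle(as.vector(frame))
  fg <- frame > thr
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg)))
  if (max(lab) < 1 || sum(fg) < min_foreground_px)
    stop("segmentation error: foreground below ", min_foreground_px, " px", tag)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  if (sum(keep) < min_foreground_px)
    stop("segmentation error: largest component below ", min_foreground_px,
         " px", tag)
  # noise dips inside the cell leave pinholes that skeletonize into loops
  keep <- EBImage::imageData(EBImage::fillHull(EBImage::Image(keep * 1))) > 0
  structure(keep, threshold = thr)
}

#' Locate the sperm head
#'
#' The head is taken as the locally widest region of the foreground (maximum
#' of the distance transform); its position is the intensity-weighted
#' centroid of the pixels whose distance-to-background exceeds 60% of that
#' maximum near it. When a prior position is given, the search is restricted
#' to a window around it.
#'
#' @param binary logical matrix from [binarize()].
#' @param intensity optional raw frame for intensity weighting.
#' @param prior optional `(x, y)` prior head position.
#' @param prior_radius_px half-size of the search window around `prior`.
#' @param frame_index optional index used in error messages.
#' @return a list of class `head_pose` with `center` `(x, y)` and
#'   `confidence`.
#' @export
locate_head <- function(binary, intensity = NULL, prior = NULL,
                        prior_radius_px = 15, frame_index = NULL) {
  tag <- if (is.null(frame_index)) "" else paste0(" (frame ", frame_index, ")")
  h <- nrow(binary); w <- ncol(binary)
  y0 <- 1; x0 <- 1
  B <- binary
  I <- intensity
  if (!is.null(prior)) {
    xs <- max(1, round(prior[1]) - prior_radius_px):
          min(w, round(prior[1]) + prior_radius_px)
    ys <- max(1, round(prior[2]) - prior_radius_px):
          min(h, round(prior[2]) + prior_radius_px)
    B <- binary[ys, xs, drop = FALSE]
    if (!is.null(I)) I <- I[ys, xs, drop = FALSE]
    y0 <- ys[1]; x0 <- xs[1]
  }
  if (!any(B))
    stop("tracking lost: no foreground in the head search window", tag)
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(B * 1)))
  dmax <- max(dm)
  peak <- which(dm == dmax, arr.ind = TRUE)[1, , drop = FALSE]
  # pixels belonging to the widest blob: deep in the distance map and close
  # to the peak (so flagellum pixels elsewhere never contribute)
  sel <- which(dm >= 0.6 * dmax, arr.ind = TRUE)
  d2 <- (sel[, 1] - peak[1])^2 + (sel[, 2] - peak[2])^2
  sel <- sel[d2 <= (2.5 * dmax)^2, , drop = FALSE]
  wgt <- if (is.null(I)) rep(1, nrow(sel)) else I[sel]
  cx <- sum((sel[, 2] + x0 - 1) * wgt) / sum(wgt)
  cy <- sum((sel[, 1] + y0 - 1) * wgt) / sum(wgt)
  conf <- min(1, nrow(sel) / (pi * dmax^2))
  structure(list(center = c(x = cx, y = cy), confidence = conf,
                 frame_index = frame_index), class = "head_pose")
}

#' Trace the flagellum as an ordered curve
#'
#' Skeletonizes the binary component, prunes spurs shorter than `prune_len`,
#' and orders the path from the skeleton endpoint nearest the head center to
#' the far endpoint (the tip). Ties between candidate head-end endpoints are
#' broken by smaller Euclidean distance to the head center, then by lower
#' point index.
#'
#' @param binary logical matrix from [binarize()].
#' @param head a `head_pose` from [locate_head()].
#' @param prune_len spur-pruning length (px).
#' @param frame_index optional index used in error messages.
#' @return a list of class `flagellum_trace` with `points` (n x 2 matrix of
#'   skeleton grid points, columns `x`, `y`, head end first),
#'   `points_smooth` (sub-pixel path after a 5-point moving average of the
#'   coordinates, which removes the staircase bias of grid paths) and
#'   `arc_length_px` (sum of consecutive point distances along the smoothed
#'   path).
#' @export
trace_flagellum <- function(binary, head, prune_len = 5, frame_index = NULL) {
  tag <- if (is.null(frame_index)) "" else paste0(" (frame ", frame_index, ")")
  idx <- which(binary, arr.ind = TRUE)
  ys <- max(1, min(idx[, 1]) - 1):min(nrow(binary), max(idx[, 1]) + 1)
  xs <- max(1, min(idx[, 2]) - 1):min(ncol(binary), max(idx[, 2]) + 1)
  S <- skeletonize(binary[ys, xs, drop = FALSE])
  S <- prune_spurs(S, prune_len)
  eps <- skeleton_endpoints(S)
  if (nrow(eps) < 2)
    stop("tracing error: skeleton has no endpoint pair (closed loop)", tag)
  if (nrow(eps) > 2)
    stop("tracing error: ", nrow(eps), " skeleton endpoints after pruning", tag)
  hx <- head$center[1] - xs[1] + 1; hy <- head$center[2] - ys[1] + 1
  d <- sqrt((eps[, 1] - hy)^2 + (eps[, 2] - hx)^2)
  ord <- order(d, seq_len(nrow(eps)))
  start <- eps[ord[1], ]
  goal <- eps[ord[2], ]
  path <- walk_path(S, start, goal)
  # thinning erodes line ends; regrow the tip along its local direction
  # while the binary foreground continues (the head end stays put: the
  # attachment point is inside the head blob, not at its rim)
  path <- extend_tip(path, binary[ys, xs, drop = FALSE])
  pts <- cbind(x = path[, 2] + xs[1] - 1, y = path[, 1] + ys[1] - 1)
  dimnames(pts) <- list(NULL, c("x", "y"))
  if (nrow(pts) < 2)
    stop("tracing error: skeleton path has fewer than 2 points", tag)
  # grid skeleton paths overestimate arc length by up to ~8% (staircase
  # effect); a short moving average on the coordinates removes the bias
  sm <- smooth_path(pts, k = 5)
  arc <- sum(sqrt(diff(sm[, 1])^2 + diff(sm[, 2])^2))
  structure(list(points = pts, points_smooth = sm, arc_length_px = arc,
                 frame_index = frame_index), class = "flagellum_trace")
}

#' Midflagellar point of a trace
#'
#' The point at half the trace's arc length, linearly interpolated between
#' skeleton points.
#'
#' @param trace a `flagellum_trace`.
#' @return `(x, y)` in pixels.
#' @export
trace_midpoint <- function(trace) {
  pts <- if (!is.null(trace$points_smooth)) trace$points_smooth
         else trace$points
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cs <- c(0, cumsum(d))
  half <- cs[length(cs)] / 2
  c(x = stats::approx(cs, pts[, 1], xout = half)$y,
    y = stats::approx(cs, pts[, 2], xout = half)$y)
}

#' Symmetry axis of the cell
#'
#' Circular mean of the head-to-midflagellum directions; the flagellar beat
#' oscillates symmetrically about the cell axis, so the mean direction over
#' whole beat cycles is the axis.
#'
#' @param directions head-to-midpoint directions (radians, y-up).
#' @return axis direction in (-pi, pi].
#' @export
symmetry_axis <- function(directions) {
  stopifnot(length(directions) >= 1)
  circular_mean(directions)
}

#' Per-frame head-to-midflagellum angle series
#'
#' For every frame: segment, locate the head (seeded by the previous frame's
#' position), trace the flagellum, take the midflagellar point, and measure
#' the signed angle (positive = counter-clockwise, y-up) between the cell's
#' symmetry axis and the head-to-midpoint direction. The axis is the circular
#' mean of the directions over the same event-aware window used for the
#' frequency fit. Frames whose segmentation or tracing fails carry a gap
#' marker and are excluded from fits; more than 10% failures aborts with
#' per-frame diagnostics.
#'
#' @param video a [video_stack()].
#' @param window_s half-window length (s) used for the symmetry axis (and
#'   downstream frequency fits).
#' @param head_prior optional `(x, y)` prior for the head in frame 1.
#' @param prune_len spur-pruning length (px), see [trace_flagellum()].
#' @param keep_traces if `TRUE`, the per-frame flagellum traces are attached
#'   as the `traces` attribute.
#' @return an object of class `angle_series`: a data frame with columns
#'   `frame`, `time_s`, `head_x`, `head_y`, `mid_x`, `mid_y`, `theta_rad`
#'   (absolute head-to-midpoint direction), `axis_rad`, `angle_rad`,
#'   `status`; attributes `fps`, `event_frames`, `window_s`.
#' @export
angle_series <- function(video, window_s = 0.5, head_prior = NULL,
                         prune_len = 5, keep_traces = FALSE) {
  n <- length(video$frames)
  traces <- if (keep_traces) vector("list", n) else NULL
  out <- data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / video$fps,
                    head_x = NA_real_, head_y = NA_real_,
                    mid_x = NA_real_, mid_y = NA_real_,
                    theta_rad = NA_real_, axis_rad = NA_real_,
                    angle_rad = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  prior <- head_prior
  for (k in seq_len(n)) {
    res <- tryCatch({
      bin <- binarize(video$frames[[k]], frame_index = k)
      head <- locate_head(bin, intensity = video$frames[[k]], prior = prior,
                          frame_index = k)
      tr <- trace_flagellum(bin, head, prune_len = prune_len, frame_index = k)
      mid <- trace_midpoint(tr)
      list(head = head$center, mid = mid, trace = tr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$status[k] <- conditionMessage(res)
    } else {
      out$head_x[k] <- res$head[1]; out$head_y[k] <- res$head[2]
      out$mid_x[k] <- res$mid[1]; out$mid_y[k] <- res$mid[2]
      out$theta_rad[k] <- atan2(-(res$mid[2] - res$head[2]),
                                res$mid[1] - res$head[1])
      if (keep_traces) traces[[k]] <- res$trace
      prior <- res$head
    }
  }
  failed <- out$status != "ok"
  if (mean(failed) > 0.10) {
    diag <- paste0("frame ", out$frame[failed], ": ", out$status[failed])
    stop("angle series failed on ", sum(failed), "/", n, " frames:\n",
         paste(utils::head(diag, 20), collapse = "\n"))
  }
  # per-frame symmetry axis over the frame's analysis window
  for (k in seq_len(n)) {
    if (failed[k]) next
    wb <- tryCatch(
      window_bounds(k, n, video$fps, window_s, video$event_frames),
      error = function(e) e)
    if (inherits(wb, "error")) {
      out$status[k] <- "window: run shorter than window"
      next
    }
    idx <- wb[1]:wb[2]
    th <- out$theta_rad[idx][!failed[idx]]
    out$axis_rad[k] <- circular_mean(th)
    out$angle_rad[k] <- wrap_angle(out$theta_rad[k] - out$axis_rad[k])
  }
  structure(out, class = c("angle_series", "data.frame"),
            fps = video$fps, event_frames = video$event_frames,
            window_s = window_s, um_per_px = video$um_per_px,
            traces = traces)
}

#' @export
print.head_pose <- function(x, ...) {
  cat(sprintf("Head pose: center (%.2f, %.2f) px, confidence %.2f\n",
              x$center[1], x$center[2], x$confidence))
  invisible(x)
}

#' @export
print.flagellum_trace <- function(x, ...) {
  cat(sprintf("Flagellum trace: %d points, arc length %.1f px\n",
              nrow(x$points), x$arc_length_px))
  invisible(x)
}
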