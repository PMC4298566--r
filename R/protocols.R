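#' Beat protocol for the synthetic tethered-sperm generator
#'
#' Describes the kinematics of a head-tethered sperm whose flagellum beats as
#' a low-amplitude traveling wave of the tangent angle. The frequency time
#' course is programmable: a constant, a step (emulating a light-flash-evoked
#' acceleration), or an arbitrary function of time.
#'
#' @param duration_s recording duration (s).
#' @param fps frame rate (Hz); dark-field recordings here emulate 200 fps.
#' @param frequency either a single number (constant beat frequency, Hz), a
#'   length-2 vector `c(f_pre, f_post)` for a step at `event_time_s`, or a
#'   function of time returning Hz.
#' @param event_time_s time of the step / light flash (s), or `NULL`.
#' @param amplitude_rad amplitude of the tangent-angle wave (rad).
#' @param wavelength_um wavelength of the traveling wave (µm).
#' @param flagellum_length_um flagellum arc length L (µm).
#' @param base_orientation_rad direction of the cell's symmetry axis (rad,
#'   y-up mathematical convention).
#' @param head_center_px head attachment point `(x, y)` in pixels.
#' @param drift_px_per_frame residual head drift `(dx, dy)` px/frame.
#' @param rotation_rad_per_frame rigid rotation of the whole cell about the
#'   head (rad/frame, CCW in the y-up frame).
#' @param seed integer seed governing all stochastic draws of the recording.
#' @return an object of class `beat_protocol`.
#' @export
beat_protocol <- function(duration_s = 2, fps = 200, frequency = 10,
                          event_time_s = NULL, amplitude_rad = 0.35,
                          wavelength_um = 120, flagellum_length_um = 60,
                          base_orientation_rad = 0,
                          head_center_px = c(64, 128),
                          drift_px_per_frame = c(0, 0),
                          rotation_rad_per_frame = 0, seed = 1L) {
  stopifnot(fps > 0, duration_s > 0, flagellum_length_um > 0,
            amplitude_rad >= 0, wavelength_um > 0)
  if (is.numeric(frequency) && length(frequency) == 2 && is.null(event_time_s))
    stop("a two-level frequency step requires 'event_time_s'")
  p <- structure(list(
    duration_s = duration_s, fps = fps, frequency = frequency,
    event_time_s = event_time_s, amplitude_rad = amplitude_rad,
    wavelength_um = wavelength_um, flagellum_length_um = flagellum_length_um,
    base_orientation_rad = base_orientation_rad,
    head_center_px = head_center_px,
    drift_px_per_frame = drift_px_per_frame,
    rotation_rad_per_frame = rotation_rad_per_frame,
    seed = as.integer(seed)), class = "beat_protocol")
  ts <- seq(0, duration_s, length.out = 101)
  if (any(frequency_at(p, ts) < 0))
    stop("frequency_fn must be non-negative over [0, duration_s]")
  p
}

#' Instantaneous beat frequency of a protocol
#'
#' @param protocol a [beat_protocol()].
#' @param t times (s), vectorized.
#' @return frequency in Hz at each `t`.
#' @export
frequency_at <- function(protocol, t) {
  f <- protocol$frequency
  if (is.function(f)) return(vapply(t, f, numeric(1)))
  if (length(f) == 1) return(rep(f, length(t)))
  ifelse(t < protocol$event_time_s, f[1], f[2])
}

#' Beat phase phi(t) = 2 pi * integral of the frequency time course
#'
#' @param protocol a [beat_protocol()].
#' @param t times (s), vectorized.
#' @return phase in radians at each `t`.
#' @export
beat_phase <- function(protocol, t) {
  f <- protocol$frequency
  if (is.function(f)) {
    # cumulative trapezoid on a fine grid, then interpolate
    grid <- seq(0, max(protocol$duration_s, max(t)), length.out = 4001)
    fg <- vapply(grid, f, numeric(1))
    ph <- 2 * pi * c(0, cumsum((fg[-1] + fg[-length(fg)]) / 2 * diff(grid)))
    return(stats::approx(grid, ph, xout = t)$y)
  }
  if (length(f) == 1) return(2 * pi * f * t)
  te <- protocol$event_time_s
  ifelse(t < te, 2 * pi * f[1] * t,
         2 * pi * (f[1] * te + f[2] * (t - te)))
}

#' Rendering parameters for synthetic dark-field frames
#'
#' Emulates the dark-field appearance: a bright cell on a dark background.
#' Intensities are on the `[0, 1]` scale used by TIFF output.
#'
#' @param image_size_px image size `(width, height)` in pixels.
#' @param um_per_px pixel calibration (µm/px); default 11/16 µm/px, an 11-µm
#'   camera pixel behind 16x total magnification.
#' @param background_level background intensity.
#' @param flagellum_peak peak intensity on the flagellar ridge crest (added to
#'   background).
#' @param line_sigma_px Gaussian cross-section sigma of the rendered flagellum
#'   (px).
#' @param head_radius_um radius of the rendered head disk (µm).
#' @param noise_sigma standard deviation of additive Gaussian noise
#'   (intensity units); the result is clipped to `[0, 1]`.
#' @param seed integer seed for the noise draws.
#' @return an object of class `render_params`.
#' @export
render_params <- function(image_size_px = c(256, 256), um_per_px = 11 / 16,
                          background_level = 0.05, flagellum_peak = 0.75,
                          line_sigma_px = 1.0, head_radius_um = 4,
                          noise_sigma = 0, seed = 1L) {
  stopifnot(flagellum_peak > 0, um_per_px > 0, noise_sigma >= 0,
            line_sigma_px > 0, head_radius_um > 0)
  structure(list(image_size_px = image_size_px, um_per_px = um_per_px,
                 background_level = background_level,
                 flagellum_peak = flagellum_peak,
                 line_sigma_px = line_sigma_px,
                 head_radius_um = head_radius_um,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "render_params")
}

#' Protocol for synthetic fluorescence traces
#'
#' Emulates plate-reader recordings (baseline, then a compound-addition
#' response) and stopped-flow recordings (response from the first samples
#' after mixing).
#'
#' @param n_samples number of samples.
#' @param sample_interval_s sampling interval (s).
#' @param baseline_level baseline fluorescence (arbitrary units, > 0).
#' @param response one of `"none"`, `"step"`, `"exp"` (saturating
#'   exponential).
#' @param response_amplitude response amplitude in intensity units (added to
#'   baseline after the event).
#' @param response_tau_s time constant of the saturating exponential (s).
#' @param event_index 1-based index of the first post-event sample (compound
#'   addition / mixing start).
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed integer seed.
#' @return an object of class `trace_protocol`.
#' @export
trace_protocol <- function(n_samples = 100, sample_interval_s = 1,
                           baseline_level = 100, response = c("none", "step", "exp"),
                           response_amplitude = 0, response_tau_s = 5,
                           event_index = 10, noise_sigma = 0, seed = 1L) {
  response <- match.arg(response)
  stopifnot(baseline_level > 0, n_samples >= 3, noise_sigma >= 0)
  if (response != "none" &&
      !(event_index >= 1 && event_index <= n_samples))
    stop("event_index must lie inside the trace")
  structure(list(n_samples = as.integer(n_samples),
                 sample_interval_s = sample_interval_s,
                 baseline_level = baseline_level, response = response,
                 response_amplitude = response_amplitude,
                 response_tau_s = response_tau_s,
                 event_index = as.integer(event_index),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "trace_protocol")
}

#' @export
print.beat_protocol <- function(x, ...) {
  f <- x$frequency
  fdesc <- if (is.function(f)) "f(t)" else paste(f, collapse = " -> ")
  cat("Beat protocol: ", x$duration_s, " s at ", x$fps, " fps, f = ",
      fdesc, " Hz", sep = "")
  if (!is.null(x$event_time_s)) cat(", event at t =", x$event_time_s, "s")
  cat("\n  L =", x$flagellum_length_um, "um, wavelength =", x$wavelength_um,
      "um, amplitude =", x$amplitude_rad, "rad\n")
  invisible(x)
}
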