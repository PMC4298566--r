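# Sliding-window sinusoid fitting of the angle series. Window placement
# follows the recording's boundary rules: every window holds exactly
# N = 2*round(window_s*fps) + 1 frames; at video boundaries or flanking a
# light flash the window is shifted (not truncated) so it keeps N frames and
# never mixes frames from both sides of an event.

#' Event-aware analysis window for one frame
#'
#' @param frame 1-based frame index.
#' @param n_frames total frame count.
#' @param fps frame rate (Hz).
#' @param window_s half-window length (s); the window holds
#'   `N = 2 * round(window_s * fps) + 1` frames.
#' @param events optional 1-based event frame indices; each event frame is
#'   the first frame of the post-event regime.
#' @return integer `c(start, end)`, a closed 1-based interval of exactly N
#'   frames containing `frame`.
#' @export
window_bounds <- function(frame, n_frames, fps, window_s, events = NULL) {
  half <- as.integer(round(window_s * fps))
  N <- 2L * half + 1L
  stopifnot(frame >= 1, frame <= n_frames)
  # event-free run [lo, hi] containing the frame
  bounds <- sort(unique(c(1L, as.integer(events), n_frames + 1L)))
  lo <- max(bounds[bounds <= frame])
  hi <- min(bounds[bounds > frame]) - 1L
  if (hi - lo + 1L < N)
    stop("window error: event-free run (", lo, "..", hi, ") around frame ",
         frame, " is shorter than the ", N, "-frame window")
  start <- as.integer(min(max(frame - half, lo), hi - N + 1L))
  c(start = start, end = start + N - 1L)
}

#' Zero-padded FFT peak frequency
#'
#' Discrete-Fourier peak of the detrended samples, used to initialize the
#' sinusoid fit and as an independent check of its result.
#'
#' @param y samples (regularly spaced).
#' @param fs sampling rate (Hz).
#' @param pad zero-padding factor.
#' @param f_range admissible frequency range (Hz).
#' @return list with `frequency` (Hz) and `bin_hz` (padded bin width).
#' @export
fft_peak_frequency <- function(y, fs, pad = 8, f_range = c(0.5, fs / 4)) {
  y <- y - mean(y)
  n <- length(y)
  np <- pad * n
  sp <- Mod(stats::fft(c(y, rep(0, np - n))))[seq_len(floor(np / 2))]
  fr <- (seq_along(sp) - 1) * fs / np
  ok <- fr >= f_range[1] & fr <= f_range[2]
  if (!any(ok)) return(list(frequency = NA_real_, bin_hz = fs / np))
  list(frequency = fr[ok][which.max(sp[ok])], bin_hz = fs / np)
}

# Linear least squares for A*sin(2*pi*f*t) + B*cos(2*pi*f*t) + c at fixed f.
# Returns list(coef, rss).
sinusoid_ls <- function(t, y, f) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t), 1)
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients)))
    return(list(coef = c(0, 0, mean(y)), rss = sum((y - mean(y))^2)))
  list(coef = fit$coefficients, rss = sum(fit$residuals^2))
}

#' Fit a sinusoid to angle samples
#'
#' Least-squares fit of `a * sin(2*pi*f*t + phase) + offset` by variable
#' projection: at fixed frequency the remaining parameters are linear, and
#' the frequency is optimized by bounded 1-D minimization seeded at the
#' zero-padded FFT peak of the detrended samples. The amplitude is reported
#' non-negative with the phase normalized to (-pi, pi]. Fits whose signal is
#' below the noise floor (amplitude < sqrt(2) times the residual standard
#' deviation) or degenerate are flagged failed and carry no frequency.
#'
#' @param t sample times (s).
#' @param y sampled angles (rad).
#' @param f_init optional initial frequency (Hz); defaults to the FFT peak.
#' @param f_range admissible frequency range (Hz); default `[0.5, fs/4]`
#'   with `fs` inferred from the median sample spacing.
#' @return an object of class `sinusoid_fit` with fields `frequency`,
#'   `amplitude`, `phase`, `offset`, `rss`, `r_squared`, `converged`.
#' @export
fit_sinusoid <- function(t, y, f_init = NULL, f_range = NULL) {
  stopifnot(length(t) == length(y))
  failed <- function(reason) structure(
    list(frequency = NA_real_, amplitude = NA_real_, phase = NA_real_,
         offset = mean(y), rss = NA_real_, r_squared = NA_real_,
         converged = FALSE, reason = reason, n = length(y)),
    class = "sinusoid_fit")
  if (length(y) < 8) return(failed("fewer than 8 samples"))
  fs <- 1 / stats::median(diff(t))
  if (is.null(f_range)) f_range <- c(0.5, fs / 4)
  tss <- sum((y - mean(y))^2)
  if (tss < .Machine$double.eps * length(y)) return(failed("constant samples"))
  pk <- fft_peak_frequency(y, fs, pad = 8, f_range = f_range)
  f0 <- if (!is.null(f_init)) f_init else pk$frequency
  if (is.na(f0)) return(failed("no spectral peak in range"))
  if (diff(range(t)) < 1 / f0) return(failed("samples span less than one period"))
  bin <- fs / length(y)
  lower <- max(f_range[1], f0 - 1.5 * bin)
  upper <- min(f_range[2], f0 + 1.5 * bin)
  rssf <- function(f) sinusoid_ls(t, y, f)$rss
  opt <- stats::optimize(rssf, lower = lower, upper = upper, tol = 1e-10)
  f <- opt$minimum
  # Brent stalls near sqrt(machine eps); two parabolic polish steps push the
  # minimum of the (locally quadratic) profile RSS to machine precision
  h <- max(1e-7, (upper - lower) * 1e-5)
  for (i in 1:2) {
    r0 <- rssf(f); rp <- rssf(f + h); rm <- rssf(f - h)
    den <- rp - 2 * r0 + rm
    if (den <= 0) break
    step <- 0.5 * h * (rm - rp) / den
    if (!is.finite(step) || abs(step) > h) break
    f <- f + step
    h <- h / 100
  }
  f <- min(max(f, f_range[1]), f_range[2])
  ls <- sinusoid_ls(t, y, f)
  a <- unname(sqrt(ls$coef[1]^2 + ls$coef[2]^2))
  phase <- unname(wrap_angle(atan2(ls$coef[2], ls$coef[1])))
  resid_sd <- sqrt(ls$rss / max(1, length(y) - 4))
  if (a < sqrt(2) * resid_sd) return(failed("amplitude below noise floor"))
  structure(list(frequency = f, amplitude = a, phase = phase,
                 offset = unname(ls$coef[3]), rss = ls$rss,
                 r_squared = 1 - ls$rss / tss, converged = TRUE,
                 reason = NULL, n = length(y)),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Sinusoid fit: failed (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "Sinusoid fit: f = %.4f Hz, amplitude = %.4f rad, R^2 = %.4f (n = %d)\n",
      x$frequency, x$amplitude, x$r_squared, x$n))
  }
  invisible(x)
}

#' @export
coef.sinusoid_fit <- function(object, ...) {
  c(frequency = object$frequency, amplitude = object$amplitude,
    phase = object$phase, offset = object$offset)
}

#' @export
predict.sinusoid_fit <- function(object, t, ...) {
  if (!object$converged) stop("cannot predict from a failed fit")
  object$amplitude * sin(2 * pi * object$frequency * t + object$phase) +
    object$offset
}

#' Per-frame beat-frequency series
#'
#' For every frame, fits a sinusoid to the gap-free angle samples inside the
#' frame's event-aware window. Frames whose window cannot be placed (run
#' shorter than N frames) or whose fit fails carry a gap; errors never abort
#' the series.
#'
#' @param angles an [angle_series()].
#' @param window_s half-window length (s); defaults to the value stored on
#'   the angle series.
#' @return an object of class `beat_frequency_series`: a data frame with
#'   per-frame `frequency_hz`, `amplitude_rad`, `phase_rad`, `offset_rad`,
#'   `r_squared`, `n_used`, `window_start`, `window_end`, `status`.
#' @export
frequency_series <- function(angles, window_s = attr(angles, "window_s")) {
  fps <- attr(angles, "fps")
  events <- attr(angles, "event_frames")
  n <- nrow(angles)
  out <- data.frame(frame = angles$frame, time_s = angles$time_s,
                    frequency_hz = NA_real_, amplitude_rad = NA_real_,
                    phase_rad = NA_real_, offset_rad = NA_real_,
                    r_squared = NA_real_, n_used = NA_integer_,
                    window_start = NA_integer_, window_end = NA_integer_,
                    status = "ok", stringsAsFactors = FALSE)
  gap <- angles$status != "ok" | is.na(angles$angle_rad)
  fprev <- NULL
  for (k in seq_len(n)) {
    if (gap[k]) { out$status[k] <- "gap: no angle sample"; next }
    wb <- tryCatch(window_bounds(k, n, fps, window_s, events),
                   error = function(e) e)
    if (inherits(wb, "error")) {
      out$status[k] <- "gap: window does not fit"
      next
    }
    idx <- wb[1]:wb[2]
    use <- idx[!gap[idx]]
    fit <- fit_sinusoid(angles$time_s[use], angles$angle_rad[use],
                        f_init = NULL, f_range = c(0.5, fps / 4))
    out$window_start[k] <- wb[1]; out$window_end[k] <- wb[2]
    out$n_used[k] <- length(use)
    if (!fit$converged) {
      out$status[k] <- paste0("gap: fit failed (", fit$reason, ")")
      next
    }
    out$frequency_hz[k] <- fit$frequency
    out$amplitude_rad[k] <- fit$amplitude
    out$phase_rad[k] <- fit$phase
    out$offset_rad[k] <- fit$offset
    out$r_squared[k] <- fit$r_squared
    fprev <- fit$frequency
  }
  structure(out, class = c("beat_frequency_series", "data.frame"),
            fps = fps, event_frames = events, window_s = window_s)
}

#' @export
print.beat_frequency_series <- function(x, ...) {
  ok <- x$status == "ok"
  cat("Beat-frequency series: ", sum(ok), "/", nrow(x),
      " frames with estimates\n", sep = "")
  if (any(ok))
    cat(sprintf("  median f = %.2f Hz (range %.2f-%.2f)\n",
                stats::median(x$frequency_hz[ok]),
                min(x$frequency_hz[ok]), max(x$frequency_hz[ok])))
  ev <- attr(x, "event_frames")
  if (!is.null(ev) && length(ev))
    cat("  event frames:", paste(ev, collapse = ", "), "\n")
  invisible(x)
}

#' Pre/post-event summary of a beat-frequency series
#'
#' @param object a `beat_frequency_series`.
#' @param ... unused.
#' @return a list of class `summary.beat_frequency_series` with per-regime
#'   mean frequencies and, when a single event is present, the fold change.
#' @export
summary.beat_frequency_series <- function(object, ...) {
  ok <- object$status == "ok"
  ev <- attr(object, "event_frames")
  res <- list(n_frames = nrow(object), n_estimated = sum(ok),
              mean_hz = mean(object$frequency_hz[ok]),
              event_frames = ev)
  if (!is.null(ev) && length(ev) == 1) {
    pre <- ok & object$frame < ev
    post <- ok & object$frame >= ev
    res$pre_event_mean_hz <- mean(object$frequency_hz[pre])
    res$post_event_mean_hz <- mean(object$frequency_hz[post])
    res$fold_change <- res$post_event_mean_hz / res$pre_event_mean_hz
  }
  structure(res, class = "summary.beat_frequency_series")
}

#' @export
print.summary.beat_frequency_series <- function(x, ...) {
  cat("Beat-frequency summary: ", x$n_estimated, "/", x$n_frames,
      " frames estimated, mean ", sprintf("%.2f", x$mean_hz), " Hz\n",
      sep = "")
  if (!is.null(x$fold_change))
    cat(sprintf("  pre-event %.2f Hz, post-event %.2f Hz, fold change %.2f\n",
                x$pre_event_mean_hz, x$post_event_mean_hz, x$fold_change))
  invisible(x)
}

#' @export
plot.beat_frequency_series <- function(x, ...) {
  ok <- x$status == "ok"
  graphics::plot(x$time_s[ok], x$frequency_hz[ok], type = "l",
                 xlab = "time (s)", ylab = "beat frequency (Hz)", ...)
  ev <- attr(x, "event_frames")
  if (!is.null(ev))
    graphics::abline(v = x$time_s[ev], lty = 2, col = "red")
  invisible(x)
}

#' Centered moving average for display
#'
#' A plain centered moving average offered for plotting frequency traces; it
#' is not equivalent to the proprietary display smoothing of graphing
#' software and is never used in any quantitative step.
#'
#' @param x numeric vector (NAs allowed).
#' @param k odd window length (samples).
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(x, k = 5) {
  stopifnot(k %% 2 == 1)
  h <- (k - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - h):min(n, i + h)]
    mean(w, na.rm = TRUE)
  }, numeric(1))
}
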