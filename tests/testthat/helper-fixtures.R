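# Shared synthetic fixtures, built once per test run and memoised, so the
# rendering cost is paid a single time per configuration.

.fixture_cache <- new.env(parent = emptyenv())

fixture_video <- function(key, protocol_args = list(), render_args = list()) {
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  p <- do.call(beat_protocol, protocol_args)
  r <- do.call(render_params, render_args)
  sv <- generate_video(p, r)
  sv$render <- r
  sv$protocol <- p
  .fixture_cache[[key]] <- sv
  sv
}

# 0.3 s noiseless recording at 10 Hz, default geometry
clean_video <- function() {
  fixture_video("clean", list(duration_s = 0.3, fps = 200, frequency = 10),
                list(noise_sigma = 0))
}

# 0.5 s recording at 10 Hz with 5% (of peak) noise
noisy_video <- function() {
  fixture_video("noisy", list(duration_s = 0.5, fps = 200, frequency = 10),
                list(noise_sigma = 0.05 * 0.75))
}

# mean minimum distance from traced points to the true curve (px)
trace_to_curve_dist <- function(trace, curve_um, head_center_px, um_per_px) {
  cv <- cbind(head_center_px[1] + curve_um[, 1] / um_per_px,
              head_center_px[2] - curve_um[, 2] / um_per_px)
  pts <- if (!is.null(trace$points_smooth)) trace$points_smooth else
    trace$points
  mean(apply(pts, 1, function(p)
    min(sqrt((cv[, 1] - p[1])^2 + (cv[, 2] - p[2])^2))))
}

# independent DFT peak (no zero padding): plain periodogram maximum over
# bins in [f_lo, fs/4]
dft_peak <- function(y, fs, f_lo = 0.5) {
  y <- y - mean(y)
  n <- length(y)
  sp <- Mod(stats::fft(y))[seq_len(floor(n / 2))]
  fr <- (seq_along(sp) - 1) * fs / n
  ok <- fr >= f_lo & fr <= fs / 4
  fr[ok][which.max(sp[ok])]
}

angdiff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  abs(d)
}
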