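# Head registration, neck azimuth and stop-motion envelope construction.

test_that("annulus defaults cover the head with a 4 um wider outer rim", {
  ann <- annulus()
  expect_equal(ann$inner_diameter_um, 16)
  expect_equal(ann$outer_diameter_um, 20)
  expect_error(annulus(16, 12))
})

test_that("registration holds a static cell still", {
  sv <- clean_video()
  gt <- sv$truth$per_frame
  ht <- register_head(sv$video, roi = list(center = c(64, 128), radius = 10))
  err <- sqrt((ht$x - gt$head_x_px)^2 + (ht$y - gt$head_y_px)^2)
  expect_lt(max(err), 0.5)
})

test_that("registration recovers a known drift within 0.5 px RMS", {
  sv <- fixture_video("drift",
    list(duration_s = 0.25, fps = 200, frequency = 10,
         drift_px_per_frame = c(0.2, -0.1)),
    list(noise_sigma = 0.05 * 0.75))
  gt <- sv$truth$per_frame
  ht <- register_head(sv$video, roi = list(center = c(64, 128), radius = 10))
  rms <- sqrt(mean((ht$x - gt$head_x_px)^2 + (ht$y - gt$head_y_px)^2))
  expect_lt(rms, 0.5)
  expect_true(all(ht$confidence > 0.5))
})

test_that("an ROI that misses the head fails at the first frame", {
  sv <- clean_video()
  expect_error(register_head(sv$video,
                             roi = list(center = c(220, 30), radius = 8)),
               "frame 1")
})

test_that("neck azimuth reads the flagellum direction at the annulus", {
  # flagellum leaving the head along +x
  img <- matrix(FALSE, 100, 100)
  img[50, 30:90] <- TRUE
  d <- sqrt(outer((1:100 - 50)^2, (1:100 - 30)^2, `+`))
  img[d <= 6] <- TRUE
  expect_equal(neck_azimuth(img, c(30, 50), annulus(), um_per_px = 1), 0,
               tolerance = 1e-6)
  # empty annulus
  blob <- matrix(FALSE, 100, 100)
  blob[45:55, 25:35] <- TRUE
  expect_error(neck_azimuth(blob, c(30, 50), annulus(), um_per_px = 1),
               "no-neck")
  # foreground in two opposite sectors
  img2 <- img
  img2[50, 1:29] <- TRUE
  expect_error(neck_azimuth(img2, c(30, 50), annulus(), um_per_px = 1),
               "ambiguous")
})

test_that("azimuth matches the base orientation for a low-amplitude beat", {
  sv <- fixture_video("lowamp",
    list(duration_s = 0.05, fps = 200, frequency = 10, amplitude_rad = 0.02,
         base_orientation_rad = 0.4),
    list(noise_sigma = 0))
  b <- binarize(sv$video$frames[[1]])
  gt <- sv$truth$per_frame
  az <- neck_azimuth(b, c(gt$head_x_px[1], gt$head_y_px[1]), annulus(),
                     sv$render$um_per_px,
                     intensity = sv$video$frames[[1]])
  expect_lt(angdiff(az, 0.4) * 180 / pi, 2)
})

test_that("superimposing identical frames reproduces the frame", {
  sv <- clean_video()
  fr <- sv$video$frames[[1]]
  v <- video_stack(rep(list(fr), 5), fps = 200,
                   um_per_px = sv$render$um_per_px)
  heads <- cbind(rep(64, 5), rep(128, 5))
  env <- align_and_superimpose(v, heads, rep(0.2, 5),
                               center_out = c(64, 128))
  # rotation angle is zero for every frame, head already at the reference
  inner <- cbind(rep(30:220, each = 191), rep(30:220, times = 191))
  expect_lt(max(abs(env$image[inner] - fr[inner])), 1e-6)
  expect_equal(env$n_frames_used, 5)
  # single frame passes through with translation/rotation only
  v1 <- video_stack(list(fr), fps = 200, um_per_px = sv$render$um_per_px)
  env1 <- align_and_superimpose(v1, cbind(64, 128), 0.2,
                                center_out = c(64, 128))
  expect_equal(env1$n_frames_used, 1)
  expect_error(align_frames(v1, cbind(64, 128), NA_real_), "all frames")
})

test_that("aligned frames keep the head fixed and the azimuth constant", {
  sv <- noisy_video()
  ht <- register_head(sv$video, roi = list(center = c(64, 128), radius = 10))
  upp <- sv$render$um_per_px
  az <- vapply(seq_len(100), function(k)
    neck_azimuth(binarize(sv$video$frames[[k]], k), c(ht$x[k], ht$y[k]),
                 annulus(), upp, intensity = sv$video$frames[[k]]),
    numeric(1))
  al <- align_frames(sv$video, ht, az)
  az2 <- vapply(seq_along(al$frames), function(i) {
    b <- binarize(al$frames[[i]], i)
    neck_azimuth(b, al$center, annulus(), upp, intensity = al$frames[[i]])
  }, numeric(1))
  expect_lt(max(angdiff(az2, al$reference_azimuth)) * 180 / pi, 2)
  hd <- vapply(seq_along(al$frames), function(i) {
    b <- binarize(al$frames[[i]], i)
    h <- locate_head(b, al$frames[[i]], prior = al$center,
                     prior_radius_px = 12)
    sqrt(sum((h$center - al$center)^2))
  }, numeric(1))
  expect_lt(max(hd), 1)
})

test_that("aligning an already-aligned stack is the identity", {
  sv <- clean_video()
  ht <- register_head(sv$video, roi = list(center = c(64, 128), radius = 10))
  upp <- sv$render$um_per_px
  az <- vapply(seq_len(10), function(k)
    neck_azimuth(binarize(sv$video$frames[[k]], k), c(ht$x[k], ht$y[k]),
                 annulus(), upp, intensity = sv$video$frames[[k]]),
    numeric(1))
  v10 <- video_stack(sv$video$frames[1:10], fps = 200, um_per_px = upp)
  al <- align_frames(v10, ht[1:10, ], az)
  v_al <- video_stack(al$frames, fps = 200, um_per_px = upp)
  heads2 <- matrix(rep(al$center, each = 10), ncol = 2)
  al2 <- align_frames(v_al, heads2, rep(al$reference_azimuth, 10),
                      reference_azimuth = al$reference_azimuth,
                      center_out = al$center)
  inner <- cbind(rep(30:220, each = 191), rep(30:220, times = 191))
  for (i in c(1, 5, 10))
    expect_lt(max(abs(al2$frames[[i]][inner] - al$frames[[i]][inner])), 1e-6)
})

test_that("one beat period spans the full waveform envelope", {
  sv <- noisy_video()   # 10 Hz at 200 fps: one period = 20 frames
  ht <- register_head(sv$video, roi = list(center = c(64, 128), radius = 10))
  upp <- sv$render$um_per_px
  az <- vapply(seq_len(100), function(k)
    neck_azimuth(binarize(sv$video$frames[[k]], k), c(ht$x[k], ht$y[k]),
                 annulus(), upp, intensity = sv$video$frames[[k]]),
    numeric(1))
  env5 <- align_and_superimpose(sv$video, ht, az)
  v1 <- video_stack(sv$video$frames[1:20], fps = 200, um_per_px = upp)
  env1 <- align_and_superimpose(v1, ht[1:20, ], az[1:20],
                                reference_azimuth = env5$reference_azimuth)
  fg5 <- binarize(env5$image)
  fg1 <- binarize(env1$image)
  expect_gte(sum(fg1 & fg5) / sum(fg5), 0.95)
})
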