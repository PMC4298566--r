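# Segmentation, skeleton tracing, midpoint and angle measurement.

test_that("binarize separates a clean two-level image and rejects degenerates", {
  img <- matrix(10 / 255, 60, 60)
  img[20:40, 10:50] <- 200 / 255
  fg <- binarize(img)
  expect_identical(which(fg), which(img > 100 / 255))
  expect_error(binarize(matrix(0.5, 50, 50)), "zero-variance")
  tiny <- matrix(0.1, 50, 50); tiny[25, 25] <- 0.9
  expect_error(binarize(tiny, frame_index = 3), "frame 3")
})

test_that("segmentation of a noisy synthetic frame matches the true mask", {
  sv <- noisy_video()
  gt <- sv$truth$per_frame
  for (k in c(2, 50)) {
    fg <- binarize(sv$video$frames[[k]], frame_index = k)
    m <- curve_mask(sv$truth$curves[[k]],
                    c(gt$head_x_px[k], gt$head_y_px[k]), sv$render)
    expect_gte(sum(m & fg) / sum(m | fg), 0.8)
  }
})

test_that("locate_head finds the centroid of a disk and errors on empty input", {
  img <- matrix(FALSE, 120, 120)
  d <- sqrt(outer((1:120 - 60)^2, (1:120 - 50)^2, `+`))
  img[d <= 8] <- TRUE
  pose <- locate_head(img)
  expect_lt(abs(pose$center[1] - 50), 0.5)
  expect_lt(abs(pose$center[2] - 60), 0.5)
  expect_error(locate_head(img, prior = c(110, 110), prior_radius_px = 5),
               "tracking lost")
})

test_that("head position tracks ground truth on a drifting cell", {
  sv <- fixture_video("drift",
    list(duration_s = 0.25, fps = 200, frequency = 10,
         drift_px_per_frame = c(0.2, -0.1)),
    list(noise_sigma = 0.05 * 0.75))
  gt <- sv$truth$per_frame
  prior <- NULL
  errs <- vapply(seq_len(50), function(k) {
    b <- binarize(sv$video$frames[[k]], k)
    h <- locate_head(b, sv$video$frames[[k]], prior = prior)
    prior <<- h$center
    sqrt((h$center[1] - gt$head_x_px[k])^2 +
         (h$center[2] - gt$head_y_px[k])^2)
  }, numeric(1))
  expect_lt(max(errs), 1)
})

test_that("trace of a straight bar runs head to tip with the right length", {
  img <- matrix(FALSE, 40, 120)
  img[19:21, 11:110] <- TRUE
  head <- structure(list(center = c(x = 11, y = 20)), class = "head_pose")
  tr <- trace_flagellum(img, head)
  expect_equal(unname(tr$points[1, 2]), 20)
  expect_lt(tr$points[1, 1], 15)                      # starts at the head end
  expect_gt(tr$points[nrow(tr$points), 1], 105)       # ends at the tip
  expect_lt(abs(tr$arc_length_px - 99), 2)
  # ring-shaped foreground has no endpoint pair
  ring <- matrix(FALSE, 60, 60)
  d <- sqrt(outer((1:60 - 30)^2, (1:60 - 30)^2, `+`))
  ring[d >= 15 & d <= 19] <- TRUE
  expect_error(trace_flagellum(ring, head), "closed loop")
})

test_that("traced curve matches the rendered ground-truth curve", {
  sv <- clean_video()
  gt <- sv$truth$per_frame
  for (k in c(1, 20, 45)) {
    b <- binarize(sv$video$frames[[k]], k)
    h <- locate_head(b, sv$video$frames[[k]])
    tr <- trace_flagellum(b, h, frame_index = k)
    d <- trace_to_curve_dist(tr, sv$truth$curves[[k]],
                             c(gt$head_x_px[k], gt$head_y_px[k]),
                             sv$render$um_per_px)
    expect_lt(d, 1)
    expect_lt(abs(tr$arc_length_px - 60 / sv$render$um_per_px) /
              (60 / sv$render$um_per_px), 0.05)
  }
})

test_that("trace ordering is defined by the head, not the walk direction", {
  img <- matrix(FALSE, 40, 120)
  img[19:21, 11:110] <- TRUE
  tr_l <- trace_flagellum(img, structure(list(center = c(11, 20)),
                                         class = "head_pose"))
  tr_r <- trace_flagellum(img, structure(list(center = c(110, 20)),
                                         class = "head_pose"))
  # head end first in both cases
  expect_lt(tr_l$points[1, 1], 15)
  expect_gt(tr_r$points[1, 1], 105)
  # on the common support the two walks are exact reversals (only the
  # regrown tip pixels differ between the two orientations)
  key <- function(m) paste(m[, 1], m[, 2])
  common <- intersect(key(tr_l$points), key(tr_r$points))
  pos_l <- match(common, key(tr_l$points))
  pos_r <- match(common, key(tr_r$points))
  expect_identical(order(pos_l), rev(order(pos_r)))
  # repeated calls are deterministic
  expect_identical(tr_l$points,
                   trace_flagellum(img, structure(list(center = c(11, 20)),
                                                  class = "head_pose"))$points)
})

test_that("midpoint interpolates at half the arc length", {
  straight <- structure(list(points = cbind(x = c(0, 100), y = c(0, 0))),
                        class = "flagellum_trace")
  expect_equal(trace_midpoint(straight), c(x = 50, y = 0))
  # right angle (0,0)->(0,30)->(40,30): half of 70 is 35, 5 px into leg 2
  bend <- structure(list(points = cbind(x = c(0, 0, 40), y = c(0, 30, 30))),
                    class = "flagellum_trace")
  expect_equal(trace_midpoint(bend), c(x = 5, y = 30))
  two <- structure(list(points = cbind(x = c(2, 6), y = c(1, 5))),
                   class = "flagellum_trace")
  expect_equal(trace_midpoint(two), c(x = 4, y = 3))
})

test_that("symmetry axis is the circular mean and fails on antipodal input", {
  expect_equal(symmetry_axis(0.7), 0.7)
  expect_equal(symmetry_axis(c(0.3, -0.3)), 0)
  expect_equal(symmetry_axis(c(3.1, -3.1)), pi)  # wraps across the cut
  expect_error(symmetry_axis(c(0, pi)), "undefined axis")
})

test_that("angle series recovers the ground-truth midpoint angle", {
  sv <- clean_video()
  a <- angle_series(sv$video, window_s = 0.1)
  gt <- sv$truth$per_frame
  ok <- a$status == "ok"
  expect_gte(mean(ok), 0.9)
  expect_lt(max(angdiff(a$angle_rad[ok], gt$midpoint_angle_rad[ok])), 0.05)
  # recovered axis within 1 degree of the generator's base orientation
  expect_lt(angdiff(symmetry_axis(a$theta_rad[ok]), 0) * 180 / pi, 1)
})

test_that("angle sign convention is counter-clockwise in a y-up frame", {
  # head at image center, midpoint straight above in storage coordinates
  # (smaller y) lies at +pi/2 for an axis along +x
  th <- atan2(-(50 - 100), 100 - 100)
  expect_equal(th, pi / 2)
})

test_that("angle series is equivariant under rotation of the cell", {
  a0 <- angle_series(clean_video()$video, window_s = 0.1)
  svr <- fixture_video("rotated",
    list(duration_s = 0.3, fps = 200, frequency = 10,
         base_orientation_rad = 0.6, head_center_px = c(80, 150)),
    list(noise_sigma = 0))
  ar <- angle_series(svr$video, window_s = 0.1)
  ok <- a0$status == "ok" & ar$status == "ok"
  expect_lt(max(angdiff(ar$axis_rad[ok], a0$axis_rad[ok] + 0.6)), 0.02)
  expect_lt(max(angdiff(ar$angle_rad[ok], a0$angle_rad[ok])), 0.02)
})

test_that("physical arc length is invariant to rendering resolution", {
  sv1 <- clean_video()
  sv2 <- fixture_video("highres",
    list(duration_s = 0.05, fps = 200, frequency = 10,
         head_center_px = c(128, 256)),
    list(noise_sigma = 0, um_per_px = 11 / 32, image_size_px = c(512, 512)))
  arc_um <- function(sv, k) {
    b <- binarize(sv$video$frames[[k]])
    h <- locate_head(b, sv$video$frames[[k]])
    trace_flagellum(b, h)$arc_length_px * sv$render$um_per_px
  }
  expect_lt(abs(arc_um(sv1, 1) - arc_um(sv2, 1)) / arc_um(sv1, 1), 0.02)
})
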