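# dF/F0 normalization: both F0 conventions and control subtraction.

test_that("plate-reader F0 is the mean pre-event baseline", {
  tr <- fluorescence_trace(times = 0:9, values = c(90, 110, rep(150, 8)),
                           event_index = 3, instrument = "plate_reader")
  nd <- dff0_platereader(tr)
  expect_equal(nd$f0, 100)
  expect_equal(nd$dff0_percent, c(-10, 10, rep(50, 8)))
  # constant trace normalizes to all zeros
  cst <- fluorescence_trace(0:9, rep(100, 10), event_index = 5,
                            instrument = "plate_reader")
  expect_equal(dff0_platereader(cst)$dff0_percent, rep(0, 10))
  # F0 must be positive
  neg <- fluorescence_trace(0:9, c(-5, 5, rep(10, 8)), event_index = 3,
                            instrument = "plate_reader")
  expect_error(dff0_platereader(neg), "F0")
})

test_that("stopped-flow F0 is the mean of the first three samples", {
  tr <- fluorescence_trace(times = 0:9, values = c(90, 100, 110, rep(130, 7)),
                           instrument = "stopped_flow")
  nd <- dff0_stoppedflow(tr)
  expect_equal(nd$f0, 100)
  expect_equal(nd$dff0_percent[4:10], rep(30, 7))
  cst <- fluorescence_trace(0:5, rep(7, 6), instrument = "stopped_flow")
  expect_equal(dff0_stoppedflow(cst)$dff0_percent, rep(0, 6))
})

test_that("a saturating response reaches its plateau as a clean percentage", {
  tp <- trace_protocol(n_samples = 400, sample_interval_s = 0.1,
                       baseline_level = 200, response = "exp",
                       response_amplitude = 0.3 * 200, response_tau_s = 2,
                       event_index = 4, noise_sigma = 0)
  tr <- generate_trace(tp, instrument = "stopped_flow")
  nd <- dff0_stoppedflow(tr)
  expect_equal(nd$f0, 200)
  plateau <- mean(nd$dff0_percent[350:400])
  expect_lt(abs(plateau - 30), 1)
})

test_that("dF/F0 is invariant under positive gain", {
  set.seed(123)
  for (i in 1:100) {
    v <- abs(rnorm(20, 100, 10)) + 1
    e <- sample(3:18, 1)
    g <- runif(1, 0.1, 10)
    a <- dff0_platereader(fluorescence_trace(1:20, v, e, "plate_reader"))
    b <- dff0_platereader(fluorescence_trace(1:20, g * v, e, "plate_reader"))
    expect_equal(a$dff0_percent, b$dff0_percent, tolerance = 1e-10)
    a2 <- dff0_stoppedflow(fluorescence_trace(1:20, v,
                                              instrument = "stopped_flow"))
    b2 <- dff0_stoppedflow(fluorescence_trace(1:20, g * v,
                                              instrument = "stopped_flow"))
    expect_equal(a2$dff0_percent, b2$dff0_percent, tolerance = 1e-10)
    # samples defining F0 average to zero by construction
    expect_equal(mean(a$dff0_percent[seq_len(e - 1)]), 0, tolerance = 1e-10)
    expect_equal(mean(a2$dff0_percent[1:3]), 0, tolerance = 1e-10)
  }
})

test_that("control subtraction is pointwise and anti-symmetric", {
  sig <- dff0_platereader(fluorescence_trace(
    1:20, c(rep(100, 9), rep(150, 11)), 10, "plate_reader"))
  ctl <- dff0_platereader(fluorescence_trace(
    1:20, c(rep(100, 9), rep(110, 11)), 10, "plate_reader"))
  res <- subtract_control(sig, ctl)
  expect_equal(res$dff0_percent[10:20], rep(40, 11))
  expect_equal(subtract_control(sig, sig)$dff0_percent, rep(0, 20))
  zero <- ctl; zero$dff0_percent <- rep(0, 20)
  expect_equal(subtract_control(sig, zero)$dff0_percent, sig$dff0_percent)
  # anti-symmetry over random traces
  set.seed(42)
  for (i in 1:100) {
    a <- dff0_stoppedflow(fluorescence_trace(
      1:15, abs(rnorm(15, 50, 5)) + 1, instrument = "stopped_flow"))
    b <- dff0_stoppedflow(fluorescence_trace(
      1:15, abs(rnorm(15, 50, 5)) + 1, instrument = "stopped_flow"))
    expect_equal(subtract_control(a, b)$dff0_percent,
                 -subtract_control(b, a)$dff0_percent, tolerance = 1e-10)
  }
  # mismatched traces are rejected
  shorter <- dff0_stoppedflow(fluorescence_trace(
    1:10, rep(50, 10), instrument = "stopped_flow"))
  expect_error(subtract_control(sig, shorter), "alignment error")
})

test_that("alternating-excitation samples are excluded from dF/F0", {
  times <- 1:20
  values <- rep(c(5, 100), 10)           # 485-nm activation reads are dim
  exc <- rep(c(485, 520), 10)
  values[seq(12, 20, by = 2)] <- 150     # response on the 520-nm channel
  tr <- fluorescence_trace(times, values, event_index = 11,
                           instrument = "plate_reader", excitation = exc)
  nd <- dff0_platereader(tr)
  expect_length(nd$dff0_percent, 10)
  expect_equal(nd$f0, 100)
  expect_equal(nd$dff0_percent[6:10], rep(50, 5))
})

test_that("traces round-trip through delimited text", {
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = 1:10,
                              value = c(rep(100, 4), rep(125, 6))),
                   tmp, row.names = FALSE)
  tr <- read_trace(tmp, event_index = 5, instrument = "plate_reader")
  nd <- dff0(tr)
  expect_equal(nd$dff0_percent[5:10], rep(25, 6))
  out <- tempfile(fileext = ".csv")
  write_normalized_trace(nd, out)
  back <- utils::read.csv(out)
  expect_equal(back$dff0_percent, nd$dff0_percent)
  unlink(c(tmp, out))
})
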