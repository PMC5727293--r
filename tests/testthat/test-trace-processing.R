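make_trace <- function(donor, acceptor, dt = 0.08, id = "t") {
  structure(
    list(time_s = (seq_along(donor) - 1) * dt, donor = donor,
         acceptor = acceptor, frame_interval_s = dt, trace_id = id),
    class = "intensity_trace")
}

test_that("apparent FRET follows I_A/(I_D + I_A) with undefined flagging", {
  tr <- make_trace(c(100, 0, 50, -10), c(100, 50, 0, 5))
  fr <- compute_fret(tr)
  expect_equal(fr$efficiency[1], 0.5)
  expect_equal(fr$efficiency[2], 1.0)
  expect_equal(fr$efficiency[3], 0.0)
  expect_true(is.na(fr$efficiency[4]))   # total <= 0: undefined, not zero
  expect_true(fr$undefined[4])
  set.seed(42)
  d <- runif(10, 10, 100); a <- runif(10, 10, 100)
  fr2 <- compute_fret(make_trace(d, a))
  expect_equal(fr2$efficiency, naive_fret(d, a))
  expect_error(compute_fret(make_trace(c(0, 0), c(0, 0))), "non-positive")
})

test_that("background subtraction recenters apparent FRET on the true split", {
  # state E = 0.8 at I = 1000 with 50/50 backgrounds reads 850/1100 = 0.773
  tr <- make_trace(rep(250, 5), rep(850, 5))
  expect_equal(compute_fret(tr)$efficiency[1], 850 / 1100)
  expect_equal(compute_fret(tr, background = c(50, 50))$efficiency[1], 0.8)
})

test_that("moving average matches the naive windowed mean everywhere", {
  expect_equal(smooth_trace(rep(3, 20), 5), rep(3, 20))
  imp <- c(rep(0, 10), 1, rep(0, 10))
  sm <- smooth_trace(imp, 5)
  expect_equal(sm[9:13], rep(0.2, 5))
  expect_equal(sum(sm), 1)
  set.seed(1)
  x <- rnorm(47)
  for (w in c(1, 3, 5, 9)) {
    expect_equal(smooth_trace(x, w), naive_moving_average(x, w),
                 tolerance = 1e-12)
  }
  expect_error(smooth_trace(x, 4), "odd")
  expect_error(smooth_trace(x, 49), "length")
})

test_that("smoothing changes the mean only through edge effects", {
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(100, sd = runif(1, 0.5, 5))
    w <- sample(c(3, 5, 7), 1)
    bound <- (w / length(x)) * diff(range(x))
    expect_lte(abs(mean(smooth_trace(x, w)) - mean(x)), bound)
  }
})

test_that("anti-correlation screen accepts real steps and rejects noise", {
  set.seed(3)
  n <- 60
  donor <- c(rep(900, 20), rep(300, 20), rep(900, 20)) + rnorm(n, 0, 10)
  acceptor <- 1000 - donor + rnorm(n, 0, 10)
  res <- check_anticorrelation(make_trace(donor, acceptor), c(21, 40))
  expect_true(res$accepted)
  expect_lt(res$score, -0.3)
  # two independent noise channels: rejected in nearly all seeds
  rejected <- 0L
  for (s in 1:40) {
    set.seed(100 + s)
    d <- rnorm(n, 500, 30); a <- rnorm(n, 500, 30)
    r <- check_anticorrelation(make_trace(d, a), c(21, 40))
    if (!isTRUE(r$accepted)) rejected <- rejected + 1L
  }
  expect_gte(rejected, 36L)
  # degenerate constant channels: rejected with undefined score
  r0 <- check_anticorrelation(make_trace(rep(5, n), rep(7, n)), c(21, 40))
  expect_false(r0$accepted)
  expect_true(is.na(r0$score))
})

test_that("bleach detection finds the truth change point within 3 frames", {
  m <- two_state_model()
  em <- emission_config(trace_length_frames = 600, bleach_rate_s = 0)
  truth <- manual_truth(matrix(c(2, 10, 20, 30), 2, byrow = TRUE),
                        duration = 48, bleach = 400 * 0.08)
  tr <- render_intensity_trace(truth, m, em, seed = 4)
  bf <- detect_bleach(tr, background_total = 100, noise_sd = 30)
  expect_true(!is.null(bf))
  expect_lte(abs(bf - 401L), 3L)
  # no-bleach trace
  truth2 <- manual_truth(matrix(c(2, 10), 1), duration = 48)
  tr2 <- render_intensity_trace(truth2, m, em, seed = 5)
  expect_null(detect_bleach(tr2, background_total = 100, noise_sd = 30))
  # dark from frame 0: unusable
  tr3 <- make_trace(rnorm(200, 50, 30), rnorm(200, 50, 30))
  expect_identical(detect_bleach(tr3, background_total = 100, noise_sd = 30),
                   0L)
  ev3 <- segment_events(tr3, background_acceptor = 50, noise_sd = 30,
                        bleach_frame = 0L)
  expect_equal(nrow(ev3), 0L)
})

test_that("noiseless segmentation recovers truth boundaries to one frame", {
  m <- two_state_model(fret = 0.7, sigma = 0)
  em <- emission_config(noise_sd = 0, bleach_rate_s = 0,
                        trace_length_frames = 600)
  dt <- em$frame_interval_s
  intervals <- matrix(c(1.0, 5.0, 10.04, 14.6, 20.0, 30.12), 3, byrow = TRUE)
  truth <- manual_truth(intervals, duration = 48)
  tr <- render_intensity_trace(truth, m, em, seed = 1)
  fr <- compute_fret(tr, background = c(50, 50))
  ev <- segment_events(tr, fr, background_acceptor = 50, noise_sd = 10,
                       bleach_frame = NA)
  expect_equal(nrow(ev), 3L)
  for (i in 1:3) {
    expect_lte(abs(ev$start_s[i] - intervals[i, 1]), dt + 1e-9)
    expect_lte(abs(ev$end_s[i] - intervals[i, 2]), dt + 1e-9)
    expect_lte(abs(ev$duration_s[i] - diff(intervals[i, ])), 2 * dt + 1e-9)
  }
  expect_false(any(ev$censored_left) || any(ev$censored_right))
  expect_equal(ev$mean_fret, rep(0.7, 3), tolerance = 0.02)
})

test_that("segmentation flags censoring and keeps events disjoint", {
  m <- two_state_model(fret = 0.7, sigma = 0)
  em <- emission_config(noise_sd = 0, bleach_rate_s = 0,
                        trace_length_frames = 100)
  # event running to the trace end
  truth <- manual_truth(matrix(c(0, 2, 5, 8), 2, byrow = TRUE), duration = 8)
  tr <- render_intensity_trace(truth, m, em, seed = 1)
  ev <- segment_events(tr, background_acceptor = 50, noise_sd = 10,
                       bleach_frame = NA)
  expect_equal(nrow(ev), 2L)
  expect_true(ev$censored_left[1])
  expect_true(ev$censored_right[2])
  # disjoint + sorted
  expect_true(all(diff(ev$start_frame) > 0))
  expect_true(all(ev$end_frame[-nrow(ev)] < ev$start_frame[-1]))
  # permanently unbound: empty
  truth0 <- structure(
    list(events = data.frame(start_s = 0, end_s = 8, state = 1L,
                             state_name = "U"),
         bleach_time_s = NA_real_, duration_s = 8, seed = 0L),
    class = "ground_truth")
  tr0 <- render_intensity_trace(truth0, m, em, seed = 2)
  expect_equal(nrow(segment_events(tr0, background_acceptor = 50,
                                   noise_sd = 10, bleach_frame = NA)), 0L)
})

test_that("events stop at the bleach frame", {
  m <- two_state_model(fret = 0.7, sigma = 0)
  em <- emission_config(noise_sd = 0, bleach_rate_s = 0,
                        trace_length_frames = 200)
  truth <- manual_truth(matrix(c(1, 10), 1), duration = 16, bleach = 5)
  tr <- render_intensity_trace(truth, m, em, seed = 3)
  bf <- detect_bleach(tr, background_total = 100, noise_sd = 5)
  ev <- segment_events(tr, background_acceptor = 50, noise_sd = 5,
                       bleach_frame = bf)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$censored_right[1])
  expect_lte(ev$end_s[1], 5 + 0.08 + 1e-9)
})

test_that("pipeline dwell times track ground truth at default SNR", {
  m <- two_state_model(k_on = 0.3, k_off = 0.25, fret = 0.7)
  em <- emission_config(trace_length_frames = 600)
  ds <- simulate_dataset(m, em, 40, seed = 13)
  proc <- process_dataset(ds)
  td <- do.call(rbind, lapply(ds$truths, truth_binding_events))
  # event counts agree to within the short-dwell detection floor
  expect_gt(nrow(proc$events), 0.85 * nrow(td))
  expect_lt(nrow(proc$events), 1.05 * nrow(td))
  # detection-corrected rate recovers the generating k_off
  kf <- fit_koff_events(proc$events, n_boot = 0)
  expect_equal(kf$k_off, 0.25, tolerance = 0.1)
  # and matches the same estimator applied to the ground-truth dwells
  kt <- sum(!td$censored_right) / sum(td$duration_s)
  expect_equal(kf$k_off, kt, tolerance = 0.1)
})
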