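test_that("model constructors validate their inputs", {
  expect_error(two_state_model(k_off = -1), ">= 0")
  expect_error(
    binding_model(matrix(c(0, 1, NA, 0), 2, 2), c(NA, 0.5), c(NA, 0.05)),
    "finite")
  expect_error(
    binding_model(matrix(c(0, 1, 1, 0), 2, 2), c(NA, 1.5), c(NA, 0.05)),
    "fret_mean")
  expect_error(emission_config(frame_interval_s = 0), "> 0")
  expect_error(titration_design(c(0, 10), koff_slope = -0.05,
                                koff_intercept = 0.4,
                                occupancy_slope = 0, occupancy_intercept = 0.7),
               "k_off")
})

test_that("an absorbing chain yields one unbound event spanning the run", {
  m <- binding_model(matrix(0, 2, 2), c(NA, 0.5), c(NA, 0.05))
  tr <- simulate_state_path(m, 100, seed = 1)
  expect_equal(nrow(tr$events), 1L)
  expect_equal(tr$events$start_s, 0)
  expect_equal(tr$events$end_s, 100)
  expect_equal(tr$events$state, 1L)
})

test_that("a symmetric two-state chain spends half its time in each state", {
  m <- two_state_model(k_on = 1, k_off = 1)
  tr <- simulate_state_path(m, 1e4, seed = 7)
  ev <- tr$events
  t_bound <- sum(ev$end_s[ev$state == 2] - ev$start_s[ev$state == 2])
  expect_equal(t_bound / 1e4, 0.5, tolerance = 0.04)  # 0.5 +/- 0.02
})

test_that("dwell times are exponential with mean 1/k_exit", {
  m <- two_state_model(k_on = 2, k_off = 0.5)
  tr <- simulate_state_path(m, 5e3, seed = 3)
  ev <- tr$events
  dw <- ev$end_s[ev$state == 2] - ev$start_s[ev$state == 2]
  dw <- dw[seq_len(length(dw) - 1L)]   # last may be truncated by run end
  expect_gt(length(dw), 1000)
  expect_equal(mean(dw), 2.0, tolerance = 0.05)
  # KS against Exp(0.5) should not reject across seeds
  rejections <- 0L
  for (s in 1:10) {
    tr_s <- simulate_state_path(m, 2.5e3, seed = 100 + s)
    ev_s <- tr_s$events
    d <- ev_s$end_s[ev_s$state == 2] - ev_s$start_s[ev_s$state == 2]
    d <- d[seq_len(length(d) - 1L)]
    p <- suppressWarnings(stats::ks.test(d, "pexp", 0.5)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("noiseless rendering splits the emission exactly", {
  m <- two_state_model(fret = 0.8, sigma = 0)
  em <- emission_config(total_intensity = 1000, background_donor = 0,
                        background_acceptor = 0, noise_sd = 0,
                        bleach_rate_s = 0, trace_length_frames = 50)
  truth <- manual_truth(matrix(c(0, 4), 1), duration = 4)
  tr <- render_intensity_trace(truth, m, em, seed = 1)
  expect_equal(tr$donor, rep(200, 50))
  expect_equal(tr$acceptor, rep(800, 50))
})

test_that("a permanently unbound trace has acceptor at background", {
  m <- two_state_model()
  em <- emission_config(noise_sd = 5, bleach_rate_s = 0,
                        trace_length_frames = 100)
  truth <- structure(
    list(events = data.frame(start_s = 0, end_s = 8, state = 1L,
                             state_name = "U"),
         bleach_time_s = NA_real_, duration_s = 8, seed = 0L),
    class = "ground_truth")
  tr <- render_intensity_trace(truth, m, em, seed = 2)
  expect_lt(abs(mean(tr$acceptor) - em$background_acceptor), 3)
  # donor stays bright while unbound (anti-correlation physics)
  expect_gt(mean(tr$donor), em$background_donor + 900)
})

test_that("frames straddling a transition use exact time-weighted mixing", {
  m <- two_state_model(fret = 0.8, sigma = 0)
  nf <- 10L
  em <- emission_config(total_intensity = 1000, background_donor = 20,
                        background_acceptor = 30, noise_sd = 0,
                        bleach_rate_s = 0, trace_length_frames = nf)
  dt <- em$frame_interval_s
  t_unbind <- 4 * dt + 0.4 * dt       # mid-frame unbind at 40% of frame 5
  truth <- manual_truth(matrix(c(0, t_unbind), 1), duration = nf * dt)
  tr <- render_intensity_trace(truth, m, em, seed = 1)
  # fine-grained oracle: integrate occupancy on a 100x finer grid
  fine <- 100L
  for (f in seq_len(nf)) {
    ts <- (f - 1) * dt + (seq_len(fine) - 0.5) * dt / fine
    occ <- mean(ts < t_unbind)
    expect_equal(tr$acceptor[f], 30 + 1000 * 0.8 * occ, tolerance = 1e-9)
    expect_equal(tr$donor[f], 20 + 1000 * (1 - 0.8 * occ), tolerance = 1e-9)
  }
})

test_that("noiseless emission conserves total intensity until bleach", {
  m <- polymerase_binding_model(fret_sigma = 0)
  em <- emission_config(noise_sd = 0, bleach_rate_s = 0.05,
                        trace_length_frames = 400)
  ds <- simulate_dataset(m, em, 5, seed = 11)
  for (i in seq_along(ds$traces)) {
    tr <- ds$traces[[i]]
    tot <- tr$donor + tr$acceptor - em$background_donor -
      em$background_acceptor
    bl <- ds$truths[[i]]$bleach_time_s
    nf <- if (is.na(bl)) 400L else floor(bl / em$frame_interval_s)
    if (nf >= 1) {
      expect_equal(tot[seq_len(nf)], rep(em$total_intensity, nf),
                   tolerance = 1e-9)
    }
    if (!is.na(bl)) {
      dark <- tot[seq_len(400) > ceiling(bl / em$frame_interval_s)]
      if (length(dark) > 0) expect_equal(dark, rep(0, length(dark)))
    }
  }
})

test_that("datasets are reproducible and the seed schedule is stable", {
  m <- polymerase_binding_model()
  em <- emission_config(trace_length_frames = 100)
  d1 <- simulate_dataset(m, em, 12, seed = 5)
  d2 <- simulate_dataset(m, em, 12, seed = 5)
  expect_identical(d1$traces, d2$traces)
  expect_identical(d1$truths, d2$truths)
  expect_length(d1$traces, 12L)
  # trace i does not depend on n_traces
  d3 <- simulate_dataset(m, em, 5, seed = 5)
  expect_identical(d1$traces[[4]], d3$traces[[4]])
})

test_that("aggregate bound time matches the stationary distribution", {
  m <- polymerase_binding_model(k_on = 0.25, k_off = 0.22,
                                high_fraction = 0.7)
  em <- emission_config(bleach_rate_s = 0, trace_length_frames = 600)
  ds <- simulate_dataset(m, em, 80, seed = 21)
  pi <- stationary_distribution(m)
  t_bound <- 0; t_tot <- 0
  for (tu in ds$truths) {
    ev <- tu$events
    t_bound <- t_bound + sum((ev$end_s - ev$start_s)[ev$state != 1L])
    t_tot <- t_tot + tu$duration_s
  }
  # chains start unbound, so allow a small burn-in deficit on bound time
  expect_equal(t_bound / t_tot, unname(pi["L"] + pi["H"]), tolerance = 0.1)
})

test_that("titration instantiates the programmed linear laws", {
  base <- polymerase_binding_model(k_on = 0.3, k_off = 0.4,
                                   high_fraction = 0.7)
  des <- titration_design(c(0, 5, 10, 15), koff_slope = -0.01,
                          koff_intercept = 0.4,
                          occupancy_slope = -0.02, occupancy_intercept = 0.7)
  for (lev in c(0, 5, 10, 15)) {
    m <- model_at_level(des, base, lev)
    expect_equal(unname(m$rate_matrix["L", "U"]), 0.4 - 0.01 * lev)
    expect_equal(unname(m$rate_matrix["H", "U"]), 0.4 - 0.01 * lev)
    pi <- stationary_distribution(m)
    expect_equal(unname(pi["H"] / (pi["L"] + pi["H"])), 0.7 - 0.02 * lev,
                 tolerance = 1e-9)
  }
  # zero slopes reproduce the base model at every level
  des0 <- titration_design(c(0, 10), koff_slope = 0, koff_intercept = 0.4,
                           occupancy_slope = 0, occupancy_intercept = 0.7)
  m0 <- model_at_level(des0, base, 0)
  m10 <- model_at_level(des0, base, 10)
  expect_equal(m0$rate_matrix, m10$rate_matrix)
  # a design whose law goes non-positive is rejected outright
  expect_error(titration_design(c(0, 50), koff_slope = -0.01,
                                koff_intercept = 0.4, occupancy_slope = 0,
                                occupancy_intercept = 0.7), "k_off")
})

test_that("trace TSV round-trips through write_dataset/read_trace_tsv", {
  m <- polymerase_binding_model()
  em <- emission_config(trace_length_frames = 50)
  ds <- simulate_dataset(m, em, 2, seed = 9)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  tr <- read_trace_tsv(file.path(dir, "trace_0001.tsv"))
  expect_equal(tr$donor, ds$traces[[1]]$donor, tolerance = 1e-9)
  expect_equal(tr$frame_interval_s, em$frame_interval_s, tolerance = 1e-9)
  gt <- readLines(file.path(dir, "ground_truth.jsonl"))
  expect_length(gt, 2L)
  rec <- jsonlite::fromJSON(gt[1])
  expect_equal(rec$events$start_s, ds$truths[[1]]$events$start_s,
               tolerance = 1e-9)
})
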