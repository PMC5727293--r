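#' Simulate an exact state path of the binding chain
#'
#' Gillespie (exact stochastic simulation) sampling of the continuous-time
#' Markov chain defined by `model`, starting from the unbound state. The
#' returned event list tiles `[0, duration_s]` without gaps or overlaps and
#' is the ground truth against which trace processing is validated.
#'
#' @param model a [binding_model()].
#' @param duration_s total simulated time, seconds.
#' @param seed integer RNG seed; the path is reproducible for a fixed seed.
#' @return an object of class `ground_truth`: list with `events`
#'   (data.frame: start_s, end_s, state, state_name), `bleach_time_s`
#'   (NA here; set by the renderer), `duration_s`, and `seed`.
#' @export
simulate_state_path <- function(model, duration_s, seed) {
  stopifnot(inherits(model, "sim_state_model"))
  if (!is.finite(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  q <- model$rate_matrix
  if (any(!is.finite(q))) stop("rates must be finite")
  n <- nrow(q)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  state <- model$unbound
  t <- 0
  # grow in blocks; chains at these rates have few events per trace
  cap <- 64L
  starts <- numeric(cap); ends <- numeric(cap); states <- integer(cap)
  m <- 0L
  while (t < duration_s) {
    k_exit <- -q[state, state]
    if (k_exit <= 0) {
      t_next <- duration_s
    } else {
      t_next <- t + stats::rexp(1, k_exit)
    }
    m <- m + 1L
    if (m > cap) {
      cap <- cap * 2L
      length(starts) <- cap; length(ends) <- cap; length(states) <- cap
    }
    starts[m] <- t
    ends[m] <- min(t_next, duration_s)
    states[m] <- state
    if (t_next >= duration_s) break
    rates <- q[state, ]
    rates[state] <- 0
    state <- sample.int(n, 1, prob = rates)
    t <- t_next
  }
  events <- data.frame(
    start_s = starts[seq_len(m)], end_s = ends[seq_len(m)],
    state = states[seq_len(m)],
    state_name = model$state_names[states[seq_len(m)]],
    stringsAsFactors = FALSE
  )
  structure(
    list(events = events, bleach_time_s = NA_real_,
         duration_s = duration_s, seed = seed),
    class = "ground_truth"
  )
}

# save/restore global RNG state so seeded helpers do not perturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Render a ground-truth state path into a two-channel intensity trace
#'
#' Camera-integration model: each frame integrates the emission over its
#' interval. The donor (on the immobilized DNA) emits `total_intensity` per
#' frame; while the acceptor-labelled polymerase is bound with apparent FRET
#' E, a fraction E of that emission transfers to the acceptor channel, so
#' binding produces simultaneous anti-correlated intensity changes. Frames
#' straddling transitions use exact time-weighted mixing. Per-frame FRET is
#' emission-sampled as N(state mean, state sigma). After a single-step donor
#' bleach, both channels fall to background plus read noise.
#'
#' @param truth a `ground_truth` from [simulate_state_path()]; if its
#'   `bleach_time_s` is NA and `emission$bleach_rate_s > 0`, a bleach time is
#'   drawn here.
#' @param model the generating `sim_state_model`.
#' @param emission an [emission_config()].
#' @param seed integer RNG seed for emission noise and bleach.
#' @param trace_id identifier stored on the trace.
#' @return an object of class `intensity_trace`: list with `time_s`, `donor`,
#'   `acceptor`, `frame_interval_s`, `trace_id`. The (possibly updated)
#'   ground truth is attached as attribute `truth`.
#' @export
render_intensity_trace <- function(truth, model, emission, seed,
                                   trace_id = "trace") {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(model, "sim_state_model"),
            inherits(emission, "emission_config"))
  nf <- emission$trace_length_frames
  dt <- emission$frame_interval_s
  if (truth$duration_s < nf * dt - 1e-9) {
    stop("truth duration shorter than trace length x frame interval")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bleach <- truth$bleach_time_s
  if (is.na(bleach)) {
    bleach <- if (emission$bleach_rate_s > 0) {
      stats::rexp(1, emission$bleach_rate_s)
    } else Inf
    truth$bleach_time_s <- if (is.finite(bleach) && bleach < nf * dt) {
      bleach
    } else NA_real_
  }
  t_end <- min(bleach, nf * dt)

  bound_states <- setdiff(seq_along(model$state_names), model$unbound)
  # per-frame occupancy of each bound state (time-weighted, exact)
  occ <- matrix(0, nrow = nf, ncol = length(bound_states))
  ev <- truth$events
  frame_start <- (seq_len(nf) - 1) * dt
  for (j in seq_along(bound_states)) {
    s <- bound_states[j]
    rows <- which(ev$state == s & ev$start_s < t_end)
    for (r in rows) {
      a <- ev$start_s[r]
      b <- min(ev$end_s[r], t_end)
      if (b <= a) next
      f0 <- max(1L, floor(a / dt) + 1L)
      f1 <- min(nf, ceiling(b / dt))
      fs <- f0:f1
      overlap <- pmin(b, frame_start[fs] + dt) - pmax(a, frame_start[fs])
      occ[fs, j] <- occ[fs, j] + pmax(overlap, 0) / dt
    }
  }
  # emission-sampled per-frame FRET for each bound state
  e_frame <- matrix(0, nrow = nf, ncol = length(bound_states))
  for (j in seq_along(bound_states)) {
    s <- bound_states[j]
    e_frame[, j] <- stats::rnorm(nf, model$fret_mean[s], model$fret_sigma[s])
  }
  transfer <- rowSums(occ * e_frame)       # E x f_bound, summed over states
  # donor live fraction of each frame (1 until bleach, partial at bleach frame)
  live <- pmin(pmax((t_end - frame_start) / dt, 0), 1)
  donor <- emission$background_donor +
    emission$total_intensity * (live - transfer)
  acceptor <- emission$background_acceptor +
    emission$total_intensity * transfer
  if (emission$noise_sd > 0) {
    donor <- donor + stats::rnorm(nf, 0, emission$noise_sd)
    acceptor <- acceptor + stats::rnorm(nf, 0, emission$noise_sd)
  }
  structure(
    list(time_s = frame_start, donor = donor, acceptor = acceptor,
         frame_interval_s = dt, trace_id = trace_id),
    class = "intensity_trace", truth = truth
  )
}

#' Simulate a dataset of trace/truth pairs
#'
#' Each trace gets a deterministic sub-seed derived from the master seed and
#' its index, so trace i is reproducible independent of `n_traces`.
#'
#' @param model a `sim_state_model`.
#' @param emission an [emission_config()].
#' @param n_traces number of traces (>= 1).
#' @param seed master integer seed.
#' @return an object of class `smfret_dataset`: list with `traces` and
#'   `truths` (parallel lists), `model`, `emission`, `seed`.
#' @export
simulate_dataset <- function(model, emission, n_traces, seed) {
  if (n_traces < 1) stop("n_traces must be >= 1")
  nf <- emission$trace_length_frames
  dur <- nf * emission$frame_interval_s
  traces <- vector("list", n_traces)
  truths <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    si <- trace_seed(seed, i)
    tr_truth <- simulate_state_path(model, dur, seed = si)
    tr <- render_intensity_trace(tr_truth, model, emission, seed = si + 1L,
                                 trace_id = sprintf("trace_%04d", i))
    traces[[i]] <- tr
    truths[[i]] <- attr(tr, "truth")
  }
  structure(
    list(traces = traces, truths = truths, model = model,
         emission = emission, seed = seed),
    class = "smfret_dataset"
  )
}

#' Simulate a full titration series
#'
#' One dataset per covariate level, with exit rates and high-FRET occupancy
#' following the design's programmed linear laws.
#'
#' @param design a [titration_design()].
#' @param base_model base `sim_state_model` supplying k_on, shuttle rate, and
#'   FRET emission parameters.
#' @param emission an [emission_config()].
#' @param n_traces_per_level traces per covariate level.
#' @param seed master seed; level l uses `seed + 1000 * l` offsets through
#'   the per-trace schedule.
#' @return named list (one entry per level) of `smfret_dataset`s; names are
#'   the covariate values.
#' @export
simulate_titration <- function(design, base_model, emission,
                               n_traces_per_level, seed) {
  stopifnot(inherits(design, "titration_design"))
  out <- vector("list", length(design$covariate_levels))
  names(out) <- as.character(design$covariate_levels)
  for (l in seq_along(design$covariate_levels)) {
    lev <- design$covariate_levels[l]
    mod_l <- model_at_level(design, base_model, lev)
    out[[l]] <- simulate_dataset(mod_l, emission, n_traces_per_level,
                                 seed = seed + 1000L * l)
    out[[l]]$covariate <- lev
  }
  out
}

#' Bound-state dwell times from ground truth
#'
#' Merges consecutive bound-state events (conformational shuttling does not
#' end a binding event) and reports each contiguous bound interval, clipped
#' at the bleach time.
#'
#' @param truth a `ground_truth`.
#' @param unbound index of the unbound state (default 1).
#' @return data.frame with start_s, end_s, duration_s, censored_right.
#' @export
truth_binding_events <- function(truth, unbound = 1L) {
  ev <- truth$events
  t_end <- if (is.na(truth$bleach_time_s)) truth$duration_s else
    min(truth$bleach_time_s, truth$duration_s)
  bound <- ev$state != unbound & ev$start_s < t_end
  if (!any(bound)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), censored_right = logical(0)))
  }
  ev <- ev[order(ev$start_s), ]
  is_b <- ev$state != unbound
  r <- rle(is_b)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  keep <- which(r$values)
  starts <- ev$start_s[idx_start[keep]]
  ends <- ev$end_s[idx_end[keep]]
  sel <- starts < t_end
  starts <- starts[sel]
  ends <- pmin(ends[sel], t_end)
  data.frame(start_s = starts, end_s = ends, duration_s = ends - starts,
             censored_right = ends >= t_end - 1e-12)
}

#' Write traces and ground truth to plain-text files
#'
#' One TSV per trace (columns time_s, donor, acceptor; header comment with
#' frame interval and id) plus a JSON-lines ground-truth file.
#'
#' @param dataset an `smfret_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(dataset$traces)) {
    tr <- dataset$traces[[i]]
    p <- file.path(dir, paste0(tr$trace_id, ".tsv"))
    df <- data.frame(time_s = tr$time_s, donor = tr$donor,
                     acceptor = tr$acceptor)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  gt <- file.path(dir, "ground_truth.jsonl")
  con <- file(gt, "w")
  on.exit(close(con))
  for (i in seq_along(dataset$truths)) {
    tu <- dataset$truths[[i]]
    rec <- list(trace_id = dataset$traces[[i]]$trace_id,
                events = tu$events,
                bleach_time_s = tu$bleach_time_s, seed = tu$seed)
    writeLines(jsonlite::toJSON(rec, dataframe = "rows", auto_unbox = TRUE,
                                na = "null", digits = NA), con)
  }
  invisible(c(paths, gt))
}

#' Read a two-channel trace from TSV
#'
#' @param path TSV with columns time_s, donor, acceptor.
#' @param trace_id identifier; defaults to the file name.
#' @return an `intensity_trace`.
#' @export
read_trace_tsv <- function(path, trace_id = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "donor", "acceptor") %in% names(df))) {
    stop("trace TSV must have columns time_s, donor, acceptor")
  }
  dt <- stats::median(diff(df$time_s))
  structure(
    list(time_s = df$time_s, donor = df$donor, acceptor = df$acceptor,
         frame_interval_s = dt,
         trace_id = trace_id %||% basename(path)),
    class = "intensity_trace"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
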