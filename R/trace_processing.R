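#' Apparent FRET efficiency of a trace
#'
#' Computes the per-frame apparent FRET efficiency E = I_A / (I_D + I_A).
#' No correction factors are applied: E is a conformational identifier, not
#' a distance. Frames with non-positive total intensity are flagged
#' undefined (NA), never silently zero.
#'
#' @param trace an `intensity_trace`.
#' @param smooth_window odd window for a centered moving average applied to
#'   both intensity channels before the ratio (NULL = no smoothing).
#'   Smoothing the channels rather than the ratio avoids noise blow-up at
#'   low total intensity.
#' @param background length-2 numeric c(donor, acceptor) subtracted from
#'   the channels before the ratio. Without this correction the apparent
#'   FRET of a state with true efficiency E is (E I + bg_A)/(I + bg_D +
#'   bg_A), systematically compressed toward the background ratio.
#' @return an object of class `fret_trace`: list with `time_s`,
#'   `efficiency`, `undefined` (logical), `smoothed`, `trace_id`.
#' @export
compute_fret <- function(trace, smooth_window = NULL, background = c(0, 0)) {
  stopifnot(inherits(trace, "intensity_trace"))
  d <- trace$donor - background[1]
  a <- trace$acceptor - background[2]
  smoothed <- FALSE
  if (!is.null(smooth_window)) {
    d <- smooth_trace(d, smooth_window)
    a <- smooth_trace(a, smooth_window)
    smoothed <- TRUE
  }
  tot <- d + a
  undef <- !(tot > 0) | !is.finite(tot)
  if (all(undef)) stop("all frames have non-positive total intensity")
  e <- rep(NA_real_, length(tot))
  e[!undef] <- a[!undef] / tot[!undef]
  structure(
    list(time_s = trace$time_s, efficiency = e, undefined = undef,
         smoothed = smoothed, trace_id = trace$trace_id),
    class = "fret_trace"
  )
}

#' Centered moving average
#'
#' The standard 5-point moving average used on intensity traces. Edges use
#' the available (shrinking) window, so the output has the input's length.
#'
#' @param values numeric vector.
#' @param window odd window size, >= 1 and <= length(values).
#' @return numeric vector of the same length.
#' @export
smooth_trace <- function(values, window = 5L) {
  n <- length(values)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 1L || window > n) stop("window must be in [1, length(values)]")
  if (window == 1L) return(values)
  h <- window %/% 2L
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Anti-correlation screen for a candidate binding interval
#'
#' Computes the Pearson correlation between frame-to-frame changes of the
#' donor and acceptor channels in windows around the interval boundaries
#' (boundary +/- margin). Genuine binding/unbinding produces simultaneous
#' opposite-sign intensity steps, so the score is strongly negative; equal
#' step magnitudes are not required. Fluctuations without anti-correlation
#' are rejected.
#'
#' @param trace an `intensity_trace`.
#' @param interval integer c(first_frame, last_frame), 1-based, >= 4 frames.
#' @param margin frames included on each side of each boundary. The default
#'   (10) gives ~40 change samples across two boundaries, putting the null
#'   (independent channels) standard error of the score near 0.16 so that
#'   uncorrelated fluctuations pass the -0.3 threshold only rarely.
#' @param threshold acceptance threshold on the score (accept iff
#'   score < threshold).
#' @param boundaries which interval boundaries are observable
#'   (c(start, end) logical); a boundary censored by the trace edge carries
#'   no transition and is excluded. If none is observable the screen is
#'   inconclusive: accepted = NA.
#' @return list(accepted, score).
#' @export
check_anticorrelation <- function(trace, interval, margin = 10L,
                                  threshold = -0.3,
                                  boundaries = c(TRUE, TRUE)) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$donor)
  i0 <- interval[1]; i1 <- interval[2]
  if (i1 - i0 + 1L < 4L) stop("interval must span at least 4 frames")
  windows <- list()
  if (boundaries[1] && i0 > 1L) {
    windows <- c(windows, list(max(1L, i0 - margin):min(n, i0 + margin)))
  }
  if (boundaries[2] && i1 < n) {
    windows <- c(windows, list(max(1L, i1 - margin):min(n, i1 + margin)))
  }
  if (length(windows) == 0L) {
    return(list(accepted = NA, score = NA_real_))
  }
  # frame-to-frame changes within each contiguous window (no join artifact)
  dd <- unlist(lapply(windows, function(w) diff(trace$donor[w])))
  da <- unlist(lapply(windows, function(w) diff(trace$acceptor[w])))
  if (length(dd) < 2L || stats::sd(dd) == 0 || stats::sd(da) == 0) {
    return(list(accepted = FALSE, score = NA_real_))
  }
  score <- stats::cor(dd, da)
  list(accepted = score < threshold, score = score)
}

#' Detect single-step photobleaching
#'
#' Change-point on total intensity: before a donor bleach the total
#' donor + acceptor signal sits near background + total_intensity regardless
#' of binding state; after, both channels are at background. Returns the
#' first frame of the dark tail, 0L if the whole trace is dark (unusable),
#' or NULL if no bleach is found.
#'
#' @param trace an `intensity_trace`.
#' @param background_total known background_donor + background_acceptor
#'   (NULL = estimate from the data).
#' @param noise_sd known per-channel read noise (NULL = estimate via the
#'   median absolute frame-to-frame difference).
#' @param min_dark_frames dark run length required to call a bleach.
#' @return integer frame index, 0L, or NULL.
#' @export
detect_bleach <- function(trace, background_total = NULL, noise_sd = NULL,
                          min_dark_frames = 5L) {
  stopifnot(inherits(trace, "intensity_trace"))
  total <- trace$donor + trace$acceptor
  n <- length(total)
  sm <- smooth_trace(total, min(5L, if (n %% 2L == 1L) n else n - 1L))
  if (is.null(noise_sd)) {
    noise_sd <- stats::mad(diff(total)) / sqrt(2)
    if (noise_sd == 0) noise_sd <- 1e-9
  }
  hi <- stats::quantile(sm, 0.98, names = FALSE)
  lo <- stats::quantile(sm, 0.02, names = FALSE)
  if (hi - lo < 6 * noise_sd) {
    # flat trace: either never bleached or dark throughout
    if (!is.null(background_total) &&
        stats::median(sm) < background_total + 4 * noise_sd) {
      return(0L)
    }
    return(NULL)
  }
  thresh <- if (is.null(background_total)) (hi + lo) / 2 else
    background_total + (hi - background_total) / 2
  below <- sm < thresh
  if (!below[n]) return(NULL)
  # first index of the terminal dark run
  r <- rle(below)
  len_last <- r$lengths[length(r$lengths)]
  if (len_last < min_dark_frames) return(NULL)
  b <- n - len_last + 1L
  if (b <= 1L) return(0L)
  b
}

#' Segment binding events from a trace
#'
#' Thresholds the (smoothed) acceptor channel above background with
#' hysteresis: candidate regions are runs above the exit threshold
#' (background + exit_k * noise) that reach the enter threshold
#' (background + enter_k * noise) at least once. Events shorter than
#' `min_event_frames` are dropped, events are clipped at the bleach frame,
#' censoring flags mark events touching the trace start, the bleach, or the
#' trace end, and events failing the anti-correlation screen are removed.
#'
#' @param trace an `intensity_trace`.
#' @param fret a `fret_trace` for the same trace (for per-event mean FRET);
#'   NULL computes it on the fly.
#' @param background_acceptor,noise_sd known emission parameters (NULL =
#'   estimated from the trace: background as the median of the below-median
#'   acceptor frames, noise from frame-to-frame differences).
#' @param bleach_frame output of [detect_bleach()] (NULL = detect here;
#'   pass NA to skip bleach handling).
#' @param enter_k,exit_k hysteresis thresholds in units of noise_sd.
#' @param min_event_frames minimum event length in frames.
#' @param anticorr_threshold acceptance threshold for the screen; events
#'   whose screen is inconclusive (fully censored) are kept.
#' @param margin frames around boundaries for the screen.
#' @return data.frame of class `binding_events`: trace_id, start_s, end_s,
#'   duration_s, start_frame, end_frame, mean_fret, censored_left,
#'   censored_right, anticorrelation_score.
#' @export
segment_events <- function(trace, fret = NULL, background_acceptor = NULL,
                           noise_sd = NULL, bleach_frame = NULL,
                           enter_k = 4, exit_k = 2, min_event_frames = 2L,
                           anticorr_threshold = -0.3, margin = 10L) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (is.null(fret)) fret <- compute_fret(trace)
  n <- length(trace$acceptor)
  dt <- trace$frame_interval_s
  acc <- smooth_trace(trace$acceptor, min(5L, if (n %% 2L == 1L) n else n - 1L))
  if (is.null(noise_sd)) {
    noise_sd <- stats::mad(diff(trace$acceptor)) / sqrt(2)
    if (noise_sd <= 0) noise_sd <- 1e-9
  }
  if (is.null(background_acceptor)) {
    background_acceptor <- stats::median(acc[acc <= stats::median(acc)])
  }
  if (is.null(bleach_frame)) {
    bleach_frame <- detect_bleach(trace, noise_sd = noise_sd)
  }
  empty <- data.frame(
    trace_id = character(0), start_s = numeric(0), end_s = numeric(0),
    duration_s = numeric(0), start_frame = integer(0), end_frame = integer(0),
    mean_fret = numeric(0), censored_left = logical(0),
    censored_right = logical(0), anticorrelation_score = numeric(0)
  )
  class(empty) <- c("binding_events", "data.frame")
  if (!is.null(bleach_frame) && !is.na(bleach_frame) && bleach_frame <= 1L) {
    return(empty)  # dark from the start: unusable trace
  }
  last_frame <- if (is.null(bleach_frame) || is.na(bleach_frame)) n else
    bleach_frame - 1L
  # smoothing spreads a step over the window; evaluate hysteresis on the
  # smoothed channel but report boundaries from the raw channel crossing
  enter_t <- background_acceptor + enter_k * noise_sd
  exit_t <- background_acceptor + exit_k * noise_sd
  above_exit <- acc[seq_len(last_frame)] > exit_t
  r <- rle(above_exit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- list()
  raw_acc <- trace$acceptor
  # smoothing bridges unbound gaps shorter than the window; split candidate
  # runs wherever the raw channel sits below the exit threshold for >= 2
  # consecutive frames (a genuine dark gap, not read noise)
  cand <- list()
  for (k in keep) {
    f0 <- starts[k]; f1 <- ends[k]
    below <- raw_acc[f0:f1] < exit_t
    r2 <- rle(below)
    e2 <- cumsum(r2$lengths); s2 <- e2 - r2$lengths + 1L
    gap <- which(r2$values & r2$lengths >= 2L)
    cuts <- c(0L, as.vector(rbind(s2[gap] - 1L, e2[gap])), f1 - f0 + 1L)
    for (g in seq_len(length(cuts) / 2L)) {
      a <- f0 + cuts[2L * g - 1L]
      b <- f0 + cuts[2L * g] - 1L
      if (b >= a) cand[[length(cand) + 1L]] <- c(a, b)
    }
  }
  for (cd in cand) {
    f0 <- cd[1]; f1 <- cd[2]
    if (max(acc[f0:f1]) < enter_t &&
        max(raw_acc[f0:f1]) < enter_t) next     # hysteresis: never entered
    # refine boundaries by half-max crossing on the raw channel: the
    # smoothing ramp and the low exit threshold otherwise stretch each
    # event by ~2 frames per edge, biasing dwell times upward
    plateau <- stats::median(raw_acc[f0:f1])
    half <- background_acceptor + (plateau - background_acceptor) / 2
    if (plateau > enter_t) {
      w0 <- max(1L, f0 - 3L):min(f1, f0 + 3L)
      hit <- w0[raw_acc[w0] >= half]
      if (length(hit) > 0L) f0 <- hit[1]
      w1 <- max(f0, f1 - 3L):min(last_frame, f1 + 3L)
      hit <- w1[raw_acc[w1] >= half]
      if (length(hit) > 0L) f1 <- hit[length(hit)]
    }
    if (f1 - f0 + 1L < min_event_frames) next
    cl <- f0 == 1L
    cr <- f1 == last_frame
    sc <- if (f1 - f0 + 1L >= 4L) {
      check_anticorrelation(trace, c(f0, f1), margin = margin,
                            threshold = anticorr_threshold,
                            boundaries = c(!cl, !cr))
    } else list(accepted = NA, score = NA_real_)  # too short to screen
    if (!is.na(sc$accepted) && !sc$accepted) next
    ef <- fret$efficiency[f0:f1]
    mf <- mean(ef, na.rm = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      trace_id = trace$trace_id,
      start_s = (f0 - 1L) * dt, end_s = f1 * dt,
      duration_s = (f1 - f0 + 1L) * dt,
      start_frame = f0, end_frame = f1,
      mean_fret = mf, censored_left = cl, censored_right = cr,
      anticorrelation_score = sc$score,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) return(empty)
  ev <- do.call(rbind, out)
  class(ev) <- c("binding_events", "data.frame")
  ev
}

#' Per-frame FRET values inside binding events
#'
#' Collects the bound-frame FRET efficiencies that feed time-binned
#' histograms and HMM fitting. Undefined frames within an event are imputed
#' by the event mean (and counted), per the histogramming convention.
#'
#' @param fret a `fret_trace`.
#' @param events `binding_events` for the same trace.
#' @param trim frames dropped from each end of every event; edge frames
#'   straddle the binding/unbinding transition and carry a mixed FRET value
#'   that fills the histogram valley and pulls the peaks inward. Default 0.
#' @return numeric vector of per-frame FRET values (one per bound frame).
#' @export
bound_fret_values <- function(fret, events, trim = 0L) {
  if (nrow(events) == 0L) return(numeric(0))
  vals <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    f0 <- events$start_frame[i] + trim
    f1 <- events$end_frame[i] - trim
    if (f1 < f0) next
    ef <- fret$efficiency[f0:f1]
    if (anyNA(ef)) ef[is.na(ef)] <- mean(ef, na.rm = TRUE)
    vals[[i]] <- ef
  }
  unlist(vals)
}

#' Per-event FRET segments
#'
#' @param fret a `fret_trace`.
#' @param events `binding_events` for the same trace.
#' @param trim frames dropped from each end of every event. Edge frames
#'   straddle the binding/unbinding transition and carry partial-occupancy
#'   FRET mixtures; trimming them leaves the conformational transitions
#'   inside the bound interval untouched. Events that vanish are dropped.
#' @return list of numeric vectors, one per surviving event (NA frames
#'   imputed by the event mean).
#' @export
bound_fret_segments <- function(fret, events, trim = 0L) {
  if (nrow(events) == 0L) return(list())
  out <- lapply(seq_len(nrow(events)), function(i) {
    f0 <- events$start_frame[i] + trim
    f1 <- events$end_frame[i] - trim
    if (f1 < f0) return(NULL)
    ef <- fret$efficiency[f0:f1]
    if (anyNA(ef)) ef[is.na(ef)] <- mean(ef, na.rm = TRUE)
    ef
  })
  Filter(Negate(is.null), out)
}

#' Write binding events to TSV
#'
#' @param events `binding_events` (possibly rbind-ed across traces).
#' @param path output file.
#' @export
write_events_tsv <- function(events, path) {
  df <- as.data.frame(events)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))  # frame-time precision
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
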