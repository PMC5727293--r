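#' Collect dwell times from binding events
#'
#' Left-censored events (already in progress at the trace start) are always
#' excluded: their durations carry no information about the entry time.
#' Right-censored events (truncated by bleach or the trace end) are kept
#' with a censoring flag under the "exposure" policy, or dropped under
#' "exclude".
#'
#' @param events `binding_events` (possibly pooled across traces).
#' @param censor_policy "exposure" (keep right-censored with flags, the
#'   default) or "exclude".
#' @return data.frame of class `dwell_set`: duration_s, censored.
#' @export
collect_dwells <- function(events, censor_policy = c("exposure", "exclude")) {
  censor_policy <- match.arg(censor_policy)
  if (nrow(events) == 0L) stop("no events supplied")
  ev <- events[!events$censored_left, , drop = FALSE]
  if (censor_policy == "exclude") {
    ev <- ev[!ev$censored_right, , drop = FALSE]
  }
  if (nrow(ev) == 0L) stop("no usable events after censoring policy")
  out <- data.frame(duration_s = ev$duration_s,
                    censored = ev$censored_right)
  class(out) <- c("dwell_set", "data.frame")
  out
}

#' Dissociation rate constant from dwell times
#'
#' Two estimators of the single-exponential dwell rate k_off. The default
#' censoring-aware maximum-likelihood estimator is
#' k = n_uncensored / (sum of all durations): right-censored dwells
#' contribute exposure time but no event. The "histogram" method reproduces
#' the classical analysis of fitting a binned dwell-time histogram to a
#' single exponential decay A exp(-k t) by least squares (uncensored dwells
#' only). A seeded bootstrap over dwells gives the 95% interval.
#'
#' @param dwells a `dwell_set` from [collect_dwells()] (or a numeric vector,
#'   treated as uncensored).
#' @param method "mle" (default) or "histogram".
#' @param n_boot bootstrap resamples for the CI (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param bin_width histogram bin width in seconds for the histogram method;
#'   default max(frame_interval, range/30).
#' @param frame_interval_s frame interval used for the default binning.
#' @param dead_time_s detection dead time: dwells shorter than this are
#'   missed entirely by event segmentation (e.g. `min_event_frames` x frame
#'   interval). By the memorylessness of the exponential, each detected
#'   dwell is dead_time + Exp(k), so the MLE subtracts the dead time from
#'   every dwell's exposure. Default 0 (no correction).
#' @return object of class `dwell_time_fit`: k_off (s^-1), ci_low, ci_high,
#'   n_events, n_censored, method, boot_k (the bootstrap draws).
#' @export
fit_exponential <- function(dwells, method = c("mle", "histogram"),
                            n_boot = 1000L, seed = 1L,
                            bin_width = NULL, frame_interval_s = 0.08,
                            dead_time_s = 0) {
  method <- match.arg(method)
  if (is.numeric(dwells)) {
    dwells <- data.frame(duration_s = dwells,
                         censored = rep(FALSE, length(dwells)))
  }
  t_all <- dwells$duration_s
  cens <- dwells$censored
  n_unc <- sum(!cens)
  if (n_unc < 10L) stop("need at least 10 uncensored dwells")
  if (sum(t_all) <= 0) stop("zero total dwell time")
  est <- function(t, cn) {
    if (method == "mle") {
      expo <- sum(pmax(t - dead_time_s, 0))
      if (expo <= 0) stop("zero exposure after dead-time correction")
      sum(!cn) / expo
    } else {
      .histogram_rate(t[!cn] - dead_time_s, bin_width, frame_interval_s)
    }
  }
  k <- est(t_all, cens)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nb <- length(t_all)
  boot_k <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nb, nb, replace = TRUE)
    boot_k[b] <- tryCatch(est(t_all[idx], cens[idx]), error = function(e) NA_real_)
  }
  ci <- stats::quantile(boot_k, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(
    list(k_off = k, ci_low = ci[1], ci_high = ci[2],
         n_events = nb, n_censored = sum(cens), method = method,
         boot_k = boot_k),
    class = "dwell_time_fit"
  )
}

# least-squares single-exponential fit of a binned dwell histogram
.histogram_rate <- function(t, bin_width, frame_interval_s) {
  if (length(t) < 5L) stop("too few dwells for histogram fit")
  if (is.null(bin_width)) {
    bin_width <- max(frame_interval_s, diff(range(t)) / 30)
  }
  edges <- seq(0, max(t) + bin_width, by = bin_width)
  h <- graphics::hist(t, breaks = edges, plot = FALSE)
  x <- h$mids; y <- h$counts
  keep <- y > 0 | x < stats::median(t) * 3
  x <- x[keep]; y <- y[keep]
  k0 <- 1 / mean(t)
  fit <- minpack.lm::nlsLM(y ~ a * exp(-k * x),
                           start = list(a = max(y), k = k0),
                           lower = c(0, 1e-9),
                           data = data.frame(x = x, y = y),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  unname(stats::coef(fit)[["k"]])
}

#' Unbound gaps between consecutive binding events
#'
#' Per-trace intervals between the end of one event and the start of the
#' next, the observable complement of the dwell times (used for the
#' missed-event correction).
#'
#' @param events `binding_events`, possibly pooled over traces.
#' @return numeric vector of gap durations in seconds.
#' @export
event_gaps <- function(events) {
  if (nrow(events) == 0L) return(numeric(0))
  gaps <- numeric(0)
  for (id in unique(events$trace_id)) {
    ev <- events[events$trace_id == id, , drop = FALSE]
    ev <- ev[order(ev$start_s), , drop = FALSE]
    if (nrow(ev) > 1L) {
      gaps <- c(gaps, ev$start_s[-1] - ev$end_s[-nrow(ev)])
    }
  }
  gaps[gaps > 0]
}

#' Dissociation rate from segmented events, with missed-event correction
#'
#' Full kinetics step of the pipeline: collects dwells (exposure policy)
#' and fits the censoring-aware exponential MLE with two small corrections
#' that follow from the camera-detection mechanism rather than from the
#' dwell model itself:
#'
#' \itemize{
#'   \item Duration floor. An event must span `min_event_frames` frames to
#'     be detected, so measured durations are floored at
#'     t_floor = min_event_frames x frame interval. For exponential dwells
#'     the expected per-event excess is E[(t_floor - t)+] ~ k t_floor^2 / 2,
#'     which is subtracted from each event's exposure (one fixed-point
#'     iteration from the naive rate).
#'   \item Missed gaps. An unbound gap is only resolved when at least
#'     `min_gap_frames` frames read fully dark; the two boundary frames are
#'     partially covered and never do, so the gap dead time is
#'     (min_gap_frames + 1) frames. Unresolved gaps merge two genuine
#'     binding events into one, deflating the event count (hence the rate)
#'     by 1 - p_miss with p_miss = 1 - exp(-k_on x gap dead time); k_on is
#'     estimated from the observed gap distribution. With fewer than 10
#'     observed gaps no merge correction is applied.
#' }
#'
#' @param events `binding_events` pooled over traces.
#' @param frame_interval_s camera frame interval, seconds.
#' @param min_event_frames detection threshold used in segmentation.
#' @param min_gap_frames dark-frame run length required to split events in
#'   segmentation (fixed at 2 there).
#' @param n_boot,seed bootstrap settings, as in [fit_exponential()].
#' @return a `dwell_time_fit` with extra fields k_off_uncorrected, p_miss,
#'   k_on_hat; `boot_k` and the CI are scaled by the same correction.
#' @export
fit_koff_events <- function(events, frame_interval_s = 0.08,
                            min_event_frames = 2L, min_gap_frames = 2L,
                            n_boot = 1000L, seed = 1L) {
  t_floor <- min_event_frames * frame_interval_s
  dwells <- collect_dwells(events)
  k0 <- sum(!dwells$censored) / sum(dwells$duration_s)
  delta <- k0 * t_floor^2 / 2
  fit <- fit_exponential(dwells, method = "mle", n_boot = n_boot,
                         seed = seed, frame_interval_s = frame_interval_s,
                         dead_time_s = delta)
  gaps <- event_gaps(events)
  p_miss <- 0
  k_on_hat <- NA_real_
  gap_dead <- (min_gap_frames + 1L) * frame_interval_s
  if (length(gaps) >= 10L) {
    k_on_hat <- length(gaps) / sum(gaps)
    p_miss <- 1 - exp(-k_on_hat * gap_dead)
  }
  corr <- 1 / (1 - p_miss)
  fit$k_off_uncorrected <- fit$k_off
  fit$k_off <- fit$k_off * corr
  fit$boot_k <- fit$boot_k * corr
  fit$ci_low <- fit$ci_low * corr
  fit$ci_high <- fit$ci_high * corr
  fit$p_miss <- p_miss
  fit$k_on_hat <- k_on_hat
  fit
}

#' Relative stabilization energy from two dissociation rates
#'
#' Evaluates ddG = -R T ln(k_alt / k_ref) in kcal/mol. A faster-dissociating
#' alternate condition (k_alt > k_ref) gives a negative ddG: the alternate
#' condition destabilizes the complex by |ddG|.
#'
#' @param k_ref reference dissociation rate, s^-1.
#' @param k_alt alternate-condition dissociation rate, s^-1.
#' @param temperature_K absolute temperature; default 294.15 K (21 C).
#' @return object of class `stabilization_energy`: delta_delta_g (kcal/mol),
#'   gas_constant (kcal mol^-1 K^-1), temperature_K, k_ref, k_alt.
#' @export
stabilization_energy <- function(k_ref, k_alt, temperature_K = 294.15) {
  if (!is.finite(k_ref) || !is.finite(k_alt) || k_ref <= 0 || k_alt <= 0) {
    stop("rates must be finite and > 0")
  }
  if (temperature_K <= 0) stop("temperature must be > 0")
  R <- 1.987204e-3   # kcal mol^-1 K^-1
  structure(
    list(delta_delta_g = -R * temperature_K * log(k_alt / k_ref),
         gas_constant = R, temperature_K = temperature_K,
         k_ref = k_ref, k_alt = k_alt),
    class = "stabilization_energy"
  )
}

#' Linear trend of k_off against a covariate
#'
#' Weighted least squares of per-level dissociation rates on the covariate,
#' with weights from the bootstrap spread of each fit.
#'
#' @param fits list of `dwell_time_fit`, one per level.
#' @param levels numeric covariate values (same length).
#' @return a `linear_fit` (see [fit_linear_trend()]).
#' @export
koff_vs_covariate <- function(fits, levels) {
  if (length(fits) != length(levels)) stop("fits and levels lengths differ")
  if (length(levels) < 2L) stop("need at least 2 covariate levels")
  k <- vapply(fits, function(f) f$k_off, numeric(1))
  se <- vapply(fits, function(f) stats::sd(f$boot_k, na.rm = TRUE), numeric(1))
  if (any(!is.finite(se)) || any(se <= 0)) se <- NULL
  fit_linear_trend(levels, k, y_err = se)
}
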