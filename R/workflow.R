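.config_schema <- list(
  top = c("label", "covariate", "model", "emission", "analysis"),
  model = c("k_on", "k_off", "high_fraction", "k_shuttle",
            "fret_low", "fret_high", "fret_sigma"),
  emission = c("frame_interval_s", "total_intensity", "background_donor",
               "background_acceptor", "noise_sd", "bleach_rate_s",
               "trace_length_frames"),
  analysis = c("n_traces", "smooth_window", "min_event_frames",
               "anticorr_threshold", "n_states", "n_boot", "bin_width")
)

#' Validate a condition configuration
#'
#' Fail-fast schema check: unknown keys anywhere are errors, required
#' sections must be present.
#'
#' @param config nested list (e.g. from [read_condition_config()]).
#' @return the config, invisibly, with defaults filled in.
#' @export
validate_config <- function(config) {
  bad <- setdiff(names(config), .config_schema$top)
  if (length(bad) > 0L) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  for (sec in c("model", "emission", "analysis")) {
    if (is.null(config[[sec]])) config[[sec]] <- list()
    extra <- setdiff(names(config[[sec]]), .config_schema[[sec]])
    if (length(extra) > 0L) {
      stop("unknown keys in '", sec, "': ", paste(extra, collapse = ", "))
    }
  }
  config$label <- config$label %||% "condition"
  config$covariate <- config$covariate %||% NA_real_
  defaults <- list(n_traces = 150L, smooth_window = 5L, min_event_frames = 2L,
                   anticorr_threshold = -0.3, n_states = 2L, n_boot = 500L,
                   bin_width = 0.02)
  for (k in names(defaults)) {
    config$analysis[[k]] <- config$analysis[[k]] %||% defaults[[k]]
  }
  invisible(config)
}

#' Read a condition configuration from YAML
#'
#' @param path YAML file with sections label, covariate, model, emission,
#'   analysis.
#' @return validated config list.
#' @export
read_condition_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

.build_model <- function(mc) {
  do.call(polymerase_binding_model, mc)
}

.build_emission <- function(ec) {
  do.call(emission_config, ec)
}

#' Process a simulated dataset into events and FRET segments
#'
#' Runs smoothing, FRET computation, bleach detection, and event
#' segmentation over every trace, using the dataset's known emission
#' parameters for the thresholds.
#'
#' @param dataset an `smfret_dataset`.
#' @param smooth_window odd moving-average window for the channels.
#' @param min_event_frames,anticorr_threshold see [segment_events()].
#' @return list: events (pooled `binding_events`), fret_traces (list of
#'   smoothed `fret_trace`s), segments (per-event raw FRET vectors for HMM
#'   fitting, with one binding-edge frame trimmed per side: the moving
#'   average correlates consecutive frames and smears conformational
#'   transitions over the window, so state inference runs on the unsmoothed
#'   signal, and edge frames are partial-occupancy mixtures that would
#'   register as a spurious intermediate state), hist_values (raw per-frame
#'   FRET inside events with one edge frame trimmed per side, for
#'   histograms), n_traces.
#' @export
process_dataset <- function(dataset, smooth_window = 5L,
                            min_event_frames = 2L,
                            anticorr_threshold = -0.3) {
  em <- dataset$emission
  all_events <- list()
  fret_traces <- vector("list", length(dataset$traces))
  segments <- list()
  hist_values <- list()
  for (i in seq_along(dataset$traces)) {
    tr <- dataset$traces[[i]]
    bg <- c(em$background_donor, em$background_acceptor)
    fr <- compute_fret(tr, smooth_window = smooth_window, background = bg)
    fr_raw <- compute_fret(tr, background = bg)
    fret_traces[[i]] <- fr
    bf <- detect_bleach(tr,
                        background_total = em$background_donor +
                          em$background_acceptor,
                        noise_sd = em$noise_sd)
    ev <- segment_events(tr, fr,
                         background_acceptor = em$background_acceptor,
                         noise_sd = em$noise_sd, bleach_frame = bf,
                         min_event_frames = min_event_frames,
                         anticorr_threshold = anticorr_threshold)
    if (nrow(ev) > 0L) {
      all_events[[length(all_events) + 1L]] <- as.data.frame(ev)
      segments <- c(segments, bound_fret_segments(fr_raw, ev, trim = 1L))
      hist_values[[length(hist_values) + 1L]] <-
        bound_fret_values(fr_raw, ev, trim = 1L)
    }
  }
  events <- if (length(all_events) > 0L) do.call(rbind, all_events) else
    segment_events(dataset$traces[[1]])[0, ]
  class(events) <- c("binding_events", "data.frame")
  list(events = events, fret_traces = fret_traces, segments = segments,
       hist_values = unlist(hist_values), n_traces = length(dataset$traces))
}

#' Run the full pipeline for one condition
#'
#' simulate -> process -> dwell kinetics -> histogram + two-Gaussian fit ->
#' HMM + transition density, returning a machine-readable report. All
#' randomness derives from `seed`; a rerun with the same seed reproduces the
#' report bit-for-bit.
#'
#' @param config validated condition config (see [validate_config()]).
#' @param seed master integer seed.
#' @param out_dir optional directory for artifacts (events TSV, histogram
#'   TSV, TDP TSV, report JSON, run manifest).
#' @return object of class `condition_report`.
#' @export
run_condition <- function(config, seed = 1L, out_dir = NULL) {
  config <- validate_config(config)
  an <- config$analysis
  model <- .build_model(config$model)
  emission <- .build_emission(config$emission)
  message("[", config$label, "] simulating ", an$n_traces, " traces")
  dataset <- simulate_dataset(model, emission, an$n_traces, seed)
  message("[", config$label, "] segmenting events")
  proc <- process_dataset(dataset, smooth_window = an$smooth_window,
                          min_event_frames = an$min_event_frames,
                          anticorr_threshold = an$anticorr_threshold)
  if (nrow(proc$events) == 0L) stop("stage 'segmentation': no events found")
  kfit <- fit_koff_events(proc$events, n_boot = an$n_boot,
                          seed = seed + 17L,
                          frame_interval_s = emission$frame_interval_s,
                          min_event_frames = an$min_event_frames)
  hist <- build_histogram(proc$hist_values, bin_width = an$bin_width,
                          n_trajectories = proc$n_traces)
  gfit <- tryCatch(fit_gaussians(hist, 2L), error = function(e) {
    stop("stage 'gaussian_fit': ", conditionMessage(e))
  })
  hff <- high_fret_fraction(gfit)
  message("[", config$label, "] fitting HMM")
  segs <- Filter(function(s) length(s) >= 3L, proc$segments)
  hmm <- tryCatch(fit_hmm(segs, an$n_states, seed = seed + 31L),
                  error = function(e) NULL)
  tdp <- NULL; sym <- NA_real_; paths <- NULL
  if (!is.null(hmm)) {
    paths <- lapply(seq_along(segs), function(i) {
      viterbi_path(hmm, segs[[i]], trace_id = paste0("seg_", i))
    })
    tdp <- build_tdp(paths, hmm, bin_width = an$bin_width)
    if (tdp$n_transitions > 0L) sym <- symmetry_score(tdp)
  }
  report <- structure(
    list(label = config$label, covariate = config$covariate,
         n_traces = proc$n_traces, n_events = nrow(proc$events),
         k_off = kfit$k_off, k_off_ci = c(kfit$ci_low, kfit$ci_high),
         dwell_fit = kfit,
         histogram = hist, mixture_fit = gfit, high_fret_fraction = hff,
         hmm = hmm, tdp = tdp, tdp_symmetry = sym,
         seed = seed, config = config),
    class = "condition_report"
  )
  if (!is.null(out_dir)) .write_condition_artifacts(report, proc, out_dir)
  report
}

.write_condition_artifacts <- function(report, proc, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(out_dir, "events.tsv")
  write_events_tsv(proc$events, p); paths <- c(paths, p)
  p <- file.path(out_dir, "histogram.tsv")
  utils::write.table(
    data.frame(fret = report$histogram$bin_centers,
               counts = report$histogram$counts),
    p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$tdp)) {
    p <- file.path(out_dir, "tdp.tsv")
    write_tdp_tsv(report$tdp, p); paths <- c(paths, p)
  }
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(condition_summary(report), p, auto_unbox = TRUE,
                       digits = NA)
  paths <- c(paths, p)
  manifest <- list(
    label = report$label, seed = report$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("fretmd")),
    files = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}

#' Flat numeric summary of a condition report
#'
#' @param report a `condition_report`.
#' @return named list of scalars suitable for JSON/TSV export.
#' @export
condition_summary <- function(report) {
  list(
    label = report$label, covariate = report$covariate,
    n_traces = report$n_traces, n_events = report$n_events,
    k_off = report$k_off,
    k_off_ci_low = report$k_off_ci[1], k_off_ci_high = report$k_off_ci[2],
    fret_peak_low = report$mixture_fit$means[1],
    fret_peak_high = report$mixture_fit$means[2],
    high_fret_fraction = report$high_fret_fraction,
    hmm_mean_low = if (!is.null(report$hmm)) report$hmm$state_means[1] else NA,
    hmm_mean_high = if (!is.null(report$hmm)) report$hmm$state_means[2] else NA,
    tdp_symmetry = report$tdp_symmetry,
    seed = report$seed
  )
}

#' Compare two conditions: rate ratio and stabilization energy
#'
#' ddG = -RT ln(k_alt / k_ref) from the two fitted dissociation rates, with
#' a bootstrap interval on the rate ratio from the paired bootstrap draws of
#' the two dwell fits.
#'
#' @param ref,alt `condition_report` objects.
#' @param temperature_K absolute temperature (default 294.15 K, i.e. 21 C).
#' @return object of class `comparison_report`: reference/alternate labels,
#'   k_ref, k_alt, ratio, ratio_ci, energy (a `stabilization_energy`),
#'   delta_delta_g.
#' @export
compare_conditions <- function(ref, alt, temperature_K = 294.15) {
  if (is.null(ref$k_off) || is.null(alt$k_off)) stop("missing k_off")
  en <- stabilization_energy(ref$k_off, alt$k_off, temperature_K)
  br <- ref$dwell_fit$boot_k
  ba <- alt$dwell_fit$boot_k
  nb <- min(length(br), length(ba))
  ratio_boot <- ba[seq_len(nb)] / br[seq_len(nb)]
  ci <- stats::quantile(ratio_boot, c(0.025, 0.975), na.rm = TRUE,
                        names = FALSE)
  structure(
    list(reference = ref$label, alternate = alt$label,
         k_ref = ref$k_off, k_alt = alt$k_off,
         ratio = alt$k_off / ref$k_off, ratio_ci = ci,
         energy = en, delta_delta_g = en$delta_delta_g,
         temperature_K = temperature_K),
    class = "comparison_report"
  )
}

#' Summarize a simulated titration: kinetics and occupancy trends
#'
#' Processes every level of a titration, fits k_off and the high-FRET area
#' fraction per level, and fits linear trends of both against the covariate.
#'
#' @param titration named list of `smfret_dataset`s from
#'   [simulate_titration()].
#' @param seed seed for the per-level bootstrap.
#' @param n_boot bootstrap resamples per level.
#' @param bin_width histogram bin width.
#' @return list: levels, koff (vector), koff_fits, high_fret (vector),
#'   koff_trend (`linear_fit`), occupancy_trend (`linear_fit`).
#' @export
titration_summary <- function(titration, seed = 1L, n_boot = 200L,
                              bin_width = 0.02) {
  levels <- vapply(titration, function(d) d$covariate %||% NA_real_,
                   numeric(1))
  koff_fits <- vector("list", length(titration))
  hff <- rep(NA_real_, length(titration))
  for (l in seq_along(titration)) {
    proc <- process_dataset(titration[[l]])
    koff_fits[[l]] <- fit_koff_events(
      proc$events, n_boot = n_boot, seed = seed + l,
      frame_interval_s = titration[[l]]$emission$frame_interval_s)
    hist <- build_histogram(proc$hist_values, bin_width = bin_width,
                            n_trajectories = proc$n_traces)
    g <- tryCatch(fit_gaussians(hist, 2L), error = function(e) NULL)
    if (!is.null(g)) hff[l] <- high_fret_fraction(g)
  }
  koff <- vapply(koff_fits, function(f) f$k_off, numeric(1))
  list(
    levels = levels, koff = koff, koff_fits = koff_fits, high_fret = hff,
    koff_trend = koff_vs_covariate(koff_fits, levels),
    occupancy_trend = fit_linear_trend(levels[!is.na(hff)], hff[!is.na(hff)])
  )
}
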