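#!/usr/bin/env Rscript
# Full trace-processing + kinetics pass over both simulated conditions:
# apparent FRET, event segmentation with anti-correlation screening and
# bleach censoring, dwell-time MLE with detection corrections, and the
# relative stabilization energy between conditions. Writes
# results/kinetics.tsv and results/comparison.json.

suppressMessages(library(fretmd))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

configs <- list(
  unmodified = list(
    label = "unmodified", covariate = 0,
    model = list(k_on = 0.25, k_off = 0.22, high_fraction = 0.7,
                 fret_low = 0.6, fret_high = 0.8, fret_sigma = 0.05),
    emission = list(), analysis = list(n_traces = 150)),
  adducted = list(
    label = "adducted", covariate = 0,
    model = list(k_on = 0.25, k_off = 0.42, high_fraction = 0.45,
                 fret_low = 0.5, fret_high = 0.75, fret_sigma = 0.05),
    emission = list(), analysis = list(n_traces = 150))
)

reports <- list()
for (nm in names(configs)) {
  reports[[nm]] <- run_condition(configs[[nm]], seed = seed + match(nm, names(configs)),
                                 out_dir = file.path("results", nm))
}

tab <- do.call(rbind, lapply(reports, function(r) {
  data.frame(condition = r$label, k_off = r$k_off,
             ci_low = r$k_off_ci[1], ci_high = r$k_off_ci[2],
             n_events = r$n_events,
             fret_peak_low = r$mixture_fit$means[1],
             fret_peak_high = r$mixture_fit$means[2],
             high_fret_fraction = r$high_fret_fraction,
             tdp_symmetry = r$tdp_symmetry)
}))
write.table(tab, "results/kinetics.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cmp <- compare_conditions(reports$unmodified, reports$adducted)
jsonlite::write_json(
  list(reference = cmp$reference, alternate = cmp$alternate,
       k_ref = cmp$k_ref, k_alt = cmp$k_alt, ratio = cmp$ratio,
       ratio_ci = cmp$ratio_ci, delta_delta_g_kcal_mol = cmp$delta_delta_g,
       temperature_K = cmp$temperature_K),
  "results/comparison.json", auto_unbox = TRUE, digits = NA)

message(sprintf(
  "k_off %s = %.3f, %s = %.3f s^-1; ratio %.2f; ddG = %+.3f kcal/mol",
  cmp$reference, cmp$k_ref, cmp$alternate, cmp$k_alt, cmp$ratio,
  cmp$delta_delta_g))
message("the adduct condition dissociates faster: a destabilized binary complex")
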