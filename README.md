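# fretmd

Single-molecule FRET binding kinetics of a DNA polymerase on primer-template
DNA, plus the trajectory observables used on the molecular-dynamics side of
such studies — as a tested, ground-truthed R pipeline.

## The problem

A Y-family translesion polymerase (Dpo4-like) binds DNA transiently. In a
camera-based smFRET experiment the DNA carries the donor dye and the
polymerase the acceptor, so binding shows up as simultaneous, anti-correlated
intensity changes at 80 ms frame resolution. The binary complex samples two
conformations — a high-FRET pre-insertion complex and a low-FRET insertion
complex — visible as two peaks in the time-binned histogram of apparent FRET,

&nbsp;&nbsp;&nbsp;&nbsp;E = I_A / (I_D + I_A),

used as a conformational identifier, not a distance. Bound-interval dwell
times are exponential with rate k_off, and the relative stabilization between
two conditions (say, unmodified DNA vs DNA carrying a bulky
benzo[a]pyrene-type adduct, or different co-solvent concentrations) is

&nbsp;&nbsp;&nbsp;&nbsp;ΔΔG = −RT · ln(k_off,alt / k_off,ref),

negative when the alternate condition dissociates faster (destabilization).

`fretmd` provides:

* a **continuous-time Markov simulator** of two-channel donor/acceptor traces
  (Gillespie state paths; camera integration with exact time-weighted frame
  mixing; Gaussian emission and read noise; single-step photobleaching;
  per-trace reproducible seeding) with full ground truth;
* **trace processing**: background subtraction, the 5-point moving average,
  apparent FRET, anti-correlation screening, bleach change-point detection,
  and hysteresis event segmentation with censoring flags;
* **dwell-time kinetics**: censoring-aware exponential MLE with
  detection-dead-time and missed-gap corrections, histogram-fit alternative,
  seeded bootstrap CIs, and ΔΔG;
* **FRET histograms**: time-binned histograms, one/two-Gaussian
  Levenberg–Marquardt fits, high-FRET area fractions, linear covariate
  trends;
* **state inference**: Gaussian-emission HMM (Baum–Welch, multi-restart,
  BIC model choice), Viterbi paths, and transition density plots with a
  reversibility (symmetry) score;
* **MD observables** on frames × atoms × 3 trajectories (multi-model PDB via
  bio3d, or XYZ): Kabsch superposition and RMSD, residue-wise DCCM and
  difference-correlation maps, radial distribution functions, tagged-site
  distances, Cartesian PCA, and toy-trajectory generators with analytic
  expectations.

## Worked example

```r
library(fretmd)

# the unmodified-template condition: k_off = 0.22 s^-1, conformational
# peaks at FRET 0.6/0.8 with the pre-insertion (high-FRET) state dominant
cfg <- list(label = "unmodified",
            model = list(k_on = 0.25, k_off = 0.22, high_fraction = 0.7,
                         fret_low = 0.6, fret_high = 0.8, fret_sigma = 0.05),
            emission = list(), analysis = list(n_traces = 150))
rep <- run_condition(cfg, seed = 11)
condition_summary(rep)
```

With seed 11 this prints (abridged):

```
$k_off               0.2165602     # s^-1; generating value 0.22
$fret_peak_low       0.600022      # fitted Gaussian peak positions
$fret_peak_high      0.7975684
$high_fret_fraction  0.7146351     # area fraction of the upper peak
$tdp_symmetry        0.991371      # reversible conformational shuttling
$n_events            675
```

i.e. the pipeline re-derives the dissociation rate to within a few percent,
places both conformational peaks within ±0.005 FRET, and finds the
transition density plot symmetric — reversible shuttling between the two
binding conformations. Comparing against a second condition with a doubled
exit rate:

```r
cfg2 <- cfg; cfg2$label <- "adducted"; cfg2$model$k_off <- 0.42
rep2 <- run_condition(cfg2, seed = 12)
compare_conditions(rep, rep2)$delta_delta_g   # -0.376 kcal/mol
```

The negative sign reads: the faster-dissociating condition destabilizes the
binary complex by ~0.4 kcal/mol at 294.15 K.

## Analysis scripts

`analysis/` holds numbered drivers that run the full study end to end and
write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | simulate both study conditions, write traces + ground truth |
| `02_binding_kinetics.R` | events → dwell MLE → ΔΔG between conditions |
| `03_dmso_titration.R` | 4-level co-solvent titration, linear trend recovery |
| `04_state_inference_tdp.R` | BIC state choice, HMM fits, TDPs and symmetry |
| `05_md_observables.R` | RMSD screen, difference correlation, RDF, site distances, PCA |

Each takes an optional seed argument: `Rscript analysis/02_binding_kinetics.R 1`.

## Documentation

The methods vignette (`vignettes/smfret-binding-dynamics.Rmd`) describes the
generative model and its defaults, the detection-physics corrections in the
kinetics estimator, the numerical choices in every stage, and what the
synthetic-data tests do and do not establish about real traces.
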