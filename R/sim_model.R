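#' Continuous-time Markov binding model
#'
#' Defines the state space of a polymerase--DNA binding/conformational model:
#' one unbound state plus one or more bound conformations, each with an
#' apparent FRET emission mean and spread, connected by first-order rates.
#'
#' @param rate_matrix square numeric matrix of transition rates in s^-1;
#'   off-diagonal entries are rates between states, the diagonal is set to
#'   minus the row sum (any supplied diagonal is overwritten).
#' @param fret_mean named or positional numeric vector of per-state apparent
#'   FRET means in (0, 1]; the unbound state must be `NA`.
#' @param fret_sigma per-state FRET emission standard deviation (same length
#'   as `fret_mean`; value at the unbound state is ignored).
#' @param unbound name or index of the unbound state.
#' @param state_names character vector of state labels; defaults to the
#'   rownames of `rate_matrix` or `S1..Sn`.
#' @return an object of class `sim_state_model`.
#' @export
binding_model <- function(rate_matrix, fret_mean, fret_sigma,
                          unbound = 1L, state_names = NULL) {
  rate_matrix <- as.matrix(rate_matrix)
  n <- nrow(rate_matrix)
  if (ncol(rate_matrix) != n) stop("rate_matrix must be square")
  if (is.null(state_names)) {
    state_names <- rownames(rate_matrix)
    if (is.null(state_names)) state_names <- paste0("S", seq_len(n))
  }
  if (length(state_names) != n) stop("state_names length must match rate_matrix")
  if (is.character(unbound)) unbound <- match(unbound, state_names)
  unbound <- as.integer(unbound)
  if (is.na(unbound) || unbound < 1L || unbound > n) {
    stop("unbound state not found")
  }
  off <- rate_matrix
  diag(off) <- 0
  if (any(!is.finite(off))) stop("rates must be finite")
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  diag(rate_matrix) <- 0
  diag(rate_matrix) <- -rowSums(rate_matrix)
  fret_mean <- as.numeric(fret_mean)
  fret_sigma <- as.numeric(fret_sigma)
  if (length(fret_mean) != n || length(fret_sigma) != n) {
    stop("fret_mean and fret_sigma must have one entry per state")
  }
  bound <- setdiff(seq_len(n), unbound)
  if (any(is.na(fret_mean[bound])) ||
      any(fret_mean[bound] <= 0) || any(fret_mean[bound] > 1)) {
    stop("bound-state fret_mean must lie in (0, 1]")
  }
  if (any(fret_sigma[bound] < 0, na.rm = TRUE)) stop("fret_sigma must be >= 0")
  dimnames(rate_matrix) <- list(state_names, state_names)
  structure(
    list(state_names = state_names, unbound = unbound,
         fret_mean = fret_mean, fret_sigma = fret_sigma,
         rate_matrix = rate_matrix),
    class = "sim_state_model"
  )
}

#' @export
print.sim_state_model <- function(x, ...) {
  cat("CTMC binding model:", length(x$state_names), "states (unbound:",
      x$state_names[x$unbound], ")\n")
  cat("FRET means:", paste(format(x$fret_mean, digits = 3), collapse = " "), "\n")
  print(x$rate_matrix)
  invisible(x)
}

#' Two-conformation polymerase binding model
#'
#' Convenience constructor for the canonical three-state chain
#' unbound (U) <-> {low-FRET insertion-type (L), high-FRET pre-insertion-type
#' (H)} used throughout the pipeline. Both bound conformations share the
#' dissociation rate `k_off`, so the total bound dwell time is exactly
#' exponential with rate `k_off` irrespective of conformational shuttling,
#' and the conditional occupancy of the high-FRET state equals
#' `high_fraction` at stationarity (entry split and shuttling equilibrium
#' are both set to it).
#'
#' @param k_on binding rate from the unbound state, s^-1.
#' @param k_off dissociation rate of each bound conformation, s^-1.
#' @param high_fraction stationary fraction of bound time spent in the
#'   high-FRET conformation, in [0, 1].
#' @param k_shuttle total conformational exchange rate scale between the two
#'   bound states, s^-1.
#' @param fret_low,fret_high apparent FRET means of the two conformations.
#' @param fret_sigma shared emission spread of both conformations.
#' @return a `sim_state_model` with states `U`, `L`, `H`.
#' @export
polymerase_binding_model <- function(k_on = 0.25, k_off = 0.22,
                                     high_fraction = 0.7, k_shuttle = 1.0,
                                     fret_low = 0.6, fret_high = 0.8,
                                     fret_sigma = 0.05) {
  if (k_on <= 0 || k_off <= 0) stop("k_on and k_off must be > 0")
  if (high_fraction < 0 || high_fraction > 1) {
    stop("high_fraction must be in [0, 1]")
  }
  w <- high_fraction
  rates <- matrix(0, 3, 3,
                  dimnames = list(c("U", "L", "H"), c("U", "L", "H")))
  rates["U", "L"] <- k_on * (1 - w)
  rates["U", "H"] <- k_on * w
  rates["L", "H"] <- k_shuttle * w
  rates["H", "L"] <- k_shuttle * (1 - w)
  rates["L", "U"] <- k_off
  rates["H", "U"] <- k_off
  binding_model(rates,
                fret_mean = c(NA, fret_low, fret_high),
                fret_sigma = c(NA, fret_sigma, fret_sigma),
                unbound = "U")
}

#' Camera emission configuration
#'
#' Photophysical and camera parameters used to render a state path into a
#' two-channel intensity trace. Defaults emulate a prism-TIRF measurement at
#' 80 ms frames with signal-to-noise comparable to typical polymerase
#' binding traces.
#'
#' @param frame_interval_s camera frame interval, seconds.
#' @param total_intensity total photons (arbitrary units) emitted by the
#'   donor/acceptor pair per frame before the energy-transfer split.
#' @param background_donor,background_acceptor additive channel offsets.
#' @param noise_sd Gaussian read noise per channel, same units as intensity.
#' @param bleach_rate_s single-step donor photobleach rate, s^-1 (0 = never).
#' @param trace_length_frames frames per trace.
#' @return an object of class `emission_config`.
#' @export
emission_config <- function(frame_interval_s = 0.08, total_intensity = 1000,
                            background_donor = 50, background_acceptor = 50,
                            noise_sd = 30, bleach_rate_s = 0.01,
                            trace_length_frames = 600) {
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (bleach_rate_s < 0) stop("bleach_rate_s must be >= 0")
  if (trace_length_frames < 1) stop("trace_length_frames must be >= 1")
  structure(
    list(frame_interval_s = frame_interval_s,
         total_intensity = total_intensity,
         background_donor = background_donor,
         background_acceptor = background_acceptor,
         noise_sd = noise_sd, bleach_rate_s = bleach_rate_s,
         trace_length_frames = as.integer(trace_length_frames)),
    class = "emission_config"
  )
}

#' Solvent titration design
#'
#' Programs linear dependences of the dissociation rate and of the high-FRET
#' stationary occupancy on a covariate (e.g. percent DMSO), mirroring a
#' titration experiment in which added co-solvent slows dissociation and
#' depletes the high-FRET conformation.
#'
#' @param covariate_levels numeric covariate values (e.g. DMSO volume
#'   fractions in percent).
#' @param koff_slope,koff_intercept linear model `k_off = intercept +
#'   slope * covariate` applied to both bound states' exit rates, s^-1.
#' @param occupancy_slope,occupancy_intercept linear model for the
#'   stationary high-FRET weight among bound states, dimensionless.
#' @return an object of class `titration_design`.
#' @export
titration_design <- function(covariate_levels, koff_slope, koff_intercept,
                             occupancy_slope, occupancy_intercept) {
  covariate_levels <- as.numeric(covariate_levels)
  if (length(covariate_levels) < 1) stop("need at least one covariate level")
  koff <- koff_intercept + koff_slope * covariate_levels
  occ <- occupancy_intercept + occupancy_slope * covariate_levels
  if (any(koff <= 0)) stop("programmed k_off must be > 0 at every level")
  if (any(occ < 0 | occ > 1)) {
    stop("programmed occupancy must be in [0, 1] at every level")
  }
  structure(
    list(covariate_levels = covariate_levels,
         koff_slope = koff_slope, koff_intercept = koff_intercept,
         occupancy_slope = occupancy_slope,
         occupancy_intercept = occupancy_intercept),
    class = "titration_design"
  )
}

#' Instantiate the binding model at one titration level
#'
#' @param design a [titration_design()].
#' @param base_model a `sim_state_model` from [polymerase_binding_model()]
#'   providing k_on, shuttle scale, and FRET emission parameters.
#' @param level one covariate value from the design.
#' @return a `sim_state_model` with the programmed k_off and occupancy.
#' @export
model_at_level <- function(design, base_model, level) {
  stopifnot(inherits(design, "titration_design"),
            inherits(base_model, "sim_state_model"))
  koff <- design$koff_intercept + design$koff_slope * level
  occ <- design$occupancy_intercept + design$occupancy_slope * level
  if (koff <= 0) stop("programmed k_off <= 0 at level ", level)
  if (occ < 0 || occ > 1) stop("programmed occupancy outside [0,1] at level ", level)
  rm0 <- base_model$rate_matrix
  u <- base_model$unbound
  il <- match("L", base_model$state_names)
  ih <- match("H", base_model$state_names)
  if (is.na(il) || is.na(ih)) {
    stop("base_model must have states L and H (see polymerase_binding_model)")
  }
  k_on <- -rm0[u, u]
  k_shuttle <- rm0[il, ih] + rm0[ih, il]
  polymerase_binding_model(
    k_on = k_on, k_off = koff, high_fraction = occ, k_shuttle = k_shuttle,
    fret_low = base_model$fret_mean[il],
    fret_high = base_model$fret_mean[ih],
    fret_sigma = base_model$fret_sigma[il]
  )
}

#' Stationary distribution of a CTMC model
#'
#' Solves pi Q = 0, sum(pi) = 1 for the model's rate matrix.
#'
#' @param model a `sim_state_model`.
#' @return named numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(model) {
  q <- model$rate_matrix
  n <- nrow(q)
  a <- rbind(t(q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(a, b)
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  names(pi) <- model$state_names
  pi
}

# Deterministic per-trace seed schedule: trace i's sub-seed depends only on
# (master seed, i), never on n_traces. Kept below 2^31.
trace_seed <- function(seed, i) {
  s0 <- as.numeric(seed) %% 1000003
  as.integer((s0 * 1103515 + as.numeric(i) * 7919 + 12345) %% 2147483646) + 1L
}
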