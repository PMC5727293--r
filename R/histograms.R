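#' Time-binned FRET histogram
#'
#' Builds the frame-weighted histogram of bound-frame FRET values: every
#' bound frame contributes one count, so long events carry more weight than
#' short ones (time-binned, not molecule-weighted).
#'
#' @param fret_values numeric vector of per-frame FRET values, typically
#'   from [bound_fret_values()] pooled over >100 trajectories.
#' @param bin_width histogram bin width in FRET units (default 0.02).
#' @param limits histogram range (default c(-0.1, 1.1)); values outside are
#'   dropped.
#' @param n_trajectories number of trajectories that contributed (metadata).
#' @return object of class `fret_histogram`: bin_edges, bin_centers, counts,
#'   n_frames, n_trajectories.
#' @export
build_histogram <- function(fret_values, bin_width = 0.02,
                            limits = c(-0.1, 1.1), n_trajectories = NA_integer_) {
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  x <- fret_values[!is.na(fret_values)]
  x <- x[x >= limits[1] & x <= limits[2]]
  if (length(x) < 1L) stop("no frames to histogram")
  edges <- seq(limits[1], limits[2] + bin_width / 2, by = bin_width)
  idx <- pmin(findInterval(x, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(
    list(bin_edges = edges,
         bin_centers = edges[-length(edges)] + bin_width / 2,
         counts = counts, n_frames = length(x),
         n_trajectories = n_trajectories),
    class = "fret_histogram"
  )
}

#' Fit one or two Gaussian components to a FRET histogram
#'
#' Nonlinear least squares of the binned counts against a sum of one or two
#' Gaussian curves (Levenberg-Marquardt), with multiple starts seeded from
#' data quantiles. Component weights are reported as area fractions
#' (amplitude x sigma, normalized), the convention behind "relative fraction
#' area" readouts. Sigmas are unconstrained and components are sorted by
#' ascending mean.
#'
#' @param hist a `fret_histogram`.
#' @param n_components 1 or 2.
#' @return object of class `gaussian_mixture_fit`: n_components, means,
#'   sigmas, weights (area fractions), amplitudes, residual_norm, converged,
#'   covariance (parameter covariance of the NLS fit, or NULL).
#' @export
fit_gaussians <- function(hist, n_components) {
  stopifnot(inherits(hist, "fret_histogram"))
  if (!n_components %in% c(1L, 2L)) stop("n_components must be 1 or 2")
  x <- hist$bin_centers
  y <- hist$counts
  nz <- sum(y > 0)
  n_par <- 3L * n_components
  if (nz <= n_par) stop("too few nonzero bins to fit ", n_par, " parameters")
  mu0 <- sum(x * y) / sum(y)
  sd0 <- sqrt(pmax(sum((x - mu0)^2 * y) / sum(y), 1e-6))
  q <- .weighted_quantile(x, y, c(0.25, 0.5, 0.75))
  starts <- list()
  if (n_components == 1L) {
    starts[[1]] <- c(a1 = max(y), m1 = mu0, s1 = sd0)
    starts[[2]] <- c(a1 = max(y), m1 = q[2], s1 = sd0 / 2)
  } else {
    starts[[1]] <- c(a1 = max(y), m1 = q[1], s1 = sd0 / 2,
                     a2 = max(y), m2 = q[3], s2 = sd0 / 2)
    starts[[2]] <- c(a1 = max(y), m1 = mu0 - sd0, s1 = sd0 / 2,
                     a2 = max(y), m2 = mu0 + sd0, s2 = sd0 / 2)
    starts[[3]] <- c(a1 = max(y) / 2, m1 = q[2], s1 = sd0,
                     a2 = max(y), m2 = q[3], s2 = sd0 / 3)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch({
      if (n_components == 1L) {
        minpack.lm::nlsLM(
          y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)),
          start = as.list(st), data = data.frame(x = x, y = y),
          lower = c(0, min(x), 1e-4),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
            a2 * exp(-(x - m2)^2 / (2 * s2^2)),
          start = as.list(st), data = data.frame(x = x, y = y),
          lower = c(0, min(x), 1e-4, 0, min(x), 1e-4),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::resid(fit)^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) {
    stop("Gaussian fit failed to converge from all starts")
  }
  cf <- stats::coef(best$fit)
  if (n_components == 1L) {
    means <- cf[["m1"]]; sigmas <- cf[["s1"]]; amps <- cf[["a1"]]
  } else {
    means <- c(cf[["m1"]], cf[["m2"]])
    sigmas <- c(cf[["s1"]], cf[["s2"]])
    amps <- c(cf[["a1"]], cf[["a2"]])
  }
  ord <- order(means)
  means <- means[ord]; sigmas <- sigmas[ord]; amps <- amps[ord]
  areas <- amps * sigmas          # Gaussian area up to the common sqrt(2*pi)
  weights <- if (sum(areas) > 0) areas / sum(areas) else
    rep(1 / n_components, n_components)
  covar <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  structure(
    list(n_components = n_components, means = means, sigmas = sigmas,
         weights = weights, amplitudes = amps,
         residual_norm = best$rn,
         converged = isTRUE(best$fit$convInfo$isConv) ||
           is.null(best$fit$convInfo),
         covariance = covar),
    class = "gaussian_mixture_fit"
  )
}

.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  sapply(probs, function(p) x[o][which(cw >= p)[1]])
}

#' Evaluate a fitted Gaussian mixture on a grid
#'
#' @param fit a `gaussian_mixture_fit`.
#' @param x numeric grid.
#' @return fitted curve values (counts scale).
#' @export
mixture_curve <- function(fit, x) {
  y <- 0
  for (i in seq_len(fit$n_components)) {
    y <- y + fit$amplitudes[i] *
      exp(-(x - fit$means[i])^2 / (2 * fit$sigmas[i]^2))
  }
  y
}

#' Area fraction of the high-FRET component
#'
#' The "relative fraction area of the high FRET state": the area weight of
#' the higher-mean component of a two-Gaussian fit.
#'
#' @param fit a `gaussian_mixture_fit` with n_components = 2.
#' @return scalar fraction in [0, 1].
#' @export
high_fret_fraction <- function(fit) {
  stopifnot(inherits(fit, "gaussian_mixture_fit"))
  if (fit$n_components != 2L) {
    stop("high-FRET fraction requires a two-component fit")
  }
  fit$weights[2]    # components are sorted by ascending mean
}

#' Weighted linear trend fit
#'
#' Ordinary or weighted least squares of y on x (slope, intercept, standard
#' errors, r-squared), as used for trends of k_off and of the high-FRET
#' fraction against the solvent covariate.
#'
#' @param x covariate levels (>= 2 distinct values).
#' @param y response values.
#' @param y_err optional standard errors of y; weights 1/y_err^2.
#' @return object of class `linear_fit`: slope, intercept, slope_se,
#'   intercept_se, r_squared, n.
#' @export
fit_linear_trend <- function(x, y, y_err = NULL) {
  if (length(unique(x)) < 2L) stop("need at least 2 distinct x values")
  if (length(x) != length(y)) stop("x and y lengths differ")
  w <- if (is.null(y_err)) NULL else {
    if (any(y_err <= 0)) stop("y_err must be > 0")
    1 / y_err^2
  }
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  # exact-line inputs trigger lm's "essentially perfect fit" note
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  slope_se <- if (nrow(co) >= 2L && ncol(co) >= 2L) co["x", "Std. Error"]
    else NA_real_
  structure(
    list(slope = unname(stats::coef(fit)["x"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         slope_se = unname(slope_se),
         intercept_se = unname(co["(Intercept)", "Std. Error"]),
         r_squared = sm$r.squared, n = length(x)),
    class = "linear_fit"
  )
}
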