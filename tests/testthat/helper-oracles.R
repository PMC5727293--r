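# Independent brute-force oracles used across the suite. These deliberately
# use naive scalar loops / exhaustive enumeration, never the package's own
# code paths.

naive_moving_average <- function(x, w) {
  h <- w %/% 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    out[i] <- mean(x[lo:hi])
  }
  out
}

naive_fret <- function(d, a) {
  n <- length(d)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (d[i] + a[i] > 0) out[i] <- a[i] / (d[i] + a[i])
  }
  out
}

naive_histogram <- function(x, edges) {
  counts <- integer(length(edges) - 1)
  for (v in x) {
    for (b in seq_len(length(edges) - 1)) {
      hi_ok <- if (b == length(edges) - 1) v <= edges[b + 1] else v < edges[b + 1]
      if (v >= edges[b] && hi_ok) {
        counts[b] <- counts[b] + 1L
        break
      }
    }
  }
  counts
}

# closed-form simple linear regression via normal equations
naive_linfit <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

naive_rmsd <- function(p, q) {
  s <- 0
  for (i in seq_len(nrow(p))) {
    s <- s + sum((p[i, ] - q[i, ])^2)
  }
  sqrt(s / nrow(p))
}

# exhaustive path-sum likelihood of a Gaussian-emission HMM
enum_forward_loglik <- function(model, seg) {
  n <- model$n_states
  tt <- length(seg)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), tt)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- model$initial_probs[s[1]] *
      stats::dnorm(seg[1], model$state_means[s[1]], model$state_sigmas[s[1]])
    if (tt > 1) {
      for (t in 2:tt) {
        p <- p * model$transition_probs[s[t - 1], s[t]] *
          stats::dnorm(seg[t], model$state_means[s[t]],
                       model$state_sigmas[s[t]])
      }
    }
    total <- total + p
  }
  log(total)
}

# exhaustive most-probable path log-probability
enum_viterbi_logprob <- function(model, seg) {
  n <- model$n_states
  tt <- length(seg)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), tt)))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(model$initial_probs[s[1]]) +
      stats::dnorm(seg[1], model$state_means[s[1]], model$state_sigmas[s[1]],
                   log = TRUE)
    if (tt > 1) {
      for (t in 2:tt) {
        lp <- lp + log(model$transition_probs[s[t - 1], s[t]]) +
          stats::dnorm(seg[t], model$state_means[s[t]],
                       model$state_sigmas[s[t]], log = TRUE)
      }
    }
    best <- max(best, lp)
  }
  best
}

# hand-built HMM model object for oracle tests
make_hmm <- function(means, sigmas, a, p0) {
  structure(
    list(n_states = length(means), state_means = means,
         state_sigmas = sigmas, transition_probs = a, initial_probs = p0,
         log_likelihood = NA_real_, bic = NA_real_, converged = TRUE,
         n_frames = NA_integer_),
    class = "hmm_model"
  )
}

# hand-built state_path from a state id vector
make_state_path <- function(states, means, trace_id = "p") {
  ch <- which(diff(states) != 0L)
  structure(
    list(trace_id = trace_id, states = states, fret_means = means[states],
         transitions = data.frame(frame = ch + 1L, from_state = states[ch],
                                  to_state = states[ch + 1L]),
         log_prob = NA_real_),
    class = "state_path"
  )
}

# simple unbound <-> single-bound-conformation chain
two_state_model <- function(k_on = 0.25, k_off = 0.22, fret = 0.7,
                            sigma = 0.05) {
  rates <- matrix(c(0, k_on, k_off, 0), 2, 2, byrow = TRUE,
                  dimnames = list(c("U", "B"), c("U", "B")))
  binding_model(rates, fret_mean = c(NA, fret), fret_sigma = c(NA, sigma),
                unbound = "U")
}

# ground truth with a single hand-specified bound interval (state 2)
manual_truth <- function(intervals, duration, bleach = NA_real_) {
  stopifnot(is.matrix(intervals))
  rows <- list()
  t <- 0
  for (i in seq_len(nrow(intervals))) {
    a <- intervals[i, 1]; b <- intervals[i, 2]
    if (a > t) rows[[length(rows) + 1L]] <- c(t, a, 1)
    rows[[length(rows) + 1L]] <- c(a, b, 2)
    t <- b
  }
  if (t < duration) rows[[length(rows) + 1L]] <- c(t, duration, 1)
  m <- do.call(rbind, rows)
  structure(
    list(events = data.frame(start_s = m[, 1], end_s = m[, 2],
                             state = as.integer(m[, 3]),
                             state_name = c("U", "B")[m[, 3]]),
         bleach_time_s = bleach, duration_s = duration, seed = 0L),
    class = "ground_truth"
  )
}
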