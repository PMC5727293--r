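#' Fit a Gaussian-emission hidden Markov model to FRET segments
#'
#' Baum-Welch maximum-likelihood fit of an n-state HMM with Gaussian
#' emissions on bound-interval FRET segments (each segment is an independent
#' observation sequence; unbound frames are excluded upstream). Multiple
#' random restarts guard against local optima; the best log-likelihood is
#' kept. State labels are canonicalized by ascending emission mean so
#' repeated runs report identical labels.
#'
#' @param fret_segments list of numeric vectors (or a single vector) of
#'   per-frame FRET values; NA frames are allowed and contribute no
#'   emission term.
#' @param n_states number of hidden states.
#' @param seed integer seed controlling the restarts (deterministic fit).
#' @param n_restarts random restarts (default 10).
#' @param max_iter maximum Baum-Welch iterations per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @return object of class `hmm_model`: n_states, state_means, state_sigmas,
#'   transition_probs (per-frame stochastic matrix), initial_probs,
#'   log_likelihood, bic, converged, n_frames.
#' @export
fit_hmm <- function(fret_segments, n_states, seed = 1L, n_restarts = 10L,
                    max_iter = 500L, tol = 1e-6) {
  if (is.numeric(fret_segments)) fret_segments <- list(fret_segments)
  segs <- Filter(function(s) sum(!is.na(s)) > 0, fret_segments)
  if (length(segs) == 0L) stop("no observed frames")
  obs <- unlist(segs)
  obs <- obs[!is.na(obs)]
  n_frames <- length(obs)
  p_free <- n_states^2 + 2L * n_states - 1L
  if (n_frames < 10L * p_free) {
    stop("need at least 10 frames per free parameter (",
         10L * p_free, " for n_states = ", n_states, ")")
  }
  s_all <- stats::sd(obs)
  if (n_states > 1L && (is.na(s_all) || s_all == 0)) {
    stop("degenerate data: zero variance")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  qs <- stats::quantile(obs, probs = (seq_len(n_states) - 0.5) / n_states,
                        names = FALSE)
  for (r in seq_len(n_restarts)) {
    mu <- if (r == 1L) qs else qs + stats::rnorm(n_states, 0, max(s_all, 0.01))
    sig <- rep(max(s_all / sqrt(n_states), 1e-3), n_states)
    a <- matrix(0.1 / max(n_states - 1L, 1L), n_states, n_states)
    diag(a) <- if (n_states > 1L) 0.9 else 1.0
    p0 <- rep(1 / n_states, n_states)
    fit <- .baum_welch(segs, mu, sig, a, p0, max_iter, tol)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  ord <- order(best$mu)
  model <- structure(
    list(n_states = n_states,
         state_means = best$mu[ord], state_sigmas = best$sigma[ord],
         transition_probs = best$a[ord, ord, drop = FALSE],
         initial_probs = best$p0[ord],
         log_likelihood = best$log_likelihood,
         bic = -2 * best$log_likelihood + p_free * log(n_frames),
         converged = best$converged, n_frames = n_frames),
    class = "hmm_model"
  )
  model
}

# emission densities with NA -> 1 (frame carries no information)
.emis <- function(x, mu, sig) {
  n <- length(mu)
  b <- matrix(1, length(x), n)
  ok <- !is.na(x)
  for (j in seq_len(n)) b[ok, j] <- stats::dnorm(x[ok], mu[j], sig[j])
  pmax(b, 1e-300)
}

.baum_welch <- function(segs, mu, sig, a, p0, max_iter, tol) {
  n <- length(mu)
  ll_old <- -Inf
  converged <- FALSE
  sig_floor <- 1e-4
  for (it in seq_len(max_iter)) {
    ll <- 0
    tr_num <- matrix(0, n, n)
    g_w <- numeric(n)          # sum of gammas
    g_wx <- numeric(n)         # sum gamma * x
    g_wx2 <- numeric(n)        # sum gamma * x^2
    p0_num <- numeric(n)
    for (s in segs) {
      b <- .emis(s, mu, sig)
      fb <- .forward_backward(b, a, p0)
      ll <- ll + fb$loglik
      g <- fb$gamma
      ok <- !is.na(s)
      g_w <- g_w + colSums(g[ok, , drop = FALSE])
      g_wx <- g_wx + colSums(g[ok, , drop = FALSE] * s[ok])
      g_wx2 <- g_wx2 + colSums(g[ok, , drop = FALSE] * s[ok]^2)
      tr_num <- tr_num + fb$xi_sum
      p0_num <- p0_num + g[1, ]
    }
    mu_new <- ifelse(g_w > 0, g_wx / pmax(g_w, 1e-300), mu)
    var_new <- g_wx2 / pmax(g_w, 1e-300) - mu_new^2
    sig_new <- sqrt(pmax(var_new, sig_floor^2))
    rs <- rowSums(tr_num)
    a_new <- a
    pos <- rs > 0
    a_new[pos, ] <- tr_num[pos, , drop = FALSE] / rs[pos]
    p0_new <- p0_num / sum(p0_num)
    mu <- mu_new; sig <- sig_new; a <- a_new; p0 <- p0_new
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sig, a = a, p0 = p0, log_likelihood = ll_old,
       converged = converged)
}

# scaled forward-backward; b = T x n emission matrix
.forward_backward <- function(b, a, p0) {
  tt <- nrow(b); n <- ncol(b)
  alpha <- matrix(0, tt, n)
  beta <- matrix(0, tt, n)
  cvec <- numeric(tt)
  alpha[1, ] <- p0 * b[1, ]
  cvec[1] <- sum(alpha[1, ])
  alpha[1, ] <- alpha[1, ] / cvec[1]
  if (tt > 1L) {
    for (t in 2:tt) {
      v <- (alpha[t - 1L, ] %*% a) * b[t, ]
      cvec[t] <- sum(v)
      alpha[t, ] <- v / cvec[t]
    }
  }
  beta[tt, ] <- 1
  if (tt > 1L) {
    for (t in (tt - 1L):1L) {
      beta[t, ] <- (a %*% (b[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, n, n)
  if (tt > 1L) {
    for (t in 1:(tt - 1L)) {
      m <- (alpha[t, ] %o% (b[t + 1L, ] * beta[t + 1L, ])) * a / cvec[t + 1L]
      xi_sum <- xi_sum + m
    }
  }
  list(loglik = sum(log(cvec)), gamma = gamma, xi_sum = xi_sum)
}

#' Forward-algorithm log-likelihood of one FRET segment
#'
#' @param model an `hmm_model`.
#' @param fret_segment numeric vector (NA frames carry no emission term).
#' @return scalar log-likelihood.
#' @export
forward_loglik <- function(model, fret_segment) {
  b <- .emis(fret_segment, model$state_means, model$state_sigmas)
  .forward_backward(b, model$transition_probs, model$initial_probs)$loglik
}

#' Select the number of HMM states by BIC
#'
#' Fits 1..max_states and returns the n with the lowest BIC; candidate n
#' with fewer than 10 frames per free parameter are skipped.
#'
#' @param fret_segments as in [fit_hmm()].
#' @param max_states largest model to consider.
#' @param seed seed passed through to each fit.
#' @param ... further arguments for [fit_hmm()].
#' @return integer selected number of states; attribute `bic` holds the
#'   per-n BIC values (NA where skipped).
#' @export
select_n_states <- function(fret_segments, max_states, seed = 1L, ...) {
  if (max_states < 1L) stop("max_states must be >= 1")
  bics <- rep(NA_real_, max_states)
  for (k in seq_len(max_states)) {
    fit <- tryCatch(fit_hmm(fret_segments, k, seed = seed, ...),
                    error = function(e) NULL)
    if (!is.null(fit)) bics[k] <- fit$bic
  }
  if (all(is.na(bics))) stop("no candidate model could be fit")
  structure(which.min(bics), bic = bics)
}

#' Viterbi state path of a FRET segment
#'
#' Most-probable hidden state sequence under a fitted model. Frames with
#' undefined FRET are bridged: they contribute no emission term, so the
#' path through them is decided by the transition structure alone.
#'
#' @param model an `hmm_model`.
#' @param fret_segment numeric vector of per-frame FRET.
#' @param trace_id identifier carried on the path.
#' @return object of class `state_path`: trace_id, states (1-based ids),
#'   fret_means (per-frame assigned state mean), transitions (data.frame:
#'   frame, from_state, to_state), log_prob.
#' @export
viterbi_path <- function(model, fret_segment, trace_id = "segment") {
  b <- log(.emis(fret_segment, model$state_means, model$state_sigmas))
  la <- log(pmax(model$transition_probs, 1e-300))
  lp0 <- log(pmax(model$initial_probs, 1e-300))
  tt <- nrow(b); n <- ncol(b)
  delta <- matrix(-Inf, tt, n)
  psi <- matrix(0L, tt, n)
  delta[1, ] <- lp0 + b[1, ]
  if (tt > 1L) {
    for (t in 2:tt) {
      for (j in seq_len(n)) {
        v <- delta[t - 1L, ] + la[, j]
        psi[t, j] <- which.max(v)
        delta[t, j] <- v[psi[t, j]] + b[t, j]
      }
    }
  }
  states <- integer(tt)
  states[tt] <- which.max(delta[tt, ])
  if (tt > 1L) {
    for (t in (tt - 1L):1L) states[t] <- psi[t + 1L, states[t + 1L]]
  }
  ch <- which(diff(states) != 0L)
  transitions <- data.frame(
    frame = ch + 1L, from_state = states[ch], to_state = states[ch + 1L]
  )
  structure(
    list(trace_id = trace_id, states = states,
         fret_means = model$state_means[states],
         transitions = transitions,
         log_prob = max(delta[tt, ])),
    class = "state_path"
  )
}

#' Serialize a fitted HMM to JSON
#'
#' @param model an `hmm_model`.
#' @param path output file.
#' @export
write_hmm_json <- function(model, path) {
  jsonlite::write_json(
    list(n_states = model$n_states, state_means = model$state_means,
         state_sigmas = model$state_sigmas,
         transition_probs = model$transition_probs,
         initial_probs = model$initial_probs,
         log_likelihood = model$log_likelihood, bic = model$bic,
         converged = model$converged, n_frames = model$n_frames),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Write Viterbi state paths as TSV
#'
#' One row per frame: trace_id, frame, state, assigned state mean.
#'
#' @param paths list of `state_path` objects.
#' @param path output file.
#' @export
write_state_paths_tsv <- function(paths, path) {
  rows <- lapply(paths, function(p) {
    data.frame(trace_id = p$trace_id, frame = seq_along(p$states),
               state = p$states, mean_fret = signif(p$fret_means, 6))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
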