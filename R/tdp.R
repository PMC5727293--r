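#' Build a transition density plot
#'
#' 2-D histogram of (FRET before, FRET after) over all Viterbi transitions
#' from a collection of state paths. Coordinates use the fitted state means
#' (idealized TDP, robust to frame noise); set `use_raw = TRUE` with
#' per-path raw FRET to place transitions at the observed values instead.
#' Diagonal cells are empty by construction: a transition changes state.
#'
#' @param paths list of `state_path` objects (see [viterbi_path()]).
#' @param model the `hmm_model` the paths were decoded under.
#' @param bin_width grid bin width in FRET units (default 0.02).
#' @param limits grid range.
#' @param use_raw if TRUE, `raw_segments` must give each path's raw FRET
#'   vector; transitions are placed at the raw FRET of the frames flanking
#'   the change point.
#' @param raw_segments list of numeric vectors parallel to `paths`.
#' @return object of class `transition_density`: counts (matrix, rows =
#'   before-bin), bin_edges, bin_centers, n_transitions.
#' @export
build_tdp <- function(paths, model, bin_width = 0.02, limits = c(-0.1, 1.1),
                      use_raw = FALSE, raw_segments = NULL) {
  if (length(paths) == 0L) stop("paths must be nonempty")
  before <- numeric(0); after <- numeric(0)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    tr <- p$transitions
    if (nrow(tr) == 0L) next
    if (use_raw) {
      seg <- raw_segments[[i]]
      before <- c(before, seg[tr$frame - 1L])
      after <- c(after, seg[tr$frame])
    } else {
      before <- c(before, model$state_means[tr$from_state])
      after <- c(after, model$state_means[tr$to_state])
    }
  }
  edges <- seq(limits[1], limits[2] + bin_width / 2, by = bin_width)
  nb <- length(edges) - 1L
  counts <- matrix(0L, nb, nb)
  if (length(before) > 0L) {
    ib <- pmin(pmax(findInterval(before, edges, rightmost.closed = TRUE), 1L), nb)
    ia <- pmin(pmax(findInterval(after, edges, rightmost.closed = TRUE), 1L), nb)
    for (k in seq_along(ib)) {
      counts[ib[k], ia[k]] <- counts[ib[k], ia[k]] + 1L
    }
  }
  structure(
    list(counts = counts, bin_edges = edges,
         bin_centers = edges[-length(edges)] + bin_width / 2,
         n_transitions = length(before)),
    class = "transition_density"
  )
}

#' Symmetry score of a transition density plot
#'
#' 1 - sum|c_ij - c_ji| / sum(c_ij + c_ji) over unordered cell pairs
#' (i < j). A reversible (detailed-balance) system gives a score near 1:
#' every forward transition is matched by a reverse one. Strictly
#' one-directional counts give 0.
#'
#' @param tdp a `transition_density` with at least one transition.
#' @return scalar in [0, 1].
#' @export
symmetry_score <- function(tdp) {
  stopifnot(inherits(tdp, "transition_density"))
  if (tdp$n_transitions < 1L) stop("empty TDP")
  cts <- tdp$counts
  asym <- sum(abs(cts - t(cts))) / 2          # each i<j pair once
  tot <- sum(cts + t(cts)) / 2 - sum(diag(cts))
  if (tot <= 0) stop("no off-diagonal transitions")
  1 - asym / tot
}

#' Export a TDP matrix as TSV
#'
#' @param tdp a `transition_density`.
#' @param path output file; rows = FRET-before bin centers.
#' @export
write_tdp_tsv <- function(tdp, path) {
  m <- tdp$counts
  dimnames(m) <- list(format(tdp$bin_centers, digits = 4),
                      format(tdp$bin_centers, digits = 4))
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
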