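#' Coordinate trajectory container
#'
#' Frames x atoms x 3 Cartesian coordinates (Angstrom) with atom and residue
#' labels, the common currency of all molecular-dynamics observables here.
#'
#' @param coords numeric array [frames, atoms, 3].
#' @param atom_names character vector, one per atom (e.g. "CA", "P").
#' @param res_ids integer residue ids, one per atom (1-based as in PDB).
#' @param res_names character residue names, one per atom.
#' @param box optional per-frame orthorhombic box lengths: matrix
#'   [frames, 3] or a length-3 vector recycled to all frames.
#' @return object of class `coordinate_trajectory`.
#' @export
coordinate_trajectory <- function(coords, atom_names = NULL, res_ids = NULL,
                                  res_names = NULL, box = NULL) {
  d <- dim(coords)
  if (length(d) != 3L || d[3] != 3L) stop("coords must be [frames, atoms, 3]")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  na <- d[2]
  if (is.null(atom_names)) atom_names <- rep("CA", na)
  if (is.null(res_ids)) res_ids <- seq_len(na)
  if (is.null(res_names)) res_names <- rep("ALA", na)
  if (length(atom_names) != na || length(res_ids) != na ||
      length(res_names) != na) {
    stop("atom/residue labels must have one entry per atom")
  }
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, d[1], 3, byrow = TRUE)
    if (any(box <= 0)) stop("box lengths must be > 0")
  }
  structure(
    list(coords = coords, atom_names = as.character(atom_names),
         res_ids = as.integer(res_ids), res_names = as.character(res_names),
         box = box, n_frames = d[1], n_atoms = na),
    class = "coordinate_trajectory"
  )
}

#' @export
print.coordinate_trajectory <- function(x, ...) {
  cat("coordinate_trajectory:", x$n_frames, "frames x", x$n_atoms, "atoms",
      if (!is.null(x$box)) "(periodic)" else "", "\n")
  invisible(x)
}

#' Read a coordinate trajectory from multi-model PDB or XYZ
#'
#' @param path input file.
#' @param format "auto" (by extension), "pdb", or "xyz".
#' @return a `coordinate_trajectory`.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (format == "pdb") .read_pdb_trajectory(path) else .read_xyz(path)
}

.read_pdb_trajectory <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                      # [models, 3*atoms]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  coordinate_trajectory(coords,
                        atom_names = pdb$atom$elety,
                        res_ids = pdb$atom$resno,
                        res_names = pdb$atom$resid)
}

# plain multi-frame XYZ: n_atoms line, comment line, then atom lines
.read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  names0 <- NULL
  model <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("XYZ parse error at line ", i, ": expected atom count")
    model <- model + 1L
    if (i + 1L + n > length(lines)) {
      stop("XYZ truncated in model ", model, " near line ", length(lines))
    }
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad) > 0L) {
      stop("XYZ parse error at line ", i + 1L + bad[1], ": need 4 fields")
    }
    nm <- vapply(parts, `[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      stop("non-numeric coordinate in model ", model)
    }
    if (is.null(names0)) {
      names0 <- nm
    } else if (length(nm) != length(names0)) {
      stop("atom-count mismatch in model ", model)
    }
    frames[[model]] <- xyz
    i <- i + 2L + n
  }
  if (model == 0L) stop("no frames found in ", path)
  na <- length(names0)
  coords <- array(NA_real_, c(model, na, 3))
  for (f in seq_len(model)) coords[f, , ] <- frames[[f]]
  coordinate_trajectory(coords, atom_names = names0,
                        res_ids = seq_len(na), res_names = rep("UNK", na))
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj a `coordinate_trajectory`.
#' @param path output file.
#' @param digits coordinate precision.
#' @export
write_xyz <- function(traj, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(c(as.character(traj$n_atoms), paste("frame", f)), con)
    m <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3)
    writeLines(sprintf("%s %.*f %.*f %.*f", traj$atom_names,
                       digits, m[, 1], digits, m[, 2], digits, m[, 3]), con)
  }
  invisible(path)
}

.sel_idx <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(traj$n_atoms))
  if (is.logical(selection)) return(which(selection))
  as.integer(selection)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal rotation and translation mapping the mobile frame
#' onto the reference over the selected atoms, plus the RMSD after
#' superposition. The rotation is always a proper rotation (det = +1),
#' including near-reflective inputs.
#'
#' @param mobile,reference numeric matrices [atoms, 3] (same atom order).
#' @param selection optional atom indices/logical mask used for the fit;
#'   the RMSD is computed over the same selection.
#' @return object of class `superposition_result`: rotation (3x3),
#'   translation (length 3), rmsd (Angstrom). The fully transformed mobile
#'   coordinates (all atoms) are attached as attribute `coords`.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) stop("frame dimensions differ")
  idx <- if (is.null(selection)) seq_len(nrow(mobile)) else {
    if (is.logical(selection)) which(selection) else as.integer(selection)
  }
  if (length(idx) < 3L) stop("need at least 3 selected atoms")
  p <- mobile[idx, , drop = FALSE]
  q <- reference[idx, , drop = FALSE]
  pc <- colMeans(p); qc <- colMeans(q)
  p0 <- sweep(p, 2, pc); q0 <- sweep(q, 2, qc)
  sv <- svd(crossprod(p0, q0))        # H = P0^T Q0 = U D V^T
  if (sv$d[2] < 1e-12) stop("selected atoms are collinear or degenerate")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- qc - as.numeric(rot %*% pc)
  fitted_sel <- sweep(p0 %*% t(rot), 2, qc, "+")
  rmsd <- sqrt(mean(rowSums((fitted_sel - q)^2)))
  all_fit <- sweep(mobile %*% t(rot), 2, trans, "+")
  structure(
    list(rotation = rot, translation = trans, rmsd = rmsd),
    class = "superposition_result", coords = all_fit
  )
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' @param traj a `coordinate_trajectory`.
#' @param reference frame index used as reference (default 1) or an
#'   [atoms, 3] matrix.
#' @param selection atoms used for the fit (all atoms are transformed).
#' @return a new `coordinate_trajectory` in the reference frame.
#' @export
superpose_trajectory <- function(traj, reference = 1L, selection = NULL) {
  ref <- if (is.matrix(reference)) reference else
    traj$coords[reference, , , drop = TRUE]
  out <- traj$coords
  for (f in seq_len(traj$n_frames)) {
    sp <- superpose(traj$coords[f, , , drop = TRUE], ref, selection)
    out[f, , ] <- attr(sp, "coords")
  }
  traj$coords <- out
  traj
}

#' Per-frame RMSD against a reference frame
#'
#' Each frame is optimally superposed (Kabsch) onto the reference over the
#' selection before the RMSD is taken, the standard stability screen for MD
#' trajectories.
#'
#' @param traj a `coordinate_trajectory`.
#' @param reference frame index or [atoms, 3] matrix.
#' @param selection atoms entering fit and RMSD.
#' @return list: rmsd (per-frame, Angstrom), mean, sd.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL) {
  ref <- if (is.matrix(reference)) reference else
    traj$coords[reference, , , drop = TRUE]
  r <- vapply(seq_len(traj$n_frames), function(f) {
    superpose(traj$coords[f, , , drop = TRUE], ref, selection)$rmsd
  }, numeric(1))
  list(rmsd = r, mean = mean(r), sd = stats::sd(r))
}

# one representative point per residue: CA if the residue has one, else P
# (nucleotides), else the geometric centroid of its atoms
.residue_representatives <- function(traj) {
  res <- unique(traj$res_ids)
  reps <- array(NA_real_, c(traj$n_frames, length(res), 3))
  for (j in seq_along(res)) {
    at <- which(traj$res_ids == res[j])
    nm <- traj$atom_names[at]
    pick <- if ("CA" %in% nm) at[nm == "CA"][1] else
      if ("P" %in% nm) at[nm == "P"][1] else NA_integer_
    if (!is.na(pick)) {
      reps[, j, ] <- traj$coords[, pick, , drop = TRUE]
    } else {
      reps[, j, ] <- apply(traj$coords[, at, , drop = FALSE], c(1, 3), mean)
    }
  }
  list(res_ids = res, coords = reps)
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' Residue-wise normalized covariance of positional fluctuations:
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>), with dr the deviation
#' of each residue's representative point from its trajectory mean.
#' Superpose the trajectory onto a common reference first (see
#' [superpose_trajectory()]); otherwise rigid-body motion masquerades as
#' correlation. Residues with zero fluctuation get NA rows/columns.
#'
#' @param traj a superposed `coordinate_trajectory`.
#' @return object of class `correlation_matrix`: values (n_res x n_res),
#'   res_ids.
#' @export
dccm <- function(traj) {
  rep_pts <- .residue_representatives(traj)
  x <- rep_pts$coords
  nr <- dim(x)[2]
  mu <- apply(x, c(2, 3), mean)
  dx <- sweep(x, c(2, 3), mu)
  # inner products: <dr_i . dr_j> over frames
  flat <- matrix(0, traj$n_frames, nr * 3)
  for (k in 1:3) flat[, (k - 1) * nr + seq_len(nr)] <- dx[, , k]
  ip <- matrix(0, nr, nr)
  for (k in 1:3) {
    blk <- flat[, (k - 1) * nr + seq_len(nr), drop = FALSE]
    ip <- ip + crossprod(blk) / traj$n_frames
  }
  v <- diag(ip)
  zero <- v <= 0
  denom <- sqrt(outer(v, v))
  cmat <- ip / denom
  cmat[zero, ] <- NA_real_
  cmat[, zero] <- NA_real_
  diag(cmat)[!zero] <- 1
  structure(
    list(values = cmat, res_ids = rep_pts$res_ids),
    class = "correlation_matrix"
  )
}

#' Difference-correlation map relative to a focus residue
#'
#' Per-residue difference C_A(focus, .) - C_B(focus, .) between two
#' correlation matrices sharing a residue index, the map used to localize
#' how couplings to a site of interest (e.g. an adducted base) change
#' between conditions. Raw values are retained; a clamped copy (default
#' [-0.5, 0.5]) is provided for display.
#'
#' @param c_a,c_b `correlation_matrix` objects with identical res_ids.
#' @param focus residue id present in both.
#' @param clamp display clamp range.
#' @return object of class `difference_correlation`: res_ids, values (raw),
#'   clamped, focus.
#' @export
difference_correlation <- function(c_a, c_b, focus, clamp = c(-0.5, 0.5)) {
  stopifnot(inherits(c_a, "correlation_matrix"),
            inherits(c_b, "correlation_matrix"))
  if (!identical(c_a$res_ids, c_b$res_ids)) {
    mism <- union(setdiff(c_a$res_ids, c_b$res_ids),
                  setdiff(c_b$res_ids, c_a$res_ids))
    stop("residue index mismatch: ", paste(mism, collapse = ", "))
  }
  fi <- match(focus, c_a$res_ids)
  if (is.na(fi)) stop("focus residue ", focus, " not in index")
  d <- c_a$values[fi, ] - c_b$values[fi, ]
  structure(
    list(res_ids = c_a$res_ids, values = d,
         clamped = pmin(pmax(d, clamp[1]), clamp[2]), focus = focus),
    class = "difference_correlation"
  )
}

#' Radial distribution function between two selections
#'
#' Frame-averaged pair-distance histogram between selections A and B,
#' normalized by the spherical shell volume 4 pi r^2 dr and the B-particle
#' number density, so an ideal gas gives g(r) = 1. Under periodic boundary
#' conditions the minimum-image convention applies and the density uses the
#' box volume; without a box the density uses the axis-aligned bounding-box
#' volume of the B selection.
#'
#' @param traj a `coordinate_trajectory`.
#' @param selection_a,selection_b atom indices (disjoint).
#' @param r_max maximum distance (Angstrom).
#' @param dr bin width (Angstrom).
#' @param pbc use periodic minimum image (requires `traj$box`).
#' @return object of class `rdf_result`: r (bin centers), g, counts,
#'   density.
#' @export
rdf <- function(traj, selection_a, selection_b, r_max, dr, pbc = FALSE) {
  if (dr <= 0 || r_max <= dr) stop("need dr > 0 and r_max > dr")
  ia <- .sel_idx(traj, selection_a)
  ib <- .sel_idx(traj, selection_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty selection")
  if (length(intersect(ia, ib)) > 0L) stop("selections must be disjoint")
  if (pbc && is.null(traj$box)) stop("pbc = TRUE requires box lengths")
  edges <- seq(0, r_max, by = dr)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + dr)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  vol_sum <- 0
  for (f in seq_len(traj$n_frames)) {
    a <- traj$coords[f, ia, , drop = FALSE][1, , , drop = TRUE]
    b <- traj$coords[f, ib, , drop = FALSE][1, , , drop = TRUE]
    if (is.null(dim(a))) a <- matrix(a, ncol = 3)
    if (is.null(dim(b))) b <- matrix(b, ncol = 3)
    if (pbc) {
      box <- traj$box[f, ]
      if (r_max > min(box) / 2) {
        stop("r_max exceeds half the smallest box length")
      }
      d2 <- matrix(0, nrow(a), nrow(b))
      for (k in 1:3) {
        dk <- outer(a[, k], b[, k], "-")
        dk <- dk - box[k] * round(dk / box[k])
        d2 <- d2 + dk^2
      }
      vol_sum <- vol_sum + prod(box)
    } else {
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      ext <- apply(b, 2, range)
      vol_sum <- vol_sum + prod(pmax(ext[2, ] - ext[1, ], dr))
    }
    dist <- sqrt(pmax(d2, 0))
    keep <- dist < r_max & dist > 0
    if (any(keep)) {
      idx <- pmin(findInterval(dist[keep], edges, rightmost.closed = TRUE), nb)
      counts <- counts + tabulate(idx, nbins = nb)
    }
  }
  vol <- vol_sum / traj$n_frames
  rho_b <- length(ib) / vol
  centers <- edges[-length(edges)] + dr / 2
  shell <- 4 * pi * centers^2 * dr
  g <- counts / (traj$n_frames * length(ia) * rho_b * shell)
  structure(
    list(r = centers, g = g, counts = counts, density = rho_b),
    class = "rdf_result"
  )
}

#' Distance between two tagged sites over a trajectory
#'
#' Per-frame Euclidean distance between two atoms (e.g. the dye attachment
#' sites of a FRET pair), with mean and standard deviation.
#'
#' @param traj a `coordinate_trajectory`.
#' @param atom_i,atom_j atom indices.
#' @return list: distance (per frame, Angstrom), mean, sd.
#' @export
site_distance <- function(traj, atom_i, atom_j) {
  if (atom_i < 1L || atom_i > traj$n_atoms ||
      atom_j < 1L || atom_j > traj$n_atoms) stop("atom index out of range")
  d <- sqrt(rowSums((traj$coords[, atom_i, ] - traj$coords[, atom_j, ])^2))
  list(distance = d, mean = mean(d), sd = stats::sd(d))
}

#' Paired comparison of a tagged-site distance between two trajectories
#'
#' @param traj_a,traj_b `coordinate_trajectory` objects.
#' @param atom_i,atom_j atom indices (same labeling in both).
#' @return list: mean_difference (mean B - mean A, Angstrom), a, b.
#' @export
compare_site_distance <- function(traj_a, traj_b, atom_i, atom_j) {
  da <- site_distance(traj_a, atom_i, atom_j)
  db <- site_distance(traj_b, atom_i, atom_j)
  list(mean_difference = db$mean - da$mean, a = da, b = db)
}

#' Principal component analysis of trajectory coordinates
#'
#' Eigendecomposition of the Cartesian coordinate covariance over frames
#' (essential dynamics). Superpose the trajectory first so rigid-body
#' motion does not dominate. Eigenvalues are non-negative and descending;
#' projections are centered.
#'
#' @param traj a superposed `coordinate_trajectory`.
#' @param selection atoms included (default all).
#' @return object of class `pca_modes`: eigenvalues, modes (columns,
#'   3N-dimensional), projections (frames x modes), variance_fraction,
#'   total_variance.
#' @export
pca_modes <- function(traj, selection = NULL) {
  idx <- .sel_idx(traj, selection)
  nf <- traj$n_frames
  if (nf <= 3L * length(idx) && nf < 100L) {
    # fewer frames than coordinates is common for toys; eigenvalues beyond
    # nf - 1 are structurally zero
  }
  x <- matrix(0, nf, 3L * length(idx))
  for (k in 1:3) {
    x[, (k - 1L) * length(idx) + seq_along(idx)] <- traj$coords[, idx, k]
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / (nf - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  proj <- xc %*% eg$vectors
  structure(
    list(eigenvalues = ev, modes = eg$vectors, projections = proj,
         variance_fraction = if (sum(ev) > 0) ev / sum(ev) else ev,
         total_variance = sum(diag(cv))),
    class = "pca_modes"
  )
}

#' Generate toy coordinate trajectories with known analytic properties
#'
#' Fixture generators standing in for solvated MD output; each kind has an
#' exact expected behavior under one of the observables.
#'
#' \itemize{
#'   \item `ideal-gas`: atoms i.i.d. uniform in a periodic cubic box each
#'     frame; RDF converges to 1.
#'   \item `rigid-motion`: a random base structure under per-frame random
#'     proper rotations and translations; superposed RMSD is 0.
#'   \item `harmonic-network`: per-atom Gaussian jitter about a base
#'     structure; atoms sharing a latent displacement (via `couples`)
#'     acquire positive DCCM entries, independent atoms decorrelate.
#'   \item `paired-coupling`: two harmonic-network trajectories (A without,
#'     B with a focus--partner coupling), for difference-correlation tests;
#'     returns list(a, b).
#' }
#'
#' @param kind one of "ideal-gas", "rigid-motion", "harmonic-network",
#'   "paired-coupling".
#' @param params list of kind-specific parameters: n_atoms, n_frames,
#'   box (ideal-gas), base (matrix, optional), sd, latent_sd,
#'   couples (list of integer groups), focus, partner.
#' @param seed integer seed.
#' @return a `coordinate_trajectory`, or list(a, b) for "paired-coupling".
#' @export
generate_toy_trajectory <- function(kind, params = list(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- params
  n_atoms <- p$n_atoms %||% 50L
  n_frames <- p$n_frames %||% 200L
  switch(
    kind,
    "ideal-gas" = {
      box <- p$box %||% 30
      coords <- array(stats::runif(n_frames * n_atoms * 3, 0, box),
                      c(n_frames, n_atoms, 3))
      coordinate_trajectory(coords, box = rep(box, 3))
    },
    "rigid-motion" = {
      base <- p$base %||% matrix(stats::rnorm(n_atoms * 3, sd = 5), ncol = 3)
      coords <- array(NA_real_, c(n_frames, nrow(base), 3))
      for (f in seq_len(n_frames)) {
        rot <- .random_rotation()
        tr <- stats::rnorm(3, sd = 10)
        coords[f, , ] <- sweep(base %*% t(rot), 2, tr, "+")
      }
      coordinate_trajectory(coords)
    },
    "harmonic-network" = {
      .harmonic_toy(n_atoms, n_frames, p)
    },
    "paired-coupling" = {
      focus <- p$focus %||% 1L
      partner <- p$partner %||% 2L
      pa <- p; pa$couples <- NULL
      pb <- p; pb$couples <- list(c(focus, partner))
      a <- .harmonic_toy(n_atoms, n_frames, pa)
      b <- .harmonic_toy(n_atoms, n_frames, pb)
      list(a = a, b = b)
    },
    stop("unknown toy trajectory kind: ", kind)
  )
}

.harmonic_toy <- function(n_atoms, n_frames, p) {
  base <- p$base %||% matrix(stats::rnorm(n_atoms * 3, sd = 10), ncol = 3)
  sd_i <- p$sd %||% 0.5
  latent_sd <- p$latent_sd %||% 1.0
  coords <- array(NA_real_, c(n_frames, nrow(base), 3))
  disp <- array(stats::rnorm(n_frames * nrow(base) * 3, sd = sd_i),
                c(n_frames, nrow(base), 3))
  if (!is.null(p$couples)) {
    for (grp in p$couples) {
      lat <- matrix(stats::rnorm(n_frames * 3, sd = latent_sd), n_frames, 3)
      for (a in grp) disp[, a, ] <- disp[, a, ] + lat
    }
  }
  for (f in seq_len(n_frames)) coords[f, , ] <- base + disp[f, , ]
  coordinate_trajectory(coords)
}

.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Write a per-residue map into the B-factor column of a PDB frame
#'
#' Writes one trajectory frame as a PDB with the supplied per-residue values
#' (e.g. a difference-correlation map) in the temperature-factor column, a
#' convenient route to structure-colored visualization.
#'
#' @param traj a `coordinate_trajectory`.
#' @param values named or positional per-residue values (order of
#'   `unique(traj$res_ids)`).
#' @param path output PDB path.
#' @param frame frame index to write.
#' @export
write_bfactor_pdb <- function(traj, values, path, frame = 1L) {
  res <- unique(traj$res_ids)
  if (length(values) != length(res)) {
    stop("need one value per residue (", length(res), ")")
  }
  bmap <- stats::setNames(values, res)
  m <- traj$coords[frame, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = 3)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(traj$n_atoms),
    substr(traj$atom_names, 1, 4), substr(traj$res_names, 1, 3),
    traj$res_ids, m[, 1], m[, 2], m[, 3], 1.0,
    as.numeric(bmap[as.character(traj$res_ids)])
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
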