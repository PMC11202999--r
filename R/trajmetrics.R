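#' Construct a conformational ensemble
#'
#' A set of frames (snapshots) of the same molecule, as produced by a
#' molecular-dynamics trajectory or any multi-model structure file.
#' Coordinates are in nanometres throughout.
#'
#' @param frames Numeric array of dimension frames x atoms x 3, or a list
#'   of atoms x 3 matrices.
#' @param masses Per-atom masses, amu; defaults to unit masses.
#' @param radii Per-atom radii, nm; defaults to 0.17 nm (a generic heavy
#'   atom) and only matters for [sasa()].
#' @param atom_labels Per-atom identifiers.
#' @param frame_times Optional per-frame times, ps.
#' @return An object of class `"conformation_ensemble"`.
#' @export
conformation_ensemble <- function(frames, masses = NULL, radii = NULL,
                                  atom_labels = NULL, frame_times = NULL) {
  if (is.list(frames)) {
    n_atoms <- nrow(frames[[1]])
    if (!all(vapply(frames, nrow, integer(1)) == n_atoms))
      stop("all frames must have the same atom count", call. = FALSE)
    arr <- array(NA_real_, dim = c(length(frames), n_atoms, 3))
    for (i in seq_along(frames)) arr[i, , ] <- as.matrix(frames[[i]])
    frames <- arr
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3, dim(frames)[3] == 3)
  n_atoms <- dim(frames)[2]
  if (is.null(masses)) masses <- rep(1, n_atoms)
  if (is.null(radii)) radii <- rep(0.17, n_atoms)
  if (is.null(atom_labels)) atom_labels <- as.character(seq_len(n_atoms))
  if (length(masses) != n_atoms || any(masses <= 0))
    stop("masses must be positive, one per atom", call. = FALSE)
  if (length(radii) != n_atoms || any(radii <= 0))
    stop("radii must be positive, one per atom", call. = FALSE)
  structure(list(frames = frames, masses = as.numeric(masses),
                 radii = as.numeric(radii),
                 atom_labels = as.character(atom_labels),
                 frame_times = frame_times),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf("Conformational ensemble: %d frames x %d atoms\n",
              dim(x$frames)[1], dim(x$frames)[2]))
  invisible(x)
}

# Element lookup tables (amu; van der Waals radii in nm) for file readers.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, NA. = 22.990, MG = 24.305,
                    K = 39.098, CL = 35.45, F = 18.998, BR = 79.904,
                    I = 126.904, FE = 55.845, ZN = 65.38)
.vdw_radii <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, P = 0.180,
                S = 0.180, NA. = 0.227, MG = 0.173, K = 0.275, CL = 0.175,
                F = 0.147, BR = 0.185, I = 0.198, FE = 0.194, ZN = 0.139)

.element_lookup <- function(elements, table, default) {
  key <- toupper(elements)
  key[key == "NA"] <- "NA."
  out <- unname(table[key])
  out[is.na(out)] <- default
  out
}

#' Read a multi-MODEL PDB file as a conformational ensemble
#'
#' Each MODEL record becomes one frame. PDB coordinates (angstroms) are
#' converted to nanometres; masses and van der Waals radii are assigned
#' from the element column (unknown elements get carbon-like defaults).
#'
#' @param path Path to a PDB file.
#' @return A [conformation_ensemble()].
#' @export
read_ensemble_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                              # frames x 3N matrix, angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3
  frames <- array(NA_real_, dim = c(n_frames, n_atoms, 3))
  for (i in seq_len(n_frames))
    frames[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
  elements <- pdb$atom$elesy
  if (is.null(elements) || all(is.na(elements)) || all(elements == ""))
    elements <- substr(trimws(pdb$atom$elety), 1, 1)
  conformation_ensemble(
    frames,
    masses = .element_lookup(elements, .atomic_masses, 12.011),
    radii = .element_lookup(elements, .vdw_radii, 0.17),
    atom_labels = paste0(trimws(pdb$atom$elety), pdb$atom$resno))
}

#' Read a multi-frame XYZ trajectory as a conformational ensemble
#'
#' The plain XYZ format: repeated blocks of an atom count line, a comment
#' line, then `element x y z` rows. Coordinates are taken as angstroms and
#' converted to nanometres.
#'
#' @param path Path to an XYZ file.
#' @return A [conformation_ensemble()].
#' @export
read_ensemble_xyz <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) | seq_along(lines) %% 1 == 0] # keep structure
  frames <- list()
  elements <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop(sprintf("malformed XYZ: expected atom count at line %d", i),
                       call. = FALSE)
    block <- lines[(i + 2):(i + 1 + n)]
    tok <- strsplit(block, "\\s+")
    els <- vapply(tok, `[[`, character(1), 1)
    coords <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (is.null(elements)) elements <- els
    frames[[length(frames) + 1]] <- coords / 10
    i <- i + 2 + n
  }
  conformation_ensemble(
    frames,
    masses = .element_lookup(elements, .atomic_masses, 12.011),
    radii = .element_lookup(elements, .vdw_radii, 0.17),
    atom_labels = elements)
}

# Weighted Kabsch superposition: returns `mobile` least-squares fitted onto
# `ref` (both N x 3), minimizing the weighted squared deviation over
# rotations and translations.
.superpose <- function(mobile, ref, weights) {
  w <- weights / sum(weights)
  com_m <- colSums(mobile * w)
  com_r <- colSums(ref * w)
  x <- sweep(mobile, 2, com_m)
  y <- sweep(ref, 2, com_r)
  h <- t(x * w) %*% y
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(x %*% t(rot), 2, com_r, `+`)
}

.weighted_rmsd <- function(a, b, weights) {
  sqrt(sum(weights * rowSums((a - b)^2)) / sum(weights))
}

#' Root-mean-square deviation series
#'
#' Each frame is optimally superposed on the reference frame (mass-weighted
#' least-squares rotation and translation, Kabsch algorithm), then the
#' mass-weighted RMSD is reported. Rigid-body motion therefore contributes
#' nothing: a rotated-and-translated copy of the reference scores 0.
#'
#' @param ensemble A [conformation_ensemble()].
#' @param reference_index Index of the reference frame (default 1).
#' @param atoms Optional integer vector restricting the calculation (and
#'   the superposition) to a subset of atoms; defaults to all atoms.
#' @return Numeric vector of per-frame RMSD values, nm.
#' @export
rmsd_series <- function(ensemble, reference_index = 1, atoms = NULL) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  n_frames <- dim(ensemble$frames)[1]
  stopifnot(reference_index >= 1, reference_index <= n_frames)
  if (is.null(atoms)) atoms <- seq_len(dim(ensemble$frames)[2])
  if (length(atoms) < 3)
    stop("superposition needs at least 3 atoms", call. = FALSE)
  w <- ensemble$masses[atoms]
  ref <- ensemble$frames[reference_index, atoms, , drop = TRUE]
  vapply(seq_len(n_frames), function(i) {
    fitted <- .superpose(ensemble$frames[i, atoms, , drop = TRUE], ref, w)
    .weighted_rmsd(fitted, ref, w)
  }, numeric(1))
}

#' Per-atom root-mean-square fluctuation
#'
#' All frames are superposed on their mean structure (iterated twice:
#' superpose on the first frame, re-average, superpose on the average),
#' then each atom's RMSF is the square root of its mean squared deviation
#' from its average position. The ensemble mean RMSF is attached as the
#' `"average"` attribute, the conventional single-number summary.
#'
#' @param ensemble A [conformation_ensemble()] with at least 2 frames.
#' @param fit_atoms Optional integer vector of atoms used for the
#'   superposition (e.g. a rigid core); fluctuations are still reported for
#'   every atom. Defaults to all atoms.
#' @return Numeric vector of per-atom RMSF values, nm, with attribute
#'   `"average"`.
#' @export
rmsf_per_atom <- function(ensemble, fit_atoms = NULL) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  n_frames <- dim(ensemble$frames)[1]
  n_atoms <- dim(ensemble$frames)[2]
  if (n_frames < 2)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  if (is.null(fit_atoms)) fit_atoms <- seq_len(n_atoms)
  if (length(fit_atoms) < 3)
    stop("superposition needs at least 3 fit atoms", call. = FALSE)
  w <- ensemble$masses[fit_atoms]
  frames <- ensemble$frames
  ref <- frames[1, fit_atoms, , drop = TRUE]
  for (pass in 1:2) {
    for (i in seq_len(n_frames)) {
      sub <- frames[i, fit_atoms, , drop = TRUE]
      wn <- w / sum(w)
      com_m <- colSums(sub * wn); com_r <- colSums(ref * wn)
      x <- sweep(sub, 2, com_m); y <- sweep(ref, 2, com_r)
      sv <- svd(t(x * wn) %*% y)
      d <- sign(det(sv$v %*% t(sv$u)))
      rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
      whole <- sweep(frames[i, , , drop = TRUE], 2, com_m)
      frames[i, , ] <- sweep(whole %*% t(rot), 2, com_r, `+`)
    }
    ref <- apply(frames[, fit_atoms, , drop = FALSE], c(2, 3), mean)
  }
  mean_pos <- apply(frames, c(2, 3), mean)
  rmsf <- sqrt(vapply(seq_len(n_atoms), function(a) {
    dev <- sweep(frames[, a, , drop = TRUE], 2, mean_pos[a, ])
    mean(rowSums(dev^2))
  }, numeric(1)))
  attr(rmsf, "average") <- mean(rmsf)
  rmsf
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the atoms from their centre
#' of mass: the standard compactness measure.
#'
#' @param frame N x 3 coordinate matrix, nm.
#' @param masses Per-atom masses; defaults to unit masses.
#' @return Radius of gyration, nm.
#' @export
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0))) # 0.5
radius_of_gyration <- function(frame, masses = NULL) {
  frame <- as.matrix(frame)
  stopifnot(ncol(frame) == 3, nrow(frame) >= 1)
  if (is.null(masses)) masses <- rep(1, nrow(frame))
  stopifnot(length(masses) == nrow(frame), all(masses > 0))
  w <- masses / sum(masses)
  com <- colSums(frame * w)
  sqrt(sum(w * rowSums(sweep(frame, 2, com)^2)))
}

# Deterministic quasi-uniform unit-sphere point set (Fibonacci lattice).
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere is expanded by the probe radius and covered with a
#' deterministic Fibonacci lattice of test points; a point is accessible
#' iff it lies outside every other atom's expanded sphere. The atom's
#' contribution is the accessible fraction times the full expanded-sphere
#' area, and the total is summed over atoms.
#'
#' Points lying exactly on another sphere's surface (to relative tolerance
#' 1e-9) are accessible unless that sphere belongs to an earlier-indexed
#' atom: this index tie-break makes duplicated atoms count their shared
#' surface exactly once instead of zero or twice.
#'
#' @param frame N x 3 coordinate matrix, nm.
#' @param radii Per-atom radii, nm.
#' @param probe_radius Solvent-probe radius, nm (default 0.14, water).
#' @param n_sphere_points Lattice points per atom (default 960; >= 32).
#' @return Total SASA in nm^2, with attribute `"per_atom"`.
#' @export
#' @examples
#' sasa(matrix(0, 1, 3), radii = 0.2) # ~ 4*pi*0.34^2
sasa <- function(frame, radii, probe_radius = 0.14, n_sphere_points = 960) {
  frame <- as.matrix(frame)
  stopifnot(ncol(frame) == 3, length(radii) == nrow(frame),
            probe_radius >= 0, n_sphere_points >= 32)
  n <- nrow(frame)
  expanded <- radii + probe_radius
  lattice <- .fibonacci_sphere(n_sphere_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(lattice * expanded[i], 2, frame[i, ], `+`)
    accessible <- rep(TRUE, n_sphere_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- rowSums(sweep(pts, 2, frame[j, ])^2)
      e2 <- expanded[j]^2
      on_surface <- abs(d2 - e2) <= e2 * 1e-9
      inside <- d2 < e2 & !on_surface
      blocked <- inside | (on_surface & j < i)
      accessible <- accessible & !blocked
      if (!any(accessible)) break
    }
    per_atom[i] <- mean(accessible) * 4 * pi * expanded[i]^2
  }
  structure(sum(per_atom), per_atom = per_atom)
}
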