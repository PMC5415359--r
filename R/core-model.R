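## Core domain types: atom tables, frames, trajectories, selections and
## minimum-image distances.  Atoms are held in a plain data.frame (one row
## per atom, topology order); a frame adds an orthorhombic box and a time
## stamp; a trajectory stores the topology once plus a coordinate array.

## Bondi-style van der Waals radii (Angstrom).  Unknown elements fall back
## to .default_vdw; the radii-set id is recorded in analysis metadata.
.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  K = 2.75, "NA" = 2.27, MG = 1.73, CA = 2.31, ZN = 1.39,
  SE = 1.90, FE = 2.00, W = 2.30 # W: coarse bead stand-in
)
.default_vdw <- 1.7
.vdw_set_id <- "bondi-1964-extended"

#' Van der Waals radius lookup
#'
#' Maps element symbols to Bondi-style vdW radii (Angstrom).  Unknown
#' elements receive the documented default of 1.7 Angstrom.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_table[toupper(element)]
  r[is.na(r)] <- .default_vdw
  unname(r)
}

#' Build an atom table
#'
#' Constructs the per-atom data.frame used throughout the package.  Residue
#' numbers follow PDB author numbering (so "G324" means author resid 324);
#' internal row indices are never exposed in reports.
#'
#' @param serial integer atom serial numbers.
#' @param name atom names (e.g. "CA").
#' @param resname residue names.
#' @param resid integer author residue numbers.
#' @param chain chain identifiers.
#' @param element element symbols; guessed from the first letter of `name`
#'   when missing.
#' @param x,y,z coordinates in Angstrom.
#' @param mass atomic masses in amu (optional, NA allowed).
#' @return data.frame with columns serial, name, resname, resid, chain,
#'   element, x, y, z, vdw, mass.
#' @export
atom_table <- function(serial, name, resname, resid, chain, element = NULL,
                       x, y, z, mass = NA_real_) {
  n <- length(x)
  if (is.null(element)) element <- gsub("[^A-Za-z].*$", "", substr(name, 1, 1))
  at <- data.frame(
    serial = as.integer(serial), name = as.character(name),
    resname = as.character(resname), resid = as.integer(resid),
    chain = as.character(chain), element = toupper(as.character(element)),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
    stop("atom positions must be finite")
  at$vdw <- vdw_radius(at$element)
  at$mass <- rep_len(as.numeric(mass), n)
  at
}

#' Construct a single frame
#'
#' @param atoms atom table (see [atom_table()]).
#' @param box orthorhombic box lengths c(Lx, Ly, Lz) in Angstrom, or NULL
#'   for a non-periodic structure.
#' @param time time stamp in ps.
#' @return object of class `md_frame`.
#' @export
md_frame <- function(atoms, box = NULL, time = 0) {
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be three positive orthorhombic lengths (Angstrom)")
  }
  structure(list(atoms = atoms, box = box, time = as.numeric(time)),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame> %d atoms, %d chain(s)%s, t = %g ps\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              if (is.null(x$box)) "" else
                sprintf(", box %.1f x %.1f x %.1f A", x$box[1], x$box[2], x$box[3]),
              x$time))
  invisible(x)
}

#' Construct a trajectory
#'
#' Stores the topology once plus an `n_atoms x 3 x n_frames` coordinate
#' array.  Optional per-frame velocities (same shape, Angstrom/ps) and
#' pair-force tables (list of data.frames with columns i, j, fx, fy, fz in
#' kJ/mol/nm; each pair listed once with f the force on atom i due to j)
#' support the local-stress module.
#'
#' @param atoms atom table (topology; coordinates in it are ignored).
#' @param xyz numeric array `c(n_atoms, 3, n_frames)`, Angstrom.
#' @param box matrix `n_frames x 3` of box lengths (Angstrom) or NULL.
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param velocities optional array like `xyz`, Angstrom/ps.
#' @param forces optional list (length n_frames) of pair-force tables.
#' @param topology_source provenance string.
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(atoms, xyz, box = NULL, times = NULL,
                          velocities = NULL, forces = NULL,
                          topology_source = "in-memory") {
  if (length(dim(xyz)) != 3L || dim(xyz)[2] != 3L)
    stop("xyz must be an n_atoms x 3 x n_frames array")
  nf <- dim(xyz)[3]
  if (dim(xyz)[1] != nrow(atoms))
    stop("atom count mismatch between topology and coordinates")
  if (is.null(times)) times <- seq_len(nf) - 1
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (!is.null(box)) {
    box <- matrix(as.numeric(box), ncol = 3)
    if (nrow(box) == 1L) box <- box[rep(1, nf), , drop = FALSE]
    if (nrow(box) != nf) stop("box must have one row per frame")
    if (any(box <= 0)) stop("box lengths must be positive")
  }
  structure(list(atoms = atoms, xyz = xyz, box = box, times = as.numeric(times),
                 velocities = velocities, forces = forces,
                 topology_source = topology_source),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, t = %g..%g ps (%s)\n",
              n_frames(x), nrow(x$atoms), x$times[1], x$times[n_frames(x)],
              x$topology_source))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Extract one frame from a trajectory
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return an `md_frame`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  at <- traj$atoms
  at$x <- traj$xyz[, 1, i]; at$y <- traj$xyz[, 2, i]; at$z <- traj$xyz[, 3, i]
  md_frame(at, box = if (is.null(traj$box)) NULL else traj$box[i, ],
           time = traj$times[i])
}

#' Build a trajectory from a list of frames
#' @param frames list of `md_frame` objects with identical atom counts.
#' @param topology_source provenance string.
#' @return an `md_trajectory`.
#' @export
frames_to_trajectory <- function(frames, topology_source = "frames") {
  n <- length(frames)
  stopifnot(n >= 1)
  na <- nrow(frames[[1]]$atoms)
  if (any(vapply(frames, function(f) nrow(f$atoms), 1L) != na))
    stop("atom count must be constant across frames of one trajectory")
  xyz <- array(NA_real_, c(na, 3, n))
  for (k in seq_len(n))
    xyz[, , k] <- as.matrix(frames[[k]]$atoms[, c("x", "y", "z")])
  boxes <- if (is.null(frames[[1]]$box)) NULL else
    t(vapply(frames, function(f) f$box, numeric(3)))
  md_trajectory(frames[[1]]$atoms, xyz, box = boxes,
                times = vapply(frames, function(f) f$time, 0),
                topology_source = topology_source)
}

## ---------------------------------------------------------------- selection

#' Selection specification
#'
#' @param chain optional chain id (single string).
#' @param resid_ranges optional list of inclusive `c(lo, hi)` author-numbered
#'   residue intervals (a single 2-vector is accepted).
#' @param atom_names optional character vector of atom names (e.g. "CA").
#' @param resnames optional character vector of residue names.
#' @return object of class `selection_spec`.
#' @export
selection_spec <- function(chain = NULL, resid_ranges = NULL,
                           atom_names = NULL, resnames = NULL) {
  if (!is.null(resid_ranges) && !is.list(resid_ranges))
    resid_ranges <- list(resid_ranges)
  structure(list(chain = chain, resid_ranges = resid_ranges,
                 atom_names = atom_names, resnames = resnames),
            class = "selection_spec")
}

#' Select atoms in a frame or atom table
#'
#' Returns topology-ordered atom indices matching a [selection_spec()].
#' An empty match is an error, never a silent empty result.
#'
#' @param x an `md_frame`, `md_trajectory` or atom table.
#' @param spec a `selection_spec`.
#' @return integer vector of atom indices (topology order).
#' @export
select_atoms <- function(x, spec) {
  at <- if (is.data.frame(x)) x else x$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(spec$chain)) keep <- keep & at$chain %in% spec$chain
  if (!is.null(spec$atom_names)) keep <- keep & at$name %in% spec$atom_names
  if (!is.null(spec$resnames)) keep <- keep & at$resname %in% spec$resnames
  if (!is.null(spec$resid_ranges)) {
    inr <- rep(FALSE, nrow(at))
    for (rg in spec$resid_ranges)
      inr <- inr | (at$resid >= rg[1] & at$resid <= rg[2])
    keep <- keep & inr
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("selection matched no atoms: ",
         paste(utils::capture.output(utils::str(unclass(spec))), collapse = " "))
  idx
}

## ------------------------------------------------------------ periodic math

#' Minimum-image distance in an orthorhombic box
#'
#' @param a,b 3-vectors (Angstrom).
#' @param box 3-vector of box lengths (Angstrom).
#' @return Euclidean distance under the minimum-image convention.
#' @export
min_image_distance <- function(a, b, box) {
  if (any(box <= 0)) stop("box lengths must be positive")
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

## vectorised minimum-image displacement: rows of A minus rows of B
.min_image_disp <- function(A, B, box) {
  D <- A - B
  if (!is.null(box))
    for (k in 1:3) D[, k] <- D[, k] - box[k] * round(D[, k] / box[k])
  D
}

#' Minimum distance between two atom sets
#'
#' Exhaustive minimum over all pairs of minimum-image distances; used for
#' lipid-contact and groove analyses.
#'
#' @param A,B numeric matrices (n x 3, m x 3), Angstrom.
#' @param box box lengths or NULL for non-periodic distance.
#' @return the smallest pairwise distance (Angstrom).
#' @export
min_pair_distance <- function(A, B, box = NULL) {
  A <- matrix(A, ncol = 3); B <- matrix(B, ncol = 3)
  best <- Inf
  for (i in seq_len(nrow(A))) {
    D <- .min_image_disp(B, matrix(A[i, ], nrow(B), 3, byrow = TRUE), box)
    best <- min(best, min(rowSums(D * D)))
  }
  sqrt(best)
}
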