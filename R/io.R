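## Structure and trajectory I/O.  PDB reading/writing goes through bio3d;
## the orthorhombic CRYST1 box is scanned directly since bio3d does not
## expose it.  Trajectories: DCD (bio3d) and a plain-text "XYZ-with-box"
## dialect used by the synthetic generators:
##
##   line 1: n_atoms
##   line 2: Lx Ly Lz time          (Angstrom, ps)
##   then n_atoms lines: name x y z [vx vy vz]
##
## repeated per frame.  XTC is not supported and is rejected with a clear
## message.

.read_cryst1 <- function(path) {
  lines <- readLines(path, n = 500L, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0L) return(NULL)
  f <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                    substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                    substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
  if (any(is.na(f))) return(NULL)
  if (all(abs(f[1:3] - 1) < 1e-6)) return(NULL)  # placeholder unit cell
  if (any(abs(f[4:6] - 90) > 0.01))
    stop("triclinic box in CRYST1 record: only orthorhombic boxes are supported")
  f[1:3]
}

#' Read a PDB structure
#'
#' Reads one model of a PDB file into an [md_frame()].  Author residue
#' numbering is preserved; the CRYST1 box is captured when present (only
#' orthorhombic cells are accepted); alternate locations are resolved by
#' keeping the highest-occupancy conformer (tie: first encountered).
#'
#' @param path PDB file path.
#' @param model_index zero-based index into the MODEL records (0 = first
#'   model; files without MODEL records have a single model 0).
#' @return an `md_frame`.
#' @export
read_structure <- function(path, model_index = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  nmod <- nrow(pdb$xyz)
  if (model_index < 0 || model_index >= nmod)
    stop(sprintf("model_index %d out of range: file has %d model(s)",
                 model_index, nmod))
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0L) stop("empty model: no ATOM/HETATM records in ", path)
  xyz <- matrix(pdb$xyz[model_index + 1L, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  ## altloc: keep highest occupancy per (chain, resno, insert, name)
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      best <- rows[which.max(occ[rows])]  # tie -> first encountered
      keep[setdiff(rows, best)] <- FALSE
    }
    at <- at[keep, , drop = FALSE]
  }
  elem <- at$elesy
  if (is.null(elem) || all(!nzchar(elem) | is.na(elem)))
    elem <- gsub("[^A-Za-z].*$", "", substr(at$elety, 1, 1))
  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain)
  atoms <- atom_table(serial = at$eleno, name = at$elety, resname = at$resid,
                      resid = at$resno, chain = chain, element = elem,
                      x = at$x, y = at$y, z = at$z)
  md_frame(atoms, box = .read_cryst1(path), time = 0)
}

#' Write a frame as PDB
#'
#' @param frame an `md_frame`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_structure <- function(frame, path) {
  at <- frame$atoms
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resid, resid = at$resname,
                   eleno = at$serial, elety = at$name, chain = at$chain,
                   elesy = at$element)
  if (!is.null(frame$box)) {
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     frame$box[1], frame$box[2], frame$box[3], 90, 90, 90)
    lines <- readLines(path, warn = FALSE)
    writeLines(c(cryst, lines), path)
  }
  invisible(path)
}

#' Write a trajectory in the XYZ-with-box dialect
#'
#' @param traj an `md_trajectory`.
#' @param path output path (conventionally `.xyzb`).
#' @return the path, invisibly.
#' @export
write_trajectory_xyzb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  na <- nrow(traj$atoms)
  hasv <- !is.null(traj$velocities)
  for (k in seq_len(n_frames(traj))) {
    box <- if (is.null(traj$box)) c(0, 0, 0) else traj$box[k, ]
    writeLines(c(as.character(na),
                 paste(format(c(box, traj$times[k]), digits = 12), collapse = " ")),
               con)
    m <- cbind(traj$xyz[, , k], if (hasv) traj$velocities[, , k])
    writeLines(paste(traj$atoms$name,
                     apply(format(m, digits = 12), 1, paste, collapse = " ")),
               con)
  }
  invisible(path)
}

.read_xyzb <- function(path, atoms) {
  lines <- readLines(path, warn = FALSE)
  pos <- 1L
  frames_xyz <- list(); boxes <- list(); times <- numeric(); vel <- list()
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na) || na <= 0) stop("corrupted XYZ-with-box file: bad atom count at line ", pos)
    hdr <- suppressWarnings(as.numeric(strsplit(trimws(lines[pos + 1L]), "\\s+")[[1]]))
    if (length(hdr) != 4L || any(is.na(hdr)))
      stop("corrupted XYZ-with-box file: bad box/time header at line ", pos + 1L)
    if (pos + 1L + na > length(lines))
      stop("corrupted XYZ-with-box file: truncated frame at line ", pos)
    body <- strsplit(trimws(lines[pos + 1L + seq_len(na)]), "\\s+")
    ncol <- length(body[[1]])
    if (!ncol %in% c(4L, 7L) || any(lengths(body) != ncol))
      stop("corrupted XYZ-with-box file: malformed atom line near line ", pos + 2L)
    num <- matrix(suppressWarnings(as.numeric(unlist(lapply(body, `[`, -1L)))),
                  nrow = na, byrow = TRUE)
    if (any(is.na(num))) stop("corrupted XYZ-with-box file: non-numeric coordinate")
    frames_xyz[[length(frames_xyz) + 1L]] <- num[, 1:3, drop = FALSE]
    if (ncol == 7L) vel[[length(frames_xyz)]] <- num[, 4:6, drop = FALSE]
    boxes[[length(boxes) + 1L]] <- hdr[1:3]
    times <- c(times, hdr[4])
    pos <- pos + 2L + na
  }
  if (length(frames_xyz) == 0L) stop("corrupted XYZ-with-box file: no frames")
  na <- nrow(frames_xyz[[1]])
  if (!is.null(atoms) && na != nrow(atoms))
    stop(sprintf("atom-count mismatch: topology has %d atoms, trajectory %d",
                 nrow(atoms), na))
  nf <- length(frames_xyz)
  xyz <- array(NA_real_, c(na, 3, nf))
  velocities <- if (length(vel) == nf && nf > 0) array(NA_real_, c(na, 3, nf)) else NULL
  for (k in seq_len(nf)) {
    xyz[, , k] <- frames_xyz[[k]]
    if (!is.null(velocities)) velocities[, , k] <- vel[[k]]
  }
  boxm <- do.call(rbind, boxes)
  if (all(boxm == 0)) boxm <- NULL
  list(xyz = xyz, box = boxm, times = times, velocities = velocities)
}

#' Read a trajectory
#'
#' Supported formats (by extension): `.xyzb`/`.xyz` (the package's
#' documented plain-text XYZ-with-box dialect) and `.dcd` (via bio3d;
#' frame times default to 0,1,2,... ps and the box, if any, is taken from
#' the topology's CRYST1 record).  XTC is rejected: no XTC reader is
#' available to R.
#'
#' @param topology PDB file path, `md_frame` or atom table supplying atom
#'   metadata in trajectory order.
#' @param traj trajectory file path.
#' @return an `md_trajectory`.
#' @export
read_trajectory <- function(topology, traj) {
  atoms <- if (is.character(topology)) read_structure(topology)$atoms
           else if (inherits(topology, "md_frame")) topology$atoms
           else topology
  ext <- tolower(tools::file_ext(traj))
  if (ext == "xtc")
    stop("XTC trajectories are not supported; convert to DCD or the ",
         "XYZ-with-box dialect")
  if (ext == "dcd") {
    m <- bio3d::read.dcd(traj, verbose = FALSE)
    nf <- nrow(m); na <- ncol(m) / 3
    if (na != nrow(atoms))
      stop(sprintf("atom-count mismatch: topology has %d atoms, trajectory %d",
                   nrow(atoms), na))
    xyz <- array(NA_real_, c(na, 3, nf))
    for (k in seq_len(nf)) xyz[, , k] <- matrix(m[k, ], ncol = 3, byrow = TRUE)
    box <- if (is.character(topology)) .read_cryst1(topology) else NULL
    return(md_trajectory(atoms, xyz,
                         box = if (is.null(box)) NULL else matrix(box, 1),
                         times = seq_len(nf) - 1, topology_source = traj))
  }
  if (ext %in% c("xyzb", "xyz")) {
    r <- .read_xyzb(traj, atoms)
    return(md_trajectory(atoms, r$xyz, box = r$box, times = r$times,
                         velocities = r$velocities, topology_source = traj))
  }
  stop("unsupported trajectory format: .", ext)
}

#' Write / read a ground-truth sidecar
#'
#' Synthetic generators record their planted parameters (event times, site
#' occupancies, thickness, ...) as a JSON sidecar so downstream recovery
#' tests never re-derive the truth.
#'
#' @param gt a ground-truth list.
#' @param path JSON file path.
#' @return `write_ground_truth`: the path, invisibly. `read_ground_truth`:
#'   the ground-truth list.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
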