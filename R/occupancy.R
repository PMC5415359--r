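## Occupancy analyses: selectivity-filter ion occupancy (S0..S4), pore
## water density and dewetting detection, and lipid-contact series.

#' Selectivity-filter ion occupancy
#'
#' Assigns each selected ion, per frame, to the filter site containing its
#' axial (z) coordinate.  The default site probability counts a site as
#' occupied when at least one ion is inside it ("probability of ions in the
#' filter"); `per_ion = TRUE` reports the mean ion count per site instead.
#'
#' @param traj an `md_trajectory`.
#' @param sites a [filter_sites()] table.
#' @param ion_spec a [selection_spec()] matching the ions (>= 1 atom).
#' @param density_bin z bin width (Angstrom) for the ion density
#'   histogram.
#' @param per_ion report mean ion counts instead of occupied-fraction
#'   probabilities.
#' @return list of class `ion_occupancy` with `probability` (data.frame
#'   site, probability), `density` (data.frame z, density per Angstrom),
#'   `n_frames`.
#' @export
ion_occupancy <- function(traj, sites, ion_spec = selection_spec(atom_names = "K"),
                          density_bin = 0.5, per_ion = FALSE) {
  idx <- select_atoms(traj$atoms, ion_spec)
  nf <- n_frames(traj)
  z <- matrix(traj$xyz[idx, 3, ], nrow = length(idx))
  occ <- sapply(seq_len(nrow(sites)), function(s) {
    inside <- z > sites$zmin[s] & z <= sites$zmax[s]
    if (per_ion) mean(colSums(inside)) else mean(colSums(inside) >= 1)
  })
  zr <- range(z)
  edges <- seq(floor(zr[1] / density_bin) * density_bin,
               ceiling(zr[2] / density_bin) * density_bin + density_bin,
               by = density_bin)
  hist <- graphics::hist(as.vector(z), breaks = edges, plot = FALSE)
  dens <- hist$counts / nf / density_bin  # mean ions per Angstrom
  structure(list(probability = data.frame(site = sites$site, probability = occ),
                 density = data.frame(z = hist$mids, density = dens),
                 n_frames = nf, per_ion = per_ion),
            class = "ion_occupancy")
}

#' Pore water profile and cavity counts
#'
#' Counts waters whose radial distance from the pore axis (the z-axis
#' through `axis_xy`) is at most `cylinder_radius`, histogrammed along z;
#' the per-frame cavity count restricts to the configured z-interval.
#'
#' @param traj an `md_trajectory`.
#' @param water_spec a [selection_spec()] for the water particles.
#' @param cavity_z inclusive z-interval `c(lo, hi)` of the cavity
#'   (Angstrom).
#' @param cylinder_radius cylinder radius (Angstrom).
#' @param axis_xy xy coordinates of the pore axis (default the origin).
#' @param density_bin z bin width (Angstrom).
#' @return list of class `water_profile` with `cavity_counts` (data.frame
#'   time, count), `density` (z, density per Angstrom).
#' @export
water_profile <- function(traj, water_spec = selection_spec(resnames = "HOH"),
                          cavity_z, cylinder_radius = 5,
                          axis_xy = c(0, 0), density_bin = 1) {
  idx <- select_atoms(traj$atoms, water_spec)
  nf <- n_frames(traj)
  counts <- numeric(nf)
  zin <- list()
  for (f in seq_len(nf)) {
    dx <- traj$xyz[idx, 1, f] - axis_xy[1]
    dy <- traj$xyz[idx, 2, f] - axis_xy[2]
    zf <- traj$xyz[idx, 3, f]
    inside <- dx^2 + dy^2 <= cylinder_radius^2
    counts[f] <- sum(inside & zf >= cavity_z[1] & zf <= cavity_z[2])
    zin[[f]] <- zf[inside]
  }
  zall <- unlist(zin)
  if (length(zall) > 0) {
    edges <- seq(floor(min(zall) / density_bin) * density_bin,
                 ceiling(max(zall) / density_bin) * density_bin + density_bin,
                 by = density_bin)
    h <- graphics::hist(zall, breaks = edges, plot = FALSE)
    dens <- data.frame(z = h$mids, density = h$counts / nf / density_bin)
  } else {
    dens <- data.frame(z = numeric(), density = numeric())
  }
  structure(list(cavity_counts = data.frame(time = traj$times, count = counts),
                 density = dens, cylinder_radius = cylinder_radius,
                 cavity_z = cavity_z),
            class = "water_profile")
}

#' Detect dewetting intervals
#'
#' Maximal runs of frames whose cavity water count is below `threshold`
#' and which last at least `min_duration` frames.  Runs separated by even
#' a single wet frame are not merged.
#'
#' @param cavity_counts integer vector of per-frame cavity water counts,
#'   or the `cavity_counts` data.frame from [water_profile()].
#' @param threshold dry if count < threshold (default 5 waters).
#' @param min_duration minimum run length in frames (default 1).
#' @param times optional frame times (ps) for the ps-resolved report.
#' @return data.frame of class `dewetting_report` with `start`, `end`
#'   (inclusive 1-based frames) and, when times are known, `start_ps`,
#'   `end_ps`.
#' @export
detect_dewetting <- function(cavity_counts, threshold = 5, min_duration = 1,
                             times = NULL) {
  if (is.data.frame(cavity_counts)) {
    if (is.null(times)) times <- cavity_counts$time
    cavity_counts <- cavity_counts$count
  }
  dry <- cavity_counts < threshold
  r <- rle(dry)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  out <- data.frame(start = starts[keep], end = ends[keep])
  if (!is.null(times) && nrow(out) > 0) {
    out$start_ps <- times[out$start]
    out$end_ps <- times[out$end]
  }
  structure(out, class = c("dewetting_report", "data.frame"),
            threshold = threshold, min_duration = min_duration)
}

#' Lipid-contact series against a target residue
#'
#' Per frame, the minimum-image minimum distance over all (lipid tail
#' atom, target residue atom) pairs, a bound flag at `threshold` (default
#' 4 Angstrom -- "bound" means a tail comes within 4 Angstrom of the
#' target), and an optional paired structural metric for correlation
#' plots.
#'
#' @param traj an `md_trajectory`.
#' @param target_spec a [selection_spec()] for the target residue's atoms
#'   (e.g. P198).
#' @param tail_spec a [selection_spec()] for the lipid tail atoms.
#' @param threshold bound threshold (Angstrom).
#' @param paired_metric optional numeric vector (one value per frame),
#'   e.g. the fenestration distance.
#' @return data.frame of class `lipid_contact_series` with `time`,
#'   `min_dist`, `bound` and, if given, `metric`.
#' @export
lipid_contact_series <- function(traj, target_spec, tail_spec, threshold = 4,
                                 paired_metric = NULL) {
  it <- select_atoms(traj$atoms, target_spec)
  il <- select_atoms(traj$atoms, tail_spec)
  nf <- n_frames(traj)
  md <- vapply(seq_len(nf), function(f) {
    box <- if (is.null(traj$box)) NULL else traj$box[f, ]
    A <- cbind(traj$xyz[it, 1, f], traj$xyz[it, 2, f], traj$xyz[it, 3, f])
    B <- cbind(traj$xyz[il, 1, f], traj$xyz[il, 2, f], traj$xyz[il, 3, f])
    min_pair_distance(A, B, box)
  }, 0)
  out <- data.frame(time = traj$times, min_dist = md,
                    bound = md < threshold)
  if (!is.null(paired_metric)) {
    stopifnot(length(paired_metric) == nf)
    out$metric <- paired_metric
  }
  structure(out, class = c("lipid_contact_series", "data.frame"),
            threshold = threshold)
}

#' Tip-groove size paired with lipid proximity
#'
#' Per chain: the groove distance (default F226 on the M2 tip to L243 on
#' the M3 tip, Calpha) paired with the minimum distance of lipid tail
#' atoms from the groove anchor residue (default S240).
#'
#' @param traj an `md_trajectory`.
#' @param tail_spec a [selection_spec()] for lipid tail atoms.
#' @param groove_pair residue pair `c(a, b)` defining the groove.
#' @param lipid_anchor residue whose atoms anchor the lipid distance.
#' @param chains chains to report.
#' @param atom atom name for the groove distance.
#' @return data.frame with `time`, `chain`, `groove`, `min_lipid_dist`.
#' @export
groove_series <- function(traj, tail_spec, groove_pair = c(226, 243),
                          lipid_anchor = 240, chains = c("A", "B"),
                          atom = "CA") {
  il <- select_atoms(traj$atoms, tail_spec)
  nf <- n_frames(traj)
  out <- list()
  for (ch in chains) {
    ia <- select_atoms(traj$atoms,
                       selection_spec(chain = ch, atom_names = atom,
                                      resid_ranges = list(rep(groove_pair[1], 2))))
    ib <- select_atoms(traj$atoms,
                       selection_spec(chain = ch, atom_names = atom,
                                      resid_ranges = list(rep(groove_pair[2], 2))))
    ian <- select_atoms(traj$atoms,
                        selection_spec(chain = ch,
                                       resid_ranges = list(rep(lipid_anchor, 2))))
    g <- numeric(nf); ld <- numeric(nf)
    for (f in seq_len(nf)) {
      box <- if (is.null(traj$box)) NULL else traj$box[f, ]
      g[f] <- min_image_distance(traj$xyz[ia[1], , f], traj$xyz[ib[1], , f],
                                 if (is.null(box)) c(Inf, Inf, Inf) else box)
      A <- cbind(traj$xyz[ian, 1, f], traj$xyz[ian, 2, f], traj$xyz[ian, 3, f])
      B <- cbind(traj$xyz[il, 1, f], traj$xyz[il, 2, f], traj$xyz[il, 3, f])
      ld[f] <- min_pair_distance(A, B, box)
    }
    out[[ch]] <- data.frame(time = traj$times, chain = ch, groove = g,
                            min_lipid_dist = ld)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
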