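## Synthetic pore-axis traces: K+ ions scheduled into the selectivity
## filter sites S0..S4 and cavity waters with planted dewetting intervals.
## The ground truth records site-occupancy fractions, per-frame water
## counts and the dewetting intervals, so occupancy analyses can be
## checked exactly.

#' Filter-site geometry
#'
#' Ordered, non-overlapping z-intervals for the selectivity-filter ion
#' binding sites S0 (extracellular) .. S4 (cavity-facing) along the pore
#' axis.
#'
#' @param boundaries numeric vector of 6 decreasing z values (Angstrom):
#'   the edges of S0..S4 from top to bottom.
#' @return data.frame of class `filter_sites` with `site`, `zmin`, `zmax`.
#' @export
filter_sites <- function(boundaries = seq(16, 1, length.out = 6)) {
  if (length(boundaries) != 6 || any(diff(boundaries) >= 0))
    stop("boundaries must be 6 strictly decreasing z values")
  structure(data.frame(site = paste0("S", 0:4),
                       zmin = boundaries[-1], zmax = boundaries[-6]),
            class = c("filter_sites", "data.frame"))
}

#' Derive filter sites from carbonyl-oxygen planes
#'
#' For real structures the site edges are taken as midpoints between
#' consecutive carbonyl-oxygen mean z-planes; S0 extends one inter-plane
#' spacing above the top plane.
#'
#' @param plane_z numeric vector of 5 decreasing carbonyl-plane z values
#'   (Angstrom), top to bottom.
#' @return a [filter_sites()] table.
#' @export
filter_sites_from_planes <- function(plane_z) {
  if (length(plane_z) != 5 || any(diff(plane_z) >= 0))
    stop("plane_z must be 5 strictly decreasing z values")
  mids <- (plane_z[-1] + plane_z[-5]) / 2
  sp <- plane_z[1] - plane_z[2]
  edges <- c(plane_z[1] + sp, mids[1], mids[2], mids[3], mids[4],
             plane_z[5] - (plane_z[4] - plane_z[5]) / 2)
  filter_sites(edges)
}

#' Pore-trace specification
#'
#' @param sites a [filter_sites()] table.
#' @param ion_site_schedule character matrix `n_frames x n_ions` of site
#'   labels ("S0".."S4") or NA for an ion outside the filter.
#' @param wet_count cavity water count outside dewetting intervals.
#' @param dewet_count cavity water count inside dewetting intervals.
#' @param dewetting_intervals list of inclusive `c(start, end)` frame
#'   intervals (1-based).
#' @param cavity_z inclusive z-interval `c(lo, hi)` of the cavity region
#'   (Angstrom).
#' @param cylinder_radius pore cylinder radius (Angstrom).
#' @param n_frames number of frames.
#' @param dt frame spacing (ps).
#' @param seed RNG seed.
#' @return a `pore_trace_spec` list.
#' @export
pore_trace_spec <- function(sites = filter_sites(),
                            ion_site_schedule = matrix("S1", nrow = 100),
                            wet_count = 20, dewet_count = 2,
                            dewetting_intervals = list(),
                            cavity_z = c(-14, 0), cylinder_radius = 5,
                            n_frames = nrow(ion_site_schedule), dt = 1,
                            seed = 1) {
  ion_site_schedule <- as.matrix(ion_site_schedule)
  if (nrow(ion_site_schedule) == 0 || ncol(ion_site_schedule) == 0)
    stop("empty ion schedule")
  if (nrow(ion_site_schedule) != n_frames)
    stop("schedule length mismatch: schedule has ", nrow(ion_site_schedule),
         " frames, spec asks for ", n_frames)
  for (iv in dewetting_intervals)
    if (iv[1] > iv[2] || iv[1] < 1 || iv[2] > n_frames)
      stop("dewetting interval outside the simulated window")
  structure(list(sites = sites, ion_site_schedule = ion_site_schedule,
                 wet_count = wet_count, dewet_count = dewet_count,
                 dewetting_intervals = dewetting_intervals,
                 cavity_z = cavity_z, cylinder_radius = cylinder_radius,
                 n_frames = n_frames, dt = dt, seed = seed),
            class = "pore_trace_spec")
}

#' Synthetic pore trace with known occupancies
#'
#' Ions are placed at the centres of their scheduled sites (on the pore
#' axis); waters are placed uniformly in the cavity cylinder, with counts
#' dropping to `dewet_count` during the planted dewetting intervals.
#'
#' @param spec a [pore_trace_spec()].
#' @return list with `trajectory` and `ground_truth` (site occupancy
#'   fractions, per-frame water counts, dewetting intervals).
#' @export
make_pore_trace <- function(spec = pore_trace_spec()) {
  set.seed(spec$seed)
  n_ions <- ncol(spec$ion_site_schedule)
  sites <- spec$sites
  centre <- setNames((sites$zmin + sites$zmax) / 2, sites$site)
  counts <- rep(spec$wet_count, spec$n_frames)
  for (iv in spec$dewetting_intervals)
    counts[iv[1]:iv[2]] <- spec$dewet_count
  max_w <- max(counts)
  na <- n_ions + max_w
  at <- atom_table(serial = seq_len(na),
                   name = c(rep("K", n_ions), rep("W", max_w)),
                   resname = c(rep("K", n_ions), rep("HOH", max_w)),
                   resid = seq_len(na),
                   chain = c(rep("I", n_ions), rep("W", max_w)),
                   element = c(rep("K", n_ions), rep("O", max_w)),
                   x = 0, y = 0, z = 0)
  box <- c(40, 40, 80)
  xyz <- array(NA_real_, c(na, 3, spec$n_frames))
  parked <- c(30, 30, 35)  # far corner, outside the pore cylinder
  for (f in seq_len(spec$n_frames)) {
    fr <- matrix(rep(parked, each = na), na, 3)
    for (j in seq_len(n_ions)) {
      s <- spec$ion_site_schedule[f, j]
      if (!is.na(s)) fr[j, ] <- c(0, 0, centre[[s]])
    }
    nw <- counts[f]
    if (nw > 0) {
      rr <- spec$cylinder_radius * sqrt(runif(nw))
      th <- runif(nw, 0, 2 * pi)
      fr[n_ions + seq_len(nw), ] <-
        cbind(rr * cos(th), rr * sin(th),
              runif(nw, spec$cavity_z[1], spec$cavity_z[2]))
    }
    xyz[, , f] <- fr
  }
  occ <- vapply(sites$site, function(s)
    mean(apply(spec$ion_site_schedule == s, 1, any, na.rm = TRUE)), 0)
  traj <- md_trajectory(at, xyz, box = matrix(box, 1),
                        times = (seq_len(spec$n_frames) - 1) * spec$dt,
                        topology_source = "synthetic-pore-trace")
  list(trajectory = traj,
       ground_truth = list(site_occupancy = as.list(occ),
                           water_counts = counts,
                           dewetting_intervals = spec$dewetting_intervals,
                           cavity_z = spec$cavity_z,
                           cylinder_radius = spec$cylinder_radius,
                           seed = spec$seed))
}
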