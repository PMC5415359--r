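## Membrane and protein geometry: cross-sectional area profile along the
## membrane normal, bilayer thickness from the head-group phosphates, and
## area per lipid from the box dimensions.
##
## The cross-sectional area at a z-slice is the area of the union of the
## vdW disks {centre (x_i, y_i), radius sqrt(r_i^2 - (z - z_i)^2)} over all
## selected atoms whose sphere intersects the slice, computed by
## rasterising the xy plane into y-scanlines: per scanline the union of
## x-intervals is exact, so only the y direction is discretised.  The
## scheme is deterministic, convergent as the raster shrinks, monotone
## under atom addition, and testable against the closed-form circle and
## two-circle lens areas.

.union_disk_area <- function(cx, cy, r, raster) {
  ## area (A^2) of a union of disks: exact x-interval unions on y-scanlines
  ## spaced `raster` apart (only the y direction is discretised)
  keep <- r > 0
  if (!any(keep)) return(0)
  cx <- cx[keep]; cy <- cy[keep]; r <- r[keep]
  y_start <- min(cy - r) + raster / 2
  y_end <- max(cy + r)
  ys <- if (y_start > y_end) (y_start + y_end - raster / 2) / 2
        else seq(y_start, y_end, by = raster)
  tot <- 0
  for (y in ys) {
    dy <- y - cy
    hit <- abs(dy) < r
    if (!any(hit)) next
    hw <- sqrt(r[hit]^2 - dy[hit]^2)
    lo <- cx[hit] - hw; hi <- cx[hit] + hw
    o <- order(lo); lo <- lo[o]; hi <- hi[o]
    len <- 0; curlo <- lo[1]; curhi <- hi[1]
    if (length(lo) > 1) for (i in 2:length(lo)) {
      if (lo[i] <= curhi) curhi <- max(curhi, hi[i])
      else { len <- len + curhi - curlo; curlo <- lo[i]; curhi <- hi[i] }
    }
    tot <- tot + (len + curhi - curlo) * raster
  }
  tot
}

#' Cross-sectional area profile of a structure
#'
#' Computes the area (nm^2) of the union of projected vdW disks for each
#' z-slice, on a grid centred at `z_origin`.  The vdW radii come from the
#' frame's atom table (bundled Bondi-style set unless the generator
#' overrode them); the radii-set id is recorded in the result's attributes.
#'
#' @param frame an `md_frame`.
#' @param spec a [selection_spec()] naming the atoms to include (default:
#'   every atom).
#' @param slice_thickness z-slice spacing (Angstrom).
#' @param raster xy raster resolution (Angstrom); must be smaller than the
#'   smallest vdW radius in the selection.
#' @param z_origin origin of the z grid (Angstrom); by default the
#'   selection's z-centroid (membrane midplane conventions are applied by
#'   [area_profile_series()]).
#' @return data.frame of class `area_profile` with columns `z` (Angstrom,
#'   slice centres relative to the origin; the cytoplasmic half is z < 0)
#'   and `area_nm2`.
#' @export
area_profile <- function(frame, spec = NULL, slice_thickness = 1,
                         raster = 0.25, z_origin = NULL) {
  idx <- if (is.null(spec)) seq_len(nrow(frame$atoms))
         else select_atoms(frame, spec)
  at <- frame$atoms[idx, ]
  if (raster >= min(at$vdw))
    stop("raster must be finer than the smallest vdW radius in the selection")
  if (is.null(z_origin)) z_origin <- mean(at$z)
  zrel <- at$z - z_origin
  zmin <- floor((min(zrel - at$vdw)) / slice_thickness) * slice_thickness
  zmax <- ceiling((max(zrel + at$vdw)) / slice_thickness) * slice_thickness
  zgrid <- seq(zmin + slice_thickness / 2, zmax - slice_thickness / 2,
               by = slice_thickness)
  area <- vapply(zgrid, function(zc) {
    dz <- zc - zrel
    hit <- abs(dz) < at$vdw
    if (!any(hit)) return(0)
    .union_disk_area(at$x[hit], at$y[hit],
                     sqrt(at$vdw[hit]^2 - dz[hit]^2), raster) / 100
  }, 0)
  structure(data.frame(z = zgrid, area_nm2 = area),
            class = c("area_profile", "data.frame"),
            slice_thickness = slice_thickness, raster = raster,
            z_origin = z_origin, radii_set = .vdw_set_id)
}

#' Mean area profile over a trajectory
#'
#' Computes a per-frame [area_profile()] after recentring each frame's
#' z-origin on the bilayer midplane (mean phosphate z of the two leaflets,
#' when a phosphate selection is given) or, absent lipids, on the
#' selection's z-centroid; profiles are then averaged on a common grid.
#'
#' @param traj an `md_trajectory`.
#' @param spec atoms to include (see [area_profile()]).
#' @param phosphate_spec optional [selection_spec()] for the head-group
#'   phosphate particles that define the bilayer midplane.
#' @param slice_thickness,raster as in [area_profile()].
#' @return data.frame with columns `z`, `mean_area_nm2`, `sd_area_nm2`,
#'   `n_frames`.
#' @export
area_profile_series <- function(traj, spec = NULL, phosphate_spec = NULL,
                                slice_thickness = 1, raster = 0.25) {
  nf <- n_frames(traj)
  profs <- vector("list", nf)
  for (k in seq_len(nf)) {
    fr <- get_frame(traj, k)
    org <- if (!is.null(phosphate_spec))
      mean(fr$atoms$z[select_atoms(fr, phosphate_spec)]) else NULL
    profs[[k]] <- area_profile(fr, spec, slice_thickness, raster,
                               z_origin = org)
  }
  zall <- sort(unique(unlist(lapply(profs, function(p) p$z))))
  m <- vapply(profs, function(p) p$area_nm2[match(zall, p$z)], numeric(length(zall)))
  m[is.na(m)] <- 0  # outside a frame's z-extent the area is 0
  m <- matrix(m, nrow = length(zall))
  data.frame(z = zall,
             mean_area_nm2 = rowMeans(m),
             sd_area_nm2 = apply(m, 1, stats::sd),
             n_frames = nf)
}

#' Bilayer thickness from the head-group phosphates
#'
#' Per frame, phosphate-like particles are assigned to leaflets by the sign
#' of their z relative to the phosphate mean, and the thickness is the
#' distance between the two leaflet mean planes.
#'
#' @param traj an `md_trajectory` (or single `md_frame`).
#' @param phosphate_spec a [selection_spec()] matching one head-group
#'   particle per lipid.
#' @return list of class `bilayer_summary` with `per_frame` (data.frame:
#'   time, thickness) and `thickness` (time-averaged, Angstrom).
#' @export
bilayer_thickness <- function(traj, phosphate_spec) {
  if (inherits(traj, "md_frame"))
    traj <- frames_to_trajectory(list(traj), "single-frame")
  idx <- select_atoms(traj$atoms, phosphate_spec)
  th <- vapply(seq_len(n_frames(traj)), function(k) {
    z <- traj$xyz[idx, 3, k]
    up <- z >= mean(z)
    if (!any(up) || all(up))
      stop("a leaflet is empty: cannot compute bilayer thickness")
    abs(mean(z[up]) - mean(z[!up]))
  }, 0)
  structure(list(per_frame = data.frame(time = traj$times, thickness = th),
                 thickness = mean(th)),
            class = "bilayer_summary")
}

#' @export
print.bilayer_summary <- function(x, ...) {
  cat(sprintf("<bilayer_summary> mean thickness %.2f A over %d frame(s)\n",
              x$thickness, nrow(x$per_frame)))
  invisible(x)
}

#' Area per lipid from the box dimensions
#'
#' @param traj an `md_trajectory` (or single `md_frame`) with a periodic
#'   box.
#' @param n_lipids_per_leaflet lipids per leaflet (> 0).
#' @return data.frame with `time` and `apl` (Angstrom^2): Lx * Ly / n.
#' @export
area_per_lipid <- function(traj, n_lipids_per_leaflet) {
  if (n_lipids_per_leaflet <= 0)
    stop("n_lipids_per_leaflet must be positive")
  if (inherits(traj, "md_frame"))
    traj <- frames_to_trajectory(list(traj), "single-frame")
  if (is.null(traj$box)) stop("area per lipid needs a periodic box")
  data.frame(time = traj$times,
             apl = traj$box[, 1] * traj$box[, 2] / n_lipids_per_leaflet)
}
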