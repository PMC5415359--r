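## Local stress tensor on a z-grid (Hardy / Irving-Kirkwood-Noll with the
## top-hat bond function along the straight minimum-image contour) and the
## lateral pressure profile derived from it.
##
## Unit conventions (recorded in output metadata): internal kJ/mol, nm, ps,
## amu; stress converted to bar with the factor 16.6054 (kJ/mol/nm^3 ->
## bar).  Pair-force tables carry one row per pair (i < j) with f the force
## on atom i due to atom j in kJ/mol/nm; positions and velocities enter in
## Angstrom and Angstrom/ps and are converted internally.
##
## Per bin b:  sigma(b) = -(1/V_b) [ sum_{i in b} m_i v_i (x) v_i
##                                 + sum_{pairs} w_b(i,j) r_ij (x) f_ij ]
## where w_b(i,j) is the fraction of the straight minimum-image segment
## from j to i lying in bin b; contributions wrap periodically, and
## sum_b w_b = 1 exactly (partition of unity).

#' Irving-Kirkwood bin weights of a pair segment
#'
#' Fraction of the straight segment from `z_start` to `z_start + dz`
#' (wrapped periodically into `[0, Lz)`) lying in each of `n_bins` equal
#' z-bins.  Weights are non-negative and sum to 1.
#'
#' @param z_start segment start (same length unit as `Lz`).
#' @param dz signed z-extent of the segment (minimum-image, |dz| <= Lz/2).
#' @param Lz box length along z.
#' @param n_bins number of equal bins.
#' @return numeric vector of length `n_bins` summing to 1.
#' @export
ik_bin_weights <- function(z_start, dz, Lz, n_bins) {
  h <- Lz / n_bins
  w <- numeric(n_bins)
  wrap <- function(z) z - Lz * floor(z / Lz)
  if (abs(dz) < 1e-12) {
    b <- min(n_bins, 1L + floor(wrap(z_start) / h))
    w[b] <- 1
    return(w)
  }
  zlo <- wrap(min(z_start, z_start + dz))
  d <- abs(dz)
  for (b in seq_len(n_bins)) {
    e0 <- (b - 1) * h; e1 <- b * h
    kmin <- floor((zlo - e1) / Lz)
    kmax <- floor((zlo + d - e0) / Lz)
    for (k in kmin:kmax) {
      lo <- max(zlo, e0 + k * Lz); hi <- min(zlo + d, e1 + k * Lz)
      if (hi > lo) w[b] <- w[b] + (hi - lo)
    }
  }
  w / d
}

.check_constant_box <- function(traj) {
  if (is.null(traj$box)) stop("local stress needs a periodic box")
  b <- traj$box
  if (nrow(b) > 1 && any(abs(sweep(b, 2, b[1, ])) > 1e-9))
    stop("local stress requires a constant box across frames")
  b[1, ]
}

#' Local stress tensor on a z-grid
#'
#' Computes the z-binned Hardy/Irving-Kirkwood stress from per-frame
#' velocities (kinetic term) and pair-force tables (virial term), averaged
#' over frames and converted to bar.
#'
#' @param traj an `md_trajectory` carrying `velocities` and `forces`
#'   (see [make_force_system()] for the force-table convention).
#' @param bin_width bin width in nm (default 0.1).
#' @param kinetic "velocities" (use the stored velocities; the default),
#'   "thermal" (substitute the ideal thermal term rho(z) kT I at
#'   `temperature`, flagged in metadata for trajectories without
#'   velocities), or "none".
#' @param temperature Kelvin; required for `kinetic = "thermal"`.
#' @return object of class `stress_field`: list with `z` (bin centres,
#'   nm), `sigma` (n_bins x 3 x 3 array, bar), `bin_width` (nm),
#'   `bin_volume` (nm^3), `n_frames`, `kinetic`, `units`.
#' @export
local_stress <- function(traj, bin_width = 0.1,
                         kinetic = c("velocities", "thermal", "none"),
                         temperature = NULL) {
  kinetic <- match.arg(kinetic)
  box <- .check_constant_box(traj) / 10  # nm
  nf <- n_frames(traj)
  Lz <- box[3]
  n_bins <- max(1L, round(Lz / bin_width))
  h <- Lz / n_bins
  if (abs(h - bin_width) > 1e-6)
    warning(sprintf("bin width rescaled from %g to %g nm to divide the box",
                    bin_width, h))
  if (kinetic == "velocities") {
    if (is.null(traj$velocities)) stop("trajectory has no velocities: ",
                                       "use kinetic = \"thermal\" or \"none\"")
    if (any(is.na(traj$atoms$mass))) stop("atom masses required for the kinetic term")
  }
  if (kinetic == "thermal" && is.null(temperature))
    stop("temperature required for kinetic = \"thermal\"")
  acc <- array(0, c(n_bins, 3, 3))
  wrap_bin <- function(z) pmin(n_bins, 1L + floor((z - Lz * floor(z / Lz)) / h))
  for (f in seq_len(nf)) {
    zs <- traj$xyz[, 3, f] / 10
    bins <- wrap_bin(zs)
    if (kinetic == "velocities") {
      v <- traj$velocities[, , f] / 10  # nm/ps
      m <- traj$atoms$mass
      for (a in seq_len(nrow(v))) {
        vv <- m[a] * tcrossprod(v[a, ])
        acc[bins[a], , ] <- acc[bins[a], , ] + vv
      }
    } else if (kinetic == "thermal") {
      kTI <- .kB * temperature * diag(3)
      for (a in seq_along(bins))
        acc[bins[a], , ] <- acc[bins[a], , ] + kTI
    }
    ft <- traj$forces[[f]]
    if (!is.null(ft) && nrow(ft) > 0) {
      for (p in seq_len(nrow(ft))) {
        i <- ft$i[p]; j <- ft$j[p]
        rij <- .min_image_disp(matrix(traj$xyz[i, , f], 1, 3),
                               matrix(traj$xyz[j, , f], 1, 3),
                               box * 10)[1, ] / 10  # nm
        fij <- c(ft$fx[p], ft$fy[p], ft$fz[p])
        rf <- outer(rij, fij)
        w <- ik_bin_weights(zs[j], rij[3], Lz, n_bins)
        nz <- which(w > 0)
        for (b in nz) acc[b, , ] <- acc[b, , ] + w[b] * rf
      }
    }
  }
  vol <- box[1] * box[2] * h
  sigma <- -acc / (vol * nf) * .PRESSURE_FACTOR
  structure(list(z = (seq_len(n_bins) - 0.5) * h, sigma = sigma,
                 bin_width = h, bin_volume = vol, n_frames = nf,
                 kinetic = kinetic,
                 units = list(stress = "bar", z = "nm",
                              conversion = .PRESSURE_FACTOR)),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("<stress_field> %d z-bins x %.3g nm, %d frame(s), kinetic=%s\n",
              length(x$z), x$bin_width, x$n_frames, x$kinetic))
  invisible(x)
}

#' Whole-box stress tensor (virial + kinetic)
#'
#' Independent global oracle: the frame-averaged stress of the entire box
#' without any spatial binning.  The volume-weighted sum of the
#' [local_stress()] bins must equal this to high relative accuracy.
#'
#' @inheritParams local_stress
#' @return 3x3 stress tensor in bar.
#' @export
global_stress <- function(traj, kinetic = c("velocities", "thermal", "none"),
                          temperature = NULL) {
  kinetic <- match.arg(kinetic)
  box <- .check_constant_box(traj) / 10
  nf <- n_frames(traj)
  acc <- matrix(0, 3, 3)
  for (f in seq_len(nf)) {
    if (kinetic == "velocities") {
      v <- traj$velocities[, , f] / 10
      m <- traj$atoms$mass
      acc <- acc + crossprod(v * sqrt(m))
    } else if (kinetic == "thermal") {
      acc <- acc + nrow(traj$atoms) * .kB * temperature * diag(3)
    }
    ft <- traj$forces[[f]]
    if (!is.null(ft) && nrow(ft) > 0) {
      for (p in seq_len(nrow(ft))) {
        rij <- .min_image_disp(matrix(traj$xyz[ft$i[p], , f], 1, 3),
                               matrix(traj$xyz[ft$j[p], , f], 1, 3),
                               box * 10)[1, ] / 10
        acc <- acc + outer(rij, c(ft$fx[p], ft$fy[p], ft$fz[p]))
      }
    }
  }
  -acc / (prod(box) * nf) * .PRESSURE_FACTOR
}

#' Lateral pressure profile from a stress field
#'
#' P = -sigma per bin; P_par = (Pxx + Pyy)/2, P_perp = Pzz,
#' P_L = P_par - P_perp.  The surface tension is the midpoint-rule
#' integral gamma = -sum_b P_L(b) * dz.
#'
#' @param field a [local_stress()] result.
#' @return data.frame of class `pressure_profile` with columns `z_nm`,
#'   `Pxx`, `Pyy`, `Pzz`, `P_par`, `P_perp`, `P_L` (bar); attributes
#'   `surface_tension_bar_A` and `surface_tension_mN_m`.
#' @export
pressure_profile <- function(field) {
  stopifnot(inherits(field, "stress_field"))
  P <- -field$sigma
  df <- data.frame(z_nm = field$z,
                   Pxx = P[, 1, 1], Pyy = P[, 2, 2], Pzz = P[, 3, 3])
  df$P_par <- (df$Pxx + df$Pyy) / 2
  df$P_perp <- df$Pzz
  df$P_L <- df$P_par - df$P_perp
  gamma_bar_A <- -sum(df$P_L) * field$bin_width * 10  # bar * Angstrom
  structure(df, class = c("pressure_profile", "data.frame"),
            surface_tension_bar_A = gamma_bar_A,
            surface_tension_mN_m = gamma_bar_A * 0.01,
            n_frames = field$n_frames, bin_width_nm = field$bin_width,
            kinetic = field$kinetic, units = field$units)
}

#' Compare two pressure profiles
#'
#' Per-bin differences (b minus a) and region-integrated changes over
#' configured z-intervals, e.g. the bilayer core and the interfacial
#' regions.
#'
#' @param a,b [pressure_profile()] tables.
#' @param regions named list of z-intervals `c(lo, hi)` in nm.
#' @param resample if TRUE and the grids differ, linearly resample the
#'   finer profile onto the coarser grid; if FALSE a grid mismatch is an
#'   error.
#' @return list with `per_bin` (z_nm, dP_L) and `regions` (region,
#'   integral_bar_nm).
#' @export
compare_profiles <- function(a, b, regions = list(), resample = FALSE) {
  if (length(a$z_nm) != length(b$z_nm) || any(abs(a$z_nm - b$z_nm) > 1e-9)) {
    if (!resample) stop("incompatible grids: enable resample to compare")
    if (length(a$z_nm) > length(b$z_nm)) a <- .resample_profile(a, b$z_nm)
    else b <- .resample_profile(b, a$z_nm)
  }
  d <- data.frame(z_nm = a$z_nm, dP_L = b$P_L - a$P_L)
  h <- if (length(d$z_nm) > 1) diff(d$z_nm)[1] else 1
  reg <- data.frame(region = character(), integral_bar_nm = numeric())
  for (nm in names(regions)) {
    iv <- regions[[nm]]
    inr <- d$z_nm >= iv[1] & d$z_nm <= iv[2]
    reg <- rbind(reg, data.frame(region = nm,
                                 integral_bar_nm = sum(d$dP_L[inr]) * h))
  }
  list(per_bin = d, regions = reg)
}

.resample_profile <- function(p, z_target) {
  out <- data.frame(z_nm = z_target)
  for (col in c("Pxx", "Pyy", "Pzz", "P_par", "P_perp", "P_L"))
    out[[col]] <- stats::approx(p$z_nm, p[[col]], z_target, rule = 2)$y
  out
}
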