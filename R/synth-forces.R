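## Particle systems with analytically known forces, used as oracles for the
## local-stress module: an ideal gas (kinetic term only), a single harmonic
## pair (virial term known in closed form), and a truncated Lennard-Jones
## fluid (pairwise forces recorded exactly as generated).  Positions are
## resampled per frame or held static -- there is no integration.

#' Force-system specification
#'
#' @param kind one of "ideal_gas", "harmonic_pair", "lj_fluid".
#' @param n_particles particle count (ignored for harmonic_pair, which has
#'   two).
#' @param temperature Kelvin (> 0); sets Maxwell-Boltzmann velocities.
#' @param box box lengths (Angstrom).
#' @param mass particle mass (amu).
#' @param k_spring harmonic spring constant (kJ/mol/A^2).
#' @param r0 harmonic rest length (Angstrom).
#' @param pair_placement for harmonic_pair: positions of the two particles,
#'   a 2 x 3 matrix (Angstrom); default spans three 0.1-nm z-bins.
#' @param epsilon,sigma,cutoff truncated-LJ parameters (kJ/mol, Angstrom,
#'   Angstrom).
#' @param seed RNG seed.
#' @return a `force_system_spec` list.
#' @export
force_system_spec <- function(kind = c("ideal_gas", "harmonic_pair", "lj_fluid"),
                              n_particles = 200, temperature = 310,
                              box = c(20, 20, 20), mass = 39.948,
                              k_spring = 100, r0 = 3,
                              pair_placement = NULL,
                              epsilon = 1, sigma = 3.4, cutoff = 8,
                              seed = 1) {
  kind <- match.arg(kind)
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(kind = kind, n_particles = n_particles,
                 temperature = temperature, box = as.numeric(box),
                 mass = mass, k_spring = k_spring, r0 = r0,
                 pair_placement = pair_placement,
                 epsilon = epsilon, sigma = sigma, cutoff = cutoff,
                 seed = seed),
            class = "force_system_spec")
}

.mb_velocities <- function(n, mass_amu, temperature) {
  ## Maxwell-Boltzmann velocities in A/ps: sd = sqrt(kT/m) in nm/ps * 10
  sdv <- sqrt(.kB * temperature / mass_amu) * 10
  matrix(rnorm(3 * n, 0, sdv), n, 3)
}

.lj_forces <- function(pos, box, epsilon, sigma, cutoff) {
  ## truncated LJ: f on i from j along r_ij = r_i - r_j; forces in kJ/mol/nm
  n <- nrow(pos)
  out <- list()
  for (i in seq_len(n - 1)) {
    D <- .min_image_disp(matrix(pos[i, ], n - i, 3, byrow = TRUE),
                         pos[(i + 1):n, , drop = FALSE], box)
    r2 <- rowSums(D * D)
    hit <- which(r2 < cutoff^2 & r2 > 1e-12)
    for (h in hit) {
      r <- sqrt(r2[h])
      sr6 <- (sigma / r)^6
      ## dU/dr = -24 eps (2 sr12 - sr6)/r ; f_i = -dU/dr * rhat (A) -> /0.1 nm
      fmag_A <- 24 * epsilon * (2 * sr6^2 - sr6) / r
      f <- fmag_A * D[h, ] / r * 10  # kJ/mol/A -> kJ/mol/nm
      out[[length(out) + 1L]] <- c(i, i + h, f)
    }
  }
  if (length(out) == 0L)
    return(data.frame(i = integer(), j = integer(),
                      fx = numeric(), fy = numeric(), fz = numeric()))
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
             fx = m[, 3], fy = m[, 4], fz = m[, 5])
}

#' Synthetic force system with exact pair-force tables
#'
#' Generates a trajectory with velocities and per-frame pair-force tables
#' whose values are known analytically: `ideal_gas` has Maxwell-Boltzmann
#' velocities and no pair forces; `harmonic_pair` has two particles with
#' f = -k (r - r0) rhat recorded exactly (zero velocities); `lj_fluid` has
#' pairwise truncated-LJ forces recorded exactly.  Force-table convention:
#' one row per pair (i < j), f the force on i due to j, in kJ/mol/nm.
#'
#' @param spec a [force_system_spec()].
#' @param n_frames number of frames.
#' @return list with `trajectory` (velocities and forces attached) and
#'   `ground_truth`.
#' @export
make_force_system <- function(spec = force_system_spec(), n_frames = 100) {
  stopifnot(inherits(spec, "force_system_spec"))
  set.seed(spec$seed)
  box <- spec$box
  if (spec$kind == "harmonic_pair") {
    pos <- spec$pair_placement
    if (is.null(pos)) pos <- rbind(c(5, 5, 4.6), c(5, 5, 4.6 + spec$r0 + 1))
    n <- 2L
  } else {
    n <- spec$n_particles
  }
  at <- atom_table(serial = seq_len(n), name = "AR", resname = "AR",
                   resid = seq_len(n), chain = "X", element = "C",
                   x = 0, y = 0, z = 0, mass = spec$mass)
  xyz <- array(NA_real_, c(n, 3, n_frames))
  vel <- array(0, c(n, 3, n_frames))
  forces <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (spec$kind == "harmonic_pair") {
      p <- pos
      frc <- {
        d <- .min_image_disp(matrix(p[1, ], 1, 3), matrix(p[2, ], 1, 3), box)
        r <- sqrt(sum(d * d))
        if (abs(r - spec$r0) < 1e-15) {
          data.frame(i = integer(), j = integer(),
                     fx = numeric(), fy = numeric(), fz = numeric())
        } else {
          fv <- -spec$k_spring * (r - spec$r0) * (d / r) * 10  # kJ/mol/nm
          data.frame(i = 1L, j = 2L, fx = fv[1], fy = fv[2], fz = fv[3])
        }
      }
    } else {
      p <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
      vel[, , f] <- .mb_velocities(n, spec$mass, spec$temperature)
      frc <- if (spec$kind == "lj_fluid")
        .lj_forces(p, box, spec$epsilon, spec$sigma, spec$cutoff)
      else data.frame(i = integer(), j = integer(),
                      fx = numeric(), fy = numeric(), fz = numeric())
    }
    xyz[, , f] <- p
    forces[[f]] <- frc
  }
  traj <- md_trajectory(at, xyz, box = matrix(box, 1),
                        times = seq_len(n_frames) - 1,
                        velocities = vel, forces = forces,
                        topology_source = paste0("synthetic-", spec$kind))
  list(trajectory = traj,
       ground_truth = list(kind = spec$kind, temperature = spec$temperature,
                           density_per_nm3 = n / prod(box / 10),
                           k_spring = spec$k_spring, r0 = spec$r0,
                           seed = spec$seed))
}
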