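## Synthetic planar bilayers: coarse pseudo-lipids (one phosphate-like head
## bead "PH" plus tail beads "T1..Tn") in two leaflets.  No chemistry; the
## generator only guarantees labelled head/tail particles at prescribed
## geometry, which is all the geometry and contact analyses require.

#' Bilayer specification
#'
#' Defaults emulate an unstretched POPC bilayer: phosphate-plane separation
#' 36 Angstrom and area per lipid 64 Angstrom^2.  A stretched-bilayer
#' stand-in is obtained with `thickness = 31` and a larger area per lipid.
#'
#' @param n_lipids_per_leaflet lipids per leaflet.
#' @param thickness phosphate-plane separation (Angstrom).
#' @param area_per_lipid Angstrom^2 per lipid; fixes the xy box area.
#' @param tail_atoms_per_lipid tail beads per lipid.
#' @param leaflet_z_jitter sd (Angstrom) of Gaussian z-jitter applied to
#'   head beads.
#' @param seed RNG seed.
#' @return a `bilayer_spec` list.
#' @export
bilayer_spec <- function(n_lipids_per_leaflet = 100, thickness = 36,
                         area_per_lipid = 64, tail_atoms_per_lipid = 3,
                         leaflet_z_jitter = 0, seed = 1) {
  if (thickness <= 0 || area_per_lipid <= 0)
    stop("thickness and area_per_lipid must be positive")
  structure(list(n_lipids_per_leaflet = n_lipids_per_leaflet,
                 thickness = thickness, area_per_lipid = area_per_lipid,
                 tail_atoms_per_lipid = tail_atoms_per_lipid,
                 leaflet_z_jitter = leaflet_z_jitter, seed = seed),
            class = "bilayer_spec")
}

.bilayer_frame <- function(spec, time = 0) {
  n <- spec$n_lipids_per_leaflet
  nt <- spec$tail_atoms_per_lipid
  L <- sqrt(n * spec$area_per_lipid)
  ng <- ceiling(sqrt(n))
  g <- (seq_len(ng) - 0.5) * L / ng
  xy <- as.matrix(expand.grid(x = g, y = g))[seq_len(n), , drop = FALSE]
  per <- nt + 1L
  name <- character(); resid <- integer(); x <- y <- z <- numeric()
  for (leaflet in c(1, -1)) {
    z0 <- leaflet * spec$thickness / 2
    jit <- if (spec$leaflet_z_jitter > 0)
      rnorm(n, 0, spec$leaflet_z_jitter) else numeric(n)
    name <- c(name, rep(c("PH", paste0("T", seq_len(nt))), n))
    resid <- c(resid, rep((if (leaflet == 1) 0L else n) + seq_len(n), each = per))
    x <- c(x, rep(xy[, 1], each = per))
    y <- c(y, rep(xy[, 2], each = per))
    z <- c(z, as.vector(vapply(seq_len(n), function(i)
      c(z0 + jit[i], z0 - leaflet * seq_len(nt) * 4), numeric(per))))
  }
  at <- atom_table(serial = seq_along(x), name = name, resname = "LIP",
                   resid = resid, chain = "L",
                   element = ifelse(name == "PH", "P", "C"),
                   x = x, y = y, z = z)
  md_frame(at, box = c(L, L, spec$thickness + 40), time = time)
}

#' Synthetic planar bilayer
#'
#' Two leaflets of coarse pseudo-lipids on a grid; one phosphate-like bead
#' per lipid at z = +/- thickness/2 (+ optional jitter); the xy box area
#' equals `n_lipids_per_leaflet * area_per_lipid` exactly.
#'
#' @param spec a [bilayer_spec()].
#' @return an `md_frame`.
#' @export
make_bilayer <- function(spec = bilayer_spec()) {
  set.seed(spec$seed)
  .bilayer_frame(spec)
}

#' Synthetic bilayer trajectory
#'
#' Repeats [make_bilayer()] with independent head-bead jitter per frame;
#' ground truth records the planted thickness and area per lipid.
#'
#' @param spec a [bilayer_spec()].
#' @param n_frames number of frames.
#' @param dt frame spacing (ps).
#' @return list with `trajectory` and `ground_truth`.
#' @export
make_bilayer_trajectory <- function(spec = bilayer_spec(), n_frames = 50,
                                    dt = 100) {
  set.seed(spec$seed)
  frames <- lapply(seq_len(n_frames), function(k)
    .bilayer_frame(spec, time = (k - 1) * dt))
  list(trajectory = frames_to_trajectory(frames, "synthetic-bilayer"),
       ground_truth = list(thickness = spec$thickness,
                           area_per_lipid = spec$area_per_lipid,
                           n_lipids_per_leaflet = spec$n_lipids_per_leaflet,
                           leaflet_z_jitter = spec$leaflet_z_jitter,
                           seed = spec$seed))
}
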