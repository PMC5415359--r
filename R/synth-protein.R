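## Synthetic two-chain channel models and down->up transition trajectories.
##
## The dimer is a C2-symmetric bundle of ideal Calpha helices (M1-M4 per
## chain).  The six residues that define the gating distances are "pinned":
## each mobile key atom (G324, W326, M322 on M4) is placed at
## partner + d * unit_vector with a state-independent direction, so the
## fenestration/zipper/expansion distances equal the stated reference values
## exactly, and moving a key atom along its direction produces an exact
## sigmoidal distance series in the transition generator.  The remaining
## helix atoms are decorative bulk used by RMSD, classification and
## cross-sectional area analyses; in the up state their cytoplasmic halves
## are splayed radially outward to emulate the lower-half expansion seen
## between the down and up crystal forms.

.helix_layout <- list(
  M1 = list(range = c(72, 102),  axis = c(15, -2), z0 = -23, phase = 0.0),
  M2 = list(range = c(186, 228), axis = c(6, 4),   z0 = -25, phase = 1.0),
  M3 = list(range = c(234, 264), axis = c(13, 6),  z0 = -15, phase = 2.0),
  M4 = list(range = c(302, 340), axis = c(10, -2), z0 = -20, phase = 3.0)
)

## pinned partner atoms (chain A frame of reference) and the fixed unit
## vectors along which the mobile M4 key atoms sit
.pinned <- local({
  unit <- function(v) v / sqrt(sum(v * v))
  list(
    partners = list(P198 = c(7, 4, -10), G212 = c(6, 7, -6), R237 = c(13, 6, -9)),
    dirs = list(
      fenestration = unit(c(0.97, 0.19, 0.15)),  # from P198 (adjacent chain)
      zipper       = unit(c(-0.5, -0.8, 0.3)),   # from R237 (same chain)
      expansion    = unit(c(0.3, -0.9, -0.3))    # from G212 (same chain)
    ),
    mobile = c(fenestration = 324, zipper = 326, expansion = 322),
    anchor = c(fenestration = 198, zipper = 237, expansion = 212)
  )
})

.c2 <- function(p) c(-p[1], -p[2], p[3])  # two-fold rotation about z

#' Default gating-pair configuration
#'
#' The three inter-residue distances that track the down/up transition of a
#' K2P channel dimer: the fenestration (G324 on M4 to P198 on M2 of the
#' adjacent chain), the zipper (W326 on M4 to R237 on M3, same chain) and
#' the expansion (M322 on M4 to G212 on M2, same chain).  The adjacent-chain
#' mapping is explicit, never inferred.
#'
#' @param atom atom name used for distances (default Calpha); set
#'   `mode = "min-heavy"` in [gating_distances()] for minimum heavy-atom
#'   distances instead.
#' @param partner_map named character vector mapping each chain to its
#'   adjacent chain.
#' @return a `gating_pairs` list.
#' @export
gating_pairs <- function(atom = "CA", partner_map = c(A = "B", B = "A")) {
  structure(list(
    fenestration = list(resid_a = 324, resid_b = 198, adjacent = TRUE),
    zipper       = list(resid_a = 326, resid_b = 237, adjacent = FALSE),
    expansion    = list(resid_a = 322, resid_b = 212, adjacent = FALSE),
    atom = atom, partner_map = partner_map
  ), class = "gating_pairs")
}

.build_chain <- function(chain_id, rotate = FALSE, ref_dist, bead_radius,
                         splay = 0, hinge_z = 0, taper = 10) {
  rise <- 1.5; hrad <- 2.3; turn <- 100 * pi / 180
  serial <- 0L
  rows <- list()
  pinned_resid <- c(.pinned$mobile, .pinned$anchor)
  for (h in names(.helix_layout)) {
    hl <- .helix_layout[[h]]
    resids <- hl$range[1]:hl$range[2]
    k <- seq_along(resids) - 1
    pos <- cbind(hl$axis[1] + hrad * cos(hl$phase + k * turn),
                 hl$axis[2] + hrad * sin(hl$phase + k * turn),
                 hl$z0 + rise * k)
    for (j in seq_along(resids)) {
      r <- resids[j]
      p <- pos[j, ]
      if (r %in% .pinned$anchor) {
        nm <- names(.pinned$anchor)[match(r, .pinned$anchor)]
        p <- .pinned$partners[[c(fenestration = "P198", zipper = "R237",
                                 expansion = "G212")[nm]]]
      } else if (r %in% .pinned$mobile) {
        nm <- names(.pinned$mobile)[match(r, .pinned$mobile)]
        anchor <- .pinned$partners[[c(fenestration = "P198", zipper = "R237",
                                      expansion = "G212")[nm]]]
        if (nm == "fenestration") anchor <- .c2(anchor)  # adjacent chain's P198
        p <- anchor + ref_dist[[nm]] * .pinned$dirs[[nm]]
      } else if (splay > 0 && p[3] < hinge_z) {
        rho <- sqrt(p[1]^2 + p[2]^2)
        f <- splay * min(1, (hinge_z - p[3]) / taper)
        p[1:2] <- p[1:2] * (rho + f) / rho
      }
      if (rotate) p <- .c2(p)
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- c(p, r)
    }
  }
  m <- do.call(rbind, rows)
  at <- atom_table(serial = seq_len(nrow(m)), name = "CA", resname = "ALA",
                   resid = m[, 4], chain = chain_id, element = "C",
                   x = m[, 1], y = m[, 2], z = m[, 3], mass = 12.011)
  at$vdw <- bead_radius  # coarse envelope radius for Calpha-only models
  at
}

#' Synthetic down/up reference pair
#'
#' Builds two-chain Calpha-only helical models of the "down" and "up"
#' conformations whose fenestration/zipper/expansion distances equal the
#' supplied reference values exactly (pinned construction, see source).
#' In the up state the cytoplasmic halves (z < `hinge_z`) of the helices
#' are splayed radially outward by `splay` Angstrom, emulating the
#' lower-half cross-sectional expansion between the down and up crystal
#' forms of mechanosensitive K2P channels.
#'
#' @param reference_distances list with elements `down` and `up`, each a
#'   named list fenestration/zipper/expansion in Angstrom.  Defaults follow
#'   the directions of change seen on membrane stretch (fenestration
#'   contracts; zipper and expansion grow).
#' @param bead_radius effective envelope radius (Angstrom) stored in the
#'   vdw column of the Calpha beads; used by area profiles.
#' @param splay radial outward displacement (Angstrom) of the up state's
#'   cytoplasmic half.
#' @param hinge_z z (Angstrom) above which no splay is applied.
#' @param box box lengths for the returned frames (Angstrom).
#' @return list with `down` and `up` frames, the realised
#'   `reference_distances`, and the `pairs` ([gating_pairs()]) they satisfy.
#' @export
make_reference_pair <- function(
    reference_distances = list(
      down = list(fenestration = 14, zipper = 8, expansion = 7),
      up   = list(fenestration = 6,  zipper = 14, expansion = 13)),
    bead_radius = 4, splay = 8, hinge_z = 0, box = c(90, 90, 140)) {
  build <- function(rd, spl) {
    at <- rbind(.build_chain("A", FALSE, rd, bead_radius, spl, hinge_z),
                .build_chain("B", TRUE, rd, bead_radius, spl, hinge_z))
    at$serial <- seq_len(nrow(at))
    md_frame(at, box = box, time = 0)
  }
  list(down = build(reference_distances$down, 0),
       up = build(reference_distances$up, splay),
       reference_distances = reference_distances,
       pairs = gating_pairs())
}

#' Transition specification for the synthetic generator
#'
#' @param n_frames number of frames.
#' @param dt frame spacing (ps).
#' @param event_times named list per chain (`A`, `B`), each
#'   `c(unzip = , expand = , close = )` in ps.  Per chain the generator
#'   enforces unzip <= expand <= close, the order observed for the
#'   stretch-induced transition.
#' @param reference_distances as in [make_reference_pair()].
#' @param noise_sd Gaussian noise sd (Angstrom) added to each gating
#'   distance series (applied along the pair direction, so the distance
#'   noise is exactly N(0, noise_sd)); either a scalar or a named list
#'   per metric (fenestration/zipper/expansion), e.g. 10 percent of each
#'   metric's step height.
#' @param sigmoid_width width (ps) of the planted sigmoidal steps; must be
#'   well below the event spacing for unambiguous recovery.
#' @param seed RNG seed.
#' @return a `transition_spec` list.
#' @export
transition_spec <- function(n_frames = 200, dt = 0.5,
                            event_times = list(A = c(unzip = 20, expand = 45, close = 70),
                                               B = c(unzip = 30, expand = 55, close = 80)),
                            reference_distances = NULL,
                            noise_sd = 0, sigmoid_width = 2, seed = 1) {
  if (is.null(reference_distances))
    reference_distances <- make_reference_pair()$reference_distances
  t_end <- (n_frames - 1) * dt
  for (ch in names(event_times)) {
    ev <- event_times[[ch]]
    if (!(ev["unzip"] <= ev["expand"] && ev["expand"] <= ev["close"]))
      stop("event order violated for chain ", ch,
           ": require unzip <= expand <= close")
    if (any(ev < 0 | ev > t_end))
      stop("event time outside the simulated window for chain ", ch)
  }
  structure(list(n_frames = n_frames, dt = dt, event_times = event_times,
                 reference_distances = reference_distances,
                 noise_sd = noise_sd, sigmoid_width = sigmoid_width,
                 seed = seed),
            class = "transition_spec")
}

## metric driven by each event
.metric_of_event <- c(unzip = "zipper", expand = "expansion", close = "fenestration")

#' Synthetic down->up transition trajectory with planted events
#'
#' Generates a two-chain trajectory in which each chain's three gating
#' distances follow sigmoidal steps centred at the planted event times
#' (zipper at `unzip`, expansion at `expand`, fenestration at `close`),
#' plus Gaussian noise of sd `noise_sd`.  The non-key atoms interpolate
#' from the down to the up reference with a sigmoid centred at the chain's
#' `expand` time.  Ground truth records the exact event times.
#'
#' @param spec a [transition_spec()].
#' @return list with `trajectory` (an `md_trajectory`) and `ground_truth`.
#' @export
make_transition_trajectory <- function(spec) {
  stopifnot(inherits(spec, "transition_spec"))
  set.seed(spec$seed)
  refs <- make_reference_pair(reference_distances = spec$reference_distances)
  atoms <- refs$down$atoms
  down_xyz <- as.matrix(refs$down$atoms[, c("x", "y", "z")])
  up_xyz <- as.matrix(refs$up$atoms[, c("x", "y", "z")])
  times <- (seq_len(spec$n_frames) - 1) * spec$dt
  sig <- function(t, t0) 1 / (1 + exp(-(t - t0) / spec$sigmoid_width))

  key_rows <- list(); anchor_rows <- integer()
  for (ch in c("A", "B")) {
    other <- if (ch == "A") "B" else "A"
    for (ev in names(.metric_of_event)) {
      metric <- .metric_of_event[[ev]]
      mob_resid <- .pinned$mobile[[metric]]
      anc_resid <- .pinned$anchor[[metric]]
      anc_chain <- if (metric == "fenestration") other else ch
      i_mob <- which(atoms$resid == mob_resid & atoms$chain == ch)
      i_anc <- which(atoms$resid == anc_resid & atoms$chain == anc_chain)
      key_rows[[paste(ch, metric)]] <- list(
        chain = ch, metric = metric, event = ev, i = i_mob,
        anchor = down_xyz[i_anc, ],
        dir = (down_xyz[i_mob, ] - down_xyz[i_anc, ]) /
          sqrt(sum((down_xyz[i_mob, ] - down_xyz[i_anc, ])^2)),
        d_down = spec$reference_distances$down[[metric]],
        d_up = spec$reference_distances$up[[metric]],
        noise_sd = if (is.list(spec$noise_sd)) spec$noise_sd[[metric]]
                   else spec$noise_sd,
        t0 = spec$event_times[[ch]][[ev]])
      anchor_rows <- c(anchor_rows, i_anc)
    }
  }
  key_idx <- vapply(key_rows, function(k) k$i, 1L)

  nf <- spec$n_frames
  xyz <- array(NA_real_, c(nrow(atoms), 3, nf))
  for (f in seq_len(nf)) {
    t <- times[f]
    fr <- down_xyz
    for (ch in c("A", "B")) {
      s <- sig(t, spec$event_times[[ch]]["expand"])
      rows <- which(atoms$chain == ch)
      rows <- setdiff(rows, c(key_idx, anchor_rows))
      fr[rows, ] <- (1 - s) * down_xyz[rows, ] + s * up_xyz[rows, ]
    }
    for (k in key_rows) {
      d <- k$d_down + (k$d_up - k$d_down) * sig(t, k$t0)
      if (k$noise_sd > 0) d <- d + rnorm(1, 0, k$noise_sd)
      fr[k$i, ] <- k$anchor + d * k$dir
    }
    xyz[, , f] <- fr
  }
  traj <- md_trajectory(atoms, xyz,
                        box = matrix(refs$down$box, 1), times = times,
                        topology_source = "synthetic-transition")
  gt <- list(event_times = spec$event_times,
             metric_of_event = as.list(.metric_of_event),
             reference_distances = spec$reference_distances,
             noise_sd = spec$noise_sd, sigmoid_width = spec$sigmoid_width,
             dt = spec$dt, seed = spec$seed)
  list(trajectory = traj, ground_truth = gt)
}
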