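## Conformational-state metrics: Kabsch superposition and RMSD to the down
## and up reference structures, the three gating distances, state
## classification, the landscape table, and event-order detection.

## match atoms 1:1 by (chain, resid, name) between two selections
.match_selection <- function(mob_atoms, mob_idx, ref_atoms, ref_idx) {
  key <- function(at, i) paste(at$chain[i], at$resid[i], at$name[i], sep = "\r")
  km <- key(mob_atoms, mob_idx); kr <- key(ref_atoms, ref_idx)
  if (anyDuplicated(km) || anyDuplicated(kr))
    stop("atom-mapping mismatch: selection keys (chain, resid, name) are not unique")
  m <- match(km, kr)
  if (any(is.na(m)) || length(km) != length(kr))
    stop("atom-mapping mismatch: selections do not map 1:1 by (chain, resid, name)")
  list(mob = mob_idx, ref = ref_idx[m])
}

.kabsch <- function(P, Q) {
  ## optimal rotation R and translation t such that P %*% R + t ~ Q
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)   # proper rotation, det = +1
  t <- cq - as.vector(cp %*% R)
  fitted <- sweep(Pc %*% R, 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Superposes `mobile` onto `reference` over the atoms named by `spec`,
#' matched 1:1 by (chain, resid, atom name).  Returns the proper rotation
#' (det = +1), translation, and the minimised Calpha RMSD.
#'
#' @param mobile,reference `md_frame` objects.
#' @param spec a [selection_spec()]; default selects all Calpha atoms.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom), and the matched atom indices.
#' @export
superpose <- function(mobile, reference,
                      spec = selection_spec(atom_names = "CA")) {
  mi <- select_atoms(mobile, spec); ri <- select_atoms(reference, spec)
  mp <- .match_selection(mobile$atoms, mi, reference$atoms, ri)
  P <- as.matrix(mobile$atoms[mp$mob, c("x", "y", "z")])
  Q <- as.matrix(reference$atoms[mp$ref, c("x", "y", "z")])
  if (nrow(P) < 3) stop("superposition needs at least 3 atoms")
  sv <- svd(sweep(Q, 2, colMeans(Q)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate (collinear) selection: superposition is ill-defined")
  c(.kabsch(P, Q), list(mobile_idx = mp$mob, reference_idx = mp$ref))
}

#' RMSD of every frame against a reference structure
#'
#' @param traj an `md_trajectory`.
#' @param reference an `md_frame`.
#' @param spec a [selection_spec()] (default: all Calpha atoms).
#' @return data.frame with columns `time` (ps) and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference,
                        spec = selection_spec(atom_names = "CA")) {
  f1 <- get_frame(traj, 1)
  mi <- select_atoms(f1, spec); ri <- select_atoms(reference, spec)
  mp <- .match_selection(f1$atoms, mi, reference$atoms, ri)
  Q <- as.matrix(reference$atoms[mp$ref, c("x", "y", "z")])
  r <- vapply(seq_len(n_frames(traj)), function(k) {
    P <- cbind(traj$xyz[mp$mob, 1, k], traj$xyz[mp$mob, 2, k],
               traj$xyz[mp$mob, 3, k])
    .kabsch(P, Q)$rmsd
  }, 0)
  data.frame(time = traj$times, rmsd = r)
}

## resolve the two atom groups of one gating pair for one chain
.pair_atoms <- function(atoms, pair, chain, pairs, mode) {
  bchain <- if (pair$adjacent) pairs$partner_map[[chain]] else chain
  pick <- function(resid, ch) {
    i <- which(atoms$resid == resid & atoms$chain == ch)
    if (mode == "ca") i <- i[atoms$name[i] == pairs$atom]
    else i <- i[atoms$element[i] != "H"]
    if (length(i) == 0L)
      stop(sprintf("residue %d (chain %s) missing from the model: %s",
                   resid, ch,
                   "analyses that need an absent residue raise an error"))
    i
  }
  list(a = pick(pair$resid_a, chain), b = pick(pair$resid_b, bchain))
}

#' Gating distances (fenestration, zipper, expansion)
#'
#' Computes the three per-chain gating distances for every frame using
#' minimum-image distances.  Default atoms are Calpha; `mode = "min-heavy"`
#' uses the minimum heavy-atom distance between the two residues instead.
#'
#' @param traj an `md_trajectory` or a single `md_frame`.
#' @param pairs a [gating_pairs()] configuration.
#' @param mode "ca" (default) or "min-heavy".
#' @return data.frame of class `gating_distances` with columns `time`,
#'   `chain`, `fenestration`, `zipper`, `expansion` (Angstrom).
#' @export
gating_distances <- function(traj, pairs = gating_pairs(),
                             mode = c("ca", "min-heavy")) {
  mode <- match.arg(mode)
  if (inherits(traj, "md_frame"))
    traj <- frames_to_trajectory(list(traj), "single-frame")
  atoms <- traj$atoms
  chains <- names(pairs$partner_map)
  metrics <- c("fenestration", "zipper", "expansion")
  sel <- list()
  for (ch in chains) for (m in metrics)
    sel[[paste(ch, m)]] <- .pair_atoms(atoms, pairs[[m]], ch, pairs, mode)
  out <- expand.grid(time = traj$times, chain = chains,
                     stringsAsFactors = FALSE)
  for (m in metrics) out[[m]] <- NA_real_
  nf <- n_frames(traj)
  for (k in seq_len(nf)) {
    box <- if (is.null(traj$box)) NULL else traj$box[k, ]
    for (ch in chains) {
      row <- which(out$time == traj$times[k] & out$chain == ch)
      for (m in metrics) {
        s <- sel[[paste(ch, m)]]
        A <- cbind(traj$xyz[s$a, 1, k], traj$xyz[s$a, 2, k], traj$xyz[s$a, 3, k])
        B <- cbind(traj$xyz[s$b, 1, k], traj$xyz[s$b, 2, k], traj$xyz[s$b, 3, k])
        out[row, m] <- min_pair_distance(A, B, box)
      }
    }
  }
  structure(out, class = c("gating_distances", "data.frame"),
            pairs = pairs, mode = mode)
}

#' Classify frames as down / up / intermediate
#'
#' Each frame is labelled by the nearer reference (by superposed RMSD over
#' `spec`) when the RMSD gap exceeds `margin`, else "intermediate".
#'
#' @param traj an `md_trajectory`.
#' @param down_ref,up_ref reference `md_frame`s.
#' @param spec a [selection_spec()].
#' @param margin classification margin (Angstrom).
#' @return data.frame with `time`, `rmsd_down`, `rmsd_up`, `label`,
#'   `margin`.
#' @export
classify_states <- function(traj, down_ref, up_ref,
                            spec = selection_spec(atom_names = "CA"),
                            margin = 0.5) {
  stopifnot(margin >= 0)
  rd <- rmsd_series(traj, down_ref, spec)$rmsd
  ru <- rmsd_series(traj, up_ref, spec)$rmsd
  label <- ifelse(rd + margin < ru, "down",
                  ifelse(ru + margin < rd, "up", "intermediate"))
  data.frame(time = traj$times, rmsd_down = rd, rmsd_up = ru,
             label = label, margin = margin)
}

#' Landscape table of gating distances
#'
#' Per-frame (time, fenestration, zipper, expansion) tuples sampled at a
#' configurable stride, plus one row per supplied crystal reference
#' computed with the same pair configuration -- the correlation-plot data
#' in which trajectories are compared against the known structures.
#'
#' @param traj an `md_trajectory`.
#' @param crystal_refs named list of `md_frame`s (may be empty).
#' @param pairs a [gating_pairs()].
#' @param stride_ps sampling stride in ps (default 1000 ps = 1 ns).
#' @return data.frame with columns `source`, `time`, `chain`,
#'   `fenestration`, `zipper`, `expansion`.
#' @export
landscape_table <- function(traj, crystal_refs = list(),
                            pairs = gating_pairs(), stride_ps = 1000) {
  keep <- !duplicated(floor(traj$times / stride_ps))
  sub <- md_trajectory(traj$atoms, traj$xyz[, , keep, drop = FALSE],
                       box = if (is.null(traj$box)) NULL else
                         traj$box[keep, , drop = FALSE],
                       times = traj$times[keep],
                       topology_source = traj$topology_source)
  gd <- gating_distances(sub, pairs)
  out <- cbind(source = "trajectory", as.data.frame(gd))
  for (nm in names(crystal_refs)) {
    g <- gating_distances(crystal_refs[[nm]], pairs)
    out <- rbind(out, cbind(source = nm, as.data.frame(g)))
  }
  rownames(out) <- NULL
  out
}

.moving_average <- function(x, w) {
  if (w <= 1) return(x)
  w <- min(w, length(x))
  as.vector(stats::filter(x, rep(1 / w, w), sides = 2)) -> y
  ## fill edge NAs with shrinking one-sided windows
  n <- length(x)
  for (i in which(is.na(y))) {
    h <- (w - 1) %/% 2
    lo <- max(1, i - h); hi <- min(n, i + h)
    y[i] <- mean(x[lo:hi])
  }
  y
}

#' Detect the unzip / expand / close event sequence
#'
#' For each chain and metric, the event time is the first frame at which
#' the moving-average-smoothed distance series crosses the midpoint between
#' its down and up reference values and remains across for at least
#' `dwell_ps`.  Chains are reported independently; `order_ok` is TRUE iff
#' all three events are detected with unzip <= expand <= close.
#'
#' @param gd a [gating_distances()] table.
#' @param down_values,up_values named lists (fenestration/zipper/expansion)
#'   of reference distances (Angstrom); must differ per metric.
#' @param smooth_ps moving-average window (ps); default 5000 ps.
#' @param dwell_ps minimum dwell beyond the midpoint (ps); default 10000 ps.
#' @return data.frame with one row per chain: `chain`, `t_unzip`,
#'   `t_expand`, `t_close` (ps; NA if not detected) and `order_ok`.
#' @export
detect_event_sequence <- function(gd, down_values, up_values,
                                  smooth_ps = 5000, dwell_ps = 10000) {
  metrics <- c("fenestration", "zipper", "expansion")
  for (m in metrics)
    if (down_values[[m]] == up_values[[m]])
      stop("down and up reference values must differ for metric ", m)
  times <- sort(unique(gd$time))
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  w <- max(1L, round(smooth_ps / dt))
  if (w %% 2 == 0) w <- w + 1L
  dwell <- max(1L, round(dwell_ps / dt))
  chains <- unique(gd$chain)
  res <- data.frame(chain = chains, t_unzip = NA_real_, t_expand = NA_real_,
                    t_close = NA_real_, order_ok = FALSE)
  ev_metric <- c(t_unzip = "zipper", t_expand = "expansion",
                 t_close = "fenestration")
  for (ci in seq_along(chains)) {
    sub <- gd[gd$chain == chains[ci], ]
    sub <- sub[order(sub$time), ]
    for (ev in names(ev_metric)) {
      m <- ev_metric[[ev]]
      s <- .moving_average(sub[[m]], w)
      mid <- (down_values[[m]] + up_values[[m]]) / 2
      dir <- sign(up_values[[m]] - down_values[[m]])
      crossed <- dir * (s - mid) > 0
      runs <- rle(crossed)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      ok <- which(runs$values & runs$lengths >= dwell)
      if (length(ok) > 0)
        res[ci, ev] <- sub$time[starts[ok[1]]]
    }
    tt <- unlist(res[ci, c("t_unzip", "t_expand", "t_close")])
    res$order_ok[ci] <- !any(is.na(tt)) &&
      tt[1] <= tt[2] && tt[2] <= tt[3]
  }
  res
}
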