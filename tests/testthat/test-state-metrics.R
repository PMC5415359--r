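# Superposition, RMSD series, gating distances, classification and event
# detection.

test_that("superpose recovers identity and is rigid-invariant", {
  refs <- make_reference_pair()
  s <- superpose(refs$down, refs$down)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)

  moved <- refs$down
  xyz <- as.matrix(moved$atoms[, c("x", "y", "z")])
  moved$atoms[, c("x", "y", "z")] <- rigid_transform(xyz)
  expect_lt(superpose(moved, refs$down)$rmsd, 1e-6)
  # rmsd invariant under rigid transform of either input, and symmetric
  expect_equal(superpose(moved, refs$up)$rmsd, superpose(refs$down, refs$up)$rmsd,
               tolerance = 1e-6)
  expect_equal(superpose(refs$up, refs$down)$rmsd,
               superpose(refs$down, refs$up)$rmsd, tolerance = 1e-6)
})

test_that("superpose errors on collinear or mismatched selections", {
  at <- atom_table(1:3, "CA", "ALA", 1:3, "A", "C",
                   x = c(0, 1, 2), y = 0, z = 0)
  line <- md_frame(at)
  expect_error(superpose(line, line), "collinear")
  refs <- make_reference_pair()
  sub <- refs$up
  sub$atoms <- sub$atoms[sub$atoms$chain == "A", ]
  expect_error(superpose(refs$down, sub), "1:1")
})

test_that("Kabsch RMSD equals the quaternion-grid brute-force minimum", {
  set.seed(42)
  worst <- 0
  for (i in 1:25) {
    P <- matrix(rnorm(15, sd = 3), 5, 3)
    Q <- P + matrix(rnorm(15, sd = 0.4), 5, 3)
    Q <- rigid_transform(Q, axis = rnorm(3), angle = runif(1, 0, pi),
                         shift = rnorm(3, sd = 5))
    at <- atom_table(1:5, "CA", "ALA", 1:5, "A", "C",
                     x = P[, 1], y = P[, 2], z = P[, 3])
    atQ <- at; atQ[, c("x", "y", "z")] <- Q
    kab <- superpose(md_frame(at), md_frame(atQ))$rmsd
    grid <- oracle_grid_rmsd(P, Q)
    expect_gte(grid - kab, -1e-9)  # grid can never beat the optimum
    worst <- max(worst, abs(grid - kab))
  }
  expect_lt(worst, 1e-3)
})

test_that("rmsd_series is monotone on a noiseless down->up interpolation", {
  refs <- make_reference_pair()
  D <- as.matrix(refs$down$atoms[, c("x", "y", "z")])
  U <- as.matrix(refs$up$atoms[, c("x", "y", "z")])
  frames <- lapply(seq(0, 1, length.out = 11), function(s) {
    at <- refs$down$atoms
    at[, c("x", "y", "z")] <- (1 - s) * D + s * U
    md_frame(at, box = refs$down$box, time = s * 10)
  })
  traj <- frames_to_trajectory(frames)
  rd <- rmsd_series(traj, refs$down)$rmsd
  ru <- rmsd_series(traj, refs$up)$rmsd
  expect_true(all(diff(rd) >= -1e-9))
  expect_true(all(diff(ru) <= 1e-9))
  expect_equal(rd[1], 0, tolerance = 1e-8)
  expect_equal(ru[11], 0, tolerance = 1e-8)
  # single-frame trajectory equals superpose output
  one <- frames_to_trajectory(frames[5])
  expect_equal(rmsd_series(one, refs$up)$rmsd,
               superpose(frames[[5]], refs$up)$rmsd)
})

test_that("gating distances: placement, missing residues, heavy-atom mode", {
  # minimal dimer carrying exactly the six configured residues per chain;
  # chain A's G324 sits 4 A from chain B's P198
  mk <- function(extra_cb = FALSE) {
    resids <- c(198, 212, 237, 322, 324, 326)
    base <- data.frame(resid = resids,
                       x = c(0, 2, 4, 6, 8, 10), y = 0, z = 0)
    rows <- do.call(rbind, lapply(c("A", "B"), function(ch) {
      b <- base
      if (ch == "B") { b$x <- b$x + 20; b$x[b$resid == 198] <- 12 }  # |8-12| = 4
      cbind(b, chain = ch)
    }))
    if (extra_cb)
      rows <- rbind(rows, data.frame(resid = 324, x = 10.5, y = 0, z = 0,
                                     chain = "A"))
    nm <- c(rep("CA", 12), if (extra_cb) "CB")
    at <- atom_table(seq_len(nrow(rows)), nm, "ALA", rows$resid, rows$chain,
                     "C", x = rows$x, y = rows$y, z = rows$z)
    md_frame(at, box = c(100, 100, 100))
  }
  pairs <- gating_pairs()
  g <- gating_distances(mk(), pairs)
  expect_equal(g$fenestration[g$chain == "A"], 4)
  # missing residue is named in the error
  broken <- mk()
  broken$atoms <- broken$atoms[broken$atoms$resid != 326, ]
  expect_error(gating_distances(broken, pairs), "residue 326")
  # CA mode >= min-heavy-atom mode once side-chain atoms exist
  fr2 <- mk(extra_cb = TRUE)  # CB of A:324 at x = 10.5, closer to B:198 (x = 12)
  gca <- gating_distances(fr2, pairs)$fenestration[1]
  ghv <- gating_distances(fr2, pairs, mode = "min-heavy")$fenestration[1]
  expect_gte(gca, ghv)
  expect_equal(ghv, 1.5)
})

test_that("state classification labels references and midpoints correctly", {
  refs <- make_reference_pair()
  d2 <- refs$down; d2$time <- 1
  down_traj <- frames_to_trajectory(list(refs$down, d2))
  up_traj <- frames_to_trajectory(list(refs$up))
  for (m in c(0, 0.5, 1)) {
    expect_true(all(classify_states(down_traj, refs$down, refs$up,
                                    margin = m)$label == "down"))
    expect_true(all(classify_states(up_traj, refs$down, refs$up,
                                    margin = m)$label == "up"))
  }
  D <- as.matrix(refs$down$atoms[, c("x", "y", "z")])
  U <- as.matrix(refs$up$atoms[, c("x", "y", "z")])
  at <- refs$down$atoms
  at[, c("x", "y", "z")] <- (D + U) / 2
  mid <- frames_to_trajectory(list(md_frame(at, box = refs$down$box)))
  expect_equal(classify_states(mid, refs$down, refs$up, margin = 0.5)$label,
               "intermediate")
})

test_that("landscape table samples at the stride and appends crystal rows", {
  r <- make_transition_trajectory(transition_spec(n_frames = 100, dt = 1))
  refs <- make_reference_pair()
  # stride 10 ps on 100 frames at 1 ps -> 10 sampled times x 2 chains
  ls <- landscape_table(r$trajectory, list(down = refs$down, up = refs$up),
                        stride_ps = 10)
  expect_equal(sum(ls$source == "trajectory"), 2 * 10)
  expect_equal(sum(ls$source == "down"), 2)
  dn <- ls[ls$source == "down" & ls$chain == "A", ]
  expect_equal(dn$fenestration, refs$reference_distances$down$fenestration,
               tolerance = 1e-6)
  ls0 <- landscape_table(r$trajectory, list(), stride_ps = 10)
  expect_true(all(ls0$source == "trajectory"))
})

test_that("event detection: noiseless exactness, constant series, noisy order recovery", {
  spec <- transition_spec(noise_sd = 0, n_frames = 200, dt = 0.5)
  r <- make_transition_trajectory(spec)
  gd <- gating_distances(r$trajectory)
  ev <- detect_event_sequence(gd, spec$reference_distances$down,
                              spec$reference_distances$up,
                              smooth_ps = 2, dwell_ps = 5)
  for (ch in c("A", "B")) {
    row <- ev[ev$chain == ch, ]
    expect_true(row$order_ok)
    expect_lte(abs(row$t_unzip - spec$event_times[[ch]]["unzip"]), 1)
    expect_lte(abs(row$t_expand - spec$event_times[[ch]]["expand"]), 1)
    expect_lte(abs(row$t_close - spec$event_times[[ch]]["close"]), 1)
  }
  # constant series -> nothing detected
  flat <- gd
  for (m in c("fenestration", "zipper", "expansion")) flat[[m]] <- 10
  ev0 <- detect_event_sequence(flat, list(fenestration = 14, zipper = 8,
                                          expansion = 7),
                               list(fenestration = 6, zipper = 14,
                                    expansion = 13),
                               smooth_ps = 2, dwell_ps = 5)
  expect_true(all(is.na(ev0$t_unzip)))
  expect_false(any(ev0$order_ok))
  expect_error(detect_event_sequence(gd, list(fenestration = 5, zipper = 8,
                                              expansion = 7),
                                     list(fenestration = 5, zipper = 14,
                                          expansion = 13)),
               "must differ")

  # noisy order recovery: 10% of each metric's step height, 30 seeds here
  # (the acceptance suite runs the full 100)
  steps <- lapply(c(fenestration = "fenestration", zipper = "zipper",
                    expansion = "expansion"), function(m)
    0.1 * abs(spec$reference_distances$up[[m]] -
                spec$reference_distances$down[[m]]))
  ok <- 0
  for (s in 1:30) {
    sp <- transition_spec(noise_sd = steps, seed = s, n_frames = 200, dt = 0.5)
    g <- gating_distances(make_transition_trajectory(sp)$trajectory)
    e <- detect_event_sequence(g, sp$reference_distances$down,
                               sp$reference_distances$up,
                               smooth_ps = 5, dwell_ps = 10)
    if (all(e$order_ok)) ok <- ok + 1
  }
  expect_gte(ok, 29)
})
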