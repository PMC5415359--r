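# Ion occupancy, water profiles, dewetting detection, and lipid contacts.

test_that("ion occupancy matches schedules and ground truth exactly", {
  sites <- filter_sites()
  # ion fixed at S1 all frames
  pt <- make_pore_trace(pore_trace_spec(ion_site_schedule = matrix("S1", 40)))
  io <- ion_occupancy(pt$trajectory, sites)
  expect_equal(io$probability$probability,
               c(S0 = 0, S1 = 1, S2 = 0, S3 = 0, S4 = 0), ignore_attr = TRUE)
  # alternating S0/S1 on even/odd frames
  sched <- matrix(rep(c("S0", "S1"), 20), ncol = 1)
  pa <- make_pore_trace(pore_trace_spec(ion_site_schedule = sched))
  ia <- ion_occupancy(pa$trajectory, sites)
  expect_equal(ia$probability$probability[1:2], c(0.5, 0.5))
  # synthetic trace probabilities equal GroundTruth exactly
  set.seed(5)
  rs <- matrix(sample(paste0("S", 0:4), 120, replace = TRUE), ncol = 2)
  pr <- make_pore_trace(pore_trace_spec(ion_site_schedule = rs))
  ir <- ion_occupancy(pr$trajectory, sites)
  expect_equal(as.list(setNames(ir$probability$probability,
                                ir$probability$site)),
               pr$ground_truth$site_occupancy)
  expect_error(ion_occupancy(pt$trajectory, sites,
                             selection_spec(atom_names = "NOPE")),
               "matched no atoms")
})

test_that("ion z-density integrates to the mean selected-ion count", {
  sched <- matrix(sample(c("S0", "S2", "S4"), 60, replace = TRUE), ncol = 2)
  pt <- make_pore_trace(pore_trace_spec(ion_site_schedule = sched))
  io <- ion_occupancy(pt$trajectory, filter_sites(), density_bin = 0.5)
  integral <- sum(io$density$density) * 0.5
  expect_equal(integral, 2, tolerance = 1e-6)  # 2 ions always in the filter
})

test_that("water profile counts cavity waters and respects the cylinder", {
  pt <- make_pore_trace(pore_trace_spec(wet_count = 10,
                                        ion_site_schedule = matrix("S1", 30)))
  wp <- water_profile(pt$trajectory, cavity_z = c(-14, 0), cylinder_radius = 5)
  expect_true(all(wp$cavity_counts$count == 10))
  # uniform waters give a roughly flat density inside the cavity interval
  inner <- wp$density$density[wp$density$z > -13 & wp$density$z < -1]
  expect_lt(stats::sd(inner) / mean(inner), 0.5)
  # a tight cylinder away from the axis sees nothing
  wp0 <- water_profile(pt$trajectory, cavity_z = c(-14, 0),
                       cylinder_radius = 1, axis_xy = c(20, 20))
  expect_true(all(wp0$cavity_counts$count == 0))
})

test_that("dewetting detection equals the run-length oracle", {
  # planted dry window
  pt <- make_pore_trace(pore_trace_spec(
    ion_site_schedule = matrix("S1", 100),
    dewetting_intervals = list(c(40, 60))))
  wp <- water_profile(pt$trajectory, cavity_z = c(-14, 0), cylinder_radius = 5)
  dw <- detect_dewetting(wp$cavity_counts, threshold = 5)
  expect_equal(unname(as.matrix(dw[, c("start", "end")])),
               matrix(c(40L, 60L), 1))
  # wet everywhere -> nothing
  expect_equal(nrow(detect_dewetting(rep(10, 50), threshold = 5)), 0)
  # two dry windows separated by one wet frame are not merged
  counts <- rep(10, 30); counts[5:8] <- 0; counts[10:13] <- 0
  dw2 <- detect_dewetting(counts, threshold = 5, min_duration = 2)
  expect_equal(dw2$start, c(5L, 10L))
  expect_equal(dw2$end, c(8L, 13L))
  # 1000 random boolean series against the naive scan oracle
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    counts <- sample(0:9, n, replace = TRUE)
    md <- sample(1:4, 1)
    got <- detect_dewetting(counts, threshold = 5, min_duration = md)
    want <- oracle_dry_intervals(counts < 5, md)
    expect_equal(matrix(as.integer(as.matrix(got[, c("start", "end")])),
                        ncol = 2),
                 matrix(as.integer(want), ncol = 2), ignore_attr = TRUE)
  }
})

test_that("dewetting ground truth round-trips through the detector", {
  pt <- make_pore_trace(pore_trace_spec(
    ion_site_schedule = matrix("S2", 200),
    dewetting_intervals = list(c(20, 35), c(100, 140))))
  wp <- water_profile(pt$trajectory, cavity_z = c(-14, 0), cylinder_radius = 5)
  dw <- detect_dewetting(wp$cavity_counts, threshold = 5, min_duration = 2)
  expect_equal(lapply(seq_len(nrow(dw)), function(i) c(dw$start[i], dw$end[i])),
               pt$ground_truth$dewetting_intervals)
})

test_that("lipid contact series matches the exhaustive pairwise oracle", {
  # tail atom 3 A from the target -> bound; 10 A -> unbound
  mkframe <- function(dist) {
    at <- atom_table(1:2, c("CA", "T1"), c("PRO", "LIP"), c(198, 500),
                     c("A", "L"), "C", x = c(0, dist), y = 0, z = 0)
    md_frame(at, box = c(50, 50, 50))
  }
  t3 <- frames_to_trajectory(list(mkframe(3)))
  s3 <- lipid_contact_series(t3, selection_spec(chain = "A"),
                             selection_spec(chain = "L"))
  expect_true(s3$bound)
  expect_equal(s3$min_dist, 3)
  t10 <- frames_to_trajectory(list(mkframe(10)))
  expect_false(lipid_contact_series(t10, selection_spec(chain = "A"),
                                    selection_spec(chain = "L"))$bound)
  # random clouds against the brute-force oracle
  set.seed(21)
  for (i in 1:25) {
    na <- sample(2:6, 1); nb <- sample(2:8, 1)
    box <- runif(3, 8, 25)
    A <- cbind(runif(na, 0, box[1]), runif(na, 0, box[2]), runif(na, 0, box[3]))
    B <- cbind(runif(nb, 0, box[1]), runif(nb, 0, box[2]), runif(nb, 0, box[3]))
    expect_equal(min_pair_distance(A, B, box), oracle_min_pair(A, B, box),
                 tolerance = 1e-12)
  }
})

test_that("groove series pairs the tip distance with lipid proximity", {
  at <- atom_table(1:7,
                   name = c("CA", "CA", "CA", "CA", "CA", "CA", "T1"),
                   resname = c(rep("ALA", 6), "LIP"),
                   resid = c(226, 243, 240, 226, 243, 240, 900),
                   chain = c("A", "A", "A", "B", "B", "B", "L"),
                   element = "C",
                   x = c(0, 8, 4, 20, 28, 24, 4.5), y = 0, z = 0)
  fr <- md_frame(at, box = c(100, 100, 100))
  traj <- frames_to_trajectory(list(fr))
  g <- groove_series(traj, selection_spec(chain = "L"))
  expect_equal(g$groove[g$chain == "A"], 8)
  # lipid near the chain-A groove centre: closer than groove/2 to S240
  expect_lt(g$min_lipid_dist[g$chain == "A"], 4)
  expect_error(groove_series(traj, selection_spec(resnames = "NOPE")),
               "matched no atoms")
})

test_that("sites derived from carbonyl planes are ordered and non-overlapping", {
  fs <- filter_sites_from_planes(c(14, 11.5, 9, 6.5, 4))
  expect_equal(fs$site, paste0("S", 0:4))
  expect_true(all(fs$zmax > fs$zmin))
  expect_true(all(diff(fs$zmax) < 0))
  expect_true(all(fs$zmin[-5] >= fs$zmax[-1] - 1e-12))
  expect_error(filter_sites(c(1, 2, 3, 4, 5, 6)), "decreasing")
})
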