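# Local stress tensor, pressure profile, and profile comparison.

kB <- 0.00831446261815324
BAR <- 16.6054

test_that("IK bin weights are a partition of unity, including wrapped segments", {
  set.seed(13)
  worst <- 0
  for (i in 1:2000) {
    Lz <- runif(1, 2, 30)
    nb <- sample(2:60, 1)
    z0 <- runif(1, -2 * Lz, 3 * Lz)          # far outside the box too
    dz <- runif(1, -Lz / 2, Lz / 2)          # minimum-image extent
    w <- ik_bin_weights(z0, dz, Lz, nb)
    expect_true(all(w >= 0))
    worst <- max(worst, abs(sum(w) - 1))
  }
  expect_lt(worst, 1e-12)
  # zero-extent segment: all weight in one bin
  w0 <- ik_bin_weights(2.5, 0, 10, 10)
  expect_equal(sum(w0 > 0), 1)
  expect_equal(sum(w0), 1)
})

test_that("a z-aligned harmonic pair is allocated by segment fraction", {
  # pair spans z = 4.6 .. 8.6 A with 1 A bins: fractions 0.1, 1, 1, 1, 0.9 / 4
  fs <- make_force_system(force_system_spec(kind = "harmonic_pair",
          box = c(10, 10, 10), k_spring = 50, r0 = 3,
          pair_placement = rbind(c(5, 5, 4.6), c(5, 5, 8.6))), n_frames = 1)
  sf <- local_stress(fs$trajectory, bin_width = 0.1, kinetic = "none")
  gz <- -sf$sigma[, 3, 3] * sf$bin_volume  # per-bin virial contribution
  nonzero <- which(abs(gz) > 1e-12)
  expect_equal(nonzero, 5:9)
  expect_equal(gz[5:9] / sum(gz), c(0.4, 1, 1, 1, 0.6) / 4, tolerance = 1e-9)
  # the allocations sum to the full r (x) f virial: r_z = -0.4 nm (atom 1
  # below atom 2), f_z on atom 1 = +k * 1 A = +500 kJ/mol/nm
  expect_equal(sum(gz), -0.4 * 500 * BAR, tolerance = 1e-9)
  gs <- global_stress(fs$trajectory, kinetic = "none")
  expect_equal(sum(gz), -gs[3, 3] * prod(fs$trajectory$box[1, ] / 10),
               tolerance = 1e-12)
})

test_that("volume-weighted bin sum equals the whole-box stress", {
  set.seed(17)
  for (i in 1:20) {
    kind <- sample(c("harmonic_pair", "lj_fluid", "ideal_gas"), 1)
    fs <- make_force_system(force_system_spec(kind = kind,
            n_particles = 20, box = c(12, 12, 15), temperature = 300,
            cutoff = 6, seed = i), n_frames = 3)
    kin <- if (kind == "harmonic_pair") "none" else "velocities"
    sf <- local_stress(fs$trajectory, bin_width = 0.1, kinetic = kin)
    gs <- global_stress(fs$trajectory, kinetic = kin)
    V <- prod(fs$trajectory$box[1, ] / 10)
    tot <- apply(sf$sigma, c(2, 3), sum) * sf$bin_volume
    scale <- max(abs(gs * V), 1e-10)
    expect_lt(max(abs(tot - gs * V)) / scale, 1e-6)
  }
})

test_that("ideal gas: every bin matches rho k T within 3 SE; P_L and gamma are null", {
  nfr <- 2000; npart <- 250; temp <- 310
  box <- c(20, 20, 5)  # 5 z-bins at the default 0.1 nm grid
  ig <- make_force_system(force_system_spec(kind = "ideal_gas",
          n_particles = npart, temperature = temp, box = box, seed = 23),
          n_frames = nfr)
  sf <- local_stress(ig$trajectory, bin_width = 0.1, kinetic = "velocities")
  pp <- pressure_profile(sf)
  rho <- npart / prod(box / 10)          # nm^-3
  kT <- kB * temp
  vb <- sf$bin_volume
  expected <- rho * kT * BAR
  se_diag <- kT * sqrt(3 * rho / (vb * nfr)) * BAR   # compound-Poisson var
  se_off <- kT * sqrt(rho / (vb * nfr)) * BAR
  for (b in seq_along(sf$z)) {
    P <- -sf$sigma[b, , ]
    for (k in 1:3) expect_lt(abs(P[k, k] - expected), 3 * se_diag)
    expect_lt(max(abs(P[upper.tri(P)])), 3 * se_off)
  }
  # P_L is statistically zero bin-wise; gamma consistent with zero
  se_pl <- kT * sqrt(3 * rho / (vb * nfr)) * BAR
  expect_true(all(abs(pp$P_L) < 3 * se_pl))
  se_gamma <- sqrt(length(sf$z)) * se_pl * sf$bin_width * 10
  expect_lt(abs(attr(pp, "surface_tension_bar_A")), 3 * se_gamma)
})

test_that("pressure profile identities and the single-bin integral", {
  # isotropic field: P_L = 0, gamma = 0
  fs <- make_force_system(force_system_spec(kind = "ideal_gas",
          n_particles = 50, box = c(10, 10, 3), seed = 3), n_frames = 10)
  sf <- local_stress(fs$trajectory, bin_width = 0.1, kinetic = "thermal",
                     temperature = 310)
  pp <- pressure_profile(sf)
  expect_equal(pp$P_L, pp$P_par - pp$P_perp)          # exact identity
  expect_true(all(abs(pp$P_L) < 1e-9))                # thermal term isotropic
  expect_equal(attr(pp, "surface_tension_bar_A"), 0, tolerance = 1e-9)
  # hand-built single-bin field with P_par - P_perp = c -> gamma = -c h
  f1 <- sf
  f1$z <- 0.05; f1$bin_width <- 0.1
  f1$sigma <- array(0, c(1, 3, 3))
  f1$sigma[1, 1, 1] <- f1$sigma[1, 2, 2] <- -100  # P_par = 100 bar
  p1 <- pressure_profile(f1)
  expect_equal(attr(p1, "surface_tension_bar_A"), -100 * 0.1 * 10)
})

test_that("local_stress validates its inputs", {
  fs <- make_force_system(force_system_spec(kind = "ideal_gas",
          n_particles = 10, box = c(10, 10, 10)), n_frames = 2)
  tr <- fs$trajectory
  tr$velocities <- NULL
  expect_error(local_stress(tr, kinetic = "velocities"), "no velocities")
  expect_error(local_stress(tr, kinetic = "thermal"), "temperature")
  expect_warning(local_stress(fs$trajectory, bin_width = 0.13), "rescaled")
})

test_that("compare_profiles: zero self-difference, planted core change, grid rules", {
  fs <- make_force_system(force_system_spec(kind = "ideal_gas",
          n_particles = 50, box = c(10, 10, 4), seed = 9), n_frames = 20)
  sf <- local_stress(fs$trajectory, bin_width = 0.1, kinetic = "velocities")
  pp <- pressure_profile(sf)
  self <- compare_profiles(pp, pp, regions = list(core = c(0.1, 0.3)))
  expect_true(all(self$per_bin$dP_L == 0))
  expect_equal(self$regions$integral_bar_nm, 0)
  # lower the core P_par by construction -> negative core-region integral
  low <- sf
  core <- sf$z > 0.1 & sf$z < 0.3
  low$sigma[core, 1, 1] <- low$sigma[core, 1, 1] + 200  # P down by 200 bar
  low$sigma[core, 2, 2] <- low$sigma[core, 2, 2] + 200
  cmp <- compare_profiles(pp, pressure_profile(low),
                          regions = list(core = c(0.1, 0.3)))
  expect_lt(cmp$regions$integral_bar_nm, 0)
  # grid mismatch without resampling is an error
  half <- pressure_profile(local_stress(fs$trajectory, bin_width = 0.2,
                                        kinetic = "velocities"))
  expect_error(compare_profiles(pp, half), "incompatible grids")
  r <- compare_profiles(pp, half, resample = TRUE)
  expect_equal(length(r$per_bin$z_nm), length(half$z_nm))
})
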