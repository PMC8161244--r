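test_that("cavity counting follows the literal membership definition", {
  # one oxygen 10 A from the 2.43 CA, clear of lipids and the 3.39 sphere
  ca <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 80, 0), c(0, -60, 0))
  m <- bw_map(c("2.43", "6.33", "3.39"), 0:2)
  pdb <- write_fixture_pdb(ca, waters = rbind(c(10, 0, 0)),
                           lipids = rbind(c(0, 0, 30)))
  top <- load_topology(pdb)
  expect_identical(cavity_water_count(top, top$first_frame, m), 1L)

  # same oxygen but 4 A from a lipid atom -> excluded
  pdb2 <- write_fixture_pdb(ca, waters = rbind(c(10, 0, 0)),
                            lipids = rbind(c(10, 0, 4)))
  top2 <- load_topology(pdb2)
  expect_identical(cavity_water_count(top2, top2$first_frame, m), 0L)

  # no water at all -> 0
  pdb3 <- write_fixture_pdb(ca)
  top3 <- load_topology(pdb3)
  expect_identical(suppressMessages(
    cavity_water_count(top3, top3$first_frame, m)), 0L)
})

test_that("cavity count equals the brute-force oracle on random scenes", {
  for (s in 1:100) {
    counts <- with_seed_counts <- NULL
    n_in <- s %% 7L
    n_out <- (s * 3L) %% 9L
    n_blk <- s %% 4L
    sc <- generate_cavity_scene(n_in, n_out, n_blk, seed = s)
    got <- cavity_water_count(sc$topology, sc$coords, sc$bw_map, quiet = TRUE)
    ora <- oracle_cavity_count(sc$topology, sc$coords, sc$bw_map,
                               cavity_criteria())
    expect_identical(got, as.integer(ora))
    expect_identical(got, sc$expected)
  }
})

test_that("helix_axis finds the axis of an ideal helix, oriented N-to-C", {
  ca <- ideal_helix(15)
  ax <- helix_axis(ca)
  expect_lt(max(abs(ax$axis - c(0, 0, 1))), 1e-3)
  rev_ax <- helix_axis(ca[15:1, ])
  expect_lt(max(abs(rev_ax$axis - c(0, 0, -1))), 1e-3)
  # collinear points degenerate to the line direction
  line <- cbind(seq_len(6), 0, 0)
  expect_equal(helix_axis(line)$axis, c(1, 0, 0), tolerance = 1e-9)
  expect_error(helix_axis(ca[1:3, ]), "at least 4")
})

test_that("planted bend/wobble angles are recovered within 0.5 degrees", {
  for (bend in c(5, 20, 35, 50, 60)) {
    for (wob in c(-150, -60, 0, 40, 150)) {
      hx <- generate_kinked_helix(bend, wob)
      got <- wobble_angle(hx$topology, hx$ca_coords, "7.57",
                          c("7.46", "7.56"), c("7.58", "7.68"), hx$bw_map)
      expect_lt(abs(got$bend_angle_deg - bend), 0.5)
      dw <- abs(got$wobble_angle_deg - wob) %% 360
      expect_lt(min(dw, 360 - dw), 0.5)
      expect_false(got$degenerate)
    }
  }
})

test_that("straight helices report zero wobble with a degenerate flag", {
  hx <- generate_kinked_helix(0, 0)
  got <- wobble_angle(hx$topology, hx$ca_coords, "7.57",
                      c("7.46", "7.56"), c("7.58", "7.68"), hx$bw_map)
  expect_lt(got$bend_angle_deg, 0.5)
  expect_identical(got$wobble_angle_deg, 0)
  expect_true(got$degenerate)
  expect_error(generate_kinked_helix(0, 40), "wobble")
})

test_that("an extra rotation about the pre-axis shifts wobble accordingly", {
  hx20 <- generate_kinked_helix(20, 40)
  hx30 <- generate_kinked_helix(20, 50)
  w20 <- wobble_angle(hx20$topology, hx20$ca_coords, "7.57",
                      c("7.46", "7.56"), c("7.58", "7.68"), hx20$bw_map)
  w30 <- wobble_angle(hx30$topology, hx30$ca_coords, "7.57",
                      c("7.46", "7.56"), c("7.58", "7.68"), hx30$bw_map)
  expect_equal(w30$wobble_angle_deg - w20$wobble_angle_deg, 10,
               tolerance = 0.5)
})

test_that("pair distances track constructed geometry and couple to wobble", {
  ca <- rbind(c(0, 0, 0), c(4.15, 0, 0), c(8, 0, 0), c(12, 0, 0))
  pdb <- write_fixture_pdb(ca)
  top <- load_topology(pdb)
  coords <- array(ca, dim = c(4, 3, 1))
  dcd <- tempfile(fileext = ".dcd")
  write_dcd(coords, dcd)
  traj <- read_frames(top, dcd)
  m <- bw_map(c("1.52", "7.67"), 0:1)
  expect_equal(pair_distance_series(top, traj, "1.52", "7.67", "CA", m),
               4.15, tolerance = 1e-3)
  same <- bw_map(c("a", "b"), c(0L, 0L))
  expect_equal(pair_distance_series(top, traj, "a", "b", "CA", same), 0)

  # trajectory of kinked helices with drifting wobble: the distance between
  # a pre-segment and a post-segment residue must correlate with the angle
  wobs <- seq(20, 120, length.out = 25)
  frames <- lapply(wobs, function(w) generate_kinked_helix(25, w)$ca_coords)
  hx <- generate_kinked_helix(25, wobs[1])
  arr <- array(0, dim = c(nrow(hx$ca_coords), 3, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  dcd2 <- tempfile(fileext = ".dcd")
  write_dcd(arr, dcd2)
  traj2 <- read_frames(hx$topology, dcd2)
  d <- pair_distance_series(hx$topology, traj2, "7.46", "7.68", "CA",
                            hx$bw_map)
  expect_gt(abs(cor(d, wobs)), 0.8)
})

test_that("TM selections form the union of contiguous BW ranges", {
  m <- bw_map(c(sprintf("5.%d", 37:63), sprintf("6.%d", 31:57)),
              c(100:126, 200:226))
  expect_length(tm_selection(m, list(c("5.37", "5.63"))), 27L)
  expect_identical(tm_selection(m, list()), integer())
  both <- tm_selection(m, list(c("5.37", "5.63"), c("6.31", "6.57")))
  expect_length(both, 54L)
  # overlap -> union without duplicates; idempotent and order-independent
  overl <- tm_selection(m, list(c("5.37", "5.50"), c("5.45", "5.63")))
  expect_identical(overl, tm_selection(m, list(c("5.37", "5.63"))))
  expect_identical(both,
                   tm_selection(m, list(c("6.31", "6.57"), c("5.37", "5.63"))))
})

test_that("superposition RMSD is rigid-invariant and matches the quaternion oracle", {
  set.seed(33)
  P <- matrix(rnorm(30 * 3, sd = 8), 30, 3)
  Rm <- random_rotation(1)
  Q <- P %*% t(Rm) + matrix(rep(c(5, -3, 2), each = 30), 30, 3)
  expect_lt(superpose_rmsd(P, P), 1e-9)
  expect_lt(superpose_rmsd(P, Q), 1e-6)
  # displaced point: Kabsch vs independent quaternion superposition
  for (s in 1:10) {
    set.seed(s)
    A <- matrix(rnorm(20 * 3, sd = 6), 20, 3)
    B <- A %*% t(random_rotation(s + 50))
    B[1, ] <- B[1, ] + rnorm(3, sd = 2)
    expect_equal(superpose_rmsd(A, B), oracle_quaternion_rmsd(A, B),
                 tolerance = 1e-6)
    # symmetry and rigid invariance
    expect_equal(superpose_rmsd(A, B), superpose_rmsd(B, A),
                 tolerance = 1e-9)
    expect_equal(superpose_rmsd(A %*% t(random_rotation(s + 99)), B),
                 superpose_rmsd(A, B), tolerance = 1e-9)
  }
  expect_error(superpose_rmsd(P, P[1:5, ]), "identical dimensions")
})

test_that("two-structure TM comparison recovers a known displacement", {
  # reference helix vs the same helix with its second half shifted: RMSD of
  # the TM selection must match a direct Kabsch on the same atoms
  ca1 <- ideal_helix(30)
  ca2 <- ca1
  ca2[16:30, 1] <- ca2[16:30, 1] + 2
  p1 <- write_fixture_pdb(ca1)
  p2 <- write_fixture_pdb(ca2)
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(paste(sprintf("1.%d", 31:60), 1:30), f1)
  writeLines(paste(sprintf("1.%d", 31:60), 1:30), f2)
  got <- tm_rmsd(p1, p2, f1, f2, list(c("1.31", "1.60")))
  expect_identical(got$n_atoms, 30L)
  expect_equal(got$rmsd, superpose_rmsd(ca1, ca2), tolerance = 1e-6)
  expect_gt(got$rmsd, 0.5)
})
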