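test_that("contact series generators are deterministic pure functions", {
  a <- generate_contact_series(R = 8, n = 40, n_states = 2,
                               flip_noise_rate = 0.1, seed = 5)
  b <- generate_contact_series(R = 8, n = 40, n_states = 2,
                               flip_noise_rate = 0.1, seed = 5)
  expect_identical(unclass(a$tensor), unclass(b$tensor))
  c3 <- generate_contact_series(R = 8, n = 40, n_states = 2,
                                flip_noise_rate = 0.1, seed = 6)
  expect_false(identical(unclass(a$tensor), unclass(c3$tensor)))
  # generators leave the caller's RNG stream untouched
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_contact_series(R = 6, n = 10, n_states = 1, seed = 1))
  expect_identical(runif(1), before)
})

test_that("noise-free single-state series is the constant archetype", {
  g <- generate_contact_series(R = 8, n = 15, n_states = 1,
                               flip_noise_rate = 0, seed = 2)
  for (t in seq_len(15))
    expect_identical(g$tensor[, , t], g$truth$archetypes[[1]])
})

test_that("every generated frame is symmetric, binary, unit-diagonal", {
  g <- generate_contact_series(R = 10, n = 30, n_states = 3,
                               flip_noise_rate = 0.2, seed = 3)
  for (t in seq_len(30)) {
    sl <- g$tensor[, , t]
    expect_identical(sl, t(sl))
    expect_true(all(sl %in% 0:1))
    expect_true(all(diag(sl) == 1L))
  }
})

test_that("observed flip fraction sits in the 99% binomial interval", {
  q <- 0.05
  g <- generate_contact_series(R = 12, n = 400, n_states = 1,
                               flip_noise_rate = q, seed = 4)
  A <- g$truth$archetypes[[1]]
  ut <- upper.tri(A)
  flips <- vapply(seq_len(400), function(t)
    sum(g$tensor[, , t][ut] != A[ut]), numeric(1))
  n_draws <- sum(ut) * 400
  ci <- qbinom(c(0.005, 0.995), n_draws, q)
  expect_gte(sum(flips), ci[1])
  expect_lte(sum(flips), ci[2])
})

test_that("autocorrelated flicker produces persistent noise", {
  g <- generate_contact_series(R = 10, n = 300, n_states = 1,
                               flip_noise_rate = 0.2, noise_autocorr = 0.9,
                               seed = 8)
  A <- g$truth$archetypes[[1]]
  ut <- which(upper.tri(A))
  flip_t <- vapply(seq_len(300), function(t)
    as.numeric(g$tensor[, , t][ut] != A[ut]), numeric(length(ut)))
  # lag-1 autocorrelation of the flip indicator must be clearly positive
  x <- as.numeric(flip_t[, -300])
  y <- as.numeric(flip_t[, -1])
  expect_gt(cor(x, y), 0.5)
})

test_that("generator input validation catches bad worlds", {
  expect_error(generate_contact_series(R = 8, n = 20, n_states = 2,
                                       transition_frames = c(25), seed = 1),
               "inside")
  expect_error(generate_contact_series(R = 8, n = 20, n_states = 3,
                                       transition_frames = c(5), seed = 1),
               "per consecutive state")
  arch <- list(diag(1L, 8), diag(1L, 7))
  expect_error(generate_contact_series(R = 8, n = 20, archetypes = arch,
                                       transition_frames = 10, seed = 1),
               "shape")
})

test_that("toy trajectories realize the planted tensor exactly at 3.5 A", {
  g <- toy_matching_series(R = 10, n = 6)
  dir <- tempfile()
  toy <- generate_toy_trajectory(g$tensor, dir = dir)
  top <- load_topology(toy$pdb)
  expect_identical(top$n_residues, 10L)
  traj <- read_frames(top, toy$dcd)
  tens <- build_contact_tensor(top, traj, cutoff_A = 3.5)
  expect_identical(unclass(tens)[seq_along(tens)],
                   unclass(g$tensor)[seq_along(g$tensor)])
})

test_that("empty contact sets give identity-diagonal maps only", {
  arch <- list(diag(1L, 6))
  g <- generate_contact_series(R = 6, n = 3, archetypes = arch,
                               flip_noise_rate = 0, seed = 1)
  toy <- generate_toy_trajectory(g$tensor, dir = tempfile())
  top <- load_topology(toy$pdb)
  tens <- build_contact_tensor(top, read_frames(top, toy$dcd))
  for (t in 1:3) expect_identical(tens[, , t], diag(1L, 6))
})

test_that("toy generator writes byte-identical files and rejects dense maps", {
  g <- toy_matching_series(R = 10, n = 4)
  d1 <- tempfile(); d2 <- tempfile()
  t1 <- generate_toy_trajectory(g$tensor, dir = d1)
  t2 <- generate_toy_trajectory(g$tensor, dir = d2)
  expect_identical(readBin(t1$dcd, "raw", file.size(t1$dcd)),
                   readBin(t2$dcd, "raw", file.size(t2$dcd)))
  expect_identical(readLines(t1$pdb), readLines(t2$pdb))

  dense <- matching_archetype(10, list(c(1, 4)))
  dense[1, 5] <- dense[5, 1] <- 1L  # residue 1 with two partners
  gd <- generate_contact_series(R = 10, n = 2, archetypes = list(dense),
                                flip_noise_rate = 0, seed = 1)
  expect_error(generate_toy_trajectory(gd$tensor, dir = tempfile()),
               "infeasible")
})

test_that("cavity scenes plant exactly the expected in-cavity count", {
  sc <- generate_cavity_scene(3, 5, 2, seed = 11)
  expect_identical(sc$expected, 3L)
  expect_identical(cavity_water_count(sc$topology, sc$coords, sc$bw_map,
                                      quiet = TRUE), 3L)
  sc0 <- generate_cavity_scene(0, 10, 0, seed = 12)
  expect_identical(cavity_water_count(sc0$topology, sc0$coords, sc0$bw_map,
                                      quiet = TRUE), 0L)
})

test_that("kinked helices are reproducible and straight when unbent", {
  h1 <- generate_kinked_helix(20, 40)
  h2 <- generate_kinked_helix(20, 40)
  expect_identical(h1$ca_coords, h2$ca_coords)
  h0 <- generate_kinked_helix(0, 0)
  ax <- helix_axis(h0$ca_coords)
  expect_lt(max(abs(ax$axis - c(0, 0, 1))), 1e-3)
})

test_that("full chain recovers planted transitions end to end", {
  # desk-scale version of the benchmark world: same generator family,
  # smaller R/n so it runs in seconds
  g <- generate_contact_series(R = 24, n = 700, n_states = 3,
                               flip_noise_rate = 0.05, seed = 17)
  I <- smooth_contacts(flatten_tensor(g$tensor), 75)
  fit <- red_nmf(I, k = 4, keep_input = FALSE)
  ev <- detect_events(fit)
  planted <- g$truth$transition_frames
  expect_identical(nrow(ev), length(planted))
  for (p in seq_along(planted))
    expect_true(any(ev$start_frame <= planted[p] & planted[p] < ev$end_frame))
})
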