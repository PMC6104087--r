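# single bead tethered by one bond to an anchored partner
dimer_ff <- function(k = 200) {
  m <- straight_chain(2)
  build_forcefield(m, empty_map())
}

test_that("identical seeds reproduce trajectories bit for bit", {
  ff <- dimer_ff()
  p <- simulation_params(steps = 2e4, stride = 100, seed = 5)
  t1 <- langevin_run(ff, matrix(c(0, 3.8, 0, 0, 0, 0), 2), p)
  t2 <- langevin_run(ff, matrix(c(0, 3.8, 0, 0, 0, 0), 2), p)
  expect_identical(t1$frames, t2$frames)
  p2 <- simulation_params(steps = 2e4, stride = 100, seed = 6)
  t3 <- langevin_run(ff, matrix(c(0, 3.8, 0, 0, 0, 0), 2), p2)
  expect_false(identical(t1$final_coords, t3$final_coords))
  # frame count contract: floor(steps/stride) + 1 including frame 0
  expect_equal(n_frames(t1), 2e4 / 100 + 1)
})

test_that("zero temperature from a minimised start stays stationary", {
  b <- make_helix_bundle(2, 10)
  cm <- cutoff_contacts(b$model, 9.5)
  ff <- build_forcefield(b$model, cm)
  mn <- sbm_minimize(ff, b$model$xyz, tol = 1e-6, max_iter = 1e4)
  expect_true(mn$converged)
  p <- simulation_params(temperature = 0, friction = 1, steps = 1e4,
                         stride = 1000, seed = 1)
  tr <- langevin_run(ff, mn$coords, p)
  drift <- max(abs(frame_coords(tr, n_frames(tr)) - mn$coords))
  expect_lt(drift, 1e-6)
})

test_that("the symplectic limit conserves energy", {
  # gamma = 0, T = 0 from a perturbed start: total energy drift stays small
  b <- make_helix_bundle(2, 10)
  cm <- cutoff_contacts(b$model, 9.5)
  ff <- build_forcefield(b$model, cm)
  set.seed(2)
  x0 <- b$model$xyz + matrix(rnorm(3 * ff$n, 0, 0.05), ncol = 3)
  p <- simulation_params(temperature = 0, friction = 0, steps = 1e5,
                         stride = 1000, seed = 1)
  tr <- langevin_run(ff, x0, p)
  etot <- tr$energy + tr$kinetic_energy
  scale <- max(abs(etot[1]), diff(range(tr$energy)))
  expect_lt(max(abs(etot - etot[1])) / scale, 1e-4)
})

test_that("a harmonic bond equilibrates to the analytic variance", {
  # V = k (r - r0)^2: by equipartition <V> = T*/2 per quadratic dof,
  # so <(r - r0)^2> = T*/(2 k)
  ff <- dimer_ff()
  p <- simulation_params(steps = 2e6, stride = 20, seed = 42)
  tr <- langevin_run(ff, matrix(c(0, 3.8, 0, 0, 0, 0), 2), p)
  r <- vapply(seq_len(n_frames(tr)), function(i) {
    x <- frame_coords(tr, i)
    sqrt(sum((x[1, ] - x[2, ])^2))
  }, numeric(1))
  r <- r[-seq_len(1000)]  # discard equilibration
  expect_equal(mean((r - 3.8)^2), 0.92 / (2 * 200), tolerance = 0.05)
})

test_that("sampled bond lengths follow the Boltzmann density", {
  ff <- dimer_ff()
  p <- simulation_params(steps = 1e6, stride = 100, seed = 9)
  tr <- langevin_run(ff, matrix(c(0, 3.8, 0, 0, 0, 0), 2), p)
  r <- vapply(seq_len(n_frames(tr)), function(i) {
    x <- frame_coords(tr, i)
    sqrt(sum((x[1, ] - x[2, ])^2))
  }, numeric(1))
  r <- r[-seq_len(500)]
  # the radial Boltzmann density for V = k (r-r0)^2 with r0 >> width is
  # close to Gaussian with sd sqrt(T/2k); thin to ~independent samples
  r_ind <- r[seq(1, length(r), by = 5)]
  ks <- suppressWarnings(
    ks.test(r_ind, function(q) {
      # numerically normalised r^2-weighted Boltzmann CDF
      grid <- seq(3.0, 4.6, length.out = 4000)
      dens <- grid^2 * exp(-200 * (grid - 3.8)^2 / 0.92)
      cdf <- cumsum(dens) / sum(dens)
      approx(grid, cdf, q, yleft = 0, yright = 1)$y
    }))
  expect_gt(ks$p.value, 0.01)
})

test_that("trajectories survive binary and PDB round-trips", {
  b <- make_helix_bundle(2, 10)
  ff <- build_forcefield(b$model, cutoff_contacts(b$model, 9.5))
  tr <- langevin_run(ff, b$model$xyz,
                     simulation_params(steps = 2000, stride = 500, seed = 3))
  tf <- withr::local_tempfile(fileext = ".tsbm")
  write_traj_bin(tr, tf)
  back <- read_traj_bin(tf)
  expect_equal(back$n_beads, ff$n)
  expect_equal(back$seed, 3L)
  expect_equal(back$frames, tr$frames, tolerance = 1e-6)  # float32 storage

  pf <- withr::local_tempfile(fileext = ".pdb")
  write_traj_pdb(tr, b$model, pf)
  lines <- readLines(pf)
  expect_equal(sum(grepl("^MODEL", lines)), n_frames(tr))
  first <- load_structure(paste(lines, collapse = "\n"), model = 1)
  expect_equal(nrow(first$atoms), ff$n)
})

test_that("divergent dynamics abort with the offending step", {
  m <- straight_chain(3)
  ff <- build_forcefield(m, empty_map())
  x_bad <- m$xyz
  x_bad[2, ] <- x_bad[1, ] + c(1e-4, 0, 0)  # catastrophic bond compression
  expect_error(
    langevin_run(ff, x_bad,
                 simulation_params(steps = 1000, stride = 1, seed = 1,
                                   timestep = 0.5)),
    "divergence|coincident")
})
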