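# minimal hand-built trajectory: supply frames directly
fake_traj <- function(frame_list) {
  frames <- do.call(rbind, lapply(frame_list, function(x) as.vector(t(x))))
  structure(list(frames = frames, n_beads = nrow(frame_list[[1]]),
                 energy = rep(0, length(frame_list)),
                 params = simulation_params(steps = length(frame_list),
                                            stride = 1)),
            class = "trajectory")
}

test_that("marker-group distances are plain centroid separations", {
  f1 <- rbind(c(0, 0, 0), c(3, 4, 0))
  tr <- fake_traj(list(f1, f1 + 1))  # rigid shift leaves distance at 5
  d <- com_distance_series(tr, 1L, 2L)
  expect_equal(d, c(5, 5))

  # group B = group A translated by v gives |v| every frame
  f2 <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 1),
              c(0, 0, 3), c(1, 1, 3), c(2, 0, 4))
  tr2 <- fake_traj(list(f2))
  expect_equal(com_distance_series(tr2, 1:3, 4:6), 3)

  expect_error(com_distance_series(tr, integer(), 2L), "empty")
  expect_error(com_distance_series(tr, 1L, 1L), "disjoint")
})

test_that("Q_int counts formed interface contacts against 120% of r0", {
  # reference frame: every pair exactly at r0 -> Q = 1
  xyz0 <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(5, 5, 0))
  mref <- bead_model(c("A", "B", "A", "B"), c(1L, 1L, 2L, 2L), xyz0)
  cm2 <- contact_map(data.frame(   # the four inter-chain pairs
    chain_a = "A", res_a = c(1L, 1L, 2L, 2L),
    chain_b = "B", res_b = c(1L, 2L, 1L, 2L),
    r0 = c(5, sqrt(50), sqrt(50), 5), class = "interface",
    strength = 0.5), "cutoff")
  tr <- fake_traj(list(xyz0))
  expect_equal(interface_Q_series(tr, cm2, mref), 1)

  # all pairs pushed beyond 1.2 r0 -> Q = 0
  far <- xyz0; far[c(2, 4), 1] <- far[c(2, 4), 1] + 100
  expect_equal(interface_Q_series(fake_traj(list(far)), cm2, mref), 0)

  # hand-built 4-contact frame with 3 formed -> 0.75
  m4 <- bead_model(rep(c("A", "B"), 4L), rep(1:4, each = 2),
                   cbind(rep(c(0, 5), 4), rep(seq(0, 30, 10), each = 2), 0))
  cm4 <- contact_map(data.frame(
    chain_a = "A", res_a = 1:4, chain_b = "B", res_b = 1:4,
    r0 = 5, class = "interface", strength = 1), "cutoff")
  frame <- m4$xyz
  frame[8, 1] <- 20  # break the 4th contact only
  expect_equal(interface_Q_series(fake_traj(list(frame)), cm4, m4), 0.75)
})

test_that("occupancy recovers trivial and Markov-chain stationary fractions", {
  alternating <- rep(c(0.9, 0.1), 50)
  o <- occupancy(alternating)
  expect_equal(o$occupancy, 0.5)
  expect_warning(o1 <- occupancy(rep(0.9, 50)), "degenerate")
  expect_equal(o1$occupancy, 1)

  q <- make_two_state_series(occupancy = 0.3, switch_rate = 0.05,
                             length = 20000L, seed = 11)
  o3 <- occupancy(q, seed = 2)
  expect_gt(o3$ci[2], 0.3 - 1e-9)
  expect_lt(o3$ci[1], 0.3 + 1e-9)
  expect_equal(o3$occupancy, 0.3, tolerance = 0.2)

  # point estimate is invariant under frame permutation
  set.seed(8)
  perm <- sample(length(q))
  expect_equal(occupancy(q[perm], seed = 2)$occupancy, o3$occupancy)

  # distance rule classifies below-threshold frames as dimerised
  d <- c(rep(5, 30), rep(60, 70))
  od <- occupancy(d, rule = "distance", threshold = 20)
  expect_equal(od$occupancy, 0.3)
})

test_that("free-energy surfaces are normalised with their minimum at zero", {
  fes1 <- free_energy_surface(rep(0.5, 100), breaks = seq(0, 1, 0.1))
  expect_equal(sum(fes1$P), 1)
  expect_equal(min(fes1$F, na.rm = TRUE), 0)
  expect_equal(sum(fes1$occupied), 1L)
  expect_equal(fes1$F[fes1$occupied], 0)

  # samples from exp(-k x^2 / T) recover F(x) = k x^2 over occupied bins
  set.seed(3)
  k <- 2; Tt <- 0.92
  x <- rnorm(2e5, 0, sqrt(Tt / (2 * k)))
  fes <- free_energy_surface(x, breaks = 30, temperature = Tt)
  mids <- (head(fes$edges[[1]], -1) + tail(fes$edges[[1]], -1)) / 2
  occ <- fes$occupied & fes$P > 5e-4   # exclude noise-dominated tails
  fitv <- k * mids[occ]^2
  fitv <- fitv - min(fitv)
  r2 <- 1 - sum((fes$F[occ] - fitv - mean(fes$F[occ] - fitv))^2) /
    sum((fes$F[occ] - mean(fes$F[occ]))^2)
  expect_gt(r2, 0.99)

  # 2D mode
  set.seed(4)
  xy <- cbind(rnorm(5000), runif(5000))
  fes2 <- free_energy_surface(xy, breaks = list(10, 8))
  expect_equal(dim(fes2$P), c(10L, 8L))
  expect_equal(sum(fes2$P), 1)
  expect_error(free_energy_surface(numeric()), "empty")
})

test_that("bisection tuning brackets a factor that meets the target", {
  # synthetic trial: occupancy is a noisy logistic in the strength factor
  mk_trial <- function(seed0) {
    function(f) {
      set.seed(seed0 + round(1000 * f))
      p <- plogis((f - 0.6) / 0.12)
      x <- rbinom(400, 1, p)
      occupancy(ifelse(x == 1, 0.9, 0.1), seed = 1)
    }
  }
  res <- tune_interface_strength(mk_trial(5), target = 0.5)
  expect_true(res$occupancy$ci[1] <= 0.5 && 0.5 <= res$occupancy$ci[2])
  expect_equal(res$factor, 0.6, tolerance = 0.25)
  expect_gte(nrow(res$trials), 3)

  # clearly decreasing occupancy aborts
  bad_trial <- function(f) {
    set.seed(round(100 * f) + 1)
    p <- plogis((0.6 - f) / 0.05)
    occupancy(ifelse(rbinom(400, 1, p) == 1, 0.9, 0.1), seed = 1)
  }
  expect_error(tune_interface_strength(bad_trial, target = 0.5),
               "not monotone")
})
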