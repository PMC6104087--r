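single_atom <- function(el = "C") {
  atomic_structure(data.frame(chain = "A", resno = 1L, resname = "ALA",
                              atom = "X", element = el, x = 0, y = 0, z = 0))
}

test_that("SASA matches the isolated-sphere closed form and is additive", {
  s <- sasa(single_atom(), probe = 1.4, n_points = 960)
  expect_equal(s$total, 4 * pi * (1.70 + 1.40)^2, tolerance = 0.01)

  two <- atomic_structure(data.frame(
    chain = "A", resno = c(1L, 2L), resname = "ALA", atom = "X",
    element = "C", x = c(0, 100), y = 0, z = 0))
  expect_equal(sasa(two)$total, 2 * sasa(single_atom())$total,
               tolerance = 1e-9)

  expect_error(sasa(single_atom("ZZ")), "no radius")
  # override table admits unknown elements
  expect_silent(sasa(single_atom("ZZ"), radii = c(ZZ = 2.0)))
})

test_that("SASA at working resolution matches a dense-sampling oracle", {
  set.seed(12)
  n <- 10
  cl <- atomic_structure(data.frame(
    chain = "A", resno = seq_len(n), resname = "ALA", atom = "X",
    element = sample(c("C", "N", "O", "S"), n, TRUE),
    x = runif(n, 0, 8), y = runif(n, 0, 8), z = runif(n, 0, 8)))
  coarse <- sasa(cl, n_points = 960)
  dense <- sasa(cl, n_points = 10000)
  expect_equal(coarse$total, dense$total,
               tolerance = 0.02 * dense$total / coarse$total)
  expect_lt(abs(coarse$total - dense$total) / dense$total, 0.02)
})

test_that("buried surface area follows its defining identity", {
  # tightly packed pair so the interface buries a substantial area
  b <- make_helix_bundle(2, 12, axis_spacing = 7)
  # parts: the two helices of one bundle (in contact)
  rep_ <- buried_surface_area(b$structure, "A:1-12", "A:16-27")
  expect_equal(rep_$bsa, rep_$sasa_a + rep_$sasa_b - rep_$sasa_ab,
               tolerance = 1e-9)
  expect_gt(rep_$bsa, 0)
  expect_equal(rep_$bsa_one_sided, rep_$bsa / 2)
  expect_gt(sum(rep_$per_residue$buried), 0)

  # symmetric in A and B
  swp <- buried_surface_area(b$structure, "A:16-27", "A:1-12")
  expect_equal(swp$bsa, rep_$bsa, tolerance = 1e-9)

  # parts far apart bury nothing
  far <- b$structure$atoms
  far$x[far$resno >= 16] <- far$x[far$resno >= 16] + 100
  rep2 <- buried_surface_area(atomic_structure(far), "A:1-12", "A:16-27")
  expect_equal(rep2$bsa, 0, tolerance = 1e-9)

  # rigid motion leaves SASA and BSA unchanged
  tr <- random_transform(21)
  rot <- b$structure$atoms
  rot[, c("x", "y", "z")] <-
    sweep(as.matrix(rot[, c("x", "y", "z")]) %*% t(tr$R), 2, -tr$t)
  # invariance holds to the sphere-sampling resolution
  rep3 <- buried_surface_area(atomic_structure(rot), "A:1-12", "A:16-27")
  expect_equal(rep3$bsa, rep_$bsa, tolerance = 0.03)

  expect_error(buried_surface_area(b$structure, "A:1-12", "A:10-27"),
               "overlap")
})

test_that("hinge angles recover constructed domain rotations", {
  set.seed(6)
  ref <- matrix(rnorm(30, 0, 5), 10)
  mov <- matrix(rnorm(30, 0, 5), 10) + 20

  # identical states: zero rotation
  h0 <- hinge_angle(ref, ref, mov, mov)
  expect_equal(h0$angle_deg, 0, tolerance = 1e-6)

  # rotate the moving domain 90 degrees about a fixed axis through a point
  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  mov2 <- sweep(sweep(mov, 2, c(20, 0, 0)) %*% t(Rz), 2, -c(20, 0, 0))
  h1 <- hinge_angle(ref, ref, mov, mov2)
  expect_equal(h1$angle_deg, 90, tolerance = 1e-6)
  expect_equal(abs(h1$axis), c(0, 0, 1), tolerance = 1e-6)

  # whole-complex rigid motion of state 2 does not change the hinge
  tr <- random_transform(33)
  move_all <- function(x) sweep(x %*% t(tr$R), 2, -tr$t)
  h2 <- hinge_angle(ref, move_all(ref), mov, move_all(mov2))
  expect_equal(h2$angle_deg, 90, tolerance = 1e-6)

  # symmetry: swapping the states gives the same angle
  h3 <- hinge_angle(ref, ref, mov2, mov)
  expect_equal(h3$angle_deg, h1$angle_deg, tolerance = 1e-6)
})

test_that("maximum reach sums rigid spans and extended linkers", {
  # single rigid rod of span 50, no linker
  rod <- straight_chain(2, spacing = 50)
  r0 <- max_reach(rod, list(list(type = "body", from = 1L, to = 2L)))
  expect_equal(r0$reach_A, 50)

  # two 50 A rods joined by a 9-residue linker: 100 + 9 * 3.8 = 134.2
  m <- bead_model(rep("A", 4), c(1L, 2L, 20L, 21L),
                  rbind(c(0, 0, 0), c(50, 0, 0), c(60, 0, 0), c(110, 0, 0)),
                  is_break = c(FALSE, TRUE, FALSE))
  r <- max_reach(m, list(
    list(type = "body", from = 1L, to = 2L),
    list(type = "linker", n = 9L),
    list(type = "body", from = 3L, to = 4L)))
  expect_equal(r$reach_A, 134.2)
  expect_equal(r$reach_nm, 13.42)

  # toy tethered pair: the bound exceeds a brute-force extended placement
  sys <- make_tethered_pair()
  reach <- sys$info$reach
  # straight-line oracle: body-anchor span + fully straight linker + span
  # from the domain junction to the marker centroid cannot exceed the bound
  direct <- sqrt(sum((colMeans(sys$docked$xyz[sys$info$marker1, , drop = FALSE]) -
                      sys$docked$xyz[49 + 9, ])^2))
  expect_gt(reach$reach_A, direct)
})
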