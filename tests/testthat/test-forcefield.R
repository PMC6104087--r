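test_that("term counts follow chain connectivity", {
  m <- kinked_chain(5)
  ff <- build_forcefield(m, empty_map())
  expect_equal(nrow(ff$bonds), 4L)
  expect_equal(nrow(ff$angles), 3L)
  expect_equal(nrow(ff$dihedrals), 2L)
  expect_equal(nrow(ff$contacts), 0L)

  # a chain break removes the terms spanning it
  mb <- m
  mb$is_break[2] <- TRUE
  ffb <- build_forcefield(mb, empty_map())
  expect_equal(nrow(ffb$bonds), 3L)
  expect_equal(nrow(ffb$angles), 1L)
  expect_equal(nrow(ffb$dihedrals), 0L)

  # one contact at strength 1 gives one term with eps = 1
  cm <- contact_map(data.frame(chain_a = "A", res_a = 1L, chain_b = "A",
                               res_b = 5L, r0 = 9.0, class = "intra",
                               strength = 1), "cutoff")
  ff1 <- build_forcefield(m, cm)
  expect_equal(nrow(ff1$contacts), 1L)
  expect_equal(ff1$contact_eps, 1)

  # interface map at factor 0.5: interface eps 0.5, intra eps 1
  sys <- make_tethered_pair()
  ffs <- build_forcefield(sys$docked, sys$intra_map, sys$interface_map)
  expect_equal(unique(ffs$contact_eps[ffs$contact_class == "interface"]), 0.5)
  expect_equal(unique(ffs$contact_eps[ffs$contact_class == "intra"]), 1.0)

  # contacts referencing removed residues are rejected with offenders named
  bad <- contact_map(data.frame(chain_a = "A", res_a = 1L, chain_b = "A",
                                res_b = 99L, r0 = 9, class = "intra",
                                strength = 1), "cutoff")
  expect_error(build_forcefield(m, bad), "A/99")
})

test_that("contact energy is exactly -eps at r0 and vanishes at range", {
  m2 <- bead_model(c("A", "B"), c(1L, 1L), rbind(c(0, 0, 0), c(6, 0, 0)))
  cm <- contact_map(data.frame(chain_a = "A", res_a = 1L, chain_b = "B",
                               res_b = 1L, r0 = 6, class = "intra",
                               strength = 1), "cutoff")
  ff <- build_forcefield(m2, cm)
  e0 <- sbm_energy(ff, m2$xyz)
  expect_identical(e0$contact, -1)            # algebraic identity at r = r0
  efar <- sbm_energy(ff, rbind(c(0, 0, 0), c(500, 0, 0)))
  expect_lt(abs(efar$contact), 1e-12)

  # scaled eps scales the minimum
  cm5 <- cm; cm5$contacts$strength <- 0.5
  ff5 <- build_forcefield(m2, cm5)
  expect_equal(sbm_energy(ff5, m2$xyz)$contact, -0.5)
})

test_that("native coordinates zero the bonded terms and minimise contacts", {
  b <- make_helix_bundle(3, 12)
  cm <- cutoff_contacts(b$model, 9.5)
  ff <- build_forcefield(b$model, cm)
  e <- sbm_energy(ff, b$model$xyz)
  expect_lt(abs(e$bond), 1e-15)
  expect_lt(abs(e$angle), 1e-15)
  expect_lt(abs(e$dihedral), 1e-15)
  # total = sum of contact minima up to the small repulsive correction
  eps_sum <- sum(ff$contact_eps)
  expect_equal(e$contact, -eps_sum, tolerance = 0.01)
  expect_lt(abs(e$total + eps_sum), 0.01 * eps_sum + e$excluded + 1e-9)
  # bonded forces vanish at the native structure (strip contacts and
  # shrink the excluded-volume core so only bonded terms remain)
  ff_b <- ff
  ff_b$contacts <- ff$contacts[0, , drop = FALSE]
  ff_b$contact_r0 <- ff_b$contact_eps <- ff_b$contact_sigma <- numeric()
  ff_b$contact_class <- character()
  ff_b$r_ex <- 1e-3
  expect_lt(max(abs(sbm_forces(ff_b, b$model$xyz))), 1e-8)

  # an isolated contact at r0 feels only the repulsive factor's gradient
  m2 <- bead_model(c("A", "B"), c(1L, 1L), rbind(c(0, 0, 0), c(6, 0, 0)))
  cmp <- contact_map(data.frame(chain_a = "A", res_a = 1L, chain_b = "B",
                                res_b = 1L, r0 = 6, class = "intra",
                                strength = 1), "cutoff")
  ffp <- build_forcefield(m2, cmp)
  expect_lt(max(abs(sbm_forces(ffp, m2$xyz))), 1e-3)
})

test_that("analytic forces match finite differences on random configurations", {
  set.seed(31)
  m <- kinked_chain(20, seed = 8)
  cm <- cutoff_contacts(m, 9.5)
  ff <- build_forcefield(m, cm)
  x <- m$xyz + matrix(rnorm(60, 0, 0.25), ncol = 3)
  expect_lt(fd_max_rel_err(ff, x), 1e-5)

  # and on the full tethered toy
  sys <- make_tethered_pair()
  ffs <- build_forcefield(sys$docked, sys$intra_map, sys$interface_map)
  xs <- sys$docked$xyz + matrix(rnorm(3 * ffs$n, 0, 0.2), ncol = 3)
  expect_lt(fd_max_rel_err(ffs, xs, beads = seq(1, ffs$n, by = 7)), 1e-5)
})

test_that("pair forces obey Newton's third law and energy is rigid-motion invariant", {
  m2 <- bead_model(c("A", "B"), c(1L, 1L), rbind(c(0, 0, 0), c(5.5, 1, 2)))
  cm <- contact_map(data.frame(chain_a = "A", res_a = 1L, chain_b = "B",
                               res_b = 1L, r0 = 6, class = "intra",
                               strength = 1), "cutoff")
  ff <- build_forcefield(m2, cm)
  F <- sbm_forces(ff, m2$xyz)
  expect_equal(F[1, ], -F[2, ], tolerance = 1e-14)

  sys <- make_tethered_pair()
  ffs <- build_forcefield(sys$docked, sys$intra_map, sys$interface_map)
  set.seed(4)
  x <- sys$docked$xyz + matrix(rnorm(3 * ffs$n, 0, 0.3), ncol = 3)
  e1 <- sbm_energy(ffs, x)$total
  for (seed in c(1, 2)) {
    tr <- random_transform(seed)
    e2 <- sbm_energy(ffs, sweep(x %*% t(tr$R), 2, -tr$t))$total
    expect_equal(e1, e2, tolerance = 1e-9)
  }
})

test_that("linker beads carry ideal bonded terms and no dihedrals or contacts", {
  m <- bead_model(rep("A", 2), c(1L, 20L), rbind(c(0, 0, 0), c(15, 0, 0)),
                  is_break = TRUE)
  m <- bridge_gap(m, c(1, 2), 4)
  ff <- build_forcefield(m, empty_map())
  expect_equal(nrow(ff$bonds), 5L)
  expect_true(all(ff$bond_r0[m$is_linker[ff$bonds[, 1]] |
                             m$is_linker[ff$bonds[, 2]]] == 3.8))
  expect_equal(nrow(ff$dihedrals), 0L)  # every quadruple touches a linker

  sys <- make_tethered_pair()
  lnk <- which(sys$docked$is_linker)
  ffs <- build_forcefield(sys$docked, sys$intra_map, sys$interface_map)
  expect_false(any(ffs$contacts %in% lnk))
  expect_false(any(ffs$dihedrals %in% lnk))
  # angles touching linkers sit at the ideal random-coil value
  touches <- apply(ffs$angles, 1, function(r) any(r %in% lnk))
  expect_true(all(ffs$angle_t0[touches] == 2.0))
})

test_that("steepest descent relaxes strain and is idempotent", {
  # stretched bond relaxes to r0
  m2 <- straight_chain(2)
  ff <- build_forcefield(m2, empty_map())
  mn <- sbm_minimize(ff, rbind(c(0, 0, 0), c(4.8, 0, 0)))
  expect_true(mn$converged)
  expect_equal(sqrt(sum(diff(mn$coords)^2)), 3.8, tolerance = 1e-3)

  # clashed docked start loses its clash under minimisation
  sys <- make_tethered_pair()
  ffs <- build_forcefield(sys$docked, sys$intra_map, sys$interface_map)
  x0 <- sys$start$xyz
  mn2 <- sbm_minimize(ffs, x0)
  expect_lt(sbm_energy(ffs, mn2$coords)$total, sbm_energy(ffs, x0)$total)
  d <- as.matrix(dist(mn2$coords))
  diag(d) <- 99
  sep <- abs(outer(seq_len(ffs$n), seq_len(ffs$n), "-")) >= 4
  expect_gt(min(d[sep]), 3.5)  # no residual bead clashes

  # a converged minimisation is a fixed point of the minimiser
  b <- make_helix_bundle(2, 10)
  ffb <- build_forcefield(b$model, cutoff_contacts(b$model, 9.5))
  set.seed(12)
  mnb <- sbm_minimize(ffb, b$model$xyz + matrix(rnorm(3 * ffb$n, 0, 0.1),
                                                ncol = 3))
  expect_true(mnb$converged)
  mnb2 <- sbm_minimize(ffb, mnb$coords)
  expect_identical(mnb2$coords, mnb$coords)
  expect_equal(mnb2$iterations, 0L)
})

test_that("topology text export round-trips", {
  sys <- make_tethered_pair()
  ff <- build_forcefield(sys$docked, sys$intra_map, sys$interface_map)
  tf <- withr::local_tempfile(fileext = ".top")
  write_topology(ff, tf)
  ff2 <- read_topology(tf)
  for (f in c("bonds", "angles", "dihedrals", "contacts"))
    expect_equal(ff2[[f]], ff[[f]], ignore_attr = TRUE)
  for (f in c("bond_r0", "angle_t0", "dihedral_p0", "contact_r0",
              "contact_eps"))
    expect_equal(ff2[[f]], ff[[f]], tolerance = 1e-7)
  e1 <- sbm_energy(ff, sys$docked$xyz)$total
  e2 <- sbm_energy(ff2, sys$docked$xyz)$total
  expect_equal(e1, e2, tolerance = 1e-5)
})
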