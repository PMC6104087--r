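test_that("superposition recovers constructed transforms exactly", {
  set.seed(42)
  A <- matrix(rnorm(30, 0, 5), 10)
  # identity case
  fit0 <- superpose(A, A)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)

  # 37 degrees about z plus a translation
  th <- 37 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  B <- sweep(A %*% t(Rz), 2, -c(1, 2, 3))
  fit <- superpose(A, B)
  expect_equal(rotation_angle(fit$rotation), 37, tolerance = 1e-6)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_transform(A, fit), B, tolerance = 1e-9)

  # mirror image: reflection corrected to a proper rotation, RMSD > 0
  M <- A; M[, 1] <- -M[, 1]
  fitm <- superpose(A, M)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0.1)

  # collinear points are rejected
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition agrees with an independent least-squares fit", {
  set.seed(7)
  A <- matrix(rnorm(24, 0, 4), 8)
  th <- 0.9
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  # noisy rotation of A keeps the optimal orthogonal fit proper, so the
  # unconstrained reference implementation solves the same problem
  B <- A %*% t(Rz) + matrix(rnorm(24, 0, 0.5), 8)
  fit <- superpose(A, B)
  expect_equal(fit$rmsd,
               sqrt(mean(rowSums((apply_transform(A, fit) - B)^2))),
               tolerance = 1e-12)
  # bio3d's superposition as the independent cross-check
  fitted_b <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(B)), mobile = as.vector(t(A))))
  rmsd_b <- sqrt(mean(rowSums((matrix(fitted_b, ncol = 3,
                                      byrow = TRUE) - B)^2)))
  expect_equal(fit$rmsd, rmsd_b, tolerance = 1e-6)
})

toy_partner <- function() make_helix_bundle(2, 10)$structure

test_that("docking onto a self-template recovers the construction", {
  p <- toy_partner()
  n <- nrow(p$atoms)
  # template: two copies of the partner at a known transform
  tr <- random_transform(3)
  a2 <- p$atoms
  a2[, c("x", "y", "z")] <-
    sweep(as.matrix(a2[, c("x", "y", "z")]) %*% t(tr$R), 2, -tr$t)
  a2$chain <- "B"
  template <- atomic_structure(rbind(p$atoms, a2))
  corr1 <- data.frame(chain = "A", resno = 1:n, t_chain = "A", t_resno = 1:n)
  corr2 <- data.frame(chain = "A", resno = 1:n, t_chain = "B", t_resno = 1:n)
  d <- build_heterodimer(p, corr1, p, corr2, template, clash_dist = 3.5)
  expect_equal(d$fit_rmsd, c(0, 0), tolerance = 1e-9)
  expect_equal(d$transforms[[2]]$rotation, tr$R, tolerance = 1e-6)
  expect_equal(d$transforms[[2]]$translation, tr$t, tolerance = 1e-6)
  expect_true(all(vapply(d$transforms,
                         function(f) det(f$rotation), numeric(1)) > 0.999))
  # the docked pose reproduces the template's second copy
  x2 <- as.matrix(d$structure$atoms[d$structure$atoms$chain == "2",
                                    c("x", "y", "z")])
  expect_equal(x2, as.matrix(a2[, c("x", "y", "z")]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("clash counting reports overlap and zero for clean poses", {
  p <- toy_partner()
  n <- nrow(p$atoms)
  far <- p$atoms; far$chain <- "B"; far$x <- far$x + 60
  template_far <- atomic_structure(rbind(p$atoms, far))
  corr1 <- data.frame(chain = "A", resno = 1:n, t_chain = "A", t_resno = 1:n)
  corr2 <- data.frame(chain = "A", resno = 1:n, t_chain = "B", t_resno = 1:n)
  d_far <- build_heterodimer(p, corr1, p, corr2, template_far)
  expect_equal(d_far$clash_count, 0L)

  # template forcing the partners on top of each other
  near <- p$atoms; near$chain <- "B"; near$x <- near$x + 0.5
  template_bad <- atomic_structure(rbind(p$atoms, near))
  d_bad <- build_heterodimer(p, corr1, p, corr2, template_bad,
                             clash_dist = 2.5)
  expect_gt(d_bad$clash_count, 0L)
})

test_that("interface extraction keeps inter-partner pairs at the set strength", {
  p <- toy_partner()
  n <- nrow(p$atoms)
  close_by <- p$atoms; close_by$chain <- "B"; close_by$x <- close_by$x + 16
  template <- atomic_structure(rbind(p$atoms, close_by))
  corr1 <- data.frame(chain = "A", resno = 1:n, t_chain = "A", t_resno = 1:n)
  corr2 <- data.frame(chain = "A", resno = 1:n, t_chain = "B", t_resno = 1:n)
  d <- build_heterodimer(p, corr1, p, corr2, template)
  cm <- interface_contacts(d, strength = 0.5, method = "cutoff", cutoff = 8)
  expect_gt(n_contacts(cm), 0L)
  expect_true(all(cm$contacts$class == "interface"))
  expect_true(all(cm$contacts$strength == 0.5))
  # no intra-partner pairs
  expect_true(all(cm$contacts$chain_a != cm$contacts$chain_b))
  # oracle: brute-force inter-partner scan at the same cutoff
  xa <- as.matrix(d$structure$atoms[d$structure$atoms$chain == "1",
                                    c("x", "y", "z")])
  xb <- as.matrix(d$structure$atoms[d$structure$atoms$chain == "2",
                                    c("x", "y", "z")])
  cnt <- sum(as.matrix(dist(rbind(xa, xb)))[seq_len(nrow(xa)),
             nrow(xa) + seq_len(nrow(xb))] <= 8)
  expect_equal(n_contacts(cm), cnt)

  # separated partners give an empty interface with a warning
  apart <- p$atoms; apart$chain <- "B"; apart$x <- apart$x + 50
  d2 <- build_heterodimer(p, corr1, p, corr2,
                          atomic_structure(rbind(p$atoms, apart)))
  expect_warning(cm2 <- interface_contacts(d2, method = "cutoff", cutoff = 8),
                 "no interface contacts")
  expect_equal(n_contacts(cm2), 0L)
})

test_that("docking is equivariant under rigid motion of the template", {
  p <- toy_partner()
  n <- nrow(p$atoms)
  shifted <- p$atoms; shifted$chain <- "B"; shifted$x <- shifted$x + 16
  template <- atomic_structure(rbind(p$atoms, shifted))
  corr1 <- data.frame(chain = "A", resno = 1:n, t_chain = "A", t_resno = 1:n)
  corr2 <- data.frame(chain = "A", resno = 1:n, t_chain = "B", t_resno = 1:n)
  d1 <- build_heterodimer(p, corr1, p, corr2, template)
  tr <- random_transform(17)
  ta <- template$atoms
  ta[, c("x", "y", "z")] <-
    sweep(as.matrix(ta[, c("x", "y", "z")]) %*% t(tr$R), 2, -tr$t)
  d2 <- build_heterodimer(p, corr1, p, corr2, atomic_structure(ta))
  cm1 <- interface_contacts(d1, method = "cutoff", cutoff = 8)
  cm2 <- interface_contacts(d2, method = "cutoff", cutoff = 8)
  expect_equal(cm1$contacts$r0, cm2$contacts$r0, tolerance = 1e-9)
  x1 <- as.matrix(d1$structure$atoms[, c("x", "y", "z")])
  x2 <- as.matrix(d2$structure$atoms[, c("x", "y", "z")])
  expect_equal(sweep(x1 %*% t(tr$R), 2, -tr$t), x2, tolerance = 1e-8,
               ignore_attr = TRUE)
})
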