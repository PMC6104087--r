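# Shared fixtures, built in code.

# hand-written 3-residue PDB (one CA per residue, plus N/C atoms on res 1)
pdb_three_res <- function() {
  c("ATOM      1  N   ALA A   1       0.000   1.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   0.500   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   2       4.500   0.800   0.000  1.00  0.00           C",
    "ATOM      5  CA  SER A   3       8.000   1.200   0.500  1.00  0.00           C",
    "END")
}

# same file with alt-locs A (occ 0.6) and B (occ 0.4) on residue 2's CA
pdb_altloc <- function() {
  c("ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA AGLY A   2       4.500   0.800   0.000  0.60  0.00           C",
    "ATOM      3  CA BGLY A   2       4.700   0.900   0.000  0.40  0.00           C",
    "ATOM      4  CA  SER A   3       8.000   1.200   0.500  1.00  0.00           C",
    "END")
}

empty_map <- function() {
  contact_map(data.frame(chain_a = character(), res_a = integer(),
                         chain_b = character(), res_b = integer(),
                         r0 = numeric(), class = character(),
                         strength = numeric()), "cutoff")
}

# straight bead chain with given spacing
straight_chain <- function(n, spacing = 3.8, chain = "A") {
  bead_model(rep(chain, n), seq_len(n),
             cbind((seq_len(n) - 1) * spacing, 0, 0))
}

# a mildly kinked chain (non-collinear, so angles/dihedrals are defined)
kinked_chain <- function(n, seed = 1) {
  set.seed(seed)
  xyz <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    dir <- dir + rnorm(3, 0, 0.35)
    dir <- dir / sqrt(sum(dir^2))
    xyz[i, ] <- xyz[i - 1, ] + 3.8 * dir
  }
  bead_model(rep("A", n), seq_len(n), xyz)
}

# random rigid transform (proper rotation + translation)
random_transform <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 5))
}

# brute-force shadow oracle: tests every (i, j, k) triple by point-to-
# segment distance, then aggregates surviving atom pairs to residue pairs
shadow_oracle <- function(atoms, cutoff, radius, min_sep) {
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  res_key <- paste(atoms$chain, atoms$resno)
  res_ids <- unique(res_key)
  out <- character()
  seg_d <- function(p, a, b) {
    ab <- b - a
    tt <- sum((p - a) * ab) / sum(ab^2)
    tt <- min(max(tt, 0), 1)
    sqrt(sum((p - (a + tt * ab))^2))
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (res_key[i] == res_key[j]) next
    if (atoms$chain[i] == atoms$chain[j] &&
        abs(atoms$resno[i] - atoms$resno[j]) < min_sep) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) > cutoff) next
    occluded <- FALSE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      if (seg_d(xyz[k, ], xyz[i, ], xyz[j, ]) < radius) {
        occluded <- TRUE
        break
      }
    }
    if (!occluded) {
      pr <- sort(c(match(res_key[i], res_ids), match(res_key[j], res_ids)))
      out <- c(out, paste(res_ids[pr[1]], res_ids[pr[2]], sep = "|"))
    }
  }
  sort(unique(out))
}

map_pair_keys <- function(cm) {
  cc <- cm$contacts
  sort(paste(paste(cc$chain_a, cc$res_a), paste(cc$chain_b, cc$res_b),
             sep = "|"))
}

# quick finite-difference force check; returns max relative error
fd_max_rel_err <- function(ff, x, h = 1e-5, beads = seq_len(nrow(x))) {
  F <- sbm_forces(ff, x)
  worst <- 0
  for (i in beads) for (d in 1:3) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    fd <- -(sbm_energy(ff, xp)$total - sbm_energy(ff, xm)$total) / (2 * h)
    worst <- max(worst, abs(fd - F[i, d]) / max(1, abs(fd)))
  }
  worst
}
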