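# ---------------------------------------------------------------------------
# Synthetic structures: ideal helix bundles, and a tethered two-domain toy
# with the statistical structure the tether analysis assumes -- two
# independently folded compact domains joined to a rigid central body by
# flexible linkers carrying no native contacts, plus a designated
# inter-domain interface contact set of tunable strength.
# ---------------------------------------------------------------------------

#' Toy system specification
#'
#' Defaults give a ~150-bead system (two 48-bead three-helix domains, a
#' 31-bead two-helix central body, two 9-residue linkers) whose full
#' simulation pipeline runs in minutes on one CPU. The interface is the
#' outward face helix of each domain; the interface map is pruned to the
#' `interface_n` closest residue pairs so that, at half native strength,
#' dimerisation is reversible on desk-scale trajectories.
#'
#' @param domain_helices,domain_len helices per domain and residues per
#'   helix
#' @param body_helices,body_len central-body bundle dimensions
#' @param linker_len residues per linker (length-2 vector or scalar); the
#'   linkers carry no native contacts
#' @param interface_n number of interface contacts kept (closest pairs)
#' @param contact_cutoff bead contact cutoff for the native maps, Angstrom
#'   (9.5 gives a contact density of ~2 per residue, emulating the density
#'   of atomistic shadow maps aggregated to residue pairs; sparser maps
#'   leave toy-scale bundles marginally stable at the working temperature)
#' @param seed geometry seed (reserved for jittered variants; the default
#'   construction is deterministic)
#' @return object of class `toy_spec`
#' @export
toy_spec <- function(domain_helices = 3L, domain_len = 14L,
                     body_helices = 2L, body_len = 14L,
                     linker_len = c(9L, 9L), interface_n = 12L,
                     contact_cutoff = 9.5, seed = 1L) {
  if (length(linker_len) == 1L) linker_len <- rep(linker_len, 2L)
  stopifnot(domain_helices >= 2L, domain_len >= 8L, body_helices >= 1L,
            body_len >= 8L, all(linker_len >= 0L), interface_n >= 1L)
  structure(list(domain_helices = as.integer(domain_helices),
                 domain_len = as.integer(domain_len),
                 body_helices = as.integer(body_helices),
                 body_len = as.integer(body_len),
                 linker_len = as.integer(linker_len),
                 interface_n = as.integer(interface_n),
                 contact_cutoff = contact_cutoff,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

#' Ideal antiparallel helix bundle
#'
#' C-alpha traces of ideal alpha helices (rise 1.5 A/residue, 100 degrees
#' per residue, helix radius 2.3 A) packed antiparallel at `axis_spacing`
#' with 3-residue connecting turns, as both a C-alpha-only atomic
#' structure and a bead model. Consecutive C-alpha spacing is 3.8 +/- 0.1
#' A throughout. Construction is deterministic.
#'
#' @param n_helices number of helices (>= 2; 4 helices pack as a 2 x 2
#'   square, fewer as a row)
#' @param helix_len residues per helix (>= 8)
#' @param axis_spacing helix axis separation, Angstrom
#' @param turn_len residues per connecting turn
#' @param chain chain id for the output
#' @return list with `structure` ([atomic_structure()]), `model`
#'   ([bead_model()]) and `helix_beads` (list of bead-index vectors, one
#'   per helix)
#' @export
make_helix_bundle <- function(n_helices = 4L, helix_len = 12L,
                              axis_spacing = 10.0, turn_len = 3L,
                              chain = "A") {
  if (n_helices < 2L) stop("bundle needs >= 2 helices")
  if (helix_len < 8L) stop("helices need >= 8 residues")
  rise <- 1.5; twist <- 100 * pi / 180; rad <- 2.3
  top <- rise * (helix_len - 1L)
  centres <- if (n_helices == 4L) {
    # 2 x 2 square visited as a ring so sequence neighbours stay adjacent
    rbind(c(0, 0), c(axis_spacing, 0), c(axis_spacing, axis_spacing),
          c(0, axis_spacing))
  } else {
    cbind((seq_len(n_helices) - 1L) * axis_spacing, 0)
  }
  helix <- function(h) {
    up <- (h %% 2L) == 1L  # odd helices run up, even run down
    tt <- seq_len(helix_len) - 1L
    th <- twist * tt
    z <- if (up) rise * tt else top - rise * tt
    cbind(centres[h, 1] + rad * cos(th), centres[h, 2] + rad * sin(th), z)
  }
  xyz <- NULL
  helix_beads <- vector("list", n_helices)
  for (h in seq_len(n_helices)) {
    hx <- helix(h)
    if (h > 1L) {
      p <- xyz[nrow(xyz), ]; q <- hx[1, ]
      d <- sqrt(sum((q - p)^2))
      if (d > 3.8 * (turn_len + 1L))
        stop("turn unbridgeable: helices too far apart")
      turn <- .arc_points(p, q, turn_len, 3.8,
                          bulge_away_from = colMeans(rbind(xyz, hx)))
      xyz <- rbind(xyz, turn)
    }
    helix_beads[[h]] <- (if (is.null(xyz)) 0L else nrow(xyz)) + seq_len(helix_len)
    xyz <- rbind(xyz, hx)
  }
  n <- nrow(xyz)
  m <- bead_model(rep(chain, n), seq_len(n), xyz)
  s <- atomic_structure(data.frame(
    chain = chain, resno = seq_len(n), resname = "ALA", atom = "CA",
    element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  list(structure = s, model = m, helix_beads = helix_beads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# proper rotations used to place units
.rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3, 3)
.rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                               0, -sin(a), cos(a)), 3, 3)
.rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3, 3)

#' Build the tethered two-domain toy system
#'
#' Two folded helix-bundle domains joined to a rigid central body by
#' flexible linkers, as one continuous chain:
#' domain 1 -- linker -- body -- linker -- domain 2. The docked reference
#' places the outward face helices of the two domains in contact (the
#' G-dimer analogue); the monomeric start separates the domains well
#' beyond twice the docked marker distance while keeping both linkers
#' within their extended reach (verified via [max_reach()]; geometrically
#' impossible linker lengths raise an error). The interface contact set
#' is the `interface_n` closest inter-domain residue pairs of the docked
#' reference; intra-domain and body maps are computed per unit so linkers
#' and body-domain incidental proximity carry no native contacts.
#'
#' @param spec [toy_spec()]
#' @return list with `start` and `docked` ([bead_model()]s), `intra_map`,
#'   `interface_map` ([contact_map()]s) and `info` (bead index sets:
#'   `domain1`, `domain2`, `body`, `linkers`, marker groups `marker1` /
#'   `marker2`, per-domain contact maps `domain_maps`, the docked marker
#'   distance and the linker reach table)
#' @export
make_tethered_pair <- function(spec = toy_spec()) {
  dh <- spec$domain_helices; dl <- spec$domain_len
  unit_dom <- make_helix_bundle(dh, dl, chain = "A")
  unit_body <- make_helix_bundle(spec$body_helices, spec$body_len,
                                 chain = "A")
  nd <- n_beads(unit_dom$model)
  nb <- n_beads(unit_body$model)
  face_centre_x <- (dh - 1L) * 10  # x of the face (last) helix axis
  dom_top <- 1.5 * (dl - 1L)
  body_top <- 1.5 * (spec$body_len - 1L)

  # Layout mirrors the tethered-tetramer architecture: both linkers leave
  # the bottom face of the central body (a two-helix bundle is entered and
  # exited on the same face, so its terminal beads sit ~6 A apart), and
  # the two domains dangle below it with their interface faces pointing
  # inwards. Each domain's interface face is the helix that carries its
  # tether attachment (domain 1's last helix ends at the chain exit;
  # domain 2, flipped upside-down by a proper rotation about x, enters
  # the chain at the top of its first helix), so the faces stay anchored
  # near each other and reversible docking is a local approach rather
  # than a long diffusive search. The separated start keeps the same
  # orientations translated outwards along x.
  place <- function(xyz, R, tvec) sweep(xyz %*% t(R), 2, -tvec)
  dxyz <- unit_dom$model$xyz
  bxyz <- unit_body$model$xyz
  clearance <- 10  # body-bottom to domain-top gap, A (room for the turns)
  face_sep <- 9.5  # docked face-helix axis separation (packed helix pair)
  sep_off <- 12    # separated-pose face offset from the body midline
  bx <- (bxyz[1, 1] + bxyz[nb, 1]) / 2  # linker-anchor midline
  zd <- -(clearance + dom_top)          # upright domain z range [zd, -clr]
  dom1_dock <- place(dxyz, diag(3),
                     c(bx - face_sep / 2 - face_centre_x, 0, zd))
  dom2_dock <- place(dxyz, .rot_x(pi),
                     c(bx + face_sep / 2, 0, -clearance))
  dom1_sep <- place(dxyz, diag(3),
                    c(bx - sep_off - face_centre_x, 0, zd))
  dom2_sep <- place(dxyz, .rot_x(pi), c(bx + sep_off, 0, -clearance))

  assemble <- function(d1, d2) {
    xyz <- rbind(d1, unit_body$model$xyz, d2)
    n <- nrow(xyz)
    brk <- rep(FALSE, n - 1L)
    brk[nd] <- TRUE            # domain1 | body
    brk[nd + nb] <- TRUE       # body | domain2
    m <- bead_model(rep("A", n), seq_len(n), xyz, is_break = brk)
    m <- bridge_gap(m, c(nd, nd + 1L), spec$linker_len[1])
    j <- nd + spec$linker_len[1] + nb
    m <- bridge_gap(m, c(j, j + 1L), spec$linker_len[2])
    m
  }
  docked <- assemble(dom1_dock, dom2_dock)
  start <- assemble(dom1_sep, dom2_sep)

  l1 <- spec$linker_len[1]; l2 <- spec$linker_len[2]
  idx_d1 <- seq_len(nd)
  idx_l1 <- nd + seq_len(l1)
  idx_b <- nd + l1 + seq_len(nb)
  idx_l2 <- nd + l1 + nb + seq_len(l2)
  idx_d2 <- nd + l1 + nb + l2 + seq_len(nd)

  # reachability: the linker must span the docked junction separation
  for (k in 1:2) {
    a <- if (k == 1) nd else nd + l1 + nb                 # pre-break bead
    b <- if (k == 1) nd + l1 + 1L else nd + l1 + nb + l2 + 1L
    dock_gap <- sqrt(sum((docked$xyz[b, ] - docked$xyz[a, ])^2))
    if (3.8 * (spec$linker_len[k] + 1L) < dock_gap)
      stop(sprintf(paste0("interface unreachable: linker %d (%d aa, reach ",
                          "%.1f A) cannot span the %.1f A docked junction"),
                   k, spec$linker_len[k], 3.8 * (spec$linker_len[k] + 1L),
                   dock_gap))
  }

  # per-unit native maps from the docked reference (units are rigid, so
  # any pose gives the same intra distances)
  unit_map <- function(idx) {
    mm <- bead_model(docked$chain[idx], docked$resno[idx],
                     docked$xyz[idx, , drop = FALSE])
    cutoff_contacts(mm, spec$contact_cutoff, min_seq_sep = 4L)
  }
  map_d1 <- unit_map(idx_d1)
  map_d2 <- unit_map(idx_d2)
  map_b <- unit_map(idx_b)
  intra_map <- combine_maps(map_d1, map_b, map_d2)

  # interface: closest inter-domain residue pairs of the docked reference
  full_map <- cutoff_contacts(docked, spec$contact_cutoff, min_seq_sep = 4L)
  cc <- full_map$contacts
  r1 <- docked$resno[idx_d1]; r2 <- docked$resno[idx_d2]
  inter <- (cc$res_a %in% r1 & cc$res_b %in% r2) |
           (cc$res_a %in% r2 & cc$res_b %in% r1)
  cc <- cc[inter, , drop = FALSE]
  if (nrow(cc) < spec$interface_n)
    stop("docked reference yields only ", nrow(cc), " interface pairs; ",
         "interface_n = ", spec$interface_n, " is not attainable")
  cc <- cc[order(cc$r0), , drop = FALSE][seq_len(spec$interface_n), ,
                                         drop = FALSE]
  cc$class <- "interface"
  cc$strength <- 0.5  # default: half as strong as the native contacts
  interface_map <- contact_map(cc, "docked-interface",
                               list(cutoff = spec$contact_cutoff,
                                    interface_n = spec$interface_n))

  # markers: interface-face helix beads of each domain (binding-pocket
  # proxies): the last helix of domain 1, the first helix of domain 2
  marker1 <- idx_d1[unit_dom$helix_beads[[dh]]]
  marker2 <- idx_d2[unit_dom$helix_beads[[1]]]
  com <- function(idx) colMeans(docked$xyz[idx, , drop = FALSE])
  dock_d <- sqrt(sum((com(marker1) - com(marker2))^2))

  reach <- max_reach(docked, list(
    list(type = "body", from = idx_b, to = nd + l1 + 1L),
    list(type = "linker", n = l1),
    list(type = "body", from = nd, to = marker1)))

  list(start = start, docked = docked, intra_map = intra_map,
       interface_map = interface_map,
       info = list(domain1 = idx_d1, domain2 = idx_d2, body = idx_b,
                   linkers = list(idx_l1, idx_l2),
                   marker1 = marker1, marker2 = marker2,
                   domain_maps = list(map_d1, map_d2),
                   docked_marker_distance = dock_d,
                   reach = reach, spec = spec))
}

#' Two-state Markov chain coordinate series
#'
#' Fixture generator for occupancy estimation: a two-state chain with a
#' chosen stationary dimerised fraction, emitting Q-like values from two
#' narrow bands (dimerised ~0.85, undimerised ~0.05).
#'
#' @param occupancy stationary probability of the dimerised state, in
#'   (0, 1)
#' @param switch_rate overall switching intensity per frame, in (0, 1)
#' @param length number of frames
#' @param seed RNG seed
#' @return numeric Q series of the requested length
#' @export
make_two_state_series <- function(occupancy = 0.5, switch_rate = 0.05,
                                  length = 1000L, seed = 1L) {
  stopifnot(occupancy > 0, occupancy < 1, switch_rate > 0, switch_rate <= 1)
  p01 <- switch_rate * occupancy         # undimerised -> dimerised
  p10 <- switch_rate * (1 - occupancy)   # dimerised -> undimerised
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  st <- integer(length)
  st[1] <- as.integer(runif(1) < occupancy)
  u <- runif(length)
  for (i in 2:length) {
    st[i] <- if (st[i - 1L] == 0L) as.integer(u[i] < p01)
             else as.integer(u[i] >= p10)
  }
  q <- ifelse(st == 1L, pmin(1, 0.85 + rnorm(length, 0, 0.05)),
              pmax(0, 0.05 + rnorm(length, 0, 0.03)))
  q
}
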