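# ---------------------------------------------------------------------------
# C-alpha structure-based potential with Gaussian native contacts.
# The native structure is the global energy minimum: bonded terms take their
# equilibrium values from the native geometry and each native contact is an
# attractive Gaussian well at its native distance, multiplied by a
# short-range repulsive core.
# ---------------------------------------------------------------------------

#' Default structure-based model parameters
#'
#' Reduced units: the native contact energy epsilon is the energy unit,
#' bead mass is 1 and the Boltzmann constant is 1; lengths are Angstrom.
#' The defaults follow the published C-alpha-with-Gaussian-contacts
#' convention: `k_bond` 200 eps/A^2, `k_angle` 40 eps/rad^2, `k_dihedral`
#' 1 eps, contact `epsilon` 1, Gaussian width `sigma` 0.5 A and excluded
#' volume radius `r_ex` 4 A. `ev_cutoff` truncates (and shifts) the
#' excluded-volume term where it is below 5e-7 eps. Inserted linker beads
#' get bonds at `linker_bond_r0` and angles at `linker_theta0` but no
#' dihedral bias and no contacts, so the linker behaves as an entropic
#' random-coil tether.
#'
#' @param k_bond,k_angle,k_dihedral bonded force constants
#' @param epsilon native contact well depth (energy unit)
#' @param sigma Gaussian contact width, Angstrom
#' @param r_ex excluded-volume radius, Angstrom
#' @param ev_cutoff excluded-volume truncation distance, Angstrom
#' @param linker_bond_r0,linker_theta0 ideal linker bond length (A) and
#'   angle (rad)
#' @return named list of parameters
#' @export
sbm_params <- function(k_bond = 200, k_angle = 40, k_dihedral = 1,
                       epsilon = 1, sigma = 0.5, r_ex = 4.0,
                       ev_cutoff = 12.0, linker_bond_r0 = 3.8,
                       linker_theta0 = 2.0) {
  stopifnot(k_bond > 0, k_angle > 0, k_dihedral > 0, epsilon > 0, sigma > 0,
            r_ex > 0, ev_cutoff > r_ex)
  list(k_bond = k_bond, k_angle = k_angle, k_dihedral = k_dihedral,
       epsilon = epsilon, sigma = sigma, r_ex = r_ex, ev_cutoff = ev_cutoff,
       linker_bond_r0 = linker_bond_r0, linker_theta0 = linker_theta0)
}

.vec_angle <- function(u, v) {
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, ct)))
}

.vec_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  m <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
         b1[1] * b2[2] - b1[2] * b2[1])
  nn <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cx <- c(m[2] * nn[3] - m[3] * nn[2], m[3] * nn[1] - m[1] * nn[3],
          m[1] * nn[2] - m[2] * nn[1])
  atan2(sum(cx * b2) / sqrt(sum(b2^2)), sum(m * nn))
}

#' Build the structure-based forcefield for a bead model
#'
#' Bonded terms follow chain connectivity only: bonds between consecutive
#' beads, angles over consecutive triples and dihedrals over consecutive
#' quadruples, all within unbroken chain segments, with equilibrium values
#' taken from the native coordinates in `m`. Each contact-map entry becomes
#' one Gaussian contact with well depth `epsilon * strength`. All remaining
#' pairs with intra-segment sequence separation >= 4 (or on different
#' segments) interact through the repulsive excluded-volume core. Linker
#' beads inserted by [bridge_gap()] receive ideal-value bonds and angles,
#' no dihedral bias and no contacts.
#'
#' @param m [bead_model()] at native coordinates
#' @param intra_map [contact_map()] of native intra-domain contacts
#' @param interface_map optional [contact_map()] of added interface
#'   contacts (strength factors are honoured per contact)
#' @param params [sbm_params()]
#' @return object of class `sbm_forcefield`
#' @export
build_forcefield <- function(m, intra_map, interface_map = NULL,
                             params = sbm_params()) {
  n <- n_beads(m)
  xyz <- m$xyz
  brk <- m$is_break
  seg <- cumsum(c(1L, as.integer(brk)))  # run id per bead
  lnk <- m$is_linker

  ok2 <- function(i) seg[i] == seg[i + 1L]
  ok3 <- function(i) seg[i] == seg[i + 2L]
  ok4 <- function(i) seg[i] == seg[i + 3L]

  bi <- which(vapply(seq_len(n - 1L), ok2, logical(1)))
  bonds <- cbind(bi, bi + 1L)
  b_r0 <- vapply(bi, function(i) {
    if (lnk[i] || lnk[i + 1L]) params$linker_bond_r0
    else sqrt(sum((xyz[i, ] - xyz[i + 1L, ])^2))
  }, numeric(1))

  ai <- if (n >= 3L) which(vapply(seq_len(n - 2L), ok3, logical(1))) else integer()
  angles <- cbind(ai, ai + 1L, ai + 2L)
  a_t0 <- vapply(ai, function(i) {
    if (any(lnk[i:(i + 2L)])) params$linker_theta0
    else .vec_angle(xyz[i, ] - xyz[i + 1L, ], xyz[i + 2L, ] - xyz[i + 1L, ])
  }, numeric(1))

  di <- if (n >= 4L) which(vapply(seq_len(n - 3L), ok4, logical(1))) else integer()
  di <- di[!vapply(di, function(i) any(lnk[i:(i + 3L)]), logical(1))]
  dihedrals <- cbind(di, di + 1L, di + 2L, di + 3L)
  d_p0 <- vapply(di, function(i)
    .vec_torsion(xyz[i, ], xyz[i + 1L, ], xyz[i + 2L, ], xyz[i + 3L, ]),
    numeric(1))

  cm <- if (is.null(interface_map)) intra_map
        else combine_maps(intra_map, interface_map)
  # a zero-depth well is no contact: drop it so the pair keeps its
  # excluded volume instead of becoming freely interpenetrable
  live <- cm$contacts$strength > 0
  cm$contacts <- cm$contacts[live, , drop = FALSE]
  idx <- contact_bead_indices(cm, m)
  if (nrow(idx) && any(lnk[idx]))
    stop("contact map touches linker beads; linkers are contact-free")
  c_eps <- params$epsilon * cm$contacts$strength
  c_class <- cm$contacts$class

  ff <- list(n = n,
             bonds = matrix(as.integer(bonds), ncol = 2),
             bond_r0 = as.numeric(b_r0),
             bond_k = rep(params$k_bond, nrow(bonds)),
             angles = matrix(as.integer(angles), ncol = 3),
             angle_t0 = as.numeric(a_t0),
             angle_k = rep(params$k_angle, nrow(angles)),
             dihedrals = matrix(as.integer(dihedrals), ncol = 4),
             dihedral_p0 = as.numeric(d_p0),
             dihedral_k = rep(params$k_dihedral, nrow(dihedrals)),
             contacts = matrix(as.integer(idx), ncol = 2),
             contact_r0 = as.numeric(cm$contacts$r0),
             contact_eps = as.numeric(c_eps),
             contact_sigma = rep(params$sigma, nrow(idx)),
             contact_class = c_class,
             r_ex = params$r_ex,
             ev_cutoff = params$ev_cutoff,
             seg_id = as.integer(seg),
             seq_pos = seq_len(n),
             params = params)
  class(ff) <- "sbm_forcefield"
  ff
}

#' @export
print.sbm_forcefield <- function(x, ...) {
  cat(sprintf(paste0("sbm_forcefield: %d beads | %d bonds, %d angles, ",
                     "%d dihedrals | %d contacts (%d interface)\n"),
              x$n, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$contacts), sum(x$contact_class == "interface")))
  invisible(x)
}

#' Potential energy by term class
#'
#' @param ff [build_forcefield()] output
#' @param coords n x 3 coordinates, Angstrom
#' @return list with `bond`, `angle`, `dihedral`, `contact`, `excluded`
#'   and `total` energies in reduced units
#' @export
sbm_energy <- function(ff, coords) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  cpp_sbm_energy(coords, unclass(ff))
}

#' Analytic forces (negative potential gradient)
#'
#' @param ff forcefield
#' @param coords n x 3 coordinates
#' @return n x 3 force matrix, reduced units per Angstrom
#' @export
sbm_forces <- function(ff, coords) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  cpp_sbm_forces(coords, unclass(ff))
}

#' Minimise the potential by steepest descent
#'
#' Backtracking line search on the normalised force direction; the energy
#' is non-increasing across accepted steps. Serves as the coarse-grained
#' relaxation step that removes small steric clashes from template-docked
#' starting structures.
#'
#' @param ff forcefield
#' @param coords starting coordinates
#' @param tol convergence threshold on the maximum force component
#'   (reduced units / Angstrom)
#' @param max_iter iteration cap
#' @param step0 initial trial displacement, Angstrom
#' @return list with `coords`, final `energy`, `max_force`, `iterations`,
#'   `converged`
#' @export
sbm_minimize <- function(ff, coords, tol = 1e-3, max_iter = 5000,
                         step0 = 0.05) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  cpp_sbm_minimize(coords, unclass(ff), tol, as.integer(max_iter), step0)
}

# ---------------------------------------------------------------------------
# Topology text export / import
# ---------------------------------------------------------------------------

#' Write a forcefield as a sectioned text topology
#'
#' Sections `[params]`, `[beads]`, `[bonds]`, `[angles]`, `[dihedrals]`,
#' `[contacts]`; round-trips through [read_topology()].
#'
#' @param ff forcefield
#' @param path output file
#' @return the path, invisibly
#' @export
write_topology <- function(ff, path) {
  p <- ff$params
  lines <- c("[params]",
             sprintf("%s %.10g", names(p), unlist(p)),
             "[beads]",
             sprintf("%d %d %d", ff$seq_pos, ff$seg_id, ff$n),
             "[bonds]",
             sprintf("%d %d %.8f %.6f", ff$bonds[, 1], ff$bonds[, 2],
                     ff$bond_r0, ff$bond_k),
             "[angles]",
             sprintf("%d %d %d %.8f %.6f", ff$angles[, 1], ff$angles[, 2],
                     ff$angles[, 3], ff$angle_t0, ff$angle_k),
             "[dihedrals]",
             sprintf("%d %d %d %d %.8f %.6f", ff$dihedrals[, 1],
                     ff$dihedrals[, 2], ff$dihedrals[, 3], ff$dihedrals[, 4],
                     ff$dihedral_p0, ff$dihedral_k),
             "[contacts]",
             sprintf("%d %d %.8f %.8f %.6f %s", ff$contacts[, 1],
                     ff$contacts[, 2], ff$contact_r0, ff$contact_eps,
                     ff$contact_sigma, ff$contact_class))
  writeLines(lines, path)
  invisible(path)
}

#' Read a text topology written by [write_topology()]
#' @param path input file
#' @return `sbm_forcefield`
#' @export
read_topology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- cumsum(grepl("^\\[", lines))
  name <- sub("\\[(.*)\\]", "\\1", lines[grepl("^\\[", lines)])
  get <- function(nm) {
    k <- match(nm, name)
    body <- lines[sec == k & !grepl("^\\[", lines)]
    body[nzchar(trimws(body))]
  }
  ptok <- strsplit(get("params"), " ")
  params <- setNames(lapply(ptok, function(t) as.numeric(t[2])),
                     vapply(ptok, `[`, character(1), 1))
  btok <- do.call(rbind, strsplit(get("beads"), " "))
  n <- as.integer(btok[1, 3])
  num <- function(rows, k) if (length(rows)) as.numeric(
    vapply(strsplit(rows, " "), `[`, character(1), k)) else numeric()
  int <- function(rows, k) as.integer(num(rows, k))
  b <- get("bonds"); a <- get("angles"); d <- get("dihedrals")
  cc <- get("contacts")
  ff <- list(n = n,
             bonds = cbind(int(b, 1), int(b, 2)),
             bond_r0 = num(b, 3), bond_k = num(b, 4),
             angles = cbind(int(a, 1), int(a, 2), int(a, 3)),
             angle_t0 = num(a, 4), angle_k = num(a, 5),
             dihedrals = cbind(int(d, 1), int(d, 2), int(d, 3), int(d, 4)),
             dihedral_p0 = num(d, 5), dihedral_k = num(d, 6),
             contacts = cbind(int(cc, 1), int(cc, 2)),
             contact_r0 = num(cc, 3), contact_eps = num(cc, 4),
             contact_sigma = num(cc, 5),
             contact_class = if (length(cc)) vapply(strsplit(cc, " "), `[`,
                                                    character(1), 6)
                             else character(),
             r_ex = params$r_ex, ev_cutoff = params$ev_cutoff,
             seg_id = as.integer(btok[, 2]),
             seq_pos = as.integer(btok[, 1]),
             params = params)
  class(ff) <- "sbm_forcefield"
  ff
}
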