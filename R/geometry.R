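# ---------------------------------------------------------------------------
# Structural geometry: solvent accessibility and buried surface area,
# superposition RMSD, hinge rotation between conformational states, and
# maximum tether reach.
# ---------------------------------------------------------------------------

# van der Waals radii (Angstrom) for the elements found in deposited
# protein models; hydrogens are not expected (X-ray models lack them)
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Point-sampling accessibility with a deterministic golden-spiral sphere
#' point set, so repeated runs give identical areas. Radii are assigned
#' per element from a documented table (C 1.70, N 1.55, O 1.52, S 1.80 A);
#' unknown elements raise an error unless an override is supplied.
#'
#' @param s [atomic_structure()]
#' @param probe probe radius, Angstrom (1.4 = water)
#' @param n_points sphere sample points per atom (>= 64)
#' @param radii optional named vector overriding / extending the radius
#'   table
#' @return list with `atom_area` (per atom, Angstrom^2) and `total`
#' @export
sasa <- function(s, probe = 1.4, n_points = 960L, radii = NULL) {
  if (n_points < 64L) stop("n_points must be >= 64")
  tab <- .vdw_radii
  if (!is.null(radii)) tab[names(radii)] <- radii
  el <- toupper(s$atoms$element)
  r <- tab[el]
  if (any(is.na(r)))
    stop("no radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "),
         " (supply an override via `radii`)")
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  a <- cpp_sasa(xyz, as.numeric(r), probe, as.integer(n_points))
  list(atom_area = a, total = sum(a))
}

#' Buried surface area of an interface
#'
#' BSA = SASA(A) + SASA(B) - SASA(AB), the solvent-accessible area lost on
#' complex formation. Reported two-sided (the A-side and B-side losses
#' summed), with the one-sided value (half) alongside, because deposited
#' interface areas are quoted in both conventions.
#'
#' @param complex [atomic_structure()] containing both parts
#' @param sel_a,sel_b disjoint selections (see [parse_selection()])
#' @param probe probe radius, Angstrom
#' @param n_points sphere samples per atom
#' @return object of class `interface_report`: SASA of A, B and AB, the
#'   two-sided and one-sided BSA, and a per-residue burial table
#' @export
buried_surface_area <- function(complex, sel_a, sel_b, probe = 1.4,
                                n_points = 960L) {
  A <- subset_structure(complex, sel_a)
  B <- subset_structure(complex, sel_b)
  key_a <- paste(A$atoms$chain, A$atoms$resno, A$atoms$atom)
  key_b <- paste(B$atoms$chain, B$atoms$resno, B$atoms$atom)
  if (length(intersect(key_a, key_b)))
    stop("selections overlap; interface parts must be disjoint")
  ab_atoms <- rbind(A$atoms, B$atoms)
  ord <- order(ab_atoms$chain, ab_atoms$resno)  # restore chain order
  AB <- atomic_structure(ab_atoms[ord, , drop = FALSE])
  sa <- sasa(A, probe, n_points)
  sb <- sasa(B, probe, n_points)
  sab <- sasa(AB, probe, n_points)
  bsa <- sa$total + sb$total - sab$total
  # per-residue burial: free-state minus complex-state residue SASA
  part <- c(rep("A", nrow(A$atoms)), rep("B", nrow(B$atoms)))[ord]
  res_key <- paste(AB$atoms$chain, AB$atoms$resno)
  free_area <- c(sa$atom_area, sb$atom_area)[ord]
  burial <- tapply(free_area - sab$atom_area, res_key, sum)
  res_tab <- data.frame(
    chain = sub(" .*", "", names(burial)),
    resno = as.integer(sub(".* ", "", names(burial))),
    part = tapply(part, res_key, `[`, 1),
    buried = as.numeric(burial))
  res_tab <- res_tab[order(res_tab$part, res_tab$chain, res_tab$resno), ]
  rownames(res_tab) <- NULL
  structure(list(sasa_a = sa$total, sasa_b = sb$total, sasa_ab = sab$total,
                 bsa = bsa, bsa_one_sided = bsa / 2, probe = probe,
                 n_points = n_points, convention = "total (two-sided)",
                 per_residue = res_tab),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(
    paste0("interface_report: BSA %.1f A^2 %s (one-sided %.1f) | ",
           "SASA A %.1f, B %.1f, AB %.1f | probe %.2f A\n"),
    x$bsa, x$convention, x$bsa_one_sided, x$sasa_a, x$sasa_b, x$sasa_ab,
    x$probe))
  invisible(x)
}

#' Hinge rotation angle between two conformational states
#'
#' States 1 and 2 are first brought into a common frame by superposing the
#' reference domain of state 2 onto state 1; the residual rigid transform
#' that then maps the moving domain of state 1 onto the moving domain of
#' state 2 is decomposed into a rotation angle (degrees) about a screw
#' axis. Coordinates must be paired row-wise within each domain.
#'
#' @param ref1,ref2 reference-domain coordinates in states 1 and 2
#' @param mov1,mov2 moving-domain coordinates in states 1 and 2
#' @return list with `angle_deg`, `axis` (unit 3-vector), and the
#'   reference-fit `rmsd`
#' @export
hinge_angle <- function(ref1, ref2, mov1, mov2) {
  fit_ref <- superpose(ref2, ref1)       # state 2 -> state 1 frame
  mov2_in1 <- apply_transform(as.matrix(mov2), fit_ref)
  fit_mov <- superpose(as.matrix(mov1), mov2_in1)
  list(angle_deg = rotation_angle(fit_mov$rotation),
       axis = rotation_axis(fit_mov$rotation),
       rmsd = fit_ref$rmsd)
}

#' Maximum tether reach of a segmented model
#'
#' Upper bound on the anchor-to-distal distance of a chain that
#' alternates rigid bodies and flexible linkers: the rigid-body internal
#' spans along the chain path are summed and each linker contributes its
#' residue count times the fully extended C-alpha spacing of 3.8 A.
#'
#' @param m [bead_model()]
#' @param path list of segments, in chain order from the anchor to the
#'   distal site. Rigid bodies are `list(type = "body", from = beads,
#'   to = beads)` (attachment/entry and exit bead indices; the span is the
#'   maximum from-to distance in the native coordinates); linkers are
#'   `list(type = "linker", n = residues)`
#' @param spacing extended per-residue contribution, Angstrom
#' @return list with `reach_A`, `reach_nm` and the per-segment table
#' @export
max_reach <- function(m, path, spacing = 3.8) {
  spans <- vapply(path, function(seg) {
    if (seg$type == "linker") {
      if (is.null(seg$n) || seg$n < 0) stop("linker segment needs n >= 0")
      return(spacing * seg$n)
    }
    if (seg$type != "body") stop("segment type must be 'body' or 'linker'")
    from <- m$xyz[seg$from, , drop = FALSE]
    to <- m$xyz[seg$to, , drop = FALSE]
    d2 <- outer(rowSums(from^2), rowSums(to^2), "+") -
      2 * tcrossprod(from, to)
    sqrt(max(pmax(d2, 0)))
  }, numeric(1))
  labels <- vapply(path, function(seg)
    if (seg$type == "linker") sprintf("linker(%d aa)", seg$n) else "body",
    character(1))
  total <- sum(spans)
  list(reach_A = total, reach_nm = total / 10,
       segments = data.frame(segment = labels, span_A = spans))
}

#' Pairwise superposition RMSD
#'
#' Convenience wrapper: optimal-fit RMSD between two paired coordinate
#' sets.
#'
#' @param a,b n x 3 coordinate matrices, paired row-wise
#' @return RMSD in Angstrom after least-squares superposition
#' @export
fit_rmsd <- function(a, b) superpose(a, b)$rmsd
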