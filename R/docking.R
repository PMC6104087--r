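# ---------------------------------------------------------------------------
# Template-based construction of the candidate hetero G-domain dimer:
# rigid least-squares superposition of each partner onto a chain of a
# template homodimer, then extraction of the inter-partner contact set.
# ---------------------------------------------------------------------------

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `mobile` onto
#' `reference`, with reflections corrected so the returned rotation is
#' always proper (determinant +1).
#'
#' @param mobile n x 3 coordinates (Angstrom), paired row-wise with
#'   `reference`
#' @param reference n x 3 coordinates
#' @return list with `rotation` (3 x 3), `translation` (length-3; the
#'   transform is `x %*% t(R) + t`), and `rmsd` after the fit
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n)
    stop("superposition needs >= 3 paired points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  sv <- svd(crossprod(A, B))  # 3x3
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set: rotation is under-determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- unname(sv$v %*% D %*% t(sv$u))
  tr <- unname(cr - as.vector(R %*% cm))
  fitted <- sweep(A %*% t(R), 2, -cr)
  rmsd <- sqrt(mean(rowSums((fitted - sweep(B, 2, -cr))^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix
#' @param fit list with `rotation` and `translation` (from [superpose()])
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(xyz, fit) {
  out <- sweep(as.matrix(xyz) %*% t(fit$rotation), 2, -fit$translation)
  dimnames(out) <- NULL
  out
}

#' Rotation angle of a rigid transform
#' @param R 3 x 3 proper rotation matrix
#' @return angle in degrees
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

# rotation axis (unit vector) of a proper rotation
rotation_axis <- function(R) {
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  nrm <- sqrt(sum(ax^2))
  if (nrm < 1e-9) {  # angle ~0 or ~180
    ev <- eigen(R)
    k <- which.min(abs(Re(ev$values) - 1))
    ax <- Re(ev$vectors[, k]); nrm <- sqrt(sum(ax^2))
  }
  ax / nrm
}

# CA coordinates for a correspondence data.frame (chain, resno) against a
# structure; errors when referenced residues are missing
.corr_coords <- function(s, corr) {
  tab <- .ca_table(s)
  key <- paste(corr$chain, corr$resno, sep = "\r")
  hit <- match(key, rownames(tab))
  if (any(is.na(hit)))
    stop("correspondence references residues without CA atoms: ",
         paste(head(key[is.na(hit)], 5), collapse = ", "))
  tab[hit, , drop = FALSE]
}

#' Build a candidate heterodimer on a template homodimer
#'
#' Each partner is rigidly superposed onto its template chain through an
#' explicit residue correspondence (a data.frame pairing partner residues
#' with template residues), then both transformed copies are merged. The
#' complex is returned regardless of steric clashes; the inter-partner
#' clash count is reported so the caller can decide whether the pose is
#' usable (a clean template fit has none).
#'
#' @param partner1,partner2 [atomic_structure()]s to be docked
#' @param corr1,corr2 data.frames with columns `chain`, `resno` (partner
#'   residues) and `t_chain`, `t_resno` (the matched template residues)
#' @param template [atomic_structure()] of the template dimer
#' @param clash_dist inter-partner atom distance counted as a clash
#'   (Angstrom; default 2.5 atomic)
#' @param chain_ids chain ids assigned to the docked partners
#' @param markers optional list of two selections naming the marker groups
#'   used for the reaction-coordinate distance (e.g. bound-nucleotide
#'   proxies or P-loop residues)
#' @return object of class `docked_complex`: merged structure, the two
#'   transforms, per-partner fit RMSD, clash count and marker groups
#' @export
build_heterodimer <- function(partner1, corr1, partner2, corr2, template,
                              clash_dist = 2.5, chain_ids = c("1", "2"),
                              markers = NULL) {
  place <- function(partner, corr, new_chain) {
    mob <- .corr_coords(partner, corr[, c("chain", "resno")])
    ref <- .corr_coords(template,
                        data.frame(chain = corr$t_chain, resno = corr$t_resno))
    if (nrow(mob) < 3L) stop("correspondence has fewer than 3 pairs")
    fit <- superpose(mob, ref)
    a <- partner$atoms
    a[, c("x", "y", "z")] <- apply_transform(as.matrix(a[, c("x", "y", "z")]),
                                             fit)
    a$chain <- new_chain
    list(atoms = a, fit = fit)
  }
  p1 <- place(partner1, corr1, chain_ids[1])
  p2 <- place(partner2, corr2, chain_ids[2])
  merged <- atomic_structure(rbind(p1$atoms, p2$atoms))
  x1 <- as.matrix(p1$atoms[, c("x", "y", "z")])
  x2 <- as.matrix(p2$atoms[, c("x", "y", "z")])
  clashes <- cpp_count_clashes(x1, x2, clash_dist)
  structure(list(structure = merged,
                 transforms = list(p1$fit, p2$fit),
                 fit_rmsd = c(p1$fit$rmsd, p2$fit$rmsd),
                 clash_count = clashes,
                 clash_dist = clash_dist,
                 chain_ids = chain_ids,
                 markers = markers),
            class = "docked_complex")
}

#' @export
print.docked_complex <- function(x, ...) {
  cat(sprintf(
    "docked_complex: chains [%s], fit RMSD %.3f / %.3f A, %d clash(es) < %.1f A\n",
    paste(x$chain_ids, collapse = " "), x$fit_rmsd[1], x$fit_rmsd[2],
    x$clash_count, x$clash_dist))
  invisible(x)
}

#' Extract the interface contact set of a docked complex
#'
#' Runs contact-map generation on the docked pose and keeps inter-partner
#' pairs only, labelled `interface`, with every contact's strength factor
#' set to `strength`. Reference distances come from the docked pose. A
#' strength of 0.5 makes the added dimerisation contacts half as strong as
#' the native intra-domain contacts.
#'
#' @param d `docked_complex`
#' @param strength dimensionless strength factor applied to every contact
#' @param method `"shadow"` (atomic occlusion screening) or `"cutoff"`
#'   (bead distance; for C-alpha-only poses)
#' @param ... parameters passed to [shadow_contacts()] / [cutoff_contacts()]
#' @return [contact_map()] with provenance `"docked-interface"`
#' @export
interface_contacts <- function(d, strength = 0.5,
                               method = c("shadow", "cutoff"), ...) {
  method <- match.arg(method)
  cm <- if (method == "shadow") {
    shadow_contacts(d$structure, ...)
  } else {
    cutoff_contacts(coarse_grain(d$structure), ...)
  }
  cc <- cm$contacts
  inter <- cc$chain_a != cc$chain_b
  cc <- cc[inter, , drop = FALSE]
  if (!nrow(cc))
    warning("no interface contacts found between docked partners")
  cc$class <- rep("interface", nrow(cc))
  cc$strength <- rep(strength, nrow(cc))
  contact_map(cc, "docked-interface",
              c(cm$params, list(strength = strength, method = method)))
}
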