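#' @useDynLib tetherSBM, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd uniroot quantile rnorm runif setNames acf ks.test
#' @importFrom utils head tail write.table read.table
NULL

# ---------------------------------------------------------------------------
# Atomic structures
# ---------------------------------------------------------------------------

#' Construct an atomic structure
#'
#' An `atomic_structure` holds all-atom coordinates with chain / residue /
#' atom labels. It is the substrate for contact-map generation and solvent
#' accessibility; coordinates are in Angstrom throughout.
#'
#' @param atoms data.frame with columns `chain` (character), `resno`
#'   (integer), `resname` (character, 3-letter), `atom` (character atom
#'   name), `element` (character), `x`, `y`, `z` (numeric, Angstrom),
#'   and optionally `occ` (occupancy, default 1) and `alt` (alternate
#'   location indicator, default `""`).
#' @return object of class `atomic_structure`
#' @export
atomic_structure <- function(atoms) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$alt)) atoms$alt <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atomic structure")
  # residue indices must strictly increase within each chain
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (any(diff(r) < 0))
      stop("residue indices do not increase within chain ", ch)
  }
  structure(list(atoms = atoms), class = "atomic_structure")
}

#' @export
print.atomic_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("atomic_structure: %d atoms, %d residues, chains [%s]\n",
              nrow(a), nrow(unique(a[, c("chain", "resno")])),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

# read file content or accept literal text lines
.as_lines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
    return(readLines(input, warn = FALSE))
  unlist(strsplit(input, "\n", fixed = TRUE))
}

#' Load an atomic structure from PDB or mmCIF
#'
#' Parses ATOM/HETATM records of the selected model. Alternate locations are
#' resolved to the highest-occupancy copy (ties broken by file order);
#' insertion codes are rejected because they make residue identity ambiguous
#' for contact maps. Parsing is delegated to bio3d.
#'
#' @param input path to a `.pdb` / `.cif` file, or the file content as a
#'   single string / character vector of lines
#' @param model 1-based model number (for multi-model files)
#' @param format `"auto"`, `"pdb"` or `"cif"`
#' @return [atomic_structure()]
#' @export
load_structure <- function(input, model = 1L, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  lines <- .as_lines(input)
  if (format == "auto") {
    is_cif <- any(grepl("^data_", lines[seq_len(min(5, length(lines)))])) ||
      (length(input) == 1L && grepl("\\.cif$", input, ignore.case = TRUE))
    format <- if (is_cif) "cif" else "pdb"
  }
  tf <- tempfile(fileext = paste0(".", format))
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- if (format == "cif") {
    bio3d::read.cif(tf, multi = TRUE, verbose = FALSE)
  } else {
    tryCatch(bio3d::read.pdb(tf, multi = TRUE, verbose = FALSE),
             error = function(e) stop("malformed PDB input: ",
                                      conditionMessage(e)))
  }
  nmod <- max(1L, nrow(pdb$xyz))
  if (model < 1L || model > nmod)
    stop("model ", model, " not present (file has ", nmod, ")")
  at <- pdb$atom
  if (!nrow(at)) stop("empty model: no ATOM/HETATM records")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  ins <- at$insert
  if (!is.null(ins) && any(!is.na(ins) & nzchar(trimws(ins))))
    stop("insertion codes present; renumber residues before loading")
  alt <- at$alt
  if (is.null(alt)) alt <- rep(NA_character_, nrow(at))
  occ <- at$o
  if (is.null(occ)) occ <- rep(1, nrow(at))
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    resname = at$resid,
    atom = at$elety,
    element = .element_of(at),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = occ,
    alt = ifelse(is.na(alt), "", alt),
    stringsAsFactors = FALSE
  )
  atoms <- .resolve_altloc(atoms)
  atomic_structure(atoms)
}

.element_of <- function(at) {
  el <- at$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(at))
  el <- trimws(el)
  guess <- toupper(substr(trimws(at$elety), 1L, 1L))
  ifelse(is.na(el) | !nzchar(el), guess, toupper(el))
}

# keep the highest-occupancy alt-loc per (chain, resno, atom name); ties ->
# first occurrence in file order
.resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
  keep <- ord[!duplicated(key[ord])]
  atoms <- atoms[sort(keep), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms$alt <- ""
  atoms
}

#' Write an atomic structure as single-model PDB
#'
#' Deterministic fixed-width writer for the documented PDB subset
#' (ATOM records, 3-decimal coordinates). Writing the same structure twice
#' yields byte-identical output, so write -> load -> write is stable.
#'
#' @param s [atomic_structure()]
#' @param path output file; if `NULL` the lines are returned invisibly
#' @return character vector of PDB lines, invisibly
#' @export
write_structure_pdb <- function(s, path = NULL) {
  a <- s$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000L,
    ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
    a$resname, substr(paste0(a$chain, " "), 1, 1), a$resno %% 10000L,
    a$x, a$y, a$z, a$occ, 0, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# ---------------------------------------------------------------------------
# Bead models (one bead per residue at the C-alpha position)
# ---------------------------------------------------------------------------

#' Construct a bead model
#'
#' One interaction site per residue at the alpha-carbon position, the
#' representation used by the coarse-grained simulation. Chain breaks are
#' flagged between consecutive beads that are not covalently continuous.
#'
#' @param chain character vector of chain ids
#' @param resno integer residue numbers
#' @param xyz n x 3 coordinate matrix (Angstrom)
#' @param is_break logical, length n-1: `TRUE` between beads i and i+1 when
#'   the backbone is not continuous there
#' @param is_linker logical, length n: beads inserted by [bridge_gap()]
#' @return object of class `bead_model`
#' @export
bead_model <- function(chain, resno, xyz, is_break = NULL, is_linker = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(chain) == n, length(resno) == n, ncol(xyz) == 3)
  if (!all(is.finite(xyz))) stop("non-finite bead coordinates")
  if (is.null(is_break)) is_break <- rep(FALSE, max(0L, n - 1L))
  if (is.null(is_linker)) is_linker <- rep(FALSE, n)
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 xyz = unname(xyz), is_break = is_break,
                 is_linker = is_linker),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("bead_model: %d beads (%d linker), %d chain break(s)\n",
              length(x$resno), sum(x$is_linker), sum(x$is_break)))
  invisible(x)
}

#' Number of beads
#' @param m bead model
#' @return integer
#' @export
n_beads <- function(m) nrow(m$xyz)

#' Coarse-grain an atomic structure to C-alpha beads
#'
#' Keeps one bead per selected residue, placed at its C-alpha coordinate.
#' Residues lacking a C-alpha are skipped with a warning. A chain break is
#' flagged between consecutive selected beads that are on different chains,
#' non-adjacent in sequence, or more than `break_dist` apart (the trans
#' peptide C-alpha spacing is ~3.8 Angstrom; 4.5 adds tolerance).
#'
#' @param s [atomic_structure()]
#' @param keep optional selection (see [parse_selection()]): character like
#'   `"A:10-50+60-80"`, or a data.frame with columns `chain`, `resno`
#' @param break_dist chain-break distance threshold in Angstrom
#' @return [bead_model()]
#' @export
coarse_grain <- function(s, keep = NULL, break_dist = 4.5) {
  a <- s$atoms
  sel_res <- unique(a[, c("chain", "resno")])
  if (!is.null(keep)) {
    ok <- .match_selection(sel_res, keep, s)
    sel_res <- sel_res[ok, , drop = FALSE]
  }
  if (nrow(sel_res) < 2L) stop("selection resolves to fewer than 2 residues")
  ca <- a[a$atom == "CA", , drop = FALSE]
  key <- paste(ca$chain, ca$resno)
  want <- paste(sel_res$chain, sel_res$resno)
  hit <- match(want, key)
  skipped <- sum(is.na(hit))
  if (skipped > 0)
    warning(skipped, " residue(s) lack a CA atom and were skipped")
  hit <- hit[!is.na(hit)]
  if (!length(hit)) stop("no CA atoms in selection")
  ca <- ca[hit, , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(xyz)
  brk <- rep(FALSE, max(0L, n - 1L))
  if (n > 1L) {
    d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
    same_chain <- ca$chain[-1] == ca$chain[-n]
    adjacent <- ca$resno[-1] == ca$resno[-n] + 1L
    brk <- !(same_chain & adjacent & d <= break_dist)
  }
  bead_model(ca$chain, ca$resno, xyz, is_break = brk)
}

#' Write a bead model as a C-alpha-only PDB
#'
#' @param m [bead_model()]
#' @param path output path, or `NULL` to return lines only
#' @return PDB lines, invisibly
#' @export
write_beads_pdb <- function(m, path = NULL) {
  s <- atomic_structure(data.frame(
    chain = m$chain, resno = m$resno,
    resname = ifelse(m$is_linker, "GLY", "ALA"),
    atom = "CA", element = "C",
    x = m$xyz[, 1], y = m$xyz[, 2], z = m$xyz[, 3]))
  write_structure_pdb(s, path)
}

#' Load a C-alpha-only PDB as a bead model
#' @param input path or PDB text
#' @return [bead_model()]
#' @export
load_beads_pdb <- function(input) {
  coarse_grain(load_structure(input, format = "pdb"))
}

# ---------------------------------------------------------------------------
# Gap bridging
# ---------------------------------------------------------------------------

#' Bridge a chain break with a smooth arc of linker beads
#'
#' Inserts `n` beads between beads `i` and `j` (which must sit across a
#' flagged chain break) on a circular arc whose consecutive spacings do not
#' exceed the trans C-alpha distance of 3.8 Angstrom. If the straight-line
#' gap already divides into segments of 3.8 the beads are placed on the
#' chord; shorter gaps bulge off-axis (away from the body of the model) so
#' that the inserted chain is never compressed below realistic spacing.
#' Inserted beads are flagged as linker beads: they carry no native contacts
#' and no dihedral bias in the forcefield.
#'
#' @param m [bead_model()]
#' @param gap integer pair `c(i, j)`: bead indices flanking the break
#'   (`j = i + 1`)
#' @param n number of residues to insert (>= 1)
#' @param spacing target inserted C-alpha spacing, Angstrom
#' @return [bead_model()] with `n` extra beads and the break flag cleared
#' @export
bridge_gap <- function(m, gap, n, spacing = 3.8) {
  i <- gap[1]; j <- gap[2]
  if (j != i + 1L) stop("gap must name consecutive beads (i, i+1)")
  if (i < 1L || j > n_beads(m)) stop("gap indices out of range")
  if (!m$is_break[i]) stop("beads ", i, ",", j, " are not flagged as a break")
  if (n < 1L) stop("n must be >= 1")
  if (m$chain[i] != m$chain[j])
    stop("bridge_gap joins segments of one chain; flanking beads are on ",
         "different chains")
  p <- m$xyz[i, ]; q <- m$xyz[j, ]
  d <- sqrt(sum((q - p)^2))
  if (d > spacing * (n + 1))
    stop(sprintf("gap unbridgeable at given n: %.2f A > %.1f * %d", d,
                 spacing, n + 1L))
  pts <- .arc_points(p, q, n, spacing, bulge_away_from = colMeans(m$xyz))
  new_xyz <- rbind(m$xyz[seq_len(i), , drop = FALSE], pts,
                   m$xyz[j:n_beads(m), , drop = FALSE])
  # renumber so residue ids remain strictly increasing along the chain:
  # inserted beads take res_lo+1..res_lo+n; the tail shifts up if needed
  res_lo <- m$resno[i]
  shift <- max(0L, res_lo + n + 1L - m$resno[j])
  tail_res <- m$resno[j:n_beads(m)]
  same_ch <- m$chain[j:n_beads(m)] == m$chain[i]
  tail_res[same_ch] <- tail_res[same_ch] + shift
  new_res <- c(m$resno[seq_len(i)], res_lo + seq_len(n), tail_res)
  new_chain <- c(m$chain[seq_len(i)], rep(m$chain[i], n),
                 m$chain[j:n_beads(m)])
  new_brk <- c(m$is_break[seq_len(i - 1)], rep(FALSE, n + 1L),
               if (j <= n_beads(m) - 1L) m$is_break[j:(n_beads(m) - 1L)])
  new_lnk <- c(m$is_linker[seq_len(i)], rep(TRUE, n),
               m$is_linker[j:n_beads(m)])
  bead_model(new_chain, new_res, new_xyz, is_break = new_brk,
             is_linker = new_lnk)
}

# n interior points on a circular arc from p to q with equal chord segments
# of length <= s. Solves sin(a/(n+1))/sin(a) = s/d for the half-angle a when
# the straight chord would compress the segments below s.
.arc_points <- function(p, q, n, s, bulge_away_from = NULL) {
  d <- sqrt(sum((q - p)^2))
  k <- n + 1L
  if (d >= s * k - 1e-9) {  # straight division at spacing d/k <= s
    tt <- seq_len(n) / k
    return(t(vapply(tt, function(u) p + u * (q - p), numeric(3))))
  }
  f <- function(a) sin(a / k) / sin(a) - s / d
  a <- uniroot(f, c(1e-8, pi - 1e-8), tol = 1e-12)$root
  R <- d / (2 * sin(a))
  # orthonormal frame: u along chord, v in the bulge plane
  u <- (q - p) / d
  ref <- if (!is.null(bulge_away_from)) (p + q) / 2 - bulge_away_from else NULL
  if (is.null(ref) || sqrt(sum(ref^2)) < 1e-8 ||
      sqrt(sum((ref - sum(ref * u) * u)^2)) < 1e-8) {
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  centre <- (p + q) / 2 - v * R * cos(a)
  # in the (u, v) frame the arc runs from angle pi/2 + a (= p) down to
  # pi/2 - a (= q); interior points divide that sweep evenly
  phis <- (pi / 2 + a) - 2 * a * seq_len(n) / k
  t(vapply(phis, function(ph) centre + R * (cos(ph) * u + sin(ph) * v),
           numeric(3)))
}

# ---------------------------------------------------------------------------
# Selections
# ---------------------------------------------------------------------------

#' Parse a chain / residue-range selection
#'
#' Selections use a compact mini-language: `"B"` selects all of chain B,
#' `"B:348-401+509-542"` selects the two inclusive residue ranges of chain
#' B, and several such terms may be supplied as a character vector.
#' Residue numbers are 1-based as deposited.
#'
#' @param sel character vector of selection terms
#' @return data.frame with columns `chain`, `lo`, `hi` (one row per range;
#'   `lo`/`hi` are `NA` for whole-chain terms)
#' @export
parse_selection <- function(sel) {
  out <- lapply(sel, function(term) {
    bits <- strsplit(term, ":", fixed = TRUE)[[1]]
    ch <- bits[1]
    if (length(bits) == 1L)
      return(data.frame(chain = ch, lo = NA_integer_, hi = NA_integer_))
    ranges <- strsplit(bits[2], "+", fixed = TRUE)[[1]]
    do.call(rbind, lapply(ranges, function(r) {
      ab <- as.integer(strsplit(r, "-", fixed = TRUE)[[1]])
      if (length(ab) == 1L) ab <- c(ab, ab)
      if (any(is.na(ab)) || ab[2] < ab[1])
        stop("bad residue range in selection: ", term)
      data.frame(chain = ch, lo = ab[1], hi = ab[2])
    }))
  })
  do.call(rbind, out)
}

# logical index over the rows of res_tbl (chain, resno)
.match_selection <- function(res_tbl, keep, s = NULL) {
  if (is.data.frame(keep) && all(c("chain", "resno") %in% names(keep))) {
    return(paste(res_tbl$chain, res_tbl$resno) %in%
             paste(keep$chain, keep$resno))
  }
  rng <- if (is.data.frame(keep)) keep else parse_selection(keep)
  ok <- rep(FALSE, nrow(res_tbl))
  for (r in seq_len(nrow(rng))) {
    hit <- res_tbl$chain == rng$chain[r]
    if (!is.na(rng$lo[r]))
      hit <- hit & res_tbl$resno >= rng$lo[r] & res_tbl$resno <= rng$hi[r]
    ok <- ok | hit
  }
  if (!any(ok)) stop("selection matches no residues: ",
                     paste(utils::capture.output(print(keep)), collapse = " "))
  ok
}

# subset an atomic structure by selection
subset_structure <- function(s, sel) {
  a <- s$atoms
  res <- a[, c("chain", "resno")]
  ok <- .match_selection(res, sel, s)
  atomic_structure(a[ok, , drop = FALSE])
}
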