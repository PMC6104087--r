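# ---------------------------------------------------------------------------
# Native contact maps: shadow-screened atomic contacts aggregated to residue
# pairs, and a plain distance-cutoff fallback for C-alpha-only models.
# ---------------------------------------------------------------------------

#' Construct a contact map
#'
#' A contact map is a residue-pair list with the native (reference)
#' C-alpha--C-alpha distance, a class label (`intra` for contacts within a
#' folded unit, `interface` for the added dimerisation contacts) and a
#' per-contact strength factor that scales the contact well depth relative
#' to the native epsilon.
#'
#' @param contacts data.frame with columns `chain_a`, `res_a`, `chain_b`,
#'   `res_b`, `r0` (Angstrom), `class`, `strength`
#' @param provenance how the map was made: `"shadow"`, `"cutoff"` or
#'   `"docked-interface"`
#' @param params named list of the generation parameters
#' @return object of class `contact_map`
#' @export
contact_map <- function(contacts,
                        provenance = c("shadow", "cutoff", "docked-interface"),
                        params = list()) {
  provenance <- match.arg(provenance)
  need <- c("chain_a", "res_a", "chain_b", "res_b", "r0", "class", "strength")
  miss <- setdiff(need, names(contacts))
  if (length(miss)) stop("contacts missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(contacts)) {
    if (any(contacts$r0 <= 0)) stop("contact r0 must be positive")
    if (any(contacts$strength < 0)) stop("contact strength must be >= 0")
    # canonical unordered order: (chain, res) of a sorts before b
    ka <- paste(contacts$chain_a, sprintf("%08d", contacts$res_a))
    kb <- paste(contacts$chain_b, sprintf("%08d", contacts$res_b))
    swap <- ka > kb
    if (any(swap)) {
      tmp <- contacts[swap, c("chain_a", "res_a")]
      contacts[swap, c("chain_a", "res_a")] <-
        contacts[swap, c("chain_b", "res_b")]
      contacts[swap, c("chain_b", "res_b")] <- tmp
    }
    key <- paste(contacts$chain_a, contacts$res_a,
                 contacts$chain_b, contacts$res_b)
    if (anyDuplicated(key)) stop("duplicate residue pairs in contact map")
    ord <- order(contacts$chain_a, contacts$res_a,
                 contacts$chain_b, contacts$res_b)
    contacts <- contacts[ord, , drop = FALSE]
    rownames(contacts) <- NULL
  }
  structure(list(contacts = contacts, provenance = provenance,
                 params = params),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cc <- x$contacts
  cat(sprintf("contact_map (%s): %d contacts (%d intra, %d interface)\n",
              x$provenance, nrow(cc), sum(cc$class == "intra"),
              sum(cc$class == "interface")))
  invisible(x)
}

#' Number of contacts
#' @param cm contact map
#' @return integer
#' @export
n_contacts <- function(cm) nrow(cm$contacts)

# C-alpha coordinate lookup for r0 assignment: named n x 3 matrix keyed by
# "chain\rresno"
.ca_table <- function(s) {
  ca <- s$atoms[s$atoms$atom == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- paste(ca$chain, ca$resno, sep = "\r")
  m
}

#' Shadow-screened native contacts
#'
#' Atomic contact candidates are all atom pairs within `cutoff` whose
#' residues satisfy the sequence-separation rule (intra-chain pairs need
#' `|i - j| >= min_seq_sep`; inter-chain pairs always qualify). A candidate
#' is discarded when any third atom occludes it: a sphere of
#' `shadow_radius` centred on the third atom intersects the open line
#' segment between the pair. Surviving atomic contacts are aggregated to
#' residue pairs (binary: a residue pair is a contact when at least one
#' atomic contact survives) and the reference distance is the
#' C-alpha--C-alpha distance in `s`. Hydrogens are ignored.
#'
#' @param s [atomic_structure()]
#' @param cutoff atomic distance cutoff, Angstrom (default 6, the published
#'   shadow convention)
#' @param shadow_radius occluding-sphere radius, Angstrom (default 1)
#' @param min_seq_sep minimum intra-chain residue separation (default 4;
#'   closer pairs are governed by the bonded terms of a C-alpha model)
#' @param class label assigned to the contacts
#' @return [contact_map()] with provenance `"shadow"`
#' @export
shadow_contacts <- function(s, cutoff = 6.0, shadow_radius = 1.0,
                            min_seq_sep = 4L, class = "intra") {
  stopifnot(cutoff > 0, shadow_radius >= 0)
  a <- s$atoms[s$atoms$element != "H", , drop = FALSE]
  res <- unique(a[, c("chain", "resno")])
  if (nrow(res) < 2L) stop("structure must have at least 2 residues")
  rid <- match(paste(a$chain, a$resno), paste(res$chain, res$resno))
  chain_id <- match(a$chain, unique(a$chain))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pairs <- cpp_shadow_pairs(xyz, as.integer(rid), as.integer(chain_id),
                            as.integer(match(res$chain, unique(a$chain))),
                            res$resno, cutoff, shadow_radius,
                            as.integer(min_seq_sep))
  .pairs_to_map(pairs, res, s, class, "shadow",
                list(cutoff = cutoff, shadow_radius = shadow_radius,
                     min_seq_sep = min_seq_sep))
}

#' Cutoff contacts on a bead model
#'
#' Distance-cutoff native contacts for C-alpha-only models (the fallback
#' used for synthetic fixtures, where there are no side-chain atoms for the
#' occlusion test to act on).
#'
#' @param m [bead_model()]
#' @param cutoff bead distance cutoff, Angstrom
#' @param min_seq_sep minimum intra-chain residue separation
#' @param class contact class label
#' @param exclude_linker drop pairs touching linker beads (default TRUE:
#'   linkers are contact-free by construction)
#' @return [contact_map()] with provenance `"cutoff"`
#' @export
cutoff_contacts <- function(m, cutoff = 8.0, min_seq_sep = 4L,
                            class = "intra", exclude_linker = TRUE) {
  stopifnot(cutoff > 0)
  n <- n_beads(m)
  chain_id <- match(m$chain, unique(m$chain))
  pr <- cpp_cutoff_pairs(m$xyz, as.integer(chain_id), m$resno, cutoff,
                         as.integer(min_seq_sep))
  if (nrow(pr) && exclude_linker) {
    keep <- !(m$is_linker[pr[, 1]] | m$is_linker[pr[, 2]])
    pr <- pr[keep, , drop = FALSE]
  }
  d <- if (nrow(pr)) {
    sqrt(rowSums((m$xyz[pr[, 1], , drop = FALSE] -
                  m$xyz[pr[, 2], , drop = FALSE])^2))
  } else numeric(0)
  contacts <- data.frame(
    chain_a = m$chain[pr[, 1]], res_a = m$resno[pr[, 1]],
    chain_b = m$chain[pr[, 2]], res_b = m$resno[pr[, 2]],
    r0 = d, class = rep(class, nrow(pr)),
    strength = rep(1.0, nrow(pr)), stringsAsFactors = FALSE)
  contact_map(contacts, "cutoff",
              list(cutoff = cutoff, min_seq_sep = min_seq_sep))
}

# residue-index pair matrix -> contact_map with r0 from CA distances
.pairs_to_map <- function(pairs, res, s, class, provenance, params) {
  cat_tab <- .ca_table(s)
  if (!nrow(pairs)) {
    return(contact_map(data.frame(chain_a = character(), res_a = integer(),
                                  chain_b = character(), res_b = integer(),
                                  r0 = numeric(), class = character(),
                                  strength = numeric()),
                       provenance, params))
  }
  ka <- paste(res$chain[pairs[, 1]], res$resno[pairs[, 1]], sep = "\r")
  kb <- paste(res$chain[pairs[, 2]], res$resno[pairs[, 2]], sep = "\r")
  pa <- cat_tab[ka, , drop = FALSE]
  pb <- cat_tab[kb, , drop = FALSE]
  if (any(is.na(pa)) || any(is.na(pb)))
    stop("contacting residue lacks a CA atom; cannot assign r0")
  contacts <- data.frame(
    chain_a = res$chain[pairs[, 1]], res_a = res$resno[pairs[, 1]],
    chain_b = res$chain[pairs[, 2]], res_b = res$resno[pairs[, 2]],
    r0 = sqrt(rowSums((pa - pb)^2)),
    class = rep(class, nrow(pairs)),
    strength = rep(1.0, nrow(pairs)), stringsAsFactors = FALSE)
  contact_map(contacts, provenance, params)
}

# ---------------------------------------------------------------------------
# Map algebra and text I/O
# ---------------------------------------------------------------------------

#' Combine contact maps
#'
#' @param ... contact maps
#' @return single [contact_map()]; provenance is taken from the first map
#' @export
combine_maps <- function(...) {
  maps <- list(...)
  cc <- do.call(rbind, lapply(maps, function(m) m$contacts))
  contact_map(cc, maps[[1]]$provenance, maps[[1]]$params)
}

#' Remove named residue pairs from a contact map
#'
#' Used for auditable map edits such as dropping a crystal-packing contact
#' between two selections before simulation.
#'
#' @param cm [contact_map()]
#' @param sel_a,sel_b selections (see [parse_selection()]); every contact
#'   with one residue in `sel_a` and the other in `sel_b` is removed
#' @return list with the edited `map` and the data.frame of `removed` pairs
#' @export
remove_contacts_between <- function(cm, sel_a, sel_b) {
  cc <- cm$contacts
  if (!nrow(cc)) return(list(map = cm, removed = cc))
  ra <- parse_selection(sel_a); rb <- parse_selection(sel_b)
  in_sel <- function(ch, res, rng) {
    hit <- rep(FALSE, length(ch))
    for (r in seq_len(nrow(rng))) {
      h <- ch == rng$chain[r]
      if (!is.na(rng$lo[r])) h <- h & res >= rng$lo[r] & res <= rng$hi[r]
      hit <- hit | h
    }
    hit
  }
  drop <- (in_sel(cc$chain_a, cc$res_a, ra) & in_sel(cc$chain_b, cc$res_b, rb)) |
          (in_sel(cc$chain_a, cc$res_a, rb) & in_sel(cc$chain_b, cc$res_b, ra))
  list(map = contact_map(cc[!drop, , drop = FALSE], cm$provenance, cm$params),
       removed = cc[drop, , drop = FALSE])
}

#' Write a contact map as whitespace-delimited text
#'
#' One line per contact (`chainA resA chainB resB r0 class strength`) after
#' a `#`-prefixed header recording provenance and parameters.
#'
#' @param cm [contact_map()]
#' @param path output file
#' @return the path, invisibly
#' @export
write_contact_map <- function(cm, path) {
  hdr <- c(sprintf("# tetherSBM contact map; provenance=%s", cm$provenance),
           sprintf("# param %s=%s", names(cm$params),
                   vapply(cm$params, function(p) paste(format(p), collapse = ","),
                          character(1))),
           "# chain_a res_a chain_b res_b r0_A class strength")
  cc <- cm$contacts
  body <- sprintf("%s %d %s %d %.6f %s %.6f", cc$chain_a, cc$res_a,
                  cc$chain_b, cc$res_b, cc$r0, cc$class, cc$strength)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a contact map written by [write_contact_map()]
#' @param path input file
#' @return [contact_map()]
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  prov <- sub(".*provenance=", "", hdr[grepl("provenance=", hdr)][1])
  params <- list()
  for (h in hdr[grepl("^# param ", hdr)]) {
    kv <- strsplit(sub("^# param ", "", h), "=", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(strsplit(kv[2], ",")[[1]]))
    params[[kv[1]]] <- if (any(is.na(val))) kv[2] else val
  }
  if (!length(body)) {
    return(contact_map(data.frame(chain_a = character(), res_a = integer(),
                                  chain_b = character(), res_b = integer(),
                                  r0 = numeric(), class = character(),
                                  strength = numeric()), prov, params))
  }
  tok <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  contact_map(data.frame(chain_a = tok[, 1], res_a = as.integer(tok[, 2]),
                         chain_b = tok[, 3], res_b = as.integer(tok[, 4]),
                         r0 = as.numeric(tok[, 5]), class = tok[, 6],
                         strength = as.numeric(tok[, 7]),
                         stringsAsFactors = FALSE),
              prov, params)
}

# map a contact list onto bead indices of a model; errors list offenders
contact_bead_indices <- function(cm, m) {
  key <- paste(m$chain, m$resno, sep = "\r")
  ia <- match(paste(cm$contacts$chain_a, cm$contacts$res_a, sep = "\r"), key)
  ib <- match(paste(cm$contacts$chain_b, cm$contacts$res_b, sep = "\r"), key)
  bad <- is.na(ia) | is.na(ib)
  if (any(bad)) {
    off <- cm$contacts[bad, c("chain_a", "res_a", "chain_b", "res_b")]
    stop("contact(s) reference residues absent from the model: ",
         paste(utils::head(apply(off, 1, paste, collapse = "/"), 10),
               collapse = "; "))
  }
  cbind(ia, ib)
}
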