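# ---------------------------------------------------------------------------
# Reaction coordinates, dimer occupancy and free-energy surfaces.
# Two coordinates are monitored: the distance between the centres of mass
# of two marker groups (nucleotide proxies), and Q_int, the fraction of
# interface contacts formed (a contact counts as formed within 120% of its
# reference distance in the docked heterodimer).
# ---------------------------------------------------------------------------

#' Marker-group centre-of-mass distance per frame
#'
#' Unweighted centroid separation (all bead masses are 1) between two
#' disjoint bead groups, per trajectory frame.
#'
#' @param t trajectory
#' @param group_a,group_b integer bead indices
#' @return numeric vector, Angstrom, one value per frame
#' @export
com_distance_series <- function(t, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("empty marker group")
  if (length(intersect(group_a, group_b)))
    stop("marker groups must be disjoint")
  ax <- 3L * (group_a - 1L)
  bx <- 3L * (group_b - 1L)
  vapply(seq_len(n_frames(t)), function(i) {
    fr <- t$frames[i, ]
    ca <- c(mean(fr[ax + 1L]), mean(fr[ax + 2L]), mean(fr[ax + 3L]))
    cb <- c(mean(fr[bx + 1L]), mean(fr[bx + 2L]), mean(fr[bx + 3L]))
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
}

#' Fraction of interface contacts formed per frame
#'
#' `Q_int` in a frame is the fraction of interface-map contacts whose
#' bead-bead distance is within `formation_factor` times the reference
#' distance in the docked complex.
#'
#' @param t trajectory
#' @param interface_map [contact_map()] of interface contacts
#' @param m [bead_model()] the trajectory was run on (for residue-to-bead
#'   lookup)
#' @param formation_factor formed-contact threshold as a multiple of r0
#'   (default 1.2, i.e. within 120%)
#' @return numeric vector in `[0, 1]`, one value per frame
#' @export
interface_Q_series <- function(t, interface_map, m, formation_factor = 1.2) {
  if (!n_contacts(interface_map)) stop("interface map is empty")
  idx <- contact_bead_indices(interface_map, m)
  lim <- formation_factor * interface_map$contacts$r0
  ax <- 3L * (idx[, 1] - 1L)
  bx <- 3L * (idx[, 2] - 1L)
  vapply(seq_len(n_frames(t)), function(i) {
    fr <- t$frames[i, ]
    d <- sqrt((fr[ax + 1L] - fr[bx + 1L])^2 +
              (fr[ax + 2L] - fr[bx + 2L])^2 +
              (fr[ax + 3L] - fr[bx + 3L])^2)
    mean(d <= lim)
  }, numeric(1))
}

# integrated autocorrelation time of a binary/numeric series (frames)
.act_frames <- function(x) {
  n <- length(x)
  if (n < 10L || sd(x) == 0) return(1)
  a <- acf(x, lag.max = min(n %/% 3L, 2000L), plot = FALSE)$acf[-1]
  pos <- which(a <= 0.05)
  m <- if (length(pos)) pos[1] else length(a)
  max(1, round(1 + 2 * sum(a[seq_len(m)])))
}

#' Dimer occupancy with a block-bootstrap confidence interval
#'
#' The fraction of frames classified as dimerised. Two classification
#' rules are provided: `"Q"` (the default) calls a frame dimerised when
#' `Q_int >= threshold`; `"distance"` when the marker distance is below
#' `threshold` Angstrom. The confidence interval comes from a circular
#' block bootstrap with block length set to the estimated autocorrelation
#' time of the state indicator, because consecutive frames are strongly
#' correlated.
#'
#' @param series numeric per-frame series (`Q_int` values, or distances
#'   for `rule = "distance"`)
#' @param rule `"Q"` or `"distance"`
#' @param threshold classification threshold (default 0.5 for `"Q"`,
#'   20 Angstrom for `"distance"`)
#' @param burn_in fraction of initial frames discarded as equilibration
#' @param n_boot bootstrap resamples
#' @param conf confidence level
#' @param seed bootstrap seed
#' @return list with `occupancy`, `ci` (two-sided), `block_length`,
#'   `n_frames`, `rule`
#' @export
occupancy <- function(series, rule = c("Q", "distance"), threshold = NULL,
                      burn_in = 0, n_boot = 200L, conf = 0.95, seed = 1L) {
  rule <- match.arg(rule)
  if (is.null(threshold)) threshold <- if (rule == "Q") 0.5 else 20
  if (burn_in > 0) {
    drop <- floor(burn_in * length(series))
    if (drop > 0) series <- series[-seq_len(drop)]
  }
  if (length(series) < 10L) stop("series must have at least 10 frames")
  state <- if (rule == "Q") as.numeric(series >= threshold)
           else as.numeric(series < threshold)
  occ <- mean(state)
  if (sd(state) == 0) {
    warning("degenerate all-constant state series; CI is a point")
    return(list(occupancy = occ, ci = c(occ, occ), block_length = NA_integer_,
                n_frames = length(state), rule = rule))
  }
  bl <- .act_frames(state)
  n <- length(state)
  nblock <- ceiling(n / bl)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    starts <- sample.int(n, nblock, replace = TRUE)
    idx <- (rep(starts, each = bl) + seq_len(bl) - 2L) %% n + 1L  # circular
    mean(state[idx[seq_len(n)]])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(occupancy = occ,
       ci = unname(quantile(boot, c(alpha, 1 - alpha))),
       block_length = bl, n_frames = n, rule = rule)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Free-energy surface from a sampled series
#'
#' Normalised histogram of one or two reaction coordinates, converted to
#' a free energy F = -T* ln P with the minimum shifted to zero. Empty
#' bins are flagged and carry no F value.
#'
#' @param series numeric vector, or a 2-column matrix / data.frame for a
#'   2D surface over (d, Q_int)
#' @param breaks bin count or breakpoint vector (list of two for 2D)
#' @param temperature reduced temperature used for the conversion
#' @return object of class `free_energy_surface`: `edges`, `P`, `F`
#'   (arrays; `F` is `NA` in empty bins), `occupied` mask
#' @export
free_energy_surface <- function(series, breaks = 40L, temperature = 0.92) {
  two_d <- (is.matrix(series) || is.data.frame(series)) && ncol(series) == 2
  if (two_d) {
    series <- as.matrix(series)
    if (!nrow(series)) stop("empty series")
    if (!is.list(breaks)) breaks <- list(breaks, breaks)
    ex <- .bin_edges(series[, 1], breaks[[1]])
    ey <- .bin_edges(series[, 2], breaks[[2]])
    ix <- .bin_index(series[, 1], ex)
    iy <- .bin_index(series[, 2], ey)
    counts <- matrix(0, length(ex) - 1L, length(ey) - 1L)
    for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
    edges <- list(ex, ey)
  } else {
    series <- as.numeric(series)
    if (!length(series)) stop("empty series")
    ex <- .bin_edges(series, if (is.list(breaks)) breaks[[1]] else breaks)
    ix <- .bin_index(series, ex)
    counts <- tabulate(ix, nbins = length(ex) - 1L)
    edges <- list(ex)
  }
  P <- counts / sum(counts)
  occupied <- P > 0
  F <- ifelse(occupied, -temperature * log(P), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  structure(list(edges = edges, P = P, F = F, occupied = occupied,
                 temperature = temperature),
            class = "free_energy_surface")
}

.bin_edges <- function(x, breaks) {
  if (length(breaks) > 1L) return(breaks)
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = breaks + 1L)
}

.bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf(
    "free_energy_surface: %s, %d/%d bins occupied, T* = %.3g\n",
    paste(vapply(x$edges, function(e) length(e) - 1L, integer(1)),
          collapse = " x "),
    sum(x$occupied), length(x$P), x$temperature))
  invisible(x)
}

#' Tune the interface strength factor to a target occupancy
#'
#' Bisection on the interface strength factor over `[lo, hi]`. Each trial
#' runs `trial_fn(factor)`, which must execute a seeded simulation and
#' return an [occupancy()] result. Bisection stops when a trial's
#' confidence interval covers the target, when the bracket is narrower
#' than `factor_tol`, or after `max_trials` trials. Occupancy must be
#' monotone non-decreasing in the factor up to CI noise; a clearly
#' non-monotone trial ladder aborts with an error.
#'
#' @param trial_fn function(factor) -> [occupancy()] result
#' @param target target occupancy in (0, 1)
#' @param lo,hi initial bracket for the strength factor
#' @param factor_tol bracket width at which bisection stops
#' @param max_trials trial cap
#' @return list with `factor`, the achieved `occupancy` result, and the
#'   `trials` ladder (data.frame: factor, occupancy, ci_lo, ci_hi)
#' @export
tune_interface_strength <- function(trial_fn, target = 0.5, lo = 0, hi = 2,
                                    factor_tol = 0.05, max_trials = 12L) {
  stopifnot(target > 0, target < 1, hi > lo)
  trials <- data.frame(factor = numeric(), occupancy = numeric(),
                       ci_lo = numeric(), ci_hi = numeric())
  run <- function(f) {
    o <- trial_fn(f)
    trials[nrow(trials) + 1L, ] <<- c(f, o$occupancy, o$ci[1], o$ci[2])
    o
  }
  o_lo <- run(lo); o_hi <- run(hi)
  if (o_lo$occupancy > o_hi$occupancy &&
      o_lo$ci[1] > o_hi$ci[2])
    stop("occupancy not monotone in strength at this budget")
  covers <- function(o) o$ci[1] <= target && target <= o$ci[2]
  best <- NULL
  if (covers(o_lo)) best <- list(factor = lo, occ = o_lo)
  if (is.null(best) && covers(o_hi)) best <- list(factor = hi, occ = o_hi)
  a <- lo; b <- hi; oa <- o_lo; ob <- o_hi
  while (is.null(best) && nrow(trials) < max_trials && (b - a) > factor_tol) {
    mid <- (a + b) / 2
    om <- run(mid)
    if (covers(om)) {
      best <- list(factor = mid, occ = om)
      break
    }
    # monotonicity audit against the bracket
    if (om$ci[1] > max(oa$ci[2], ob$ci[2]) + 0.1 &&
        om$occupancy > ob$occupancy)
      stop("occupancy not monotone in strength at this budget")
    if (om$occupancy < target) { a <- mid; oa <- om } else { b <- mid; ob <- om }
  }
  if (is.null(best)) {
    # closest trial to the target
    k <- which.min(abs(trials$occupancy - target))
    best <- list(factor = trials$factor[k],
                 occ = list(occupancy = trials$occupancy[k],
                            ci = c(trials$ci_lo[k], trials$ci_hi[k])))
  }
  list(factor = best$factor, occupancy = best$occ, trials = trials)
}
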