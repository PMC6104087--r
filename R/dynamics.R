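# ---------------------------------------------------------------------------
# Langevin dynamics in reduced units (BAOAB splitting).
# ---------------------------------------------------------------------------

#' Simulation parameters
#'
#' Reduced-unit Langevin settings. The defaults reproduce the sampling
#' regime used for tethered-dimerisation surfaces: dimensionless timestep
#' 0.0005, friction coupling 1 and reduced temperature 0.92 -- low enough
#' to keep individual folded domains stable, high enough to sample
#' reversible dimerisation. The desk-scale default step count is 5e6 with
#' a recording stride of 1000; production-scale counts (up to 5e9) are
#' configuration values, not defaults.
#'
#' @param timestep integration step, reduced time
#' @param friction Langevin coupling constant, reduced
#' @param temperature reduced temperature T* (kB = 1)
#' @param steps number of integration steps
#' @param stride record every `stride`-th step (frame 0 always recorded)
#' @param seed integer random seed; identical seed and parameters give a
#'   bit-identical trajectory
#' @return object of class `simulation_params`
#' @export
simulation_params <- function(timestep = 0.0005, friction = 1,
                              temperature = 0.92, steps = 5e6,
                              stride = 1000L, seed = 1L) {
  stopifnot(timestep > 0, friction >= 0, temperature >= 0, steps >= 1,
            stride >= 1)
  structure(list(timestep = timestep, friction = friction,
                 temperature = temperature, steps = as.numeric(steps),
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "simulation_params")
}

#' Run Langevin dynamics
#'
#' BAOAB Langevin leapfrog at temperature T* with friction gamma,
#' Boltzmann constant 1 and bead mass 1. With `friction = 0` and
#' `temperature = 0` the integrator reduces to velocity Verlet and
#' conserves energy. Initial velocities are Maxwell-Boltzmann at T*
#' (zero at T* = 0). No centre-of-mass motion removal is applied: the
#' observables are internal distances and a tethered body's diffusion is
#' part of the physics.
#'
#' @param ff `sbm_forcefield`
#' @param coords n x 3 starting coordinates
#' @param p [simulation_params()]
#' @return object of class `trajectory`: `frames` (list of n x 3
#'   matrices), per-frame `energy` (potential), `contact_energy`,
#'   `kinetic_energy`, `final_coords`, and the `params` used
#' @export
langevin_run <- function(ff, coords, p = simulation_params()) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite starting coordinates")
  if (nrow(coords) != ff$n)
    stop("coordinate count does not match forcefield")
  res <- cpp_langevin_run(coords, unclass(ff), p$timestep, p$friction,
                          p$temperature, p$steps, p$stride, p$seed,
                          ff$ev_cutoff, 2.0)
  structure(list(frames = res$frames,  # nf x 3n row-major frame matrix
                 n_beads = ff$n,
                 energy = res$energy,
                 contact_energy = res$contact_energy,
                 kinetic_energy = res$kinetic_energy,
                 final_coords = res$final_coords,
                 final_velocities = res$final_velocities,
                 params = p),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d frames x %d beads | T* = %.3g, dt = %.2g, seed = %d\n",
    n_frames(x), x$n_beads, x$params$temperature, x$params$timestep,
    x$params$seed))
  invisible(x)
}

#' Number of recorded frames (including frame 0)
#' @param t trajectory
#' @return integer
#' @export
n_frames <- function(t) nrow(t$frames)

#' Extract one frame as an n x 3 coordinate matrix
#' @param t trajectory
#' @param i 1-based frame index
#' @return n x 3 matrix
#' @export
frame_coords <- function(t, i) {
  matrix(t$frames[i, ], ncol = 3, byrow = TRUE)
}

# ---------------------------------------------------------------------------
# Trajectory interchange formats
# ---------------------------------------------------------------------------

#' Write a trajectory as multi-model PDB
#'
#' @param t trajectory
#' @param m [bead_model()] providing chain / residue labels
#' @param path output file
#' @param frames which frames to write (default all)
#' @return the path, invisibly
#' @export
write_traj_pdb <- function(t, m, path, frames = seq_len(n_frames(t))) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (k in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    mm <- m
    mm$xyz <- frame_coords(t, frames[k])
    writeLines(head(write_beads_pdb(mm), -1L), con)  # strip END
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Binary trajectory container: ASCII magic "TSBMTRJ1", then int32
# (n_frames, n_beads, stride, seed), then float32 xyz per frame,
# little-endian, bead-major within frame.

#' Write a trajectory in the package's binary container
#' @param t trajectory
#' @param path output file
#' @return the path, invisibly
#' @export
write_traj_bin <- function(t, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("TSBMTRJ1"), con)
  writeBin(as.integer(c(n_frames(t), t$n_beads, t$params$stride,
                        t$params$seed)), con, size = 4L, endian = "little")
  for (i in seq_len(n_frames(t)))
    writeBin(as.numeric(t$frames[i, ]), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a binary trajectory container
#' @param path input file
#' @return list with `frames` (nf x 3n matrix), `n_beads`, `stride`, `seed`
#' @export
read_traj_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (magic != "TSBMTRJ1") stop("not a tetherSBM trajectory file")
  hdr <- readBin(con, "integer", 4L, size = 4L, endian = "little")
  nf <- hdr[1]; nb <- hdr[2]
  frames <- matrix(0, nf, 3L * nb)
  for (i in seq_len(nf))
    frames[i, ] <- readBin(con, "numeric", 3L * nb, size = 4L,
                           endian = "little")
  list(frames = frames, n_beads = nb, stride = hdr[3], seed = hdr[4])
}
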