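---
title: "Coarse-grained simulation of tethered G-domain dimerisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained simulation of tethered G-domain dimerisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetherSBM)
```

## The scientific question

Bacterial dynamin-like proteins (DLPs) can assemble into hetero-oligomers in
which two GTPase (G) domains are joined to a rigid central dimer through a
short flexible peptide linker. Assembly-stimulated GTP hydrolysis in these
systems requires head-to-head association of two G-domains across their
nucleotide-binding pockets (G-dimerisation). Whether a linker of only nine
residues leaves that association geometrically and thermodynamically
accessible is not obvious from a crystal structure, in which the G-domains
are held apart by packing: the question is one of conformational statistics,
and the natural tool is a coarse-grained structure-based ("Go-like")
simulation in which the tethered complex explores its accessible
configurations and the dimerised fraction can be measured.

`tetherSBM` implements that pipeline end to end: native-contact map
generation (shadow and cutoff definitions), template-based construction of
the candidate G-domain heterodimer and extraction of its interface contacts
at a tunable strength, a C-alpha structure-based potential with Gaussian
contact wells, Langevin dynamics in reduced units, and the reaction-
coordinate analysis (marker-group distance, fraction of interface contacts
formed, occupancy with block-bootstrap confidence intervals, free-energy
surfaces). A synthetic-structure generator provides a tethered two-domain
toy with the same statistical structure, so every stage is testable without
any external download.

## The model

Each residue is one bead at its C-alpha position. The potential is the
standard C-alpha structure-based form with Gaussian contacts:

* bonds: $V_b = k_b (r - r_0)^2$ over consecutive beads, $k_b = 200\,
  \varepsilon/\mathrm{\AA}^2$;
* angles: $V_a = k_a (\theta - \theta_0)^2$ over consecutive triples,
  $k_a = 40\, \varepsilon/\mathrm{rad}^2$;
* dihedrals: $V_d = k_d [(1 - \cos\Delta\phi) + \tfrac12 (1 - \cos
  3\Delta\phi)]$ over consecutive quadruples, $k_d = 1\,\varepsilon$;
* native contacts: $V_c = \varepsilon_{ij} [(1 + (r_{ex}/r)^{12})
  (1 - e^{-(r - r_0)^2 / 2\sigma^2}) - 1]$ with $\sigma = 0.5$ Å and
  $r_{ex} = 4$ Å — an attractive Gaussian well of depth exactly
  $\varepsilon_{ij}$ at the native distance, multiplied by a hard core;
* excluded volume: $(r_{ex}/r)^{12}$ between all remaining pairs with
  intra-chain separation of at least 4 residues (or on different chain
  segments), truncated and shifted at 12 Å where the term is below
  $5\times10^{-7}\,\varepsilon$.

Equilibrium values of all bonded terms are read from the native structure,
so the native configuration zeroes the bonded energy and sits at the bottom
of every contact well; this is the defining property of a structure-based
model. Units are reduced: $\varepsilon = 1$ is the energy unit, bead mass
is 1, $k_B = 1$, lengths are in Angstrom and the timestep is the
dimensionless $0.0005$ used with this forcefield family.

Native contacts come from the *shadow* definition on all-atom input: an
atom pair within 6 Å is a candidate, and it is discarded if any third atom
occludes the open segment between the two (a sphere of radius 1 Å centred
on the third atom intersecting the segment). Surviving atomic contacts are
aggregated to residue pairs. For C-alpha-only synthetic models, where there
are no side-chain atoms to occlude anything, a plain distance cutoff is
used instead.

### The tethered system and its interface

The simulated species is one chain: folded domain 1, a flexible linker, the
rigid central body, a second linker, folded domain 2. Linker beads carry
bonds ($r_0 = 3.8$ Å) and angles ($\theta_0 = 2.0$ rad) at ideal values but
no dihedral bias and no contacts: the linker is an entropic random-coil
tether, which is exactly the role the nine-residue linker plays in the real
complex. Dimerisation is made possible by an additional set of *interface*
contacts taken from a docked reference of the two domains; their well depth
is a tunable fraction of the native depth (the strength factor). The
forcefield builder rejects any map that touches linker beads.

For deposited structures the docked reference is produced by rigid
least-squares superposition of each G-domain onto one chain of a template
homodimer through an explicit residue correspondence. A flexible aligner
could produce slightly different cores, but rigid superposition over a
stated correspondence is deterministic, dependency-free and adequate for
compact G-domain cores; the correspondence is configuration, never guessed.
The resulting pose is reported with its inter-partner clash count, and the
coarse-grained steepest-descent minimiser stands in for an explicit-solvent
relaxation: at one bead per residue, the only role of that step — relieving
small steric overlaps — is served by minimising the same potential the
simulation uses (descent stops when the maximum force component drops
below $10^{-3}$ reduced units, or after a capped number of iterations).

## Sampling regime

Dynamics are Langevin with a BAOAB splitting: deterministic velocity-Verlet
half-kicks and drifts around an exact Ornstein-Uhlenbeck velocity update,
which is stable at the stated timestep and reduces to energy-conserving
velocity Verlet when friction and temperature are zero (a property the test
suite checks). Friction is 1 and the reduced temperature is 0.92 — low
enough that individual folded domains stay folded (median fraction of
intra-domain contacts formed above 0.8 is the working criterion), high
enough that dimerisation is reversible rather than frozen. Initial
velocities are Maxwell-Boltzmann; no centre-of-mass motion is removed,
since a tethered body's diffusion is part of the physics and all
observables are internal distances. A fixed integer seed makes every
trajectory bit-reproducible.

Two reaction coordinates are monitored, following the convention of
plotting both a distance and a contact-fraction coordinate:

* $d$: the centre-of-mass distance between two *marker groups*, one per
  domain. In a deposited structure these default to bound-nucleotide
  HETATM records when present, else a configured pocket residue set; how a
  nucleotide is best represented in a one-bead-per-residue model is
  genuinely underdetermined, so the choice is explicit configuration. In
  the toy they are the interface-face helices.
* $Q_\mathrm{int}$: the fraction of interface contacts formed, a contact
  counting as formed within 120% of its reference distance in the docked
  complex.

A frame is classified dimerised by $Q_\mathrm{int} \ge 0.5$ (default);
the alternative rule $d < 20$ Å is computed alongside, because the
classification boundary between the two coordinates is a convention and
reporting both makes the choice auditable. Occupancy is the dimerised
fraction of frames after discarding the first 10% as equilibration, with a
circular block bootstrap (block length = estimated autocorrelation time of
the state indicator, 200 resamples) for the confidence interval —
consecutive frames are strongly correlated, so a naive binomial interval
would be far too narrow. Free-energy surfaces are $-T^* \ln P$ over binned
coordinates with the minimum shifted to zero and empty bins masked rather
than assigned a value.

## What the synthetic generator emulates — and what it does not

`make_tethered_pair()` builds the desk-scale analogue of the tethered
tetramer: two three-helix bundles (48 beads each) joined through
nine-residue linkers to a two-helix central body (31 beads), ~150 beads in
total, so that a multi-million-step trajectory takes minutes on one CPU.
Helices are ideal C-alpha traces (rise 1.5 Å/residue, 100°/residue, radius
2.3 Å) packed at 10 Å; native maps use a 9.5 Å bead cutoff, giving ~2
contacts per residue — the density an atomistic shadow map aggregated to
residues produces for real folded domains, and enough to keep the toy
domains folded at $T^* = 0.92$ (an 8 Å bead cutoff leaves them marginally
stable, which is a property of bead-level maps, not of the proteins the
toy stands in for).

Both linkers leave the same face of the central body, and each domain's
interface face is the helix carrying its tether attachment. This mirrors
the real architecture, where the linker emerges next to the G-domain
interface, and it is what makes the desk-scale experiment feasible: the
faces stay anchored within a few tether lengths of each other, so
association is a local, frequently-attempted event. The docked reference
packs the two face helices at 9.5 Å; its twelve closest inter-domain
residue pairs form the interface set. Twelve contacts put the fully-formed
interface energy at the scale of a few $k_B T^*$ per unit strength factor,
which is the regime in which occupancy responds smoothly to the factor and
transitions are observable in runs of a few million steps; the real
complex, with hundreds of interface contacts and a $5\times10^9$-step
trajectory, sits at a scale the toy deliberately does not reproduce.

Simulations start from the minimised *native* (docked) configuration by
default — the same convention as simulating a deposited structure, whose
coordinates are the model's energy minimum. This matters at desk scale:
with purely short-range contact wells, a first face-to-face encounter from
a fully separated start is a diffusive search with a waiting time far
beyond desk-scale trajectories (production-scale workflows spend billions
of steps for this reason). From the native start, dissociation at
weak coupling is immediate, and the tether keeps the released domains in a
proximal ensemble from which genuine re-association events occur within
millions of steps, so occupancy reflects reversible two-state sampling:
at the defaults, the strength factor sweep 0 / 0.5 / 1 / 2 gives
occupancies near 0 / 0.01 / 0.5 / 1 with dozens of transitions in the
middle of that range. The toy's 50%-occupancy point sits near factor 1
rather than at any particular literature value: where it falls depends on
the interface contact count and the tether entropy of the specific system,
which is exactly why the strength factor is exposed and tunable. The
`start = "separated"` configuration is kept for contract tests (a
separated start must show zero interface formation).

What passing toy-scale tests therefore shows is that the *machinery* is
correct — maps, potential, integrator, estimators, and the qualitative
mechanism (occupancy rises monotonically with interface strength; a longer
tether lowers, never raises, occupancy; an unreachable interface gives
zero) — not that any particular real system has 50% occupancy at half
strength. The generator makes no attempt to mimic real DLP sequences,
side-chain packing, or nucleotide chemistry.

## Numerical choices

* Alternate locations resolve to the highest occupancy (ties: first in
  file); insertion codes are rejected outright, because silently
  renumbering residues would corrupt every downstream contact map.
* Chain breaks are flagged beyond 4.5 Å between consecutive C-alphas
  (trans peptide ~3.8 Å plus tolerance). Excised segments are re-joined by
  `bridge_gap()`, which places inserted beads on a circular arc with equal
  chords of at most 3.8 Å, bulging away from the body of the model; a gap
  longer than 3.8 (n+1) Å is unbridgeable at n inserted residues and is an
  error, not a stretched chain.
* The occlusion test uses the open segment, so an atom exactly at an
  endpoint never occludes its own contact.
* The excluded-volume neighbour list (Verlet, 2 Å skin, displacement-
  triggered rebuild) is an implementation device only: energies with and
  without the list agree identically because the potential itself is
  truncated at the list's inner radius.
* Solvent accessibility uses Shrake-Rupley with a deterministic
  golden-spiral point set (960 points/atom, probe 1.4 Å; radii C 1.70,
  N 1.55, O 1.52, S 1.80 Å). Published interface areas are sensitive to
  these conventions, so they are stated in every report, and buried areas
  are printed in both the two-sided (sum of both partners' losses) and
  one-sided conventions.
* Steepest-descent minimisation uses a backtracking line search on the
  normalised force direction, so energy never increases across accepted
  steps and a single overlapping pair cannot catapult the system.

## A worked toy run

```{r pipeline, eval = FALSE}
cfg <- run_config(interface_strength = 1,
                  sim = list(steps = 2e6, stride = 1000, seed = 1))
res <- run_tether_pipeline(cfg)
res$occupancy_Q
res$fes_2d
```

The pipeline logs each stage with the exact contact counts and any map
edits (removed pairs are listed), serialises the configuration into the
manifest, and writes the coordinate series, occupancy summary and binary
trajectory when an output directory is set. Re-running the same
configuration and seed reproduces the series byte for byte.

Strength tuning inverts the occupancy curve by bisection:

```{r tuning, eval = FALSE}
trial <- function(f) {
  r <- run_tether_pipeline(run_config(
    interface_strength = f,
    sim = list(steps = 2e6, stride = 1000, seed = 7)), quiet = TRUE)
  r$occupancy_Q
}
tune_interface_strength(trial, target = 0.5)
```

Each trial is seeded, the trial ladder is returned for audit, and a
clearly non-monotone ladder aborts rather than returning a spurious root.

## Problem sizes used by the shipped checks

The test suite and the acceptance script size their simulations for a
single CPU: equipartition and Boltzmann-distribution checks use a
two-bead dimer over 1-2 million steps; folding-stability and occupancy
checks use the default ~150-bead toy over 1-2 million steps per strength
factor, with seeds fixed throughout. These sizes are the package's chosen
desk-scale study conditions; the production-scale counts the method
supports (up to $5\times10^9$ steps) are plain configuration values.

## Known limitations

* One bead per residue cannot represent nucleotide chemistry; "GDP
  occupancy" exists only through marker groups.
* The shadow map operates on heavy atoms as deposited; missing side
  chains in poorly resolved regions thin the map there.
* Occupancy estimates at strength factors far from the transition region
  have one-sided, boundary-touching confidence intervals; the bootstrap
  does not correct for a dimerisation dwell time comparable to the whole
  trajectory (the estimator is honest but the trajectory may simply be
  too short — the CI width says so).
* No replica exchange or reweighting: surfaces are single-ensemble
  histograms, as in the workflow the package reproduces.
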