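# tetherSBM

Coarse-grained structure-based simulation of tethered GTPase-domain
dimerisation, with the structural-geometry toolbox that supports the
analysis (buried surface areas, superposition RMSD, hinge rotations,
maximum tether reach).

## The problem

Heterotypic bacterial dynamin-like protein (DLP) complexes couple two
GTPase (G) domains to a rigid central dimer through a short flexible
peptide linker. Their assembly-stimulated GTP hydrolysis requires the two
G-domains to dimerise head-to-head across their nucleotide-binding
pockets. Whether a nine-residue linker leaves that dimerisation accessible
is a question about conformational statistics, not about any single
structure. The standard way to answer it is a C-alpha structure-based
("Go-like") model: one bead per residue, native geometry as the energy
minimum, Gaussian native-contact wells, plus an extra set of *interface*
contacts — taken from a template-docked G-domain heterodimer — whose
strength is a tunable fraction of the native contact strength. Langevin
dynamics in reduced units then samples the tethered complex, and the
dimerised fraction of frames (the occupancy) is measured as a function of
interface strength.

The potential is

V = Σ k_b (r−r0)² + Σ k_a (θ−θ0)² + Σ k_d [(1−cos Δφ) + ½(1−cos 3Δφ)]
  + Σ ε_ij [(1+(r_ex/r)¹²)(1−exp(−(r−r0)²/2σ²)) − 1] + Σ (r_ex/r)¹²

with k_b = 200 ε/Å², k_a = 40 ε/rad², k_d = 1 ε, σ = 0.5 Å, r_ex = 4 Å,
reduced temperature T* = 0.92, friction 1, timestep 0.0005. Two reaction
coordinates are tracked: the marker-group centre-of-mass distance d, and
Q_int, the fraction of interface contacts within 120% of their docked
reference distance. Occupancy (default rule Q_int ≥ 0.5) carries a
circular block-bootstrap confidence interval; free-energy surfaces are
−T* ln P over the binned coordinates.

For whom: structural biologists and simulators who want a reproducible,
dependency-light pipeline for tether-accessibility questions, and a tested
reference implementation of shadow contact maps, the C-alpha+Gaussian
forcefield, and the accompanying interface geometry calculations.

## A worked example

The built-in synthetic system is the desk-scale analogue of the tethered
complex: two folded three-helix domains joined to a rigid two-helix body
by nine-residue contact-free linkers, with a 12-contact docked interface.

```r
library(tetherSBM)
cfg <- run_config(interface_strength = 1,
                  sim = list(steps = 2e6, stride = 1000, seed = 1))
res <- run_tether_pipeline(cfg)
#>   system: 145 beads, 344 intra contacts, 12 interface contacts
#> [..] build forcefield (0.0s)
#> [..] minimise start (1.1s)
#>   minimised: E = -355.59, max|F| = 0.03 (2149 iter)
#> [..] langevin 2e+06 steps (81.1s)
#>   occupancy: Q-rule 0.184 [0.086, 0.322]; d-rule 1.000
res$occupancy_Q$occupancy   # dimerised fraction of frames, Q_int >= 0.5
#> [1] 0.184342
res$fes_2d
#> free_energy_surface: 40 x 40, 184/1600 bins occupied, T* = 0.92
```

The Q-rule occupancy of 0.18 with a [0.09, 0.32] interval says the
interface forms reversibly and is populated roughly a fifth of the time at
this strength and seed — the interval is wide by design, because frames
are autocorrelated and the block bootstrap says so. The distance rule
saturates at 1.0 on this toy: its 20 Å threshold is generous for a tether
whose markers rarely exceed ~30 Å, which is exactly why both
classification rules are reported side by side. Sweeping the strength
factor over 0 / 0.5 / 1 / 2 (matched seeds) moves the Q-rule occupancy
from ~0 through the transition region to ~1.

`tune_interface_strength()` inverts the occupancy curve by bisection over
the strength factor, returning the trial ladder for audit.
`run_geometry_report()` computes buried surface areas (both two-sided and
one-sided conventions stated inline), superposition RMSDs, hinge rotation
angles and maximum tether reach from one declarative request list; with
deposited structures downloaded (e.g. via `fetch_pdb()`), the same
functions reproduce interface areas and hinge angles of real DLP models.

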