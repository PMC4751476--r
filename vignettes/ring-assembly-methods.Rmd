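---
title: "Methods: from a peptide ensemble to ring-shaped oligomer models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from a peptide ensemble to ring-shaped oligomer models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoring)
```

## The modelling problem

Small soluble oligomers of the 42-residue amyloid-beta peptide — in
particular quasi-circular pentamers and hexamers ("paranuclei") — are
prime suspects in amyloid toxicity, yet they resist direct structure
determination. `oligoring` implements a conformational-selection route to
atomistic ring models: characterize the monomer's conformational
ensemble, select an aggregation-prone conformation, self-dock it rigidly
at coarse-grained resolution, and ask which dimer interfaces, when
repeated as a screw operation, wrap into closed rings.

The package deliberately separates three layers: ensemble observables
and clustering (`backbone_dihedrals`, `jcoupling_profile`,
`secondary_shift`, `ss_propensity`, `free_energy_surface`,
`gromos_cluster`), coarse-grained docking (`coarse_grain`,
`generate_start_poses`, `minimize_pose`, `cluster_and_rank`), and screw
geometry with ring construction (`transform_from_dimer`,
`screw_from_transform`, `filter_candidates`, `cyclize`, `ring_metrics`,
`stack_rings`). A synthetic generator (`build_backbone`,
`sample_ensemble`, `make_ideal_dimer`) supplies every input, so the whole
workflow runs from scratch with no molecular-dynamics engine.

## Ensemble observables

**J-couplings.** Three-bond HN-Halpha scalar couplings report on the
backbone phi dihedral through the Karplus relation
$J(\phi) = A\cos^2(\phi - 60^\circ) + B\cos(\phi - 60^\circ) + C$.
The packaged coefficients (A = 6.51, B = -1.76, C = 1.60 Hz) are the
standard empirical parameterization of Vuister and Bax; they live in a
data file (`inst/extdata/karplus_vuister_bax.tsv`) rather than in code so
alternative parameterizations are drop-in. Per-residue couplings are
averaged over frames; `karplus_range()` gives the analytic minimum and
maximum of the curve, a useful sanity envelope for any averaged profile.

**Secondary chemical shifts.** Computed as
$\Delta\delta = \delta_{coil} - \delta$ against the packaged random-coil
Calpha/Cbeta reference (Wishart-style values keyed by amino acid).
This sign convention is implemented exactly as stated; the more common
$\delta - \delta_{coil}$ is available via `flip = TRUE`. Shift
*prediction* from structure is out of scope: observed or back-calculated
shift tables are inputs.

**Secondary structure.** A deterministic phi/psi-region rule classifies
residues as helical, extended, turn or coil; the regions are coarse
Ramachandran boxes (helix: phi in [-100, -30], psi in [-80, -5]; strand:
phi in [-180, -90], psi in [90, 180]; two turn boxes; checked in that
order). This is an explicit stand-in for an external assigner, not a
reimplementation of one; output of external assigners can be ingested
with `read_ss_assignments()`, whose letters are grouped H/G/I to helix,
E/B to strand, T to turn — the same three-class grouping used for the
propensity profiles.

**Free-energy surface.** Frames are binned by (RMSD to a reference
conformer, radius of gyration) and converted to free energies by
$F = -k_B T \ln N$ with the global minimum shifted to zero and empty
bins masked. With $k_B = 0.0019872$ kcal/mol/K and the default
T = 300 K, a count ratio of e:1 is exactly 0.596 kcal/mol. Only
free-energy *differences* are meaningful; scaling all counts leaves them
unchanged, which the tests assert.

**Clustering.** `gromos_cluster` is the greedy neighbor-count algorithm:
count neighbors within the RMSD cutoff (canonically 0.2 nm), promote the
frame with the most neighbors to cluster center, remove the cluster,
repeat. Two choices are under-determined in the literature and fixed
here for determinism: ties on neighbor count resolve to the lowest frame
index, and the pairwise RMSD uses backbone heavy atoms (N, CA, C) unless
another selection is requested.

## Coarse-grained docking

**Bead model.** Two beads per residue: a backbone bead on the CA and a
side-chain bead at the side-chain heavy-atom centroid (none for Gly).
Side chains of Asp/Glu carry -1 e, Lys/Arg +1 e; chain termini carry
+1/-1 on their backbone beads. Radii and well depths are a packaged,
editable table. This parameterization makes no claim to reproduce any
published coarse-grained force field; it only needs to produce plausible
packed interfaces, and every test that depends on it tests the
machinery, not the chemistry.

**Energy.** Soft-core Lennard-Jones,
$4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ with
$\sigma_{ij} = (r_i + r_j)/2^{1/6}$ so the pair minimum sits at the sum
of the bead radii, plus Coulomb with a distance-dependent dielectric
$\varepsilon_r = 4r$. The soft core substitutes
$(r^6 + (0.3\sigma)^6)^{1/6}$ for $r$, keeping the energy finite at
overlap. Pairs beyond 12 A contribute exactly zero; between 10 and 12 A
the pair energy is tapered by the standard cubic switching function.
The taper matters in practice: with a hard truncation, charged pairs
crossing the cutoff leave discontinuities of a few tenths of kcal/mol
on which a simplex minimizer never meets a tight convergence criterion.

**Start poses and minimization.** Ligand centroids are placed on a
deterministic Fibonacci-spiral sphere of radius 1.2 times the receptor's
largest dimension ("slightly larger than its largest dimension"), with a
deterministic set of orientations per point — the whole run is
reproducible with no hidden randomness, which a test asserts bit for
bit. Because start poses sit outside the interaction cutoff where the
energy is exactly flat, minimization is preceded by a deterministic
approach phase that slides the ligand along the line of centers until
its closest bead pair enters the interaction shell. The minimizer proper
is Nelder-Mead over three translations plus three axis-angle rotation
increments composed onto the current orientation (no Euler
singularities); the start pose is in the initial simplex, so the final
energy never exceeds the starting energy. Poses that exhaust the
iteration budget are flagged unconverged and excluded from ranking.

**Pose clustering.** Single linkage on ligand-bead RMSD between posed
copies (receptor frame fixed, no re-superposition), cut at 0.5 nm;
representatives are each cluster's lowest-energy member, ranked
ascending. The cutoff and the similarity definition are package choices;
neither is standardized across docking tools.

## Screw geometry and rings

A dimer defines the rigid transform mapping protomer 1 onto protomer 2
(least-squares superposition on matched CA atoms). Chasles' theorem
decomposes any proper rigid motion into a rotation by theta about an
axis plus a rise d along it: theta from the rotation's trace, the axis
from the skew-symmetric part (eigenvector route near 180 degrees), the
rise as the translation's axial projection, and the axis point as the
minimal-norm solution of the in-plane fixed-point equation via
pseudoinverse. Derived descriptors: protomers per turn n = 360/|theta|,
pitch P = n|d| (reported in nm), handedness = sign(theta d).

Convention: the axis direction is chosen so theta is positive; rotations
below 0.1 degree are flagged degenerate (pure translation) and yield no
descriptors rather than unstable numbers. Under this convention,
swapping the protomer order flips the axis direction (and with it the
world-frame axial displacement) while preserving n, pitch and
handedness. Pitch is reported as an absolute value with handedness
carried separately.

**Ring gate.** Candidate interfaces pass if 5 <= n <= 6 (inclusive) and
P < 2 nm (strict) — the classic near-cyclic selection window for
pentamer/hexamer paranuclei, operationalized without any additional
circularity score. A further screen asks whether
a marker residue (default the C-terminus) points at the ring center:
true iff the marker CA's mean radial distance from the axis, averaged
over protomers, is strictly smaller than the protomer's mean CA radial
distance. This makes "oriented towards the ring center" — usually a
visual judgement — an explicit, testable rule.

**Cyclization.** `cyclize` first projects the interface screw onto the
cyclic manifold — rotation exactly 360/N, zero rise, same axis — so
N-fold closure is exact by construction (closure error below 1e-3 A is
asserted for every ring the package ever returns; in practice it is at
machine precision). A Metropolis Monte-Carlo walk then refines the
protomer's rigid placement: rotations up to 2 degrees about its centroid
and translations up to 0.5 A per move, annealed over four cycles with
amplitudes and temperature shrinking by 0.4 per cycle, against the
coarse-grained energy of the adjacent interface. The best state visited
is returned, so the final energy never exceeds the projected starting
energy. Closure could alternatively be treated as a soft penalty traded
against energy; the hard constraint was chosen because it makes the
closure guarantee unconditional.

**Metrics.** The ring descriptors are operationalized geometrically:
outer diameter = twice the maximum heavy-atom radial distance from the
axis, height = heavy-atom extent along the axis, pore diameter = twice
the minimum heavy-atom radial distance, all in nm. Literature values
for full-size amyloid-beta pentamer/hexamer rings (about 5.1/5.8 nm
diameter, 2.1 nm height, 1.2/1.5 nm pore) are comparison points for
these definitions, not quantities this package claims to reproduce at
desk scale. Contact maps
use a 0.45 nm heavy-atom cutoff, the common convention. Ring-on-ring
stacking reuses the docking engine with ring 1 fixed and labels each
pose by which face (N = the side of the ring plane holding residues 1-9)
meets which.

## The synthetic generator

`build_backbone` places N, CA, C, O and CB by sequential
internal-coordinate (NeRF) construction with ideal bond lengths and
angles (packaged as data), trans peptide bonds, and the CB improper set
for L-amino acids; measured dihedrals of the output equal the inputs to
well under half a degree, which makes dihedral-level round trips exact
enough to anchor the observable machinery. `sample_ensemble` draws each
frame's state from configured weights, jitters the state's per-residue
phi/psi targets, builds the backbone and adds Cartesian noise — a pure
function of its seed.

Two stock configurations define the study conditions:

* `two_state_config()`: a 12-residue central amyloid-beta fragment
  (KLVFFAEDVGSN) mixing a compact helical state (-60, -45) and an
  extended state (-120, 130) at weights 0.3/0.7, angular jitter sd
  4 degrees, Cartesian noise 0.05 A. The jitter is chosen so each
  state's internal spread stays well below the 0.2 nm clustering scale —
  that is what this fixture exists to provide: two tight, well-separated
  populations with known occupancies, so cluster sizes and
  secondary-structure propensities have exact ground truth.
* `disordered_ab42_config()`: the full 42-mer mixing a compact state
  with a short N-terminal helix (residues 4-8) and an extended state
  with strands at 14-20 and 34-36 over a coil baseline with broad
  (sd 20 degrees) jitter — a caricature of a disordered ensemble with
  segment-wise propensities.

What the generator does *not* emulate: force-field energetics,
solvation, side chains beyond CB, kinetics, or any correlation structure
between residues beyond the state mixture. Tests passing on these
ensembles therefore validate the statistical and geometric machinery —
estimator correctness, invariances, ground-truth recovery — not the
biophysics of real amyloid-beta, whose published ensemble statistics
(cluster counts near 200, correlation coefficients near 0.5-0.7) derive
from microseconds of replica-exchange sampling that is explicitly out of
scope.

## Numerical choices and degenerate inputs

* Internal length unit is A (PDB native); RMSD, Rg, pitch and all ring
  metrics are returned in nm because the field quotes them in nm.
* Kabsch superposition uses SVD with the determinant correction; inputs
  with fewer than 3 non-collinear points are rejected.
* Clustering and pose-clustering tie-breaks are deterministic (lowest
  index); every stochastic component (ensemble generation, Monte-Carlo
  cyclization) takes an explicit seed and restores the caller's RNG
  state.
* Pair energies are finite for any geometry including exact bead
  overlap (soft core); degenerate screws (|theta| < 0.1 degree) are
  flagged, never silently numeric.
* Problem sizes in the tests and analysis scripts (hundreds to a
  thousand frames, 12-25 residue toys, tens of docking starts) were
  chosen as the smallest sizes at which every property under test is
  sharply decided; all of them run on a laptop-class single core.

## Known limitations

* The bead parameterization is generic; interface energies rank poses
  but have no calibrated physical scale.
* The phi/psi-region assigner is cruder than a real secondary-structure
  algorithm near region boundaries.
* Rigid-body docking cannot capture induced fit; the protomer is frozen
  at selection time, exactly as in the conformational-selection picture.
* `cyclize` optimizes the adjacent interface only; for small N where
  next-nearest protomers touch, their contribution is reflected in the
  final energy but not targeted by the moves.
* Headline counts from full-scale studies (cluster counts, pose counts,
  candidate counts) depend on sampling volume and docking engine and are
  not desk-scale reproducible; the package's end-to-end checks are
  property-based plus the screw-geometry recovery of the reference
  near-cyclic interface (5.2 protomers per turn, 1.1 nm pitch), which
  `scripts/acceptance.R` recomputes from scratch.
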