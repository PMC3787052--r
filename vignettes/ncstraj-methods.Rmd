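---
title: "Methods: trajectory, energy-map and NOE analysis in ncstraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory, energy-map and NOE analysis in ncstraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncstraj)
```

`ncstraj` packages the standard battery of structural analyses used to ask
whether molecular-dynamics ensembles of an EF-hand calcium sensor such as
NCS-1 have converged to a common conformational state: segment-resolved
backbone RMSD, centre-of-mass distance series, conformational clustering,
NOE back-calculation and inter-residue interaction-energy maps. This
vignette documents the models behind each operator, the parameters that
matter, the numerical conventions, and what the synthetic-data generator
does and does not establish.

## Structures, trajectories and the segment registry

A *structure* is a tidy atom table (one row per atom: serial, name,
residue, chain, element, mass, Cartesian coordinates in Å); a *trajectory*
is an ordered list of coordinate frames sharing one topology, with a fixed
inter-frame time step `dt` in ps. PDB parsing is delegated to bio3d;
`read_structure()` adds the conventions this analysis needs: heteroatoms
(waters, ions, glycols) are dropped by default, so a calcium-loaded crystal
entry yields the polypeptide only; alternate locations keep the
highest-occupancy copy with ties resolved toward altLoc `A`; insertion
codes are rejected rather than silently renumbered (the NCS-1 entries have
none). Author residue numbering is taken at face value.

The segment registry (`ncs1_segments()`) carries the NCS-1 secondary
structure in author numbering: helices H1 (11–18) through H9 (166–174),
strands β1–β6, loops L1–L3, the hinge loop (93–98), and the protein core
`PC` = 11–174 — the span between H1 and H9 over which all alignments are
performed. The C-terminal tail appears under two conventions in the
literature, 175–187 and 176–190; rather than privileging one, both are
registered (`L3` and `L3_METHODS`) and the caller chooses.

The *backbone* atom set defaults to {N, CA, C, O}. Published backbone RMSDs
do not always state whether the carbonyl oxygen was included, so
`select_atoms()` accepts a narrowed convention ({N, CA, C} or {CA});
empirically the difference is a few tenths of an Å on segment-scale RMSDs,
which is why the validation bands on the crystal-versus-solution
comparison are ±0.3–0.4 Å.

## Superposition and partial RMSD

`superpose()` solves the least-squares rigid superposition with the Kabsch
SVD construction, with the determinant correction that rejects improper
(mirror) solutions; the result always satisfies `det(R) = +1` to 1e-9.
Degenerate fits (< 3 atoms, or collinear atoms) are errors. The test suite
cross-checks the returned RMSD against an independent quaternion
(Horn eigenvalue) implementation on random point clouds at 1e-6 Å.

Two different structures are paired by the `(chain, resid, name)` key, not
by atom order, so a crystal structure and an NMR model with different
hydrogen content compare over their common atoms; order-based pairing is
used only inside a trajectory, where the topology is shared by
construction.

*Partial RMSD* (`rmsd_partial()`) is the two-selection operation used for
segment mobility: the transform is fitted on the `fit` selection only
(typically `PC` backbone) and the deviation is then measured over the
`measure` selection without refitting. With `fit == measure` it reduces
exactly to `superpose()$rmsd`, which the tests assert.

`smooth_series()` is a centred moving average with truncated edge windows,
default width 51 frames. It exists for plotting only and is never used in
any statistic; the default width is cosmetic (about 2.5 ns of smoothing at
a 50 ps sampling interval).

Centres of mass are mass-weighted by default, using standard atomic masses
inferred from the element when the file carries none; a geometric centroid
is available by flag. `com_distance_series()` reports the Euclidean
distance of two selection COMs per frame — the order parameter for
tail-docking-style motions.

## Inter-residue energy maps

The pair energy of two parameterised atoms at distance `r` is

```
E(r) = S(r) * [ 332.0636 q_i q_j / r
              + eps_ij ( (Rmin/r)^12 − 2 (Rmin/r)^6 ) ]
```

with `eps_ij = sqrt(eps_i eps_j)` and `Rmin = rmin_half_i + rmin_half_j`
(the CHARMM combining convention, matching the force-field family these
simulations use) and `S(r)` the CHARMM cubic switching function: 1 up to
10 Å, 0 beyond 12 Å, smooth in between. Continuity at both radii is a
tested invariant. The Coulomb constant is fixed at 332.0636 kcal·Å/(mol·e²)
with a vacuum dielectric: the map operator averages explicit-solvent
frames and is not a solvation model.

A residue pair's energy sums the atom-pair energies over all atoms of the
two residues, with three conventions:

- **Cutoff gate.** The pair is evaluated only when the minimum heavy-atom
  distance between the residues is within 12 Å; beyond that the energy is
  exactly 0. This implements the neglect of long-range electrostatics at
  the simulation's own nonbonded cutoff, and is numerically identical to a
  gate-free sum because `S(r)` vanishes beyond 12 Å (a tested oracle
  equivalence against a naive double loop, at 1e-9 kcal/mol).
- **Bonded exclusions.** Atom pairs separated by ≤ 3 covalent bonds (1-2,
  1-3, 1-4 across the peptide bond) are excluded, with no scaled-1-4
  special case. Without this, sequence-adjacent residues would be dominated
  by their shared bonded terms rather than by nonbonded contacts. Bonds are
  perceived geometrically on the topology frame (heavy–heavy < 1.9 Å, X–H
  < 1.3 Å) and held fixed across frames, as in any fixed-topology MD
  analysis. The threshold is configurable (`exclude_bonded = 0` disables).
- **Symmetry.** The map is symmetric with a zero diagonal; the diagonal is
  excluded from classification and filtering.

`compute_iem()` samples frames every `stride` ps (default 50) over the
final `window` ns (default 100, counted back from the trajectory end, with
each frame standing for `dt` of sampling so a 2000-frame, 50 ps trajectory
is used in full) and takes the plain arithmetic time mean. Block averaging
is not used: the operator is defined as the mean over sampled frames.
Residues excluded by id (calcium ions kept as residues, for instance) are
absent from the matrix entirely rather than zeroed.

Energies are read through fixed interaction classes with bin edges at
−30, −15, −2 and 0 kcal/mol (each edge belonging to the more-negative
class): `ionic` below −30, `strong_polar` to −15, `hbond_like` to −2 — the
range typical of hydrogen bonds — `weak` to 0, `repulsive` above.
`filter_map()` applies a strict `E < threshold` rule (default −30) to
extract salt bridges, and `conserved_bridges()` intersects two maps,
requiring the strict threshold in *both* — the criterion for calling a
bridge conserved across independent trajectories.

## NOE back-calculation and violation statistics

A restraint couples two groups of equivalent protons with an upper
distance bound. The effective distance combines all proton pairs of the
two groups by the sixth power, `r_eff = (Σ r⁻⁶)^(−1/6)`, reflecting the
r⁻⁶ scaling of the NOE intensity; the *sum* convention is the default
(appropriate when the experimental bound was calibrated for the group as a
whole), with a `combine = "mean"` flag for cross-checks against software
that normalises by the pair count. Over an ensemble the r⁻⁶ sums are
averaged over sampled frames before inverting, so transient close
approaches pull the effective distance down just as they raise the
measured intensity.

Scoring follows the published convention literally, including its
asymmetry: a restraint is **violated** when the effective distance exceeds
`upper + 0.6` Å, but the violation magnitude is measured from the raw
upper limit, `V = r_eff − upper` — so a 5.2 Å distance against a 4.5 Å
bound is violated with V = 0.7 Å, while 5.0 Å is not violated at all. The
summary's average violation ⟨V⟩ runs over the violated restraints only
(denominator `n_violated`) and is reported absent (`NA`) when nothing is
violated. Restraints referencing protons absent from the model are a hard
error naming the missing atom, never a silent skip.

## Conformational clustering

`rmsd_matrix()` computes the all-pairs superpose-then-RMSD matrix over a
fitted selection for the sampled frames. `cluster_frames()` cuts a
complete-linkage dendrogram at a fixed height, default 2 Å. Complete
linkage is the deliberate choice among the standard linkages because it is
the only one whose cut height certifies the property the state-identity
argument needs: every pair of frames within a cluster is within the cutoff
of each other (an asserted invariant, not just a tendency). Cluster ids
are ordered by population, descending, with ties broken by the smallest
member frame index, so cluster 1 is always the most populated; permuting
frame order can therefore relabel but never re-partition. The
representative of a cluster is its medoid — the member minimising the
summed RMSD to the rest, ties to the smallest frame index — which is the
usual operational meaning of "most representative structure". The matrix
is held dense; at the default 50 ps sampling over 100 ns (2000 frames) the
half-matrix is small enough that nothing sparser is warranted.

## The synthetic-data generator

Every downstream operator is exercised against generated inputs with
planted ground truth:

- `build_helix()` constructs an ideal α-helical backbone (φ = −57°,
  ψ = −47°, ω = 180°, canonical bond geometry) by natural-extension
  internal-to-Cartesian placement. The recomputed dihedrals are within 1°
  of the targets and the i→i+4 O···N pairs land at 3.09 Å, inside the
  2.8–3.2 Å hydrogen-bond band — both tested geometrically.
- `plant_salt_bridge()` adds one charged pseudo-atom to each of two
  residues, placed on an outward ray perpendicular to the molecule's
  principal axis (so terminal residues do not park the charge inside the
  backbone) at an exact separation, and emits a matching parameter table
  in which all other atoms are neutral with a small dispersion well
  (ε = 0.05 kcal/mol, Rmin/2 = 2 Å). Pseudo-atoms rather than full
  sidechain rotamers: the energy pipeline is what is under test, and a
  rotamer library would add machinery without adding discrimination.
- `make_trajectory()` adds independent isotropic Gaussian displacements to
  every atom, per frame, with a per-axis amplitude defaulting to 0.15 Å —
  a small-amplitude, well-equilibrated fluctuation scale chosen once as
  realistic for heavy-atom positional noise — plus an optional linear
  rigid drift of a named segment to emulate tail docking. Frames are
  bitwise reproducible for a fixed seed (Mersenne–Twister, restored
  afterwards so the caller's RNG stream is untouched).
- `make_restraints()` assigns upper bounds from the actual distances so
  the ground truth is exact by construction: satisfied restraints get 1 Å
  of slack, violated ones get `upper = r − depth − 0.6`, making the
  planted V equal `depth + 0.6` exactly on the static structure and the
  violated count equal `round(n · fraction)` deterministically.

The presets bundle these: `bridge` (24-residue helix, ±1e pair at 3 Å,
10 frames at 50 ps), `noe` (60-residue helix, 200 restraints, 20% planted
violations of depth 0.3 Å, 20-frame ensemble) and `twostate` (30-residue
helix with its final third displaced 9 Å, 15 + 15 frames). These sizes are
the package's chosen validation scale: large enough for the planted signal
to dominate the Gaussian noise, small enough that the full suite runs in
well under a minute.

What passing these tests shows — and does not. The generator's Gaussian
model has no covariance structure, no solvent, no force-field fidelity and
no realistic kinetics; recovery of planted bridges, violations and states
therefore validates the *operators* (the algebra, averaging, thresholds
and tie rules), not the scientific conclusions one would draw on real
trajectories. Conversely, the operators are model-agnostic: nothing in
them assumes the Gaussian fixture.

## Validation against the deposited structures

The one validation that uses real data — the protein-core backbone RMSD of
about 4.4 Å between the crystal (1G8I chain B) and solution (2LCP model 1)
structures, with partial values near 6.4 Å for H1, 4.0 Å for H9 and 3.2 Å
for L1 — requires the two PDB entries, which are not redistributed with
the package. `compare_deposited()` computes exactly those numbers when the
files are supplied (`options(ncstraj.pdb_dir = ...)`), and the
corresponding test blocks run whenever the files are present. The ±0.3–0.4
Å bands absorb the backbone-set convention discussed above.

Quantities that depend on the original multi-hundred-ns trajectories —
RMSD plateau levels, cluster counts of a specific simulation, its NOE
satisfaction percentage — are not desk-reproducible and are deliberately
not asserted anywhere; the report structures carry the right fields for
them, and the planted-truth suites pin the arithmetic.

## Known limitations

- PDB only; no mmCIF, no PSF topologies, no hydrogen building.
- Geometric bond perception assumes reasonable input geometry; grossly
  distorted topology frames would mis-perceive bonds (the exclusions can
  always be supplied precomputed via the `bonds` argument).
- Residue identity in energy maps is keyed by residue id, so duplicate
  numbering across chains should be resolved (or chains analysed
  separately) before mapping.
- No periodic-boundary unwrapping: frames are assumed to contain whole
  molecules.
- The electrostatics is deliberately short-range and undielectric; the map
  is an interaction fingerprint, not an energy decomposition of a solvated
  system.
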