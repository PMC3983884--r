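---
title: "Reconstructing ion-channel structures from ternary contact maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ion-channel structures from ternary contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c2s)
```

## The problem

A residue–residue contact map records, for every pair of positions in a
protein, whether their representative atoms lie within a distance threshold.
`c2s` reconstructs full heavy-atom, three-dimensional models — monomers and
homotetrameric ion channels — from *ternary* contact maps over
$\{1, 0, -1\}$: contact, non-contact, and unknown. The `-1` state matters
because real contact information (from coevolution predictors, crosslinking,
or deliberately degraded maps in benchmarking) is always incomplete, and
treating an unknown pair as a non-contact injects false repulsion.

The package also implements the two benchmarking axes that the ternary
representation enables — random *reduction* (known entries → unknown) and
*error injection* (contacts flipped to non-contacts, or both directions) —
plus the structural and electrostatic model-quality metrics needed to
measure what those perturbations cost.

## The reconstruction pipeline

**Monomers.** `run_monomer_pipeline()` chains four stages:

1. *Trace reconstruction* (`reconstruct_ca`). A seeded random walk with the
   virtual Cα–Cα bond fixed at 3.8 Å, confined to a compact ball of radius
   $(3/4\pi)^{1/3} L^{1/3}\cdot 4$ Å, is refined by iterative constraint
   projection: a contact pair beyond the threshold is pulled together by
   half its violation; a non-contact pair inside the threshold is pushed to
   threshold + 0.1 Å; bonded neighbours are reset to 3.8 Å; unknown pairs
   impose nothing. When the satisfied fraction stagnates, only the residues
   that still violate constraints receive a Gaussian kick (σ = 1 Å); the
   best trace seen is kept.
2. *Chirality resolution* (`fix_chirality`). A contact map is blind to
   reflection, so each refined trace is examined through its 4-residue Cα
   pseudo-dihedrals; if the left-handed sign dominates, the mirror image is
   taken. Handedness is resolved here, once, rather than inside refinement.
3. *Backbone completion* (`build_backbone`). Each peptide unit between
   consecutive Cα atoms carries an ideal trans peptide plane (N–Cα 1.46 Å,
   Cα–C 1.52 Å, C–N 1.33 Å, ω = 180°); the plane's rotation about the Cα–Cα
   axis is chosen so the N–Cα–C angle at each residue is 111°. The rotation
   has two solutions related by reflection; in trans, L-amino-acid
   conformations the carbonyl offset stays on a predictable side of the
   chain, so the scan window [20°, 160°] of the local in-plane basis picks
   the protein-like root. Cα coordinates are never moved.
4. *Side chains* (`place_sidechains`, `relieve_clashes`). A minimal embedded
   rotamer library (staggered χ1 wells at −65°/180°/+62° with prior weights
   0.5/0.3/0.2, trans or ring-typical higher χ) builds side chains in
   internal coordinates; the highest-weight clash-free rotamer wins, and
   greedy sweeps afterwards reduce the hard-sphere overlap count (a clash is
   a non-bonded pair closer than 0.8× the sum of van der Waals radii).
   This deliberately replaces fragment-library backbone assembly and
   energy-based rotamer optimization with deterministic, dependency-free
   geometry: the dominant error component is the trace stage, not the
   completion stages.

**Tetramers.** Chains are concatenated in one map. Because the refiner bonds
consecutive rows, `insert_dummy_loops()` first inserts 15 all-unknown
rows/columns at each chain junction: a neutral "loop" that lets the chain
termini separate. After reconstruction the loops are trimmed
(`trim_dummy()`), the symmetry frame of the asymmetric model is estimated by
superposing each chain onto the next and averaging the rotation axes and
fixed points (`estimate_symmetry_frame()`), and each subunit — plus the
Kabsch-averaged subunit — is projected four times about the axis
(`assemble_channels()`), giving five exactly C4-symmetric channels per run.
Side chains are then placed *symmetrically*: every rotamer decision made for
the first chain is applied to all four copies simultaneously and scored
against the full replicated context, so exact symmetry survives completion.

## Electrostatic assessment

Channels work through the potential inside their pore, so structural RMSD is
complemented by a functional measure. With zero ionic strength the
linearized Poisson–Boltzmann equation reduces to the variable-dielectric
Poisson equation, which `solve_poisson()` discretizes with a 7-point stencil
and harmonic-mean dielectric on half-edges: ε = 4 inside any atom's van der
Waals sphere, ε = 80 elsewhere (including the pore). Charges are trilinearly
splatted onto the grid; the boundary is the Coulomb sum in solvent
dielectric; red-black SOR iterates to a relative residual of 1e-6. The
default grid is cubic 129³ at 1 Å spacing. `axial_profile()` samples the
potential along the pore axis, `profile_params()` extracts Fmax, Fmin and
zmin (mV, Å), and `profile_distance()` returns the RMSE and relative
deviations against a template (native) profile.

The default charge scheme is formal: −1 e split over Asp/Glu carboxylates,
+1 e on Lys NZ, +0.5 e on each Arg NH, ±1 e on the termini. Absolute
potential values therefore depend on the charging; reproducing a particular
force-field-grade profile requires PQR input (`assign_charges(scheme =
"pqr")`). Relative comparisons — profile RMSE and deviations across models
of the same system — are robust to the scheme, and those are what the
experiments use.

## Model-quality metrics

All RMSDs are built on a closed-form least-squares superposition
(`kabsch_superpose`, proper rotations only). `global_rmsd()` minimizes over
the model's mirror image (contact maps carry no handedness) and over cyclic
chain relabelings (a C4 model's chains have no canonical names); without the
latter, symmetric models would be penalized by an arbitrary label choice.
`subset_rmsd(align_on = "subset")` is the selectivity-filter convention:
superpose on the selection itself, then measure it. `local_rmsd()` holds one
global alignment fixed and scores each residue's shared heavy atoms.
`structure_diameter()` is the plain distance between a marker residue on two
opposite chains. Rank statistics (`kendall_tau`, tie-corrected τ-b;
`ranksum_test`, tie-corrected normal approximation) quantify the association
between structural and electrostatic quality across an ensemble.

## The synthetic test systems

`make_toy_tetramer()` is the package's stand-in for a real tetrameric
channel: four helix-turn-helix subunits in exact C4 symmetry, an inner
pore-lining helix (pore radius 3.5 Å by default), a short turn, and an outer
helix packed antiparallel at 8.5 Å axis separation, with Glu/Lys rings on
outward-facing positions of both helices so the pore has a smooth,
channel-scale axial potential profile (tens of mV). Two aspects of the
charge layout are deliberate: the charges are spread over six rings per
tetramer — with only a couple, the profile error tracks individual rotamer
flips instead of structure — and none point into the pore, because a naked
charged side chain near the axis turns the profile into a point-charge
spike. The helix-turn-helix topology is equally deliberate: it is what
gives the contact map enough long-range, inter-helix information to
determine the fold.
`make_compact_coil()` (a confined self-avoiding walk, contact density ≈ 19)
plays the role of a generic compact globular chain; `make_ideal_helix()` and
`make_hairpin()` provide clean secondary-structure geometry;
`make_charge_pair()` is the minimal solver test system. All generators are
deterministic given their seed.

What the fixtures do *not* emulate: real side-chain packing diversity,
loops and disordered termini, experimental coordinate error, and realistic
charge distributions. Passing the test suite therefore demonstrates the
correctness of the algorithms under controlled geometry, not prediction
accuracy on crystallographic structures.

## What a contact map cannot determine

A point worth stating explicitly, because it shapes which self-reconstruction
checks are meaningful. For an *isolated, straight* secondary-structure
element — a single ideal helix or an isolated hairpin — all the information
in a Cα/8 Å map sits within a few residues of the diagonal, and the decisive
non-contacts (e.g. the i, i+5 pairs of a helix at 8.7 Å) sit just past the
threshold. A gentle global bend of curvature radius $R$ changes a span-$s$
pair distance by $O(s^3/R^2)$ — roughly 0.1 Å for realistic bends — far
below the threshold's resolution. Consequently conformations bent many
Ångströms away from the ideal geometry satisfy *every* constraint, and no
reconstruction algorithm can distinguish them from the original. We measured
exactly this: refined traces of the 30-residue helix map reach constraint
satisfaction 1.0 at 6–10 Å Cα RMSD from the straight helix.

Compact folds do not suffer from this: the compact coil (contact density
≈ 19) self-reconstructs to ~0.5 Å, and the helix-turn-helix tetramer trace
to ~1.8 Å. Self-reconstruction accuracy claims are therefore asserted on
compact systems, and extended fixtures are used for geometry and bookkeeping
tests only.

## Numerical and design choices

* **Refiner schedule.** Defaults: satisfaction target 0.995, 1000 sweeps,
  3 restarts per model (best-satisfaction restart kept), stagnation window
  5 sweeps. A looser target (0.98) measurably strands runs in local optima:
  on the tetramer map, runs stopping at ≈ 0.986 sit ~8 Å from the native
  region while runs reaching ≥ 0.999 sit at ~1.8 Å. Satisfaction is cheap to
  compute and discriminates sharply, which is why restarts select on it.
* **Soft hinge margin.** Satisfied pairs within 1 Å of the threshold receive
  a gentle (0.1×) nudge toward the constraint interior, plus a 200-sweep
  polish phase after convergence. This max-margin regularization cannot
  create violations (the polish result is kept only if satisfaction does not
  drop) and improves the conditioning of marginal solutions.
* **Counting conventions.** The diagonal is self-contact and excluded from
  every count; perturbations draw without replacement from the upper
  triangle and mirror, so symmetry is structural; counts round half away
  from zero.
* **Dummy loop length.** 15 positions per junction allow termini to separate
  by up to ≈ 60 Å, comfortably above the inter-terminal distances of a
  channel-sized tetramer.
* **Degenerate inputs.** Coincident points during refinement get a random
  separation direction; ties in profile minima take the first occurrence and
  set a flag; fewer than three superposition points fall back to
  translation-only with a degeneracy flag; single-chain maps pass through
  dummy-loop insertion unchanged with a warning.
* **Seeding.** Experiments derive one seed per (variant, map replicate,
  model) by integer hashing below 2^31, so any slice of an experiment is
  reproducible in isolation.

## Experiment scale

`run_experiment()` defaults mirror the benchmarking design of the channel
case study: 10 randomized maps per perturbation level and 50 models per map,
with structural metrics per channel. The package's own test suite and the
acceptance script run the same experiment at reduced scale — 2 randomized
maps × 3 models per level, electrostatics on the averaged channel with a
57³ grid — which keeps the full suite in the minutes range on one core
while preserving every qualitative contrast (complete vs positive-only,
monotone degradation, the RMSD/RMSE correlation). The problem sizes are
stated in the corresponding helper and script.

## Known limitations

* Backbone completion is ideal-geometry: φ/ψ land within a few tens of
  degrees of canonical values, with ~0.4–0.6 Å backbone RMSD on native
  traces. Fragment-based completion would be tighter.
* The rotamer library is minimal (staggered wells, ring-typical χ2); it
  resolves hard-sphere clashes, not packing energetics.
* The formal charge scheme makes absolute Fmax/Fmin values scheme-dependent;
  use PQR input when absolute potentials matter.
* Cyclic (Cn) symmetry only; no dihedral or helical assemblies.
* Extended, contact-sparse folds are underdetermined by their maps (see
  above); this is a property of the representation, not of the solver.
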