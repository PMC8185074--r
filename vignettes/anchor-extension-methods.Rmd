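---
title: "Anchor-extension design of macrocyclic binders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-extension design of macrocyclic binders: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`anchorext` builds head-to-tail cyclic peptides around a fixed,
pocket-bound anchor residue and ranks them by surrogate interface
metrics. This vignette is the package's own account of the science: the
models, their assumptions, the tunable parameters, what the synthetic
fixtures do and do not emulate, and the numerical choices made where
the design was genuinely open.

## The structural model

A `Pose` is an ordered list of residues — coordinates per heavy atom —
plus hetero entities: zinc sites and water sites. Waters are oxygen
positions only, flagged structural and held rigid; hydrogen-bond
geometry involving them is evaluated distance-only. Chains can be
marked head-to-tail cyclic (an amide between the last residue's C and
the first residue's N).

Residue chemistry lives in a template registry. Each template defines
its heavy atoms in internal coordinates: a bond length, bond angle and
torsion against three previously placed reference atoms, with symbolic
torsions (`phi`, `psi`, `omega`, `chiK`, optionally offset) bound at
build time. The registry ships the 20 canonical L amino acids, their D
mirrors (every numeric torsion negated, rotamer chi signs flipped —
mirror images are exact by construction), achiral glycine, and the
thiol anchor residue: an alpha amino acid with a five-methylene side
chain ending in a sulfur, so the sulfur sits six bonds from the alpha
carbon and can reach a pocket-bottom zinc while the backbone stays at
the pocket mouth. User templates load from a small text format (one
atom per line; see `inst/extdata/anchor_templates.txt`) and can be
auto-mirrored.

Assumptions worth stating plainly:

- Geometry is ideal. Chains are built (and rebuilt during minimization)
  from fixed bond lengths and angles; only torsions move. Structures
  read from PDB keep their coordinates until a rebuild idealizes them.
- Hydrogens are implicit. Polar chemistry is carried by a per-atom role
  (donor-heavy / acceptor / both), not by explicit protons.
- Ring chemistry in side chains (proline, histidine, aromatics) is
  built from internal coordinates without enforcing ring-closure bonds;
  the geometry is near-ideal but the ring bond itself is not a degree
  of freedom. Proline's backbone restriction is carried by its torsion
  preference table instead.

## Torsion preferences

Backbone (phi, psi) preferences are smooth analytic basin mixtures
(two to three periodic Gaussians per class), not statistical tables:
a general-L class (alpha-R, beta, and a minor alpha-L basin), its
exact mirror for D residues, a mirror-symmetric glycine class, and a
proline class with phi pinned near -63 degrees. The score is the
negative log of the unnormalized mixture density; lower is better. Only
the symmetry properties are externally meaningful, and those are what
the tests pin down: glycine invariant under (phi, psi) -> (-phi, -psi),
and every D template scoring as its L parent at the mirrored point.
The acceptance threshold for sampled conformers (`rama_cutoff`,
default 5.0 on this scale) was calibrated on the closure harness —
roughly the score two standard deviations out from a basin center —
and is configuration, not a physical constant.

## Kinematic closure

To close a macrocycle, non-pivot torsions are drawn from the torsion
preference distributions and the six torsions flanking three pivot
residues are solved. The solve is a Levenberg–Marquardt root find: the
chain is extended past the last residue by a virtual N and CA placed
with ideal bond geometry and a trans amide, and the residual is the
3+3-coordinate mismatch between those virtual atoms and the real
first-residue N and CA. At a root, the closure bond length, both
flanking angles and the closure omega are ideal *by construction*; the
solver accepts only residuals below 1e-6 Å. This replaces the classic
analytic triaxial formulation with a numerically exact root find that
meets the same contract (validated in the tests against brute-force
grid refinement on a 5-ring, where solutions require strained
torsions).

Design choices here:

- **Pivot choice.** Solved pivot torsions land anywhere on the torus,
  so pivots at narrow-basin residues almost always fail the torsion
  filter. Pivots are therefore drawn preferentially from glycine-class
  (broad-basin) residues, randomized within that set per attempt; the
  filter itself is unchanged.
- **Ring register.** Closure runs in a rotated register that puts the
  anchor at ring position 1, so the anchor's coordinates are the fixed
  frame and the solved joint is the bond entering the anchor. Frozen
  residues (the anchor; the water-motif pair in method 2; scanned
  cells in methods 3–4) keep their torsions, not just their
  coordinates.
- **Filters.** Solutions must pass the torsion-preference cutoff on
  every residue and carry at least `min_genkic_hbonds` (default 2)
  internal backbone N···O hydrogen bonds (N–O < 3.5 Å, excluding
  adjacent residues, ring-adjacency aware); final ensembles re-check
  `min_final_hbonds`. Omega is fixed trans during sampling.
- **Tolerances.** Ideal C–N 1.328 Å; closure accepted within 0.02 Å
  and 5 degrees.

## The surrogate energy

The scoring function is an explicit surrogate on a kcal/mol-like
scale, additive over terms: split 12-6 Lennard-Jones (repulsive and
attractive parts separated at the vdW-contact minimum, deep overlaps
flattened below 0.6 sigma for optimizer stability), a distance-only
hydrogen-bond well (Gaussian centered at 2.9 Å, donors and acceptors
by template role, waters both), a screened-Coulomb term with
rule-based charges (full formal charges on Arg/Lys/Asp/Glu termini,
±0.2 on other polar atoms), the torsion-preference sum, a harmonic
restraint pulling a ligand thiol sulfur to each zinc's target
coordination distance (default 2.3 Å), and for cyclic chains a
harmonic closure penalty. vdW radii: C 1.7, N 1.55, O 1.52, S 1.8 Å.

Consequences of surrogacy: the shape-complementarity threshold
(Sc > 0.65) is scale-free and transfers directly from practice, while
the interface energy-gap threshold (ΔΔG < -10) lives on the surrogate
scale and is exposed as configuration — on the toy systems it behaves
like a demanding cut, as intended, but it is not calibrated against
any physical unit.

`ddg_bind` is E(complex) − E(receptor) − E(peptide). Without
repacking, separated-state coordinates are identical and the value
isolates inter-chain terms plus the zinc restraint (which only exists
in the complex); with repacking, the unbound peptide's side chains are
re-optimized greedily over the rotamer set first.

Shape complementarity follows the median-dot formulation: van der
Waals surface dots per chain (golden-spiral, default 5 dots/Å²,
occluded dots removed), and for each interface dot the *exact*
distance and normal against the partner's sphere-union surface
(minimum over atoms of |x−c|−r). The statistic is the mean of the two
directional medians of −(n₁·n₂)·exp(−0.5 d²), over dots within 1.5 Å
of the partner surface. Computing the distance against the analytic
surface rather than against the partner's dots makes the value nearly
independent of dot density (the tests hold it within 0.02 of a
25 dots/Å² brute-force oracle). One honest limitation: a union of
equal spheres cannot be perfectly complementary to another one, so
even ideally nested surfaces measure Sc ≈ 0.8 under this surface
model, not the ≈0.95+ that smoother molecular-surface definitions
give. The 0.65 threshold still separates nested from mismatched
surfaces by a wide margin.

Buried unsatisfied polar atoms: Shrake–Rupley SASA (probe 1.4 Å, 92
dots/atom), burial below 5 Å², partner = any complementary polar heavy
atom within 3.5 Å that is not bonded within three bonds; waters count
as partners. Clashes: non-bonded heavy pairs closer than the radii sum
minus 0.5 Å.

## Design methods

Method 1 docks pre-built cyclic scaffolds by least-squares
superposition of each scaffold residue's {C, N, O, CA, CB} onto the
anchor's (4 atoms and a flag for glycine registers), grafts the anchor
side chain into the aligned register at the anchor's chi angles, and
screens by backbone–receptor clashes (default budget 3, then relax).
Methods 2–4 grow the chain from the anchor (ideal geometry, torsions
re-sampled until the backbone is clash-free), optionally scan the
anchor-flanking residue — a full (phi, psi) grid at 30 degrees gives
144 bins per residue type, with the L or D variant chosen by the sign
of phi — close the ring in the pocket, and design.

Sequence design is simulated-annealing Monte Carlo over the designable
positions: identity moves enter at the best enumerated rotamer
(rotamer trials), rotamer moves perturb chi angles, acceptance follows
a geometric temperature schedule (3.0 → 0.3). Rotamers are chi
enumerations at {-60, 60, 180} per chi (first three chis; proline uses
its two ring-compatible pairs) rather than a statistical library — a
deliberate desk-scale simplification. The anchor's identity and
coordinates are never touched by any stage; with the method-2 water
motif, the anchor and its preceding residue additionally keep their
backbone torsions and the structural waters take part in all scoring.

Filtering applies the hard cut-offs first (Sc > 0.65, ΔΔG < -10),
then keeps the intersection of the per-metric top fractions (total
score and ΔΔG lowest; Sc and contacts highest) — "top 1% of all
metrics" is read as an intersection, not a joint rank.

## Funnel analysis

Folding landscapes are ensembles of closed, filtered, optionally
minimized conformers, scored and measured by cyclic-register-aware
backbone RMSD (minimum over ring renumberings with matching residue
types) against a reference conformation. Pnear uses lambda = 1.5 Å and
kT = 1 surrogate unit; the energy gap is the best energy beyond the
1.5 Å near-cutoff minus the best within it (positive = funnel centered
on the reference). When one side of the cutoff is unsampled the gap
falls back to ±(energy spread), a bound that keeps comparisons
well-defined. These defaults are configuration: no published parameter
values exist for them on this energy scale.

The benchmark pair (`make_funnel_pair()`) contrasts a *structured*
macrocycle — cyclo(Glu-Pro-Gly-Arg-Gly-Gly-Gly), rigidified by a
proline and a Glu/Arg salt bridge, whose reference is the energy
minimum of a deep (55-conformer) probe — with a *flexible* one —
cyclo(Ser-Gly₆), whose reference is a median-energy probe conformer.
The asymmetric reference choice is the point: a stability-designed
macrocycle is built to have its bound conformation *be* the free-state
minimum, while a merely functional one binds in a conformation that
the free-state ensemble does not favor. Single residues (Ser; the
bridge pair) also break the ring's register symmetry so that RMSD
comparisons are not flattered by register freedom.

## The synthetic fixtures

The toy receptor is a rigid cylindrical cup of alanine pseudo-residues
(side chains lining the cavity), a catalytic zinc at the base, and two
structural waters at the rim. Its defaults (radius 6.5 Å, depth 9 Å)
were chosen from the anchor's geometry: the fully extended thiol side
chain spans about 6.6 Å, so with the sulfur at the 2.3 Å coordination
distance the backbone lands at the pocket mouth, as in the enzyme
channel it emulates. Generation is deterministic per seed and every
fixture carries a manifest of its planted features; tests assert
against manifests, never magic numbers.

What the fixtures do **not** emulate — and hence what passing tests do
not show about real systems: receptor flexibility and induced fit;
real active-site electrostatics and desolvation; sequence-dependent
water networks (the two waters are positional only); the conformational
preferences of real side chains beyond three-state chi enumeration;
and any absolute energy scale. The fixtures validate the machinery —
geometry, closure exactness, metric semantics, filter logic, statistics
— not binding predictions.

Dose-response tables follow the assay's serial-dilution design: by
default five 1:10 steps from 1 µM to 100 pM, activities from the
four-parameter logistic. Under the printed parameterization an
inhibition curve has a negative Hill slope (the generator's default);
the fit leaves the slope free in [-10, 10], fixes the bottom at 0,
bounds the top below 120, and multi-starts from IC50 deciles of the
observed range with Hill starts of ±1. Noise is relative (the standard
deviation is the given percentage of each predicted activity), and
replicate series model the duplicate measurements typical of these
assays. IC50 scale-equivariance (multiplying concentrations by c
multiplies the fitted IC50 by c exactly) follows from fitting in
log-concentration space.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is exactly
reproducible. The shipped tests run the pipeline at the scales the
toolkit targets: 250-attempt closure batches, ensembles of 20–55
conformers, scans of 36–144 bins over one to two residue types, design
runs of tens of Monte Carlo steps, 100-replicate fit recoveries. The
same machinery runs at larger budgets by raising the corresponding
arguments; nothing in the implementation is specific to these sizes.

## Known limitations

- The energy function is a surrogate; its ΔΔG scale is internally
  consistent but not transferable, and electrostatics are schematic.
- Receptors are rigid throughout; there is no repacking or backbone
  relaxation of the target.
- Side-chain rings are not closed kinematically; proline is handled by
  torsion preference rather than ring geometry.
- The rotamer set is a three-state enumeration plus local minimization,
  which under-samples long side chains.
- Only rigid anchor-superposition docking is provided; flexible docking
  is out of scope.
- Landscape ensembles at desk scale (tens of conformers) carry
  sampling noise; the funnel statistics are comparative tools, not
  converged free-energy estimates.
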