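---
title: "Contact-guided coarse-grained protein-peptide docking: models and methods"
author: "CGPepDock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-guided coarse-grained protein-peptide docking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CGPepDock)
```

# Scope

CGPepDock is a desk-scale implementation of contact-information-driven
flexible protein-peptide docking: a coarse-grained representation, a
replica-exchange Monte Carlo sampler for a fully flexible peptide
around a fluctuating receptor, a soft distance-restraint energy term
that injects fragmentary residue-residue contact knowledge into the
search, and a post-processing pipeline (contact filtering, energy
filtering, clustering, scoring, quality evaluation). This vignette
documents the models, the tunable parameters, the numerical choices,
and what the test suite does and does not demonstrate.

# The coarse-grained representation

Each residue is reduced to up to four pseudo-atoms:

* **CA** - the alpha carbon, taken from the input structure;
* **CB** - the beta carbon (absent for glycine);
* **SC** - the unweighted center of mass of the side-chain heavy
  atoms, CB included (for glycine SC := CA, for alanine SC = CB).
  Whether CB belongs in the side-chain center is a genuine convention
  choice; we include it, so that SC is defined for every residue with
  any side-chain atom and degrades gracefully for alanine;
* **CP** - the midpoint of the peptide bond C(i)-N(i+1); when either
  backbone atom is missing, the midpoint of the two CA atoms; absent
  for the last residue of a chain.

Coordinates are continuous (off-lattice). All quantities the package
reports - SC-SC distances, RMSDs, contact maps - are
lattice-independent, so nothing is lost by not discretizing, and the
geometry code stays elementary. Alternate locations in the input PDB
are resolved to the highest-occupancy conformer (ties: first in file);
hydrogens are ignored; selenomethionine is read as methionine.

Peptides built from sequence (`buildPeptide()`) are self-avoiding CA
chains with exact 3.8 Angstrom virtual bonds and pseudo-bond angles in
[75, 150] degrees, grown by internal-coordinate extension with
rejection. CB and SC sites are placed along the local bisector frame at
per-residue-type distances. The chain is regrown until the dressed
peptide is free of internal soft-core clashes; without that check a
small fraction of grown conformations carry intrinsic SC-SC overlaps
that no rigid placement can remove. A secondary-structure string biases
the sampling windows (helix: angle near 91 degrees, dihedral near 52;
extended: angle 115-135, dihedral near 180); secondary structure is
accepted as *input* only - the package does not predict it.

# Energy model

The docking energy is a sum of four transparent components
(`totalEnergy()`); energies are dimensionless simulation units
throughout, since no physical unit is defined for them anywhere in the
protocol.

**Receptor-peptide interaction.** A residue-type square well on SC-SC
distances: pair (a, b) contributes e(a, b) when the distance lies in
[4.0, 6.5] Angstrom. The 20 x 20 table shipped with the package is a
hydrophobicity-derived scale (normalized Kyte-Doolittle weights w_a,
e(a, b) = -(0.2 + 1.5 w_a w_b), range -1.7 to -0.2): contacts between
hydrophobic residues are most favourable, every contact is weakly
attractive. This deliberately simple stand-in replaces the
knowledge-based statistical potential of lattice docking engines, which
is defined only by reference to its own derivation data and is not part
of this protocol's contribution; the claims the package tests
(restraint effect, filtering, clustering) are potential-agnostic, and
the table is a plain-text file that can be swapped
(`contactPotential(file)`).

**Excluded volume.** Soft-core repulsion k(r_clash - d)^2 for CA-CA
pairs below 3.5 Angstrom and SC-SC pairs below 3.0 Angstrom (k = 10
energy/Angstrom^2), over inter-chain pairs and intra-chain pairs at
least two positions apart.

**Intra-peptide geometry.** Harmonic bond term (k = 5) about 3.8
Angstrom, flat-bottom angle term (zero inside [75, 150] degrees,
harmonic in radians outside, k = 5), and an optional
secondary-structure bias (weight 0.5) pulling pseudo-angles and
pseudo-dihedrals towards helical or extended targets.

**Contact restraints.** The linear flat-bottom term

$$E_\mathrm{contact}(d) = \begin{cases} 0 & d \le D_0 \\ s\,(d - D_0) & d > D_0 \end{cases}$$

summed over restraints, with defaults D0 = 5.0 Angstrom and s = 1.0.
The defaults are soft on purpose: within the cutoff the peptide is
completely free, and a violation of 1 Angstrom costs exactly s - small
against a single contact-well depth, so the restraint guides the search
without freezing the pose. Ambiguous restraints (receptor residue
against all peptide residues) contribute one term at the *minimum*
SC-SC distance with D0 = peptide length + 12 Angstrom; one penalty per
restraint, not per peptide residue, which is the standard
ambiguous-restraint contract.

The restraint term is active at constant strength through the whole
simulation (no ramping): ramping schedules would add a parameter the
protocol nowhere defines, and the soft default makes them unnecessary.

The receptor has no internal energy; its fluctuations are governed
entirely by a harmonic positional tether (k = 1.0 energy/Angstrom^2) to
the input coordinates, which realizes "small backbone fluctuations"
with a single interpretable constant. Large-scale receptor
rearrangements are out of scope.

# Sampling

Replica-exchange Metropolis Monte Carlo with a geometric temperature
ladder (default 10 replicas, T = 1.0 to 3.0). Each replica starts from
an independently built peptide conformation placed uniformly on a shell
at R_surface + 10 Angstrom around the receptor with random orientation,
rejection-sampled until sterically clash-free (up to 1000 tries).

One sweep comprises, per peptide residue, a local move (single-residue
displacement up to 0.7 Angstrom, or with probability 0.3 a two-residue
crankshaft rotation up to 30 degrees about the flanking-CA axis), one
rigid-body peptide move (translation up to 2 Angstrom or rotation up to
30 degrees), and n_rec/10 receptor single-residue jitter moves (up to
0.3 Angstrom). Moves are accepted by the Metropolis criterion on the
full energy including restraints and tether. Neighbouring replicas
attempt configuration swaps every 10 sweeps with the standard
acceptance min(1, exp((1/T_i - 1/T_j)(E_i - E_j))), alternating pair
parity. The move magnitudes and ladder were chosen once for roughly
30-50% sweep acceptance on the toy systems - ordinary Monte Carlo
practice, as none of these constants is prescribed by the protocol
itself.

Snapshots are recorded at fixed sweep intervals from *all* replicas
(not only the coldest) until 10 000 models are collected (default
split: 10 replicas x 1000 snapshots; only the total is part of the
protocol). Filtering by energy afterwards presupposes exactly this kind
of heterogeneous pool. Every snapshot carries its full energy
decomposition and the current per-restraint SC-SC distances, so
post-processing never recomputes them. A run is bit-reproducible for a
fixed seed: all randomness flows from one seeded RNG stream.

# Post-processing

Stages, in fixed order (`runPipeline()`):

1. **Contact filter.** A model satisfies a restraint iff its recorded
   distance is at most D0 - the zero-energy region of the restraint
   term, which is the most natural reading of "satisfying the contact
   criterion" (documented as this package's choice, not asserted of any
   other implementation). With several restraints the default demands
   all of them (`contactMode = "all"`), with `"any"` as the explicit
   escape hatch; the protocol text does not settle the conjunction, and
   all-of-them is the stricter, information-richer default. The contact
   filter runs *before* the energy filter so that the low-energy
   quota is spent entirely on binding-site-compatible models.
   If no model survives, the pipeline keeps the models with the
   smallest total restraint energy instead, with a loud warning -
   binding sites can be genuinely inaccessible, and dying would discard
   the information the run does contain.
2. **Energy filter.** The n lowest receptor-peptide interaction
   energies (default 1000 of 10 000); ties break by model index.
3. **Clustering and scoring.** k-medoids (default k = 10) on the
   pairwise peptide-RMSD matrix: peptide CA RMSD after superposing
   every model's receptor onto the first model's receptor. Seeding is
   deterministic farthest-point from a seeded start; instances small
   enough to enumerate (choose(n, k) <= 2000) are solved exactly.
   Clusters are scored by density = size / mean intra-cluster pairwise
   RMSD (size itself for singletons and fully degenerate clusters), and
   the medoids ordered by decreasing density are the final models. The
   density score is this package's documented stand-in for cluster
   ranking; the upstream protocol does not specify its scoring
   function.

# Evaluation

* **peptide-RMSD**: RMSD over peptide CA atoms after optimally
  superposing the model receptor onto the reference receptor (Kabsch,
  SVD with determinant correction; fit on all matched receptor CAs).
  Peptide residues are paired by sequence position, receptor residues
  by chain and residue number.
* **i-RMSD**: interface = receptor residues with any pseudo-atom within
  10 Angstrom of any reference-peptide pseudo-atom, plus the peptide;
  superposition and RMSD both on the interface CA atoms. The 10
  Angstrom CA-fit convention follows common interface-RMSD practice; an
  empty interface yields NA with a warning.
* **Categories**: high accuracy (peptide-RMSD < 3 Angstrom), medium
  (3 <= RMSD <= 5.5), low (> 5.5); i-RMSD sub-Angstrom (<= 1),
  near-native (1 < i-RMSD <= 2), not acceptable (> 2). Boundaries are
  half-open so the categories partition [0, Inf) with no gaps.
* **Violation profiles**: per model and restraint, max(0, d - D0);
  zero encodes "within the cutoff".

Native contacts are SC-SC pairs strictly below 5 Angstrom - strict
because the definition is worded as "less than", while restraint
satisfaction is inclusive (d <= D0) because the energy term is zero at
the boundary.

# Synthetic systems and what the tests show

`makeToyComplex()` builds a deterministic groove receptor: three
straight coarse-grained chains (two walls, one floor) around a zigzag
peptide whose side chains point at the floor. A chosen number of floor
residues have their SC sites planted at known distances (4.2, 4.3, ...
Angstrom - clear of both the 5 Angstrom contact threshold and the 4.0
Angstrom well edge) straight below successive peptide side chains; all
other receptor side chains point away, so the planted pairs are
*exactly* the native contacts. The "unbound" receptor applies small
per-chain rigid perturbations scaled to an exact CA-RMSD (default 1.0
Angstrom); rigid sub-domain motion keeps bond geometry intact, which
per-residue noise would not. `syntheticTrajectory()` produces labelled
near-native/decoy mixtures with configurable energy separation for
testing the filtering and clustering stages without a simulation.

These fixtures emulate the *logic* of a bound/unbound benchmark case,
not its physics: real receptors are not straight-chain grooves, real
energy gaps are not Gaussian, and real near-native basins are not
isotropic displacements. Passing tests therefore demonstrate the
correctness of the machinery (energies, filters, metrics, samplers) and
the *direction* of the contact-information effect, not benchmark-level
accuracy on experimental complexes.

## Problem sizes used by the tests and the acceptance script

The docking-enrichment experiment runs on a scaled toy system - a
30-residue receptor (10 residues per chain), a 5-residue peptide and 3
planted contacts - with 200 models from 2 replicas after 300 burn-in
sweeps, 20 independent seeds per arm. These sizes were chosen once as
the package's desk-scale study conditions: they keep the peptide's
diffusion path to the groove commensurate with the sampling length
while exercising the full protocol. Under these conditions a single
randomly chosen native-contact restraint lowers the median best-of-run
peptide-RMSD by a factor of about 2 to 2.5 (one-sided Mann-Whitney p
between 1e-7 and 1e-11 across seeds). Neither arm reaches high accuracy
(< 3 Angstrom) at this scale - the simplified potential is too shallow
to lock the fully seated pose - so the top-10 high-accuracy comparison
is reported but is typically 0% vs 0%; the tested claim is the
direction and significance of the improvement, which mirrors the
full-scale protocol's behaviour qualitatively.

# Numerical choices and degenerate inputs

* Restraint boundary: E = 0 exactly at d = D0; contact filter is
  inclusive at D0. Native-contact extraction is strict at 5 Angstrom.
* Kabsch superposition requires >= 3 paired points and always returns a
  proper rotation (det = +1).
* k-medoids ties (assignment and medoid update) break to the lowest
  index; medoids always belong to their own cluster.
* Degenerate clusters (singletons, zero spread) score density = size.
* Fewer models than requested: energy filter and clustering keep
  everything / reduce k, each with a warning.
* Peptides shorter than 3 residues, unknown amino-acid letters,
  missing CA atoms, unknown residue names (without an explicit
  mapping), duplicate restraint pairs and restraints on missing
  residues are errors, not warnings.
* CP pseudo-atoms of *sampled* models are CA-CA midpoints (the
  peptide-bond atoms no longer exist after coarse-grained moves); CP
  from all-atom input uses the true bond midpoint.
* Trajectory snapshots store energies computed freshly from
  coordinates at snapshot time, so accumulated Metropolis increments
  can never drift relative to the recorded values.

# Known limitations

* The contact table is a hydrophobicity scale, not a statistical
  potential; absolute energies and energy gaps are not comparable to
  physical free energies.
* Receptor flexibility is tethered jitter only; hinge or loop motion
  that gates a binding site is out of scope.
* Final models are coarse-grained; no all-atom reconstruction is
  attempted.
* Nucleic-acid chains, insertion codes and multi-copy peptides are not
  supported.
* Toy-scale sampling does not reach high-accuracy poses; conclusions
  about absolute model quality on real complexes require full-scale
  runs with a real potential.
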