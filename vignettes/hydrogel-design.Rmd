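---
title: "In-silico design of crosslinked PVA hydrogels for pesticide absorption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico design of crosslinked PVA hydrogels for pesticide absorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrosieve)
```

## The design problem

Dimethoate (DMT) is a widely used organophosphorus insecticide and a
water contaminant of concern. One remediation strategy is absorption
into a chemically crosslinked poly(vinyl alcohol) (PVA) hydrogel: a
hydroxyl-rich polymer network whose porosity, and hence affinity for a
guest molecule, is controlled by the choice and density of the
crosslinking agent. `hydrosieve` implements the computational arm of
that design workflow:

1. **Crosslinker screening.** A model *nanopore* — two short PVA chains
   covalently bridged by a pair of dicarboxylic-acid linkers — is
   assembled for each of 14 candidate diacids, and the affinity of each
   pore for DMT is estimated by rigid-body Monte-Carlo sampling of the
   supermolecular interaction energy. Candidates are ranked by the
   average interaction energy over eight pore topologies.
2. **Network construction.** The selected crosslinker is used to build
   a periodic, full-scale polymer matrix: chains packed into a box,
   then joined by a cyclic random-esterification algorithm at a chosen
   monomer:crosslinker composition.
3. **Trajectory observables.** Frames of a solvated hydrogel/pesticide
   system are scored for solvent-accessible surface area (SASA), radius
   of gyration (RGYR), hydration-shell water counts, DMT capture
   percentage, and hydrogel-DMT hydrogen bonds.
4. **Absorption kinetics statistics.** A two-level factorial design
   with center points characterizes experimental DMT retention as a
   function of contact time and hydrogel mass, via ordinary least
   squares with an interaction term and a standardized-effects (Pareto)
   analysis.

## Molecular model

### Structures and charges

Molecules are plain atom tables (element, coordinates, fixed partial
charge, Bondi van der Waals radius, role label) plus a bond list.
Seventeen templates ship with the package: DMT, water, a PVA monomer,
and the fourteen diacids with both carboxylates deprotonated — the
state dictated by the working pH of 5.5, since carboxylic-acid pKa
(about 4.7) lies below it and hydroxyl pKa (about 10.6) far above it.
`assign_protonation()` applies exactly this rule to arbitrary
structures and is idempotent.

Template geometries are idealized 3-D structures generated with Open
Babel; charges are Gasteiger-type values adjusted so each template sums
exactly to its formal charge. These are deliberately simple, fixed
inputs: they make every energy in the package bit-reproducible. Users
who need a different charge model can overwrite the `charge` column.

PVA chains are built on an idealized tetrahedral backbone (C–C 1.54 Å)
with one hydroxyl per monomer, each registered as a crosslink site.
Two conformations are available: the all-trans zigzag used for
nanopore walls (a 5-monomer wall spans close to the 10 Å design
length of the cavity), and a self-avoiding random coil (trans/gauche
rotamers, followed by a short steepest-descent clean-up) used when many
long chains must share a box — the realistic shape for a packing
problem that rigid rods of near-box length cannot satisfy.

### The energy model

The screen's default backend is a pairwise Lennard-Jones + Coulomb
surrogate with UFF per-element parameters and Lorentz–Berthelot
combination; the energy of an isolated molecule is zero by
construction, so the supermolecular interaction energy

$$\Delta E = E_\mathrm{complex} - (E_\mathrm{mol1} + E_\mathrm{mol2})$$

reduces to the intermolecular sum. Absolute values from this surrogate
are **not** comparable to the semi-empirical (PM7) energies behind the
published per-acid table; the package therefore ships those published
averages as reference data (`reference_interaction_energies()`) for
ranking, and treats the surrogate as a trend/ranking tool. An adapter
for an external MOPAC-style PM7 executable is provided
(`pm7_backend()`) but nothing requires it.

### Rigid-body Monte-Carlo screen

Each sample repeats five steps: center both molecules at their mass
centers; draw a rotation uniformly over SO(3) (via uniform unit
quaternions — naive uniform Euler triples are pole-biased, so the Haar
measure is the defensible reading of "random orientation"); draw a
uniform random direction; translate the rotated guest along it until
the van der Waals surfaces touch; evaluate a single-point energy at
the frozen geometry. The touching distance is solved analytically —
for every atom pair the contact condition is a quadratic in the
translation magnitude, and the contact distance is the maximum larger
root — which is exact, fast, and testable against a one-dimensional
bisection oracle.

The per-acid score is the unweighted mean of the eight per-form
ensemble means. Samples are never Boltzmann-weighted; the protocol
averages plainly, and the package follows it.

### The eight pore forms

Published sketches of such nanopores are pictorial, so the
package defines the eight forms constructively: linker attachment at
the outer (monomers 1 and 5) or inner (monomers 2 and 4) register on
each wall, crossed with parallel or antiparallel wall orientation.
This spans narrow/wide and symmetric/skewed cavities. Wall
stereochemistry presents only the register hydroxyls to the cavity;
the rest point outward. The wall separation is set by the linker's
carboxylate-to-carboxylate span plus two ester bond lengths, so longer
diacids make wider pores; when the idealized geometry still leaves a
hard-sphere clash (tilted bridges in skewed forms), the cavity is
widened in 0.3 Å steps until every non-bonded pair (1-4 and beyond)
clears 70% of the summed van der Waals radii.

## Network construction

`pack_chains()` distributes coil conformers at random rigid placements
in a periodic box, rejecting placements that bring two chains within
`min_sep` (default 5 Å) of each other under the minimum-image
convention. Near the jamming density pure rejection stalls, so chains
whose attempt budget is exhausted keep their best attempt and a
deterministic rigid-body refinement pushes offending pairs apart along
their closest-contact vector until the constraint holds — the same
end state a practical packer reaches by optimization. The resulting
625-monomer matrix (25 chains of 25 monomers in a 70 Å box) is audited
by a brute-force all-pairs distance scan in the test suite.

`build_network()` then iterates the three-step crosslinking cycle:
uniform random selection of two unused hydroxyl sites on *different*
chains within 10 Å (measured between the reactive oxygens, minimum
image); insertion of one diacid forming two ester bonds; a short local
steepest-descent relaxation. The 10:2, 10:4 and 10:6
monomer:crosslinker compositions correspond to 125, 250 and 375
bridges on 625 monomers (`composition_to_links()`). Because each
bridge consumes two hydroxyls, the 10:6 target (750 site-uses on 625
sites) saturates by construction; the builder reports saturation
honestly rather than silently under-delivering, which mirrors the fact
that a fully double-esterified 10:6 stoichiometry is not realizable on
this matrix.

Esterification bookkeeping: with the acids deprotonated, each ester
eliminates the chain hydroxyl proton and one carboxylate oxygen (a
hydroxide-equivalent leaving group) and raises the net charge by one,
so every completed bridge is exactly charge neutral. A mass-balance
test audits this convention.

The per-cycle relaxation is a steric-relief heuristic, not a physical
force field: harmonic bond terms toward reference lengths plus UFF
Lennard-Jones over non-bonded pairs, steepest descent with
backtracking, displacement capped at 0.2 Å per step, non-bonded list
frozen at entry. Angle and torsion terms are deliberately omitted —
the step's job is to remove clashes and settle the new ester bonds,
and the simpler surrogate keeps it fast and strictly monotone in
energy.

## Trajectory observables

All observables work on explicit frames (any source: the synthetic
generator, or multi-model PDB plus a JSON topology sidecar).

* **SASA** is Shrake–Rupley with a deterministic Fibonacci lattice
  (default 960 points, probe 1.4 Å), evaluated in the selection's
  principal-axis frame so the estimate is exactly invariant under
  rigid motion. Accuracy is about 1% against the isolated-sphere
  closed form and 2% against a 10,000-point lattice.
* **RGYR** is the mass-weighted RMS distance to the center of mass.
* **Water-shell occupancy** counts waters whose oxygen is within 3.0 Å
  of any hydrogel heavy atom *or* within a center-of-mass radius
  (conventionally the hydrogel's RGYR). The union is the default
  reading of the two published criteria; both cutoffs are exposed.
* **Capture** declares a pesticide molecule captured when any of its
  atoms is within 4.5 Å of any hydrogel heavy atom ("backbone" is
  interpreted as all heavy atoms — the conservative superset). The
  series is summarized by the first time 100% is reached.
* **Hydrogen bonds** use a geometric rule that reported protocols
  typically leave unstated; the package adopts VMD-like defaults: donor–acceptor
  distance at most 3.0 Å (3.5 Å for sulfur acceptors, since DMT's
  thioether sulfur is an acceptor), with at most 30° deviation from
  D–H⋯A linearity. Only hydrogel↔DMT bonds are counted.

Brute-force O(N·M) implementations of every distance criterion are
kept in the test suite as oracles.

## Synthetic data: what it does and does not show

`make_planted_trajectory()` builds frames whose capture fraction,
hydration-shell count and hydrogen-bond count are known *by
construction*: captured pesticides sit with their nearest heavy atom in
a 3.6–4.3 Å band (inside the 4.5 Å capture cutoff but above every
hydrogen-bond cutoff), free pesticides at ≥9 Å, planted hydrogen bonds
as textbook collinear O–H⋯O=C geometries at 2.8 Å, and candidate
placements that would create *unscheduled* hydrogen bonds are rejected
using the same geometric rule, checked in both donation directions.
The distance bands were chosen with safety margins on both sides of
every cutoff so floating-point noise cannot flip a count.

Passing these round-trips shows the analyzers implement their
documented criteria exactly. It does **not** show that a real
molecular-dynamics trajectory would reproduce the published capture or
hydration curves — those depend on force fields and dynamics the
package deliberately does not simulate. Synthetic frames have static
hydrogel coordinates, no thermal noise, and no water structure beyond
minimum-distance constraints.

`make_noisy_design()` generates factorial responses from known
coefficients plus Gaussian noise, which backs the estimator-recovery
and interval-coverage tests of the regression module.

## The factorial regression

The retention design is a $2^2$ factorial in contact time (10–90 min)
and hydrogel mass (34.2–101.3 mg) with three center points, fitted by
OLS as

$$y = b_0 + b_1 A + b_2 B + b_3 AB + \varepsilon$$

using the *printed coded levels verbatim* — the center points carry
small non-zero mass codes because the weighed masses deviate from the
nominal center, and only this exact coding reproduces the published
coefficients (98.6, +2.66, +2.53, −2.70) and R² of 84.35 on the
percent scale. Standardized effects are $b_i/\mathrm{SE}(b_i)$ against
the two-sided Student-t critical value with $n-4$ degrees of freedom;
on this design no effect is significant at 95%, with time and mass
positive and their interaction negative. The response surface is
evaluated on a coded grid and summarized by its grid argmax only — the
fitted corner values are nearly tied, so the package reports the
argmax without asserting a qualitative "maximum at the end of the
intervals" reading. Absorbance-based absorption percentages use
$(A_0 - A)/A_0 \times 100$ at 280 nm.

## Numerical choices and problem sizes

* Contact solving: analytic quadratic roots, 1e-6 Å tolerance at the
  returned pose.
* Rotation sampling: quaternions from four standard normals; ZYZ Euler
  angles reported for interoperability.
* Relaxation: force constant 300 kcal/mol/Å² on bonds, LJ clamp at
  0.5 Å, backtracking halving with a 20-step line-search cap.
* Ties in the crosslinker ranking break alphabetically; the sort is
  stable.
* Default Monte-Carlo sample counts are 1,000 per pore form in the
  functions and command line (the published protocol used 100,000;
  the estimator is the same and the default keeps interactive runs
  pleasant — pass `n_samples` for production runs).
* The test suite exercises the full 625-monomer matrix once (packing
  audit plus a complete 125-bridge build with relaxation capped at 3
  steps per cycle) and keeps every other fixture small (toy systems of
  2–3 chains, frames under 1,500 atoms).

## Known limitations

* The surrogate backend ranks and trends; it does not reproduce
  semi-empirical absolute interaction energies, and the published
  per-acid averages are shipped as reference data rather than
  recomputed.
* Template geometries are generated idealizations, not the original
  DFT-optimized structures (which were never published); pore widths
  therefore depend on each template's conformer.
* The crosslinking algorithm bonds both carboxylates of a bridge in
  one cycle; single-ended ("dangling") crosslinker attachment is not
  modelled, which is why over-stoichiometric compositions saturate.
* No molecular dynamics: trajectory observables analyze frames, they
  do not generate them.
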