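---
title: "Methods: hydrogen-bond patterns in pentapeptide self-assembly"
author: "pepassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen-bond patterns in pentapeptide self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepassembly)
```

## The system and the question

CREKA (Cys-Arg-Glu-Lys-Ala) is a tumor-homing pentapeptide; CRENKA is
its variant in which the glutamate backbone nitrogen carries a methyl
group instead of an amide hydrogen. That single methylation removes one
backbone hydrogen-bond donor per chain and restricts the backbone
conformation, which changes how the peptide self-assembles. This
package implements the structural-analysis half of that story: given
all-atom snapshots of multi-chain systems, it asks *which hydrogen-bond
patterns are present, and how do they depend on how the chains are
organised* — isolated, or part of an aggregate of a given size.

The molecular-dynamics engine that would produce real trajectories is
deliberately out of scope. Every input the pipeline needs is generated
synthetically by the package itself, which makes all stages testable
with known ground truth.

## Hydrogen bonds and salt bridges

A hydrogen bond is accepted when the H···O distance is strictly below
0.30 nm and the angle at the hydrogen (N–H···O) strictly above 120.0°.
Both inequalities are strict, and the angle vertex is at the hydrogen.
Donors are the backbone amide N–H groups (residues 2–5; the methylated
nitrogen of CRENKA has no hydrogen and can never donate), the
N-terminal ammonium, the arginine guanidinium (five N–H) and the
lysine ammonium (three N–H). Acceptors are every backbone carbonyl
oxygen, both C-terminal carboxylate oxygens and both Glu/MEG side-chain
carboxylate oxygens. The cysteine thiol is excluded on both sides by
default (the criterion names N–H donors and O acceptors); it can be
enabled through `interaction_config()`. Pairs inside one amide unit
(the C=O of residue *i* with the N–H of residue *i*+1) are never
counted: at a trans peptide bond they sit near 0.3 nm by construction
without being a bond.

Distinct atoms matter here: the C-terminal residue contributes exactly
two oxygens (O and OXT), so a CREKA chain at the pH-7 protonation state
has 8 acceptor atoms (4 amide carbonyls, 2 terminal, 2 side-chain), and
15 donor hydrogens.

Detection runs either over all donor–acceptor pairs or through a cell
list with cells of one cutoff width; the two paths return identical
bond sets and are cross-checked against each other in the tests. Salt
bridges are charged-nitrogen/carboxylate-oxygen pairs below 0.40 nm
(heavy atoms), a common literature convention — the cutoff is a
package choice, configurable.

## Aggregates and the seven-way classification

Two chains are in contact when they share an intermolecular hydrogen
bond or salt bridge, or any heavy-atom pair below 0.45 nm. Aggregates
are connected components of the contact graph; a chain with no contact
is an aggregate of size 1 — a free chain. The 0.45 nm heavy-atom
criterion is our choice: it makes "aggregate" a superset of
bond-linked clusters, so salt-bridge-only assemblies still count.

Every detected bond falls into exactly one of seven categories:

* intramolecular, main chain: **β-turn** (donor residue = acceptor
  residue + 3), **γ-turn** (+2), **other intramolecular** (anything
  else);
* intramolecular with a side-chain or terminal group: **intra side**;
* intermolecular, main chain: **β-sheet** when both partner residues
  are in β-strand conformation, otherwise **M–M**;
* intermolecular with a side-chain or terminal group: **inter side**.

Terminal ammonium and carboxylate groups are *not* amide groups, so
bonds involving them are classified with the side-chain categories.

Residue conformations come from a Ramachandran-box assignment on
(φ, ψ): β-strand for φ ∈ [−180, −90]°, ψ ∈ [90, 180]° ∪ [−180, −170]°;
turn/helical for φ ∈ [−120, −30]°, ψ ∈ [−80, 30]°; anything else is
"other". These boundaries are conventional choices, configurable via
`conformation_regions()`; nothing in the analysis pins them down more
precisely. Terminal residues have only one defined dihedral and would
be unclassifiable, so they inherit the label of the adjacent interior
residue — the β-sheet category describes *chains* in strand
conformation, and an ideal strand should be β along its full length,
including the backbone bonds donated by residue 5.

Per-bond attribution uses the donor chain's aggregate size (donor and
acceptor are in the same aggregate by construction for intermolecular
bonds). Statistics over a trajectory pool raw counts over frames and
normalise per size bin at the end; pooling counts rather than averaging
percentages keeps frames with few bonds from dominating. A
last-frame-only mode mirrors single-snapshot analyses.

Sheet orientation for a bonded strand pair is the sign of the dot
product of the two Cα(1)→Cα(5) end-to-end vectors: positive parallel,
negative antiparallel.

## Synthetic systems

All fixtures are built from ideal internal coordinates (N–Cα 0.1458 nm,
Cα–C 0.1525 nm, C–N 0.1329 nm, ω = 180°, polar hydrogens only; the
side-chain Cβ improper is +123°, the L-configuration). Backbone
dihedral presets are textbook values — antiparallel strand
(−139, +135), parallel strand (−119, +113), type-I β-turn interior
(−60, −30)/(−90, 0), γ-turn (+75, −65) — none of them fitted to
anything, all exposed as configuration.

* `build_chain()` realises requested (φ, ψ) exactly at zero noise.
* `build_sheet_pair()` docks a second ideal strand by rigid-body
  Nelder–Mead refinement against the canonical hydrogen-bond register
  of the requested orientation (for the antiparallel 6−*i* register,
  the alternating rungs (3,3) and (5,1); for parallel, alternating
  rungs with the donor strand switching along the ladder), with an
  angle reward and a soft steric penalty. A CREKA pair realises 4
  inter-main-chain bonds; the CRENKA twin, lacking the residue-3
  donors, at most 2 — the methylation effect by construction.
* `build_turn_chain()` starts at the turn presets and refines the free
  backbone dihedrals until the defining i→i+3 or i→i+2 bond satisfies
  the detection criteria.
* `build_salt_bridge_dimer()` docks two turn chains so that an
  Arg···carboxylate contact forms while all backbone H···O pairs stay
  beyond 0.40 nm.
* `build_minimum_bias_box()` rejection-samples random rotations and
  positions until all chain centres are ≥ 1.8 nm apart (and no
  heavy-atom pair below 0.5 nm) inside a 9.5 × 8.5 × 9.0 nm box with
  15 chains — the "minimum-bias" starting condition in which chains
  are essentially non-interacting. With a hard 1.8 nm floor in this
  box, the mean nearest-neighbour spacing comes out near 2 nm.
* The noise model is an isotropic, seeded Gaussian per atom
  (`perturb_frame()`); every builder is bitwise deterministic for a
  fixed seed.

What the generator does **not** emulate: solvent and ions (counterions
are bookkeeping only), force-field energetics, thermal ensembles, and
the conformational heterogeneity of a real trajectory. Passing tests
on these fixtures therefore validate the *analysis* — detection,
classification, stratification — not any claim about what real CREKA
ensembles contain.

## Charges and counterions

With pKa values Glu 4.2, Arg 12.5, Lys 10.5, N-terminus ≈ 8 and
C-terminus ≈ 3, and the rule "protonated iff pH < pKa" (ties resolve
deprotonated), the dominant-state net charge of either peptide is +2
at pH 4, +1 at pH 7 and 0 at pH 10 — so fifteen chains at neutral pH
need fifteen chloride counterions, one per strand. The cysteine thiol
(pKa ≈ 8.3) is treated as non-titrating by default because the
+2/+1/0 ladder across pH 4–10 ignores it; `default_sites(include_cys
= TRUE)` enables it. `fractional_charge()` is the smooth
Henderson–Hasselbalch companion, useful for checking that the step
function is its |pH − pKa| → ∞ limit.

## The dendrite model

The two-step mechanism — fractal pre-nucleation by diffusion-limited
aggregation, then coalescence of the pre-nucleated scaffold by surface
deposition — is embodied as a deliberately simple 2-D lattice model:
classic DLA (walkers from a launch circle at cluster radius + 5, kill
radius 3×, 4-neighbour sticking with probability 1 by default),
followed by deposition into concave perimeter sites (≥ 2 occupied
neighbours), which provably never increases the perimeter-to-area
ratio. It is an illustrative embodiment of a qualitative mechanism:
lattice particles are not peptide molecules, and no quantitative
morphology claim is attached.

The box-counting dimension estimator fits log occupied-box count
against log(1/size) over dyadic box sizes from 2 up to a quarter of
the cluster extent, requiring at least four scales; it is exact on the
analytic anchors (filled square → 2, straight line → 1). A caveat the
tests document honestly: on desk-scale DLA clusters (5 000 particles)
plain box counting reads ≈ 1.5 rather than the asymptotic ≈ 1.71,
because the one-site-wide branches make small-scale box counts scale
like branch *length*. The bias shrinks only slowly with cluster size
(≈ 1.53 at 20 000 particles). The complementary `mass_radius_dimension()`
estimator, much less sensitive to branch width, reads ≈ 1.6–1.67 on
the same clusters. Both estimators are exported; neither was tuned to
any target.

## Numerical choices and degenerate inputs

* Internal unit is nm everywhere; PDB I/O converts to/from ångström,
  so file round-trips are exact to the 10⁻³ Å column precision.
* Strict inequalities at both bond criteria, exactly as stated; a pair
  at d = 0.30 nm or 120.0° is not a bond.
* `read_structure()` reports unparsable records with their line
  number; with `strict_h = FALSE` missing amide hydrogens are rebuilt
  in the amide plane from the C(i−1), N, Cα geometry instead of
  erroring.
* Docking and turn refinement are Nelder–Mead with multiple
  deterministic starts; no RNG is consumed, so the builders only use
  their seed for coordinate noise and placement.
* Empty frames, bond-free frames and zero-fill calls are identities or
  typed empties, never errors; percentage tables skip unpopulated size
  bins rather than dividing by zero.
* Problem sizes in the test-suite: contact frames of 2–15 chains
  (≤ ~900 atoms), 50-frame oracle-equivalence sweeps, 100-case
  normalisation property, DLA clusters of 1 500–5 000 sites — all
  chosen as the package's own desk-scale defaults.

## Known limitations

Only the two registered pentapeptides are supported (further sequences
can be registered, but nothing beyond them is tested). No periodic
wrap is applied by default — synthetic fixtures are whole molecules —
though a minimum-image option exists for boxed frames. The classifier
assumes protonation states are encoded in the topology (presence of
HE2/H1–H3/OXT), not computed from pH; the charge module is the
pH-aware component. Aggregate-size statistics from a handful of
synthetic frames say nothing about equilibrium populations of real
peptide solutions.
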