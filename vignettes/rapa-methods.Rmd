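---
title: "Methods: hydrogen-bond-driven rotamer and protonation assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen-bond-driven rotamer and protonation assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapa)
```

## The model

`rapa` treats side-chain ambiguity resolution as a discrete
combinatorial assignment problem scored purely by local polar
interactions. The working assumptions are:

* **Locality.** Whether a rotamer/protonation (RP) state is viable is
  decided by its hydrogen bonds and clashes with *proximal* partners —
  polar heavy atoms within 3.8 Å. There is no long-range
  electrostatics, no solvation term, and no pKa model; a residue with
  no proximal polar partner is assumed solvent-exposed and keeps its
  input state.
* **Geometry proxy.** A hydrogen bond is scored by two coordinates
  only: the heavy-atom distance d and the donor-heavy–H–acceptor-heavy
  angle θ, read from a precomputed table on the grid
  d ∈ [2.5, 4.0] Å (0.1 Å) × θ ∈ [90°, 180°] (0.1°). The donor
  hydrogen used for θ is the candidate position closest to the
  acceptor heavy atom.
* **Clash inversion.** Two facing donors or two facing acceptors are
  penalized by exactly the *negative* of the h-bond energy at the same
  geometry. This single symmetry makes the right-side-up and flipped
  amide orientations differ by swapping h-bonds for clashes, which is
  what gives the method its discriminating power.
* **Energetic degeneracy.** States within a cutoff (default
  1 kcal/mol) of the local minimum are indistinguishable at the
  accuracy of this model and are *all* retained, by branching the
  structure.

## The energy table

The shipped table is an analytic stand-in for a quantum-mechanical
water-dimer potential-energy surface, factorized as
E(d, θ) = D · f(d) · g(θ) with

* f(d) = 1 − (1 − e^{−a(d − d₀)})², a Morse-type well equal to 1 at
  d₀ = 2.8 Å (the canonical water-dimer O–O distance) with steepness
  a = 1.8 Å⁻¹;
* g(θ) = cos²(180° − θ), rising smoothly from 0 at 90° to 1 at
  linearity;
* D = −5.0 kcal/mol, a typical water-dimer binding energy, so the
  global minimum is exactly D at (2.8 Å, 180°).

On the tabulated grid f stays positive, so every entry is ≤ 0 and each
row is monotonically non-increasing toward 180°; short-range repulsion
is not modelled radially (the clash inversion is the repulsive
mechanism). Absolute energies from this surrogate are not comparable
with a QM-derived table — only energy *differences* between states of
the same residue matter, and those are dominated by the
h-bond-versus-clash swap, which is robust to the radial form. Users
with their own surface can serialize it in the documented TSV format
(`write_energy_table()` / `read_energy_table()`; round trips are
bit-exact) and pass it to `rapa_run(table = ...)`.

Lookups use the *nearest grid point*, not interpolation: the table is
a lookup table, and at 0.1 Å / 0.1° resolution the discretization
error is orders of magnitude below the 1 kcal/mol cutoff. Out-of-range
queries are defined as: d > 4.0 Å or θ < 90° → 0 (no interaction);
d < 2.5 Å → clamped to the 2.5 Å row.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 1.0 | kcal/mol | degeneracy window; states within it of the minimum are all kept. Larger values are more conservative (more configurations). |
| `proximal` | 3.8 | Å | heavy-atom distance defining which polar sites interact and which residues are neighbors |
| `disulfide` | 2.3 | Å | SG–SG distance below which a CYS pair is bridged and deprotonated |
| well depth `D` | −5.0 | kcal/mol | table minimum; rescales all energies and hence the effective meaning of `cutoff` |
| `max_branches` | 4096 | — | resource cap on explored configurations; exceeding it is an explicit error naming the residues still ambiguous |
| `max_environments` | 10⁶ | — | cap on the neighbor-state product evaluated per residue |

The degeneracy test is *inclusive* (≤ cutoff), so an exact tie always
branches; "uniquely favorable" in the resolution step uses the same
cutoff (every alternative must be more than `cutoff` above the best
state), which keeps the fixing and branching criteria mutually
consistent — a residue is either uniquely resolvable or degenerate,
never neither.

## The workflow

1. **Initialization.** Backbone amide N (donor; proline excepted, as
   it has no amide hydrogen) and carbonyl O (acceptor) are typed for
   every residue. TRP (NE1 donor), LYS (charged NZ), ARG (NE/NH1/NH2)
   and CYS (thiol donor, or deprotonated and siteless when disulfide-
   bridged) are known immediately. HIS, ASN, GLN, SER, THR and TYR
   start ambiguous. ASP/GLU are known-deprotonated unless their
   carboxylates sit within 3.8 Å of another ASP/GLU's, in which case
   the pair forms an *acid dyad* — a single ambiguous unit enumerating
   the four singly-protonated states plus the deprotonated reference,
   which guarantees at most one proton across the four oxygens.
2. **Evaluation passes.** Ambiguous residues are visited in chain/
   sequence order. Each residue's states are scored by their best-case
   environment: the minimum, over the Cartesian product of proximal
   ambiguous neighbors' state lists, of the summed pairwise energies
   incident to the residue (known neighbors contribute their fixed
   state). A residue fixed mid-pass is immediately visible to later
   residues in the same pass.
3. **Branching.** When a full pass fixes nothing, the first ambiguous
   residue in sequence order branches: one child per within-cutoff
   state, explored depth-first with the lowest-energy child first, so
   outputs arrive in a natural priority order.
4. **Termination.** Fully-known branches are emitted; duplicates from
   reconverging branches are removed by exact assignment equality.
   Termination is guaranteed: every level either fixes at least one
   residue or branches while fixing one, so recursion depth is bounded
   by the number of ambiguous residues and the output count by the
   product of per-residue state counts.

## Design choices where the design was open

* **Flips are rigid rotations, not name swaps.** The amide (ASN chi2 /
  GLN chi3) and imidazole flips rotate the terminal group 180° about
  the preceding bond axis. On distorted experimental geometry this
  preserves the non-ideal bond lengths and angles, which is what
  "flipping the fitted model" means; a name swap would silently
  idealize the geometry. Flips are exact involutions (to < 1e-9 Å).
* **Hydroxyl directionality does not branch.** The SER/THR hydroxyl
  enumerates one state carrying nine hydrogen candidates (the three
  staggered sp3 positions ± 20°, measured as the H–O–C–C(antecedent)
  dihedral with CA as antecedent, O–H 0.96 Å, C–O–H 109.5°); TYR
  carries two in-plane sp2 candidates (C–O–H 120°). The donor-versus-
  acceptor role of an "either" site is resolved *per interaction* by
  taking the most favorable feasible role assignment, and the written
  hydrogen is the candidate closest to the nearest proximal acceptor.
  Configuration multiplicity is therefore driven by ASN/GLN/HIS and
  dyads; a hydroxyl can make a partner degenerate but never spawns
  branches itself. The cost of this choice is that a hydroxyl serving
  two partners is scored per-pair (its single proton could not really
  satisfy both simultaneously); the alternative — branching on nine
  directions per hydroxyl — would explode the output count with
  distinctions far below the model's accuracy.
* **Acceptor–acceptor clash angle.** No carrier hydrogen exists
  between two acceptors, so the clash is evaluated at the heavy-atom
  distance with θ = 180°, the maximally penalizing column. Two donors
  use each donor's best hydrogen geometry and keep the more
  unfavorable of the two.
* **HIP carries no charge prior.** The doubly-protonated tautomer is
  enumerated on equal footing; no pKa-based correction biases against
  it, and charged donors (LYS/ARG/HIP) use the same neutral table
  unscaled.
* **Dyad hydrogen orientation.** The proton on a dyad oxygen is placed
  in its carboxylate plane pointing toward the partner's nearest
  oxygen — the orientation that can actually realize the inter-acid
  hydrogen bond being tested.
* **Fully-solvated HIS keeps its input tautomer** when the input names
  one (HID/HIE/HIP); a plain HIS defaults to HIE, the common neutral
  default in force fields.
* **Alternate locations** keep the highest-occupancy copy (ties go to
  'A'); insertion codes are preserved in residue ordering. Input
  hydrogens are never trusted: polar hydrogens are re-placed at
  idealized geometry (N–H 1.01 Å, O–H 0.96 Å, S–H 1.34 Å), so results
  do not depend on upstream preparation.
* **Flip-aware adjacency.** The neighbor graph is built from input
  coordinates, but a HIS flip moves its ring nitrogens by ~2 Å, so
  residue adjacency additionally considers the flipped ring-N
  positions; otherwise an interaction reachable only in the flipped
  rotamer could be silently missed.

## What the synthetic fixtures emulate — and what they do not

The generator builds minimal idealized motifs: an amide facing a
hydroxyl, two facing amides, a HIS ring between donor/acceptor probes,
an acid dyad, a disulfide pair, isolated residues, and k-fold
replicated copies ≥ 15 Å apart. Their key construction is *exact
symmetry*: each motif places the flip axis and all partner polar atoms
so that a single mirror isometry maps every residue onto its own
flipped state, making flip-related state pairs degenerate to machine
precision — the sharpest possible probe of the branching logic, since
any bookkeeping asymmetry would break an exact tie. A `perturb`
parameter tilts the partner continuously, driving the state gap across
the cutoff (the two-configuration output collapses to one), and seeded
jitter (≤ 0.05 Å) probes robustness of the nearest-grid lookup.

What passing these tests does *not* show: behavior on real, crowded
protein interiors (many-body networks, bifurcated h-bonds, waters and
ligands — which are stripped on input), sensitivity to the surrogate
radial form, or agreement with experimental pKa/tautomer assignments.
The fixtures validate the *machinery* — enumeration, scoring
symmetries, propagation, branching, termination, I/O — not the
chemistry of any particular protein.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run motifs of 1–8 residues
(up to k = 4 independent copies, 16 output configurations), 100 seeded
jitter replicates for the involution/round-trip properties, and
full-grid scans of the 16 × 901 energy table — sizes chosen so the
whole suite exercises every branch of the protocol in about a minute.
Exact ties are compared at 1e-9 Å (flip involution), PDB text I/O at
1e-3 Å (the format carries three decimals), and degeneracy ties use a
1e-9 kcal/mol tolerance so that floating-point noise cannot turn an
exact tie into a spurious resolution.

## Known limitations

* No solvation, long-range electrostatics, or pKa shifts; buried
  charged states (notably HIP) are judged only by local h-bonds.
* ASP/GLU outside dyads are fixed deprotonated; protonated internal
  acids are out of reach unless re-opened by the user.
* The hydroxyl single-proton constraint is enforced per interaction,
  not globally (see above).
* N/C-terminal protonation, metal coordination, nucleic acids, mmCIF
  and multi-model inputs are out of scope; waters and ligands are
  removed before analysis, so a residue coordinated only by a ligand
  is treated as solvated.
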