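# rapa

Rotamer and protonation assignment for protein structures from
hydrogen-bond network energetics.

## The problem

X-ray electron density at typical resolutions cannot distinguish the
terminal oxygen and nitrogen of the ASN/GLN amide, so the deposited
side chain may be flipped 180° about its last chi angle. Histidine is
worse: the imidazole ring can be flipped *and* carries an ambiguous
protonation state — HID (Nδ-protonated), HIE (Nε-protonated) or HIP
(both, +1). Hydroxyls (SER/THR/TYR) can donate or accept a hydrogen
bond depending on an invisible proton, proximal ASP/GLU pairs can share
a proton (acid dyad), and CYS may or may not be disulfide-bonded.
Downstream modelling — docking, molecular dynamics, free-energy
calculations — needs all of these resolved, and a single "best guess"
structure hides genuinely ambiguous cases.

`rapa` resolves these ambiguities from local hydrogen-bond energetics
and, crucially, keeps *every* assignment that the structure cannot
discriminate, returning one output structure per energetically viable
configuration.

## The method

Each polar heavy atom is typed as donor, acceptor, or either. Two sites
interact when their heavy atoms are **proximal** (≤ 3.8 Å). A
donor–acceptor contact scores as a hydrogen bond via a lookup table
E(d, θ) over heavy-atom distance d (2.5–4.0 Å, 0.1 Å steps) and
donor-heavy–H–acceptor-heavy angle θ (90–180°, 0.1° steps); two facing
donors or two facing acceptors score as an electrostatic **clash**,
the exact negative of the h-bond energy at the same geometry. The
shipped table is an analytic water-dimer-like surface
E(d, θ) = D·f(d)·g(θ) with a Morse radial well (minimum D = −5 kcal/mol
at 2.8 Å) and g(θ) = cos²(180° − θ); a user-supplied table in the same
TSV format can replace it.

Ambiguous residues enumerate their rotamer/protonation (RP) states —
6 for HIS, 2 for ASN/GLN, 9 hydroxyl-hydrogen candidates for SER/THR,
2 for TYR, 4+1 protonation states per acid dyad — and the protocol
iterates:

1. score every state of each ambiguous residue against *all* state
   combinations of its proximal neighbors, keeping each state's
   best-case environment energy;
2. fix any residue whose best state beats every alternative by more
   than the degeneracy cutoff (default 1 kcal/mol);
3. when no residue can be fixed, **branch**: the first degenerate
   residue spawns one copy of the system per within-cutoff state,
   each processed recursively;
4. terminate when all residues are known; deduplicate reconverged
   branches.

Each ASN/GLN/HIS is labeled `fixed` (one viable state),
`degenerate` (several), or `fully_solvated` (no protein h-bond; keeps
its input state).

## Worked example

Two facing asparagine amides whose flip axes are collinear — a motif
where the two self-consistent pairings are exactly degenerate:

```r
library(rapa)
s <- read_structure(make_fixture("asn_asn", distance = 2.9))
s
#> rapa_structure: 2 residues, 16 heavy atoms, 0 hydrogens
#>   composition: ASN:2

r <- rapa_run(s, cutoff = 1.0)
r
#> rapa_result: 2 configuration(s), cutoff 1 kcal/mol
#>   labels: degenerate:2

r$report
#>   chain resno resname      label n_states_within_cutoff best_energy runner_up_gap
#> 1     A     1     ASN degenerate                      2   -6.925963       0.00000
#> 2     A     2     ASN degenerate                      1   -6.925963      15.03561
```

The first ASN sees two states at identical best-case energy
(−6.93 kcal/mol, gap 0.00 < 1 kcal/mol), so the run branches on it;
in each branch the partner then resolves uniquely (gap 15.0 kcal/mol:
the mismatched pairing would replace two hydrogen bonds with two
clashes). The two surviving configurations are the self-consistent
pairings:

```r
vapply(r$configurations, function(cf) cf$signature, character(1))
#> [1] "ASN:rot0;ASN:rot0" "ASN:rot1;ASN:rot1"

write_rapa_result(r, "out", "pair")   # pair_rapa_0.pdb, pair_rapa_1.pdb,
                                      # label report TSV, summary JSON
```

The same pipeline is scriptable from a shell via the installed `rapa`
executable (`rapa run input.pdb -o out/`, `rapa fixtures --kind asn_ser
--out f.pdb`, `rapa table --out table.tsv`).

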