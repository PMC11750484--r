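---
title: "Generating polyurethane fragment libraries and classifying catalytic poses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating polyurethane fragment libraries and classifying catalytic poses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Polyurethane (PUR) polymers are networks of isocyanate- and
alcohol-derived units joined by urethane (carbamate) bonds. Enzymatic
PUR degradation studies need small-molecule stand-ins for the polymer:
oligomeric fragments short enough to dock and simulate, but built from
the same comonomer chemistry. `purfrag` generates such fragments
combinatorially, profiles them, and scores docked fragment poses
against the catalytic geometry of serine hydrolases.

This vignette records the model, the tunable parameters, and the design
decisions that were genuinely open.

## Chain chemistry

A monomer is validated by detecting its reactive groups on the
molecular graph:

* isocyanate site: an N=C=O unit — a carbon with exactly two double
  bonds, one to N, one to O;
* hydroxyl site: an oxygen with a single bond to one sp³ carbon and an
  implicit hydrogen. Hydroxyls on carbonyl carbons (carboxylic and
  carbamic acids) and on unsaturated or aromatic carbons (enols,
  phenols) are not accepted as reactive alcohol sites. Phenols are a
  genuinely open case — the default building blocks contain none, and
  we exclude them so that only aliphatic polyol chemistry enters the
  chain; users wanting phenolic monomers would need to relax
  `find_hydroxyl_sites()`.

Monomers with more than two reactive groups are rejected from
enumeration: crosslinking chemistry produces branched networks rather
than the linear chain fragments this package models.

The urethane coupling is the formal addition R–N=C=O + HO–R′ →
R–NH–C(=O)–O–R′. On the implicit-hydrogen graph this is exactly two
edits (N=C becomes N–C; a new O–C bond), so no atoms are created or
destroyed and the product mass is the sum of the reactant masses by
construction — a property the test suite asserts to 1e-4 u.

### Topologies

Chain lengths are counted in comonomer units:

| code | units | composition | requires |
|------|-------|-------------|----------|
| IA   | 2 | one isocyanate + one alcohol | — |
| IAI  | 3 | two copies of the isocyanate around a diol | difunctional alcohol |
| AIA  | 3 | two alcohol copies around a diisocyanate | difunctional isocyanate |
| IAIA | 4 | alternating I–A–I–A | both difunctional |

One product is generated per (isocyanate, alcohol, topology)
combination. For asymmetric diisocyanates (2,4-TDI, 2,4′-MDI) the two
N=C=O groups are chemically distinct, so a regiochemistry choice is
unavoidable; we react sites deterministically in lowest-atom-index
order of the input graph. Enumerating both regioisomers would inflate
the library beyond the closed-form count

$$N=n_i n_a + n_i n_{a2} + n_{i2} n_a + n_{i2} n_{a2}$$

(summed over requested lengths), which `count_expected()` exposes as a
counting oracle and which the default set satisfies: 160 + 198 + 56 =
414 fragments.

### Capping

Residual N=C=O groups are replaced after chain assembly by one of three
neutral end groups, chosen to avoid the artificial charge build-up a
truncated polymer chain would otherwise show in docking:

* amine (–NH₂): per-site ΔMW −25.99 u,
* methyl (–CH₃): −26.98 u,
* carbamic acid (–NH–C(=O)OH): +18.02 u (formal water addition).

Capping is idempotent and a no-op on molecules without free isocyanate
groups. Terminal hydroxyls are left as-is. The default cap is amine,
matching common practice for preparing such fragments for docking.
Fragment ids (`dimer_N` / `trimer_N` / `tetramer_N`) are stable given
the input order — numbered over (isocyanate order, alcohol order,
topology IAI-before-AIA) — but are not meaningful across different
building-block sets.

## Default building blocks

The ten default isocyanates are the industrially dominant ones: methyl
and benzyl isocyanate (monofunctional), three MDI and two TDI isomers,
HDI, IPDI and HMDI (difunctional). Stereocentres in IPDI/HMDI are left
unspecified — the library is enumerated at the constitutional level.

The sixteen default alcohols (9 mono-, 7 difunctional, all aliphatic,
with ether- and ester-containing members emulating polyether and
polyester polyols) are this package's own composition: they satisfy the
documented functionality split and include methanol, 1,4-butanediol and
isopentyl 2-hydroxypropanoate. Statistics that depend only on
functionality and aromaticity (library size, unit-length shares,
aromatic-ring shares, size minima) are therefore reproducible exactly;
statistics that depend on the precise alcohol identities (ester/ether
shares, the upper end of the cLogP and MW ranges) are
alcohol-set-specific and are documented as such, not asserted.

## Descriptors

* **MW, TPSA**: OpenBabel (Ertl fragment contributions for TPSA).
* **cLogP, MR**: the Wildman–Crippen atom-contribution scheme,
  implemented in this package from the published atom classes and
  parameters (typing cascade in first-match order; implicit hydrogens
  contribute through the H classes). The test suite cross-checks
  against RDKit — an independent implementation of the same scheme —
  to within 0.01 on a benchmark set.
* **Aromaticity**: perceived once per molecule by OpenBabel (SYBYL
  typing); the aromatic-ring counter counts six-membered aromatic
  carbocycles, which covers all default building blocks.
* **Rotatable bonds**: non-ring single bonds between two non-terminal
  heavy atoms, excluding amide/carbamate C–N bonds. Note that RDKit's
  "strict" variant additionally excludes ester C(=O)–O single bonds, so
  rotatable-bond counts are deliberately not RDKit-identical.
* **Ester/ether flags**: the urethane motif N–C(=O)–O is excluded from
  both. Ester requires a carbon (not nitrogen) on the carbonyl;
  ether requires both oxygen neighbours to be non-carbonyl carbons.
  The flags are booleans ("presence of"), not counts.

## Conformers

`generate_conformers()` embeds a rule-based 3D structure (`obabel
--gen3d`), then runs Confab's systematic torsion search, testing up to
`max_n` conformations (default 20) and keeping those within
`energy_window` (default 50 kcal/mol) of the best found and pairwise
separated by at least `rmsd_cutoff` (default 0.5 Å) heavy-atom RMSD —
the cited method's defaults. Both steps are deterministic (rule-based
builder, exhaustive grid), so no random seed is exposed. Energies are
MMFF94 single points via `obenergy` and may be `NA` if the tool is
absent. Molecules with more than `rotor_limit` rotatable bonds
(default 15) skip the systematic search — the torsion grid grows
exponentially — and return the single embedded conformer, which is why
large tetramers may legitimately yield one conformer.

## Pose classification

A docked pose is a *near-attack configuration* (productive) when

1. d(Ser Oγ, carbonyl C of the nearest cleavable bond) ≤ t,
2. d(oxyanion probe 1, carbonyl O of that bond) ≤ t, and
3. d(oxyanion probe 2, carbonyl O) ≤ t,

with t = 4.5 Å by default and all comparisons inclusive. Cleavable
bonds are urethanes (N–C(=O)–O–C) and esters (C–C(=O)–O–C, carbonyl
carbon not bonded to N); the *nearest* bond is chosen by criterion 1
alone, which the tests verify against a brute-force minimum. "All
three distances" must pass — one bad oxyanion contact disqualifies a
pose. The serine oxygen is the side-chain O named in the site
specification (Oγ for serine); whether to admit other serine oxygens
was an open point and we fix the side-chain atom, which is the
nucleophile.

The oxyanion probes are the backbone amide NH groups. Depending on
receptor preparation the amide hydrogens may or may not be present, so
the probe is selectable: `H` (amide hydrogen), `N` (backbone nitrogen)
or `auto` (H when both oxyanion residues carry one, else N). The two
modes genuinely differ by ~1 Å of geometry and the chosen probe is
recorded in every classification row.

PDBQT pose files carry no bond orders, so ligand chemistry for such
poses is taken from the matching generated fragment (by id) rather than
re-perceived from coordinates; the heavy-atom element sequence must
match, which is validated. Poses with no cleavable bond — impossible
for PUR fragments but possible for arbitrary ligands — classify as
non-productive with a `"none"` bond tag rather than erroring.

Aggregation (`summarize_poses()`) reports the productive percentage
overall and per isocyanate class (MDI and TDI isomers are pooled, as is
conventional), and, among productive poses of ligands carrying both
bond kinds, the share whose attacked bond is the urethane.

## Synthetic fixtures

`make_site_fixture()` builds a minimal receptor (one serine with Oγ,
two oxyanion residues with backbone N/H in standard PDB naming) and a
one-urethane ligand posed so that the three NAC distances equal the
requested values exactly; files are also written (PDB, MOL2) so tests
exercise the real parsers. The geometry is a scaffold, not a protein
model: it realizes distances, not sterics, so passing tests demonstrate
the classifier's geometry handling, not docking realism.
`make_monomer_set()` generates random aliphatic monomer sets with an
exact functionality split, reproducibly per seed, for property-style
tests of the enumeration count law.

What the fixtures deliberately do not emulate: receptor flexibility,
protonation equilibria, docking pose diversity, and the scale of a real
docking campaign (tens of thousands of poses). Statements about real
enzymes require real docking runs, which are out of scope.

## Numerical choices and problem sizes

* Percentages round half away from zero to integer percent; with this
  rule the default library's unit-length shares are 39 % and 48 %
  (the 4-unit share, 56/414 = 13.5 %, rounds to 14 and is therefore
  reported as a count).
* Distance comparisons are inclusive (≤); nearest-bond ties break to
  the first bond in atom-index order.
* Masses use average atomic weights; mass-conservation checks use
  1e-4 u, capping-delta checks 1e-2 u (two printed decimals).
* The test suite runs the full 414-fragment enumeration (seconds), a
  100-configuration enumeration-vs-closed-form sweep, and
  conformer/pose checks on molecules of 3–25 heavy atoms — all sized
  so the whole suite completes in well under a minute.

## Known limitations

* Charged species, tautomers, salts and stereochemistry are out of
  scope; the library is constitutional.
* The aromatic-ring counter recognizes six-membered aromatic
  carbocycles only.
* Crippen parameters cover neutral C/H/N/O/halogen/S/P chemistry; exotic
  elements fall back to the published generic classes.
* MOL2/PDBQT reading is geometry-oriented: partial charges and docking
  metadata are ignored.
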