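# purfrag

Polyurethanes (PUR) are among the few mass-produced plastics with a
realistic path to enzymatic recycling: serine hydrolases (cutinases,
urethanases) can attack the carbamate and ester linkages of the polymer
backbone. Studying those interactions *in silico* needs ligands that look
like polymer chains — short PUR oligomer fragments — in bulk, with
consistent chemistry, descriptors and 3D structures. Building such
libraries by hand does not scale.

`purfrag` is an R package for people doing exactly that: it generates
combinatorial PUR fragment libraries from isocyanate and alcohol
building blocks, profiles them, writes structure files ready for docking
pipelines, and post-processes docked poses with a catalytic-geometry
classifier.

## What it computes

**Library generation.** The urethane (carbamate) bond is formed
explicitly as the addition of an alcohol O–H across an isocyanate
N=C=O group:

    R–N=C=O + HO–R′  →  R–NH–C(=O)–O–R′

Fragments of 2, 3 and 4 comonomer units are enumerated under
functionality-driven topology rules (a middle unit must be
difunctional; 4-unit chains alternate I–A–I–A and need both monomers
difunctional). One product is generated per (isocyanate, alcohol,
topology) combination, so the library size has the closed form

    N = nᵢ·nₐ + nᵢ·nₐ₂ + nᵢ₂·nₐ + nᵢ₂·nₐ₂

summed over the requested lengths (subscript 2 marks difunctional
counts). Residual N=C=O groups are capped with amine (–NH₂), methyl
(–CH₃) or carbamic acid (–NH–C(=O)OH) end groups.

**Descriptors.** Per fragment: molecular weight, heavy atoms, rotatable
bonds, ester/ether presence (the urethane motif is excluded from both),
aromatic atom count and proportion, Wildman–Crippen cLogP and molar
refraction (authored implementation of the published atom-contribution
scheme, cross-checked against RDKit), and Ertl TPSA.

**Conformers.** Up to *n* diverse conformers per fragment by systematic
torsion driving (Confab, via OpenBabel) with an RMSD-diversity cutoff
and an energy window; rotor-rich fragments fall back to a single
embedded conformer.

**Pose analysis.** For docked poses against a serine hydrolase, a pose
is classified *productive* (a near-attack configuration, NAC) when the
catalytic serine oxygen lies within a threshold (default 4.5 Å) of the
carbonyl carbon of the nearest cleavable bond (urethane or ester), and
both oxyanion-hole backbone NH probes lie within the threshold of that
bond's carbonyl oxygen.

## Worked example

```r
library(purfrag)

lib <- enumerate_library(default_isocyanates(), default_alcohols())
lib
#> <pur_library> 414 fragments (cap: amine)
#> units
#>   2   3   4
#> 160 198  56

tab <- property_table(lib)
head(tab[, c("id", "smiles", "units", "isocyanate", "alcohol",
             "mw", "heavy_atoms", "clogp", "tpsa")], 4)
#>        id        smiles units isocyanate alcohol     mw heavy_atoms   clogp  tpsa
#> 1 dimer_1     CNC(=O)OC     2        MIC    MeOH  89.09           6 -0.0278 38.33
#> 2 dimer_2    CCOC(=O)NC     2        MIC    EtOH 103.12           7  0.3623 38.33
#> 3 dimer_3 CNC(=O)OC(C)C     2        MIC   iPrOH 117.15           8  0.7508 38.33
#> 4 dimer_4  CCCCOC(=O)NC     2        MIC  1-BuOH 131.17           9  1.1425 38.33
```

The default building blocks (10 industrial isocyanates, 16 aliphatic
alcohols of which 7 are diols) give 414 fragments: 160 two-unit (39 %),
198 three-unit (48 %) and 56 four-unit fragments, spanning 6–68 heavy
atoms and 89–967 u, with 0/1/2/4 aromatic rings in 39/19/32/10 % of the
library. The smallest member is the methyl isocyanate + methanol dimer,
methyl N-methylcarbamate (`CNC(=O)OC`, 6 heavy atoms, MW 89).

Pose classification against a synthetic active-site fixture:

```r
fx <- make_site_fixture(4.0, 2.6, 3.7)   # Ser-O...C=O and oxyanion H...O=C distances
classify_pose(fx$pose, fx$receptor, fx$site, threshold = 4.5)
#>      ligand pose bond_kind d_ser d_oxy1 d_oxy2 productive probe
#> 1 nac_probe    1  urethane     4    2.6    3.7       TRUE     H
```

A thin command-line wrapper covers the same pipeline
(`inst/exec/purfrag`): `generate`, `properties`, `conformers` and
`analyze-poses` subcommands, each writing a manifest of parameters and
output checksums.

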