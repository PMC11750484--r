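Package: purfrag
Title: Combinatorial Polyurethane Fragment Libraries and Catalytic-Site
    Pose Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates combinatorial libraries of polyurethane (PUR)
    oligomer fragments from isocyanate and alcohol building blocks by
    explicit urethane-bond formation, with topology rules for 2-, 3- and
    4-unit chains, capping chemistry for residual isocyanate groups,
    per-compound descriptor tables (Wildman-Crippen cLogP and molar
    refraction, Ertl TPSA, aromaticity, rotatable bonds, ester/ether
    detection), systematic conformer generation, and structure-file
    output (MOL, MOL2, SDF, SMILES). Also implements a
    near-attack-configuration (NAC) classifier for docked
    serine-hydrolase ligand poses: the distance from the catalytic
    serine oxygen to the carbonyl carbon of the nearest cleavable bond
    (urethane or ester) and the distances from the oxyanion-hole
    backbone NH groups to the carbonyl oxygen decide whether a pose is
    productive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel command-line tools (obabel, obenergy) for
    conformer generation.
Config/testthat/edition: 3
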