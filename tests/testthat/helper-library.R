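# Shared lazily-built fixtures (the full default library takes a couple
# of seconds; build it once per test run).
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache))
    assign(key, expr, envir = .test_cache)
  get(key, envir = .test_cache)
}

default_library <- function() {
  cached("default_library",
         enumerate_library(default_isocyanates(), default_alcohols()))
}

default_property_table <- function() {
  cached("default_property_table", property_table(default_library()))
}

# integer percent, rounding half away from zero
pct_int <- function(x, n) floor(100 * x / n + 0.5)

# reference Crippen/TPSA values computed by RDKit (independent
# implementation of the same published schemes), via the python on PATH
rdkit_reference <- function(smiles) {
  script <- paste(
    "import sys, json",
    "from rdkit import Chem",
    "from rdkit.Chem import Crippen, rdMolDescriptors",
    "rows = []",
    "for smi in sys.stdin.read().split():",
    "    m = Chem.MolFromSmiles(smi)",
    "    rows.append({'smiles': smi,",
    "                 'clogp': Crippen.MolLogP(m),",
    "                 'mr': Crippen.MolMR(m),",
    "                 'tpsa': rdMolDescriptors.CalcTPSA(m),",
    "                 'heavy': m.GetNumHeavyAtoms()})",
    "print(json.dumps(rows))", sep = "\n")
  out <- system2("python", c("-c", shQuote(script)),
                 input = paste(smiles, collapse = "\n"), stdout = TRUE)
  do.call(rbind, lapply(jsonlite::fromJSON(out, simplifyVector = FALSE),
                        as.data.frame))
}

# squared-distance helper for pose geometry checks
dist3 <- function(a, b) sqrt(sum((a - b)^2))
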