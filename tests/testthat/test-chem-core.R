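test_that("monomer parsing detects functionality and validates roles", {
  expect_equal(parse_monomer("CN=C=O", "isocyanate", "MIC")$functionality, 1)
  expect_equal(parse_monomer("O=C=NCCCCCCN=C=O", "isocyanate",
                             "HDI")$functionality, 2)
  expect_equal(parse_monomer("OCCCCO", "alcohol", "BDO")$functionality, 2)
  expect_error(parse_monomer("CCO", "isocyanate"), "no N=C=O")
  expect_error(parse_monomer("CCCC", "alcohol"), "no C-OH")
  expect_error(mol_from_smiles("C(("), "parse error")
})

test_that("every default isocyanate has its nominal functionality", {
  isos <- default_isocyanates()
  fun <- vapply(isos, `[[`, integer(1), "functionality")
  ids <- vapply(isos, `[[`, character(1), "id")
  expected <- ifelse(ids %in% c("MIC", "BIC"), 1L, 2L)
  expect_equal(fun, expected)
  expect_length(isos, 10)
})

test_that("hydroxyl detection excludes acids, carbamates and phenols", {
  # carbamic acid -C(=O)OH from capping is not a reactive alcohol
  capped <- cap_isocyanates(mol_from_smiles("CN=C=O")[[1]], "carbamate")
  expect_equal(nrow(find_hydroxyl_sites(capped)), 0)
  expect_equal(nrow(find_hydroxyl_sites(mol_from_smiles("CC(=O)O")[[1]])), 0)
  expect_equal(nrow(find_hydroxyl_sites(mol_from_smiles("Oc1ccccc1")[[1]])), 0)
  # ester-containing monool keeps exactly its one aliphatic hydroxyl
  expect_equal(nrow(find_hydroxyl_sites(
    mol_from_smiles("CC(O)C(=O)OCCC(C)C")[[1]])), 1)
})

test_that("urethane coupling yields the carbamate product", {
  mics <- mol_from_smiles(c("CN=C=O", "CO"))
  prod <- couple_urethane(mics[[1]], 1, mics[[2]], 1)
  ref <- mol_from_smiles("CNC(=O)OC")[[1]]
  expect_true(mol_identical(prod, ref))
  expect_equal(unname(mol_mw(prod)), 89.09, tolerance = 1e-3)
  expect_equal(pf_smarts_count(prod, .pf_pat$urethane), 1L)
})

test_that("coupling conserves mass and leaves unreacted sites intact", {
  hdi <- parse_monomer("O=C=NCCCCCCN=C=O", "isocyanate", "HDI")
  bdo <- parse_monomer("OCCCCO", "alcohol", "BDO")
  prod <- couple_urethane(hdi, 1, bdo, 1)
  expect_equal(unname(mol_mw(prod)),
               unname(mol_mw(hdi$mol)) + unname(mol_mw(bdo$mol)),
               tolerance = 1e-4)
  expect_equal(nrow(find_isocyanate_sites(prod)), 1)
  expect_equal(nrow(find_hydroxyl_sites(prod)), 1)
  expect_true(mol_identical(prod,
    mol_from_smiles("O=C=NCCCCCCNC(=O)OCCCCO")[[1]]))
})

test_that("coupling conserves mass for random monomer pairs", {
  set <- make_monomer_set(4, 2, 4, 2, seed = 11)
  for (iso in set$isos) {
    for (ol in set$ols) {
      prod <- couple_urethane(iso, 1, ol, 1)
      expect_equal(unname(mol_mw(prod)),
                   unname(mol_mw(iso$mol)) + unname(mol_mw(ol$mol)),
                   tolerance = 1e-4)
      expect_equal(pf_smarts_count(prod, .pf_pat$urethane),
                   pf_smarts_count(iso$mol, .pf_pat$urethane) +
                     pf_smarts_count(ol$mol, .pf_pat$urethane) + 1L)
    }
  }
})

test_that("coupling rejects out-of-range site indices", {
  mics <- mol_from_smiles(c("CN=C=O", "CO"))
  expect_error(couple_urethane(mics[[1]], 2, mics[[2]], 1), "out of range")
  expect_error(couple_urethane(mics[[1]], 1, mics[[2]], 3), "out of range")
})

test_that("capping removes all isocyanate groups with the documented mass deltas", {
  m <- mol_from_smiles("O=C=NCCCCCCNC(=O)OC")[[1]]
  deltas <- c(amine = -25.99, methyl = -26.98, carbamate = 18.02)
  for (cap in names(deltas)) {
    capped <- cap_isocyanates(m, cap)
    expect_equal(nrow(find_isocyanate_sites(capped)), 0)
    expect_equal(unname(mol_mw(capped) - mol_mw(m)), unname(deltas[cap]),
                 tolerance = 1e-2)
    expect_equal(unname(cap_mw_delta(cap)), unname(deltas[cap]),
                 tolerance = 1e-2)
    # idempotence
    expect_true(mol_identical(cap_isocyanates(capped, cap), capped))
  }
  expect_true(mol_identical(cap_isocyanates(m, "amine"),
                            mol_from_smiles("NCCCCCCNC(=O)OC")[[1]]))
  # both sites of a diisocyanate are capped
  hdi <- mol_from_smiles("O=C=NCCCCCCN=C=O")[[1]]
  expect_true(mol_identical(cap_isocyanates(hdi, "amine"),
                            mol_from_smiles("NCCCCCCN")[[1]]))
})

test_that("capping is a no-op on molecules without isocyanate groups", {
  m <- mol_from_smiles("CNC(=O)OC")[[1]]
  expect_true(mol_identical(cap_isocyanates(m, "amine"), m))
  expect_true(mol_identical(cap_isocyanates(m, "methyl"), m))
})

test_that("SMILES round-trip preserves the molecular graph", {
  for (mon in c(default_isocyanates(), default_alcohols())) {
    back <- mol_from_smiles(unname(mol_to_smiles(mon$mol)))[[1]]
    expect_true(mol_identical(mon$mol, back))
    expect_equal(pf_natoms(back), pf_natoms(mon$mol))
  }
})
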